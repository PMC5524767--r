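test_that("identical point sets match perfectly at distance zero", {
  set.seed(1)
  pts <- cbind(runif(40, 0, 100), runif(40, 0, 100), runif(40, 0, 100))
  m <- match_detections(pts, pts, tolerance_um = 5)
  expect_equal(nrow(m$pairs), 40)
  expect_equal(sum(m$pairs$dist_um), 0)
  expect_length(m$unmatched_truth, 0)
})

test_that("the tolerance separates matches from false positives", {
  m <- match_detections(matrix(c(0, 0, 0), 1),
                        rbind(c(0, 0, 3), c(0, 0, 9)), tolerance_um = 5)
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$dist_um, 3)
  expect_equal(m$unmatched_detected, 2L)
  expect_error(match_detections(matrix(0, 1, 3), matrix(0, 1, 3), -1), "tolerance")
})

test_that("optimal assignment beats greedy on crossed configurations", {
  truth <- rbind(c(0, 0, 0), c(10, 0, 0))
  det <- rbind(c(9, 0, 0), c(1, 0, 0))
  m <- match_detections(truth, det, tolerance_um = 20)
  # brute force over both possible complete assignments
  d <- function(a, b) sqrt(sum((a - b)^2))
  opt <- min(d(truth[1, ], det[1, ]) + d(truth[2, ], det[2, ]),
             d(truth[1, ], det[2, ]) + d(truth[2, ], det[1, ]))
  expect_equal(sum(m$pairs$dist_um), opt)
  greedy <- d(truth[1, ], det[2, ]) + d(truth[2, ], det[1, ])
  expect_equal(sum(m$pairs$dist_um), greedy)  # here optimal = crossed pairing
  expect_lt(sum(m$pairs$dist_um),
            d(truth[1, ], det[1, ]) + d(truth[2, ], det[2, ]))
})

test_that("matching equals brute-force optimal assignment on small instances", {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  set.seed(2)
  for (rep in 1:5) {
    n <- sample(3:6, 1)
    truth <- cbind(runif(n, 0, 30), runif(n, 0, 30), runif(n, 0, 30))
    det <- truth + matrix(rnorm(3 * n, 0, 2), n, 3)
    tol <- 6
    dm <- sqrt(outer(truth[, 1], det[, 1], "-")^2 +
               outer(truth[, 2], det[, 2], "-")^2 +
               outer(truth[, 3], det[, 3], "-")^2)
    best <- -1; bestd <- Inf
    for (p in perms(seq_len(n))) {
      ok <- dm[cbind(seq_len(n), p)] <= tol
      nm <- sum(ok); td <- sum(dm[cbind(seq_len(n), p)][ok])
      if (nm > best || (nm == best && td < bestd)) { best <- nm; bestd <- td }
    }
    m <- match_detections(truth, det, tol)
    expect_equal(nrow(m$pairs), best)
    expect_equal(sum(m$pairs$dist_um), bestd, tolerance = 1e-9)
  }
})

test_that("recall and precision follow the B/B1 and B/B2 definitions", {
  s <- score_detection(90, B1 = 100, B2 = 95)
  expect_equal(s$recall, 0.900)
  expect_equal(s$precision, 90 / 95)
  expect_equal(round(s$precision, 3), 0.947)
  s2 <- score_detection(50, 50, 50)
  expect_equal(s2$recall, 1)
  expect_equal(s2$precision, 1)
  s3 <- score_detection(0, 10, 10)
  expect_equal(s3$recall, 0)
  expect_true(is.na(score_detection(0, 0, 5)$recall))
  expect_error(score_detection(10, 5, 20), "exceed")
})

test_that("metrics respond monotonically to spurious and deleted detections", {
  set.seed(5)
  truth <- cbind(runif(100, 0, 200), runif(100, 0, 200), runif(100, 0, 200))
  base <- match_detections(truth, truth, 5)
  s0 <- score_detection(base, 100, 100)
  spur <- rbind(truth, c(500, 500, 500))
  s1 <- score_detection(match_detections(truth, spur, 5), 100, 101)
  expect_lte(s1$precision, s0$precision)
  del <- truth[-1, , drop = FALSE]
  s2 <- score_detection(match_detections(truth, del, 5), 100, 99)
  expect_lte(s2$recall, s0$recall)
})

test_that("recall and precision are invariant under rigid motion of both sets", {
  set.seed(6)
  truth <- cbind(runif(60, 0, 100), runif(60, 0, 100), runif(60, 0, 100))
  det <- truth[-(1:5), ] + matrix(rnorm(165, 0, 1), 55, 3)
  m0 <- match_detections(truth, det, 5)
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  shift <- matrix(c(20, -5, 40), 1, 3)
  m1 <- match_detections(truth %*% R + shift[rep(1, 60), ],
                         det %*% R + shift[rep(1, 55), ], 5)
  expect_equal(nrow(m0$pairs), nrow(m1$pairs))
})

test_that("the cube protocol is deterministic and perfect on identical sets", {
  set.seed(7)
  tr <- cbind(runif(3000, 0, 800), runif(3000, 0, 800), runif(3000, 0, 800))
  e1 <- evaluate_cubes(tr, tr, c(800, 800, 800), seed = 3)
  e2 <- evaluate_cubes(tr, tr, c(800, 800, 800), seed = 3)
  expect_identical(e1, e2)
  expect_true(all(e1$per_cube$recall == 1))
  expect_true(all(e1$per_cube$precision == 1))
  expect_equal(unname(e1$summary$recall["mean"]), 1)
  expect_error(evaluate_cubes(tr, tr, c(200, 800, 800), cube_um = 300),
               "smaller")
})
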