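# feature matrix generator: regions with controlled soma shapes
synth_features <- function(n_per = c(40, 40, 40), seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_along(n_per), function(r) {
    n <- n_per[r]
    rl <- rnorm(n, 5 + r, 0.3)
    rs <- rnorm(n, 3 + 0.5 * r, 0.2)
    data.frame(region_id = r, r_longest = rl, r_shortest = rs,
               r_average = (rl + rs) / 2,
               surface_um2 = 4 * pi * ((rl + rs) / 2)^2 * runif(n, 0.95, 1.05),
               volume_um3 = 4 / 3 * pi * rl * rs^2 * runif(n, 0.95, 1.05),
               ratio = rl / rs)
  }))
}

test_that("region cube sampling is deterministic and captures cube residents", {
  g <- voxel_geometry(c(64, 150, 150), c(2, 2, 2))
  ct <- rbind(region_spec(1, "A", 8000), region_spec(2, "B", 8000))
  lab <- build_label_volume(g, ct, list(
    cuboid(1, c(0, 0, 0), c(64, 150, 75)), cuboid(2, c(0, 0, 75), c(64, 150, 150))))
  tr <- place_neurons(lab, seed = 3)
  nr <- assign_regions(tr, lab, g)
  nr$r_longest <- 5; nr$r_shortest <- 3; nr$r_average <- 4
  nr$surface_um2 <- 200; nr$volume_um3 <- 190; nr$ratio <- 5 / 3
  f1 <- sample_region_cubes(nr, lab, g, cube_um = 100, seed = 7)
  f2 <- sample_region_cubes(nr, lab, g, cube_um = 100, seed = 7)
  expect_identical(f1, f2)
  expect_setequal(unique(f1$region_id), c(1, 2))
  # a cube coinciding with a cube-shaped region returns all its neurons
  g2 <- voxel_geometry(c(60, 60, 60), c(2, 2, 2))
  ct2 <- region_spec(1, "A", 8000)
  lab2 <- build_label_volume(g2, ct2, list(cuboid(1, c(0, 0, 0), c(60, 60, 60))))
  tr2 <- assign_regions(place_neurons(lab2, seed = 5), lab2, g2)
  tr2$r_longest <- 5; tr2$r_shortest <- 3; tr2$r_average <- 4
  tr2$surface_um2 <- 200; tr2$volume_um3 <- 190; tr2$ratio <- 5 / 3
  f3 <- sample_region_cubes(tr2, lab2, g2, region_ids = 1, cube_um = 120,
                            seed = 1)
  expect_equal(nrow(f3), nrow(tr2))
  # a region smaller than the cube is skipped with a warning
  expect_warning(sample_region_cubes(nr, lab, g, region_ids = 1,
                                     cube_um = 4000, seed = 1), "skip")
})

test_that("PCA standardizes, fixes signs, normalizes scores and reports variance", {
  fm <- synth_features()
  p <- pca_two_components(fm)
  expect_equal(sum(p$explained), 1)
  expect_gte(p$explained[1], p$explained[2])
  expect_true(all(p$scores$pc1 >= 0 & p$scores$pc1 <= 1))
  expect_equal(range(p$scores$pc1), c(0, 1))
  # loadings orthonormal
  expect_equal(unname(crossprod(p$loadings)), diag(2), tolerance = 1e-8)
  # sign convention: largest-magnitude entry of each loading is positive
  expect_gt(p$loadings[which.max(abs(p$loadings[, 1])), 1], 0)
  # duplicated rows receive identical scores
  fm2 <- rbind(fm, fm[1, ])
  p2 <- pca_two_components(fm2)
  expect_equal(as.numeric(p2$scores[nrow(fm2), c("pc1", "pc2")]),
               as.numeric(p2$scores[1, c("pc1", "pc2")]))
})

test_that("rank-2 feature data loads onto two components almost entirely", {
  set.seed(5)
  n <- 150
  f1 <- rnorm(n); f2 <- rnorm(n)
  X <- cbind(f1, f2, f1 + f2, 2 * f1 - f2, f1 - 3 * f2, 0.5 * f1 + 0.1 * f2) +
    matrix(rnorm(n * 6, 0, 1e-5), n)
  fm <- data.frame(region_id = rep(1:3, each = n / 3),
                   r_longest = X[, 1] + 10, r_shortest = X[, 2] + 5,
                   r_average = X[, 3] + 8, surface_um2 = X[, 4] + 300,
                   volume_um3 = X[, 5] + 500, ratio = X[, 6] + 2)
  p <- pca_two_components(fm)
  expect_gt(sum(p$explained[1:2]), 0.99)
})

test_that("regions under the minimum cell count are excluded before PCA", {
  fm <- synth_features(c(30, 30, 2))  # third region mirrors the 2-neuron cube
  expect_warning(p <- pca_two_components(fm), "excluding region")
  expect_equal(p$dropped_regions, 3L)
  expect_false(3 %in% p$scores$region_id)
  expect_error(suppressWarnings(pca_two_components(synth_features(c(2, 2, 2)))),
               "at least 3 rows")
})

test_that("concentration keeps floor(fraction x n) rows nearest the region mean", {
  sc <- data.frame(region_id = 1L, pc1 = c(rep(0.5, 9), 0.99),
                   pc2 = c(seq(0.45, 0.53, 0.01), 0.99))
  out <- concentrate(sc, 0.8)
  expect_equal(nrow(out), 8)                       # floor(0.8 * 10)
  expect_false(any(out$pc1 == 0.99))               # planted outlier removed
  out9 <- concentrate(sc, 0.9)
  expect_equal(nrow(out9), 9)
  expect_false(any(out9$pc1 == 0.99))
  expect_equal(nrow(concentrate(sc, 1.0)), 10)     # identity at fraction 1
  expect_error(concentrate(sc, 0), "fraction")
  expect_error(concentrate(sc, 1.2), "fraction")
})

test_that("intra-region SDs use the n-1 denominator and flag singletons", {
  sc <- data.frame(region_id = rep(1:2, c(3, 1)),
                   pc1 = c(0.1, 0.2, 0.3, 0.5), pc2 = c(0.4, 0.4, 0.4, 0.2))
  sim <- region_similarity(sc)
  expect_equal(sim$sd_pc1[sim$region_id == 1], 0.1)
  expect_equal(sim$sd_pc2[sim$region_id == 1], 0)
  expect_true(is.na(sim$sd_pc1[sim$region_id == 2]))
  expect_match(sim$flags[sim$region_id == 2], "sd_undefined")
})

test_that("concentration cannot increase the dispersion", {
  set.seed(8)
  sc <- data.frame(region_id = 1L, pc1 = c(rnorm(19, 0.5, 0.02), 0.95),
                   pc2 = c(rnorm(19, 0.5, 0.02), 0.95))
  full_sd <- stats::sd(sc$pc1)
  conc <- concentrate(sc, 0.8)
  expect_lte(stats::sd(conc$pc1), full_sd)
})

test_that("two-group ANOVA equals the squared pooled-variance t statistic", {
  set.seed(11)
  for (i in 1:5) {
    va <- rnorm(15); vb <- rnorm(18, 0.4)
    f <- braincensus:::anova_two_group(va, vb)
    tt <- stats::t.test(va, vb, var.equal = TRUE)
    expect_equal(f$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(f$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("pairwise tests detect separated groups and pass degenerate cases", {
  set.seed(12)
  sc <- data.frame(region_id = rep(1:2, each = 20),
                   pc1 = c(rnorm(20, 0, 0.1), rnorm(20, 1, 0.1)),
                   pc2 = rnorm(40, 0.5, 0.1))
  res <- pairwise_tests(sc)
  t1 <- res$tests[res$tests$component == "pc1", ]
  expect_true(t1$significant)
  expect_false(res$pairs$not_different)
  # identical groups: p = 1 by the degenerate-variance convention
  same <- data.frame(region_id = rep(1:2, each = 3), pc1 = rep(c(1, 2, 3), 2),
                     pc2 = rep(0.5, 6))
  r2 <- pairwise_tests(same)
  expect_equal(r2$tests$p[r2$tests$component == "pc2"], 1)
  expect_false(any(r2$tests$significant))
})

test_that("type-I error of the pairwise test is near the nominal 0.05", {
  set.seed(13)
  reps <- 400
  hits <- vapply(seq_len(reps), function(i) {
    braincensus:::anova_two_group(rnorm(50), rnorm(50))$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("the workflow is invariant to row order of the feature matrix", {
  fm <- synth_features(seed = 2)
  p1 <- pca_two_components(fm)
  set.seed(3); perm <- sample(nrow(fm))
  p2 <- pca_two_components(fm[perm, ])
  o1 <- p1$scores[order(p1$scores$pc1, p1$scores$pc2), ]
  o2 <- p2$scores[order(p2$scores$pc1, p2$scores$pc2), ]
  expect_equal(o1$pc1, o2$pc1, tolerance = 1e-10)
  expect_equal(o1$region_id, o2$region_id)
  s1 <- region_similarity(concentrate(p1$scores))
  s2 <- region_similarity(concentrate(p2$scores))
  expect_equal(s1$sd_pc1, s2$sd_pc1, tolerance = 1e-10)
})
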