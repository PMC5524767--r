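test_that("a single rendered ellipsoid yields one detection within 1 um of truth", {
  tr <- make_truth(matrix(c(40, 38, 60), 1), semi = c(5, 4, 3))
  sc <- render_fixed(tr, c(64, 256, 256))
  det <- detect_somas(sc$signal, sc$geometry)
  expect_equal(nrow(det), 1)
  expect_lt(sqrt(sum((c(det$x_um, det$y_um, det$z_um) - c(40, 38, 60))^2)), 1)
})

test_that("pure background noise yields no detections", {
  set.seed(10)
  blk <- array(as.integer(pmax(0, round(rpois(48^3, 100) + rnorm(48^3, 0, 5)))),
               c(48, 48, 48))
  det <- detect_somas(blk, voxel_geometry(c(48, 48, 48)))
  expect_equal(nrow(det), 0)
})

test_that("detection recovers seeded scenes through noise and trunks", {
  sc <- small_scene(seed = 21, trunk_probability = 0.5, trunk_labels = TRUE)
  det <- detect_somas(sc$signal, sc$geometry)
  m <- match_detections(sc$truth, det, tolerance_um = 5)
  expect_equal(nrow(m$pairs), nrow(sc$truth))   # full recall
  expect_length(m$unmatched_detected, 0)        # no trunk-only detections
  # per-soma masks exclude at least 90% of that soma's labeled trunk voxels
  masks <- attr(det, "masks")
  for (i in seq_len(nrow(m$pairs))) {
    nid <- sc$truth$neuron_id[m$pairs$truth_idx[i]]
    ntr <- sum(sc$trunk_labels == nid)
    if (ntr == 0) next
    mk <- masks[[m$pairs$det_idx[i]]] + 1L
    overlap <- sum(sc$trunk_labels[cbind(mk[, 1], mk[, 2], mk[, 3])] == nid)
    expect_lte(overlap / ntr, 0.10)
  }
})

test_that("touching somas separated by one expected radius are split", {
  ctr <- rbind(c(40, 40, 60), c(48, 40, 60))  # 8 um apart, radii ~4.5
  tr <- make_truth(ctr, semi = c(4.5, 4.5, 4.5))
  sc <- render_fixed(tr, c(64, 256, 256))
  det <- detect_somas(sc$signal, sc$geometry)
  expect_equal(nrow(det), 2)
  m <- match_detections(tr, det, tolerance_um = 4)
  expect_equal(nrow(m$pairs), 2)
})

test_that("detections are equivariant to whole-voxel translations", {
  tr1 <- make_truth(matrix(c(30, 30, 50), 1), semi = c(5, 4, 3))
  tr2 <- make_truth(matrix(c(30 + 10 * 0.32, 30 + 6 * 0.32, 50 + 4 * 2), 1),
                    semi = c(5, 4, 3))
  sc1 <- render_fixed(tr1, c(56, 224, 224))
  sc2 <- render_fixed(tr2, c(56, 224, 224))
  d1 <- detect_somas(sc1$signal, sc1$geometry)
  d2 <- detect_somas(sc2$signal, sc2$geometry)
  expect_equal(nrow(d1), 1)
  expect_equal(nrow(d2), 1)
  expect_equal(c(d2$x_um - d1$x_um, d2$y_um - d1$y_um, d2$z_um - d1$z_um),
               c(10 * 0.32, 6 * 0.32, 4 * 2), tolerance = 1e-8)
})

test_that("detections are invariant to a global intensity rescaling", {
  tr <- make_truth(rbind(c(30, 30, 50), c(50, 45, 80)), semi = c(5, 4, 4))
  sc <- render_fixed(tr, c(64, 224, 224))
  d1 <- detect_somas(sc$signal, sc$geometry)
  scaled <- sc$signal * 7L
  d2 <- detect_somas(scaled, sc$geometry)
  expect_equal(nrow(d1), nrow(d2))
  expect_equal(d1[, c("x_um", "y_um", "z_um", "n_voxels")],
               d2[, c("x_um", "y_um", "z_um", "n_voxels")])
})

test_that("recall degrades monotonically along a noise ladder", {
  recalls <- vapply(c(5, 200, 900), function(nsd) {
    sc <- small_scene(seed = 33, shape = c(48, 192, 192), peak = 2000,
                      noise = noise_spec(100, nsd, shot = TRUE))
    det <- detect_somas(sc$signal, sc$geometry)
    m <- match_detections(sc$truth, det, tolerance_um = 5)
    nrow(m$pairs) / nrow(sc$truth)
  }, numeric(1))
  expect_true(all(diff(recalls) <= 0))
  expect_equal(recalls[1], 1)
})

test_that("blocks below the minimum detection footprint are rejected", {
  expect_error(detect_somas(array(0L, c(1, 4, 4)), voxel_geometry(c(1, 4, 4))),
               "footprint")
})

test_that("morphology of digitized spheres matches analytic values", {
  for (r in c(3, 4, 5)) {
    d <- digitize_ellipsoid(c(r, r, r))
    f <- measure_morphology(d$mask, d$geometry)
    expect_lt(abs(f$volume_um3 / (4 / 3 * pi * r^3) - 1), 0.10)
    expect_lt(abs(f$surface_um2 / (4 * pi * r^2) - 1), 0.15)
    expect_gte(f$ratio, 1)
    expect_lte(f$ratio, 1.2)
    expect_true(f$r_shortest <= f$r_average && f$r_average <= f$r_longest)
  }
})

test_that("morphology of a digitized 2:1 ellipsoid recovers the axis ratio", {
  d <- digitize_ellipsoid(c(8, 4, 4))
  f <- measure_morphology(d$mask, d$geometry)
  expect_lt(abs(f$ratio / 2 - 1), 0.15)
  expect_lt(abs(f$volume_um3 / (4 / 3 * pi * 8 * 4 * 4) - 1), 0.10)
})

test_that("single-voxel masks get the degenerate half-edge treatment", {
  f <- measure_morphology(matrix(c(3L, 3L, 3L), 1), voxel_geometry(c(8, 8, 8)))
  expect_true(f$degenerate)
  expect_equal(f$volume_um3, 0.32 * 0.32 * 2)
  expect_equal(f$r_longest, 1)       # half the 2 um axial edge
  expect_equal(f$r_shortest, 0.16)   # half the 0.32 um lateral edge
})
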