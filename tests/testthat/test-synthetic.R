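test_that("label volume construction places each region with exact voxel counts", {
  g <- voxel_geometry(c(50, 100, 200), c(1, 1, 1))
  ct <- rbind(region_spec(1, "A", 1000), region_spec(2, "B", 500))
  lab <- build_label_volume(g, ct, list(
    cuboid(1, c(0, 0, 0), c(50, 100, 100)),
    cuboid(2, c(0, 0, 100), c(50, 100, 200))))
  expect_equal(sum(lab$labels == 1L), 500000)
  expect_equal(sum(lab$labels == 2L), 500000)
  expect_equal(sum(lab$labels == 0L), 0)
})

test_that("layered slab stacks form parallel labels with requested thicknesses", {
  g <- voxel_geometry(c(20, 50, 30), c(1, 1, 1))
  ct <- do.call(rbind, lapply(1:5, function(i)
    region_spec(i, paste0("L", i), 100, parent_area = "ctx", layer_index = i)))
  lab <- build_label_volume(g, ct, list(
    slab_stack(1:5, c(0, 0, 0), c(20, 50, 30), c(5, 15, 10, 10, 10), axis = 2)))
  expect_equal(as.vector(table(lab$labels)),
               c(5, 15, 10, 10, 10) * 20 * 30)
  # slabs are parallel: label depends only on the y index
  expect_true(all(apply(lab$labels, 2, function(sl) length(unique(c(sl)))) == 1))
})

test_that("overlapping layout elements and unknown regions are rejected", {
  g <- voxel_geometry(c(10, 10, 10), c(1, 1, 1))
  ct <- rbind(region_spec(1, "A", 0), region_spec(2, "B", 0))
  expect_error(build_label_volume(g, ct, list(
    cuboid(1, c(0, 0, 0), c(10, 10, 6)),
    cuboid(2, c(0, 0, 4), c(10, 10, 10)))), "conflict")
  expect_error(build_label_volume(g, ct, list(cuboid(7, c(0, 0, 0), c(5, 5, 5)))),
               "not in catalog")
})

test_that("neuron counts are Poisson with mean intensity x region volume", {
  # 0.001 mm^3 region (125,000 voxels at 2 um isotropic), 20,000 cells/mm^3
  g <- voxel_geometry(c(50, 50, 50), c(2, 2, 2))
  ct <- region_spec(1, "A", 20000)
  lab <- build_label_volume(g, ct, list(cuboid(1, c(0, 0, 0), c(50, 50, 50))))
  counts <- vapply(1:200, function(s) nrow(place_neurons(lab, seed = s)),
                   numeric(1))
  se <- sqrt(20 / 200)  # Poisson SE of the mean of 200 draws
  expect_lt(abs(mean(counts) - 20), 3 * se)
  expect_gt(stats::var(counts), 20 * 0.6)  # dispersion consistent with Poisson
})

test_that("zero intensity yields zero neurons and placement is deterministic", {
  g <- voxel_geometry(c(20, 20, 20), c(2, 2, 2))
  ct <- rbind(region_spec(1, "A", 0), region_spec(2, "B", 50000))
  lab <- build_label_volume(g, ct, list(
    cuboid(1, c(0, 0, 0), c(20, 20, 10)), cuboid(2, c(0, 0, 10), c(20, 20, 20))))
  t1 <- place_neurons(lab, seed = 9)
  t2 <- place_neurons(lab, seed = 9)
  expect_identical(t1, t2)
  expect_equal(sum(t1$region_id == 1), 0)
  expect_gt(sum(t1$region_id == 2), 0)
})

test_that("every placed neuron sits in a voxel carrying its region label", {
  for (s in 1:3) {
    g <- voxel_geometry(c(24, 48, 48), c(1, 1, 1))
    ct <- rbind(region_spec(1, "A", 2e5), region_spec(2, "B", 1e5))
    lab <- build_label_volume(g, ct, list(
      cuboid(1, c(2, 2, 2), c(22, 46, 24)), cuboid(2, c(2, 2, 24), c(22, 46, 46))))
    tr <- place_neurons(lab, seed = s)
    vox <- um_to_voxel(as.matrix(tr[, c("x_um", "y_um", "z_um")]), g)
    labs <- lab$labels[cbind(vox[, 3] + 1L, vox[, 2] + 1L, vox[, 1] + 1L)]
    expect_equal(labs, tr$region_id)
  }
})

test_that("minimum separation is honored and infeasible requests error", {
  g <- voxel_geometry(c(20, 40, 40), c(1, 1, 1))
  ct <- region_spec(1, "A", 3e5)
  lab <- build_label_volume(g, ct, list(cuboid(1, c(0, 0, 0), c(20, 40, 40))))
  tr <- place_neurons(lab, seed = 4, min_separation_um = 6)
  if (nrow(tr) >= 2) {
    D <- as.matrix(dist(tr[, c("x_um", "y_um", "z_um")]))
    diag(D) <- Inf
    expect_gte(min(D), 6)
  }
  expect_error(place_neurons(lab, seed = 4, min_separation_um = 500,
                             max_tries = 50L),
               "separation infeasible")
})

test_that("rendered soma peak lies at the soma center and render is deterministic", {
  tr <- make_truth(matrix(c(40, 40, 64), 1), semi = c(5, 5, 5))
  sc1 <- render_fixed(tr, c(64, 256, 256))
  sc2 <- render_fixed(tr, c(64, 256, 256))
  expect_identical(sc1$signal, sc2$signal)
  w <- which(sc1$signal == max(sc1$signal), arr.ind = TRUE)[1, ]
  peak_um <- c((w[3] - 0.5) * 0.32, (w[2] - 0.5) * 0.32, (w[1] - 0.5) * 2)
  expect_true(all(abs(peak_um - c(40, 40, 64)) <= c(0.32, 0.32, 2)))
})

test_that("background and read noise match the declared noise model", {
  g <- voxel_geometry(c(32, 200, 200), c(1, 1, 1))
  ct <- region_spec(1, "A", 0)
  lab <- build_label_volume(g, ct, list(cuboid(1, c(0, 0, 0), c(32, 200, 200))))
  tr <- place_neurons(lab, seed = 1)
  sc <- render_scene(tr, lab, noise = noise_spec(100, 5, shot = FALSE),
                     seed = 2, channels = "signal")
  v <- as.numeric(sc$signal)
  expect_gt(length(v), 1e6)
  expect_lt(abs(mean(v) - 100), 0.05)
  expect_lt(abs(stats::sd(v) - 5), 0.05)
})

test_that("counterstain marks every labeled soma center plus extra nuclei", {
  g <- voxel_geometry(c(32, 128, 128), c(1, 1, 1))
  ct <- region_spec(1, "A", 1e5)
  lab <- build_label_volume(g, ct, list(cuboid(1, c(4, 4, 4), c(28, 124, 124))))
  tr <- place_neurons(lab, seed = 3)
  sc <- render_scene(tr, lab, noise = noise_spec(0, 0, FALSE), seed = 4)
  vox <- um_to_voxel(as.matrix(tr[, c("x_um", "y_um", "z_um")]), g)
  at_centers <- sc$counterstain[cbind(vox[, 3] + 1L, vox[, 2] + 1L, vox[, 1] + 1L)]
  expect_true(all(at_centers > 0))
  # unlabeled nuclei bring substantially more bright voxels than somas alone
  sc_sig <- render_scene(tr, lab, noise = noise_spec(0, 0, FALSE), seed = 4,
                         channels = "signal")
  expect_gt(sum(sc$counterstain > 0), sum(sc_sig$signal > 0))
})
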