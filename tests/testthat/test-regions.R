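test_that("region assignment follows the containing-voxel rule", {
  g <- voxel_geometry(c(10, 10, 10), c(1, 1, 1))
  ct <- region_spec(1, "A", 0)
  lab <- build_label_volume(g, ct, list(cuboid(1, c(0, 0, 0), c(10, 10, 10))))
  nr <- data.frame(neuron_id = 1:2, x_um = c(5, 3), y_um = c(5, 3),
                   z_um = c(5, 3), region_id = 0L)
  out <- assign_regions(nr, lab, g)
  expect_equal(out$region_id, c(1L, 1L))
  # centers outside the labeled extent raise an assignment error
  bad <- data.frame(neuron_id = 1L, x_um = 11, y_um = 5, z_um = 5,
                    region_id = 0L)
  expect_error(assign_regions(bad, lab, g), "assignment error")
})

test_that("background-assigned neurons are retained and counted separately", {
  g <- voxel_geometry(c(10, 10, 10), c(1, 1, 1))
  ct <- region_spec(1, "A", 0)
  lab <- build_label_volume(g, ct, list(cuboid(1, c(0, 0, 5), c(10, 10, 10))))
  nr <- data.frame(neuron_id = 1:3, x_um = c(1, 2, 7), y_um = 5, z_um = 5,
                   region_id = 0L)
  out <- assign_regions(nr, lab, g)
  expect_equal(out$region_id, c(0L, 0L, 1L))
  s <- summarize_regions(out, lab, g)
  expect_equal(s$background_count, 2)
  expect_equal(s$regions$count[s$regions$region_id == 1], 1)
  # conservation: region counts + background = total
  expect_equal(sum(s$regions$count) + s$background_count, nrow(out))
})

test_that("region volumes convert voxel counts to mm^3 exactly", {
  # 1e6 voxels at 1 um isotropic -> 1e-3 mm^3
  g1 <- voxel_geometry(c(100, 100, 100), c(1, 1, 1))
  ct <- region_spec(1, "A", 0)
  lab1 <- build_label_volume(g1, ct, list(cuboid(1, c(0, 0, 0), c(100, 100, 100))))
  expect_equal(region_volume(lab1, g1, 1), 1e-3)
  # 1e6 voxels at the native anisotropic geometry -> 2.048e-4 mm^3
  g2 <- voxel_geometry(c(100, 100, 100))
  lab2 <- build_label_volume(g2, ct, list(cuboid(1, c(0, 0, 0), c(100, 100, 100))))
  expect_equal(region_volume(lab2, g2, 1), 2.048e-4)
  expect_error(region_volume(lab2, g2, 99), "catalog error")
})

test_that("density is count over volume, with undefined and zero cases", {
  expect_equal(density_cells_mm3(100, 0.01), 10000)
  expect_equal(density_cells_mm3(0, 0.01), 0)
  expect_equal(density_cells_mm3(20, 0.001), 20000)  # densest-tier boundary
  expect_true(is.na(density_cells_mm3(5, 0)))
})

test_that("nuclei distance matches hand arithmetic and the brute-force oracle", {
  expect_equal(nuclei_distance(cbind(c(0, 15), 0, 0)), 15)
  expect_equal(nuclei_distance(cbind(c(0, 10, 30), 0, 0)), 40 / 3)
  expect_true(is.na(nuclei_distance(cbind(1, 1, 1))))
  for (s in 1:10) {
    set.seed(s)
    n <- sample(50:2000, 1)
    pts <- cbind(runif(n, 0, 300), runif(n, 0, 300), runif(n, 0, 300))
    expect_equal(nuclei_distance(pts), mean(nn_brute(pts)), tolerance = 1e-12)
    expect_lt(abs(nuclei_distance(pts) - mean(nn_brute(pts))), 1e-9)
  }
})

test_that("nuclei distance is invariant under rigid motion", {
  set.seed(4)
  pts <- cbind(runif(200, 0, 100), runif(200, 0, 100), runif(200, 0, 100))
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- pts %*% R + matrix(c(50, -20, 11), 200, 3, byrow = TRUE)
  expect_equal(nuclei_distance(pts), nuclei_distance(moved), tolerance = 1e-9)
})

test_that("summaries recover per-region densities and satisfy identities", {
  g <- voxel_geometry(c(64, 128, 128), c(2, 2, 2))
  ct <- rbind(region_spec(1, "dense", 20000, group = "g1"),
              region_spec(2, "mid", 5000, group = "g1"),
              region_spec(3, "sparse", 500, group = "g2"))
  lab <- build_label_volume(g, ct, list(
    cuboid(1, c(0, 0, 0), c(64, 128, 42)),
    cuboid(2, c(0, 0, 42), c(64, 128, 84)),
    cuboid(3, c(0, 0, 84), c(64, 128, 128))))
  tr <- place_neurons(lab, seed = 6)
  nr <- assign_regions(tr, lab, g)
  s <- summarize_regions(nr, lab, g)
  # density x volume = count identically
  expect_equal(s$regions$density_cells_per_mm3 * s$regions$volume_mm3,
               s$regions$count)
  # group rollups aggregate counts and volumes before dividing
  g1 <- s$regions[s$regions$group == "g1", ]
  expect_equal(s$groups$density_cells_per_mm3[s$groups$group == "g1"],
               sum(g1$count) / sum(g1$volume_mm3))
  # whole-brain density over the nonzero-label volume
  expect_equal(s$whole_brain$density,
               sum(s$regions$count) / sum(s$regions$volume_mm3))
  # estimated densities within 3 Poisson SD of the generating intensities
  for (i in 1:3) {
    lam <- ct$neuron_intensity[i] * s$regions$volume_mm3[i]
    expect_lt(abs(s$regions$count[i] - lam), 3 * sqrt(lam) + 1e-9)
  }
})

test_that("layer profiles peak where the generating intensity peaks", {
  g <- voxel_geometry(c(48, 200, 120), c(2, 2, 2))
  intens <- c(300, 15000, 5000, 600, 800)  # L1, L2/3, L4, L5, L6
  ct <- do.call(rbind, lapply(1:5, function(i)
    region_spec(i, c("L1", "L2/3", "L4", "L5", "L6")[i], intens[i],
                group = "isocortex", parent_area = "ctx", layer_index = i)))
  lab <- build_label_volume(g, ct, list(
    slab_stack(1:5, c(0, 0, 0), c(48, 200, 120), c(20, 60, 40, 40, 40),
               axis = 2)))
  tr <- place_neurons(lab, seed = 13)
  nr <- assign_regions(tr, lab, g)
  s <- summarize_regions(nr, lab, g)
  expect_equal(nrow(s$layers), 5)
  expect_equal(s$layers$name[which.max(s$layers$density_cells_per_mm3)],
               "L2/3")
})
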