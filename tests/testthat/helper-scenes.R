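# Shared fixtures, built in code at test time.

# small single-region scene: cuboid region with margin, seeded neurons
small_scene <- function(seed = 1, shape = c(64, 256, 256),
                        intensity = 30000, semi = c(4, 5.5), peak = 3000,
                        trunk_probability = 0, min_separation_um = 12,
                        noise = noise_spec(), trunk_labels = FALSE) {
  g <- voxel_geometry(shape)
  ct <- region_spec(1, "r1", intensity, semi, peak, trunk_probability)
  m <- pmax(shape %/% 16L, 2L)
  lab <- build_label_volume(g, ct, list(
    cuboid(1, m, shape - m)))
  truth <- place_neurons(lab, ct, g, seed = seed,
                         min_separation_um = min_separation_um)
  sc <- render_scene(truth, lab, ct, g, noise = noise, seed = seed + 1000,
                     channels = "signal", trunk_labels = trunk_labels)
  sc
}

# brute-force nearest-neighbor oracle: all-pairs distances
nn_brute <- function(pts) {
  D <- as.matrix(stats::dist(pts))
  diag(D) <- Inf
  apply(D, 1, min)
}

# digitized sphere / axis-aligned ellipsoid masks on an isotropic grid
digitize_ellipsoid <- function(semi_xyz, h = 0.5, margin = 4) {
  half <- max(semi_xyz) + margin * h
  n <- ceiling(2 * half / h)
  ctr <- n * h / 2
  ax <- (seq_len(n) - 0.5) * h
  m <- array(FALSE, c(n, n, n))
  for (z in seq_len(n))
    m[z, , ] <- outer(((ax - ctr) / semi_xyz[2])^2,
                      ((ax - ctr) / semi_xyz[1])^2, "+") +
      ((ax[z] - ctr) / semi_xyz[3])^2 <= 1
  list(mask = m, geometry = voxel_geometry(c(n, n, n), c(h, h, h)))
}

# render a fixed truth table (axis-aligned somas) into a blank volume
render_fixed <- function(truth, shape, size_um = c(0.32, 0.32, 2),
                         noise = noise_spec(0, 0, FALSE), seed = 1) {
  g <- voxel_geometry(shape, size_um)
  ct <- region_spec(1, "r1", 0)
  lab <- build_label_volume(g, ct, list(cuboid(1, c(0, 0, 0), shape)))
  render_scene(truth, lab, ct, g, noise = noise, seed = seed,
               channels = "signal")
}

# minimal truth table constructor
make_truth <- function(centers, semi = c(5, 5, 5), peak = 3000,
                       region_id = 1L) {
  n <- nrow(centers)
  out <- data.frame(neuron_id = seq_len(n), x_um = centers[, 1],
                    y_um = centers[, 2], z_um = centers[, 3],
                    region_id = region_id,
                    a_um = semi[1], b_um = semi[2], c_um = semi[3],
                    peak = peak, trunk = FALSE)
  attr(out, "rotations") <- matrix(rep(as.vector(diag(3)), each = n), n, 9)
  out
}

sorted_centers <- function(tab) {
  m <- as.matrix(tab[, c("x_um", "y_um", "z_um")])
  m[order(m[, 3], m[, 2], m[, 1]), , drop = FALSE]
}
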