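#' Build a region label volume from a geometric layout
#'
#' Rasterizes a layout of non-overlapping elements into an integer label
#' volume (0 = background / outside brain). Two element types are supported:
#'
#' * `cuboid(region_id, lo, hi)` — an axis-aligned box with half-open voxel
#'   bounds `lo`/`hi` in `(z, y, x)` order;
#' * `slab_stack(region_ids, lo, size, thickness, axis)` — a stack of
#'   parallel slabs emulating cortical layers: `region_ids` are the ordered
#'   layer labels, `thickness` their voxel thicknesses along `axis`
#'   (1 = z, 2 = y, 3 = x), and `lo`/`size` place the stack's footprint.
#'
#' @param geometry a [voxel_geometry()].
#' @param catalog region catalog; every region referenced by the layout must
#'   be present.
#' @param layout list of layout elements (see above).
#' @return A `region_label_volume`: list with `labels` (integer 3D array) and
#'   `catalog`.
#' @examples
#' g <- voxel_geometry(c(20, 40, 40), c(1, 1, 1))
#' cat <- rbind(region_spec(1, "A", 1000), region_spec(2, "B", 500))
#' lab <- build_label_volume(g, cat, list(
#'   cuboid(1, c(0, 0, 0), c(20, 40, 20)),
#'   cuboid(2, c(0, 0, 20), c(20, 40, 40))))
#' table(lab$labels)
#' @export
build_label_volume <- function(geometry, catalog, layout) {
  catalog <- as_region_catalog(catalog)
  arr <- array(0L, dim = geometry$shape)
  for (el in layout) {
    ids <- if (identical(el$type, "slab_stack")) el$region_ids else el$region_id
    missing <- setdiff(ids, catalog$region_id)
    if (length(missing))
      stop(sprintf("layout references region(s) not in catalog: %s",
                   paste(missing, collapse = ", ")))
    if (identical(el$type, "cuboid")) {
      lo <- as.integer(el$lo); hi <- as.integer(el$hi)
      check_box(lo, hi, geometry$shape)
      sl <- list((lo[1] + 1):hi[1], (lo[2] + 1):hi[2], (lo[3] + 1):hi[3])
      if (any(arr[sl[[1]], sl[[2]], sl[[3]]] != 0L))
        stop("layout conflict: overlapping layout elements")
      arr[sl[[1]], sl[[2]], sl[[3]]] <- el$region_id
    } else if (identical(el$type, "slab_stack")) {
      lo <- as.integer(el$lo); size <- as.integer(el$size)
      th <- as.integer(el$thickness); ax <- as.integer(el$axis)
      if (length(th) != length(el$region_ids))
        stop("slab_stack: one thickness per region id required")
      if (sum(th) != size[ax])
        stop("slab_stack: thicknesses must sum to the stack size along its axis")
      check_box(lo, lo + size, geometry$shape)
      off <- 0L
      for (k in seq_along(th)) {
        l2 <- lo; h2 <- lo + size
        l2[ax] <- lo[ax] + off; h2[ax] <- lo[ax] + off + th[k]
        sl <- list((l2[1] + 1):h2[1], (l2[2] + 1):h2[2], (l2[3] + 1):h2[3])
        if (any(arr[sl[[1]], sl[[2]], sl[[3]]] != 0L))
          stop("layout conflict: overlapping layout elements")
        arr[sl[[1]], sl[[2]], sl[[3]]] <- el$region_ids[k]
        off <- off + th[k]
      }
    } else stop("unknown layout element type: ", el$type)
  }
  structure(list(labels = arr, catalog = catalog, geometry = geometry),
            class = "region_label_volume")
}

check_box <- function(lo, hi, shape) {
  if (any(lo < 0L) || any(hi > shape) || any(hi <= lo))
    stop("layout element outside the volume or empty")
}

#' @rdname build_label_volume
#' @param region_id,lo,hi,region_ids,size,thickness,axis see Description.
#' @export
cuboid <- function(region_id, lo, hi) {
  list(type = "cuboid", region_id = as.integer(region_id), lo = lo, hi = hi)
}

#' @rdname build_label_volume
#' @export
slab_stack <- function(region_ids, lo, size, thickness, axis = 2) {
  list(type = "slab_stack", region_ids = as.integer(region_ids), lo = lo,
       size = size, thickness = thickness, axis = axis)
}

#' Place ground-truth neurons by region-wise Poisson sampling
#'
#' Per region, the neuron count is Poisson with mean
#' `neuron_intensity x region volume (mm^3)` and centers are uniform within
#' the region's voxels, emulating the regional density diversity of labeled
#' neurons across brain areas. Each neuron also receives ellipsoid semi-axes
#' (uniform in the region's range), a uniformly random 3D orientation, a peak
#' brightness (lognormal around the region mean, sd 15%), and a trunk flag
#' drawn with the region's trunk probability.
#'
#' @param label_volume a `region_label_volume` from [build_label_volume()].
#' @param catalog region catalog (defaults to the one in `label_volume`).
#' @param geometry a [voxel_geometry()] (defaults to the one in `label_volume`).
#' @param seed integer seed; the table is a pure function of inputs and seed.
#' @param min_separation_um minimum center-to-center distance enforced by
#'   rejection sampling; 0 (default) allows touching cells.
#' @param max_tries rejection-sampling cap per neuron before a
#'   separation-infeasible error naming the region.
#' @return data.frame with columns `neuron_id`, `x_um`, `y_um`, `z_um`,
#'   `region_id`, `a_um`, `b_um`, `c_um`, `peak`, `trunk`, and an attached
#'   `"rotations"` attribute (n x 9 row-major world-to-body matrices).
#' @export
place_neurons <- function(label_volume, catalog = label_volume$catalog,
                          geometry = label_volume$geometry, seed = 1L,
                          min_separation_um = 0, max_tries = 1000L) {
  catalog <- as_region_catalog(catalog)
  arr <- label_volume$labels
  vox_mm3 <- voxel_volume_um3(geometry) * 1e-9
  with_seed(seed, {
    rows <- list()
    rots <- list()
    nvox_total <- length(arr)
    region_nvox <- tabulate(arr, nbins = max(catalog$region_id))
    for (i in seq_len(nrow(catalog))) {
      reg <- catalog[i, ]
      nvox <- region_nvox[reg$region_id]
      if (!nvox || reg$neuron_intensity <= 0) next
      n <- stats::rpois(1, reg$neuron_intensity * nvox * vox_mm3)
      if (n == 0L) next
      # uniform voxel sampler for this region: rejection over the whole
      # grid when the region is a decent fraction of it (no large
      # temporaries), otherwise via its materialized voxel list
      frac <- nvox / nvox_total
      if (n / frac <= 5e6) {
        buf <- integer(0)
        next_voxel <- function() {
          while (!length(buf)) {
            cand <- sample.int(nvox_total, max(64L, ceiling(2 / frac)),
                               replace = TRUE)
            buf <<- cand[arr[cand] == reg$region_id]
          }
          v <- buf[1]; buf <<- buf[-1]; v
        }
      } else {
        vox_list <- which(arr == reg$region_id)
        next_voxel <- function() vox_list[sample.int(length(vox_list), 1L)]
      }
      accepted <- matrix(NA_real_, 0, 3)
      tries <- 0L
      while (nrow(accepted) < n) {
        k3 <- arrayInd(next_voxel(), dim(arr))  # (z, y, x), 1-based
        u <- stats::runif(3)
        p <- c((k3[3] - 1 + u[1]) * geometry$size_x,
               (k3[2] - 1 + u[2]) * geometry$size_y,
               (k3[1] - 1 + u[3]) * geometry$size_z)
        ok <- TRUE
        if (min_separation_um > 0 && nrow(accepted) > 0) {
          d2 <- (accepted[, 1] - p[1])^2 + (accepted[, 2] - p[2])^2 +
                (accepted[, 3] - p[3])^2
          ok <- all(d2 >= min_separation_um^2)
        }
        if (ok) {
          accepted <- rbind(accepted, p)
          tries <- 0L
        } else {
          tries <- tries + 1L
          if (tries > max_tries)
            stop(sprintf("separation infeasible in region %d (%s): %d of %d placed",
                         reg$region_id, reg$name, nrow(accepted), n))
        }
      }
      semi <- matrix(stats::runif(3 * n, reg$semi_min_um, reg$semi_max_um), n, 3)
      peak <- reg$peak * exp(stats::rnorm(n, 0, 0.15))
      trunk <- stats::runif(n) < reg$trunk_prob
      rows[[length(rows) + 1L]] <- data.frame(
        x_um = accepted[, 1], y_um = accepted[, 2], z_um = accepted[, 3],
        region_id = reg$region_id, a_um = semi[, 1], b_um = semi[, 2],
        c_um = semi[, 3], peak = peak, trunk = trunk)
      rots[[length(rots) + 1L]] <- random_rotations(n)
    }
    if (!length(rows)) {
      out <- data.frame(neuron_id = integer(0), x_um = numeric(0),
                        y_um = numeric(0), z_um = numeric(0),
                        region_id = integer(0), a_um = numeric(0),
                        b_um = numeric(0), c_um = numeric(0),
                        peak = numeric(0), trunk = logical(0))
      attr(out, "rotations") <- matrix(numeric(0), 0, 9)
      return(out)
    }
    out <- do.call(rbind, rows)
    out <- cbind(neuron_id = seq_len(nrow(out)), out)
    rownames(out) <- NULL
    attr(out, "rotations") <- do.call(rbind, rots)
    out
  })
}

#' Noise model for rendered channels
#'
#' @param background mean background level (16-bit units).
#' @param read_sd standard deviation of additive Gaussian read noise.
#' @param shot logical; apply Poisson shot noise to the mean photon signal.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(background = 100, read_sd = 5, shot = TRUE) {
  if (background < 0 || read_sd < 0) stop("noise parameters must be >= 0")
  structure(list(background = background, read_sd = read_sd,
                 shot = isTRUE(shot)), class = "noise_spec")
}

#' Render a two-channel synthetic scene from a ground-truth table
#'
#' Somas are rendered as oriented ellipsoids with quadratic intensity falloff
#' from the peak at the center to background at the surface. Somas flagged
#' with a trunk additionally emit a bright cylinder (the thick dendritic
#' trunk artifact that soma detectors must reject) starting at the soma
#' surface in a random direction. The counterstain channel renders a small
#' nucleus at every labeled soma center plus unlabeled-cell nuclei at
#' `unlabeled_factor` times each region's labeled density, emulating a
#' nuclear counterstain that marks all cells. Mean signal plus background is
#' passed through Poisson shot noise (optional) and additive read noise,
#' then clipped to the 16-bit range.
#'
#' @param truth ground-truth table from [place_neurons()] (or constructed
#'   with the same columns; a missing `"rotations"` attribute defaults to
#'   axis-aligned somas).
#' @param label_volume,catalog,geometry as in [place_neurons()].
#' @param noise a [noise_spec()].
#' @param seed integer seed for noise, trunk geometry and unlabeled nuclei.
#' @param channels which channels to render: `"signal"`, `"counterstain"`, or
#'   both (default). Skipping the counterstain halves render time.
#' @param trunk_radius_um,trunk_length_um cylinder radius (<= 1.5 um) and
#'   length range in um.
#' @param unlabeled_factor unlabeled-nuclei density as a multiple of the
#'   labeled density.
#' @param nucleus_radius_um counterstain nucleus radius.
#' @param trunk_labels logical; also return an integer volume labeling each
#'   trunk voxel with its neuron id (soma-interior voxels excluded), for
#'   validating trunk rejection.
#' @return A `synthetic_scene`: list with `geometry`, `labels`
#'   (`region_label_volume`), `signal`, `counterstain` (16-bit integer
#'   arrays or NULL), `truth`, `noise`, `seed`, and optionally
#'   `trunk_labels`.
#' @export
render_scene <- function(truth, label_volume, catalog = label_volume$catalog,
                         geometry = label_volume$geometry,
                         noise = noise_spec(), seed = 1L,
                         channels = c("signal", "counterstain"),
                         trunk_radius_um = 1.0, trunk_length_um = c(10, 50),
                         unlabeled_factor = 5, nucleus_radius_um = 2.5,
                         trunk_labels = FALSE) {
  if (!inherits(noise, "noise_spec")) stop("`noise` must be a noise_spec()")
  if (trunk_radius_um > 1.5) stop("`trunk_radius_um` must be <= 1.5 um")
  channels <- match.arg(channels, c("signal", "counterstain"), several.ok = TRUE)
  dimv <- geometry$shape
  ez <- edge_zyx(geometry)
  n <- nrow(truth)
  rot <- attr(truth, "rotations")
  if (is.null(rot)) rot <- matrix(rep(as.vector(diag(3)), each = n), n, 9)

  with_seed(seed, {
    out <- list(geometry = geometry, labels = label_volume, truth = truth,
                noise = noise, seed = seed, signal = NULL, counterstain = NULL)

    if ("signal" %in% channels) {
      sig <- array(0, dim = dimv)
      trunk_owner <- if (trunk_labels) {
        a <- array(0L, dim = dimv); a
      } else integer(0)
      has_trunk <- which(truth$trunk)
      if (length(has_trunk)) {
        dirs <- matrix(stats::rnorm(3 * length(has_trunk)), ncol = 3)
        dirs <- dirs / sqrt(rowSums(dirs^2))
        lens <- stats::runif(length(has_trunk), trunk_length_um[1],
                             trunk_length_um[2])
        # start each trunk where its direction ray exits the soma surface
        starts <- matrix(0, length(has_trunk), 3)
        for (j in seq_along(has_trunk)) {
          i <- has_trunk[j]
          R <- matrix(rot[i, ], 3, 3, byrow = TRUE)
          d_body <- R %*% dirs[j, ]
          s <- 1 / sqrt(sum((d_body / c(truth$a_um[i], truth$b_um[i],
                                        truth$c_um[i]))^2))
          starts[j, ] <- c(truth$x_um[i], truth$y_um[i], truth$z_um[i]) +
            s * dirs[j, ]
        }
        cpp_render_cylinders(sig, dimv, trunk_owner, starts, dirs, lens,
                             rep(trunk_radius_um, length(has_trunk)),
                             truth$peak[has_trunk],
                             as.integer(truth$neuron_id[has_trunk]), ez)
      }
      if (n > 0)
        cpp_render_ellipsoids(sig, dimv,
                              as.matrix(truth[, c("x_um", "y_um", "z_um")]),
                              as.matrix(truth[, c("a_um", "b_um", "c_um")]),
                              rot, truth$peak, ez)
      if (trunk_labels && length(has_trunk)) {
        # trunk voxels swallowed by the soma ellipsoid are soma, not trunk
        tv <- which(trunk_owner != 0L)
        if (length(tv)) {
          own <- trunk_owner[tv]
          ai <- arrayInd(tv, dimv)
          ctr <- cbind((ai[, 3] - 0.5) * geometry$size_x,
                       (ai[, 2] - 0.5) * geometry$size_y,
                       (ai[, 1] - 0.5) * geometry$size_z)
          inside <- logical(length(tv))
          for (id in unique(own)) {
            i <- match(id, truth$neuron_id)
            sel <- own == id
            R <- matrix(rot[i, ], 3, 3, byrow = TRUE)
            w <- ctr[sel, , drop = FALSE] -
              matrix(c(truth$x_um[i], truth$y_um[i], truth$z_um[i]),
                     sum(sel), 3, byrow = TRUE)
            u <- w %*% t(R)
            q <- (u[, 1] / truth$a_um[i])^2 + (u[, 2] / truth$b_um[i])^2 +
              (u[, 3] / truth$c_um[i])^2
            inside[sel] <- q <= 1
          }
          trunk_owner[tv[inside]] <- 0L
        }
        out$trunk_labels <- trunk_owner
      }
      out$signal <- apply_noise(sig, noise)
    }

    if ("counterstain" %in% channels) {
      cst <- array(0, dim = dimv)
      # nuclei of the labeled neurons
      if (n > 0) {
        nuc_r <- matrix(nucleus_radius_um, n, 3)
        cpp_render_ellipsoids(cst, dimv,
                              as.matrix(truth[, c("x_um", "y_um", "z_um")]),
                              nuc_r, matrix(rep(as.vector(diag(3)), each = n), n, 9),
                              rep(1000, n), ez)
      }
      # unlabeled-cell nuclei at unlabeled_factor x the labeled density
      extra_cat <- catalog
      extra_cat$neuron_intensity <- extra_cat$neuron_intensity * unlabeled_factor
      extra_cat$trunk_prob <- 0
      extra <- place_neurons(label_volume, extra_cat, geometry,
                             seed = child_seed(seed, 7L))
      if (nrow(extra) > 0) {
        m <- nrow(extra)
        cpp_render_ellipsoids(cst, dimv,
                              as.matrix(extra[, c("x_um", "y_um", "z_um")]),
                              matrix(nucleus_radius_um, m, 3),
                              matrix(rep(as.vector(diag(3)), each = m), m, 9),
                              rep(1000, m), ez)
      }
      out$counterstain <- apply_noise(cst, noise)
    }
    class(out) <- "synthetic_scene"
    out
  })
}

# mean signal -> observed 16-bit counts under the noise model; processed in
# fixed-size chunks into a preallocated buffer so peak memory stays at one
# extra copy of the volume regardless of its size
apply_noise <- function(mean_signal, noise, chunk = 2^22) {
  dimv <- dim(mean_signal)
  n <- length(mean_signal)
  out <- integer(n)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1, n)
    v <- mean_signal[lo:hi] + noise$background
    if (noise$shot) v <- stats::rpois(length(v), v)
    if (noise$read_sd > 0) v <- v + stats::rnorm(length(v), 0, noise$read_sd)
    out[lo:hi] <- as.integer(round(pmin(pmax(v, 0), 65535)))
  }
  dim(out) <- dimv
  out
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic_scene: %d x %d x %d voxels, %d neurons, seed %s\n",
              x$geometry$shape[1], x$geometry$shape[2], x$geometry$shape[3],
              nrow(x$truth), format(x$seed)))
  invisible(x)
}

#' Demonstration catalog and scene
#'
#' `demo_catalog()` returns a four-region catalog spanning the density
#' diversity seen across brain regions (from >20,000 cells/mm^3 nuclei down
#' to sparse areas). `demo_scene()` builds a labeled volume partitioned into
#' the four regions (with a background margin), places neurons and renders
#' the channels at the native anisotropic geometry.
#'
#' @param seed integer seed.
#' @param shape voxel counts `(nz, ny, nx)`.
#' @param size_um voxel edges, `(x, y, z)` um.
#' @param channels channels to render, as in [render_scene()].
#' @param trunk_probability trunk artifact probability applied to all regions.
#' @param min_separation_um passed to [place_neurons()].
#' @param noise a [noise_spec()].
#' @return `demo_scene()` returns a `synthetic_scene`.
#' @export
demo_catalog <- function(trunk_probability = 0) {
  rbind(
    region_spec(1, "dense nucleus", 60000, c(3.5, 5.5), 4000,
                trunk_probability, group = "hypothalamus"),
    region_spec(2, "mid nucleus", 25000, c(4, 6), 3000,
                trunk_probability, group = "amygdala"),
    region_spec(3, "sparse area", 8000, c(3.5, 6), 2500,
                trunk_probability, group = "isocortex"),
    region_spec(4, "very sparse area", 2500, c(4, 6.5), 3500,
                trunk_probability, group = "isocortex"))
}

#' @rdname demo_catalog
#' @export
demo_scene <- function(seed = 1L, shape = c(256, 512, 512),
                       size_um = c(0.32, 0.32, 2),
                       channels = "signal", trunk_probability = 0,
                       min_separation_um = 0, noise = noise_spec()) {
  g <- voxel_geometry(shape, size_um)
  cat <- demo_catalog(trunk_probability)
  m <- pmax(shape %/% 16L, 2L)  # background margin
  zi <- c(m[1], shape[1] - m[1]); yi <- c(m[2], shape[2] - m[2])
  xi <- c(m[3], shape[3] - m[3])
  xmid <- xi[1] + (xi[2] - xi[1]) %/% 2L
  ymid <- yi[1] + (yi[2] - yi[1]) %/% 2L
  lab <- build_label_volume(g, cat, list(
    cuboid(1, c(zi[1], yi[1], xi[1]), c(zi[2], ymid, xmid)),
    cuboid(2, c(zi[1], ymid, xi[1]), c(zi[2], yi[2], xmid)),
    cuboid(3, c(zi[1], yi[1], xmid), c(zi[2], ymid, xi[2])),
    cuboid(4, c(zi[1], ymid, xmid), c(zi[2], yi[2], xi[2]))))
  truth <- place_neurons(lab, cat, g, seed = child_seed(seed, 1L),
                         min_separation_um = min_separation_um)
  render_scene(truth, lab, cat, g, noise = noise,
               seed = child_seed(seed, 2L), channels = channels,
               trunk_labels = trunk_probability > 0)
}
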