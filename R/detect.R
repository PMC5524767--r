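#' Detection parameters
#'
#' Tunables of the soma detection pipeline. All length scales are physical
#' micrometres; the anisotropic voxel geometry is applied internally.
#'
#' The pipeline is: robust background / noise estimation (percentile and MAD
#' of a deterministic voxel subsample), Gaussian smoothing at soma scale,
#' regional-maximum seeding above a relative threshold with minimum seed
#' separation of one expected radius (equal-intensity neighboring maxima
#' merge to one seed at their centroid), seeded region growing to a
#' relative-intensity boundary with contested voxels assigned to the
#' physically nearest seed, a morphological opening at the trunk-radius
#' scale that strips thin dendritic-trunk attachments from each mask, and a
#' final shape gate rejecting components whose minor principal extent is
#' below the trunk cutoff (elongated trunk-only structures) or whose size is
#' outside the expected soma radius range.
#'
#' Thresholds are relative (to the block background, peak and noise level),
#' so detections are invariant to a global intensity rescaling.
#'
#' @param radius_um expected soma radius range `(min, max)` in um.
#' @param sigma_um smoothing scale; default half the minimum expected radius.
#' @param background_percentile percentile of the raw intensities used as
#'   the background estimate.
#' @param noise_k seeds must exceed background by `noise_k` x the noise SD
#'   at the smoothed scale (the raw robust SD times the exact white-noise
#'   attenuation of the smoothing kernel).
#' @param rel_floor seeds must also exceed background by `rel_floor` x the
#'   raw dynamic range (peak minus background).
#' @param boundary_frac region growing keeps voxels whose smoothed intensity
#'   is at least `background + boundary_frac * (seed - background)`.
#' @param trunk_cutoff_um minor-principal-extent cutoff and opening radius:
#'   structures thinner than this are treated as dendritic trunks, not somas.
#' @param min_separation_um minimum seed separation; default one expected
#'   (mean-range) radius.
#' @param max_reach_factor growth is confined within
#'   `max_reach_factor * max(radius_um)` of the seed.
#' @return A `detection_params` list.
#' @export
detection_params <- function(radius_um = c(2.5, 8), sigma_um = NULL,
                             background_percentile = 0.5, noise_k = 8,
                             rel_floor = 0.05, boundary_frac = 0.25,
                             trunk_cutoff_um = 2,
                             min_separation_um = NULL,
                             max_reach_factor = 1.5) {
  if (length(radius_um) != 2L || any(radius_um <= 0) ||
      radius_um[1] > radius_um[2])
    stop("`radius_um` must be (min, max) with 0 < min <= max")
  if (is.null(sigma_um)) sigma_um <- radius_um[1] / 2
  if (is.null(min_separation_um)) min_separation_um <- mean(radius_um)
  structure(list(radius_um = radius_um, sigma_um = sigma_um,
                 background_percentile = background_percentile,
                 noise_k = noise_k, rel_floor = rel_floor,
                 boundary_frac = boundary_frac,
                 trunk_cutoff_um = trunk_cutoff_um,
                 min_separation_um = min_separation_um,
                 max_reach_factor = max_reach_factor),
            class = "detection_params")
}

#' Detect somas in an image block
#'
#' Runs the detection pipeline described in [detection_params()] on one
#' in-memory block. Each sufficiently bright compact blob within the
#' expected radius range yields exactly one detection; thin elongated
#' structures (dendritic trunks) yield none; touching somas whose centers
#' are at least one expected radius apart are split by the nearest-seed
#' partition.
#'
#' @param block integer or numeric 3D array, dim `(nz, ny, nx)`.
#' @param geometry a [voxel_geometry()] giving the block's voxel edges (its
#'   `shape` is ignored in favor of `dim(block)`).
#' @param params a [detection_params()].
#' @param calibration optional [calibrate_detection()] result (background,
#'   raw noise SD, raw peak). When detecting block-by-block, pass one global
#'   calibration so every block applies identical thresholds -- that is what
#'   makes tiled detection equivalent to whole-volume detection. `NULL`
#'   (default) self-calibrates from the block.
#' @return A data.frame (class `soma_detections`) with one row per
#'   detection: block-local physical center `x_um`, `y_um`, `z_um`, `peak`
#'   (seed intensity), `n_voxels`, and the morphology features of
#'   [measure_morphology()]. The voxel masks (0-based `(z, y, x)` integer
#'   matrices, block-local) are attached as attribute `"masks"`.
#' @export
detect_somas <- function(block, geometry, params = detection_params(),
                         calibration = NULL) {
  stopifnot_volume(block)
  dimv <- dim(block)
  ez <- edge_zyx(geometry)
  # minimum footprint: the block must fit one smallest expected soma
  if (any(dimv * ez < 2 * params$radius_um[1]))
    stop(sprintf("block of %s voxels is below the minimum detection footprint",
                 paste(dimv, collapse = "x")))
  v <- block
  if (is.null(calibration)) calibration <- calibrate_detection(v, params)

  sigma_vox <- params$sigma_um / ez  # per-axis sigma in voxel units (z,y,x)
  sm <- cpp_gauss_smooth(v, dimv, sigma_vox)

  bg <- calibration$background
  thr <- bg + max(params$noise_k * calibration$noise_sd *
                    smoothing_attenuation(sigma_vox),
                  params$rel_floor * (calibration$peak - bg))
  if (thr <= bg || !(max(sm) > thr)) return(empty_detections(dimv))

  cand <- cpp_local_maxima(sm, dimv, thr)
  if (nrow(cand) == 0) return(empty_detections(dimv))
  seeds <- select_seeds(cand, ez, params$min_separation_um)
  if (nrow(seeds) == 0) return(empty_detections(dimv))

  # grow on the raw volume: smoothing inflates thin structures by ~2 sigma,
  # which would let dendritic trunks survive the trunk-scale opening
  seed_raw <- v[cbind(seeds$z + 1L, seeds$y + 1L, seeds$x + 1L)]
  claims <- cpp_region_grow(v, dimv, seeds$z, seeds$y, seeds$x, seed_raw,
                            bg, params$boundary_frac,
                            params$max_reach_factor * params$radius_um[2], ez)
  idx <- which(claims != 0L)
  if (!length(idx)) return(empty_detections(dimv))
  by_seed <- split(idx, claims[idx])

  masks <- list(); centers <- list(); peaks <- numeric(0)
  min_vol_um3 <- 0.15 * (4 / 3) * pi * params$radius_um[1]^3
  min_vox <- max(1, floor(min_vol_um3 / voxel_volume_um3(geometry)))
  for (s in names(by_seed)) {
    k <- as.integer(s)
    vox <- arrayInd(by_seed[[s]], dimv)  # 1-based (z, y, x)
    mk <- refine_mask(vox, c(seeds$z[k], seeds$y[k], seeds$x[k]) + 1L,
                      dimv, ez, params)
    if (is.null(mk) || nrow(mk) < min_vox) next
    if (!pass_shape_gate(mk, ez, params)) next
    w <- v[cbind(mk[, 1], mk[, 2], mk[, 3])] - bg
    w[w < 0] <- 0
    if (sum(w) <= 0) w <- rep(1, nrow(mk))
    ctr <- c(sum((mk[, 3] - 0.5) * ez[3] * w),
             sum((mk[, 2] - 0.5) * ez[2] * w),
             sum((mk[, 1] - 0.5) * ez[1] * w)) / sum(w)  # (x, y, z) um
    masks[[length(masks) + 1L]] <- mk - 1L  # store 0-based
    centers[[length(centers) + 1L]] <- ctr
    peaks <- c(peaks, seeds$value[k])
  }
  if (!length(masks)) return(empty_detections(dimv))

  feats <- do.call(rbind, lapply(masks, function(m)
    as.data.frame(measure_morphology(m, geometry))))
  ctrm <- do.call(rbind, centers)
  out <- data.frame(x_um = ctrm[, 1], y_um = ctrm[, 2], z_um = ctrm[, 3],
                    peak = peaks, n_voxels = vapply(masks, nrow, integer(1)))
  out <- cbind(out, feats)
  attr(out, "masks") <- masks
  attr(out, "block_dim") <- dimv
  class(out) <- c("soma_detections", "data.frame")
  out
}

#' Global detection calibration
#'
#' Estimates the background level (percentile), robust noise SD (MAD) and
#' peak intensity of a volume from the raw intensities, using a
#' deterministic voxel subsample for the order statistics. Computed once
#' per dataset and passed to every block, it makes the detection thresholds
#' identical regardless of how the volume is tiled. All three statistics
#' scale with the data, so thresholds remain invariant to a global
#' intensity rescaling.
#'
#' @param source 3D array, or a TIFF path written by [write_volume()]
#'   (streamed in z-chunks).
#' @param params a [detection_params()] (for the background percentile).
#' @return List with `background`, `noise_sd`, `peak` (raw intensity
#'   units).
#' @export
calibrate_detection <- function(source, params = detection_params()) {
  if (is.character(source)) {
    nz <- stored_shape(source)[1]
    samp <- c(); peak <- -Inf
    for (z0 in seq(1L, nz, by = 64L)) {
      z1 <- min(z0 + 63L, nz)
      pages <- tiff::readTIFF(source, all = z0:z1, as.is = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      chunk <- unlist(pages, use.names = FALSE)
      stride <- max(1L, as.integer(length(chunk) %/% (1e6 * (z1 - z0 + 1L) / nz)))
      samp <- c(samp, chunk[seq(1L, length(chunk), by = stride)])
      peak <- max(peak, max(chunk))
    }
  } else {
    n <- length(source)
    stride <- max(1L, as.integer(n %/% 1e6))
    samp <- as.numeric(source[seq(1L, n, by = stride)])
    peak <- as.numeric(max(source))
  }
  bg <- as.numeric(stats::quantile(samp, params$background_percentile,
                                   names = FALSE))
  list(background = bg, noise_sd = stats::mad(samp, center = bg),
       peak = peak)
}

# exact white-noise SD attenuation of the separable truncated-Gaussian
# smoothing: product over axes of sqrt(sum(kernel^2)); mirrors the C++ kernel
smoothing_attenuation <- function(sigma_vox) {
  f <- 1
  for (s in sigma_vox) {
    if (s <= 0) next
    r <- max(1L, as.integer(ceiling(3 * s)))
    k <- exp(-((-r):r)^2 / (2 * s^2))
    k <- k / sum(k)
    f <- f * sqrt(sum(k^2))
  }
  f
}

empty_detections <- function(dimv) {
  out <- data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                    peak = numeric(0), n_voxels = integer(0),
                    r_longest = numeric(0), r_shortest = numeric(0),
                    r_average = numeric(0), surface_um2 = numeric(0),
                    volume_um3 = numeric(0), ratio = numeric(0),
                    degenerate = logical(0))
  attr(out, "masks") <- list()
  attr(out, "block_dim") <- dimv
  class(out) <- c("soma_detections", "data.frame")
  out
}

# greedy non-maximum suppression with centroid merge of equal-value ties;
# deterministic order: value desc, then (z, y, x)
select_seeds <- function(cand, ez, min_sep_um) {
  o <- order(-cand$value, cand$z, cand$y, cand$x)
  cand <- cand[o, , drop = FALSE]
  n <- nrow(cand)
  px <- cand$x * ez[3]; py <- cand$y * ez[2]; pz <- cand$z * ez[1]
  keep <- integer(0)
  groups <- list()  # merged plateau members per kept seed
  for (i in seq_len(n)) {
    if (length(keep)) {
      d2 <- (px[keep] - px[i])^2 + (py[keep] - py[i])^2 + (pz[keep] - pz[i])^2
      near <- which(d2 < min_sep_um^2)
      if (length(near)) {
        j <- near[1]
        if (cand$value[keep[j]] == cand$value[i])
          groups[[j]] <- c(groups[[j]], i)
        next
      }
    }
    keep <- c(keep, i)
    groups[[length(keep)]] <- i
  }
  out <- data.frame(z = integer(length(keep)), y = integer(length(keep)),
                    x = integer(length(keep)), value = cand$value[keep])
  for (j in seq_along(keep)) {
    g <- groups[[j]]
    out$z[j] <- as.integer(round(mean(cand$z[g])))
    out$y[j] <- as.integer(round(mean(cand$y[g])))
    out$x[j] <- as.integer(round(mean(cand$x[g])))
  }
  out
}

# opening at trunk scale on the local bounding box, then keep the connected
# component holding (or nearest to) the seed voxel
refine_mask <- function(vox, seed_zyx, dimv, ez, params) {
  r_open <- 0.6 * params$trunk_cutoff_um
  pad <- pmax(1L, as.integer(ceiling(r_open / ez)) + 1L)
  lo <- pmax(1L, apply(vox, 2, min) - pad)
  hi <- pmin(dimv, apply(vox, 2, max) + pad)
  ld <- hi - lo + 1L
  loc <- array(FALSE, dim = ld)
  loc[cbind(vox[, 1] - lo[1] + 1L, vox[, 2] - lo[2] + 1L,
            vox[, 3] - lo[3] + 1L)] <- TRUE
  er <- cpp_binary_morph(loc, ld, r_open, ez, 0L)
  if (!any(er)) return(NULL)
  op <- cpp_binary_morph(er, ld, r_open, ez, 1L)
  op <- op & loc  # opening never exceeds the original mask
  lab <- cpp_label_components(op, ld)
  if (max(lab) == 0L) return(NULL)
  sv <- seed_zyx - lo + 1L
  sv <- pmin(pmax(sv, 1L), ld)
  comp <- lab[sv[1], sv[2], sv[3]]
  # a seed whose voxel does not survive the opening sits on a structure
  # thinner than the trunk cutoff (a dendritic trunk, not a soma): reject
  if (comp == 0L) return(NULL)
  sel <- which(lab == comp)
  ai <- arrayInd(sel, ld)
  cbind(ai[, 1] + lo[1] - 1L, ai[, 2] + lo[2] - 1L, ai[, 3] + lo[3] - 1L)
}

# reject thin elongated structures and size outliers
pass_shape_gate <- function(mask_vox, ez, params) {
  p <- cbind(mask_vox[, 3] * ez[3], mask_vox[, 2] * ez[2],
             mask_vox[, 1] * ez[1])
  if (nrow(p) >= 4) {
    ev <- eigen(stats::cov(p), symmetric = TRUE, only.values = TRUE)$values
    minor_extent <- 4 * sqrt(max(ev[3], 0))
    if (minor_extent < params$trunk_cutoff_um) return(FALSE)
  }
  r_eq <- (3 * nrow(p) * prod(ez) / (4 * pi))^(1 / 3)
  if (r_eq > 1.6 * params$radius_um[2]) return(FALSE)
  TRUE
}

#' Measure soma morphology features
#'
#' Computes the six shape features of a segmented soma mask: the longest,
#' shortest and average radii (distances from the mask centroid to surface
#' voxel centers, in um), the surface area (triangulated isosurface of the
#' mask at physical scale, um^2), the cell volume (voxel count times voxel
#' volume, um^3), and the longest-to-shortest radius ratio.
#'
#' The isosurface is extracted by marching tetrahedra on a lightly smoothed
#' indicator field at level 0.5, which removes the staircase overestimate a
#' raw voxel-face surface would give. A single-voxel mask is flagged
#' degenerate and measured from the voxel half-edges instead of a surface
#' triangulation.
#'
#' @param mask either a logical 3D array or an integer matrix (n x 3) of
#'   0-based `(z, y, x)` voxel indices.
#' @param geometry a [voxel_geometry()] supplying voxel edge lengths.
#' @return A list with `r_longest`, `r_shortest`, `r_average` (um),
#'   `surface_um2`, `volume_um3`, `ratio`, `degenerate`.
#' @export
measure_morphology <- function(mask, geometry) {
  ez <- edge_zyx(geometry)
  if (length(dim(mask)) == 3L) {
    vox <- which(mask, arr.ind = TRUE)  # 1-based (z,y,x)
  } else {
    vox <- as.matrix(mask) + 1L
  }
  if (nrow(vox) == 0) stop("empty mask")
  vol <- nrow(vox) * prod(ez)
  if (nrow(vox) == 1L) {
    half <- ez / 2  # (z, y, x)
    sa <- 2 * (ez[3] * ez[2] + ez[3] * ez[1] + ez[2] * ez[1])
    return(list(r_longest = max(half), r_shortest = min(half),
                r_average = mean(half), surface_um2 = sa, volume_um3 = vol,
                ratio = max(half) / min(half), degenerate = TRUE))
  }
  lo <- apply(vox, 2, min); hi <- apply(vox, 2, max)
  pad <- 4L
  ld <- hi - lo + 1L + 2L * pad
  loc <- array(0, dim = ld)
  lvox <- cbind(vox[, 1] - lo[1] + 1L + pad, vox[, 2] - lo[2] + 1L + pad,
                vox[, 3] - lo[3] + 1L + pad)
  loc[lvox] <- 1
  field <- cpp_gauss_smooth(loc, ld, c(0.8, 0.8, 0.8))
  sa <- cpp_mt_surface_area(field, ld, ez, 0.5)

  # surface voxels: mask voxels with a 6-neighbor outside
  lm <- loc > 0.5
  surf <- logical(nrow(lvox))
  for (k in seq_len(3)) {
    for (s in c(-1L, 1L)) {
      nb <- lvox
      nb[, k] <- nb[, k] + s
      surf <- surf | !lm[nb]
    }
  }
  ctr_all <- cbind((vox[, 3] - 0.5) * ez[3], (vox[, 2] - 0.5) * ez[2],
                   (vox[, 1] - 0.5) * ez[1])
  centroid <- colMeans(ctr_all)
  sp <- ctr_all[surf, , drop = FALSE]
  if (nrow(sp) == 0) sp <- ctr_all
  d <- sqrt((sp[, 1] - centroid[1])^2 + (sp[, 2] - centroid[2])^2 +
            (sp[, 3] - centroid[3])^2)
  r_long <- max(d); r_short <- min(d)
  list(r_longest = r_long, r_shortest = r_short, r_average = mean(d),
       surface_um2 = sa, volume_um3 = vol,
       ratio = if (r_short > 0) r_long / r_short else Inf,
       degenerate = FALSE)
}
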