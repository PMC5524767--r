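#' Assign neurons to anatomical regions by center voxel
#'
#' Each neuron's `region_id` becomes the label of the voxel containing its
#' center (containing-voxel rule: `floor(coordinate / edge)`), matching
#' center-based counting: a soma straddling a boundary belongs wholly to its
#' center's region. Centers in background (label 0) are retained with
#' `region_id` 0 and are reported separately by the summaries, never
#' silently dropped.
#'
#' @param neurons neuron table with `x_um`, `y_um`, `z_um`.
#' @param labels a `region_label_volume` (or a bare integer 3D array).
#' @param geometry a [voxel_geometry()].
#' @return The neuron table with `region_id` filled in.
#' @export
assign_regions <- function(neurons, labels, geometry) {
  arr <- if (inherits(labels, "region_label_volume")) labels$labels else labels
  stopifnot_volume(arr)
  if (nrow(neurons) == 0) return(neurons)
  vox <- um_to_voxel(as.matrix(neurons[, c("x_um", "y_um", "z_um")]), geometry)
  d <- dim(arr)
  bad <- vox[, 1] < 0L | vox[, 1] >= d[3] | vox[, 2] < 0L | vox[, 2] >= d[2] |
    vox[, 3] < 0L | vox[, 3] >= d[1]
  if (any(bad))
    stop(sprintf("assignment error: %d neuron center(s) outside the labeled volume (ids: %s)",
                 sum(bad),
                 paste(utils::head(neurons$neuron_id[bad], 10), collapse = ", ")))
  neurons$region_id <- arr[cbind(vox[, 3] + 1L, vox[, 2] + 1L, vox[, 1] + 1L)]
  neurons
}

#' Region volume from the label volume
#'
#' Volume = labeled voxel count x voxel volume, converted from um^3 to mm^3
#' (factor 1e-9).
#'
#' @param labels a `region_label_volume` or integer 3D array.
#' @param geometry a [voxel_geometry()].
#' @param region_id region id; must be in the catalog when `labels` carries
#'   one.
#' @return Volume in mm^3 (0 with a warning when the region is absent from
#'   the volume).
#' @export
region_volume <- function(labels, geometry, region_id) {
  arr <- if (inherits(labels, "region_label_volume")) labels$labels else labels
  if (inherits(labels, "region_label_volume") &&
      !(region_id %in% labels$catalog$region_id))
    stop(sprintf("catalog error: unknown region_id %s", format(region_id)))
  nvox <- sum(arr == region_id)
  if (nvox == 0) warning(sprintf("region %s absent from the label volume",
                                 format(region_id)))
  nvox * voxel_volume_um3(geometry) * 1e-9
}

#' Neuron density
#'
#' @param count neuron count (cells).
#' @param volume region volume in mm^3.
#' @return Density in cells/mm^3; `NA` with attribute `undefined = TRUE`
#'   when the volume is 0.
#' @export
density_cells_mm3 <- function(count, volume) {
  out <- ifelse(volume > 0, count / volume, NA_real_)
  if (any(volume <= 0)) attr(out, "undefined") <- TRUE
  out
}

#' Nuclei distance of a region
#'
#' The region statistic summarizing how tightly labeled neurons pack: for
#' each neuron, the Euclidean distance (um) to its nearest other neuron of
#' the same region; the statistic is the mean of these nearest distances
#' over all the region's neurons. Computed with a uniform-grid spatial
#' index that reproduces the all-pairs computation exactly.
#'
#' @param neurons neuron table with `x_um`, `y_um`, `z_um` (already
#'   restricted to one region), or an n x 3 coordinate matrix.
#' @return Mean nearest-neighbor distance in um; `NA` (flagged undefined)
#'   when fewer than 2 neurons.
#' @export
nuclei_distance <- function(neurons) {
  pts <- if (is.matrix(neurons)) neurons
  else as.matrix(neurons[, c("x_um", "y_um", "z_um")])
  if (nrow(pts) < 2) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  mean(cpp_nn_distance(pts))
}

#' Summarize the regional distribution of a neuron census
#'
#' Produces the per-region distribution statistics: neuron count, region
#' volume (mm^3), density (cells/mm^3), and nuclei distance (um); parent
#' group roll-ups (counts and volumes aggregated over the catalog `group`
#' before dividing); layer profiles for any parent area whose catalog rows
#' carry `parent_area`/`layer_index`; and the whole-brain summary (total
#' count over total nonzero-label volume). Background-assigned neurons
#' (`region_id` 0) are reported in `background_count`.
#'
#' @param neurons assigned neuron table (see [assign_regions()]).
#' @param labels a `region_label_volume`.
#' @param geometry a [voxel_geometry()].
#' @param catalog region catalog (defaults to the one in `labels`).
#' @return List with `regions`, `groups`, `layers` (data.frames),
#'   `whole_brain` (list: count, volume_mm3, density), `background_count`.
#' @export
summarize_regions <- function(neurons, labels, geometry,
                              catalog = labels$catalog) {
  catalog <- as_region_catalog(catalog)
  arr <- if (inherits(labels, "region_label_volume")) labels$labels else labels
  vox_mm3 <- voxel_volume_um3(geometry) * 1e-9
  counts_vox <- tabulate(arr[arr != 0L], nbins = max(catalog$region_id))
  vol_mm3 <- counts_vox[catalog$region_id] * vox_mm3
  n_per <- vapply(catalog$region_id,
                  function(id) sum(neurons$region_id == id), numeric(1))
  nd <- vapply(catalog$region_id, function(id) {
    sub <- neurons[neurons$region_id == id, , drop = FALSE]
    as.numeric(nuclei_distance(sub))
  }, numeric(1))
  regions <- data.frame(region_id = catalog$region_id, name = catalog$name,
                        group = catalog$group, count = n_per,
                        volume_mm3 = vol_mm3,
                        density_cells_per_mm3 = density_cells_mm3(n_per, vol_mm3),
                        nuclei_distance_um = nd,
                        flags = ifelse(n_per < 2, "nuclei_distance_undefined", ""))
  groups <- do.call(rbind, lapply(split(regions, regions$group), function(gr) {
    data.frame(group = gr$group[1], count = sum(gr$count),
               volume_mm3 = sum(gr$volume_mm3),
               density_cells_per_mm3 = density_cells_mm3(sum(gr$count),
                                                         sum(gr$volume_mm3)))
  }))
  rownames(groups) <- NULL
  layer_rows <- catalog[!is.na(catalog$parent_area) &
                          !is.na(catalog$layer_index), , drop = FALSE]
  layers <- if (nrow(layer_rows)) {
    do.call(rbind, lapply(split(layer_rows, layer_rows$parent_area),
                          function(lr) {
      lr <- lr[order(lr$layer_index), , drop = FALSE]
      i <- match(lr$region_id, regions$region_id)
      data.frame(parent_area = lr$parent_area, layer_index = lr$layer_index,
                 region_id = lr$region_id, name = lr$name,
                 density_cells_per_mm3 = regions$density_cells_per_mm3[i])
    }))
  } else data.frame(parent_area = character(0), layer_index = integer(0),
                    region_id = integer(0), name = character(0),
                    density_cells_per_mm3 = numeric(0))
  rownames(layers) <- NULL
  total_vol <- sum(arr != 0L) * vox_mm3
  fg <- sum(neurons$region_id > 0)
  list(regions = regions, groups = groups, layers = layers,
       whole_brain = list(count = fg, volume_mm3 = total_vol,
                          density = density_cells_mm3(fg, total_vol)),
       background_count = sum(neurons$region_id == 0))
}
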