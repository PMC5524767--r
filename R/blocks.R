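#' Plan guard-zoned block tiling of a volume
#'
#' Tiles a voxel grid into non-overlapping core blocks of `block_edge`
#' voxels per axis (the last block per axis truncated at the boundary), each
#' expanded by `guard_width` voxels into a padded extent clipped to the
#' volume. Cores partition the volume exactly, which is what makes the merge
#' rule count each soma exactly once; guards make objects near core
#' boundaries fully visible to at least one block.
#'
#' @param shape voxel counts `(nz, ny, nx)`.
#' @param block_edge core block edge in voxels (default 512).
#' @param guard_width guard zone width in voxels (default 50).
#' @return A `block_plan`: list with `blocks` (data.frame of half-open core
#'   bounds `z0..x1` and padded bounds `pz0..px1`, 0-based), `shape`,
#'   `block_edge`, `guard_width`.
#' @examples
#' plan_blocks(c(600, 1024, 512), 512, 50)
#' @export
plan_blocks <- function(shape, block_edge = 512L, guard_width = 50L) {
  shape <- as.integer(shape)
  block_edge <- as.integer(block_edge)
  guard_width <- as.integer(guard_width)
  if (length(shape) != 3L || any(shape <= 0L))
    stop("`shape` must be three positive voxel counts")
  if (is.na(block_edge) || block_edge <= 0L)
    stop("`block_edge` must be a positive number of voxels")
  if (guard_width < 0L) stop("`guard_width` must be >= 0")
  if (block_edge <= 2L * guard_width)
    warning("block_edge <= 2 * guard_width: guards dominate the blocks")
  starts <- lapply(shape, function(s) seq.int(0L, s - 1L, by = block_edge))
  grid <- expand.grid(z0 = starts[[1]], y0 = starts[[2]], x0 = starts[[3]],
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$z0, grid$y0, grid$x0), , drop = FALSE]
  b <- data.frame(block_id = seq_len(nrow(grid)))
  b$z0 <- grid$z0; b$y0 <- grid$y0; b$x0 <- grid$x0
  b$z1 <- pmin(grid$z0 + block_edge, shape[1])
  b$y1 <- pmin(grid$y0 + block_edge, shape[2])
  b$x1 <- pmin(grid$x0 + block_edge, shape[3])
  b$pz0 <- pmax(b$z0 - guard_width, 0L)
  b$py0 <- pmax(b$y0 - guard_width, 0L)
  b$px0 <- pmax(b$x0 - guard_width, 0L)
  b$pz1 <- pmin(b$z1 + guard_width, shape[1])
  b$py1 <- pmin(b$y1 + guard_width, shape[2])
  b$px1 <- pmin(b$x1 + guard_width, shape[3])
  structure(list(blocks = b, shape = shape, block_edge = block_edge,
                 guard_width = guard_width),
            class = "block_plan")
}

#' @export
print.block_plan <- function(x, ...) {
  cat(sprintf("block_plan: %d blocks (edge %d, guard %d) over %s voxels\n",
              nrow(x$blocks), x$block_edge, x$guard_width,
              paste(x$shape, collapse = " x ")))
  invisible(x)
}

#' Run detection over all blocks of a plan
#'
#' Processes each block independently on its padded extent: reads the
#' window (from an in-memory array or a TIFF path via
#' [read_volume_window()]), runs [detect_somas()], and converts centers to
#' absolute physical coordinates. Processing order does not affect results.
#'
#' @param source 3D integer array or path to a TIFF written by
#'   [write_volume()].
#' @param plan a [plan_blocks()] plan.
#' @param geometry a [voxel_geometry()].
#' @param params a [detection_params()].
#' @param calibration global [calibrate_detection()] result; computed from
#'   `source` when `NULL`. One shared calibration keeps the thresholds of
#'   every block identical, which is what makes the tiled result equal the
#'   whole-volume result.
#' @param verbose log per-block progress.
#' @return List of per-block data.frames with absolute `x_um`, `y_um`,
#'   `z_um` and a `block_id` column.
#' @export
run_blocks <- function(source, plan, geometry, params = detection_params(),
                       calibration = NULL, verbose = FALSE) {
  if (is.null(calibration)) calibration <- calibrate_detection(source, params)
  guard_needed <- ceiling((params$max_reach_factor * params$radius_um[2] +
                             3 * params$sigma_um) / min(edge_zyx(geometry)))
  if (plan$guard_width > 0 && plan$guard_width < guard_needed)
    warning(sprintf("guard width %d voxels is below the detection influence radius (%d voxels); tiled results may differ from whole-volume detection",
                    plan$guard_width, guard_needed))
  b <- plan$blocks
  lapply(seq_len(nrow(b)), function(i) {
    lo <- c(b$pz0[i], b$py0[i], b$px0[i])
    hi <- c(b$pz1[i], b$py1[i], b$px1[i])
    block <- tryCatch({
      if (is.character(source)) read_volume_window(source, lo, hi)
      else source[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2], (lo[3] + 1):hi[3],
                  drop = FALSE]
    }, error = function(e)
      stop(sprintf("block %d window read failed: %s", b$block_id[i],
                   conditionMessage(e))))
    det <- detect_somas(block, geometry, params, calibration)
    det$x_um <- det$x_um + lo[3] * geometry$size_x
    det$y_um <- det$y_um + lo[2] * geometry$size_y
    det$z_um <- det$z_um + lo[1] * geometry$size_z
    det$block_id <- rep(b$block_id[i], nrow(det))
    if (verbose)
      message(sprintf("block %d/%d: %d detections", i, nrow(b), nrow(det)))
    as.data.frame(det)
  })
}

#' Merge per-block detections into a whole-volume neuron table
#'
#' Ownership rule: a detection survives iff the voxel containing its center
#' lies inside its source block's core extent. Cores partition the volume,
#' so a soma seen by several overlapping padded blocks is counted exactly
#' once -- by the block that owns its center voxel. Merged neuron ids are
#' reassigned deterministically in `(z, y, x)` center order.
#'
#' @param tables list of per-block tables from [run_blocks()] (absolute
#'   coordinates, `block_id` column).
#' @param plan the [plan_blocks()] plan the tables came from.
#' @param geometry a [voxel_geometry()].
#' @return data.frame of `neuron_record`s: `neuron_id`, `x_um`, `y_um`,
#'   `z_um`, `region_id` (0 until assigned), morphology features,
#'   `block_id`, and an `oversize` flag marking somas whose diameter exceeds
#'   the physical guard width (outside the tiling's validity domain).
#' @export
merge_blocks <- function(tables, plan, geometry) {
  all <- do.call(rbind, tables)
  if (is.null(all) || nrow(all) == 0) return(empty_neuron_table())
  b <- plan$blocks
  i <- match(all$block_id, b$block_id)
  vox <- um_to_voxel(as.matrix(all[, c("x_um", "y_um", "z_um")]), geometry)
  inside_pad <- vox[, 3] >= b$pz0[i] & vox[, 3] < b$pz1[i] &
    vox[, 2] >= b$py0[i] & vox[, 2] < b$py1[i] &
    vox[, 1] >= b$px0[i] & vox[, 1] < b$px1[i]
  if (any(!inside_pad))
    stop(sprintf("integrity error: %d detection(s) outside their padded extent",
                 sum(!inside_pad)))
  own <- vox[, 3] >= b$z0[i] & vox[, 3] < b$z1[i] &
    vox[, 2] >= b$y0[i] & vox[, 2] < b$y1[i] &
    vox[, 1] >= b$x0[i] & vox[, 1] < b$x1[i]
  kept <- all[own, , drop = FALSE]
  if (nrow(kept) == 0) return(empty_neuron_table())
  kept <- kept[order(kept$z_um, kept$y_um, kept$x_um), , drop = FALSE]
  guard_um <- plan$guard_width * min(edge_zyx(geometry))
  out <- data.frame(neuron_id = seq_len(nrow(kept)),
                    x_um = kept$x_um, y_um = kept$y_um, z_um = kept$z_um,
                    region_id = 0L,
                    r_longest = kept$r_longest, r_shortest = kept$r_shortest,
                    r_average = kept$r_average, surface_um2 = kept$surface_um2,
                    volume_um3 = kept$volume_um3, ratio = kept$ratio,
                    degenerate = kept$degenerate, n_voxels = kept$n_voxels,
                    peak = kept$peak, block_id = kept$block_id,
                    oversize = 2 * kept$r_longest > guard_um)
  if (plan$guard_width > 0L && any(out$oversize))
    warning(sprintf("%d soma(s) larger than the guard width; merge validity not guaranteed for them",
                    sum(out$oversize)))
  rownames(out) <- NULL
  out
}

empty_neuron_table <- function() {
  data.frame(neuron_id = integer(0), x_um = numeric(0), y_um = numeric(0),
             z_um = numeric(0), region_id = integer(0),
             r_longest = numeric(0), r_shortest = numeric(0),
             r_average = numeric(0), surface_um2 = numeric(0),
             volume_um3 = numeric(0), ratio = numeric(0),
             degenerate = logical(0), n_voxels = integer(0),
             peak = numeric(0), block_id = integer(0), oversize = logical(0))
}

#' Whole-volume census: plan, run and merge in one call
#'
#' Convenience wrapper for the complete counting stage. With
#' `block_edge >= max(shape)` the plan degenerates to a single block, which
#' is also the reference path for checking tiling equivalence.
#'
#' @inheritParams run_blocks
#' @param block_edge,guard_width tiling parameters, see [plan_blocks()].
#' @param shape voxel shape of the source (required when `source` is a
#'   path; inferred from an array source).
#' @param calibration optional precomputed [calibrate_detection()] result.
#' @return Merged neuron table, as from [merge_blocks()].
#' @export
count_neurons <- function(source, geometry, params = detection_params(),
                          block_edge = 512L, guard_width = 50L,
                          shape = NULL, calibration = NULL, verbose = FALSE) {
  if (is.null(shape)) {
    if (!is.character(source)) shape <- dim(source)
    else stop("`shape` is required when `source` is a file path")
  }
  if (is.null(calibration)) calibration <- calibrate_detection(source, params)
  plan <- plan_blocks(shape, block_edge, guard_width)
  tabs <- run_blocks(source, plan, geometry, params, calibration,
                     verbose = verbose)
  merge_blocks(tabs, plan, geometry)
}
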