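#' Write / read a 3D volume as a multi-page TIFF
#'
#' Volumes are stored one z-plane per page, ascending z, grayscale, 8- or
#' 16-bit, uncompressed by default. The physical geometry goes to a YAML
#' sidecar (`<path>.yaml`) rather than TIFF tags, avoiding tag-dialect
#' ambiguity.
#'
#' @param vol integer 3D array, dim `(nz, ny, nx)`, values within the bit
#'   depth.
#' @param path output TIFF path.
#' @param geometry optional [voxel_geometry()]; written to the sidecar.
#' @param bits bits per sample, 8 or 16.
#' @param compression TIFF compression, passed to [tiff::writeTIFF()].
#' @return `read_volume` returns the integer array, with the sidecar
#'   geometry attached as attribute `"geometry"` when present.
#' @export
write_volume <- function(vol, path, geometry = NULL, bits = 16,
                         compression = "none") {
  stopifnot_volume(vol)
  if (!bits %in% c(8, 16)) stop("`bits` must be 8 or 16")
  maxv <- 2^bits - 1
  if (min(vol) < 0 || max(vol) > maxv)
    stop(sprintf("volume values outside the %d-bit range", bits))
  pages <- lapply(seq_len(dim(vol)[1]),
                  function(z) vol[z, , , drop = TRUE] / maxv)
  tiff::writeTIFF(pages, path, bits.per.sample = bits,
                  compression = compression)
  meta <- list(shape = as.integer(dim(vol)), bits = bits)
  if (!is.null(geometry))
    meta$size_um <- c(geometry$size_x, geometry$size_y, geometry$size_z)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  arr <- pages_to_array(pages)
  sidecar <- paste0(path, ".yaml")
  if (file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    if (!is.null(meta$size_um))
      attr(arr, "geometry") <- voxel_geometry(meta$shape, meta$size_um)
  }
  arr
}

# voxel shape of a stored volume, from the metadata sidecar (or by reading
# the first page plus the page directory when no sidecar is present)
stored_shape <- function(path) {
  sidecar <- paste0(path, ".yaml")
  if (file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    return(as.integer(meta$shape))
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  c(length(pages), dim(pages[[1]])[1], dim(pages[[1]])[2])
}

pages_to_array <- function(pages) {
  d <- dim(pages[[1]])
  if (any(vapply(pages, function(p) !identical(dim(p), d), logical(1))))
    stop("format error: TIFF pages have mismatched shapes")
  arr <- array(0L, dim = c(length(pages), d[1], d[2]))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
  arr
}

#' Read a voxel window from a stored volume
#'
#' Reads only the z-pages the window touches and crops in y/x, so blocks of
#' a volume too large to hold in memory can be processed one at a time.
#' Windows are half-open voxel bounds `[lo, hi)` in `(z, y, x)` order,
#' 0-based.
#'
#' @param path TIFF path written by [write_volume()].
#' @param lo,hi integer window bounds `(z, y, x)`, half-open.
#' @return Integer array of dim `hi - lo`.
#' @export
read_volume_window <- function(path, lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  shape <- stored_shape(path)
  if (any(lo < 0L) || any(hi > shape) || any(hi <= lo))
    stop(sprintf("window [(%s), (%s)) out of bounds for stored extent (%s)",
                 paste(lo, collapse = ","), paste(hi, collapse = ","),
                 paste(shape, collapse = ",")))
  pages <- tiff::readTIFF(path, all = (lo[1] + 1):hi[1], as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- pages_to_array(pages)
  arr[, (lo[2] + 1):hi[2], (lo[3] + 1):hi[3], drop = FALSE]
}

#' Write / read a neuron table
#'
#' Delimited-text (CSV) tables with a fixed documented header. Coordinates
#' are written to 0.01 um; other numeric fields keep full precision.
#' Required columns on read: `neuron_id`, `x_um`, `y_um`, `z_um`,
#' `region_id`; any further columns (morphology features, block ids, flags)
#' round-trip as-is.
#'
#' @param records neuron table (detections or ground truth) with um
#'   coordinates.
#' @param path CSV path.
#' @return `read_neuron_table` returns the data.frame.
#' @export
write_neuron_table <- function(records, path) {
  req <- c("neuron_id", "x_um", "y_um", "z_um", "region_id")
  missing <- setdiff(req, names(records))
  if (length(missing))
    stop("neuron table missing required column(s): ",
         paste(missing, collapse = ", "))
  out <- records
  for (cc in c("x_um", "y_um", "z_um")) out[[cc]] <- round(out[[cc]], 2)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_neuron_table
#' @export
read_neuron_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("neuron_id", "x_um", "y_um", "z_um", "region_id")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("schema error: neuron table missing column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Write a synthetic scene to a directory
#'
#' Writes the signal and counterstain channels and the label volume as
#' multi-page 3D TIFFs, the ground-truth table as CSV (documented columns:
#' neuron_id, x_um, y_um, z_um, region_id, a_um, b_um, c_um, peak), the
#' region catalog as YAML, and a scene metadata file recording geometry,
#' noise and seed.
#'
#' @param scene a `synthetic_scene` from [render_scene()] / [demo_scene()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- scene$geometry
  if (!is.null(scene$signal))
    write_volume(scene$signal, file.path(dir, "signal.tif"), g)
  if (!is.null(scene$counterstain))
    write_volume(scene$counterstain, file.path(dir, "counterstain.tif"), g)
  write_volume(scene$labels$labels, file.path(dir, "labels.tif"), g)
  tr <- scene$truth
  tr <- tr[, intersect(c("neuron_id", "x_um", "y_um", "z_um", "region_id",
                         "a_um", "b_um", "c_um", "peak"), names(tr))]
  write_neuron_table(tr, file.path(dir, "truth.csv"))
  write_region_catalog(scene$labels$catalog, file.path(dir, "catalog.yaml"))
  yaml::write_yaml(list(shape = as.integer(g$shape),
                        size_um = c(g$size_x, g$size_y, g$size_z),
                        noise = unclass(scene$noise), seed = scene$seed),
                   file.path(dir, "scene.yaml"))
  invisible(dir)
}
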