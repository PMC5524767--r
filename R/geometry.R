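#' Voxel geometry of an image volume
#'
#' Describes the physical sampling of a 3D stack: per-axis voxel edge lengths
#' in micrometres and the voxel counts. Volumes produced by whole-brain
#' sectioning tomography are strongly anisotropic (the default geometry is
#' 0.32 um laterally and 2 um axially), so every physical computation in the
#' package goes through this object rather than assuming cubic voxels.
#'
#' Conventions: array axis order is `(z, y, x)` with z the page (section)
#' axis; indices are 0-based in physical formulas; the volume origin is the
#' outer corner of voxel `(0, 0, 0)` and a voxel's center sits at
#' `(index + 0.5) * edge` micrometres.
#'
#' @param shape integer vector of voxel counts, `(nz, ny, nx)`.
#' @param size_um numeric vector of voxel edge lengths in micrometres,
#'   `(x, y, z)` order; default `c(0.32, 0.32, 2)`.
#' @return An object of class `voxel_geometry` with fields `shape`
#'   (`(nz, ny, nx)`), `size_x`, `size_y`, `size_z` (um).
#' @examples
#' g <- voxel_geometry(c(64, 128, 128))
#' voxel_volume_um3(g)
#' extent_um(g)
#' @export
voxel_geometry <- function(shape, size_um = c(0.32, 0.32, 2)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape <= 0L))
    stop("`shape` must be three positive voxel counts (nz, ny, nx)")
  size_um <- as.numeric(size_um)
  if (length(size_um) != 3L || any(!is.finite(size_um)) || any(size_um <= 0))
    stop("`size_um` must be three positive edge lengths (x, y, z) in um")
  structure(list(shape = shape,
                 size_x = size_um[1], size_y = size_um[2], size_z = size_um[3]),
            class = "voxel_geometry")
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf("voxel_geometry: %d x %d x %d voxels (z,y,x), %.3g x %.3g x %.3g um\n",
              x$shape[1], x$shape[2], x$shape[3], x$size_x, x$size_y, x$size_z))
  invisible(x)
}

#' Physical volume of one voxel in cubic micrometres
#' @param geometry a [voxel_geometry()].
#' @return Scalar, um^3.
#' @export
voxel_volume_um3 <- function(geometry) {
  geometry$size_x * geometry$size_y * geometry$size_z
}

#' Physical extent of a volume in micrometres
#' @param geometry a [voxel_geometry()].
#' @return Named numeric `(x, y, z)` extent in um.
#' @export
extent_um <- function(geometry) {
  c(x = geometry$shape[3] * geometry$size_x,
    y = geometry$shape[2] * geometry$size_y,
    z = geometry$shape[1] * geometry$size_z)
}

# per-axis edge lengths in (z, y, x) order, matching array axis order
edge_zyx <- function(geometry) {
  c(geometry$size_z, geometry$size_y, geometry$size_x)
}

#' Map physical coordinates to containing voxel indices
#'
#' A point belongs to the voxel `floor(coordinate / edge)`; points exactly on
#' a boundary go to the higher voxel, which makes block core ownership and
#' region assignment unambiguous.
#'
#' @param xyz_um numeric matrix (n x 3) or vector of `(x, y, z)` in um.
#' @param geometry a [voxel_geometry()].
#' @return Integer matrix (n x 3) of 0-based voxel indices `(ix, iy, iz)`.
#' @export
um_to_voxel <- function(xyz_um, geometry) {
  m <- if (is.matrix(xyz_um)) xyz_um else matrix(xyz_um, ncol = 3)
  out <- cbind(floor(m[, 1] / geometry$size_x),
               floor(m[, 2] / geometry$size_y),
               floor(m[, 3] / geometry$size_z))
  storage.mode(out) <- "integer"
  colnames(out) <- c("ix", "iy", "iz")
  out
}

#' Physical center of voxels
#' @param ixyz integer matrix (n x 3) of 0-based voxel indices `(ix, iy, iz)`.
#' @param geometry a [voxel_geometry()].
#' @return Numeric matrix (n x 3) of `(x, y, z)` voxel centers in um.
#' @export
voxel_center_um <- function(ixyz, geometry) {
  m <- if (is.matrix(ixyz)) ixyz else matrix(ixyz, ncol = 3)
  out <- cbind((m[, 1] + 0.5) * geometry$size_x,
               (m[, 2] + 0.5) * geometry$size_y,
               (m[, 3] + 0.5) * geometry$size_z)
  colnames(out) <- c("x", "y", "z")
  out
}
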