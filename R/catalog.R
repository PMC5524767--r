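#' Region specification for the synthetic brain generator
#'
#' One row of a region catalog: an anatomical region with its expected
#' labeled-neuron density, soma size range, brightness, and the probability
#' that a soma carries a thick dendritic-trunk artifact.
#'
#' @param region_id positive integer, unique within a catalog; 0 is reserved
#'   for background (outside brain).
#' @param name region name.
#' @param neuron_intensity expected labeled neurons per mm^3.
#' @param soma_semi_axes_range `(min, max)` of the ellipsoid semi-axes in um;
#'   each soma's three semi-axes are drawn independently from this range.
#' @param peak_brightness mean peak intensity above background (arbitrary
#'   16-bit units).
#' @param trunk_probability fraction of somas that emit a dendritic-trunk
#'   cylinder.
#' @param group parent anatomical group used for roll-up statistics.
#' @param parent_area,layer_index optional: mark this region as an ordered
#'   cortical layer of `parent_area` (used by layer profiles).
#' @return A one-row data.frame; rbind rows to form a catalog.
#' @seealso [build_label_volume()], [place_neurons()], [render_scene()]
#' @export
region_spec <- function(region_id, name, neuron_intensity,
                        soma_semi_axes_range = c(3.5, 6),
                        peak_brightness = 3000, trunk_probability = 0,
                        group = "brain", parent_area = NA_character_,
                        layer_index = NA_integer_) {
  region_id <- as.integer(region_id)
  if (is.na(region_id) || region_id <= 0L)
    stop("`region_id` must be a positive integer (0 is reserved for background)")
  if (!is.finite(neuron_intensity) || neuron_intensity < 0)
    stop("`neuron_intensity` must be a finite non-negative density (cells/mm^3)")
  r <- as.numeric(soma_semi_axes_range)
  if (length(r) != 2L || any(r <= 0) || r[1] > r[2])
    stop("`soma_semi_axes_range` must be (min, max) with 0 < min <= max")
  if (trunk_probability < 0 || trunk_probability > 1)
    stop("`trunk_probability` must be in [0, 1]")
  data.frame(region_id = region_id, name = name,
             neuron_intensity = as.numeric(neuron_intensity),
             semi_min_um = r[1], semi_max_um = r[2],
             peak = as.numeric(peak_brightness),
             trunk_prob = as.numeric(trunk_probability),
             group = group, parent_area = parent_area,
             layer_index = as.integer(layer_index),
             stringsAsFactors = FALSE)
}

as_region_catalog <- function(catalog) {
  if (!is.data.frame(catalog) || !all(c("region_id", "name") %in% names(catalog)))
    stop("catalog must be a data.frame with at least region_id and name")
  if (anyDuplicated(catalog$region_id))
    stop("duplicated region_id in catalog")
  catalog
}

catalog_row <- function(catalog, region_id) {
  i <- match(region_id, catalog$region_id)
  if (is.na(i)) stop(sprintf("region_id %d not in catalog", region_id))
  catalog[i, , drop = FALSE]
}

#' Write / read a region catalog
#'
#' Catalogs are stored as structured YAML keyed by region id, so they stay
#' human-editable and diffable.
#'
#' @param catalog a region catalog data.frame (rbind of [region_spec()] rows).
#' @param path file path.
#' @return `read_region_catalog` returns the catalog data.frame.
#' @export
write_region_catalog <- function(catalog, path) {
  catalog <- as_region_catalog(catalog)
  lst <- lapply(seq_len(nrow(catalog)), function(i) {
    r <- catalog[i, ]
    list(region_id = r$region_id, name = r$name,
         neuron_intensity = r$neuron_intensity,
         semi_min_um = r$semi_min_um, semi_max_um = r$semi_max_um,
         peak = r$peak, trunk_prob = r$trunk_prob, group = r$group,
         parent_area = if (is.na(r$parent_area)) NULL else r$parent_area,
         layer_index = if (is.na(r$layer_index)) NULL else r$layer_index)
  })
  names(lst) <- as.character(catalog$region_id)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_region_catalog
#' @export
read_region_catalog <- function(path) {
  lst <- yaml::read_yaml(path)
  rows <- lapply(lst, function(r) {
    region_spec(r$region_id, r$name, r$neuron_intensity,
                c(r$semi_min_um, r$semi_max_um), r$peak, r$trunk_prob,
                group = if (is.null(r$group)) "brain" else r$group,
                parent_area = if (is.null(r$parent_area)) NA_character_ else r$parent_area,
                layer_index = if (is.null(r$layer_index)) NA_integer_ else r$layer_index)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
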