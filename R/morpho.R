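#' Sample one feature cube per region
#'
#' For each requested region, places one axis-aligned cube of edge
#' `cube_um` uniformly at random fully inside the region and returns the
#' six morphology features of the neurons whose centers fall in the cube,
#' tagged by region. Regions too small for the cube are skipped with a
#' warning. Placement is deterministic given the seed.
#'
#' @param neurons assigned neuron table carrying the morphology feature
#'   columns (`r_longest`, `r_shortest`, `r_average`, `surface_um2`,
#'   `volume_um3`, `ratio`).
#' @param labels a `region_label_volume`.
#' @param geometry a [voxel_geometry()].
#' @param region_ids regions to sample; default all catalog regions.
#' @param cube_um cube edge in um (default 200).
#' @param seed integer seed.
#' @param max_tries placement attempts per region before skipping it.
#' @return Feature matrix data.frame: `region_id` plus the six feature
#'   columns, one row per sampled neuron.
#' @export
sample_region_cubes <- function(neurons, labels, geometry,
                                region_ids = labels$catalog$region_id,
                                cube_um = 200, seed = 1L, max_tries = 100L) {
  arr <- labels$labels
  d <- dim(arr)
  feats <- c("r_longest", "r_shortest", "r_average", "surface_um2",
             "volume_um3", "ratio")
  missing <- setdiff(feats, names(neurons))
  if (length(missing))
    stop("neuron table lacks feature column(s): ",
         paste(missing, collapse = ", "))
  edge <- c(geometry$size_x, geometry$size_y, geometry$size_z)
  with_seed(seed, {
    out <- list()
    for (id in region_ids) {
      vox <- which(arr == id)
      if (!length(vox)) { warning(sprintf("region %d absent; skipped", id)); next }
      ai <- arrayInd(vox, d)  # (z, y, x) 1-based
      lo_um <- c(min(ai[, 3]) - 1, min(ai[, 2]) - 1, min(ai[, 1]) - 1) * edge
      hi_um <- c(max(ai[, 3]), max(ai[, 2]), max(ai[, 1])) * edge
      if (any(hi_um - lo_um < cube_um)) {
        warning(sprintf("region %d smaller than the %g um cube; skipped",
                        id, cube_um))
        next
      }
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        corner <- lo_um + stats::runif(3) * (hi_um - lo_um - cube_um)
        # probe: corners and center must carry the region's label; probes
        # are inset so a cube flush against the region face still counts
        eps <- 1e-6
        probes <- rbind(corner + cube_um / 2,
                        t(corner + t(expand.grid(c(eps, cube_um - eps),
                                                 c(eps, cube_um - eps),
                                                 c(eps, cube_um - eps)))))
        pv <- um_to_voxel(probes, geometry)
        pv[] <- pmin(pmax(pv, 0L), matrix(rev(d) - 1L, nrow(pv), 3, byrow = TRUE))
        labs <- arr[cbind(pv[, 3] + 1L, pv[, 2] + 1L, pv[, 1] + 1L)]
        if (all(labs == id)) { placed <- TRUE; break }
      }
      if (!placed) {
        warning(sprintf("no %g um cube fits fully inside region %d; skipped",
                        cube_um, id))
        next
      }
      inside <- neurons$x_um >= corner[1] & neurons$x_um < corner[1] + cube_um &
        neurons$y_um >= corner[2] & neurons$y_um < corner[2] + cube_um &
        neurons$z_um >= corner[3] & neurons$z_um < corner[3] + cube_um
      sub <- neurons[inside, feats, drop = FALSE]
      if (nrow(sub))
        out[[length(out) + 1L]] <- cbind(region_id = id, sub)
    }
    if (!length(out))
      return(cbind(data.frame(region_id = integer(0)),
                   stats::setNames(as.data.frame(matrix(numeric(0), 0, 6)),
                                   feats)))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' PCA of the six soma features to two components
#'
#' Regions with fewer than `min_cells` neurons are excluded first (the
#' dispersion and test statistics are undefined below that). Features are
#' standardized (zero mean, unit variance) across the pooled matrix,
#' decomposed by PCA, and the top-2 scores are min-max normalized to [0, 1]
#' over the pooled rows. The sign convention fixes each loading's
#' largest-magnitude entry positive, making the component orientation
#' deterministic.
#'
#' @param features feature matrix from [sample_region_cubes()] (column
#'   `region_id` plus the six features).
#' @param min_cells minimum neurons per region (default 3).
#' @return A `pca_space`: list with `loadings` (p x 2), `explained`
#'   (variance fractions of all components), `scores` (data.frame:
#'   `region_id`, `pc1`, `pc2` in [0, 1]), `dropped_regions`,
#'   `dropped_features`.
#' @export
pca_two_components <- function(features, min_cells = 3L) {
  tab <- table(features$region_id)
  drop_reg <- as.integer(names(tab)[tab < min_cells])
  if (length(drop_reg)) {
    warning(sprintf("excluding region(s) with < %d neurons in the cube: %s",
                    min_cells, paste(drop_reg, collapse = ", ")))
    features <- features[!features$region_id %in% drop_reg, , drop = FALSE]
  }
  if (nrow(features) < 3) stop("need at least 3 rows for PCA")
  featcols <- setdiff(names(features), "region_id")
  x <- as.matrix(features[, featcols])
  if (any(!is.finite(x))) stop("feature matrix contains non-finite values")
  sds <- apply(x, 2, stats::sd)
  drop_feat <- featcols[sds == 0]
  if (length(drop_feat)) {
    warning("dropping zero-variance feature column(s): ",
            paste(drop_feat, collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  if (ncol(x) < 2) stop("fewer than 2 usable feature columns")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  if (ncol(pc$rotation) < 2) stop("fewer than 2 usable components")
  load2 <- pc$rotation[, 1:2, drop = FALSE]
  scores <- pc$x[, 1:2, drop = FALSE]
  for (k in 1:2) {
    j <- which.max(abs(load2[, k]))
    if (load2[j, k] < 0) { load2[, k] <- -load2[, k]; scores[, k] <- -scores[, k] }
  }
  norm01 <- function(v) {
    r <- range(v)
    if (r[2] > r[1]) (v - r[1]) / (r[2] - r[1]) else rep(0.5, length(v))
  }
  structure(list(
    loadings = load2,
    explained = pc$sdev^2 / sum(pc$sdev^2),
    scores = data.frame(region_id = features$region_id,
                        pc1 = norm01(scores[, 1]), pc2 = norm01(scores[, 2])),
    dropped_regions = drop_reg,
    dropped_features = drop_feat), class = "pca_space")
}

#' @export
print.pca_space <- function(x, ...) {
  cat(sprintf("pca_space: %d neurons, %d regions; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), length(unique(x$scores$region_id)),
              100 * x$explained[1], 100 * x$explained[2]))
  invisible(x)
}

#' Concentration filtering of normalized scores
#'
#' Per region, takes the mean point in the normalized two-component space
#' as origin and keeps the `floor(fraction * n)` rows closest to it by
#' Euclidean distance, eliminating deviation points before dispersion and
#' significance statistics. Distance ties break by stable row order.
#'
#' @param scores scores data.frame from [pca_two_components()] (`region_id`,
#'   `pc1`, `pc2`), or the scores of a single region.
#' @param fraction fraction to keep, in (0, 1]; default 0.8.
#' @return The concentrated subset (same columns), with per-region totals
#'   attached as attribute `"n_total"`.
#' @export
concentrate <- function(scores, fraction = 0.8) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("`fraction` must be in (0, 1]")
  if (!"region_id" %in% names(scores)) scores$region_id <- 0L
  parts <- split(seq_len(nrow(scores)), scores$region_id)
  keep <- unlist(lapply(parts, function(ii) {
    n <- length(ii)
    k <- floor(fraction * n)
    if (k < 1) return(integer(0))
    mu <- c(mean(scores$pc1[ii]), mean(scores$pc2[ii]))
    d <- sqrt((scores$pc1[ii] - mu[1])^2 + (scores$pc2[ii] - mu[2])^2)
    ii[order(d, seq_along(ii))[seq_len(k)]]
  }), use.names = FALSE)
  keep <- sort(keep)
  out <- scores[keep, , drop = FALSE]
  attr(out, "n_total") <- vapply(parts, length, integer(1))
  rownames(out) <- NULL
  out
}

#' Intra-region dispersion of the two main features
#'
#' Sample standard deviation (n - 1 denominator) of each normalized
#' component's scores on the concentrated subset; lower SD means more
#' uniform soma morphology within the region.
#'
#' @param concentrated concentrated scores from [concentrate()].
#' @return data.frame: `region_id`, `n_total`, `n_concentrated`, `sd_pc1`,
#'   `sd_pc2`, `flags` (`sd_undefined` for single-row subsets).
#' @export
region_similarity <- function(concentrated) {
  totals <- attr(concentrated, "n_total")
  parts <- split(concentrated, concentrated$region_id)
  out <- do.call(rbind, lapply(parts, function(p) {
    n <- nrow(p)
    data.frame(region_id = p$region_id[1],
               n_total = if (!is.null(totals))
                 totals[[as.character(p$region_id[1])]] else n,
               n_concentrated = n,
               sd_pc1 = if (n >= 2) stats::sd(p$pc1) else NA_real_,
               sd_pc2 = if (n >= 2) stats::sd(p$pc2) else NA_real_,
               flags = if (n < 2) "sd_undefined" else "")
  }))
  rownames(out) <- NULL
  out
}

#' Pairwise region significance tests on the two main features
#'
#' For every unordered pair of regions and each normalized component, a
#' one-way two-group analysis-of-variance F test; significant iff
#' p < `alpha`. No multiple-testing correction is applied by default
#' (`p_adjust = "none"`); any [stats::p.adjust()] method can be requested.
#' A pair is reported "not different" iff both components are
#' non-significant. Degenerate inputs (zero variance in both groups with
#' equal means, or a region compared with itself) give p = 1 by convention.
#'
#' @param concentrated concentrated scores from [concentrate()].
#' @param alpha significance level (default 0.05).
#' @param p_adjust multiple-testing correction method (default `"none"`).
#' @return List with `tests` (data.frame: `region_a`, `region_b`,
#'   `component`, `F`, `p`, `significant`) and `pairs` (per-pair
#'   `not_different` flag).
#' @export
pairwise_tests <- function(concentrated, alpha = 0.05, p_adjust = "none") {
  ids <- sort(unique(concentrated$region_id))
  usable <- ids[vapply(ids, function(id)
    sum(concentrated$region_id == id) >= 2, logical(1))]
  if (length(usable) < 2)
    stop("need at least 2 regions with >= 2 concentrated rows")
  combs <- utils::combn(usable, 2)
  rows <- list()
  for (j in seq_len(ncol(combs))) {
    a <- combs[1, j]; b <- combs[2, j]
    for (comp in c("pc1", "pc2")) {
      va <- concentrated[[comp]][concentrated$region_id == a]
      vb <- concentrated[[comp]][concentrated$region_id == b]
      res <- anova_two_group(va, vb)
      rows[[length(rows) + 1L]] <- data.frame(
        region_a = a, region_b = b, component = comp,
        F = res$F, p = res$p)
    }
  }
  tests <- do.call(rbind, rows)
  tests$p <- stats::p.adjust(tests$p, method = p_adjust)
  tests$significant <- tests$p < alpha
  pairs <- do.call(rbind, lapply(seq_len(ncol(combs)), function(j) {
    sel <- tests$region_a == combs[1, j] & tests$region_b == combs[2, j]
    data.frame(region_a = combs[1, j], region_b = combs[2, j],
               not_different = !any(tests$significant[sel]))
  }))
  list(tests = tests, pairs = pairs)
}

# one-way ANOVA for two groups via the standard equal-variance F test;
# degenerate zero-variance cases resolved by convention
anova_two_group <- function(va, vb) {
  ssw <- sum((va - mean(va))^2) + sum((vb - mean(vb))^2)
  if (ssw == 0) {
    if (isTRUE(all.equal(mean(va), mean(vb))))
      return(list(F = 0, p = 1))
    return(list(F = Inf, p = 0))
  }
  ft <- stats::oneway.test(v ~ g,
                           data = data.frame(v = c(va, vb),
                                             g = rep(c("a", "b"),
                                                     c(length(va), length(vb)))),
                           var.equal = TRUE)
  list(F = unname(ft$statistic), p = unname(ft$p.value))
}

#' Full soma-morphology similarity workflow
#'
#' Chains [sample_region_cubes()], [pca_two_components()], [concentrate()],
#' [region_similarity()] and [pairwise_tests()].
#'
#' @inheritParams sample_region_cubes
#' @inheritParams concentrate
#' @inheritParams pairwise_tests
#' @param min_cells minimum neurons per region, see [pca_two_components()].
#' @return List: `features`, `pca`, `concentrated`, `similarity`, `tests`.
#' @export
morphology_workflow <- function(neurons, labels, geometry,
                                region_ids = labels$catalog$region_id,
                                cube_um = 200, fraction = 0.8,
                                min_cells = 3L, alpha = 0.05, seed = 1L) {
  features <- sample_region_cubes(neurons, labels, geometry, region_ids,
                                  cube_um = cube_um, seed = seed)
  pca <- pca_two_components(features, min_cells = min_cells)
  conc <- concentrate(pca$scores, fraction = fraction)
  sim <- region_similarity(conc)
  tst <- if (length(unique(conc$region_id)) >= 2)
    pairwise_tests(conc, alpha = alpha) else NULL
  list(features = features, pca = pca, concentrated = conc,
       similarity = sim, tests = tst)
}
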