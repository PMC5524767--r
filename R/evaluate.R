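#' Match detections to ground truth by optimal assignment
#'
#' One-to-one matching between truth and detected centers that maximizes
#' the number of pairs within `tolerance_um` and, among those, minimizes
#' total matched distance (optimal bipartite assignment on the thresholded
#' distance graph, solved by the Hungarian algorithm on a padded cost
#' matrix). Optimal -- not greedy -- assignment is deterministic and
#' resolves crossed configurations correctly.
#'
#' @param truth,detected n x 3 matrices (or data.frames with `x_um`,
#'   `y_um`, `z_um`) of centers in um.
#' @param tolerance_um maximum center distance for a correct detection;
#'   default 5 um, about one soma radius.
#' @return List with `pairs` (data.frame: `truth_idx`, `det_idx`,
#'   `dist_um`), `unmatched_truth`, `unmatched_detected` (index vectors).
#' @export
match_detections <- function(truth, detected, tolerance_um = 5) {
  if (!is.numeric(tolerance_um) || tolerance_um <= 0)
    stop("`tolerance_um` must be > 0")
  tm <- as_xyz(truth); dm <- as_xyz(detected)
  nt <- nrow(tm); nd <- nrow(dm)
  empty <- list(pairs = data.frame(truth_idx = integer(0),
                                   det_idx = integer(0), dist_um = numeric(0)),
                unmatched_truth = seq_len(nt), unmatched_detected = seq_len(nd))
  if (nt == 0 || nd == 0) return(empty)
  dmat <- sqrt(outer(tm[, 1], dm[, 1], "-")^2 +
               outer(tm[, 2], dm[, 2], "-")^2 +
               outer(tm[, 3], dm[, 3], "-")^2)
  # padded square cost: real pair if within tolerance; dummies absorb
  # unmatched points. The unmatch penalty exceeds any achievable distance
  # sum, so cardinality is maximized first, then total distance.
  n <- nt + nd
  pen <- (n + 1) * tolerance_um
  big <- 4 * pen * (n + 1)
  cost <- matrix(0, n, n)                     # dummy-dummy cells cost 0
  cost[seq_len(nt), seq_len(nd)] <- ifelse(dmat <= tolerance_um, dmat, big)
  cost[seq_len(nt), nd + seq_len(nt)] <- pen  # truth left unmatched
  cost[nt + seq_len(nd), seq_len(nd)] <- pen  # detection left unmatched
  assign <- cpp_hungarian(cost)
  ti <- seq_len(nt)
  di <- assign[ti]
  ok <- di >= 1 & di <= nd
  ok[ok] <- dmat[cbind(ti[ok], di[ok])] <= tolerance_um
  pairs <- data.frame(truth_idx = ti[ok], det_idx = di[ok],
                      dist_um = dmat[cbind(ti[ok], di[ok])])
  list(pairs = pairs,
       unmatched_truth = setdiff(seq_len(nt), pairs$truth_idx),
       unmatched_detected = setdiff(seq_len(nd), pairs$det_idx))
}

as_xyz <- function(x) {
  if (is.data.frame(x)) as.matrix(x[, c("x_um", "y_um", "z_um")])
  else {
    m <- as.matrix(x)
    if (length(m) == 0) matrix(numeric(0), 0, 3) else m
  }
}

#' Recall and precision of a matching
#'
#' With B1 ground-truth neurons, B2 detections, and B correctly detected
#' (matched) neurons: recall R = B/B1 and precision P = B/B2. Metrics with
#' a zero denominator are flagged undefined (NA).
#'
#' @param matching a [match_detections()] result, or the count B directly.
#' @param B1,B2 ground-truth and detected totals.
#' @return An `eval_result`: list with `B1`, `B2`, `B`, `recall`,
#'   `precision`.
#' @export
score_detection <- function(matching, B1, B2) {
  B <- if (is.list(matching)) nrow(matching$pairs) else as.integer(matching)
  if (B > min(B1, B2)) stop("B cannot exceed min(B1, B2)")
  structure(list(B1 = B1, B2 = B2, B = B,
                 recall = if (B1 > 0) B / B1 else NA_real_,
                 precision = if (B2 > 0) B / B2 else NA_real_),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("eval_result: B1 = %d, B2 = %d, B = %d; recall %s, precision %s\n",
              x$B1, x$B2, x$B,
              if (is.na(x$recall)) "undefined" else sprintf("%.1f%%", 100 * x$recall),
              if (is.na(x$precision)) "undefined" else sprintf("%.1f%%", 100 * x$precision)))
  invisible(x)
}

#' Randomized evaluation-cube protocol
#'
#' Places `n_cubes` cubes of edge `cube_um` uniformly at random fully
#' inside the physical extent, restricts both point sets to each cube
#' (centers-inside rule, half-open bounds), matches them, and reports
#' per-cube recall and precision plus the protocol summary (highest,
#' lowest and mean of each).
#'
#' @param truth,detected center tables or n x 3 matrices in um.
#' @param extent_um physical extent `(x, y, z)` of the evaluated volume in
#'   um (e.g. `extent_um(geometry)`).
#' @param n_cubes number of cubes (default 12).
#' @param cube_um cube edge (default 300).
#' @param tolerance_um matching tolerance, see [match_detections()].
#' @param seed integer seed for cube placement.
#' @return List with `per_cube` (data.frame: cube id, corner, B1, B2, B,
#'   recall, precision) and `summary` (min/max/mean of recall and
#'   precision over cubes where they are defined).
#' @export
evaluate_cubes <- function(truth, detected, extent_um, n_cubes = 12L,
                           cube_um = 300, tolerance_um = 5, seed = 1L) {
  tm <- as_xyz(truth); dm <- as_xyz(detected)
  ext <- as.numeric(extent_um)
  if (any(ext < cube_um))
    stop(sprintf("volume extent (%s um) smaller than the %g um evaluation cube",
                 paste(round(ext, 1), collapse = " x "), cube_um))
  with_seed(seed, {
    rows <- lapply(seq_len(n_cubes), function(i) {
      corner <- stats::runif(3) * (ext - cube_um)
      tin <- tm[, 1] >= corner[1] & tm[, 1] < corner[1] + cube_um &
        tm[, 2] >= corner[2] & tm[, 2] < corner[2] + cube_um &
        tm[, 3] >= corner[3] & tm[, 3] < corner[3] + cube_um
      din <- dm[, 1] >= corner[1] & dm[, 1] < corner[1] + cube_um &
        dm[, 2] >= corner[2] & dm[, 2] < corner[2] + cube_um &
        dm[, 3] >= corner[3] & dm[, 3] < corner[3] + cube_um
      m <- match_detections(tm[tin, , drop = FALSE], dm[din, , drop = FALSE],
                            tolerance_um)
      s <- score_detection(m, sum(tin), sum(din))
      data.frame(cube = i, x0_um = corner[1], y0_um = corner[2],
                 z0_um = corner[3], B1 = s$B1, B2 = s$B2, B = s$B,
                 recall = s$recall, precision = s$precision)
    })
    per_cube <- do.call(rbind, rows)
    summ <- function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) c(min = NA_real_, max = NA_real_, mean = NA_real_)
      else c(min = min(v), max = max(v), mean = mean(v))
    }
    list(per_cube = per_cube,
         summary = list(recall = summ(per_cube$recall),
                        precision = summ(per_cube$precision)))
  })
}
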