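# Internal helpers shared across modules.

# Evaluate `expr` under a locally fixed RNG state. The generator kind is
# pinned so results do not depend on the session's RNG settings; the caller's
# RNG state is restored on exit, making every seeded stage a pure function of
# (parameters, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    suppressWarnings(set.seed(seed, kind = "Mersenne-Twister",
                              normal.kind = "Inversion", sample.kind = "Rejection"))
  }
  expr
}

# stable child seed for a named sub-stage, kept below 2^31
child_seed <- function(seed, salt) {
  (as.numeric(seed) * 48271 + salt) %% 2147483629
}

stopifnot_volume <- function(vol) {
  if (!is.array(vol) || length(dim(vol)) != 3L)
    stop("expected a 3D array with dim = (nz, ny, nx)")
}

# uniform random rotation matrices (n x 9 row-major, world->body), drawn from
# random axis-angle; consumed by the renderer
random_rotations <- function(n) {
  if (n == 0L) return(matrix(numeric(0), 0, 9))
  out <- matrix(0, n, 9)
  for (i in seq_len(n)) {
    ax <- stats::rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    th <- stats::runif(1, 0, 2 * pi)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
                byrow = TRUE)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    out[i, ] <- as.vector(t(R))
  }
  out
}
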