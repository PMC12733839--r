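#' @keywords internal
#' @importFrom stats rnorm runif rbinom dnorm sd plogis qt qnorm
"_PACKAGE"

## Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.  All randomness in the package funnels
# through this so that user sessions are never perturbed.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic derivation of sub-seeds from a base seed, kept inside the
# 32-bit integer range.
derive_seed <- function(base_seed, ...) {
  key <- paste(c(base_seed, ...), collapse = "/")
  h <- utils::head(strtoi(substring(digest_hex(key), 1:7, 1:7), 16L), 7L)
  as.integer(sum(h * 16L^(0:6)) %% .Machine$integer.max)
}

# Tiny stable string hash (FNV-1a, hex) -- used only for seed derivation and
# therefore implemented locally rather than pulling in a digest dependency.
digest_hex <- function(x) {
  bytes <- utils::head(utf8ToInt(x), 512L)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# floor(x + 0.5): round-half-up, the package-wide quantization convention.
round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Vectorized bilinear sampling of matrix `m` at fractional 0-based (row, col)
# coordinates, with clamped-edge padding.  Backs resample_to() and the
# augmentation rotations so both share one geometry convention.
bilinear_sample <- function(m, rows, cols) {
  nr <- nrow(m); nc <- ncol(m)
  rows <- clamp(rows, 0, nr - 1)
  cols <- clamp(cols, 0, nc - 1)
  r0 <- floor(rows); c0 <- floor(cols)
  r1 <- pmin(r0 + 1, nr - 1); c1 <- pmin(c0 + 1, nc - 1)
  fr <- rows - r0; fc <- cols - c0
  v00 <- m[cbind(r0 + 1, c0 + 1)]
  v10 <- m[cbind(r1 + 1, c0 + 1)]
  v01 <- m[cbind(r0 + 1, c1 + 1)]
  v11 <- m[cbind(r1 + 1, c1 + 1)]
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  invisible(x)
}
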