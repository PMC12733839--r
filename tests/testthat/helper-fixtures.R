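# Shared fixtures and independent reference implementations used as oracles.

# Desk-scale network configuration: small enough to train inside a test run.
tiny_net_cfg <- function(seed = 1L, input_size = 32) {
  param_net_config(conv_channels = c(8, 12, 16, 24, 32),
                   fc_widths = c(128, 64, 16, 3),
                   dropout_rate = 0.2, pooled_size = 2,
                   input_size = input_size, seed = seed)
}

# Even smaller: for contract tests where no learning is involved.
micro_net_cfg <- function(seed = 1L) {
  param_net_config(conv_channels = c(2, 2, 3, 3, 4),
                   fc_widths = c(8, 6, 4, 3), dropout_rate = 0,
                   pooled_size = 2, input_size = 32, seed = seed)
}

rand_uint8 <- function(n, m = n, seed = 1L) {
  set.seed(seed)
  matrix(sample(0L:255L, n * m, replace = TRUE), n, m)
}

# Brute-force EME: explicit double loop over blocks, independent of the
# vectorized implementation.
eme_reference <- function(img8, block_size = 8) {
  nbr <- nrow(img8) %/% block_size
  nbc <- ncol(img8) %/% block_size
  vals <- c()
  for (i in seq_len(nbr)) for (j in seq_len(nbc)) {
    blk <- img8[((i - 1) * block_size + 1):(i * block_size),
                ((j - 1) * block_size + 1):(j * block_size)]
    vals <- c(vals, 20 * log10((max(blk) + 1) / (min(blk) + 1)))
  }
  mean(vals)
}

# Direct per-pixel CLAHE reference for the same dialect: reflection padding
# to a full tile grid, relative clip with single-pass uniform
# redistribution, identity mapping for single-level tiles, bilinear
# interpolation between clamped tile centers.  Written as plain loops.
clahe_reference <- function(img8, tiles = c(8, 8), clip_limit = 1,
                            n_bins = 256) {
  tr <- tiles[1]; tc <- tiles[2]
  H <- nrow(img8); W <- ncol(img8)
  th <- ceiling(H / tr); tw <- ceiling(W / tc)
  m <- img8
  if (th * tr > H) m <- rbind(m, m[H:(2 * H - th * tr + 1), , drop = FALSE])
  if (tw * tc > W) m <- cbind(m, m[, W:(2 * W - tw * tc + 1), drop = FALSE])
  lut_for <- function(i, j) {
    vals <- as.vector(m[((i - 1) * th + 1):(i * th),
                        ((j - 1) * tw + 1):(j * tw)])
    if (max(vals) == min(vals)) return(0:255)
    bins <- pmin(floor(vals / 256 * n_bins), n_bins - 1)
    h <- tabulate(bins + 1, nbins = n_bins)
    if (is.finite(clip_limit)) {
      cl <- clip_limit * length(vals) / n_bins
      hc <- pmin(h, cl)
      h <- hc + (sum(h) - sum(hc)) / n_bins
    }
    cdf <- cumsum(h) / length(vals)
    vbin <- pmin(floor((0:255) / 256 * n_bins), n_bins - 1)
    floor(cdf[vbin + 1] * 255 + 0.5)
  }
  luts <- array(0, c(tr, tc, 256))
  for (i in seq_len(tr)) for (j in seq_len(tc)) luts[i, j, ] <- lut_for(i, j)
  out <- matrix(0L, H, W)
  for (y in seq_len(H)) for (x in seq_len(W)) {
    ty <- min(max((y - 0.5) / th - 0.5, 0), tr - 1)
    tx <- min(max((x - 0.5) / tw - 0.5, 0), tc - 1)
    y0 <- floor(ty); x0 <- floor(tx)
    y1 <- min(y0 + 1, tr - 1); x1 <- min(x0 + 1, tc - 1)
    wy <- ty - y0; wx <- tx - x0
    v <- img8[y, x] + 1
    val <- (1 - wy) * (1 - wx) * luts[y0 + 1, x0 + 1, v] +
           wy * (1 - wx) * luts[y1 + 1, x0 + 1, v] +
           (1 - wy) * wx * luts[y0 + 1, x1 + 1, v] +
           wy * wx * luts[y1 + 1, x1 + 1, v]
    out[y, x] <- min(max(floor(val + 0.5), 0), 255)
  }
  out
}

# Textbook paired t statistic, written from the formula.
ttest_reference <- function(x, y) {
  d <- y - x
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), n - 1), df = n - 1)
}

# A small cached pool of phantoms shared across tests in one file run.
local_phantom <- function(stage = "chronic", size = 64, seed = 3, ...) {
  make_phantom(phantom_spec(stage, image_size = size, seed = seed, ...))
}

STAGES_local <- function() c("hyperacute", "acute", "subacute", "chronic",
                             "normal")

# Rebuild a phantom_spec with some fields replaced (re-validates invariants).
modifyList2 <- function(spec, ...) {
  new <- utils::modifyList(unclass(spec), list(...))
  do.call(phantom_spec, c(list(stage = new$stage),
                          new[setdiff(names(new), "stage")]))
}

clampCT <- function(x) pmin(pmax(x, -1024), 3071)

check8 <- function(m) { storage.mode(m) <- "integer"; m }
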