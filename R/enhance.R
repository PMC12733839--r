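## Contrast enhancement: the constrained linear HU transform, CLAHE with a
## tunable clip limit, their composition (the enhancement pipeline that the
## parameter network optimizes), and six classical enhancers used by the
## comparison harness.

# Hard parameter ranges of the enhancement triple.  These ranges are part of
# the method: the network's outputs are squashed into them and out-of-range
# values are rejected everywhere else.
PARAM_RANGES <- list(alpha = c(0.5, 2.0), beta = c(-5, 5),
                     gamma_clip = c(0.1, 2.0))

param_midpoints <- function() vapply(PARAM_RANGES, mean, 0)
param_halfwidths <- function() vapply(PARAM_RANGES, function(r) diff(r) / 2, 0)

#' The enhancement parameter triple
#'
#' Slope and intercept of the linear HU transform plus the CLAHE clip
#' limit, with hard range invariants: `alpha` in \[0.5, 2\], `beta` in
#' \[-5, 5\] HU, `gamma_clip` in \[0.1, 2\] (relative to the mean histogram
#' bin count).
#'
#' @param alpha linear-transform slope (dimensionless).
#' @param beta linear-transform intercept (HU).
#' @param gamma_clip CLAHE clip limit (dimensionless, relative convention).
#' @return an object of class `enhancement_params`.
#' @export
enhancement_params <- function(alpha, beta, gamma_clip) {
  v <- c(alpha = alpha, beta = beta, gamma_clip = gamma_clip)
  for (nm in names(PARAM_RANGES)) {
    r <- PARAM_RANGES[[nm]]
    if (!is.finite(v[[nm]]) || v[[nm]] < r[1] || v[[nm]] > r[2])
      stop(sprintf("%s = %g outside its allowed range [%g, %g]",
                   nm, v[[nm]], r[1], r[2]), call. = FALSE)
  }
  structure(as.list(v), class = "enhancement_params")
}

#' @export
print.enhancement_params <- function(x, ...) {
  cat(sprintf("<enhancement_params alpha=%.4f beta=%.4f gamma=%.4f>\n",
              x$alpha, x$beta, x$gamma_clip))
  invisible(x)
}

#' Constrained linear HU transform
#'
#' `HU' = alpha * HU + beta`, pixelwise, in HU space (before windowing and
#' quantization).  Parameters outside the method's ranges are rejected.
#'
#' @param img an [hu_image] or numeric matrix.
#' @param alpha slope in \[0.5, 2\].
#' @param beta intercept in \[-5, 5\] HU.
#' @return transformed [hu_image].
#' @export
linear_transform <- function(img, alpha, beta) {
  enhancement_params(alpha, beta, 1)   # range validation for (alpha, beta)
  px <- as_hu_pixels(img)
  hu_update(img, alpha * px + beta,
            sprintf("linear_transform(%.4g, %.4g)", alpha, beta))
}

#' CLAHE configuration
#'
#' Dialect defaults: an 8 x 8 tile grid, 256 histogram bins, and a clip
#' limit expressed relative to the mean bin count (`clip_limit` times
#' `tile_pixels / n_bins`), which keeps the \[0.1, 2\] clip range meaningful
#' across tile sizes.
#'
#' @param tiles integer length-2 tile grid (rows, cols), each >= 1.
#' @param clip_limit positive relative clip factor; `Inf` disables clipping
#'   (plain AHE).
#' @param n_bins histogram bins (>= 2).
#' @return an object of class `clahe_config`.
#' @export
clahe_config <- function(tiles = c(8, 8), clip_limit = 1, n_bins = 256) {
  if (length(tiles) == 1) tiles <- c(tiles, tiles)
  tiles <- as.integer(tiles)
  if (any(tiles < 1)) stop("tiles must be >= 1 x 1", call. = FALSE)
  if (!is.finite(n_bins) || n_bins < 2) stop("n_bins must be >= 2",
                                             call. = FALSE)
  if (is.na(clip_limit) || clip_limit <= 0)
    stop("clip_limit must be positive", call. = FALSE)
  structure(list(tiles = tiles, clip_limit = clip_limit,
                 n_bins = as.integer(n_bins)), class = "clahe_config")
}

# Cache of per-geometry interpolation indices (tile ids and bilinear
# weights per pixel), keyed by image and grid dimensions.
.clahe_geom_cache <- new.env(parent = emptyenv())

clahe_geometry <- function(H, W, tr, tc, th, tw) {
  key <- paste(H, W, tr, tc, th, tw, sep = "x")
  g <- .clahe_geom_cache[[key]]
  if (!is.null(g)) return(g)
  ty <- clamp((seq_len(H) - 0.5) / th - 0.5, 0, tr - 1)
  tx <- clamp((seq_len(W) - 0.5) / tw - 0.5, 0, tc - 1)
  y0 <- floor(ty); x0 <- floor(tx)
  y1 <- pmin(y0 + 1, tr - 1); x1 <- pmin(x0 + 1, tc - 1)
  wy <- ty - y0; wx <- tx - x0
  Y0 <- matrix(y0, H, W); Y1 <- matrix(y1, H, W)
  X0 <- matrix(x0, H, W, byrow = TRUE); X1 <- matrix(x1, H, W, byrow = TRUE)
  WY <- matrix(wy, H, W); WX <- matrix(wx, H, W, byrow = TRUE)
  g <- list(
    t00 = Y0 + tr * X0 + 1L, t10 = Y1 + tr * X0 + 1L,
    t01 = Y0 + tr * X1 + 1L, t11 = Y1 + tr * X1 + 1L,
    w00 = (1 - WY) * (1 - WX), w10 = WY * (1 - WX),
    w01 = (1 - WY) * WX, w11 = WY * WX)
  .clahe_geom_cache[[key]] <- g
  g
}

# Equalization lookup table (length 256 -> [0, 255]) from an intensity
# vector.  A tile with a single intensity level has no contrast to
# redistribute and maps to itself (identity), the package's degenerate-tile
# convention.
clahe_tile_lut <- function(vals, clip_limit, n_bins) {
  if (max(vals) == min(vals)) return(0:255)
  bins <- pmin(floor(vals / 256 * n_bins), n_bins - 1L)
  h <- tabulate(bins + 1L, nbins = n_bins)
  if (is.finite(clip_limit)) {
    ceiling_count <- clip_limit * length(vals) / n_bins
    hc <- pmin(h, ceiling_count)
    h <- hc + (sum(h) - sum(hc)) / n_bins   # single-pass uniform spread
  }
  cdf <- cumsum(h) / length(vals)
  # LUT over the full 8-bit domain: value v falls in bin floor(v/256*n_bins)
  vbin <- pmin(floor((0:255) / 256 * n_bins), n_bins - 1L)
  round_half_up(cdf[vbin + 1L] * 255)
}

#' Contrast-limited adaptive histogram equalization
#'
#' The image is padded by edge reflection so the tile grid divides it
#' evenly; each tile's histogram is clipped at `clip_limit * tile_pixels /
#' n_bins` with the excess redistributed uniformly in a single pass; tile
#' equalization mappings are combined by bilinear interpolation between
#' tile centers (clamped at the borders).  Tiles with a single intensity
#' level map identically, so constant images pass through unchanged.
#'
#' @param img8 integer matrix in \[0, 255\].
#' @param cfg a [clahe_config].
#' @return integer matrix in \[0, 255\], same shape.
#' @export
clahe <- function(img8, cfg = clahe_config()) {
  check_uint8(img8)
  tr <- cfg$tiles[1]; tc <- cfg$tiles[2]
  H <- nrow(img8); W <- ncol(img8)
  th <- ceiling(H / tr); tw <- ceiling(W / tc)
  if (th < 2 || tw < 2) stop("tiles smaller than 2 x 2 pixels", call. = FALSE)
  Hp <- th * tr; Wp <- tw * tc
  m <- img8
  if (Hp > H) m <- rbind(m, m[H:(2 * H - Hp + 1), , drop = FALSE])
  if (Wp > W) m <- cbind(m, m[, W:(2 * W - Wp + 1), drop = FALSE])

  luts <- matrix(0L, tr * tc, 256)
  for (j in seq_len(tc)) {
    colsel <- ((j - 1) * tw + 1):(j * tw)
    for (i in seq_len(tr)) {
      vals <- m[((i - 1) * th + 1):(i * th), colsel]
      luts[(j - 1) * tr + i, ] <- clahe_tile_lut(as.vector(vals),
                                                 cfg$clip_limit, cfg$n_bins)
    }
  }

  g <- clahe_geometry(H, W, tr, tc, th, tw)
  ntiles <- tr * tc
  voff <- as.vector(img8) * ntiles          # linear index into luts
  out <- g$w00 * luts[g$t00 + voff] + g$w10 * luts[g$t10 + voff] +
         g$w01 * luts[g$t01 + voff] + g$w11 * luts[g$t11 + voff]
  out <- round_half_up(matrix(out, H, W))
  storage.mode(out) <- "integer"
  clamp(out, 0L, 255L)
}

#' Full enhancement pipeline
#'
#' Linear HU transform, window clamp, 8-bit quantization, then CLAHE with
#' the clip limit taken from `params`.  Quantization happens after the
#' linear transformation, matching the preprocessing order the enhancement
#' was designed around.
#'
#' @param img an [hu_image] or HU matrix.
#' @param params an [enhancement_params] triple.
#' @param window a [window_config].
#' @param cfg a [clahe_config]; its `clip_limit` is overridden by
#'   `params$gamma_clip`.
#' @return list of class `enhance_result` with `enhanced8` (final 8-bit
#'   image), `pre_clahe8` (post-LT, windowed, quantized), `hu_lt` (post-LT
#'   HU image), `ref8` (windowed 8-bit original, the PSNR reference) and
#'   `params`.
#' @export
enhance_pipeline <- function(img, params, window = window_config(),
                             cfg = clahe_config()) {
  if (!inherits(params, "enhancement_params"))
    params <- do.call(enhancement_params, as.list(unlist(params)))
  hu_lt <- linear_transform(img, params$alpha, params$beta)
  lo <- window$center - window$width / 2
  hi <- window$center + window$width / 2
  pre8 <- to_uint8(hu_window(hu_lt, window), lo, hi)
  cfg$clip_limit <- params$gamma_clip
  enh <- clahe(pre8, cfg)
  structure(list(enhanced8 = enh, pre_clahe8 = pre8, hu_lt = hu_lt,
                 ref8 = window_uint8(img, window), params = params),
            class = "enhance_result")
}

## ---- classical enhancers (8-bit in, 8-bit out) -----------------------------

#' Classical intensity enhancers
#'
#' The six global/adaptive enhancers used in the before/after linear-
#' transform comparison: gamma correction (`out = 255 (in/255)^g`),
#' power law (same family with an explicit scale `c`), log transform
#' (`out = 255 c log(1 + in) / log(256)`), global histogram equalization,
#' and adaptive histogram equalization (CLAHE with the clip disabled).
#' All map \[0, 255\] into \[0, 255\] and preserve shape.
#'
#' @param img8 integer matrix in \[0, 255\].
#' @param g exponent (> 0).
#' @param c scale factor (> 0).
#' @param tiles tile grid for [ahe].
#' @return integer matrix in \[0, 255\].
#' @name classic_enhancers
NULL

#' @rdname classic_enhancers
#' @export
gamma_correct <- function(img8, g = 0.7) power_law(img8, c = 1, g = g)

#' @rdname classic_enhancers
#' @export
power_law <- function(img8, c = 1, g = 1.3) {
  check_uint8(img8)
  if (!is.finite(g) || g <= 0 || !is.finite(c) || c <= 0)
    stop("`g` and `c` must be positive", call. = FALSE)
  out <- round_half_up(clamp(255 * c * (img8 / 255)^g, 0, 255))
  storage.mode(out) <- "integer"
  out
}

#' @rdname classic_enhancers
#' @export
log_transform <- function(img8, c = 1) {
  check_uint8(img8)
  if (!is.finite(c) || c <= 0) stop("`c` must be positive", call. = FALSE)
  out <- round_half_up(clamp(255 * c * log1p(img8) / log(256), 0, 255))
  storage.mode(out) <- "integer"
  out
}

#' @rdname classic_enhancers
#' @export
he <- function(img8) {
  check_uint8(img8)
  if (max(img8) == min(img8)) return(img8)   # no contrast to redistribute
  h <- tabulate(img8 + 1L, nbins = 256)
  cdf <- cumsum(h) / length(img8)
  lut <- round_half_up(cdf * 255)
  out <- matrix(lut[img8 + 1L], nrow(img8), ncol(img8))
  storage.mode(out) <- "integer"
  out
}

#' @rdname classic_enhancers
#' @export
ahe <- function(img8, tiles = c(8, 8)) {
  clahe(img8, clahe_config(tiles = tiles, clip_limit = Inf))
}
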