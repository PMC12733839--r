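## Image-quality metrics and the composite training objective.  EME rewards
## local contrast, PSNR penalizes departure from the windowed original, and
## a quadratic range penalty keeps the enhancement triple away from its
## bounds; their weighted sum is the loss the parameter network minimizes.

#' Measure of enhancement (EME)
#'
#' Block-based contrast score: the image is partitioned into non-overlapping
#' `block_size` x `block_size` blocks (trailing partial blocks dropped) and
#' each block contributes `20 log10((max + 1) / (min + 1))`; the score is
#' the mean over blocks.  The `+1` offsets guard the logarithm at zero.
#' Always non-negative; 0 for a constant image.
#'
#' @param img8 integer matrix in \[0, 255\].
#' @param block_size block side in pixels (>= 2).
#' @return a non-negative scalar.
#' @export
eme <- function(img8, block_size = 8) {
  check_uint8(img8)
  stopifnot_scalar(block_size, "block_size")
  if (block_size < 2) stop("block_size must be >= 2", call. = FALSE)
  nbr <- nrow(img8) %/% block_size
  nbc <- ncol(img8) %/% block_size
  if (nbr < 1 || nbc < 1)
    stop("image smaller than a single block", call. = FALSE)
  m <- img8[seq_len(nbr * block_size), seq_len(nbc * block_size),
            drop = FALSE]
  a <- array(m, c(block_size, nbr, block_size, nbc))
  bm <- matrix(aperm(a, c(1, 3, 2, 4)), block_size * block_size)
  mx <- apply(bm, 2, max)
  mn <- apply(bm, 2, min)
  mean(20 * log10((mx + 1) / (mn + 1)))
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(255^2 / MSE)` between two 8-bit images of identical shape.
#' Identical images (zero MSE) return the documented 100 dB cap.
#'
#' @param ref8,test8 integer matrices in \[0, 255\], same shape.
#' @return PSNR in dB.
#' @export
psnr <- function(ref8, test8) {
  check_uint8(ref8, "ref8"); check_uint8(test8, "test8")
  if (!all(dim(ref8) == dim(test8)))
    stop("images must have the same shape", call. = FALSE)
  mse <- mean((as.numeric(ref8) - as.numeric(test8))^2)
  if (mse == 0) return(100)
  min(10 * log10(255^2 / mse), 100)
}

#' Loss weights for the composite objective
#'
#' Defaults: `w1 = 0.8` (EME term), `w2 = 0.2` (PSNR term), `lam = 0.01`
#' (range regularization).  `eme_scale = 50` and `psnr_scale = 40` bring
#' both metric terms to order one on brain-window CT (typical EME 25--50,
#' PSNR 17--38 dB), so the printed weights carry their intended meaning.
#'
#' @param w1,w2 non-negative metric weights.
#' @param lam non-negative regularization coefficient.
#' @param eme_scale,psnr_scale positive normalization constants.
#' @return an object of class `loss_weights`.
#' @export
loss_weights <- function(w1 = 0.8, w2 = 0.2, lam = 0.01,
                         eme_scale = 50, psnr_scale = 40) {
  if (w1 < 0 || w2 < 0 || lam < 0)
    stop("weights must be non-negative", call. = FALSE)
  if (eme_scale <= 0 || psnr_scale <= 0)
    stop("scales must be positive", call. = FALSE)
  structure(list(w1 = w1, w2 = w2, lam = lam,
                 eme_scale = eme_scale, psnr_scale = psnr_scale),
            class = "loss_weights")
}

# Squared normalized deviation of the triple from its range midpoints;
# 0 at the midpoints, 1 when a single parameter sits at a range endpoint.
reg_loss <- function(params) {
  v <- c(params$alpha, params$beta, params$gamma_clip)
  mid <- param_midpoints(); half <- param_halfwidths()
  sum(((v - mid) / half)^2)
}

#' Composite enhancement loss
#'
#' `loss = w1 * eme_loss + w2 * psnr_loss + lam * reg_loss` with
#' `eme_loss = -eme(enhanced)/eme_scale`,
#' `psnr_loss = -psnr(orig, enhanced)/psnr_scale` and `reg_loss` the squared
#' normalized deviation of the parameters from their range midpoints.
#' Lower is better: the EME term promotes enhancement, the PSNR term
#' preserves fidelity to the windowed original, the regularizer penalizes
#' extreme parameter values.
#'
#' @param orig8 the 8-bit reference image (windowed original).
#' @param enhanced8 the 8-bit enhanced image, same shape.
#' @param params the [enhancement_params] being scored.
#' @param w a [loss_weights].
#' @param block_size EME block size.
#' @return a `metric_report`: list with `eme`, `psnr`, `loss` and
#'   `components` (`eme_loss`, `psnr_loss`, `reg_loss`).
#' @export
combined_loss <- function(orig8, enhanced8, params, w = loss_weights(),
                          block_size = 8) {
  if (!inherits(params, "enhancement_params"))
    params <- do.call(enhancement_params, as.list(unlist(params)))
  e <- eme(enhanced8, block_size)
  p <- psnr(orig8, enhanced8)
  comp <- c(eme_loss = -e / w$eme_scale,
            psnr_loss = -p / w$psnr_scale,
            reg_loss = reg_loss(params))
  structure(list(eme = e, psnr = p,
                 loss = w$w1 * comp[["eme_loss"]] +
                        w$w2 * comp[["psnr_loss"]] +
                        w$lam * comp[["reg_loss"]],
                 components = comp),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report eme=%.3f psnr=%.2f dB loss=%.4f>\n",
              x$eme, x$psnr, x$loss))
  invisible(x)
}

# Loss of a parameter triple on one HU image: runs the enhancement pipeline
# and scores it against the windowed original.  The workhorse behind both
# the grid-search oracle and network training.
pipeline_loss <- function(img, params, w = loss_weights(),
                          window = window_config(), cfg = clahe_config(),
                          block_size = 8, ref8 = NULL) {
  res <- enhance_pipeline(img, params, window, cfg)
  if (is.null(ref8)) ref8 <- res$ref8
  combined_loss(ref8, res$enhanced8, res$params, w, block_size)
}
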