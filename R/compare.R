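## Paired comparison harness: does a prior linear HU transformation improve
## what a subsequent non-linear enhancer achieves?  For each enhancer the
## harness scores every image twice -- enhanced directly (t0) and enhanced
## after the linear transform (t1) -- and runs paired t-tests on EME and
## PSNR.

#' Paired t-test
#'
#' Two-sided paired t-test of `y - x` with sample standard deviation
#' (n - 1 denominator) and df = n - 1.  Zero-variance differences are
#' degenerate: the test is flagged and no p-value is produced.
#'
#' @param x,y paired numeric vectors of equal length n >= 2.
#' @return list with `t`, `p`, `df`, `mean_diff`, `degenerate`.
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)",
                                   call. = FALSE)
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- y - x
  if (stats::sd(d) == 0)
    return(list(t = NA_real_, p = NA_real_, df = n - 1,
                mean_diff = mean(d), degenerate = TRUE))
  tt <- stats::t.test(y, x, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = mean(d), degenerate = FALSE)
}

# The six enhancers of the comparison design, by table name.
comparison_methods <- function() {
  list(
    "Gamma"     = function(img8) gamma_correct(img8),
    "Power Law" = function(img8) power_law(img8),
    "Log"       = function(img8) log_transform(img8),
    "CLAHE"     = function(img8) clahe(img8, clahe_config(clip_limit = 1)),
    "HE"        = function(img8) he(img8),
    "AHE"       = function(img8) ahe(img8))
}

#' Before/after linear-transform enhancement comparison
#'
#' For each of the six enhancers (gamma, power law, log, CLAHE, HE, AHE),
#' computes EME and PSNR of the enhancer applied to the windowed 8-bit
#' original (t0) and to the linearly transformed image (t1), then paired
#' t-tests of t1 vs t0 per metric.  PSNR is referenced to the
#' untransformed windowed original in both arms so the pairs are
#' comparable.
#'
#' @param samples list of `staged_sample` or [hu_image] objects (>= 2).
#' @param static_lt length-2 numeric `(alpha, beta)` of the prior linear
#'   transform.
#' @param window a [window_config].
#' @param block_size EME block size.
#' @param bonferroni if `TRUE`, p-values are Bonferroni-corrected across
#'   the 12 tests; raw p-values by default.
#' @return data.frame with one row per method x metric: `mean_t0`,
#'   `mean_t1`, `t_statistic`, `p_value`, `df`, `n`, `degenerate`.
#' @export
enhancement_comparison <- function(samples, static_lt = c(1.25, 0),
                                   window = window_config(),
                                   block_size = 8, bonferroni = FALSE) {
  if (length(samples) < 2) stop("need at least 2 samples", call. = FALSE)
  imgs <- lapply(samples, function(s)
    if (inherits(s, "staged_sample")) s$image else s)
  lo <- window$center - window$width / 2
  hi <- window$center + window$width / 2
  ref <- lapply(imgs, window_uint8, cfg = window)
  lt8 <- lapply(imgs, function(im)
    to_uint8(hu_window(linear_transform(im, static_lt[1], static_lt[2]),
                       window), lo, hi))
  methods <- comparison_methods()
  out <- list()
  for (nm in names(methods)) {
    f <- methods[[nm]]
    e0 <- lapply(ref, f)
    e1 <- lapply(lt8, f)
    for (metric in c("EME", "PSNR")) {
      v0 <- if (metric == "EME")
        vapply(e0, eme, 0, block_size = block_size)
      else mapply(psnr, ref, e0)
      v1 <- if (metric == "EME")
        vapply(e1, eme, 0, block_size = block_size)
      else mapply(psnr, ref, e1)
      tt <- paired_ttest(v0, v1)
      out[[length(out) + 1L]] <- data.frame(
        method = nm, metric = metric, mean_t0 = mean(v0), mean_t1 = mean(v1),
        t_statistic = tt$t, p_value = tt$p, df = tt$df,
        n = length(v0), degenerate = tt$degenerate)
    }
  }
  res <- do.call(rbind, out)
  if (bonferroni) res$p_value <- pmin(res$p_value * nrow(res), 1)
  rownames(res) <- NULL
  res
}
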