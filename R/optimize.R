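## Parameter optimization: a convolutional network predicts, per scan, the
## enhancement triple (slope, intercept, CLAHE clip limit) that minimizes
## the composite loss; an exhaustive grid search over the constrained
## parameter box serves as the per-image verification oracle; stage-
## stratified summaries report 95% confidence intervals of the learned
## parameters.

#' Parameter-network architecture configuration
#'
#' Five 3x3 conv blocks (batch norm, ReLU, 2x2 max pool), adaptive average
#' pooling to `pooled_size^2` spatial bins, then four fully connected
#' layers (ReLU + dropout between hidden layers) ending in the three raw
#' parameter outputs.  Defaults are desk-scale: training the default net
#' on a CPU stays in the minutes range.
#'
#' @param conv_channels integer vector of exactly 5 conv widths.
#' @param fc_widths integer vector of exactly 4 fully connected widths, the
#'   last equal to 3.
#' @param dropout_rate dropout probability between hidden FC layers,
#'   in \[0, 1).
#' @param pooled_size spatial size after adaptive average pooling
#'   (default 8).
#' @param input_size square input side in pixels.
#' @param seed initialization seed.
#' @return an object of class `param_net_config`.
#' @export
param_net_config <- function(conv_channels = c(16, 32, 64, 128, 128),
                             fc_widths = c(512, 128, 32, 3),
                             dropout_rate = 0.3, pooled_size = 8,
                             input_size = 256, seed = 1L) {
  if (length(conv_channels) != 5 || any(conv_channels < 1))
    stop("exactly 5 positive conv widths are required", call. = FALSE)
  if (length(fc_widths) != 4 || fc_widths[4] != 3)
    stop("exactly 4 fc widths are required, the last equal to 3",
         call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)", call. = FALSE)
  if (pooled_size < 1) stop("pooled_size must be >= 1", call. = FALSE)
  if (input_size < 16) stop("input_size must be >= 16", call. = FALSE)
  structure(list(conv_channels = as.integer(conv_channels),
                 fc_widths = as.integer(fc_widths),
                 dropout_rate = dropout_rate,
                 pooled_size = as.integer(pooled_size),
                 input_size = as.integer(input_size),
                 seed = as.integer(seed)),
            class = "param_net_config")
}

#' Build a parameter-prediction network
#'
#' Seeded He initialization; the output head starts near zero so an
#' untrained network predicts the range midpoints.
#'
#' @param cfg a [param_net_config].
#' @return an object of class `param_net` with a `param_count` attribute.
#' @export
build_param_net <- function(cfg = param_net_config()) {
  if (!inherits(cfg, "param_net_config"))
    stop("`cfg` must be a param_net_config", call. = FALSE)
  params <- with_seed(cfg$seed, init_net_params(cfg))
  net <- structure(c(list(cfg = cfg), params), class = "param_net")
  attr(net, "param_count") <- net_param_count(net)
  net
}

#' @export
print.param_net <- function(x, ...) {
  cat(sprintf(
    "<param_net input %dx%d, conv (%s), fc (%s), %d parameters%s>\n",
    x$cfg$input_size, x$cfg$input_size,
    paste(x$cfg$conv_channels, collapse = ","),
    paste(x$cfg$fc_widths, collapse = ","),
    attr(x, "param_count"),
    if (isTRUE(attr(x, "trained"))) ", trained" else ""))
  invisible(x)
}

#' Map raw network outputs into the constrained parameter box
#'
#' Each raw value is squashed as `lo + (hi - lo) * logistic(raw)`, so any
#' finite output lies strictly inside its range: slope in (0.5, 2),
#' intercept in (-5, 5), clip limit in (0.1, 2).  Raw zeros map to the
#' exact midpoints (1.25, 0, 1.05).
#'
#' @param raw_triple numeric length-3 vector of finite raw outputs.
#' @return an [enhancement_params].
#' @export
constrain_params <- function(raw_triple) {
  if (length(raw_triple) != 3 || !all(is.finite(raw_triple)))
    stop("`raw_triple` must be 3 finite values", call. = FALSE)
  v <- constrain_raw_matrix(matrix(raw_triple, 1))
  enhancement_params(v[1, 1], v[1, 2], v[1, 3])
}

constrain_raw_matrix <- function(raw) {
  lo <- vapply(PARAM_RANGES, `[`, 0, 1)
  hi <- vapply(PARAM_RANGES, `[`, 0, 2)
  s <- stats::plogis(raw)
  sweep(sweep(s, 2, hi - lo, "*"), 2, lo, "+")
}

# d(param)/d(raw) of the logistic reparameterization, elementwise.
constrain_jacobian <- function(raw) {
  lo <- vapply(PARAM_RANGES, `[`, 0, 1)
  hi <- vapply(PARAM_RANGES, `[`, 0, 2)
  s <- stats::plogis(raw)
  sweep(s * (1 - s), 2, hi - lo, "*")
}

# Windowed, [0,1]-scaled, input_size-resampled tensor slice for the net.
prepare_net_input <- function(img, cfg, window = window_config()) {
  img <- resample_to(img, cfg$input_size)
  window_uint8(img, window) / 255
}

#' Predict enhancement parameters for one image
#'
#' Deterministic inference (dropout disabled, batch-norm running
#' statistics).  Images whose size differs from the configured input size
#' are resampled internally with a warning.
#'
#' @param net a [build_param_net] network.
#' @param img an [hu_image] or HU matrix.
#' @param window a [window_config].
#' @return an [enhancement_params].
#' @export
predict_params <- function(net, img, window = window_config()) {
  px <- as_hu_pixels(img)
  if (nrow(px) != net$cfg$input_size || ncol(px) != net$cfg$input_size)
    warning(sprintf("resampling %dx%d input to the network's %dx%d",
                    nrow(px), ncol(px), net$cfg$input_size,
                    net$cfg$input_size), call. = FALSE)
  x <- array(prepare_net_input(img, net$cfg, window),
             c(net$cfg$input_size, net$cfg$input_size, 1, 1))
  raw <- net_forward(net, x, train = FALSE)$raw
  constrain_params(as.numeric(raw))
}

#' Exhaustive grid-search oracle
#'
#' Evaluates the composite loss over a uniform `grid_resolution^3` grid on
#' the constrained parameter box and returns the argmin.  Ties are broken
#' toward the smallest slope, then intercept, then clip limit.  Used as
#' the independent verification oracle for the learned optimizer.
#'
#' @param img an [hu_image] or HU matrix.
#' @param grid_resolution points per axis (>= 3); either a single count for
#'   all three axes or a length-3 vector `(alpha, beta, gamma)` for
#'   anisotropic grids (e.g. a fine clip-limit axis over a coarse
#'   slope/intercept plane).
#' @param w a [loss_weights].
#' @param window a [window_config].
#' @param cfg a [clahe_config] (clip limit supplied by the grid).
#' @param block_size EME block size.
#' @return list with `params` (the optimal [enhancement_params]), `loss`,
#'   and `losses` (the full named grid of evaluated losses).
#' @export
grid_search_params <- function(img, grid_resolution = 9,
                               w = loss_weights(), window = window_config(),
                               cfg = clahe_config(), block_size = 8) {
  if (!length(grid_resolution) %in% c(1L, 3L) || any(grid_resolution < 3))
    stop("grid_resolution must be one or three counts, each >= 3",
         call. = FALSE)
  grid_resolution <- rep_len(as.integer(grid_resolution), 3L)
  axes <- Map(function(r, n) seq(r[1], r[2], length.out = n),
              PARAM_RANGES, grid_resolution)
  ref8 <- window_uint8(img, window)
  lo <- window$center - window$width / 2
  hi <- window$center + window$width / 2
  best <- list(loss = Inf, params = NULL)
  losses <- array(NA_real_, grid_resolution,
                  dimnames = list(alpha = signif(axes$alpha, 6),
                                  beta = signif(axes$beta, 6),
                                  gamma = signif(axes$gamma_clip, 6)))
  for (ia in seq_along(axes$alpha)) for (ib in seq_along(axes$beta)) {
    hu_lt <- linear_transform(img, axes$alpha[ia], axes$beta[ib])
    pre8 <- to_uint8(hu_window(hu_lt, window), lo, hi)
    for (ig in seq_along(axes$gamma_clip)) {
      cfg$clip_limit <- axes$gamma_clip[ig]
      enh <- clahe(pre8, cfg)
      pr <- enhancement_params(axes$alpha[ia], axes$beta[ib],
                               axes$gamma_clip[ig])
      l <- combined_loss(ref8, enh, pr, w, block_size)$loss
      losses[ia, ib, ig] <- l
      if (l < best$loss) best <- list(loss = l, params = pr)
    }
  }
  list(params = best$params, loss = best$loss, losses = losses)
}

#' Training configuration
#'
#' @param epochs number of passes over the training split (>= 1).
#' @param batch_size minibatch size (>= 1).
#' @param learning_rate Adam step size.
#' @param weights a [loss_weights].
#' @param stage_filter optional stage label: train only on that stage
#'   (stage-specific models are independently trained copies).
#' @param val_frac held-out validation fraction (stratified by stage).
#' @param fd_step central-difference step for the loss gradient w.r.t. the
#'   constrained parameters, as a fraction of each range half-width.
#' @param n_starts number of independent restarts (fresh seeded
#'   initializations); the start with the lowest final mean training loss
#'   is kept.  The optimization is non-convex and its interior optima can
#'   be shallow, so multi-start selection is recommended when conditions
#'   vary; 1 reproduces a single deterministic run.
#' @param seed seed governing the split, shuffling and dropout.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 250, batch_size = 16,
                         learning_rate = 1e-3, weights = loss_weights(),
                         stage_filter = NULL, val_frac = 0.2,
                         fd_step = 0.1, n_starts = 1L, seed = 1L) {
  if (epochs < 1 || batch_size < 1)
    stop("epochs and batch_size must be >= 1", call. = FALSE)
  if (fd_step <= 0 || fd_step > 0.5)
    stop("fd_step must be in (0, 0.5]", call. = FALSE)
  if (n_starts < 1) stop("n_starts must be >= 1", call. = FALSE)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weights = weights,
                 stage_filter = stage_filter, val_frac = val_frac,
                 fd_step = fd_step, n_starts = as.integer(n_starts),
                 seed = as.integer(seed)),
            class = "train_config")
}

# Central-difference gradient of the pipeline loss w.r.t. the constrained
# triple, evaluated with steps wide enough to see through the 8-bit
# quantization.  Also returns the center loss.
param_loss_grad <- function(img, p, w, window, cfg, block_size, ref8,
                            fd_step) {
  half <- param_halfwidths()
  lo <- vapply(PARAM_RANGES, `[`, 0, 1)
  hi <- vapply(PARAM_RANGES, `[`, 0, 2)
  v <- c(p$alpha, p$beta, p$gamma_clip)
  eval_at <- function(vv) {
    pipeline_loss(img, enhancement_params(vv[1], vv[2], vv[3]), w, window,
                  cfg, block_size, ref8)$loss
  }
  center <- eval_at(v)
  g <- numeric(3)
  for (j in 1:3) {
    step <- fd_step * half[j]
    up <- v; up[j] <- min(v[j] + step, hi[j])
    dn <- v; dn[j] <- max(v[j] - step, lo[j])
    g[j] <- (eval_at(up) - eval_at(dn)) / (up[j] - dn[j])
  }
  list(loss = center, grad = g)
}

#' Train a parameter-prediction network
#'
#' Minimizes the composite loss over a phantom (or real) dataset.  Each
#' step runs the network forward, squashes the raw outputs into the
#' parameter box, pushes each image through the hard enhancement pipeline,
#' measures the loss, and backpropagates: the gradient of the loss with
#' respect to the three constrained parameters is taken by wide-step
#' central differences through the full pipeline (the pipeline is
#' piecewise constant under 8-bit quantization, so infinitesimal
#' differences carry no signal), then chained analytically through the
#' logistic reparameterization and the network.  The split, shuffling and
#' dropout are all seeded, so identical data + configuration reproduce the
#' history exactly.
#'
#' @param dataset non-empty list of `staged_sample` objects (or `hu_image`s,
#'   which are treated as unlabeled).
#' @param net a [build_param_net] network.
#' @param tcfg a [train_config].
#' @param window a [window_config].
#' @param cfg a [clahe_config].
#' @param block_size EME block size.
#' @param verbose print per-epoch progress.
#' @return list with `net` (trained) and `history` (data.frame with one row
#'   per epoch: train_loss, val_loss, val_eme, val_psnr).
#' @export
train_param_net <- function(dataset, net, tcfg = train_config(),
                            window = window_config(), cfg = clahe_config(),
                            block_size = 8, verbose = FALSE) {
  if (length(dataset) == 0) stop("dataset is empty", call. = FALSE)
  if ((tcfg$n_starts %||% 1L) > 1L) {
    best <- NULL
    for (sidx in seq_len(tcfg$n_starts)) {
      ncfg <- net$cfg
      ncfg$seed <- if (sidx == 1L) net$cfg$seed else
        derive_seed(net$cfg$seed, "start", sidx)
      tcfg_s <- tcfg
      tcfg_s$n_starts <- 1L
      tcfg_s$seed <- if (sidx == 1L) tcfg$seed else
        derive_seed(tcfg$seed, "start", sidx)
      run <- train_param_net(dataset, build_param_net(ncfg), tcfg_s,
                             window, cfg, block_size, verbose)
      # select by final mean loss over the full dataset (deterministic)
      imgs_all <- lapply(dataset, function(s)
        if (inherits(s, "staged_sample")) s$image else s)
      if (!is.null(tcfg$stage_filter)) {
        keep <- vapply(dataset, function(s)
          inherits(s, "staged_sample") && s$stage == tcfg$stage_filter,
          TRUE)
        imgs_all <- imgs_all[keep]
      }
      score <- mean(vapply(imgs_all, function(im) {
        p <- suppressWarnings(predict_params(run$net, im, window))
        pipeline_loss(im, p, tcfg$weights, window, cfg, block_size)$loss
      }, 0))
      if (is.null(best) || score < best$score)
        best <- list(run = run, score = score, start = sidx)
    }
    out <- best$run
    out$start <- best$start
    return(out)
  }
  stages <- vapply(dataset, function(s)
    if (inherits(s, "staged_sample")) s$stage else "unlabeled", "")
  if (!is.null(tcfg$stage_filter)) {
    keep <- stages == tcfg$stage_filter
    if (!any(keep)) stop("no samples match stage_filter", call. = FALSE)
    dataset <- dataset[keep]; stages <- stages[keep]
  }
  imgs <- lapply(dataset, function(s)
    if (inherits(s, "staged_sample")) s$image else s)
  n <- length(imgs)

  # stratified 80/20 (val_frac) split, seeded
  val_idx <- with_seed(derive_seed(tcfg$seed, "split"), {
    unlist(lapply(split(seq_len(n), stages), function(ix) {
      k <- max(if (length(ix) >= 2) 1L else 0L,
               round(tcfg$val_frac * length(ix)))
      if (k == 0) integer() else sample(ix, k)
    }), use.names = FALSE)
  })
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(tr_idx) == 0) tr_idx <- seq_len(n)

  S <- net$cfg$input_size
  xin <- lapply(imgs, function(im)
    prepare_net_input(im, net$cfg, window))
  ref8 <- lapply(imgs, window_uint8, cfg = window)

  state <- adam_init(net)
  hist <- vector("list", tcfg$epochs)
  for (ep in seq_len(tcfg$epochs)) {
    ep_losses <- c()
    with_seed(derive_seed(tcfg$seed, "epoch", ep), {
      ord <- sample(tr_idx)
      batches <- split(ord, ceiling(seq_along(ord) / tcfg$batch_size))
      for (bt in batches) {
        x <- array(unlist(xin[bt]), c(S, S, 1, length(bt)))
        fwd <- net_forward(net, x, train = TRUE, cache = TRUE)
        net <- fwd$net                      # batch-norm running stats
        pmat <- constrain_raw_matrix(fwd$raw)
        gmat <- matrix(0, length(bt), 3)
        for (k in seq_along(bt)) {
          i <- bt[k]
          pg <- param_loss_grad(
            imgs[[i]],
            enhancement_params(pmat[k, 1], pmat[k, 2], pmat[k, 3]),
            tcfg$weights, window, cfg, block_size, ref8[[i]], tcfg$fd_step)
          if (!is.finite(pg$loss))
            stop(sprintf("non-finite loss at epoch %d, sample %d", ep, i),
                 call. = FALSE)
          gmat[k, ] <- pg$grad
          ep_losses <- c(ep_losses, pg$loss)
        }
        draw <- gmat * constrain_jacobian(fwd$raw) / length(bt)
        grads <- net_backward(net, fwd, draw)
        up <- adam_step(net, grads, state, tcfg$learning_rate)
        net <- up$net; state <- up$state
      }
    })
    vl <- ve <- vp <- NA_real_
    if (length(val_idx)) {
      vls <- vapply(val_idx, function(i) {
        raw <- net_forward(net, array(xin[[i]], c(S, S, 1, 1)))$raw
        r <- pipeline_loss(imgs[[i]], constrain_params(as.numeric(raw)),
                           tcfg$weights, window, cfg, block_size, ref8[[i]])
        c(r$loss, r$eme, r$psnr)
      }, numeric(3))
      vl <- mean(vls[1, ]); ve <- mean(vls[2, ]); vp <- mean(vls[3, ])
    }
    hist[[ep]] <- data.frame(epoch = ep, train_loss = mean(ep_losses),
                             val_loss = vl, val_eme = ve, val_psnr = vp)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  eme %.2f  psnr %.2f",
                      ep, mean(ep_losses), vl, ve, vp))
  }
  attr(net, "trained") <- TRUE
  list(net = net, history = do.call(rbind, hist))
}

#' Stage-stratified summary of predicted parameters
#'
#' Predicts the enhancement triple for every sample and reports, per
#' stage, the mean and 95% confidence interval of each parameter
#' (t-quantile below 30 samples, normal approximation otherwise).  Bounds
#' are clamped to the parameter ranges.
#'
#' @param nets named list mapping stage label to a trained network (a
#'   single unnamed network is applied to all stages).
#' @param datasets list of `staged_sample` objects.
#' @param window a [window_config].
#' @return data.frame of class `stage_param_summary`: one row per stage,
#'   mean/lb/ub columns for slope, intercept and clip limit, plus `n`.
#' @export
summarize_stage_params <- function(nets, datasets,
                                   window = window_config()) {
  stages <- vapply(datasets, function(s) s$stage, "")
  out <- list()
  for (st in unique(stages)) {
    ix <- which(stages == st)
    if (length(ix) < 2)
      stop(sprintf("stage %s has fewer than 2 samples", st), call. = FALSE)
    net <- if (inherits(nets, "param_net")) nets
           else nets[[st]] %||% nets[[1]]
    pm <- t(vapply(ix, function(i) {
      p <- suppressWarnings(predict_params(net, datasets[[i]]$image, window))
      c(p$alpha, p$beta, p$gamma_clip)
    }, numeric(3)))
    n <- nrow(pm)
    q <- if (n < 30) stats::qt(0.975, n - 1) else stats::qnorm(0.975)
    mu <- colMeans(pm)
    se <- apply(pm, 2, stats::sd) / sqrt(n)
    lo <- vapply(PARAM_RANGES, `[`, 0, 1)
    hi <- vapply(PARAM_RANGES, `[`, 0, 2)
    lb <- clamp(mu - q * se, lo, hi); ub <- clamp(mu + q * se, lo, hi)
    out[[st]] <- data.frame(
      stage = st, n = n,
      slope_mean = mu[1], slope_lb = lb[1], slope_ub = ub[1],
      intercept_mean = mu[2], intercept_lb = lb[2], intercept_ub = ub[2],
      clip_mean = mu[3], clip_lb = lb[3], clip_ub = ub[3])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("stage_param_summary", "data.frame")
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a parameter network checkpoint
#'
#' Single-file checkpoint holding the configuration, weights, batch-norm
#' running statistics and training flag.
#'
#' @param net a `param_net`.
#' @param path file path.
#' @return `load_param_net` returns the network.
#' @export
save_param_net <- function(net, path) {
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_param_net
#' @export
load_param_net <- function(path) readRDS(path)
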