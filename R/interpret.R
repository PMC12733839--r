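## Grad-CAM over the conv encoder: verifies that classification attends to
## lesion regions.  The classifier explained here is a linear probe (one
## linear layer per class) over the encoder's adaptive-average-pooled
## features; the class score is therefore linear in the pooled activations
## and the gradient with respect to the target conv layer (the last conv
## block's output, just before adaptive pooling) is exact and cheap.

#' Train a linear classification probe on encoder features
#'
#' Fits a ridge-penalized logistic model (binomial or multinomial) on the
#' pooled conv-encoder features of 8-bit images.  The result pairs the
#' frozen encoder with per-class linear weights and is the unit Grad-CAM
#' explains.
#'
#' @param encoder a `param_net` used as frozen feature extractor.
#' @param imgs8 list of 8-bit image matrices.
#' @param labels class labels (length matching `imgs8`).
#' @param seed fitting seed.
#' @param lambda ridge penalty.
#' @return an object of class `cam_classifier` with elements `encoder`,
#'   `W` (features x classes), `b`, `classes`.
#' @export
train_linear_probe <- function(encoder, imgs8, labels, seed = 1L,
                               lambda = 1e-2) {
  feats <- t(vapply(imgs8, function(im)
    as.numeric(extract_features(im, encoder)),
    numeric(length(extract_features(imgs8[[1]], encoder)))))
  y <- factor(labels)
  fit <- with_seed(seed, {
    fam <- if (nlevels(y) == 2) "binomial" else "multinomial"
    suppressWarnings(
      glmnet::glmnet(feats, y, family = fam, alpha = 0, lambda = lambda))
  })
  cf <- stats::coef(fit)
  if (nlevels(y) == 2) {
    w1 <- as.numeric(cf)[-1]; b1 <- as.numeric(cf)[1]
    W <- cbind(-w1, w1); b <- c(-b1, b1)   # symmetric two-class scores
  } else {
    W <- do.call(cbind, lapply(cf, function(m) as.numeric(m)[-1]))
    b <- vapply(cf, function(m) as.numeric(m)[1], 0)
  }
  colnames(W) <- levels(y)
  structure(list(encoder = encoder, W = W, b = b, classes = levels(y)),
            class = "cam_classifier")
}

#' Predict classes with a linear probe
#' @param clf a `cam_classifier`.
#' @param imgs8 list of 8-bit images.
#' @return character vector of predicted classes.
#' @export
predict_linear_probe <- function(clf, imgs8) {
  vapply(imgs8, function(im) {
    f <- as.numeric(extract_features(im, clf$encoder))
    clf$classes[which.max(as.numeric(f %*% clf$W) + clf$b)]
  }, "")
}

# Forward the encoder keeping the target conv activations (output of the
# fifth conv block, the input to adaptive pooling).
encoder_activations <- function(encoder, img8) {
  S <- encoder$cfg$input_size
  if (!all(dim(img8) == c(S, S)))
    img8 <- to_uint8(resample_to(img8 * 1, S), lo = 0, hi = 255)
  x <- array(img8 / 255, c(S, S, 1, 1))
  net <- encoder
  for (i in seq_along(net$conv)) {
    cf <- conv_forward(x, net$conv[[i]]$W, net$conv[[i]]$b)
    bf <- bn_forward(cf$y, net$bn[[i]]$gamma, net$bn[[i]]$beta,
                     net$bn[[i]]$rmean, net$bn[[i]]$rvar, train = FALSE)
    x <- maxpool_forward(bf$y * (bf$y > 0))$y
  }
  ap <- adaptpool_forward(x, net$cfg$pooled_size)
  list(A = x[, , , 1, drop = FALSE], pooled = ap)
}

#' Grad-CAM attention map
#'
#' Channel weights are the spatial average of the gradients of the target
#' class score with respect to the last conv block's activations; the map
#' is `ReLU(sum_c weight_c * A_c)`, bilinearly upsampled to the input size
#' and max-normalized to \[0, 1\].  A map with zero gradient everywhere is
#' returned all-zero with `all_zero = TRUE`.  Works on both classifier
#' flavours: the linear probe of [train_linear_probe] (exact linear
#' gradient through the pooling) and the end-to-end conv classifier of
#' [train_image_classifier] (gradient backpropagated through the FC stack).
#'
#' @param clf a `cam_classifier` or `image_classifier`.
#' @param img8 8-bit input image.
#' @param target_class class label whose score is explained (default: the
#'   predicted class).
#' @return an `attention_map`: list with `heat` (matrix in \[0, 1\], input
#'   shape), `target`, `layer_id`, `all_zero`.
#' @export
gradcam <- function(clf, img8, target_class = NULL) UseMethod("gradcam")

#' @export
gradcam.cam_classifier <- function(clf, img8, target_class = NULL) {
  check_uint8(img8)
  enc <- clf$encoder
  act <- encoder_activations(enc, img8)
  A <- act$A                                   # (h, w, C, 1)
  f <- as.numeric(t(matrix(act$pooled$y, length(act$pooled$y), 1)))
  scores <- as.numeric(f %*% clf$W) + clf$b
  if (is.null(target_class))
    target_class <- clf$classes[which.max(scores)]
  k <- match(target_class, clf$classes)
  if (is.na(k)) stop("unknown target class: ", target_class, call. = FALSE)

  # d(score)/d(pooled features), then exact backprop through average
  # pooling onto the conv activations.
  P <- enc$cfg$pooled_size
  C <- dim(A)[3]
  dpool <- array(clf$W[, k], c(P, P, C, 1))
  dA <- adaptpool_backward(dpool, act$pooled)   # (h, w, C, 1)
  finish_cam(A, dA, img8, target_class)
}

#' @export
gradcam.image_classifier <- function(clf, img8, target_class = NULL) {
  check_uint8(img8)
  net <- clf$net
  S <- net$cfg$input_size
  x8 <- img8
  if (!all(dim(x8) == c(S, S)))
    x8 <- to_uint8(resample_to(x8 * 1, S), lo = 0, hi = 255)
  x <- array(x8 / 255, c(S, S, 1, 1))
  fwd <- net_forward(net, x, train = FALSE, cache = TRUE)
  logits <- fwd$raw[1, seq_along(clf$classes)]
  if (is.null(target_class)) target_class <- clf$classes[which.max(logits)]
  k <- match(target_class, clf$classes)
  if (is.na(k)) stop("unknown target class: ", target_class, call. = FALSE)
  draw <- matrix(0, 1, ncol(fwd$raw))
  draw[1, k] <- 1                              # d(score_k)/d(raw)
  dA <- net_conv_grad(net, fwd, draw)
  finish_cam(fwd$caches$conv_out, dA, img8, target_class)
}

# Shared Grad-CAM tail: GAP channel weights, ReLU combination, upsampling
# to the input size and max-normalization.
finish_cam <- function(A, dA, img8, target_class) {
  C <- dim(A)[3]
  wts <- apply(dA[, , , 1, drop = FALSE], 3, mean)   # GAP of gradients
  cam <- matrix(0, dim(A)[1], dim(A)[2])
  for (ci in seq_len(C)) cam <- cam + wts[ci] * A[, , ci, 1]
  cam[cam < 0] <- 0

  S <- nrow(img8)
  heat <- as_hu_pixels(resample_to(rbind_pad(cam, 16), max(S, 16)))
  heat <- heat[seq_len(S), seq_len(S), drop = FALSE]
  all_zero <- max(heat) <= 0
  if (!all_zero) heat <- heat / max(heat)
  heat[heat < 0] <- 0
  structure(list(heat = heat, target = target_class,
                 layer_id = "conv5", all_zero = all_zero),
            class = "attention_map")
}

#' Train an end-to-end convolutional stage classifier
#'
#' Trains the package's conv architecture as a small image classifier
#' (softmax cross-entropy over the first `n_classes` head outputs) on 8-bit
#' images.  This is the desk-scale analog of the deep classifiers whose
#' decisions Grad-CAM explains: unlike the frozen-encoder linear probe, its
#' conv filters learn lesion-sensitive features.
#'
#' @param imgs8 list of 8-bit image matrices.
#' @param labels class labels (at most 3 distinct).
#' @param cfg a [param_net_config]; `input_size` should match the images.
#' @param epochs,batch_size,learning_rate training hyperparameters.
#' @param n_starts independent seeded restarts; the start with the lowest
#'   final cross-entropy is kept (small-batch training of a small net is
#'   non-convex and an occasional initialization stalls).
#' @param seed seed for initialization, shuffling and dropout.
#' @return an `image_classifier`: list with `net`, `classes`, `history`
#'   (per-epoch mean cross-entropy and accuracy).
#' @export
train_image_classifier <- function(imgs8, labels, cfg, epochs = 10,
                                   batch_size = 8, learning_rate = 1e-3,
                                   n_starts = 1L, seed = 1L) {
  if (n_starts > 1L) {
    best <- NULL
    for (sidx in seq_len(n_starts)) {
      cfg_s <- cfg
      cfg_s$seed <- if (sidx == 1L) cfg$seed else
        derive_seed(cfg$seed, "start", sidx)
      run <- train_image_classifier(imgs8, labels, cfg_s, epochs,
                                    batch_size, learning_rate, 1L,
                                    if (sidx == 1L) seed else
                                      derive_seed(seed, "start", sidx))
      score <- utils::tail(run$history$cross_entropy, 1)
      if (is.null(best) || score < best$score) best <- list(run = run,
                                                            score = score)
    }
    return(best$run)
  }
  y <- factor(labels)
  if (nlevels(y) > 3)
    stop("the 3-output head supports at most 3 classes", call. = FALSE)
  S <- cfg$input_size
  xs <- lapply(imgs8, function(m) {
    check_uint8(m)
    if (!all(dim(m) == c(S, S))) m <- to_uint8(resample_to(m * 1, S), 0, 255)
    m / 255
  })
  net <- build_param_net(cfg)
  state <- adam_init(net)
  ky <- as.integer(y)
  hist <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ce <- acc <- c()
    with_seed(derive_seed(seed, "clf-epoch", ep), {
      ord <- sample(seq_along(xs))
      for (bt in split(ord, ceiling(seq_along(ord) / batch_size))) {
        x <- array(unlist(xs[bt]), c(S, S, 1, length(bt)))
        fwd <- net_forward(net, x, train = TRUE, cache = TRUE)
        net <- fwd$net
        logit <- fwd$raw[, seq_len(nlevels(y)), drop = FALSE]
        pr <- exp(logit - apply(logit, 1, max))
        pr <- pr / rowSums(pr)
        onehot <- matrix(0, length(bt), nlevels(y))
        onehot[cbind(seq_along(bt), ky[bt])] <- 1
        ce <- c(ce, -mean(log(pmax(pr[onehot == 1], 1e-12))))
        acc <- c(acc, mean(max.col(pr) == ky[bt]))
        draw <- matrix(0, length(bt), ncol(fwd$raw))
        draw[, seq_len(nlevels(y))] <- (pr - onehot) / length(bt)
        up <- adam_step(net, net_backward(net, fwd, draw), state,
                        learning_rate)
        net <- up$net; state <- up$state
      }
    })
    hist[[ep]] <- data.frame(epoch = ep, cross_entropy = mean(ce),
                             accuracy = mean(acc))
  }
  structure(list(net = net, classes = levels(y),
                 history = do.call(rbind, hist)),
            class = "image_classifier")
}

#' Predict classes with a trained image classifier
#' @param clf an `image_classifier`.
#' @param imgs8 list of 8-bit images.
#' @return character vector of predicted classes.
#' @export
predict_image_classifier <- function(clf, imgs8) {
  S <- clf$net$cfg$input_size
  vapply(imgs8, function(m) {
    if (!all(dim(m) == c(S, S))) m <- to_uint8(resample_to(m * 1, S), 0, 255)
    x <- array(m / 255, c(S, S, 1, 1))
    r <- net_forward(clf$net, x, train = FALSE)$raw
    clf$classes[which.max(r[1, seq_along(clf$classes)])]
  }, "")
}

# resample_to requires >= 16 px; replicate-pad tiny conv grids first.
rbind_pad <- function(m, minsize) {
  while (nrow(m) < minsize) m <- m[rep(seq_len(nrow(m)), each = 2),
                                   , drop = FALSE]
  while (ncol(m) < minsize) m <- m[, rep(seq_len(ncol(m)), each = 2),
                                   drop = FALSE]
  m
}

#' @export
print.attention_map <- function(x, ...) {
  cat(sprintf("<attention_map target=%s layer=%s max=%.2f%s>\n",
              x$target, x$layer_id, max(x$heat),
              if (x$all_zero) " (all zero)" else ""))
  invisible(x)
}

#' Fraction of attention mass inside a lesion mask
#'
#' @param map an `attention_map` (or heat matrix).
#' @param mask logical matrix, same shape; must be non-empty.
#' @return scalar in \[0, 1\]; for uniform heat it equals the mask's area
#'   fraction.
#' @export
localization_score <- function(map, mask) {
  heat <- if (inherits(map, "attention_map")) map$heat else map
  if (!all(dim(heat) == dim(mask)))
    stop("map and mask shapes differ", call. = FALSE)
  if (!any(mask)) stop("empty lesion mask", call. = FALSE)
  tot <- sum(heat)
  if (tot == 0) return(0)
  sum(heat[mask]) / tot
}

#' Write a Grad-CAM overlay PNG
#'
#' Grayscale input blended with a red-yellow colormapped heat layer
#' (alpha proportional to heat).
#'
#' @param map an `attention_map`.
#' @param img8 the 8-bit image that was explained.
#' @param path output PNG path.
#' @param alpha maximum blend weight of the heat layer.
#' @return invisibly, `path`.
#' @export
write_gradcam_png <- function(map, img8, path, alpha = 0.5) {
  g <- img8 / 255
  h <- map$heat
  r <- clamp(g + alpha * h, 0, 1)
  gg <- clamp(g + alpha * h * 0.6, 0, 1)
  b <- clamp(g - alpha * h * 0.6, 0, 1)
  arr <- array(c(r, gg, b), c(nrow(g), ncol(g), 3))
  png::writePNG(arr, path)
  invisible(path)
}
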