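## Downstream stage classification: pooled conv-encoder features, three
## classical classifiers (ridge logistic regression, RBF SVM, random
## forest) behind one interface, stratified k-fold cross-validation and
## table-shaped reporting.  The desk-scale feature extractor is the
## parameter network's own conv encoder; a pretrained backbone (e.g.
## DenseNet121 weights) can be plugged in as any function mapping an 8-bit
## image to a numeric vector.

#' Extract a feature vector from an 8-bit image
#'
#' Default backbone: the conv encoder of a [build_param_net] network run in
#' inference mode, with the adaptive-average-pooled activations flattened
#' into a fixed-length vector.  Any function `img8 -> numeric` can be
#' supplied instead (e.g. a wrapper around externally loaded pretrained
#' weights).
#'
#' @param img8 integer matrix in \[0, 255\].
#' @param backbone a `param_net`, or a function taking `img8`.
#' @return numeric feature vector with attribute `extractor_id`.
#' @export
extract_features <- function(img8, backbone) {
  check_uint8(img8)
  if (is.function(backbone)) {
    v <- backbone(img8)
    if (!is.numeric(v) || !all(is.finite(v)))
      stop("backbone must return finite numeric features", call. = FALSE)
    attr(v, "extractor_id") <- "custom"
    return(v)
  }
  if (!inherits(backbone, "param_net"))
    stop("unknown backbone: supply a param_net or a function", call. = FALSE)
  S <- backbone$cfg$input_size
  if (!all(dim(img8) == c(S, S))) {
    img8 <- to_uint8(resample_to(img8 * 1, S), lo = 0, hi = 255)
  }
  x <- array(img8 / 255, c(S, S, 1, 1))
  v <- as.numeric(net_forward(backbone, x, train = FALSE)$features)
  attr(v, "extractor_id") <- sprintf("param_net_encoder_%dd", length(v))
  v
}

# Confusion-matrix metrics.  Binary when `positive` is given; otherwise
# macro-averaged over classes.  Undefined ratios (no predicted positives /
# no actual positives) contribute 0, the conservative convention.
confusion_metrics <- function(truth, pred, positive = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  acc <- mean(truth == pred)
  one <- function(cls) {
    tp <- sum(pred == cls & truth == cls)
    fp <- sum(pred == cls & truth != cls)
    fn <- sum(pred != cls & truth == cls)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(ppv = prec, recall = rec, f1 = f1)
  }
  m <- if (!is.null(positive)) one(positive)
       else rowMeans(vapply(sort(unique(truth)), one, numeric(3)))
  c(acc = acc, m)
}

fit_predict_classifier <- function(model_id, xtr, ytr, xte, seed) {
  ytr <- factor(ytr)
  with_seed(seed, {
    if (model_id == "LR") {
      fam <- if (nlevels(ytr) == 2) "binomial" else "multinomial"
      # small training folds trip glmnet's class-size advisory; harmless here
      fit <- suppressWarnings(
        glmnet::glmnet(xtr, ytr, family = fam, alpha = 0,
                       lambda = 1 / nrow(xtr)))
      as.character(stats::predict(fit, xte, type = "class"))
    } else if (model_id == "SVM") {
      fit <- e1071::svm(xtr, ytr, kernel = "radial", cost = 1, scale = FALSE)
      as.character(stats::predict(fit, xte))
    } else if (model_id == "RF") {
      fit <- randomForest::randomForest(xtr, ytr, ntree = 500)
      as.character(stats::predict(fit, xte))
    } else stop("unknown model_id: ", model_id, call. = FALSE)
  })
}

#' Stratified k-fold cross-validated classification
#'
#' Stratified fold assignment (seeded), per-fold feature standardization
#' fitted on the training portion only, then fit/predict with one of the
#' three supported classifiers: `"LR"` (ridge-penalized logistic
#' regression), `"SVM"` (RBF kernel, cost 1) or `"RF"` (random forest, 500
#' trees).  PPV/recall/F1 are macro-averaged for multiclass labels.
#'
#' @param features numeric matrix, one row per sample.
#' @param labels vector of class labels.
#' @param model_id `"LR"`, `"SVM"` or `"RF"`.
#' @param k number of folds (default 25).
#' @param seed fold-assignment seed.
#' @param positive optional positive class for binary metrics.
#' @param strict if `TRUE`, error when a class has fewer than `k` samples;
#'   otherwise reduce `k` with a warning.
#' @return a `classification_report`: list with `folds` (per-fold metric
#'   data.frame), `summary` (mean and SD per metric), `k`, `model_id`,
#'   `labels`.
#' @export
crossval_classify <- function(features, labels, model_id = "LR", k = 25,
                              seed = 1L, positive = NULL, strict = FALSE) {
  features <- as.matrix(features)
  if (nrow(features) != length(labels))
    stop("features and labels disagree in length", call. = FALSE)
  labels <- as.character(labels)
  mincl <- min(table(labels))
  if (mincl < k) {
    if (strict)
      stop(sprintf("smallest class has %d < k = %d samples", mincl, k),
           call. = FALSE)
    warning(sprintf("reducing k from %d to %d (smallest class size)",
                    k, mincl), call. = FALSE)
    k <- mincl
  }
  if (k < 2) stop("need at least 2 folds", call. = FALSE)
  fold <- integer(length(labels))
  with_seed(derive_seed(seed, "folds"), {
    for (cl in unique(labels)) {
      ix <- sample(which(labels == cl))
      fold[ix] <- rep_len(seq_len(k), length(ix))
    }
  })
  rows <- lapply(seq_len(k), function(f) {
    te <- fold == f; tr <- !te
    mu <- colMeans(features[tr, , drop = FALSE])
    sdv <- apply(features[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- 1
    xtr <- sweep(sweep(features[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
    xte <- sweep(sweep(features[te, , drop = FALSE], 2, mu), 2, sdv, "/")
    pred <- fit_predict_classifier(model_id, xtr, labels[tr], xte,
                                   derive_seed(seed, "fit", f))
    data.frame(fold = f,
               t(confusion_metrics(labels[te], pred, positive)))
  })
  folds <- do.call(rbind, rows)
  met <- c("acc", "ppv", "recall", "f1")
  summ <- data.frame(metric = met,
                     mean = vapply(met, function(m) mean(folds[[m]]), 0),
                     sd = vapply(met, function(m) stats::sd(folds[[m]]), 0))
  rownames(summ) <- NULL
  structure(list(folds = folds, summary = summ, k = k, model_id = model_id,
                 labels = sort(unique(labels))),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report %s, %d-fold, classes: %s>\n",
              x$model_id, x$k, paste(x$labels, collapse = ", ")))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-7s %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}

# Enhance one sample under a parameter source; returns the 8-bit image.
enhance_with_source <- function(sample, source, window, cfg, oracle_res) {
  img <- sample$image
  params <- if (inherits(source, "enhancement_params")) source
  else if (inherits(source, "param_net"))
    suppressWarnings(predict_params(source, img, window))
  else if (identical(source, "oracle"))
    grid_search_params(img, oracle_res, window = window, cfg = cfg)$params
  else stop("unknown parameter source", call. = FALSE)
  enhance_pipeline(img, params, window, cfg)$enhanced8
}

#' Enhancement-source ablation for stage classification
#'
#' For every non-normal stage, builds the stage-vs-normal binary task,
#' enhances each image under every parameter source (a fixed
#' [enhancement_params] triple, the string `"oracle"` for per-image grid
#' search, or a trained `param_net` -- a named list of nets selects the
#' net per stage), extracts features and cross-validates every classifier.
#'
#' @param samples list of `staged_sample` objects including normal
#'   controls.
#' @param param_sources named list of sources (e.g. `list(static = ...,
#'   network = ...)`).
#' @param backbone feature extractor for [extract_features].
#' @param classifiers character subset of `c("LR", "SVM", "RF")`.
#' @param k folds.
#' @param seed seed.
#' @param window a [window_config].
#' @param cfg a [clahe_config].
#' @param oracle_res grid resolution for the `"oracle"` source.
#' @return data.frame with one row per stage x source x classifier, mean
#'   and SD columns per metric.
#' @export
enhancement_ablation <- function(samples, param_sources, backbone,
                                 classifiers = c("LR", "SVM", "RF"),
                                 k = 5, seed = 1L,
                                 window = window_config(),
                                 cfg = clahe_config(), oracle_res = 5) {
  stages <- vapply(samples, function(s) s$stage, "")
  if (!any(stages == "normal"))
    stop("stage-vs-normal tasks need normal controls", call. = FALSE)
  lesion_stages <- setdiff(unique(stages), "normal")
  out <- list()
  for (st in lesion_stages) {
    ix <- which(stages %in% c(st, "normal"))
    for (src_name in names(param_sources)) {
      src <- param_sources[[src_name]]
      if (is.list(src) && !inherits(src, "enhancement_params") &&
          !inherits(src, "param_net"))
        src <- src[[st]] %||% src[[1]]
      feats <- t(vapply(ix, function(i) {
        e8 <- enhance_with_source(samples[[i]], src, window, cfg, oracle_res)
        as.numeric(extract_features(e8, backbone))
      }, extract_features(
        enhance_with_source(samples[[ix[1]]], src, window, cfg, oracle_res),
        backbone) * 0))
      for (cls in classifiers) {
        rep <- crossval_classify(feats, stages[ix], cls, k = k,
                                 seed = derive_seed(seed, st, src_name, cls),
                                 positive = st)
        s <- rep$summary
        out[[length(out) + 1L]] <- data.frame(
          stage = st, source = src_name, classifier = cls, k = rep$k,
          acc = s$mean[s$metric == "acc"], acc_sd = s$sd[s$metric == "acc"],
          ppv = s$mean[s$metric == "ppv"], ppv_sd = s$sd[s$metric == "ppv"],
          recall = s$mean[s$metric == "recall"],
          recall_sd = s$sd[s$metric == "recall"],
          f1 = s$mean[s$metric == "f1"], f1_sd = s$sd[s$metric == "f1"])
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
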