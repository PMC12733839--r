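test_that("confusion metrics match hand-computed values", {
  # TP=3, FP=1, FN=1, TN=5
  truth <- c(rep("pos", 4), rep("neg", 6))
  pred <- c("pos", "pos", "pos", "neg", "pos", rep("neg", 5))
  m <- asNamespace("deepclahe")$confusion_metrics(truth, pred,
                                                  positive = "pos")
  expect_equal(unname(m["acc"]), 0.8)
  expect_equal(unname(m["ppv"]), 0.75)
  expect_equal(unname(m["recall"]), 0.75)
  expect_equal(unname(m["f1"]), 0.75)
})

test_that("separable features give perfect cross-validated accuracy", {
  set.seed(1)
  x <- rbind(matrix(rnorm(50 * 3, 0), 50),
             matrix(rnorm(50 * 3, 8), 50))
  y <- rep(c("a", "b"), each = 50)
  for (mdl in c("LR", "SVM", "RF")) {
    rep <- crossval_classify(x, y, mdl, k = 5, seed = 2, positive = "b")
    expect_equal(rep$summary$mean[rep$summary$metric == "acc"], 1)
    expect_equal(rep$summary$sd[rep$summary$metric == "acc"], 0)
  }
})

test_that("permuted labels score at chance level", {
  set.seed(7)
  x <- matrix(rnorm(120 * 4), 120)
  y <- sample(rep(c("a", "b"), each = 60))   # labels independent of x
  rep <- crossval_classify(x, y, "LR", k = 5, seed = 3, positive = "b")
  acc <- rep$folds$acc
  expect_lt(abs(mean(acc) - 0.5), 3 * stats::sd(acc) + 1e-9)
})

test_that("stratified folds partition every sample exactly once", {
  set.seed(5)
  x <- matrix(rnorm(100 * 3), 100)
  y <- rep(c("a", "b"), each = 50)
  rep <- crossval_classify(x, y, "LR", k = 25, seed = 9, positive = "b")
  expect_equal(rep$k, 25)
  # per-fold test sizes must sum to n with stratified balance
  expect_equal(nrow(rep$folds), 25)
  # reconstruct fold assignment the same way and verify the partition
  fold <- integer(length(y))
  dc <- asNamespace("deepclahe")
  dc$with_seed(dc$derive_seed(9, "folds"), {
    for (cl in unique(y)) {
      ix <- sample(which(y == cl))
      fold[ix] <- rep_len(seq_len(25), length(ix))
    }
  })
  expect_true(all(fold >= 1 & fold <= 25))
  expect_equal(sum(table(fold)), 100)
  expect_true(all(table(fold, y) >= 1))
})

test_that("report invariants hold and k reduces with small classes", {
  set.seed(2)
  x <- matrix(rnorm(30 * 3), 30)
  y <- rep(c("a", "b"), c(20, 10))
  expect_warning(rep <- crossval_classify(x, y, "RF", k = 25, seed = 1,
                                          positive = "b"), "reducing k")
  expect_equal(rep$k, 10)
  expect_true(all(rep$summary$mean >= 0 & rep$summary$mean <= 1))
  expect_true(all(rep$summary$sd >= 0))
  expect_error(crossval_classify(x, y, "RF", k = 25, strict = TRUE),
               "smallest class")
  expect_error(crossval_classify(x, y[1:10], "LR"), "disagree")
  expect_error(crossval_classify(x, y, "boost", k = 5), "unknown model_id")
})

test_that("cross-validation reports are reproducible under fixed seeds", {
  set.seed(11)
  x <- matrix(rnorm(60 * 5), 60)
  y <- rep(c("a", "b"), each = 30)
  r1 <- crossval_classify(x, y, "RF", k = 5, seed = 4, positive = "b")
  r2 <- crossval_classify(x, y, "RF", k = 5, seed = 4, positive = "b")
  expect_identical(r1$folds, r2$folds)
})

test_that("feature extraction is deterministic and level-sensitive", {
  net <- build_param_net(micro_net_cfg(seed = 8))
  img <- matrix(120L, 32, 32)
  f1 <- extract_features(img, net)
  f2 <- extract_features(img, net)
  expect_identical(f1, f2)
  expect_true(all(is.finite(f1)))
  f3 <- extract_features(matrix(30L, 32, 32), net)
  expect_false(isTRUE(all.equal(as.numeric(f1), as.numeric(f3))))
  expect_length(f3, length(f1))
  # custom function backbone
  f4 <- extract_features(img, function(m) c(mean(m), stats::sd(m)))
  expect_equal(as.numeric(f4), c(120, 0))
  expect_error(extract_features(img, "densenet"), "unknown backbone")
})

test_that("enhancement ablation emits one row per stage, source, classifier", {
  samples <- c(lapply(1:6, function(i)
                 local_phantom("chronic", seed = 40 + i)),
               lapply(1:6, function(i)
                 local_phantom("normal", seed = 60 + i)))
  net <- build_param_net(micro_net_cfg(seed = 1))
  tbl <- enhancement_ablation(
    samples,
    param_sources = list(static = enhancement_params(1.25, 0, 1),
                         network = net),
    backbone = net, classifiers = c("LR", "RF"), k = 3, seed = 5)
  expect_equal(nrow(tbl), 1 * 2 * 2)
  expect_setequal(unique(tbl$source), c("static", "network"))
  expect_true(all(tbl$acc >= 0 & tbl$acc <= 1))
  tbl2 <- enhancement_ablation(
    samples,
    param_sources = list(static = enhancement_params(1.25, 0, 1),
                         network = net),
    backbone = net, classifiers = c("LR", "RF"), k = 3, seed = 5)
  expect_identical(tbl, tbl2)
})
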