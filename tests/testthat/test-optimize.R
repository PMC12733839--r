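test_that("grid search returns a verified argmin with deterministic ties", {
  s <- local_phantom("acute", seed = 12)
  im <- resample_to(s$image, 64)
  res <- grid_search_params(im, 5)
  # independent re-evaluation of every grid point confirms the argmin
  dc <- asNamespace("deepclahe")
  expect_equal(min(res$losses), res$loss)
  recheck <- dc$pipeline_loss(im, res$params)$loss
  expect_equal(recheck, res$loss, tolerance = 1e-12)
  # the midpoint triple is on every odd grid; argmin can only be better
  mid <- dc$pipeline_loss(im, enhancement_params(1.25, 0, 1.05))$loss
  expect_lte(res$loss, mid)
})

test_that("finer grids never lose to coarser grids", {
  s <- local_phantom("subacute", seed = 13)
  im <- resample_to(s$image, 64)
  l3 <- grid_search_params(im, 3)$loss
  l9 <- grid_search_params(im, 9)$loss
  expect_lte(l9, l3)   # 9-point axes contain the 3-point axes
  aniso <- grid_search_params(im, c(3, 3, 5))
  expect_equal(dim(aniso$losses), c(3L, 3L, 5L))
  expect_error(grid_search_params(im, 2), ">= 3")
})

test_that("saturating constant input leaves only the regularizer active", {
  # air-valued constant slice: every transform windows to constant 0 and
  # CLAHE passes constants through, so EME = 0 and PSNR caps for all
  # parameters; the argmin is the midpoint triple (smallest reg term)
  im <- hu_image(matrix(-1000, 32, 32))
  res <- grid_search_params(im, 5)
  expect_equal(res$params$alpha, 1.25)
  expect_equal(res$params$beta, 0)
  expect_equal(res$params$gamma_clip, 1.05)
})

test_that("short training run completes, logs history and reduces loss", {
  samples <- make_dataset(10, "chronic", base_seed = 15, image_size = 64)
  net <- build_param_net(tiny_net_cfg(seed = 5))
  tr <- train_param_net(samples, net,
                        train_config(epochs = 2, batch_size = 4,
                                     learning_rate = 0.01, seed = 3))
  expect_equal(nrow(tr$history), 2)
  expect_true(all(is.finite(tr$history$train_loss)))
  expect_true(all(c("val_loss", "val_eme", "val_psnr") %in%
                  names(tr$history)))
  expect_true(isTRUE(attr(tr$net, "trained")))
  expect_error(train_param_net(list(), net), "empty")
  expect_error(train_param_net(samples, net,
                               train_config(stage_filter = "normal")),
               "stage_filter")
})

test_that("training histories are bit-reproducible under fixed seeds", {
  samples <- make_dataset(6, "acute", base_seed = 21, image_size = 64)
  cfg <- micro_net_cfg(seed = 9)
  t1 <- train_param_net(samples, build_param_net(cfg),
                        train_config(epochs = 2, batch_size = 3,
                                     learning_rate = 0.01, seed = 11))
  t2 <- train_param_net(samples, build_param_net(cfg),
                        train_config(epochs = 2, batch_size = 3,
                                     learning_rate = 0.01, seed = 11))
  expect_identical(t1$history, t2$history)
  dc <- asNamespace("deepclahe")
  expect_identical(dc$net_checksum(t1$net), dc$net_checksum(t2$net))
})

test_that("stage parameter summaries respect ranges and shrink with n", {
  net <- build_param_net(micro_net_cfg(seed = 2))
  mk <- function(n, stage, seed0)
    lapply(seq_len(n), function(i)
      local_phantom(stage, size = 32, seed = seed0 + i))
  small <- c(mk(5, "acute", 200), mk(5, "normal", 300))
  summ <- summarize_stage_params(net, small)
  expect_s3_class(summ, "stage_param_summary")
  expect_setequal(summ$stage, c("acute", "normal"))
  for (p in c("slope", "intercept", "clip")) {
    expect_true(all(summ[[paste0(p, "_lb")]] <= summ[[paste0(p, "_ub")]]))
  }
  expect_true(all(summ$slope_lb >= 0.5 & summ$slope_ub <= 2))
  expect_true(all(summ$clip_lb >= 0.1 & summ$clip_ub <= 2))
  # CI width shrinks roughly as 1/sqrt(n) on the same distribution
  big <- mk(20, "acute", 400)
  w_small <- with(summarize_stage_params(net, mk(6, "acute", 400)),
                  clip_ub - clip_lb)
  w_big <- with(summarize_stage_params(net, big), clip_ub - clip_lb)
  expect_lte(w_big, w_small + 1e-12)
  expect_error(summarize_stage_params(net, mk(1, "acute", 1)), "fewer than 2")
})

test_that("checkpoints round-trip through disk", {
  net <- build_param_net(micro_net_cfg(seed = 3))
  path <- tempfile(fileext = ".rds")
  save_param_net(net, path)
  back <- load_param_net(path)
  dc <- asNamespace("deepclahe")
  expect_identical(dc$net_checksum(net), dc$net_checksum(back))
  expect_identical(back$cfg, net$cfg)
  unlink(path)
})
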