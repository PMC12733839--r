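# Build a hand-crafted cam_classifier whose score is driven by one conv
# channel that passes brightness straight through: conv centers 1 in one
# channel, batch-norm neutralized, so bright regions stay bright down the
# stack and the linear head reads only that channel.
handmade_classifier <- function(cfg = micro_net_cfg(seed = 1)) {
  cfg$input_size <- 128L   # 4x4 map at the target conv layer
  net <- build_param_net(cfg)
  for (i in seq_along(net$conv)) {
    W <- matrix(0, nrow(net$conv[[i]]$W), ncol(net$conv[[i]]$W))
    W[5, 1] <- 1             # center tap of input channel 1 -> channel 1
    net$conv[[i]]$W <- W
    net$conv[[i]]$b <- rep(0, length(net$conv[[i]]$b))
    net$bn[[i]]$gamma <- rep(1, length(net$bn[[i]]$gamma))
    net$bn[[i]]$beta <- rep(0, length(net$bn[[i]]$beta))
    net$bn[[i]]$rmean <- rep(0, length(net$bn[[i]]$rmean))
    net$bn[[i]]$rvar <- rep(1, length(net$bn[[i]]$rvar))
  }
  C <- utils::tail(cfg$conv_channels, 1)
  P <- cfg$pooled_size
  w_pos <- rep(c(1, rep(0, C - 1)), each = P * P)   # read channel 1 only
  structure(list(encoder = net,
                 W = cbind(neg = -w_pos, pos = w_pos),
                 b = c(0, 0), classes = c("neg", "pos")),
            class = "cam_classifier")
}

test_that("attention maps are input-shaped, normalized and targeted", {
  clf <- handmade_classifier()
  img8 <- matrix(0L, 128, 128)
  img8[20:55, 70:115] <- 200L    # bright square
  map <- gradcam(clf, img8, "pos")
  expect_identical(dim(map$heat), dim(img8))
  expect_gte(min(map$heat), 0); expect_lte(max(map$heat), 1)
  expect_equal(max(map$heat), 1)
  expect_false(map$all_zero)
  # peak lies inside the known active region (one pooled cell of slack)
  pk <- which(map$heat == max(map$heat), arr.ind = TRUE)[1, ]
  expect_true(pk[1] >= 1 && pk[1] <= 80 && pk[2] >= 48 && pk[2] <= 128)
  mask <- matrix(FALSE, 128, 128); mask[20:55, 70:115] <- TRUE
  expect_gt(localization_score(map, mask), mean(mask))
})

test_that("negating the score flips the map through the ReLU", {
  clf <- handmade_classifier()
  img8 <- matrix(0L, 128, 128)
  img8[20:55, 70:115] <- 200L
  pos <- gradcam(clf, img8, "pos")
  neg <- gradcam(clf, img8, "neg")
  expect_true(neg$all_zero)            # all gradients negative -> ReLU zeroes
  expect_false(isTRUE(all.equal(pos$heat, neg$heat)))
})

test_that("maps are invariant to positive rescaling of activations", {
  clf <- handmade_classifier()
  img8 <- matrix(0L, 128, 128)
  img8[40:80, 10:60] <- 180L
  m1 <- gradcam(clf, img8, "pos")
  clf2 <- clf
  for (i in seq_along(clf2$encoder$bn))
    clf2$encoder$bn[[i]]$gamma <- clf2$encoder$bn[[i]]$gamma * 3
  m2 <- gradcam(clf2, img8, "pos")
  expect_equal(m1$heat, m2$heat, tolerance = 1e-9)
})

test_that("localization score is a heat-mass fraction", {
  heat <- matrix(1, 32, 32)
  mask <- matrix(FALSE, 32, 32); mask[1:8, 1:13] <- TRUE
  map <- structure(list(heat = heat / max(heat)), class = "attention_map")
  expect_equal(localization_score(map, mask), sum(mask) / length(mask))
  heat2 <- matrix(0, 32, 32); heat2[mask] <- 1
  expect_equal(localization_score(structure(list(heat = heat2),
                                            class = "attention_map"), mask),
               1)
  expect_error(localization_score(map, matrix(FALSE, 32, 32)), "empty")
  expect_error(localization_score(map, matrix(TRUE, 16, 16)), "differ")
})

test_that("a trained classifier attends to large chronic lesions", {
  samples <- c(lapply(1:10, function(i)
                 local_phantom("chronic", seed = 500 + i)),
               lapply(1:10, function(i)
                 local_phantom("normal", seed = 600 + i)))
  imgs8 <- lapply(samples, function(s)
    asNamespace("deepclahe")$window_uint8(s$image))
  labels <- vapply(samples, function(s) s$stage, "")
  # a frozen random encoder + linear probe separates the classes...
  enc <- build_param_net(tiny_net_cfg(seed = 4, input_size = 128))
  probe <- train_linear_probe(enc, imgs8, labels, seed = 2)
  expect_gt(mean(predict_linear_probe(probe, imgs8) == labels), 0.95)
  # ... and an end-to-end trained classifier localizes its evidence
  cfg <- param_net_config(conv_channels = c(8, 12, 16, 24, 32),
                          fc_widths = c(128, 64, 16, 3),
                          dropout_rate = 0.1, pooled_size = 4,
                          input_size = 128, seed = 4)
  clf <- train_image_classifier(imgs8, labels, cfg, epochs = 10,
                                batch_size = 8, learning_rate = 3e-3,
                                seed = 2)
  expect_gt(mean(predict_image_classifier(clf, imgs8) == labels), 0.95)
  # attention concentrates on lesions more than uniform attention would
  scores <- vapply(which(labels == "chronic"), function(i) {
    map <- gradcam(clf, imgs8[[i]], "chronic")
    mask <- samples[[i]]$lesion_mask
    localization_score(map, mask) / mean(mask)
  }, 0)
  expect_gt(mean(scores), 1)
})

test_that("gradcam overlay writer emits a readable PNG", {
  clf <- handmade_classifier()
  img8 <- matrix(0L, 128, 128); img8[20:55, 70:115] <- 200L
  map <- gradcam(clf, img8, "pos")
  path <- tempfile(fileext = ".png")
  write_gradcam_png(map, img8, path)
  arr <- png::readPNG(path)
  expect_equal(dim(arr), c(128, 128, 3))
  unlink(path)
})
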