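test_that("linear transform is exact, invertible and range-guarded", {
  img <- hu_image(matrix(40, 16, 16))
  expect_equal(linear_transform(img, 1, 0)$pixels, img$pixels)
  expect_equal(linear_transform(img, 1.25, -0.05)$pixels[1, 1], 49.95)
  # invertible for alpha != 0
  set.seed(2)
  m <- hu_image(matrix(rnorm(256, 30, 10), 16))
  fwd <- linear_transform(m, 1.6, 3)
  back <- hu_image((fwd$pixels - 3) / 1.6)
  expect_equal(back$pixels, m$pixels, tolerance = 1e-12)
  expect_error(linear_transform(img, 3.0, 0), "range")
  expect_error(linear_transform(img, 1, 9), "range")
  expect_error(enhancement_params(1, 0, 5), "range")
})

test_that("clahe matches the per-pixel reference implementation", {
  for (seed in 1:4) {
    img8 <- rand_uint8(48, 48, seed = seed)
    for (clip in c(0.5, 1, 2, Inf)) {
      expect_equal(clahe(img8, clahe_config(tiles = c(4, 4),
                                            clip_limit = clip)),
                   clahe_reference(img8, c(4, 4), clip),
                   ignore_attr = TRUE)
    }
  }
  # non-square image, non-dividing tile grid (exercises reflection padding)
  img8 <- rand_uint8(50, 38, seed = 9)
  expect_equal(clahe(img8, clahe_config(tiles = c(3, 5), clip_limit = 1)),
               clahe_reference(img8, c(3, 5), 1), ignore_attr = TRUE)
})

test_that("single-tile unclipped clahe equals global histogram equalization", {
  for (seed in 1:6) {
    img8 <- rand_uint8(64, 64, seed = seed)
    expect_identical(clahe(img8, clahe_config(tiles = 1, clip_limit = Inf)),
                     he(img8))
  }
})

test_that("clahe degenerate and range contracts", {
  cst <- matrix(77L, 32, 32)
  expect_identical(clahe(cst, clahe_config()), cst)  # constant passes through
  img8 <- rand_uint8(40, 40, seed = 3)
  out <- clahe(img8, clahe_config(tiles = c(5, 5), clip_limit = 0.3))
  expect_gte(min(out), 0); expect_lte(max(out), 255)
  expect_identical(dim(out), dim(img8))
  expect_error(clahe(img8, clahe_config(tiles = c(40, 40))), "2 x 2")
  expect_error(clahe(matrix(300L, 32, 32), clahe_config()), "0, 255")
})

test_that("histogram equalization flattens and maps the two-level example", {
  # equal counts at levels 10 and 20 -> approximately 127/128 and 255
  img8 <- matrix(c(rep(10L, 128), rep(20L, 128)), 16)
  out <- he(img8)
  lv <- sort(unique(as.vector(out)))
  expect_lte(abs(lv[1] - 127), 1)
  expect_identical(lv[2], 255L)
  # 16-bin histogram variance does not increase for rich inputs
  img8 <- rand_uint8(64, 64, seed = 5)^2 %/% 256   # skewed distribution
  hvar <- function(m) stats::var(tabulate(m %/% 16 + 1, 16) / length(m))
  expect_lte(hvar(he(check8(img8))), hvar(check8(img8)))
})

test_that("classical enhancers: identities, degenerate cases, ranges", {
  img8 <- rand_uint8(32, 32, seed = 7)
  expect_equal(gamma_correct(img8, g = 1), img8, ignore_attr = TRUE)
  expect_equal(power_law(img8, c = 1, g = 1), img8, ignore_attr = TRUE)
  expect_identical(log_transform(matrix(0L, 16, 16))[1, 1], 0L)
  expect_identical(ahe(img8), clahe(img8, clahe_config(clip_limit = Inf)))
  for (f in list(function(x) gamma_correct(x, 0.4),
                 function(x) power_law(x, 1.2, 2),
                 function(x) log_transform(x, 0.8),
                 he, ahe)) {
    out <- f(img8)
    expect_gte(min(out), 0); expect_lte(max(out), 255)
    expect_identical(dim(out), dim(img8))
  }
  expect_error(gamma_correct(img8, g = -1), "positive")
  expect_error(log_transform(img8, c = 0), "positive")
})

test_that("enhancement pipeline composes its stages and is deterministic", {
  s <- local_phantom("subacute", seed = 6)
  p <- enhancement_params(1, 0, 1.0)
  res <- enhance_pipeline(s$image, p)
  # identity LT: pre-CLAHE stage equals the windowed 8-bit original
  expect_identical(res$pre_clahe8, res$ref8)
  expect_identical(res$enhanced8,
                   clahe(res$ref8, clahe_config(clip_limit = 1)))
  res2 <- enhance_pipeline(s$image, p)
  expect_identical(res2$enhanced8, res$enhanced8)
  # on a two-tone image the stretched pipeline raises EME over the input
  m <- matrix(20, 64, 64); m[, 33:64] <- 45
  set.seed(1)
  two <- hu_image(m + matrix(rnorm(64 * 64, 0, 1), 64))
  res3 <- enhance_pipeline(two, enhancement_params(1.25, 0, 1.0))
  expect_gte(eme(res3$enhanced8), eme(res3$ref8))
})
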