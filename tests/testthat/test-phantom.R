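test_that("identical spec and seed give bit-identical phantoms", {
  a <- local_phantom("acute", seed = 9)
  b <- local_phantom("acute", seed = 9)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$lesion_mask, b$lesion_mask)
  c <- local_phantom("acute", seed = 10)
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("normal stage has no lesion; other stages have in-brain masks", {
  nrm <- local_phantom("normal", seed = 1)
  expect_equal(sum(nrm$lesion_mask), 0)
  expect_equal(nrm$spec$lesion_delta_hu, 0)
  for (st in c("hyperacute", "acute", "subacute", "chronic")) {
    s <- local_phantom(st, seed = 4)
    expect_gt(sum(s$lesion_mask), 0)
    # mask entirely inside the brain: all mask pixels well above air
    clean <- make_phantom(modifyList2(s$spec, lesion_delta_hu = 0,
                                      noise_sd = 0))
    expect_true(all(clean$image$pixels[s$lesion_mask] > 0))
  }
})

test_that("noiseless hard-edge lesion lowers mask mean by exactly delta", {
  sp <- phantom_spec("chronic", image_size = 64, noise_sd = 0,
                     edge_softness = 0, lesion_delta_hu = -20, seed = 3)
  les <- make_phantom(sp)
  clean <- make_phantom(modifyList2(sp, lesion_delta_hu = 0))
  d <- mean(les$image$pixels[les$lesion_mask]) -
       mean(clean$image$pixels[clean$lesion_mask])
  expect_equal(d, -20, tolerance = 1e-12)
  # soft edges only erode the boundary: depth shrinks slightly, never grows
  sp2 <- modifyList2(sp, edge_softness = 0.5)
  les2 <- make_phantom(sp2)
  d2 <- mean(les2$image$pixels[les2$lesion_mask]) -
        mean(clean$image$pixels[clean$lesion_mask])
  expect_gt(d2, -20)
  expect_lt(d2, -18)
})

test_that("stage defaults order lesion depth hyperacute -> chronic", {
  deltas <- vapply(c("hyperacute", "acute", "subacute", "chronic"),
                   function(st) abs(default_stage_spec(st)$lesion_delta_hu),
                   0)
  expect_true(all(diff(deltas) > 0))
  # chronic lesions sit near CSF attenuation (volume-loss analog)
  ch <- default_stage_spec("chronic")
  expect_lt(abs((ch$wm_hu + ch$lesion_delta_hu) - ch$csf_hu), 5)
  # all five stage specs are valid and distinct
  specs <- lapply(STAGES_local(), default_stage_spec)
  expect_length(unique(vapply(specs, function(s) s$stage, "")), 5)
})

test_that("measured lesion contrast increases monotonically with stage", {
  contrast <- vapply(c("hyperacute", "acute", "subacute", "chronic"),
                     function(st) {
    sp <- default_stage_spec(st, seed = 8)
    sp$noise_sd <- 0; sp$image_size <- 64L
    les <- make_phantom(sp)
    clean <- make_phantom(modifyList2(sp, lesion_delta_hu = 0))
    abs(mean(les$image$pixels[les$lesion_mask]) -
        mean(clean$image$pixels[clean$lesion_mask]))
  }, 0)
  expect_true(all(diff(contrast) > 0))
})

test_that("phantoms respect CT bounds and rejection rules", {
  s <- local_phantom("chronic", seed = 2, noise_sd = 50)
  expect_gte(min(s$image$pixels), -1024)
  expect_lte(max(s$image$pixels), 3071)
  expect_error(phantom_spec("chronic", image_size = 8), "at least")
  expect_error(phantom_spec("chronic", lesion_delta_hu = 5), "hypodense")
  expect_error(make_phantom(phantom_spec("chronic",
                                         lesion_radius_frac = 2)),
               "larger than the brain")
  expect_error(phantom_spec("acute", gm_hu = 30, wm_hu = 32), "gm_hu")
})

test_that("dataset generation counts, augmentation factor and determinism", {
  d <- make_dataset(4, stages = STAGES_local(), base_seed = 5,
                    image_size = 64)
  expect_length(d, 20)
  da <- make_dataset(4, stages = STAGES_local(), base_seed = 5,
                     augment = TRUE, image_size = 64)
  expect_length(da, 60)   # flip + rotation triple the set
  d2 <- make_dataset(4, stages = STAGES_local(), base_seed = 5,
                     image_size = 64)
  expect_identical(lapply(d, function(s) s$image$pixels),
                   lapply(d2, function(s) s$image$pixels))
  expect_error(make_dataset(3, stages = character()), "non-empty")
})

test_that("augmented copies preserve stage and transform the mask", {
  da <- make_dataset(1, stages = "chronic", base_seed = 11, augment = TRUE,
                     image_size = 64)
  expect_length(da, 3)
  expect_true(all(vapply(da, function(s) s$stage, "") == "chronic"))
  base <- da[[1]]; flipped <- da[[2]]
  expect_identical(flipped$image$pixels,
                   base$image$pixels[, 64:1])
  expect_identical(flipped$lesion_mask, base$lesion_mask[, 64:1])
  rot <- da[[3]]
  expect_gt(sum(rot$lesion_mask), 0.5 * sum(base$lesion_mask))
})

test_that("scanner variation applies the recorded affine draw", {
  s <- local_phantom("normal", seed = 1)
  same <- apply_scanner_variation(s$image, 0, 0, seed = 3)
  expect_equal(same$pixels, s$image$pixels)
  plus2 <- apply_scanner_variation(s$image, 0, c(2, 2), seed = 3)
  expect_equal(plus2$pixels, clampCT(s$image$pixels + 2))
  a <- apply_scanner_variation(s$image, 0.05, 3, seed = 9)
  b <- apply_scanner_variation(s$image, 0.05, 3, seed = 9)
  expect_identical(a$pixels, b$pixels)
  expect_named(a$provenance$scanner_draw, c("slope", "intercept"))
})
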