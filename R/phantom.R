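## Synthetic brain-CT phantoms.  Each phantom is an elliptical skull ring
## enclosing a gray-matter band, a white-matter core and a central CSF
## ventricle, with one optional hypodense lesion whose depth and extent
## depend on the temporal stage of the simulated infarct.  The generator
## exists so that every downstream stage (enhancement, optimization,
## classification, interpretability) is testable without patient data; it
## emulates the statistical structure of real non-contrast CT -- subtle
## GM/WM contrast, stage-dependent hypodensity, scanner noise and affine
## inter-scanner jitter -- not anatomy.

STAGES <- c("hyperacute", "acute", "subacute", "chronic", "normal")

# Per-stage lesion depth in HU below surrounding tissue.  The temporal
# ordering (hyperacute barely below the 2 HU noise floor, chronic dropping
# white matter to near-CSF attenuation, the gliosis/volume-loss analog) is a
# documented package convention: clinical stage descriptions are
# qualitative and publish no HU numbers.
STAGE_DELTAS <- c(hyperacute = -3, acute = -6, subacute = -12,
                  chronic = -22, normal = 0)
STAGE_RADII <- c(hyperacute = 0.30, acute = 0.30, subacute = 0.35,
                 chronic = 0.30, normal = 0)

#' Specification of a synthetic CT phantom
#'
#' @param stage one of `"hyperacute"`, `"acute"`, `"subacute"`, `"chronic"`,
#'   `"normal"`.
#' @param image_size side length in pixels (default 256; 512 matches a
#'   clinical matrix).
#' @param gm_hu,wm_hu,csf_hu,skull_hu mean attenuation of gray matter, white
#'   matter, CSF and bone, in HU.  Must satisfy
#'   `skull_hu > gm_hu > wm_hu > csf_hu >= 0`.
#' @param noise_sd additive Gaussian scanner-noise SD in HU.
#' @param lesion_delta_hu mean lesion hypodensity relative to surrounding
#'   tissue (HU, must be <= 0; forced to 0 for the normal stage).
#' @param lesion_radius_frac lesion radius as a fraction of the brain's
#'   semi-minor axis.
#' @param edge_softness Gaussian blur SD (pixels) applied to the lesion
#'   boundary; 0 gives a hard edge.
#' @param seed RNG seed; identical spec + seed gives bit-identical phantoms.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(stage, image_size = 256,
                         gm_hu = 40, wm_hu = 32, csf_hu = 8, skull_hu = 700,
                         noise_sd = 2,
                         lesion_delta_hu = STAGE_DELTAS[[stage]],
                         lesion_radius_frac = if (stage == "normal") 0 else
                           STAGE_RADII[[stage]],
                         edge_softness = 1, seed = 1L) {
  stage <- match.arg(stage, STAGES)
  stopifnot_scalar(image_size, "image_size")
  if (image_size < 32) stop("image_size must be at least 32", call. = FALSE)
  if (stage == "normal") lesion_delta_hu <- 0
  if (!(gm_hu > wm_hu && wm_hu > csf_hu && csf_hu >= 0))
    stop("tissue attenuations must satisfy gm_hu > wm_hu > csf_hu >= 0",
         call. = FALSE)
  if (skull_hu <= gm_hu) stop("skull_hu must exceed gm_hu", call. = FALSE)
  if (lesion_delta_hu > 0)
    stop("lesion_delta_hu must be <= 0 (ischemic lesions are hypodense)",
         call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  structure(list(stage = stage, image_size = as.integer(image_size),
                 gm_hu = gm_hu, wm_hu = wm_hu, csf_hu = csf_hu,
                 skull_hu = skull_hu, noise_sd = noise_sd,
                 lesion_delta_hu = lesion_delta_hu,
                 lesion_radius_frac = lesion_radius_frac,
                 edge_softness = edge_softness, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default phantom specification for a temporal stage
#'
#' Returns the package's documented per-stage defaults.  Lesion depth
#' increases in magnitude from hyperacute (-3 HU, below the default 2 HU
#' noise floor, so detection is genuinely hard) through acute (-6) and
#' subacute (-12, with a slightly larger radius for edema/swelling) to
#' chronic (-22 HU, bringing white matter near CSF attenuation as a
#' volume-loss analog).
#'
#' @param stage stage label.
#' @param seed RNG seed stored in the spec.
#' @return a [phantom_spec].
#' @export
default_stage_spec <- function(stage, seed = 1L) {
  stage <- match.arg(stage, STAGES)
  phantom_spec(stage = stage, seed = seed)
}

# Normalized elliptical radius of every pixel w.r.t. center (cy, cx) and
# semi-axes (ay, ax); 0-based pixel-center coordinates.
ellipse_r <- function(size, cy, cx, ay, ax) {
  y <- matrix(seq_len(size) - 1, size, size)
  x <- matrix(seq_len(size) - 1, size, size, byrow = TRUE)
  sqrt(((y - cy) / ay)^2 + ((x - cx) / ax)^2)
}

# Separable Gaussian blur with clamped edges; sd in pixels.
gauss_blur <- function(m, sd) {
  if (sd <= 0) return(m)
  half <- max(1L, ceiling(3 * sd))
  k <- dnorm(seq(-half, half), sd = sd)
  k <- k / sum(k)
  pad <- function(v, n) c(rep(v[1], n), v, rep(v[length(v)], n))
  conv1 <- function(v) {
    stats::filter(pad(v, half), k, sides = 2)[(half + 1):(half + length(v))]
  }
  m1 <- apply(m, 2, conv1)
  t(apply(t(m1), 2, conv1))
}

#' Generate a synthetic stage-labeled CT phantom
#'
#' Builds the skull/GM/WM/CSF geometry described in [phantom_spec], carves
#' one elliptical hypodense lesion for non-normal stages (boundary smoothed
#' by `edge_softness`), adds seeded Gaussian noise and clamps to the CT
#' range \[-1024, 3071\] HU.  The lesion mask records lesion pixels before
#' boundary smoothing.
#'
#' @param spec a [phantom_spec].
#' @return a `staged_sample`: list with `image` ([hu_image]), `stage`,
#'   `lesion_mask` (logical matrix) and `spec`.
#' @export
make_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    stop("`spec` must be a phantom_spec", call. = FALSE)
  S <- spec$image_size
  cy <- (S - 1) / 2; cx <- (S - 1) / 2
  skull_ax <- 0.44 * S; skull_ay <- 0.48 * S   # head slightly taller than wide
  ring <- 0.035 * S
  brain_ax <- skull_ax - ring; brain_ay <- skull_ay - ring

  r_skull <- ellipse_r(S, cy, cx, skull_ay, skull_ax)
  r_brain <- ellipse_r(S, cy, cx, brain_ay, brain_ax)

  img <- matrix(-1000, S, S)                    # air
  img[r_skull <= 1] <- spec$skull_hu            # bone ring
  brain <- r_brain <= 1
  img[brain & r_brain > 0.78] <- spec$gm_hu     # cortical gray-matter band
  img[r_brain <= 0.78] <- spec$wm_hu            # white-matter core
  r_vent <- ellipse_r(S, cy, cx, 0.16 * brain_ay, 0.10 * brain_ax)
  img[r_vent <= 1] <- spec$csf_hu               # central ventricle

  mask <- matrix(FALSE, S, S)
  if (spec$stage != "normal") {
    if (spec$lesion_radius_frac <= 0)
      stop("non-normal stages need a positive lesion_radius_frac",
           call. = FALSE)
    les_r <- spec$lesion_radius_frac * brain_ax
    if (les_r >= 0.9 * brain_ax)
      stop("lesion larger than the brain region", call. = FALSE)
    placement <- with_seed(derive_seed(spec$seed, "lesion"), {
      side <- sample(c(-1, 1), 1)
      ang <- runif(1, -0.35 * pi, 0.35 * pi)
      # keep the whole lesion inside the brain, clear of the ventricle
      rad <- runif(1, 0.35, 0.9 - spec$lesion_radius_frac) * brain_ax
      c(side = side, ang = ang, rad = rad)
    })
    ly <- cy + placement[["rad"]] * sin(placement[["ang"]]) * 0.6
    lx <- cx + placement[["side"]] * placement[["rad"]] *
      cos(placement[["ang"]])
    r_les <- ellipse_r(S, ly, lx, les_r, les_r)
    mask <- r_les <= 1 & brain
    delta <- matrix(0, S, S)
    delta[mask] <- spec$lesion_delta_hu
    delta <- gauss_blur(delta, spec$edge_softness)
    img <- img + delta
  }

  if (spec$noise_sd > 0) {
    noise <- with_seed(derive_seed(spec$seed, "noise"),
                       matrix(rnorm(S * S, sd = spec$noise_sd), S, S))
    img <- img + noise
  }
  img <- clamp(img, -1024, 3071)

  structure(list(image = hu_image(img,
                                  provenance = list(phantom = TRUE,
                                                    stage = spec$stage,
                                                    seed = spec$seed)),
                 stage = spec$stage, lesion_mask = mask, spec = spec),
            class = "staged_sample")
}

#' @export
print.staged_sample <- function(x, ...) {
  cat(sprintf("<staged_sample stage=%s %dx%d, lesion pixels=%d>\n",
              x$stage, nrow(x$image$pixels), ncol(x$image$pixels),
              sum(x$lesion_mask)))
  invisible(x)
}

#' Horizontal (left-right) flip of a staged sample
#' @param sample a `staged_sample`.
#' @return the flipped sample (image and mask).
#' @export
flip_sample <- function(sample) {
  fl <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
  sample$image <- hu_update(sample$image, fl(sample$image$pixels), "flip_lr")
  sample$lesion_mask <- fl(sample$lesion_mask)
  sample
}

# Rotate a matrix about its center by `angle` degrees (bilinear inverse
# mapping); out-of-support pixels take `fill`.
rotate_matrix <- function(m, angle, fill = min(m), nearest = FALSE) {
  th <- angle * pi / 180
  S <- nrow(m)
  cy <- (S - 1) / 2; cx <- (ncol(m) - 1) / 2
  y <- matrix(seq_len(S) - 1, S, ncol(m)) - cy
  x <- matrix(seq_len(ncol(m)) - 1, S, ncol(m), byrow = TRUE) - cx
  ys <- cy + cos(th) * y - sin(th) * x
  xs <- cx + sin(th) * y + cos(th) * x
  inside <- ys >= 0 & ys <= S - 1 & xs >= 0 & xs <= ncol(m) - 1
  if (nearest) { ys <- round(ys); xs <- round(xs) }
  out <- matrix(bilinear_sample(m, as.vector(ys), as.vector(xs)),
                S, ncol(m))
  out[!inside] <- fill
  out
}

#' Rotate a staged sample by a small angle
#'
#' Bilinear resampling for the image (padding with the image's minimum HU)
#' and nearest-neighbour resampling for the mask.
#'
#' @param sample a `staged_sample`.
#' @param angle rotation in degrees (augmentation draws use \[-7, 7\]).
#' @return the rotated sample.
#' @export
rotate_sample <- function(sample, angle) {
  px <- sample$image$pixels
  sample$image <- hu_update(sample$image,
                            rotate_matrix(px, angle, fill = min(px)),
                            sprintf("rotate(%.2f)", angle))
  mk <- rotate_matrix(sample$lesion_mask * 1, angle, fill = 0,
                      nearest = TRUE) > 0.5
  sample$lesion_mask <- mk
  sample
}

#' Generate a seeded phantom dataset
#'
#' Produces `n_per_stage` samples per requested stage, each from a
#' per-sample jittered copy of the stage default spec (tissue HU +/- 1,
#' lesion depth and radius +/- 10%, all seeded).  With `augment = TRUE`
#' every sample additionally yields a horizontally flipped copy and a copy
#' rotated by a uniform draw in \[-7, 7\] degrees, tripling the set -- the
#' same augmentation factor used when a training set grows from 1184 to
#' 3552 slices.
#'
#' @param n_per_stage samples per stage (>= 1).
#' @param stages character vector of stage labels (non-empty).
#' @param base_seed seed from which all per-sample seeds are derived.
#' @param augment logical; apply flip + rotation augmentation.
#' @param image_size side length passed to each spec.
#' @param noise_sd scanner-noise SD passed to each spec.
#' @return list of `staged_sample` objects.
#' @export
make_dataset <- function(n_per_stage, stages = STAGES, base_seed = 1L,
                         augment = FALSE, image_size = 256, noise_sd = 2) {
  if (length(stages) == 0) stop("`stages` must be non-empty", call. = FALSE)
  stages <- vapply(stages, match.arg, "", choices = STAGES)
  stopifnot_scalar(n_per_stage, "n_per_stage")
  if (n_per_stage < 1) stop("n_per_stage must be >= 1", call. = FALSE)
  out <- list()
  for (stage in stages) {
    for (i in seq_len(n_per_stage)) {
      sseed <- derive_seed(base_seed, stage, i)
      jit <- with_seed(derive_seed(sseed, "jitter"),
                       c(runif(3, -1, 1), runif(2, 0.9, 1.1)))
      base <- default_stage_spec(stage, seed = sseed)
      spec <- phantom_spec(
        stage = stage, image_size = image_size,
        gm_hu = base$gm_hu + jit[1], wm_hu = base$wm_hu + jit[2],
        csf_hu = max(0.5, base$csf_hu + jit[3]),
        noise_sd = noise_sd,
        lesion_delta_hu = base$lesion_delta_hu * jit[4],
        lesion_radius_frac = base$lesion_radius_frac * jit[5],
        edge_softness = base$edge_softness, seed = sseed)
      smp <- make_phantom(spec)
      out[[length(out) + 1L]] <- smp
      if (augment) {
        out[[length(out) + 1L]] <- flip_sample(smp)
        ang <- with_seed(derive_seed(sseed, "angle"), runif(1, -7, 7))
        out[[length(out) + 1L]] <- rotate_sample(smp, ang)
      }
    }
  }
  out
}

#' Emulate inter-scanner affine HU variation
#'
#' Draws a random affine recalibration `HU -> slope * HU + intercept` and
#' applies it pixelwise, recording the draw in provenance.  A scalar jitter
#' `j` means a uniform draw on `[1 - j, 1 + j]` for the slope and `[-j, j]`
#' for the intercept; a length-2 vector fixes the draw's range explicitly.
#'
#' @param img an [hu_image].
#' @param slope_jitter scalar half-width or length-2 range for the slope.
#' @param intercept_jitter scalar half-width or length-2 range (HU) for the
#'   intercept.
#' @param seed RNG seed for the draw.
#' @return the recalibrated [hu_image].
#' @export
apply_scanner_variation <- function(img, slope_jitter = 0.02,
                                    intercept_jitter = 2, seed = 1L) {
  rng <- function(j, center) {
    if (length(j) == 2) j else c(center - j, center + j)
  }
  if (!all(is.finite(slope_jitter)) || !all(is.finite(intercept_jitter)))
    stop("jitters must be finite", call. = FALSE)
  sr <- rng(slope_jitter, 1); ir <- rng(intercept_jitter, 0)
  draw <- with_seed(derive_seed(seed, "scanner"),
                    c(slope = runif(1, sr[1], sr[2]),
                      intercept = runif(1, ir[1], ir[2])))
  px <- as_hu_pixels(img) * draw[["slope"]] + draw[["intercept"]]
  out <- hu_update(img, clamp(px, -1024, 3071), "scanner_variation")
  out$provenance$scanner_draw <- draw
  out
}

#' Write a phantom sample to disk
#'
#' Writes an 8-bit windowed PNG preview, the lesion mask as PNG, and a JSON
#' sidecar with the spec, stage and seed.  With RNifti available the raw HU
#' grid is also written as NIfTI.
#'
#' @param sample a `staged_sample`.
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @param window a [window_config] used for the preview.
#' @return invisibly, the paths written.
#' @export
write_phantom <- function(sample, dir, name = "phantom",
                          window = window_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  u8 <- window_uint8(sample$image, window)
  p <- file.path(dir, paste0(name, ".png"))
  png::writePNG(u8 / 255, p); paths <- c(paths, p)
  p <- file.path(dir, paste0(name, "_mask.png"))
  png::writePNG(sample$lesion_mask * 1, p); paths <- c(paths, p)
  p <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(list(stage = sample$stage,
                            spec = unclass(sample$spec)),
                       p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  if (requireNamespace("RNifti", quietly = TRUE)) {
    p <- file.path(dir, paste0(name, ".nii"))
    RNifti::writeNifti(RNifti::asNifti(sample$image$pixels), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
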