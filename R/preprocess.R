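## HU-space preprocessing: rescale to Hounsfield units, resample, window,
## quantize to 8 bits.  These four steps reproduce a standard non-contrast
## brain-CT preprocessing chain; every enhancement operation downstream
## consumes their output.

#' Construct an HU image
#'
#' A light container for a single axial CT slice held in Hounsfield Units:
#' a numeric matrix plus optional pixel spacing and free-form provenance
#' (scanner id, rescale pair, transform history).
#'
#' @param pixels numeric matrix of attenuation values in HU, at least 16 x 16.
#' @param pixel_spacing optional in-plane spacing in mm (length 1 or 2).
#' @param provenance named list of free-form metadata.
#' @return an object of class `hu_image`.
#' @export
hu_image <- function(pixels, pixel_spacing = NULL, provenance = list()) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 16L || ncol(pixels) < 16L)
    stop("HU images must be at least 16 x 16 pixels", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("HU images must contain only finite values", call. = FALSE)
  structure(list(pixels = pixels, pixel_spacing = pixel_spacing,
                 provenance = provenance),
            class = "hu_image")
}

#' @export
print.hu_image <- function(x, ...) {
  cat(sprintf("<hu_image %d x %d, HU range [%.1f, %.1f]>\n",
              nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

as_hu_pixels <- function(img) {
  if (inherits(img, "hu_image")) img$pixels
  else if (is.matrix(img)) img
  else stop("expected an `hu_image` or a numeric matrix", call. = FALSE)
}

# Rebuild an hu_image around new pixels, appending a provenance step.
hu_update <- function(img, pixels, step) {
  if (!inherits(img, "hu_image"))
    return(hu_image(pixels, provenance = list(history = list(step))))
  prov <- img$provenance
  prov$history <- c(prov$history, list(step))
  hu_image(pixels, pixel_spacing = img$pixel_spacing, provenance = prov)
}

#' Convert raw CT pixel data to Hounsfield Units
#'
#' Applies the scanner rescale pair stored in DICOM headers:
#' `HU = slope * raw + intercept`, pixelwise.  Scans missing the rescale
#' metadata cannot be calibrated and are rejected.
#'
#' @param raw_pixels numeric matrix of stored pixel values.
#' @param rescale_slope,rescale_intercept the DICOM rescale pair; the slope
#'   must be non-zero and neither may be missing.
#' @param pixel_spacing optional in-plane spacing in mm.
#' @return an [hu_image] whose provenance records the rescale pair.
#' @export
dicom_to_hu <- function(raw_pixels, rescale_slope, rescale_intercept,
                        pixel_spacing = NULL) {
  if (missing(rescale_slope) || missing(rescale_intercept) ||
      is.null(rescale_slope) || is.null(rescale_intercept) ||
      anyNA(rescale_slope) || anyNA(rescale_intercept))
    stop("rescale slope/intercept metadata are required to calibrate HU",
         call. = FALSE)
  stopifnot_scalar(rescale_slope, "rescale_slope")
  stopifnot_scalar(rescale_intercept, "rescale_intercept")
  if (rescale_slope == 0)
    stop("rescale_slope must be non-zero", call. = FALSE)
  hu <- rescale_slope * raw_pixels + rescale_intercept
  hu_image(hu, pixel_spacing = pixel_spacing,
           provenance = list(rescale = c(slope = rescale_slope,
                                         intercept = rescale_intercept)))
}

#' Resample an HU image to a square matrix size
#'
#' Bilinear resampling with aligned pixel centers and clamped edges.  An
#' input already at the requested size is returned unchanged.
#'
#' @param img an [hu_image] or numeric matrix.
#' @param size target side length in pixels (>= 16).
#' @return an [hu_image] of dimension `size x size`.
#' @export
resample_to <- function(img, size) {
  stopifnot_scalar(size, "size")
  size <- as.integer(size)
  if (size < 16L) stop("target size must be at least 16 pixels", call. = FALSE)
  px <- as_hu_pixels(img)
  if (nrow(px) == size && ncol(px) == size)
    return(if (inherits(img, "hu_image")) img else hu_image(px))
  sy <- nrow(px) / size
  sx <- ncol(px) / size
  ctr <- seq_len(size) - 0.5
  rows <- matrix(ctr * sy - 0.5, size, size)
  cols <- matrix(ctr * sx - 0.5, size, size, byrow = TRUE)
  out <- matrix(bilinear_sample(px, as.vector(rows), as.vector(cols)),
                size, size)
  hu_update(img, out, step = sprintf("resample_to(%d)", size))
}

#' Brain window configuration
#'
#' @param center window center in HU (default 35, the standard brain window
#'   used throughout the pipeline).
#' @param width window width in HU (default 70); must be positive.
#' @return an object of class `window_config`.
#' @export
window_config <- function(center = 35, width = 70) {
  stopifnot_scalar(center, "center")
  stopifnot_scalar(width, "width")
  if (width <= 0) stop("window width must be positive", call. = FALSE)
  structure(list(center = center, width = width), class = "window_config")
}

#' Apply an HU display window (clamping)
#'
#' Values are clamped to `[center - width/2, center + width/2]`; in-band
#' values pass through unchanged.  Scaling to the 8-bit display range is a
#' separate step ([to_uint8]), so either ordering of windowing and linear
#' transformation is expressible.
#'
#' @param img an [hu_image] or numeric matrix.
#' @param cfg a [window_config].
#' @return windowed [hu_image].
#' @export
hu_window <- function(img, cfg = window_config()) {
  if (!inherits(cfg, "window_config")) stop("`cfg` must be a window_config",
                                            call. = FALSE)
  px <- as_hu_pixels(img)
  lo <- cfg$center - cfg$width / 2
  hi <- cfg$center + cfg$width / 2
  hu_update(img, clamp(px, lo, hi),
            step = sprintf("window(%g/%g)", cfg$center, cfg$width))
}

#' Quantize an HU image to 8 bits
#'
#' `out = floor(255 * (clamp(x, lo, hi) - lo) / (hi - lo) + 0.5)` --
#' round-half-up, stated explicitly because the 8-bit histogram feeding CLAHE
#' depends bit-exactly on the rounding rule.
#'
#' @param img an [hu_image] or numeric matrix.
#' @param lo,hi HU values mapped to 0 and 255; `hi` must exceed `lo`.
#'   Defaults are the edges of the standard 35/70 brain window.
#' @return an integer matrix with values in `[0, 255]`.
#' @export
to_uint8 <- function(img, lo = 0, hi = 70) {
  stopifnot_scalar(lo, "lo"); stopifnot_scalar(hi, "hi")
  if (hi <= lo) stop("`hi` must be strictly greater than `lo`", call. = FALSE)
  px <- as_hu_pixels(img)
  out <- round_half_up(255 * (clamp(px, lo, hi) - lo) / (hi - lo))
  storage.mode(out) <- "integer"
  out
}

# The canonical 8-bit reference image: window-clamp then quantize at the
# window edges.  Used as the PSNR reference throughout.
window_uint8 <- function(img, cfg = window_config()) {
  lo <- cfg$center - cfg$width / 2
  hi <- cfg$center + cfg$width / 2
  to_uint8(hu_window(img, cfg), lo = lo, hi = hi)
}

check_uint8 <- function(img8, name = "img8") {
  if (!is.matrix(img8) || !is.numeric(img8))
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  if (anyNA(img8) || min(img8) < 0 || max(img8) > 255 ||
      any(img8 != round(img8)))
    stop(sprintf("`%s` must be integer-valued in [0, 255]", name),
         call. = FALSE)
  invisible(img8)
}

#' Read a CT slice from file
#'
#' Supports single-slice NIfTI (`.nii`, `.nii.gz`; requires RNifti) holding
#' HU values, and PNG previews written by [write_phantom()] (mapped back
#' through the recorded window).  Raw DICOM pixel arrays are handled by
#' [dicom_to_hu()].
#'
#' @param path file path.
#' @return an [hu_image].
#' @export
read_ct <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("reading NIfTI requires the RNifti package", call. = FALSE)
    arr <- RNifti::asNifti(RNifti::readNifti(path))
    m <- as.matrix(arr[, , drop = TRUE])
    return(hu_image(m, provenance = list(source = path)))
  }
  stop("unsupported CT input format: ", path, call. = FALSE)
}
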