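# ---- fluorescence image correction, calibration, quantification ------------

#' Construct an image stack
#'
#' @param frames A list of numeric matrices (all the same shape) or a 3-D
#'   array `[row, col, frame]`; intensities must be >= 0 (14-bit cameras
#'   typically deliver 0..16383).
#' @param frame_interval_s Optional time between frames, seconds.
#' @param pixel_size_um Optional pixel size, micrometers.
#' @return An `image_stack` object wrapping a 3-D array.
#' @export
image_stack <- function(frames, frame_interval_s = NULL, pixel_size_um = NULL) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) stop("all frames must share one shape")
    frames <- array(unlist(frames), dim = c(dims[[1L]], length(frames)))
  }
  if (length(dim(frames)) == 2L) frames <- array(frames, c(dim(frames), 1L))
  stopifnot(length(dim(frames)) == 3L)
  if (any(frames < 0, na.rm = TRUE)) stop("intensities must be >= 0")
  structure(list(frames = frames, frame_interval_s = frame_interval_s,
                 pixel_size_um = pixel_size_um),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %d frame(s) of %d x %d", d[3L], d[1L], d[2L]))
  if (!is.null(x$frame_interval_s)) {
    cat(sprintf(", interval %.6g s", x$frame_interval_s))
  }
  cat("\n")
  invisible(x)
}

#' Read a multi-page TIFF into an image stack
#'
#' @param path TIFF file path.
#' @param frame_interval_s,pixel_size_um Passed to [image_stack()].
#' @param as_is Keep raw integer sample values (default) rather than the
#'   0..1 scaling `tiff::readTIFF` applies otherwise.
#' @return An `image_stack`.
#' @export
read_image_stack <- function(path, frame_interval_s = NULL,
                             pixel_size_um = NULL, as_is = TRUE) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = as_is)
  if (!is.list(frames)) frames <- list(frames)
  image_stack(frames, frame_interval_s, pixel_size_um)
}

# full-scale count used when persisting intensities to 16-bit TIFF
TIFF_FULL_SCALE <- 65535

#' Write an image stack as a multi-page 16-bit TIFF
#'
#' Intensities are stored as 16-bit counts (values are clipped to
#' `[0, 65535]` and rounded to the nearest count), which holds 14-bit camera
#' data losslessly.
#'
#' @param stack An [image_stack()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  n <- dim(stack$frames)[3L]
  frames <- lapply(seq_len(n), function(i) {
    pmin(pmax(stack$frames[, , i], 0), TIFF_FULL_SCALE) / TIFF_FULL_SCALE
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' Build a darkfield/flatfield correction model
#'
#' The camera-offset image is the pixelwise mean of the darkfield frames;
#' the illumination profile is the pixelwise median of the flatfield frames
#' minus that offset. Pixels whose dark-subtracted flatfield is not positive
#' cannot be normalized and are masked invalid.
#'
#' @param darkfields An [image_stack()] of darkfield frames (>= 1; 100 is
#'   the usual acquisition).
#' @param flatfields An [image_stack()] of flatfield frames, same shape.
#' @return A `correction_model`: list with matrices `darkfield`,
#'   `flat_minus_dark`, and logical `valid`.
#' @export
build_correction <- function(darkfields, flatfields) {
  stopifnot(inherits(darkfields, "image_stack"),
            inherits(flatfields, "image_stack"))
  if (!identical(dim(darkfields$frames)[1:2], dim(flatfields$frames)[1:2])) {
    stop("darkfield and flatfield shapes differ")
  }
  dark <- apply(darkfields$frames, c(1L, 2L), mean)
  flat_med <- apply(flatfields$frames, c(1L, 2L), stats::median)
  fmd <- flat_med - dark
  valid <- fmd > 0
  structure(list(darkfield = dark, flat_minus_dark = fmd, valid = valid),
            class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf(
    "<correction_model> %d x %d, %d invalid pixel(s)\n",
    nrow(x$darkfield), ncol(x$darkfield), sum(!x$valid)))
  invisible(x)
}

#' Apply darkfield/flatfield correction to one frame
#'
#' `corrected = (raw - darkfield) / flat_minus_dark` on valid pixels; masked
#' pixels propagate as `NA`. Values are not clipped: noise may make them
#' negative.
#'
#' @param raw Numeric matrix, same shape as the model.
#' @param model A `correction_model` from [build_correction()].
#' @return Corrected numeric matrix with `NA` at invalid pixels.
#' @export
correct_image <- function(raw, model) {
  stopifnot(inherits(model, "correction_model"))
  if (!identical(dim(raw), dim(model$darkfield))) stop("shape mismatch")
  out <- (raw - model$darkfield) / model$flat_minus_dark
  out[!model$valid] <- NA_real_
  out
}

#' Define a rectangular region of interest
#'
#' @param row,col Top-left pixel (1-based).
#' @param height,width Extent in pixels (default 100 x 100, the
#'   quantification window used throughout).
#' @return An `roi` object.
#' @export
roi <- function(row = 1L, col = 1L, height = 100L, width = 100L) {
  stopifnot(row >= 1, col >= 1, height >= 1, width >= 1)
  structure(list(row = as.integer(row), col = as.integer(col),
                 height = as.integer(height), width = as.integer(width)),
            class = "roi")
}

#' Median intensity within a region of interest
#'
#' Median over the valid (unmasked) pixels of the ROI; with an even count
#' the mean of the two middle values is used.
#'
#' @param corrected Numeric matrix (typically from [correct_image()]).
#' @param region An [roi()]; must fit inside the frame.
#' @return Scalar median intensity.
#' @export
roi_median <- function(corrected, region = roi()) {
  stopifnot(inherits(region, "roi"))
  if (region$row + region$height - 1L > nrow(corrected) ||
      region$col + region$width - 1L > ncol(corrected)) {
    stop("roi does not fit inside the frame")
  }
  px <- corrected[region$row:(region$row + region$height - 1L),
                  region$col:(region$col + region$width - 1L)]
  px <- px[!is.na(px)]
  if (!length(px)) stop("roi is fully masked")
  stats::median(px)
}

#' Normalize an intensity to a per-well reference
#'
#' Per-well reference normalization removes well-to-well differences in
#' liquid column height: intensities are divided by the median intensity
#' measured for the 0.5 uM reference solution in the same well.
#'
#' @param intensity Measured intensity (scalar or vector).
#' @param reference_intensity Reference intensity (> 0).
#' @return `intensity / reference_intensity`.
#' @export
normalize_to_reference <- function(intensity, reference_intensity) {
  if (!is.finite(reference_intensity) || reference_intensity <= 0) {
    stop("reference intensity must be positive")
  }
  intensity / reference_intensity
}

#' Fit a linear intensity-concentration calibration
#'
#' Ordinary least squares of intensity on concentration over a dilution
#' series of known concentrations.
#'
#' @param concentration Numeric vector of known concentrations (>= 2
#'   distinct values).
#' @param intensity Numeric vector of measured intensities, same length.
#' @return A `calibration_curve`: `slope`, `intercept`, `residual_se`, `n`,
#'   and `se_defined` (`FALSE` when n = 2 leaves no residual degrees of
#'   freedom; `residual_se` is then reported as 0).
#' @examples
#' fit_calibration(c(0, 2.5, 5, 7.5), c(0, 0.25, 0.5, 0.75))
#' @export
fit_calibration <- function(concentration, intensity) {
  stopifnot(length(concentration) == length(intensity),
            length(concentration) >= 2L)
  if (length(unique(concentration)) < 2L) {
    stop("calibration needs at least two distinct concentrations")
  }
  fit <- stats::lm(intensity ~ concentration)
  co <- stats::coef(fit)
  n <- length(concentration)
  se_defined <- n > 2L
  rse <- if (se_defined) sqrt(stats::deviance(fit) / (n - 2L)) else 0
  structure(list(slope = unname(co[["concentration"]]),
                 intercept = unname(co[["(Intercept)"]]),
                 residual_se = rse, n = n, se_defined = se_defined,
                 fit = fit),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> intensity = %.6g * C + %.6g (n = %d, residual SE %.4g%s)\n",
    x$slope, x$intercept, x$n, x$residual_se,
    if (!x$se_defined) ", undefined" else ""))
  invisible(x)
}

#' Invert a calibration curve to concentrations
#'
#' @param intensity Intensity value(s) on the calibration's scale.
#' @param curve A `calibration_curve` (slope must be nonzero).
#' @return Concentration(s) `(intensity - intercept) / slope`; values below
#'   zero are returned as-is with a logical `below_zero` attribute.
#' @export
to_concentration <- function(intensity, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stop("zero slope: calibration is not invertible")
  conc <- (intensity - curve$intercept) / curve$slope
  attr(conc, "below_zero") <- conc < 0
  conc
}

#' Quantify a fluorescence time-lapse into a concentration time course
#'
#' Per frame: darkfield/flatfield correction, ROI median, per-well reference
#' normalization, and calibration inversion (the calibration being expressed
#' in reference-normalized units).
#'
#' @param stack An [image_stack()] with a `frame_interval_s`.
#' @param model A `correction_model`.
#' @param region An [roi()].
#' @param curve A `calibration_curve` fitted on reference-normalized
#'   intensities.
#' @param reference_intensity Median corrected intensity of the reference
#'   solution in the same well (> 0).
#' @return Data frame with `time_s`, `intensity`, `relative_intensity`,
#'   `concentration`.
#' @export
quantify_timeseries <- function(stack, model, region, curve,
                                reference_intensity) {
  stopifnot(inherits(stack, "image_stack"))
  dt <- stack$frame_interval_s
  if (is.null(dt)) stop("stack has no frame interval")
  n <- dim(stack$frames)[3L]
  intensity <- vapply(seq_len(n), function(i) {
    roi_median(correct_image(stack$frames[, , i], model), region)
  }, 0)
  rel <- normalize_to_reference(intensity, reference_intensity)
  conc <- as.numeric(to_concentration(rel, curve))
  data.frame(time_s = (seq_len(n) - 1L) * dt, intensity = intensity,
             relative_intensity = rel, concentration = conc)
}

#' Persist a correction model as TIFF plus JSON sidecar
#'
#' @param model A `correction_model`.
#' @param tiff_path Two-frame float TIFF (darkfield, flat-minus-dark).
#' @param json_path Sidecar recording shape and invalid-pixel indices.
#' @return Invisibly, `tiff_path`.
#' @export
write_correction <- function(model, tiff_path, json_path) {
  stopifnot(inherits(model, "correction_model"))
  # stored as 32-bit float scaled into [0, 1] by the full 16-bit count range
  frames <- lapply(list(model$darkfield, model$flat_minus_dark), function(m) {
    pmin(pmax(m, 0), TIFF_FULL_SCALE) / TIFF_FULL_SCALE
  })
  tiff::writeTIFF(frames, tiff_path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(shape = dim(model$darkfield), invalid = which(!model$valid)),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(tiff_path)
}

#' Read back a persisted correction model
#'
#' @param tiff_path,json_path Paths written by [write_correction()].
#' @return A `correction_model`.
#' @export
read_correction <- function(tiff_path, json_path) {
  frames <- tiff::readTIFF(tiff_path, all = TRUE)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  dark <- frames[[1L]] * TIFF_FULL_SCALE
  fmd <- frames[[2L]] * TIFF_FULL_SCALE
  valid <- fmd > 0
  if (length(meta$invalid)) valid[meta$invalid] <- FALSE
  structure(list(darkfield = dark, flat_minus_dark = fmd, valid = valid),
            class = "correction_model")
}
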