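# ---- seeded synthetic-data generators with attached ground truth -----------

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

phantom_truth <- function(generator, seed, params) {
  structure(list(generator = generator, seed = seed, params = params),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %s (seed %s)\n", x$generator,
              format(x$seed)))
  utils::str(x$params, max.level = 1, give.attr = FALSE)
  invisible(x)
}

#' Write a phantom truth record as a JSON sidecar
#'
#' @param truth A `phantom_truth`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "phantom_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# radial vignetting field on a (rows x cols) grid, 1 at center
vignette_field <- function(shape, strength) {
  r <- (seq_len(shape[1L]) - (shape[1L] + 1) / 2) / (shape[1L] / 2)
  c <- (seq_len(shape[2L]) - (shape[2L] + 1) / 2) / (shape[2L] / 2)
  rad2 <- outer(r^2, c^2, `+`)
  1 - strength * rad2 / max(rad2)
}

#' Generate synthetic darkfield and flatfield reference stacks
#'
#' Emulates the reference acquisitions used to build a correction model:
#' darkfield frames are the camera offset plus noise; flatfield frames add a
#' flat illumination level shaped by a radial vignetting field.
#'
#' @param shape `(rows, cols)` of each frame.
#' @param dark_level Camera offset level.
#' @param flat_level Illumination level above the offset at the field
#'   center.
#' @param vignette Vignetting strength in `[0, 1)` (relative fall-off at the
#'   corners; 0 = perfectly flat).
#' @param noise_sd Gaussian read-noise standard deviation.
#' @param n Frames per stack (default 100, the usual acquisition).
#' @param seed Integer seed.
#' @return List with `darkfields`, `flatfields` (both [image_stack()]s) and
#'   `truth` (a `phantom_truth` recording the vignette field).
#' @export
make_reference_stacks <- function(shape = c(64L, 64L), dark_level = 100,
                                  flat_level = 200, vignette = 0,
                                  noise_sd = 0, n = 100L, seed = 1L) {
  stopifnot(dark_level > 0, flat_level > 0, vignette >= 0, vignette < 1)
  vg <- vignette_field(shape, vignette)
  res <- with_seed(seed, {
    darks <- lapply(seq_len(n), function(i) {
      matrix(dark_level + stats::rnorm(prod(shape), 0, noise_sd),
             shape[1L], shape[2L])
    })
    flats <- lapply(seq_len(n), function(i) {
      dark_level + flat_level * vg +
        matrix(stats::rnorm(prod(shape), 0, noise_sd), shape[1L], shape[2L])
    })
    list(darks = darks, flats = flats)
  })
  list(darkfields = image_stack(lapply(res$darks, pmax, 0)),
       flatfields = image_stack(lapply(res$flats, pmax, 0)),
       truth = phantom_truth("make_reference_stacks", seed,
                             list(shape = shape, dark_level = dark_level,
                                  flat_level = flat_level,
                                  vignette = vignette, noise_sd = noise_sd,
                                  n = n, vignette_field = vg)))
}

# render a corrected-unit signal level into a raw frame under the shading
# model: raw = dark + signal * flat_level * vignette + noise
render_raw_frame <- function(signal, shape, dark_level, flat_level, vg,
                             noise_sd) {
  pmax(dark_level + signal * flat_level * vg +
         matrix(stats::rnorm(prod(shape), 0, noise_sd), shape[1L], shape[2L]),
       0)
}

#' Generate a synthetic dilution series
#'
#' One frame per known concentration, emulating pre-mixed tracer solutions
#' imaged under the shading model of [make_reference_stacks()]. The signal
#' in corrected-intensity units is `intercept + slope * C`, so running the
#' frames through the correction pipeline and [fit_calibration()] should
#' recover `(slope, intercept)` exactly at zero noise.
#'
#' @param concentrations Known concentrations (>= 0), including 0.5 to
#'   exercise the per-well reference normalization.
#' @param slope,intercept Calibration truth in corrected-intensity units
#'   per concentration unit.
#' @param noise_sd Raw-frame Gaussian noise sd.
#' @param shape Frame shape.
#' @param seed Integer seed.
#' @param reference A result of [make_reference_stacks()] to share shading
#'   with; generated internally (seed + 1) when `NULL`.
#' @return List with `frames` (an [image_stack()], one frame per
#'   concentration), `concentrations`, `reference`, and `truth`.
#' @export
make_dilution_series <- function(concentrations = c(0, 0.5, 1.5, 2.5, 5, 7.5),
                                 slope = 2, intercept = 0, noise_sd = 0,
                                 shape = c(64L, 64L), seed = 1L,
                                 reference = NULL) {
  stopifnot(all(concentrations >= 0))
  if (is.null(reference)) {
    reference <- make_reference_stacks(shape = shape, seed = seed + 1L)
  }
  p <- reference$truth$params
  vg <- p$vignette_field
  frames <- with_seed(seed, lapply(concentrations, function(C) {
    render_raw_frame(intercept + slope * C, shape, p$dark_level,
                     p$flat_level, vg, noise_sd)
  }))
  list(frames = image_stack(frames),
       concentrations = concentrations,
       reference = reference,
       truth = phantom_truth("make_dilution_series", seed,
                             list(concentrations = concentrations,
                                  slope = slope, intercept = intercept,
                                  noise_sd = noise_sd, shape = shape)))
}

#' Simulate the dispersed concentration trace of a valve schedule
#'
#' Expands a schedule into its per-cycle delivered concentrations, smooths
#' them with a causal moving-average kernel of `dispersion_cycles` cycles
#' (the blending of alternating pulses along the delivery tubing), adds
#' measurement noise, and samples the result at the imaging frame interval.
#' Optionally renders the samples into raw fluorescence frames through the
#' shading and calibration model so the full quantification pipeline can be
#' exercised end to end.
#'
#' @param schedule A `valve_schedule` from [schedule_profile()].
#' @param stocks Stock compositions (default the schedule's).
#' @param solute Which solute to trace (default the first).
#' @param dispersion_cycles Width of the causal smoothing kernel in cycles
#'   (0 = no dispersion, the raw square wave).
#' @param noise_sd Gaussian noise sd on the sampled concentrations (or, when
#'   rendering, on the raw frames).
#' @param frame_interval_s Sampling interval, seconds (default 0.5).
#' @param seed Integer seed.
#' @param render If `TRUE`, also return raw frames plus the reference stacks
#'   and calibration truth needed to quantify them.
#' @param shape,slope,intercept Rendering parameters (ignored unless
#'   `render = TRUE`); `slope`/`intercept` are in reference-normalized
#'   units.
#' @return List with `series` (data frame `time_s`, `concentration`),
#'   `cycle_concentration` (per-cycle, post-dispersion), and `truth`; when
#'   rendering also `frames`, `reference`, `reference_intensity_signal`.
#' @export
make_pwm_trace <- function(schedule, stocks = schedule$cfg$stocks,
                           solute = NULL, dispersion_cycles = 5,
                           noise_sd = 0, frame_interval_s = 0.5, seed = 1L,
                           render = FALSE, shape = c(120L, 120L),
                           slope = NULL, intercept = 0) {
  stopifnot(inherits(schedule, "valve_schedule"))
  A <- stock_matrix(stocks)
  if (is.null(solute)) solute <- rownames(A)[1L]
  p <- schedule$pulses
  keys <- unique(p[c("window", "cycle")])
  conc <- vapply(seq_len(nrow(keys)), function(i) {
    delivered_concentration(schedule, stocks, window = keys$window[i],
                            cycles = keys$cycle[i])[[solute]]
  }, 0)
  if (dispersion_cycles > 0) {
    w <- as.integer(ceiling(dispersion_cycles))
    # causal moving average; the tube starts filled with the first level
    padded <- c(rep(conc[1L], w - 1L), conc)
    smoothed <- stats::filter(padded, rep(1 / w, w), sides = 1)
    conc_s <- as.numeric(smoothed[w:length(padded)])
  } else conc_s <- conc
  cycle_s <- schedule$cfg$cycle_ms / 1000
  total_s <- length(conc_s) * cycle_s
  t <- seq(0, total_s - frame_interval_s / 2, by = frame_interval_s)
  idx <- pmin(length(conc_s), 1L + floor(t / cycle_s))
  sampled <- conc_s[idx]
  truth <- phantom_truth("make_pwm_trace", seed,
                         list(solute = solute,
                              dispersion_cycles = dispersion_cycles,
                              noise_sd = noise_sd,
                              frame_interval_s = frame_interval_s,
                              cycle_concentration = conc_s))
  if (!render) {
    noisy <- with_seed(seed,
                       sampled + stats::rnorm(length(sampled), 0, noise_sd))
    return(list(series = data.frame(time_s = t, concentration = noisy),
                cycle_concentration = conc_s, truth = truth))
  }
  # reference-normalized signal: 1.0 at the reference concentration 0.5
  if (is.null(slope)) slope <- 2      # signal 1.0 per 0.5 concentration units
  reference <- make_reference_stacks(shape = shape, seed = seed + 1L)
  rp <- reference$truth$params
  res <- with_seed(seed, {
    frames <- lapply(sampled, function(C) {
      render_raw_frame(intercept + slope * C, shape, rp$dark_level,
                       rp$flat_level, rp$vignette_field, noise_sd)
    })
    ref_frame <- render_raw_frame(intercept + slope * 0.5, shape,
                                  rp$dark_level, rp$flat_level,
                                  rp$vignette_field, noise_sd)
    list(frames = frames, ref_frame = ref_frame)
  })
  list(series = data.frame(time_s = t, concentration = sampled),
       cycle_concentration = conc_s,
       frames = image_stack(res$frames, frame_interval_s = frame_interval_s),
       reference_frame = res$ref_frame,
       reference = reference,
       calibration = list(slope = slope, intercept = intercept),
       truth = truth)
}

#' Generate a gastruloid phantom image with ground truth
#'
#' A stadium-shaped (capsule) gastruloid of the given length and width on a
#' uniform background, carrying a graded axial reporter field: a baseline
#' body expression plus a Gaussian bump (sd 0.15 in normalized arc length)
#' centered at `peak_position` along the posterior-to-anterior axis, with
#' the posterior pole at the peak-proximal end. The straight central axis,
#' the true mask, and all parameters are returned as ground truth.
#'
#' @param length_px Pole-to-pole length (>= `width_px`).
#' @param width_px Body width (the inscribed-circle diameter).
#' @param peak_position True peak position in `[0, 1]` (0 = posterior pole).
#' @param amplitude Peak expression above the body baseline.
#' @param background Image background level outside the gastruloid.
#' @param body_fraction Baseline body expression as a fraction of
#'   `amplitude` (keeps the whole body segmentable; default 0.3).
#' @param noise_sd Gaussian noise sd.
#' @param margin_px Background margin around the gastruloid.
#' @param sigma_axial Bump width in normalized arc length (default 0.15).
#' @param seed Integer seed.
#' @return List with `image`, `axis` (an [axis_polyline()], posterior
#'   first), `mask` (true `gastruloid_mask`), and `truth`.
#' @export
make_gastruloid_phantom <- function(length_px = 240, width_px = 80,
                                    peak_position = 0.15, amplitude = 600,
                                    background = 80, body_fraction = 0.3,
                                    noise_sd = 0, margin_px = 50,
                                    sigma_axial = 0.15, seed = 1L) {
  stopifnot(length_px >= width_px, peak_position >= 0, peak_position <= 1,
            width_px >= 4)
  rows <- as.integer(width_px + 2 * margin_px)
  cols <- as.integer(length_px + 2 * margin_px)
  r0 <- (rows + 1) / 2
  c_post <- margin_px + 1          # posterior pole column
  c_ant <- margin_px + length_px   # anterior pole column
  half_w <- width_px / 2
  # centerline segment of the stadium is inset by half the width at each end
  s0 <- c_post + half_w; s1 <- c_ant - half_w
  rr <- matrix(seq_len(rows), rows, cols)
  cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  cx <- pmin(pmax(cc, s0), s1)
  dist_center <- sqrt((rr - r0)^2 + (cc - cx)^2)
  mask <- dist_center <= half_w
  u <- pmin(pmax((cc - c_post) / (c_ant - c_post), 0), 1)
  bump <- exp(-(u - peak_position)^2 / (2 * sigma_axial^2))
  signal <- amplitude * (body_fraction + (1 - body_fraction) * bump)
  img <- matrix(background, rows, cols)
  img[mask] <- background + signal[mask]
  img <- with_seed(seed,
                   pmax(img + matrix(stats::rnorm(rows * cols, 0, noise_sd),
                                     rows, cols), 0))
  axis <- axis_polyline(rbind(c(r0, c_post), c(r0, c_ant)))
  list(image = img, axis = axis,
       mask = structure(list(mask = mask, threshold = NA_real_),
                        class = "gastruloid_mask"),
       truth = phantom_truth("make_gastruloid_phantom", seed,
                             list(length_px = length_px, width_px = width_px,
                                  elongation = length_px / width_px,
                                  peak_position = peak_position,
                                  amplitude = amplitude,
                                  background = background,
                                  body_fraction = body_fraction,
                                  noise_sd = noise_sd,
                                  sigma_axial = sigma_axial)))
}

#' Generate a condition's worth of gastruloid phantoms
#'
#' Draws `n` phantoms with per-gastruloid parameters sampled from the given
#' ranges (uniform) and peak distribution (normal, truncated to `[0.02,
#' 0.98]`), emulating the four-to-seven gastruloids recovered per condition.
#'
#' @param n Number of gastruloids (>= 1).
#' @param peak_mean,peak_sd Normal distribution of true peak positions.
#' @param elongation_range Uniform range of true elongations.
#' @param width_px Body width of every phantom.
#' @param amplitude,background,body_fraction,noise_sd,margin_px,sigma_axial
#'   Passed to [make_gastruloid_phantom()].
#' @param seed Integer seed.
#' @param render Render the phantom images (default). With `render = FALSE`
#'   only the drawn ground-truth parameters are returned, which is all a
#'   statistical power simulation over many condition draws needs.
#' @return List with `phantoms` (list of [make_gastruloid_phantom()]
#'   results; `NULL` when `render = FALSE`) and `truth` (drawn parameters
#'   per gastruloid).
#' @export
make_condition_set <- function(n = 7L, peak_mean = 0.85, peak_sd = 0.05,
                               elongation_range = c(1.5, 3), width_px = 40,
                               amplitude = 600, background = 80,
                               body_fraction = 0.3, noise_sd = 5,
                               margin_px = 45, sigma_axial = 0.15,
                               seed = 1L, render = TRUE) {
  stopifnot(n >= 1L)
  draws <- with_seed(seed, {
    peaks <- pmin(pmax(stats::rnorm(n, peak_mean, peak_sd), 0.02), 0.98)
    elong <- stats::runif(n, elongation_range[1L], elongation_range[2L])
    subseeds <- sample.int(.Machine$integer.max - 1L, n)
    list(peaks = peaks, elong = elong, subseeds = subseeds)
  })
  phantoms <- if (!render) NULL else lapply(seq_len(n), function(i) {
    make_gastruloid_phantom(
      length_px = round(draws$elong[i] * width_px), width_px = width_px,
      peak_position = draws$peaks[i], amplitude = amplitude,
      background = background, body_fraction = body_fraction,
      noise_sd = noise_sd, margin_px = margin_px,
      sigma_axial = sigma_axial, seed = draws$subseeds[i])
  })
  list(phantoms = phantoms,
       truth = phantom_truth("make_condition_set", seed,
                             list(n = n, peak_mean = peak_mean,
                                  peak_sd = peak_sd,
                                  peaks = draws$peaks,
                                  elongations = draws$elong,
                                  width_px = width_px,
                                  noise_sd = noise_sd)))
}
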