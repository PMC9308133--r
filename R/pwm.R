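# ---- PWM valve scheduling ---------------------------------------------------

#' Define a PWM formulator configuration
#'
#' The pulse-width-modulation formulator mixes up to six stock inputs by
#' opening one inflow valve at a time within a fixed cycle; the share of the
#' cycle an input occupies (its duty cycle) sets its share of the output.
#'
#' @param stocks Named list of stock compositions, one per input, each a
#'   named numeric vector of solute concentrations (an empty vector is plain
#'   buffer). Input order fixes tie-breaking in quantization.
#' @param cycle_ms Total cycle time in ms (default 1500).
#' @param min_pulse_ms Minimum nonzero pulse, ms (default 100).
#' @param resolution_ms Pulse quantization step, ms (default 100); must
#'   divide `cycle_ms`.
#' @return A `pwm_config` object.
#' @examples
#' pwm_config(list(fitc = c(FITC = 7.5), buffer = numeric()))
#' @export
pwm_config <- function(stocks, cycle_ms = 1500, min_pulse_ms = 100,
                       resolution_ms = 100) {
  stopifnot(cycle_ms > 0, min_pulse_ms > 0, resolution_ms > 0,
            min_pulse_ms <= cycle_ms)
  if (cycle_ms %% resolution_ms != 0) {
    stop("resolution_ms must divide cycle_ms")
  }
  stopifnot(is.list(stocks), length(stocks) >= 1L, length(stocks) <= 6L,
            !is.null(names(stocks)))
  stocks <- lapply(stocks, as.numeric_named)
  structure(list(stocks = stocks, cycle_ms = cycle_ms,
                 min_pulse_ms = min_pulse_ms, resolution_ms = resolution_ms),
            class = "pwm_config")
}

# stack stock compositions into a (solute x input) matrix over the solute union
stock_matrix <- function(stocks) {
  solutes <- unique(unlist(lapply(stocks, names)))
  A <- matrix(0, nrow = length(solutes), ncol = length(stocks),
              dimnames = list(solutes, names(stocks)))
  for (j in seq_along(stocks)) {
    s <- stocks[[j]]
    if (length(s)) A[names(s), j] <- s
  }
  A
}

#' Duty-cycle fractions realizing a target composition
#'
#' Finds per-input time fractions `f >= 0`, `sum(f) = 1`, such that the
#' time-weighted mixture of the stocks matches the target concentrations:
#' `sum_i f_i * stock_i(solute) = target(solute)` for every solute. With two
#' inputs the solution is closed-form; with more, a nonnegative
#' least-squares mixture is used and exactness is checked against `tol`.
#'
#' @param target Named numeric vector of target concentrations; an empty
#'   vector or all zeros targets plain buffer.
#' @param stocks Named list of stock compositions (see [pwm_config()]).
#' @param tol Maximum tolerated relative mismatch per solute (relative to
#'   the largest stock concentration of that solute).
#' @return Named numeric vector of fractions summing to 1.
#' @examples
#' duty_fractions(c(FITC = 0.5), list(stock = c(FITC = 7.5),
#'                                    buffer = numeric()))  # 1/15, 14/15
#' @export
duty_fractions <- function(target, stocks, tol = 1e-9) {
  target <- as.numeric_named(target)
  stocks <- lapply(stocks, as.numeric_named)
  A <- stock_matrix(stocks)
  t_full <- stats::setNames(rep(0, nrow(A)), rownames(A))
  unknown <- setdiff(names(target), rownames(A))
  if (length(unknown) && any(target[unknown] > 0)) {
    stop("infeasible target: solute '",
         unknown[which(target[unknown] > 0)[1L]],
         "' is absent from every stock")
  }
  t_full[intersect(names(target), rownames(A))] <-
    target[intersect(names(target), rownames(A))]
  n <- ncol(A)
  if (nrow(A) == 0L) {            # all stocks are buffer; any split works
    f <- stats::setNames(c(1, rep(0, n - 1L)), colnames(A))
    return(f)
  }
  if (n == 2L) {
    # f1 minimizes ||f1 (a1 - a2) + a2 - t||^2 on [0, 1]; closed form
    d <- A[, 1L] - A[, 2L]
    if (sum(d^2) == 0) f1 <- 0 else {
      f1 <- sum(d * (t_full - A[, 2L])) / sum(d^2)
      f1 <- min(max(f1, 0), 1)
    }
    f <- stats::setNames(c(f1, 1 - f1), colnames(A))
  } else {
    w <- 1e6 * max(abs(A), 1)
    Aw <- rbind(A, rep(w, n))
    bw <- c(t_full, w)
    f <- pracma::lsqnonneg(Aw, bw)$x
    if (sum(f) <= 0) stop("infeasible target: no nonnegative mixture exists")
    f <- stats::setNames(f / sum(f), colnames(A))
  }
  achieved <- drop(A %*% f)
  scale <- pmax(apply(abs(A), 1L, max), 1e-300)
  rel <- abs(achieved - t_full) / scale
  if (any(rel > tol)) {
    worst <- rownames(A)[which.max(rel)]
    stop(sprintf(
      "infeasible target: solute '%s' unreachable (wanted %.6g, best %.6g)",
      worst, t_full[[worst]], achieved[[worst]]))
  }
  f
}

# enumerate all compositions of n_units into n_inputs parts (each 0 or >= m)
compositions_with_min <- function(n_units, n_inputs, m) {
  if (n_inputs == 1L) {
    if (n_units == 0L || n_units >= m) return(matrix(n_units, 1L, 1L))
    return(matrix(numeric(0), 0L, 1L))
  }
  out <- list()
  for (k in c(0L, seq.int(m, n_units))) {
    if (k > n_units) next
    rest <- compositions_with_min(n_units - k, n_inputs - 1L, m)
    if (nrow(rest)) out[[length(out) + 1L]] <- cbind(k, rest, deparse.level = 0)
  }
  if (!length(out)) matrix(numeric(0), 0L, n_inputs) else do.call(rbind, out)
}

#' Quantize duty-cycle fractions into valve pulses
#'
#' Converts ideal fractions into pulse lengths that are multiples of the
#' quantization step, sum to the cycle time, and respect the minimum nonzero
#' pulse. Among all feasible pulse vectors the one minimizing the absolute
#' concentration error (Euclidean over solutes, using the configured stocks)
#' is chosen; ties go to the lower-index input.
#'
#' @param fractions Named numeric vector of per-input fractions (>= 0,
#'   summing to 1), ordered as `cfg$stocks`.
#' @param cfg A [pwm_config()].
#' @param allow_rounding If `FALSE`, a target that no pulse vector represents
#'   exactly raises a quantization error carrying the nearest achievable
#'   composition (attribute `nearest` of the condition).
#' @return Named numeric vector of pulse lengths in ms.
#' @examples
#' cfg <- pwm_config(list(stock = c(FITC = 7.5), buffer = numeric()))
#' quantize_cycle(c(stock = 1/15, buffer = 14/15), cfg)  # 100, 1400
#' @export
quantize_cycle <- function(fractions, cfg, allow_rounding = TRUE) {
  stopifnot(inherits(cfg, "pwm_config"))
  n <- length(cfg$stocks)
  stopifnot(length(fractions) == n)
  if (abs(sum(fractions) - 1) > 1e-9 || any(fractions < -1e-12)) {
    stop("fractions must be nonnegative and sum to 1")
  }
  N <- cfg$cycle_ms %/% cfg$resolution_ms
  m <- as.integer(ceiling(cfg$min_pulse_ms / cfg$resolution_ms))
  A <- stock_matrix(cfg$stocks)
  target_conc <- if (nrow(A)) drop(A %*% fractions) else numeric()
  cand <- compositions_with_min(N, n, m)
  if (!nrow(cand)) stop("no feasible quantization for this configuration")
  if (nrow(A)) {
    conc <- cand %*% t(A) / N                   # candidate x solute
    err <- sqrt(rowSums((conc - matrix(target_conc, nrow(cand), nrow(A),
                                       byrow = TRUE))^2))
  } else {
    err <- sqrt(rowSums((cand / N - matrix(fractions, nrow(cand), n,
                                           byrow = TRUE))^2))
  }
  best_err <- min(err)
  ties <- which(err <= best_err + 1e-15)
  if (length(ties) > 1L) {         # prefer pushing units to lower-index inputs
    ord <- do.call(order, lapply(seq_len(n), function(j) -cand[ties, j]))
    best <- ties[ord[1L]]
  } else best <- ties
  pulses <- stats::setNames(cand[best, ] * cfg$resolution_ms, names(cfg$stocks))
  if (!allow_rounding && nrow(A)) {
    achieved <- drop(A %*% (pulses / cfg$cycle_ms))
    if (max(abs(achieved - target_conc)) > 1e-9 * max(abs(A), 1)) {
      cond <- simpleError(
        "quantization error: target not exactly representable")
      attr(cond, "nearest") <- achieved
      stop(cond)
    }
  }
  pulses
}

#' Describe one segment of a target concentration profile
#'
#' @param start_s,end_s Segment window in seconds (`end_s > start_s`); the
#'   window length sets how many PWM cycles the segment occupies.
#' @param kind One of `"hold"`, `"step"`, `"ramp"`, `"staircase"`.
#' @param target Named concentration vector (`hold`/`step`), the ramp start
#'   (`ramp`), or ignored for `staircase`.
#' @param target_end Ramp end concentrations (`ramp` only).
#' @param levels List of named concentration vectors (`staircase` only),
#'   each occupying an equal share of the window.
#' @param well Destination well id.
#' @return A `profile_segment` object.
#' @export
profile_segment <- function(start_s, end_s, kind = c("hold", "step", "ramp",
                                                     "staircase"),
                            target = numeric(), target_end = NULL,
                            levels = NULL, well = "well1") {
  kind <- match.arg(kind)
  stopifnot(end_s > start_s)
  if (kind == "ramp" && is.null(target_end)) stop("ramp needs target_end")
  if (kind == "staircase" && (is.null(levels) || !length(levels))) {
    stop("staircase needs levels")
  }
  structure(list(start_s = start_s, end_s = end_s, kind = kind,
                 target = as.numeric_named(target),
                 target_end = if (!is.null(target_end))
                   as.numeric_named(target_end),
                 levels = if (!is.null(levels))
                   lapply(levels, as.numeric_named),
                 well = well),
            class = "profile_segment")
}

#' Assemble a target concentration profile
#'
#' @param segments List of [profile_segment()]s; per well they must not
#'   overlap in time.
#' @return A `target_profile` object.
#' @export
target_profile <- function(segments) {
  if (inherits(segments, "profile_segment")) segments <- list(segments)
  lapply(segments, function(s) stopifnot(inherits(s, "profile_segment")))
  wells <- vapply(segments, `[[`, "", "well")
  for (w in unique(wells)) {
    seg <- segments[wells == w]
    seg <- seg[order(vapply(seg, `[[`, 0, "start_s"))]
    if (length(seg) > 1L) {
      for (i in 2:length(seg)) {
        if (seg[[i]]$start_s < seg[[i - 1L]]$end_s - 1e-9) {
          stop("overlapping segments for well ", w)
        }
      }
    }
  }
  structure(list(segments = segments), class = "target_profile")
}

# per-cycle target sequence for one segment, plus wash flags at level switches
segment_cycle_targets <- function(seg, cycle_s) {
  n_cyc <- max(1L, as.integer(round((seg$end_s - seg$start_s) / cycle_s)))
  switch(seg$kind,
    hold = ,
    step = list(targets = rep(list(seg$target), n_cyc),
                switch_at = 1L),
    ramp = {
      frac <- (seq_len(n_cyc) - 0.5) / n_cyc
      tg <- lapply(frac, function(f) seg$target +
                     f * (seg$target_end - seg$target))
      list(targets = tg, switch_at = 1L)
    },
    staircase = {
      k <- length(seg$levels)
      idx <- pmin(k, 1L + (seq_len(n_cyc) - 1L) %/% max(1L, n_cyc %/% k))
      # equal split; any remainder cycles stay on the last level
      per <- n_cyc %/% k
      if (per >= 1L) idx <- pmin(k, 1L + (seq_len(n_cyc) - 1L) %/% per)
      list(targets = seg$levels[idx],
           switch_at = which(c(TRUE, diff(idx) != 0)))
    })
}

#' Schedule a target profile into quantized valve pulses
#'
#' Converts a [target_profile()] into an ordered valve schedule: one
#' dispensing window per well (the multiplexer serves one well at a time, so
#' windows are laid out sequentially in well order), each window a sequence
#' of PWM cycles whose quantized pulses realize the per-cycle target. Ramps
#' are discretized one target per cycle; a half-wash marker is recorded at
#' every discrete concentration switch so the carryover in the formulation
#' path can be purged.
#'
#' @param profile A [target_profile()].
#' @param cfg A [pwm_config()].
#' @param insert_washes Record half-wash markers at concentration switches
#'   (default `TRUE`).
#' @return A `valve_schedule`: list with `pulses` (data frame: `window`,
#'   `well`, `cycle`, `t_start_s`, `input_id`, `pulse_ms`), `washes` (data
#'   frame: `window`, `well`, `cycle`), and the `cfg` used.
#' @export
schedule_profile <- function(profile, cfg, insert_washes = TRUE) {
  stopifnot(inherits(profile, "target_profile"), inherits(cfg, "pwm_config"))
  cycle_s <- cfg$cycle_ms / 1000
  wells <- unique(vapply(profile$segments, `[[`, "", "well"))
  pulses <- list(); washes <- list()
  window <- 0L; t_cursor <- 0
  prev_target <- NULL
  for (w in wells) {
    window <- window + 1L
    seg_w <- profile$segments[vapply(profile$segments, `[[`, "", "well") == w]
    seg_w <- seg_w[order(vapply(seg_w, `[[`, 0, "start_s"))]
    cyc_no <- 0L
    for (seg in seg_w) {
      ct <- segment_cycle_targets(seg, cycle_s)
      for (j in seq_along(ct$targets)) {
        tg <- ct$targets[[j]]
        f <- duty_fractions(tg, cfg$stocks)
        p <- quantize_cycle(f, cfg)
        cyc_no <- cyc_no + 1L
        if (is.null(prev_target)) prev_target <- tg   # no wash at start-up
        switched <- !identical(prev_target, tg)
        if (insert_washes && switched && j %in% ct$switch_at) {
          washes[[length(washes) + 1L]] <- data.frame(
            window = window, well = w, cycle = cyc_no,
            stringsAsFactors = FALSE)
        }
        prev_target <- tg
        pulses[[length(pulses) + 1L]] <- data.frame(
          window = window, well = w, cycle = cyc_no, t_start_s = t_cursor,
          input_id = names(p), pulse_ms = unname(p),
          stringsAsFactors = FALSE)
        t_cursor <- t_cursor + cycle_s
      }
    }
  }
  structure(list(pulses = do.call(rbind, pulses),
                 washes = if (length(washes)) do.call(rbind, washes) else
                   data.frame(window = integer(), well = character(),
                              cycle = integer()),
                 cfg = cfg),
            class = "valve_schedule")
}

#' Structurally validate a valve schedule
#'
#' Checks the hard constraints every schedule must satisfy: pulses are
#' multiples of the quantization step, nonzero pulses respect the minimum
#' pulse, every cycle's pulses sum to the cycle time, and each dispensing
#' window addresses exactly one well (multiplexer exclusivity).
#'
#' @param schedule A `valve_schedule`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "valve_schedule"))
  p <- schedule$pulses; cfg <- schedule$cfg
  if (any(p$pulse_ms %% cfg$resolution_ms != 0)) {
    stop("pulse not a multiple of resolution_ms")
  }
  nz <- p$pulse_ms > 0
  if (any(p$pulse_ms[nz] < cfg$min_pulse_ms)) {
    stop("nonzero pulse below min_pulse_ms")
  }
  sums <- tapply(p$pulse_ms, interaction(p$window, p$cycle, drop = TRUE), sum)
  if (any(sums != cfg$cycle_ms)) stop("cycle pulses do not sum to cycle_ms")
  per_window <- tapply(p$well, p$window, function(x) length(unique(x)))
  if (any(per_window != 1L)) stop("a window addresses more than one well")
  invisible(TRUE)
}

#' @export
print.valve_schedule <- function(x, ...) {
  nw <- length(unique(x$pulses$window))
  nc <- nrow(unique(x$pulses[c("window", "cycle")]))
  cat(sprintf("<valve_schedule> %d window(s), %d cycle(s), %d wash marker(s)\n",
              nw, nc, nrow(x$washes)))
  invisible(x)
}

#' Predicted delivered concentration of a schedule window
#'
#' The scheduler's own pre-dispersion prediction: the time-weighted mean of
#' the stock concentrations over the pulses of the window's cycles.
#'
#' @param schedule A `valve_schedule`.
#' @param stocks Named list of stock compositions; defaults to the
#'   schedule's configuration.
#' @param window Window number (default 1), or `cycles` to restrict further.
#' @param cycles Optional cycle numbers within the window.
#' @return Named numeric vector of mean delivered concentrations.
#' @examples
#' cfg <- pwm_config(list(stock = c(FITC = 7.5), buffer = numeric()))
#' sch <- schedule_profile(target_profile(profile_segment(
#'   0, 15, "hold", c(FITC = 2.5))), cfg)
#' delivered_concentration(sch)  # 2.5
#' @export
delivered_concentration <- function(schedule, stocks = schedule$cfg$stocks,
                                    window = 1L, cycles = NULL) {
  stopifnot(inherits(schedule, "valve_schedule"))
  p <- schedule$pulses[schedule$pulses$window == window, ]
  if (!is.null(cycles)) p <- p[p$cycle %in% cycles, ]
  if (!nrow(p)) stop("empty window")
  A <- stock_matrix(stocks)
  if (!nrow(A)) return(stats::setNames(numeric(), character()))
  tot <- stats::setNames(rep(0, nrow(A)), rownames(A))
  for (cyc in unique(p$cycle)) {
    pc <- p[p$cycle == cyc, ]
    frac <- stats::setNames(pc$pulse_ms, pc$input_id)[colnames(A)] /
      schedule$cfg$cycle_ms
    frac[is.na(frac)] <- 0
    tot <- tot + drop(A %*% frac)
  }
  tot / length(unique(p$cycle))
}

#' Volume of a cylindrical fluidic path
#'
#' @param length_cm Tubing length in cm.
#' @param inner_diameter_mm Inner diameter in mm.
#' @return Volume in uL (`pi * (d/2)^2 * L`).
#' @examples
#' tubing_volume(37.5, 0.56)  # ~92.4 uL
#' @export
tubing_volume <- function(length_cm, inner_diameter_mm) {
  stopifnot(length_cm >= 0, inner_diameter_mm >= 0)
  r_cm <- inner_diameter_mm / 20
  pi * r_cm^2 * length_cm * 1000
}

#' Define a delivery-path mixing context
#'
#' @param tubing_length_cm Fluidic path length, cm (default 37.5, the
#'   validated geometry).
#' @param inner_diameter_mm Tubing inner diameter, mm (default 0.56).
#' @param volumetric_flow_uL_s Volumetric flow, uL/s (e.g. set volume over
#'   fill time).
#' @param homogeneity_threshold_cycles Minimum number of PWM cycles that must
#'   be resident in the path for the alternating pulses to mix to a
#'   homogeneous output (default 5).
#' @return A `mixing_context` object.
#' @export
mixing_context <- function(tubing_length_cm = 37.5, inner_diameter_mm = 0.56,
                           volumetric_flow_uL_s,
                           homogeneity_threshold_cycles = 5) {
  stopifnot(tubing_length_cm > 0, inner_diameter_mm > 0,
            volumetric_flow_uL_s > 0, homogeneity_threshold_cycles >= 0)
  structure(list(tubing_length_cm = tubing_length_cm,
                 inner_diameter_mm = inner_diameter_mm,
                 volumetric_flow_uL_s = volumetric_flow_uL_s,
                 homogeneity_threshold_cycles = homogeneity_threshold_cycles),
            class = "mixing_context")
}

#' Check pulse mixing homogeneity for a delivery path
#'
#' Whether alternating stock pulses blend to a homogeneous output depends on
#' how many PWM cycles' worth of liquid the path holds: the resident-cycle
#' count is the tubing volume divided by the volume delivered per cycle
#' (flow x cycle time). The check passes when at least
#' `homogeneity_threshold_cycles` cycles are resident.
#'
#' @param cfg A [pwm_config()].
#' @param ctx A [mixing_context()].
#' @return List with `cycles_resident` and logical `pass`.
#' @examples
#' cfg <- pwm_config(list(stock = c(FITC = 7.5), buffer = numeric()))
#' homogeneity_check(cfg, mixing_context(volumetric_flow_uL_s = 10))
#' @export
homogeneity_check <- function(cfg, ctx) {
  stopifnot(inherits(cfg, "pwm_config"), inherits(ctx, "mixing_context"))
  vol <- tubing_volume(ctx$tubing_length_cm, ctx$inner_diameter_mm)
  per_cycle <- ctx$volumetric_flow_uL_s * cfg$cycle_ms / 1000
  cycles <- vol / per_cycle
  list(cycles_resident = cycles,
       pass = cycles >= ctx$homogeneity_threshold_cycles)
}

#' Export a valve schedule to CSV or JSON
#'
#' @param schedule A `valve_schedule`.
#' @param csv_path Path for the pulse table CSV (`window`, `well`, `cycle`,
#'   `t_start_s`, `input_id`, `pulse_ms`).
#' @param json_path Optional path for a JSON export of pulses and wash
#'   markers.
#' @return Invisibly, `csv_path`.
#' @export
write_schedule <- function(schedule, csv_path, json_path = NULL) {
  stopifnot(inherits(schedule, "valve_schedule"))
  utils::write.csv(schedule$pulses, csv_path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  if (!is.null(json_path)) {
    jsonlite::write_json(list(pulses = schedule$pulses,
                              washes = schedule$washes),
                         json_path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(csv_path)
}

#' Read a valve-schedule pulse table back from CSV
#'
#' @param csv_path Path written by [write_schedule()].
#' @param cfg The [pwm_config()] the schedule was built with.
#' @return A `valve_schedule` (wash markers are not round-tripped via CSV).
#' @export
read_schedule <- function(csv_path, cfg) {
  p <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  structure(list(pulses = p,
                 washes = data.frame(window = integer(), well = character(),
                                     cycle = integer()),
                 cfg = cfg),
            class = "valve_schedule")
}
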