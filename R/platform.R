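# ---- domain types -----------------------------------------------------------

#' Define a medium source
#'
#' A medium source is one of the (up to six) stock inputs feeding the
#' pulse-width-modulation (PWM) formulator: a plain buffer, a base medium, or
#' a medium carrying one or more solutes at known concentrations.
#'
#' @param id Short identifier, e.g. `"chir"` or `"buffer"`.
#' @param solutes Named numeric vector of solute concentrations (values >= 0).
#'   An empty vector describes plain buffer.
#' @param units Either a single unit string applied to every solute or a named
#'   character vector parallel to `solutes`. Units are carried as text and
#'   never converted; mixing the same solute under different unit texts is an
#'   error downstream.
#' @param label Free-text description.
#' @return A `medium_source` object.
#' @examples
#' medium_source("chir", c(CHIR99021 = 3), units = "uM")
#' @export
medium_source <- function(id, solutes = numeric(), units = "uM", label = "") {
  stopifnot(is.character(id), length(id) == 1L)
  solutes <- as.numeric_named(solutes)
  if (any(solutes < 0)) stop("solute concentrations must be >= 0")
  if (anyDuplicated(names(solutes))) stop("solute names must be unique")
  if (length(units) == 1L && is.null(names(units))) {
    units <- stats::setNames(rep(units, length(solutes)), names(solutes))
  }
  structure(list(id = id, solutes = solutes, units = units, label = label),
            class = "medium_source")
}

#' Define a well configuration
#'
#' Captures the per-well fluidic geometry and programmed phase timings of one
#' culture well under the fluidic lid: the set (leveled) culture volume, the
#' dead volume that full emptying cannot remove (150 uL in hydrogel microwell
#' arrays, where it protects the aggregates), and the measured times to empty,
#' fill and level the well.
#'
#' @param plate_type One of `"standard-24"`, `"imaging-24"`, `"gri3d-24"`.
#' @param set_volume Leveled culture volume, uL.
#' @param dead_volume Residual volume after a full empty, uL
#'   (`0 <= dead_volume < set_volume`).
#' @param fill_overshoot_fraction Fraction of `set_volume` to which automated
#'   exchange cycles fill before leveling, in `[1, 1.5]`. Default 1: fill to
#'   the level and trim, so leveling removes no resident solute and the
#'   carryover per cycle is exactly `dead_volume / set_volume`.
#' @param empty_s,fill_s,level_s Programmed phase times, seconds. `fill_s` is
#'   the time to deliver one set volume; partial fills are pro-rated.
#' @return A `well_config` object.
#' @examples
#' well_config("gri3d-24", set_volume = 1330, dead_volume = 150,
#'             empty_s = 90, fill_s = 270, level_s = 60)
#' @export
well_config <- function(plate_type = c("standard-24", "imaging-24", "gri3d-24"),
                        set_volume, dead_volume = 0,
                        fill_overshoot_fraction = 1.0,
                        empty_s, fill_s, level_s) {
  plate_type <- match.arg(plate_type)
  stopifnot(set_volume > 0, dead_volume >= 0, dead_volume < set_volume,
            empty_s > 0, fill_s > 0, level_s > 0)
  if (fill_overshoot_fraction < 1 || fill_overshoot_fraction > 1.5) {
    stop("fill_overshoot_fraction must lie in [1.0, 1.5]")
  }
  structure(list(plate_type = plate_type, set_volume = set_volume,
                 dead_volume = dead_volume,
                 fill_overshoot_fraction = fill_overshoot_fraction,
                 empty_s = empty_s, fill_s = fill_s, level_s = level_s),
            class = "well_config")
}

#' Define a platform configuration
#'
#' A platform addresses up to eight individually configured wells through a
#' single formulation/multiplexing path, drawing from up to six medium
#' sources. Automated events execute sequentially, one well at a time.
#'
#' @param wells Named list of [well_config()] objects (1--8 entries).
#' @param sources List of [medium_source()] objects (at most 6).
#' @return A `platform_config` object.
#' @export
platform_config <- function(wells, sources = list()) {
  if (inherits(wells, "well_config")) wells <- list(well = wells)
  stopifnot(length(wells) >= 1L, length(wells) <= 8L)
  if (is.null(names(wells)) || any(!nzchar(names(wells)))) {
    names(wells) <- paste0("well", seq_along(wells))
  }
  lapply(wells, function(w) stopifnot(inherits(w, "well_config")))
  if (length(sources) > 6L) stop("at most 6 medium sources are supported")
  lapply(sources, function(s) stopifnot(inherits(s, "medium_source")))
  names(sources) <- vapply(sources, `[[`, "", "id")
  structure(list(wells = wells, sources = sources), class = "platform_config")
}

#' Create a well state
#'
#' The mutable ledger of one well: current volume, per-solute mass
#' (concentration unit x uL), unit text per solute, and elapsed time.
#' Contents are treated as instantaneously well mixed, so
#' `concentration = mass / volume`.
#'
#' @param volume Current volume, uL (>= 0).
#' @param concentration Named numeric vector of solute concentrations used to
#'   initialise the masses (mass = concentration x volume).
#' @param units Unit text, recycled across solutes.
#' @param clock Elapsed time, seconds.
#' @return A `well_state` object with fields `volume`, `solute_mass`, `units`,
#'   `clock`.
#' @examples
#' s <- well_state(1330, c(CHIR99021 = 3))
#' concentrations(s)
#' @export
well_state <- function(volume = 0, concentration = numeric(), units = "uM",
                       clock = 0) {
  stopifnot(volume >= 0, clock >= 0)
  concentration <- as.numeric_named(concentration)
  if (any(concentration < 0)) stop("concentrations must be >= 0")
  units <- recycle_units(units, names(concentration))
  structure(list(volume = volume, solute_mass = concentration * volume,
                 units = units, clock = clock),
            class = "well_state")
}

#' Current solute concentrations of a well state
#'
#' @param state A [well_state()].
#' @return Named numeric vector of concentrations (mass / volume); an all-`NA`
#'   vector when the well is empty.
#' @export
concentrations <- function(state) {
  stopifnot(inherits(state, "well_state"))
  if (state$volume <= 0) {
    return(stats::setNames(rep(NA_real_, length(state$solute_mass)),
                           names(state$solute_mass)))
  }
  state$solute_mass / state$volume
}

#' @export
print.well_state <- function(x, ...) {
  cat(sprintf("<well_state> volume %.6g uL, clock %.6g s\n", x$volume, x$clock))
  conc <- concentrations(x)
  if (length(conc)) {
    for (s in names(conc)) {
      cat(sprintf("  %s: %.6g %s (mass %.6g)\n", s, conc[[s]],
                  unit_of(x$units, s), x$solute_mass[[s]]))
    }
  } else cat("  (no solutes)\n")
  invisible(x)
}

#' @export
print.well_config <- function(x, ...) {
  cat(sprintf(
    "<well_config> %s: set %.6g uL, dead %.6g uL, overshoot %.3g, timings (%g, %g, %g) s\n",
    x$plate_type, x$set_volume, x$dead_volume, x$fill_overshoot_fraction,
    x$empty_s, x$fill_s, x$level_s))
  invisible(x)
}

#' @export
print.platform_config <- function(x, ...) {
  cat(sprintf("<platform_config> %d well(s), %d source(s)\n",
              length(x$wells), length(x$sources)))
  for (nm in names(x$wells)) {
    cat(" ", nm, ": ", sep = ""); print(x$wells[[nm]])
  }
  invisible(x)
}

# ---- internal helpers -------------------------------------------------------

as.numeric_named <- function(x) {
  if (length(x) == 0L) return(stats::setNames(numeric(), character()))
  stopifnot(!is.null(names(x)), all(nzchar(names(x))))
  stats::setNames(as.numeric(x), names(x))
}

recycle_units <- function(units, solute_names) {
  if (length(solute_names) == 0L) return(stats::setNames(character(), character()))
  if (length(units) == 1L && is.null(names(units))) {
    return(stats::setNames(rep(units, length(solute_names)), solute_names))
  }
  stopifnot(all(solute_names %in% names(units)))
  units[solute_names]
}

unit_of <- function(units, solute) {
  if (solute %in% names(units)) units[[solute]] else ""
}

# merge formulation units into state units; error on unit-text clash
merge_units <- function(state_units, new_units) {
  for (s in names(new_units)) {
    if (s %in% names(state_units) && state_units[[s]] != new_units[[s]]) {
      stop(sprintf("unit mismatch for solute '%s': '%s' vs '%s'",
                   s, state_units[[s]], new_units[[s]]))
    }
    state_units[[s]] <- new_units[[s]]
  }
  state_units
}

# scale all solute masses by a factor (homogeneous removal)
scale_masses <- function(state, factor) {
  state$solute_mass <- state$solute_mass * factor
  state
}

formulation_units <- function(formulation, units) {
  formulation <- as.numeric_named(formulation)
  if (any(formulation < 0)) stop("formulation concentrations must be >= 0")
  list(conc = formulation, units = recycle_units(units, names(formulation)))
}

add_volume <- function(state, volume, formulation = numeric(), units = "uM") {
  f <- formulation_units(formulation, units)
  state$units <- merge_units(state$units, f$units)
  add_mass <- f$conc * volume
  for (s in names(add_mass)) {
    cur <- if (s %in% names(state$solute_mass)) state$solute_mass[[s]] else 0
    state$solute_mass[[s]] <- cur + add_mass[[s]]
  }
  state$volume <- state$volume + volume
  state
}

# ---- core operations --------------------------------------------------------

#' Empty a well down to its dead volume
#'
#' Full emptying through the outflow channel leaves the configured dead
#' volume behind; with well-mixed contents every solute mass is scaled by
#' `dead_volume / volume`. The clock advances by the programmed emptying time.
#'
#' @param state A [well_state()].
#' @param cfg A [well_config()].
#' @return The updated `well_state`.
#' @examples
#' cfg <- well_config("gri3d-24", 1330, 150, empty_s = 90, fill_s = 270,
#'                    level_s = 60)
#' st <- well_state(1330, c(CHIR99021 = 3))
#' concentrations(empty_well(st, cfg))  # unchanged at 3
#' @export
empty_well <- function(state, cfg) {
  stopifnot(inherits(state, "well_state"), inherits(cfg, "well_config"))
  if (state$volume < cfg$dead_volume - 1e-9) {
    stop("invalid state: well volume below dead volume")
  }
  if (state$volume > 0) {
    state <- scale_masses(state, cfg$dead_volume / state$volume)
  }
  state$volume <- cfg$dead_volume
  state$clock <- state$clock + cfg$empty_s
  state
}

#' Fill a well to a target fraction of its set volume
#'
#' Dispenses freshly formulated medium until the volume reaches
#' `target_fraction * set_volume`; the added volume carries the formulation's
#' concentrations and masses add. Fill time is pro-rated from the programmed
#' `fill_s` (the time to deliver one set volume).
#'
#' @param state A [well_state()].
#' @param cfg A [well_config()].
#' @param formulation Named numeric vector of concentrations in the dispensed
#'   medium (empty for plain medium).
#' @param target_fraction Target volume as a fraction of `set_volume`
#'   (<= 1.5); defaults to the configured overshoot fraction.
#' @param units Unit text for the formulation.
#' @return The updated `well_state`.
#' @export
fill_well <- function(state, cfg, formulation = numeric(),
                      target_fraction = cfg$fill_overshoot_fraction,
                      units = "uM") {
  stopifnot(inherits(state, "well_state"), inherits(cfg, "well_config"))
  if (target_fraction > 1.5 + 1e-12) stop("target_fraction must be <= 1.5")
  target <- target_fraction * cfg$set_volume
  if (target < state$volume - 1e-9) {
    stop("invalid request: fill target below current volume")
  }
  added <- max(target - state$volume, 0)
  state <- add_volume(state, added, formulation, units)
  state$volume <- target
  state$clock <- state$clock + cfg$fill_s * added / cfg$set_volume
  state
}

#' Level a well back to its set volume
#'
#' The level-setting efflux draws the volume down to `set_volume`.
#' Aspiration from a well-mixed column is modeled as homogeneous removal, so
#' concentrations are invariant and masses scale by `set_volume / volume`.
#'
#' @inheritParams empty_well
#' @return The updated `well_state`.
#' @export
level_well <- function(state, cfg) {
  stopifnot(inherits(state, "well_state"), inherits(cfg, "well_config"))
  if (state$volume < cfg$set_volume - 1e-9) {
    stop("invalid request: cannot level a well below its set volume")
  }
  if (state$volume > 0) {
    state <- scale_masses(state, min(cfg$set_volume / state$volume, 1))
  }
  state$volume <- cfg$set_volume
  state$clock <- state$clock + cfg$level_s
  state
}

#' Run one full medium exchange cycle
#'
#' Empty to the dead volume, re-fill with fresh medium to the configured
#' overshoot fraction, and re-set the level: the automated routine that
#' replaces all but the dead volume of a well's medium.
#'
#' @inheritParams fill_well
#' @return A list with `state` (the updated [well_state()]) and `duration_s`.
#' @examples
#' cfg <- well_config("standard-24", 750, 0, empty_s = 45, fill_s = 75,
#'                    level_s = 30)
#' run_exchange_cycle(well_state(750), cfg, c(FITC = 7.5))$duration_s  # 150
#' @export
run_exchange_cycle <- function(state, cfg, formulation = numeric(),
                               units = "uM") {
  t0 <- state$clock
  state <- empty_well(state, cfg)
  state <- fill_well(state, cfg, formulation,
                     target_fraction = cfg$fill_overshoot_fraction,
                     units = units)
  state <- level_well(state, cfg)
  list(state = state, duration_s = state$clock - t0)
}

#' Run one half-wash cycle
#'
#' At medium switches the dead volume would carry the previous formulation
#' into the new one. A half-wash purges it: top the well up to 150% of its
#' set volume with the new formulation, empty completely, re-fill, and
#' re-level. Its carryover is strictly below a plain exchange's whenever the
#' dead volume is positive.
#'
#' @inheritParams fill_well
#' @return A list with `state`, `duration_s`, and `peak_volume_uL` (the 150%
#'   top-up volume reached mid-cycle).
#' @export
run_half_wash <- function(state, cfg, formulation = numeric(), units = "uM") {
  t0 <- state$clock
  state <- fill_well(state, cfg, formulation, target_fraction = 1.5,
                     units = units)
  peak <- state$volume
  state <- empty_well(state, cfg)
  state <- fill_well(state, cfg, formulation,
                     target_fraction = cfg$fill_overshoot_fraction,
                     units = units)
  state <- level_well(state, cfg)
  list(state = state, duration_s = state$clock - t0, peak_volume_uL = peak)
}

#' Closed-form carryover after repeated exchange cycles
#'
#' The fraction of pre-existing solute mass that survives `n_cycles` full
#' exchange cycles is `(dead_volume / set_volume)^n_cycles`: each empty
#' retains the dead-volume share and the fill-and-level adds only fresh
#' medium. Equals the simulated fraction exactly.
#'
#' @param cfg A [well_config()].
#' @param n_cycles Non-negative integer number of exchange cycles.
#' @return The retained old-solute mass fraction in `[0, 1]`.
#' @examples
#' cfg <- well_config("gri3d-24", 1330, 150, empty_s = 90, fill_s = 270,
#'                    level_s = 60)
#' carryover_fraction(cfg, 2)  # (150/1330)^2
#' @export
carryover_fraction <- function(cfg, n_cycles) {
  stopifnot(inherits(cfg, "well_config"), n_cycles >= 0,
            n_cycles == round(n_cycles))
  (cfg$dead_volume / cfg$set_volume)^n_cycles
}
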