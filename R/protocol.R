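# ---- protocol events and the discrete-event driver -------------------------

EVENT_KINDS <- c("EMPTY", "FILL", "LEVEL", "EXCHANGE", "HALF_WASH",
                 "MANUAL_ADD", "MANUAL_REMOVE", "WAIT")

#' Construct a fluidic protocol event
#'
#' Events are the atoms of an automated or manual liquid-handling protocol:
#' the programmed phases (`EMPTY`, `FILL`, `LEVEL`), the composite automated
#' routines (`EXCHANGE`, `HALF_WASH`), the hand-pipetting ledger entries
#' (`MANUAL_ADD`, `MANUAL_REMOVE`), and incubation gaps (`WAIT`).
#'
#' @param kind Event kind, one of `EMPTY`, `FILL`, `LEVEL`, `EXCHANGE`,
#'   `HALF_WASH`, `MANUAL_ADD`, `MANUAL_REMOVE`, `WAIT`.
#' @param well Well id the event addresses (ignored for `WAIT`).
#' @param formulation Named concentration vector of the dispensed medium
#'   (`FILL`, `EXCHANGE`, `HALF_WASH`, `MANUAL_ADD`).
#' @param volume Volume in uL for manual events (> 0).
#' @param duration Duration in seconds (`WAIT` requires it; manual events
#'   default to 0).
#' @param target_fraction Fill target as a fraction of the set volume
#'   (`FILL` only; defaults to the well's overshoot fraction).
#' @param units Unit text for `formulation`.
#' @return A `fluid_event` object.
#' @examples
#' fluid_event("MANUAL_ADD", "well1", c(CHIR99021 = 3), volume = 1050)
#' @export
fluid_event <- function(kind, well = NA_character_, formulation = numeric(),
                        volume = NA_real_, duration = NA_real_,
                        target_fraction = NA_real_, units = "uM") {
  kind <- match.arg(kind, EVENT_KINDS)
  if (kind %in% c("MANUAL_ADD", "MANUAL_REMOVE")) {
    if (!is.finite(volume) || volume <= 0) stop("manual events need volume > 0")
  }
  if (kind == "WAIT" && (!is.finite(duration) || duration < 0)) {
    stop("WAIT events need a non-negative duration")
  }
  structure(list(kind = kind, well = well, formulation = as.numeric_named(formulation),
                 volume = volume, duration = duration,
                 target_fraction = target_fraction, units = units),
            class = "fluid_event")
}

#' Run a liquid-handling protocol on a platform
#'
#' Applies an ordered list of [fluid_event()]s to the wells of a platform,
#' one event at a time (the single formulation/multiplexing path serves one
#' well at a time), and returns the full per-well trace of volume and
#' concentrations after every event.
#'
#' @param cfg A [platform_config()].
#' @param events List of [fluid_event()] objects, applied in order.
#' @param initial Optional named list of [well_state()]s giving starting
#'   contents per well; wells default to empty (volume 0).
#' @return A `routine_result`: list with `trace` (tidy data frame, one row per
#'   event x well x solute, columns `clock_s`, `well`, `volume_uL`, `solute`,
#'   `concentration`, `unit`), `events` (event log data frame), `final`
#'   (named list of final well states), and `duration_s`.
#' @examples
#' cfg <- platform_config(list(
#'   a1 = well_config("gri3d-24", 1330, 150, empty_s = 90, fill_s = 270,
#'                    level_s = 60)))
#' ledger <- list(
#'   fluid_event("MANUAL_ADD", "a1", volume = 1000),
#'   fluid_event("MANUAL_REMOVE", "a1", volume = 850),
#'   fluid_event("MANUAL_ADD", "a1", c(CHIR99021 = 3), volume = 1050),
#'   fluid_event("MANUAL_ADD", "a1", volume = 130))
#' res <- run_protocol(cfg, ledger)
#' res$final$a1$volume                  # 1330
#' concentrations(res$final$a1)         # 3 * 1050 / 1330
#' @export
run_protocol <- function(cfg, events, initial = NULL) {
  stopifnot(inherits(cfg, "platform_config"))
  states <- lapply(cfg$wells, function(w) well_state(0))
  if (!is.null(initial)) {
    for (nm in names(initial)) {
      if (!nm %in% names(states)) stop("initial state for unknown well: ", nm)
      states[[nm]] <- initial[[nm]]
    }
  }
  clock <- 0
  trace <- list()
  log <- list()
  for (i in seq_along(events)) {
    ev <- events[[i]]
    stopifnot(inherits(ev, "fluid_event"))
    if (ev$kind != "WAIT") {
      if (!ev$well %in% names(states)) {
        stop("event references unknown well: ", ev$well)
      }
      st <- states[[ev$well]]
      st$clock <- clock
      wcfg <- cfg$wells[[ev$well]]
      st <- switch(ev$kind,
        EMPTY = empty_well(st, wcfg),
        FILL = fill_well(st, wcfg, ev$formulation,
                         target_fraction = if (is.finite(ev$target_fraction))
                           ev$target_fraction else wcfg$fill_overshoot_fraction,
                         units = ev$units),
        LEVEL = level_well(st, wcfg),
        EXCHANGE = run_exchange_cycle(st, wcfg, ev$formulation, ev$units)$state,
        HALF_WASH = run_half_wash(st, wcfg, ev$formulation, ev$units)$state,
        MANUAL_ADD = {
          st2 <- add_volume(st, ev$volume, ev$formulation, ev$units)
          st2$clock <- st$clock + if (is.finite(ev$duration)) ev$duration else 0
          st2
        },
        MANUAL_REMOVE = {
          if (ev$volume > st$volume + 1e-9) {
            stop("cannot remove ", ev$volume, " uL from a well holding ",
                 st$volume, " uL")
          }
          st2 <- scale_masses(st, (st$volume - ev$volume) / st$volume)
          st2$volume <- st$volume - ev$volume
          st2$clock <- st$clock + if (is.finite(ev$duration)) ev$duration else 0
          st2
        })
      dur <- st$clock - clock
      clock <- st$clock
      states[[ev$well]] <- st
      conc <- concentrations(st)
      solutes <- if (length(conc)) names(conc) else NA_character_
      trace[[length(trace) + 1L]] <- data.frame(
        clock_s = clock, well = ev$well, volume_uL = st$volume,
        solute = solutes,
        concentration = if (length(conc)) unname(conc) else NA_real_,
        unit = if (length(conc))
          vapply(names(conc), unit_of, "", units = st$units) else NA_character_,
        stringsAsFactors = FALSE)
    } else {
      dur <- ev$duration
      clock <- clock + dur
    }
    log[[length(log) + 1L]] <- data.frame(
      event = i, kind = ev$kind, well = ev$well,
      t_start_s = clock - dur, t_end_s = clock, stringsAsFactors = FALSE)
  }
  structure(list(trace = do.call(rbind, trace),
                 events = do.call(rbind, log),
                 final = states, duration_s = clock),
            class = "routine_result")
}

#' @export
print.routine_result <- function(x, ...) {
  cat(sprintf("<routine_result> %d event(s), total duration %.6g s\n",
              nrow(x$events), x$duration_s))
  for (nm in names(x$final)) {
    cat(" ", nm, ": ", sep = ""); print(x$final[[nm]])
  }
  invisible(x)
}

#' Export a protocol trace to CSV and its event log to JSON
#'
#' @param result A `routine_result` from [run_protocol()].
#' @param csv_path Path for the tidy trace CSV (columns `clock_s`, `well`,
#'   `volume_uL`, `solute`, `concentration`, `unit`).
#' @param json_path Optional path for the event-log JSON.
#' @return Invisibly, `csv_path`.
#' @export
write_routine_result <- function(result, csv_path, json_path = NULL) {
  stopifnot(inherits(result, "routine_result"))
  utils::write.csv(result$trace, csv_path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  if (!is.null(json_path)) {
    jsonlite::write_json(result$events, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(csv_path)
}
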