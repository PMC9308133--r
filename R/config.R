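# ---- run configuration, validation, subcommand dispatch ---------------------

CONFIG_SCHEMA_VERSION <- 1L

# allowed parameter keys per subcommand; unknown keys are rejected
SUBCOMMAND_SCHEMA <- list(
  simulate = c("preset", "wells", "events"),
  schedule = c("stocks", "cycle_ms", "min_pulse_ms", "resolution_ms",
               "segments", "insert_washes"),
  quantify = c("stack", "darkfields", "flatfields", "frame_interval_s",
               "roi", "calibration", "reference_intensity"),
  morph = c("image", "axes", "n_segments", "band_width_px", "degree"),
  synth = c("generator", "args")
)

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) run configuration, validates it against the
#' subcommand schema (unknown keys are rejected with a field-level message),
#' fills defaults, and records the file's MD5 hash for provenance.
#'
#' @param path Path to a YAML or JSON configuration file with top-level keys
#'   `schema_version`, `subcommand`, optional `seed` (default 1), optional
#'   `out_dir` (default `"."`), and `params` (subcommand-specific).
#' @return A `run_config` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else yaml::read_yaml(path)
  allowed_top <- c("schema_version", "subcommand", "seed", "out_dir", "params")
  extra <- setdiff(names(cfg), allowed_top)
  if (length(extra)) {
    stop("unknown top-level config key(s): ", paste(extra, collapse = ", "))
  }
  if (is.null(cfg$subcommand)) stop("config field 'subcommand' is required")
  if (!cfg$subcommand %in% names(SUBCOMMAND_SCHEMA)) {
    stop("unknown subcommand '", cfg$subcommand, "'; expected one of: ",
         paste(names(SUBCOMMAND_SCHEMA), collapse = ", "))
  }
  sv <- if (is.null(cfg$schema_version)) CONFIG_SCHEMA_VERSION else
    cfg$schema_version
  if (sv != CONFIG_SCHEMA_VERSION) {
    stop("unsupported schema_version ", sv, " (expected ",
         CONFIG_SCHEMA_VERSION, ")")
  }
  params <- if (is.null(cfg$params)) list() else cfg$params
  bad <- setdiff(names(params), SUBCOMMAND_SCHEMA[[cfg$subcommand]])
  if (length(bad)) {
    stop("unknown key(s) in params for subcommand '", cfg$subcommand, "': ",
         paste(bad, collapse = ", "))
  }
  structure(list(schema_version = sv, subcommand = cfg$subcommand,
                 seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed),
                 out_dir = if (is.null(cfg$out_dir)) "." else cfg$out_dir,
                 params = params,
                 config_md5 = unname(tools::md5sum(path)),
                 config_path = path),
            class = "run_config")
}

#' Save a run configuration back to YAML
#'
#' @param config A `run_config`.
#' @param path Output YAML path.
#' @return Invisibly, `path`. A saved configuration loads back equal (hash
#'   and source path aside).
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(list(schema_version = config$schema_version,
                        subcommand = config$subcommand,
                        seed = config$seed, out_dir = config$out_dir,
                        params = config$params),
                   path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> %s (seed %d, out_dir %s, md5 %s)\n",
              x$subcommand, x$seed, x$out_dir, substr(x$config_md5, 1, 8)))
  invisible(x)
}

parse_formulation <- function(x) {
  if (is.null(x) || !length(x)) return(numeric())
  stats::setNames(as.numeric(unlist(x)), names(x))
}

config_events <- function(events) {
  lapply(events, function(e) {
    fluid_event(kind = e$kind,
                well = if (is.null(e$well)) NA_character_ else e$well,
                formulation = parse_formulation(e$formulation),
                volume = if (is.null(e$volume)) NA_real_ else e$volume,
                duration = if (is.null(e$duration)) NA_real_ else e$duration,
                target_fraction = if (is.null(e$target_fraction)) NA_real_
                else e$target_fraction)
  })
}

config_platform <- function(params) {
  if (!is.null(params$preset)) return(platform_preset(params$preset))
  wells <- lapply(params$wells, function(w) {
    well_config(w$plate_type, set_volume = w$set_volume,
                dead_volume = if (is.null(w$dead_volume)) 0 else w$dead_volume,
                fill_overshoot_fraction =
                  if (is.null(w$fill_overshoot_fraction)) 1.0
                else w$fill_overshoot_fraction,
                empty_s = w$empty_s, fill_s = w$fill_s, level_s = w$level_s)
  })
  platform_config(wells)
}

config_segments <- function(segments) {
  target_profile(lapply(segments, function(s) {
    profile_segment(start_s = s$start_s, end_s = s$end_s, kind = s$kind,
                    target = parse_formulation(s$target),
                    target_end = if (is.null(s$target_end)) NULL else
                      parse_formulation(s$target_end),
                    levels = if (is.null(s$levels)) NULL else
                      lapply(s$levels, parse_formulation),
                    well = if (is.null(s$well)) "well1" else s$well)
  }))
}

write_run_log <- function(config, artifacts) {
  log <- list(subcommand = config$subcommand, seed = config$seed,
              config_md5 = config$config_md5,
              package_version =
                as.character(utils::packageVersion("platesim")),
              r_version = paste(R.version$major, R.version$minor, sep = "."),
              artifacts = artifacts)
  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Execute a configured subcommand
#'
#' Runs one of the toolkit's subcommands from a validated [load_config()]
#' result: `simulate` (protocol to per-well trace CSV), `schedule` (target
#' profile to valve-pulse CSV/JSON), `quantify` (image stacks to a
#' concentration time-course CSV), `morph` (gastruloid images plus axes to
#' morphometry CSVs), `synth` (synthetic generators to TIFF plus truth
#' JSON). Every run writes `run_log.json` with the seed, package version and
#' config hash next to its artifacts.
#'
#' @param config A `run_config` from [load_config()].
#' @return Invisibly, a character vector of artifact paths written.
#' @export
run_subcommand <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  out <- function(...) file.path(config$out_dir, ...)
  artifacts <- switch(config$subcommand,
    simulate = {
      platform <- config_platform(p)
      res <- run_protocol(platform, config_events(p$events))
      write_routine_result(res, out("trace.csv"), out("events.json"))
      c(out("trace.csv"), out("events.json"))
    },
    schedule = {
      stocks <- lapply(p$stocks, parse_formulation)
      cfg <- pwm_config(stocks,
                        cycle_ms = p$cycle_ms %||% 1500,
                        min_pulse_ms = p$min_pulse_ms %||% 100,
                        resolution_ms = p$resolution_ms %||% 100)
      sch <- schedule_profile(config_segments(p$segments), cfg,
                              insert_washes = p$insert_washes %||% TRUE)
      write_schedule(sch, out("schedule.csv"), out("schedule.json"))
      c(out("schedule.csv"), out("schedule.json"))
    },
    quantify = {
      darks <- read_image_stack(p$darkfields)
      flats <- read_image_stack(p$flatfields)
      model <- build_correction(darks, flats)
      stack <- read_image_stack(p$stack,
                                frame_interval_s = p$frame_interval_s %||% 0.5)
      region <- if (is.null(p$roi)) roi() else
        roi(p$roi$row %||% 1L, p$roi$col %||% 1L,
            p$roi$height %||% 100L, p$roi$width %||% 100L)
      curve <- structure(list(slope = p$calibration$slope,
                              intercept = p$calibration$intercept %||% 0,
                              residual_se = NA_real_, n = NA_integer_,
                              se_defined = FALSE),
                         class = "calibration_curve")
      ts <- quantify_timeseries(stack, model, region, curve,
                                p$reference_intensity)
      utils::write.csv(ts, out("timeseries.csv"), row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
      out("timeseries.csv")
    },
    morph = {
      img_stack <- read_image_stack(p$image)
      axes <- read_axes_csv(p$axes)
      n_frames <- dim(img_stack$frames)[3L]
      results <- lapply(seq_along(axes), function(i) {
        frame <- img_stack$frames[, , min(i, n_frames)]
        analyze_gastruloid(frame, axes[[i]],
                           n_segments = p$n_segments %||% 10L,
                           band_width_px = p$band_width_px %||% 80,
                           id = names(axes)[i])
      })
      names(results) <- names(axes)
      tab <- morphometry_table(results)
      utils::write.csv(tab, out("morphometry.csv"), row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
      fit <- fit_condition(lapply(results, `[[`, "profile"),
                           degree = p$degree %||% 4L)
      xs <- seq(0.05, 0.95, by = 0.01)
      utils::write.csv(data.frame(position = xs,
                                  fitted = predict(fit, xs)),
                       out("condition_fit.csv"), row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
      c(out("morphometry.csv"), out("condition_fit.csv"))
    },
    synth = {
      gen <- p$generator
      args <- p$args %||% list()
      if (is.null(args$seed)) args$seed <- config$seed
      if (gen == "make_pwm_trace" && is.character(args$schedule)) {
        stocks <- lapply(args$stocks, parse_formulation)
        args$schedule <- read_schedule(args$schedule, pwm_config(stocks))
        args$stocks <- NULL
      }
      res <- do.call(get(gen, envir = asNamespace("platesim")), args)
      paths <- character()
      if (gen == "make_reference_stacks") {
        write_image_stack(res$darkfields, out("darkfields.tif"))
        write_image_stack(res$flatfields, out("flatfields.tif"))
        paths <- c(out("darkfields.tif"), out("flatfields.tif"))
      } else if (gen == "make_dilution_series") {
        write_image_stack(res$frames, out("dilution.tif"))
        paths <- out("dilution.tif")
      } else if (gen == "make_gastruloid_phantom") {
        write_image_stack(image_stack(list(res$image)), out("phantom.tif"))
        utils::write.csv(data.frame(id = "phantom",
                                    row = res$axis$vertices[, 1L],
                                    col = res$axis$vertices[, 2L]),
                         out("phantom_axis.csv"), row.names = FALSE,
                         quote = FALSE, fileEncoding = "UTF-8")
        paths <- c(out("phantom.tif"), out("phantom_axis.csv"))
      } else if (gen == "make_pwm_trace") {
        utils::write.csv(res$series, out("trace.csv"), row.names = FALSE,
                         quote = FALSE, fileEncoding = "UTF-8")
        paths <- out("trace.csv")
      } else stop("unknown generator '", gen, "'")
      write_truth(res$truth, out("truth.json"))
      c(paths, out("truth.json"))
    })
  write_run_log(config, artifacts)
  invisible(c(artifacts, file.path(config$out_dir, "run_log.json")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
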