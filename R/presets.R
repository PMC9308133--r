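# ---- packaged platform presets ----------------------------------------------

#' List the packaged platform presets
#'
#' @return Character vector of preset names usable with [platform_preset()].
#' @export
list_presets <- function() {
  files <- list.files(system.file("extdata", "presets", package = "platesim"),
                      pattern = "\\.yaml$")
  sub("\\.yaml$", "", files)
}

#' Load a packaged platform preset
#'
#' Three presets ship with the package, named after the programmed operating
#' configurations of the platform: `"epilc-1plex"` (one standard 24-well,
#' 750 uL, timings 45/75/30 s), `"pwm-mux-8plex"` (eight imaging 24-wells,
#' 750 uL, worst-case timings 120/180/60 s), and `"gri3d-8plex"` (eight
#' Gri3D hydrogel microwell array wells, 1330 uL set volume with a 150 uL
#' dead volume, timings 90/270/60 s).
#'
#' @param name Preset name; see [list_presets()].
#' @return A [platform_config()] with the preset's wells; the raw preset
#'   fields (including the inflow pressure and timing ranges) are attached
#'   as attribute `"preset"`.
#' @examples
#' cfg <- platform_preset("gri3d-8plex")
#' cfg$wells[[1]]$set_volume   # 1330
#' @export
platform_preset <- function(name) {
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "platesim")
  if (!nzchar(path)) {
    stop("unknown preset '", name, "'; available: ",
         paste(list_presets(), collapse = ", "))
  }
  p <- yaml::read_yaml(path)
  wc <- well_config(p$plate_type,
                    set_volume = p$set_volume_uL,
                    dead_volume = p$dead_volume_uL,
                    fill_overshoot_fraction = p$fill_overshoot_fraction,
                    empty_s = p$timing_s$empty,
                    fill_s = p$timing_s$fill,
                    level_s = p$timing_s$level)
  wells <- stats::setNames(rep(list(wc), p$n_wells),
                           paste0("well", seq_len(p$n_wells)))
  cfg <- platform_config(wells)
  attr(cfg, "preset") <- p
  cfg
}
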