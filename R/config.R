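#' Simulation configuration for a seeded-aggregation live-imaging experiment
#'
#' Builds the parameter set for one experimental condition: a cell line
#' ("control" or "mutant"), a lysate type and dose, and the imaging,
#' rendering and hazard parameters shared by all wells of that condition.
#' Hazards are piecewise-constant (exponential clocks): each cell draws an
#' aggregation-onset time, a death time whose hazard switches from
#' `death_base_hazard_per_h` to `death_base_hazard_per_h *
#' death_post_onset_multiplier` at onset, and an independent field-exit
#' time (censoring). The onset hazard scales as
#' `(dose_ug / 10)^onset_hazard_dose_exponent`, multiplied by
#' `onset_hazard_line_multiplier` for the mutant line; control lysate and
#' dose 0 never seed (onset hazard forced to zero).
#'
#' @param line_label `"control"` or `"mutant"`.
#' @param lysate lysate type: `"rTg4510"` (seed-competent), `"control"`,
#'   or `"none"`. Only `"rTg4510"` at dose > 0 produces seeding.
#' @param dose_ug total lysate protein per well, micrograms; the paper's
#'   design uses 0 (no lysate) and 1, 5 or 10 ug.
#' @param n_wells replicate wells for this condition.
#' @param frames number of frames; 84 frames at 2 h covers 7 d.
#' @param frame_interval_h hours between frames.
#' @param image_size_px square field side, pixels.
#' @param pixel_size_um microns per pixel (default 0.65, typical for a
#'   10x objective on a widefield imager).
#' @param n_cells_per_well neurons seeded per field.
#' @param onset_base_hazard_per_h onset hazard (1/h) for the control line
#'   at the 10 ug reference dose.
#' @param onset_hazard_line_multiplier hazard ratio mutant : control.
#' @param onset_hazard_dose_exponent exponent of the (dose/10) scaling.
#' @param death_base_hazard_per_h baseline death hazard (1/h).
#' @param death_post_onset_multiplier death hazard ratio after onset.
#' @param exit_hazard_per_h hazard (1/h) of drifting out of the field
#'   (right-censoring).
#' @param transient_prob probability that an onset is transient (the
#'   aggregate later dissolves).
#' @param transient_dwell_mean_h mean dwell of a transient aggregate, h.
#' @param morphology_mix named probability vector over the archetypes
#'   `Ordered`, `Disordered`, `Speckles`, `Other`; must sum to 1.
#' @param morphology_death_multiplier named vector of extra post-onset
#'   death-hazard multipliers per morphology (default all 1); used to
#'   simulate strain-dependent toxicity.
#' @param neurite_seed_rate_per_h expected neurite seed puncta per cell
#'   per hour at the 10 ug reference dose (same dose scaling as onset,
#'   no line effect).
#' @param death_flash_fold factor by which the background-subtracted
#'   nuclear-dye signal over the nucleus jumps at lysis.
#' @param punctum_amplitude_gray peak amplitude of rendered aggregate
#'   puncta above their surroundings, gray levels.
#' @param soma_intensity_gray mean diffuse reporter level of a soma above
#'   background (log-normal across cells, sdlog 0.25).
#' @param neurite_intensity_frac neurite brightness as a fraction of the
#'   soma level.
#' @param nuclear_intensity_gray live-nucleus dye level above background.
#' @param background_gray camera background level.
#' @param noise_sigma_gray Gaussian read-noise standard deviation.
#' @param soma_radius_px,nucleus_radius_px rendered soma / nucleus radii.
#' @param drift_speed_px_per_frame mean linear drift speed per cell
#'   (speeds are uniform on 0..2x this value, directions uniform).
#' @param n_background_nuclei bright fragmented dead-cell nuclei present
#'   from the first frame (no reporter signal, so never tracked).
#' @param t0_offset_h hours between seed addition and the first frame
#'   (at most one imaging interval).
#' @param rng_seed integer master seed; every well derives its own
#'   stream from it, so identical configs reproduce bit-identical data.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(line_label = c("control", "mutant"),
                       lysate = c("rTg4510", "control", "none"),
                       dose_ug = 10,
                       n_wells = 2,
                       frames = 84,
                       frame_interval_h = 2,
                       image_size_px = 256,
                       pixel_size_um = 0.65,
                       n_cells_per_well = 60,
                       onset_base_hazard_per_h = 0.004,
                       onset_hazard_line_multiplier = 2.5,
                       onset_hazard_dose_exponent = 1,
                       death_base_hazard_per_h = 0.002,
                       death_post_onset_multiplier = 4,
                       exit_hazard_per_h = 8e-4,
                       transient_prob = 0.05,
                       transient_dwell_mean_h = 30,
                       morphology_mix = c(Ordered = 0.45, Disordered = 0.35,
                                          Speckles = 0.10, Other = 0.10),
                       morphology_death_multiplier = c(Ordered = 1, Disordered = 1,
                                                       Speckles = 1, Other = 1),
                       neurite_seed_rate_per_h = 0.015,
                       death_flash_fold = 5,
                       punctum_amplitude_gray = 15000,
                       soma_intensity_gray = 6000,
                       neurite_intensity_frac = 0.3,
                       nuclear_intensity_gray = 1500,
                       background_gray = 2000,
                       noise_sigma_gray = 500,
                       soma_radius_px = 9,
                       nucleus_radius_px = 4.5,
                       drift_speed_px_per_frame = 0.1,
                       n_background_nuclei = 4,
                       t0_offset_h = 2,
                       rng_seed = 1L) {
  line_label <- match.arg(line_label)
  lysate <- match.arg(lysate)
  cfg <- list(
    line_label = line_label, lysate = lysate, dose_ug = dose_ug,
    n_wells = as.integer(n_wells), frames = as.integer(frames),
    frame_interval_h = frame_interval_h, image_size_px = as.integer(image_size_px),
    pixel_size_um = pixel_size_um, n_cells_per_well = as.integer(n_cells_per_well),
    onset_base_hazard_per_h = onset_base_hazard_per_h,
    onset_hazard_line_multiplier = onset_hazard_line_multiplier,
    onset_hazard_dose_exponent = onset_hazard_dose_exponent,
    death_base_hazard_per_h = death_base_hazard_per_h,
    death_post_onset_multiplier = death_post_onset_multiplier,
    exit_hazard_per_h = exit_hazard_per_h,
    transient_prob = transient_prob,
    transient_dwell_mean_h = transient_dwell_mean_h,
    morphology_mix = morphology_mix,
    morphology_death_multiplier = morphology_death_multiplier,
    neurite_seed_rate_per_h = neurite_seed_rate_per_h,
    death_flash_fold = death_flash_fold,
    punctum_amplitude_gray = punctum_amplitude_gray,
    soma_intensity_gray = soma_intensity_gray,
    neurite_intensity_frac = neurite_intensity_frac,
    nuclear_intensity_gray = nuclear_intensity_gray,
    background_gray = background_gray,
    noise_sigma_gray = noise_sigma_gray,
    soma_radius_px = soma_radius_px,
    nucleus_radius_px = nucleus_radius_px,
    drift_speed_px_per_frame = drift_speed_px_per_frame,
    n_background_nuclei = as.integer(n_background_nuclei),
    t0_offset_h = t0_offset_h,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$image_size_px <= 0) stop("image_size_px must be positive")
  if (cfg$frames < 2) stop("frames must be >= 2")
  if (cfg$frame_interval_h <= 0 || cfg$pixel_size_um <= 0)
    stop("calibration (frame interval, pixel size) must be strictly positive")
  if (cfg$t0_offset_h < 0 || cfg$t0_offset_h > cfg$frame_interval_h)
    stop("t0_offset_h must lie within one imaging interval")
  mm <- cfg$morphology_mix
  arch <- c("Ordered", "Disordered", "Speckles", "Other")
  if (is.null(names(mm)) || !all(names(mm) %in% c(arch, "Toxic")))
    stop("morphology_mix must be named over Ordered/Disordered/Speckles/Other")
  if (any(mm[names(mm) == "Toxic"] > 0))
    stop("no archetype is defined for the 'Toxic' label; its mix weight must be 0")
  if (abs(sum(mm) - 1) > 1e-9) stop("morphology_mix must sum to 1")
  if (any(mm < 0)) stop("morphology_mix entries must be non-negative")
  haz <- c(cfg$onset_base_hazard_per_h, cfg$death_base_hazard_per_h,
           cfg$exit_hazard_per_h, cfg$death_post_onset_multiplier,
           cfg$onset_hazard_line_multiplier)
  if (any(haz < 0)) stop("hazards and hazard multipliers must be >= 0")
  if (cfg$dose_ug < 0) stop("dose_ug must be >= 0")
  cfg
}

#' Effective onset hazard implied by a configuration
#'
#' Zero unless the lysate is seed-competent (`rTg4510`) at a positive
#' dose; otherwise the base hazard scaled by the line multiplier (mutant
#' only) and the `(dose/10)^exponent` dose response.
#'
#' @param cfg a [sim_config()].
#' @return hazard in 1/h.
#' @export
effective_onset_hazard <- function(cfg) {
  if (cfg$lysate != "rTg4510" || cfg$dose_ug <= 0) return(0)
  mult <- if (cfg$line_label == "mutant") cfg$onset_hazard_line_multiplier else 1
  cfg$onset_base_hazard_per_h * mult * (cfg$dose_ug / 10)^cfg$onset_hazard_dose_exponent
}

#' @keywords internal
effective_seed_rate <- function(cfg) {
  if (cfg$lysate != "rTg4510" || cfg$dose_ug <= 0) return(0)
  cfg$neurite_seed_rate_per_h * (cfg$dose_ug / 10)^cfg$onset_hazard_dose_exponent
}

#' Write / read a simulation configuration as YAML
#'
#' @param cfg a [sim_config()].
#' @param path file path.
#' @return `write_sim_config` returns `path` invisibly;
#'   `read_sim_config` returns a validated `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  out <- unclass(cfg)
  for (f in c("morphology_mix", "morphology_death_multiplier"))
    out[[f]] <- as.list(out[[f]])   # keep names through YAML
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("morphology_mix", "morphology_death_multiplier"))
    raw[[f]] <- unlist(raw[[f]])
  cfg <- structure(raw, class = "sim_config")
  validate_sim_config(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %s line, %s lysate %g ug; %d wells x %d cells; %d frames @ %g h\n",
              x$line_label, x$lysate, x$dose_ug, x$n_wells, x$n_cells_per_well,
              x$frames, x$frame_interval_h))
  cat(sprintf("  onset hazard %.4g/h (effective), death %.4g/h (x%g post-onset), exit %.4g/h\n",
              effective_onset_hazard(x), x$death_base_hazard_per_h,
              x$death_post_onset_multiplier, x$exit_hazard_per_h))
  invisible(x)
}
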