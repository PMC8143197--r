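# End-to-end orchestration: simulate -> detect -> track -> analyse, one
# well in memory at a time, plus validation of every stage against the
# generator's ground truth.

# first frame time at or after a continuous event time
discretize_to_frame <- function(t, frame_interval_h, t0_offset_h = 0) {
  t0_offset_h + ceiling((t - t0_offset_h) / frame_interval_h - 1e-9) * frame_interval_h
}

#' Run the full simulated live-imaging pipeline
#'
#' For each configuration (one condition each), simulates wells one at a
#' time, runs neurite-seed counting and/or single-cell tracking, then
#' the downstream statistics. The master seeds inside the configs fully
#' determine all stochastic behaviour; rerunning with the same configs
#' is bit-identical.
#'
#' @param configs list of [sim_config()] objects (one per condition).
#' @param analyses subset of `c("seeding", "survival", "morphology")`.
#' @param out_dir optional directory for CSV artifacts (event table,
#'   seed series, morphology calls, manifest).
#' @param early_threshold_h "early aggregator" cutoff, hours post seed
#'   addition (default 48).
#' @param tracking_args named list of overrides for [track_cells()].
#' @return list: `events`, `measures`, `truth` (bound tables),
#'   `seed_series`, `seeding` (baseline-corrected series, AUC table,
#'   ANOVA, slopes), `survival` (early-vs-others log-rank per line,
#'   cumulative onset, post-onset comparison, Cox fit, fractions),
#'   `morphology` (calls + statistics), `config_hash`.
#' @export
run_pipeline <- function(configs, analyses = c("seeding", "survival", "morphology"),
                         out_dir = NULL, early_threshold_h = 48,
                         tracking_args = list()) {
  if (inherits(configs, "sim_config")) configs <- list(configs)
  analyses <- match.arg(analyses, several.ok = TRUE)
  need_track <- any(c("survival", "morphology") %in% analyses)
  all_events <- list(); all_meas <- list(); all_truth <- list()
  all_seeds <- list(); series <- list()
  for (cfg in configs) {
    for (w in seq_len(cfg$n_wells)) {
      sim <- simulate_well(cfg, w)
      wid <- sim$cells$well_id[1]
      all_truth[[wid]] <- sim$cells
      all_seeds[[wid]] <- dplyr::mutate(sim$seeds, well_id = wid, .before = 1)
      if ("seeding" %in% analyses)
        series[[wid]] <- dplyr::mutate(count_series(sim$stack),
                                       line = cfg$line_label, dose_ug = cfg$dose_ug,
                                       lysate = cfg$lysate)
      if (need_track) {
        tc <- do.call(track_cells, c(list(stack = sim$stack), tracking_args))
        all_events[[wid]] <- tc$events
        all_meas[[wid]] <- tc$measures
      }
    }
  }
  events <- if (length(all_events)) {
    normalize_t0_intensity(dplyr::bind_rows(all_events),
                           group_vars = c("line", "well_id"))
  }
  measures <- if (length(all_meas)) dplyr::bind_rows(all_meas)
  truth <- dplyr::bind_rows(all_truth)
  out <- list(events = events, measures = measures, truth = truth,
              neurite_seed_truth = dplyr::bind_rows(all_seeds),
              seed_series = if (length(series)) dplyr::bind_rows(series),
              config_hash = rlang::hash(lapply(configs, unclass)))

  if ("seeding" %in% analyses && length(series)) {
    ss <- out$seed_series
    corrected <- list()
    for (ln in unique(ss$line)) {
      base <- ss[ss$line == ln & (ss$lysate == "none" | ss$dose_ug == 0), ]
      lys <- ss[ss$line == ln & ss$lysate == "rTg4510" & ss$dose_ug > 0, ]
      bl <- if (nrow(base)) mean(base$raw) else 0
      lys$baseline <- bl
      lys$corrected <- lys$raw - bl
      base$baseline <- bl
      base$corrected <- base$raw - bl
      corrected[[ln]] <- dplyr::bind_rows(lys, base)
    }
    corrected <- dplyr::bind_rows(corrected)
    seeded <- corrected[corrected$lysate == "rTg4510" & corrected$dose_ug > 0, ]
    auc_tbl <- if (nrow(seeded)) {
      seeded |>
        dplyr::group_by(.data$line, .data$dose_ug, .data$well_id) |>
        dplyr::summarise(auc = auc_trapezoid(dplyr::pick(dplyr::everything())),
                         .groups = "drop")
    } else tibble::tibble(line = character(), dose_ug = numeric(),
                          well_id = character(), auc = numeric())
    anova_tbl <- if (length(unique(auc_tbl$dose_ug)) >= 2 &&
                       length(unique(auc_tbl$line)) >= 2 &&
                       min(table(auc_tbl$line, auc_tbl$dose_ug)) >= 2)
      anova_line_by_dose(auc_tbl) else NULL
    top <- if (nrow(auc_tbl)) max(auc_tbl$dose_ug) else -1
    slope_in <- corrected[corrected$dose_ug == top & corrected$lysate == "rTg4510", ]
    slopes <- if (nrow(slope_in))
      seeding_slope(dplyr::rename(slope_in, replicate = "well_id")) else NULL
    out$seeding <- list(corrected_series = corrected, auc = auc_tbl,
                        anova = anova_tbl, slopes = slopes)
  }

  if ("survival" %in% analyses && !is.null(events)) {
    out$survival <- analyze_survival(events, early_threshold_h)
  }
  if ("morphology" %in% analyses && !is.null(events)) {
    calls <- classify_cells(events, measures)
    stats <- tryCatch(morphology_statistics(calls, events),
                      error = function(e) e$message)
    out$morphology <- list(calls = calls, statistics = stats)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(events)) write_event_table(events, file.path(out_dir, "events.csv"))
    if (!is.null(out$seed_series))
      utils::write.csv(out$seed_series, file.path(out_dir, "seed_series.csv"),
                       row.names = FALSE)
    if (!is.null(out$morphology))
      utils::write.csv(out$morphology$calls,
                       file.path(out_dir, "morphology_calls.csv"), row.names = FALSE)
    manifest <- list(config_hash = out$config_hash,
                     seeds = vapply(configs, `[[`, 0L, "rng_seed"),
                     r_version = as.character(getRversion()),
                     timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  out
}

#' Survival analyses of a tracked event table
#'
#' The central comparisons: early aggregators (onset within the
#' threshold) versus all other neurons per line on the seed-addition
#' clock; cumulative onset incidence between lines; post-onset-clock
#' survival between lines; a Cox model with line and early-aggregation
#' covariates; and aggregate fractions at 48 h and 7 d.
#'
#' @param events event tibble (with `t0_intensity_norm` if correlations
#'   are wanted).
#' @param early_threshold_h early-aggregator cutoff, hours.
#' @return named list of results.
#' @export
analyze_survival <- function(events, early_threshold_h = 48) {
  ev <- dplyr::mutate(events,
                      time_h = dplyr::coalesce(.data$death_h, .data$censor_h),
                      event = !is.na(.data$death_h),
                      early = !is.na(.data$onset_h) &
                        .data$onset_h <= early_threshold_h)
  res <- list()
  res$early_vs_others <- lapply(split(ev, ev$line), function(sub) {
    if (length(unique(sub$early)) < 2 || !any(sub$event)) return(NULL)
    c(list(km_early = km_estimate(sub$time_h[sub$early], sub$event[sub$early]),
           km_others = km_estimate(sub$time_h[!sub$early], sub$event[!sub$early])),
      as.list(log_rank(sub$time_h, sub$event, sub$early)))
  })
  onr <- onset_records(ev)
  if (length(unique(onr$line)) == 2 && any(onr$event)) {
    res$cumulative_onset <- lapply(split(onr, onr$line), function(s)
      cumulative_onset(s$time_h, s$event))
    res$onset_logrank <- log_rank(onr$time_h, onr$event, onr$line)
  }
  por <- post_onset_records(ev)
  if (length(unique(por$line)) == 2 && any(por$event)) {
    res$post_onset_km <- lapply(split(por, por$line), function(s)
      km_estimate(s$time_h, s$event))
    res$post_onset_logrank <- log_rank(por$time_h, por$event, por$line)
  }
  if (length(unique(ev$line)) >= 2 && length(unique(ev$early)) >= 2 &&
        any(ev$event)) {
    res$cox <- cox_fit(dplyr::mutate(ev, line = factor(.data$line)),
                       covariates = c("line", "early"))
  }
  res$fractions <- aggregate_fraction_at(ev)
  if ("t0_intensity_norm" %in% names(ev) && sum(!is.na(ev$onset_h)) >= 6) {
    res$onset_expression <- tryCatch(
      onset_expression_correlation(ev, "onset"), error = function(e) NULL)
    res$lifespan_expression <- tryCatch(
      onset_expression_correlation(ev, "lifespan"), error = function(e) NULL)
  }
  res
}

#' Match tracked cells to ground-truth cells by t0 position
#'
#' Greedy unique nearest-neighbour matching of track starting positions
#' to true cell positions at the first frame.
#'
#' @param events tracked event table.
#' @param truth_cells `$cells` table of a `sim_truth` (same wells).
#' @param max_dist_px matching radius.
#' @return tibble: `cell_id` (track), `truth_id`, `dist_px`.
#' @export
match_events_to_truth <- function(events, truth_cells, max_dist_px = 6) {
  out <- lapply(unique(events$well_id), function(wid) {
    ev <- events[events$well_id == wid, ]
    tr <- truth_cells[truth_cells$well_id == wid, ]
    if (!nrow(ev) || !nrow(tr)) return(NULL)
    D <- sqrt(outer(ev$x0, tr$x0, "-")^2 + outer(ev$y0, tr$y0, "-")^2)
    D[D > max_dist_px] <- Inf
    pairs <- list()
    while (any(is.finite(D))) {
      ij <- which(D == min(D), arr.ind = TRUE)[1, ]
      pairs[[length(pairs) + 1L]] <- tibble::tibble(
        cell_id = ev$cell_id[ij[1]], truth_id = tr$cell_id[ij[2]],
        dist_px = D[ij[1], ij[2]])
      D[ij[1], ] <- Inf; D[, ij[2]] <- Inf
    }
    dplyr::bind_rows(pairs)
  })
  dplyr::bind_rows(out)
}

# ground-truth class labels via the same grammar the tracker uses
truth_class_labels <- function(truth_cells, horizon_h, frame_interval_h,
                               t0_offset_h = 0) {
  vapply(seq_len(nrow(truth_cells)), function(i) {
    ce <- truth_cells[i, ]
    died <- !is.na(ce$true_death_h)
    end_time <- if (died) ce$true_death_h
                else min(ce$true_exit_h, horizon_h, na.rm = TRUE)
    has_onset <- !is.na(ce$true_onset_h) && ce$true_onset_h < end_time
    # aggregate state at the last frame at/before the event time; a
    # recorded transient means the aggregate dissolved before the end
    endA <- FALSE
    if (has_onset && !isTRUE(ce$transient)) {
      last_frame_t <- if (died) {
        discretize_to_frame(end_time, frame_interval_h, t0_offset_h) -
          frame_interval_h
      } else end_time
      endA <- last_frame_t >=
        discretize_to_frame(ce$true_onset_h, frame_interval_h, t0_offset_h)
    }
    paste("O", if (endA) "A" else "O", if (died) "D" else "A", sep = "+")
  }, "")
}

#' Validate pipeline output against simulation ground truth
#'
#' Event-time errors (in frames), censored-versus-death status
#' agreement, class-label and morphology confusion matrices.
#'
#' Onset recovery is scored over the union of called onsets and
#' *callable* true onsets — those whose aggregate is rendered in at
#' least `persistence_frames` frames; an onset occurring within one
#' frame of death (or a transient that dissolves immediately) leaves no
#' scoreable evidence in the images, for an automated caller and a
#' human scorer alike. Likewise a death in the first two frames
#' precedes any nuclear-dye baseline and is not callable.
#'
#' @param events tracked event table.
#' @param truth a `sim_truth` covering the same wells.
#' @param calls optional morphology calls from [classify_cells()].
#' @param persistence_frames the onset-persistence rule used by the
#'   tracker (default 2).
#' @return list: `matching`, `n_tracks`, `n_truth`,
#'   `onset_within_1_frame`, `death_within_1_frame`,
#'   `status_agreement`, `onset_errors_frames`, `death_errors_frames`,
#'   `class_confusion`, `morphology_confusion` (when `calls` given),
#'   `morphology_recovery`.
#' @export
validate_against_truth <- function(events, truth, calls = NULL,
                                   persistence_frames = 2) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!any(events$well_id %in% truth$cells$well_id))
    stop("events and truth share no wells")
  iv <- truth$frame_interval_h
  t0 <- truth$config$t0_offset_h
  mt <- match_events_to_truth(events, truth$cells)
  ev <- dplyr::left_join(mt, events, by = "cell_id")
  tr <- truth$cells[match(mt$truth_id, truth$cells$cell_id), ]
  true_onset_f <- ifelse(is.na(tr$true_onset_h), NA,
                         discretize_to_frame(tr$true_onset_h, iv, t0))
  true_death_f <- ifelse(is.na(tr$true_death_h), NA,
                         discretize_to_frame(tr$true_death_h, iv, t0))
  # frames in which the aggregate is actually rendered
  agg_stop <- pmin(ifelse(is.na(tr$true_death_h), Inf, tr$true_death_h),
                   ifelse(is.na(tr$true_exit_h), Inf, tr$true_exit_h),
                   ifelse(is.na(tr$agg_dissolve_h), Inf, tr$agg_dissolve_h),
                   truth$horizon_h + iv / 2)
  n_agg_frames <- ifelse(is.na(true_onset_f) | agg_stop <= true_onset_f, 0,
                         floor((agg_stop - true_onset_f) / iv - 1e-9) + 1)
  onset_callable <- !is.na(true_onset_f) & n_agg_frames >= persistence_frames
  death_callable <- !is.na(true_death_f) &
    true_death_f >= t0 + 2 * iv  # needs >= 2 baseline frames
  onset_err <- (ev$onset_h - true_onset_f) / iv
  death_err <- (ev$death_h - true_death_f) / iv
  both_onset <- !is.na(ev$onset_h) & !is.na(true_onset_f)
  onset_union <- !is.na(ev$onset_h) | onset_callable
  both_death <- !is.na(ev$death_h) & !is.na(true_death_f)
  death_union <- !is.na(ev$death_h) | death_callable
  status_true <- !is.na(tr$true_death_h)
  status_called <- !is.na(ev$death_h)
  truth_lab <- truth_class_labels(tr, truth$horizon_h, iv, t0)
  out <- list(
    matching = mt, n_tracks = nrow(events), n_truth = nrow(truth$cells),
    onset_within_1_frame =
      sum(both_onset & abs(onset_err) <= 1, na.rm = TRUE) / max(sum(onset_union), 1),
    death_within_1_frame =
      sum(both_death & abs(death_err) <= 1, na.rm = TRUE) / max(sum(death_union), 1),
    status_agreement = mean(status_true == status_called),
    onset_errors_frames = onset_err[both_onset],
    death_errors_frames = death_err[both_death],
    class_confusion = table(truth = truth_lab, called = ev$class_label)
  )
  if (!is.null(calls)) {
    cc <- dplyr::inner_join(calls, mt, by = "cell_id")
    tm <- truth$cells$morphology_label[match(cc$truth_id, truth$cells$cell_id)]
    keep <- !is.na(tm) & cc$label != "Unclassifiable"
    out$morphology_confusion <- table(truth = tm[keep], called = cc$label[keep])
    out$morphology_recovery <- mean(tm[keep] == cc$label[keep])
  }
  out
}

#' Precision and recall of neurite-seed detection against truth
#'
#' Greedy unique matching of detections to rendered ground-truth
#' puncta within a pixel tolerance.
#'
#' @param detections tibble with `x`, `y` (from
#'   [detect_neurite_seeds()]).
#' @param truth_points tibble with `x`, `y` of rendered puncta.
#' @param tol_px matching radius (default 3).
#' @return tibble: `n_detected`, `n_truth`, `true_positives`,
#'   `precision`, `recall`.
#' @export
evaluate_seed_detection <- function(detections, truth_points, tol_px = 3) {
  nd <- nrow(detections); nt <- nrow(truth_points)
  tp <- 0L
  if (nd && nt) {
    D <- sqrt(outer(detections$x, truth_points$x, "-")^2 +
                outer(detections$y, truth_points$y, "-")^2)
    D[D > tol_px] <- Inf
    while (any(is.finite(D))) {
      ij <- which(D == min(D), arr.ind = TRUE)[1, ]
      tp <- tp + 1L
      D[ij[1], ] <- Inf; D[, ij[2]] <- Inf
    }
  }
  tibble::tibble(n_detected = nd, n_truth = nt, true_positives = tp,
                 precision = if (nd) tp / nd else NA_real_,
                 recall = if (nt) tp / nt else NA_real_)
}
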