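# Aggregate-morphology classification: summarise per-frame aggregate
# descriptors over each cell's aggregate-bearing window into a feature
# tuple, then apply fixed rules to assign a strain label.

MORPHOLOGY_LABELS <- c("Ordered", "Disordered", "Speckles", "Toxic", "Other",
                       "Unclassifiable")

#' Summarise aggregate descriptors into morphology features
#'
#' Uses the frames from aggregation onset to death or the end of
#' observation. Requires at least `min_frames` aggregate-positive
#' frames; otherwise the cell is unclassifiable (returns `NULL`).
#'
#' @param descriptors per-frame tibble (from [detect_soma_aggregate()] /
#'   [measure_tracks()]) with `aggregate_positive`, `n_components`,
#'   `total_area_px`, `largest_area_px`, `largest_area_fraction`,
#'   `nuclear_overlap_fraction`, `largest_elongation` and `time_h`.
#' @param min_frames minimum aggregate-positive frames (default 3).
#' @return tibble of features (`punctum_count_median`,
#'   `largest_component_area_fraction`, `nuclear_overlap_fraction`,
#'   `elongation_median`, `compaction_slope_per_h`, `frames_used`), or
#'   `NULL` when too few frames.
#' @export
extract_morphology_features <- function(descriptors, min_frames = 3) {
  pos <- descriptors[descriptors$aggregate_positive, ]
  if (nrow(pos) < min_frames) return(NULL)
  # relative change of the largest component's area per hour
  slope <- if (nrow(pos) >= 2 && stats::sd(pos$time_h) > 0) {
    unname(stats::coef(stats::lm(largest_area_px ~ time_h, data = pos))[2]) /
      max(median(pos$largest_area_px), 1)
  } else 0
  tibble::tibble(
    punctum_count_median = median(pos$n_components),
    largest_component_area_fraction = median(pos$largest_area_fraction),
    nuclear_overlap_fraction = median(pos$nuclear_overlap_fraction),
    elongation_median = median(pos$largest_elongation),
    compaction_slope_per_h = slope,
    frames_used = nrow(pos)
  )
}

#' Classify aggregate morphology from its features
#'
#' Fixed rules mirroring the visual taxonomy: nuclear confinement marks
#' Speckles; a dominant single component is Ordered unless strongly
#' elongated (lenticular), which marks Other; many persistent puncta
#' mark Disordered; the remainder is Other. Thresholds were frozen once
#' against the simulator archetypes. Classification is deterministic
#' and, since every feature is a ratio or count, invariant to uniform
#' intensity rescaling.
#'
#' @param features tibble from [extract_morphology_features()], or
#'   `NULL` (unclassifiable).
#' @param speckles_overlap nuclear-overlap threshold (default 0.5).
#' @param ordered_fraction largest-component area-fraction threshold
#'   (default 0.6).
#' @param disordered_count minimum median punctum count (default 5).
#' @param lenticular_elongation axis-ratio threshold separating
#'   lens-shaped (Other) from compact (Ordered) single components.
#' @return tibble: `label` plus the feature columns (`NA` features for
#'   Unclassifiable).
#' @export
classify_morphology <- function(features, speckles_overlap = 0.5,
                                ordered_fraction = 0.6, disordered_count = 5,
                                lenticular_elongation = 2.2) {
  if (is.null(features) || !nrow(features)) {
    return(tibble::tibble(label = "Unclassifiable", punctum_count_median = NA_real_,
                          largest_component_area_fraction = NA_real_,
                          nuclear_overlap_fraction = NA_real_,
                          elongation_median = NA_real_,
                          compaction_slope_per_h = NA_real_, frames_used = 0L))
  }
  stopifnot(all(is.finite(unlist(features[1, c(
    "punctum_count_median", "largest_component_area_fraction",
    "nuclear_overlap_fraction", "elongation_median")]))))
  label <- if (features$nuclear_overlap_fraction > speckles_overlap) {
    "Speckles"
  } else if (features$largest_component_area_fraction > ordered_fraction) {
    if (features$elongation_median > lenticular_elongation) "Other" else "Ordered"
  } else if (features$punctum_count_median >= disordered_count) {
    "Disordered"
  } else "Other"
  dplyr::bind_cols(tibble::tibble(label = label), features)
}

#' Classify every aggregate-bearing cell in a tracked well
#'
#' Joins the per-frame measurements to the event table, restricts each
#' cell to its onset-to-death/end window and classifies it.
#'
#' @param events event tibble from [track_cells()].
#' @param measures per-frame measurement tibble from [track_cells()].
#' @param ... thresholds passed to [classify_morphology()].
#' @return tibble: `cell_id`, `line`, `well_id`, `label` and features.
#' @export
classify_cells <- function(events, measures, ...) {
  formers <- events[!is.na(events$onset_h), ]
  out <- lapply(seq_len(nrow(formers)), function(i) {
    ev <- formers[i, ]
    end_time <- if (!is.na(ev$death_h)) ev$death_h else ev$censor_h
    mm <- measures[measures$cell_id == ev$cell_id &
                     measures$time_h >= ev$onset_h &
                     measures$time_h <= end_time, ]
    cl <- classify_morphology(extract_morphology_features(mm), ...)
    dplyr::bind_cols(tibble::tibble(cell_id = ev$cell_id, line = ev$line,
                                    well_id = ev$well_id), cl)
  })
  dplyr::bind_rows(out)
}

#' Morphology frequencies and outcome comparisons
#'
#' Per-line class proportions (after excluding Unclassifiable) with
#' standard errors and two-proportion tests between lines per class,
#' plus within-line Ordered-versus-Disordered Welch t comparisons of
#' neuronal lifespan, onset time and aggregate lifespan (observed
#' aggregate-bearing duration; censoring status is reported alongside,
#' not imputed).
#'
#' @param calls tibble from [classify_cells()].
#' @param events matching event tibble.
#' @return list: `proportions`, `proportion_tests`, `comparisons`
#'   (skipped comparisons carry a `note`).
#' @export
morphology_statistics <- function(calls, events) {
  cl <- calls[calls$label != "Unclassifiable", ]
  if (length(unique(cl$label)) < 2)
    stop("need >= 2 morphology classes present")
  props <- cl |>
    dplyr::count(.data$line, .data$label) |>
    dplyr::group_by(.data$line) |>
    dplyr::mutate(n_line = sum(.data$n), proportion = .data$n / .data$n_line,
                  se = sqrt(.data$proportion * (1 - .data$proportion) / .data$n_line)) |>
    dplyr::ungroup()
  lines <- unique(cl$line)
  prop_tests <- NULL
  if (length(lines) == 2) {
    prop_tests <- lapply(unique(cl$label), function(lb) {
      x <- vapply(lines, function(l) sum(cl$line == l & cl$label == lb), 0)
      n <- vapply(lines, function(l) sum(cl$line == l), 0)
      pt <- suppressWarnings(stats::prop.test(x, n))  # small classes expected
      tibble::tibble(label = lb, p = pt$p.value,
                     prop_1 = unname(pt$estimate[1]), prop_2 = unname(pt$estimate[2]))
    })
    prop_tests <- dplyr::bind_rows(prop_tests)
  }
  df <- dplyr::left_join(cl, events, by = c("cell_id", "line", "well_id")) |>
    dplyr::mutate(end_time = dplyr::coalesce(.data$death_h, .data$censor_h),
                  lifespan_h = .data$death_h,
                  aggregate_lifespan_h = .data$end_time - .data$onset_h,
                  aggregate_censored = is.na(.data$death_h))
  comparisons <- list()
  for (ln in unique(df$line)) {
    for (metric in c("lifespan_h", "onset_h", "aggregate_lifespan_h")) {
      a <- df[[metric]][df$line == ln & df$label == "Ordered"]
      b <- df[[metric]][df$line == ln & df$label == "Disordered"]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) < 2 || length(b) < 2) {
        comparisons[[paste(ln, metric)]] <- tibble::tibble(
          line = ln, metric = metric, mean_ordered = NA_real_,
          mean_disordered = NA_real_, t = NA_real_, p = NA_real_,
          note = "skipped: a class is absent or has < 2 cells")
        next
      }
      tt <- tryCatch(stats::t.test(a, b), error = function(e)
        list(statistic = NA_real_, p.value = NA_real_))
      comparisons[[paste(ln, metric)]] <- tibble::tibble(
        line = ln, metric = metric, mean_ordered = mean(a),
        mean_disordered = mean(b), t = unname(tt$statistic), p = tt$p.value,
        note = if (is.na(tt$p.value)) "degenerate variance" else NA_character_)
    }
  }
  list(proportions = props, proportion_tests = prop_tests,
       comparisons = dplyr::bind_rows(comparisons))
}
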