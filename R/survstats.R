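# Survival and seeding-curve statistics: Kaplan-Meier with Greenwood
# bands, log-rank (asymptotic and permutation), Cox proportional hazards
# with Efron ties, cumulative onset incidence, aggregate fractions,
# trapezoidal AUC, two-way dose ANOVA, early-window slopes and
# expression correlations.

#' @importFrom survival Surv survfit survdiff coxph
NULL

#' Kaplan-Meier product-limit estimate
#'
#' Right-censored product-limit estimator with a Greenwood-based 95%
#' band (log transform). A leading row at time 0 with S = 1 is included.
#'
#' @param time_h event/censor times (> 0 somewhere).
#' @param event logical, `TRUE` = event.
#' @return tibble: `time_h`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`, `lower`, `upper`.
#' @export
km_estimate <- function(time_h, event) {
  stopifnot(length(time_h) == length(event), length(time_h) >= 1)
  if (all(time_h <= 0)) stop("all times non-positive")
  fit <- survival::survfit(survival::Surv(time_h, as.integer(event)) ~ 1,
                           conf.type = "log")
  tibble::tibble(
    time_h = c(0, fit$time),
    n_risk = c(length(time_h), fit$n.risk),
    n_event = c(0, fit$n.event),
    n_censor = c(0, fit$n.censor),
    survival = c(1, fit$surv),
    lower = c(1, fit$lower),
    upper = c(1, fit$upper)
  )
}

# vectorised two-group log-rank chi-square; group01 is 0/1
logrank_chisq_stat <- function(time, event, group01) {
  et <- sort(unique(time[event]))
  if (!length(et)) return(NA_real_)
  R <- outer(time, et, ">=")
  Dm <- outer(time, et, "==") & event
  d <- colSums(Dm); n <- colSums(R)
  n1 <- as.numeric(group01 %*% R)
  d1 <- as.numeric(group01 %*% Dm)
  ok <- n > 1
  E <- sum(d * n1 / n)
  V <- sum((d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1))[ok])
  (sum(d1) - E)^2 / V
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic (1 df chi-square) via
#' [survival::survdiff()], optionally with a permutation p value
#' obtained by permuting group labels and recomputing the statistic.
#'
#' @param time_h,event survival records.
#' @param group two-level factor/vector.
#' @param permutations number of label permutations (0 = asymptotic
#'   only).
#' @return tibble: `chi_square`, `df`, `p`, and `p_permutation`,
#'   `n_permutations` when requested.
#' @export
log_rank <- function(time_h, event, group, permutations = 0) {
  g <- factor(group)
  if (nlevels(g) != 2) stop("log_rank requires exactly two groups")
  if (any(table(g) == 0)) stop("a group is empty")
  if (!any(event)) stop("no events in either group")
  sd <- survival::survdiff(survival::Surv(time_h, as.integer(event)) ~ g)
  chisq <- unname(sd$chisq)
  out <- tibble::tibble(chi_square = chisq, df = 1,
                        p = stats::pchisq(chisq, 1, lower.tail = FALSE))
  if (permutations > 0) {
    g01 <- as.numeric(g == levels(g)[1])
    et <- sort(unique(time_h[event]))
    R <- outer(time_h, et, ">=")
    Dm <- outer(time_h, et, "==") & event
    d <- colSums(Dm); n <- colSums(R)
    ok <- n > 1
    n_sub <- length(time_h)
    G <- vapply(seq_len(permutations), function(b) sample(g01), numeric(n_sub))
    N1 <- crossprod(G, R)          # permutations x J
    D1 <- crossprod(G, Dm)
    E <- as.numeric(N1 %*% (d / n))
    # V = sum_j w_j n1_j - (w_j / n_j) n1_j^2, w_j = d_j (n_j - d_j) / ((n_j - 1) n_j)
    w <- ifelse(n > 1, d * (n - d) / ((n - 1) * n), 0)
    V <- as.numeric(N1 %*% w - (N1^2) %*% (w / n))
    stat <- (rowSums(D1) - E)^2 / V
    obs <- logrank_chisq_stat(time_h, event, g01)
    out$p_permutation <- (1 + sum(stat >= obs - 1e-12)) / (permutations + 1)
    out$n_permutations <- permutations
  }
  out
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit via [survival::coxph()] with the Efron tie
#' correction by default (frame-grid discretisation makes ties heavy).
#' Wald confidence intervals and p values per covariate; the score test
#' statistic is reported (for a single binary covariate it matches the
#' log-rank chi-square asymptotically).
#'
#' @param data tibble containing the model columns.
#' @param covariates character vector of covariate column names.
#' @param time_col,event_col column names of time and event indicator.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return list: `coefficients` tibble (`term`, `coef`, `hr`,
#'   `hr_lower`, `hr_upper`, `se`, `p`), `score_chisq`, `ties_method`,
#'   `converged`, `separation_flag`, `fit` (the coxph object).
#' @export
cox_fit <- function(data, covariates, time_col = "time_h", event_col = "event",
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time_col, ", as.integer(", event_col, ")) ~ ",
    paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = data, ties = ties)
  s <- summary(fit)
  co <- s$coefficients
  coefs <- tibble::tibble(
    term = rownames(co), coef = co[, "coef"], hr = exp(co[, "coef"]),
    hr_lower = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
    hr_upper = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
    se = co[, "se(coef)"], p = co[, "Pr(>|z|)"]
  )
  list(coefficients = coefs,
       score_chisq = unname(s$sctest["test"]),
       ties_method = ties,
       converged = fit$info %||% TRUE,
       separation_flag = any(abs(coefs$coef) > 10 | coefs$se > 100),
       fit = fit)
}

#' Survival records for aggregation onset (cumulative incidence input)
#'
#' Onset is the event; death or censoring before onset censors the
#' onset clock.
#'
#' @param events event tibble with `onset_h`, `death_h`, `censor_h`.
#' @return tibble: `cell_id`, `line`, `well_id`, `time_h`, `event`.
#' @export
onset_records <- function(events) {
  end_time <- dplyr::coalesce(events$death_h, events$censor_h)
  has_onset <- !is.na(events$onset_h)
  tibble::tibble(cell_id = events$cell_id, line = events$line,
                 well_id = events$well_id,
                 time_h = ifelse(has_onset, events$onset_h, end_time),
                 event = has_onset)
}

#' Survival records on the post-onset clock
#'
#' Restricted to aggregate-forming cells; each cell's clock restarts at
#' onset (left truncation is deliberately ignored, matching a
#' post-onset "survival clock" construction).
#'
#' @param events event tibble.
#' @return tibble: `cell_id`, `line`, `well_id`, `time_h`, `event`.
#' @export
post_onset_records <- function(events) {
  ev <- events[!is.na(events$onset_h), ]
  end_time <- dplyr::coalesce(ev$death_h, ev$censor_h)
  tibble::tibble(cell_id = ev$cell_id, line = ev$line, well_id = ev$well_id,
                 time_h = pmax(end_time - ev$onset_h, 1e-9),
                 event = !is.na(ev$death_h))
}

#' Cumulative onset incidence curve
#'
#' One minus the Kaplan-Meier estimate treating onset as the event
#' (death/censoring before onset censors).
#'
#' @param time_h,event onset records (see [onset_records()]).
#' @return tibble: `time_h`, `incidence`, `lower`, `upper`.
#' @export
cumulative_onset <- function(time_h, event) {
  if (!any(event)) {
    return(tibble::tibble(time_h = c(0, max(time_h)), incidence = c(0, 0),
                          lower = c(0, 0), upper = c(0, 0)))
  }
  km <- km_estimate(time_h, event)
  tibble::tibble(time_h = km$time_h, incidence = 1 - km$survival,
                 lower = 1 - km$upper, upper = 1 - km$lower)
}

#' Aggregate-bearing fraction at fixed time points
#'
#' Per replicate: the fraction of tracked neurons with onset at or
#' before the time point among those still observable then (event or
#' censor time not earlier). Groups are compared per time point with a
#' Welch t test across replicates.
#'
#' @param events event tibble.
#' @param timepoints_h time points in hours (default 48 h and 7 d).
#' @param group_col,replicate_col grouping columns.
#' @return list: `fractions` (per replicate), `summary` (mean +- SD per
#'   group), `tests` (Welch t per time point).
#' @export
aggregate_fraction_at <- function(events, timepoints_h = c(48, 168),
                                  group_col = "line", replicate_col = "well_id") {
  end_time <- dplyr::coalesce(events$death_h, events$censor_h)
  out <- lapply(timepoints_h, function(tp) {
    df <- tibble::tibble(group = events[[group_col]],
                         replicate = events[[replicate_col]],
                         observable = end_time >= tp,
                         positive = !is.na(events$onset_h) & events$onset_h <= tp &
                           end_time >= tp)
    df |>
      dplyr::group_by(.data$group, .data$replicate) |>
      dplyr::summarise(n_observable = sum(.data$observable),
                       fraction = sum(.data$positive) / max(sum(.data$observable), 1),
                       .groups = "drop") |>
      dplyr::mutate(timepoint_h = tp)
  })
  fr <- dplyr::bind_rows(out)
  summ <- fr |>
    dplyr::group_by(.data$timepoint_h, .data$group) |>
    dplyr::summarise(mean_fraction = mean(.data$fraction),
                     sd_fraction = stats::sd(.data$fraction),
                     n_replicates = dplyr::n(), .groups = "drop")
  tests <- lapply(timepoints_h, function(tp) {
    sub <- fr[fr$timepoint_h == tp, ]
    gl <- unique(sub$group)
    if (length(gl) != 2 || any(table(sub$group) < 2))
      return(tibble::tibble(timepoint_h = tp, t = NA_real_, df = NA_real_,
                            p = NA_real_))
    tt <- stats::t.test(fraction ~ group, data = sub)
    tibble::tibble(timepoint_h = tp, t = unname(tt$statistic),
                   df = unname(tt$parameter), p = tt$p.value)
  })
  list(fractions = fr, summary = summ, tests = dplyr::bind_rows(tests))
}

#' Trapezoidal area under a seed-count series
#'
#' @param series a `seed_count_series` (uses `corrected` vs `time_h`),
#'   or a plain data frame with those columns.
#' @return scalar AUC (count x hours).
#' @export
auc_trapezoid <- function(series) {
  t <- series$time_h; y <- series$corrected
  if (length(t) < 2) stop("need at least 2 time points")
  if (is.unsorted(t, strictly = TRUE)) stop("times must be strictly increasing")
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Two-way ANOVA of seeding AUC on cell line and lysate dose
#'
#' Line and dose enter as factors with their interaction; Type II sums
#' of squares (identical to Type I/III for the balanced designs the
#' simulator produces).
#'
#' @param df tibble with columns `auc`, `line`, `dose_ug`.
#' @return tibble: `term`, `sum_sq`, `df`, `f`, `p` (Residuals row
#'   included with `f`, `p` = NA).
#' @export
anova_line_by_dose <- function(df) {
  stopifnot(all(c("auc", "line", "dose_ug") %in% names(df)))
  d <- data.frame(auc = df$auc, line = factor(df$line),
                  dose = factor(df$dose_ug))
  if (nlevels(d$line) < 2 || nlevels(d$dose) < 2)
    stop("need >= 2 levels per factor")
  if (any(table(d$line, d$dose) == 0)) stop("empty design cell")
  fit <- stats::aov(auc ~ line * dose, data = d)
  tab <- car::Anova(fit, type = 2)
  tibble::tibble(term = rownames(tab), sum_sq = tab[["Sum Sq"]],
                 df = tab[["Df"]], f = tab[["F value"]], p = tab[["Pr(>F)"]])
}

#' Early-window seeding slopes and between-line comparison
#'
#' Least-squares slope of corrected counts versus hours within the
#' window, one slope per replicate; the two lines are compared with a
#' Welch t test on the replicate slopes.
#'
#' @param series_tbl long tibble: `time_h`, `corrected`, `line`,
#'   `replicate`.
#' @param window_h inclusive window, hours (default 24-48).
#' @return list: `slopes` (per replicate), `test` (Welch t).
#' @export
seeding_slope <- function(series_tbl, window_h = c(24, 48)) {
  sub <- series_tbl[series_tbl$time_h >= window_h[1] &
                      series_tbl$time_h <= window_h[2], ]
  if (!nrow(sub)) stop("window outside the series")
  slopes <- sub |>
    dplyr::group_by(.data$line, .data$replicate) |>
    dplyr::summarise(n_points = dplyr::n(),
                     slope = {
                       if (dplyr::n() < 2) stop("need >= 2 points inside window")
                       unname(stats::coef(stats::lm(corrected ~ time_h))[2])
                     },
                     .groups = "drop")
  test <- if (length(unique(slopes$line)) == 2 && all(table(slopes$line) >= 2)) {
    tt <- tryCatch(stats::t.test(slope ~ line, data = slopes),
                   error = function(e)   # degenerate within-group variance
                     list(statistic = NA_real_, parameter = NA_real_,
                          p.value = NA_real_))
    tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value)
  } else tibble::tibble(t = NA_real_, df = NA_real_, p = NA_real_)
  list(slopes = slopes, test = test)
}

#' Correlation of t0 reporter expression with onset time or lifespan
#'
#' Pearson correlation per cell line between normalised first-frame
#' reporter intensity and either aggregation-onset time (aggregate
#' formers only) or lifespan (cells that died only). Because a plain r
#' squared, and the adjusted R squared of the corresponding simple
#' regression, answer slightly different questions, all three are
#' reported side by side.
#'
#' @param events event tibble with `t0_intensity_norm`.
#' @param outcome `"onset"` or `"lifespan"`.
#' @return tibble per line: `line`, `n`, `r`, `p`, `r_squared`,
#'   `adj_r_squared`.
#' @export
onset_expression_correlation <- function(events, outcome = c("onset", "lifespan")) {
  outcome <- match.arg(outcome)
  ev <- if (outcome == "onset") events[!is.na(events$onset_h), ]
        else events[!is.na(events$death_h), ]
  y_col <- if (outcome == "onset") "onset_h" else "death_h"
  out <- lapply(split(ev, ev$line), function(sub) {
    if (nrow(sub) < 3) stop("need >= 3 cells per line")
    if (stats::sd(sub$t0_intensity_norm) == 0 || stats::sd(sub[[y_col]]) == 0)
      stop("zero variance in correlation input")
    ct <- stats::cor.test(sub$t0_intensity_norm, sub[[y_col]])
    lmfit <- suppressWarnings(
      summary(stats::lm(sub[[y_col]] ~ sub$t0_intensity_norm)))
    tibble::tibble(line = sub$line[1], n = nrow(sub),
                   r = unname(ct$estimate), p = ct$p.value,
                   r_squared = unname(ct$estimate)^2,
                   adj_r_squared = lmfit$adj.r.squared)
  })
  dplyr::bind_rows(out)
}
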