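# Survival statistics: product-limit oracle checks, log-rank asymptotic
# and permutation agreement, Cox behaviour, seeding-curve analytics.

test_that("KM matches the hand product-limit on small fixtures", {
  # events at t=1 (n=4, d=1) and t=3 (n=2, d=1), censor at t=2
  time <- c(1, 2, 3, 4); event <- c(TRUE, FALSE, TRUE, FALSE)
  km <- km_estimate(time, event)
  expect_equal(km$survival[km$time_h == 1], 0.75)
  expect_equal(km$survival[km$time_h == 3], 0.375)
  expect_equal(km$survival[km$time_h == 0], 1)
  # random small fixtures against the definition-level oracle
  set.seed(10)
  for (i in 1:8) {
    n <- sample(5:30, 1)
    d <- sim_surv(n, 0.1, cens_frac = 0.3)
    km <- km_estimate(d$time, d$event)
    orc <- km_oracle(d$time, d$event)
    got <- km$survival[match(orc$time, km$time_h)]
    expect_equal(got, orc$surv, tolerance = 1e-12)
  }
  # all censored: S identically 1
  kmc <- km_estimate(c(1, 2, 3), c(FALSE, FALSE, FALSE))
  expect_true(all(kmc$survival == 1))
  expect_error(km_estimate(c(0, -1), c(TRUE, TRUE)), "non-positive")
})

test_that("KM without censoring equals the empirical survival fraction", {
  set.seed(11)
  t <- rexp(40, 0.2)
  km <- km_estimate(t, rep(TRUE, 40))
  for (q in c(0.5, 2, 5)) {
    s_km <- min(km$survival[km$time_h <= q])
    if (!any(km$time_h[-1] <= q)) s_km <- 1
    expect_equal(s_km, mean(t > q))
  }
})

test_that("log-rank matches the hand O-E computation and handles nulls", {
  # identical groups: statistic 0, p 1
  t0 <- c(1, 2, 3, 4, 1, 2, 3, 4)
  e0 <- rep(TRUE, 8)
  g0 <- rep(c("a", "b"), each = 4)
  lr0 <- log_rank(t0, e0, g0)
  expect_equal(lr0$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)
  # 10-record fixture equals the definition-level oracle
  set.seed(12)
  t1 <- c(2, 3, 5, 7, 8, 1, 4, 6, 9, 12)
  e1 <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
  g1 <- rep(c("a", "b"), each = 5)
  expect_equal(log_rank(t1, e1, g1)$chi_square, logrank_oracle(t1, e1, g1),
               tolerance = 1e-10)
  # the internal vectorised statistic agrees with survdiff on fixtures
  for (i in 1:6) {
    d <- sim_surv(30, 0.1, 0.25)
    g <- sample(rep(c("a", "b"), 15))
    expect_equal(tauseedr:::logrank_chisq_stat(d$time, d$event,
                                               as.numeric(factor(g) == "a")),
                 log_rank(d$time, d$event, g)$chi_square, tolerance = 1e-10)
  }
  expect_error(log_rank(t1, e1, rep("a", 10)), "two groups")
  expect_error(log_rank(t1, rep(FALSE, 10), g1), "no events")
})

test_that("permutation p agrees with the asymptotic p on moderate fixtures", {
  set.seed(13)
  for (i in 1:3) {
    n <- sample(c(20, 30, 40), 1)
    d <- sim_surv(n, 0.15, 0.25)
    g <- sample(rep(c("a", "b"), n / 2))
    lr <- log_rank(d$time, d$event, g, permutations = 4000)
    expect_lt(abs(lr$p - lr$p_permutation), 0.02)
  }
})

test_that("Cox fit recovers null and matches log-rank via the score test", {
  set.seed(14)
  d <- sim_surv(120, 0.1, 0.2)
  d$group <- sample(rep(c("a", "b"), 60))
  cf <- cox_fit(tibble::tibble(time_h = d$time, event = d$event,
                               group = factor(d$group)), "group")
  # null covariate: CI covers log HR 0
  expect_gt(cf$coefficients$hr_upper, 1)
  expect_lt(cf$coefficients$hr_lower, 1)
  expect_false(cf$separation_flag)
  # score test approximately equals the log-rank chi-square
  lr <- log_rank(d$time, d$event, d$group)
  expect_lt(abs(cf$score_chisq - lr$chi_square) / max(lr$chi_square, 1), 0.05)
  expect_equal(cf$ties_method, "efron")
})

test_that("cumulative onset is 1 - KM with onset as the event", {
  # no onsets: flat zero
  flat <- cumulative_onset(c(5, 10, 15), c(FALSE, FALSE, FALSE))
  expect_true(all(flat$incidence == 0))
  # all onset at t = 10: step to 1
  step <- cumulative_onset(rep(10, 6), rep(TRUE, 6))
  expect_equal(max(step$incidence), 1)
  expect_equal(step$incidence[step$time_h == 0], 0)
})

test_that("onset and post-onset record builders apply the clock rules", {
  ev <- tibble::tibble(
    cell_id = c("a", "b", "c"), line = "l", well_id = "w",
    onset_h = c(20, NA, 30), death_h = c(60, 50, NA), censor_h = c(NA, NA, 166))
  onr <- onset_records(ev)
  expect_equal(onr$time_h, c(20, 50, 30))
  expect_equal(onr$event, c(TRUE, FALSE, TRUE))
  por <- post_onset_records(ev)
  expect_equal(nrow(por), 2)
  expect_equal(por$time_h, c(40, 136))
  expect_equal(por$event, c(TRUE, FALSE))
})

test_that("trapezoidal AUC matches hand results", {
  z <- tibble::tibble(time_h = c(0, 5, 10), corrected = c(0, 0, 0))
  expect_equal(auc_trapezoid(z), 0)
  const <- tibble::tibble(time_h = c(0, 10), corrected = c(2, 2))
  expect_equal(auc_trapezoid(const), 20)
  tri <- tibble::tibble(time_h = c(0, 2, 4), corrected = c(0, 4, 8))
  expect_equal(auc_trapezoid(tri), 16)
  bad <- tibble::tibble(time_h = c(4, 2, 0), corrected = c(0, 4, 8))
  expect_error(auc_trapezoid(bad), "increasing")
  expect_error(auc_trapezoid(tibble::tibble(time_h = 1, corrected = 2)),
               "2 time points")
})

test_that("two-way ANOVA equals the hand sums-of-squares decomposition", {
  set.seed(15)
  df <- tibble::tibble(
    line = rep(rep(c("control", "mutant"), each = 3), 4),
    dose_ug = rep(c(1, 5, 10), 8),
    auc = rnorm(24, mean = rep(c(1, 5, 10), 8)))
  tab <- anova_line_by_dose(df)
  # balanced design: classic SS decomposition by hand
  y <- df$auc
  gm <- mean(y)
  ml <- tapply(y, df$line, mean)
  md <- tapply(y, factor(df$dose_ug), mean)
  mc <- tapply(y, interaction(df$line, df$dose_ug), mean)
  ss_line <- 12 * sum((ml - gm)^2)
  ss_dose <- 8 * sum((md - gm)^2)
  ss_cell <- 4 * sum((mc - gm)^2)
  ss_int <- ss_cell - ss_line - ss_dose
  ss_res <- sum((y - mc[interaction(df$line, df$dose_ug)])^2)
  f_dose <- (ss_dose / 2) / (ss_res / 18)
  expect_equal(tab$sum_sq[tab$term == "dose"], ss_dose, tolerance = 1e-8)
  expect_equal(tab$sum_sq[tab$term == "line"], ss_line, tolerance = 1e-8)
  expect_equal(tab$sum_sq[tab$term == "line:dose"], ss_int, tolerance = 1e-8)
  expect_equal(tab$f[tab$term == "dose"], f_dose, tolerance = 1e-8)
  expect_equal(tab$df[tab$term == "dose"], 2)
  expect_equal(tab$df[tab$term == "Residuals"], 18)
  expect_error(anova_line_by_dose(df[df$line == "control", ]), "2 levels")
})

test_that("two-way ANOVA null and power behave over replicates", {
  set.seed(16)
  null_p <- replicate(150, {
    df <- tibble::tibble(line = rep(rep(c("a", "b"), each = 3), 4),
                         dose_ug = rep(c(1, 5, 10), 8), auc = rnorm(24))
    anova_line_by_dose(df)$p[1:3]
  })
  rej <- rowMeans(null_p < 0.05)
  expect_true(all(rej > 0.005 & rej < 0.12))
  # dose effect only: dose term powered, line term near alpha
  pw <- replicate(60, {
    df <- tibble::tibble(line = rep(rep(c("a", "b"), each = 3), 4),
                         dose_ug = rep(c(1, 5, 10), 8),
                         auc = rnorm(24) + rep(c(0, 1.5, 3), 8))
    anova_line_by_dose(df)$p[1:2]
  })
  expect_gt(mean(pw[2, ] < 0.01), 0.9)   # dose
  expect_lt(mean(pw[1, ] < 0.05), 0.2)   # line
})

test_that("seeding slopes are exact on linear series and compare lines", {
  tt <- seq(0, 166, by = 2)
  mk <- function(slope, rep_id, line, noise = 0)
    tibble::tibble(time_h = tt, corrected = slope * tt + noise * rnorm(length(tt)),
                   line = line, replicate = rep_id)
  flat <- mk(0, "r1", "a")
  exact <- seeding_slope(dplyr::bind_rows(flat, mk(3, "r3", "b")))
  expect_equal(exact$slopes$slope[exact$slopes$replicate == "r1"], 0,
               tolerance = 1e-10)
  expect_equal(exact$slopes$slope[exact$slopes$replicate == "r3"], 3,
               tolerance = 1e-10)
  set.seed(20)
  s0 <- seeding_slope(dplyr::bind_rows(
    mk(0, "r1", "a", 1), mk(0, "r2", "a", 1), mk(0, "r5", "a", 1),
    mk(3, "r3", "b", 1), mk(3, "r4", "b", 1), mk(3, "r6", "b", 1)))
  expect_lt(s0$test$p, 1e-4)
  expect_error(seeding_slope(flat, window_h = c(500, 600)), "window")
})

test_that("expression correlations report r, r2 and adjusted R2", {
  ev <- tibble::tibble(
    line = rep("control", 10), cell_id = letters[1:10], well_id = "w",
    t0_intensity_norm = c(0.5, 0.7, 0.8, 0.9, 1.0, 1.1, 1.2, 1.3, 1.5, 1.0),
    onset_h = c(30, 42, 35, 50, 44, 60, 52, 66, 70, 48),
    death_h = NA_real_, censor_h = 166)
  out <- onset_expression_correlation(ev, "onset")
  r_hand <- sum((ev$t0_intensity_norm - mean(ev$t0_intensity_norm)) *
                  (ev$onset_h - mean(ev$onset_h))) /
    (9 * sd(ev$t0_intensity_norm) * sd(ev$onset_h))
  expect_equal(out$r, r_hand, tolerance = 1e-10)
  expect_equal(out$r_squared, r_hand^2, tolerance = 1e-10)
  # perfect affine relation: r = 1
  ev2 <- ev; ev2$onset_h <- 10 + 5 * ev2$t0_intensity_norm
  expect_equal(onset_expression_correlation(ev2, "onset")$r, 1)
  # lifespan variant restricted to died cells
  ev3 <- ev; ev3$death_h <- ev3$onset_h + 20; ev3$censor_h <- NA
  out3 <- onset_expression_correlation(ev3, "lifespan")
  expect_equal(out3$n, 10)
  ev4 <- ev; ev4$t0_intensity_norm <- 1
  expect_error(onset_expression_correlation(ev4, "onset"), "variance")
})

test_that("aggregate fractions recover configured onset probabilities", {
  # truth-level: exponential onsets with known 48-h fractions
  set.seed(17)
  mk_events <- function(p48, n, line, wells = 4) {
    haz <- -log(1 - p48) / 48
    dplyr::bind_rows(lapply(seq_len(wells), function(w) {
      onset <- rexp(n, haz)
      tibble::tibble(cell_id = paste0(line, w, "_", seq_len(n)),
                     line = line, well_id = paste0(line, "_w", w),
                     onset_h = ifelse(onset <= 166, onset, NA),
                     death_h = NA_real_, censor_h = 166)
    }))
  }
  ev <- dplyr::bind_rows(mk_events(0.34, 400, "mutant"),
                         mk_events(0.17, 400, "control"))
  fr <- aggregate_fraction_at(ev, timepoints_h = c(48, 168))
  m48 <- fr$summary$mean_fraction[fr$summary$timepoint_h == 48]
  names(m48) <- fr$summary$group[fr$summary$timepoint_h == 48]
  expect_lt(abs(m48[["mutant"]] - 0.34), 0.05)
  expect_lt(abs(m48[["control"]] - 0.17), 0.05)
  expect_lt(fr$tests$p[fr$tests$timepoint_h == 48], 0.01)
})
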