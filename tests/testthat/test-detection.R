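# Detection: local background, punctum rules, exclusion, counting,
# baseline subtraction, soma-aggregate calls, neurite-area surrogate.

test_that("local background reproduces flat fields and ignores outliers", {
  cc <- matrix(1234, 64, 64)
  expect_equal(local_background(cc, 5), cc)
  one <- cc; one[30, 30] <- 60000
  bg <- local_background(one, 5)
  expect_equal(bg[30, 30], 1234)
  expect_error(local_background(cc, 40), "larger than the image")
})

test_that("local background follows slow shading to within the noise", {
  set.seed(1)
  n <- 128
  shading <- 3000 + 1500 * sin(outer(seq_len(n), rep(1, n)) * 2 * pi / n)
  fr <- shading + rnorm(n * n, 0, 300)
  bg <- local_background(fr, 6)
  core <- 20:(n - 20)
  expect_lt(max(abs(bg[core, core] - shading[core, core])), 300)
})

test_that("punctum detection applies the intensity and size rules", {
  blank <- matrix(2000, 128, 128) + matrix(rnorm(128^2, 0, 500), 128)
  expect_equal(nrow(detect_neurite_seeds(blank, 0.65)), 0)

  # peak 5000 above background: below the 10000 gray-level rule
  dim5k <- matrix(2000, 128, 128)
  dim5k[60:61, 60:61] <- 2000 + 5000
  expect_equal(nrow(detect_neurite_seeds(dim5k, 0.65)), 0)

  # bright disc of diameter 10 um: rejected as a large bright area
  big <- matrix(2000, 128, 128)
  r_px <- 5 / 0.65
  for (i in 1:128) for (j in 1:128)
    if ((i - 64)^2 + (j - 64)^2 <= r_px^2) big[i, j] <- 40000
  expect_equal(nrow(detect_neurite_seeds(big, 0.65)), 0)

  # an accepted punctum reports calibrated geometry
  one <- matrix(2000, 128, 128)
  one[40:41, 80:81] <- 2000 + 15000
  det <- detect_neurite_seeds(one, 0.65)
  expect_equal(nrow(det), 1)
  expect_equal(det$area_px, 4L)
  expect_equal(det$equivalent_diameter_um, 2 * sqrt(4 / pi) * 0.65)
  expect_equal(det$x, 80.5); expect_equal(det$y, 40.5)
  expect_gt(det$peak_minus_background_gray, 10000)
  expect_error(detect_neurite_seeds(one, NULL), "calibration")
})

test_that("detection matches the brute-force oracle and finds all rendered puncta", {
  soma_centers <- cbind(c(40, 130, 215), c(200, 45, 150))
  mk <- make_punctum_frame(25, soma_centers = soma_centers, seed = 42)
  bg <- local_background(mk$frame, 15)
  excl <- build_exclusion_mask(mk$frame, bg, 0.65)
  det <- detect_neurite_seeds(mk$frame, 0.65, exclusion_mask = excl,
                              background = bg)
  expect_equal(nrow(det), 25)
  pr <- evaluate_seed_detection(det, mk$puncta, tol_px = 3)
  expect_equal(pr$precision, 1)
  expect_equal(pr$recall, 1)
  # exact agreement with the naive per-pixel threshold + flood-fill oracle
  oracle <- bruteforce_seeds(mk$frame, bg, 0.65, exclusion_mask = excl)
  expect_equal(nrow(det), nrow(oracle))
  o <- order(det$x, det$y); oo <- order(oracle$x, oracle$y)
  expect_equal(det$x[o], oracle$x[oo])
  expect_equal(det$y[o], oracle$y[oo])
  expect_equal(as.integer(det$area_px[o]), oracle$area[oo])
})

test_that("counts are invariant to constant offsets and monotone in threshold", {
  mk <- make_punctum_frame(15, seed = 7)
  bg <- local_background(mk$frame, 15)
  n0 <- nrow(detect_neurite_seeds(mk$frame, 0.65, background = bg))
  shifted <- mk$frame + 3000
  n1 <- nrow(detect_neurite_seeds(shifted, 0.65))
  expect_equal(n0, n1)
  counts <- vapply(c(6000, 10000, 13000, 16000), function(th)
    nrow(detect_neurite_seeds(mk$frame, 0.65, intensity_threshold_gray = th,
                              background = bg)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("baseline subtraction is elementwise with the overall no-lysate mean", {
  s <- tibble::tibble(well_id = "a", time_h = c(0, 2, 4), raw = c(5L, 7L, 9L),
                      baseline = 0, corrected = c(5, 7, 9))
  nl <- tibble::tibble(well_id = "nl", time_h = c(0, 2, 4), raw = c(2L, 2L, 2L),
                       baseline = 0, corrected = c(2, 2, 2))
  out <- subtract_baseline(s, nl)
  expect_equal(out$corrected, c(3, 5, 7))
  expect_equal(out$baseline, rep(2, 3))
  # a series corrected against itself has mean zero
  self <- subtract_baseline(nl, nl)
  expect_equal(mean(self$corrected), 0)
  bad <- nl; bad$time_h <- c(0, 3, 6)
  expect_error(subtract_baseline(s, bad), "time grids")
  # technical replicates sum elementwise
  expect_equal(sum_series(s, s)$raw, c(10L, 14L, 18L))
})

test_that("count series tracks the rendered punctum number within Poisson error", {
  cfg <- sim_config(n_wells = 1, n_cells_per_well = 15, frames = 30,
                    image_size_px = 192, neurite_seed_rate_per_h = 0.08,
                    onset_base_hazard_per_h = 0, death_base_hazard_per_h = 0,
                    exit_hazard_per_h = 0, rng_seed = 13)
  sim <- simulate_well(cfg, 1)
  cs <- count_series(sim$stack)
  expect_s3_class(cs, "seed_count_series")
  for (k in c(10, 20, 30)) {
    truth_k <- nrow(seed_positions_at(sim$seeds, k))
    expect_lt(abs(cs$raw[k] - truth_k), 2 * sqrt(truth_k) + 2)
  }
  # counts accumulate: late counts exceed early counts
  expect_gt(mean(cs$raw[25:30]), mean(cs$raw[1:5]))
})

test_that("soma-aggregate detection flags the rendered window only", {
  # diffuse soma only: never positive
  P <- 71
  ax <- seq(-35, 35)
  soma <- 6000 * (sqrt(outer(ax^2, ax^2, "+")) <= 9)
  patch0 <- array(2000 + soma, dim = c(P, P, 5))
  d0 <- detect_soma_aggregate(patch0)
  expect_false(any(d0$aggregate_positive))

  # 3 um blob present in frames 20-30 of 40
  stack <- array(0, dim = c(P, P, 40))
  blob <- matrix(0, P, P)
  for (dx in -4:4) for (dy in -4:4)
    blob[36 + dy, 36 + dx + 4] <- 15000 * exp(-(dx^2 + dy^2) / (2 * 1.5^2))
  set.seed(2)
  for (k in 1:40)
    stack[, , k] <- 2000 + soma + (if (k >= 20 && k <= 30) blob else 0) +
      matrix(rnorm(P * P, 0, 500), P, P)
  dd <- detect_soma_aggregate(stack)
  expect_true(all(dd$aggregate_positive[20:30]))
  expect_false(any(dd$aggregate_positive[c(1:19, 31:40)]))
  expect_error(detect_soma_aggregate(array(0, c(1, 1, 1))), "patch")
})

test_that("neurite area surrogate recovers the rendered mask area", {
  base <- function(n, seed) sim_config(
    n_wells = 1, n_cells_per_well = n, frames = 2, image_size_px = 192,
    onset_base_hazard_per_h = 0, death_base_hazard_per_h = 0,
    exit_hazard_per_h = 0, neurite_seed_rate_per_h = 0,
    n_background_nuclei = 0, rng_seed = seed)
  for (sd in c(17, 23)) {
    cfg <- base(8, sd)
    fr <- simulate_well(cfg, 1)$stack$pixels[, , 1, 1]
    m <- neurite_area(fr, cfg$pixel_size_um)
    expect_gt(m$soma_area_um2, 0)
    # truth: the noiseless footprint above half the rendered neurite
    # contrast (neurite_intensity_frac * soma level ~ 1800 -> ~1000
    # after the soft-edge blur), outside soma cores
    cfg0 <- cfg; cfg0$noise_sigma_gray <- 0
    fr0 <- simulate_well(cfg0, 1)$stack$pixels[, , 1, 1]
    truth_area <- (sum((fr0 - 2000) > 1000) - sum((fr0 - 2000) > 2500)) *
      cfg$pixel_size_um^2
    expect_lt(abs(m$neurite_area_um2 - truth_area) / truth_area, 0.2)
  }
  # blank frame: essentially zero neurite area
  set.seed(99)
  blank <- matrix(2000, 192, 192) + matrix(rnorm(192^2, 0, 500), 192)
  expect_lt(neurite_area(blank, 0.65)$neurite_area_um2, 10)
  # additivity: the same cell rendered once vs twice (disjoint copies)
  cfg1 <- base(1, 31); cfg1$noise_sigma_gray <- 0
  cell <- simulate_well(cfg1, 1)$stack$pixels[, , 1, 1] - 2000
  patch <- cell[30:130, 30:130]
  one <- matrix(2000, 224, 224); two <- matrix(2000, 224, 224)
  one[20:120, 20:120] <- one[20:120, 20:120] + patch
  two[20:120, 20:120] <- two[20:120, 20:120] + patch
  two[110:210, 110:210] <- two[110:210, 110:210] + patch
  set.seed(7)
  one <- one + matrix(rnorm(224^2, 0, 500), 224)
  two <- two + matrix(rnorm(224^2, 0, 500), 224)
  a1 <- neurite_area(one, 0.65)$neurite_area_um2
  a2 <- neurite_area(two, 0.65)$neurite_area_um2
  expect_gt(a2 / a1, 1.6)
  expect_lt(a2 / a1, 2.4)
})
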