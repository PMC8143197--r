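# Generator: configuration validation, hazard semantics, determinism,
# closed-form checks of the event-time distributions.

test_that("config validation enforces the documented invariants", {
  expect_error(sim_config(image_size_px = 0), "image_size_px")
  expect_error(sim_config(frames = 1), "frames")
  expect_error(sim_config(morphology_mix = c(Ordered = 0.7, Disordered = 0.4)),
               "sum to 1")
  expect_error(sim_config(death_base_hazard_per_h = -1), "hazards")
  expect_error(sim_config(t0_offset_h = 5), "imaging interval")
  expect_error(sim_config(morphology_mix = c(Ordered = 0.5, Toxic = 0.5)),
               "Toxic")
})

test_that("control lysate and dose zero never seed", {
  expect_equal(effective_onset_hazard(sim_config(lysate = "control", dose_ug = 10)), 0)
  expect_equal(effective_onset_hazard(sim_config(lysate = "none", dose_ug = 0)), 0)
  expect_equal(effective_onset_hazard(sim_config(dose_ug = 0)), 0)
  cfg <- sim_config(dose_ug = 5, line_label = "mutant",
                    onset_base_hazard_per_h = 0.004,
                    onset_hazard_line_multiplier = 2.5,
                    onset_hazard_dose_exponent = 1)
  expect_equal(effective_onset_hazard(cfg), 0.004 * 2.5 * 0.5)
})

test_that("zero onset hazard gives no onsets and no aggregate puncta", {
  cfg <- sim_config(lysate = "none", dose_ug = 0, n_wells = 1,
                    n_cells_per_well = 12, frames = 10, image_size_px = 160,
                    rng_seed = 2)
  sim <- simulate_well(cfg, 1)
  expect_true(all(is.na(sim$cells$true_onset_h)))
  expect_equal(nrow(sim$seeds), 0)
  # no puncta detected anywhere outside the soma exclusion mask
  for (k in c(1, 10)) {
    fr <- sim$stack$pixels[, , 1, k]
    bg <- local_background(fr, 15)
    excl <- build_exclusion_mask(fr, bg, cfg$pixel_size_um)
    det <- detect_neurite_seeds(fr, cfg$pixel_size_um, exclusion_mask = excl,
                                background = bg)
    expect_equal(nrow(det), 0)
  }
})

test_that("zero death and exit hazards keep every cell alive and in frame", {
  cfg <- sim_config(death_base_hazard_per_h = 0, exit_hazard_per_h = 0,
                    n_wells = 1, n_cells_per_well = 15, frames = 8,
                    image_size_px = 160, rng_seed = 3)
  sim <- simulate_well(cfg, 1, render = FALSE)
  expect_true(all(is.na(sim$cells$true_death_h)))
  expect_true(all(is.na(sim$cells$true_exit_h)))
})

test_that("identical config and seed reproduce bit-identical output", {
  cfg <- sim_config(n_wells = 1, n_cells_per_well = 10, frames = 6,
                    image_size_px = 128, rng_seed = 11)
  a <- simulate_well(cfg, 1)
  b <- simulate_well(cfg, 1)
  expect_identical(a$stack$pixels, b$stack$pixels)
  expect_identical(a$cells, b$cells)
  expect_identical(a$seeds, b$seeds)
  # different wells use different streams
  c2 <- simulate_well(cfg, 2)
  expect_false(identical(a$cells$x0, c2$cells$x0))
})

test_that("empirical onset fraction matches the exponential CDF", {
  # hazard chosen so P(onset <= 48 h) = 0.3
  haz <- -log(1 - 0.3) / 48
  cfg <- sim_config(n_wells = 1, n_cells_per_well = 2000,
                    onset_base_hazard_per_h = haz, death_base_hazard_per_h = 0,
                    exit_hazard_per_h = 0, frames = 84, rng_seed = 4)
  sim <- simulate_well(cfg, 1, render = FALSE)
  frac <- mean(sim$cells$latent_onset_h <= 48)
  expect_lt(abs(frac - 0.3), 0.03)
})

test_that("latent event times pass KS tests against configured exponentials", {
  cfg <- sim_config(n_wells = 1, n_cells_per_well = 1500,
                    onset_base_hazard_per_h = 0.01,
                    death_base_hazard_per_h = 0.004,
                    death_post_onset_multiplier = 1,  # pure exponential death
                    exit_hazard_per_h = 0.002, frames = 84, rng_seed = 5)
  sim <- simulate_well(cfg, 1, render = FALSE)
  expect_gt(ks.test(sim$cells$latent_onset_h, pexp, 0.01)$p.value, 0.01)
  expect_gt(ks.test(sim$cells$latent_death_h, pexp, 0.004)$p.value, 0.01)
  expect_gt(ks.test(sim$cells$latent_exit_h, pexp, 0.002)$p.value, 0.01)
})

test_that("death hazard switches at onset (piecewise exponential)", {
  cfg <- sim_config(n_wells = 1, n_cells_per_well = 4000,
                    onset_base_hazard_per_h = 1e9,  # onset immediately
                    death_base_hazard_per_h = 0.002,
                    death_post_onset_multiplier = 4,
                    exit_hazard_per_h = 0, frames = 84, rng_seed = 6)
  sim <- simulate_well(cfg, 1, render = FALSE)
  post <- sim$cells$latent_death_h - sim$cells$latent_onset_h
  expect_gt(ks.test(post, pexp, 0.008)$p.value, 0.01)
})

test_that("truth_event_table applies the censoring rules", {
  cfg <- sim_config(n_wells = 1, n_cells_per_well = 5, frames = 84, rng_seed = 7)
  sim <- simulate_experiment(cfg, render = FALSE)
  tr <- sim$truth
  # death before exit -> death event at the death time
  tr$cells$true_death_h[1] <- 30; tr$cells$true_exit_h[1] <- NA
  # exit before death -> censored at exit
  tr$cells$true_death_h[2] <- NA; tr$cells$true_exit_h[2] <- 20
  tr$cells$true_death_h[3] <- NA; tr$cells$true_exit_h[3] <- NA
  tab <- truth_event_table(tr)
  expect_equal(tab$time_h[1], 30); expect_true(tab$event[1])
  expect_equal(tab$time_h[2], 20); expect_false(tab$event[2])
  expect_equal(tab$time_h[3], tr$horizon_h); expect_false(tab$event[3])
  expect_error(truth_event_table(tr, horizon_h = 1e6), "exceeds")
})

test_that("KM of the truth event table tracks the analytic survival curve", {
  cfg <- sim_config(n_wells = 1, n_cells_per_well = 1000,
                    onset_base_hazard_per_h = 0, death_base_hazard_per_h = 0.004,
                    exit_hazard_per_h = 0.001, frames = 84, rng_seed = 8)
  sim <- simulate_experiment(cfg, render = FALSE)
  tab <- truth_event_table(sim$truth)
  km <- km_estimate(tab$time_h, tab$event)
  dev <- abs(km$survival - exp(-0.004 * km$time_h))
  expect_lt(max(dev), 0.05)
})

test_that("config and stack round-trip through YAML / TIFF with sidecar", {
  cfg <- sim_config(n_wells = 1, n_cells_per_well = 6, frames = 4,
                    image_size_px = 96, rng_seed = 9)
  yml <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, yml)
  cfg2 <- read_sim_config(yml)
  expect_equal(unclass(cfg), unclass(cfg2), tolerance = 1e-12)
  sim <- simulate_well(cfg, 1)
  tf <- tempfile(fileext = ".tif")
  write_stack(sim$stack, tf)
  back <- read_stack(tf)
  expect_identical(back$pixels, sim$stack$pixels)
  expect_equal(back$pixel_size_um, cfg$pixel_size_um)
  file.remove(tf, paste0(tf, ".json"))
  expect_error(read_stack(tf), "sidecar|cannot")
})

test_that("rendered nuclei fragment into multiple components at death", {
  cfg <- sim_config(n_wells = 1, n_cells_per_well = 4, frames = 6,
                    image_size_px = 128, death_base_hazard_per_h = 0.2,
                    noise_sigma_gray = 0, n_background_nuclei = 0,
                    exit_hazard_per_h = 0, rng_seed = 10)
  sim <- simulate_well(cfg, 1)
  dead <- which(!is.na(sim$cells$true_death_h) & sim$cells$true_death_h < 8)
  skip_if(length(dead) == 0, "no early death drawn")
  i <- dead[1]
  nuc <- sim$stack$pixels[, , 2, 6] - cfg$background_gray
  patch <- nuc[round(sim$cells$y0[i]) + (-8:8), round(sim$cells$x0[i]) + (-8:8)]
  comps <- EBImage::bwlabel(patch > 1000)
  expect_gte(max(comps), 2)
})
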