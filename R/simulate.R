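# Synthetic two-channel time-lapse generator.
#
# Rendering is template-based: each cell gets a static reporter template
# (soma disc + neurite segments, softly blurred) and nuclear templates
# (live disc; fragmented bright cluster after lysis) computed once, then
# stamped additively into each frame at the drifted position. Aggregates
# are stamped per morphology archetype. Gaussian read noise is added last
# and frames are clamped to the 16-bit range.

#' @importFrom stats rexp rlnorm rnorm rpois runif rbinom median setNames
NULL

# soft-edged disc patch (odd side), values in [0, 1]
disc_patch <- function(radius) {
  half <- ceiling(radius + 1)
  ax <- seq(-half, half)
  d <- sqrt(outer(ax^2, ax^2, "+"))
  pmin(pmax(radius + 0.5 - d, 0), 1)
}

# rotated anisotropic Gaussian stamp with given peak amplitude
gauss_stamp <- function(amplitude, sigma_x, sigma_y = sigma_x, angle = 0) {
  half <- ceiling(3 * max(sigma_x, sigma_y))
  ax <- seq(-half, half)
  gx <- outer(rep(1, length(ax)), ax)   # column offsets (x)
  gy <- outer(ax, rep(1, length(ax)))   # row offsets (y)
  u <- gx * cos(angle) + gy * sin(angle)
  v <- -gx * sin(angle) + gy * cos(angle)
  amplitude * exp(-(u^2 / (2 * sigma_x^2) + v^2 / (2 * sigma_y^2)))
}

# linear indices + values of `patch` placed at integer (cx, cy) in an
# H x W canvas, clipped at the borders; NULL if fully outside. Used to
# batch-accumulate stamps per frame without repeated canvas copies.
stamp_idx <- function(patch, cx, cy, H, W) {
  half <- (nrow(patch) - 1L) %/% 2L
  r0 <- max(1L, cy - half); r1 <- min(H, cy + half)
  c0 <- max(1L, cx - half); c1 <- min(W, cx + half)
  if (r0 > r1 || c0 > c1) return(NULL)
  rows <- r0:r1; cols <- c0:c1
  sub <- patch[rows - (cy - half) + 1L, cols - (cx - half) + 1L, drop = FALSE]
  list(idx = as.integer(outer(rows, (cols - 1L) * H, "+")),
       val = as.numeric(sub))
}

# add `patch` (odd side) into `frame` centred at integer (cx = col, cy = row),
# clipping at the borders; returns the modified frame
add_stamp <- function(frame, patch, cx, cy) {
  half <- (nrow(patch) - 1L) %/% 2L
  H <- nrow(frame); W <- ncol(frame)
  r0 <- max(1L, cy - half); r1 <- min(H, cy + half)
  c0 <- max(1L, cx - half); c1 <- min(W, cx + half)
  if (r0 > r1 || c0 > c1) return(frame)
  pr <- (r0:r1) - (cy - half) + 1L
  pc <- (c0:c1) - (cx - half) + 1L
  frame[r0:r1, c0:c1] <- frame[r0:r1, c0:c1] + patch[pr, pc, drop = FALSE]
  frame
}

# sample n points in [lo, hi]^2 with pairwise separation >= min_sep
sample_positions <- function(n, lo, hi, min_sep, max_tries = 20000L) {
  xs <- numeric(0); ys <- numeric(0); tries <- 0L
  while (length(xs) < n && tries < max_tries) {
    tries <- tries + 1L
    x <- runif(1, lo, hi); y <- runif(1, lo, hi)
    if (!length(xs) || all((xs - x)^2 + (ys - y)^2 >= min_sep^2)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  if (length(xs) < n)
    stop("could not place ", n, " cells at separation ", min_sep,
         " in the field; reduce n_cells_per_well or enlarge the image")
  cbind(x = xs, y = ys)
}

# reporter-channel template for one cell: soma disc + neurite segments.
# Returns list(patch, half, neurites = data.frame(angle, length)).
make_cell_template <- function(cfg, soma_intensity) {
  n_neur <- sample(2:4, 1)
  ang <- runif(n_neur, 0, 2 * pi)
  len <- runif(n_neur, 16, 32)
  half <- ceiling(max(len) + 3)
  ax <- seq(-half, half)
  gx <- outer(rep(1, length(ax)), ax)
  gy <- outer(ax, rep(1, length(ax)))
  d0 <- sqrt(gx^2 + gy^2)
  soma <- pmin(pmax(cfg$soma_radius_px + 0.5 - d0, 0), 1)
  neur <- matrix(0, nrow(gx), ncol(gx))
  for (j in seq_len(n_neur)) {
    ux <- cos(ang[j]); uy <- sin(ang[j])
    tproj <- pmin(pmax(gx * ux + gy * uy, 0), len[j])
    dseg <- sqrt((gx - tproj * ux)^2 + (gy - tproj * uy)^2)
    neur <- pmax(neur, pmin(pmax(1.3 - dseg, 0), 1))
  }
  patch <- soma_intensity * (soma + cfg$neurite_intensity_frac * neur * (1 - soma))
  patch <- as.matrix(EBImage::gblur(patch, sigma = 0.8))
  list(patch = patch, half = half, neurites = data.frame(angle = ang, length = len))
}

# live and fragmented (post-lysis) nuclear templates; the fragment
# amplitude is scaled so the mean dye signal over the nuclear disc jumps
# by exactly `death_flash_fold`
make_nuclear_templates <- function(cfg) {
  live <- cfg$nuclear_intensity_gray * disc_patch(cfg$nucleus_radius_px)
  phi <- runif(1, 0, 2 * pi)
  frag_unit <- matrix(0, 17, 17)
  for (a in phi + c(0, 2 * pi / 3, 4 * pi / 3)) {
    fp <- disc_patch(2.2)
    frag_unit <- add_stamp(frag_unit, fp, 9L + as.integer(round(3.5 * cos(a))),
                           9L + as.integer(round(3.5 * sin(a))))
  }
  # mean over the central nuclear disc, live vs unit-amplitude fragments
  nr <- ceiling(cfg$nucleus_radius_px)
  in_disc <- function(m) {
    half <- (nrow(m) - 1L) %/% 2L
    ax <- seq(-half, half)
    mask <- sqrt(outer(ax^2, ax^2, "+")) <= nr
    mean(m[mask])
  }
  amp <- cfg$death_flash_fold * in_disc(live) / max(in_disc(frag_unit), 1e-9)
  list(live = live, dead = amp * frag_unit)
}

# archetype-specific aggregate stamp state for one cell
make_aggregate_state <- function(cfg, morph) {
  A0 <- cfg$punctum_amplitude_gray
  rho <- runif(1, 0, 2 * pi)
  if (morph == "Ordered") {
    return(list(kind = "Ordered", offset = 6.5 * c(cos(rho), sin(rho)),
                sigma0 = 2.5, amp0 = A0))
  }
  if (morph == "Other") {
    st <- gauss_stamp(1.3 * A0, 3.2, 1.0, runif(1, 0, pi))
    return(list(kind = "Other", offset = 6.5 * c(cos(rho), sin(rho)), stamp = st))
  }
  # soma aggregates are rendered brighter than neurite seeds (they are
  # condensations of the soma's own reporter pool on top of its diffuse
  # signal)
  if (morph == "Disordered") { n_p <- 8; r_lo <- 5; r_hi <- 8; sep <- 3.5; sg <- 0.9 }
  else                       { n_p <- 5; r_lo <- 0; r_hi <- 4.0; sep <- 2.5; sg <- 0.9 }
  pts <- matrix(NA_real_, 0, 2)
  tries <- 0L
  while (nrow(pts) < n_p && tries < 500L) {
    tries <- tries + 1L
    a <- runif(1, 0, 2 * pi); r <- sqrt(runif(1, (r_lo / r_hi)^2, 1)) * r_hi
    p <- c(r * cos(a), r * sin(a))
    if (!nrow(pts) || all(sqrt(colSums((t(pts) - p)^2)) >= sep))
      pts <- rbind(pts, p)
  }
  half <- ceiling(r_hi + 3 * sg) + 1L
  stamp <- matrix(0, 2L * half + 1L, 2L * half + 1L)
  g <- gauss_stamp(1.8 * A0, sg)
  for (i in seq_len(nrow(pts)))
    stamp <- add_stamp(stamp, g, half + 1L + as.integer(round(pts[i, 1])),
                       half + 1L + as.integer(round(pts[i, 2])))
  list(kind = morph, offset = c(0, 0), stamp = stamp)
}

aggregate_stamp_at <- function(state, frames_since_onset) {
  if (state$kind == "Ordered") {
    s <- max(1.2, state$sigma0 * 0.98^frames_since_onset)
    a <- state$amp0 * min(2, 1.015^frames_since_onset)
    gauss_stamp(a, s)
  } else state$stamp
}

# Poisson-process neurite seed puncta for one well; positions lie along
# neurites, >= 14 px from every soma centre, on the integer grid.
# Seeds sit inside neurites, so at render time they move with the
# common field drift.
sample_neurite_seeds <- function(cfg, cells, templates, horizon_h) {
  rate <- effective_seed_rate(cfg) * nrow(cells)
  n <- rpois(1, rate * horizon_h)
  if (n == 0)
    return(tibble::tibble(x = integer(), y = integer(), appear_h = numeric(),
                          sigma_px = numeric(), amplitude_gray = numeric()))
  times <- sort(runif(n, 0, horizon_h))
  xs <- ys <- integer(0); ts <- sg <- numeric(0)
  for (t in times) {
    for (try in 1:20) {
      ci <- sample(nrow(cells), 1)
      nb <- templates[[ci]]$neurites
      j <- sample(nrow(nb), 1)
      if (nb$length[j] < 17) next
      u <- runif(1, 16, nb$length[j])
      jit <- runif(1, -0.7, 0.7)
      px <- as.integer(round(cells$x0[ci] + u * cos(nb$angle[j]) - jit * sin(nb$angle[j])))
      py <- as.integer(round(cells$y0[ci] + u * sin(nb$angle[j]) + jit * cos(nb$angle[j])))
      if (px < 16 || py < 16 || px > cfg$image_size_px - 15 ||
            py > cfg$image_size_px - 15) next
      if (any((cells$x0 - px)^2 + (cells$y0 - py)^2 < 16^2)) next
      # puncta stay distinct: at 8 px separation their diffuse skirts
      # never merge into an excludable "large bright area"
      if (length(xs) && any((xs - px)^2 + (ys - py)^2 < 64)) next
      xs <- c(xs, px); ys <- c(ys, py); ts <- c(ts, t)
      sg <- c(sg, runif(1, 0.8, 1.5))
      break
    }
  }
  tibble::tibble(x = xs, y = ys, appear_h = ts, sigma_px = sg,
                 amplitude_gray = cfg$punctum_amplitude_gray)
}

#' Simulate one well of a seeded-aggregation live-imaging experiment
#'
#' @param cfg a [sim_config()].
#' @param well_index well number within the condition (drives the
#'   per-well RNG stream derived from `cfg$rng_seed`).
#' @param render if `FALSE`, skip pixel rendering and return only the
#'   ground-truth tables (much faster; used for statistics-level
#'   replicate studies).
#' @return a list with `stack` (a `timelapse_stack`, or `NULL` when
#'   `render = FALSE`), `cells` (per-cell ground truth) and `seeds`
#'   (rendered neurite seed puncta).
#' @export
simulate_well <- function(cfg, well_index = 1L, render = TRUE) {
  validate_sim_config(cfg)
  well_seed <- as.integer((as.double(cfg$rng_seed) + 104729 * well_index) %% 2147483647)
  set.seed(well_seed)
  H <- cfg$image_size_px
  n <- cfg$n_cells_per_well
  iv <- cfg$frame_interval_h
  horizon <- cfg$t0_offset_h + (cfg$frames - 1L) * iv
  well_id <- sprintf("%s_d%g_w%02d", cfg$line_label, cfg$dose_ug, well_index)

  # without rendering, cells never share pixels, so statistics-level
  # simulations may use any n; positions are then drawn unconstrained
  pos <- if (render) sample_positions(n, 24, H - 24, min_sep = 22,
                                      max_tries = 50000L)
         else cbind(x = runif(n, 24, H - 24), y = runif(n, 24, H - 24))
  # drift = common stage drift per well plus small per-cell motility
  # jitter, so neighbouring somata never collide during the experiment
  well_theta <- runif(1, 0, 2 * pi)
  jit_theta <- runif(n, 0, 2 * pi)
  jit_speed <- runif(n, 0, 0.02)
  vx_all <- cfg$drift_speed_px_per_frame * cos(well_theta) + jit_speed * cos(jit_theta)
  vy_all <- cfg$drift_speed_px_per_frame * sin(well_theta) + jit_speed * sin(jit_theta)
  soma_int <- rlnorm(n, log(cfg$soma_intensity_gray) - 0.25^2 / 2, 0.25)

  h_on <- effective_onset_hazard(cfg)
  lat_on <- if (h_on > 0) rexp(n, h_on) else rep(Inf, n)
  e1 <- rexp(n, max(cfg$death_base_hazard_per_h, 1e-12))
  if (cfg$death_base_hazard_per_h == 0) e1 <- rep(Inf, n)
  morph <- sample(names(cfg$morphology_mix), n, TRUE, prob = cfg$morphology_mix)
  mdm <- cfg$morphology_death_multiplier[morph]
  mdm[is.na(mdm)] <- 1
  post_h <- cfg$death_base_hazard_per_h * cfg$death_post_onset_multiplier * mdm
  lat_death <- ifelse(e1 < lat_on, e1,
                      lat_on + ifelse(post_h > 0, rexp(n, pmax(post_h, 1e-12)), Inf))
  lat_exit <- if (cfg$exit_hazard_per_h > 0) rexp(n, cfg$exit_hazard_per_h) else rep(Inf, n)
  transient <- rbinom(n, 1, cfg$transient_prob) == 1
  dwell <- rexp(n, 1 / cfg$transient_dwell_mean_h)

  # recorded (observable) event times
  exit_eff <- ifelse(lat_exit < lat_death, lat_exit, Inf)
  onset_rec <- ifelse(lat_on < pmin(lat_death, exit_eff, horizon), lat_on, NA_real_)
  death_rec <- ifelse(lat_death <= horizon & lat_death < exit_eff, lat_death, NA_real_)
  exit_rec <- ifelse(lat_exit <= horizon & lat_exit < lat_death, lat_exit, NA_real_)
  agg_end <- ifelse(transient, lat_on + dwell, Inf)
  transient_rec <- !is.na(onset_rec) & transient &
    (lat_on + dwell) < pmin(lat_death, exit_eff, horizon)

  cells <- tibble::tibble(
    cell_id = sprintf("%s_c%03d", well_id, seq_len(n)),
    well_id = well_id, line = cfg$line_label, dose_ug = cfg$dose_ug,
    x0 = pos[, "x"], y0 = pos[, "y"],
    vx = vx_all, vy = vy_all,
    t0_soma_intensity = soma_int,
    morphology_label = ifelse(is.na(onset_rec), NA_character_, morph),
    transient = transient_rec,
    agg_dissolve_h = ifelse(transient_rec, lat_on + dwell, NA_real_),
    true_onset_h = onset_rec, true_death_h = death_rec, true_exit_h = exit_rec,
    latent_onset_h = lat_on, latent_death_h = lat_death, latent_exit_h = lat_exit
  )

  if (!render) {
    seeds <- tibble::tibble(x = integer(), y = integer(), appear_h = numeric(),
                            sigma_px = numeric(), amplitude_gray = numeric(),
                            drift_vx = numeric(), drift_vy = numeric())
    return(list(stack = NULL, cells = cells, seeds = seeds))
  }
  templates <- lapply(seq_len(n), function(i) make_cell_template(cfg, soma_int[i]))
  seeds <- sample_neurite_seeds(cfg, cells, templates, horizon)
  seeds$drift_vx <- rep(cfg$drift_speed_px_per_frame * cos(well_theta), nrow(seeds))
  seeds$drift_vy <- rep(cfg$drift_speed_px_per_frame * sin(well_theta), nrow(seeds))

  nuc_tpl <- lapply(seq_len(n), function(i) make_nuclear_templates(cfg))
  agg_state <- lapply(seq_len(n), function(i)
    if (is.finite(lat_on[i])) make_aggregate_state(cfg, morph[i]) else NULL)
  seed_stamps <- lapply(seq_len(nrow(seeds)), function(i)
    gauss_stamp(seeds$amplitude_gray[i], seeds$sigma_px[i]))
  bg_nuc <- if (cfg$n_background_nuclei > 0)
    sample_positions(cfg$n_background_nuclei, 15, H - 15, min_sep = 10) else NULL
  bg_nuc_tpl <- lapply(seq_len(cfg$n_background_nuclei),
                       function(i) make_nuclear_templates(cfg)$dead)

  # death rendering: the soma stays visible through the lysis-flash
  # frame (first frame at/after the latent death time), then disperses
  # to a faint residue; the nuclear channel shows the bright fragmented
  # nucleus from the flash frame on
  death_frame_t <- ifelse(is.finite(lat_death),
                          discretize_to_frame(lat_death, iv, cfg$t0_offset_h), Inf)
  frames_out <- vector("list", cfg$frames)
  bg_parts <- lapply(seq_len(cfg$n_background_nuclei), function(b)
    stamp_idx(bg_nuc_tpl[[b]], as.integer(round(bg_nuc[b, "x"])),
              as.integer(round(bg_nuc[b, "y"])), H, H))
  for (k in seq_len(cfg$frames)) {
    t <- cfg$t0_offset_h + (k - 1L) * iv
    partsR <- list(); partsN <- bg_parts
    for (i in seq_len(n)) {
      if (t >= exit_eff[i]) next
      cx <- as.integer(round(cells$x0[i] + cells$vx[i] * (k - 1L)))
      cy <- as.integer(round(cells$y0[i] + cells$vy[i] * (k - 1L)))
      dead <- t >= lat_death[i]
      dispersed <- t > death_frame_t[i] + 1e-9
      body <- if (!dispersed) templates[[i]]$patch else 0.25 * templates[[i]]$patch
      partsR[[length(partsR) + 1L]] <- stamp_idx(body, cx, cy, H, H)
      if (!dead && is.finite(lat_on[i]) && t >= lat_on[i] && t < agg_end[i]) {
        st <- agg_state[[i]]
        fr <- floor((t - lat_on[i]) / iv)
        partsR[[length(partsR) + 1L]] <- stamp_idx(
          aggregate_stamp_at(st, fr),
          cx + as.integer(round(st$offset[1])),
          cy + as.integer(round(st$offset[2])), H, H)
      }
      partsN[[length(partsN) + 1L]] <- stamp_idx(
        if (dead) nuc_tpl[[i]]$dead else nuc_tpl[[i]]$live, cx, cy, H, H)
    }
    if (nrow(seeds)) for (s in which(seeds$appear_h <= t))
      partsR[[length(partsR) + 1L]] <- stamp_idx(
        seed_stamps[[s]],
        seeds$x[s] + as.integer(round(seeds$drift_vx[s] * (k - 1L))),
        seeds$y[s] + as.integer(round(seeds$drift_vy[s] * (k - 1L))), H, H)
    compose <- function(parts) {
      ch <- if (cfg$noise_sigma_gray > 0)
        cfg$background_gray + rnorm(H * H, 0, cfg$noise_sigma_gray)
      else rep(as.numeric(cfg$background_gray), H * H)
      parts <- parts[!vapply(parts, is.null, TRUE)]
      if (length(parts)) {
        ii <- unlist(lapply(parts, `[[`, "idx"), use.names = FALSE)
        vv <- unlist(lapply(parts, `[[`, "val"), use.names = FALSE)
        ag <- rowsum(vv, ii, reorder = FALSE)
        at <- as.integer(rownames(ag))
        ch[at] <- ch[at] + ag[, 1]
      }
      as.integer(pmin(pmax(round(ch), 0), 65535))
    }
    frames_out[[k]] <- c(compose(partsR), compose(partsN))
  }
  px <- array(unlist(frames_out, use.names = FALSE), dim = c(H, H, 2L, cfg$frames))
  stack <- structure(list(
    pixels = px,
    channel_names = c("reporter_yfp", "nuclear_far_red"),
    pixel_size_um = cfg$pixel_size_um, frame_interval_h = iv,
    t0_offset_h = cfg$t0_offset_h, well_id = well_id,
    line = cfg$line_label, dose_ug = cfg$dose_ug, lysate = cfg$lysate
  ), class = "timelapse_stack")
  list(stack = stack, cells = cells, seeds = seeds)
}

#' Frame acquisition times of a stack, hours post seed addition
#' @param stack a `timelapse_stack`.
#' @export
frame_times <- function(stack) {
  stack$t0_offset_h + (seq_len(dim(stack$pixels)[4]) - 1L) * stack$frame_interval_h
}

#' @export
print.timelapse_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<timelapse_stack> %s: %dx%d px, %d channels, %d frames @ %g h, %g um/px\n",
              x$well_id, d[1], d[2], d[3], d[4], x$frame_interval_h, x$pixel_size_um))
  invisible(x)
}

#' Simulate a full experimental condition (all wells)
#'
#' @inheritParams simulate_well
#' @param render render pixel data (see [simulate_well()]).
#' @return list with `stacks` (list of `timelapse_stack`) and `truth`
#'   (a `sim_truth`: `$cells` per-cell event table with latent and
#'   recorded times, `$neurite_seeds` rendered punctum table, plus the
#'   calibration needed to interpret them). Identical config and seed
#'   give bit-identical output.
#' @export
simulate_experiment <- function(cfg, render = TRUE) {
  wells <- lapply(seq_len(cfg$n_wells), function(w) simulate_well(cfg, w, render))
  truth <- structure(list(
    cells = dplyr::bind_rows(lapply(wells, `[[`, "cells")),
    neurite_seeds = dplyr::bind_rows(lapply(wells, function(w)
      dplyr::mutate(w$seeds, well_id = w$cells$well_id[1], .before = 1))),
    horizon_h = cfg$t0_offset_h + (cfg$frames - 1L) * cfg$frame_interval_h,
    frame_interval_h = cfg$frame_interval_h,
    config = cfg
  ), class = "sim_truth")
  list(stacks = if (render) lapply(wells, `[[`, "stack"), truth = truth)
}

#' Convert simulation ground truth to censored survival records
#'
#' Each cell contributes one record on the seed-addition clock: death is
#' the event; leaving the field of view or reaching the horizon censors.
#'
#' @param truth a `sim_truth`.
#' @param horizon_h analysis horizon in hours (defaults to the simulated
#'   duration; must not exceed it).
#' @return tibble with `cell_id`, `well_id`, `line`, `dose_ug`,
#'   `time_h`, `event` (TRUE = death), `onset_h`, `morphology_label`,
#'   `transient`.
#' @export
truth_event_table <- function(truth, horizon_h = truth$horizon_h) {
  stopifnot(inherits(truth, "sim_truth"))
  if (horizon_h > truth$horizon_h)
    stop("horizon_h exceeds the simulated duration")
  ce <- truth$cells
  death <- ifelse(!is.na(ce$true_death_h) & ce$true_death_h <= horizon_h,
                  ce$true_death_h, NA_real_)
  exit <- ifelse(!is.na(ce$true_exit_h) & ce$true_exit_h <= horizon_h,
                 ce$true_exit_h, NA_real_)
  event <- !is.na(death)
  time <- ifelse(event, death, pmin(ifelse(is.na(exit), Inf, exit), horizon_h))
  tibble::tibble(
    cell_id = ce$cell_id, well_id = ce$well_id, line = ce$line,
    dose_ug = ce$dose_ug, time_h = time, event = event,
    onset_h = ifelse(!is.na(ce$true_onset_h) & ce$true_onset_h <= horizon_h,
                     ce$true_onset_h, NA_real_),
    morphology_label = ce$morphology_label, transient = ce$transient
  )
}

#' Expand per-cell drift parameters to a per-frame trajectory table
#' @param truth a `sim_truth`.
#' @return long tibble: `cell_id`, `frame`, `time_h`, `x`, `y` for the
#'   frames in which the cell is rendered.
#' @export
truth_trajectory <- function(truth) {
  cfg <- truth$config
  iv <- truth$frame_interval_h
  ks <- seq_len(cfg$frames) - 1L
  t <- cfg$t0_offset_h + ks * iv
  out <- lapply(seq_len(nrow(truth$cells)), function(i) {
    ce <- truth$cells[i, ]
    exit_eff <- if (!is.na(ce$true_exit_h)) ce$true_exit_h else Inf
    keep <- t < exit_eff
    tibble::tibble(cell_id = ce$cell_id, frame = ks[keep] + 1L, time_h = t[keep],
                   x = ce$x0 + ce$vx * ks[keep], y = ce$y0 + ce$vy * ks[keep])
  })
  dplyr::bind_rows(out)
}

#' Write / read a time-lapse stack as multi-page TIFF with JSON sidecar
#'
#' Pages are interleaved frame-major (frame 1 channel 1, frame 1
#' channel 2, frame 2 channel 1, ...); the sidecar (`<path>.json`)
#' records the interleave, channel names and physical calibration.
#'
#' @param stack a `timelapse_stack`.
#' @param path TIFF file path.
#' @return `write_stack` returns `path` invisibly; `read_stack` a
#'   `timelapse_stack`.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$pixels)
  pages <- vector("list", d[3] * d[4])
  idx <- 1L
  for (k in seq_len(d[4])) for (ch in seq_len(d[3])) {
    pages[[idx]] <- stack$pixels[, , ch, k] / 65535
    idx <- idx + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sidecar <- list(
    well_id = stack$well_id, channel_names = stack$channel_names,
    page_order = "frame_major_channel_interleaved",
    n_frames = d[4], n_channels = d[3],
    pixel_size_um = stack$pixel_size_um,
    frame_interval_h = stack$frame_interval_h,
    t0_offset_h = stack$t0_offset_h,
    line = stack$line, dose_ug = stack$dose_ug, lysate = stack$lysate
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path))
    stop("sidecar calibration file missing: ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  nc <- side$n_channels; nf <- side$n_frames
  px <- array(0L, dim = c(H, W, nc, nf))
  idx <- 1L
  for (k in seq_len(nf)) for (ch in seq_len(nc)) {
    px[, , ch, k] <- as.integer(round(pages[[idx]] * 65535))
    idx <- idx + 1L
  }
  structure(list(pixels = px, channel_names = side$channel_names,
                 pixel_size_um = side$pixel_size_um,
                 frame_interval_h = side$frame_interval_h,
                 t0_offset_h = side$t0_offset_h, well_id = side$well_id,
                 line = side$line, dose_ug = side$dose_ug, lysate = side$lysate),
            class = "timelapse_stack")
}

#' Rendered positions of neurite seed puncta at a given frame
#'
#' Seeds sit inside neurites and move with the common field drift;
#' this returns the integer pixel positions at which seeds visible in
#' frame `k` were rendered.
#'
#' @param seeds seed table from [simulate_well()] / `sim_truth`.
#' @param k frame index (1-based).
#' @param frame_interval_h hours per frame.
#' @param t0_offset_h offset of the first frame.
#' @return tibble with `x`, `y` of seeds already visible at frame `k`.
#' @export
seed_positions_at <- function(seeds, k, frame_interval_h = 2, t0_offset_h = 2) {
  t <- t0_offset_h + (k - 1) * frame_interval_h
  vis <- seeds[seeds$appear_h <= t, ]
  tibble::tibble(x = vis$x + as.integer(round(vis$drift_vx * (k - 1))),
                 y = vis$y + as.integer(round(vis$drift_vy * (k - 1))))
}

#' Write simulation ground truth as CSV
#' @param truth a `sim_truth`.
#' @param cells_path,seeds_path output CSV paths (seeds optional).
#' @export
write_truth <- function(truth, cells_path, seeds_path = NULL) {
  utils::write.csv(truth$cells, cells_path, row.names = FALSE)
  if (!is.null(seeds_path))
    utils::write.csv(truth$neurite_seeds, seeds_path, row.names = FALSE)
  invisible(cells_path)
}
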