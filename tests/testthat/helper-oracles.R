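# Independent oracles and tiny fixture builders shared across tests.

# Kaplan-Meier product-limit straight from the definition (loops, no
# survival package): returns data.frame(time, surv) at event times.
km_oracle <- function(time, event) {
  ut <- sort(unique(time[event]))
  s <- 1
  out <- data.frame(time = numeric(0), surv = numeric(0))
  for (t in ut) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event)
    s <- s * (1 - d / n_risk)
    out <- rbind(out, data.frame(time = t, surv = s))
  }
  out
}

# two-group log-rank chi-square from the O-E table definition (loops)
logrank_oracle <- function(time, event, group) {
  g <- as.integer(factor(group)) == 1L
  ut <- sort(unique(time[event]))
  O <- E <- V <- 0
  for (t in ut) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & g)
    d <- sum(time == t & event); d1 <- sum(time == t & event & g)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# brute-force punctum detector: per-pixel threshold against a given
# background, flood fill with 4-connectivity, then the same size and
# exclusion rules as the detector under test
bruteforce_seeds <- function(frame, background, pixel_size_um,
                             threshold = 10000, band_um = c(0.1, 4),
                             exclusion_mask = NULL) {
  H <- nrow(frame); W <- ncol(frame)
  above <- (frame - background) > threshold
  lab <- matrix(0L, H, W)
  cur <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (!above[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= H && q[2] >= 1 && q[2] <= W &&
              above[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- cur
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  if (cur == 0L) return(data.frame(x = numeric(0), y = numeric(0)))
  area <- tabulate(lab[lab > 0L], nbins = cur)
  eq_diam <- 2 * sqrt(area / pi) * pixel_size_um
  excl <- exclusion_mask
  # dilated footprints of oversized components also exclude
  big <- which(eq_diam > band_um[2])
  if (length(big)) {
    bm <- matrix(lab %in% big, H, W)
    dil <- matrix(FALSE, H, W)
    for (j in seq_len(W)) for (i in seq_len(H)) if (bm[i, j]) {
      for (di in -2:2) for (dj in -2:2) {
        if (sqrt(di^2 + dj^2) > 2.5) next
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) dil[ii, jj] <- TRUE
      }
    }
    excl <- if (is.null(excl)) dil else (excl | dil)
  }
  min_area <- max(1, floor(pi * (band_um[1] / 2 / pixel_size_um)^2))
  keep <- logical(cur)
  for (k in seq_len(cur)) {
    px <- which(lab == k)
    bad <- eq_diam[k] > band_um[2] || area[k] < min_area ||
      (!is.null(excl) && any(excl[px]))
    keep[k] <- !bad
  }
  res <- data.frame(x = numeric(0), y = numeric(0), area = integer(0))
  for (k in which(keep)) {
    px <- which(lab == k)
    rows <- ((px - 1L) %% H) + 1L
    cols <- ((px - 1L) %/% H) + 1L
    res <- rbind(res, data.frame(x = mean(cols), y = mean(rows), area = area[k]))
  }
  res
}

# frame with Gaussian puncta at integer positions plus uniform somata
# discs; returns list(frame, puncta = data.frame(x, y))
make_punctum_frame <- function(n_puncta = 25, size = 256, background = 2000,
                               amplitude = 15000, noise_sigma = 500,
                               sigma_range = c(0.8, 1.6), soma_centers = NULL,
                               soma_intensity = 6000, soma_radius = 9,
                               seed = 1) {
  set.seed(seed)
  fr <- matrix(background, size, size)
  if (!is.null(soma_centers)) {
    for (i in seq_len(nrow(soma_centers))) {
      cx <- soma_centers[i, 1]; cy <- soma_centers[i, 2]
      for (dx in -soma_radius:soma_radius) for (dy in -soma_radius:soma_radius) {
        if (dx^2 + dy^2 > soma_radius^2) next
        fr[cy + dy, cx + dx] <- fr[cy + dy, cx + dx] + soma_intensity
      }
    }
  }
  pts <- data.frame(x = integer(0), y = integer(0))
  while (nrow(pts) < n_puncta) {
    x <- sample(20:(size - 20), 1); y <- sample(20:(size - 20), 1)
    if (nrow(pts) && any((pts$x - x)^2 + (pts$y - y)^2 < 144)) next
    if (!is.null(soma_centers) &&
          any((soma_centers[, 1] - x)^2 + (soma_centers[, 2] - y)^2 < 625)) next
    pts <- rbind(pts, data.frame(x = x, y = y))
  }
  for (i in seq_len(nrow(pts))) {
    sg <- runif(1, sigma_range[1], sigma_range[2])
    half <- ceiling(3 * sg)
    for (dx in -half:half) for (dy in -half:half) {
      fr[pts$y[i] + dy, pts$x[i] + dx] <- fr[pts$y[i] + dy, pts$x[i] + dx] +
        amplitude * exp(-(dx^2 + dy^2) / (2 * sg^2))
    }
  }
  if (noise_sigma > 0) fr <- fr + rnorm(length(fr), 0, noise_sigma)
  list(frame = pmin(pmax(round(fr), 0), 65535), puncta = pts)
}

# tiny survival fixture generator: exponential with uniform censoring
sim_surv <- function(n, rate, cens_frac = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t_ev <- rexp(n, rate)
  t_c <- rexp(n, rate * cens_frac / (1 - cens_frac))
  data.frame(time = pmin(t_ev, t_c), event = t_ev <= t_c)
}
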