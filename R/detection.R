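# Frame-level detection: local-background estimation, neurite seed
# punctum detection with size/intensity rules, soma-aggregate detection
# in tracked patches, baseline subtraction and a neurite-area surrogate.

#' Local background of a frame by median filtering
#'
#' Robust per-pixel background estimate: a running median over a square
#' window of the given radius. Puncta and thin neurites are much smaller
#' than the window, so they do not bias the estimate; subtracting it
#' makes detection invariant to constant offsets and slow shading.
#'
#' @param frame 2D numeric/integer matrix (16-bit gray levels).
#' @param radius_px window radius in pixels (>= 1).
#' @return matrix of the same shape.
#' @export
local_background <- function(frame, radius_px = 15) {
  stopifnot(is.matrix(frame), radius_px >= 1)
  if (2 * radius_px + 1 > min(dim(frame)))
    stop("median radius larger than the image")
  as.matrix(EBImage::medianFilter(frame / 65535, radius_px)) * 65535
}

# connected-component statistics of a logical mask: per-label area,
# centroid, peak of `values`, membership pixels
label_components <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  list(labels = lab, n = n,
       area = if (n > 0) tabulate(lab[lab > 0L], nbins = n) else integer(0))
}

#' Detect neurite seed puncta in a single frame
#'
#' Thresholds the frame against its local background, labels connected
#' components, and applies the size rules: components whose equivalent
#' diameter (`2*sqrt(area/pi)` in microns) exceeds the band maximum are
#' rejected and — dilated by 2 px — also exclude anything they touch
#' (bright soma clusters); components below the band minimum are
#' rejected only when smaller than one pixel, since the 0.1 um lower
#' bound is sub-pixel at typical 10x sampling.
#'
#' @param frame 2D matrix, 16-bit gray levels.
#' @param pixel_size_um microns per pixel (must be given).
#' @param intensity_threshold_gray detection threshold above local
#'   background (default 10000 gray levels).
#' @param diameter_band_um accepted equivalent-diameter band, microns.
#' @param exclusion_mask optional logical matrix; detections overlapping
#'   it (e.g. cell bodies) are rejected.
#' @param background optional precomputed background (else computed with
#'   [local_background()] at `bg_radius_px`).
#' @param bg_radius_px median-filter radius for the background.
#' @return tibble of accepted detections: `x`, `y` (centroid, 1-based,
#'   x = column), `area_px`, `equivalent_diameter_um`,
#'   `peak_minus_background_gray`.
#' @export
detect_neurite_seeds <- function(frame, pixel_size_um,
                                 intensity_threshold_gray = 10000,
                                 diameter_band_um = c(0.1, 4),
                                 exclusion_mask = NULL,
                                 background = NULL,
                                 bg_radius_px = 15) {
  if (missing(pixel_size_um) || is.null(pixel_size_um) || !is.finite(pixel_size_um))
    stop("pixel_size_um calibration is required")
  stopifnot(intensity_threshold_gray > 0)
  if (is.null(background)) background <- local_background(frame, bg_radius_px)
  diff <- frame - background
  mask <- diff > intensity_threshold_gray
  comp <- label_components(mask)
  empty <- tibble::tibble(x = numeric(0), y = numeric(0), area_px = integer(0),
                          equivalent_diameter_um = numeric(0),
                          peak_minus_background_gray = numeric(0))
  if (comp$n == 0) return(empty)
  eq_diam <- 2 * sqrt(comp$area / pi) * pixel_size_um
  min_area <- max(1, floor(pi * (diameter_band_um[1] / 2 / pixel_size_um)^2))
  too_big <- which(eq_diam > diameter_band_um[2])
  excl <- if (!is.null(exclusion_mask)) exclusion_mask else
    matrix(FALSE, nrow(frame), ncol(frame))
  if (length(too_big)) {
    big_mask <- matrix(comp$labels %in% too_big, nrow(frame), ncol(frame))
    big_mask <- as.matrix(EBImage::dilate(
      EBImage::Image(big_mask * 1), EBImage::makeBrush(5, "disc"))) > 0
    excl <- excl | big_mask
  }
  keep <- setdiff(which(eq_diam <= diameter_band_um[2] & comp$area >= min_area),
                  unique(comp$labels[excl & comp$labels > 0L]))
  if (!length(keep)) return(empty)
  idx <- which(comp$labels > 0L & matrix(comp$labels %in% keep, nrow(frame), ncol(frame)))
  lab_v <- comp$labels[idx]
  rows <- ((idx - 1L) %% nrow(frame)) + 1L
  cols <- ((idx - 1L) %/% nrow(frame)) + 1L
  xs <- tapply(cols, lab_v, mean)
  ys <- tapply(rows, lab_v, mean)
  pk <- tapply(diff[idx], lab_v, max)
  ord <- match(sort(keep), as.integer(names(xs)))
  tibble::tibble(x = as.numeric(xs[ord]), y = as.numeric(ys[ord]),
                 area_px = comp$area[sort(keep)],
                 equivalent_diameter_um = eq_diam[sort(keep)],
                 peak_minus_background_gray = as.numeric(pk[ord]))
}

#' Exclusion mask of large bright areas (cell bodies, clusters)
#'
#' Somata are bright relative to background but diffuse, well below the
#' punctum threshold, so they are segmented at a lower soma-level
#' threshold; components larger than `min_diameter_um` equivalent
#' diameter are dilated and returned as an exclusion mask for
#' [detect_neurite_seeds()].
#'
#' @param frame 2D matrix.
#' @param background precomputed local background (or `NULL`).
#' @param pixel_size_um microns per pixel.
#' @param soma_threshold_gray threshold above background for diffuse
#'   bright areas (default 2500).
#' @param min_diameter_um only components larger than this are excluded.
#' @param dilate_px dilation of the excluded footprint.
#' @return logical matrix.
#' @export
build_exclusion_mask <- function(frame, background = NULL, pixel_size_um,
                                 soma_threshold_gray = 2500,
                                 min_diameter_um = 4, dilate_px = 2) {
  if (is.null(background)) background <- local_background(frame, 15)
  diff <- frame - background
  comp <- label_components(diff > soma_threshold_gray)
  if (comp$n == 0) return(matrix(FALSE, nrow(frame), ncol(frame)))
  eq_diam <- 2 * sqrt(comp$area / pi) * pixel_size_um
  big <- which(eq_diam > min_diameter_um)
  if (!length(big)) return(matrix(FALSE, nrow(frame), ncol(frame)))
  m <- matrix(comp$labels %in% big, nrow(frame), ncol(frame))
  as.matrix(EBImage::dilate(EBImage::Image(m * 1),
                            EBImage::makeBrush(2 * dilate_px + 1, "disc"))) > 0
}

#' Per-frame neurite seed counts for one well
#'
#' Runs [detect_neurite_seeds()] on the reporter channel of every frame,
#' excluding large bright areas via [build_exclusion_mask()]. Counts are
#' raw (baseline not yet subtracted; see [subtract_baseline()]).
#'
#' @param stack a `timelapse_stack` (needs >= 2 frames).
#' @param intensity_threshold_gray,diameter_band_um,bg_radius_px passed
#'   to [detect_neurite_seeds()].
#' @param soma_threshold_gray passed to [build_exclusion_mask()].
#' @return a `seed_count_series` tibble: `well_id`, `time_h`, `raw`,
#'   `baseline` (0 until subtraction), `corrected`.
#' @export
count_series <- function(stack, intensity_threshold_gray = 10000,
                         diameter_band_um = c(0.1, 4),
                         soma_threshold_gray = 2500, bg_radius_px = 15) {
  d <- dim(stack$pixels)
  if (d[4] < 2) stop("count_series needs at least 2 frames")
  times <- frame_times(stack)
  raw <- integer(d[4])
  for (k in seq_len(d[4])) {
    fr <- stack$pixels[, , 1L, k]
    bg <- local_background(fr, bg_radius_px)
    excl <- build_exclusion_mask(fr, bg, stack$pixel_size_um,
                                 soma_threshold_gray = soma_threshold_gray)
    det <- detect_neurite_seeds(fr, stack$pixel_size_um,
                                intensity_threshold_gray, diameter_band_um,
                                exclusion_mask = excl, background = bg)
    raw[k] <- nrow(det)
  }
  out <- tibble::tibble(well_id = stack$well_id, time_h = times,
                        raw = raw, baseline = 0, corrected = as.numeric(raw))
  class(out) <- c("seed_count_series", class(out))
  out
}

#' Sum technical-replicate seed-count series elementwise
#' @param ... `seed_count_series` on the same time grid.
#' @param well_id label for the combined series.
#' @export
sum_series <- function(..., well_id = NULL) {
  ss <- list(...)
  stopifnot(length(ss) >= 1)
  for (s in ss[-1])
    if (!isTRUE(all.equal(s$time_h, ss[[1]]$time_h)))
      stop("series time grids differ")
  out <- ss[[1]]
  out$raw <- Reduce(`+`, lapply(ss, `[[`, "raw"))
  out$baseline <- 0
  out$corrected <- as.numeric(out$raw)
  out$well_id <- well_id %||% paste(vapply(ss, function(s) s$well_id[1], ""),
                                    collapse = "+")
  out
}

#' Subtract the no-lysate baseline from a seed-count series
#'
#' The baseline is the overall mean raw count of the no-lysate series
#' across all its time points (quantification noise); it is subtracted
#' from every time point. Negative corrected counts are retained so that
#' downstream AUC statistics stay unbiased.
#'
#' @param series a `seed_count_series`.
#' @param no_lysate_series baseline `seed_count_series` on the same grid.
#' @return the corrected `seed_count_series`.
#' @export
subtract_baseline <- function(series, no_lysate_series) {
  if (!isTRUE(all.equal(series$time_h, no_lysate_series$time_h)))
    stop("series and baseline are on different time grids")
  bl <- mean(no_lysate_series$raw)
  series$baseline <- bl
  series$corrected <- series$raw - bl
  series
}

#' Detect soma aggregates in a tracked-cell patch time series
#'
#' Each frame of the patch (default 70 x 70 px, centred on the tracked
#' soma) is thresholded against its own median (the patch is mostly
#' background, so the median is a robust patch-local background).
#' A frame is aggregate-positive when at least one connected component
#' inside the soma region exceeds the threshold with at least
#' `min_area_px` pixels. Per-frame descriptors feed the morphology
#' classifier.
#'
#' @param patch_stack numeric array `P x P x T` (reporter channel).
#' @param nuclear_masks optional logical array `P x P x T` (or a single
#'   `P x P` matrix) marking the nucleus; used for the nuclear-overlap
#'   descriptor. If `NULL`, a central disc of radius `nucleus_radius_px`
#'   is assumed.
#' @param intensity_threshold_gray threshold above patch background.
#' @param min_area_px minimum component area (default 4, suppressing
#'   single-pixel noise).
#' @param soma_radius_px radius of the central region searched.
#' @param soma_level_gray diffuse soma level: aggregates must lie on the
#'   connected above-this-level component that contains the patch
#'   centre, so bright puncta on neighbouring cells or neurites crossing
#'   the patch are not attributed to this soma.
#' @param nucleus_radius_px fallback nuclear-disc radius.
#' @param background_value optional per-frame background estimate (gray
#'   levels) replacing the per-patch median.
#' @return tibble per frame: `frame`, `aggregate_positive`,
#'   `n_components`, `total_area_px`, `largest_area_px`,
#'   `largest_area_fraction`, `nuclear_overlap_fraction`,
#'   `largest_elongation` (second-moment axis ratio).
#' @export
detect_soma_aggregate <- function(patch_stack, nuclear_masks = NULL,
                                  intensity_threshold_gray = 10000,
                                  min_area_px = 4, soma_radius_px = 12,
                                  soma_level_gray = 2500,
                                  nucleus_radius_px = 4.5,
                                  background_value = NULL) {
  if (is.matrix(patch_stack))
    patch_stack <- array(patch_stack, dim = c(dim(patch_stack), 1L))
  d <- dim(patch_stack)
  if (length(d) != 3 || d[1] < 3 || d[2] < 3) stop("empty or malformed patch stack")
  P1 <- d[1]; P2 <- d[2]; TT <- d[3]
  ctr <- c((P2 + 1) / 2, (P1 + 1) / 2)  # (x, y)
  cols <- matrix(rep(seq_len(P2), each = P1), P1, P2)
  rows <- matrix(rep(seq_len(P1), P2), P1, P2)
  soma_region <- (cols - ctr[1])^2 + (rows - ctr[2])^2 <= soma_radius_px^2
  central <- (cols - ctr[1])^2 + (rows - ctr[2])^2 <= 9
  default_nuc <- (cols - ctr[1])^2 + (rows - ctr[2])^2 <= nucleus_radius_px^2
  brush <- EBImage::makeBrush(5, "disc")
  out <- vector("list", TT)
  for (k in seq_len(TT)) {
    fr <- patch_stack[, , k]
    diff <- fr - (if (is.null(background_value)) median(fr) else background_value[k])
    # the soma's own footprint: the above-soma-level component under the
    # patch centre (absent once the cell has lysed and dispersed)
    slab <- EBImage::bwlabel(diff > soma_level_gray)
    clab <- setdiff(unique(as.integer(slab[central])), 0L)
    soma_pix <- if (length(clab)) matrix(slab %in% clab, P1, P2)
                else matrix(FALSE, P1, P2)
    soma_mask <- if (length(clab)) {
      as.matrix(EBImage::dilate(EBImage::Image(soma_pix * 1), brush)) > 0
    } else soma_pix
    # inside the soma the relevant local background is the soma's own
    # diffuse reporter level, so an aggregate must exceed the component
    # median by the threshold; a uniformly bright soma never triggers
    soma_level <- if (any(soma_pix)) median(fr[soma_pix]) else median(fr)
    mask <- (fr - soma_level) > intensity_threshold_gray & soma_region & soma_mask
    comp <- label_components(mask)
    keep <- which(comp$area >= min_area_px)
    nuc <- if (is.null(nuclear_masks)) default_nuc
           else if (is.matrix(nuclear_masks)) nuclear_masks
           else nuclear_masks[, , k]
    if (!length(keep)) {
      out[[k]] <- tibble::tibble(frame = k, aggregate_positive = FALSE,
                                 n_components = 0L, total_area_px = 0L,
                                 largest_area_px = 0L, largest_area_fraction = NA_real_,
                                 nuclear_overlap_fraction = NA_real_,
                                 largest_elongation = NA_real_)
      next
    }
    areas <- comp$area[keep]
    total <- sum(areas)
    big <- keep[which.max(areas)]
    in_any <- matrix(comp$labels %in% keep, P1, P2)
    overlap <- sum(in_any & nuc) / total
    bidx <- which(comp$labels == big)
    bx <- cols[bidx]; by <- rows[bidx]
    if (length(bidx) > 1) {
      cv <- stats::cov(cbind(bx, by)) + diag(2) / 12
      ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
      elong <- sqrt(max(ev) / max(min(ev), 1e-9))
    } else elong <- 1
    out[[k]] <- tibble::tibble(frame = k, aggregate_positive = TRUE,
                               n_components = length(keep), total_area_px = total,
                               largest_area_px = max(areas),
                               largest_area_fraction = max(areas) / total,
                               nuclear_overlap_fraction = overlap,
                               largest_elongation = elong)
  }
  dplyr::bind_rows(out)
}

#' Neurite- and soma-area surrogate measurement
#'
#' Thresholds the (lightly smoothed) background-subtracted reporter
#' frame: large bright components are somata; the remaining
#' above-background signal is neurite area. A simple surrogate for
#' trainable segmentation, adequate for comparing neurite density
#' between conditions.
#'
#' @param frame 2D matrix (reporter channel).
#' @param pixel_size_um microns per pixel.
#' @param soma_threshold_gray threshold for soma cores.
#' @param neurite_threshold_gray threshold for neurite signal, applied
#'   after Gaussian smoothing (`smooth_sigma`); thin dim processes need
#'   smoothing before a low threshold is usable at realistic noise.
#' @param smooth_sigma Gaussian smoothing sigma, pixels.
#' @param min_soma_area_px minimum soma component size.
#' @param min_neurite_px minimum neurite component size after a 3 x 3
#'   morphological closing; removes isolated noise excursions while
#'   keeping line fragments.
#' @param background optional precomputed background.
#' @param bg_radius_px median-filter radius for the background (wider
#'   than for punctum detection; see note in the source).
#' @return tibble: `neurite_area_um2`, `soma_area_um2`.
#' @export
neurite_area <- function(frame, pixel_size_um, soma_threshold_gray = 2500,
                         neurite_threshold_gray = 400, smooth_sigma = 0.8,
                         min_soma_area_px = 50, min_neurite_px = 15,
                         background = NULL, bg_radius_px = 25) {
  # a wide background window: somata must stay a minor fraction of it,
  # or the median inflates near cells and suppresses the faint neurites
  if (is.null(background)) background <- local_background(frame, bg_radius_px)
  diff <- frame - background
  sm <- as.matrix(EBImage::gblur(diff, sigma = smooth_sigma))
  comp <- label_components(diff > soma_threshold_gray)
  soma_mask <- matrix(FALSE, nrow(frame), ncol(frame))
  if (comp$n > 0) {
    big <- which(comp$area >= min_soma_area_px)
    if (length(big)) {
      m <- matrix(comp$labels %in% big, nrow(frame), ncol(frame))
      soma_mask <- as.matrix(EBImage::dilate(EBImage::Image(m * 1),
                                             EBImage::makeBrush(5, "disc"))) > 0
    }
  }
  nm <- (sm > neurite_threshold_gray) & !soma_mask
  closed <- as.matrix(EBImage::closing(EBImage::Image(nm * 1),
                                       EBImage::makeBrush(3, "box"))) > 0
  nl <- EBImage::bwlabel(closed)
  na <- if (max(nl) > 0) tabulate(nl[nl > 0L], nbins = max(nl)) else integer(0)
  keep <- which(na >= min_neurite_px)
  neur_mask <- matrix(nl %in% keep, nrow(frame), ncol(frame)) & nm
  tibble::tibble(neurite_area_um2 = sum(neur_mask) * pixel_size_um^2,
                 soma_area_um2 = sum(soma_mask) * pixel_size_um^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
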