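#' Doughnut-mask enrichment at a TEM
#'
#' The enrichment factor is the ratio of raw per-area intensities of the
#' signal doughnut (hole dilated by `d1`, minus the hole) to the background
#' doughnut (a further `d2` dilation, minus the first), so a spatially
#' uniform fluorescence scores exactly 1 (no enrichment). The
#' background-corrected signal, `sum(signal band) - background-per-area *
#' area(signal band)`, divided by the hole perimeter gives the intensity per
#' unit perimeter used to follow signal across closure.
#'
#' @param frame intensity matrix.
#' @param tem_mask logical hole mask.
#' @param d1,d2 dilation radii in px (>= 1).
#' @param cell_mask optional cell mask the bands are clipped to.
#' @param perimeter hole perimeter in px; computed from the mask contour
#'   when `NULL`.
#' @return list with `E`, `corrected` (background-corrected band sum, may be
#'   negative), `intensity_per_perimeter`, `perimeter`.
#' @export
tem_enrichment <- function(frame, tem_mask, d1 = 3, d2 = 3,
                           cell_mask = NULL, perimeter = NULL) {
  bands <- make_doughnuts(tem_mask, d1 = d1, d2 = d2, cell_mask = cell_mask)
  if (!any(bands$background)) stop("empty background band")
  if (!any(bands$signal)) stop("empty signal band")
  sig_mean <- mean(frame[bands$signal])
  bg_mean <- mean(frame[bands$background])
  E <- sig_mean / bg_mean
  corrected <- sum(frame[bands$signal]) - bg_mean * sum(bands$signal)
  if (is.null(perimeter)) {
    perimeter <- tryCatch(as.numeric(contour_perimeter(tem_mask, "outer")),
                          error = function(e) NA_real_)
  }
  list(E = E, corrected = corrected,
       intensity_per_perimeter = corrected / perimeter,
       perimeter = perimeter)
}

#' Normalized probe profile
#'
#' Elementwise ratio of the background-corrected probe bin means to the
#' background-corrected membrane bin means. Bins with nonpositive membrane
#' signal are missing, not zero.
#'
#' @param probe_profile,membrane_profile numeric vectors of per-bin means
#'   sharing the same binning.
#' @return numeric vector of per-bin ratios.
#' @export
normalized_probe <- function(probe_profile, membrane_profile) {
  stopifnot(length(probe_profile) == length(membrane_profile))
  ok <- !is.na(membrane_profile) & membrane_profile > 0
  if (!any(ok)) stop("all membrane bins are nonpositive")
  out <- rep(NA_real_, length(probe_profile))
  out[ok] <- probe_profile[ok] / membrane_profile[ok]
  out
}

#' Classify boundary bins as flattening, lagging, or neither
#'
#' Flattening: positive curvature becoming less positive (kappa > 0 and
#' d kappa/dt < 0). Lagging: positive curvature becoming more positive
#' (kappa > 0 and d kappa/dt > 0). Everything else — nonpositive curvature,
#' zero or missing derivative — is neither.
#'
#' @param profile data.frame with columns `kappa` and `dkappa_dt` (e.g. from
#'   [tem_edge_profile()]).
#' @return the profile with an added character column `label`.
#' @export
classify_regions <- function(profile) {
  stopifnot(all(c("kappa", "dkappa_dt") %in% names(profile)))
  k <- profile$kappa; dk <- profile$dkappa_dt
  lab <- rep("neither", nrow(profile))
  lab[!is.na(k) & !is.na(dk) & k > 0 & dk < 0] <- "flattening"
  lab[!is.na(k) & !is.na(dk) & k > 0 & dk > 0] <- "lagging"
  profile$label <- lab
  profile
}

#' Pooled flattening-over-lagging fold enrichment
#'
#' Mean of the normalized probe values over all flattening bins divided by
#' the mean over all lagging bins, pooling every (frame, bin) sample of one
#' TEM. A probe with no preference scores 1. Missing (`NA`) if either class
#' is empty.
#'
#' @param values numeric normalized probe values.
#' @param labels character labels from [classify_regions()].
#' @return a single ratio, or `NA`.
#' @export
fold_enrichment <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  f <- values[labels == "flattening"]
  l <- values[labels == "lagging"]
  mf <- if (any(!is.na(f))) mean(f, na.rm = TRUE) else NA_real_
  ml <- if (any(!is.na(l))) mean(l, na.rm = TRUE) else NA_real_
  if (is.na(mf) || is.na(ml) || ml == 0) return(NA_real_)
  mf / ml
}

#' Rotation null for the flattening/lagging enrichment
#'
#' For each rotation offset k, the normalized fluorescence bins of each TEM
#' are circularly shifted by k bins (one increment = 360/n_bins degrees,
#' 7.2 degrees in the 50-bin TEM mode) while the geometric labels stay
#' fixed, and the pooled fold enrichment is recomputed per TEM. At each
#' offset the per-TEM scores are compared with the no-preference null of 1
#' by a two-tailed one-sample t test; no multiple-testing correction is
#' applied. A genuine spatial coupling between probe and flattening shows up
#' as a fold-enrichment peak at zero rotation.
#'
#' @param profiles list of per-TEM data.frames, each with columns `frame`,
#'   `bin`, `normalized`, `label` (see [classify_regions()]); >= 2 TEMs are
#'   required for the test.
#' @param n_rotations number of offsets to evaluate (default: one full turn,
#'   `n_bins` offsets starting at 0).
#' @return data.frame of class `RotationNullTable`: `offset`, `offset_deg`,
#'   `mean`, `sd`, `n`, `p`, plus attribute `scores` (offset x TEM matrix).
#' @export
rotation_scan <- function(profiles, n_rotations = NULL) {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  n_bins <- max(profiles[[1]]$bin)
  for (pr in profiles) {
    stopifnot(max(pr$bin) == n_bins)
  }
  if (is.null(n_rotations)) n_rotations <- n_bins
  offsets <- seq_len(n_rotations) - 1L
  scores <- matrix(NA_real_, length(offsets), length(profiles))
  for (j in seq_along(profiles)) {
    pr <- profiles[[j]]
    frames <- sort(unique(pr$frame))
    V <- matrix(NA_real_, n_bins, length(frames))
    L <- matrix("neither", n_bins, length(frames))
    for (fi in seq_along(frames)) {
      sel <- pr$frame == frames[fi]
      V[pr$bin[sel], fi] <- pr$normalized[sel]
      L[pr$bin[sel], fi] <- pr$label[sel]
    }
    for (oi in seq_along(offsets)) {
      k <- offsets[oi] %% n_bins
      Vr <- V[mod1(seq_len(n_bins) - k, n_bins), , drop = FALSE]
      scores[oi, j] <- fold_enrichment(as.vector(Vr), as.vector(L))
    }
  }
  stat <- t(apply(scores, 1, function(s) {
    s <- s[is.finite(s)]
    n <- length(s)
    p <- if (n >= 2 && stats::sd(s) > 0) {
      stats::t.test(s, mu = 1)$p.value
    } else NA_real_
    c(mean = if (n > 0) mean(s) else NA_real_,
      sd = if (n > 1) stats::sd(s) else NA_real_, n = n, p = p)
  }))
  out <- data.frame(offset = offsets, offset_deg = offsets * 360 / n_bins,
                    mean = stat[, "mean"], sd = stat[, "sd"],
                    n = as.integer(stat[, "n"]), p = stat[, "p"])
  attr(out, "scores") <- scores
  class(out) <- c("RotationNullTable", class(out))
  out
}

#' Spearman trend of per-perimeter intensity across closure
#'
#' Rank correlation (mid-ranked ties) of the background-corrected intensity
#' per unit perimeter against frame index (or against hole perimeter, which
#' decreases as the TEM closes). One coefficient per TEM and channel is the
#' unit of downstream comparisons between channels.
#'
#' @param series data.frame from [tem_series()] restricted to one channel,
#'   or any data.frame with columns `frame`, `perimeter_px`,
#'   `intensity_per_perimeter`.
#' @param x `"frame"` (default) or `"perimeter"`.
#' @return Spearman rho, or `NA` for constant series.
#' @export
perimeter_trend <- function(series, x = c("frame", "perimeter")) {
  x <- match.arg(x)
  xv <- if (x == "frame") series$frame else series$perimeter_px
  yv <- series$intensity_per_perimeter
  ok <- is.finite(xv) & is.finite(yv)
  if (sum(ok) < 3L) stop("need at least 3 frames for a trend")
  if (stats::sd(yv[ok]) == 0 || stats::sd(xv[ok]) == 0) return(NA_real_)
  stats::cor(xv[ok], yv[ok], method = "spearman")
}

#' Spearman correlation of normalized probe signal with edge velocity
#'
#' Pools all (frame, bin) samples of one cell or TEM with nonmissing
#' velocity and normalized probe signal.
#'
#' @param profile data.frame with columns `velocity` and `normalized`.
#' @return Spearman rho, or `NA` when velocity is constant.
#' @export
velocity_signal_correlation <- function(profile) {
  ok <- is.finite(profile$velocity) & is.finite(profile$normalized)
  if (sum(ok) < 10L) stop("need at least 10 paired (velocity, signal) samples")
  if (stats::sd(profile$velocity[ok]) == 0) return(NA_real_)
  stats::cor(profile$velocity[ok], profile$normalized[ok], method = "spearman")
}

#' Ratio of background-corrected per-area intensities of two compartments
#'
#' Each segment's integrated intensity is corrected by the cytosolic per-area
#' mean times the segment's area; the score is the per-area corrected target
#' intensity over the per-area corrected reference intensity (e.g.
#' lamellipodia over filopodia, or ring band over its dilated background).
#'
#' @param frame intensity matrix.
#' @param target_mask,reference_mask,cytosol_mask disjoint logical masks;
#'   the cytosol mask must be nonempty.
#' @return the ratio, or `NA` when the corrected reference is nonpositive.
#' @export
compartment_ratio <- function(frame, target_mask, reference_mask,
                              cytosol_mask) {
  stopifnot(any(cytosol_mask))
  if (any(target_mask & reference_mask) || any(target_mask & cytosol_mask) ||
      any(reference_mask & cytosol_mask)) {
    stop("compartment masks must be disjoint")
  }
  cyt <- mean(frame[cytosol_mask])
  at <- sum(target_mask); ar <- sum(reference_mask)
  ct <- sum(frame[target_mask]) - cyt * at
  cr <- sum(frame[reference_mask]) - cyt * ar
  if (cr <= 0) return(NA_real_)
  (ct / at) / (cr / ar)
}

#' Filopodia-like compartment from an eroded cell mask
#'
#' Thin peripheral structures are the part of the cell mask removed by a
#' morphological opening with a disc: `cell & !opening(cell, radius)`.
#'
#' @param cell_mask logical cell mask.
#' @param radius opening disc radius in px.
#' @return logical mask.
#' @export
filopodia_mask <- function(cell_mask, radius = 3) {
  op <- matrix(as.numeric(EBImage::opening(cell_mask * 1, disc_brush(radius))) > 0.5,
               nrow = nrow(cell_mask))
  cell_mask & !op
}

#' Manders M1 colocalization coefficient
#'
#' Fraction of channel A intensity (within the ROI) residing in pixels where
#' channel B exceeds its threshold; inputs are expected background
#' subtracted. The default threshold is Otsu on channel B within the ROI.
#'
#' @param channel_a,channel_b co-registered intensity matrices.
#' @param roi logical region of interest (nonempty).
#' @param b_threshold numeric threshold for channel B, or `NULL` for Otsu.
#' @return M1 in `[0, 1]`, or `NA` when channel A has zero total intensity
#'   in the ROI.
#' @export
manders_m1 <- function(channel_a, channel_b, roi, b_threshold = NULL) {
  stopifnot(any(roi), all(dim(channel_a) == dim(channel_b)))
  if (is.null(b_threshold)) {
    vals <- channel_b
    vals[!roi] <- 0
    b_threshold <- otsu_threshold(vals)
  }
  a_tot <- sum(channel_a[roi])
  if (a_tot == 0) return(NA_real_)
  sum(channel_a[roi & channel_b > b_threshold]) / a_tot
}

#' Scrambled-image control for in-mask intensity
#'
#' Compares the mean intensity inside a mask with the mean inside the same
#' mask of a seeded uniform random permutation of ALL pixel values of the
#' frame — the spatial-randomization control for concentration of signal in
#' a compartment.
#'
#' @param frame intensity matrix.
#' @param mask nonempty logical mask.
#' @param seed integer seed for the permutation.
#' @return list with `mean_signal` and `mean_scrambled`.
#' @export
scramble_control <- function(frame, mask, seed = 1L) {
  stopifnot(any(mask))
  scrambled <- with_seed(substream_seed(seed, "scramble"), {
    matrix(sample(as.vector(frame)), nrow = nrow(frame))
  })
  list(mean_signal = mean(frame[mask]),
       mean_scrambled = mean(scrambled[mask]))
}

# integer-pixel translation of mask_t1 maximizing overlap with mask_t0
align_masks <- function(mask_t0, mask_t1, max_shift = 5L) {
  best <- c(0L, 0L); best_ov <- -1
  ny <- nrow(mask_t0); nx <- ncol(mask_t0)
  for (dy in (-max_shift):max_shift) for (dx in (-max_shift):max_shift) {
    y0 <- max(1, 1 + dy); y1 <- min(ny, ny + dy)
    x0 <- max(1, 1 + dx); x1 <- min(nx, nx + dx)
    ov <- sum(mask_t0[y0:y1, x0:x1] &
                mask_t1[(y0:y1) - dy, (x0:x1) - dx])
    if (ov > best_ov) { best_ov <- ov; best <- c(dy, dx) }
  }
  out <- matrix(FALSE, ny, nx)
  dy <- best[1]; dx <- best[2]
  y0 <- max(1, 1 + dy); y1 <- min(ny, ny + dy)
  x0 <- max(1, 1 + dx); x1 <- min(nx, nx + dx)
  out[y0:y1, x0:x1] <- mask_t1[(y0:y1) - dy, (x0:x1) - dx]
  attr(out, "shift") <- best
  out
}

#' Protrusion morphometrics from a mask difference map
#'
#' Each connected component of `mask_t1 & !mask_t0` is one protrusion event.
#' Its length is the maximum Euclidean distance of component pixels from the
#' t0 region; its width is the chord of the component at half that length
#' (pixels whose distance from t0 lies within +/- 0.5 px of length/2); its
#' speed is length over elapsed time.
#'
#' @param mask_t0,mask_t1 logical masks of consecutive segmentations.
#' @param elapsed elapsed time in seconds (> 0).
#' @param pixel_size optional nm/px for physical units.
#' @param min_area smallest protrusion area kept (px^2).
#' @param align apply integer-pixel drift correction (translation of
#'   `mask_t1` maximizing overlap with `mask_t0`) before differencing.
#' @param max_shift drift-correction search radius in px.
#' @return data.frame (one row per protrusion): `protrusion`, `area_px2`,
#'   `length_px`, `width_px`, `speed_px_min`, and `length_um`, `width_um`,
#'   `speed_um_min` when `pixel_size` is given. Empty when there are no
#'   protrusions.
#' @export
protrusion_metrics <- function(mask_t0, mask_t1, elapsed, pixel_size = NULL,
                               min_area = 2L, align = FALSE, max_shift = 5L) {
  stopifnot(elapsed > 0, all(dim(mask_t0) == dim(mask_t1)))
  m0 <- mask_t0 > 0; m1 <- mask_t1 > 0
  if (align) m1 <- align_masks(m0, m1, max_shift)
  diffmap <- m1 & !m0
  empty <- data.frame(protrusion = integer(0), area_px2 = integer(0),
                      length_px = numeric(0), width_px = numeric(0),
                      speed_px_min = numeric(0))
  if (!any(diffmap)) return(empty)
  lab <- matrix(as.integer(EBImage::bwlabel(diffmap * 1)),
                nrow = nrow(diffmap))
  d_from_t0 <- matrix(as.numeric(EBImage::distmap((1 - m0) * 1)),
                      nrow = nrow(m0))
  rows <- list()
  for (id in seq_len(max(lab))) {
    comp <- lab == id
    a <- sum(comp)
    if (a < min_area) next
    dvals <- d_from_t0[comp]
    len <- max(dvals)
    width <- sum(abs(dvals - len / 2) <= 0.5)
    rows[[length(rows) + 1L]] <- data.frame(
      protrusion = id, area_px2 = a, length_px = len, width_px = width,
      speed_px_min = len / (elapsed / 60))
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out$protrusion <- seq_len(nrow(out))
  if (!is.null(pixel_size)) {
    out$length_um <- out$length_px * pixel_size / 1000
    out$width_um <- out$width_px * pixel_size / 1000
    out$speed_um_min <- out$speed_px_min * pixel_size / 1000
  }
  out
}
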