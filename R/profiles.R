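#' Per-frame, per-angular-bin edge profile of a closing TEM
#'
#' Runs the full geometric pipeline on a two-channel TEM stack: per frame,
#' the membrane channel is segmented (holes preserved), the hole boundary is
#' traced as a 1000-point sub-pixel spline, signed osculating-circle
#' curvature and distance-transform edge velocity are computed per point,
#' and curvature, velocity and background-corrected band fluorescence are
#' averaged into equal angular bins around the hole center. The normalized
#' probe profile is the per-bin ratio of background-corrected probe to
#' background-corrected membrane signal. The per-bin curvature derivative
#' defaults to the central difference (kappa(t+1) - kappa(t-1)) / 2, which
#' keeps the frame-t classification independent of the frame-t contour
#' noise shared with the fluorescence measurement (see the vignette); the
#' forward difference kappa(t+1) - kappa(t) is available instead.
#'
#' @param stack an [image_stack()] with membrane and probe channels.
#' @param membrane,probe channel names or indices.
#' @param n_points boundary points (default 1000).
#' @param S curvature scale parameter (default 10, the TEM setting).
#' @param n_bins angular bins (default 50, i.e. 7.2 degree increments).
#' @param half_width fluorescence band half-width in px.
#' @param smoothing_sigma,threshold,erosion_radius passed to
#'   [segment_region()].
#' @param background `"hole"` (default: scalar local background estimated
#'   from the eroded hole interior, which is off-cell by construction) or
#'   `"tophat"` (rolling-ball style top-hat of radius `background_radius`;
#'   note a top-hat leaves plateau-dominated frames' constant offset in
#'   place, which biases the probe/membrane ratio).
#' @param background_radius top-hat disc radius; default `0.3 * min(Y, X)`.
#' @param velocity_method passed to [edge_velocity()].
#' @param dkappa `"central"` (default) or `"forward"` difference for
#'   d kappa/dt.
#' @param boundary_smoothing_scale contour smoothing sd as a fraction of the
#'   hole perimeter. The default (0.045) suppresses pixel-scale contour
#'   noise below the curvature signal sensed by the short three-point span
#'   of the S = 10 osculating fit; see the package vignette.
#' @return data.frame with one row per (frame, bin): `frame`, `bin`,
#'   `theta`, `kappa`, `dkappa_dt`, `velocity`, `membrane`, `probe`,
#'   `normalized`. Frames without a detectable hole are skipped (recorded in
#'   attribute `skipped`); per-frame hole perimeter and area are attached as
#'   attribute `morphometry`.
#' @export
tem_edge_profile <- function(stack, membrane = "membrane", probe = "probe",
                             n_points = 1000L, S = 10L, n_bins = 50L,
                             half_width = 2, smoothing_sigma = 2,
                             threshold = "otsu", erosion_radius = 0,
                             background = c("hole", "tophat"),
                             background_radius = NULL,
                             velocity_method = "central",
                             dkappa = c("central", "forward"),
                             boundary_smoothing_scale = 0.045) {
  background <- match.arg(background)
  dkappa <- match.arg(dkappa)
  nt <- n_frames(stack)
  dims <- dim(stack$data)[1:2]
  if (is.null(background_radius)) background_radius <- round(0.3 * min(dims))

  cells <- vector("list", nt); holes <- vector("list", nt)
  skipped <- integer(0)
  for (t in seq_len(nt)) {
    cell <- tryCatch(
      segment_region(get_frame(stack, t, membrane), smoothing_sigma,
                     threshold, erosion_radius),
      error = function(e) NULL)
    h <- if (is.null(cell)) NULL else hole_mask(cell)
    if (is.null(h) || !any(h)) {
      skipped <- c(skipped, t)
      next
    }
    cells[[t]] <- cell; holes[[t]] <- h
  }

  correct_bg <- function(frame, hole) {
    if (background == "tophat") {
      th <- EBImage::whiteTopHat(EBImage::Image(frame),
                                 disc_brush(background_radius))
      matrix(as.numeric(th), nrow = dims[1])
    } else {
      core <- matrix(as.numeric(EBImage::erode(
        hole * 1, disc_brush(max(1, round(half_width + 2))))) > 0.5,
        nrow = dims[1])
      bg <- if (any(core)) mean(frame[core]) else min(frame)
      frame - bg
    }
  }

  per_frame <- list()
  morpho <- list()
  for (t in seq_len(nt)) {
    if (is.null(holes[[t]])) next
    hole <- holes[[t]]
    idx <- which(hole)
    center <- c(mean((ceiling(idx / dims[1])) - 1),
                mean(((idx - 1) %% dims[1])))
    hb <- extract_boundary(cells[[t]], n_points, which = "hole",
                           smoothing_scale = boundary_smoothing_scale)
    kap <- signed_curvature(hb, S)
    kb <- angular_profile(hb$x, hb$y, kap, center, n_bins)
    vel <- rep(NA_real_, n_points)
    if (t > 1 && t < nt && !is.null(cells[[t - 1]]) && !is.null(cells[[t + 1]])) {
      vel <- edge_velocity(hb, cells[[t - 1]], cells[[t + 1]],
                           method = velocity_method)
    }
    vb <- angular_profile(hb$x, hb$y, vel, center, n_bins)
    band <- boundary_band(hb, half_width, dims)
    bidx <- which(band)
    bx <- ceiling(bidx / dims[1]) - 1
    by <- (bidx - 1) %% dims[1]
    memc <- correct_bg(get_frame(stack, t, membrane), hole)
    prbc <- correct_bg(get_frame(stack, t, probe), hole)
    mb <- angular_profile(bx, by, memc[bidx], center, n_bins)
    pb <- angular_profile(bx, by, prbc[bidx], center, n_bins)
    norm <- normalized_probe(pb$mean, mb$mean)
    per_frame[[length(per_frame) + 1L]] <- data.frame(
      frame = t, bin = kb$bin, theta = kb$theta, kappa = kb$mean,
      velocity = vb$mean, membrane = mb$mean, probe = pb$mean,
      normalized = norm)
    morpho[[length(morpho) + 1L]] <- data.frame(
      frame = t, perimeter = boundary_length(hb), area = sum(hole))
  }
  if (length(per_frame) == 0L) stop("no frame contained a detectable hole")
  prof <- do.call(rbind, per_frame)

  # per-bin curvature time derivative across the frames actually present
  frames <- sort(unique(prof$frame))
  kmat <- matrix(NA_real_, n_bins, length(frames))
  for (j in seq_along(frames)) {
    kmat[, j] <- prof$kappa[prof$frame == frames[j]]
  }
  dk <- matrix(NA_real_, n_bins, length(frames))
  for (j in seq_along(frames)) {
    if (dkappa == "forward") {
      if (j < length(frames) && frames[j + 1] == frames[j] + 1) {
        dk[, j] <- kmat[, j + 1] - kmat[, j]
      }
    } else {
      if (j > 1 && j < length(frames) &&
          frames[j + 1] == frames[j] + 1 && frames[j - 1] == frames[j] - 1) {
        dk[, j] <- (kmat[, j + 1] - kmat[, j - 1]) / 2
      }
    }
  }
  prof$dkappa_dt <- NA_real_
  for (j in seq_along(frames)) {
    prof$dkappa_dt[prof$frame == frames[j]] <- dk[, j]
  }
  prof <- prof[c("frame", "bin", "theta", "kappa", "dkappa_dt", "velocity",
                 "membrane", "probe", "normalized")]
  attr(prof, "skipped") <- skipped
  attr(prof, "morphometry") <- do.call(rbind, morpho)
  prof
}

#' Per-frame TEM morphometrics and enrichment series
#'
#' For every frame with a detectable hole, computes the hole perimeter and
#' area and, per channel, the doughnut enrichment factor and
#' background-corrected intensity per unit perimeter (see
#' [tem_enrichment()]).
#'
#' @inheritParams tem_edge_profile
#' @param d1,d2 doughnut dilation radii in px.
#' @param channels channels to score (default: all).
#' @return data.frame (frame, channel, perimeter_px, area_px2, E,
#'   intensity_per_perimeter).
#' @export
tem_series <- function(stack, membrane = "membrane", channels = NULL,
                       d1 = 3, d2 = 3, smoothing_sigma = 2,
                       threshold = "otsu", erosion_radius = 0) {
  if (is.null(channels)) channels <- stack$channel_names
  nt <- n_frames(stack)
  out <- list()
  for (t in seq_len(nt)) {
    cell <- tryCatch(
      segment_region(get_frame(stack, t, membrane), smoothing_sigma,
                     threshold, erosion_radius),
      error = function(e) NULL)
    if (is.null(cell)) next
    hole <- hole_mask(cell)
    if (!any(hole)) next
    perim <- tryCatch(as.numeric(contour_perimeter(hole, "outer")),
                      error = function(e) NA_real_)
    for (ch in channels) {
      enr <- tem_enrichment(get_frame(stack, t, ch), hole, d1 = d1, d2 = d2,
                            cell_mask = fill_holes(cell), perimeter = perim)
      out[[length(out) + 1L]] <- data.frame(
        frame = t, channel = ch, perimeter_px = perim, area_px2 = sum(hole),
        E = enr$E, intensity_per_perimeter = enr$intensity_per_perimeter)
    }
  }
  if (length(out) == 0L) stop("no frame contained a detectable hole")
  do.call(rbind, out)
}
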