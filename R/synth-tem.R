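#' Synthetic closing transendothelial macroaperture (TEM)
#'
#' Generates a seeded two-channel time-lapse of a circular hole closing
#' inside a disc-shaped cell. The hole boundary at frame t is the polar
#' curve
#' \deqn{\rho(\theta, t) = r(t)\,\{1 + a \cos(m\theta)\, g(t)\},}
#' with mean radius `r(t) = r0 - closure_rate * (t - 1)` and an exponentially
#' decaying lag profile `g(t) = exp(-(t - 1) / lag_tau)`. The decaying
#' mode-`m` perturbation guarantees both flattening (kappa > 0, d kappa/dt <
#' 0) and lagging (kappa > 0, d kappa/dt > 0) boundary regions, which a
#' perfect shrinking circle cannot provide.
#'
#' The membrane channel is a uniform density over the cell region. The probe
#' channel is, per boundary point, either
#' `I = b0 + b1 * max(kappa, 0) + b2 * max(-d kappa/dt, 0)` deposited along
#' the hole rim (`probe_mode = "boundary"`, plus a uniform cytosolic level),
#' or `b0 / membrane_density` times the membrane channel
#' (`probe_mode = "proportional"`, giving a constant normalized profile).
#' Both channels then pass through the PSF/noise model of [noise_params()].
#'
#' @param r0 initial mean hole radius (px).
#' @param closure_rate radial closure speed (px/frame).
#' @param n_frames number of frames (>= 3).
#' @param lag_mode integer angular mode m of the lag perturbation.
#' @param lag_amplitude relative amplitude a in `[0, 1)`.
#' @param lag_tau decay time constant of `g(t)` in frames.
#' @param b0,b1,b2 probe coupling: baseline, curvature coupling, flattening
#'   coupling (intensity units; `b1`, `b2` only used in `"boundary"` mode).
#' @param probe_mode `"boundary"` or `"proportional"`.
#' @param membrane_density membrane channel intensity over the cell.
#' @param cytosol_level optional uniform probe level over the cell
#'   (boundary mode); default 0, a pure boundary-deposited probe.
#' @param cell_radius radius of the cell disc (px); default `0.45 * min(dim)`.
#' @param dim image dimensions `c(Y, X)`.
#' @param min_radius smallest admissible mean radius (px); the radius
#'   schedule must stay above it for all frames.
#' @param psf_sigma Gaussian PSF sd (px).
#' @param noise a [noise_params()].
#' @param pixel_size nm/px; @param frame_interval s/frame.
#' @param n_deposit boundary deposit points per frame.
#' @param seed master seed; all randomness derives from named substreams.
#' @return list with elements `stack` (an [image_stack()] with channels
#'   `membrane`, `probe`) and `truth` (a `GroundTruth` carrying the analytic
#'   per-frame, per-angle radius, curvature, curvature forward difference,
#'   edge speed and probe deposit rate).
#' @export
make_closing_tem <- function(r0 = 22, closure_rate = 1.5, n_frames = 8L,
                             lag_mode = 3L, lag_amplitude = 0.1, lag_tau = 3,
                             b0 = 60, b1 = 0, b2 = 0,
                             probe_mode = c("boundary", "proportional"),
                             membrane_density = 100, cytosol_level = 0,
                             cell_radius = NULL, dim = c(128L, 128L),
                             min_radius = 4, psf_sigma = 2,
                             noise = noise_params(),
                             pixel_size = 110, frame_interval = 5,
                             n_deposit = 2000L, seed = 1L) {
  probe_mode <- match.arg(probe_mode)
  stopifnot(n_frames >= 3L, lag_amplitude >= 0, lag_amplitude < 1,
            r0 > 0, closure_rate >= 0, min_radius > 0)
  r_sched <- r0 - closure_rate * (seq_len(n_frames) - 1)
  if (any(r_sched * (1 - lag_amplitude) <= min_radius)) {
    stop(sprintf(
      "radius schedule reaches <= %.1f px before frame %d; shorten the movie or slow the closure",
      min_radius, n_frames))
  }
  if (is.null(cell_radius)) cell_radius <- 0.45 * min(dim)
  if (r0 * (1 + lag_amplitude) >= cell_radius) {
    stop("initial hole does not fit inside the cell disc")
  }
  p <- list(r0 = r0, closure_rate = closure_rate, n_frames = n_frames,
            lag_mode = lag_mode, lag_amplitude = lag_amplitude,
            lag_tau = lag_tau, b0 = b0, b1 = b1, b2 = b2,
            probe_mode = probe_mode, membrane_density = membrane_density,
            cytosol_level = cytosol_level, cell_radius = cell_radius,
            dim = dim, min_radius = min_radius, psf_sigma = psf_sigma,
            noise = noise, pixel_size = pixel_size,
            frame_interval = frame_interval, n_deposit = n_deposit,
            center = c((dim[2] - 1) / 2, (dim[1] - 1) / 2))

  th <- seq(0, 2 * pi, length.out = n_deposit + 1L)[-(n_deposit + 1L)]
  arr <- array(0, c(dim[1], dim[2], 2L, n_frames))
  rows <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    geo <- tem_truth_theta(p, th, t)
    cell <- tem_cell_mask_impl(p, t)
    mem <- cell * membrane_density
    if (probe_mode == "proportional") {
      probe <- mem * (b0 / membrane_density)
      dep_rate <- rep(b0, length(th))
    } else {
      dep_rate <- b0 + b1 * pmax(geo$kappa, 0) + b2 * pmax(-geo$dkappa_dt, 0)
      ds <- geo$arc_ds
      probe <- deposit_points(cell * cytosol_level,
                              p$center[1] + geo$rho * cos(th),
                              p$center[2] + geo$rho * sin(th),
                              dep_rate * ds)
    }
    arr[, , 1, t] <- mem
    arr[, , 2, t] <- probe
    rows[[t]] <- data.frame(frame = t, theta = th, rho = geo$rho,
                            kappa_true = geo$kappa,
                            dkappa_dt_true = geo$dkappa_dt,
                            v_true = geo$v, deposit_rate = dep_rate,
                            arc_ds = geo$arc_ds)
  }
  arr <- blur_array(arr, psf_sigma, noise$background)
  arr <- noise_array(arr, noise, seed)
  stack <- image_stack(arr, pixel_size = pixel_size,
                       frame_interval = frame_interval,
                       channel_names = c("membrane", "probe"))
  truth <- structure(list(type = "closing_tem", seed = as.integer(seed),
                          params = p, r = r_sched,
                          table = do.call(rbind, rows)),
                     class = "GroundTruth")
  list(stack = stack, truth = truth)
}

# analytic geometry of the polar hole boundary at angles th, frame t
tem_truth_theta <- function(p, th, t) {
  a <- p$lag_amplitude; m <- p$lag_mode
  r <- function(t) p$r0 - p$closure_rate * (t - 1)
  g <- function(t) exp(-(t - 1) / p$lag_tau)
  kappa_at <- function(t) {
    rho <- r(t) * (1 + a * g(t) * cos(m * th))
    d1 <- -r(t) * a * g(t) * m * sin(m * th)
    d2 <- -r(t) * a * g(t) * m^2 * cos(m * th)
    (rho^2 + 2 * d1^2 - rho * d2) / (rho^2 + d1^2)^1.5
  }
  rho <- r(t) * (1 + a * g(t) * cos(m * th))
  d1 <- -r(t) * a * g(t) * m * sin(m * th)
  kappa <- kappa_at(t)
  # instantaneous time derivative of the closed-form curvature
  h <- 1e-3
  dk <- (kappa_at(t + h) - kappa_at(t - h)) / (2 * h)
  # normal advance speed of the cell edge (positive = hole closing)
  rho_t <- -p$closure_rate * (1 + a * g(t) * cos(m * th)) +
    r(t) * a * cos(m * th) * (-g(t) / p$lag_tau)
  v <- -rho_t / sqrt(1 + (d1 / rho)^2)
  ds <- sqrt(rho^2 + d1^2) * (2 * pi / length(th))  # arc length per deposit
  list(rho = rho, kappa = kappa, dkappa_dt = dk, v = v, arc_ds = ds)
}

tem_cell_mask_impl <- function(p, t) {
  ny <- p$dim[1]; nx <- p$dim[2]
  xs <- matrix(rep(0:(nx - 1), each = ny), ny) - p$center[1]
  ys <- matrix(rep(0:(ny - 1), nx), ny) - p$center[2]
  R <- sqrt(xs^2 + ys^2)
  th <- atan2(ys, xs)
  r <- p$r0 - p$closure_rate * (t - 1)
  g <- exp(-(t - 1) / p$lag_tau)
  rho <- r * (1 + p$lag_amplitude * g * cos(p$lag_mode * th))
  (R <= p$cell_radius & R >= rho) * 1
}

#' True cell mask of a synthetic TEM at one frame
#' @param truth `GroundTruth` from [make_closing_tem()].
#' @param frame frame index.
#' @return 0/1 matrix.
#' @export
tem_true_cell_mask <- function(truth, frame) {
  stopifnot(inherits(truth, "GroundTruth"), truth$type == "closing_tem")
  tem_cell_mask_impl(truth$params, frame)
}

#' Angularly binned analytic truth of a synthetic TEM
#'
#' Aggregates the dense ground-truth table to `n_bins` angular bins per
#' frame, using the same binning and differencing conventions as the
#' estimators: bin means of the analytic curvature, a discrete time
#' difference of the binned curvature for the label (central by default,
#' matching [tem_edge_profile()]; frames without a defined difference carry
#' no label).
#'
#' @param truth `GroundTruth` from [make_closing_tem()].
#' @param n_bins angular bins.
#' @param dkappa `"central"` or `"forward"` difference for the label.
#' @return data.frame (frame, bin, kappa_true, dkappa_dt_true, v_true,
#'   deposit_rate, label).
#' @export
tem_truth_profile <- function(truth, n_bins = 50L,
                              dkappa = c("central", "forward")) {
  dkappa <- match.arg(dkappa)
  tab <- truth$table
  width <- 2 * pi / n_bins
  tab$bin <- pmin(floor((tab$theta %% (2 * pi)) / width), n_bins - 1L) + 1L
  agg <- stats::aggregate(
    tab[c("kappa_true", "v_true", "deposit_rate")],
    by = list(frame = tab$frame, bin = tab$bin), FUN = mean)
  agg <- agg[order(agg$frame, agg$bin), ]
  nt <- max(agg$frame)
  k <- matrix(agg$kappa_true, nrow = n_bins)  # bins x frames
  dk <- if (dkappa == "forward") {
    cbind(k[, -1, drop = FALSE] - k[, -nt, drop = FALSE], NA)
  } else {
    cbind(NA, (k[, -(1:2), drop = FALSE] - k[, 1:(nt - 2), drop = FALSE]) / 2, NA)
  }
  agg$dkappa_dt_true <- as.numeric(dk)
  agg$label <- ifelse(is.na(agg$dkappa_dt_true) | agg$kappa_true <= 0, "neither",
                      ifelse(agg$dkappa_dt_true < 0, "flattening",
                             ifelse(agg$dkappa_dt_true > 0, "lagging", "neither")))
  agg
}

#' Analytic pooled fold enrichment of a synthetic TEM
#'
#' Pools the deposited probe intensity of all (frame, bin) samples with a
#' truth label and returns mean(flattening) / mean(lagging) — the quantity
#' the estimation pipeline should recover.
#'
#' @inheritParams tem_truth_profile
#' @export
tem_true_fold <- function(truth, n_bins = 50L) {
  prof <- tem_truth_profile(truth, n_bins)
  fold_enrichment(prof$deposit_rate, prof$label)
}

#' Flattening coupling producing a prescribed true fold enrichment
#'
#' For the boundary-deposited probe `I = b0 + b2 * max(-dkappa/dt, 0)` the
#' pooled analytic fold enrichment is `(b0 + b2*Mf) / (b0 + b2*Ml)` where
#' `Mf`, `Ml` are the pooled class means of `max(-dkappa/dt, 0)` over the
#' flattening and lagging bins of the analytic geometry. This solves for the
#' `b2` attaining a target fold, using geometry alone (no images).
#'
#' @param fold target fold enrichment (> 1).
#' @param b0 probe baseline.
#' @param ... geometry arguments passed to [make_closing_tem()] (couplings
#'   and noise are irrelevant: only the deterministic geometry is used).
#' @param n_bins angular bins used by the downstream classification.
#' @return the required `b2` (intensity units).
#' @export
tem_coupling_for_fold <- function(fold, b0 = 20, ..., n_bins = 50L) {
  stopifnot(fold > 1)
  sim <- make_closing_tem(b0 = 1, b1 = 0, b2 = 0, probe_mode = "boundary",
                          noise = noise_params(0, 0, 0), psf_sigma = 0,
                          seed = 1L, ...)
  prof <- tem_truth_profile(sim$truth, n_bins)
  tab <- sim$truth$table
  width <- 2 * pi / n_bins
  tab$bin <- pmin(floor((tab$theta %% (2 * pi)) / width), n_bins - 1L) + 1L
  tab$flat_drive <- pmax(-tab$dkappa_dt_true, 0)
  agg <- stats::aggregate(tab["flat_drive"],
                          by = list(frame = tab$frame, bin = tab$bin), FUN = mean)
  merged <- merge(agg, prof[c("frame", "bin", "label")], by = c("frame", "bin"))
  Mf <- mean(merged$flat_drive[merged$label == "flattening"])
  Ml <- mean(merged$flat_drive[merged$label == "lagging"])
  if (!is.finite(Mf) || !is.finite(Ml)) stop("geometry lacks both classes")
  denom <- Mf - fold * Ml
  if (denom <= 0) stop("target fold unattainable for this geometry")
  b0 * (fold - 1) / denom
}
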