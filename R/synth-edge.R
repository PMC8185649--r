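#' Synthetic advancing leading edge with lagging segments
#'
#' Generates a seeded two-channel time-lapse of a cell front advancing
#' upward (toward smaller y). The cell occupies the rows below the front
#' \deqn{y_f(x, t) = y_0 - v_0 (t-1) - A\,[1 - e^{-(t-1)/\tau}]\sin(2\pi x/\lambda),}
#' so the true per-column advance speed is
#' `v(x, t) = v0 + (A / tau) * exp(-(t-1)/tau) * sin(2 pi x / lambda)`:
#' columns differ in speed while the lag develops. The probe channel
#' deposits, per column of the front, the affine function
#' `c0 + coupling * v(x, t)` of the true local edge speed (scaled by local
#' arc length); the membrane channel is a uniform fill of the cell.
#'
#' @param front_speed mean advance speed v0 (px/frame, > 0).
#' @param lag_wavelength lateral wavelength lambda (px).
#' @param lag_amplitude final lag depth A (px).
#' @param lag_tau lag development time constant (frames).
#' @param coupling velocity-coupling coefficient of the probe deposit.
#' @param c0 probe deposit baseline.
#' @param membrane_density membrane fill intensity.
#' @param cytosol_level uniform probe level over the cell.
#' @param y0 initial front row; default `0.75 * Y`.
#' @param dim image dimensions `c(Y, X)`.
#' @param n_frames number of frames.
#' @param psf_sigma,noise,pixel_size,frame_interval,seed as in
#'   [make_closing_tem()].
#' @return list with `stack` (channels `membrane`, `probe`) and `truth`
#'   (per frame and column: front position, true speed, deposit rate).
#' @export
make_leading_edge <- function(front_speed = 1.5, lag_wavelength = 48,
                              lag_amplitude = 4, lag_tau = 4, coupling = 1,
                              c0 = 50, membrane_density = 100,
                              cytosol_level = 10, y0 = NULL,
                              dim = c(128L, 128L), n_frames = 8L,
                              psf_sigma = 2, noise = noise_params(),
                              pixel_size = 110, frame_interval = 5,
                              seed = 1L) {
  stopifnot(front_speed > 0, lag_amplitude >= 0, lag_wavelength > 0,
            n_frames >= 2L)
  if (2 * pi * lag_amplitude / lag_wavelength >= 1.5) {
    stop("lag amplitude/wavelength would create an overhanging (self-intersecting) front")
  }
  if (lag_amplitude / lag_tau >= front_speed) {
    stop("lag develops faster than the front advances (retreating columns)")
  }
  ny <- dim[1]; nx <- dim[2]
  if (is.null(y0)) y0 <- 0.75 * ny
  front_at <- function(x, t) {
    y0 - front_speed * (t - 1) -
      lag_amplitude * (1 - exp(-(t - 1) / lag_tau)) * sin(2 * pi * x / lag_wavelength)
  }
  yf_min <- min(front_at(0:(nx - 1), n_frames))
  if (yf_min < 6 || max(front_at(0:(nx - 1), 1)) > ny - 3) {
    stop("front leaves the field of view; reduce n_frames or front_speed")
  }
  xs <- 0:(nx - 1)
  arr <- array(0, c(ny, nx, 2L, n_frames))
  rows <- vector("list", n_frames)
  yy <- matrix(rep(0:(ny - 1), nx), ny)
  for (t in seq_len(n_frames)) {
    yf <- front_at(xs, t)
    cell <- (yy >= matrix(rep(yf, each = ny), ny)) * 1
    v_true <- front_speed + (lag_amplitude / lag_tau) * exp(-(t - 1) / lag_tau) *
      sin(2 * pi * xs / lag_wavelength)
    slope <- -lag_amplitude * (1 - exp(-(t - 1) / lag_tau)) *
      (2 * pi / lag_wavelength) * cos(2 * pi * xs / lag_wavelength)
    dep <- (c0 + coupling * v_true) * sqrt(1 + slope^2)
    arr[, , 1, t] <- cell * membrane_density
    arr[, , 2, t] <- deposit_points(cell * cytosol_level, xs, yf, dep)
    rows[[t]] <- data.frame(frame = t, x = xs, y_front = yf,
                            v_true = v_true, deposit_rate = c0 + coupling * v_true)
  }
  arr <- blur_array(arr, psf_sigma, noise$background)
  arr <- noise_array(arr, noise, seed)
  stack <- image_stack(arr, pixel_size = pixel_size,
                       frame_interval = frame_interval,
                       channel_names = c("membrane", "probe"))
  truth <- structure(list(type = "leading_edge", seed = as.integer(seed),
                          params = list(front_speed = front_speed,
                                        lag_wavelength = lag_wavelength,
                                        lag_amplitude = lag_amplitude,
                                        lag_tau = lag_tau, coupling = coupling,
                                        c0 = c0, y0 = y0, dim = dim,
                                        psf_sigma = psf_sigma, noise = noise),
                          table = do.call(rbind, rows)),
                     class = "GroundTruth")
  list(stack = stack, truth = truth)
}

#' Synthetic field of annular nanorings
#'
#' Places `n_rings` non-overlapping annuli ("rings") of known center-line
#' diameter (drawn from a normal distribution, in nm) at random positions,
#' rasterizes each as a band of pixels within `thickness / 2` of the
#' center-line circle, and applies the PSF/noise model. The truth table
#' lists the exact diameter of every ring.
#'
#' @param n_rings number of rings.
#' @param diameter_mean,diameter_sd center-line diameter distribution (nm).
#' @param thickness radial ring thickness (px).
#' @param ring_intensity deposited intensity of ring pixels.
#' @param pixel_size nm/px.
#' @param dim image dimensions `c(Y, X)`.
#' @param min_gap minimum gap between ring outer edges (px).
#' @param psf_sigma,noise,seed as in [make_closing_tem()].
#' @return list with `stack` (single channel `rings`, single frame) and
#'   `truth` (truth table: ring, x, y, radius_px, diameter_nm).
#' @export
make_ring_field <- function(n_rings = 25L, diameter_mean = 230,
                            diameter_sd = 25, thickness = 2,
                            ring_intensity = 150, pixel_size = 23,
                            dim = c(256L, 256L), min_gap = 4,
                            psf_sigma = 2, noise = noise_params(),
                            seed = 1L) {
  stopifnot(n_rings >= 1L, diameter_mean >= 4 * pixel_size, thickness > 0)
  ny <- dim[1]; nx <- dim[2]
  placement <- with_seed(substream_seed(seed, "placement"), {
    d_nm <- stats::rnorm(n_rings, diameter_mean, diameter_sd)
    d_nm <- pmax(d_nm, 4 * pixel_size)
    r_px <- d_nm / 2 / pixel_size
    cx <- numeric(0); cy <- numeric(0); rr <- numeric(0); dd <- numeric(0)
    tries <- 0L
    for (i in seq_len(n_rings)) {
      repeat {
        tries <- tries + 1L
        if (tries > 2000L * n_rings) {
          stop("field too small to place the requested rings without overlap")
        }
        margin <- r_px[i] + thickness / 2 + psf_sigma + 2
        x <- stats::runif(1, margin, nx - 1 - margin)
        y <- stats::runif(1, margin, ny - 1 - margin)
        if (length(cx) == 0L ||
            all(sqrt((cx - x)^2 + (cy - y)^2) >
                rr + r_px[i] + thickness + min_gap)) break
      }
      cx <- c(cx, x); cy <- c(cy, y); rr <- c(rr, r_px[i]); dd <- c(dd, d_nm[i])
    }
    data.frame(ring = seq_len(n_rings), x = cx, y = cy,
               radius_px = rr, diameter_nm = dd)
  })
  img <- matrix(0, ny, nx)
  xg <- matrix(rep(0:(nx - 1), each = ny), ny)
  yg <- matrix(rep(0:(ny - 1), nx), ny)
  for (i in seq_len(n_rings)) {
    R <- sqrt((xg - placement$x[i])^2 + (yg - placement$y[i])^2)
    img[abs(R - placement$radius_px[i]) <= thickness / 2] <- ring_intensity
  }
  arr <- array(img, c(ny, nx, 1L, 1L))
  arr <- blur_array(arr, psf_sigma, noise$background)
  arr <- noise_array(arr, noise, seed)
  stack <- image_stack(arr, pixel_size = pixel_size, frame_interval = 1,
                       channel_names = "rings")
  truth <- structure(list(type = "ring_field", seed = as.integer(seed),
                          params = list(n_rings = n_rings,
                                        diameter_mean = diameter_mean,
                                        diameter_sd = diameter_sd,
                                        thickness = thickness,
                                        ring_intensity = ring_intensity,
                                        pixel_size = pixel_size, dim = dim,
                                        psf_sigma = psf_sigma, noise = noise),
                          table = placement),
                     class = "GroundTruth")
  list(stack = stack, truth = truth)
}
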