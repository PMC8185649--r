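#' Signed osculating-circle curvature along a boundary
#'
#' At each boundary point P the unique circle through P and the two points
#' `S` indices before and after it (periodic indexing on the equal-arc
#' resampled contour) approximates the osculating circle; curvature is the
#' inverse of its radius. The sign is positive when the circle's center lies
#' on the outward (non-region) side of the boundary: a circular hole inside
#' a cell has kappa > 0 everywhere, a convex cell bulge kappa < 0.
#'
#' @param b a [boundary()] satisfying the interior-left orientation contract.
#' @param S index offset of the flanking points (`1 <= S < N/2`). Typical
#'   values: 10 for TEM holes, 44 for a migrating-cell edge, both on a
#'   1000-point contour.
#' @param region_mask optional region mask used to (re-)establish the
#'   boundary orientation before signing.
#' @return numeric vector of signed curvature (1/px); exactly collinear
#'   triplets yield 0.
#' @export
signed_curvature <- function(b, S, region_mask = NULL) {
  n <- b$n
  stopifnot(S >= 1, S < n / 2)
  if (!is.null(region_mask)) b <- orient_boundary(b, region_mask)
  i <- seq_len(n)
  ip <- mod1(i + S, n); im <- mod1(i - S, n)
  x1 <- b$x[im]; y1 <- b$y[im]
  x2 <- b$x[i];  y2 <- b$y[i]
  x3 <- b$x[ip]; y3 <- b$y[ip]
  # circumcenter of (P1, P2, P3) relative to P2
  bx <- x1 - x2; by <- y1 - y2
  cx <- x3 - x2; cy <- y3 - y2
  d <- 2 * (bx * cy - by * cx)
  b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  degenerate <- abs(d) < 1e-12 * (b2 + c2 + 1e-300)
  dd <- ifelse(degenerate, 1, d)
  ux <- (cy * b2 - by * c2) / dd
  uy <- (bx * c2 - cx * b2) / dd
  r <- sqrt(ux^2 + uy^2)
  # outward normal = rightward perpendicular of the chord P1 -> P3
  tx <- x3 - x1; ty <- y3 - y1
  s <- sign(ux * ty - uy * tx)   # (center - P) . (ty, -tx)
  kappa <- ifelse(degenerate | r == 0, 0, s / r)
  kappa
}

#' Edge velocity from signed distance transforms
#'
#' The normal velocity of the region edge at each boundary point of frame t
#' is estimated as the central difference of the inside-positive signed
#' Euclidean distance transforms of the masks at frames t-1 and t+1,
#' interpolated bilinearly at the sub-pixel boundary coordinates:
#' `v(P) = (sdt_next(P) - sdt_prev(P)) / 2` px/frame. Positive values mean
#' the edge is advancing (cell protruding, hole closing). The literal
#' average `(sdt_next(P) + sdt_prev(P)) / 2` is available for comparison as
#' `method = "average"` but is ~0 for steady motion.
#'
#' @param b a [boundary()] at frame t.
#' @param mask_prev,mask_next region masks at frames t-1 and t+1.
#' @param method `"central"` (default) or `"average"`.
#' @return numeric vector, px/frame.
#' @export
edge_velocity <- function(b, mask_prev, mask_next,
                          method = c("central", "average")) {
  method <- match.arg(method)
  stopifnot(all(dim(mask_prev) == dim(mask_next)))
  if (any(b$x < -1) || any(b$x > ncol(mask_prev)) ||
      any(b$y < -1) || any(b$y > nrow(mask_prev))) {
    stop("boundary points fall outside the mask bounding box")
  }
  sp <- signed_distance(mask_prev)
  sn <- signed_distance(mask_next)
  vp <- bilinear_interp(sp, b$x, b$y)
  vn <- bilinear_interp(sn, b$x, b$y)
  if (method == "central") (vn - vp) / 2 else (vn + vp) / 2
}

#' Convert an edge velocity from px/frame to um/min
#' @param v velocity in px/frame.
#' @param pixel_size nm per px.
#' @param frame_interval seconds per frame.
#' @export
velocity_um_min <- function(v, pixel_size, frame_interval) {
  v * (pixel_size / 1000) * (60 / frame_interval)
}

#' Bin samples by angle around a center
#'
#' Assigns each sample the angle `atan2(y - cy, x - cx)` (degrees, taken
#' modulo 360) and averages values within equal-width bins partitioning
#' `[0, 360)`. Empty bins are reported as `NA`, never zero.
#'
#' @param x,y sample coordinates (0-based px).
#' @param value sample values.
#' @param center `(x, y)` of the angular origin.
#' @param n_bins number of bins (>= 2); 50 gives the 7.2 degree TEM binning,
#'   1000 the migrating-cell binning.
#' @return data.frame with `bin` (1-based), `theta` (bin center, degrees),
#'   `mean`, `n`.
#' @export
angular_profile <- function(x, y, value, center, n_bins = 50L) {
  stopifnot(n_bins >= 2L, length(x) == length(y), length(x) == length(value))
  width <- 360 / n_bins
  theta <- (atan2(y - center[2], x - center[1]) * 180 / pi) %% 360
  bin <- pmin(floor(theta / width), n_bins - 1L) + 1L
  ok <- is.finite(value)
  means <- rep(NA_real_, n_bins)
  counts <- integer(n_bins)
  if (any(ok)) {
    agg <- tapply(value[ok], bin[ok], mean)
    means[as.integer(names(agg))] <- as.numeric(agg)
    cnt <- table(bin[ok])
    counts[as.integer(names(cnt))] <- as.integer(cnt)
  }
  if (sum(counts > 0L) == 1L && n_bins > 1L) {
    warning("all samples fall into a single angular bin (degenerate geometry)")
  }
  data.frame(bin = seq_len(n_bins), theta = (seq_len(n_bins) - 0.5) * width,
             mean = means, n = counts)
}

#' Fit a circle to points
#'
#' Exactly three points give the circumscribed circle; more points give the
#' algebraic (Kasa) least-squares circle. Collinear input is flagged
#' degenerate with zero curvature (infinite radius).
#'
#' @param x,y coordinates (>= 3 points).
#' @return list with `center` `(x, y)`, `radius`, `kappa = 1/radius`, and
#'   logical `degenerate`.
#' @export
fit_circle <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  n <- length(x)
  if (n == 3L) {
    bx <- x[1] - x[2]; by <- y[1] - y[2]
    cx <- x[3] - x[2]; cy <- y[3] - y[2]
    d <- 2 * (bx * cy - by * cx)
    scale <- bx^2 + by^2 + cx^2 + cy^2
    if (abs(d) < 1e-12 * (scale + 1e-300)) {
      return(list(center = c(NA_real_, NA_real_), radius = Inf, kappa = 0,
                  degenerate = TRUE))
    }
    b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
    ux <- (cy * b2 - by * c2) / d
    uy <- (bx * c2 - cx * b2) / d
    center <- c(x[2] + ux, y[2] + uy)
    r <- sqrt(ux^2 + uy^2)
    return(list(center = center, radius = r, kappa = 1 / r, degenerate = FALSE))
  }
  A <- cbind(x, y, 1)
  rhs <- x^2 + y^2
  fit <- tryCatch(qr.solve(A, rhs), error = function(e) NULL)
  if (is.null(fit)) {
    return(list(center = c(NA_real_, NA_real_), radius = Inf, kappa = 0,
                degenerate = TRUE))
  }
  center <- c(fit[1] / 2, fit[2] / 2)
  r2 <- fit[3] + sum(center^2)
  if (!is.finite(r2) || r2 <= 0) {
    return(list(center = c(NA_real_, NA_real_), radius = Inf, kappa = 0,
                degenerate = TRUE))
  }
  r <- sqrt(r2)
  list(center = center, radius = r, kappa = 1 / r, degenerate = FALSE)
}

#' Equivalent-circle diameter from a perimeter
#'
#' Diameter of the perfect circle sharing the particle's perimeter:
#' `d = C / pi`, in whatever units `C` carries.
#'
#' @param C perimeter (> 0).
#' @export
ring_diameter <- function(C) {
  if (any(!is.finite(C) | C <= 0)) stop("perimeter must be positive")
  C / pi
}

#' Sub-pixel perimeter of a labelled particle
#'
#' Arc length of the smoothed 0.5 iso-level contour polygon of the particle.
#' `which = "centerline"` averages the outer and (largest) inner contour
#' lengths when the particle encloses a hole — the unbiased choice for
#' annular particles — and falls back to the outer contour otherwise.
#'
#' @param particle logical mask of a single particle (>= 8 px).
#' @param which `"outer"` or `"centerline"`.
#' @param smoothing arc-length smoothing sd in px for the contour; `NULL`
#'   uses the [extract_boundary()] default stiffness.
#' @return perimeter in px; attribute `has_hole` records whether an inner
#'   contour was found.
#' @export
contour_perimeter <- function(particle, which = c("outer", "centerline"),
                              smoothing = NULL) {
  which <- match.arg(which)
  m <- particle > 0
  if (sum(m) < 8L) stop("particle too small: need >= 8 pixels")
  if (any(m[1, ]) || any(m[nrow(m), ]) || any(m[, 1]) || any(m[, ncol(m)])) {
    warning("particle touches the image border; perimeter underestimated")
  }
  smooth_len <- function(poly) {
    b <- boundary(poly$x, poly$y)
    perim <- boundary_length(b)
    np <- max(256L, min(2000L, round(4 * perim)))
    b <- resample_boundary(b, np)
    sm <- if (is.null(smoothing)) min(3, max(0.5, 0.0055 * perim)) else smoothing
    if (sm > 0) {
      b <- boundary(circular_smooth(b$x, sm * np / perim),
                    circular_smooth(b$y, sm * np / perim))
    }
    boundary_length(b)
  }
  conts <- iso_contours(m)
  inside <- vapply(conts, function(p) contour_interior_value(m, p), 0)
  areas <- vapply(conts, function(p) abs(polygon_area(p)), 0)
  outer_i <- which(inside > 0.5)
  if (length(outer_i) == 0L) stop("no outer contour found")
  outer_i <- outer_i[which.max(areas[outer_i])]
  C <- smooth_len(conts[[outer_i]])
  hole_i <- which(inside < 0.5)
  has_hole <- length(hole_i) > 0L
  if (which == "centerline" && has_hole) {
    hole_i <- hole_i[which.max(areas[hole_i])]
    C <- (C + smooth_len(conts[[hole_i]])) / 2
  }
  attr(C, "has_hole") <- has_hole
  C
}
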