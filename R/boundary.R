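#' Ordered closed boundary of a segmented region
#'
#' A `Boundary` is a closed polyline of `N` points in 0-based pixel
#' coordinates (x = column, y = row, y increasing downward), approximately
#' equally spaced in arc length, traversed so that the segmented region's
#' interior lies to the LEFT of the direction of travel. With the left
#' perpendicular of a direction `(dx, dy)` defined as `(-dy, dx)`, the
#' outward normal is the rightward perpendicular `(dy, -dx)`. Under this
#' contract a circular hole in a cell carries positive signed curvature and
#' the outer rim of a convex cell carries negative signed curvature.
#'
#' @param x,y numeric coordinates of the closed polyline (the closing edge
#'   from the last point back to the first is implicit).
#' @param frame 1-based frame index the boundary belongs to.
#' @param role one of `"outer"` or `"hole"` (informational).
#' @return an object of class `Boundary`.
#' @export
boundary <- function(x, y, frame = 1L, role = "outer") {
  stopifnot(length(x) == length(y), length(x) >= 3L,
            all(is.finite(x)), all(is.finite(y)))
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 frame = as.integer(frame), n = length(x), role = role),
            class = "Boundary")
}

#' @export
print.Boundary <- function(x, ...) {
  cat(sprintf("Boundary (%s): %d points, frame %d, perimeter %.2f px\n",
              x$role, x$n, x$frame, boundary_length(x)))
  invisible(x)
}

#' Arc length of a closed boundary polyline
#' @param b a `Boundary`.
#' @return perimeter in px.
#' @export
boundary_length <- function(b) {
  dx <- diff(c(b$x, b$x[1])); dy <- diff(c(b$y, b$y[1]))
  sum(sqrt(dx^2 + dy^2))
}

#' Analytic circular boundary
#'
#' Constructs an exact circle resampled to `n` points with the orientation
#' demanded by the `Boundary` contract: counter-clockwise (in x/y algebra)
#' for the outer rim of a disk-shaped region, clockwise for a circular hole
#' whose region lies outside the circle.
#'
#' @param center numeric `(x, y)` in 0-based px.
#' @param radius radius in px.
#' @param n number of points.
#' @param role `"outer"` (region = disk) or `"hole"` (region outside).
#' @param frame frame index.
#' @return a `Boundary`.
#' @export
circle_boundary <- function(center, radius, n = 1000L,
                            role = c("outer", "hole"), frame = 1L) {
  role <- match.arg(role)
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  if (role == "hole") th <- rev(th)
  boundary(center[1] + radius * cos(th), center[2] + radius * sin(th),
           frame = frame, role = role)
}

#' Resample a boundary to equal arc-length spacing
#' @param b a `Boundary`.
#' @param n target number of points.
#' @return a `Boundary` with `n` points.
#' @export
resample_boundary <- function(b, n) {
  xs <- c(b$x, b$x[1]); ys <- c(b$y, b$y[1])
  seg <- sqrt(diff(xs)^2 + diff(ys)^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  keep <- c(TRUE, seg > 1e-12)  # drop coincident points
  xs <- xs[keep]; ys <- ys[keep]; s <- s[keep]
  target <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  boundary(stats::approx(s, xs, xout = target, rule = 2)$y,
           stats::approx(s, ys, xout = target, rule = 2)$y,
           frame = b$frame, role = b$role)
}

#' Enforce the interior-left orientation contract against a mask
#'
#' Samples the mask a fixed offset to the left of the traversal direction at
#' every point; if the majority of samples fall outside the region the
#' traversal is reversed.
#'
#' @param b a `Boundary`.
#' @param mask logical region mask the boundary delineates.
#' @param offset sampling offset in px.
#' @return a `Boundary` satisfying the contract.
#' @export
orient_boundary <- function(b, mask, offset = 2) {
  frac <- interior_left_fraction(b, mask, offset)
  if (frac < 0.5) {
    b <- boundary(rev(b$x), rev(b$y), frame = b$frame, role = b$role)
  }
  b
}

# fraction of points whose leftward offset lands inside the mask
interior_left_fraction <- function(b, mask, offset = 2) {
  n <- b$n
  ip <- mod1(seq_len(n) + 1L, n); im <- mod1(seq_len(n) - 1L, n)
  dx <- b$x[ip] - b$x[im]; dy <- b$y[ip] - b$y[im]
  len <- sqrt(dx^2 + dy^2); len[len == 0] <- 1
  lx <- b$x - offset * dy / len   # left perpendicular of (dx, dy) is (-dy, dx)
  ly <- b$y + offset * dx / len
  xi <- round(lx) + 1L; yi <- round(ly) + 1L
  ok <- xi >= 1L & xi <= ncol(mask) & yi >= 1L & yi <= nrow(mask)
  if (!any(ok)) return(0)
  mean(mask[cbind(yi[ok], xi[ok])] > 0)
}

#' Outward normals of a boundary
#'
#' Rightward perpendicular of the central-difference tangent; under the
#' orientation contract this points away from the segmented region.
#'
#' @param b a `Boundary`.
#' @return `n x 2` matrix of unit normals `(nx, ny)`.
#' @export
boundary_normals <- function(b) {
  n <- b$n
  ip <- mod1(seq_len(n) + 1L, n); im <- mod1(seq_len(n) - 1L, n)
  dx <- b$x[ip] - b$x[im]; dy <- b$y[ip] - b$y[im]
  len <- sqrt(dx^2 + dy^2); len[len == 0] <- 1
  cbind(nx = dy / len, ny = -dx / len)
}
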