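#' Sub-pixel iso-contours of a binary mask
#'
#' Traces the 0.5 iso-level of a (0-padded) binary mask by marching squares
#' with bilinear interpolation, yielding closed sub-pixel polylines in
#' 0-based pixel-center coordinates.
#'
#' @param mask logical or 0/1 matrix.
#' @param level iso level (default 0.5).
#' @return list of data.frames with columns `x`, `y`.
#' @keywords internal
iso_contours <- function(mask, level = 0.5) {
  m <- (mask > 0) * 1
  ny <- nrow(m); nx <- ncol(m)
  z <- matrix(0, ny + 2L, nx + 2L)
  z[2:(ny + 1L), 2:(nx + 1L)] <- m
  # contourLines: first index of z runs along its `x` argument -> our rows (y)
  cl <- grDevices::contourLines(x = (-1):ny, y = (-1):nx, z = z, levels = level)
  lapply(cl, function(cc) data.frame(x = cc$y, y = cc$x))
}

# shoelace area of a closed polygon (positive for one traversal sense)
polygon_area <- function(p) {
  x <- p$x; y <- p$y
  n <- length(x)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# even-odd ray-casting point-in-polygon test
point_in_polygon <- function(px, py, poly) {
  x <- poly$x; y <- poly$y
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  crossing <- ((y > py) != (y[j] > py)) &
    (px < (x[j] - x) * (py - y) / (y[j] - y) + x)
  sum(crossing) %% 2L == 1L
}

# mask value (0/1) just inside a closed contour: sample a short normal
# offset on whichever side lies inside the polygon, voting over vertices
contour_interior_value <- function(mask, poly) {
  n <- nrow(poly)
  idx <- unique(round(seq(1, n, length.out = min(12L, n))))
  votes <- numeric(0)
  for (i in idx) {
    ip <- if (i == n) 1L else i + 1L
    im <- if (i == 1L) n else i - 1L
    tx <- poly$x[ip] - poly$x[im]; ty <- poly$y[ip] - poly$y[im]
    len <- sqrt(tx^2 + ty^2)
    if (len == 0) next
    nx <- -ty / len; ny <- tx / len
    for (s in c(0.71, -0.71)) {
      px <- poly$x[i] + s * nx; py <- poly$y[i] + s * ny
      if (point_in_polygon(px, py, poly)) {
        xi <- round(px) + 1L; yi <- round(py) + 1L
        if (xi >= 1L && xi <= ncol(mask) && yi >= 1L && yi <= nrow(mask)) {
          votes <- c(votes, as.numeric(mask[yi, xi] > 0))
        }
        break
      }
    }
  }
  if (length(votes) == 0L) return(0)
  as.numeric(mean(votes) >= 0.5)
}

#' Segment the main region of a fluorescence frame
#'
#' Three-step classical segmentation: Gaussian smoothing, intensity
#' thresholding (fixed or per-frame Otsu), and binary erosion with a disc
#' structuring element. The largest connected component is returned with its
#' interior holes preserved, so closing macroapertures remain detectable.
#'
#' @param frame nonnegative numeric matrix.
#' @param smoothing_sigma Gaussian smoothing sd in px (0 disables).
#' @param threshold numeric intensity threshold, or `"otsu"` for an automatic
#'   per-frame threshold.
#' @param erosion_radius disc radius in px for binary erosion (0 disables;
#'   the default, appropriate when the threshold already places the binary
#'   edge at the apparent membrane edge).
#' @return logical mask of class `BinaryMask` with attribute `role = "cell"`.
#' @export
segment_region <- function(frame, smoothing_sigma = 2, threshold = "otsu",
                           erosion_radius = 0) {
  stopifnot(all(frame >= 0), erosion_radius >= 0)
  sm <- if (smoothing_sigma > 0) blur_gaussian(frame, smoothing_sigma) else frame
  thr <- if (identical(threshold, "otsu")) otsu_threshold(sm) else threshold
  m <- sm > thr
  if (!any(m)) stop("no region found: threshold removed every pixel")
  if (erosion_radius >= 1) {
    m <- matrix(as.numeric(EBImage::erode(m * 1, disc_brush(erosion_radius))) > 0.5,
                nrow = nrow(m))
    if (!any(m)) stop("no region found: erosion removed every pixel")
  }
  out <- largest_component(m)
  attr(out, "role") <- "cell"
  class(out) <- c("BinaryMask", class(out))
  out
}

#' Hole mask of a segmented region
#'
#' Pixels enclosed by the region but not part of it (e.g. a transendothelial
#' macroaperture inside a cell mask).
#'
#' @param mask logical region mask.
#' @return logical mask of the largest hole (`role = "tem_hole"`); all-FALSE
#'   if the region is simply connected.
#' @export
hole_mask <- function(mask) {
  h <- fill_holes(mask) & !mask
  out <- if (any(h)) largest_component(h) else h
  attr(out, "role") <- "tem_hole"
  class(out) <- c("BinaryMask", class(out))
  out
}

#' Extract a spline-smoothed, equally spaced sub-pixel boundary
#'
#' Traces the 0.5 iso-level contour of the mask, smooths the closed polyline
#' with a periodic Gaussian smoother acting in arc length (stiffness
#' proportional to contour length), resamples to `n_points` at equal arc
#' length, and orients it so the region interior lies to the left of travel.
#'
#' @param mask logical region mask.
#' @param n_points number of resampled points (default 1000).
#' @param which `"outer"` for the region's outer rim, `"hole"` for the
#'   boundary of an interior hole.
#' @param smoothing arc-length smoothing sd in px; `NULL` uses
#'   `smoothing_scale * perimeter` clamped to `[0.5, 3]` px.
#' @param smoothing_scale proportionality constant for the default stiffness.
#' @param anchor optional `(x, y)` picking the hole nearest that point when
#'   several exist (largest hole otherwise).
#' @return a [boundary()].
#' @export
extract_boundary <- function(mask, n_points = 1000L,
                             which = c("outer", "hole"),
                             smoothing = NULL, smoothing_scale = 0.004,
                             anchor = NULL) {
  which <- match.arg(which)
  stopifnot(n_points >= 8L)
  conts <- iso_contours(mask)
  if (length(conts) == 0L) stop("mask has no contour")
  inside <- vapply(conts, function(p) contour_interior_value(mask, p), 0)
  areas <- vapply(conts, function(p) abs(polygon_area(p)), 0)
  if (which == "outer") {
    cand <- which(inside > 0.5)
    if (length(cand) == 0L) stop("no outer contour found")
    poly <- conts[[cand[which.max(areas[cand])]]]
  } else {
    cand <- which(inside < 0.5)
    if (length(cand) == 0L) stop("mask is simply connected: no hole to trace")
    if (!is.null(anchor)) {
      d <- vapply(cand, function(i) {
        (mean(conts[[i]]$x) - anchor[1])^2 + (mean(conts[[i]]$y) - anchor[2])^2
      }, 0)
      poly <- conts[[cand[which.min(d)]]]
    } else {
      poly <- conts[[cand[which.max(areas[cand])]]]
    }
  }
  b <- boundary(poly$x, poly$y, role = which)
  # dense equal-arc resampling, periodic smoothing, final resampling
  perim <- boundary_length(b)
  m <- max(1024L, 4L * n_points)
  b <- resample_boundary(b, m)
  if (is.null(smoothing)) smoothing <- min(12, max(0.5, smoothing_scale * perim))
  if (smoothing > 0) {
    sd_samples <- smoothing * m / perim
    b <- boundary(circular_smooth(b$x, sd_samples),
                  circular_smooth(b$y, sd_samples), role = which)
  }
  b <- resample_boundary(b, n_points)
  orient_boundary(b, mask)
}

#' Concentric doughnut masks around a TEM hole
#'
#' Signal band: dilation of the hole mask by `d1` px minus the hole.
#' Background band: dilation of the signal's outer edge by a further `d2` px
#' minus the first dilation. Dilations use a Euclidean disc. Bands are
#' disjoint from each other and from the hole by construction; pixels falling
#' outside a supplied cell mask are clipped with a warning.
#'
#' @param tem_mask logical hole mask.
#' @param d1,d2 dilation radii in px (>= 1).
#' @param cell_mask optional logical cell mask to clip the bands to.
#' @return list with logical masks `signal` and `background` and the integer
#'   count of clipped pixels as attribute `clipped`.
#' @export
make_doughnuts <- function(tem_mask, d1 = 3, d2 = 3, cell_mask = NULL) {
  if (d1 < 1 || d2 < 1) stop("dilation radii d1 and d2 must be >= 1 px")
  tem <- tem_mask > 0
  dil1 <- euclidean_dilate(tem, d1)
  dil2 <- euclidean_dilate(dil1, d2)
  signal <- dil1 & !tem
  background <- dil2 & !dil1
  clipped <- 0L
  if (!is.null(cell_mask)) {
    cm <- cell_mask > 0
    clipped <- sum(signal & !cm) + sum(background & !cm)
    if (clipped > 0L) {
      warning(sprintf("doughnut bands clipped to cell mask: %d px removed",
                      clipped))
      signal <- signal & cm
      background <- background & cm
    }
  }
  out <- list(signal = signal, background = background)
  attr(out, "clipped") <- clipped
  out
}

#' Band of pixels within a fixed distance of a boundary polyline
#'
#' Expands a boundary symmetrically in both directions, producing the
#' ring-shaped region used to read fluorescence along the membrane edge.
#'
#' @param boundary a [boundary()].
#' @param half_width band half-width in px (>= 1).
#' @param dim image dimensions `c(Y, X)`.
#' @return logical mask.
#' @export
boundary_band <- function(boundary, half_width, dim) {
  stopifnot(half_width >= 1)
  # coarse candidate set from the rasterized polyline, then exact sub-pixel
  # distances to the (densely resampled) polyline vertices
  b <- resample_boundary(boundary,
                         max(512L, ceiling(4 * boundary_length(boundary))))
  bm <- matrix(0, dim[1], dim[2])
  xi <- pmin(pmax(round(b$x) + 1L, 1L), dim[2])
  yi <- pmin(pmax(round(b$y) + 1L, 1L), dim[1])
  bm[cbind(yi, xi)] <- 1
  coarse <- matrix(as.numeric(EBImage::distmap(1 - bm)), nrow = dim[1])
  cand <- which(coarse <= half_width + 1.5)
  out <- matrix(FALSE, dim[1], dim[2])
  if (length(cand) == 0L) return(out)
  px <- ceiling(cand / dim[1]) - 1
  py <- (cand - 1) %% dim[1]
  hw2 <- half_width^2
  chunk <- 2048L
  keep <- logical(length(cand))
  for (s in seq(1, length(cand), by = chunk)) {
    e <- min(s + chunk - 1L, length(cand))
    dx <- outer(px[s:e], b$x, "-")
    dy <- outer(py[s:e], b$y, "-")
    d2 <- dx * dx + dy * dy
    mins <- d2[cbind(seq_len(nrow(d2)), max.col(-d2, ties.method = "first"))]
    keep[s:e] <- mins <= hw2
  }
  out[cand[keep]] <- TRUE
  out
}

#' Detect candidate ring particles in a single frame
#'
#' Rolling-ball style background subtraction (grayscale white top-hat with a
#' disc), thresholding, connected-component labelling and an area filter.
#'
#' @param frame nonnegative numeric matrix.
#' @param background_radius disc radius in px for the top-hat background.
#' @param threshold numeric, or `"otsu"` on the background-subtracted frame.
#' @param min_area,max_area particle area bounds in px^2.
#' @return integer label matrix (0 = background), labels `1..K`; the
#'   background-subtracted frame is attached as attribute `corrected`.
#' @export
segment_rings <- function(frame, background_radius = 8, threshold = "otsu",
                          min_area = 10, max_area = Inf) {
  stopifnot(all(frame >= 0))
  th <- EBImage::whiteTopHat(EBImage::Image(frame),
                             disc_brush(background_radius))
  corrected <- matrix(pmax(as.numeric(th), 0), nrow = nrow(frame))
  thr <- if (identical(threshold, "otsu")) otsu_threshold(corrected) else threshold
  m <- corrected > thr
  lab <- matrix(as.integer(EBImage::bwlabel(m * 1)), nrow = nrow(frame))
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_area & sizes <= max_area)
    relab <- integer(max(lab))
    relab[keep] <- seq_along(keep)
    lab[lab > 0L] <- relab[lab[lab > 0L]]
  }
  attr(lab, "corrected") <- corrected
  lab
}
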