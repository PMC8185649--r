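#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state so
#' seeded generators never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a named substream seed from a master seed
#'
#' One master seed spawns independent named substreams (e.g. "placement",
#' "poisson", "read") so that toggling one noise source does not shift the
#' draws of another. Result always lies in [1, 2^31 - 2].
#'
#' @param seed master integer seed.
#' @param name substream name.
#' @return integer seed.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.character(name), length(name) == 1L)
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 1000003
  as.integer((abs(as.numeric(seed)) * 100003 + h * 7919 + 13) %% 2147483645 + 1)
}

#' Unit-sum isotropic Gaussian kernel
#' @param sigma standard deviation in px.
#' @return square matrix summing to 1.
#' @keywords internal
gaussian_kernel <- function(sigma) {
  stopifnot(sigma > 0)
  half <- max(1L, ceiling(3 * sigma))
  ax <- (-half):half
  k <- outer(exp(-ax^2 / (2 * sigma^2)), exp(-ax^2 / (2 * sigma^2)))
  k / sum(k)
}

#' Gaussian blur with a unit-sum kernel
#'
#' Convolution via FFT with circular boundary, so the total intensity of the
#' field is conserved exactly (photon budget).
#'
#' @param img numeric matrix.
#' @param sigma PSF standard deviation in px; `sigma <= 0` returns `img`.
#' @return blurred matrix of the same dimensions.
#' @export
blur_gaussian <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel(sigma)
  out <- EBImage::filter2(img, k, boundary = "circular")
  matrix(as.numeric(out), nrow = nrow(img))
}

#' Bilinear interpolation at sub-pixel coordinates
#'
#' @param img numeric matrix indexed `[y + 1, x + 1]`.
#' @param x,y 0-based coordinates (x = column, y = row).
#' @return interpolated values; coordinates are clamped to the image.
#' @keywords internal
bilinear_interp <- function(img, x, y) {
  ny <- nrow(img); nx <- ncol(img)
  x <- pmin(pmax(x, 0), nx - 1)
  y <- pmin(pmax(y, 0), ny - 1)
  x0 <- pmin(floor(x), nx - 2); x1 <- x0 + 1
  y0 <- pmin(floor(y), ny - 2); y1 <- y0 + 1
  fx <- x - x0; fy <- y - y0
  img[cbind(y0 + 1, x0 + 1)] * (1 - fx) * (1 - fy) +
    img[cbind(y0 + 1, x1 + 1)] * fx * (1 - fy) +
    img[cbind(y1 + 1, x0 + 1)] * (1 - fx) * fy +
    img[cbind(y1 + 1, x1 + 1)] * fx * fy
}

#' Otsu threshold of a nonnegative image
#' @param img numeric matrix.
#' @return threshold on the intensity scale of `img`.
#' @keywords internal
otsu_threshold <- function(img) {
  hi <- max(img)
  if (hi <= 0) return(0)
  hi * EBImage::otsu(EBImage::Image(img / hi), range = c(0, 1), levels = 256)
}

#' Disc structuring element of a given radius
#' @param r radius in px (>= 1).
#' @keywords internal
disc_brush <- function(r) {
  r <- as.integer(round(r))
  stopifnot(r >= 1)
  EBImage::makeBrush(2L * r + 1L, shape = "disc")
}

#' Largest connected component of a binary mask
#' @param mask logical or 0/1 matrix.
#' @return logical matrix (all-FALSE if the mask is empty).
#' @keywords internal
largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow = nrow(mask))
  if (max(lab) == 0L) return(matrix(FALSE, nrow(mask), ncol(mask)))
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

#' Fill interior holes of a binary mask
#' @keywords internal
fill_holes <- function(mask) {
  out <- EBImage::fillHull(mask * 1)
  matrix(as.numeric(out) > 0.5, nrow = nrow(mask))
}

#' Signed Euclidean distance transform
#'
#' Positive inside the region, negative outside; magnitude is the Euclidean
#' distance to the nearest pixel of the opposite phase.
#'
#' @param mask logical or 0/1 matrix.
#' @return numeric matrix.
#' @export
signed_distance <- function(mask) {
  m <- (mask > 0) * 1
  din <- matrix(as.numeric(EBImage::distmap(m)), nrow = nrow(m))
  dout <- matrix(as.numeric(EBImage::distmap(1 - m)), nrow = nrow(m))
  d <- din - dout
  # pixel-center distances overshoot the 0.5-level boundary by half a pixel
  # on each side; recentre so the zero level sits on the mask edge
  d - 0.5 * sign(d)
}

#' Binary dilation by an exact Euclidean disc
#'
#' A pixel belongs to the dilation iff its Euclidean distance to the mask is
#' at most `r` (computed via the distance transform, so the structuring
#' element is the true disc of radius `r`, not a rasterized approximation).
#'
#' @param mask logical or 0/1 matrix.
#' @param r disc radius in px.
#' @return logical matrix.
#' @export
euclidean_dilate <- function(mask, r) {
  m <- mask > 0
  if (!any(m)) return(m)
  d <- matrix(as.numeric(EBImage::distmap((1 - m) * 1)), nrow = nrow(m))
  m | (d <= r + 1e-4)  # distmap works in single precision
}

# circular (periodic) Gaussian smoothing of a numeric vector; sd in samples
circular_smooth <- function(v, sd_samples) {
  if (sd_samples <= 0) return(v)
  half <- max(1L, ceiling(4 * sd_samples))
  n <- length(v)
  half <- min(half, floor((n - 1) / 2))
  k <- exp(-((-half):half)^2 / (2 * sd_samples^2))
  k <- k / sum(k)
  as.numeric(stats::filter(v, k, method = "convolution", sides = 2, circular = TRUE))
}

# mod helper for 0-based circular indices
mod1 <- function(i, n) ((i - 1L) %% n) + 1L
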