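#' Noise parameters for the synthetic-microscopy generators
#'
#' The detection model applied to every synthetic channel: the deposited
#' intensity field is blurred by a unit-sum Gaussian PSF, a constant
#' background is added, shot noise is drawn as
#' `Poisson(intensity * poisson_scale) / poisson_scale`, Gaussian read noise
#' of sd `read_sd` is added, and the result is clamped at zero.
#'
#' @param poisson_scale photons per intensity unit; 0 disables shot noise.
#' @param read_sd Gaussian read-noise sd (intensity units); 0 disables.
#' @param background constant background level added before shot noise.
#' @return list of class `noise_params`.
#' @export
noise_params <- function(poisson_scale = 1, read_sd = 2, background = 5) {
  stopifnot(poisson_scale >= 0, read_sd >= 0, background >= 0)
  structure(list(poisson_scale = poisson_scale, read_sd = read_sd,
                 background = background), class = "noise_params")
}

# bilinear splatting of point deposits into an image (0-based coords)
deposit_points <- function(img, x, y, intensity) {
  ny <- nrow(img); nx <- ncol(img)
  x <- pmin(pmax(x, 0), nx - 1.001)
  y <- pmin(pmax(y, 0), ny - 1.001)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  lin <- c((x0) * ny + y0, (x0 + 1) * ny + y0,
           (x0) * ny + y0 + 1, (x0 + 1) * ny + y0 + 1) + 1
  w <- c(intensity * (1 - fx) * (1 - fy), intensity * fx * (1 - fy),
         intensity * (1 - fx) * fy, intensity * fx * fy)
  sums <- rowsum(w, lin)
  img[as.integer(rownames(sums))] <- img[as.integer(rownames(sums))] + sums[, 1]
  img
}

# PSF + background for a whole [Y,X,C,T] array (deterministic part)
blur_array <- function(arr, psf_sigma, background) {
  d <- dim(arr)
  for (t in seq_len(d[4])) for (c in seq_len(d[3])) {
    arr[, , c, t] <- blur_gaussian(arr[, , c, t], psf_sigma) + background
  }
  arr
}

# shot + read noise for a whole array, each from its own named substream
noise_array <- function(arr, noise, seed) {
  if (noise$poisson_scale > 0) {
    arr <- with_seed(substream_seed(seed, "poisson"), {
      v <- stats::rpois(length(arr), lambda = pmax(arr, 0) * noise$poisson_scale)
      array(v / noise$poisson_scale, dim(arr))
    })
  }
  if (noise$read_sd > 0) {
    arr <- with_seed(substream_seed(seed, "read"), {
      arr + array(stats::rnorm(length(arr), sd = noise$read_sd), dim(arr))
    })
  }
  pmax(arr, 0)
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat(sprintf("GroundTruth (%s): seed %d\n", x$type, x$seed))
  if (!is.null(x$table)) {
    cat(sprintf("  truth table: %d rows\n", nrow(x$table)))
  }
  invisible(x)
}

#' Write a ground-truth table and its parameters to disk
#'
#' @param truth a `GroundTruth`.
#' @param csv_path path for the tidy truth table CSV.
#' @param yaml_path optional path for the generator parameters.
#' @export
write_ground_truth <- function(truth, csv_path, yaml_path = NULL) {
  utils::write.csv(truth$table, csv_path, row.names = FALSE)
  if (!is.null(yaml_path)) {
    yaml::write_yaml(c(list(type = truth$type, seed = truth$seed),
                       lapply(truth$params, function(p) {
                         if (inherits(p, "noise_params")) unclass(p) else p
                       })), yaml_path)
  }
  invisible(csv_path)
}
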