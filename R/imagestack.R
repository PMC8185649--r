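#' Multichannel time-lapse image stack
#'
#' Container for a calibrated T-frame, C-channel intensity grid. Pixel data
#' are stored as a 4-D array indexed `[y, x, channel, frame]` with 0-based
#' (x = column, y = row, y increasing downward) coordinates used throughout
#' the package interfaces.
#'
#' @param data numeric array, either `[Y, X]` (single frame, single channel),
#'   `[Y, X, C]` (single frame) or `[Y, X, C, T]`. All intensities must be
#'   nonnegative and finite.
#' @param pixel_size physical size of one pixel in nm.
#' @param frame_interval time between frames in seconds.
#' @param channel_names character vector of length C, e.g.
#'   `c("membrane", "probe")`.
#' @return an object of class `ImageStack`.
#' @export
image_stack <- function(data, pixel_size, frame_interval = 1,
                        channel_names = NULL) {
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L, 1L)
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 4L)
  if (any(!is.finite(data)) || any(data < 0)) {
    stop("image intensities must be finite and nonnegative")
  }
  stopifnot(pixel_size > 0, frame_interval > 0)
  nc <- dim(data)[3]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  stopifnot(length(channel_names) == nc)
  dimnames(data) <- list(NULL, NULL, channel_names, NULL)
  structure(
    list(data = data, pixel_size = pixel_size,
         frame_interval = frame_interval, channel_names = channel_names),
    class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "ImageStack: %d frame(s) x %d channel(s) x %d x %d px\n", d[4], d[3], d[1], d[2]))
  cat(sprintf("  channels: %s\n", paste(x$channel_names, collapse = ", ")))
  cat(sprintf("  pixel size %.3g nm/px, frame interval %.3g s\n",
              x$pixel_size, x$frame_interval))
  invisible(x)
}

#' @export
dim.ImageStack <- function(x) dim(x$data)

#' Number of frames / channels of an [image_stack()]
#' @param stack an `ImageStack`.
#' @export
n_frames <- function(stack) dim(stack$data)[4]

#' @rdname n_frames
#' @export
n_channels <- function(stack) dim(stack$data)[3]

#' Extract one frame of one channel as a plain matrix
#'
#' @param stack an `ImageStack`.
#' @param frame 1-based frame index.
#' @param channel channel name or 1-based index.
#' @return numeric matrix `[Y, X]`.
#' @export
get_frame <- function(stack, frame = 1L, channel = 1L) {
  stopifnot(inherits(stack, "ImageStack"))
  if (is.character(channel)) {
    channel <- match(channel, stack$channel_names)
    if (is.na(channel)) stop("unknown channel name")
  }
  stopifnot(frame >= 1, frame <= n_frames(stack))
  stack$data[, , channel, frame]
}

#' Write an image stack as a 16-bit multi-page TIFF with a YAML sidecar
#'
#' Pages are ordered frame-major, channel-minor (page = (t-1)*C + c). The
#' intensity scale used for 16-bit quantisation and the physical calibration
#' are recorded in `<path>.yaml` so [read_image_stack()] can round-trip.
#'
#' @param stack an `ImageStack`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ImageStack"))
  d <- dim(stack$data)
  scale <- max(stack$data, 1e-12)
  pages <- vector("list", d[3] * d[4])
  for (t in seq_len(d[4])) for (c in seq_len(d[3])) {
    pages[[(t - 1) * d[3] + c]] <- stack$data[, , c, t] / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  side <- list(
    pixel_size_nm = stack$pixel_size,
    frame_interval_s = stack$frame_interval,
    channel_names = as.list(stack$channel_names),
    n_frames = d[4], n_channels = d[3],
    intensity_scale = scale)
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param path TIFF path; `<path>.yaml` must exist.
#' @return an `ImageStack`.
#' @export
read_image_stack <- function(path) {
  side_path <- paste0(path, ".yaml")
  if (!file.exists(side_path)) stop("missing sidecar YAML: ", side_path)
  side <- yaml::read_yaml(side_path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nt <- side$n_frames; nc <- side$n_channels
  stopifnot(length(pages) == nt * nc)
  d <- dim(pages[[1]])
  arr <- array(0, c(d[1], d[2], nc, nt))
  for (t in seq_len(nt)) for (c in seq_len(nc)) {
    arr[, , c, t] <- pages[[(t - 1) * nc + c]] * side$intensity_scale
  }
  image_stack(arr, pixel_size = side$pixel_size_nm,
              frame_interval = side$frame_interval_s,
              channel_names = unlist(side$channel_names))
}
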