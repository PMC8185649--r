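# shared fixtures built in code: rasterized shapes and brute-force oracles

raster_disk <- function(r, dim = 128L, center = NULL) {
  if (is.null(center)) center <- c((dim - 1) / 2, (dim - 1) / 2)
  xs <- matrix(rep(0:(dim - 1), each = dim), dim)
  ys <- matrix(rep(0:(dim - 1), dim), dim)
  ((xs - center[1])^2 + (ys - center[2])^2 <= r^2) * 1
}

# big cell disk with a circular hole of radius r_hole at the center
raster_cell_with_hole <- function(r_hole, r_cell = 57, dim = 128L) {
  m <- raster_disk(r_cell, dim)
  m * (1 - raster_disk(r_hole, dim))
}

# brute-force Euclidean distance of every pixel to a pixel set (small grids)
brute_distance_to <- function(mask) {
  dim <- dim(mask)
  idx <- which(mask > 0, arr.ind = TRUE)
  out <- matrix(Inf, dim[1], dim[2])
  for (y in seq_len(dim[1])) for (x in seq_len(dim[2])) {
    out[y, x] <- sqrt(min((idx[, 1] - y)^2 + (idx[, 2] - x)^2))
  }
  out
}

# scanline polygon rasterization (even-odd), 0-based pixel centers
rasterize_polygon <- function(px, py, dim) {
  out <- matrix(FALSE, dim[1], dim[2])
  n <- length(px)
  j <- c(n, seq_len(n - 1L))
  for (row in seq_len(dim[1])) {
    yc <- row - 1
    crossing <- which((py > yc) != (py[j] > yc))
    if (length(crossing) == 0L) next
    xs <- px[j][crossing] + (yc - py[j][crossing]) *
      (px[crossing] - px[j][crossing]) / (py[crossing] - py[j][crossing])
    xs <- sort(xs)
    for (k in seq(1, length(xs) - 1, by = 2)) {
      cols <- seq(ceiling(xs[k]), floor(xs[k + 1])) + 1L
      cols <- cols[cols >= 1 & cols <= dim[2]]
      out[row, cols] <- TRUE
    }
  }
  out
}

# exact circumcircle of three points (independent oracle for curvature)
circumcircle3 <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  list(center = c(ux, uy), radius = sqrt((ax - ux)^2 + (ay - uy)^2))
}
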