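test_that("three-point curvature agrees with an independent circumcircle oracle", {
  # ellipse sampled at its flat vertex; compare against the exact
  # circumscribed circle of the same three points
  a <- 60; b <- 30
  th <- seq(0, 2 * pi, length.out = 1001)[-1001]
  bd <- boundary(64 + a * cos(th), 64 + b * sin(th))  # CCW: region = ellipse
  S <- 25L
  kap <- signed_curvature(bd, S)
  for (i in c(1, 250, 433)) {
    n <- bd$n
    im <- ((i - 1 - S) %% n) + 1; ip <- ((i - 1 + S) %% n) + 1
    oracle <- circumcircle3(c(bd$x[im], bd$y[im]), c(bd$x[i], bd$y[i]),
                            c(bd$x[ip], bd$y[ip]))
    expect_equal(abs(kap[i]), 1 / oracle$radius, tolerance = 1e-9)
  }
  expect_true(all(kap < 0))  # convex region boundary
})

test_that("curvature is scale-equivariant and rigid-motion invariant", {
  b1 <- circle_boundary(c(0, 0), 20, 600, role = "outer")
  k1 <- signed_curvature(b1, 10)
  b2 <- boundary(b1$x * 3, b1$y * 3)
  expect_equal(signed_curvature(b2, 10), k1 / 3, tolerance = 1e-9)
  phi <- 0.7
  b3 <- boundary(cos(phi) * b1$x - sin(phi) * b1$y + 11,
                 sin(phi) * b1$x + cos(phi) * b1$y - 4)
  expect_equal(abs(signed_curvature(b3, 10)), abs(k1), tolerance = 1e-9)
})

test_that("collinear triplets give zero curvature without error", {
  sq <- boundary(c(0, 1, 2, 3, 3, 3, 3, 2, 1, 0, 0, 0),
                 c(0, 0, 0, 0, 1, 2, 3, 3, 3, 3, 2, 1))
  kap <- signed_curvature(sq, 1)
  expect_true(any(kap == 0))
  expect_true(all(is.finite(kap)))
})

test_that("edge velocity recovers a uniformly translating disk", {
  mk <- function(dx) raster_disk(25, 128, center = c(50 + dx, 63.5))
  b <- extract_boundary(mk(2), 500, "outer")
  v <- edge_velocity(b, mk(0), mk(4))
  nrm <- boundary_normals(b)
  # pointwise worst case sits at the tangent poles where the distance
  # transform is quantization-limited; the bulk of the boundary is tight
  expect_lt(stats::quantile(abs(v - 2 * nrm[, "nx"]), 0.95), 0.5)
  expect_lt(mean(abs(v - 2 * nrm[, "nx"])), 0.25)
  # the literal averaging variant is ~0 for steady translation
  v_avg <- edge_velocity(b, mk(0), mk(4), method = "average")
  expect_lt(mean(abs(v_avg)), 0.6)
  expect_lt(abs(mean(v_avg)), 0.3)
})

test_that("angular profiles bin correctly and flag degenerate input", {
  n <- 5000
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  prof <- angular_profile(cos(th), sin(th), cos(th), c(0, 0), 50)
  expect_equal(prof$theta[2] - prof$theta[1], 7.2)
  # analytic bin-averaged cosine
  edges <- seq(0, 2 * pi, length.out = 51)
  expected <- diff(sin(edges)) / diff(edges)
  expect_equal(prof$mean, expected, tolerance = 1e-3)

  const <- angular_profile(cos(th), sin(th), rep(3.5, n), c(0, 0), 20)
  expect_true(all(const$mean == 3.5))

  half <- th < pi
  p2 <- angular_profile(cos(th)[half], sin(th)[half], th[half], c(0, 0), 8)
  expect_true(all(is.na(p2$mean[p2$n == 0])))
  expect_warning(angular_profile(c(1, 1.1), c(0.01, 0.02), c(1, 2), c(0, 0), 10),
                 "single angular bin")
})

test_that("circle fits handle exact, degenerate, and noisy input", {
  f <- fit_circle(c(0, 1, 0), c(1, 0, -1))
  expect_equal(f$center, c(0, 0), tolerance = 1e-12)
  expect_equal(f$kappa, 1)
  expect_false(f$degenerate)

  g <- fit_circle(c(0, 1, 2), c(0, 0, 0))
  expect_true(g$degenerate)
  expect_equal(g$kappa, 0)

  set.seed(42)
  th <- runif(20, 0, 2 * pi)
  h <- fit_circle(5 * cos(th) + rnorm(20, 0, 0.05),
                  5 * sin(th) + rnorm(20, 0, 0.05))
  expect_lt(abs(h$radius / 5 - 1), 0.02)
})

test_that("ring diameter is C/pi with positive-perimeter guard", {
  expect_equal(ring_diameter(pi), 1)
  expect_equal(ring_diameter(2 * pi * 115), 230)
  expect_error(ring_diameter(0), "positive")
  expect_error(ring_diameter(-3), "positive")
})

test_that("contour perimeters track analytic values", {
  C <- contour_perimeter(raster_disk(50, 128))
  expect_lt(abs(as.numeric(C) / (100 * pi) - 1), 0.01)
  d20 <- contour_perimeter(raster_disk(20, 64))
  expect_lt(abs(ring_diameter(as.numeric(d20)) / 40 - 1), 0.02)

  sq <- matrix(0, 96, 96); sq[30:69, 30:69] <- 1
  Cs <- contour_perimeter(sq)
  expect_lt(abs(as.numeric(Cs) / 160 - 1), 0.02)

  expect_error(contour_perimeter(matrix(c(1, 1, 1, rep(0, 61)), 8, 8)),
               "too small")
  border <- matrix(0, 32, 32); border[1:10, 5:12] <- 1
  expect_warning(contour_perimeter(border), "border")
})

test_that("centerline perimeter of an annular particle averages both contours", {
  ann <- raster_disk(12, 64) - raster_disk(8, 64)
  outer_only <- as.numeric(contour_perimeter(ann, "outer"))
  center <- as.numeric(contour_perimeter(ann, "centerline"))
  expect_true(attr(contour_perimeter(ann, "centerline"), "has_hole"))
  expect_lt(abs(outer_only / (2 * pi * 12.5) - 1), 0.05)
  expect_lt(abs(center / (2 * pi * 10.5) - 1), 0.05)
})

test_that("synthetic closing TEM curvature is positive and rises as the hole shrinks", {
  sim <- make_closing_tem(seed = 31, probe_mode = "proportional")
  prof <- tem_edge_profile(sim$stack)
  mean_k <- tapply(prof$kappa, prof$frame, mean, na.rm = TRUE)
  expect_true(all(mean_k > 0))
  expect_true(all(diff(mean_k) > 0))
})
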