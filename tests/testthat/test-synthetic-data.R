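test_that("unperturbed closing TEM has circular curvature 1/r and constant probe", {
  sim <- make_closing_tem(lag_amplitude = 0, b1 = 0, b2 = 0,
                          noise = noise_params(0, 0, 0), seed = 1)
  tab <- sim$truth$table
  for (t in unique(tab$frame)) {
    r_t <- sim$truth$r[t]
    expect_equal(tab$kappa_true[tab$frame == t], rep(1 / r_t, sum(tab$frame == t)),
                 tolerance = 1e-12)
  }
  expect_true(all(tab$deposit_rate == tab$deposit_rate[1]))
  expect_true(all(diff(sim$truth$r) < 0))
})

test_that("closed-form perturbed curvature matches a dense finite-difference oracle", {
  sim <- make_closing_tem(lag_mode = 3, lag_amplitude = 0.1,
                          noise = noise_params(0, 0, 0), seed = 1)
  tab <- sim$truth$table
  p <- sim$truth$params
  for (t in c(1, 4)) {
    th <- tab$theta[tab$frame == t]
    rho <- tab$rho[tab$frame == t]
    x <- rho * cos(th); y <- rho * sin(th)
    n <- length(th)
    ip <- c(2:n, 1); im <- c(n, 1:(n - 1))
    dth <- 2 * pi / n
    xp <- (x[ip] - x[im]) / (2 * dth); yp <- (y[ip] - y[im]) / (2 * dth)
    xpp <- (x[ip] - 2 * x + x[im]) / dth^2; ypp <- (y[ip] - 2 * y + y[im]) / dth^2
    kappa_fd <- abs(xp * ypp - yp * xpp) / (xp^2 + yp^2)^1.5
    # relative to the typical curvature scale: pointwise kappa touches 0 at
    # the lobe troughs when a*g*(m^2 - 1) approaches 1
    scale_k <- mean(tab$kappa_true[tab$frame == t])
    expect_lt(max(abs(kappa_fd - tab$kappa_true[tab$frame == t])) / scale_k,
              0.005)
  }
})

test_that("decaying mode-3 lag produces flattening and lagging bins while the lag is active", {
  sim <- make_closing_tem(lag_mode = 3, lag_amplitude = 0.1,
                          noise = noise_params(0, 0, 0), seed = 1)
  p <- sim$truth$params
  prof <- tem_truth_profile(sim$truth, 50)
  labelled <- unique(prof$frame[prof$label != "neither"])
  # flattening requires the lag-decay curvature term to beat the secular
  # curvature increase of closure: a g (m^2-1) / (r tau) > closure / r^2
  for (t in labelled) {
    r_t <- sim$truth$r[t]
    lag_term <- p$lag_amplitude * exp(-(t - 1) / p$lag_tau) *
      (p$lag_mode^2 - 1) / (r_t * p$lag_tau)
    sec_term <- p$closure_rate / r_t^2
    labs <- prof$label[prof$frame == t]
    expect_true(any(labs == "lagging"), info = paste("frame", t))
    if (lag_term > 1.3 * sec_term) {
      expect_true(any(labs == "flattening"), info = paste("frame", t))
    }
  }
  # binned curvature is positive everywhere (a closing hole in a cell)
  expect_true(all(prof$kappa_true > 0))
})

test_that("generators are bit-reproducible from (parameters, seed)", {
  a <- make_closing_tem(seed = 33)
  b <- make_closing_tem(seed = 33)
  expect_identical(a$stack$data, b$stack$data)
  c1 <- make_ring_field(seed = 12)
  c2 <- make_ring_field(seed = 12)
  expect_identical(c1$truth$table, c2$truth$table)
  expect_identical(c1$stack$data, c2$stack$data)
  d <- make_closing_tem(seed = 34)
  expect_false(identical(a$stack$data, d$stack$data))
})

test_that("changing one noise source leaves the others' draws in place", {
  base <- make_closing_tem(seed = 5, noise = noise_params(1, 0, 0))
  readon <- make_closing_tem(seed = 5, noise = noise_params(1, 2, 0))
  # Poisson structure is shared: removing the read noise recovers the base
  expect_false(identical(base$stack$data, readon$stack$data))
  expect_lt(max(abs(base$stack$data - readon$stack$data)), 15)
  expect_gt(cor(as.vector(base$stack$data), as.vector(readon$stack$data)), 0.999)
})

test_that("noiseless channels conserve the deposited photon budget through the PSF", {
  sim <- make_closing_tem(noise = noise_params(0, 0, 0), seed = 2,
                          b0 = 60, b2 = 0)
  p <- sim$truth$params
  for (t in c(1, 5)) {
    mem <- get_frame(sim$stack, t, "membrane")
    expected_mem <- sum(tem_true_cell_mask(sim$truth, t)) * p$membrane_density
    expect_equal(sum(mem), expected_mem, tolerance = 1e-6)
    tab <- sim$truth$table[sim$truth$table$frame == t, ]
    probe <- get_frame(sim$stack, t, "probe")
    deposited <- sum(tab$deposit_rate * tab$arc_ds)
    expect_equal(sum(probe), deposited, tolerance = 1e-6)
  }
})

test_that("degenerate generator parameters are rejected with clear errors", {
  expect_error(make_closing_tem(r0 = 10, closure_rate = 2, n_frames = 8),
               "radius schedule")
  expect_error(make_closing_tem(r0 = 60, dim = c(128L, 128L)), "does not fit")
  expect_error(make_ring_field(n_rings = 200, dim = c(64L, 64L), seed = 1),
               "too small")
  expect_error(make_leading_edge(front_speed = 0.2, n_frames = 300), "leaves the field|advances")
  expect_error(make_leading_edge(lag_amplitude = 20, lag_wavelength = 30),
               "self-intersecting|overhanging")
})

test_that("leading edge truth obeys its analytic speed field", {
  flat <- make_leading_edge(lag_amplitude = 0, noise = noise_params(0, 0, 0),
                            seed = 3)
  expect_true(all(flat$truth$table$v_true == flat$truth$params$front_speed))
  sim <- make_leading_edge(coupling = 1, noise = noise_params(0, 0, 0), seed = 3)
  tab <- sim$truth$table
  expect_gt(cor(tab$deposit_rate, tab$v_true, method = "spearman"), 0.999)
  # affine coupling: deposit difference equals speed difference
  t1 <- tab[tab$frame == 2, ]
  expect_equal(max(t1$deposit_rate) - min(t1$deposit_rate),
               max(t1$v_true) - min(t1$v_true), tolerance = 1e-9)
})

test_that("ring field rasterization matches a direct annulus rasterization", {
  sim <- make_ring_field(n_rings = 3, diameter_mean = 230, diameter_sd = 0,
                         pixel_size = 23, thickness = 2, psf_sigma = 0,
                         noise = noise_params(0, 0, 0), dim = c(128L, 128L),
                         seed = 4)
  # 230 nm at 23 nm/px -> center-line radius exactly 5 px
  expect_equal(sim$truth$table$radius_px, rep(5, 3))
  img <- get_frame(sim$stack, 1, 1)
  xs <- matrix(rep(0:127, each = 128), 128)
  ys <- matrix(rep(0:127, 128), 128)
  oracle <- matrix(0, 128, 128)
  for (i in 1:3) {
    R <- sqrt((xs - sim$truth$table$x[i])^2 + (ys - sim$truth$table$y[i])^2)
    oracle[abs(R - 5) <= 1] <- sim$truth$params$ring_intensity
  }
  expect_identical(img > 0, oracle > 0)
  expect_equal(sum(img > 0), sum(oracle > 0))
})

test_that("image stacks survive a 16-bit TIFF + YAML round trip", {
  sim <- make_closing_tem(seed = 9, n_frames = 3L, dim = c(64L, 64L),
                          r0 = 12, closure_rate = 1)
  path <- file.path(tempdir(), "stack.tif")
  write_image_stack(sim$stack, path)
  back <- read_image_stack(path)
  expect_equal(dim(back$data), dim(sim$stack$data))
  expect_equal(back$pixel_size, sim$stack$pixel_size)
  expect_equal(back$channel_names, sim$stack$channel_names)
  rel <- max(abs(back$data - sim$stack$data)) / max(sim$stack$data)
  expect_lt(rel, 1e-4)  # 16-bit quantisation
  unlink(c(path, paste0(path, ".yaml")))
})

test_that("image stack invariants are enforced", {
  expect_error(image_stack(array(-1, c(4, 4, 1, 1)), pixel_size = 100),
               "nonnegative")
  expect_error(image_stack(array(1, c(4, 4, 1, 1)), pixel_size = 0))
  s <- image_stack(matrix(1, 4, 4), pixel_size = 50)
  expect_equal(n_frames(s), 1L)
  expect_error(get_frame(s, 1, "missing"), "unknown channel")
})
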