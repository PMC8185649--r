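test_that("doughnut enrichment matches brute-force pixel sums and anchors at 1", {
  cell <- raster_cell_with_hole(12, 30, 72)
  hole <- hole_mask(cell)
  # uniform fluorescence over the cell, zero in the hole -> no enrichment
  uni <- cell * 80
  enr <- tem_enrichment(uni, hole)
  expect_equal(enr$E, 1, tolerance = 1e-12)
  # doubled signal band
  d <- brute_distance_to(hole)
  img <- cell * 50
  img[d > 0 & d <= 3] <- 100
  enr2 <- tem_enrichment(img, hole)
  expect_equal(enr2$E, 2, tolerance = 1e-12)
  expect_equal(enr2$corrected, (100 - 50) * sum(d > 0 & d <= 3), tolerance = 1e-9)
  # arbitrary deposit: exact agreement with direct enumeration
  set.seed(7)
  img3 <- cell * 50 + matrix(runif(72 * 72, 0, 20), 72)
  bands <- make_doughnuts(hole, 3, 3)
  E_oracle <- mean(img3[bands$signal]) / mean(img3[bands$background])
  enr3 <- tem_enrichment(img3, hole)
  expect_equal(enr3$E, E_oracle, tolerance = 1e-12)
  expect_equal(enr3$intensity_per_perimeter,
               (sum(img3[bands$signal]) -
                  mean(img3[bands$background]) * sum(bands$signal)) /
                 enr3$perimeter, tolerance = 1e-9)
})

test_that("normalized probe is an elementwise guarded ratio", {
  expect_equal(normalized_probe(c(2, 6), c(2, 6)), c(1, 1))
  expect_equal(normalized_probe(c(3, 9), c(1, 3)), c(3, 3))
  out <- normalized_probe(c(1, 1), c(2, 0))
  expect_equal(out, c(0.5, NA))
  expect_error(normalized_probe(c(1, 1), c(0, -2)), "nonpositive")
})

test_that("flattening/lagging classification follows the sign rules", {
  prof <- data.frame(kappa = c(0.10, 0.10, -0.05, 0.10, NA),
                     dkappa_dt = c(-0.02, 0.02, -0.02, 0, 0.01))
  lab <- classify_regions(prof)$label
  expect_equal(lab, c("flattening", "lagging", "neither", "neither", "neither"))
})

test_that("fold enrichment pools class means with missing-value semantics", {
  vals <- c(2, 2, 1, 1, 5)
  labs <- c("flattening", "flattening", "lagging", "lagging", "neither")
  expect_equal(fold_enrichment(vals, labs), 2)
  expect_equal(fold_enrichment(rep(1.3, 4),
                               c("flattening", "lagging", "flattening", "lagging")), 1)
  expect_true(is.na(fold_enrichment(c(1, 2), c("flattening", "neither"))))
})

test_that("rotation scan closes on itself and peaks where the signal sits", {
  # constructed cohort: probe matched to flattening labels exactly
  mk_prof <- function(shift) {
    nb <- 10
    lab <- rep("lagging", nb); lab[3:5] <- "flattening"
    val <- rep(1, nb); val[((3:5 - 1 + shift) %% nb) + 1] <- 2
    data.frame(frame = 1, bin = 1:nb, normalized = val, label = lab)
  }
  profs <- list(mk_prof(0), mk_prof(0), mk_prof(0))
  rot <- rotation_scan(profs, n_rotations = 11)
  expect_equal(rot$mean[1], 2)
  expect_equal(rot$mean[11], rot$mean[1])  # full turn reproduces offset 0
  expect_equal(which.max(rot$mean), 1)
  expect_true(all(rot$mean[1] >= rot$mean))
  # uniform probes: fold 1 at every offset, no test possible (sd = 0)
  uni <- lapply(1:3, function(i) {
    data.frame(frame = 1, bin = 1:10, normalized = 1,
               label = rep(c("flattening", "lagging"), 5))
  })
  rotu <- rotation_scan(uni)
  expect_true(all(rotu$mean == 1))
  expect_true(all(is.na(rotu$p)))
})

test_that("rotation scan propagates empty classes as missing TEM-offsets", {
  p1 <- data.frame(frame = 1, bin = 1:6, normalized = c(2, 1, 1, NA, NA, NA),
                   label = c("flattening", "lagging", "lagging",
                             "neither", "neither", "neither"))
  # at some offsets all flattening bins are NA -> missing score
  rot <- rotation_scan(list(p1), n_rotations = 6)
  expect_true(any(!is.finite(attr(rot, "scores"))))
  expect_true(all(is.na(rot$p)))  # a single TEM can never be tested
})

test_that("perimeter trends give signed Spearman rho with missing for constants", {
  ser <- data.frame(frame = 1:6, perimeter_px = 60 - 1:6,
                    intensity_per_perimeter = c(1, 2, 3, 5, 8, 9))
  expect_equal(perimeter_trend(ser), 1)
  ser$intensity_per_perimeter <- rev(ser$intensity_per_perimeter)
  expect_equal(perimeter_trend(ser), -1)
  expect_equal(perimeter_trend(ser, x = "perimeter"), 1)
  ser$intensity_per_perimeter <- 4
  expect_true(is.na(perimeter_trend(ser)))
  expect_error(perimeter_trend(ser[1:2, ]), "at least 3")
})

test_that("velocity-signal correlation pools bins and guards degenerate input", {
  prof <- data.frame(velocity = seq(0.1, 2, length.out = 40))
  prof$normalized <- prof$velocity^2 + 3   # monotone map
  expect_equal(velocity_signal_correlation(prof), 1)
  with_seed <- function(s, n) { set.seed(s); rnorm(n) }
  prof2 <- data.frame(velocity = with_seed(1, 1000),
                      normalized = with_seed(2, 1000))
  expect_lt(abs(velocity_signal_correlation(prof2)), 0.1)
  expect_error(velocity_signal_correlation(prof[1:5, ]), "at least 10")
  prof3 <- data.frame(velocity = rep(1, 20), normalized = rnorm(20))
  expect_true(is.na(velocity_signal_correlation(prof3)))
})

test_that("compartment ratios are background-corrected per-area ratios", {
  img <- matrix(1, 40, 40)       # cytosol level 1
  target <- matrix(FALSE, 40, 40); target[5:8, 5:12] <- TRUE
  refer <- matrix(FALSE, 40, 40); refer[20:27, 20:23] <- TRUE
  cyt <- matrix(FALSE, 40, 40); cyt[32:39, 2:39] <- TRUE
  img[target] <- 3; img[refer] <- 2
  expect_equal(compartment_ratio(img, target, refer, cyt), 2)  # (3-1)/(2-1)
  img[refer] <- 2
  img[target] <- 2
  expect_equal(compartment_ratio(img, target, refer, cyt), 1)
  img[refer] <- 1   # corrected reference = 0 -> undefined
  expect_true(is.na(compartment_ratio(img, target, refer, cyt)))
  expect_error(compartment_ratio(img, target, target, cyt), "disjoint")
  # exact agreement with direct sums for arbitrary intensities
  set.seed(11)
  img2 <- matrix(runif(1600, 1, 5), 40)
  ct <- sum(img2[target]) - mean(img2[cyt]) * sum(target)
  cr <- sum(img2[refer]) - mean(img2[cyt]) * sum(refer)
  expect_equal(compartment_ratio(img2, target, refer, cyt),
               (ct / sum(target)) / (cr / sum(refer)), tolerance = 1e-12)
})

test_that("Manders M1 is the thresholded intensity fraction", {
  a <- matrix(0, 20, 20); b <- matrix(0, 20, 20)
  roi <- matrix(TRUE, 20, 20)
  a[5:10, 5:10] <- 2; b[5:10, 5:10] <- 7
  expect_equal(manders_m1(a, b, roi, b_threshold = 1), 1)
  b[] <- 0; b[15:18, 15:18] <- 9
  expect_equal(manders_m1(a, b, roi, b_threshold = 1), 0)
  # half-overlap oracle
  b[] <- 0; b[5:10, 8:13] <- 9
  m1 <- manders_m1(a, b, roi, b_threshold = 1)
  expect_equal(m1, sum(a[b > 1]) / sum(a), tolerance = 1e-12)
  expect_equal(m1, 0.5)
  expect_true(is.na(manders_m1(matrix(0, 20, 20), b, roi, 1)))
})

test_that("scramble control preserves means under uniformity and detects concentration", {
  mask <- matrix(FALSE, 30, 30); mask[10:20, 10:20] <- TRUE
  uni <- matrix(4, 30, 30)
  sc <- scramble_control(uni, mask, seed = 3)
  expect_equal(sc$mean_signal, sc$mean_scrambled)
  conc <- matrix(0, 30, 30); conc[mask] <- 10
  sc2 <- scramble_control(conc, mask, seed = 3)
  expect_gt(sc2$mean_signal, sc2$mean_scrambled)
  sc3 <- scramble_control(conc, mask, seed = 3)
  expect_identical(sc2$mean_scrambled, sc3$mean_scrambled)
})

test_that("protrusion metrics measure rectangular and curved extensions", {
  m0 <- matrix(FALSE, 64, 64); m0[40:63, ] <- TRUE   # flat cell front
  m1 <- m0; m1[30:39, 20:23] <- TRUE                 # 10 x 4 extension
  tab <- protrusion_metrics(m0, m1, elapsed = 60)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$length_px, 10)
  expect_equal(tab$width_px, 4)
  expect_equal(tab$speed_px_min, 10)
  expect_equal(nrow(protrusion_metrics(m0, m0, 60)), 0)

  # semicircular bulge of radius 8 centered on the t0 edge (y = 38.5):
  # length 8, width from a brute-force chord
  m2 <- m0
  xs <- matrix(rep(0:63, each = 64), 64); ys <- matrix(rep(0:63, 64), 64)
  bulge <- (xs - 40)^2 + (ys - 38.5)^2 <= 64 & ys < 38.5
  m2[bulge] <- TRUE
  tab2 <- protrusion_metrics(m0, m2, elapsed = 60)
  expect_equal(tab2$length_px, 8)
  d <- brute_distance_to(m0)
  comp <- m2 & !m0
  chord_oracle <- sum(abs(d[comp] - tab2$length_px / 2) <= 0.5)
  expect_equal(tab2$width_px, chord_oracle)
})

test_that("integer drift correction restores protrusion measurements", {
  m0 <- matrix(FALSE, 64, 64); m0[40:55, 8:56] <- TRUE
  m1 <- m0; m1[30:39, 20:23] <- TRUE
  # drift the t1 mask down by 3 px
  m1_shift <- matrix(FALSE, 64, 64)
  m1_shift[4:64, ] <- m1[1:61, ]
  tab <- protrusion_metrics(m0, m1_shift, elapsed = 60, align = TRUE)
  expect_equal(tab$length_px, 10)
  expect_equal(tab$width_px, 4)
})

test_that("scores are invariant to a global intensity scale", {
  cell <- raster_cell_with_hole(10, 28, 64)
  hole <- hole_mask(cell)
  set.seed(9)
  img <- cell * 60 + matrix(runif(64 * 64, 0, 10), 64)
  e1 <- tem_enrichment(img, hole)$E
  e2 <- tem_enrichment(img * 7.3, hole)$E
  expect_equal(e1, e2, tolerance = 1e-12)
  roi <- matrix(TRUE, 64, 64)
  expect_equal(manders_m1(img, img, roi, 30),
               manders_m1(img * 2, img, roi, 30), tolerance = 1e-12)
})

test_that("filopodia mask keeps only structures thinner than the opening disc", {
  cell <- raster_disk(20, 64)
  cell[10:31, 50:52] <- 1  # 3-px-wide spike
  fil <- filopodia_mask(cell > 0, radius = 3)
  expect_true(any(fil[10:25, 50:52]))
  expect_false(any(fil[raster_disk(15, 64) > 0]))
})
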