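#' Run configuration for the analysis pipelines
#'
#' Bundles every tunable of the generators and analyses into a serializable
#' list with the standard defaults: 1000 boundary points, curvature scale
#' S = 10 with 50 angular bins for TEM mode and S = 44 with 1000 bins for
#' cell-edge mode, 3 px doughnut dilations, and a master seed. A persisted
#' config re-executes to identical outputs.
#'
#' @param mode `"tem"`, `"edge"`, or `"rings"`.
#' @param ... overrides of the defaults (unknown names are rejected).
#' @return list of class `RunConfig`.
#' @export
run_config <- function(mode = c("tem", "edge", "rings"), ...) {
  mode <- match.arg(mode)
  defaults <- switch(mode,
    tem = list(
      mode = "tem", input = NULL, n_tems = 3L, seed = 1L,
      synth = list(), membrane = "membrane", probe = "probe",
      n_points = 1000L, S = 10L, n_bins = 50L, half_width = 2,
      d1 = 3, d2 = 3, smoothing_sigma = 2, threshold = "otsu",
      erosion_radius = 0, background = "hole", background_radius = NULL,
      velocity_method = "central", dkappa = "central",
      n_rotations = NULL, out_dir = NULL),
    edge = list(
      mode = "edge", input = NULL, seed = 1L, synth = list(),
      membrane = "membrane", probe = "probe",
      n_points = 1000L, S = 44L, n_bins = 1000L, half_width = 2,
      smoothing_sigma = 2, threshold = "otsu", erosion_radius = 0,
      background = "offcell", background_radius = NULL,
      velocity_method = "central", border_margin = 4, out_dir = NULL),
    rings = list(
      mode = "rings", input = NULL, seed = 1L, synth = list(),
      channel = 1L, background_radius = 8, threshold = "otsu",
      min_area = 10, max_area = Inf, hist_binwidth_nm = 20,
      pixel_size = NULL, out_dir = NULL))
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  }
  defaults[names(overrides)] <- overrides
  class(defaults) <- c("RunConfig", "list")
  defaults
}

#' Save / load a [run_config()] as YAML
#' @param config a `RunConfig`.
#' @param path YAML file path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, c(list(mode = cfg$mode), cfg[setdiff(names(cfg), "mode")]))
}

# short provenance hash of a config (output location excluded: it does not
# affect the computation)
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  s <- yaml::as.yaml(cfg)
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_provenance_csv <- function(df, path, config) {
  con <- file(path, "w")
  writeLines(sprintf("# memcurve %s config %s",
                     as.character(utils::packageVersion("memcurve")),
                     config_hash(config)), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

# obtain the cohort of TEM stacks described by a config
tem_cohort <- function(config) {
  if (!is.null(config$input)) {
    stacks <- lapply(config$input, read_image_stack)
    return(list(stacks = stacks, truths = NULL))
  }
  sims <- lapply(seq_len(config$n_tems), function(i) {
    args <- config$synth
    args$seed <- substream_seed(config$seed, paste0("tem", i))
    do.call(make_closing_tem, args)
  })
  list(stacks = lapply(sims, `[[`, "stack"),
       truths = lapply(sims, `[[`, "truth"))
}

#' End-to-end TEM analysis
#'
#' For every TEM of a cohort (read from `config$input` TIFFs or generated
#' from `config$synth` parameters with per-TEM seeds spawned from
#' `config$seed`): per-frame hole segmentation, doughnut enrichment series,
#' sub-pixel hole boundary, binned curvature/velocity/fluorescence profile,
#' flattening/lagging classification and pooled fold enrichment, then the
#' cohort-level rotation null. With `config$out_dir` set, tidy CSVs
#' (profiles, series, rotation table, per-TEM summary) and a provenance YAML
#' are written.
#'
#' @param config a [run_config()] of mode `"tem"`.
#' @return list with `profiles` (list of classified per-TEM profiles),
#'   `series` (combined [tem_series()] rows with a `tem` column),
#'   `rotation` (a [rotation_scan()] table), `fold` (per-TEM zero-rotation
#'   fold enrichment), `trend` (per TEM x channel Spearman rho of intensity
#'   per perimeter vs frame).
#' @export
run_tem_analysis <- function(config = run_config("tem")) {
  stopifnot(inherits(config, "RunConfig"), config$mode == "tem")
  cohort <- tem_cohort(config)
  stacks <- cohort$stacks
  profiles <- list(); series <- list()
  for (i in seq_along(stacks)) {
    prof <- tem_edge_profile(
      stacks[[i]], membrane = config$membrane, probe = config$probe,
      n_points = config$n_points, S = config$S, n_bins = config$n_bins,
      half_width = config$half_width, smoothing_sigma = config$smoothing_sigma,
      threshold = config$threshold, erosion_radius = config$erosion_radius,
      background = config$background,
      background_radius = config$background_radius,
      velocity_method = config$velocity_method, dkappa = config$dkappa)
    profiles[[i]] <- classify_regions(prof)
    ser <- tem_series(stacks[[i]], membrane = config$membrane,
                      d1 = config$d1, d2 = config$d2,
                      smoothing_sigma = config$smoothing_sigma,
                      threshold = config$threshold,
                      erosion_radius = config$erosion_radius)
    ser$tem <- i
    series[[i]] <- ser
  }
  rotation <- rotation_scan(profiles, n_rotations = config$n_rotations)
  fold <- vapply(profiles, function(pr) {
    fold_enrichment(pr$normalized, pr$label)
  }, 0)
  ser_all <- do.call(rbind, series)
  trend <- do.call(rbind, lapply(seq_along(stacks), function(i) {
    do.call(rbind, lapply(unique(series[[i]]$channel), function(ch) {
      data.frame(tem = i, channel = ch,
                 rho = perimeter_trend(series[[i]][series[[i]]$channel == ch, ]))
    }))
  }))
  out <- list(profiles = profiles, series = ser_all, rotation = rotation,
              fold = fold, trend = trend)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    prof_all <- do.call(rbind, lapply(seq_along(profiles), function(i) {
      cbind(tem = i, profiles[[i]])
    }))
    write_provenance_csv(prof_all, file.path(config$out_dir, "profiles.csv"), config)
    write_provenance_csv(ser_all, file.path(config$out_dir, "series.csv"), config)
    write_provenance_csv(as.data.frame(rotation),
                         file.path(config$out_dir, "rotation.csv"), config)
    write_provenance_csv(data.frame(tem = seq_along(fold), fold = fold),
                         file.path(config$out_dir, "fold.csv"), config)
    write_provenance_csv(trend, file.path(config$out_dir, "trend.csv"), config)
    save_config(config, file.path(config$out_dir, "config.yaml"))
  }
  out
}

#' Per-frame, per-bin profile of a migrating-cell leading edge
#'
#' Cell-edge analogue of [tem_edge_profile()]: the outer cell boundary is
#' traced (default 1000 points, S = 44, 1000 angular bins around the cell
#' centroid), and curvature, velocity and normalized band fluorescence are
#' binned. Boundary points within `border_margin` px of the image border
#' (where the contour follows the field of view, not the membrane) are
#' excluded.
#'
#' @inheritParams tem_edge_profile
#' @param background `"offcell"` (default: scalar background from pixels
#'   more than 3 px outside the cell mask) or `"tophat"` (rolling-ball
#'   style top-hat of radius `background_radius`).
#' @param border_margin exclusion margin in px.
#' @return data.frame as in [tem_edge_profile()].
#' @export
cell_edge_profile <- function(stack, membrane = "membrane", probe = "probe",
                              n_points = 1000L, S = 44L, n_bins = 1000L,
                              half_width = 2, smoothing_sigma = 2,
                              threshold = "otsu", erosion_radius = 0,
                              background = c("offcell", "tophat"),
                              background_radius = NULL,
                              velocity_method = "central",
                              border_margin = 4) {
  background <- match.arg(background)
  if (!(membrane %in% stack$channel_names) && !is.numeric(membrane)) {
    stop("configuration error: membrane channel not found in stack")
  }
  nt <- n_frames(stack)
  dims <- dim(stack$data)[1:2]
  if (is.null(background_radius)) background_radius <- round(0.3 * min(dims))
  cells <- lapply(seq_len(nt), function(t) {
    segment_region(get_frame(stack, t, membrane), smoothing_sigma,
                   threshold, erosion_radius)
  })
  out <- list()
  for (t in seq_len(nt)) {
    bd <- extract_boundary(cells[[t]], n_points, which = "outer")
    interior_pt <- !(bd$x < border_margin | bd$x > dims[2] - 1 - border_margin |
                       bd$y < border_margin | bd$y > dims[1] - 1 - border_margin)
    idx <- which(cells[[t]])
    center <- c(mean(ceiling(idx / dims[1]) - 1), mean((idx - 1) %% dims[1]))
    kap <- signed_curvature(bd, S)
    kap[!interior_pt] <- NA_real_
    vel <- rep(NA_real_, n_points)
    if (t > 1 && t < nt) {
      vel <- edge_velocity(bd, cells[[t - 1]], cells[[t + 1]],
                           method = velocity_method)
      vel[!interior_pt] <- NA_real_
    }
    kb <- angular_profile(bd$x, bd$y, kap, center, n_bins)
    vb <- angular_profile(bd$x, bd$y, vel, center, n_bins)
    offcell <- matrix(as.numeric(EBImage::dilate(cells[[t]] * 1,
                                                 disc_brush(3))), nrow = dims[1]) < 0.5
    correct <- function(frame) {
      if (background == "tophat") {
        matrix(as.numeric(EBImage::whiteTopHat(
          EBImage::Image(frame), disc_brush(background_radius))), nrow = dims[1])
      } else {
        bg <- if (any(offcell)) mean(frame[offcell]) else min(frame)
        frame - bg
      }
    }
    # per-point fluorescence: the boundary expanded both ways along its
    # normal, averaged over offsets in [-half_width, half_width]
    nrm <- boundary_normals(bd)
    band_mean <- function(frame) {
      acc <- numeric(n_points); cnt <- 0L
      for (off in seq(-half_width, half_width, by = 1)) {
        acc <- acc + bilinear_interp(frame, bd$x + off * nrm[, "nx"],
                                     bd$y + off * nrm[, "ny"])
        cnt <- cnt + 1L
      }
      v <- acc / cnt
      v[!interior_pt] <- NA_real_
      v
    }
    mem_pt <- band_mean(correct(get_frame(stack, t, membrane)))
    prb_pt <- band_mean(correct(get_frame(stack, t, probe)))
    mb <- angular_profile(bd$x, bd$y, mem_pt, center, n_bins)
    pb <- angular_profile(bd$x, bd$y, prb_pt, center, n_bins)
    norm <- normalized_probe(pb$mean, mb$mean)
    out[[t]] <- data.frame(frame = t, bin = kb$bin, theta = kb$theta,
                           kappa = kb$mean, velocity = vb$mean,
                           membrane = mb$mean, probe = pb$mean,
                           normalized = norm)
  }
  do.call(rbind, out)
}

#' End-to-end leading-edge analysis
#'
#' Generates (or reads) a leading-edge stack, builds the 1000-bin edge
#' profile, and reports the pooled Spearman correlation between normalized
#' probe signal and edge velocity.
#'
#' @param config a [run_config()] of mode `"edge"`.
#' @return list with `profile` and `rho`.
#' @export
run_edge_analysis <- function(config = run_config("edge")) {
  stopifnot(inherits(config, "RunConfig"), config$mode == "edge")
  if (!is.null(config$input)) {
    stack <- read_image_stack(config$input)
  } else {
    args <- config$synth
    args$seed <- substream_seed(config$seed, "edge")
    stack <- do.call(make_leading_edge, args)$stack
  }
  prof <- cell_edge_profile(
    stack, membrane = config$membrane, probe = config$probe,
    n_points = config$n_points, S = config$S, n_bins = config$n_bins,
    half_width = config$half_width, smoothing_sigma = config$smoothing_sigma,
    threshold = config$threshold, erosion_radius = config$erosion_radius,
    background = config$background,
    background_radius = config$background_radius,
    velocity_method = config$velocity_method,
    border_margin = config$border_margin)
  rho <- velocity_signal_correlation(prof)
  out <- list(profile = prof, rho = rho)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_provenance_csv(prof, file.path(config$out_dir, "edge_profile.csv"), config)
    write_provenance_csv(data.frame(rho = rho),
                         file.path(config$out_dir, "edge_correlation.csv"), config)
    save_config(config, file.path(config$out_dir, "config.yaml"))
  }
  out
}

#' Ring table from a single frame
#'
#' Segments candidate ring particles ([segment_rings()]), measures each
#' particle's sub-pixel center-line perimeter, and converts to the
#' equivalent-circle diameter d = C / pi in px and nm.
#'
#' @param frame intensity matrix.
#' @param pixel_size nm/px.
#' @param background_radius,threshold,min_area,max_area passed to
#'   [segment_rings()].
#' @param refine_halfmax re-threshold each particle at half its peak
#'   background-subtracted intensity before tracing contours. The FWHM band
#'   of a PSF-blurred annulus is symmetric about the ring center line, so
#'   this removes the outer-contour bias for dim or blur-filled rings.
#' @return data.frame (label, x, y, area_px2, perimeter_px, diameter_px,
#'   diameter_nm, has_hole); zero rows when nothing is found.
#' @export
ring_table <- function(frame, pixel_size, background_radius = 8,
                       threshold = "otsu", min_area = 10, max_area = Inf,
                       refine_halfmax = TRUE) {
  lab <- segment_rings(frame, background_radius, threshold, min_area, max_area)
  corrected <- attr(lab, "corrected")
  empty <- data.frame(label = integer(0), x = numeric(0), y = numeric(0),
                      area_px2 = integer(0), perimeter_px = numeric(0),
                      diameter_px = numeric(0), diameter_nm = numeric(0),
                      has_hole = logical(0))
  if (max(lab) == 0L) return(empty)
  rows <- list()
  ny <- nrow(frame)
  for (id in seq_len(max(lab))) {
    m <- lab == id
    if (sum(m) < 8L) next
    if (refine_halfmax) {
      m2 <- m & corrected >= 0.5 * max(corrected[m])
      m2 <- largest_component(m2)
      if (sum(m2) >= 8L) m <- m2
    }
    C <- tryCatch(contour_perimeter(m, "centerline"), error = function(e) NULL)
    if (is.null(C)) next
    idx <- which(m)
    d_px <- ring_diameter(as.numeric(C))
    rows[[length(rows) + 1L]] <- data.frame(
      label = id, x = mean(ceiling(idx / ny) - 1), y = mean((idx - 1) %% ny),
      area_px2 = sum(m), perimeter_px = as.numeric(C), diameter_px = d_px,
      diameter_nm = d_px * pixel_size, has_hole = attr(C, "has_hole"))
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

#' End-to-end ring analysis
#'
#' Segmentation, per-ring perimeter and C/pi diameter for every frame of the
#' input, plus a diameter summary (median, and histogram mode at a stated
#' bin width).
#'
#' @param config a [run_config()] of mode `"rings"`.
#' @return list with `rings` (ring table, `frame` column added) and
#'   `summary` (n, median_nm, mode_nm, hist_binwidth_nm; `NA`s when empty).
#' @export
run_ring_analysis <- function(config = run_config("rings")) {
  stopifnot(inherits(config, "RunConfig"), config$mode == "rings")
  if (!is.null(config$input)) {
    stack <- read_image_stack(config$input)
  } else {
    args <- config$synth
    args$seed <- substream_seed(config$seed, "rings")
    stack <- do.call(make_ring_field, args)$stack
  }
  pixel_size <- if (is.null(config$pixel_size)) stack$pixel_size else config$pixel_size
  tabs <- lapply(seq_len(n_frames(stack)), function(t) {
    tab <- ring_table(get_frame(stack, t, config$channel), pixel_size,
                      config$background_radius, config$threshold,
                      config$min_area, config$max_area)
    if (nrow(tab) > 0L) cbind(frame = t, tab) else NULL
  })
  rings <- do.call(rbind, tabs)
  if (is.null(rings)) {
    rings <- data.frame()
    summary <- data.frame(n = 0L, median_nm = NA_real_, mode_nm = NA_real_,
                          hist_binwidth_nm = config$hist_binwidth_nm)
  } else {
    bw <- config$hist_binwidth_nm
    breaks <- seq(0, max(rings$diameter_nm) + bw, by = bw)
    h <- graphics::hist(rings$diameter_nm, breaks = breaks, plot = FALSE)
    summary <- data.frame(n = nrow(rings),
                          median_nm = stats::median(rings$diameter_nm),
                          mode_nm = h$mids[which.max(h$counts)],
                          hist_binwidth_nm = bw)
  }
  out <- list(rings = rings, summary = summary)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_provenance_csv(rings, file.path(config$out_dir, "rings.csv"), config)
    write_provenance_csv(summary, file.path(config$out_dir, "ring_summary.csv"), config)
    save_config(config, file.path(config$out_dir, "config.yaml"))
  }
  out
}
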