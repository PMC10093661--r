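#' Synthetic-slide simulation configuration
#'
#' Describes a synthetic cytokeratin slide: a rectangular tissue with a
#' homogeneous Poisson background of tumor buds, one or more Gaussian bud
#' clusters (the densest of which is the planted hotspot), Poisson
#' distractor objects (non-buds), and an imperfect "teacher" detector whose
#' likelihoods follow a high mode at true buds (Beta(8, 2)) and a low mode at
#' false positives (Beta(2, 8)) — so a 0.80 likelihood cut separates the two
#' imperfectly, as a real teacher network would.
#'
#' Defaults emulate a 10 x 10 mm section with a background of 1 bud/mm^2 and
#' a single dominant cluster of 25 buds (sd 50 um), against 1 distractor/mm^2
#' and 0.5 teacher false positives/mm^2.
#'
#' @param width_mm,height_mm Tissue extent, millimeters.
#' @param background_rate Background buds per mm^2.
#' @param clusters List of clusters, each `list(center_um = c(x, y) | NULL,
#'   sd_um, n_buds)`; `NULL` centers are placed uniformly at random with a
#'   1 mm margin.
#' @param distractor_rate Non-bud objects per mm^2.
#' @param teacher_fp_rate Teacher false positives per mm^2.
#' @param likelihood_true,likelihood_false Length-2 Beta shape parameters for
#'   teacher likelihoods at true and false objects.
#' @param manual_fraction Fraction of true buds (and of distractors) that
#'   carry sparse manual TB / NON_TB annotations.
#' @param seed Integer seed; every stochastic draw is governed by it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(width_mm = 10, height_mm = 10,
                              background_rate = 1,
                              clusters = list(list(center_um = NULL,
                                                   sd_um = 50, n_buds = 25)),
                              distractor_rate = 1,
                              teacher_fp_rate = 0.5,
                              likelihood_true = c(8, 2),
                              likelihood_false = c(2, 8),
                              manual_fraction = 0.1,
                              seed = 1L) {
  stopifnot(width_mm > 0, height_mm > 0, background_rate >= 0,
            distractor_rate >= 0, teacher_fp_rate >= 0,
            manual_fraction >= 0, manual_fraction <= 1)
  for (cl in clusters)
    stopifnot(is.list(cl), cl$sd_um > 0, cl$n_buds >= 0)
  structure(list(width_mm = width_mm, height_mm = height_mm,
                 background_rate = background_rate, clusters = clusters,
                 distractor_rate = distractor_rate,
                 teacher_fp_rate = teacher_fp_rate,
                 likelihood_true = likelihood_true,
                 likelihood_false = likelihood_false,
                 manual_fraction = manual_fraction,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a synthetic slide
#'
#' Draws the point patterns described by a [simulation_config()] and computes
#' the ground-truth planted hotspot with the exhaustive densest-disk scan, so
#' every downstream stage (density, hotspot selection, scoring, pseudo-label
#' filtering, evaluation) can be validated against known truth.
#'
#' @param config A [simulation_config()].
#' @param hotspot_radius_um Radius of the planted ground-truth field
#'   (default 500).
#' @param oracle_spacing_um Grid spacing of the densest-disk scan (default 8).
#' @return An object of class `synthetic_slide`: detection tables
#'   `true_buds`, `distractors`, `manual_annotations`, `teacher_detections`;
#'   `planted_hotspot` (a [circle()]) with `planted_count`; the tissue
#'   `geometry` (a [slide_geometry()] at `oracle_spacing_um`); and `config`.
#' @export
simulate_slide <- function(config = simulation_config(),
                           hotspot_radius_um = 500, oracle_spacing_um = 8) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  w <- config$width_mm * 1000; h <- config$height_mm * 1000
  area_mm2 <- config$width_mm * config$height_mm

  # background buds: homogeneous Poisson
  n_bg <- rpois(1, config$background_rate * area_mm2)
  bx <- runif(n_bg, 0, w); by <- runif(n_bg, 0, h)

  # cluster buds: isotropic Gaussian around (possibly random) centers
  cx <- numeric(); cy <- numeric()
  margin <- min(1000, w / 4, h / 4)
  for (cl in config$clusters) {
    ctr <- cl$center_um
    if (is.null(ctr))
      ctr <- c(runif(1, margin, w - margin), runif(1, margin, h - margin))
    cx <- c(cx, rnorm(cl$n_buds, ctr[1], cl$sd_um))
    cy <- c(cy, rnorm(cl$n_buds, ctr[2], cl$sd_um))
  }
  true_buds <- detection_table(c(bx, cx), c(by, cy), likelihood = NA_real_,
                               label = "TB", certainty = NA_real_,
                               source = "DETECTOR")

  n_dis <- rpois(1, config$distractor_rate * area_mm2)
  distractors <- detection_table(runif(n_dis, 0, w), runif(n_dis, 0, h),
                                 likelihood = NA_real_, label = "NON_TB",
                                 certainty = NA_real_, source = "DETECTOR")

  # sparse manual annotations: a labeled subset of buds and distractors
  n_tb <- nrow(true_buds)
  man_tb <- sort(sample(n_tb, round(config$manual_fraction * n_tb)))
  man_nt <- sort(sample(n_dis, round(config$manual_fraction * n_dis)))
  manual <- rbind(
    if (length(man_tb)) detection_table(true_buds$x_um[man_tb],
                                        true_buds$y_um[man_tb],
                                        label = "TB", certainty = 1,
                                        source = "MANUAL"),
    if (length(man_nt)) detection_table(distractors$x_um[man_nt],
                                        distractors$y_um[man_nt],
                                        label = "NON_TB", certainty = 1,
                                        source = "MANUAL"))
  if (is.null(manual)) manual <- detection_table(numeric(), numeric())

  # teacher: true buds at high-mode likelihood + Poisson false positives
  lk_true <- rbeta(n_tb, config$likelihood_true[1], config$likelihood_true[2])
  n_fp <- rpois(1, config$teacher_fp_rate * area_mm2)
  lk_fp <- rbeta(n_fp, config$likelihood_false[1], config$likelihood_false[2])
  teacher <- detection_table(
    c(true_buds$x_um, runif(n_fp, 0, w)),
    c(true_buds$y_um, runif(n_fp, 0, h)),
    likelihood = c(lk_true, lk_fp), label = "UNLABELED",
    certainty = NA_real_, source = "DETECTOR")
  teacher$truth <- rep(c("TRUE_BUD", "FALSE_POSITIVE"), c(n_tb, n_fp))

  geometry <- slide_geometry(w, h, spacing_um = oracle_spacing_um)
  if (nrow(true_buds) > 0) {
    planted <- densest_disk_oracle(true_buds$x_um, true_buds$y_um,
                                   radius_um = hotspot_radius_um,
                                   geometry = geometry)
  } else {
    planted <- list(circle = NULL, count = 0L)
  }
  structure(list(true_buds = true_buds, distractors = distractors,
                 manual_annotations = manual, teacher_detections = teacher,
                 planted_hotspot = planted$circle,
                 planted_count = planted$count,
                 geometry = geometry, config = config),
            class = "synthetic_slide")
}

#' @export
print.synthetic_slide <- function(x, ...) {
  cat(sprintf(
    paste0("synthetic_slide: %.0f x %.0f mm, %d buds, %d distractors, ",
           "%d manual, %d teacher detections\n"),
    x$config$width_mm, x$config$height_mm, nrow(x$true_buds),
    nrow(x$distractors), nrow(x$manual_annotations),
    nrow(x$teacher_detections)))
  if (!is.null(x$planted_hotspot))
    cat(sprintf("  planted hotspot: (%.0f, %.0f) um, count %d\n",
                x$planted_hotspot$cx, x$planted_hotspot$cy, x$planted_count))
  invisible(x)
}

#' Exhaustive densest-disk scan
#'
#' Brute-force reference for hotspot selection: counts the points inside the
#' disk centered at every raster cell center (naive per-center scan over all
#' points, compiled) and returns the maximum-count disk, ties broken by the
#' smallest row-major cell index — the same tie rule [select_hotspots()]
#' uses, so the two are directly comparable.
#'
#' @param x,y Point coordinates, micrometers (non-empty).
#' @param radius_um Disk radius (default 500).
#' @param grid_spacing_um Scan grid spacing when `geometry` is `NULL`.
#' @param geometry Optional [slide_geometry()] defining the scan grid;
#'   defaults to the points' bounding box padded by `radius_um`.
#' @return List: `circle` (the max-count disk), `count`, and the full integer
#'   `counts` matrix of the scan.
#' @export
densest_disk_oracle <- function(x, y, radius_um = 500, grid_spacing_um = 8,
                                geometry = NULL) {
  stopifnot(length(x) == length(y), length(x) > 0, radius_um > 0)
  if (is.null(geometry))
    geometry <- geometry_from_points(x, y, pad_um = radius_um,
                                     spacing_um = grid_spacing_um)
  xc <- col_centers(geometry); yc <- row_centers(geometry)
  counts <- .disk_scan_counts(as.numeric(x), as.numeric(y), xc, yc,
                              as.numeric(radius_um))
  m <- max(counts)
  idx <- which(counts == m)
  ii <- ((idx - 1L) %% geometry$nrow) + 1L
  jj <- ((idx - 1L) %/% geometry$nrow) + 1L
  first <- order(ii, jj)[1L]
  list(circle = circle(xc[jj[first]], yc[ii[first]], radius_um),
       count = as.integer(m), counts = counts, geometry = geometry)
}

#' Render a synthetic DAB tile
#'
#' Forward model of the stained appearance: a white background on which every
#' bud is drawn as a disk of DAB chromogen and every distractor as a disk of
#' hematoxylin, converted to RGB through Beer--Lambert transmittance
#' `I = 255 * 10^(-M'c)` with the same stain matrix the deconvolution
#' inverts, plus bounded uniform pixel noise. Rendering a region keeps tiles
#' small; coordinates stay in the slide frame via the tile offset.
#'
#' @param slide A `synthetic_slide`.
#' @param spacing_um Micrometers per rendered pixel (default 2).
#' @param blob_radius_um Drawn object radius (default 8 um; a one-to-few-cell
#'   footprint). Must be at least `2 * spacing_um`.
#' @param region Length-4 numeric `c(x0, y0, width, height)` um; default the
#'   whole tissue.
#' @param dab_od,hematoxylin_od Peak stain concentrations of drawn blobs.
#' @param noise Half-width of additive uniform intensity noise (default 2).
#' @param basis A [hdab_basis()].
#' @return An [rgb_tile()].
#' @export
render_ihc <- function(slide, spacing_um = 2, blob_radius_um = 8,
                       region = NULL, dab_od = 1.0, hematoxylin_od = 0.8,
                       noise = 2, basis = hdab_basis()) {
  stopifnot(inherits(slide, "synthetic_slide"))
  if (blob_radius_um < 2 * spacing_um)
    stop("blob_radius_um must be at least 2 * spacing_um")
  if (is.null(region))
    region <- c(0, 0, slide$config$width_mm * 1000,
                slide$config$height_mm * 1000)
  nr <- max(1L, as.integer(ceiling(region[4] / spacing_um)))
  nc <- max(1L, as.integer(ceiling(region[3] / spacing_um)))
  xs <- region[1] + (seq_len(nc) - 0.5) * spacing_um
  ys <- region[2] + (seq_len(nr) - 0.5) * spacing_um

  paint <- function(conc, px, py, od) {
    r2 <- blob_radius_um^2
    for (k in seq_along(px)) {
      jr <- which(abs(xs - px[k]) <= blob_radius_um)
      ir <- which(abs(ys - py[k]) <= blob_radius_um)
      if (!length(jr) || !length(ir)) next
      blk <- outer((ys[ir] - py[k])^2, (xs[jr] - px[k])^2, "+") <= r2
      sub <- conc[ir, jr, drop = FALSE]
      sub[blk] <- pmax(sub[blk], od)
      conc[ir, jr] <- sub
    }
    conc
  }
  c_dab <- paint(matrix(0, nr, nc), slide$true_buds$x_um,
                 slide$true_buds$y_um, dab_od)
  c_hem <- paint(matrix(0, nr, nc), slide$distractors$x_um,
                 slide$distractors$y_um, hematoxylin_od)

  m <- unclass(basis)
  px <- array(0, dim = c(nr, nc, 3L))
  for (ch in 1:3) {
    od <- c_hem * m[1, ch] + c_dab * m[2, ch]
    px[, , ch] <- 255 * 10^(-od)
  }
  if (noise > 0)
    px <- px + runif(length(px), -noise, noise)
  px[px < 0] <- 0; px[px > 255] <- 255
  rgb_tile(px, spacing_um = spacing_um, offset = region[1:2])
}
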