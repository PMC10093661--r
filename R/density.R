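#' Tumor-bud density map by disk-scan counting
#'
#' For every raster cell the number of counted detections lying within
#' `radius_um` (closed disk) of the cell center is recorded. This is the exact
#' point-in-disk count at cell centers: detection coordinates are never binned,
#' so the map is independent of how points fall relative to cell boundaries.
#'
#' @param detections A detection table (see [detection_table()]).
#' @param geometry A [slide_geometry()], or `NULL` to use the detections'
#'   bounding box padded by `radius_um` at `spacing_um` per cell.
#' @param radius_um Disk radius, micrometers; default 500 (the 0.785 mm^2
#'   scoring field).
#' @param spacing_um Raster spacing when `geometry` is `NULL`.
#' @param tb_only If `TRUE` (default) only rows labeled `"TB"` are counted;
#'   otherwise every row is counted.
#' @return An object of class `density_map`: a list with the integer matrix
#'   `counts` (rows = raster rows), `geometry`, `radius_um`, `total_buds`, and
#'   after [normalize_density()] also `normalized`.
#' @seealso [select_hotspots()], [shannon_entropy()]
#' @export
compute_density <- function(detections, geometry = NULL, radius_um = 500,
                            spacing_um = 8, tb_only = TRUE) {
  detections <- validate_detections(detections)
  if (!is.numeric(radius_um) || radius_um <= 0) stop("radius_um must be > 0")
  keep <- if (tb_only) is_tb(detections) else rep(TRUE, nrow(detections))
  px <- detections$x_um[keep]; py <- detections$y_um[keep]
  if (is.null(geometry)) {
    if (length(px) == 0)
      stop("cannot derive a geometry from an empty detection set; ",
           "pass 'geometry' explicitly")
    geometry <- geometry_from_points(px, py, pad_um = radius_um,
                                     spacing_um = spacing_um)
  }
  stopifnot(inherits(geometry, "slide_geometry"))

  counts <- matrix(0L, geometry$nrow, geometry$ncol)
  xc <- col_centers(geometry); yc <- row_centers(geometry)
  r2 <- radius_um^2
  sp <- geometry$spacing_um
  # per-detection window accumulation: each point only touches cells whose
  # centers can lie within the disk
  for (k in seq_along(px)) {
    jr <- which(abs(xc - px[k]) <= radius_um)
    ir <- which(abs(yc - py[k]) <= radius_um)
    if (!length(jr) || !length(ir)) next
    dx2 <- (xc[jr] - px[k])^2
    dy2 <- (yc[ir] - py[k])^2
    inside <- outer(dy2, dx2, "+") <= r2
    counts[ir, jr] <- counts[ir, jr] + inside
  }
  structure(list(counts = counts, geometry = geometry,
                 radius_um = as.numeric(radius_um),
                 total_buds = length(px), normalized = NULL,
                 zero_density = length(px) == 0L),
            class = "density_map")
}

#' Normalize a density map by the slide's total bud count
#'
#' Divides every cell by the total number of counted buds, giving the fraction
#' of the slide's budding burden captured by each scoring field. With zero
#' buds no normalized grid is produced and the `zero_density` flag is set.
#'
#' @param map A `density_map` from [compute_density()].
#' @return The map with a `normalized` matrix in `[0, 1]` (or `NULL` when
#'   `total_buds == 0`).
#' @export
normalize_density <- function(map) {
  stopifnot(inherits(map, "density_map"))
  if (map$total_buds > 0) {
    map$normalized <- map$counts / map$total_buds
    map$zero_density <- FALSE
  } else {
    map$normalized <- NULL
    map$zero_density <- TRUE
  }
  map
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf(
    "density_map: %d x %d cells (%.1f um), radius %.0f um, %d bud(s), max %d\n",
    x$geometry$nrow, x$geometry$ncol, x$geometry$spacing_um, x$radius_um,
    x$total_buds, max(x$counts)))
  if (isTRUE(x$zero_density)) cat("  (zero density: no buds counted)\n")
  invisible(x)
}

#' @export
plot.density_map <- function(x, hotspots = NULL, main = "tumor-bud density",
                             ...) {
  g <- x$geometry
  image(col_centers(g), row_centers(g), t(x$counts)[, g$nrow:1, drop = FALSE],
        col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
        xlab = "x (um)", ylab = "y (um, flipped)", main = main,
        useRaster = TRUE, asp = 1, ...)
  if (!is.null(hotspots) && nrow(hotspots) > 0) {
    th <- seq(0, 2 * pi, length.out = 120)
    for (i in seq_len(nrow(hotspots)))
      lines(hotspots$cx_um[i] + hotspots$radius_um[i] * cos(th),
            g$offset[2] + g$height_um -
              (hotspots$cy_um[i] - g$offset[2]) +
              hotspots$radius_um[i] * sin(th))
  }
  invisible(x)
}
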