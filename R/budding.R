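#' Quantify tumor budding on one slide
#'
#' The central per-slide analysis: from a table of bud detections it computes
#' the disk-scan density map, extracts the `k` strongest non-overlapping
#' hotspots, scores the rank-1 hotspot count on the ITBCC three-tier scale,
#' and summarizes the spatial spread of budding as Shannon entropy of the
#' density map.
#'
#' @param detections A detection table (see [detection_table()]); only
#'   `"TB"`-labeled rows are counted unless `tb_only = FALSE`.
#' @param geometry Optional [slide_geometry()]; defaults to the detections'
#'   bounding box padded by `radius_um`.
#' @param radius_um Hotspot field radius, micrometers (default 500 = 0.5 mm,
#'   a 0.785 mm^2 field).
#' @param spacing_um Density raster spacing (default 8 um).
#' @param k Number of hotspots to extract (default 10).
#' @param tb_only Count only `"TB"`-labeled rows (default `TRUE`).
#' @return An object of class `tb_budding`: a list with `detections`,
#'   `density` (a `density_map`, normalized), `hotspots`, `score` (list with
#'   `count` and `tier`), `entropy` (an `entropy_score`, or `NULL` for a
#'   zero-density slide), and the call parameters.
#' @examples
#' sl <- simulate_slide(simulation_config(width_mm = 4, height_mm = 4,
#'                                        seed = 7))
#' fit <- tb_budding(sl$true_buds, geometry = sl$geometry)
#' fit
#' coef(fit)
#' @export
tb_budding <- function(detections, geometry = NULL, radius_um = 500,
                       spacing_um = 8, k = 10, tb_only = TRUE) {
  density <- compute_density(detections, geometry = geometry,
                             radius_um = radius_um, spacing_um = spacing_um,
                             tb_only = tb_only)
  density <- normalize_density(density)
  hs <- suppressWarnings(select_hotspots(density, k = k))
  count <- if (nrow(hs)) hs$count[1] else 0L
  entropy <- if (density$total_buds > 0) shannon_entropy(density) else NULL
  structure(list(detections = detections, density = density, hotspots = hs,
                 score = list(count = count, tier = itbcc_tier(count)),
                 entropy = entropy,
                 params = list(radius_um = radius_um, spacing_um = spacing_um,
                               k = k, tb_only = tb_only)),
            class = "tb_budding")
}

#' @export
print.tb_budding <- function(x, ...) {
  cat("Tumor budding quantification\n")
  cat(sprintf("  buds counted: %d; hotspots extracted: %d (radius %.0f um)\n",
              x$density$total_buds, nrow(x$hotspots), x$params$radius_um))
  cat(sprintf("  hotspot count: %d  ->  ITBCC tier %s\n",
              x$score$count, as.character(x$score$tier)))
  if (!is.null(x$entropy))
    cat(sprintf("  density entropy: %.4f (normalized %.4f)\n",
                x$entropy$entropy, x$entropy$normalized_entropy))
  else cat("  density entropy: undefined (zero-density slide)\n")
  invisible(x)
}

#' @export
summary.tb_budding <- function(object, ...) {
  cat("Tumor budding quantification\n\n")
  print(object$density)
  if (nrow(object$hotspots)) {
    cat("\nHotspots (rank / center um / count):\n")
    print(as.data.frame(object$hotspots)[, c("rank", "cx_um", "cy_um",
                                             "count")], row.names = FALSE)
  } else cat("\nNo hotspots (zero density).\n")
  cat(sprintf("\nITBCC: %d bud(s) in the rank-1 field -> %s\n",
              object$score$count, as.character(object$score$tier)))
  if (!is.null(object$entropy)) print(object$entropy)
  invisible(object)
}

#' @export
coef.tb_budding <- function(object, ...) {
  c(hotspot_count = as.numeric(object$score$count),
    tier = as.numeric(object$score$tier),
    total_buds = as.numeric(object$density$total_buds),
    entropy = if (is.null(object$entropy)) NA_real_ else
      object$entropy$entropy,
    normalized_entropy = if (is.null(object$entropy)) NA_real_ else
      object$entropy$normalized_entropy)
}

#' @export
plot.tb_budding <- function(x, ...) {
  plot(x$density, hotspots = x$hotspots,
       main = sprintf("density map (tier %s, %d buds in hotspot)",
                      as.character(x$score$tier), x$score$count), ...)
  invisible(x)
}
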