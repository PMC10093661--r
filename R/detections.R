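#' Detection tables
#'
#' A detection table is a plain `data.frame` with one row per candidate object
#' and the columns
#' \describe{
#'   \item{x_um, y_um}{position in micrometers, slide frame}
#'   \item{likelihood}{detector confidence in `[0, 1]`; `NA` when no detector
#'     produced the object (e.g. manual annotations)}
#'   \item{label}{`"TB"` (tumor bud), `"NON_TB"`, or `"UNLABELED"`}
#'   \item{certainty}{supervision weight in `[0, 1]`; manual annotations carry
#'     1.0, pseudo-labels a reduced value (default 0.80)}
#'   \item{source}{`"MANUAL"`, `"PSEUDO"`, or `"DETECTOR"`}
#' }
#' `detection_table()` builds and validates such a table; `is_tb()` returns the
#' rows counted as tumor buds.
#'
#' @param x_um,y_um Numeric coordinate vectors (micrometers).
#' @param likelihood Numeric in `[0, 1]` or `NA`; recycled.
#' @param label Character; one of `"TB"`, `"NON_TB"`, `"UNLABELED"`; recycled.
#' @param certainty Numeric in `[0, 1]`; recycled.
#' @param source Character; one of `"MANUAL"`, `"PSEUDO"`, `"DETECTOR"`;
#'   recycled.
#' @param slide_id Optional slide identifier; recycled.
#' @return A validated `data.frame` of detections.
#' @examples
#' detection_table(c(100, 200), c(100, 300), likelihood = 0.9,
#'                 label = "TB", source = "DETECTOR")
#' @export
detection_table <- function(x_um, y_um, likelihood = NA_real_,
                            label = "UNLABELED", certainty = NA_real_,
                            source = "DETECTOR", slide_id = NULL) {
  n <- length(x_um)
  stopifnot(length(y_um) == n)
  d <- data.frame(
    x_um = as.numeric(x_um),
    y_um = as.numeric(y_um),
    likelihood = rep_len(as.numeric(likelihood), n),
    label = rep_len(as.character(label), n),
    certainty = rep_len(as.numeric(certainty), n),
    source = rep_len(as.character(source), n),
    stringsAsFactors = FALSE
  )
  if (!is.null(slide_id)) d$slide_id <- rep_len(slide_id, n)
  validate_detections(d)
}

DETECTION_LABELS <- c("TB", "NON_TB", "UNLABELED")
DETECTION_SOURCES <- c("MANUAL", "PSEUDO", "DETECTOR")

#' @rdname detection_table
#' @param d A detection table.
#' @export
validate_detections <- function(d) {
  stopifnot(is.data.frame(d))
  need <- c("x_um", "y_um", "likelihood", "label", "certainty", "source")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("detection table lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(d$label %in% DETECTION_LABELS))
    stop("label must be one of ", paste(DETECTION_LABELS, collapse = "/"))
  if (!all(d$source %in% DETECTION_SOURCES))
    stop("source must be one of ", paste(DETECTION_SOURCES, collapse = "/"))
  bad_l <- !is.na(d$likelihood) & (d$likelihood < 0 | d$likelihood > 1)
  bad_c <- !is.na(d$certainty) & (d$certainty < 0 | d$certainty > 1)
  if (any(bad_l)) stop("likelihood outside [0, 1]")
  if (any(bad_c)) stop("certainty outside [0, 1]")
  if (any(d$source == "MANUAL" & d$label == "UNLABELED"))
    stop("MANUAL detections must carry a TB or NON_TB label")
  d
}

#' @rdname detection_table
#' @export
is_tb <- function(d) d$label == "TB"

#' Slide raster geometry
#'
#' Describes the raster on which density maps are computed: physical extent in
#' micrometers and the spacing of one raster cell. Cell (i, j) (1-based row,
#' column) has its center at `offset + ((j - 0.5) * spacing, (i - 0.5) *
#' spacing)`.
#'
#' @param width_um,height_um Physical extent, micrometers (> 0).
#' @param spacing_um Micrometers per raster cell (> 0). Density maps default to
#'   8 um; the hotspot localization error is then at most half a cell, which is
#'   negligible against the 500 um field radius.
#' @param offset Length-2 numeric, micrometers: slide-frame position of the
#'   raster's top-left corner.
#' @return An object of class `slide_geometry`.
#' @export
slide_geometry <- function(width_um, height_um, spacing_um = 8,
                           offset = c(0, 0)) {
  if (!is.numeric(width_um) || width_um <= 0 ||
      !is.numeric(height_um) || height_um <= 0 ||
      !is.numeric(spacing_um) || spacing_um <= 0)
    stop("width_um, height_um and spacing_um must all be positive")
  stopifnot(length(offset) == 2L, is.numeric(offset))
  structure(list(
    width_um = as.numeric(width_um), height_um = as.numeric(height_um),
    spacing_um = as.numeric(spacing_um), offset = as.numeric(offset),
    nrow = max(1L, as.integer(ceiling(height_um / spacing_um))),
    ncol = max(1L, as.integer(ceiling(width_um / spacing_um)))
  ), class = "slide_geometry")
}

#' @export
print.slide_geometry <- function(x, ...) {
  cat(sprintf("slide_geometry: %.0f x %.0f um at %.2f um/cell (%d x %d cells)\n",
              x$width_um, x$height_um, x$spacing_um, x$nrow, x$ncol))
  invisible(x)
}

# centers of raster columns / rows in slide-frame micrometers
col_centers <- function(g) g$offset[1] + (seq_len(g$ncol) - 0.5) * g$spacing_um
row_centers <- function(g) g$offset[2] + (seq_len(g$nrow) - 0.5) * g$spacing_um

# geometry covering a detection set: bounding box padded by `pad_um`
geometry_from_points <- function(x, y, pad_um, spacing_um = 8) {
  stopifnot(length(x) == length(y), length(x) > 0)
  x0 <- min(x) - pad_um; y0 <- min(y) - pad_um
  slide_geometry(width_um = diff(range(x)) + 2 * pad_um,
                 height_um = diff(range(y)) + 2 * pad_um,
                 spacing_um = spacing_um, offset = c(x0, y0))
}
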