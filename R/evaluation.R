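#' Sensitivity against a sparse candidate reference
#'
#' With a sparsely annotated reference (not every object on the slide is
#' labeled) only true positives and false negatives are identifiable, so the
#' detector is scored by sensitivity alone: the fraction of reference tumor
#' buds that have a predicted detection within `match_radius_um`. Matching is
#' greedy one-to-one nearest-first — candidate pairs within the radius are
#' sorted by distance (ties by reference then prediction index) and accepted
#' when both endpoints are still free — so one prediction cannot account for
#' two reference buds.
#'
#' @param reference Detection table with `"TB"`/`"NON_TB"` labels.
#' @param predicted Detection table of detector output.
#' @param match_radius_um Hit radius, micrometers (> 0); default 25.
#' @return List of class `sensitivity_report`: `n_reference_tb`, `n_hit`,
#'   `sensitivity`, `match_radius_um`, and `hits` (indices of matched
#'   reference TBs).
#' @export
sensitivity <- function(reference, predicted, match_radius_um = 25) {
  reference <- validate_detections(reference)
  predicted <- validate_detections(predicted)
  stopifnot(match_radius_um > 0)
  ref <- reference[is_tb(reference), , drop = FALSE]
  n_ref <- nrow(ref)
  if (n_ref == 0)
    stop("undefined sensitivity: reference contains no TB-labeled objects")
  if (nrow(predicted) == 0)
    return(structure(list(n_reference_tb = n_ref, n_hit = 0L, sensitivity = 0,
                          match_radius_um = match_radius_um, hits = integer()),
                     class = "sensitivity_report"))
  # all candidate pairs within radius
  d2max <- match_radius_um^2
  pairs <- NULL
  for (i in seq_len(n_ref)) {
    d2 <- (predicted$x_um - ref$x_um[i])^2 + (predicted$y_um - ref$y_um[i])^2
    j <- which(d2 <= d2max)
    if (length(j))
      pairs <- rbind(pairs, cbind(i = i, j = j, d2 = d2[j]))
  }
  hits <- integer()
  if (!is.null(pairs)) {
    pairs <- pairs[order(pairs[, "d2"], pairs[, "i"], pairs[, "j"]), ,
                   drop = FALSE]
    used_ref <- rep(FALSE, n_ref)
    used_pred <- rep(FALSE, nrow(predicted))
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, "i"]; j <- pairs[k, "j"]
      if (!used_ref[i] && !used_pred[j]) {
        used_ref[i] <- TRUE; used_pred[j] <- TRUE
        hits <- c(hits, i)
      }
    }
  }
  structure(list(n_reference_tb = n_ref, n_hit = length(hits),
                 sensitivity = length(hits) / n_ref,
                 match_radius_um = match_radius_um, hits = sort(hits)),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("sensitivity: %.3f (%d / %d reference buds hit within %.0f um)\n",
              x$sensitivity, x$n_hit, x$n_reference_tb, x$match_radius_um))
  invisible(x)
}

#' Paired comparison of manual and automatic hotspot counts
#'
#' Pearson product-moment correlation between per-slide manual and automatic
#' bud counts from the same field, plus the mean count ratio
#' automatic / manual (a systematic over-detection shows up as a ratio above
#' 1).
#'
#' @param manual,auto Paired numeric count vectors (same slides, same order),
#'   or a two-column data frame in `manual`.
#' @return List of class `count_comparison`: `pearson_r`, `mean_ratio`,
#'   `n`, and the `pairs` data frame.
#' @export
compare_counts <- function(manual, auto = NULL) {
  if (is.data.frame(manual) && is.null(auto)) {
    stopifnot(ncol(manual) >= 2)
    auto <- manual[[2]]; manual <- manual[[1]]
  }
  stopifnot(length(manual) == length(auto))
  if (length(manual) < 3)
    stop("need at least 3 slide pairs")
  if (var(manual) == 0 || var(auto) == 0)
    stop("undefined correlation: a count vector has zero variance")
  structure(list(pearson_r = cor(manual, auto, method = "pearson"),
                 mean_ratio = mean(auto) / mean(manual),
                 n = length(manual),
                 pairs = data.frame(manual = manual, auto = auto)),
            class = "count_comparison")
}

#' @export
print.count_comparison <- function(x, ...) {
  cat(sprintf("count comparison over %d slides: Pearson r = %.3f, auto/manual ratio = %.2f\n",
              x$n, x$pearson_r, x$mean_ratio))
  invisible(x)
}

#' Cohort-level hotspot agreement fractions
#'
#' Aggregates per-slide [match_hotspots()] reports into the fractions of
#' slides whose manual hotspot matched an automatic hotspot in the top 3, in
#' the top 10, or not at all. By construction `top3 <= top10` and
#' `top10 + none = 1`.
#'
#' @param reports Non-empty list of `hotspot_match` objects.
#' @return List of class `hotspot_agreement`: `top3`, `top10`, `none`,
#'   `n_slides`.
#' @export
hotspot_agreement <- function(reports) {
  stopifnot(length(reports) > 0,
            all(vapply(reports, inherits, logical(1), "hotspot_match")))
  n <- length(reports)
  top3 <- mean(vapply(reports, `[[`, logical(1), "top3_match"))
  top10 <- mean(vapply(reports, `[[`, logical(1), "top10_match"))
  structure(list(top3 = top3, top10 = top10, none = 1 - top10, n_slides = n),
            class = "hotspot_agreement")
}

#' @export
print.hotspot_agreement <- function(x, ...) {
  cat(sprintf(
    "hotspot agreement over %d slides: top-3 %.0f%%, top-10 %.0f%%, none %.0f%%\n",
    x$n_slides, 100 * x$top3, 100 * x$top10, 100 * x$none))
  invisible(x)
}
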