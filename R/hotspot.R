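#' Iterative hotspot extraction with overlap suppression
#'
#' Greedy selection on the density map: (1) take the raster cell with the
#' highest in-disk bud count as the next hotspot center, recording its count;
#' (2) zero every cell whose center lies within one radius of that center;
#' (3) repeat until `k` hotspots are found or the map is exhausted. Zeroing a
#' full radius around each pick guarantees successive centers are at least one
#' radius apart, bounding the mutual overlap of reported fields.
#'
#' Ties at the argmax are broken by the smallest row-major cell index
#' (row first, then column), which makes selection deterministic.
#'
#' @param map A `density_map` from [compute_density()].
#' @param k Maximum number of hotspots (default 10).
#' @param radius_um Suppression/field radius; defaults to the map's radius and
#'   must equal it (counting and suppression use the same field).
#' @param detections Optional detection table. When supplied, the
#'   remove-and-recount mode (`recount = TRUE`) recomputes in-disk counts after
#'   deleting the buds inside each selected hotspot instead of zeroing cells.
#' @param recount Use remove-points-and-recount suppression (off by default;
#'   the zeroing semantics above are canonical).
#' @return A `data.frame` of class `hotspots` with columns `rank`, `cx_um`,
#'   `cy_um`, `radius_um`, `count`, `source`. Fewer than `k` rows (with a
#'   warning) when the density is exhausted first.
#' @export
select_hotspots <- function(map, k = 10, radius_um = NULL,
                            detections = NULL, recount = FALSE) {
  stopifnot(inherits(map, "density_map"), k >= 1)
  if (is.null(radius_um)) radius_um <- map$radius_um
  if (!isTRUE(all.equal(radius_um, map$radius_um)))
    stop("radius_um does not match the radius the density map was computed with")
  g <- map$geometry
  xc <- col_centers(g); yc <- row_centers(g)
  work <- map$counts
  pts <- NULL
  if (recount) {
    if (is.null(detections))
      stop("recount mode needs the detection table")
    keep <- is_tb(detections)
    pts <- cbind(detections$x_um[keep], detections$y_um[keep])
  }

  out <- vector("list", k)
  nsel <- 0L
  for (iter in seq_len(k)) {
    m <- max(work)
    if (m <= 0L) break
    idx <- which(work == m)                   # column-major positions
    ii <- ((idx - 1L) %% g$nrow) + 1L
    jj <- ((idx - 1L) %/% g$nrow) + 1L
    first <- order(ii, jj)[1L]                # row-major tie-break
    i <- ii[first]; j <- jj[first]
    nsel <- nsel + 1L
    out[[nsel]] <- data.frame(rank = nsel, cx_um = xc[j], cy_um = yc[i],
                              radius_um = radius_um, count = as.integer(m),
                              source = "AUTO", stringsAsFactors = FALSE)
    if (recount) {
      inside <- (pts[, 1] - xc[j])^2 + (pts[, 2] - yc[i])^2 <= radius_um^2
      pts <- pts[!inside, , drop = FALSE]
      sub <- compute_density(
        detection_table(pts[, 1], pts[, 2], label = "TB", source = "DETECTOR"),
        geometry = g, radius_um = radius_um, tb_only = TRUE)
      work <- sub$counts
      next
    }
    # zero all cells whose centers fall within radius of the chosen center
    jr <- which(abs(xc - xc[j]) <= radius_um)
    ir <- which(abs(yc - yc[i]) <= radius_um)
    blk <- outer((yc[ir] - yc[i])^2, (xc[jr] - xc[j])^2, "+") <= radius_um^2
    sub <- work[ir, jr, drop = FALSE]
    sub[blk] <- 0L
    work[ir, jr] <- sub
  }
  if (nsel < k)
    warning(sprintf("density exhausted after %d hotspot(s) (requested %d)",
                    nsel, k))
  res <- if (nsel) do.call(rbind, out[seq_len(nsel)]) else
    data.frame(rank = integer(), cx_um = numeric(), cy_um = numeric(),
               radius_um = numeric(), count = integer(),
               source = character(), stringsAsFactors = FALSE)
  class(res) <- c("hotspots", "data.frame")
  res
}

#' Count tumor buds inside a circle
#'
#' Boundary-inclusive in-disk count of `"TB"`-labeled detections; used both
#' for automatic fields and to re-count inside manually placed hotspots.
#'
#' @param detections A detection table.
#' @param circle A [circle()].
#' @param tb_only Count only `"TB"` rows (default).
#' @return Integer count.
#' @export
count_in_circle <- function(detections, circle, tb_only = TRUE) {
  detections <- validate_detections(detections)
  keep <- if (tb_only) is_tb(detections) else rep(TRUE, nrow(detections))
  sum(point_in_circle(detections$x_um[keep], detections$y_um[keep], circle))
}

#' Match a manual hotspot against ranked automatic hotspots
#'
#' The best match is the lowest-rank automatic hotspot whose dice overlap with
#' the manual field reaches `dice_threshold` (default 0.7). The report flags
#' whether that rank falls in the top 3 or top 10, or whether no automatic
#' field matches at all.
#'
#' @param manual A [circle()] (the manually selected field), or a one-row
#'   `hotspots` data frame.
#' @param auto A `hotspots` data frame ordered by rank, as returned by
#'   [select_hotspots()].
#' @param dice_threshold Match threshold in (0, 1]; default 0.7.
#' @return A list of class `hotspot_match`: `matched_rank` (or `NA`),
#'   `dice` of the best match, and logical `top3_match`, `top10_match`,
#'   `no_match`.
#' @export
match_hotspots <- function(manual, auto, dice_threshold = 0.7) {
  stopifnot(dice_threshold > 0, dice_threshold <= 1)
  if (inherits(manual, "data.frame")) {
    stopifnot(nrow(manual) == 1L)
    manual <- circle(manual$cx_um, manual$cy_um, manual$radius_um)
  }
  stopifnot(inherits(manual, "circle"))
  res <- list(matched_rank = NA_integer_, dice = NA_real_,
              top3_match = FALSE, top10_match = FALSE, no_match = TRUE)
  if (!is.null(auto) && nrow(auto) > 0) {
    o <- order(auto$rank)
    for (i in o) {
      d <- circle_dice(manual,
                       circle(auto$cx_um[i], auto$cy_um[i], auto$radius_um[i]))
      if (d >= dice_threshold) {
        res$matched_rank <- auto$rank[i]
        res$dice <- d
        res$top10_match <- auto$rank[i] <= 10L
        res$top3_match <- auto$rank[i] <= 3L
        res$no_match <- !res$top10_match
        break
      }
    }
  }
  class(res) <- "hotspot_match"
  res
}

#' @export
print.hotspot_match <- function(x, ...) {
  if (is.na(x$matched_rank)) cat("hotspot match: none\n")
  else cat(sprintf("hotspot match: rank %d (dice %.3f)%s\n", x$matched_rank,
                   x$dice, if (x$top3_match) " [top 3]" else
                     if (x$top10_match) " [top 10]" else ""))
  invisible(x)
}
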