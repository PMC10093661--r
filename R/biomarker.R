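#' ITBCC three-tier budding score
#'
#' Converts a hotspot bud count into the consensus three-tier score:
#' Bd1 (low, 0--4 buds), Bd2 (intermediate, 5--9), Bd3 (high, 10 or more).
#'
#' @param count Non-negative integer bud count(s); vectorized.
#' @return Factor with levels `Bd1 < Bd2 < Bd3`.
#' @examples
#' itbcc_tier(c(0, 4, 5, 9, 10, 40))
#' @export
itbcc_tier <- function(count) {
  if (!is.numeric(count) || any(!is.finite(count)) || any(count < 0))
    stop("'count' must be non-negative")
  if (any(count != floor(count))) stop("'count' must be whole numbers")
  tier <- ifelse(count >= 10, "Bd3", ifelse(count >= 5, "Bd2", "Bd1"))
  factor(tier, levels = c("Bd1", "Bd2", "Bd3"), ordered = TRUE)
}

#' Shannon entropy of a density map
#'
#' Quantifies how the budding burden is spread over the slide. The cell counts
#' of the density map are normalized to a probability distribution p over
#' raster cells and H = -sum p log p is returned, together with H / log(K)
#' (K = number of raster cells), which is 1 for a perfectly uniform spread and
#' 0 when all density mass sits in a single cell.
#'
#' @param map A `density_map`, or a numeric matrix/vector of non-negative
#'   weights.
#' @param base Logarithm base; default `exp(1)` (nats).
#' @return A list of class `entropy_score`: `entropy`, `normalized_entropy`,
#'   `n_support` (cells with positive density), `n_cells`, `base`.
#'   An all-zero map gives an error (`undefined entropy`), which is distinct
#'   from an entropy of zero.
#' @export
shannon_entropy <- function(map, base = exp(1)) {
  w <- if (inherits(map, "density_map")) map$counts else map
  if (!is.numeric(w) || any(w < 0)) stop("density weights must be non-negative")
  tot <- sum(w)
  if (tot <= 0) stop("undefined entropy: density map has no positive cells")
  p <- as.numeric(w) / tot
  pos <- p > 0
  h <- -sum(p[pos] * log(p[pos], base = base))
  k <- length(p)
  structure(list(entropy = h,
                 normalized_entropy = if (k > 1) h / log(k, base = base) else NA_real_,
                 n_support = sum(pos), n_cells = k, base = base),
            class = "entropy_score")
}

#' @export
print.entropy_score <- function(x, ...) {
  cat(sprintf("Shannon entropy: %.4f (normalized %.4f over %d cells, %d with mass)\n",
              x$entropy, x$normalized_entropy, x$n_cells, x$n_support))
  invisible(x)
}

#' Dichotomize per-slide biomarker values
#'
#' Splits continuous per-slide scores into high/low groups for downstream
#' survival or association analysis. Three rules are supported:
#' \describe{
#'   \item{`"median"`}{high iff value > median of the cohort (ties go low);
#'     the rule used for fully automated counts and entropies}
#'   \item{`"itbcc"`}{high iff the count maps to tier Bd3 (>= 10 buds);
#'     `itbcc_high` can lower this to Bd2+Bd3 (>= 5)}
#'   \item{`"fixed"`}{high iff value > `cutoff`}
#' }
#'
#' @param values Numeric per-slide values (non-empty).
#' @param rule `"median"`, `"itbcc"` or `"fixed"`.
#' @param cutoff Threshold for `rule = "fixed"`.
#' @param itbcc_high Tiers counted as high under `"itbcc"`; default `"Bd3"`.
#' @return A list with `labels` (factor `low`/`high`), `cutoff` (the value
#'   used; `NA` for `"itbcc"`), and `rule`.
#' @examples
#' dichotomize(c(1, 2, 3, 4))                 # cutoff 2.5
#' dichotomize(c(3, 7, 12), rule = "itbcc")
#' @export
dichotomize <- function(values, rule = c("median", "itbcc", "fixed"),
                        cutoff = NULL, itbcc_high = c("Bd3", "Bd2")) {
  rule <- match.arg(rule)
  if (!length(values)) stop("'values' must be non-empty")
  if (rule == "median") {
    cutoff <- median(values)
    high <- values > cutoff
  } else if (rule == "fixed") {
    if (is.null(cutoff)) stop("rule 'fixed' needs a 'cutoff'")
    high <- values > cutoff
  } else {
    itbcc_high <- match.arg(itbcc_high)
    tier <- itbcc_tier(values)
    high <- if (itbcc_high == "Bd3") tier == "Bd3" else tier >= "Bd2"
    cutoff <- NA_real_
  }
  list(labels = factor(ifelse(high, "high", "low"), levels = c("low", "high")),
       cutoff = cutoff, rule = rule)
}
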