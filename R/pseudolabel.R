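#' Pseudo-labeling configuration
#'
#' Bundles the thresholds of the teacher--student dataset construction:
#' teacher detections are kept only above a strict likelihood threshold
#' (default > 0.80), retained pseudo-labels carry a reduced certainty of 0.80
#' while manual annotations keep 1.0, a pseudo-label colliding with a manual
#' annotation is dropped in favor of the manual one, and candidates outside
#' the DAB-positive mask are rejected.
#'
#' @param likelihood_threshold Strict lower bound on teacher likelihood,
#'   in (0, 1); default 0.80.
#' @param pseudo_certainty Certainty given to retained pseudo-labels
#'   (default 0.80); must not exceed `manual_certainty`.
#' @param manual_certainty Certainty of manual annotations (default 1.0).
#' @param collision_radius_um Pseudo-labels within this distance of a manual
#'   annotation are dropped; default 15 um (about one cell diameter).
#' @param mask_tolerance_um Maximum distance from a DAB-positive pixel center
#'   at which a candidate still passes the mask filter; default 0 (the point
#'   must land on a positive pixel).
#' @param patch_side_px,patch_spacing_um Training patch geometry recorded in
#'   the manifest (defaults 512 px at 1 um/px).
#' @return A list of class `pseudolabel_config`.
#' @export
pseudolabel_config <- function(likelihood_threshold = 0.80,
                               pseudo_certainty = 0.80,
                               manual_certainty = 1.0,
                               collision_radius_um = 15,
                               mask_tolerance_um = 0,
                               patch_side_px = 512L,
                               patch_spacing_um = 1) {
  stopifnot(likelihood_threshold > 0, likelihood_threshold < 1,
            pseudo_certainty >= 0, pseudo_certainty <= manual_certainty,
            manual_certainty <= 1, collision_radius_um >= 0,
            mask_tolerance_um >= 0)
  structure(list(likelihood_threshold = likelihood_threshold,
                 pseudo_certainty = pseudo_certainty,
                 manual_certainty = manual_certainty,
                 collision_radius_um = collision_radius_um,
                 mask_tolerance_um = mask_tolerance_um,
                 patch_side_px = as.integer(patch_side_px),
                 patch_spacing_um = patch_spacing_um),
            class = "pseudolabel_config")
}

#' Likelihood filter for teacher detections
#'
#' Retains detections whose likelihood is strictly greater than the threshold;
#' a likelihood of exactly 0.80 is rejected at the default. Manual-source
#' detections bypass the filter (they carry no teacher likelihood).
#'
#' @param detections A detection table.
#' @param threshold Strict lower bound; default 0.80.
#' @return The retained subset, row order preserved.
#' @export
filter_by_likelihood <- function(detections, threshold = 0.80) {
  detections <- validate_detections(detections)
  manual <- detections$source == "MANUAL"
  keep <- manual | (!is.na(detections$likelihood) &
                      detections$likelihood > threshold)
  detections[keep, , drop = FALSE]
}

#' DAB-mask filter for pseudo-label candidates
#'
#' A non-manual detection is retained only when its point lands on a
#' DAB-positive mask pixel, or within `tolerance_um` of the center of one.
#' Detections outside the mask extent are rejected (attributed reason
#' `"out_of_extent"`). Manual detections bypass the filter.
#'
#' @param detections A detection table.
#' @param mask A [dab_mask()].
#' @param tolerance_um Distance tolerance; default 0 (strict containment).
#' @return The retained subset; attribute `"rejected"` holds a data frame of
#'   dropped rows with a `reason` column.
#' @export
filter_by_dab <- function(detections, mask, tolerance_um = 0) {
  detections <- validate_detections(detections)
  stopifnot(inherits(mask, "dab_mask"), tolerance_um >= 0)
  n <- nrow(detections)
  if (n == 0) return(detections)
  nr <- nrow(mask$mask); nc <- ncol(mask$mask); sp <- mask$spacing_um
  # pixel indices containing each point
  jj <- floor((detections$x_um - mask$offset[1]) / sp) + 1
  ii <- floor((detections$y_um - mask$offset[2]) / sp) + 1
  in_extent <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
  keep <- detections$source == "MANUAL"
  reason <- rep(NA_character_, n)
  pos <- which(mask$mask)
  pix_x <- mask$offset[1] + (((pos - 1L) %/% nr) + 0.5) * sp
  pix_y <- mask$offset[2] + (((pos - 1L) %% nr) + 0.5) * sp
  for (k in which(!keep)) {
    if (!in_extent[k]) { reason[k] <- "out_of_extent"; next }
    if (mask$mask[ii[k], jj[k]]) { keep[k] <- TRUE; next }
    if (tolerance_um > 0 && length(pos)) {
      d2 <- (pix_x - detections$x_um[k])^2 + (pix_y - detections$y_um[k])^2
      if (min(d2) <= tolerance_um^2) { keep[k] <- TRUE; next }
    }
    reason[k] <- "outside_dab_mask"
  }
  out <- detections[keep, , drop = FALSE]
  rej <- detections[!keep, , drop = FALSE]
  if (nrow(rej)) rej$reason <- reason[!keep]
  attr(out, "rejected") <- rej
  out
}

#' Merge pseudo-labels with manual annotations into a training manifest
#'
#' Manual annotations are always retained and stamped with
#' `manual_certainty` (1.0); pseudo-labels are stamped with
#' `pseudo_certainty` (0.80), relabeled `"TB"` and `"PSEUDO"`-sourced, and a
#' pseudo-label within `collision_radius_um` of any manual annotation is
#' dropped so that no object is supervised twice. The result carries the
#' training-patch geometry for each record.
#'
#' @param pseudo Detection table of filtered teacher candidates.
#' @param manual Detection table of manual annotations (source `"MANUAL"`).
#' @param config A [pseudolabel_config()].
#' @return A `data.frame` of class `training_manifest` with the detection
#'   columns plus `patch_side_px` and `patch_spacing_um`; attribute
#'   `"n_collisions"` records how many pseudo-labels were dropped.
#' @export
merge_and_weight <- function(pseudo, manual, config = pseudolabel_config()) {
  pseudo <- validate_detections(pseudo)
  manual <- validate_detections(manual)
  stopifnot(inherits(config, "pseudolabel_config"))
  if (nrow(manual) && !all(manual$source == "MANUAL"))
    stop("'manual' must contain only MANUAL-source detections")
  manual$certainty <- rep(config$manual_certainty, nrow(manual))
  if (nrow(pseudo)) {
    pseudo$source <- "PSEUDO"
    pseudo$label <- "TB"
    pseudo$certainty <- config$pseudo_certainty
  }
  collide <- rep(FALSE, nrow(pseudo))
  if (nrow(pseudo) && nrow(manual) && config$collision_radius_um >= 0) {
    r2 <- config$collision_radius_um^2
    for (k in seq_len(nrow(pseudo))) {
      d2 <- (manual$x_um - pseudo$x_um[k])^2 + (manual$y_um - pseudo$y_um[k])^2
      collide[k] <- any(d2 <= r2)
    }
  }
  common <- intersect(names(manual), names(pseudo))
  out <- rbind(manual[common], pseudo[!collide, common, drop = FALSE])
  rownames(out) <- NULL
  out$patch_side_px <- config$patch_side_px
  out$patch_spacing_um <- config$patch_spacing_um
  attr(out, "n_collisions") <- sum(collide)
  class(out) <- c("training_manifest", "data.frame")
  out
}

#' Full pseudo-label dataset construction
#'
#' Convenience pipeline: likelihood filter, optional DAB-mask filter, then
#' merge with manual annotations under certainty weights.
#'
#' @param teacher Detection table of raw teacher detections.
#' @param manual Detection table of manual annotations.
#' @param mask Optional [dab_mask()].
#' @param config A [pseudolabel_config()].
#' @return A `training_manifest` (see [merge_and_weight()]).
#' @export
build_training_manifest <- function(teacher, manual, mask = NULL,
                                    config = pseudolabel_config()) {
  keep <- filter_by_likelihood(teacher, config$likelihood_threshold)
  keep <- keep[keep$source != "MANUAL", , drop = FALSE]
  if (!is.null(mask))
    keep <- filter_by_dab(keep, mask, config$mask_tolerance_um)
  merge_and_weight(keep, manual, config)
}
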