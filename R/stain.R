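#' RGB IHC tile
#'
#' A small image tile in slide coordinates: an H x W x 3 array of intensities
#' in `[0, 255]` with its pixel size and the slide-frame position of the
#' top-left pixel corner.
#'
#' @param pixels Numeric H x W x 3 array, values in `[0, 255]`.
#' @param spacing_um Micrometers per pixel (> 0).
#' @param offset Length-2 numeric `(x, y)` in micrometers.
#' @return An object of class `rgb_tile`.
#' @export
rgb_tile <- function(pixels, spacing_um, offset = c(0, 0)) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L,
            spacing_um > 0, length(offset) == 2L)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("tile intensities must lie in [0, 255]")
  structure(list(pixels = pixels, spacing_um = as.numeric(spacing_um),
                 offset = as.numeric(offset)),
            class = "rgb_tile")
}

#' H-DAB stain basis for color deconvolution
#'
#' Unit optical-density vectors for hematoxylin and DAB, using the published
#' Ruifrok--Johnston values; the third (residual) vector is their normalized
#' cross product and absorbs any remaining chromogen (e.g. a red CD8 dye),
#' which is ignored downstream. Per-slide bases may be supplied by passing
#' explicit vectors.
#'
#' @param hematoxylin,dab Length-3 numeric OD vectors; normalized internally.
#' @return A `stain_basis`: 3 x 3 matrix with rows hematoxylin, dab, residual.
#' @export
hdab_basis <- function(hematoxylin = c(0.650, 0.704, 0.286),
                       dab = c(0.268, 0.570, 0.776)) {
  stopifnot(length(hematoxylin) == 3L, length(dab) == 3L)
  h <- hematoxylin / sqrt(sum(hematoxylin^2))
  d <- dab / sqrt(sum(dab^2))
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  nr <- sqrt(sum(r^2))
  if (nr < 1e-8) stop("hematoxylin and dab vectors are collinear")
  m <- rbind(hematoxylin = h, dab = d, residual = r / nr)
  structure(m, class = c("stain_basis", class(m)))
}

#' Color deconvolution of an RGB IHC tile
#'
#' Converts intensities to optical density, `OD_c = -log10((I_c + 1)/255)`
#' (the +1 guards `log(0)` at full black), and unmixes through the inverse of
#' the stain matrix into per-pixel hematoxylin, DAB and residual
#' concentrations. Negative concentrations (noise outside the stain simplex)
#' are clipped to zero.
#'
#' @param tile An [rgb_tile()].
#' @param basis A [hdab_basis()] (or compatible 3 x 3 stain matrix).
#' @return List of class `stain_concentrations` with H x W matrices
#'   `hematoxylin`, `dab`, `residual`, plus `spacing_um` and `offset`.
#' @export
deconvolve <- function(tile, basis = hdab_basis()) {
  stopifnot(inherits(tile, "rgb_tile"))
  m <- unclass(basis)
  stopifnot(is.matrix(m), all(dim(m) == c(3L, 3L)))
  if (abs(det(m)) < 1e-8) stop("stain basis is singular")
  dm <- dim(tile$pixels)
  od <- -log10((matrix(tile$pixels, ncol = 3L) + 1) / 255)
  conc <- od %*% solve(m)            # rows: pixels; cols: stains
  conc[conc < 0] <- 0
  shape <- function(k) matrix(conc[, k], dm[1], dm[2])
  structure(list(hematoxylin = shape(1L), dab = shape(2L),
                 residual = shape(3L),
                 spacing_um = tile$spacing_um, offset = tile$offset),
            class = "stain_concentrations")
}

#' DAB-positive binary mask with connected components
#'
#' Thresholds the DAB concentration image, cleans it with a morphological
#' opening (disk structuring element), labels 8-connected components, and
#' removes components smaller than `min_area_um2`. The mask is the gate used
#' to reject pseudo-labeled candidates that fall outside chromogen-positive
#' tissue.
#'
#' @param dab A `stain_concentrations` object, or a numeric H x W DAB
#'   concentration matrix.
#' @param spacing_um,offset Geometry, taken from `dab` when it is a
#'   `stain_concentrations`.
#' @param od_threshold Concentration threshold (> 0); default 0.15.
#' @param min_area_um2 Minimum component area; default 30 um^2.
#' @param opening_radius_px Disk radius of the opening in pixels; 0 disables.
#' @return Object of class `dab_mask`: logical `mask`, `spacing_um`, `offset`,
#'   `od_threshold`, and a `components` data frame (`component`, `n_pixels`,
#'   `area_um2`, `cx_um`, `cy_um`) plus the integer `labels` matrix.
#' @export
dab_mask <- function(dab, spacing_um = NULL, offset = NULL,
                     od_threshold = 0.15, min_area_um2 = 30,
                     opening_radius_px = 1) {
  if (inherits(dab, "stain_concentrations")) {
    spacing_um <- dab$spacing_um; offset <- dab$offset
    dab <- dab$dab
  }
  stopifnot(is.matrix(dab), is.numeric(spacing_um), spacing_um > 0)
  if (is.null(offset)) offset <- c(0, 0)
  if (od_threshold <= 0) stop("od_threshold must be > 0")
  mask <- dab >= od_threshold
  if (opening_radius_px > 0 && any(mask)) {
    kern <- EBImage::makeBrush(2L * as.integer(opening_radius_px) + 1L,
                               shape = "disc")
    op <- EBImage::opening(EBImage::Image(mask * 1), kern)
    mask <- EBImage::imageData(op) > 0.5
  }
  lab <- label_components_8(mask)
  comp <- summarize_components(lab, spacing_um, offset)
  if (nrow(comp) > 0 && min_area_um2 > 0) {
    drop <- comp$component[comp$area_um2 < min_area_um2]
    if (length(drop)) {
      mask[lab %in% drop] <- FALSE
      lab[lab %in% drop] <- 0L
      comp <- comp[!(comp$component %in% drop), , drop = FALSE]
      # relabel 1..n to keep ids dense
      if (nrow(comp) > 0) {
        new <- match(lab, comp$component)
        lab <- matrix(ifelse(is.na(new), 0L, new), nrow(lab), ncol(lab))
        comp$component <- seq_len(nrow(comp))
      }
      rownames(comp) <- NULL
    }
  }
  structure(list(mask = mask, labels = lab, spacing_um = spacing_um,
                 offset = as.numeric(offset), od_threshold = od_threshold,
                 components = comp),
            class = "dab_mask")
}

# 8-connected labeling by vectorized frontier flood fill.
label_components_8 <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  todo <- which(mask)
  if (!length(todo)) return(lab)
  nxt <- 0L
  off_i <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  off_j <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  for (seed in todo) {
    if (lab[seed] != 0L) next
    nxt <- nxt + 1L
    lab[seed] <- nxt
    frontier <- seed
    while (length(frontier)) {
      fi <- ((frontier - 1L) %% nr) + 1L
      fj <- ((frontier - 1L) %/% nr) + 1L
      ni <- rep(fi, each = 8L) + off_i
      nj <- rep(fj, each = 8L) + off_j
      ok <- ni >= 1L & ni <= nr & nj >= 1L & nj <= nc
      idx <- unique((nj[ok] - 1L) * nr + ni[ok])
      idx <- idx[mask[idx] & lab[idx] == 0L]
      lab[idx] <- nxt
      frontier <- idx
    }
  }
  lab
}

summarize_components <- function(lab, spacing_um, offset) {
  pos <- which(lab > 0L)
  if (!length(pos))
    return(data.frame(component = integer(), n_pixels = integer(),
                      area_um2 = numeric(), cx_um = numeric(),
                      cy_um = numeric()))
  nr <- nrow(lab)
  ii <- ((pos - 1L) %% nr) + 1L
  jj <- ((pos - 1L) %/% nr) + 1L
  id <- lab[pos]
  n <- tapply(rep(1L, length(pos)), id, sum)
  # pixel centers in slide frame
  cx <- tapply(offset[1] + (jj - 0.5) * spacing_um, id, mean)
  cy <- tapply(offset[2] + (ii - 0.5) * spacing_um, id, mean)
  data.frame(component = as.integer(names(n)), n_pixels = as.integer(n),
             area_um2 = as.numeric(n) * spacing_um^2,
             cx_um = as.numeric(cx), cy_um = as.numeric(cy))
}

#' @export
print.dab_mask <- function(x, ...) {
  cat(sprintf(
    "dab_mask: %d x %d px (%.2f um/px), threshold %.2f OD, %d component(s), %.0f um^2 positive\n",
    nrow(x$mask), ncol(x$mask), x$spacing_um, x$od_threshold,
    nrow(x$components), sum(x$mask) * x$spacing_um^2))
  invisible(x)
}

#' Candidate detections from a DAB mask
#'
#' Emits one `DETECTOR`-source detection per mask component, at the component
#' centroid in slide-frame micrometers. A simple size heuristic sets the
#' likelihood: components whose area falls inside `bud_area_band` (a plausible
#' 1--4-cell bud footprint) get likelihood 1, all others 0.5. This classical
#' detector lets the downstream density/hotspot/scoring stages run without any
#' learned model.
#'
#' @param mask A [dab_mask()].
#' @param bud_area_band Length-2 numeric, um^2; default `c(50, 700)`.
#' @return A detection table (possibly zero rows).
#' @export
candidates_from_mask <- function(mask, bud_area_band = c(50, 700)) {
  stopifnot(inherits(mask, "dab_mask"), length(bud_area_band) == 2L)
  comp <- mask$components
  if (nrow(comp) == 0)
    return(detection_table(numeric(), numeric()))
  lk <- ifelse(comp$area_um2 >= bud_area_band[1] &
                 comp$area_um2 <= bud_area_band[2], 1, 0.5)
  detection_table(comp$cx_um, comp$cy_um, likelihood = lk,
                  label = "UNLABELED", certainty = NA_real_,
                  source = "DETECTOR")
}
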