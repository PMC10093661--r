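#' Read and write detection tables
#'
#' Detections travel as UTF-8 CSV (comma separator, dot decimal, `.` for
#' missing values) with the mandatory header columns `x_um, y_um, likelihood,
#' label, certainty, source` (plus optional `slide_id` and any extra columns,
#' which are preserved), or as a GeoJSON `FeatureCollection` of `Point`
#' features carrying the same names as properties. Coordinates are always
#' physical micrometers in a slide-local frame; raster indices never appear
#' in files.
#'
#' @param d A detection table.
#' @param path File path; format chosen by extension (`.csv` vs
#'   `.geojson`/`.json`) unless `format` is given.
#' @param format `"csv"` or `"geojson"`.
#' @return `read_detections()` returns a validated detection table;
#'   `write_detections()` returns `path` invisibly.
#' @export
write_detections <- function(d, path, format = NULL) {
  d <- validate_detections(d)
  format <- format %||% guess_format(path)
  if (format == "csv") {
    write.csv(d, path, row.names = FALSE, na = ".")
  } else {
    feats <- lapply(seq_len(nrow(d)), function(i) {
      props <- as.list(d[i, setdiff(names(d), c("x_um", "y_um")), drop = FALSE])
      props <- lapply(props, function(v) if (is.na(v)) NULL else v)
      props <- props[!vapply(props, is.null, logical(1))]
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(d$x_um[i], d$y_um[i])),
           properties = props)
    })
    fc <- list(type = "FeatureCollection",
               crs = list(type = "name",
                          properties = list(name = "slide-local-micrometers")),
               features = feats)
    jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path, format = NULL) {
  format <- format %||% guess_format(path)
  if (format == "csv") {
    d <- read.csv(path, na.strings = c("NA", "."), stringsAsFactors = FALSE)
  } else {
    fc <- jsonlite::read_json(path)
    if (is.null(fc$features)) stop("not a GeoJSON FeatureCollection: ", path)
    if (!length(fc$features)) return(detection_table(numeric(), numeric()))
    rows <- lapply(fc$features, function(f) {
      co <- unlist(f$geometry$coordinates)
      out <- list(x_um = as.numeric(co[1]), y_um = as.numeric(co[2]))
      for (nm in names(f$properties)) out[[nm]] <- f$properties[[nm]]
      out
    })
    nm <- unique(unlist(lapply(rows, names)))
    cols <- lapply(nm, function(n)
      sapply(rows, function(r) if (is.null(r[[n]])) NA else r[[n]]))
    names(cols) <- nm
    d <- as.data.frame(cols, stringsAsFactors = FALSE)
  }
  for (col in c("likelihood", "certainty"))
    if (col %in% names(d)) d[[col]] <- as.numeric(d[[col]])
  if (!"likelihood" %in% names(d)) d$likelihood <- NA_real_
  if (!"certainty" %in% names(d)) d$certainty <- NA_real_
  if (!"label" %in% names(d)) d$label <- "UNLABELED"
  if (!"source" %in% names(d)) d$source <- "DETECTOR"
  validate_detections(d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("geojson", "json")) "geojson" else "csv"
}

#' Read and write hotspot lists
#'
#' Hotspots are serialized as JSON:
#' `{slide_id, radius_um, hotspots: [{rank, cx_um, cy_um, radius_um, count,
#' source}, ...]}`. The same schema reads manual hotspots (a one-element
#' list).
#'
#' @param h A `hotspots` data frame (see [select_hotspots()]).
#' @param path File path.
#' @param slide_id Optional identifier stored alongside.
#' @param extra Optional named list merged into the document (e.g. a match
#'   report or provenance).
#' @return `read_hotspots()` returns a `hotspots` data frame;
#'   `write_hotspots()` returns `path` invisibly.
#' @export
write_hotspots <- function(h, path, slide_id = NULL, extra = NULL) {
  stopifnot(is.data.frame(h))
  doc <- list(slide_id = slide_id,
              radius_um = if (nrow(h)) h$radius_um[1] else NULL,
              hotspots = h)
  doc <- c(doc[!vapply(doc, is.null, logical(1))], extra)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_hotspots
#' @export
read_hotspots <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  h <- doc$hotspots
  if (is.null(h)) stop("no 'hotspots' field in ", path)
  if (!length(h))
    h <- data.frame(rank = integer(), cx_um = numeric(), cy_um = numeric(),
                    radius_um = numeric(), count = integer(),
                    source = character(), stringsAsFactors = FALSE)
  h <- as.data.frame(h, stringsAsFactors = FALSE)
  need <- c("rank", "cx_um", "cy_um", "radius_um", "count")
  miss <- setdiff(need, names(h))
  if (length(miss))
    stop("hotspot file lacks field(s): ", paste(miss, collapse = ", "))
  if (!"source" %in% names(h)) h$source <- "AUTO"
  class(h) <- c("hotspots", "data.frame")
  h
}

#' Read and write density maps
#'
#' The count grid travels as a single-channel 32-bit TIFF (values scaled to
#' `[0, 1]` by the recorded maximum count) next to a JSON sidecar
#' `<path>.json` holding `{spacing_um, radius_um, total_buds, offset,
#' max_count}`, so integer counts are recovered exactly. An 8-bit heatmap PNG
#' can be written for visual inspection.
#'
#' @param map A `density_map`.
#' @param path TIFF path; the sidecar is written at `paste0(path, ".json")`.
#' @return `read_density_map()` returns a `density_map`;
#'   writers return `path` invisibly.
#' @export
write_density_map <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  mx <- max(map$counts)
  img <- if (mx > 0) map$counts / mx else map$counts * 0
  tiff::writeTIFF(img, path, bits.per.sample = 32L)
  g <- map$geometry
  side <- list(spacing_um = g$spacing_um, radius_um = map$radius_um,
               total_buds = map$total_buds, offset = g$offset,
               max_count = mx, width_um = g$width_um, height_um = g$height_um,
               zero_density = isTRUE(map$zero_density))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_density_map
#' @export
read_density_map <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  img <- tiff::readTIFF(path)
  counts <- matrix(as.integer(round(img * side$max_count)),
                   nrow(img), ncol(img))
  g <- slide_geometry(side$width_um, side$height_um, side$spacing_um,
                      offset = side$offset)
  structure(list(counts = counts, geometry = g, radius_um = side$radius_um,
                 total_buds = side$total_buds, normalized = NULL,
                 zero_density = isTRUE(side$zero_density)),
            class = "density_map")
}

#' @rdname write_density_map
#' @export
write_density_png <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  mx <- max(map$counts)
  img <- if (mx > 0) map$counts / mx else map$counts * 0
  png::writePNG(img, path)
  invisible(path)
}

#' Write a DAB mask
#'
#' Single-channel 8-bit TIFF (0 background / 255 positive) plus a JSON
#' sidecar `{spacing_um, offset, threshold, components}`.
#'
#' @param mask A [dab_mask()].
#' @param path TIFF path; sidecar at `paste0(path, ".json")`.
#' @export
write_dab_mask <- function(mask, path) {
  stopifnot(inherits(mask, "dab_mask"))
  tiff::writeTIFF((mask$mask * 1), path, bits.per.sample = 8L)
  side <- list(spacing_um = mask$spacing_um, offset = mask$offset,
               threshold = mask$od_threshold, components = mask$components)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}

#' Read and write RGB tiles
#'
#' TIFF or PNG, with pixel size and slide-frame offset in a JSON sidecar
#' (`<path>.json`) when written by this package; `spacing_um`/`offset` may be
#' passed explicitly when reading third-party tiles.
#'
#' @param tile An [rgb_tile()].
#' @param path Image path (`.tif`/`.tiff` or `.png`).
#' @param spacing_um,offset Geometry override when no sidecar exists.
#' @export
write_tile <- function(tile, path) {
  stopifnot(inherits(tile, "rgb_tile"))
  img <- tile$pixels / 255
  if (tolower(tools::file_ext(path)) == "png") png::writePNG(img, path)
  else tiff::writeTIFF(img, path, bits.per.sample = 8L)
  jsonlite::write_json(list(spacing_um = tile$spacing_um,
                            offset = tile$offset),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tile
#' @export
read_tile <- function(path, spacing_um = NULL, offset = NULL) {
  img <- if (tolower(tools::file_ext(path)) == "png") png::readPNG(path)
  else tiff::readTIFF(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    spacing_um <- spacing_um %||% side$spacing_um
    offset <- offset %||% side$offset
  }
  if (is.null(spacing_um))
    stop("no pixel size available for ", path,
         ": pass spacing_um or provide a sidecar")
  rgb_tile(img * 255, spacing_um = spacing_um, offset = offset %||% c(0, 0))
}

#' Run configuration
#'
#' One document bundling every tunable default of the pipeline. Unknown
#' fields in a config file fail fast with the offending field path;
#' unspecified fields take the documented defaults.
#'
#' @return `default_run_config()` returns the named list of defaults;
#'   `read_run_config()` returns the defaults overridden by a YAML or JSON
#'   file.
#' @export
default_run_config <- function() {
  list(radius_um = 500, spacing_um = 8, k = 10, dice_threshold = 0.7,
       likelihood_threshold = 0.80, pseudo_certainty = 0.80,
       manual_certainty = 1.0, collision_radius_um = 15,
       mask_tolerance_um = 0, od_threshold = 0.15, min_area_um2 = 30,
       opening_radius_px = 1, match_radius_um = 25, seed = 1L)
}

#' @rdname default_run_config
#' @param path YAML (`.yml`/`.yaml`) or JSON config file.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  user <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_run_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  cfg
}

# short stable hash of a config (content fingerprint embedded in artifacts)
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(cfg[order(names(cfg))], f, auto_unbox = TRUE,
                       digits = NA)
  unname(substr(tools::md5sum(f), 1, 12))
}
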