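# Independent reference computations used across the suite. These are kept
# deliberately naive (per-pixel scans, rasterized masks) and never share code
# with the package internals they check.

# per-pixel brute force: for every raster cell scan every point
brute_force_counts <- function(px, py, g, radius) {
  xc <- g$offset[1] + (seq_len(g$ncol) - 0.5) * g$spacing_um
  yc <- g$offset[2] + (seq_len(g$nrow) - 0.5) * g$spacing_um
  counts <- matrix(0L, g$nrow, g$ncol)
  if (!length(px)) return(counts)
  r2 <- radius^2
  dx2 <- outer(px, xc, "-")^2            # points x cols
  for (i in seq_len(g$nrow)) {
    dy2 <- (py - yc[i])^2
    counts[i, ] <- as.integer(colSums(dx2 + dy2 <= r2))
  }
  counts
}

# rasterized-mask dice of two circles at a given raster spacing
raster_dice <- function(a, b, spacing = 1) {
  x0 <- min(a$cx - a$radius, b$cx - b$radius)
  x1 <- max(a$cx + a$radius, b$cx + b$radius)
  y0 <- min(a$cy - a$radius, b$cy - b$radius)
  y1 <- max(a$cy + a$radius, b$cy + b$radius)
  xs <- seq(x0 + spacing / 2, x1, by = spacing)
  ys <- seq(y0 + spacing / 2, y1, by = spacing)
  ina <- outer((ys - a$cy)^2, (xs - a$cx)^2, "+") <= a$radius^2
  inb <- outer((ys - b$cy)^2, (xs - b$cx)^2, "+") <= b$radius^2
  denom <- sum(ina) + sum(inb)
  if (denom == 0) return(NA_real_)
  2 * sum(ina & inb) / denom
}

# random detection instance on a small raster
random_instance <- function(seed, max_points = 500, max_cells = 150,
                            spacing = 8, radius = 500) {
  set.seed(seed)
  nrow <- sample(40:max_cells, 1)
  ncol <- sample(40:max_cells, 1)
  n <- sample(c(0, 5:max_points), 1)
  w <- ncol * spacing; h <- nrow * spacing
  g <- slide_geometry(w, h, spacing)
  d <- detection_table(runif(n, 0, w), runif(n, 0, h), label = "TB",
                       source = "DETECTOR")
  list(d = d, g = g, radius = radius)
}
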