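#' Circular hotspot field
#'
#' Constructs a circle in slide coordinates. The scoring field recommended for
#' tumor budding is a circle of radius 0.5 mm (area 0.785 mm^2) centered on the
#' densest bud region.
#'
#' @param cx,cy Center, micrometers (slide frame).
#' @param radius Radius in micrometers; must be positive. Default 500 (0.5 mm).
#' @return An object of class `circle`: a list with `cx`, `cy`, `radius`.
#' @examples
#' circle(1000, 1000, 500)
#' @export
circle <- function(cx, cy, radius = 500) {
  stopifnot(is.numeric(cx), is.numeric(cy), is.numeric(radius),
            length(cx) == 1L, length(cy) == 1L, length(radius) == 1L)
  if (!is.finite(radius) || radius <= 0)
    stop("'radius' must be a positive number of micrometers")
  structure(list(cx = as.numeric(cx), cy = as.numeric(cy),
                 radius = as.numeric(radius)),
            class = "circle")
}

#' @export
print.circle <- function(x, ...) {
  cat(sprintf("circle: center (%.1f, %.1f) um, radius %.1f um, area %.3f mm^2\n",
              x$cx, x$cy, x$radius, disk_area(x$radius)))
  invisible(x)
}

#' Area of a disk in square millimeters
#'
#' For the standard hotspot radius of 500 um this is pi * 0.5^2 = 0.785 mm^2,
#' the field area in which buds are counted for scoring.
#'
#' @param radius Radius in micrometers (positive).
#' @return Area in mm^2.
#' @examples
#' disk_area(500)   # 0.785
#' @export
disk_area <- function(radius) {
  if (!is.numeric(radius) || any(!is.finite(radius)) || any(radius <= 0))
    stop("'radius' must be positive (micrometers)")
  pi * (radius / 1000)^2
}

#' Closed-disk membership test
#'
#' Boundary-inclusive: a point at exactly `radius` from the center counts as
#' inside. Squared distances are compared, so no square root is taken.
#'
#' @param x,y Point coordinates in micrometers (vectorized).
#' @param circle A [circle()].
#' @return Logical vector.
#' @export
point_in_circle <- function(x, y, circle) {
  stopifnot(inherits(circle, "circle"), length(x) == length(y))
  (x - circle$cx)^2 + (y - circle$cy)^2 <= circle$radius^2
}

#' Dice overlap of two disks
#'
#' Analytic Sorensen--Dice coefficient 2|A n B| / (|A| + |B|) of two closed
#' disks, from the circular-lens intersection area. A manual and an automatic
#' hotspot are conventionally declared a match when their dice is at least 0.7;
#' for equal radii r that corresponds to a center distance of about 0.476 r.
#'
#' @param a,b Objects of class [circle()]. Radii may differ (general lens
#'   formula).
#' @return Dice coefficient in `[0, 1]`.
#' @examples
#' a <- circle(0, 0, 500); b <- circle(500, 0, 500)
#' circle_dice(a, b)   # ~0.391
#' @export
circle_dice <- function(a, b) {
  stopifnot(inherits(a, "circle"), inherits(b, "circle"))
  r1 <- a$radius; r2 <- b$radius
  d <- sqrt((a$cx - b$cx)^2 + (a$cy - b$cy)^2)
  inter <- lens_area(d, r1, r2)
  2 * inter / (pi * r1^2 + pi * r2^2)
}

# Intersection area of two disks with radii r1, r2 at center distance d.
# Standard circular-segment decomposition; handles containment and disjoint.
lens_area <- function(d, r1, r2) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  # clamp acos arguments against rounding at the configuration boundaries
  ca1 <- (d^2 + r1^2 - r2^2) / (2 * d * r1)
  ca2 <- (d^2 + r2^2 - r1^2) / (2 * d * r2)
  ca1 <- min(1, max(-1, ca1)); ca2 <- min(1, max(-1, ca2))
  r1^2 * acos(ca1) + r2^2 * acos(ca2) -
    0.5 * sqrt(max(0, (-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2)))
}

#' Center distance at which two equal disks reach a given dice
#'
#' Inverts the analytic dice by bisection. Useful to construct hotspot
#' configurations with a prescribed overlap, e.g. `dice_threshold = 0.7`
#' gives d ~ 0.476 r.
#'
#' @param dice Target dice in (0, 1).
#' @param radius Common radius, micrometers.
#' @return Center distance in micrometers.
#' @export
dice_to_distance <- function(dice, radius = 500) {
  stopifnot(dice > 0, dice < 1, radius > 0)
  f <- function(d) circle_dice(circle(0, 0, radius), circle(d, 0, radius)) - dice
  uniroot(f, c(0, 2 * radius), tol = 1e-10)$root
}
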