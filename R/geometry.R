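## Shared geometry helpers: analytic shapes used by the simulator's ground
## truth and the shape descriptors used by segmentation. Shapes are either a
## single rotated ellipse or a union of rotated ellipses (mitotic chromosome
## masses). Pixel coordinates are 1-based, origin at the top-left, x across
## columns of the rendered image, y down.

## point-in-ellipse test, vectorised over (x, y)
ellipse_contains <- function(x, y, cx, cy, a, b, theta) {
  dx <- x - cx; dy <- y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

## shape: list(type = "ellipse"|"multi_ellipse", parts = list of
## list(cx, cy, a, b, theta))
shape_contains <- function(shape, x, y) {
  inside <- rep(FALSE, length(x))
  for (e in shape$parts) {
    inside <- inside | ellipse_contains(x, y, e$cx, e$cy, e$a, e$b, e$theta)
  }
  inside
}

shape_bbox <- function(shape, pad = 2) {
  xs <- range(vapply(shape$parts, function(e) e$cx, 0))
  ys <- range(vapply(shape$parts, function(e) e$cy, 0))
  r <- max(vapply(shape$parts, function(e) max(e$a, e$b), 0))
  c(xmin = xs[1] - r - pad, xmax = xs[2] + r + pad,
    ymin = ys[1] - r - pad, ymax = ys[2] + r + pad)
}

## Rasterise a shape onto an integer pixel grid restricted to its bounding
## box; returns a logical matrix plus the grid offsets.
shape_rasterize <- function(shape) {
  bb <- shape_bbox(shape)
  x0 <- max(1L, floor(bb["xmin"])); x1 <- ceiling(bb["xmax"])
  y0 <- max(1L, floor(bb["ymin"])); y1 <- ceiling(bb["ymax"])
  xs <- x0:x1; ys <- y0:y1
  g <- expand.grid(x = xs, y = ys)
  m <- matrix(shape_contains(shape, g$x, g$y), nrow = length(xs))
  list(mask = m, x0 = x0, y0 = y0)
}

#' Perimeter of a binary object by corrected contour chain length
#'
#' The perimeter estimator used throughout the package: the object boundary
#' is traced as an 8-connected pixel contour and the perimeter is the
#' corner-corrected chain length of Vossepoel & Smeulders,
#' `0.980 * n_axial + 1.406 * n_diagonal - 0.091 * n_corners`, where
#' `n_axial` and `n_diagonal` count axial and diagonal chain steps and
#' `n_corners` counts direction changes. Unlike the raw chain length (which
#' overestimates a digitised circle's circumference by ~5% with a strong
#' raster-alignment dependence), this estimator is accurate to well under
#' 1% on disks of radius >= 10 px, while remaining a local measure that
#' preserves concavities of lobed objects.
#'
#' @param mask Logical or 0/1 matrix containing a single connected object
#'   (multiple objects are summed).
#' @return Perimeter length in pixel units.
#' @export
mask_perimeter <- function(mask) {
  m <- EBImage::bwlabel(mask != 0)
  oc <- EBImage::ocontour(m)
  if (length(oc) == 0L) return(0)
  per_obj <- vapply(oc, function(p) {
    n <- nrow(p)
    if (n < 2L) return(4)   # isolated pixel: unit-square boundary
    if (n == 2L) return(2)
    stp <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE]) - p
    diag_step <- stp[, 1] != 0 & stp[, 2] != 0
    nxt <- rbind(stp[-1, , drop = FALSE], stp[1, , drop = FALSE])
    corners <- sum(stp[, 1] != nxt[, 1] | stp[, 2] != nxt[, 2])
    0.980 * sum(!diag_step) + 1.406 * sum(diag_step) - 0.091 * corners
  }, 0)
  sum(per_obj)
}

#' Circularity of a binary object
#'
#' Circularity is `4 * pi * A / P^2` with area `A` the pixel count and
#' perimeter `P` from [mask_perimeter()]; the value is clamped to at most 1.
#' A disk scores close to 1, elongated or lobed objects score lower.
#'
#' @param mask Logical or 0/1 matrix containing a single connected object.
#' @return Circularity in (0, 1].
#' @export
mask_circularity <- function(mask) {
  A <- sum(mask != 0)
  if (A == 0L) return(NA_real_)
  P <- mask_perimeter(mask)
  if (P <= 0) return(1)
  min(1, 4 * pi * A / P^2)
}

## analytic area of a shape (used for ground truth); unions are measured on
## the raster to account for overlap between lobes
shape_area_circularity <- function(shape) {
  r <- shape_rasterize(shape)
  c(area = sum(r$mask), circularity = mask_circularity(r$mask))
}

## uniform random point inside an ellipse
runif_in_ellipse <- function(n, e) {
  r <- sqrt(stats::runif(n)); phi <- stats::runif(n, 0, 2 * pi)
  u <- r * e$a * cos(phi); v <- r * e$b * sin(phi)
  cbind(x = e$cx + u * cos(e$theta) - v * sin(e$theta),
        y = e$cy + u * sin(e$theta) + v * cos(e$theta))
}

## random point on a scaled ellipse boundary (chromosome periphery)
runif_on_ellipse_rim <- function(n, e, scale_range = c(1.1, 1.35)) {
  s <- stats::runif(n, scale_range[1], scale_range[2])
  phi <- stats::runif(n, 0, 2 * pi)
  u <- s * e$a * cos(phi); v <- s * e$b * sin(phi)
  cbind(x = e$cx + u * cos(e$theta) - v * sin(e$theta),
        y = e$cy + u * sin(e$theta) + v * cos(e$theta))
}
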