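#' Trunk growth orientation and breast-height location
#'
#' The ground plane is fitted to the segmented ground points; trunk pixels
#' between two ground-referenced heights are split into equal-height
#' stripes; per image row the trunk center pixel is taken; each stripe's
#' centers are fitted with a 3-D line; the averaged stripe direction is the
#' growth orientation; and the center pixel whose height along that
#' orientation is closest to breast height (1.4 m) anchors the measurement.
#'
#' @name trunk-axis
NULL

#' Total-least-squares ground plane
#'
#' Fits `A x + B y + C z + D = 0` by the smallest principal component of
#' the centered point scatter, with `A^2+B^2+C^2 = 1`. When `gravity` is
#' given the normal is oriented away from the earth so that signed heights
#' above ground are positive.
#'
#' @param points n x 3 matrix of ground points (meters), n >= 3.
#' @param gravity optional unit 3-vector (toward the earth).
#' @return object of class `ground_plane`: numeric `c(A, B, C, D)` in
#'   `$coef`.
#' @export
fit_ground_plane <- function(points, gravity = NULL) {
  points <- points[stats::complete.cases(points), , drop = FALSE]
  if (nrow(points) < 3) stop("plane fit error: need at least 3 points")
  ctr <- colMeans(points)
  sc <- sweep(points, 2, ctr)
  ev <- eigen(crossprod(sc), symmetric = TRUE)
  # collinear (or coincident) points leave two near-null directions
  if (ev$values[2] <= 1e-12 * max(ev$values[1], 1e-300))
    stop("plane fit error: degenerate (collinear) point set")
  n <- ev$vectors[, 3]
  if (!is.null(gravity) && sum(n * gravity) > 0) n <- -n
  coef <- c(n, -sum(n * ctr))
  structure(list(coef = coef), class = "ground_plane")
}

#' Perpendicular distance of each pixel's point to the ground plane
#'
#' @param points a `point_map` or an n x 3 matrix.
#' @param plane a `ground_plane`.
#' @return matrix (or vector) of distances in meters, `>= 0`.
#' @export
perpendicular_height_map <- function(points, plane) {
  cf <- plane$coef / sqrt(sum(plane$coef[1:3]^2))
  if (inherits(points, "point_map")) {
    co <- points$coords
    abs(co[, , 1] * cf[1] + co[, , 2] * cf[2] + co[, , 3] * cf[3] + cf[4])
  } else {
    abs(points[, 1] * cf[1] + points[, 2] * cf[2] + points[, 3] * cf[3] + cf[4])
  }
}

#' Height along the trunk orientation, referenced to the ground plane
#'
#' `h = |(A x + B y + C z + D) / (A a + B b + C c)|` for orientation
#' `o = (a, b, c)`: the distance from the plane measured along `o`. Equals
#' the perpendicular height when `o` is the plane normal, and exceeds it by
#' `1/|cos|` otherwise.
#'
#' @param points a `point_map` or n x 3 matrix. @param plane a
#'   `ground_plane`. @param o unit orientation 3-vector.
#' @return heights in meters.
#' @export
oriented_height_map <- function(points, plane, o) {
  cf <- plane$coef / sqrt(sum(plane$coef[1:3]^2))
  denom <- sum(cf[1:3] * o)
  if (abs(denom) < 1e-6)
    stop("degenerate orientation: parallel to the ground plane")
  perpendicular_height_map(points, plane) / abs(denom)
}

#' Stripe construction and per-row trunk centers
#'
#' Every image row crossing the trunk contributes one center pixel: the
#' trunk pixel closest to the row's mean trunk column. Rows are assigned to
#' `stripe_count` equal bands over `(h1, h5]` — half-open, `(hk, hk+1]` —
#' by the perpendicular height of their center pixel. Using the full
#' trunk-mask row (rather than per-pixel band membership) keeps the center
#' on the trunk midline: depth varies across the visible arc, so a height
#' band cuts each row in a partial, off-center arc segment when the row is
#' far from the optical axis.
#'
#' @param trunk_mask logical H x W. @param hperp H x W perpendicular-height
#'   matrix. @param points a `point_map` (to attach 3-D coordinates).
#' @param config a [pipeline_config()].
#' @return object of class `stripe_set`: `bands` (K x 2), and per-band
#'   data frames `centers` with row, col, x, y, z.
#' @export
build_stripes <- function(trunk_mask, hperp, points, config = pipeline_config()) {
  if (!any(trunk_mask)) stop("insufficient-stripe error: empty trunk mask")
  K <- config$stripe_count
  edges <- seq(config$stripe_h1, config$stripe_h5, length.out = K + 1)
  idx <- which(trunk_mask, arr.ind = TRUE)
  ctr <- do.call(rbind, lapply(split(idx[, 2], idx[, 1]), function(cols) {
    c(0L, cols[which.min(abs(cols - mean(cols)))])
  }))
  ctr[, 1] <- as.integer(rownames(ctr))
  ok <- points$valid[ctr] & is.finite(hperp[ctr])
  ctr <- ctr[ok, , drop = FALSE]
  hv <- hperp[ctr]
  co <- points$coords
  centers <- vector("list", K)
  for (k in seq_len(K)) {
    inb <- which(hv > edges[k] & hv <= edges[k + 1])
    if (length(inb) < config$min_stripe_rows)
      stop("insufficient-stripe error: band ", k, " has fewer than ",
           config$min_stripe_rows, " center rows")
    rows <- ctr[inb, 1]; cols <- ctr[inb, 2]
    centers[[k]] <- data.frame(
      row = rows, col = cols,
      x = co[cbind(rows, cols, 1)],
      y = co[cbind(rows, cols, 2)],
      z = co[cbind(rows, cols, 3)])
  }
  structure(list(bands = cbind(edges[-(K + 1)], edges[-1]), centers = centers),
            class = "stripe_set")
}

#' Total-least-squares 3-D line fit
#'
#' Centroid plus first principal direction of the points; the direction is
#' sign-fixed upward (positive dot product with minus gravity).
#'
#' @param pts n x 3 matrix, n >= 2 distinct points.
#' @param gravity unit 3-vector toward the earth.
#' @return list with `base` (3-vector) and unit `direction`.
#' @export
fit_stripe_line <- function(pts, gravity = c(0, -1, 0)) {
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  if (nrow(pts) < 2) stop("line fit error: need at least 2 points")
  ctr <- colMeans(pts)
  sc <- sweep(pts, 2, ctr)
  if (max(abs(sc)) < 1e-12) stop("line fit error: all points identical")
  ev <- eigen(crossprod(sc), symmetric = TRUE)
  dir <- ev$vectors[, 1]
  if (sum(dir * -gravity) < 0) dir <- -dir
  list(base = ctr, direction = dir)
}

#' Average the per-stripe orientations
#'
#' Component-wise mean of the (upward sign-aligned) unit stripe directions,
#' re-normalized to a unit vector.
#'
#' @param dirs K x 3 matrix of unit directions.
#' @return unit 3-vector.
#' @export
average_orientation <- function(dirs) {
  dirs <- as.matrix(dirs)
  o <- colMeans(dirs)
  o / sqrt(sum(o^2))
}

#' Locate the breast-height anchor among the stripe centers
#'
#' Picks the center pixel whose oriented height is closest to the target
#' (ties break on smaller row, then column) and returns it with its 3-D
#' point.
#'
#' @param centers data.frame with row, col, x, y, z (all stripe centers).
#' @param h_values oriented heights of those centers (meters).
#' @param target target height (meters), conventionally 1.4.
#' @return object of class `breast_height_anchor`: `pixel` (row, col),
#'   `point` (3-vector), `height`.
#' @export
locate_breast_height <- function(centers, h_values, target = 1.4) {
  stopifnot(nrow(centers) > 0, length(h_values) == nrow(centers))
  ord <- order(abs(h_values - target), centers$row, centers$col)
  i <- ord[1]
  structure(list(pixel = c(centers$row[i], centers$col[i]),
                 point = c(centers$x[i], centers$y[i], centers$z[i]),
                 height = h_values[i]),
            class = "breast_height_anchor")
}
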