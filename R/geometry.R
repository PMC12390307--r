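#' Pinhole geometry: back-projection, depth upsampling, normals, alignment
#'
#' Conventions used throughout the package: pixel coordinates are
#' `(u, v) = (column, row)`, 0-based, with pixel centers at integer
#' coordinates; grids are stored as R matrices with `rows = H` (v) and
#' `cols = W` (u); depth `s` is the distance along the optical axis (the z
#' component of the world point); the world frame coincides with the camera
#' frame (origin at the optical center, z in the capture direction, y up in
#' portrait orientation). Lengths are meters.
#'
#' @name geometry
NULL

# Reduce a 3x4 projection matrix to pinhole form K[I|0]. The world frame is
# the camera frame, so the translation column must vanish and the leading
# 3x3 block (up to scale) is the intrinsic matrix with last row (0,0,1).
.intrinsics_from_projection <- function(P) {
  stopifnot(is.matrix(P), nrow(P) == 3, ncol(P) == 4)
  if (qr(P)$rank < 3) stop("projection matrix must have rank 3")
  K <- P[, 1:3]
  if (abs(det(K)) < 1e-12)
    stop("singular leading 3x3 block: general projection not supported")
  K <- K / K[3, 3]
  if (max(abs(P[, 4])) > 1e-9 * max(abs(K)))
    stop("projection has a non-zero translation column; world frame must be the camera frame")
  if (max(abs(K[3, 1:2])) > 1e-9 || max(abs(c(K[1, 2], K[2, 1]))) > 1e-6)
    stop("expected an axis-aligned pinhole intrinsic matrix")
  list(fx = K[1, 1], fy = K[2, 2], cx = K[1, 3], cy = K[2, 3])
}

#' Build a 3x4 projection matrix from pinhole intrinsics
#'
#' @param fx,fy focal lengths in pixels (fy may be negative when the image
#'   row axis points against the world y axis, the portrait-up convention).
#' @param cx,cy principal point, 0-based pixel coordinates.
#' @return 3x4 projection matrix `K[I|0]`.
#' @export
projection_matrix <- function(fx, fy, cx, cy) {
  cbind(matrix(c(fx, 0, 0, 0, fy, 0, cx, cy, 1), 3, 3), c(0, 0, 0))
}

#' Upsample a low-resolution depth grid to the RGB resolution
#'
#' Bilinear interpolation with the low-resolution grid corners mapped to the
#' high-resolution grid corners. Any output pixel whose 2x2 interpolation
#' stencil touches an invalid (`NA`) sample is invalid.
#'
#' @param depth_low matrix (h x w) of depths in meters, `NA` = invalid.
#' @param target_shape integer c(H, W).
#' @return H x W depth matrix, `NA` where invalid.
#' @export
upsample_depth <- function(depth_low, target_shape) {
  stopifnot(is.matrix(depth_low), nrow(depth_low) >= 2, ncol(depth_low) >= 2)
  H <- as.integer(target_shape[1]); W <- as.integer(target_shape[2])
  if (H < 2 || W < 2) stop("degenerate target shape")
  h <- nrow(depth_low); w <- ncol(depth_low)
  r <- 1 + (seq_len(H) - 1) * (h - 1) / (H - 1)
  c_ <- 1 + (seq_len(W) - 1) * (w - 1) / (W - 1)
  i0 <- pmin(floor(r), h - 1); fr <- r - i0
  j0 <- pmin(floor(c_), w - 1); fc <- c_ - j0
  Z00 <- depth_low[i0, j0, drop = FALSE]
  Z10 <- depth_low[i0 + 1, j0, drop = FALSE]
  Z01 <- depth_low[i0, j0 + 1, drop = FALSE]
  Z11 <- depth_low[i0 + 1, j0 + 1, drop = FALSE]
  FR <- matrix(fr, H, W); FC <- matrix(fc, H, W, byrow = TRUE)
  # 0 * NA is NA in R, so invalidity propagates through the whole stencil
  (1 - FR) * (1 - FC) * Z00 + FR * (1 - FC) * Z10 +
    (1 - FR) * FC * Z01 + FR * FC * Z11
}

#' Back-project a depth grid to a per-pixel point map
#'
#' Solves `s [u, v, 1]^T = P [xw, yw, zw, 1]^T` per pixel for the world
#' point. For canonical `P = K[I|0]` this is
#' `((u - cx) s / fx, (v - cy) s / fy, s)`.
#'
#' @param depth_high H x W depth matrix (meters, `NA` invalid).
#' @param P 3x4 projection matrix (see [projection_matrix()]).
#' @return object of class `point_map`: list with `coords` (H x W x 3 array)
#'   and `valid` (H x W logical).
#' @export
backproject <- function(depth_high, P) {
  K <- .intrinsics_from_projection(P)
  H <- nrow(depth_high); W <- ncol(depth_high)
  u <- matrix(seq_len(W) - 1, H, W, byrow = TRUE)
  v <- matrix(seq_len(H) - 1, H, W)
  coords <- array(NA_real_, c(H, W, 3))
  coords[, , 1] <- (u - K$cx) * depth_high / K$fx
  coords[, , 2] <- (v - K$cy) * depth_high / K$fy
  coords[, , 3] <- depth_high
  structure(list(coords = coords, valid = is.finite(depth_high)),
            class = "point_map")
}

#' Re-project a point map through the projection matrix
#'
#' Inverse check of [backproject()]: returns per-pixel `(u, v)` recovered
#' from the 3-D coordinates.
#'
#' @param points a `point_map`. @param P 3x4 projection matrix.
#' @return list of H x W matrices `u`, `v` (`NA` on invalid pixels).
#' @export
reproject <- function(points, P) {
  K <- .intrinsics_from_projection(P)
  z <- points$coords[, , 3]
  list(u = K$fx * points$coords[, , 1] / z + K$cx,
       v = K$fy * points$coords[, , 2] / z + K$cy)
}

# central differences along one matrix dimension with one-sided borders
.central_diff <- function(M, along = c("col", "row")) {
  along <- match.arg(along)
  if (along == "row") return(t(.central_diff(t(M), "col")))
  W <- ncol(M)
  D <- (M[, c(2:W, W), drop = FALSE] - M[, c(1, 1:(W - 1)), drop = FALSE])
  D[, 2:(W - 1)] <- D[, 2:(W - 1)] / 2  # interior: central; borders: one-sided
  D
}

#' Per-pixel tangent vectors and unit surface normals
#'
#' Tangents are first differences of the point map along the pixel grid
#' (central in the interior, one-sided at borders); the normal is their
#' normalized cross product. Pixels where the cross product is degenerate
#' (norm below 1e-12) or any stencil point is invalid are invalid.
#'
#' @param points a `point_map`.
#' @return object of class `normal_map`: `tangent_u`, `tangent_v`, `normal`
#'   (H x W x 3 arrays) and `valid` (H x W logical).
#' @export
tangent_normal_map <- function(points) {
  co <- points$coords
  H <- dim(co)[1]; W <- dim(co)[2]
  Tu <- array(NA_real_, c(H, W, 3)); Tv <- Tu
  for (k in 1:3) {
    Tu[, , k] <- .central_diff(co[, , k], "col")
    Tv[, , k] <- .central_diff(co[, , k], "row")
  }
  nx <- Tu[, , 2] * Tv[, , 3] - Tu[, , 3] * Tv[, , 2]
  ny <- Tu[, , 3] * Tv[, , 1] - Tu[, , 1] * Tv[, , 3]
  nz <- Tu[, , 1] * Tv[, , 2] - Tu[, , 2] * Tv[, , 1]
  nn <- sqrt(nx^2 + ny^2 + nz^2)
  valid <- is.finite(nn) & nn > 1e-12
  nn[!valid] <- NA_real_
  normal <- array(NA_real_, c(H, W, 3))
  normal[, , 1] <- nx / nn; normal[, , 2] <- ny / nn; normal[, , 3] <- nz / nn
  structure(list(tangent_u = Tu, tangent_v = Tv, normal = normal,
                 valid = valid),
            class = "normal_map")
}

#' Rigid transform aligning the trunk orientation with the y axis
#'
#' Builds the rotation `R` that maps the (upward-pointing) trunk orientation
#' `o = (a, b, c)` onto the world y axis — a rotation about z zeroing the x
#' component followed by a rotation about x zeroing the z component — and
#' the rigid transform `x -> R (x - anchor) + anchor` that keeps the
#' breast-height anchor fixed. The recorded angles are the precession
#' `theta_x = acos(a / sqrt(a^2 + b^2))` and nutation `theta_z = -asin(c)`.
#'
#' @param o unit 3-vector, trunk growth orientation. If its y component is
#'   negative the sign is flipped first.
#' @param anchor 3-vector kept fixed by the transform (meters).
#' @return object of class `alignment_transform`: `R`, `theta_x`, `theta_z`,
#'   `anchor`.
#' @export
alignment_from_orientation <- function(o, anchor = c(0, 0, 0)) {
  stopifnot(length(o) == 3, length(anchor) == 3)
  o <- o / sqrt(sum(o^2))
  if (o[2] < 0) o <- -o
  a <- o[1]; b <- o[2]; c_ <- o[3]
  r <- sqrt(a^2 + b^2)
  if (r < 1e-12) stop("degenerate orientation: trunk along the optical axis")
  Rz <- matrix(c(b / r, a / r, 0, -a / r, b / r, 0, 0, 0, 1), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, r, -c_, 0, c_, r), 3, 3)
  R <- Rx %*% Rz
  structure(list(R = R, theta_x = acos(a / r), theta_z = -asin(c_),
                 anchor = as.numeric(anchor)),
            class = "alignment_transform")
}

#' Apply an alignment transform to points
#'
#' @param transform an `alignment_transform`.
#' @param x 3-vector, n x 3 matrix, or H x W x 3 array.
#' @return transformed coordinates with the same shape.
#' @export
apply_transform <- function(transform, x) {
  R <- transform$R; c0 <- transform$anchor
  t0 <- c0 - as.vector(R %*% c0)
  if (is.array(x) && length(dim(x)) == 3) {
    d <- dim(x)
    m <- matrix(x, prod(d[1:2]), 3)
    out <- m %*% t(R)
    out <- sweep(out, 2, t0, "+")
    return(array(out, d))
  }
  if (is.null(dim(x))) return(as.vector(R %*% x) + t0)
  sweep(x %*% t(R), 2, t0, "+")
}
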