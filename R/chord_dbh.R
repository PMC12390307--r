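#' Breast-height slab selection and initial chord-geometry diameter
#'
#' After aligning the trunk with the y axis, the trunk pixels within a thin
#' ground-referenced slab around breast height are collected; the trunk's
#' pixel width there (`N_BH`), together with the arc-average depth `p_tilde`
#' and the focal length, gives the underestimated chord
#' `l_tilde = p_tilde * N_BH / f` and the initial diameter `d_tilde` by
#' tangent-circle geometry.
#'
#' @name chord-dbh
NULL

#' Select the breast-height slab and measure (N_BH, p_tilde)
#'
#' Under the default `"mask"` policy the slab is organized by image rows:
#' a row belongs to the slab when the oriented ground-referenced height of
#' its trunk center pixel lies within `breast_height +/- slab_half_width`
#' (the 1.39–1.41 m band by default). `N_BH` — the trunk width in pixels
#' at breast height — is the mean count of trunk-mask pixels over the slab
#' rows, rounded to the nearest integer; `p_tilde` is the mean aligned z
#' (referenced to the aligned camera position, in cm) over the slab-row
#' trunk pixels, restricted to `trusted` pixels when a trust mask is given.
#' Row-based selection matters because per-pixel height varies with depth
#' across the visible arc, so a thin height band would cut a diagonal,
#' off-center sliver of the arc and bias the depth average.
#'
#' The `"strict"` policy instead takes per-pixel height membership for
#' both quantities (the literal thin-slab rule), kept for comparison.
#'
#' @param points a `point_map`. @param trunk_mask logical H x W.
#' @param h oriented-height matrix (meters), from [oriented_height_map()].
#' @param transform an `alignment_transform` (identity permitted).
#' @param f focal length in pixels.
#' @param config a [pipeline_config()].
#' @param trusted optional logical H x W: pixels whose upsampled depth is
#'   supported entirely by trunk-interior samples (no silhouette blending);
#'   see [trunk_interior_trust()].
#' @return object of class `chord_sample`: `n_bh`, `p_tilde` (cm), `f`,
#'   `slab_pixels` (n x 2 row/col used for `p_tilde`), `slab_points`
#'   (aligned, meters), `rows` (slab rows), `border` (TRUE if the slab
#'   touches the left/right image border — the chord may be truncated).
#' @export
select_slab <- function(points, trunk_mask, h, transform, f,
                        config = pipeline_config(), trusted = NULL) {
  lo <- config$breast_height - config$slab_half_width
  hi <- config$breast_height + config$slab_half_width
  if (config$nbh_policy == "strict") {
    member <- trunk_mask & points$valid & is.finite(h) & h > lo & h < hi
    if (!any(member)) stop("breast-height-not-visible: empty slab")
    idx <- which(member, arr.ind = TRUE)
    rows <- sort(unique(idx[, 1]))
    n_bh <- mean(tabulate(match(idx[, 1], rows), length(rows)))
  } else {
    idxm <- which(trunk_mask, arr.ind = TRUE)
    ctr <- do.call(rbind, lapply(split(idxm[, 2], idxm[, 1]), function(cols) {
      c(0L, cols[which.min(abs(cols - mean(cols)))])
    }))
    ctr[, 1] <- as.integer(rownames(ctr))
    hc <- h[ctr]
    ok <- points$valid[ctr] & is.finite(hc) & hc > lo & hc < hi
    rows <- ctr[ok, 1]
    if (length(rows) == 0) stop("breast-height-not-visible: empty slab")
    inrow <- trunk_mask & points$valid &
      (row(trunk_mask) %in% rows)
    if (!is.null(trusted)) inrow <- inrow & trusted
    if (!any(inrow)) stop("breast-height-not-visible: no usable slab pixels")
    idx <- which(inrow, arr.ind = TRUE)
    counts <- vapply(rows, function(r) sum(trunk_mask[r, ]), numeric(1))
    n_bh <- mean(counts)
  }
  pts <- cbind(points$coords[cbind(idx[, 1], idx[, 2], 1)],
               points$coords[cbind(idx[, 1], idx[, 2], 2)],
               points$coords[cbind(idx[, 1], idx[, 2], 3)])
  aligned <- apply_transform(transform, pts)
  cam <- apply_transform(transform, c(0, 0, 0))
  # the bias model defines the arc-average depth uniformly over the chord
  # abscissa; pixels sample the arc uniformly in image u, which over-weights
  # the near part of the arc, so each point carries its trapezoidal weight
  # in the aligned chord coordinate x (per row, summed across rows)
  zrel <- aligned[, 3] - cam[3]
  num <- 0; den <- 0; span <- 0; nspan <- 0
  for (g in split(seq_len(nrow(aligned)), idx[, 1])) {
    if (length(g) < 2) next
    ordx <- g[order(aligned[g, 1])]
    x <- aligned[ordx, 1]
    wts <- c(x[2] - x[1], diff(x, lag = 2) / 2, x[length(x)] - x[length(x) - 1])
    num <- num + sum(wts * zrel[ordx])
    den <- den + sum(wts)
    span <- span + x[length(x)] - x[1]
    nspan <- nspan + 1
  }
  p_tilde <- if (den > 0) num / den * 100 else mean(zrel) * 100
  p_tilde_pixel <- mean(zrel) * 100   # plain per-pixel mean, kept for the
                                      # naive (no-alignment) estimator
  half_span_cm <- if (nspan > 0) span / nspan / 2 * 100 else NA_real_
  border <- min(idx[, 2]) == 1 || max(idx[, 2]) == ncol(trunk_mask)
  # n_bh keeps its sub-pixel mean for the chord computation; round only
  # when reporting an integer pixel count
  structure(list(n_bh = n_bh, p_tilde = p_tilde,
                 p_tilde_pixel = p_tilde_pixel, f = f,
                 half_span_cm = half_span_cm,
                 slab_pixels = idx, slab_points = aligned, rows = rows,
                 border = border),
            class = "chord_sample")
}

#' Trust mask for trunk-interior depth support
#'
#' Bilinear depth upsampling blends trunk and background depths within one
#' low-resolution cell of the silhouette. A high-resolution pixel is
#' trusted when all four low-resolution samples of its interpolation
#' stencil fall inside the trunk mask, so its depth mixes trunk surface
#' only.
#'
#' @param trunk_mask logical H x W (RGB resolution).
#' @param depth_shape c(h, w) of the LiDAR grid.
#' @return logical H x W.
#' @export
trunk_interior_trust <- function(trunk_mask, depth_shape) {
  H <- nrow(trunk_mask); W <- ncol(trunk_mask)
  h <- depth_shape[1]; w <- depth_shape[2]
  # low-res sample positions on the high-res grid (corner-aligned)
  ri <- round(1 + (seq_len(h) - 1) * (H - 1) / (h - 1))
  ci <- round(1 + (seq_len(w) - 1) * (W - 1) / (w - 1))
  low_in <- trunk_mask[ri, ci, drop = FALSE]
  marker <- matrix(0, h, w)
  marker[!low_in] <- NA_real_
  !is.na(upsample_depth(marker, c(H, W)))
}

#' Model-consistent chord refinement for leaning trunks
#'
#' The pixel width `N_BH` converts to a chord length through the pinhole
#' scale at the *optical* depth of the limb generators (the apparent trunk
#' edges), whereas the circle relations live in the cross-section plane
#' perpendicular to the trunk axis, where depths are the *aligned* z. For
#' a vertical trunk the two coincide; under lean they differ by several
#' percent, enough to bias the diameter by centimeters. Starting from the
#' plain [initial_diameter()] estimate, this iterates: solve the bias model
#' for the implied true `(d, p)`; compensate the limb-truncation deficit of
#' the measured arc average ([arc_average_depth_truncated()]); reconstruct
#' the implied limb points in the aligned frame, map them back through the
#' inverse alignment, and rescale the chord by their mean optical depth.
#'
#' @param sample a `chord_sample` from [select_slab()].
#' @param transform the `alignment_transform` used for the sample.
#' @param iters fixed-point passes (the corrections are a few percent, so
#'   two or three passes converge).
#' @return a `chord_geometry` with fields `truncation_cm` (arc-average
#'   deficit added) and `limb_depth_cm` (optical limb depth used for the
#'   pixel-width conversion).
#' @export
refine_chord <- function(sample, transform, iters = 3) {
  geom <- initial_diameter(sample)
  if (!is.finite(sample$half_span_cm)) return(geom)
  cam_al <- apply_transform(transform, c(0, 0, 0))
  xrel <- sample$slab_points[, 1] - cam_al[1]
  xc <- (max(xrel) + min(xrel)) / 2        # chord mid, camera-referenced
  ybar <- mean(sample$slab_points[, 2])    # aligned axial position of slab
  Rinv <- t(transform$R)
  c0 <- transform$anchor
  pt0 <- geom$p_tilde
  pt <- pt0; dt <- geom$d_tilde; l_tilde <- geom$l_tilde
  delta <- 0; zlimb <- NA_real_
  for (i in seq_len(iters)) {
    sol <- tryCatch(solve_exact(dt, pt), error = function(e) NULL)
    if (is.null(sol)) return(geom)
    l <- chord_from_depth(sol$d, sol$p)
    # limb-truncation deficit of the measured arc average
    delta <- if (sample$half_span_cm < l / 2)
      arc_average_depth(sol$d, l, sol$p) -
        arc_average_depth_truncated(sol$d, l, sol$p, sample$half_span_cm)
    else 0
    pt <- pt0 + delta
    # implied limb points in the aligned frame (meters), mapped back to the
    # camera frame for the pinhole depth of the silhouette generators
    limbs_al <- rbind(
      c(cam_al[1] + xc + l / 200, ybar, cam_al[3] + sol$p / 100),
      c(cam_al[1] + xc - l / 200, ybar, cam_al[3] + sol$p / 100))
    limbs_cam <- sweep(sweep(limbs_al, 2, c0) %*% t(Rinv), 2, c0, "+")
    zlimb <- mean(limbs_cam[, 3]) * 100
    l_tilde <- (sample$n_bh / sample$f) * zlimb * (pt / sol$p)
    dt <- circle_diameter(l_tilde, pt)
  }
  structure(list(l_tilde = l_tilde,
                 d_tilde = dt, p_tilde = pt,
                 n_bh = sample$n_bh, f = sample$f,
                 truncation_cm = delta, limb_depth_cm = zlimb),
            class = "chord_geometry")
}

#' Initial (underestimated) diameter from a chord sample
#'
#' `l_tilde = p_tilde * N_BH / f`; `d_tilde` from tangent-circle geometry,
#' the unique solution of `sqrt(d^2 - l^2) = l^2 / (2 p)` at
#' `(l_tilde, p_tilde)`.
#'
#' @param sample a `chord_sample`, or a list with `n_bh`, `p_tilde`, `f`.
#' @return object of class `chord_geometry`: `l_tilde`, `d_tilde`,
#'   `p_tilde` (cm), `n_bh`, `f`.
#' @export
initial_diameter <- function(sample) {
  if (sample$n_bh <= 0 || sample$p_tilde <= 0 || sample$f <= 0)
    stop("domain error: N_BH, p_tilde and f must be positive")
  l_tilde <- sample$p_tilde * sample$n_bh / sample$f
  structure(list(l_tilde = l_tilde,
                 d_tilde = circle_diameter(l_tilde, sample$p_tilde),
                 p_tilde = sample$p_tilde, n_bh = sample$n_bh, f = sample$f),
            class = "chord_geometry")
}
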