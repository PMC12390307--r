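#' End-to-end DBH estimation pipeline
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' Defaults follow the field settings for a full-height tree: normal
#' thresholds `eps_t = 0.3` (trunk) and `eps_g = 0.1` (ground), a 500-pixel
#' seed window, stripes over (1.0, 1.8] m in four bands, breast height at
#' 1.4 m with a 2-cm slab. `close_range_config()` is the short-subject
#' override used for tabletop cylinder measurements: a single stripe over
#' (4, 8] cm and the slab centered at 6 cm.
#'
#' @param eps_t trunk-normal threshold (unitless, in (0,1)).
#' @param eps_g ground-normal threshold (unitless, in (0,1)).
#' @param window_Mt seed window side (pixels).
#' @param stripe_h1,stripe_h5 stripe band limits (meters).
#' @param stripe_count number of equal-height bands.
#' @param breast_height measurement height along the trunk (meters).
#' @param slab_half_width slab half-thickness (meters).
#' @param min_stripe_rows minimum center rows per band.
#' @param depth_continuity region-growing depth jump tolerance (meters).
#' @param min_region_px minimum segment size (pixels).
#' @param nbh_policy `"mask"` (trunk-mask row width; default) or `"strict"`
#'   (literal slab-member count per row); see [select_slab()].
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(eps_t = 0.3, eps_g = 0.1, window_Mt = 500,
                            stripe_h1 = 1.0, stripe_h5 = 1.8,
                            stripe_count = 4, breast_height = 1.4,
                            slab_half_width = 0.01, min_stripe_rows = 3,
                            depth_continuity = 0.05, min_region_px = 100,
                            nbh_policy = c("mask", "strict")) {
  stopifnot(eps_t > 0, eps_t < 1, eps_g > 0, eps_g < 1, window_Mt >= 1,
            stripe_h1 < stripe_h5, stripe_count >= 1, slab_half_width > 0)
  structure(list(eps_t = eps_t, eps_g = eps_g, window_Mt = window_Mt,
                 stripe_h1 = stripe_h1, stripe_h5 = stripe_h5,
                 stripe_count = stripe_count, breast_height = breast_height,
                 slab_half_width = slab_half_width,
                 min_stripe_rows = min_stripe_rows,
                 depth_continuity = depth_continuity,
                 min_region_px = min_region_px,
                 nbh_policy = match.arg(nbh_policy)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param ... overrides passed to [pipeline_config()].
#' @export
close_range_config <- function(...) {
  defaults <- list(stripe_h1 = 0.04, stripe_h5 = 0.08, stripe_count = 1,
                   breast_height = 0.06)
  do.call(pipeline_config, utils::modifyList(defaults, list(...)))
}

#' Estimate DBH from a capture frame
#'
#' Runs the full pipeline: depth upsampling, back-projection, (unless masks
#' are supplied) normal-map seeds and segmentation, ground-plane fit,
#' stripes, per-stripe line fits, averaged growth orientation,
#' breast-height anchor, alignment, slab measurement, chord-geometry
#' initial diameter, and LUT correction. Deterministic for fixed inputs.
#'
#' @param frame a `capture_frame`.
#' @param config a [pipeline_config()].
#' @param lut a `correction_lut`, or `NULL` to skip correction (the result
#'   then reports `d = d_tilde` with a warning flag).
#' @param masks optional `segmentation_masks` to bypass segmentation.
#' @param segmenter segmentation function with the
#'   [segment_region_growing()] contract.
#' @param align if `FALSE`, skip the trunk-axis alignment (identity
#'   rotation); for studying the effect of the alignment step.
#' @return object of class `dbh_result`: `d_cm`, `d_tilde_cm`,
#'   `p_tilde_cm`, `l_tilde_cm`, `n_bh`, `orientation`, `anchor_m`,
#'   `theta_x`, `theta_z`, `warnings`, `diagnostics`.
#' @export
estimate_dbh <- function(frame, config = pipeline_config(), lut = NULL,
                         masks = NULL, segmenter = segment_region_growing,
                         align = TRUE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "]: ", conditionMessage(e), call. = FALSE))
  }
  warnings <- character(0)
  H <- frame$meta$rgb_shape[1]; W <- frame$meta$rgb_shape[2]
  if (H == 0) { H <- nrow(frame$depth_low); W <- ncol(frame$depth_low) }
  depth <- stage("upsample", upsample_depth(frame$depth_low, c(H, W)))
  points <- stage("backproject", backproject(depth, frame$projection))
  K <- .intrinsics_from_projection(frame$projection)
  f <- mean(abs(c(K$fx, K$fy)))

  if (is.null(masks)) {
    normals <- stage("normals", tangent_normal_map(points))
    seeds <- stage("seeds", select_seeds(normals, depth, frame$gravity, config))
    masks <- stage("segment", segmenter(frame, normals, depth, seeds, config))
  }

  gidx <- which(masks$ground & points$valid, arr.ind = TRUE)
  gpts <- cbind(points$coords[cbind(gidx[, 1], gidx[, 2], 1)],
                points$coords[cbind(gidx[, 1], gidx[, 2], 2)],
                points$coords[cbind(gidx[, 1], gidx[, 2], 3)])
  plane <- stage("ground-plane", fit_ground_plane(gpts, frame$gravity))
  hperp <- stage("height-map", perpendicular_height_map(points, plane))
  stripes <- stage("stripes", build_stripes(masks$trunk, hperp, points, config))

  fits <- stage("stripe-fits", lapply(stripes$centers, function(ctr)
    fit_stripe_line(as.matrix(ctr[, c("x", "y", "z")]), frame$gravity)))
  o <- stage("orientation",
             average_orientation(do.call(rbind, lapply(fits, `[[`, "direction"))))

  h <- stage("oriented-height", oriented_height_map(points, plane, o))
  all_centers <- do.call(rbind, stripes$centers)
  hc <- h[cbind(all_centers$row, all_centers$col)]
  anchor <- stage("breast-height",
                  locate_breast_height(all_centers, hc, config$breast_height))

  transform <- stage("alignment",
                     alignment_from_orientation(o, anchor$point))
  if (!align) {
    transform$R <- diag(3)
  }
  trusted <- stage("trust-mask",
                   trunk_interior_trust(masks$trunk, dim(frame$depth_low)))
  sample <- stage("slab", select_slab(points, masks$trunk, h, transform, f,
                                      config, trusted = trusted))
  if (sample$border)
    warnings <- c(warnings, "slab touches image border; chord may be truncated")
  if (align) {
    # the chord is perpendicular to the trunk axis; a horizontal image row
    # cuts the silhouette wider by 1/cos of the projected axis tilt
    c1 <- anchor$point + 0.05 * o
    du <- K$fx * (c1[1] / c1[3] - anchor$point[1] / anchor$point[3])
    dv <- K$fy * (c1[2] / c1[3] - anchor$point[2] / anchor$point[3])
    cospsi <- abs(dv) / sqrt(du^2 + dv^2)
    sample$n_bh <- sample$n_bh * cospsi
    geom <- stage("chord", refine_chord(sample, transform))
  } else {
    # naive estimator on untransformed points: plain pixel-mean depth,
    # literal chord formulas, no refinement — the published contrast case
    sample$p_tilde <- sample$p_tilde_pixel
    geom <- stage("chord", initial_diameter(sample))
  }

  d <- geom$d_tilde
  if (is.null(lut)) {
    warnings <- c(warnings, "no LUT supplied; reporting uncorrected d_tilde")
  } else {
    d <- tryCatch(lut_lookup(lut, geom$d_tilde, geom$p_tilde),
                  error = function(e) {
                    warnings <<- c(warnings,
                                   paste0("LUT lookup failed (",
                                          conditionMessage(e),
                                          "); reporting uncorrected d_tilde"))
                    geom$d_tilde
                  })
  }
  structure(list(d_cm = d, d_tilde_cm = geom$d_tilde,
                 p_tilde_cm = geom$p_tilde, l_tilde_cm = geom$l_tilde,
                 n_bh = sample$n_bh, orientation = o,
                 anchor_m = anchor$point, anchor_height_m = anchor$height,
                 theta_x = transform$theta_x, theta_z = transform$theta_z,
                 aligned = align, f_px = f,
                 warnings = warnings,
                 diagnostics = list(n_slab_rows = length(sample$rows),
                                    n_slab_pixels = nrow(sample$slab_pixels),
                                    n_ground_pixels = nrow(gidx))),
            class = "dbh_result")
}

#' @export
print.dbh_result <- function(x, ...) {
  cat("Single-shot DBH estimate\n")
  cat(sprintf("  corrected DBH d        : %.2f cm\n", x$d_cm))
  cat(sprintf("  initial estimate d~    : %.2f cm\n", x$d_tilde_cm))
  cat(sprintf("  arc-average depth p~   : %.2f cm\n", x$p_tilde_cm))
  cat(sprintf("  chord l~ / width N_BH  : %.2f cm / %d px\n",
              x$l_tilde_cm, as.integer(round(x$n_bh))))
  cat(sprintf("  orientation o          : [%.3f, %.3f, %.3f]\n",
              x$orientation[1], x$orientation[2], x$orientation[3]))
  cat(sprintf("  anchor height          : %.3f m\n", x$anchor_height_m))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
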