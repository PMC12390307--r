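#' Trunk and ground segmentation from gravity-vs-normal agreement
#'
#' A near-vertical trunk has surface normals roughly perpendicular to
#' gravity (`|ng . n| < eps_t`), while the ground has normals roughly
#' parallel to gravity (`|ng . n| > 1 - eps_g`). Seed pixels are selected
#' automatically from these conditions and handed to a segmenter. The
#' default segmenter is a deterministic region grower (flood fill over
#' pixels satisfying the seed's normal condition, with a depth-continuity
#' constraint between neighbours); any external segmenter can be plugged in
#' behind the same contract.
#'
#' @name segmentation
NULL

#' Automatic seed selection
#'
#' The trunk seed is the smallest-depth pixel satisfying the trunk condition
#' inside a centered square window of side `window_Mt` (clipped to the
#' image). The ground seed is, among all pixels satisfying the ground
#' condition, the one whose depth is closest to the mean depth of that set.
#' Ties break on smaller row, then smaller column.
#'
#' @param normals a `normal_map` (see [tangent_normal_map()]).
#' @param depth H x W depth matrix (meters).
#' @param gravity unit 3-vector.
#' @param config a [pipeline_config()].
#' @return object of class `seed_pair`: `trunk_seed`, `ground_seed`
#'   (row, col, 1-based), with their `|ng . n|` scores.
#' @export
select_seeds <- function(normals, depth, gravity, config = pipeline_config()) {
  gdot <- abs(normals$normal[, , 1] * gravity[1] +
                normals$normal[, , 2] * gravity[2] +
                normals$normal[, , 3] * gravity[3])
  H <- nrow(depth); W <- ncol(depth)
  half <- floor(config$window_Mt / 2)
  rc <- round(H / 2); cc <- round(W / 2)
  rows <- max(1, rc - half):min(H, rc + half)
  cols <- max(1, cc - half):min(W, cc + half)
  win_score <- gdot[rows, cols, drop = FALSE]
  win_depth <- depth[rows, cols, drop = FALSE]
  cand <- which(is.finite(win_score) & win_score < config$eps_t &
                  is.finite(win_depth), arr.ind = TRUE)
  if (nrow(cand) == 0) stop("no trunk in view: empty trunk-seed candidate set")
  dvals <- win_depth[cand]
  ord <- order(dvals, cand[, 1], cand[, 2])
  tr <- unname(cand[ord[1], ])
  trunk_seed <- c(rows[tr[1]], cols[tr[2]])

  gcand <- which(is.finite(gdot) & gdot > 1 - config$eps_g & is.finite(depth),
                 arr.ind = TRUE)
  if (nrow(gcand) == 0) stop("no ground in view: empty ground-seed candidate set")
  gd <- depth[gcand]
  ord <- order(abs(gd - mean(gd)), gcand[, 1], gcand[, 2])
  gr <- unname(gcand[ord[1], ])
  structure(list(trunk_seed = trunk_seed, ground_seed = c(gr[1], gr[2]),
                 trunk_score = gdot[trunk_seed[1], trunk_seed[2]],
                 ground_score = gdot[gr[1], gr[2]]),
            class = "seed_pair")
}

#' Reference region-growing segmenter
#'
#' Grows 4-connected regions from the trunk and ground seeds. A pixel is
#' eligible for a region when it satisfies the seed's normal condition, or
#' when its normal/depth data are missing but its color matches the seed's
#' (the depth grid is much coarser than the RGB, so a band around the trunk
#' silhouette has blended or invalid depth — there the RGB carries the
#' boundary, which is exactly why the original pipeline delegates
#' segmentation to an RGB model). Growth across valid depth additionally
#' requires depth continuity (`|delta s| <= depth_continuity`). When the
#' frame carries an RGB image, color agreement with the seed gates both
#' regions; without RGB the segmenter is purely geometric.
#'
#' @param frame a `capture_frame` (RGB used when present).
#' @param normals a `normal_map`. @param depth H x W depth matrix.
#' @param seeds a `seed_pair`. @param config a [pipeline_config()].
#' @param color_tol per-channel color tolerance against the seed pixel.
#' @return object of class `segmentation_masks`: logical `trunk`, `ground`.
#' @export
segment_region_growing <- function(frame, normals, depth, seeds,
                                   config = pipeline_config(),
                                   color_tol = 0.1) {
  gravity <- frame$gravity
  gdot <- abs(normals$normal[, , 1] * gravity[1] +
                normals$normal[, , 2] * gravity[2] +
                normals$normal[, , 3] * gravity[3])
  fin <- is.finite(gdot)
  trunk_ok <- fin & gdot < config$eps_t
  ground_ok <- fin & gdot > 1 - config$eps_g
  depth_ff <- depth
  if (!is.null(frame$rgb)) {
    color_ok <- function(seed) {
      ref <- frame$rgb[seed[1], seed[2], ]
      abs(frame$rgb[, , 1] - ref[1]) <= color_tol &
        abs(frame$rgb[, , 2] - ref[2]) <= color_tol &
        abs(frame$rgb[, , 3] - ref[3]) <= color_tol
    }
    # the coarse depth grid smears a band around the silhouette: normals
    # there are undefined or meaningless (steep blended gradients). Inside
    # that band the RGB boundary takes over, both for eligibility and for
    # the depth-continuity check.
    steep <- abs(normals$tangent_u[, , 3]) > config$depth_continuity |
      abs(normals$tangent_v[, , 3]) > config$depth_continuity
    steep[is.na(steep)] <- FALSE
    depth_ff[steep] <- NA_real_
    trunk_ok <- (trunk_ok | !fin | steep) & color_ok(seeds$trunk_seed)
    ground_ok <- (ground_ok | !fin | steep) & color_ok(seeds$ground_seed)
  }
  trunk <- .flood_fill_cpp(trunk_ok, depth_ff, seeds$trunk_seed[1],
                           seeds$trunk_seed[2], config$depth_continuity)
  ground <- .flood_fill_cpp(ground_ok, depth_ff, seeds$ground_seed[1],
                            seeds$ground_seed[2], config$depth_continuity)
  if (sum(trunk) < config$min_region_px)
    stop("segmentation failure: trunk region below ", config$min_region_px,
         " pixels")
  if (sum(ground) < config$min_region_px)
    stop("segmentation failure: ground region below ", config$min_region_px,
         " pixels")
  ground <- ground & !trunk
  structure(list(trunk = trunk, ground = ground), class = "segmentation_masks")
}

#' Wrap precomputed masks in the segmentation contract
#'
#' @param trunk,ground logical matrices (disjoint).
#' @return a `segmentation_masks`.
#' @export
segmentation_masks <- function(trunk, ground) {
  stopifnot(is.logical(trunk), is.logical(ground),
            identical(dim(trunk), dim(ground)))
  if (any(trunk & ground)) stop("trunk and ground masks must be disjoint")
  structure(list(trunk = trunk, ground = ground), class = "segmentation_masks")
}
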