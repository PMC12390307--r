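#' Arc-average depth bias model and correction lookup table
#'
#' A single camera sees only the arc of the trunk cross-section between the
#' two sight-line tangent points. Averaging the depth of the visible arc
#' (which is what the measured mean pixel depth does) yields a value
#' systematically below the true chord depth, and consequently an
#' underestimated diameter. These functions implement the exact forward model
#' from true diameter/chord depth to the observed (underestimated) pair, its
#' inversion, and a pre-computed lookup table for fast correction.
#'
#' All quantities in this layer are in centimeters, matching the scale at
#' which DBH is conventionally reported.
#'
#' @name bias-model
NULL

#' Chord length of the visible arc from tangent-sight-line geometry
#'
#' For a circle of diameter `d` whose chord between the two tangent points
#' lies at perpendicular depth `p` from the camera, the chord length `l`
#' satisfies `d = l/(2p) * sqrt(l^2 + 4 p^2)`; this is its algebraic inverse,
#' `l^2 = 2 p (sqrt(p^2 + d^2) - p)`.
#'
#' @param d true diameter (cm), positive.
#' @param p true chord depth (cm); must exceed `d/2` (camera outside trunk).
#' @return chord length `l` (cm), always `< d`.
#' @export
chord_from_depth <- function(d, p) {
  stopifnot(all(d > 0), all(p > 0))
  # algebraically 2p(sqrt(p^2+d^2)-p); this form avoids cancellation at d << p
  d * sqrt(2 * p / (sqrt(p^2 + d^2) + p))
}

#' Circle diameter from chord length and chord depth
#'
#' Tangent-sight-line geometry: `d = l/(2p) * sqrt(l^2 + 4 p^2)`. Satisfies
#' the tangency identity `sqrt(d^2 - l^2) = l^2 / (2 p)` and `d >= l` always.
#'
#' @param l chord length (cm), positive.
#' @param p chord depth (cm), positive.
#' @return circle diameter (cm).
#' @export
circle_diameter <- function(l, p) {
  stopifnot(all(l > 0), all(p > 0))
  l / (2 * p) * sqrt(l^2 + 4 * p^2)
}

#' Arc-average depth (closed form)
#'
#' Mean depth of the visible arc of a circle of diameter `d`, chord length
#' `l` at chord depth `p`:
#' `p_tilde = p + 1/2 sqrt(d^2-l^2) - d^2/(4l) * (asin(l/d) + (l/d) sqrt(1 - l^2/d^2))`.
#' Limits: `l -> 0` gives `p`; `l -> d` gives `p - pi*d/8`.
#'
#' @param d diameter (cm). @param l chord length (cm), `0 < l <= d`.
#' @param p chord depth (cm).
#' @return arc-average depth `p_tilde` (cm), always `< p`.
#' @export
arc_average_depth <- function(d, l, p) {
  stopifnot(all(l > 0), all(l <= d * (1 + 1e-12)))
  r2 <- pmax(1 - (l / d)^2, 0)
  p + 0.5 * sqrt(d^2 - l^2) -
    d^2 / (4 * l) * (asin(pmin(l / d, 1)) + (l / d) * sqrt(r2))
}

#' Arc-average depth by adaptive quadrature (independent oracle)
#'
#' Evaluates the integral form
#' `p + 1/2 sqrt(d^2-l^2) - (2/l) * integral_0^{l/2} sqrt(d^2/4 - x^2) dx`
#' with adaptive numerical quadrature. Used to cross-check the closed form;
#' the two agree to better than 1e-9 relative.
#'
#' @inheritParams arc_average_depth
#' @return arc-average depth (cm).
#' @export
arc_average_depth_quadrature <- function(d, l, p) {
  if (l <= 0 || l > d) stop("require 0 < l <= d")
  quad <- stats::integrate(function(x) sqrt(pmax(d^2 / 4 - x^2, 0)),
                           lower = 0, upper = l / 2,
                           rel.tol = 1e-12, abs.tol = 1e-13)
  p + 0.5 * sqrt(d^2 - l^2) - (2 / l) * quad$value
}

#' Arc-average depth over a symmetric sub-interval of the chord
#'
#' Average depth of the visible arc restricted to chord abscissae
#' `[-w, w]`, `0 < w <= l/2`: the measured pixel set misses the outermost
#' arc near the tangent points (silhouette-blended depths are excluded),
#' and this gives the model value of such a truncated average. At
#' `w = l/2` it equals [arc_average_depth()].
#'
#' @inheritParams arc_average_depth
#' @param w observed half-span of the chord abscissa (cm).
#' @return truncated arc-average depth (cm).
#' @export
arc_average_depth_truncated <- function(d, l, p, w) {
  stopifnot(w > 0)
  w <- pmin(w, l / 2)
  r <- d / 2
  zc <- p + 0.5 * sqrt(pmax(d^2 - l^2, 0))
  # (1/w) * integral_0^w sqrt(r^2 - x^2) dx
  avg_sqrt <- (w / 2 * sqrt(pmax(r^2 - w^2, 0)) +
                 r^2 / 2 * asin(pmin(w / r, 1))) / w
  zc - avg_sqrt
}

#' Compensate the limb-truncation bias of a measured arc average
#'
#' The depth average excludes a band at each silhouette edge, where the
#' arc is deepest; the plain average is therefore biased low. Given the
#' measured `(d_tilde, p_tilde)`, the trunk pixel width `n_bh`, the focal
#' length and the observed chord half-span `w` (cm), this solves the bias
#' model for the implied `(d, p)`, evaluates the model's truncated-average
#' deficit, adds it to `p_tilde`, and recomputes `(l_tilde, d_tilde)`.
#' A fixed small number of fixed-point passes suffices (the deficit is a
#' few percent at most).
#'
#' @param geom a `chord_geometry` (see [initial_diameter()]).
#' @param w_cm observed chord half-span (cm).
#' @param iters fixed-point passes.
#' @return corrected `chord_geometry` with an added `truncation_cm` field.
#' @export
truncation_correction <- function(geom, w_cm, iters = 2) {
  pt <- geom$p_tilde
  dt <- geom$d_tilde
  delta <- 0
  for (i in seq_len(iters)) {
    sol <- tryCatch(solve_exact(dt, pt), error = function(e) NULL)
    if (is.null(sol)) break
    l <- chord_from_depth(sol$d, sol$p)
    if (w_cm >= l / 2) { delta <- 0; break }
    full <- arc_average_depth(sol$d, l, sol$p)
    trunc <- arc_average_depth_truncated(sol$d, l, sol$p, w_cm)
    delta <- full - trunc
    pt <- geom$p_tilde + delta
    dt <- circle_diameter(pt * geom$n_bh / geom$f, pt)
  }
  if (delta <= 0) return(geom)
  structure(list(l_tilde = pt * geom$n_bh / geom$f,
                 d_tilde = dt,
                 p_tilde = pt, n_bh = geom$n_bh, f = geom$f,
                 truncation_cm = delta),
            class = "chord_geometry")
}

#' Forward bias model: true (d, p) to observed (d_tilde, p_tilde)
#'
#' Chains the tangent-geometry chord, the arc-average depth, the
#' underestimated chord `l_tilde = l * p_tilde / p`, and the underestimated
#' diameter `d_tilde = circle_diameter(l_tilde, p_tilde)`. Vectorized;
#' exactly scale-invariant: `forward_observables(k*d, k*p)` scales all four
#' outputs by `k`.
#'
#' @param d true diameter (cm). @param p true chord depth (cm), `> d/2`.
#' @return list with numeric components `d_tilde`, `p_tilde`, `l`, `l_tilde`
#'   (all cm).
#' @export
forward_observables <- function(d, p) {
  if (any(d <= 0)) stop("diameter must be positive")
  if (any(p <= d / 2)) stop("chord depth must exceed d/2 (camera outside trunk)")
  l <- chord_from_depth(d, p)
  p_tilde <- arc_average_depth(d, l, p)
  l_tilde <- l * p_tilde / p
  d_tilde <- circle_diameter(l_tilde, p_tilde)
  list(d_tilde = d_tilde, p_tilde = p_tilde, l = l, l_tilde = l_tilde)
}

# Observed ratio d_tilde/p_tilde as a function of rho = d/p (scale-free form
# of the forward model). Monotone increasing on the physical domain.
.obs_ratio <- function(rho) {
  f <- forward_observables(rho, 1)
  f$d_tilde / f$p_tilde
}

#' Exact correction: solve the forward model for the true (d, p)
#'
#' Inverts the five-equation chord/arc system: finds the true diameter and
#' chord depth whose observables equal the given `(d_tilde, p_tilde)`.
#' Because the forward map is scale-invariant, the inversion reduces to a
#' one-dimensional bracketed root-find on the ratio `d/p`, followed by a
#' rescale — deterministic and globally convergent on the attainable region.
#' This is the oracle against which the lookup table is validated.
#'
#' @param d_tilde observed initial diameter (cm).
#' @param p_tilde observed arc-average depth (cm).
#' @param tol root tolerance on the observed ratio (default 1e-12).
#' @return list with `d` and `p` (cm); `forward_observables(d, p)` reproduces
#'   the query to ~1e-8 cm.
#' @export
solve_exact <- function(d_tilde, p_tilde, tol = 1e-12) {
  stopifnot(length(d_tilde) == 1, length(p_tilde) == 1)
  if (!is.finite(d_tilde) || !is.finite(p_tilde) || d_tilde <= 0 || p_tilde <= 0)
    stop("observed pair must be positive and finite")
  q <- d_tilde / p_tilde
  lo <- 1e-9
  hi <- 2 - 1e-9                       # p > d/2 bounds rho = d/p below 2
  if (q <= .obs_ratio(lo) || q >= .obs_ratio(hi))
    stop("observed pair outside the attainable region of the bias model")
  rho <- stats::uniroot(function(r) .obs_ratio(r) - q,
                        lower = lo, upper = hi, tol = tol)$root
  scale <- p_tilde / forward_observables(rho, 1)$p_tilde
  list(d = rho * scale, p = scale)
}

#' Specification of a correction lookup table
#'
#' @param d_range range of true diameters swept by the forward model (cm).
#' @param p_range range of true chord depths swept (cm).
#' @param m1,n1 forward sampling counts for d and p.
#' @param m2,n2 lookup-grid cell counts for d_tilde and p_tilde.
#' @return object of class `lut_spec`.
#' @export
lut_spec <- function(d_range = c(0.5, 100), p_range = c(25, 500),
                     m1 = 996, n1 = 4996, m2 = 500, n2 = 1000) {
  stopifnot(length(d_range) == 2, length(p_range) == 2,
            d_range[1] > 0, diff(d_range) > 0,
            p_range[1] > 0, diff(p_range) > 0,
            m1 >= 2, n1 >= 2, m2 >= 2, n2 >= 2)
  structure(list(d_range = as.numeric(d_range), p_range = as.numeric(p_range),
                 m1 = as.integer(m1), n1 = as.integer(n1),
                 m2 = as.integer(m2), n2 = as.integer(n2)),
            class = "lut_spec")
}

#' Build the bias-correction lookup table
#'
#' Sweeps `m1 x n1` forward samples of true `(d, p)`, producing a structured
#' set of correspondences `(d_tilde, p_tilde) -> d`; determines the observed
#' ranges; then fills an `(m2+1) x (n2+1)` node grid over
#' `[d_tilde_min, d_tilde_max] x [p_tilde_min, p_tilde_max]` by
#' piecewise-linear interpolation along the forward grid lines (linear in
#' p_tilde along each constant-d curve, then linear in d_tilde across
#' curves). Nodes outside the attainable region are `NA`.
#'
#' @param spec a [lut_spec()].
#' @return object of class `correction_lut`: the spec, the observed ranges
#'   (`dt_range`, `pt_range`) and the node grid of corrected diameters (cm).
#' @export
build_lut <- function(spec = lut_spec()) {
  stopifnot(inherits(spec, "lut_spec"))
  d_s <- seq(spec$d_range[1], spec$d_range[2], length.out = spec$m1)
  p_s <- seq(spec$p_range[1], spec$p_range[2], length.out = spec$n1)

  # forward sweep (vectorized over the full grid); samples violating the
  # p > d/2 visibility constraint are dropped row-wise below
  D <- matrix(d_s, spec$m1, spec$n1)
  P <- matrix(p_s, spec$m1, spec$n1, byrow = TRUE)
  ok <- P > D / 2
  L <- D * sqrt(2 * P / (sqrt(P^2 + D^2) + P))
  PT <- P + 0.5 * sqrt(pmax(D^2 - L^2, 0)) -
    D^2 / (4 * L) * (asin(pmin(L / D, 1)) + (L / D) * sqrt(pmax(1 - (L / D)^2, 0)))
  LT <- L * PT / P
  DT <- LT / (2 * PT) * sqrt(LT^2 + 4 * PT^2)
  DT[!ok] <- NA_real_
  PT[!ok] <- NA_real_
  if (!any(ok)) stop("LUT spec produces an empty attainable region")

  dt_range <- range(DT, na.rm = TRUE)
  pt_range <- range(PT, na.rm = TRUE)
  dt_nodes <- seq(dt_range[1], dt_range[2], length.out = spec$m2 + 1L)
  pt_nodes <- seq(pt_range[1], pt_range[2], length.out = spec$n2 + 1L)

  # pass 1: for each constant-d forward curve, interpolate d_tilde at the
  # p_tilde node positions (p_tilde is monotone in p at fixed d)
  dt_at <- matrix(NA_real_, spec$m1, spec$n2 + 1L)
  for (i in seq_len(spec$m1)) {
    v <- ok[i, ]
    if (sum(v) < 2) next
    dt_at[i, ] <- stats::approx(PT[i, v], DT[i, v], xout = pt_nodes,
                                rule = 1, ties = "ordered")$y
  }
  # pass 2: across curves, interpolate true d at the d_tilde node positions
  grid <- matrix(NA_real_, spec$m2 + 1L, spec$n2 + 1L)
  for (j in seq_len(spec$n2 + 1L)) {
    col <- dt_at[, j]
    v <- is.finite(col)
    if (sum(v) < 2) next
    grid[, j] <- stats::approx(col[v], d_s[v], xout = dt_nodes,
                               rule = 1, ties = "ordered")$y
  }
  structure(list(spec = spec, dt_range = dt_range, pt_range = pt_range,
                 dt_nodes = dt_nodes, pt_nodes = pt_nodes, grid = grid),
            class = "correction_lut")
}

#' Corrected diameter from the lookup table
#'
#' Indexes the cell containing the query with the ceiling rule
#' `m = ceil(m2 * (d_tilde - d_tilde_min) / (d_tilde_max - d_tilde_min))`
#' (clamped to the first/last cell at the edges), gathers the four
#' surrounding nodes, and refines by bilinear interpolation. Queries at a
#' grid node return that node's value exactly.
#'
#' @param lut a [build_lut()] result.
#' @param d_tilde,p_tilde observed pair (cm). Vectorized.
#' @return corrected diameter(s) d (cm). Errors if a query is outside the
#'   observed ranges; falls back to the nearest valid node (with a warning)
#'   if any of the four surrounding nodes is unattainable.
#' @export
lut_lookup <- function(lut, d_tilde, p_tilde) {
  stopifnot(inherits(lut, "correction_lut"))
  n <- max(length(d_tilde), length(p_tilde))
  d_tilde <- rep_len(d_tilde, n)
  p_tilde <- rep_len(p_tilde, n)
  eps <- 1e-9
  if (any(d_tilde < lut$dt_range[1] - eps | d_tilde > lut$dt_range[2] + eps |
          p_tilde < lut$pt_range[1] - eps | p_tilde > lut$pt_range[2] + eps))
    stop("query outside the observed (d_tilde, p_tilde) ranges of the LUT")
  m2 <- lut$spec$m2; n2 <- lut$spec$n2
  fm <- m2 * (d_tilde - lut$dt_range[1]) / diff(lut$dt_range)
  fn <- n2 * (p_tilde - lut$pt_range[1]) / diff(lut$pt_range)
  m <- pmin(pmax(ceiling(fm), 1L), m2)   # cell index; nodes m-1, m bound it
  nn <- pmin(pmax(ceiling(fn), 1L), n2)
  tx <- pmin(pmax(fm - (m - 1), 0), 1)
  ty <- pmin(pmax(fn - (nn - 1), 0), 1)
  g <- lut$grid
  idx <- function(i, j) g[cbind(i, j)]
  v00 <- idx(m, nn); v10 <- idx(m + 1L, nn)
  v01 <- idx(m, nn + 1L); v11 <- idx(m + 1L, nn + 1L)
  out <- (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
    (1 - tx) * ty * v01 + tx * ty * v11
  bad <- !is.finite(out)
  if (any(bad)) {
    warning("query adjacent to unattainable LUT nodes; nearest-valid fallback")
    valid <- which(is.finite(g), arr.ind = TRUE)
    for (k in which(bad)) {
      dd <- (lut$dt_nodes[valid[, 1]] - d_tilde[k])^2 +
        (lut$pt_nodes[valid[, 2]] - p_tilde[k])^2
      out[k] <- g[valid[which.min(dd), , drop = FALSE]]
    }
  }
  out
}

#' Bilinear refinement over four explicit corner values
#'
#' The final lookup step used by [lut_lookup()], exposed on its own: given
#' the four corner coordinates and their corrected diameters, interpolate at
#' the query. Coordinates must form an axis-aligned rectangle.
#'
#' @param dt_lo,dt_hi,pt_lo,pt_hi corner coordinates (cm).
#' @param v corner values in order (lo,lo), (hi,lo), (lo,hi), (hi,hi).
#' @param d_tilde,p_tilde query (cm).
#' @return interpolated diameter (cm).
#' @export
bilinear_corners <- function(dt_lo, dt_hi, pt_lo, pt_hi, v, d_tilde, p_tilde) {
  stopifnot(length(v) == 4, dt_hi > dt_lo, pt_hi > pt_lo)
  tx <- (d_tilde - dt_lo) / (dt_hi - dt_lo)
  ty <- (p_tilde - pt_lo) / (pt_hi - pt_lo)
  (1 - tx) * (1 - ty) * v[1] + tx * (1 - ty) * v[2] +
    (1 - tx) * ty * v[3] + tx * ty * v[4]
}

#' Write / read a correction LUT (binary grid + JSON sidecar)
#'
#' The node grid is stored as little-endian doubles; the sidecar records the
#' spec, ranges and dimensions so the pair round-trips exactly.
#'
#' @param lut a `correction_lut`. @param path basename; writes `path` (binary)
#'   and `path.json`.
#' @return `write_lut`: `path`, invisibly. `read_lut`: the `correction_lut`.
#' @export
write_lut <- function(lut, path) {
  stopifnot(inherits(lut, "correction_lut"))
  side <- list(spec = unclass(lut$spec), dt_range = lut$dt_range,
               pt_range = lut$pt_range, dim = dim(lut$grid))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(lut$grid), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_lut
#' @export
read_lut <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spec <- do.call(lut_spec, side$spec[c("d_range", "p_range",
                                        "m1", "n1", "m2", "n2")])
  con <- file(path, "rb")
  on.exit(close(con))
  grid <- matrix(readBin(con, "double", n = prod(side$dim), size = 8,
                         endian = "little"),
                 side$dim[1], side$dim[2])
  structure(list(spec = spec, dt_range = side$dt_range,
                 pt_range = side$pt_range,
                 dt_nodes = seq(side$dt_range[1], side$dt_range[2],
                                length.out = side$dim[1]),
                 pt_nodes = seq(side$pt_range[1], side$pt_range[2],
                                length.out = side$dim[2]),
                 grid = grid),
            class = "correction_lut")
}

#' Validate a LUT against the exact solver
#'
#' Draws random attainable queries and compares [lut_lookup()] with
#' [solve_exact()].
#'
#' @param lut a `correction_lut`. @param n number of queries.
#' @param seed RNG seed.
#' @return data.frame with the queries, both answers and their difference.
#' @export
validate_lut <- function(lut, n = 1000, seed = 1L) {
  set.seed(seed)
  res <- data.frame(d_tilde = numeric(0), p_tilde = numeric(0),
                    lut = numeric(0), exact = numeric(0))
  while (nrow(res) < n) {
    d <- stats::runif(2 * n, lut$spec$d_range[1], lut$spec$d_range[2])
    p <- stats::runif(2 * n, lut$spec$p_range[1], lut$spec$p_range[2])
    keep <- p > d / 2
    d <- d[keep][seq_len(min(sum(keep), n - nrow(res)))]
    p <- p[keep][seq_len(length(d))]
    fw <- forward_observables(d, p)
    lu <- lut_lookup(lut, fw$d_tilde, fw$p_tilde)
    ex <- vapply(seq_along(d), function(k)
      solve_exact(fw$d_tilde[k], fw$p_tilde[k])$d, numeric(1))
    res <- rbind(res, data.frame(d_tilde = fw$d_tilde, p_tilde = fw$p_tilde,
                                 lut = lu, exact = ex))
  }
  res$diff <- res$lut - res$exact
  res
}
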