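# Shared fixtures, built once per test run. The renders and the full-spec
# correction LUT are the expensive pieces; everything downstream reuses them.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

shared_lut <- function() fixture("lut_full", function() build_lut(lut_spec()))

# close-range tabletop cylinder, the worked-example scale: d = 22 cm at
# 0.39 m, arc-average depth ~30 cm
scene_close22 <- function() fixture("close22", function()
  render_scene(scene_spec(22, 0.39, camera_height = 0.25,
                          measure_height = 0.06), rgb = TRUE))

# mid-range gently leaning trunk at tree scale
scene_mid40 <- function() fixture("mid40", function()
  render_scene(scene_spec(40, 2.0, lean_deg = 5, lean_azimuth_deg = 45),
               rgb = TRUE))

truth_masks <- function(sc)
  segmentation_masks(sc$truth$trunk_mask, sc$truth$ground_mask)

# pipeline front half, shared by stage-level tests
scene_stages <- function(sc) {
  frame <- sc$frame
  H <- frame$meta$rgb_shape[1]; W <- frame$meta$rgb_shape[2]
  depth <- upsample_depth(frame$depth_low, c(H, W))
  points <- backproject(depth, frame$projection)
  list(frame = frame, depth = depth, points = points)
}

# binary dilation by n pixels (4-neighbourhood, applied n times)
dilate_mask <- function(m, n = 1) {
  for (i in seq_len(n)) {
    H <- nrow(m); W <- ncol(m)
    m <- m |
      rbind(m[-1, , drop = FALSE], FALSE) |
      rbind(FALSE, m[-H, , drop = FALSE]) |
      cbind(m[, -1, drop = FALSE], FALSE) |
      cbind(FALSE, m[, -W, drop = FALSE])
  }
  m
}

# random attainable forward pairs (true diameter cm, chord depth cm)
random_forward_pairs <- function(n, seed, d_range = c(1, 100),
                                 p_range = c(25, 500)) {
  set.seed(seed)
  d <- numeric(0); p <- numeric(0)
  while (length(d) < n) {
    dd <- runif(n, d_range[1], d_range[2])
    pp <- runif(n, p_range[1], p_range[2])
    ok <- pp > dd / 2
    d <- c(d, dd[ok]); p <- c(p, pp[ok])
  }
  list(d = d[seq_len(n)], p = p[seq_len(n)])
}
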