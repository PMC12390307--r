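test_that("bilinear upsampling maps grid corners and preserves constants", {
  expect_equal(upsample_depth(matrix(2, 3, 3), c(7, 9)),
               matrix(2, 7, 9))
  # 2x2 -> 2x4: the interior columns follow the closed-form bilinear weights
  up <- upsample_depth(matrix(c(1, 1, 3, 3), 2, 2), c(2, 4))
  expect_equal(up[1, ], c(1, 1 + 2 / 3, 1 + 4 / 3, 3), tolerance = 1e-12)
  expect_error(upsample_depth(matrix(1, 2, 2), c(1, 4)), "degenerate")
})

test_that("an invalid sample invalidates exactly the pixels that touch it", {
  z <- matrix(1, 4, 4); z[2, 2] <- NA
  up <- upsample_depth(z, c(7, 7))
  # high-res pixels supported only by samples != (2,2) stay valid
  expect_false(anyNA(up[6:7, ]))
  expect_false(anyNA(up[, 6:7]))
  expect_true(all(is.na(up[2:3, 2:3])))
})

test_that("back-projection solves the pinhole relation and inverts exactly", {
  f <- 1451.99
  # a pixel exactly at the principal point, at the worked-example chord depth
  P2 <- projection_matrix(f, -f, 719, 959)
  z2 <- matrix(0.2984, 961, 721)
  pm <- backproject(z2, P2)
  expect_equal(pm$coords[960, 720, ], c(0, 0, 0.2984), tolerance = 1e-12)

  set.seed(5)
  depth <- matrix(runif(30 * 40, 0.3, 5), 30, 40)
  P3 <- projection_matrix(321.7, -298.3, 19.2, 14.8)
  pm3 <- backproject(depth, P3)
  rp <- reproject(pm3, P3)
  u <- matrix(0:39, 30, 40, byrow = TRUE); v <- matrix(0:29, 30, 40)
  expect_lt(max(abs(rp$u - u)), 1e-6)
  expect_lt(max(abs(rp$v - v)), 1e-6)
  # projective scaling: doubling depth doubles all coordinates
  pm6 <- backproject(2 * depth, P3)
  expect_equal(pm6$coords, 2 * pm3$coords, tolerance = 1e-12)
})

test_that("normals recover a plane and a cylinder's axis-perpendicularity", {
  # oblique view of the ground plane y = -1.2
  f <- 500; H <- 120; W <- 100
  P <- projection_matrix(f, -f, (W - 1) / 2, (H - 1) / 2)
  v <- matrix(0:(H - 1), H, W)
  ey <- -(v - (H - 1) / 2) / f
  depth <- ifelse(ey < -0.05, 1.2 / -ey, NA)   # rows looking down
  pm <- backproject(depth, P)
  nm <- tangent_normal_map(pm)
  ok <- which(nm$valid, arr.ind = TRUE)
  ok <- ok[ok[, 1] > min(ok[, 1]) + 2, ]       # clear of the validity border
  ny <- abs(nm$normal[, , 2][ok])
  expect_gt(min(ny), 1 - 1e-6)

  # rendered cylinder: interior normals are perpendicular to gravity
  sc <- scene_close22()
  st <- scene_stages(sc)
  nm2 <- tangent_normal_map(st$points)
  trust <- trunk_interior_trust(sc$truth$trunk_mask, dim(sc$frame$depth_low))
  sel <- trust & nm2$valid
  gdot <- abs(nm2$normal[, , 2][sel])
  expect_lt(stats::quantile(gdot, 0.99), 1e-3)

  # degenerate: constant point map has no surface
  cpm <- structure(list(coords = array(1, c(8, 8, 3)),
                        valid = matrix(TRUE, 8, 8)), class = "point_map")
  expect_false(any(tangent_normal_map(cpm)$valid))
})

test_that("alignment maps the orientation to the y axis and is an isometry", {
  tr0 <- alignment_from_orientation(c(0, 1, 0), c(1, 2, 3))
  expect_equal(tr0$R, diag(3), tolerance = 1e-12)
  expect_equal(tr0$theta_x, pi / 2)
  expect_equal(tr0$theta_z, 0)

  o <- c(-0.153, 0.961, 0.230); o <- o / sqrt(sum(o^2))
  tr <- alignment_from_orientation(o, c(0.1, -0.2, 0.4))
  expect_lt(max(abs(tr$R %*% o - c(0, 1, 0))), 1e-9)
  expect_lt(max(abs(crossprod(tr$R) - diag(3))), 1e-9)
  expect_equal(det(tr$R), 1, tolerance = 1e-9)
  expect_equal(apply_transform(tr, c(0.1, -0.2, 0.4)), c(0.1, -0.2, 0.4))

  set.seed(7)
  for (i in 1:20) {
    oo <- c(rnorm(1), abs(rnorm(1)) + 0.1, rnorm(1))
    oo <- oo / sqrt(sum(oo^2))
    anch <- rnorm(3)
    trr <- alignment_from_orientation(oo, anch)
    expect_lt(max(abs(trr$R %*% oo - c(0, 1, 0))), 1e-9)
    # points along the axis share x and z after the transform
    pts <- outer(seq(-1, 1, length.out = 5), oo) +
      matrix(anch, 5, 3, byrow = TRUE)
    ali <- apply_transform(trr, pts)
    expect_lt(diff(range(ali[, 1])), 1e-9)
    expect_lt(diff(range(ali[, 3])), 1e-9)
    # isometry: pairwise distances preserved
    expect_equal(as.numeric(dist(ali)), as.numeric(dist(pts)),
                 tolerance = 1e-9)
  }
  expect_error(alignment_from_orientation(c(0, 0, 1)), "degenerate")
})
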