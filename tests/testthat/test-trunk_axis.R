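test_that("ground plane fit is exact on a plane and robust to noise", {
  set.seed(3)
  pts <- cbind(runif(200, -2, 2), -1.2, runif(200, 1, 5))
  pl <- fit_ground_plane(pts, gravity = c(0, -1, 0))
  expect_equal(abs(pl$coef), c(0, 1, 0, 1.2), tolerance = 1e-9)
  expect_gt(pl$coef[2], 0)                       # oriented away from gravity

  # isotropic 5 mm noise, 5000 points: normal within 0.5 degrees
  set.seed(42)
  base <- cbind(runif(5000, -2, 2), -1.2, runif(5000, 1, 5))
  noisy <- base + matrix(rnorm(15000, 0, 0.005), ncol = 3)
  pln <- fit_ground_plane(noisy, gravity = c(0, -1, 0))
  ang <- acos(abs(sum(pln$coef[1:3] * c(0, 1, 0)))) * 180 / pi
  expect_lt(ang, 0.5)

  expect_error(fit_ground_plane(cbind(1:3, 1:3, 1:3)), "degenerate")
  expect_error(fit_ground_plane(matrix(1, 2, 3)), "3 points")
})

test_that("height maps measure plane distance, with the 1/cos scaling", {
  pl <- structure(list(coef = c(0, 1, 0, 1.2)), class = "ground_plane")
  pts <- rbind(c(0.3, -1.2, 2),                  # on the plane
               c(0.3, -1.2, 2) + 1.4 * c(0, 1, 0))
  expect_equal(perpendicular_height_map(pts, pl), c(0, 1.4))
  # normalization invariance
  pl2 <- structure(list(coef = 2 * pl$coef), class = "ground_plane")
  expect_equal(perpendicular_height_map(pts, pl2),
               perpendicular_height_map(pts, pl))
  # o at 60 degrees from the normal doubles the height
  o60 <- c(sin(pi / 3), cos(pi / 3), 0)
  expect_equal(oriented_height_map(pts, pl, o60),
               2 * perpendicular_height_map(pts, pl))
  expect_equal(oriented_height_map(pts, pl, c(0, 1, 0)),
               perpendicular_height_map(pts, pl))
  expect_error(oriented_height_map(pts, pl, c(1, 0, 0)), "degenerate")
})

test_that("h along the orientation never falls below the perpendicular h", {
  set.seed(9)
  for (i in 1:50) {
    n <- rnorm(3); n <- n / sqrt(sum(n^2))
    pl <- structure(list(coef = c(n, rnorm(1))), class = "ground_plane")
    o <- rnorm(3); o <- o / sqrt(sum(o^2))
    if (abs(sum(n * o)) < 1e-3) next
    pts <- matrix(rnorm(30), 10, 3)
    expect_true(all(oriented_height_map(pts, pl, o) >=
                      perpendicular_height_map(pts, pl) - 1e-12))
  }
})

test_that("stripes assign rows half-open by center height and center by mean column", {
  H <- 40; W <- 30
  trunk <- matrix(FALSE, H, W)
  hperp <- matrix(NA_real_, H, W)
  co <- array(0, c(H, W, 3))
  # rows 1..40 with trunk pixels at columns 10..12 and known heights
  hv <- seq(0.95, 1.85, length.out = H)
  for (i in 1:H) {
    trunk[i, 10:12] <- TRUE
    hperp[i, ] <- hv[i]
    co[i, , 2] <- hv[i] - 1.5
    co[i, , 3] <- 2
    co[i, , 1] <- (seq_len(W) - 15) * 0.01
  }
  pm <- structure(list(coords = co, valid = matrix(TRUE, H, W)),
                  class = "point_map")
  cfg <- pipeline_config()
  st <- build_stripes(trunk, hperp, pm, cfg)
  expect_length(st$centers, 4)
  expect_true(all(vapply(st$centers, function(x) all(x$col == 11), TRUE)))
  # half-open bands: a center at exactly 1.2 belongs to (1.0, 1.2]
  i12 <- which.min(abs(hv - 1.2))
  hperp[i12, ] <- 1.2
  st2 <- build_stripes(trunk, hperp, pm, cfg)
  expect_true(i12 %in% st2$centers[[1]]$row)
  expect_false(i12 %in% st2$centers[[2]]$row)

  expect_error(build_stripes(matrix(FALSE, H, W), hperp, pm, cfg), "empty")
  # band with too few rows
  hperp2 <- hperp; hperp2[hv > 1.2 & hv <= 1.4, ] <- 0.5
  expect_error(build_stripes(trunk, hperp2, pm, cfg), "band 2")
})

test_that("stripe line fits are exact on lines and accurate under noise", {
  pts <- outer(seq(0, 0.2, length.out = 10), c(0, 1, 0)) +
    matrix(c(0.5, 0, 2), 10, 3, byrow = TRUE)
  fit <- fit_stripe_line(pts)
  expect_equal(abs(fit$direction), c(0, 1, 0), tolerance = 1e-12)
  expect_gt(fit$direction[2], 0)                 # upward sign

  two <- fit_stripe_line(rbind(c(0, 0, 0), c(0.1, 0.2, 0.05)))
  expect_equal(two$direction,
               c(0.1, 0.2, 0.05) / sqrt(sum(c(0.1, 0.2, 0.05)^2)),
               tolerance = 1e-12)

  set.seed(14)
  dirtrue <- c(0.1, 0.99, 0.1); dirtrue <- dirtrue / sqrt(sum(dirtrue^2))
  base <- outer(seq(0, 0.2, length.out = 60), dirtrue)
  noisy <- base + matrix(rnorm(180, 0, 0.002), ncol = 3)
  fitn <- fit_stripe_line(noisy)
  ang <- acos(min(abs(sum(fitn$direction * dirtrue)), 1)) * 180 / pi
  expect_lt(ang, 2)

  expect_error(fit_stripe_line(matrix(1, 5, 3)), "identical")
})

test_that("orientation averaging renormalizes and respects symmetry", {
  d <- c(0.2, 0.9, -0.1); d <- d / sqrt(sum(d^2))
  expect_equal(average_orientation(rbind(d, d, d, d)), d, tolerance = 1e-12)
  a <- c(0.3, 0.9, 0); a <- a / sqrt(sum(a^2))
  b <- c(-0.3, 0.9, 0); b <- b / sqrt(sum(b^2))
  expect_equal(average_orientation(rbind(a, b)), c(0, 1, 0), tolerance = 1e-12)
  expect_equal(sqrt(sum(average_orientation(rbind(a, b, d))^2)), 1,
               tolerance = 1e-12)
})

test_that("breast-height anchor takes the closest center, ties to smaller row", {
  ctr <- data.frame(row = c(5, 9, 2), col = c(1, 1, 1),
                    x = 1:3, y = 4:6, z = 7:9)
  a <- locate_breast_height(ctr, c(1.30, 1.39, 1.52), target = 1.4)
  expect_equal(a$pixel, c(9, 1))
  expect_equal(a$point, c(2, 5, 8))
  single <- locate_breast_height(ctr[1, ], 1.1)
  expect_equal(single$pixel, c(5, 1))
  ctr2 <- data.frame(row = c(9, 5, 2), col = c(1, 1, 1),
                     x = 1:3, y = 4:6, z = 7:9)
  tie <- locate_breast_height(ctr2, c(1.4 + 0.05, 1.4 + 0.05, 1.4 + 0.2))
  expect_equal(tie$pixel[1], 5)                  # exact tie: smaller row
})

test_that("estimated orientation on noiseless renders is within 0.5 degrees", {
  for (sc in list(scene_close22(), scene_mid40())) {
    st <- scene_stages(sc)
    masks <- truth_masks(sc)
    cfg <- if (sc$truth$p_cm < 60) close_range_config() else pipeline_config()
    gidx <- which(masks$ground & st$points$valid, arr.ind = TRUE)
    gpts <- cbind(st$points$coords[cbind(gidx[, 1], gidx[, 2], 1)],
                  st$points$coords[cbind(gidx[, 1], gidx[, 2], 2)],
                  st$points$coords[cbind(gidx[, 1], gidx[, 2], 3)])
    plane <- fit_ground_plane(gpts, sc$frame$gravity)
    hperp <- perpendicular_height_map(st$points, plane)
    stripes <- build_stripes(masks$trunk, hperp, st$points, cfg)
    dirs <- do.call(rbind, lapply(stripes$centers, function(ctr)
      fit_stripe_line(as.matrix(ctr[, c("x", "y", "z")]),
                      sc$frame$gravity)$direction))
    o <- average_orientation(dirs)
    ang <- acos(min(abs(sum(o * sc$truth$axis)), 1)) * 180 / pi
    expect_lt(ang, 0.5)
  }
})

test_that("orientation estimation is equivariant under rigid rotation", {
  # stripe centers on a known line, rotated together with gravity
  set.seed(21)
  dirtrue <- c(0.15, 0.96, 0.23); dirtrue <- dirtrue / sqrt(sum(dirtrue^2))
  pts <- outer(seq(0, 0.5, length.out = 40), dirtrue) +
    matrix(rnorm(120, 0, 0.001), ncol = 3)
  g <- c(0, -1, 0)
  o1 <- fit_stripe_line(pts, g)$direction
  th <- 0.4
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  o2 <- fit_stripe_line(pts %*% t(Rz), as.vector(Rz %*% g))$direction
  expect_equal(o2, as.vector(Rz %*% o1), tolerance = 1e-6)
})
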