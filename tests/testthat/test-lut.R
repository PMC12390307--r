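test_that("closed-form arc average agrees with quadrature and its limits", {
  rp <- random_forward_pairs(200, seed = 16)
  l <- chord_from_depth(rp$d, rp$p)
  for (i in seq_len(50)) {
    cf <- arc_average_depth(rp$d[i], l[i], rp$p[i])
    qd <- arc_average_depth_quadrature(rp$d[i], l[i], rp$p[i])
    expect_lt(abs(cf - qd) / abs(qd), 1e-9)
  }
  # l -> d (grazing): p~ -> p - pi d / 8
  expect_equal(arc_average_depth(30, 30, 300), 300 - pi * 30 / 8,
               tolerance = 1e-12)
  # l -> 0: p~ -> p
  expect_equal(arc_average_depth(30, 1e-4, 300), 300, tolerance = 1e-6)
  expect_error(arc_average_depth_quadrature(10, 11, 50), "0 < l")
})

test_that("the truncated arc average interpolates between chord depth and full average", {
  d <- 40; p <- 120
  l <- chord_from_depth(d, p)
  full <- arc_average_depth(d, l, p)
  expect_equal(arc_average_depth_truncated(d, l, p, l / 2), full,
               tolerance = 1e-9)
  # shrinking the window moves the average toward the front of the arc,
  # so the truncated value grows with w toward the full average
  w <- seq(0.1, 1, length.out = 10) * l / 2
  vals <- vapply(w, function(x) arc_average_depth_truncated(d, l, p, x),
                 numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals <= full + 1e-12))
})

test_that("forward observables hit the documented regimes", {
  # p >> d: nearly the whole half-circle is visible, l -> d
  fw <- forward_observables(10, 5000)
  expect_equal(fw$l, 10, tolerance = 1e-3)
  expect_equal(fw$p_tilde, 5000 - pi * 10 / 8, tolerance = 1e-2)
  # the Table-1 cross-check pair: d = 30.99, p = 361.5 maps to ~(30, 350)
  fw2 <- forward_observables(30.9871, 361.5166)
  expect_equal(fw2$d_tilde, 30, tolerance = 0.01)
  expect_equal(fw2$p_tilde, 350, tolerance = 0.01)
  # scale invariance
  fw3 <- forward_observables(22, 90)
  fw6 <- forward_observables(44, 180)
  expect_equal(fw6$d_tilde, 2 * fw3$d_tilde, tolerance = 1e-10)
  expect_equal(fw6$p_tilde, 2 * fw3$p_tilde, tolerance = 1e-10)
  expect_error(forward_observables(30, 14), "exceed")
})

test_that("the exact solver inverts the forward model", {
  fw <- forward_observables(40, 100)
  sol <- solve_exact(fw$d_tilde, fw$p_tilde)
  expect_equal(sol$d, 40, tolerance = 1e-6)
  expect_equal(sol$p, 100, tolerance = 1e-6)
  rp <- random_forward_pairs(50, seed = 23)
  fw2 <- forward_observables(rp$d, rp$p)
  for (i in seq_len(50)) {
    s <- solve_exact(fw2$d_tilde[i], fw2$p_tilde[i])
    expect_lt(abs(s$d - rp$d[i]), 1e-6)
  }
  expect_error(solve_exact(100, 30), "attainable")
})

test_that("LUT construction, lookup, serialization and edge rules", {
  spec <- lut_spec(d_range = c(5, 60), p_range = c(30, 300),
                   m1 = 150, n1 = 250, m2 = 80, n2 = 120)
  lut <- build_lut(spec)
  expect_s3_class(lut, "correction_lut")
  expect_equal(dim(lut$grid), c(81, 121))

  # round trip against known forward pairs
  rp <- random_forward_pairs(100, seed = 31, d_range = c(8, 55),
                             p_range = c(40, 280))
  fw <- forward_observables(rp$d, rp$p)
  keep <- fw$d_tilde > lut$dt_range[1] & fw$d_tilde < lut$dt_range[2] &
    fw$p_tilde > lut$pt_range[1] & fw$p_tilde < lut$pt_range[2]
  got <- suppressWarnings(lut_lookup(lut, fw$d_tilde[keep], fw$p_tilde[keep]))
  expect_lt(max(abs(got - rp$d[keep])), 0.15)
  # correction never reduces the initial estimate
  expect_true(all(got >= fw$d_tilde[keep] - 1e-9))

  # a query at a grid node returns the node value
  m <- 40; n <- 60
  expect_equal(lut_lookup(lut, lut$dt_nodes[m + 1], lut$pt_nodes[n + 1]),
               lut$grid[m + 1, n + 1])
  expect_error(lut_lookup(lut, lut$dt_range[2] + 1, 100), "outside")

  # edge clamp at d~min on a fully finite grid: the boundary query reads
  # the first cell pair
  toy <- structure(list(
    spec = lut_spec(m1 = 2, n1 = 2, m2 = 4, n2 = 3),
    dt_range = c(10, 30), pt_range = c(50, 80),
    dt_nodes = seq(10, 30, length.out = 5),
    pt_nodes = seq(50, 80, length.out = 4),
    grid = outer(seq(10, 30, length.out = 5),
                 seq(50, 80, length.out = 4),
                 function(a, b) 2 * a - 0.01 * b)),
    class = "correction_lut")
  expect_equal(lut_lookup(toy, 10, 60), 2 * 10 - 0.01 * 60)
  expect_equal(lut_lookup(toy, 17.5, 62.5), 2 * 17.5 - 0.01 * 62.5)

  td <- withr::local_tempdir()
  write_lut(lut, file.path(td, "lut.bin"))
  lut2 <- read_lut(file.path(td, "lut.bin"))
  expect_identical(lut2$grid, lut$grid)
  expect_equal(lut2$dt_range, lut$dt_range)
  expect_equal(lut_lookup(lut2, 30, 150), lut_lookup(lut, 30, 150))
})

test_that("the LUT is monotone: increasing in d~, non-increasing in p~", {
  lut <- shared_lut()
  g <- lut$grid
  expect_gt(mean(is.finite(g)), 0.25)   # a substantial attainable region
  up_cols <- apply(g, 2, function(col) {
    x <- col[is.finite(col)]
    length(x) < 2 || all(diff(x) > 0)
  })
  down_rows <- apply(g, 1, function(row) {
    x <- row[is.finite(row)]
    length(x) < 2 || all(diff(x) <= 1e-9)
  })
  expect_true(all(up_cols))
  expect_true(all(down_rows))
})

test_that("LUT validation against the exact solver stays within 0.15 cm", {
  lut <- shared_lut()
  v <- suppressWarnings(validate_lut(lut, n = 200, seed = 77))
  expect_lt(max(abs(v$diff)), 0.15)
})
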