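test_that("gaussian filter leaves constants unchanged and never raises the max", {
  v <- suv_volume(array(3.2, dim = c(8, 8, 8)), spacing = c(2, 2, 2))
  g <- gaussian_filter(v, 3)
  expect_equal(g$values, v$values, tolerance = 1e-12)
  set.seed(5)
  for (i in 1:20) {
    v <- suv_volume(array(runif(6^3, 0, 10), dim = c(6, 6, 6)),
                    spacing = c(2, 2, 2))
    expect_lte(max(gaussian_filter(v, 4)$values), max(v$values) + 1e-12)
  }
  expect_error(gaussian_filter(v, -1), "positive")
})

test_that("gaussian filter of a point source matches dense kernel summation", {
  v <- suv_volume(array(0, dim = c(9, 9, 9)), spacing = c(4, 4, 4))
  v$values[5, 5, 5] <- 100
  g <- gaussian_filter(v, 4)  # sigma = 1 voxel on every axis
  sig <- 1
  r <- ceiling(4 * sig)
  w <- dnorm(-r:r, sd = sig); w <- w / sum(w)
  oracle <- array(0, dim = c(9, 9, 9))
  for (a in -r:r) for (b in -r:r) for (cc in -r:r) {
    p <- c(5 + a, 5 + b, 5 + cc)
    if (all(p >= 1 & p <= 9))
      oracle[p[1], p[2], p[3]] <- 100 * w[a + r + 1] * w[b + r + 1] * w[cc + r + 1]
  }
  expect_equal(g$values, oracle, tolerance = 1e-12)
  expect_equal(g$values[5, 5, 5], 100 * w[r + 1]^3, tolerance = 1e-12)
})

test_that("resampling keeps constants, identity spacing, and mask volume", {
  v <- suv_volume(array(2.5, dim = c(12, 12, 12)), spacing = c(1, 1, 1))
  r <- resample_volume(v, 4, mode = "linear")
  expect_true(all(abs(r$values - 2.5) < 1e-12))
  expect_equal(r$spacing, c(4, 4, 4))

  set.seed(8)
  v2 <- suv_volume(array(runif(10^3), dim = c(10, 10, 10)), spacing = c(2, 2, 2))
  same <- resample_volume(v2, 2, mode = "linear")
  expect_equal(same$values, v2$values, tolerance = 1e-12)

  ball <- ball_mask(10, spacing = 1)
  mtv1 <- sum(ball$values) * prod(ball$spacing) / 1000
  b2 <- resample_volume(ball, 2, mode = "nearest")
  mtv2 <- sum(b2$values) * prod(b2$spacing) / 1000
  expect_lt(abs(mtv2 - mtv1) / mtv1, 0.05)
  expect_error(resample_volume(v, c(0, 1, 1)), "positive")
})

test_that("linear resampling reproduces a linear field inside the input extent", {
  v <- suv_volume(array(0, dim = c(9, 9, 9)), spacing = c(2, 2, 2))
  cx <- (0:8) * 2
  v$values <- outer(outer(1 + 0.3 * cx, 0.2 * cx, `+`), 0.1 * cx, `+`)
  r <- resample_volume(v, 3, mode = "linear")
  cx2 <- (seq_len(dim(r$values)[1]) - 1) * 3
  inside <- cx2 <= max(cx)
  expv <- outer(outer(1 + 0.3 * cx2, 0.2 * cx2, `+`), 0.1 * cx2, `+`)
  expect_equal(r$values[inside, inside, inside],
               expv[inside, inside, inside], tolerance = 1e-12)
})

test_that("discretization uses the exact 60/192 bin width with clamping", {
  p <- discretization_params()
  expect_equal(p$width, 0.3125)
  v <- suv_volume(array(c(0, 0.32, 60, 75, 30, -1, 59.99, 0.3124),
                        dim = c(8, 1, 1)))
  m <- lesion_mask(array(TRUE, dim = c(8, 1, 1)))
  d <- discretize(v, m, p)
  expect_equal(d$levels[1, 1, 1], 1L)    # lower edge
  expect_equal(d$levels[2, 1, 1], 2L)    # floor(.32/.3125) = 1 -> level 2
  expect_equal(d$levels[3, 1, 1], 192L)  # upper edge clamps into top bin
  expect_equal(d$levels[4, 1, 1], 192L)  # out of range clamps too
  expect_equal(d$levels[6, 1, 1], 1L)    # below range clamps to 1
  expect_equal(d$levels[8, 1, 1], 1L)
  # monotone in v and surjective when values span the range
  vals <- seq(0, 60, length.out = 5000)
  dd <- discretize(suv_volume(array(vals, dim = c(5000, 1, 1))),
                   lesion_mask(array(TRUE, dim = c(5000, 1, 1))), p)
  lv <- dd$levels[, 1, 1]
  expect_true(all(diff(lv) >= 0))
  expect_equal(sort(unique(lv)), 1:192)
  expect_error(discretize(v, lesion_mask(array(FALSE, dim = c(8, 1, 1))), p),
               "empty")
})
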