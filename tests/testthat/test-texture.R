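const_dvol <- function(value, dim = c(3, 3, 3), g = 6) {
  discretize(suv_volume(array(value, dim = dim)),
             lesion_mask(array(TRUE, dim = dim)),
             discretization_params(0, g, g))
}

test_that("GLCM of simple configurations matches hand counts", {
  d <- const_dvol(2.5, g = 6)  # every voxel at level 3
  m <- glcm(d)
  expect_equal(sum(m$p), 1)
  expect_equal(m$p[3, 3], 1)

  # two-voxel VOI at levels 1, 2
  v <- suv_volume(array(c(0.2, 1.2, 0, 0), dim = c(2, 2, 1)))
  mk <- lesion_mask(array(c(TRUE, TRUE, FALSE, FALSE), dim = c(2, 2, 1)))
  d2 <- discretize(v, mk, discretization_params(0, 2, 2))
  m2 <- glcm(d2)
  expect_equal(m2$p[1, 2], 0.5)
  expect_equal(m2$p[2, 1], 0.5)
  expect_equal(m2$p[1, 1], 0)
})

test_that("GLCM equals the exhaustive pair-enumeration oracle", {
  set.seed(31)
  for (i in 1:25) {
    d <- random_dvol(g = sample(3:5, 1))
    expect_equal(glcm(d)$p, oracle_glcm(d), tolerance = 1e-12)
  }
})

test_that("GLCM features have their closed forms", {
  d <- const_dvol(1.4, g = 6)
  f <- glcm_features(glcm(d))
  expect_equal(unname(f["joint_entropy_log10"]), 0)
  expect_equal(unname(f["inverse_difference_moment"]), 1)
  # two equal off-diagonal cells at |i - j| = 1
  m <- structure(list(p = matrix(c(0, 0.5, 0.5, 0), 2, 2)),
                 class = "cooccurrence_matrix")
  f2 <- glcm_features(m)
  expect_equal(unname(f2["joint_entropy_log10"]), log10(2), tolerance = 1e-12)
  expect_equal(unname(f2["inverse_difference_moment"]), 0.5, tolerance = 1e-12)
})

test_that("GLRLM run counting matches hand-worked merged-direction cases", {
  # constant 4x1x1 line at level 3: direction (1,0,0) gives one run of 4,
  # the other 12 merged directions give 4 runs of length 1 each
  d <- discretize(suv_volume(array(2.5, dim = c(4, 1, 1))),
                  lesion_mask(array(TRUE, dim = c(4, 1, 1))),
                  discretization_params(0, 6, 6))
  m <- glrlm(d)
  expect_equal(m$n_runs, 49)
  f <- glrlm_features(d)
  expect_equal(unname(f["short_run_emphasis"]), (48 + 1 / 16) / 49,
               tolerance = 1e-12)
  expect_equal(unname(f["long_run_emphasis"]), (48 + 16) / 49,
               tolerance = 1e-12)

  # alternating levels along a line: every run has length 1
  v <- suv_volume(array(c(0.5, 1.5, 0.5, 1.5), dim = c(4, 1, 1)))
  d2 <- discretize(v, lesion_mask(array(TRUE, dim = c(4, 1, 1))),
                   discretization_params(0, 2, 2))
  f2 <- glrlm_features(d2)
  expect_equal(unname(f2["short_run_emphasis"]), 1)
  expect_equal(unname(f2["long_run_emphasis"]), 1)
})

test_that("GLRLM equals the explicit run-scanning oracle", {
  set.seed(32)
  for (i in 1:25) {
    d <- random_dvol(g = sample(2:4, 1))
    runs <- oracle_glrlm(d)
    g <- d$params$levels
    cnt <- matrix(0, g, max(runs[, 2]))
    for (r in seq_len(nrow(runs)))
      cnt[runs[r, 1], runs[r, 2]] <- cnt[runs[r, 1], runs[r, 2]] + 1
    got <- glrlm(d)
    expect_equal(got$counts, cnt)
    expect_equal(got$n_runs, nrow(runs))
  }
})

test_that("GLSZM zone counting matches hand cases and the igraph oracle", {
  d <- const_dvol(2.5, g = 6)  # single zone at level 3
  f <- glszm_features(d)
  expect_equal(unname(f["low_gray_zone_emphasis"]), 1 / 9)
  expect_equal(unname(f["high_gray_zone_emphasis"]), 9)

  # two separated single-voxel zones at levels 1 and 2
  v <- suv_volume(array(c(0.2, 0, 0, 0, 0, 0, 0, 0, 1.2), dim = c(9, 1, 1)))
  mk <- lesion_mask(array(c(TRUE, rep(FALSE, 7), TRUE), dim = c(9, 1, 1)))
  d2 <- discretize(v, mk, discretization_params(0, 2, 2))
  f2 <- glszm_features(d2)
  expect_equal(unname(f2["low_gray_zone_emphasis"]), (1 + 1 / 4) / 2)
  expect_equal(unname(f2["high_gray_zone_emphasis"]), (1 + 4) / 2)

  skip_if_not_installed("igraph")
  set.seed(33)
  for (i in 1:25) {
    d <- random_dvol(g = sample(2:4, 1))
    z <- oracle_glszm(d)
    f <- glszm_features(d)
    expect_equal(unname(f["low_gray_zone_emphasis"]),
                 sum(1 / z[, "level"]^2) / nrow(z), tolerance = 1e-12)
    expect_equal(unname(f["high_gray_zone_emphasis"]),
                 sum(z[, "level"]^2) / nrow(z), tolerance = 1e-12)
    expect_equal(glszm(d)$n_zones, nrow(z))
  }
})

test_that("texture features are translation invariant", {
  set.seed(34)
  vals <- array(runif(4^3, 0, 4), dim = c(4, 4, 4))
  m <- array(runif(64) < 0.7, dim = c(4, 4, 4)); m[1] <- TRUE
  pad <- function(a, fill) {
    out <- array(fill, dim = c(8, 8, 8))
    out[3:6, 3:6, 3:6] <- a
    out
  }
  d1 <- discretize(suv_volume(vals), lesion_mask(m),
                   discretization_params(0, 4, 4))
  d2 <- discretize(suv_volume(pad(vals, 0)), lesion_mask(pad(m, FALSE)),
                   discretization_params(0, 4, 4))
  expect_equal(glcm(d1)$p, glcm(d2)$p)
  expect_equal(glrlm_features(d1), glrlm_features(d2))
  expect_equal(glszm_features(d1), glszm_features(d2))
})
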