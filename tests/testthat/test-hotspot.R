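test_that("locate_suv_max finds the hot voxel with deterministic tie-break", {
  v <- array(1, dim = c(6, 6, 6)); v[3, 4, 2] <- 9
  vol <- suv_volume(v); m <- lesion_mask(array(TRUE, dim = dim(v)))
  loc <- locate_suv_max(vol, m)
  expect_equal(loc$index, c(2, 3, 1))  # 0-based
  expect_equal(loc$value, 9)

  v[5, 5, 5] <- 9  # tie; (3,4,2) has the smaller linear index
  expect_message(loc2 <- locate_suv_max(suv_volume(v), m), "tie")
  expect_equal(loc2$index, c(2, 3, 1))
  expect_true(loc2$tied)

  set.seed(14)
  for (i in 1:5) {
    vals <- array(runif(10^3), dim = c(10, 10, 10))
    keep <- array(runif(1000) < 0.5, dim = c(10, 10, 10)); keep[1] <- TRUE
    got <- locate_suv_max(suv_volume(vals), lesion_mask(keep))
    expect_equal(got$value, max(vals[keep]))  # exhaustive scan
  }
})

test_that("locate_suv_peak equals the brute-force sphere-mean oracle", {
  u <- suv_volume(array(4.2, dim = c(8, 8, 8)), spacing = c(4, 4, 4))
  m <- lesion_mask(array(TRUE, dim = c(8, 8, 8)), spacing = c(4, 4, 4))
  expect_equal(locate_suv_peak(u, m)$value, 4.2, tolerance = 1e-12)

  set.seed(21)
  for (i in 1:25) {
    sp <- sample(c(2, 3, 4), 1)
    v <- suv_volume(array(runif(8^3, 0, 15), dim = c(8, 8, 8)),
                    spacing = rep(sp, 3))
    keep <- array(runif(512) < 0.3, dim = c(8, 8, 8)); keep[200] <- TRUE
    mk <- lesion_mask(keep, spacing = rep(sp, 3))
    got <- locate_suv_peak(v, mk)
    exp <- oracle_peak(v, mk)
    expect_equal(got$value, exp$value, tolerance = 1e-10)
  }
})

test_that("an isolated hot voxel spreads over the explicit neighbor count", {
  v <- array(0, dim = c(9, 9, 9)); v[5, 5, 5] <- 70
  vol <- suv_volume(v, spacing = c(4, 4, 4))
  m <- lesion_mask(v > 0, spacing = c(4, 4, 4))
  r <- (3000 / (4 * pi))^(1 / 3)
  n_in <- 0  # explicit enumeration of centers within r of the hot center
  for (a in -2:2) for (b in -2:2) for (cc in -2:2)
    if (sqrt(sum((4 * c(a, b, cc))^2)) <= r) n_in <- n_in + 1
  # 6.2 mm ball on a 4 mm grid: center + 6 faces + 12 edge diagonals
  expect_equal(n_in, 19)
  expect_equal(locate_suv_peak(vol, m)$value, 70 / n_in, tolerance = 1e-12)
})

test_that("NHOC and NHOP recover hot-spot displacement on digital balls", {
  ball <- ball_mask(20, spacing = 1)
  g <- lesion_geometry(ball)
  dm <- dim(ball$values)
  center_vox <- round((dm - 1) / 2)
  mkloc <- function(idx) {
    v <- array(0, dim = dm); v[idx[1] + 1, idx[2] + 1, idx[3] + 1] <- 1
    locate_suv_max(suv_volume(v, spacing = ball$spacing), ball)
  }
  vol0 <- suv_volume(array(1, dim = dm), spacing = ball$spacing)

  loc_c <- mkloc(center_vox)
  expect_lt(nhoc(vol0, ball, loc_c, g), 0.05)       # d ~ 0 at the centroid
  expect_equal(nhop(vol0, ball, loc_c, g), 1, tolerance = 0.05)

  loc_h <- mkloc(center_vox + c(10, 0, 0))          # 10 mm off center
  expect_equal(nhoc(vol0, ball, loc_h, g), 0.5, tolerance = 0.05)
  expect_equal(nhop(vol0, ball, loc_h, g), 0.5, tolerance = 0.05)

  loc_s <- mkloc(center_vox + c(20, 0, 0))          # on the surface
  expect_equal(nhoc(vol0, ball, loc_s, g), 1, tolerance = 0.05)
  expect_lt(nhop(vol0, ball, loc_s, g), 0.05)

  for (d in c(0, 5, 10, 15, 20)) {                  # collinearity on a ball
    l <- mkloc(center_vox + c(d, 0, 0))
    expect_equal(nhoc(vol0, ball, l, g) + nhop(vol0, ball, l, g), 1,
                 tolerance = 0.05)
  }
  # the three perimeter estimators agree within a voxel diagonal
  l <- mkloc(center_vox + c(7, 0, 0))
  d_srf <- nhop(vol0, ball, l, g, method = "surface") * g$r_eq_mm
  d_out <- nhop(vol0, ball, l, g, method = "outside") * g$r_eq_mm
  d_bnd <- nhop(vol0, ball, l, g, method = "boundary") * g$r_eq_mm
  expect_lt(abs(d_out - d_srf), sqrt(3) + 1e-9)
  expect_lt(abs(d_bnd - d_srf), sqrt(3) + 1e-9)
})

test_that("NHOC/NHOP are invariant to intensity and spatial scale", {
  ph <- make_phantom(phantom_spec(hotspot_fraction = 0.5, noise_sd = 0,
                                  seed = 2))
  seed <- ph$seed
  m <- threshold_segment(ph$volume, seed)
  a1 <- nhoc(ph$volume, m); b1 <- nhop(ph$volume, m)
  v2 <- suv_volume(ph$volume$values * 11, spacing = ph$volume$spacing)
  expect_equal(nhoc(v2, m), a1, tolerance = 1e-12)
  expect_equal(nhop(v2, m), b1, tolerance = 1e-12)
  # isotropic rescaling: same grid declared at 2 mm instead of 1 mm
  v3 <- suv_volume(ph$volume$values, spacing = c(2, 2, 2))
  m3 <- lesion_mask(m$values, spacing = c(2, 2, 2))
  expect_equal(nhoc(v3, m3), a1, tolerance = 1e-12)
  expect_equal(nhop(v3, m3), b1, tolerance = 1e-12)
})

test_that("nSPD behaves like an in-plane NHOP on the equatorial slice", {
  ball <- ball_mask(15, spacing = 1)
  dm <- dim(ball$values)
  center_vox <- round((dm - 1) / 2)
  v <- array(0, dim = dm)
  v[center_vox[1] + 1, center_vox[2] + 1, center_vox[3] + 1] <- 5
  vol <- suv_volume(v, spacing = ball$spacing)
  expect_equal(nspd_2d(vol, ball), 1, tolerance = 0.08)
  v2 <- array(0, dim = dm)
  v2[center_vox[1] + 15, center_vox[2] + 1, center_vox[3] + 1] <- 5
  expect_lt(nspd_2d(suv_volume(v2, spacing = ball$spacing), ball), 0.1)
  # random blob: matches a finely sampled scan over exposed pixel edges
  set.seed(9)
  blob <- array(runif(12^3) < 0.5, dim = c(12, 12, 12))
  blob[6, 6, 6] <- TRUE
  bm <- lesion_mask(blob)
  bv <- array(0, dim = c(12, 12, 12)); bv[6, 6, 6] <- 3
  got <- nspd_2d(suv_volume(bv), bm)
  sl <- blob[, , 6]
  hx <- 5; hy <- 5  # 0-based in-plane hot-spot coordinates
  dmin <- Inf
  tt <- seq(-0.5, 0.5, length.out = 201)
  for (i in 1:12) for (j in 1:12) {
    if (!sl[i, j]) next
    x0 <- i - 1; y0 <- j - 1
    nb <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
    for (d in nb) {
      ii <- i + d[1]; jj <- j + d[2]
      exposed <- ii < 1 || ii > 12 || jj < 1 || jj > 12 || !sl[ii, jj]
      if (!exposed) next
      if (d[1] != 0) {  # vertical edge at x0 + d/2, sampled along y
        ex <- x0 + d[1] / 2; ey <- y0 + tt
      } else {
        ex <- x0 + tt; ey <- y0 + d[2] / 2
      }
      dmin <- min(dmin, min(sqrt((ex - hx)^2 + (ey - hy)^2)))
    }
  }
  expect_equal(got, dmin / sqrt(sum(sl) / pi), tolerance = 1e-4)
})

test_that("sphericity matches closed forms and shape ordering", {
  cube <- lesion_mask(array(TRUE, dim = c(5, 5, 5)))
  expect_equal(sphericity(cube, "voxel_faces"), (pi / 6)^(1 / 3),
               tolerance = 1e-12)
  ball <- ball_mask(20, spacing = 1)
  expect_gte(sphericity(ball, "mesh"), 0.97)
  expect_lte(sphericity(ball, "mesh"), 1.02)
  rod <- lesion_mask(array(TRUE, dim = c(10, 1, 1)))
  expect_lt(sphericity(rod, "voxel_faces"),
            sphericity(cube, "voxel_faces"))
})

test_that("extraction applies the small-lesion SUVpeak fallback", {
  ph <- make_phantom(phantom_spec(semiaxes_mm = c(4, 4, 4),
                                  dim = c(24, 24, 24),
                                  hotspot_sigma_mm = 2,
                                  hotspot_fraction = 0, seed = 4))
  m <- threshold_segment(ph$volume, ph$seed)
  fv <- extract_features(ph$volume, m)  # 2 R_eq ~ 8 mm < 12 mm
  expect_true(fv$peak_fallback_used)
  expect_equal(fv$suv_peak, fv$suv_max)
  expect_equal(fv$nhoc_peak, fv$nhoc_max)
  expect_equal(fv$nhop_peak, fv$nhop_max)
})

test_that("feature vector satisfies its internal identities", {
  ph <- make_phantom(phantom_spec(hotspot_fraction = 0.4, seed = 6))
  m <- close_mask(threshold_segment(ph$volume, ph$seed), 2)
  fv <- extract_features(ph$volume, m)
  expect_lte(fv$suv_min, fv$suv_mean)
  expect_lte(fv$suv_mean, fv$suv_max)
  expect_lte(fv$suv_peak, fv$suv_max)
  expect_equal(fv$tlg, fv$mtv_cm3 * fv$suv_mean, tolerance = 1e-12)
  expect_gte(fv$nhoc_max, 0)
  expect_gte(fv$nhop_max, 0)
  expect_lte(fv$nhop_max, 1 + max(ph$volume$spacing) / fv$geometry$r_eq_mm)
  expect_false(fv$peak_fallback_used)
  # bit-reproducible on a fixed seeded phantom
  ph2 <- make_phantom(phantom_spec(hotspot_fraction = 0.4, seed = 6))
  m2 <- close_mask(threshold_segment(ph2$volume, ph2$seed), 2)
  fv2 <- extract_features(ph2$volume, m2)
  expect_identical(as.data.frame(fv), as.data.frame(fv2))
})
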