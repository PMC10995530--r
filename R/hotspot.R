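#' Locate the SUVmax hot spot
#'
#' Returns the in-mask voxel with maximal SUV. Ties are broken by the
#' smallest linear array index (deterministic under any input); a tie is
#' reported via the `tied` field and a message.
#'
#' @param vol a [suv_volume()].
#' @param mask a non-empty [lesion_mask()] on the same grid.
#' @return A `hotspot_location`: `kind` (`"max"`), `index` (0-based voxel
#'   triple), `world` (mm), `value` (SUV), `tied` (logical).
#' @export
locate_suv_max <- function(vol, mask) {
  stopifnot(inherits(vol, "suv_volume"), inherits(mask, "lesion_mask"))
  check_same_geometry(vol, mask)
  lin <- which(mask$values)
  if (length(lin) == 0L) stop("mask is empty")
  v <- vol$values[lin]
  vmax <- max(v)
  hits <- lin[v == vmax]
  if (length(hits) > 1L)
    message("SUVmax tie among ", length(hits),
            " voxels; keeping smallest linear index")
  hotspot_location("max", hits[1L], vmax, vol, tied = length(hits) > 1L)
}

#' Locate the SUVpeak hot spot
#'
#' For every in-mask candidate center, averages the SUV over all *image*
#' voxels whose centers lie within the radius of a sphere of volume
#' `sphere_volume_cm3` (default 1 cm^3, radius ~ 6.2035 mm) of the
#' candidate's center, and returns the candidate maximizing that mean
#' (PERCIST-style: the sphere is anchored in the lesion but may average
#' voxels outside the mask; parts of the sphere beyond the grid are
#' dropped from the average). Ties go to the smallest linear index.
#'
#' @inheritParams locate_suv_max
#' @param sphere_volume_cm3 sphere volume in cm^3.
#' @return A `hotspot_location` with `kind = "peak"`; `value` is the
#'   maximal sphere-mean SUV and `index`/`world` the maximizing center.
#' @export
locate_suv_peak <- function(vol, mask, sphere_volume_cm3 = 1.0) {
  stopifnot(inherits(vol, "suv_volume"), inherits(mask, "lesion_mask"))
  check_same_geometry(vol, mask)
  if (!any(mask$values)) stop("mask is empty")
  if (sphere_volume_cm3 <= 0) stop("'sphere_volume_cm3' must be positive")
  r_mm <- (3 * sphere_volume_cm3 * 1000 / (4 * pi))^(1 / 3)
  off <- ball_offsets(r_mm, vol$spacing)
  sums <- ball_sum(vol$values, off)
  cnts <- ball_sum(array(1, dim = dim(vol$values)), off)
  means <- sums / cnts
  lin <- which(mask$values)
  m <- means[lin]
  mmax <- max(m)
  hits <- lin[m == mmax]
  if (length(hits) > 1L)
    message("SUVpeak tie among ", length(hits),
            " centers; keeping smallest linear index")
  hotspot_location("peak", hits[1L], mmax, vol, tied = length(hits) > 1L)
}

hotspot_location <- function(kind, lin, value, vol, tied = FALSE) {
  idx <- drop(arr_ind(lin, dim(vol$values))) - 1L
  structure(list(kind = kind, index = idx,
                 world = idx * vol$spacing + vol$origin,
                 value = value, tied = tied),
            class = "hotspot_location")
}

#' @export
print.hotspot_location <- function(x, ...) {
  cat("<hotspot_location> SUV", x$kind, " = ", format(x$value, digits = 4),
      " at voxel (", paste(x$index, collapse = ", "), "), world (",
      paste(format(x$world, digits = 4), collapse = ", "), ") mm\n", sep = "")
  invisible(x)
}

resolve_hotspot <- function(vol, mask, locator, sphere_volume_cm3 = 1.0) {
  if (inherits(locator, "hotspot_location")) return(locator)
  locator <- match.arg(locator, c("max", "peak"))
  if (locator == "max") locate_suv_max(vol, mask)
  else locate_suv_peak(vol, mask, sphere_volume_cm3)
}

#' Normalized hot-spot-to-centroid distance (NHOC)
#'
#' Euclidean distance (mm) from the hot spot (SUVmax or SUVpeak
#' location) to the unweighted centroid of the lesion mask, divided by
#' `R_eq`, the radius of the hypothetical sphere with the lesion's
#' volume. Dimensionless and non-negative; values above 1 occur for
#' elongated lesions, where the hot spot can sit farther from the
#' centroid than `R_eq`.
#'
#' @inheritParams locate_suv_max
#' @param locator `"max"`, `"peak"`, or a precomputed
#'   `hotspot_location`.
#' @param geom optional precomputed [lesion_geometry()] of `mask`.
#' @return Dimensionless non-negative scalar.
#' @export
nhoc <- function(vol, mask, locator = "max", geom = NULL) {
  loc <- resolve_hotspot(vol, mask, locator)
  if (is.null(geom)) geom <- lesion_geometry(mask)
  sqrt(sum((loc$world - geom$centroid_mm)^2)) / geom$r_eq_mm
}

#' Normalized hot-spot-to-perimeter distance (NHOP, 3D)
#'
#' Minimum Euclidean distance (mm) from the hot spot to the lesion
#' perimeter, divided by `R_eq`. The perimeter of a voxelized mask is
#' the union of its exposed voxel faces (faces between an in-mask voxel
#' and an out-of-mask voxel or the grid edge); the default
#' (`method = "surface"`) computes the exact point-to-face distance,
#' which carries no estimator bias. Two point-set approximations are
#' also offered: `"outside"` (nearest out-of-mask voxel center, up to
#' half a voxel beyond the surface) and `"boundary"` (nearest in-mask
#' boundary voxel center, up to a voxel inside it); all three agree
#' within one voxel diagonal.
#'
#' @inheritParams nhoc
#' @param method `"surface"`, `"outside"` or `"boundary"`.
#' @return Dimensionless non-negative scalar; at most 1 up to
#'   voxelization (the distance to the perimeter cannot exceed the
#'   inradius, which cannot exceed `R_eq`).
#' @export
nhop <- function(vol, mask, locator = "max", geom = NULL,
                 method = c("surface", "outside", "boundary")) {
  method <- match.arg(method)
  loc <- resolve_hotspot(vol, mask, locator)
  if (is.null(geom)) geom <- lesion_geometry(mask)
  if (method == "surface") {
    d <- surface_distance(mask, loc$world)
  } else if (method == "outside" && !all(mask$values)) {
    idx <- which(!mask$values, arr.ind = TRUE) - 1L
    w <- idx * matrix(mask$spacing, nrow(idx), 3, byrow = TRUE) +
      matrix(mask$origin, nrow(idx), 3, byrow = TRUE)
    d <- min(sqrt(rowSums((w - matrix(loc$world, nrow(w), 3,
                                      byrow = TRUE))^2)))
  } else {
    b <- geom$boundary_mm
    d <- min(sqrt(rowSums((b - matrix(loc$world, nrow(b), 3,
                                      byrow = TRUE))^2)))
  }
  d / geom$r_eq_mm
}

# exact Euclidean distance from a world point to the union of exposed
# voxel faces (axis-aligned rectangles) of the mask
surface_distance <- function(mask, point) {
  m <- mask$values
  s <- mask$spacing
  best <- Inf
  axes <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (ax in 1:3) for (sgn in c(-1L, 1L)) {
    nb <- take_shifted(m, sgn * axes[[ax]], pad = "zero", fill = FALSE)
    idx <- which(m & !nb, arr.ind = TRUE) - 1L
    if (nrow(idx) == 0L) next
    w <- idx * matrix(s, nrow(idx), 3, byrow = TRUE) +
      matrix(mask$origin, nrow(idx), 3, byrow = TRUE)
    d2 <- numeric(nrow(idx))
    for (j in 1:3) {
      dj <- point[j] - w[, j]
      d2 <- d2 + if (j == ax) (dj - sgn * s[j] / 2)^2
                 else pmax(0, abs(dj) - s[j] / 2)^2
    }
    best <- min(best, min(d2))
  }
  sqrt(best)
}

#' 2D normalized hot-spot-to-perimeter distance (nSPD)
#'
#' The single-slice predecessor of [nhop()]: on the axial slice (third
#' axis) containing the hot spot, the minimum in-plane distance (mm)
#' from the hot spot to the slice's in-plane perimeter (exact distance
#' to the exposed pixel edges, the 2D analogue of [nhop()]'s surface
#' method), normalized by the radius of the circle with the same area
#' as the slice's mask cross-section.
#'
#' @inheritParams nhoc
#' @return Dimensionless non-negative scalar.
#' @export
nspd_2d <- function(vol, mask, locator = "max") {
  loc <- resolve_hotspot(vol, mask, locator)
  k <- loc$index[3] + 1L
  sl <- mask$values[, , k]
  if (!any(sl)) stop("mask is empty on the hot spot's axial slice")
  if (all(sl)) stop("mask fills the hot spot's axial slice")
  dmx <- dim(sl)
  s <- mask$spacing[1:2]
  shift2 <- function(m, di, dj) {
    n <- matrix(FALSE, dmx[1], dmx[2])
    si <- seq_len(dmx[1]) + di; sj <- seq_len(dmx[2]) + dj
    ok_i <- si >= 1L & si <= dmx[1]; ok_j <- sj >= 1L & sj <= dmx[2]
    n[ok_i, ok_j] <- m[si[ok_i], sj[ok_j]]
    n
  }
  best <- Inf
  dirs <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  for (d2 in dirs) {
    nb <- shift2(sl, d2[1], d2[2])
    idx <- which(sl & !nb, arr.ind = TRUE) - 1L
    if (nrow(idx) == 0L) next
    w <- cbind(idx[, 1] * s[1] + mask$origin[1],
               idx[, 2] * s[2] + mask$origin[2])
    ax <- which(d2 != 0L)
    lat <- 3L - ax
    dperp <- loc$world[ax] - (w[, ax] + d2[ax] * s[ax] / 2)
    dlat <- pmax(0, abs(loc$world[lat] - w[, lat]) - s[lat] / 2)
    best <- min(best, min(dperp^2 + dlat^2))
  }
  area_mm2 <- sum(sl) * s[1] * s[2]
  sqrt(best) / sqrt(area_mm2 / pi)
}

#' Sphericity of a lesion mask
#'
#' `pi^(1/3) * (6 V)^(2/3) / A` with `V` the mask volume and `A` the
#' surface area; 1 for a perfect sphere, smaller for any other shape.
#' `surface_method = "mesh"` (default) triangulates the 0.5 isosurface
#' of a lightly smoothed mask indicator by marching tetrahedra, which
#' converges to the true area for smooth shapes; `"voxel_faces"` counts
#' exposed voxel faces, which is exact for axis-aligned boxes but
#' overestimates the area of curved surfaces (a digital ball then gets a
#' sphericity near `(pi/6)^(1/3)` ~ 0.806 rather than 1).
#'
#' @param mask a non-empty [lesion_mask()].
#' @param surface_method `"mesh"` or `"voxel_faces"`.
#' @return Sphericity in (0, 1] up to discretization error.
#' @export
sphericity <- function(mask, surface_method = c("mesh", "voxel_faces")) {
  surface_method <- match.arg(surface_method)
  stopifnot(inherits(mask, "lesion_mask"))
  if (!any(mask$values)) stop("mask is empty")
  v_mm3 <- sum(mask$values) * prod(mask$spacing)
  a_mm2 <- if (surface_method == "voxel_faces")
    voxel_face_area(mask) else mesh_surface_area(mask)
  pi^(1 / 3) * (6 * v_mm3)^(2 / 3) / a_mm2
}

voxel_face_area <- function(mask) {
  m <- mask$values
  s <- mask$spacing
  face <- c(s[2] * s[3], s[1] * s[3], s[1] * s[2])
  a <- 0
  axes <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (ax in 1:3) for (sgn in c(-1L, 1L)) {
    nb <- take_shifted(m, sgn * axes[[ax]], pad = "zero", fill = FALSE)
    a <- a + sum(m & !nb) * face[ax]
  }
  a
}

# triangulated area of the 0.5 isosurface of the smoothed mask indicator
mesh_surface_area <- function(mask, sigma_vox = 0.9) {
  dm <- dim(mask$values)
  pad <- 3L
  a <- array(0, dim = dm + 2L * pad)
  a[pad + seq_len(dm[1]), pad + seq_len(dm[2]), pad + seq_len(dm[3])] <-
    as.numeric(mask$values)
  for (ax in 1:3) {  # separable gaussian in voxel units
    r <- ceiling(3 * sigma_vox)
    w <- stats::dnorm(-r:r, sd = sigma_vox); w <- w / sum(w)
    acc <- array(0, dim = dim(a))
    for (s in seq_along(w)) {
      offv <- c(0L, 0L, 0L); offv[ax] <- s - r - 1L
      acc <- acc + w[s] * take_shifted(a, offv, pad = "zero")
    }
    a <- acc
  }
  if (max(a) < 0.5) {  # mask too small for smoothing; use binary field
    a <- array(0, dim = dm + 2L * pad)
    a[pad + seq_len(dm[1]), pad + seq_len(dm[2]), pad + seq_len(dm[3])] <-
      as.numeric(mask$values)
  }
  f <- a - 0.5
  dmp <- dim(f)
  # cells (lower corner index) whose 8 corners straddle the level set
  cin <- f >= 0
  cells <- which(
    (cin[-dmp[1], -dmp[2], -dmp[3]] | cin[-1, -dmp[2], -dmp[3]] |
       cin[-dmp[1], -1, -dmp[3]] | cin[-1, -1, -dmp[3]] |
       cin[-dmp[1], -dmp[2], -1] | cin[-1, -dmp[2], -1] |
       cin[-dmp[1], -1, -1] | cin[-1, -1, -1]) &
      !(cin[-dmp[1], -dmp[2], -dmp[3]] & cin[-1, -dmp[2], -dmp[3]] &
          cin[-dmp[1], -1, -dmp[3]] & cin[-1, -1, -dmp[3]] &
          cin[-dmp[1], -dmp[2], -1] & cin[-1, -dmp[2], -1] &
          cin[-dmp[1], -1, -1] & cin[-1, -1, -1]),
    arr.ind = TRUE)
  if (nrow(cells) == 0L) return(voxel_face_area(mask))
  s <- mask$spacing
  # cube corners in unit-cell coordinates; 6 tetrahedra sharing c0-c6
  corners <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                   c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  tets <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))
  cornval <- function(cidx) {
    f[cbind(cells[, 1] + corners[cidx, 1], cells[, 2] + corners[cidx, 2],
            cells[, 3] + corners[cidx, 3])]
  }
  cornpos <- function(cidx) {
    cbind((cells[, 1] - 1 + corners[cidx, 1]) * s[1],
          (cells[, 2] - 1 + corners[cidx, 2]) * s[2],
          (cells[, 3] - 1 + corners[cidx, 3]) * s[3])
  }
  area <- 0
  for (t in seq_len(nrow(tets))) {
    vv <- lapply(1:4, function(q) cornval(tets[t, q]))
    pp <- lapply(1:4, function(q) cornpos(tets[t, q]))
    area <- area + tet_isosurface_area(vv, pp)
  }
  area
}

# total area of the zero level set inside tetrahedra given 4 corner
# values (vectors over tets) and positions (n x 3 matrices)
tet_isosurface_area <- function(vv, pp) {
  inside <- sapply(vv, function(v) v >= 0)
  if (is.null(dim(inside))) inside <- matrix(inside, nrow = 1)
  code <- inside %*% c(1L, 2L, 4L, 8L)
  total <- 0
  cross_pt <- function(ia, ib, rows) {
    va <- vv[[ia]][rows]; vb <- vv[[ib]][rows]
    tt <- va / (va - vb)
    pp[[ia]][rows, , drop = FALSE] +
      tt * (pp[[ib]][rows, , drop = FALSE] - pp[[ia]][rows, , drop = FALSE])
  }
  tri_area <- function(p1, p2, p3) {
    u <- p2 - p1; v <- p3 - p1
    cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
    cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
    cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
    0.5 * sqrt(cx^2 + cy^2 + cz^2)
  }
  singles <- list(`1` = c(1L, 2L, 3L, 4L), `2` = c(2L, 1L, 3L, 4L),
                  `4` = c(3L, 1L, 2L, 4L), `8` = c(4L, 1L, 2L, 3L))
  for (cd in names(singles)) {
    iso <- singles[[cd]]
    for (targ in c(as.integer(cd), 15L - as.integer(cd))) {
      rows <- which(code == targ)
      if (length(rows) == 0L) next
      q1 <- cross_pt(iso[1], iso[2], rows)
      q2 <- cross_pt(iso[1], iso[3], rows)
      q3 <- cross_pt(iso[1], iso[4], rows)
      total <- total + sum(tri_area(q1, q2, q3))
    }
  }
  pairs <- list(`3` = rbind(c(1L, 2L), c(3L, 4L)),
                `5` = rbind(c(1L, 3L), c(2L, 4L)),
                `9` = rbind(c(1L, 4L), c(2L, 3L)))
  for (cd in names(pairs)) {
    pr <- pairs[[cd]]
    for (targ in c(as.integer(cd), 15L - as.integer(cd))) {
      rows <- which(code == targ)
      if (length(rows) == 0L) next
      a1 <- pr[1, 1]; a2 <- pr[1, 2]; b1 <- pr[2, 1]; b2 <- pr[2, 2]
      # quad cycle: (a1,b1) (a1,b2) (a2,b2) (a2,b1)
      q1 <- cross_pt(a1, b1, rows)
      q2 <- cross_pt(a1, b2, rows)
      q3 <- cross_pt(a2, b2, rows)
      q4 <- cross_pt(a2, b1, rows)
      total <- total + sum(tri_area(q1, q2, q3)) + sum(tri_area(q1, q3, q4))
    }
  }
  total
}
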