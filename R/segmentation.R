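#' Segmentation parameters
#'
#' Controls the isocontour delineation of the metabolically active
#' lesion: the threshold as a fraction of the SUVmax found inside the
#' seed VOI (default 40%), the radius of the ball structuring element
#' used by the optional morphological closing that swallows internal
#' necrotic areas (0 disables; `NULL` means twice the largest voxel
#' spacing), and whether to keep only the connected component containing
#' the SUVmax voxel.
#'
#' @param threshold_fraction fraction of in-seed SUVmax, in (0, 1).
#' @param closing_radius_mm closing ball radius in mm, `>= 0`;
#'   `NULL` = `2 * max(spacing)` of the volume at hand.
#' @param keep_largest keep only the 26-connected component that
#'   contains the SUVmax voxel (default `TRUE`).
#' @return A `segmentation_params` object.
#' @export
segmentation_params <- function(threshold_fraction = 0.40,
                                closing_radius_mm = NULL,
                                keep_largest = TRUE) {
  if (!is.numeric(threshold_fraction) || length(threshold_fraction) != 1L ||
      threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("'threshold_fraction' must be in (0, 1)")
  if (!is.null(closing_radius_mm) &&
      (!is.numeric(closing_radius_mm) || closing_radius_mm < 0))
    stop("'closing_radius_mm' must be >= 0 (or NULL for the default)")
  structure(list(threshold_fraction = threshold_fraction,
                 closing_radius_mm = closing_radius_mm,
                 keep_largest = isTRUE(keep_largest)),
            class = "segmentation_params")
}

#' Isocontour lesion segmentation
#'
#' Delineates the lesion as the set of seed-VOI voxels with SUV at or
#' above `threshold_fraction` times the maximum SUV found *inside the
#' seed* (the threshold is lesion-relative, so the result is invariant
#' to global intensity scaling). With `keep_largest`, the mask is
#' restricted to the 26-connected component containing the SUVmax voxel,
#' which discards disconnected bright structures caught by a generous
#' seed box.
#'
#' Closing is *not* applied here; call [close_mask()] on the result (the
#' necrosis on/off comparisons toggle exactly that step).
#'
#' @param vol a [suv_volume()].
#' @param seed_voi a non-empty [lesion_mask()] on the same grid (a
#'   manually drawn box or rough region known to contain the lesion).
#' @param params a [segmentation_params()].
#' @return A [lesion_mask()] of the segmented lesion.
#' @export
threshold_segment <- function(vol, seed_voi, params = segmentation_params()) {
  stopifnot(inherits(vol, "suv_volume"), inherits(seed_voi, "lesion_mask"))
  check_same_geometry(vol, seed_voi)
  if (!any(seed_voi$values)) stop("seed VOI is empty")
  inseed <- which(seed_voi$values)
  vmax <- max(vol$values[inseed])
  if (vmax <= 0) stop("SUVmax within the seed VOI must be positive")
  thr <- params$threshold_fraction * vmax
  keep <- seed_voi$values & (vol$values >= thr)
  if (!any(keep)) stop("no voxel at or above the threshold")
  if (params$keep_largest) {
    labs <- label_components(keep, connectivity = 26L)
    hot <- inseed[vol$values[inseed] == vmax][1L]  # smallest linear index
    keep <- labs == labs[hot]
  }
  lesion_mask(keep, spacing = vol$spacing, origin = vol$origin)
}

#' Morphological closing of a mask
#'
#' Dilation followed by erosion with a ball structuring element of the
#' given physical radius (mm), computed on a grid padded by the ball
#' radius so the operation is not clipped at the array border. Closing
#' fills internal cavities (necrotic cores) narrower than the ball; the
#' output always contains the input and `radius_mm = 0` is the identity.
#'
#' @param mask a [lesion_mask()].
#' @param radius_mm ball radius in mm, `>= 0`.
#' @return The closed [lesion_mask()].
#' @export
close_mask <- function(mask, radius_mm) {
  stopifnot(inherits(mask, "lesion_mask"))
  if (!is.numeric(radius_mm) || length(radius_mm) != 1L || radius_mm < 0)
    stop("'radius_mm' must be a single number >= 0")
  off <- ball_offsets(radius_mm, mask$spacing)
  if (nrow(off) <= 1L) return(mask)
  pad <- unname(apply(abs(off), 2, max))
  dm <- dim(mask$values)
  big <- array(FALSE, dim = dm + 2L * pad)
  core <- lapply(1:3, function(ax) seq_len(dm[ax]) + pad[ax])
  big[core[[1]], core[[2]], core[[3]]] <- mask$values
  dil <- array(FALSE, dim = dim(big))
  for (r in seq_len(nrow(off)))
    dil <- dil | take_shifted(big, off[r, ], pad = "zero", fill = FALSE)
  ero <- array(TRUE, dim = dim(big))
  for (r in seq_len(nrow(off)))
    ero <- ero & take_shifted(dil, off[r, ], pad = "zero", fill = FALSE)
  out <- ero[core[[1]], core[[2]], core[[3]], drop = FALSE] | mask$values
  lesion_mask(out, spacing = mask$spacing, origin = mask$origin)
}

#' Lesion geometry summary
#'
#' Computes the geometric quantities every displacement feature relies
#' on: voxel count, metabolic tumor volume MTV (cm^3, voxel count times
#' voxel volume), the unweighted centroid of in-mask voxel centers
#' (world mm), the equivalent-sphere radius `R_eq = (3 MTV / 4 pi)^(1/3)`
#' (mm) of the hypothetical sphere with the lesion's volume, and the
#' boundary voxels (in-mask voxels with at least one of their 6 face
#' neighbors outside the mask or beyond the grid edge).
#'
#' @param mask a non-empty [lesion_mask()].
#' @return A `lesion_geometry` list: `n_voxels`, `mtv_cm3`,
#'   `centroid_mm`, `r_eq_mm`, `boundary` (n x 3 matrix of 0-based voxel
#'   indices), `boundary_mm` (world coordinates).
#' @export
lesion_geometry <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  if (!any(mask$values)) stop("mask is empty")
  n <- sum(mask$values)
  mtv <- n * voxel_volume_cm3(mask)
  w <- mask_world_coords(mask)
  centroid <- colMeans(w)
  r_eq <- (3 * mtv * 1000 / (4 * pi))^(1 / 3)  # cm^3 -> mm^3
  inner <- array(TRUE, dim = dim(mask$values))
  for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1)))
    inner <- inner & take_shifted(mask$values, off, pad = "zero", fill = FALSE)
  bnd <- mask$values & !inner
  bidx <- which(bnd, arr.ind = TRUE) - 1L
  bmm <- bidx * matrix(mask$spacing, nrow(bidx), 3, byrow = TRUE) +
    matrix(mask$origin, nrow(bidx), 3, byrow = TRUE)
  structure(list(n_voxels = n, mtv_cm3 = mtv, centroid_mm = centroid,
                 r_eq_mm = r_eq, boundary = bidx, boundary_mm = bmm),
            class = "lesion_geometry")
}

#' @export
print.lesion_geometry <- function(x, ...) {
  cat("<lesion_geometry> ", x$n_voxels, " voxels, MTV ",
      format(x$mtv_cm3, digits = 4), " cm^3, R_eq ",
      format(x$r_eq_mm, digits = 4), " mm\n", sep = "")
  invisible(x)
}
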