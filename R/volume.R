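#' 3D SUV volume container
#'
#' A `suv_volume` holds a 3D grid of standardized uptake values (SUV,
#' dimensionless) together with its physical geometry: per-axis voxel
#' spacing in mm and the world position (mm) of the *center* of voxel
#' `(0, 0, 0)`. All distances computed by the package are Euclidean
#' distances in mm in this physical space, so anisotropic voxels are
#' handled correctly.
#'
#' Voxel indices are 0-based triples `(i, j, k)` with `i` the
#' fastest-varying array dimension (x). World coordinates follow the
#' voxel-center convention `world = origin + index * spacing`.
#'
#' @param values numeric 3D array of finite SUV values.
#' @param spacing numeric length-3, strictly positive voxel size in mm.
#' @param origin numeric length-3, world position (mm) of the center of
#'   voxel `(0,0,0)`.
#' @return An object of class `suv_volume` with fields `values`,
#'   `spacing`, `origin`.
#' @seealso [lesion_mask()], [read_volume()], [voxel_to_world()]
#' @export
#' @examples
#' v <- suv_volume(array(1, dim = c(4, 4, 4)), spacing = c(4, 4, 4))
#' v
suv_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- check_grid(values)
  if (!is.numeric(values)) stop("'values' must be numeric")
  if (!all(is.finite(values))) stop("SUV values must all be finite")
  structure(list(values = values,
                 spacing = check_spacing(spacing),
                 origin = check_origin(origin)),
            class = "suv_volume")
}

#' Binary lesion mask container
#'
#' A `lesion_mask` is a boolean 3D grid on the same voxel-center geometry
#' as [suv_volume()]. It represents a volume of interest (VOI), e.g. the
#' metabolically active part of a lesion after isocontour segmentation.
#'
#' @param values logical (or 0/1 numeric) 3D array.
#' @inheritParams suv_volume
#' @return An object of class `lesion_mask`.
#' @export
#' @examples
#' m <- lesion_mask(array(c(TRUE, FALSE), dim = c(2, 2, 2)))
#' sum(m$values)
lesion_mask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- check_grid(values)
  if (is.numeric(values)) {
    if (!all(values %in% c(0, 1))) stop("numeric mask values must be 0/1")
    values <- array(values != 0, dim = dim(values))
  }
  if (!is.logical(values)) stop("'values' must be logical or 0/1 numeric")
  if (anyNA(values)) stop("mask values must not be NA")
  structure(list(values = values,
                 spacing = check_spacing(spacing),
                 origin = check_origin(origin)),
            class = "lesion_mask")
}

check_grid <- function(values) {
  if (is.null(dim(values)) || length(dim(values)) != 3L)
    stop("grid must be a 3D array, got ",
         if (is.null(dim(values))) "a vector" else paste0(length(dim(values)), "D"))
  if (length(values) == 0L) stop("grid must be non-empty")
  values
}

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive voxel sizes in mm")
  spacing
}

check_origin <- function(origin) {
  origin <- as.numeric(origin)
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("'origin' must be 3 finite world coordinates in mm")
  origin
}

#' @export
print.suv_volume <- function(x, ...) {
  cat("<suv_volume> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = " x "),
      " mm\n  SUV range [", format(min(x$values)), ", ",
      format(max(x$values)), "]\n", sep = "")
  invisible(x)
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat("<lesion_mask> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = " x "),
      " mm, ", sum(x$values), " in mask\n", sep = "")
  invisible(x)
}

# shared geometry check for volume/mask pairs
check_same_geometry <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)))
    stop("volume and mask have different grid shapes")
  if (max(abs(a$spacing - b$spacing)) > 1e-6 ||
      max(abs(a$origin - b$origin)) > 1e-4)
    stop("volume and mask have different physical geometry")
  invisible(TRUE)
}

voxel_volume_cm3 <- function(x) prod(x$spacing) / 1000

#' Voxel/world coordinate conversion
#'
#' Converts 0-based voxel indices to world coordinates (mm) of the voxel
#' centers, and back. The mapping is `world = origin + index * spacing`,
#' applied per axis.
#'
#' @param index integer triple (or n x 3 matrix) of 0-based voxel indices.
#' @param vol a [suv_volume()] or [lesion_mask()].
#' @return `voxel_to_world()`: numeric triple (or n x 3 matrix) of mm
#'   coordinates; `world_to_voxel()`: integer indices after rounding to
#'   the nearest voxel center.
#' @export
#' @examples
#' v <- suv_volume(array(0, dim = c(5, 5, 5)), spacing = c(4, 4, 4))
#' voxel_to_world(c(1, 2, 3), v)
voxel_to_world <- function(index, vol) {
  idx <- as_index_matrix(index)
  dm <- dim(vol$values)
  if (any(idx < 0) || any(idx >= matrix(dm, nrow(idx), 3, byrow = TRUE)))
    stop("voxel index out of grid bounds")
  w <- idx * matrix(vol$spacing, nrow(idx), 3, byrow = TRUE) +
    matrix(vol$origin, nrow(idx), 3, byrow = TRUE)
  if (nrow(w) == 1L) drop(w) else w
}

#' @rdname voxel_to_world
#' @param world numeric triple (or n x 3 matrix) of world mm coordinates.
#' @export
world_to_voxel <- function(world, vol) {
  w <- as_index_matrix(world)
  idx <- round((w - matrix(vol$origin, nrow(w), 3, byrow = TRUE)) /
                 matrix(vol$spacing, nrow(w), 3, byrow = TRUE))
  storage.mode(idx) <- "integer"
  if (nrow(idx) == 1L) drop(idx) else idx
}

as_index_matrix <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 3L) stop("index/point matrix must have 3 columns")
    x
  } else {
    if (length(x) != 3L) stop("index/point must have 3 components")
    matrix(as.numeric(x), 1L, 3L)
  }
}

# world coordinates (n x 3) of all in-mask voxel centers
mask_world_coords <- function(mask) {
  idx <- which(mask$values, arr.ind = TRUE) - 1L
  idx * matrix(mask$spacing, nrow(idx), 3, byrow = TRUE) +
    matrix(mask$origin, nrow(idx), 3, byrow = TRUE)
}
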