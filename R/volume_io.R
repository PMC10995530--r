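#' Read and write 3D SUV volumes and masks as NIfTI-1
#'
#' `read_volume()` loads a 3D NIfTI-1 file into a [suv_volume()];
#' `read_mask()` loads a 0/1-coded file into a [lesion_mask()].
#' Voxel spacing is taken from the header `pixdim` and the origin from
#' the translation part of the qform/sform; any rotation component is
#' ignored, which is safe here because every feature computed by the
#' package is a rotation-covariant quantity measured in mm.
#'
#' @param path path to a `.nii` or `.nii.gz` file containing 3D data.
#' @return A [suv_volume()] or [lesion_mask()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  arr <- array(as.vector(arr), dim = dim(arr))  # drop niftiImage attributes
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1L]
  if (length(dim(arr)) != 3L)
    stop("expected 3D data, got ", length(dim(arr)), "D in ", path)
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("non-positive voxel spacing in header of ", path)
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- if (inherits(xf, "try-error")) c(0, 0, 0) else as.numeric(xf[1:3, 4])
  suv_volume(arr, spacing = spacing, origin = origin)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  if (!all(v$values %in% c(0, 1)))
    stop("mask file must contain only 0/1 values: ", path)
  lesion_mask(v$values != 0, spacing = v$spacing, origin = v$origin)
}

#' @rdname read_volume
#' @param vol a [suv_volume()] or [lesion_mask()] to serialize. Masks are
#'   written as 0/1 integers; volumes in double precision so that a
#'   read/write round trip reproduces values bit-exactly.
#' @export
write_volume <- function(vol, path) {
  is_mask <- inherits(vol, "lesion_mask")
  arr <- if (is_mask) array(as.integer(vol$values), dim = dim(vol$values))
         else vol$values
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol$spacing
  m <- diag(4)
  m[1, 1] <- vol$spacing[1]; m[2, 2] <- vol$spacing[2]; m[3, 3] <- vol$spacing[3]
  m[1:3, 4] <- vol$origin
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path,
                     datatype = if (is_mask) "uint8" else "double")
  invisible(path)
}
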