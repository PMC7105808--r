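#' 4D functional volume container
#'
#' The unit all pipeline stages consume and produce: a 4D intensity grid
#' (x, y, z, t) together with the voxel size in mm, the repetition time in
#' seconds, and an optional binary brain mask on the same spatial grid.
#'
#' @param data numeric 4D array (x, y, z, t).
#' @param voxel_mm positive numeric triple, voxel edge lengths in mm.
#' @param tr_seconds positive scalar, repetition time in seconds.
#' @param mask optional logical 3D array matching the spatial grid.
#' @return an object of class `volume4d`.
#' @export
volume4d <- function(data, voxel_mm = c(3, 3, 3), tr_seconds = 1.8, mask = NULL) {
  stopifnot(length(dim(data)) == 4L, all(is.finite(data)),
            length(voxel_mm) == 3L, all(voxel_mm > 0), tr_seconds > 0)
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(data)[1:3]))
    mask <- array(as.logical(mask), dim(mask))
  }
  structure(list(data = data, voxel_mm = as.numeric(voxel_mm),
                 tr_seconds = as.numeric(tr_seconds), mask = mask),
            class = "volume4d")
}

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume4d> %d x %d x %d grid, %d volumes, voxel %s mm, TR %.3g s%s\n",
              d[1], d[2], d[3], d[4], paste(x$voxel_mm, collapse = "x"),
              x$tr_seconds,
              if (is.null(x$mask)) "" else sprintf(", mask %d voxels", sum(x$mask))))
  invisible(x)
}

#' @export
dim.volume4d <- function(x) dim(x$data)

n_volumes <- function(vol) dim(vol$data)[4]

# Extract the in-mask data as a T x V matrix (V = in-mask voxels).
vol_matrix <- function(vol, mask = vol$mask) {
  stopifnot(!is.null(mask))
  d <- dim(vol$data)
  m <- matrix(vol$data, prod(d[1:3]), d[4])
  t(m[as.vector(mask), , drop = FALSE])
}

# Rebuild a 3D array from an in-mask vector (zero outside the mask).
unmask <- function(values, mask) {
  out <- array(0, dim(mask))
  out[mask] <- values
  out
}

#' Read a 4D NIfTI file as a `volume4d`
#'
#' @param path NIfTI-1 file (.nii or .nii.gz).
#' @param mask optional path to a 3D mask NIfTI on the same grid.
#' @return a [volume4d()] object; TR and voxel size are taken from the header.
#' @export
read_volume4d <- function(path, mask = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 3L) d <- c(d, 1L)
  pix <- RNifti::pixdim(img)
  tr <- if (length(pix) >= 4 && pix[4] > 0) pix[4] else 1
  m <- NULL
  if (!is.null(mask)) m <- array(as.array(RNifti::readNifti(mask)) > 0.5, d[1:3])
  volume4d(array(as.array(img), d), voxel_mm = pix[1:3], tr_seconds = tr, mask = m)
}

#' Write a `volume4d` (and optionally its mask) to NIfTI-1
#'
#' @param vol a [volume4d()] object.
#' @param path output path for the 4D data.
#' @param mask_path optional output path for the binary mask.
#' @return `path`, invisibly.
#' @export
write_volume4d <- function(vol, path, mask_path = NULL) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- c(vol$voxel_mm, vol$tr_seconds)
  RNifti::writeNifti(img, path)
  if (!is.null(mask_path)) {
    stopifnot(!is.null(vol$mask))
    m <- RNifti::asNifti(array(as.integer(vol$mask), dim(vol$mask)))
    RNifti::pixdim(m) <- vol$voxel_mm
    RNifti::writeNifti(m, mask_path)
  }
  invisible(path)
}

# Write any 3D/4D array as NIfTI with given voxel size.
write_map_nifti <- function(arr, path, voxel_mm = c(3, 3, 3)) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxel_mm[seq_len(min(3, length(dim(arr))))]
  RNifti::writeNifti(img, path)
  invisible(path)
}
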