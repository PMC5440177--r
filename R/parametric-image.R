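# Container for 3D voxel maps of a single outcome parameter.

#' Parametric image
#'
#' A 3D voxel map of one outcome (VT, BPND or SUV) with the mask it was
#' fitted in and simple provenance fields. Out-of-mask and failed voxels
#' hold `NaN`.
#'
#' @param data 3D numeric array.
#' @param mask Logical 3D array of the fitted voxels.
#' @param outcome Outcome name, e.g. `"VT"`, `"BPND"`, `"SUV"`.
#' @param ... Further provenance fields stored as attributes (e.g.
#'   `n_fitted`, `n_failed`, `reference_region`).
#' @return A `parametric_image` object.
#' @export
parametric_image <- function(data, mask, outcome, ...) {
  if (!identical(dim(data), dim(mask))) {
    abort("`data` and `mask` must have identical dimensions.")
  }
  structure(data,
    mask = array(as.logical(mask), dim(mask)),
    outcome = outcome,
    provenance = list(...),
    class = "parametric_image"
  )
}

#' @export
print.parametric_image <- function(x, ...) {
  m <- attr(x, "mask")
  vals <- x[m & is.finite(x)]
  cat(sprintf(
    "<parametric_image:%s> %s voxels, %d in mask (%d finite), range %.3g..%.3g\n",
    attr(x, "outcome"), paste(dim(x), collapse = "x"), sum(m),
    length(vals), min(vals), max(vals)
  ))
  invisible(x)
}

#' @export
as_tibble.parametric_image <- function(x, ...) {
  d <- dim(x)
  idx <- which(attr(x, "mask"))
  coords <- arrayInd(idx, d)
  tibble(
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    value = as.numeric(x)[idx]
  )
}

#' Write a parametric image (or any 3D/4D array) as NIfTI
#'
#' @param img A `parametric_image` or plain array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_mm Voxel size in mm (scalar or length 3).
#' @return `path`, invisibly.
#' @export
write_parametric_nifti <- function(img, path, voxel_mm = 4) {
  arr <- unclass(img)
  attributes(arr) <- list(dim = dim(img))
  voxel_mm <- rep_len(voxel_mm, 3)
  nii <- RNifti::asNifti(arr, pixdim = voxel_mm, datatype = "float")
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Read a NIfTI image as a plain array
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @return A numeric array.
#' @export
read_nifti_array <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  arr
}
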