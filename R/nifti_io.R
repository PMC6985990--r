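#' Write a label volume as NIfTI
#'
#' @param arr integer/logical 3D array.
#' @param spacing voxel spacing in mm.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_label_volume <- function(arr, spacing, path) {
  img <- RNifti::asNifti(array(as.integer(arr), dim(arr)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label volume from NIfTI
#'
#' @param path NIfTI file path.
#' @param dict optional label dictionary (default [head_labels()]).
#' @return list with `labels` (integer array), `spacing`, `dict`,
#'   as consumed by [compute_volumes()].
#' @export
read_label_volume <- function(path, dict = head_labels()) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  list(labels = array(as.integer(img), dim(img)[1:3]), spacing = sp,
       dict = dict)
}
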