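# NIfTI-1 input/output (via RNifti).
#
# Grid convention: the first array axis is the left-right axis; the world
# origin is placed at the grid centre so the midline plane sits at x = 0 mm.

nifti_image <- function(arr, voxel_size_mm, tr_s = NULL) {
    vs <- rep(voxel_size_mm, length.out = 3)
    pd <- if (length(dim(arr)) == 4L) c(vs, tr_s %||% 1) else vs
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- pd
    img
}

#' Write a 3-D volume or 4-D series as NIfTI-1
#' @param arr numeric array (3-D) or `bold_series` / 4-D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm voxel size in mm (ignored for `bold_series`).
#' @param tr_s repetition time stored in the 4th pixdim slot.
#' @export
write_volume <- function(arr, path, voxel_size_mm = 3, tr_s = NULL) {
    if (inherits(arr, "bold_series")) {
        voxel_size_mm <- arr$voxel_size_mm
        tr_s <- arr$tr_s
        arr <- arr$data
    }
    RNifti::writeNifti(nifti_image(arr, voxel_size_mm, tr_s), path)
    invisible(path)
}

#' Read a 3-D NIfTI volume as a plain array
#' @param path file path.
#' @export
read_volume <- function(path) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    attr(arr, "pixdim") <- RNifti::pixdim(img)
    arr
}

#' Read a 4-D NIfTI series as a [bold_series()]
#' @param path file path.
#' @param tr_s repetition time; defaults to the file's 4th pixdim slot.
#' @param subject_id optional identifier attached to the series.
#' @export
read_bold <- function(path, tr_s = NULL, subject_id = NULL) {
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)
    arr <- as.array(img)
    attributes(arr) <- list(dim = dim(arr))
    if (length(dim(arr)) != 4L) stopf("%s is not a 4-D series", path)
    bold_series(arr, voxel_size_mm = pd[1:3],
                tr_s = tr_s %||% (if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1),
                subject_id = subject_id)
}
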