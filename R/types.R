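# Core data containers.

#' Construct a BOLD series
#'
#' A 4-D voxel-by-time grid with its acquisition metadata. The first array
#' axis is taken to be the left-right axis (the convention used throughout
#' the package; [mirror_index()] operates along it).
#'
#' @param data 4-D numeric array (x, y, z, time).
#' @param voxel_size_mm voxel size in mm (scalar or length 3).
#' @param tr_s repetition time in seconds.
#' @param subject_id optional subject identifier.
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(data, voxel_size_mm, tr_s, subject_id = NULL) {
    if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
    if (length(dim(data)) != 4L) stopf("data must be a 4-D array")
    if (!all(is.finite(data))) stopf("BOLD data must be finite")
    vs <- rep(voxel_size_mm, length.out = 3)
    if (any(vs <= 0)) stopf("voxel sizes must be positive")
    if (!is_scalar_num(tr_s) || tr_s <= 0) stopf("tr_s must be positive")
    structure(list(data = data, voxel_size_mm = vs, tr_s = tr_s,
                   subject_id = subject_id),
              class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
    d <- dim(x$data)
    cat(sprintf("BOLD series%s: %dx%dx%d voxels at %s mm, %d volumes, TR %g s\n",
                if (is.null(x$subject_id)) "" else paste0(" [", x$subject_id, "]"),
                d[1], d[2], d[3], paste(x$voxel_size_mm, collapse = "x"),
                d[4], x$tr_s))
    invisible(x)
}

n_volumes <- function(series) dim(series$data)[4]

grid_dim <- function(series) dim(series$data)[1:3]

# Time-by-voxel matrix view of a bold_series (copies).
as_time_matrix <- function(series) {
    d <- dim(series$data)
    t(matrix(series$data, prod(d[1:3]), d[4]))
}

from_time_matrix <- function(mat, template) {
    d <- dim(template$data)
    arr <- array(t(mat), dim = c(d[1:3], nrow(mat)))
    out <- template
    out$data <- arr
    out
}

#' Construct a motion trace
#'
#' Per-volume rigid-body motion parameters: three translations in mm followed
#' by three rotations in radians (the SPM `rp_*.txt` column convention).
#'
#' @param mat numeric matrix with 6 columns.
#' @return A `motion_trace` (matrix with standard column names).
#' @export
motion_trace <- function(mat) {
    mat <- as.matrix(mat)
    if (ncol(mat) != 6L) stopf("motion trace must have 6 columns")
    if (!all(is.finite(mat))) stopf("motion parameters must be finite")
    colnames(mat) <- c("tx_mm", "ty_mm", "tz_mm", "rx_rad", "ry_rad", "rz_rad")
    class(mat) <- c("motion_trace", "matrix")
    mat
}

#' Read / write motion parameters in the 6-column text convention
#' @param path file path.
#' @return [read_motion()] returns a `motion_trace`.
#' @export
read_motion <- function(path) {
    motion_trace(as.matrix(read.table(path, header = FALSE)))
}

#' @rdname read_motion
#' @param motion a `motion_trace`.
#' @export
write_motion <- function(motion, path) {
    write.table(format(unclass(motion), digits = 10), path,
                row.names = FALSE, col.names = FALSE, quote = FALSE)
    invisible(path)
}
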