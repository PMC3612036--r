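# Voxel-mirrored homotopic connectivity.

#' Fisher z-transform of a correlation
#'
#' `z = atanh(r)` with `r` clipped to `[-1 + 1e-7, 1 - 1e-7]` so degenerate
#' correlations stay finite. Odd and strictly increasing.
#'
#' @param r correlation(s) in `[-1, 1]`.
#' @export
fisher_z <- function(r) {
    if (any(abs(r) > 1, na.rm = TRUE)) stopf("correlations must lie in [-1, 1]")
    atanh(clamp(r, -1 + 1e-7, 1 - 1e-7))
}

#' Compute a subject's VMHC map
#'
#' For every voxel of the unilateral gray-matter mask, the Pearson
#' correlation between the voxel's residual time series and that of its
#' mirrored interhemispheric counterpart, Fisher z-transformed. The value is
#' computed once per homotopic pair and copied to the mirror voxel, so the
#' map is mirror-symmetric bit-exactly; midline voxels (their own mirrors)
#' are excluded. Zero-variance series yield a missing voxel with a warning.
#'
#' @param residual a preprocessed [bold_series()] on the symmetric grid, with
#'   at least 4 time points.
#' @param space a [build_symmetric_space()] result on the same grid.
#' @return An object of class `vmhc_map`: `z` (3-D array, `NA` outside the
#'   mask), `subject_id`.
#' @export
compute_vmhc <- function(residual, space) {
    if (!identical(grid_dim(residual), as.integer(space$dim)) &&
        !identical(as.integer(grid_dim(residual)), as.integer(space$dim)))
        stopf("series grid does not match the symmetric space")
    if (n_volumes(residual) < 4L) stopf("need at least 4 time points")
    pairs <- unilateral_pairs(space)
    mat <- as_time_matrix(residual)
    L <- mat[, pairs$left, drop = FALSE]
    R <- mat[, pairs$right, drop = FALSE]
    L <- sweep(L, 2, colMeans(L))
    R <- sweep(R, 2, colMeans(R))
    ss_l <- colSums(L^2)
    ss_r <- colSums(R^2)
    bad <- ss_l == 0 | ss_r == 0
    r <- rep(NA_real_, length(ss_l))
    r[!bad] <- colSums(L[, !bad, drop = FALSE] * R[, !bad, drop = FALSE]) /
        sqrt(ss_l[!bad] * ss_r[!bad])
    r[!bad] <- clamp(r[!bad], -1, 1)  # guard rounding at |r| ~ 1
    if (any(bad))
        warnf("%d zero-variance voxel pair(s) set to missing", sum(bad))
    z <- fisher_z_allow_na(r)
    zmap <- array(NA_real_, space$dim)
    zmap[pairs$left] <- z
    zmap[pairs$right] <- z
    structure(list(z = zmap, subject_id = residual$subject_id),
              class = "vmhc_map")
}

fisher_z_allow_na <- function(r) {
    out <- rep(NA_real_, length(r))
    ok <- !is.na(r)
    out[ok] <- fisher_z(r[ok])
    out
}

#' Stack per-subject VMHC maps for group analysis
#'
#' Aligns the maps with the metadata rows, drops subjects excluded by the FD
#' rule, and applies the complete-case policy: voxels missing in any retained
#' subject are dropped from the analysis mask.
#'
#' @param maps list of [compute_vmhc()] results, one per row of `records`.
#' @param records subject metadata table (must contain `id`; `excluded` is
#'   honoured when present).
#' @param space the shared `symmetric_space`.
#' @return An object of class `vmhc_stack`: `z` (subjects x voxels matrix),
#'   `voxels` (linear indices into the unilateral mask), `records`, `space`.
#' @export
cohort_vmhc <- function(maps, records, space) {
    if (!length(maps)) stopf("empty cohort")
    if (length(maps) != nrow(records))
        stopf("%d maps for %d metadata rows", length(maps), nrow(records))
    keep <- if ("excluded" %in% names(records)) !records$excluded else
        rep(TRUE, nrow(records))
    if (!any(keep)) stopf("all subjects excluded")
    maps <- maps[keep]
    records <- records[keep, , drop = FALSE]
    pairs <- unilateral_pairs(space)
    z <- t(vapply(maps, function(m) {
        if (!identical(dim(m$z), as.integer(space$dim)))
            stopf("VMHC map grid mismatch for subject %s", m$subject_id %||% "?")
        m$z[pairs$left]
    }, numeric(length(pairs$left))))
    complete <- colSums(is.na(z)) == 0L
    structure(list(z = z[, complete, drop = FALSE],
                   voxels = pairs$left[complete],
                   records = records, space = space),
              class = "vmhc_stack")
}

#' @export
print.vmhc_stack <- function(x, ...) {
    cat(sprintf("VMHC stack: %d subjects x %d unilateral voxels\n",
                nrow(x$z), ncol(x$z)))
    invisible(x)
}
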