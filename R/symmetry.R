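# Symmetric template, masks, and the mirror-index map.

#' Mirror a voxel index across the midline plane
#'
#' The first array axis is the left-right axis; with an odd extent `nx` the
#' midline column `(nx + 1) / 2` maps to itself and `i` maps to `nx + 1 - i`
#' (1-based indices). The map is an involution.
#'
#' @param i integer voxel index (vectorized).
#' @param nx x-axis extent (must be odd).
#' @return The mirrored index.
#' @export
mirror_index <- function(i, nx) {
    if (nx %% 2 == 0)
        stopf("symmetric grids must have an odd x dimension, got %d", nx)
    if (any(i < 1 | i > nx)) stopf("index out of range 1..%d", nx)
    nx + 1L - as.integer(i)
}

#' Left-right mirror of a volume
#' @param volume 3-D array with odd x extent.
#' @export
mirror_volume <- function(volume) {
    nx <- dim(volume)[1]
    if (nx %% 2 == 0)
        stopf("symmetric grids must have an odd x dimension, got %d", nx)
    volume[nx:1, , , drop = FALSE]
}

#' Symmetrize a volume about the midline plane
#'
#' Averages the volume with its left-right mirror:
#' `out(i,j,k) = (in(i,j,k) + in(mirror(i),j,k)) / 2`. The operation is a
#' linear, idempotent projection onto mirror-symmetric volumes.
#'
#' @param volume 3-D array with odd x extent.
#' @export
symmetrize <- function(volume) {
    (volume + mirror_volume(volume)) / 2
}

#' Build the symmetric analysis space
#'
#' Averages the subjects' gray-matter probability maps, symmetrizes the mean
#' to obtain the study-specific symmetric template, thresholds it into the
#' gray-matter analysis mask, and derives the unilateral (left-hemisphere,
#' midline excluded) mask on which each homotopic pair contributes exactly
#' one statistic.
#'
#' @param gm_maps list of 3-D gray-matter probability maps on a common grid.
#' @param gm_threshold probability threshold defining the analysis mask.
#' @param voxel_size_mm voxel size in mm.
#' @return An object of class `symmetric_space` with fields `template`,
#'   `brain_mask`, `gm_mask`, `unilateral_mask`, `midline`, `dim`,
#'   `voxel_size_mm`.
#' @export
build_symmetric_space <- function(gm_maps, gm_threshold = 0.2,
                                  voxel_size_mm = 3) {
    if (!length(gm_maps)) stopf("at least one gray-matter map is required")
    dims <- lapply(gm_maps, dim)
    if (!all(vapply(dims, identical, logical(1), dims[[1]])))
        stopf("gray-matter maps are on inconsistent grids")
    dim3 <- dims[[1]]
    mean_map <- Reduce(`+`, lapply(gm_maps, function(m) array(as.numeric(m), dim3))) /
        length(gm_maps)
    template <- symmetrize(mean_map)
    gm_mask <- template > gm_threshold
    if (!any(gm_mask))
        stopf("gray-matter mask is empty at threshold %g (template max %g)",
              gm_threshold, max(template))
    mid <- (dim3[1] + 1L) %/% 2L
    unilateral <- gm_mask
    unilateral[mid:dim3[1], , ] <- FALSE
    space <- structure(list(template = template,
                            brain_mask = template > 0,
                            gm_mask = gm_mask,
                            unilateral_mask = unilateral,
                            midline = mid,
                            dim = dim3,
                            voxel_size_mm = rep(voxel_size_mm, length.out = 3)),
                       class = "symmetric_space")
    assert_symmetric_space(space)
    space
}

# Post-construction invariants of a symmetric space.
assert_symmetric_space <- function(space) {
    stopifnot(identical(space$template, symmetrize(space$template)),
              identical(space$gm_mask, space$gm_mask & mirror_volume(space$gm_mask)))
    mirrored <- mirror_volume(space$unilateral_mask)
    if (any(space$unilateral_mask & mirrored))
        stopf("unilateral mask overlaps its own mirror")
    midplane <- space$gm_mask
    midplane[-space$midline, , ] <- FALSE
    full <- space$unilateral_mask | mirrored | midplane
    if (!identical(full, space$gm_mask))
        stopf("unilateral mask, its mirror and the midline do not tile the gm mask")
    invisible(space)
}

#' @export
print.symmetric_space <- function(x, ...) {
    cat(sprintf("Symmetric space: %s voxels at %s mm\n",
                paste(x$dim, collapse = "x"),
                paste(x$voxel_size_mm, collapse = "x")))
    cat(sprintf("  gm mask %d voxels; unilateral %d voxels (midline column %d)\n",
                sum(x$gm_mask), sum(x$unilateral_mask), x$midline))
    invisible(x)
}

# Linear indices of the unilateral-mask voxels and of their mirrors.
unilateral_pairs <- function(space) {
    idx <- which(space$unilateral_mask)
    ijk <- index_to_ijk(idx, space$dim)
    mirrored <- mirror_index(ijk[, 1], space$dim[1]) +
        space$dim[1] * (ijk[, 2] - 1L) +
        space$dim[1] * space$dim[2] * (ijk[, 3] - 1L)
    list(left = idx, right = as.integer(mirrored))
}
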