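# Monte-Carlo cluster-extent correction (AlphaSim-style) and cluster tables.

#' Label connected components of a binary 3-D map
#'
#' Components under a 6 (faces), 18 (faces + edges) or 26 (full neighbour)
#' connectivity. Labels are assigned deterministically in order of each
#' component's first voxel in column-major scan order.
#'
#' @param binary_map logical (or 0/1) 3-D array.
#' @param connectivity 6, 18 or 26.
#' @return A list: `labels` (integer 3-D array, 0 = background), `sizes`
#'   (voxel count per label).
#' @export
label_clusters <- function(binary_map, connectivity = 6L) {
    if (!connectivity %in% c(6L, 18L, 26L))
        stopf("connectivity must be 6, 18 or 26")
    dim3 <- dim(binary_map)
    if (length(dim3) != 3L) stopf("binary_map must be 3-D")
    mask <- as.logical(binary_map)
    mask[is.na(mask)] <- FALSE
    labels <- .cpp_label_components(mask, as.integer(dim3),
                                    as.integer(connectivity))
    n <- max(labels)
    list(labels = labels,
         sizes = if (n > 0) tabulate(labels[labels > 0], n) else integer(0))
}

#' Monte-Carlo null distribution of the maximum cluster size
#'
#' Per iteration: the bounding box of the mask is filled with unit Gaussian
#' noise, smoothed at the stated FWHM, restricted to the mask and
#' re-standardized to unit variance within the mask (smoothing deflates
#' variance and the per-voxel p must stay nominal), then thresholded
#' two-tailed at `voxel_p`; the maximum cluster size over both signs
#' (positive and negative clusters never merged) is recorded.
#'
#' @param mask logical 3-D array (typically the unilateral gray-matter mask).
#' @param voxel_p per-voxel two-tailed p threshold.
#' @param fwhm_mm smoothness of the simulated fields, in mm.
#' @param voxel_size_mm voxel size in mm.
#' @param n_iterations number of iterations (>= 100).
#' @param connectivity cluster neighbourhood.
#' @param seed integer seed; the same seed reproduces the distribution.
#' @return Sorted integer vector of per-iteration maximum cluster sizes, with
#'   the simulation parameters attached as the `"spec"` attribute.
#' @export
simulate_cluster_null <- function(mask, voxel_p = 0.01, fwhm_mm = 6,
                                  voxel_size_mm = 3, n_iterations = 1000L,
                                  connectivity = 6L, seed = 1L) {
    dim3_in <- dim(mask)
    if (is.null(dim3_in) || length(dim3_in) != 3L)
        stopf("mask must be a 3-D array")
    mask <- as.logical(mask)
    mask[is.na(mask)] <- FALSE
    dim(mask) <- dim3_in
    if (!any(mask)) stopf("mask is empty")
    if (n_iterations < 100L) stopf("at least 100 iterations are required")
    dim3 <- dim(mask)
    ijk <- index_to_ijk(which(mask), dim3)
    lo <- apply(ijk, 2, min); hi <- apply(ijk, 2, max)
    box_dim <- hi - lo + 1L
    sub_mask <- array(FALSE, box_dim)
    sub_mask[cbind(ijk[, 1] - lo[1] + 1L, ijk[, 2] - lo[2] + 1L,
                   ijk[, 3] - lo[3] + 1L)] <- TRUE
    sigma <- fwhm_to_sigma(fwhm_mm, rep(voxel_size_mm, length.out = 3))
    zcrit <- qnorm(1 - voxel_p / 2)
    set.seed(seed)
    max_sizes <- integer(n_iterations)
    n_box <- prod(box_dim)
    for (it in seq_len(n_iterations)) {
        field <- array(rnorm(n_box), box_dim)
        if (fwhm_mm > 0)
            field <- .cpp_smooth_gaussian(field, box_dim, sigma)
        vals <- field[sub_mask]
        vals <- (vals - mean(vals)) / stats::sd(vals)
        z <- array(0, box_dim)
        z[sub_mask] <- vals
        best <- 0L
        for (sgn in c(1, -1)) {
            supra <- (sgn * z) > zcrit & sub_mask
            if (any(supra)) {
                cl <- label_clusters(supra, connectivity)
                best <- max(best, max(cl$sizes))
            }
        }
        max_sizes[it] <- best
    }
    structure(sort(max_sizes),
              spec = list(voxel_p = voxel_p, fwhm_mm = fwhm_mm,
                          voxel_size_mm = voxel_size_mm,
                          n_iterations = n_iterations,
                          connectivity = connectivity, seed = seed,
                          mask_voxels = sum(mask)))
}

#' Minimum significant cluster size from a null distribution
#'
#' The smallest integer `k` such that the fraction of null iterations whose
#' maximum cluster size reaches `k` is at most `alpha`.
#'
#' @param null_distribution output of [simulate_cluster_null()].
#' @param alpha corrected family-wise level in (0, 1).
#' @return A list: `k_voxels` and, when the null carries its spec,
#'   `size_mm3`.
#' @export
cluster_size_threshold <- function(null_distribution, alpha = 0.05) {
    if (alpha <= 0 || alpha > 1) stopf("alpha must lie in (0, 1]")
    if (!length(null_distribution)) stopf("empty null distribution")
    n <- length(null_distribution)
    for (k in seq_len(max(null_distribution) + 1L)) {
        if (sum(null_distribution >= k) / n <= alpha) break
    }
    spec <- attr(null_distribution, "spec")
    out <- list(k_voxels = as.integer(k))
    if (!is.null(spec))
        out$size_mm3 <- k * prod(rep(spec$voxel_size_mm, length.out = 3))
    out
}

#' Apply cluster-extent correction to a statistic map
#'
#' Thresholds `|Z|` at the two-tailed `voxel_p` quantile within the
#' unilateral mask, labels sign-separated clusters, drops clusters below the
#' minimum size, and reports each surviving cluster's size (voxels and mm^3),
#' signed peak Z and peak world (MNI-style) coordinate, with the midline
#' plane at x = 0.
#'
#' @param stat_result a [glm_ttest_map()] / [clinical_corr_map()] result.
#' @param voxel_p per-voxel two-tailed p threshold.
#' @param min_size_voxels minimum cluster extent in voxels.
#' @param space the `symmetric_space` (for the mask and geometry).
#' @param connectivity cluster neighbourhood.
#' @return A data frame with columns `label`, `sign`, `size_voxels`,
#'   `size_mm3`, `peak_z`, `peak_x_mm`, `peak_y_mm`, `peak_z_mm` (empty when
#'   nothing survives).
#' @export
apply_cluster_correction <- function(stat_result, voxel_p = 0.01,
                                     min_size_voxels = 1L,
                                     space = stat_result$space,
                                     connectivity = 6L) {
    if (!identical(as.integer(dim(stat_result$z_map)), as.integer(space$dim)))
        stopf("statistic map and mask are on different grids")
    zcrit <- qnorm(1 - voxel_p / 2)
    zmap <- stat_result$z_map
    mask <- space$unilateral_mask & !is.na(zmap)
    rows <- list()
    label_counter <- 0L
    for (sgn in c(1, -1)) {
        supra <- array(FALSE, space$dim)
        supra[mask] <- sgn * zmap[mask] > zcrit
        if (!any(supra)) next
        cl <- label_clusters(supra, connectivity)
        for (lab in seq_along(cl$sizes)) {
            if (cl$sizes[lab] < min_size_voxels) next
            vox <- which(cl$labels == lab)
            zv <- zmap[vox]
            peak <- vox[which.max(abs(zv))]
            pijk <- index_to_ijk(peak, space$dim)
            world <- voxel_to_world(pijk, space$dim, space$voxel_size_mm)
            label_counter <- label_counter + 1L
            rows[[length(rows) + 1L]] <- data.frame(
                label = label_counter,
                sign = if (sgn > 0) "positive" else "negative",
                size_voxels = cl$sizes[lab],
                size_mm3 = cl$sizes[lab] * prod(space$voxel_size_mm),
                peak_z = zmap[peak],
                peak_x_mm = world[1], peak_y_mm = world[2],
                peak_z_mm = world[3],
                stringsAsFactors = FALSE)
        }
    }
    if (!length(rows))
        return(data.frame(label = integer(0), sign = character(0),
                          size_voxels = integer(0), size_mm3 = numeric(0),
                          peak_z = numeric(0), peak_x_mm = numeric(0),
                          peak_y_mm = numeric(0), peak_z_mm = numeric(0),
                          stringsAsFactors = FALSE))
    do.call(rbind, rows)
}

#' Binary mask of one corrected cluster
#'
#' Rebuilds the voxel set of a row of [apply_cluster_correction()] output.
#' @inheritParams apply_cluster_correction
#' @param row one row of the cluster table.
#' @return Logical 3-D array (unilateral).
#' @export
cluster_mask <- function(stat_result, row, voxel_p = 0.01,
                         space = stat_result$space, connectivity = 6L) {
    zcrit <- qnorm(1 - voxel_p / 2)
    sgn <- if (row$sign == "positive") 1 else -1
    zmap <- stat_result$z_map
    mask <- space$unilateral_mask & !is.na(zmap)
    supra <- array(FALSE, space$dim)
    supra[mask] <- sgn * zmap[mask] > zcrit
    cl <- label_clusters(supra, connectivity)
    peak_ijk <- round(rbind(c(row$peak_x_mm, row$peak_y_mm, row$peak_z_mm)) /
                          rep(space$voxel_size_mm, length.out = 3) +
                          (space$dim + 1) / 2)
    lab <- cl$labels[peak_ijk[1], peak_ijk[2], peak_ijk[3]]
    cl$labels == lab & lab > 0
}
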