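# Gray-matter ROI confound check for clusters with VMHC differences.

#' Mean gray-matter value within cluster masks, per subject
#'
#' @param gm_maps list of 3-D gray-matter maps (one per subject).
#' @param cluster_masks list of logical 3-D masks on the same grid.
#' @return Numeric matrix, subjects x clusters.
#' @export
roi_means <- function(gm_maps, cluster_masks) {
    if (!length(cluster_masks)) stopf("no cluster masks supplied")
    for (m in cluster_masks) if (!any(m)) stopf("empty cluster mask")
    out <- sapply(cluster_masks, function(mask)
        vapply(gm_maps, function(g) mean(g[mask]), numeric(1)))
    out <- matrix(out, nrow = length(gm_maps))
    colnames(out) <- names(cluster_masks) %||%
        paste0("cluster", seq_along(cluster_masks))
    out
}

#' Group comparison of ROI gray-matter means
#'
#' Covariate-adjusted (age, gender) group t-test per cluster, with Bonferroni
#' adjustment over the number of clusters; used to rule out structural
#' (gray-matter volume) confounds behind VMHC group differences.
#'
#' @param means subjects x clusters matrix from [roi_means()].
#' @param records metadata table aligned with the rows of `means` (needs
#'   `group`, `age`, `gender`).
#' @param covariates covariate names (subset of `c("age", "gender")`),
#'   or `character(0)` for a plain two-sample comparison.
#' @return A data frame: `cluster`, `mean_patient`, `mean_control`, `t`,
#'   `df`, `p`, `p_bonferroni`.
#' @export
roi_group_test <- function(means, records, covariates = c("age", "gender")) {
    groups <- records$group
    if (min(table(groups)) < 2L) stopf("each group needs at least 2 subjects")
    g <- as.numeric(groups == "patient")
    X <- cbind(intercept = 1, group = g)
    if (length(covariates))
        X <- cbind(X, covariate_matrix(records)[, covariates, drop = FALSE])
    fit <- fit_tmap(as.matrix(means), X, coef = "group")
    p <- 2 * pt(abs(fit$t), fit$df, lower.tail = FALSE)
    data.frame(cluster = colnames(means) %||% paste0("cluster", seq_along(p)),
               mean_patient = colMeans(means[g == 1, , drop = FALSE]),
               mean_control = colMeans(means[g == 0, , drop = FALSE]),
               t = fit$t, df = fit$df, p = p,
               p_bonferroni = bonferroni(p, ncol(means)),
               row.names = NULL, stringsAsFactors = FALSE)
}
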