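# Voxel-wise covariate-adjusted statistics and the demographic-table tests.

# Common least-squares machinery: t statistic of one design column fitted to
# many response columns at once.
fit_tmap <- function(Y, X, coef) {
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
        bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
        stopf("design is rank deficient; collinear column(s): %s",
              paste(bad, collapse = ", "))
    }
    ci <- if (is.character(coef)) match(coef, colnames(X)) else coef
    beta <- qr.coef(qrX, Y)
    res <- Y - X %*% beta
    df <- nrow(X) - ncol(X)
    if (df < 1L) stopf("no residual degrees of freedom")
    sigma2 <- colSums(res^2) / df
    xtx_inv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(pmax(sigma2 * xtx_inv[ci, ci], 0))
    t <- ifelse(se > 0, beta[ci, ] / se, 0)
    list(t = t, df = df, beta = beta[ci, ], se = se)
}

# Build the covariate part of a design (mean-centred; affects only the
# intercept).
covariate_matrix <- function(records, use_fd = FALSE) {
    X <- cbind(age = records$age,
               gender = as.numeric(records$gender == "male"))
    if (use_fd) X <- cbind(X, mean_fd = records$mean_fd)
    sweep(X, 2, colMeans(X))
}

#' Voxel-wise covariate-adjusted two-sample t map
#'
#' Fits, at every voxel of the stack, VMHC on
#' `[intercept, group, age, gender, mean FD]` by ordinary least squares; the
#' reported t is the group coefficient over its standard error (two-tailed
#' convention, positive = patients above controls). The t map is also
#' converted to a Z map via [t_to_z()].
#'
#' @param stack a [cohort_vmhc()] stack.
#' @param covariates character subset of `c("age", "gender", "mean_fd")`;
#'   defaults to all three (the group analysis of the pipeline).
#' @return An object of class `stat_result` with `t_map`, `z_map` (3-D arrays
#'   on the unilateral mask), `df`, `kind = "group_t"`.
#' @export
glm_ttest_map <- function(stack, covariates = c("age", "gender", "mean_fd")) {
    rec <- stack$records
    groups <- rec$group
    if (length(unique(groups)) != 2L) stopf("exactly two groups are required")
    if (min(table(groups)) < 2L) stopf("each group needs at least 2 subjects")
    g <- as.numeric(groups == "patient")
    X <- cbind(intercept = 1, group = g)
    if ("age" %in% covariates || "gender" %in% covariates || "mean_fd" %in% covariates) {
        cm <- covariate_matrix(rec, use_fd = "mean_fd" %in% covariates)
        keep <- intersect(c("age", "gender", "mean_fd"), covariates)
        X <- cbind(X, cm[, intersect(colnames(cm), keep), drop = FALSE])
    }
    fit <- fit_tmap(stack$z, X, coef = "group")
    as_stat_result(fit$t, fit$df, stack, kind = "group_t")
}

#' Voxel-wise clinical (partial) correlation map
#'
#' Residualizes both the VMHC values and the clinical score on
#' `[intercept, covariates]` and correlates the residuals at every voxel.
#' Significance via `t = r sqrt(df / (1 - r^2))`, `df = n - 2 - n_covariates`;
#' the t values are converted to Z via [t_to_z()]. With no covariates this
#' reduces to the plain Pearson correlation.
#'
#' @param stack a [cohort_vmhc()] stack restricted to the patient group.
#' @param score numeric clinical score per subject (or the name of a column
#'   of the stack's records).
#' @param covariates character subset of `c("age", "gender", "mean_fd")`.
#' @return A `stat_result` with `r_map`, `z_map`, `df`, `kind = "clinical_r"`.
#' @export
clinical_corr_map <- function(stack, score, covariates = c("age", "gender")) {
    rec <- stack$records
    if (is.character(score) && length(score) == 1L) score <- rec[[score]]
    n <- nrow(stack$z)
    if (length(score) != n) stopf("score length does not match the stack")
    if (n < 4L) stopf("need at least 4 subjects")
    X <- cbind(intercept = rep(1, n))
    if (length(covariates)) {
        cm <- covariate_matrix(rec, use_fd = "mean_fd" %in% covariates)
        X <- cbind(X, cm[, intersect(colnames(cm),
                                     intersect(c("age", "gender", "mean_fd"),
                                               covariates)), drop = FALSE])
    }
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) stopf("covariates are collinear")
    s_res <- qr.resid(qrX, score)
    if (sum(s_res^2) < 1e-12 * max(1, sum(score^2)))
        stopf("score has no residual variance after covariate adjustment")
    Y_res <- qr.resid(qrX, stack$z)
    s_res <- s_res / sqrt(sum(s_res^2))
    ss <- colSums(Y_res^2)
    r <- ifelse(ss > 0, colSums(Y_res * s_res) / sqrt(ss), 0)
    r <- clamp(r, -1, 1)
    df <- n - 2L - (ncol(X) - 1L)
    if (df < 1L) stopf("no degrees of freedom for the correlation test")
    t <- r * sqrt(df / pmax(1 - r^2, 1e-12))
    out <- as_stat_result(t, df, stack, kind = "clinical_r")
    rmap <- array(NA_real_, stack$space$dim)
    rmap[stack$voxels] <- r
    out$r_map <- rmap
    out
}

as_stat_result <- function(t, df, stack, kind) {
    tmap <- array(NA_real_, stack$space$dim)
    tmap[stack$voxels] <- t
    zmap <- array(NA_real_, stack$space$dim)
    zmap[stack$voxels] <- t_to_z(t, df)
    structure(list(t_map = tmap, z_map = zmap, df = df, kind = kind,
                   voxels = stack$voxels, space = stack$space),
              class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
    v <- x$z_map[x$voxels]
    cat(sprintf("Voxel-wise %s map: %d voxels, df = %d, Z range [%.3f, %.3f]\n",
                x$kind, length(v), x$df, min(v), max(v)))
    invisible(x)
}

#' Convert a t statistic to a standard-normal Z score
#'
#' `Z = sign(t) * qnorm(1 - p_one_tailed(|t|, df))`, evaluated in log space
#' so large statistics stay finite and the map is strictly monotone in t.
#'
#' @param t statistic(s).
#' @param df residual degrees of freedom (`>= 1`).
#' @export
t_to_z <- function(t, df) {
    if (any(df < 1)) stopf("df must be at least 1")
    log_p <- pt(abs(t), df, lower.tail = FALSE, log.p = TRUE)
    sign(t) * qnorm(log_p, lower.tail = FALSE, log.p = TRUE)
}

#' Pooled two-sample t-test from summary statistics
#'
#' Student's t with pooled variance, `df = n1 + n2 - 2`, two-tailed p value;
#' reproduces the demographics-table comparisons computed from printed
#' means and standard deviations.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries.
#' @return A list: `t`, `df`, `p`.
#' @export
summary_ttest <- function(mean1, sd1, n1, mean2, sd2, n2) {
    if (n1 < 2 || n2 < 2) stopf("both groups need n >= 2")
    if (sd1 < 0 || sd2 < 0 || (sd1 == 0 && sd2 == 0))
        stopf("invalid standard deviations")
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    list(t = t, df = df, p = 2 * pt(abs(t), df, lower.tail = FALSE))
}

#' Pearson chi-squared test for a 2x2 table (no continuity correction)
#'
#' `chi2 = N (ad - bc)^2 / (r1 r2 c1 c2)` on counts `a, b / c, d`, df = 1.
#'
#' @param a,b,c,d cell counts (rows = groups).
#' @return A list: `chi2`, `df`, `p`.
#' @export
chi2_2x2 <- function(a, b, c, d) {
    counts <- c(a, b, c, d)
    if (any(counts < 0)) stopf("counts must be nonnegative")
    n <- sum(counts)
    r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
    if (any(c(r1, r2, c1, c2) == 0)) stopf("all table margins must be positive")
    chi2 <- n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2)
    list(chi2 = chi2, df = 1L, p = pchisq(chi2, 1, lower.tail = FALSE))
}

#' Bonferroni adjustment
#' @param p p value(s) in `[0, 1]`.
#' @param m number of tests.
#' @export
bonferroni <- function(p, m) {
    if (any(p < 0 | p > 1)) stopf("p values must lie in [0, 1]")
    if (m < 1) stopf("m must be at least 1")
    pmin(1, m * p)
}
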