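# Calibration and validation studies: parameter recovery, family-wise error
# calibration, and end-to-end effect/null recovery under the study
# conditions. These run the same pipeline code as any analysis; they exist
# so the package's statistical guarantees are recomputable on demand.

#' Ground-truth regions for the parameter-recovery study
#'
#' Five disjoint 7x9x9-voxel boxes inside the left gray-matter shell of a
#' 41x49x41 grid, carrying homotopic correlations 0, 0.2, 0.4, 0.6 and 0.8
#' (identical in both groups).
#' @export
recovery_regions <- function() {
    rho <- c(0, 0.2, 0.4, 0.6, 0.8)
    boxes <- list(list(x = c(10L, 16L), y = c(11L, 19L), z = c(17L, 25L)),
                  list(x = c(10L, 16L), y = c(21L, 29L), z = c(17L, 25L)),
                  list(x = c(10L, 16L), y = c(31L, 39L), z = c(17L, 25L)),
                  list(x = c(10L, 16L), y = c(21L, 29L), z = c(8L, 16L)),
                  list(x = c(10L, 16L), y = c(21L, 29L), z = c(26L, 34L)))
    Map(function(b, r) list(box = b, rho_patient = r, rho_control = r),
        boxes, rho)
}

erode_box <- function(box, by = 2L) {
    lapply(box, function(rng) c(rng[1] + by, rng[2] - by))
}

box_indices <- function(box, dim3) {
    arr <- array(FALSE, dim3)
    arr[box$x[1]:box$x[2], box$y[1]:box$y[2], box$z[1]:box$z[2]] <- TRUE
    which(arr)
}

# Mean of a VMHC map over a box interior (eroded so the smoothing kernel
# cannot mix across the region boundary).
region_mean_z <- function(zmap, box, erode = 2L) {
    b <- erode_box(box, erode)
    mean(zmap[b$x[1]:b$x[2], b$y[1]:b$y[2], b$z[1]:b$z[2]], na.rm = TRUE)
}

#' VMHC parameter-recovery study
#'
#' Generates a cohort whose mirrored-pair correlations are known exactly in
#' five regions (rho = 0, 0.2, 0.4, 0.6, 0.8), runs the full preprocessing
#' and VMHC chain, and regresses the recovered region-mean Fisher z on
#' `atanh(rho)`. Region means are taken over box interiors eroded by 2
#' voxels. An unbiased pipeline gives slope 1; the rho = 0 region doubles as
#' a bias check, with its theoretical standard error computed from the
#' band-pass temporal degrees of freedom (2 bins per retained frequency) and
#' a conservative one-resel-per-smoothing-kernel count of independent
#' voxels.
#'
#' @param seed integer seed.
#' @param n_subjects cohort size.
#' @param n_volumes acquired volumes (10 are discarded).
#' @return A list: `measurements` (subject x region data frame), `slope`,
#'   `intercept`, `zero_rho_mean_z`, `zero_rho_se`, `config`.
#' @export
vmhc_recovery_study <- function(seed = 1L, n_subjects = 10L,
                                n_volumes = 210L) {
    regions <- recovery_regions()
    cfg <- sim_config(grid_shape = c(41L, 49L, 41L), n_volumes = n_volumes,
                      n_per_group = n_subjects %/% 2L, baseline_rho = 0.45,
                      effect_regions = regions, clinical_model = list(),
                      seed = seed)
    params <- pipeline_config(sim = cfg, seed = seed)
    records <- generate_demographics(cfg)
    gm_maps <- lapply(seq_len(nrow(records)), function(i)
        make_tissue_maps(cfg, subject_seed(cfg, i))$gm)
    space <- build_symmetric_space(gm_maps, params$gm_threshold,
                                   cfg$voxel_size_mm)
    rows <- list()
    for (i in seq_len(nrow(records))) {
        sub <- generate_subject(cfg, records[i, ], subject_seed(cfg, i))
        pp <- preprocess_subject(sub, params)
        vm <- compute_vmhc(pp$residual, space)
        for (r in seq_along(regions)) {
            rows[[length(rows) + 1L]] <- data.frame(
                subject = records$id[i], region = r,
                rho = regions[[r]]$rho_control,
                mean_z = region_mean_z(vm$z, regions[[r]]$box))
        }
    }
    meas <- do.call(rbind, rows)
    fit <- stats::lm(mean_z ~ atanh(rho), data = meas)
    zero <- meas$mean_z[meas$rho == 0]
    n_bins <- length(passband_bins(n_volumes - cfg$n_discard, cfg$tr_s))
    z_sd <- 1 / sqrt(2 * n_bins - 3)
    b0 <- erode_box(regions[[1]]$box, 2L)
    n_interior <- prod(vapply(b0, function(r) r[2] - r[1] + 1, numeric(1)))
    resel <- prod(fwhm_to_sigma(params$fwhm_mm, rep(cfg$voxel_size_mm, 3)) *
                      2 * sqrt(2 * log(2)))
    zero_se <- z_sd / sqrt(length(zero) * n_interior / max(resel, 1))
    list(measurements = meas,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         zero_rho_mean_z = mean(zero),
         zero_rho_se = zero_se,
         config = cfg)
}

#' Family-wise error calibration of the Monte-Carlo cluster threshold
#'
#' Derives the minimum cluster size from one set of null simulations and
#' measures, on an independent set, how often a fresh smoothed Gaussian null
#' field produces a surviving cluster. With correct calibration the
#' family-wise positive rate matches `alpha` up to binomial error (the
#' integer cluster-size threshold makes it conservative).
#'
#' @param seed integer seed.
#' @param mask logical 3-D array; default a 20^3 box.
#' @param voxel_p,fwhm_mm,alpha,connectivity simulation settings.
#' @param n_calibration,n_validation iteration counts.
#' @return A list: `k_voxels`, `fp_rate`, `ci` (95% binomial interval around
#'   `alpha`), `alpha`.
#' @export
fwe_calibration_study <- function(seed = 1L, mask = array(TRUE, c(20, 20, 20)),
                                  voxel_p = 0.01, fwhm_mm = 6,
                                  alpha = 0.05, connectivity = 6L,
                                  n_calibration = 1000L,
                                  n_validation = 1000L) {
    null_cal <- simulate_cluster_null(mask, voxel_p = voxel_p,
                                      fwhm_mm = fwhm_mm,
                                      n_iterations = n_calibration,
                                      connectivity = connectivity,
                                      seed = derive_seed(seed, 1L))
    k <- cluster_size_threshold(null_cal, alpha)$k_voxels
    null_val <- simulate_cluster_null(mask, voxel_p = voxel_p,
                                      fwhm_mm = fwhm_mm,
                                      n_iterations = n_validation,
                                      connectivity = connectivity,
                                      seed = derive_seed(seed, 2L))
    fp <- mean(null_val >= k)
    half <- qnorm(0.975) * sqrt(alpha * (1 - alpha) / n_validation)
    list(k_voxels = k, fp_rate = fp, ci = c(alpha - half, alpha + half),
         alpha = alpha)
}

#' End-to-end effect-recovery study
#'
#' Runs the complete study under the default conditions (17 patients, 17
#' controls, homotopic correlation dropping from 0.6 to 0.3 in one
#' left-hemisphere region) and reports whether a corrected negative cluster
#' overlaps the true region, together with the group difference in regional
#' mean VMHC (analytic target `atanh(0.6) - atanh(0.3) = 0.3836`).
#'
#' @param seed integer seed.
#' @param n_iterations Monte-Carlo iterations for the cluster threshold.
#' @return A list: `study` (the `vmhc_study`), `detected`,
#'   `overlap_voxels`, `z_diff`, `z_diff_target`.
#' @export
effect_recovery_study <- function(seed = 1L, n_iterations = 1000L) {
    cfg <- sim_config(seed = seed)
    params <- pipeline_config(sim = cfg, n_iterations = n_iterations,
                              seed = seed)
    study <- run_full(params)
    region <- cfg$effect_regions[[1]]
    target_idx <- box_indices(region$box, cfg$grid_shape)
    neg <- study$group_clusters[study$group_clusters$sign == "negative", ,
                                drop = FALSE]
    overlap <- 0L
    if (nrow(neg)) {
        for (r in seq_len(nrow(neg))) {
            cm <- cluster_mask(study$group_stat, neg[r, ], params$voxel_p,
                               study$space, params$connectivity)
            overlap <- max(overlap, sum(which(cm) %in% target_idx))
        }
    }
    interior <- box_indices(erode_box(region$box, 2L), cfg$grid_shape)
    cols <- match(interior, study$stack$voxels)
    cols <- cols[!is.na(cols)]
    zmeans <- rowMeans(study$stack$z[, cols, drop = FALSE])
    pat <- study$stack$records$group == "patient"
    z_diff <- mean(zmeans[!pat]) - mean(zmeans[pat])
    list(study = study, detected = overlap > 0, overlap_voxels = overlap,
         z_diff = z_diff, z_diff_target = atanh(0.6) - atanh(0.3))
}

#' Null-cohort false-positive study
#'
#' Repeats the end-to-end analysis on cohorts with no group effect and
#' counts how often the corrected group comparison reports any cluster.
#' Under a calibrated threshold this is a family-wise error check of the
#' whole pipeline. Runs use scaled-down cohorts (8 per group, 120 analyzed
#' volumes, 21x25x21 grid); the Monte-Carlo cluster threshold is computed
#' once and shared, since every run uses the same mask geometry.
#'
#' @param seed integer seed.
#' @param n_runs number of independent cohorts.
#' @param n_iterations Monte-Carlo iterations for the shared threshold.
#' @return A list: `n_false_positive_runs`, `n_runs`, `fp_runs_rate`,
#'   `k_voxels`.
#' @export
null_fp_study <- function(seed = 1L, n_runs = 20L, n_iterations = 1000L) {
    base_cfg <- function(s)
        sim_config(grid_shape = c(21L, 25L, 21L), n_volumes = 130L,
                   n_per_group = 8L, effect_regions = list(),
                   clinical_model = list(), seed = s)
    params0 <- pipeline_config(sim = base_cfg(derive_seed(seed, 0L)),
                               n_iterations = n_iterations,
                               seed = derive_seed(seed, 0L))
    first <- run_full(params0, through = "group_stats")
    k <- first$min_cluster_size_voxels
    hits <- integer(0)
    for (run in seq_len(n_runs)) {
        s <- derive_seed(seed, run)
        params <- pipeline_config(sim = base_cfg(s), seed = s)
        st <- run_full(params, through = "group_stats",
                       min_cluster_size_voxels = k)
        hits <- c(hits, nrow(st$group_clusters) > 0)
    }
    list(n_false_positive_runs = sum(hits), n_runs = n_runs,
         fp_runs_rate = mean(hits), k_voxels = k)
}
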