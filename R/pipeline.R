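# End-to-end orchestration: cohort -> preprocessing/QC -> symmetric space ->
# VMHC -> group and clinical statistics -> Monte-Carlo cluster correction ->
# gray-matter ROI check -> report files.

PIPELINE_STAGES <- c("preprocess", "vmhc", "group_stats", "clinical_stats",
                     "vbm", "report")

#' Write a synthetic cohort to disk
#'
#' Thin wrapper around [generate_cohort()] using the simulation block of a
#' [pipeline_config()].
#'
#' @param config a [pipeline_config()] (or [sim_config()]).
#' @param out_dir cohort directory (created if missing).
#' @export
run_simulate <- function(config, out_dir) {
    sim <- if (inherits(config, "sim_config")) config else config$sim
    generate_cohort(sim, out_dir)
}

#' Run the full VMHC study
#'
#' Executes the analysis end to end and (optionally) writes the report
#' bundle: a demographics table with group tests, the per-subject motion QC
#' table, the corrected group-difference cluster table, one clinical
#' correlation cluster table per clinical variable, the gray-matter ROI
#' check, and the symmetric-space and statistic maps as NIfTI-1.
#'
#' @param config a [pipeline_config()].
#' @param input_dir a cohort directory written by [run_simulate()]; with
#'   `NULL` the cohort defined by `config$sim` is generated in memory,
#'   subject by subject.
#' @param out_dir report directory, or `NULL` to skip writing files.
#' @param through last stage to run: one of `"preprocess"`, `"vmhc"`,
#'   `"group_stats"`, `"clinical_stats"`, `"vbm"`, `"report"`. Earlier
#'   stages always run (the pipeline recomputes upstream results in memory).
#' @param min_cluster_size_voxels optional precomputed cluster-extent
#'   threshold; when `NULL` it is derived by Monte-Carlo simulation on the
#'   unilateral gray-matter mask.
#' @param write_maps also write NIfTI maps (template, masks, statistic maps,
#'   per-subject VMHC maps) into `out_dir`.
#' @return An object of class `vmhc_study` (invisibly when `out_dir` is
#'   given).
#' @export
run_full <- function(config, input_dir = NULL, out_dir = NULL,
                     through = "report", min_cluster_size_voxels = NULL,
                     write_maps = FALSE) {
    through <- match.arg(through, PIPELINE_STAGES)
    stage_i <- match(through, PIPELINE_STAGES)
    log <- character(0)
    note <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))

    if (is.null(input_dir)) {
        sim <- config$sim
        records <- generate_demographics(sim)
        get_subject <- function(i) generate_subject(sim, records[i, ],
                                                    subject_seed(sim, i))
        get_gm <- function(i) make_tissue_maps(sim, subject_seed(sim, i))$gm
        note("cohort: synthetic, %d subjects, grid %s, seed %d",
             nrow(records), paste(sim$grid_shape, collapse = "x"), sim$seed)
    } else {
        cohort <- read_cohort(input_dir)
        records <- cohort$records
        get_subject <- function(i) {
            s <- read_cohort_subject(input_dir, records$id[i])
            s$record <- as.list(records[i, ])
            s
        }
        get_gm <- function(i) read_volume(file.path(input_dir, records$id[i],
                                                    "gm.nii.gz"))
        note("cohort: %s, %d subjects", input_dir, nrow(records))
    }
    voxel_size <- config$sim$voxel_size_mm

    # -- symmetric space from all subjects' gray-matter maps ----------------
    gm_maps <- lapply(seq_len(nrow(records)), get_gm)
    space <- build_symmetric_space(gm_maps, config$gm_threshold, voxel_size)
    note("symmetric space: gm mask %d voxels, unilateral %d, gm threshold %g",
         sum(space$gm_mask), sum(space$unilateral_mask), config$gm_threshold)

    # -- preprocessing, QC and per-subject VMHC ----------------------------
    maps <- vector("list", nrow(records))
    qc <- data.frame(id = records$id, mean_fd = NA_real_,
                     n_over_threshold = NA_integer_, excluded = NA,
                     max_translation_mm = NA_real_, max_rotation_deg = NA_real_,
                     stringsAsFactors = FALSE)
    for (i in seq_len(nrow(records))) {
        sub <- get_subject(i)
        pp <- preprocess_subject(sub, config)
        qc$mean_fd[i] <- pp$fd$mean_fd
        qc$n_over_threshold[i] <- pp$fd$n_over_threshold
        qc$excluded[i] <- pp$fd$excluded
        qc$max_translation_mm[i] <- pp$screen$max_translation_mm
        qc$max_rotation_deg[i] <- pp$screen$max_rotation_deg
        if (stage_i >= 2L) maps[[i]] <- compute_vmhc(pp$residual, space)
    }
    records$mean_fd <- qc$mean_fd
    records$excluded <- qc$excluded
    note("preprocessing: discard %d, smooth %g mm, band %g-%g Hz; %d excluded by FD > %g mm on > %d volumes",
         config$n_discard, config$fwhm_mm, config$band_hz[1], config$band_hz[2],
         sum(qc$excluded), config$fd_threshold_mm, config$fd_max_count)

    demo <- demographics_table(records)
    study <- structure(list(config = config, space = space, records = records,
                            qc = qc, demographics = demo, log = log),
                       class = "vmhc_study")
    if (stage_i < 2L) return(finish_study(study, out_dir, write_maps,
                                          maps = NULL))

    stack <- cohort_vmhc(maps, records, space)
    study$stack <- stack
    note("VMHC stack: %d subjects x %d voxels (complete-case)",
         nrow(stack$z), ncol(stack$z))
    study$log <- log
    if (stage_i < 3L) return(finish_study(study, out_dir, write_maps, maps))

    # -- group statistics and cluster correction ---------------------------
    group_stat <- glm_ttest_map(stack)
    study$group_stat <- group_stat
    if (is.null(min_cluster_size_voxels)) {
        null_dist <- simulate_cluster_null(space$unilateral_mask,
                                           voxel_p = config$voxel_p,
                                           fwhm_mm = config$fwhm_mm,
                                           voxel_size_mm = voxel_size,
                                           n_iterations = config$n_iterations,
                                           connectivity = config$connectivity,
                                           seed = derive_seed(config$seed, 777L))
        thr <- cluster_size_threshold(null_dist, config$alpha)
        study$null_dist <- null_dist
        min_cluster_size_voxels <- thr$k_voxels
        note("Monte-Carlo cluster threshold: %d voxels (%g mm^3) at voxel p %g, alpha %g, %d iterations",
             thr$k_voxels, thr$size_mm3 %||% NA, config$voxel_p, config$alpha,
             config$n_iterations)
    } else {
        note("cluster threshold supplied: %d voxels", min_cluster_size_voxels)
    }
    study$min_cluster_size_voxels <- min_cluster_size_voxels
    study$group_clusters <- apply_cluster_correction(
        group_stat, config$voxel_p, min_cluster_size_voxels, space,
        config$connectivity)
    note("group comparison: df %d, %d corrected cluster(s)",
         group_stat$df, nrow(study$group_clusters))
    study$log <- log
    if (stage_i < 4L) return(finish_study(study, out_dir, write_maps, maps))

    # -- clinical correlations (patients only) -----------------------------
    patients <- records$group == "patient" & !records$excluded
    pat_stack <- cohort_vmhc(maps[records$group == "patient"],
                             records[records$group == "patient", , drop = FALSE],
                             space)
    clin_cov <- c("age", "gender",
                  if (config$fd_covariate_clinical) "mean_fd")
    study$clinical <- list()
    study$clinical_stats <- list()
    for (v in clinical_variables()) {
        score <- pat_stack$records[[v]]
        if (is.null(score) || anyNA(score) || stats::sd(score) == 0) {
            note("clinical variable %s skipped (missing or constant)", v)
            next
        }
        cs <- tryCatch(clinical_corr_map(pat_stack, score,
                                         covariates = clin_cov),
                       error = function(e) {
                           note("clinical variable %s skipped: %s", v,
                                conditionMessage(e))
                           NULL
                       })
        if (is.null(cs)) next
        study$clinical_stats[[v]] <- cs
        study$clinical[[v]] <- apply_cluster_correction(
            cs, config$voxel_p, min_cluster_size_voxels, space,
            config$connectivity)
    }
    note("clinical correlations: %s (covariates: %s)",
         paste(names(study$clinical), collapse = ", "),
         paste(clin_cov, collapse = ", "))
    study$log <- log
    if (stage_i < 5L) return(finish_study(study, out_dir, write_maps, maps))

    # -- gray-matter ROI check ---------------------------------------------
    if (nrow(study$group_clusters)) {
        kept <- !records$excluded
        gm_kept <- gm_maps[kept]
        masks <- lapply(seq_len(nrow(study$group_clusters)), function(r)
            cluster_mask(group_stat, study$group_clusters[r, ],
                         config$voxel_p, space, config$connectivity))
        names(masks) <- paste0("cluster", study$group_clusters$label)
        means <- roi_means(gm_kept, masks)
        study$vbm <- roi_group_test(means, records[kept, , drop = FALSE])
        note("gray-matter ROI check over %d cluster(s)", length(masks))
    } else {
        study$vbm <- data.frame()
        note("gray-matter ROI check skipped: no corrected group cluster")
    }
    study$log <- log
    finish_study(study, out_dir, write_maps, maps)
}

finish_study <- function(study, out_dir, write_maps, maps) {
    if (is.null(out_dir)) return(study)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg <- study$config
    write.csv(study$demographics, file.path(out_dir, "demographics.csv"),
              row.names = FALSE)
    write.csv(study$qc, file.path(out_dir, "qc_fd.csv"), row.names = FALSE)
    tsv <- function(df, path) write.table(df, path, sep = "\t",
                                          row.names = FALSE, quote = FALSE)
    if (!is.null(study$group_clusters))
        tsv(study$group_clusters, file.path(out_dir, "group_clusters.tsv"))
    for (v in names(study$clinical))
        tsv(study$clinical[[v]],
            file.path(out_dir, sprintf("clinical_%s_clusters.tsv", v)))
    if (!is.null(study$vbm) && nrow(study$vbm))
        write.csv(study$vbm, file.path(out_dir, "vbm_roi.csv"),
                  row.names = FALSE)
    if (!is.null(study$null_dist)) {
        writeLines(as.character(as.integer(study$null_dist)),
                   file.path(out_dir, "null_max_cluster_sizes.txt"))
        writeLines(jsonlite::toJSON(attr(study$null_dist, "spec"),
                                    auto_unbox = TRUE, pretty = TRUE),
                   file.path(out_dir, "null_max_cluster_sizes.json"))
    }
    writeLines(study$log, file.path(out_dir, "pipeline_log.txt"))
    if (write_maps) {
        vs <- study$space$voxel_size_mm
        write_volume(study$space$template,
                     file.path(out_dir, "template.nii.gz"), vs)
        write_volume(study$space$gm_mask * 1,
                     file.path(out_dir, "gm_mask.nii.gz"), vs)
        write_volume(study$space$unilateral_mask * 1,
                     file.path(out_dir, "unilateral_mask.nii.gz"), vs)
        if (!is.null(study$group_stat)) {
            write_volume(study$group_stat$t_map,
                         file.path(out_dir, "group_t.nii.gz"), vs)
            write_volume(study$group_stat$z_map,
                         file.path(out_dir, "group_z.nii.gz"), vs)
        }
        if (!is.null(maps)) {
            dir.create(file.path(out_dir, "vmhc"), showWarnings = FALSE)
            for (m in maps)
                if (!is.null(m))
                    write_volume(ifelse(is.na(m$z), 0, m$z),
                                 file.path(out_dir, "vmhc",
                                           sprintf("%s_vmhc.nii.gz",
                                                   m$subject_id)), vs)
            # 4-D stack of the retained (post-QC) subjects + row map
            kept <- which(!study$records$excluded)
            if (length(kept) && !any(vapply(maps[kept], is.null, logical(1)))) {
                stack4d <- array(0, c(study$space$dim, length(kept)))
                for (j in seq_along(kept))
                    stack4d[, , , j] <- ifelse(is.na(maps[[kept[j]]]$z), 0,
                                               maps[[kept[j]]]$z)
                write_volume(stack4d, file.path(out_dir, "vmhc_stack.nii.gz"),
                             vs, tr_s = 1)
                write.csv(data.frame(volume = seq_along(kept),
                                     id = study$records$id[kept]),
                          file.path(out_dir, "vmhc_stack_rows.csv"),
                          row.names = FALSE)
            }
        }
    }
    invisible(study)
}

#' Demographics table with group tests
#'
#' Mean +- SD per group for the continuous variables (pooled two-sample t
#' test) and the male/female split (Pearson chi-squared without continuity
#' correction), in the layout of a clinical characteristics table.
#'
#' @param records subject metadata table.
#' @return A data frame: `variable`, `patients`, `controls`, `p`.
#' @export
demographics_table <- function(records) {
    pat <- records[records$group == "patient", , drop = FALSE]
    con <- records[records$group == "control", , drop = FALSE]
    fmt <- function(x) sprintf("%.2f±%.2f", mean(x), stats::sd(x))
    rows <- list()
    gtab <- c(sum(pat$gender == "male"), sum(pat$gender == "female"),
              sum(con$gender == "male"), sum(con$gender == "female"))
    gp <- chi2_2x2(gtab[1], gtab[2], gtab[3], gtab[4])$p
    rows[[1]] <- data.frame(variable = "gender_male_female",
                            patients = sprintf("%d/%d", gtab[1], gtab[2]),
                            controls = sprintf("%d/%d", gtab[3], gtab[4]),
                            p = gp, stringsAsFactors = FALSE)
    both <- c("age", "education", "hdrs_total", "anxiety", "weight_loss",
              "cognitive_disturbance", "retardation", "sleep_disturbance",
              "mean_fd")
    for (v in intersect(both, names(records))) {
        if (anyNA(pat[[v]]) || anyNA(con[[v]])) next
        tt <- if (stats::sd(pat[[v]]) == 0 && stats::sd(con[[v]]) == 0)
            list(p = 1) else
            summary_ttest(mean(pat[[v]]), stats::sd(pat[[v]]), nrow(pat),
                          mean(con[[v]]), stats::sd(con[[v]]), nrow(con))
        rows[[length(rows) + 1L]] <- data.frame(
            variable = v, patients = fmt(pat[[v]]), controls = fmt(con[[v]]),
            p = tt$p, stringsAsFactors = FALSE)
    }
    if ("illness_duration" %in% names(records) && !anyNA(pat$illness_duration))
        rows[[length(rows) + 1L]] <- data.frame(
            variable = "illness_duration", patients = fmt(pat$illness_duration),
            controls = "-", p = NA_real_, stringsAsFactors = FALSE)
    do.call(rbind, rows)
}

#' @export
print.vmhc_study <- function(x, ...) {
    cat("VMHC study\n")
    cat(sprintf("  %d subjects (%d excluded by motion QC)\n",
                nrow(x$records), sum(x$qc$excluded)))
    if (!is.null(x$group_stat))
        cat(sprintf("  group map df %d; cluster threshold %d voxels; %d corrected cluster(s)\n",
                    x$group_stat$df, x$min_cluster_size_voxels %||% NA,
                    nrow(x$group_clusters)))
    if (!is.null(x$clinical) && length(x$clinical)) {
        hits <- vapply(x$clinical, nrow, integer(1))
        cat(sprintf("  clinical maps: %s\n",
                    paste(sprintf("%s (%d)", names(hits), hits),
                          collapse = ", ")))
    }
    if (!is.null(x$vbm) && nrow(x$vbm))
        cat(sprintf("  gray-matter ROI check: min adjusted p %.3f\n",
                    min(x$vbm$p_bonferroni)))
    invisible(x)
}
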