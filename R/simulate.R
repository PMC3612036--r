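# Synthetic cohort generator.
#
# Generative model
# ----------------
# The brain is a symmetric ellipsoid on the grid. For every mirrored voxel
# pair with target homotopic correlation rho, the two time series are
#     x_L = sqrt(rho) s + sqrt(1 - rho) e_L
#     x_R = sqrt(rho) s + sqrt(1 - rho) e_R
# where s, e_L, e_R are independent unit-variance Gaussian processes living
# entirely on the passband DFT bins of the post-discard analysis window, so
# the population correlation of the pair is exactly rho and survives ideal
# band-pass filtering. Out-of-band AR(1) noise, a slow linear drift and a
# constant offset are added on top; all three are removed by the
# preprocessing chain (nuisance regression and band-pass).

SIGNAL_BAND_HZ <- c(0.01, 0.08)

# Normalized ellipsoidal radius (0 at the grid centre), symmetric about the
# midline plane by construction.
ellipsoid_radius <- function(dim3) {
    centre <- (dim3 + 1) / 2
    semi <- (dim3 - 1) / 2 * 0.95
    dx2 <- ((seq_len(dim3[1]) - centre[1]) / semi[1])^2
    dy2 <- ((seq_len(dim3[2]) - centre[2]) / semi[2])^2
    dz2 <- ((seq_len(dim3[3]) - centre[3]) / semi[3])^2
    sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
}

# Tissue probability maps for one subject. Geometry is deterministic given
# the config; the gray-matter map carries a symmetric, smooth, seeded
# perturbation so subjects differ while staying exactly mirror-symmetric.
make_tissue_maps <- function(config, subject_seed) {
    dim3 <- config$grid_shape
    d <- ellipsoid_radius(dim3)
    centre <- (dim3 + 1L) %/% 2L
    vent <- array(FALSE, dim3)
    vent[(centre[1] - 1L):(centre[1] + 1L),
         (centre[2] - 1L):(centre[2] + 1L), centre[3]] <- TRUE
    brain <- d < 0.97
    wm_core <- d < 0.22 & !vent
    gm_shell <- d >= 0.22 & d < 0.93 & !vent & brain

    brain_p <- ifelse(brain, 0.96, 0)
    wm_p <- ifelse(wm_core, 0.95, ifelse(brain, 0.02, 0))
    vent_p <- ifelse(vent, 0.85, ifelse(brain, 0.01, 0))
    gm_p <- ifelse(gm_shell, 0.85, ifelse(brain, 0.05, 0))

    set.seed(derive_seed(subject_seed, 11L))
    noise <- array(rnorm(prod(dim3)), dim3)
    noise <- .cpp_smooth_gaussian(noise, dim3, rep(1, 3))
    noise <- noise / stats::sd(noise) * 0.04
    gm_p <- clamp(gm_p + symmetrize(noise) * brain, 0.01, 1) * brain

    list(brain = brain_p, gm = gm_p, wm = wm_p, ventricle = vent_p,
         brain_mask = brain, radius = d)
}

# Per-voxel target homotopic correlation for one subject, defined on the
# left-hemisphere brain voxels (the mirror is implied). Clinical couplings
# apply to patients only, centred on the nominal patient score mean, so they
# do not move the group means.
build_rho_map <- function(config, record) {
    dim3 <- config$grid_shape
    rho <- array(config$baseline_rho, dim3)
    is_patient <- identical(record$group, "patient")
    for (r in config$effect_regions) {
        b <- r$box
        rho[b$x[1]:b$x[2], b$y[1]:b$y[2], b$z[1]:b$z[2]] <-
            if (is_patient) r$rho_patient else r$rho_control
    }
    if (is_patient) {
        for (cm in config$clinical_model) {
            p <- clinical_score_params("patient")[[cm$score]]
            if (p[2] <= 0) next
            zscore <- (record[[cm$score]] - p[1]) / p[2]
            delta <- cm$slope * zscore + rnorm(1, 0, cm$noise_sd)
            b <- cm$box
            sel <- rho[b$x[1]:b$x[2], b$y[1]:b$y[2], b$z[1]:b$z[2]] + delta
            if (any(sel < 0) || any(sel >= 1))
                warnf("clinical coupling pushed rho outside [0, 1); clipped")
            rho[b$x[1]:b$x[2], b$y[1]:b$y[2], b$z[1]:b$z[2]] <-
                clamp(sel, 0, 0.99)
        }
    }
    rho
}

# Passband DFT bins of the analysis window.
passband_bins <- function(n_analysis, tr_s, band = SIGNAL_BAND_HZ) {
    k_lo <- ceiling(band[1] * n_analysis * tr_s)
    k_hi <- floor(band[2] * n_analysis * tr_s)
    k_lo <- max(k_lo, 1L)
    if (k_lo > k_hi)
        stopf("no DFT bin falls in the %g-%g Hz passband at %d frames, TR %g s",
              band[1], band[2], n_analysis, tr_s)
    seq.int(k_lo, k_hi)
}

# n_total x n_series matrix of unit-variance Gaussian processes confined to
# the passband bins of the last n_analysis frames (earlier frames are the
# periodic extension of the same sinusoids).
synth_band_limited <- function(n_series, n_total, n_analysis, tr_s) {
    bins <- passband_bins(n_analysis, tr_s)
    amps <- 1 / sqrt(bins + 2)
    amps <- amps / sqrt(sum(amps^2))
    t_idx <- seq.int(n_analysis - n_total, n_analysis - 1)
    ang <- outer(t_idx, bins) * (2 * pi / n_analysis)
    basis <- cbind(cos(ang), sin(ang)) %*% diag(rep(amps, 2), 2 * length(bins))
    coefs <- matrix(rnorm(2 * length(bins) * n_series), 2 * length(bins), n_series)
    basis %*% coefs
}

# AR(1) noise whose passband content on the analysis window is projected out.
synth_oob_noise <- function(n_series, n_total, n_analysis, tr_s, phi) {
    innov_sd <- sqrt(1 - phi^2)
    x <- matrix(0, n_total, n_series)
    x[1, ] <- rnorm(n_series)
    for (t in 2:n_total)
        x[t, ] <- phi * x[t - 1, ] + rnorm(n_series, sd = innov_sd)
    bins <- passband_bins(n_analysis, tr_s)
    win <- (n_total - n_analysis + 1):n_total
    f <- mvfft(x[win, , drop = FALSE])
    f[bins + 1L, ] <- 0
    f[n_analysis + 1L - bins, ] <- 0
    x[win, ] <- Re(mvfft(f, inverse = TRUE)) / n_analysis
    x
}

clinical_score_params <- function(group) {
    if (group == "patient") {
        list(illness_duration = c(6.75, 7.26), hdrs_total = c(26.58, 3.43),
             anxiety = c(7.94, 2.07), weight_loss = c(1.24, 0.75),
             cognitive_disturbance = c(5.65, 1.50), retardation = c(7.59, 1.70),
             sleep_disturbance = c(4.12, 1.65))
    } else {
        list(illness_duration = c(NA, NA), hdrs_total = c(3.30, 2.65),
             anxiety = c(0.65, 0.59), weight_loss = c(0, 0),
             cognitive_disturbance = c(0.60, 0.65), retardation = c(1.02, 0.90),
             sleep_disturbance = c(1.03, 0.93))
    }
}

#' Generate cohort demographics and clinical scores
#'
#' Draws a group-balanced subject table: ages and education from a common
#' distribution, genders fixed at an 8/9 vs 9/8 male/female split for 17 per
#' group (proportionally otherwise), illness duration (patients only) from a
#' gamma distribution, and Hamilton depression totals and symptom-factor
#' scores from group-specific Gaussians, truncated at plausible bounds.
#'
#' @param config a [sim_config()].
#' @return A data frame with one row per subject (`subject_record` table).
#' @export
generate_demographics <- function(config) {
    set.seed(derive_seed(config$seed, 1L))
    n <- config$n_per_group
    group <- rep(c("patient", "control"), each = n)
    id <- sprintf("sub-%03d", seq_len(2 * n))
    n_male_pat <- max(1L, floor(n / 2))
    n_male_con <- min(n - 1L, ceiling(n / 2))
    gender <- c(rep(c("male", "female"), c(n_male_pat, n - n_male_pat)),
                rep(c("male", "female"), c(n_male_con, n - n_male_con)))
    age <- round(clamp(rnorm(2 * n, 34.4, 12.7), 18, 60), 1)
    education <- round(clamp(rnorm(2 * n, 13.2, 2.35), 6, 22), 1)
    dur_mean <- 6.75; dur_sd <- 7.26
    shape <- (dur_mean / dur_sd)^2
    illness_duration <- ifelse(group == "patient",
        round(clamp(stats::rgamma(2 * n, shape = shape,
                                  rate = shape / dur_mean), 1, 24), 1), NA)
    df <- data.frame(id = id, group = group, gender = gender, age = age,
                     education = education, illness_duration = illness_duration,
                     stringsAsFactors = FALSE)
    for (v in setdiff(clinical_variables(), "illness_duration")) {
        vals <- numeric(2 * n)
        for (g in c("patient", "control")) {
            p <- clinical_score_params(g)[[v]]
            sel <- group == g
            draw <- rnorm(sum(sel), p[1], p[2])
            lo <- if (v == "hdrs_total" && g == "patient") 17 else 0
            vals[sel] <- round(clamp(draw, lo, Inf), 1)
        }
        df[[v]] <- vals
    }
    df$mean_fd <- NA_real_
    df
}

#' Generate one synthetic subject
#'
#' Produces the 4-D BOLD series, rigid-body motion trace and tissue
#' probability maps for a single subject under the configured ground truth.
#' The same `(config, record, seed)` triple reproduces the subject
#' bit-exactly.
#'
#' @param config a [sim_config()].
#' @param record one row of the table from [generate_demographics()] (a list
#'   or single-row data frame with at least `id`, `group` and the clinical
#'   scores named in the config's clinical model).
#' @param seed integer seed for this subject.
#' @return A list with elements `bold` ([bold_series()]), `motion`
#'   ([motion_trace()]), `gm`, `wm`, `ventricle`, `brain` (probability maps),
#'   `rho` (the per-voxel target correlation, left hemisphere) and `record`.
#' @export
generate_subject <- function(config, record, seed) {
    record <- as.list(record)
    dim3 <- config$grid_shape
    nvox <- prod(dim3)
    n_vol <- config$n_volumes
    n_an <- n_vol - config$n_discard
    maps <- make_tissue_maps(config, seed)
    rho <- build_rho_map(config, record)

    mid <- (dim3[1] + 1L) %/% 2L
    brain <- maps$brain_mask
    ijk <- index_to_ijk(which(brain), dim3)
    brain_idx <- which(brain)
    xcoord <- ijk[, 1]
    left <- brain_idx[xcoord < mid]
    left_ijk <- ijk[xcoord < mid, , drop = FALSE]
    right <- (mid + (mid - left_ijk[, 1])) +
        dim3[1] * (left_ijk[, 2] - 1L) + dim3[1] * dim3[2] * (left_ijk[, 3] - 1L)
    if (!all(brain[right]))
        stopf("internal error: brain mask is not mirror-symmetric")
    midline <- brain_idx[xcoord == mid]

    set.seed(derive_seed(seed, 22L))
    n_pairs <- length(left)
    s <- synth_band_limited(n_pairs, n_vol, n_an, config$tr_s)
    e_l <- synth_band_limited(n_pairs, n_vol, n_an, config$tr_s)
    e_r <- synth_band_limited(n_pairs, n_vol, n_an, config$tr_s)
    rho_pair <- rho[left]
    w_s <- sqrt(rho_pair)
    w_e <- sqrt(1 - rho_pair)
    x_l <- sweep(s, 2, w_s, "*") + sweep(e_l, 2, w_e, "*")
    x_r <- sweep(s, 2, w_s, "*") + sweep(e_r, 2, w_e, "*")
    x_m <- if (length(midline))
        synth_band_limited(length(midline), n_vol, n_an, config$tr_s) else NULL

    data_mat <- matrix(0, n_vol, nvox)
    data_mat[, left] <- x_l
    data_mat[, right] <- x_r
    if (length(midline)) data_mat[, midline] <- x_m

    n_brain <- length(brain_idx)
    if (config$noise_sd > 0) {
        noise <- synth_oob_noise(n_brain, n_vol, n_an, config$tr_s,
                                 config$ar1_coef)
        data_mat[, brain_idx] <- data_mat[, brain_idx] + config$noise_sd * noise
    }
    t_c <- seq_len(n_vol) - (n_vol + 1) / 2
    slopes <- runif(n_brain, -0.003, 0.003)
    data_mat[, brain_idx] <- data_mat[, brain_idx] + outer(t_c, slopes) + 100

    set.seed(derive_seed(seed, 33L))
    scale <- exp(rnorm(1, 0, config$motion_scale_log_sd))
    step_t <- config$motion_sd_mm * scale
    motion <- sapply(c(rep(step_t, 3), rep(step_t / 50, 3)), function(sd) {
        x <- numeric(n_vol)
        innov <- rnorm(n_vol, sd = sd)
        x[1] <- innov[1]
        for (t in 2:n_vol) x[t] <- 0.95 * x[t - 1] + innov[t]
        x
    })

    bold <- bold_series(array(t(data_mat), dim = c(dim3, n_vol)),
                        voxel_size_mm = config$voxel_size_mm,
                        tr_s = config$tr_s, subject_id = record$id)
    list(bold = bold, motion = motion_trace(motion), gm = maps$gm,
         wm = maps$wm, ventricle = maps$ventricle, brain = maps$brain,
         rho = rho, record = record)
}

subject_seed <- function(config, i) derive_seed(config$seed, 100L + i)

#' Generate a full synthetic cohort
#'
#' Draws the demographics table and, when `out_dir` is given, writes each
#' subject to disk (`func.nii.gz`, `rp_<id>.txt` motion file, tissue
#' probability maps), together with `metadata.csv` and a `manifest.json`
#' recording the seed and a content hash of the configuration. With
#' `out_dir = NULL` the subjects are returned in memory (only advisable for
#' small grids).
#'
#' @param config a [sim_config()] (requires `n_per_group >= 2`).
#' @param out_dir output directory, created if missing, or `NULL`.
#' @return Invisibly, a list with `records` (the metadata table) and either
#'   `dir` or `subjects`.
#' @export
generate_cohort <- function(config, out_dir = NULL) {
    if (config$n_per_group < 2L) stopf("n_per_group must be at least 2")
    records <- generate_demographics(config)
    if (is.null(out_dir)) {
        subjects <- lapply(seq_len(nrow(records)), function(i)
            generate_subject(config, records[i, ], subject_seed(config, i)))
        return(invisible(list(records = records, subjects = subjects)))
    }
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(records))) {
        sub <- generate_subject(config, records[i, ], subject_seed(config, i))
        sd <- file.path(out_dir, records$id[i])
        dir.create(sd, showWarnings = FALSE)
        write_volume(sub$bold, file.path(sd, "func.nii.gz"))
        write_motion(sub$motion, file.path(sd, sprintf("rp_%s.txt", records$id[i])))
        for (m in c("gm", "wm", "ventricle", "brain"))
            write_volume(sub[[m]], file.path(sd, paste0(m, ".nii.gz")),
                         voxel_size_mm = config$voxel_size_mm)
    }
    write.csv(records, file.path(out_dir, "metadata.csv"), row.names = FALSE)
    manifest <- list(seed = config$seed, n_subjects = nrow(records),
                     config_hash = config_hash(config),
                     package_version = as.character(utils::packageVersion("vmhc")))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
               file.path(out_dir, "manifest.json"))
    invisible(list(records = records, dir = out_dir))
}

# djb2-style content hash of the serialized config (hex string).
config_hash <- function(config) {
    bytes <- as.integer(serialize(unclass(config), NULL, xdr = TRUE))
    h <- 5381
    for (b in bytes) h <- (h * 33 + b) %% 4294967296
    sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Read a cohort written by [generate_cohort()] or [run_simulate()]
#' @param dir cohort directory.
#' @return A list with `records` and `dir`.
#' @export
read_cohort <- function(dir) {
    meta <- file.path(dir, "metadata.csv")
    if (!file.exists(meta)) stopf("no metadata.csv under %s", dir)
    list(records = read.csv(meta, stringsAsFactors = FALSE), dir = dir)
}

read_cohort_subject <- function(dir, id, tr_s = NULL) {
    sd <- file.path(dir, id)
    list(bold = read_bold(file.path(sd, "func.nii.gz"), tr_s = tr_s,
                          subject_id = id),
         motion = read_motion(file.path(sd, sprintf("rp_%s.txt", id))),
         gm = read_volume(file.path(sd, "gm.nii.gz")),
         wm = read_volume(file.path(sd, "wm.nii.gz")),
         ventricle = read_volume(file.path(sd, "ventricle.nii.gz")),
         brain = read_volume(file.path(sd, "brain.nii.gz")))
}
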