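#' Simulation configuration for a synthetic VMHC cohort
#'
#' Describes the generative model used by [generate_subject()] and
#' [generate_cohort()]: a symmetric brain-shaped grid in which every mirrored
#' voxel pair shares a band-limited common signal with a controllable
#' population correlation `rho`, plus out-of-band AR(1) noise, slow linear
#' drift, rigid-body motion traces, and Table-1-style demographics with
#' clinical scores that can be coupled (negatively) to regional homotopic
#' correlation in patients.
#'
#' Homotopic signals are synthesized on the exact discrete-Fourier bins of the
#' post-discard analysis window that fall in the 0.01-0.08 Hz passband, and
#' the AR(1) noise has its passband content projected out, so the engineered
#' correlation `rho` survives the preprocessing chain exactly and
#' `atanh(rho)` is an exact recovery target for the VMHC estimate.
#'
#' @param grid_shape integer(3), grid size in voxels; the x (left-right)
#'   dimension must be odd so a midline plane exists.
#' @param voxel_size_mm isotropic voxel size in mm.
#' @param n_volumes number of acquired volumes (before any discard).
#' @param n_discard number of initial volumes the downstream pipeline will
#'   discard; the generator aligns its signal bins to the remaining window.
#' @param tr_s repetition time in seconds.
#' @param ar1_coef AR(1) coefficient of the out-of-band noise, in `[0, 1)`.
#' @param noise_sd standard deviation of the out-of-band AR(1) noise relative
#'   to the unit-variance in-band signal.
#' @param baseline_rho homotopic correlation outside effect regions, `[0, 1)`.
#' @param effect_regions list of effect specifications, each a list with
#'   `box` (2x3 matrix or list of 1-based index ranges `x`, `y`, `z` on the
#'   left hemisphere), `rho_patient` and `rho_control`.
#' @param clinical_model list of clinical couplings, each a list with `box`,
#'   `score` (a clinical variable name), `slope` (change in rho per standard
#'   deviation of the score; negative means higher score, lower rho) and
#'   `noise_sd` (subject-level rho jitter).
#' @param motion_sd_mm baseline per-step standard deviation of the motion
#'   random walk (mm for translations; divided by 50 for rotations in rad).
#' @param motion_scale_log_sd log-normal spread of the per-subject motion
#'   scale multiplier (default 0.4 makes roughly 5% of subjects exceed the
#'   framewise-displacement exclusion rule).
#' @param n_per_group subjects per group (patients and controls).
#' @param seed integer seed; a fixed seed reproduces the cohort bit-exactly.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(grid_shape = c(25L, 31L, 25L),
                       voxel_size_mm = 3,
                       n_volumes = 210L,
                       n_discard = 10L,
                       tr_s = 2,
                       ar1_coef = 0.4,
                       noise_sd = 0.5,
                       baseline_rho = 0.45,
                       effect_regions = list(default_effect_region()),
                       clinical_model = list(default_clinical_coupling()),
                       motion_sd_mm = 0.042,
                       motion_scale_log_sd = 0.4,
                       n_per_group = 17L,
                       seed = 1L) {
    cfg <- list(grid_shape = as.integer(grid_shape),
                voxel_size_mm = voxel_size_mm,
                n_volumes = as.integer(n_volumes),
                n_discard = as.integer(n_discard),
                tr_s = tr_s,
                ar1_coef = ar1_coef,
                noise_sd = noise_sd,
                baseline_rho = baseline_rho,
                effect_regions = lapply(effect_regions, normalize_region),
                clinical_model = lapply(clinical_model, normalize_clinical),
                motion_sd_mm = motion_sd_mm,
                motion_scale_log_sd = motion_scale_log_sd,
                n_per_group = as.integer(n_per_group),
                seed = as.integer(seed))
    class(cfg) <- "sim_config"
    validate_sim_config(cfg)
    cfg
}

#' Default group-effect region (reduced homotopic correlation in patients)
#'
#' A 7x7x7-voxel box on the left hemisphere of the default grid in which the
#' homotopic correlation drops from 0.6 (controls) to 0.3 (patients).
#' @export
default_effect_region <- function() {
    list(box = list(x = c(4L, 10L), y = c(12L, 18L), z = c(10L, 16L)),
         rho_patient = 0.3, rho_control = 0.6)
}

#' Default clinical coupling region
#'
#' A left-hemisphere box, disjoint from [default_effect_region()], in which a
#' patient's cognitive-disturbance score lowers the regional homotopic
#' correlation (slope -0.12 per score standard deviation).
#' @export
default_clinical_coupling <- function() {
    list(box = list(x = c(4L, 10L), y = c(20L, 26L), z = c(10L, 16L)),
         score = "cognitive_disturbance", slope = -0.12, noise_sd = 0.04)
}

normalize_region <- function(r) {
    b <- r$box
    if (is.matrix(b)) b <- list(x = b[, 1], y = b[, 2], z = b[, 3])
    r$box <- lapply(b[c("x", "y", "z")], function(v) as.integer(range(v)))
    r
}

normalize_clinical <- function(cm) {
    cm <- normalize_region(cm)
    if (!cm$score %in% clinical_variables())
        stopf("unknown clinical score '%s'", cm$score)
    cm
}

#' Clinical variables analyzed by the pipeline
#' @export
clinical_variables <- function() {
    c("illness_duration", "hdrs_total", "anxiety", "weight_loss",
      "cognitive_disturbance", "retardation", "sleep_disturbance")
}

validate_sim_config <- function(cfg) {
    stopifnot(length(cfg$grid_shape) == 3L, all(cfg$grid_shape >= 3L))
    if (cfg$grid_shape[1] %% 2L == 0L)
        stopf("x dimension must be odd so that a midline plane exists")
    stopifnot(is_scalar_num(cfg$voxel_size_mm), cfg$voxel_size_mm > 0,
              cfg$n_volumes >= 2L, cfg$n_discard >= 0L,
              cfg$n_discard < cfg$n_volumes,
              is_scalar_num(cfg$tr_s), cfg$tr_s > 0,
              cfg$ar1_coef >= 0, cfg$ar1_coef < 1,
              cfg$noise_sd >= 0,
              cfg$motion_sd_mm >= 0, cfg$n_per_group >= 1L)
    check_rho <- function(r, what) {
        if (!is_scalar_num(r) || r < 0 || r >= 1)
            stopf("%s must lie in [0, 1), got %s", what, format(r))
    }
    check_rho(cfg$baseline_rho, "baseline_rho")
    mid <- (cfg$grid_shape[1] + 1L) %/% 2L
    for (r in cfg$effect_regions) {
        check_rho(r$rho_patient, "rho_patient")
        check_rho(r$rho_control, "rho_control")
        check_box(r$box, cfg$grid_shape, mid)
    }
    for (cm in cfg$clinical_model) check_box(cm$box, cfg$grid_shape, mid)
    invisible(cfg)
}

check_box <- function(box, dim3, midline) {
    for (ax in 1:3) {
        rng <- box[[ax]]
        if (rng[1] < 1L || rng[2] > dim3[ax])
            stopf("effect box exceeds the grid on axis %d (%d:%d vs 1:%d)",
                  ax, rng[1], rng[2], dim3[ax])
    }
    if (box$x[2] >= midline)
        stopf("effect boxes must lie strictly on the left hemisphere (x < %d)",
              midline)
    invisible(box)
}

#' @export
print.sim_config <- function(x, ...) {
    cat("Synthetic VMHC cohort configuration\n")
    cat(sprintf("  grid %s voxels at %g mm, %d volumes (TR %g s, discard %d)\n",
                paste(x$grid_shape, collapse = "x"), x$voxel_size_mm,
                x$n_volumes, x$tr_s, x$n_discard))
    cat(sprintf("  baseline rho %.2f; %d effect region(s); %d clinical coupling(s)\n",
                x$baseline_rho, length(x$effect_regions), length(x$clinical_model)))
    cat(sprintf("  %d subjects per group, seed %d\n", x$n_per_group, x$seed))
    invisible(x)
}

#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis. The defaults reproduce
#' the study settings: discard 10 volumes, 6-mm FWHM Gaussian smoothing,
#' 0.01-0.08 Hz ideal band-pass, tissue-mask thresholds 0.7/0.9/0.5
#' (ventricle/white matter/whole brain), framewise-displacement exclusion at
#' FD > 0.5 mm on more than 35 volumes, voxel-wise p = 0.01 two-tailed with
#' Monte-Carlo cluster-extent correction at corrected alpha = 0.05 on the
#' unilateral gray-matter mask.
#'
#' @param sim a [sim_config()] describing the synthetic cohort (used when the
#'   pipeline generates its own data).
#' @param n_discard initial volumes to discard.
#' @param fwhm_mm Gaussian smoothing kernel full-width at half-maximum (mm).
#' @param band_hz length-2 passband in Hz.
#' @param mask_thresholds named thresholds for the ventricle, white-matter and
#'   whole-brain probability masks (strict `>`).
#' @param fd_threshold_mm,fd_max_count a subject is excluded when more than
#'   `fd_max_count` volumes have FD above `fd_threshold_mm`.
#' @param head_radius_mm sphere radius converting rotations to mm in FD.
#' @param gm_threshold gray-matter probability threshold defining the
#'   analysis mask on the symmetric template.
#' @param voxel_p per-voxel two-tailed p threshold before clustering.
#' @param alpha corrected family-wise cluster alpha.
#' @param n_iterations Monte-Carlo iterations for the cluster null.
#' @param connectivity cluster neighbourhood: 6, 18 or 26.
#' @param fd_covariate_clinical include mean FD as a covariate in the
#'   clinical correlation maps (the group analysis always includes it).
#' @param seed integer seed for every stochastic step.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(seed = seed),
                            n_discard = 10L,
                            fwhm_mm = 6,
                            band_hz = c(0.01, 0.08),
                            mask_thresholds = c(ventricle = 0.7,
                                                white_matter = 0.9,
                                                brain = 0.5),
                            fd_threshold_mm = 0.5,
                            fd_max_count = 35L,
                            head_radius_mm = 50,
                            gm_threshold = 0.2,
                            voxel_p = 0.01,
                            alpha = 0.05,
                            n_iterations = 1000L,
                            connectivity = 6L,
                            fd_covariate_clinical = FALSE,
                            seed = 1L) {
    cfg <- list(sim = sim, n_discard = as.integer(n_discard), fwhm_mm = fwhm_mm,
                band_hz = band_hz, mask_thresholds = mask_thresholds,
                fd_threshold_mm = fd_threshold_mm,
                fd_max_count = as.integer(fd_max_count),
                head_radius_mm = head_radius_mm, gm_threshold = gm_threshold,
                voxel_p = voxel_p, alpha = alpha,
                n_iterations = as.integer(n_iterations),
                connectivity = as.integer(connectivity),
                fd_covariate_clinical = isTRUE(fd_covariate_clinical),
                seed = as.integer(seed))
    stopifnot(cfg$fwhm_mm >= 0, length(cfg$band_hz) == 2L,
              cfg$band_hz[1] < cfg$band_hz[2],
              cfg$voxel_p > 0, cfg$voxel_p < 1, cfg$alpha > 0, cfg$alpha < 1,
              cfg$connectivity %in% c(6L, 18L, 26L))
    class(cfg) <- "pipeline_config"
    cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the `sim` key
#' mirrors [sim_config()]. Missing keys keep their defaults.
#' @param path path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
    raw <- yaml::read_yaml(path)
    sim_args <- raw$sim %||% list()
    raw$sim <- NULL
    if (!is.null(raw$seed) && is.null(sim_args$seed)) sim_args$seed <- raw$seed
    sim <- do.call(sim_config, sim_args)
    do.call(pipeline_config, c(list(sim = sim), raw))
}

#' @export
print.pipeline_config <- function(x, ...) {
    cat("VMHC pipeline configuration\n")
    cat(sprintf("  discard %d volumes; smooth %g mm FWHM; band-pass %g-%g Hz\n",
                x$n_discard, x$fwhm_mm, x$band_hz[1], x$band_hz[2]))
    cat(sprintf("  FD exclusion: > %g mm on > %d volumes; gm threshold %g\n",
                x$fd_threshold_mm, x$fd_max_count, x$gm_threshold))
    cat(sprintf("  voxel p %g, corrected alpha %g, %d MC iterations, connectivity %d\n",
                x$voxel_p, x$alpha, x$n_iterations, x$connectivity))
    invisible(x)
}
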