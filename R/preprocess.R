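# Functional preprocessing: volume discard, Gaussian smoothing, nuisance
# regression, ideal band-pass filtering, and motion quality control.
#
# The pipeline order is fixed: discard -> smooth -> nuisance regression ->
# band-pass. Tissue signals for the nuisance set are extracted from the
# smoothed series.

#' Discard initial volumes
#' @param series a [bold_series()].
#' @param n_discard number of leading volumes to drop.
#' @export
discard_initial <- function(series, n_discard) {
    nt <- n_volumes(series)
    if (n_discard >= nt)
        stopf("cannot discard %d of %d volumes", n_discard, nt)
    if (n_discard == 0L) return(series)
    out <- series
    out$data <- series$data[, , , (n_discard + 1):nt, drop = FALSE]
    out
}

fwhm_to_sigma <- function(fwhm_mm, voxel_size_mm) {
    fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
}

#' Gaussian smoothing of a volume or series
#'
#' Separable Gaussian convolution with per-axis sigma
#' `fwhm / (2 sqrt(2 log 2)) / voxel_size` (so anisotropic voxels are
#' handled), kernel truncated at 4 sigma and normalized to sum 1. Values
#' outside the grid are treated as zero (zero-padding boundary). `fwhm = 0`
#' is the identity.
#'
#' @param x a [bold_series()] or a 3-D array.
#' @param fwhm_mm kernel full-width at half-maximum in mm.
#' @param voxel_size_mm voxel size (used only for plain arrays).
#' @return The smoothed object, same shape as the input.
#' @export
smooth_gaussian <- function(x, fwhm_mm, voxel_size_mm = 3) {
    if (fwhm_mm < 0) stopf("fwhm must be nonnegative")
    if (fwhm_mm == 0) return(x)
    if (inherits(x, "bold_series")) {
        sigma <- fwhm_to_sigma(fwhm_mm, x$voxel_size_mm)
        out <- x
        out$data <- .cpp_smooth_gaussian(x$data, dim(x$data)[1:3], sigma)
        return(out)
    }
    sigma <- fwhm_to_sigma(fwhm_mm, rep(voxel_size_mm, length.out = 3))
    .cpp_smooth_gaussian(x, dim(x)[1:3], sigma)
}

#' Assemble the nuisance regressor set
#'
#' Columns: the six rigid-body motion parameters, a centred linear drift
#' ramp, and the mean signals within the ventricular, white-matter and
#' whole-brain masks obtained by thresholding the probability maps at 0.7,
#' 0.9 and 0.5 respectively (strict `>`).
#'
#' @param series a [bold_series()] (post-discard, typically smoothed).
#' @param motion a [motion_trace()] with one row per volume of `series`.
#' @param ventricle,white_matter,brain tissue probability maps on the grid.
#' @param thresholds named mask thresholds.
#' @return An object of class `nuisance_set`: a list with the design columns
#'   and the thresholds used.
#' @export
build_nuisance_set <- function(series, motion, ventricle, white_matter, brain,
                               thresholds = c(ventricle = 0.7,
                                              white_matter = 0.9,
                                              brain = 0.5)) {
    nt <- n_volumes(series)
    if (nrow(motion) != nt)
        stopf("motion trace has %d rows for %d volumes", nrow(motion), nt)
    maps <- list(ventricle = ventricle, white_matter = white_matter,
                 brain = brain)
    mat <- as_time_matrix(series)
    tissue <- lapply(names(maps), function(nm) {
        mask <- as.numeric(maps[[nm]]) > thresholds[[nm]]
        if (!any(mask))
            stopf("%s mask is empty at threshold %g", nm, thresholds[[nm]])
        rowMeans(mat[, mask, drop = FALSE])
    })
    names(tissue) <- names(maps)
    drift <- seq_len(nt) - (nt + 1) / 2
    structure(list(motion = unclass(motion)[, 1:6, drop = FALSE],
                   linear_drift = drift,
                   ventricle_signal = tissue$ventricle,
                   white_matter_signal = tissue$white_matter,
                   global_signal = tissue$brain,
                   mask_thresholds = thresholds),
              class = "nuisance_set")
}

nuisance_design <- function(nuisance, nt) {
    X <- cbind(intercept = 1, nuisance$motion, drift = nuisance$linear_drift,
               ventricle = nuisance$ventricle_signal,
               white_matter = nuisance$white_matter_signal,
               global = nuisance$global_signal)
    if (nrow(X) != nt) stopf("nuisance columns do not match the series length")
    X
}

#' Regress nuisance signals out of a series
#'
#' Per-voxel ordinary least-squares residuals against the design
#' (intercept + nuisance columns). Residuals are orthogonal to every design
#' column. A rank-deficient design is rejected with the offending columns
#' named.
#'
#' @param series a [bold_series()].
#' @param nuisance a [build_nuisance_set()] result.
#' @return The residual [bold_series()].
#' @export
regress_nuisance <- function(series, nuisance) {
    X <- nuisance_design(nuisance, n_volumes(series))
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
        bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
        stopf("nuisance design is rank deficient; collinear column(s): %s",
              paste(bad, collapse = ", "))
    }
    Y <- as_time_matrix(series)
    # all-zero voxels (outside the head) are their own residuals
    active <- which(colSums(abs(Y)) > 0)
    res <- matrix(0, nrow(Y), ncol(Y))
    if (length(active))
        res[, active] <- qr.resid(qrX, Y[, active, drop = FALSE])
    from_time_matrix(res, series)
}

#' Ideal band-pass filter
#'
#' Rectangular frequency-domain filter: discrete-Fourier coefficients with
#' `|f|` inside `[low_hz, high_hz]` (inclusive) are retained, all others --
#' including the zero-frequency term, so the output has mean zero -- are set
#' to zero.
#'
#' @param series a [bold_series()].
#' @param low_hz,high_hz passband edges in Hz; `high_hz` must be below the
#'   Nyquist frequency `1 / (2 TR)`.
#' @return The filtered [bold_series()].
#' @export
bandpass <- function(series, low_hz = 0.01, high_hz = 0.08) {
    nyquist <- 1 / (2 * series$tr_s)
    if (high_hz >= nyquist)
        stopf("high cutoff %g Hz is not below the Nyquist frequency %g Hz",
              high_hz, nyquist)
    if (low_hz >= high_hz) stopf("low cutoff must be below the high cutoff")
    nt <- n_volumes(series)
    freqs <- seq_len(nt) - 1
    freqs <- pmin(freqs, nt - freqs) / (nt * series$tr_s)
    keep <- freqs >= low_hz & freqs <= high_hz
    Y <- as_time_matrix(series)
    active <- which(colSums(abs(Y)) > 0)
    out <- matrix(0, nrow(Y), ncol(Y))
    if (length(active)) {
        f <- mvfft(Y[, active, drop = FALSE])
        f[!keep, ] <- 0
        out[, active] <- Re(mvfft(f, inverse = TRUE)) / nt
    }
    from_time_matrix(out, series)
}

#' Framewise displacement and the motion exclusion rule
#'
#' `FD_t = |d tx| + |d ty| + |d tz| + r (|d rx| + |d ry| + |d rz|)` with the
#' rotations converted to mm on a sphere of radius `r` (50 mm), and
#' `FD_1 = 0`. A subject is flagged excluded when FD exceeds
#' `fd_threshold_mm` on more than `max_count` volumes.
#'
#' @param motion a [motion_trace()] (at least two rows).
#' @param head_radius_mm rotation-to-mm conversion radius.
#' @param fd_threshold_mm,max_count exclusion rule parameters.
#' @return A list of class `fd_record`: `fd`, `mean_fd`, `n_over_threshold`,
#'   `excluded`.
#' @export
compute_fd <- function(motion, head_radius_mm = 50, fd_threshold_mm = 0.5,
                       max_count = 35L) {
    if (nrow(motion) < 2L) stopf("need at least two volumes to compute FD")
    d <- abs(diff(unclass(motion)))
    fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
                head_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
    n_over <- sum(fd > fd_threshold_mm)
    structure(list(fd = fd, mean_fd = mean(fd), n_over_threshold = n_over,
                   excluded = n_over > max_count),
              class = "fd_record")
}

#' Gross-motion screen
#'
#' Fails when any translation reaches 1 mm or any rotation reaches 1 degree
#' in absolute value.
#'
#' @param motion a [motion_trace()].
#' @param max_translation_mm,max_rotation_deg screen limits.
#' @return A list: `pass`, `max_translation_mm`, `max_rotation_deg`.
#' @export
motion_screen <- function(motion, max_translation_mm = 1, max_rotation_deg = 1) {
    m <- unclass(motion)
    max_t <- max(abs(m[, 1:3]))
    max_r <- max(abs(m[, 4:6])) * 180 / pi
    list(pass = max_t < max_translation_mm && max_r < max_rotation_deg,
         max_translation_mm = max_t, max_rotation_deg = max_r)
}

#' Preprocess one subject
#'
#' Runs the fixed chain discard -> smooth -> nuisance regression (tissue
#' signals extracted from the smoothed series) -> band-pass, and computes the
#' framewise-displacement record on the analyzed (post-discard) volumes.
#'
#' @param subject list with `bold`, `motion`, `gm`, `wm`, `ventricle`,
#'   `brain` (as produced by [generate_subject()] or read from disk).
#' @param params a [pipeline_config()] (only its preprocessing fields are
#'   used).
#' @return A list: `residual` ([bold_series()]), `fd` (`fd_record`),
#'   `screen`, `nuisance`.
#' @export
preprocess_subject <- function(subject, params = pipeline_config()) {
    series <- discard_initial(subject$bold, params$n_discard)
    motion_an <- motion_trace(unclass(subject$motion)[
        (params$n_discard + 1):nrow(subject$motion), , drop = FALSE])
    smoothed <- smooth_gaussian(series, params$fwhm_mm)
    nuis <- build_nuisance_set(smoothed, motion_an, subject$ventricle,
                               subject$wm, subject$brain,
                               params$mask_thresholds)
    resid <- regress_nuisance(smoothed, nuis)
    filtered <- bandpass(resid, params$band_hz[1], params$band_hz[2])
    fd <- compute_fd(motion_an, params$head_radius_mm,
                     params$fd_threshold_mm, params$fd_max_count)
    list(residual = filtered, fd = fd,
         screen = motion_screen(subject$motion), nuisance = nuis)
}
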