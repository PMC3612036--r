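# Preprocessing chain: discard, smoothing, nuisance regression, band-pass,
# motion QC.

test_that("initial-volume discard keeps order and counts", {
    s <- noise_series(c(5, 5, 5), nt = 210)
    out <- discard_initial(s, 10)
    expect_equal(dim(out$data)[4], 200)
    expect_equal(out$data[, , , 1], s$data[, , , 11])
    expect_identical(discard_initial(s, 0), s)
    s5 <- noise_series(c(5, 5, 5), nt = 5)
    expect_error(discard_initial(s5, 10), "discard")
})

test_that("Gaussian smoothing matches a dense convolution oracle", {
    set.seed(1)
    vol <- array(rnorm(9 * 9 * 9), c(9, 9, 9))
    got <- smooth_gaussian(vol, fwhm_mm = 6, voxel_size_mm = 3)
    expect_equal(got, oracle_smooth(vol, 6, 3), tolerance = 1e-12)

    # impulse: discretized Gaussian, total mass conserved (interior impulse)
    imp <- array(0, c(11, 11, 11)); imp[6, 6, 6] <- 1
    sm <- smooth_gaussian(imp, 6, 3)
    expect_equal(sum(sm), 1, tolerance = 1e-6)
    expect_equal(sm, oracle_smooth(imp, 6, 3), tolerance = 1e-12)

    # constant volume unchanged in the interior (zero-padding affects only
    # voxels within one kernel radius, 4 sigma ~ 4 voxels, of an edge)
    cst <- array(2, c(13, 13, 13))
    smc <- smooth_gaussian(cst, 6, 3)
    expect_equal(smc[5:9, 5:9, 5:9], cst[5:9, 5:9, 5:9], tolerance = 1e-10)

    expect_identical(smooth_gaussian(vol, 0), vol)
    expect_error(smooth_gaussian(vol, -1), "nonnegative")
})

test_that("anisotropic voxels get per-axis sigmas (fwhm/2.3548/voxel)", {
    s <- vmhc:::fwhm_to_sigma(6, c(3, 2, 6))
    expect_equal(s, 6 / (2 * sqrt(2 * log(2))) / c(3, 2, 6))
    expect_equal(s[1], 0.8493, tolerance = 1e-4)
})

test_that("nuisance set extracts thresholded tissue means and a drift ramp", {
    s <- noise_series(c(5, 5, 5), nt = 30)
    motion <- motion_trace(matrix(rnorm(30 * 6, sd = 0.01), 30, 6))
    uni <- array(0.95, c(5, 5, 5))
    nuis <- build_nuisance_set(s, motion, ventricle = uni, white_matter = uni,
                               brain = uni)
    mat <- t(matrix(s$data, 125, 30))
    expect_equal(nuis$global_signal, rowMeans(mat))
    expect_equal(nuis$linear_drift, seq_len(30) - 15.5)
    # threshold semantics are strict >
    low <- array(0.6, c(5, 5, 5))
    expect_error(build_nuisance_set(s, motion, ventricle = low,
                                    white_matter = uni, brain = uni),
                 "ventricle mask is empty")
    # a pure ramp series has global signal correlating 1 with the drift
    ramp <- bold_series(array(rep(seq_len(30), each = 125), c(5, 5, 5, 30)),
                        3, 2)
    nr <- build_nuisance_set(ramp, motion, uni, uni, uni)
    expect_equal(cor(nr$global_signal, nr$linear_drift), 1)
})

test_that("nuisance regression equals the explicit normal-equations solve", {
    s <- noise_series(c(5, 5, 5), nt = 40, seed = 2)
    motion <- motion_trace(matrix(rnorm(40 * 6, sd = 0.05), 40, 6))
    tm <- tissue_maps(c(5, 5, 5))
    nuis <- build_nuisance_set(s, motion, tm$ventricle, tm$white_matter,
                               tm$brain)
    res <- regress_nuisance(s, nuis)
    X <- vmhc:::nuisance_design(nuis, 40)
    Y <- t(matrix(s$data, 125, 40))
    expect_equal(t(matrix(res$data, 125, 40)), oracle_residuals(Y, X),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # residuals orthogonal to every design column
    R <- t(matrix(res$data, 125, 40))
    dots <- abs(t(X) %*% R)
    norms <- outer(sqrt(colSums(X^2)), sqrt(pmax(colSums(R^2), 1e-30)))
    expect_lt(max(dots / pmax(norms, 1e-30)), 1e-6)
})

test_that("a voxel matching a nuisance signal is annihilated", {
    nt <- 40
    set.seed(12)
    motion <- motion_trace(matrix(rnorm(nt * 6, sd = 0.05), nt, 6))
    sig <- sin(seq_len(nt))
    s <- noise_series(c(3, 3, 3), nt = nt, seed = 13)
    s$data[1, 1, 1, ] <- sig    # the ventricle-mask voxel defines the signal
    s$data[2, 2, 2, ] <- sig    # a gray-matter voxel carrying the same series
    tm <- tissue_maps(c(3, 3, 3))
    nuis <- build_nuisance_set(s, motion, tm$ventricle, tm$white_matter,
                               tm$brain)
    expect_equal(nuis$ventricle_signal, sig)
    res <- regress_nuisance(s, nuis)
    expect_lt(max(abs(res$data[2, 2, 2, ])), 1e-10)
})

test_that("a rank-deficient nuisance design is rejected with names", {
    nt <- 30
    motion <- matrix(rnorm(nt * 6, sd = 0.05), nt, 6)
    motion[, 2] <- 2 * motion[, 1]   # collinear motion columns
    s <- noise_series(c(3, 3, 3), nt = nt)
    tm <- tissue_maps(c(3, 3, 3))
    nuis <- build_nuisance_set(s, motion_trace(motion), tm$ventricle,
                               tm$white_matter, tm$brain)
    expect_error(regress_nuisance(s, nuis), "collinear")
})

test_that("the ideal band-pass keeps in-band bins and kills out-of-band bins", {
    nt <- 200; tr <- 2
    t_sec <- (seq_len(nt) - 1) * tr
    mk <- function(f) bold_series(array(rep(sin(2 * pi * f * t_sec), each = 8),
                                        c(2, 2, 2, nt)), 3, tr)
    pass <- bandpass(mk(0.05), 0.01, 0.08)
    expect_gt(sd(pass$data[1, 1, 1, ]) / sd(mk(0.05)$data[1, 1, 1, ]), 0.99)
    stopp <- bandpass(mk(0.2), 0.01, 0.08)
    expect_lt(sqrt(mean(stopp$data^2)) / sqrt(mean(mk(0.2)$data^2)), 0.01)
    zero <- bold_series(array(0, c(2, 2, 2, nt)), 3, tr)
    expect_equal(bandpass(zero)$data, zero$data)
    # output is mean-free (zero frequency removed)
    shifted <- bandpass(mk(0.05), 0.01, 0.08)
    expect_lt(abs(mean(shifted$data[1, 1, 1, ])), 1e-12)
    expect_error(bandpass(mk(0.05), 0.01, 0.3), "Nyquist")
    expect_error(bandpass(mk(0.05), 0.08, 0.01), "below the high")
})

test_that("framewise displacement follows the 50 mm sphere formula", {
    zero <- motion_trace(matrix(0, 50, 6))
    fd0 <- compute_fd(zero)
    expect_equal(fd0$fd, rep(0, 50))
    expect_equal(fd0$mean_fd, 0)
    expect_false(fd0$excluded)

    m <- matrix(0, 10, 6); m[5:10, 1] <- 0.1      # one 0.1 mm step in tx
    expect_equal(compute_fd(motion_trace(m))$fd[5], 0.1)
    m2 <- matrix(0, 10, 6); m2[5:10, 4] <- 0.01   # one 0.01 rad step in rx
    expect_equal(compute_fd(motion_trace(m2))$fd[5], 0.5)
    # FD invariant to constant offsets
    m3 <- matrix(rnorm(60, sd = 0.05), 10, 6)
    expect_equal(compute_fd(motion_trace(m3))$fd,
                 compute_fd(motion_trace(sweep(m3, 2, c(1, -2, 3, 0.1, 0.2, -0.1), "+")))$fd)
    expect_error(compute_fd(motion_trace(matrix(0, 1, 6))), "at least two")
})

test_that("the FD exclusion rule triggers strictly above 35 volumes", {
    # alternating 0 / 0.6 mm translations: 2k volumes with FD > 0.5
    step_trace <- function(k) {
        tx <- rep(0, 120)
        tx[seq_len(2 * k)] <- rep(c(0, 0.6), k)
        motion_trace(cbind(tx, 0, 0, 0, 0, 0))
    }
    expect_false(compute_fd(step_trace(17))$excluded)  # 34 exceedances
    r35 <- compute_fd(step_trace(18))                  # 35 + 1 settle step
    expect_equal(r35$n_over_threshold, 36)
    expect_true(r35$excluded)
})

test_that("the gross-motion screen applies the 1 mm / 1 degree rule", {
    ok <- matrix(0, 10, 6); ok[5, 1] <- 0.9; ok[6, 5] <- 0.5 * pi / 180
    expect_true(motion_screen(motion_trace(ok))$pass)
    bad_t <- matrix(0, 10, 6); bad_t[3, 2] <- 1.2
    expect_false(motion_screen(motion_trace(bad_t))$pass)
    bad_r <- matrix(0, 10, 6); bad_r[3, 4] <- 0.0175  # 1.003 degrees
    res <- motion_screen(motion_trace(bad_r))
    expect_false(res$pass)
    expect_gt(res$max_rotation_deg, 1)
})

test_that("nuisance regression plus band-pass preserves engineered correlation", {
    cfg <- tiny_sim_config(seed = 17, n_volumes = 210, baseline_rho = 0.5,
                           effect_regions = list())
    rec <- generate_demographics(cfg)[1, ]
    sub <- generate_subject(cfg, rec, 55)
    params <- pipeline_config(sim = cfg, fwhm_mm = 0, seed = 1)
    pp <- preprocess_subject(sub, params)
    space <- build_symmetric_space(list(sub$gm), 0.2, 3)
    vm <- compute_vmhc(pp$residual, space)
    z <- vm$z[space$unilateral_mask]
    n_eff <- 2 * length(vmhc:::passband_bins(200, 2))
    se <- (1 / sqrt(n_eff - 3)) / sqrt(sum(space$unilateral_mask))
    expect_lt(abs(mean(z, na.rm = TRUE) - atanh(0.5)), 4 * se)
})
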