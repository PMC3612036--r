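# Synthetic cohort generator.

test_that("configuration validation rejects impossible settings", {
    expect_error(sim_config(grid_shape = c(14, 17, 15)), "odd")
    expect_error(tiny_sim_config(baseline_rho = 1), "\\[0, 1\\)")
    expect_error(tiny_sim_config(effect_regions = list(
        list(box = list(x = c(3, 6), y = c(6, 30), z = c(6, 10)),
             rho_patient = 0.2, rho_control = 0.6))), "exceeds the grid")
    expect_error(tiny_sim_config(effect_regions = list(
        list(box = list(x = c(3, 9), y = c(6, 10), z = c(6, 10)),
             rho_patient = 0.2, rho_control = 0.6))), "left hemisphere")
    expect_error(tiny_sim_config(effect_regions = list(
        tiny_effect_region(rho_patient = -0.1))), "\\[0, 1\\)")
})

test_that("the same seed reproduces a subject bit-exactly", {
    cfg <- tiny_sim_config(seed = 5)
    rec <- generate_demographics(cfg)[1, ]
    a <- generate_subject(cfg, rec, 42)
    b <- generate_subject(cfg, rec, 42)
    expect_identical(a$bold$data, b$bold$data)
    expect_identical(unclass(a$motion), unclass(b$motion))
    expect_identical(a$gm, b$gm)
    c <- generate_subject(cfg, rec, 43)
    expect_false(identical(a$bold$data, c$bold$data))
})

test_that("generated gray-matter maps equal their own mirror exactly", {
    cfg <- tiny_sim_config(seed = 3)
    rec <- generate_demographics(cfg)[1, ]
    sub <- generate_subject(cfg, rec, 11)
    expect_identical(sub$gm, mirror_volume(sub$gm))
    expect_identical(sub$brain, mirror_volume(sub$brain))
    expect_gt(min(sub$gm[sub$brain > 0.5]), 0)
})

# Mirrored-pair correlations measured on the band-passed analysis window,
# where the engineered correlation is exact.
pair_correlations <- function(cfg, sub) {
    series <- bandpass(discard_initial(sub$bold, cfg$n_discard))
    dim3 <- cfg$grid_shape
    mid <- (dim3[1] + 1) %/% 2
    brain <- sub$brain > 0.5
    idx <- which(brain)
    ijk <- arrayInd(idx, dim3)
    left <- idx[ijk[, 1] < mid]
    lijk <- ijk[ijk[, 1] < mid, , drop = FALSE]
    right <- (dim3[1] + 1 - lijk[, 1]) + dim3[1] * (lijk[, 2] - 1) +
        dim3[1] * dim3[2] * (lijk[, 3] - 1)
    mat <- t(matrix(series$data, prod(dim3), dim(series$data)[4]))
    vapply(seq_along(left), function(i) cor(mat[, left[i]], mat[, right[i]]),
           numeric(1))
}

test_that("rho = 0 everywhere gives near-zero mean pair correlation", {
    cfg <- tiny_sim_config(seed = 9, baseline_rho = 0,
                           effect_regions = list(), n_volumes = 110)
    rec <- generate_demographics(cfg)[1, ]
    sub <- generate_subject(cfg, rec, 21)
    r <- pair_correlations(cfg, sub)
    # 2 * n_passband_bins effective dof per correlation
    n_eff <- 2 * length(vmhc:::passband_bins(100, 2))
    se_mean <- (1 / sqrt(n_eff - 3)) / sqrt(length(r))
    expect_lt(abs(mean(r)), 3 * se_mean)
})

test_that("an engineered rho = 0.6 region recovers atanh(0.6) in Fisher z", {
    cfg <- sim_config(grid_shape = c(15, 17, 15), n_volumes = 210,
                      n_per_group = 2, baseline_rho = 0.3,
                      effect_regions = list(tiny_effect_region(0.6, 0.6)),
                      clinical_model = list(), seed = 13)
    rec <- generate_demographics(cfg)[1, ]
    sub <- generate_subject(cfg, rec, 77)
    r <- pair_correlations(cfg, sub)
    idx <- which(sub$brain > 0.5)
    ijk <- arrayInd(idx, cfg$grid_shape)
    left <- ijk[ijk[, 1] < 8, , drop = FALSE]
    b <- cfg$effect_regions[[1]]$box
    in_box <- left[, 1] >= b$x[1] & left[, 1] <= b$x[2] &
        left[, 2] >= b$y[1] & left[, 2] <= b$y[2] &
        left[, 3] >= b$z[1] & left[, 3] <= b$z[2]
    z <- atanh(r[in_box])
    n_eff <- 2 * length(vmhc:::passband_bins(200, 2))
    tol <- 3 * (1 / sqrt(n_eff - 3)) / sqrt(sum(in_box))
    expect_equal(mean(z), atanh(0.6), tolerance = tol / atanh(0.6))
    expect_lt(abs(mean(z) - atanh(0.6)), tol)
})

test_that("demographics tables have the study's shape and group structure", {
    cfg <- sim_config(n_per_group = 17, seed = 2)
    rec <- generate_demographics(cfg)
    expect_equal(nrow(rec), 34)
    expect_equal(sum(rec$group == "patient"), 17)
    expect_equal(table(rec$gender[rec$group == "patient"])[["male"]], 8)
    expect_equal(table(rec$gender[rec$group == "control"])[["male"]], 9)
    expect_true(all(is.na(rec$illness_duration[rec$group == "control"])))
    expect_true(all(!is.na(rec$illness_duration[rec$group == "patient"])))
    expect_true(all(rec$hdrs_total[rec$group == "patient"] >
                        rec$hdrs_total[rec$group == "control"] + 5))
})

test_that("patients get the reduced rho and clinical couplings stay in range", {
    cfg <- tiny_sim_config(seed = 4, n_per_group = 3)
    rec <- generate_demographics(cfg)
    pat <- generate_subject(cfg, rec[1, ], 1)
    con <- generate_subject(cfg, rec[4, ], 2)
    b <- cfg$effect_regions[[1]]$box
    expect_equal(unique(as.vector(
        pat$rho[b$x[1]:b$x[2], b$y[1]:b$y[2], b$z[1]:b$z[2]])), 0.2)
    expect_equal(unique(as.vector(
        con$rho[b$x[1]:b$x[2], b$y[1]:b$y[2], b$z[1]:b$z[2]])), 0.6)
    # an absurd slope is clipped with a warning, never leaves [0, 1)
    cfg2 <- tiny_sim_config(seed = 4, n_per_group = 3, clinical_model = list(
        list(box = list(x = c(3, 6), y = c(12, 14), z = c(6, 10)),
             score = "cognitive_disturbance", slope = -5, noise_sd = 0)))
    expect_warning(sub <- generate_subject(cfg2, generate_demographics(cfg2)[1, ], 3),
                   "clipped")
    expect_true(all(sub$rho >= 0 & sub$rho < 1))
})

test_that("cohorts written to disk round-trip through the readers", {
    dir <- withr::local_tempdir()
    cfg <- tiny_sim_config(seed = 6, n_per_group = 2)
    res <- generate_cohort(cfg, dir)
    expect_true(file.exists(file.path(dir, "metadata.csv")))
    expect_true(file.exists(file.path(dir, "manifest.json")))
    expect_equal(nrow(read_cohort(dir)$records), 4)
    sub_disk <- vmhc:::read_cohort_subject(dir, "sub-001")
    sub_mem <- generate_subject(cfg, res$records[1, ],
                                vmhc:::subject_seed(cfg, 1))
    expect_equal(sub_disk$bold$data, sub_mem$bold$data, tolerance = 1e-12)
    expect_equal(unclass(sub_disk$motion), unclass(sub_mem$motion),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # same seed twice -> identical manifest
    dir2 <- withr::local_tempdir()
    generate_cohort(cfg, dir2)
    expect_identical(readLines(file.path(dir, "manifest.json")),
                     readLines(file.path(dir2, "manifest.json")))
})
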