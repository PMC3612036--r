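# Cluster labeling, Monte-Carlo null simulation and cluster-extent
# correction.

test_that("labeling handles singletons, corner contacts and empty maps", {
    m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
    res <- label_clusters(m, 6)
    expect_equal(res$sizes, 1L)

    corner <- array(FALSE, c(5, 5, 5))
    corner[2, 2, 2] <- TRUE; corner[3, 3, 3] <- TRUE   # share only a corner
    expect_equal(length(label_clusters(corner, 6)$sizes), 2)
    expect_equal(length(label_clusters(corner, 18)$sizes), 2)
    expect_equal(length(label_clusters(corner, 26)$sizes), 1)
    edge <- array(FALSE, c(5, 5, 5))
    edge[2, 2, 2] <- TRUE; edge[3, 3, 2] <- TRUE       # share an edge
    expect_equal(length(label_clusters(edge, 6)$sizes), 2)
    expect_equal(length(label_clusters(edge, 18)$sizes), 1)

    empty <- array(FALSE, c(4, 4, 4))
    expect_equal(length(label_clusters(empty, 6)$sizes), 0)
    expect_error(label_clusters(m, 10), "connectivity")
})

test_that("labeling agrees with a brute-force flood fill on random maps", {
    set.seed(11)
    for (i in 1:3) {
        m <- array(runif(1000) < 0.25, c(10, 10, 10))
        for (conn in c(6, 18, 26)) {
            got <- label_clusters(m, conn)
            ref <- oracle_label(m, conn)
            expect_identical(component_signature(got$labels),
                             component_signature(ref))
            expect_equal(sort(got$sizes),
                         sort(as.integer(table(ref[ref > 0]))))
        }
    }
})

test_that("unsmoothed null fields reach threshold at the nominal voxel rate", {
    mask <- array(TRUE, c(5, 5, 5))
    null <- simulate_cluster_null(mask, voxel_p = 0.01, fwhm_mm = 0,
                                  n_iterations = 600, seed = 21)
    # P(any of 125 iid voxels suprathreshold) = 1 - 0.99^125 = 0.715
    frac_any <- mean(null >= 1)
    p_any <- 1 - 0.99^125
    ci <- qnorm(0.999) * sqrt(p_any * (1 - p_any) / 600)
    expect_lt(abs(frac_any - p_any), ci)
    # determinism
    null2 <- simulate_cluster_null(mask, voxel_p = 0.01, fwhm_mm = 0,
                                   n_iterations = 600, seed = 21)
    expect_identical(as.integer(null), as.integer(null2))
})

test_that("smoothing makes null maximum clusters stochastically larger", {
    mask <- array(TRUE, c(12, 12, 12))
    null0 <- simulate_cluster_null(mask, fwhm_mm = 0, n_iterations = 300,
                                   seed = 5)
    null6 <- simulate_cluster_null(mask, fwhm_mm = 6, n_iterations = 300,
                                   seed = 5)
    expect_gt(mean(null6), mean(null0))
    w <- wilcox.test(as.integer(null6), as.integer(null0),
                     alternative = "greater", exact = FALSE)
    expect_lt(w$p.value, 1e-6)
})

test_that("the cluster-size threshold is the smallest alpha-controlling k", {
    nd <- structure(sort(c(rep(0L, 900), rep(3L, 60), rep(8L, 40))),
                    spec = list(voxel_size_mm = 3))
    # P(max >= 4) = 40/1000 <= 0.05 but P(max >= 1) = 0.1
    thr <- cluster_size_threshold(nd, 0.05)
    expect_equal(thr$k_voxels, 4L)
    expect_equal(thr$size_mm3, 4 * 27)
    all0 <- structure(rep(0L, 500), spec = list(voxel_size_mm = 3))
    expect_equal(cluster_size_threshold(all0, 0.05)$k_voxels, 1L)
    expect_equal(cluster_size_threshold(nd, 1)$k_voxels, 1L)
    # monotone: non-increasing threshold as alpha grows
    ks <- vapply(c(0.01, 0.05, 0.2, 0.5),
                 function(a) cluster_size_threshold(nd, a)$k_voxels, integer(1))
    expect_true(all(diff(ks) <= 0))
})

fake_stat <- function(zmap, space) {
    structure(list(z_map = zmap, t_map = zmap, df = 30, kind = "group_t",
                   voxels = which(space$unilateral_mask), space = space),
              class = "stat_result")
}

test_that("cluster correction reports sizes in exact voxel multiples of mm^3", {
    gm <- array(0.6, c(11, 9, 9))
    space <- build_symmetric_space(list(gm), 0.2, 3)
    zmap <- array(0, space$dim)
    blob <- expand.grid(x = 2:4, y = 3:5, z = 3:5)          # 27 voxels
    zmap[as.matrix(blob)] <- -4
    zmap[2, 7, 7] <- -4                                      # singleton
    zmap[4, 7, 7] <- 4.5                                     # positive peak
    res <- apply_cluster_correction(fake_stat(zmap, space), voxel_p = 0.01,
                                    min_size_voxels = 2, space = space)
    expect_equal(nrow(res), 1)                               # blob survives
    expect_equal(res$size_voxels, 27)
    expect_equal(res$size_mm3, 27 * 27)
    expect_equal(res$sign, "negative")
    expect_true(all(res$size_mm3 %% 27 == 0))
    # 30 voxels at 3 mm isotropic -> 810 mm^3
    zmap2 <- array(0, space$dim)
    blob2 <- expand.grid(x = 2:4, y = 2:6, z = 2:3)          # 30 voxels
    zmap2[as.matrix(blob2)] <- 3.5
    res2 <- apply_cluster_correction(fake_stat(zmap2, space), 0.01, 30, space)
    expect_equal(res2$size_mm3, 810)
    # peak coordinate: world x of the peak is negative (left hemisphere)
    expect_lt(res2$peak_x_mm, 0)
    # nothing suprathreshold -> empty table
    res3 <- apply_cluster_correction(fake_stat(array(0, space$dim), space),
                                     0.01, 1, space)
    expect_equal(nrow(res3), 0)
})

test_that("positive and negative clusters are never merged", {
    gm <- array(0.6, c(9, 7, 7))
    space <- build_symmetric_space(list(gm), 0.2, 3)
    zmap <- array(0, space$dim)
    zmap[2:3, 3, 3] <- 4
    zmap[4, 3, 3] <- -4    # adjacent to the positive pair
    res <- apply_cluster_correction(fake_stat(zmap, space), 0.01, 1, space)
    expect_equal(nrow(res), 2)
    expect_setequal(res$sign, c("positive", "negative"))
    expect_equal(sort(res$size_voxels), c(1, 2))
})

test_that("cluster_mask rebuilds the voxel set of a reported cluster", {
    gm <- array(0.6, c(11, 9, 9))
    space <- build_symmetric_space(list(gm), 0.2, 3)
    zmap <- array(0, space$dim)
    blob <- expand.grid(x = 2:4, y = 3:5, z = 3:5)
    zmap[as.matrix(blob)] <- -4
    stat <- fake_stat(zmap, space)
    tab <- apply_cluster_correction(stat, 0.01, 1, space)
    cm <- cluster_mask(stat, tab[1, ], 0.01, space)
    expect_equal(sum(cm), tab$size_voxels[1])
    expect_true(all(zmap[cm] == -4))
})
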