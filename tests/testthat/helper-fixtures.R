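# Shared fixtures and independent brute-force oracles.

# Small study conditions used by most unit tests (kept fast; acceptance tests
# use the full-scale conditions).
tiny_sim_config <- function(seed = 1L, n_per_group = 3L, n_volumes = 60L,
                            effect_regions = list(tiny_effect_region()),
                            clinical_model = list(), ...) {
    sim_config(grid_shape = c(15L, 17L, 15L), n_volumes = n_volumes,
               n_per_group = n_per_group, effect_regions = effect_regions,
               clinical_model = clinical_model, seed = seed, ...)
}

tiny_effect_region <- function(rho_patient = 0.2, rho_control = 0.6) {
    list(box = list(x = c(3L, 6L), y = c(6L, 11L), z = c(6L, 10L)),
         rho_patient = rho_patient, rho_control = rho_control)
}

# A deterministic bold_series from white noise.
noise_series <- function(dim3 = c(7, 7, 7), nt = 40, tr_s = 2, seed = 1) {
    set.seed(seed)
    bold_series(array(rnorm(prod(dim3) * nt), dim = c(dim3, nt)),
                voxel_size_mm = 3, tr_s = tr_s, subject_id = "test")
}

# Oracle: dense separable Gaussian convolution with zero padding, written
# independently of the package's compiled implementation.
oracle_smooth <- function(vol, fwhm_mm, voxel_size_mm = 3) {
    sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / rep(voxel_size_mm, 3)
    out <- vol
    for (axis in 1:3) {
        s <- sigma[axis]
        r <- ceiling(4 * s)
        k <- exp(-0.5 * (-r:r)^2 / s^2)
        k <- k / sum(k)
        nxt <- array(0, dim(out))
        n <- dim(out)[axis]
        for (d in -r:r) {
            src <- seq_len(n) + d
            ok <- src >= 1 & src <= n
            idx_to <- which(ok)
            idx_from <- src[ok]
            if (axis == 1) nxt[idx_to, , ] <- nxt[idx_to, , ] +
                    k[d + r + 1] * out[idx_from, , ]
            if (axis == 2) nxt[, idx_to, ] <- nxt[, idx_to, ] +
                    k[d + r + 1] * out[, idx_from, ]
            if (axis == 3) nxt[, , idx_to] <- nxt[, , idx_to] +
                    k[d + r + 1] * out[, , idx_from]
        }
        out <- nxt
    }
    out
}

# Oracle: connected components by plain flood fill over an explicit
# neighbour list.
oracle_label <- function(mask, connectivity) {
    dim3 <- dim(mask)
    offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    m <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
    offs <- offs[m > 0 & m <= switch(as.character(connectivity),
                                     "6" = 1, "18" = 2, "26" = 3), ]
    labels <- array(0L, dim3)
    nxt <- 0L
    for (idx in which(mask)) {
        if (labels[idx] != 0L) next
        nxt <- nxt + 1L
        frontier <- idx
        labels[idx] <- nxt
        while (length(frontier)) {
            cur <- frontier[1]
            frontier <- frontier[-1]
            z <- (cur - 1) %/% (dim3[1] * dim3[2]) + 1
            rem <- (cur - 1) %% (dim3[1] * dim3[2])
            y <- rem %/% dim3[1] + 1
            x <- rem %% dim3[1] + 1
            for (r in seq_len(nrow(offs))) {
                xx <- x + offs$dx[r]; yy <- y + offs$dy[r]; zz <- z + offs$dz[r]
                if (xx < 1 || xx > dim3[1] || yy < 1 || yy > dim3[2] ||
                    zz < 1 || zz > dim3[3]) next
                nb <- xx + dim3[1] * (yy - 1) + dim3[1] * dim3[2] * (zz - 1)
                if (mask[nb] && labels[nb] == 0L) {
                    labels[nb] <- nxt
                    frontier <- c(frontier, nb)
                }
            }
        }
    }
    labels
}

# Oracle: chi-squared from explicit expected-count loops.
oracle_chi2 <- function(tab) {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - E)^2 / E)
}

# Oracle: OLS residuals through the explicit normal equations.
oracle_residuals <- function(Y, X) {
    Y - X %*% solve(t(X) %*% X, t(X) %*% Y)
}

# Distinct tissue probability maps on a common grid (so the extracted
# tissue signals are not collinear).
tissue_maps <- function(dim3) {
    vent <- array(0, dim3); vent[1, 1, 1] <- 0.9
    wm <- array(0, dim3); wm[dim3[1], dim3[2], dim3[3]] <- 0.95
    wm[1, dim3[2], 1] <- 0.95
    brain <- array(0.95, dim3)
    list(ventricle = vent, white_matter = wm, brain = brain)
}

# Canonical component signature invariant to label permutation: sorted list
# of sorted voxel-index sets.
component_signature <- function(labels) {
    sets <- split(which(labels > 0), labels[labels > 0])
    sets <- lapply(sets, sort)
    unname(sets[order(vapply(sets, min, numeric(1)))])
}
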