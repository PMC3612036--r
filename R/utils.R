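# Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Derive a bounded per-subject seed from a cohort seed.
derive_seed <- function(seed, i) {
    as.integer((as.numeric(seed) + 1009 * as.numeric(i)) %% 2147483646) + 1L
}

# Voxel (1-based) -> world mm coordinate with the midline plane at x = 0 and
# the grid centre at the origin of the other two axes.
voxel_to_world <- function(ijk, dim3, voxel_size_mm) {
    centre <- (dim3 + 1) / 2
    sweep(rbind(ijk), 2, centre, "-") * rep(voxel_size_mm, length.out = 3)[col(rbind(ijk))]
}

# linear index -> (i,j,k) for a 3-D grid
index_to_ijk <- function(idx, dim3) {
    idx0 <- idx - 1L
    i <- idx0 %% dim3[1]
    j <- (idx0 %/% dim3[1]) %% dim3[2]
    k <- idx0 %/% (dim3[1] * dim3[2])
    cbind(i + 1L, j + 1L, k + 1L)
}
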