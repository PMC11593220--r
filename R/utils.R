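# Internal helpers shared across modules.

# Sum of a numeric/logical matrix over non-overlapping patch_px x patch_px
# tiles, trimming any remainder at the right/bottom edge. Returns a
# (pr x pc) matrix of tile sums.
patch_block_sums <- function(m, patch_px) {
    pr <- nrow(m) %/% patch_px
    pc <- ncol(m) %/% patch_px
    stopifnot(pr >= 1L, pc >= 1L)
    m <- m[seq_len(pr * patch_px), seq_len(pc * patch_px), drop = FALSE]
    s <- rowsum(m * 1, rep(seq_len(pr), each = patch_px))
    t(rowsum(t(s), rep(seq_len(pc), each = patch_px)))
}

# Expand a patch-level matrix to pixel level by repeating each entry in a
# patch_px x patch_px block.
expand_patches <- function(pm, patch_px) {
    pm[rep(seq_len(nrow(pm)), each = patch_px),
       rep(seq_len(ncol(pm)), each = patch_px), drop = FALSE]
}

# Deterministic per-patient / per-purpose sub-seed below 2^31.
derive_seed <- function(seed, index, salt = 0L) {
    as.integer((as.numeric(seed) %% 65011 * 20011 +
                as.numeric(index) * 7919 +
                as.numeric(salt) * 104729 + 17) %% 2147483587)
}

# Binary dilation of a logical matrix by `k` pixels in the 4-neighbour
# sense (used only for the cheap boundary band in the simulator).
dilate4 <- function(m, k = 1L) {
    for (i in seq_len(k)) {
        up <- rbind(m[-1L, , drop = FALSE], FALSE)
        dn <- rbind(FALSE, m[-nrow(m), , drop = FALSE])
        lf <- cbind(m[, -1L, drop = FALSE], FALSE)
        rt <- cbind(FALSE, m[, -ncol(m), drop = FALSE])
        m <- m | up | dn | lf | rt
    }
    m
}

# Content hash of an arbitrary R object (used for the run manifest).
object_hash <- function(x) {
    f <- tempfile()
    on.exit(unlink(f))
    saveRDS(x, f, version = 2, compress = FALSE)
    unname(tools::md5sum(f))
}
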