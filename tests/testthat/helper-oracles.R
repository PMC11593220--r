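# Independent oracles used across the suite. These deliberately share no
# code with the package implementation.

# Brute-force co-occurrence matrix: loop over every cell and every one of
# the 8 neighbour offsets, count ordered pairs, halve, normalize.
brute_cm <- function(m, distance = 1L) {
    lv <- sort(unique(as.vector(m[!is.na(m)])))
    L <- length(lv)
    counts <- matrix(0, L, L, dimnames = list(lv, lv))
    offs <- expand.grid(dr = c(-distance, 0L, distance),
                        dc = c(-distance, 0L, distance))
    offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
    for (r in seq_len(nrow(m))) for (c in seq_len(ncol(m))) {
        a <- m[r, c]
        if (is.na(a)) next
        for (k in seq_len(nrow(offs))) {
            r2 <- r + offs$dr[k]; c2 <- c + offs$dc[k]
            if (r2 < 1 || r2 > nrow(m) || c2 < 1 || c2 > ncol(m)) next
            b <- m[r2, c2]
            if (is.na(b)) next
            counts[as.character(a), as.character(b)] <-
                counts[as.character(a), as.character(b)] + 1
        }
    }
    counts <- counts / 2
    counts / sum(counts)
}

# Direct product-limit computation over risk sets.
brute_km <- function(time, event) {
    tt <- sort(unique(time[event == 1]))
    s <- 1
    out <- numeric(length(tt))
    for (i in seq_along(tt)) {
        n_risk <- sum(time >= tt[i])
        d <- sum(time == tt[i] & event == 1)
        s <- s * (1 - d / n_risk)
        out[i] <- s
    }
    list(time = tt, surv = out)
}

# Hand log-rank: sum of (O - E) over pooled risk sets, squared over the
# hypergeometric variance.
hand_logrank <- function(time, event, group) {
    g1 <- group == levels(factor(group))[1L]
    tt <- sort(unique(time[event == 1]))
    OE <- V <- 0
    for (t in tt) {
        at <- time >= t
        n <- sum(at); n1 <- sum(at & g1)
        d <- sum(time == t & event == 1)
        d1 <- sum(time == t & event == 1 & g1)
        OE <- OE + d1 - d * n1 / n
        if (n > 1)
            V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    OE^2 / V
}

# Small synthetic parameter sets (6x6 patch maps) keep unit tests fast.
small_params <- function(...) {
    args <- list(...)
    defaults <- list(n_patients = 2L, map_side_px = 186L, seed = 1L)
    do.call(syntheticParams, utils::modifyList(defaults, args))
}

# A tiny hand-built LayerStack: `nlayer` uniform-TRUE layers on a
# square grid of `npatch` x `npatch` patches of `patch_px` pixels.
toy_stack <- function(npatch = 4L, patch_px = 4L, layers = NULL,
                      dcis = NULL) {
    side <- npatch * patch_px
    if (is.null(layers))
        layers <- list(layer_a = matrix(TRUE, side, side))
    if (is.null(dcis)) dcis <- matrix(FALSE, side, side)
    new("LayerStack", layers = layers, dcis_mask = dcis,
        tissue_mask = matrix(TRUE, side, side),
        pixel_size_um = 1, patch_side_um = patch_px)
}
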