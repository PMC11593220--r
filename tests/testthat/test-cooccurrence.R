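test_that("a single horizontal pair gives p(1,2) = p(2,1) = 0.5", {
    cm <- buildCoocMatrix(matrix(c(1L, 2L), 1, 2))
    expect_equal(coocProb(cm), matrix(c(0, 0.5, 0.5, 0), 2, 2))
})

test_that("a constant map concentrates all mass on the diagonal", {
    cm <- buildCoocMatrix(matrix(2L, 5, 7))
    expect_equal(coocProb(cm), matrix(1, 1, 1))
    st <- textureStats(cm)
    expect_equal(st[["contrast"]], 0)
    expect_equal(st[["homogeneity"]], 1)
    expect_equal(st[["heterogeneity"]], 0)
    expect_equal(st[["uniformity"]], 1)
    expect_equal(st[["entropy"]], 0)
    expect_equal(attr(st, "degenerate"), "correlation")
})

test_that("build_cm equals brute-force pair enumeration on small maps", {
    set.seed(101)
    for (nr in 2:5) for (nc in 2:5) for (rep in 1:3) {
        L <- sample(2:3, 1)
        m <- matrix(sample.int(L, nr * nc, replace = TRUE), nr, nc)
        if (length(unique(as.vector(m))) < 1) next
        cm <- buildCoocMatrix(m)
        expect_equal(unname(coocProb(cm)), unname(brute_cm(m)),
                     tolerance = 1e-12,
                     info = sprintf("map %dx%d rep %d", nr, nc, rep))
    }
})

test_that("brute-force equivalence holds with invalid (NA) patches", {
    set.seed(202)
    for (rep in 1:10) {
        m <- matrix(sample.int(3L, 25, replace = TRUE), 5, 5)
        m[sample(25, 6)] <- NA
        if (sum(!is.na(m)) < 4) next
        cm <- buildCoocMatrix(m)
        expect_equal(unname(coocProb(cm)), unname(brute_cm(m)),
                     tolerance = 1e-12)
    }
})

test_that("CM is always a symmetric probability distribution", {
    set.seed(303)
    for (rep in 1:25) {
        nr <- sample(2:12, 1); nc <- sample(2:12, 1)
        m <- matrix(sample.int(4L, nr * nc, replace = TRUE), nr, nc)
        p <- coocProb(buildCoocMatrix(m))
        expect_equal(sum(p), 1, tolerance = 1e-12)
        expect_equal(p, t(p), tolerance = 1e-12)
        expect_true(all(p >= 0))
    }
})

test_that("a single valid patch yields an undefined-CM error", {
    m <- matrix(NA_integer_, 3, 3); m[2, 2] <- 1L
    expect_error(buildCoocMatrix(m), "undefined")
})

test_that("checkerboard statistics match the hand-enumerated CM", {
    m <- (outer(1:4, 1:4, `+`) %% 2L) + 1L      # 4x4 checkerboard
    st <- textureStats(buildCoocMatrix(m))
    # 24 of the 42 unordered neighbour pairs cross levels (all 12
    # horizontal + 12 vertical), 18 diagonal pairs are same-level
    expect_equal(st[["contrast"]], 24 / 42)
    expect_equal(st[["dissimilarity"]], 24 / 42)
    expect_equal(st[["homogeneity"]], 18 / 42 + (24 / 42) / 2)
})

test_that("uniform 2-level CM has uniformity 0.25 and 2 bits of entropy", {
    cm <- new("CoocMatrix", p = matrix(0.25, 2, 2), levels = c(1, 2),
              distance = 1L, directions = 8L)
    st <- textureStats(cm)
    expect_equal(st[["uniformity"]], 0.25)
    expect_equal(st[["energy"]], 0.5)
    expect_equal(st[["entropy"]], 2)
})

test_that("texture statistics respect their analytic bounds", {
    set.seed(404)
    for (rep in 1:25) {
        m <- matrix(sample.int(sample(2:4, 1), 64, replace = TRUE), 8, 8)
        st <- textureStats(buildCoocMatrix(m))
        expect_gte(st[["homogeneity"]], 0); expect_lte(st[["homogeneity"]], 1)
        expect_gte(st[["uniformity"]], 0); expect_lte(st[["uniformity"]], 1)
        expect_gte(st[["contrast"]], 0)
        expect_gte(st[["dissimilarity"]], 0)
        expect_gte(st[["entropy"]], 0)
        expect_equal(st[["heterogeneity"]] + st[["homogeneity"]], 1)
        expect_equal(st[["energy"]], sqrt(st[["uniformity"]]))
        expect_gte(st[["correlation"]], -1 - 1e-12)
        expect_lte(st[["correlation"]], 1 + 1e-12)
    }
})

test_that("shuffling a clustered map never decreases expected contrast", {
    base <- matrix(rep(1:3, each = 27), 9, 9)   # three contiguous bands
    c0 <- textureStats(buildCoocMatrix(base))[["contrast"]]
    set.seed(505)
    shuffled <- replicate(50, {
        m <- matrix(sample(as.vector(base)), 9, 9)
        textureStats(buildCoocMatrix(m))[["contrast"]]
    })
    expect_gte(mean(shuffled), c0)
})

test_that("colocalization endpoints and arithmetic", {
    expect_equal(as.numeric(colocalization(c(0.5, 0, 0.3), c(0, 0.4, 0))), 0)
    v <- c(0.2, 0.7, 0.1)
    expect_equal(as.numeric(colocalization(v, v)), 1)
    expect_equal(as.numeric(colocalization(c(0.2, 0.4), c(0.4, 0.2))), 0.5)
    expect_error(colocalization(c(0.1), c(0.1, 0.2)), "equal length")
    both0 <- colocalization(c(0, 0), c(0, 0))
    expect_equal(as.numeric(both0), 0)
    expect_true(attr(both0, "missing"))
})

test_that("colocalization stays within [0, 1] on random vectors", {
    set.seed(606)
    for (rep in 1:20) {
        a <- runif(30); b <- runif(30)
        v <- as.numeric(colocalization(a, b))
        expect_gte(v, 0); expect_lte(v, 1)
    }
})

test_that("default catalogue emits 162 aligned features", {
    cat162 <- defaultCatalogue()
    expect_equal(nrow(catalogueDefs(cat162)), 162L)
    p <- small_params(seed = 13L)
    sim <- simulateLayerStack(p, 1)
    fv <- computeFeatures(patchify(excludeDCIS(sim$stack)))
    expect_length(fv, 162L)
    expect_identical(names(fv), catalogueDefs(cat162)$name)
})

test_that("a fully homogeneous stack sits at the heterogeneity floor", {
    p <- small_params(theta_dist = c(1e-12, 1), dcis_frac = 0, seed = 17L)
    sim <- simulateLayerStack(p, 1)
    fv <- computeFeatures(patchify(sim$stack))
    # constant layers (region covers everything -> tissue constant) give
    # contrast 0 / heterogeneity 0 wherever the presence map is constant
    het <- fv[grep("__heterogeneity$", names(fv))]
    expect_true(all(het[!is.na(het)] >= 0))
    # the dominant region layer of the segregated map is near-constant
    expect_lt(fv[["region_tumor__heterogeneity"]], 0.25)
    # band layouts confine cross-level pairs to the band boundaries; an
    # i.i.d. presence map at p = 0.5 would sit near 2 p (1 - p) = 0.5
    expect_lt(fv[["grade_g2__contrast"]], 0.4)
})

test_that("mixing strictly increases contrast features (paired seeds)", {
    diffs <- matrix(NA_real_, 20, 18)
    for (s in 1:20) {
        p0 <- small_params(theta_dist = c(1e-12, 1), dcis_frac = 0,
                           map_side_px = 372L, seed = 100L + s)
        p1 <- small_params(theta_dist = c(1, 1e-12), dcis_frac = 0,
                           map_side_px = 372L, seed = 100L + s)
        f0 <- computeFeatures(patchify(simulateLayerStack(p0, 1)$stack))
        f1 <- computeFeatures(patchify(simulateLayerStack(p1, 1)$stack))
        ctr <- grep("__contrast$", names(f0))
        diffs[s, ] <- f1[ctr] - f0[ctr]
    }
    # every contrast feature increases on average under full mixing
    expect_true(all(colMeans(diffs) > 0))
    # and strictly per pair for the dense (non-sparse-nuclei) layers
    dense <- c(1:4, 9:18)
    expect_true(all(diffs[, dense] > 0))
})

test_that("catalogue YAML round-trips", {
    f <- tempfile(fileext = ".yaml")
    cat162 <- defaultCatalogue()
    writeCatalogue(cat162, f)
    back <- readCatalogue(f)
    expect_equal(catalogueDefs(back), catalogueDefs(cat162))
})
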