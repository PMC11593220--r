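# Helper: wrap a plain matrix + cohort in an ITHExperiment.
make_exp <- function(m, cohort = NULL, scaled = FALSE) {
    x <- buildFeatureMatrix(m, cohort = cohort)
    if (scaled) S4Vectors::metadata(x)$scaled <- TRUE
    x
}

test_that("min-max scaling maps (2, 4, 6) to (0, 50, 100)", {
    m <- matrix(c(2, 4, 6), 1, 3,
                dimnames = list("f", sprintf("P%d", 1:3)))
    expect_equal(unname(scaleFeatures(m)[1, ]), c(0, 50, 100))
})

test_that("constant features are dropped with a warning", {
    m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
    colnames(m) <- sprintf("P%d", 1:3)
    x <- make_exp(m)
    expect_warning(xs <- scaleFeatures(x), "constant")
    expect_equal(rownames(xs), "a")
    expect_identical(S4Vectors::metadata(xs)$dropped, "b")
})

test_that("scaled features span exactly [0, 100] per retained feature", {
    set.seed(21)
    m <- matrix(rnorm(50 * 20), 50, 20,
                dimnames = list(sprintf("f%02d", 1:50),
                                sprintf("P%02d", 1:20)))
    s <- scaleFeatures(m)
    expect_equal(unname(apply(s, 1, min)), rep(0, 50))
    expect_equal(unname(apply(s, 1, max)), rep(100, 50))
})

test_that("family score is the pairwise-complete mean of member features", {
    co <- generateCohort(small_params(n_patients = 4L, seed = 23L))
    x <- buildFeatureMatrix(co$stacks, cohort = co$cohort)
    xs <- suppressWarnings(scaleFeatures(x))
    fam <- SummarizedExperiment::rowData(xs)$family
    v <- featureValues(xs)
    for (f in c("differentiation", "stroma", "TILs")) {
        manual <- colMeans(v[fam == f, , drop = FALSE], na.rm = TRUE)
        expect_equal(familyScore(xs, f), manual)
        expect_true(all(familyScore(xs, f) >= 0 &
                        familyScore(xs, f) <= 100, na.rm = TRUE))
    }
})

test_that("family score trivial cases: mean of two members, zero floor", {
    m <- rbind(a = c(40, 0), b = c(60, 0))
    colnames(m) <- c("P1", "P2")
    x <- make_exp(m, scaled = TRUE)
    SummarizedExperiment::rowData(x)$family <- c("TILs", "TILs")
    expect_equal(unname(familyScore(x, "TILs")), c(50, 0))
})

test_that("unscaled input to familyScore is refused", {
    m <- rbind(a = c(1, 2))
    colnames(m) <- c("P1", "P2")
    expect_error(familyScore(make_exp(m), "TILs"), "scale")
})

test_that("screening keeps ~alpha of pure-noise features under the null", {
    p <- syntheticParams(n_patients = 500L, log_hr_per_theta = 0,
                         seed = 21L)
    th <- withr::with_seed(50L, rbeta(500, 1.5, 1.5))
    co <- simulateSurvival(th, p)
    noise <- withr::with_seed(51L, matrix(
        rnorm(200 * 500), 200, 500,
        dimnames = list(sprintf("n%03d", 1:200), co$patient_id)))
    x <- make_exp(noise, cohort = co)
    scr <- screenFeatures(x, alpha = 0.05)
    rate <- length(scr) / 200
    # binomial(200, 0.05): central 99.9% region
    expect_gte(rate, 0.005)
    expect_lte(rate, 0.105)
})

test_that("a feature carrying the true log-risk is retained", {
    p <- syntheticParams(n_patients = 500L, log_hr_per_theta = 1.5,
                         seed = 33L)
    th <- withr::with_seed(60L, rbeta(500, 1.5, 1.5))
    co <- simulateSurvival(th, p)
    m <- matrix(th * 100, 1, 500,
                dimnames = list("signal", co$patient_id))
    scr <- screenFeatures(make_exp(m, cohort = co), alpha = 0.05)
    expect_identical(as.character(scr), "signal")
})

test_that("screening a cohort without events errors", {
    co <- data.frame(patient_id = c("P1", "P2"), time_months = c(5, 6),
                     event = c(0, 0), theta = c(0.1, 0.2))
    m <- matrix(rnorm(4), 2, 2,
                dimnames = list(c("a", "b"), co$patient_id))
    expect_error(screenFeatures(make_exp(m, cohort = co)), "event")
})

test_that("the ITH model recovers a planted effect on its single feature", {
    p <- syntheticParams(n_patients = 1000L, log_hr_per_theta = 1,
                         seed = 11L)
    th <- withr::with_seed(99L, rbeta(1000, 1.5, 1.5))
    co <- simulateSurvival(th, p)
    m <- matrix(th, 1, 1000, dimnames = list("theta_copy", co$patient_id))
    x <- make_exp(m, cohort = co, scaled = TRUE)
    fit <- fitITHModel(x, "theta_copy")
    expect_lt(abs(fit@betas[["theta_copy"]] - 1), 0.15)
    sc <- ithScore(fit, x)
    expect_equal(unname(sc), unname(fit@intercept +
                                    fit@betas[["theta_copy"]] * th))
})

test_that("an all-zero-beta model scores every patient at the intercept", {
    m <- matrix(runif(20), 2, 10,
                dimnames = list(c("a", "b"), sprintf("P%02d", 1:10)))
    model <- new("ITHModel", features = c("a", "b"),
                 betas = c(a = 0, b = 0), intercept = 3.5,
                 cutoff = NA_real_, alpha = 0.05,
                 medians = c(a = 0.5, b = 0.5), diagnostics = list())
    expect_equal(unname(ithScore(model, m)), rep(3.5, 10))
})

test_that("the score is exactly affine in each feature", {
    set.seed(77)
    m <- matrix(runif(30), 3, 10,
                dimnames = list(c("a", "b", "c"), sprintf("P%02d", 1:10)))
    betas <- c(a = 0.4, b = -1.2, c = 2.0)
    model <- new("ITHModel", features = names(betas), betas = betas,
                 intercept = 1, cutoff = NA_real_, alpha = 0.05,
                 medians = c(a = 0, b = 0, c = 0), diagnostics = list())
    s0 <- ithScore(model, m)
    for (f in names(betas)) {
        m2 <- m
        m2[f, ] <- m2[f, ] + 10
        expect_equal(ithScore(model, m2), s0 + betas[[f]] * 10)
    }
})

test_that("perfectly collinear screened features are pruned, fit converges", {
    p <- syntheticParams(n_patients = 300L, log_hr_per_theta = 1.5,
                         seed = 44L)
    th <- withr::with_seed(70L, rbeta(300, 1.5, 1.5))
    co <- simulateSurvival(th, p)
    m <- rbind(f1 = th, f2 = 2 * th + 1)   # exact linear image
    colnames(m) <- co$patient_id
    x <- make_exp(m, cohort = co, scaled = TRUE)
    fit <- suppressWarnings(fitITHModel(x, c("f1", "f2")))
    expect_length(fit@features, 1L)
    expect_length(fit@diagnostics$pruned, 1L)
    expect_true(fit@diagnostics$converged)
})

test_that("well-separated score clusters put the cut-off between them", {
    set.seed(88)
    n <- 60
    sc <- c(rnorm(n / 2, 0, 0.3), rnorm(n / 2, 10, 0.3))
    co <- data.frame(
        time_months = c(rexp(n / 2, 0.01), rexp(n / 2, 0.15)),
        event = 1)
    cp <- optimalCutpoint(sc, co)
    expect_gt(cp@cutoff, max(sc[1:(n / 2)]) - 1)
    expect_lt(cp@cutoff, min(sc[(n / 2 + 1):n]) + 1)
    expect_lt(cp@p_min, 1e-6)
    expect_gte(cp@p_corrected, cp@p_min)
})

test_that("tied scores collapse to a distinct-value candidate grid", {
    sc <- rep(c(1, 2, 3), each = 10)
    set.seed(89)
    co <- data.frame(time_months = rexp(30, 0.05), event = 1)
    cp <- optimalCutpoint(sc, co, min_group_frac = 0.1)
    expect_equal(cp@candidates, c(1.5, 2.5))
})

test_that("degenerate cut-point inputs error", {
    co <- data.frame(time_months = rexp(10, 0.05), event = 1)
    expect_error(optimalCutpoint(rep(1, 10), co), "distinct")
    expect_error(optimalCutpoint(seq_len(10), co, min_group_frac = 0.6),
                 "group-size")
})

test_that("dichotomization sends scores at the cut-off to the low group", {
    expect_equal(as.character(dichotomize(c(4.8, 4.9, 5.0), 4.9)),
                 c("low", "low", "high"))
    g <- dichotomize(runif(20), 2)
    expect_true(all(g == "low"))
    g2 <- dichotomize(c(1, 3, 2, 4), 2.5)
    expect_equal(sum(table(g2)), 4)
})

test_that("ITH model JSON round-trips", {
    model <- new("ITHModel", features = c("a", "b"),
                 betas = c(a = 0.12, b = -0.5), intercept = 0,
                 cutoff = 4.9, alpha = 0.05,
                 medians = c(a = 50, b = 40),
                 diagnostics = list(converged = TRUE, penalty = 0,
                                    univariate_p = numeric(0),
                                    pruned = character(0)))
    f <- tempfile(fileext = ".json")
    writeITHModel(model, f)
    back <- readITHModel(f)
    expect_equal(back@betas, model@betas)
    expect_equal(back@cutoff, model@cutoff)
    expect_equal(back@medians, model@medians)
})
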