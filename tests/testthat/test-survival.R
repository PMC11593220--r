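test_that("KM with no events is flat at 1", {
    co <- data.frame(time_months = c(3, 5, 9), event = c(0, 0, 0))
    km <- kmEstimate(co)[["all"]]
    expect_true(all(km@surv == 1))
})

test_that("KM closed form: three events give 2/3, 1/3, 0", {
    co <- data.frame(time_months = c(1, 2, 3), event = c(1, 1, 1))
    km <- kmEstimate(co)[["all"]]
    expect_equal(km@surv, c(2 / 3, 1 / 3, 0))
})

test_that("KM matches the brute-force risk-set product on random cohorts", {
    set.seed(11)
    for (rep in 1:5) {
        n <- 40
        co <- data.frame(time_months = round(rexp(n, 0.05), 1),
                         event = rbinom(n, 1, 0.7))
        if (sum(co$event) == 0) next
        km <- kmEstimate(co)[["all"]]
        oracle <- brute_km(co$time_months, co$event)
        at_events <- km@surv[km@n_event > 0]
        expect_equal(at_events, oracle$surv, tolerance = 1e-12)
    }
})

test_that("KM curves are non-increasing and match empirical survival
           without censoring", {
    set.seed(12)
    t <- round(rexp(50, 0.1), 2)
    co <- data.frame(time_months = t, event = 1)
    km <- kmEstimate(co)[["all"]]
    expect_true(all(diff(km@surv) <= 1e-12))
    for (i in seq_along(km@time))
        expect_equal(km@surv[i], mean(t > km@time[i]))
})

test_that("log-rank on duplicated groups is exactly zero", {
    co <- data.frame(time_months = rep(c(2, 5, 8, 11), 2),
                     event = rep(c(1, 0, 1, 1), 2))
    lr <- logrankTest(co, rep(c("a", "b"), each = 4))
    expect_equal(lr$statistic, 0, tolerance = 1e-12)
})

test_that("log-rank equals the hand O-E/V computation on a toy cohort", {
    co <- data.frame(time_months = c(1, 2, 3, 4, 5, 6),
                     event = c(1, 1, 0, 1, 1, 0))
    g <- c("a", "b", "a", "b", "a", "b")
    lr <- logrankTest(co, g)
    expect_equal(lr$statistic,
                 hand_logrank(co$time_months, co$event, g),
                 tolerance = 1e-10)
})

test_that("log-rank holds its size under the exchangeable null", {
    set.seed(13)
    rej <- replicate(1000, {
        n <- 40
        co <- data.frame(time_months = rexp(n, 0.05),
                         event = rbinom(n, 1, 0.8))
        logrankTest(co, rep(c("a", "b"), n / 2))$p < 0.05
    })
    expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("log-rank is invariant to strictly increasing time transforms", {
    set.seed(14)
    co <- data.frame(time_months = rexp(30, 0.05) + 0.1,
                     event = rbinom(30, 1, 0.7))
    g <- rep(c("a", "b"), 15)
    lr1 <- logrankTest(co, g)
    co2 <- co; co2$time_months <- co$time_months^2
    expect_equal(logrankTest(co2, g)$statistic, lr1$statistic,
                 tolerance = 1e-12)
})

test_that("log-rank needs two groups and at least one event", {
    co <- data.frame(time_months = 1:4, event = c(1, 1, 0, 0))
    expect_error(logrankTest(co, rep("a", 4)), "two groups")
    co0 <- data.frame(time_months = 1:4, event = rep(0, 4))
    expect_error(logrankTest(co0, rep(c("a", "b"), 2)), "event")
})

test_that("Cox fit on a null covariate is unbiased with nominal size", {
    set.seed(15)
    z <- replicate(20, {
        co <- data.frame(time_months = rexp(200, 0.05),
                         event = rbinom(200, 1, 0.8), x = rnorm(200))
        fit <- coxFit(co, "x")
        fit@betas[["x"]] / fit@se[1]
    })
    # |z| > 2 should occur for ~5% of null fits; 5+/20 would be p < 1e-3
    expect_lte(sum(abs(z) > 2), 4)
    expect_lt(abs(mean(z)), 2 / sqrt(20))
    co <- data.frame(time_months = rexp(200, 0.05),
                     event = rbinom(200, 1, 0.8), x = rnorm(200))
    fit <- coxFit(co, "x")
    expect_equal(fit@hr, exp(fit@betas[[1]]))
    expect_equal(fit@ci_lower, exp(fit@betas[[1]] - 1.96 * fit@se[1]))
})

test_that("Cox partial likelihood attains the analytic optimum", {
    # subjects (t=1, x=1), (t=2, x=0), (t=3, x=1), all events:
    # d/db log PL = 0  <=>  2 e^{2b} = 1  <=>  b = -log(2)/2
    co <- data.frame(time_months = c(1, 2, 3), event = c(1, 1, 1),
                     x = c(1, 0, 1))
    fit <- coxFit(co, "x")
    expect_equal(fit@betas[["x"]], -log(2) / 2, tolerance = 1e-6)
})

test_that("Cox recovers beta = 1 within 0.15 at n = 1000", {
    p <- syntheticParams(n_patients = 1000L, log_hr_per_theta = 1,
                         seed = 11L)
    th <- withr::with_seed(99L, rbeta(1000, 1.5, 1.5))
    co <- simulateSurvival(th, p)
    fit <- coxFit(data.frame(co, th = th), "th")
    expect_lt(abs(fit@betas[[1]] - 1), 0.15)
})

test_that("Cox beta sign agrees with the log-rank disadvantaged group", {
    set.seed(16)
    for (rep in 1:10) {
        n <- 100
        x <- rbinom(n, 1, 0.5)
        co <- data.frame(time_months = rexp(n, 0.03 * exp(0.8 * x)),
                         event = 1, x = x)
        fit <- coxFit(co, "x")
        lr <- logrankTest(co, x)
        # group with more observed than expected events has higher hazard
        excess <- (lr$observed - lr$expected)[2]   # group x = 1
        expect_equal(sign(fit@betas[[1]]), sign(excess))
    }
})

test_that("PH-check p-values are uniform under exact proportional hazards", {
    set.seed(17)
    ps <- replicate(200, {
        n <- 100
        x <- rnorm(n)
        co <- data.frame(time_months = rexp(n, 0.05 * exp(0.5 * x)),
                         event = 1, x = x)
        phCheck(co, "x")$p
    })
    ks <- suppressWarnings(stats::ks.test(ps, "punif"))
    expect_gt(ks$p.value, 0.01)
    expect_gt(mean(ps >= 0.05), 0.90)   # PH deemed satisfied almost always
})

test_that("PH-check detects a strongly time-decaying effect", {
    set.seed(18)
    sim_decay <- function(n) {
        x <- rbinom(n, 1, 0.5)
        lam0 <- 0.02; t0 <- 15
        u <- rexp(n)
        r1 <- lam0 * exp(2 * x)
        t <- ifelse(u < r1 * t0, u / r1, t0 + (u - r1 * t0) / lam0)
        data.frame(time_months = t, event = 1, x = x)
    }
    hits <- replicate(30, phCheck(sim_decay(500), "x")$p < 0.05)
    expect_gt(mean(hits), 0.8)
})

test_that("PH-check refuses a constant covariate", {
    co <- data.frame(time_months = rexp(20, 0.1), event = 1, x = 1)
    expect_error(phCheck(co, "x"), "constant")
})

test_that("chi-square association matches the hand formula", {
    g <- rep(c("low", "high"), c(50, 50))
    cat2 <- c(rep(c("A", "B"), c(20, 30)), rep(c("A", "B"), c(40, 10)))
    at <- associationTable(g, cat2)
    # E = 30/20 per cell; X2 = 2*(100/30) + 2*(100/20)
    expect_equal(unname(at$statistic), 2 * 100 / 30 + 2 * 100 / 20,
                 tolerance = 1e-12)
    balanced <- associationTable(rep(c("a", "b"), each = 20),
                                 rep(c("X", "Y"), 20))
    expect_equal(unname(balanced$statistic), 0, tolerance = 1e-12)
})

test_that("association table rejects degenerate margins", {
    expect_error(associationTable(rep("a", 10), rep(c("X", "Y"), 5)),
                 "margins")
})

test_that("ANOVA returns F = 0 for identical group means", {
    out <- anovaAcross(rep(c("a", "b", "c"), each = 3),
                       rep(c(1, 2, 3), 3))
    expect_equal(out$F, 0)
    expect_error(anovaAcross(rep("a", 5), rnorm(5)), "two groups")
})

test_that("cohort validation catches malformed tables", {
    expect_error(kmEstimate(data.frame(time_months = -1, event = 1)),
                 "non-negative")
    expect_error(kmEstimate(data.frame(time_months = 1, event = 2)),
                 "0/1")
    expect_error(check_cohort <- kmEstimate(
        data.frame(patient_id = c("P1", "P1"), time_months = c(1, 2),
                   event = c(1, 0))), "duplicate")
})
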