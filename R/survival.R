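#' @include AllClasses.R
NULL

check_cohort <- function(cohort) {
    need <- c("time_months", "event")
    if (!all(need %in% names(cohort)))
        stop("cohort must contain columns time_months and event")
    if (any(cohort$time_months < 0)) stop("times must be non-negative")
    if (!all(cohort$event %in% c(0, 1))) stop("event must be 0/1")
    if (!is.null(cohort$patient_id) && anyDuplicated(cohort$patient_id))
        stop("duplicate patient ids")
    invisible(cohort)
}

#' Kaplan-Meier estimate
#'
#' Product-limit survival estimate, overall or per group; censored
#' subjects leave the risk set after their censoring time.
#'
#' @param cohort data.frame with `time_months`, `event`.
#' @param group optional group labels aligned to the cohort.
#' @return A list of [KMCurve-class] objects, one per group (a single
#'   curve named `"all"` when `group` is NULL).
#' @export
kmEstimate <- function(cohort, group = NULL) {
    check_cohort(cohort)
    if (nrow(cohort) < 1L) stop("cohort is empty")
    if (is.null(group)) group <- rep("all", nrow(cohort))
    group <- as.character(group)
    if (any(table(group) == 0L)) stop("empty group")
    out <- lapply(sort(unique(group)), function(g) {
        sub <- cohort[group == g, , drop = FALSE]
        if (!nrow(sub)) stop("empty group: ", g)
        sf <- survival::survfit(
            survival::Surv(time_months, event) ~ 1, data = sub)
        new("KMCurve", time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
            n_event = sf$n.event, n_censor = sf$n.censor, group = g)
    })
    names(out) <- sort(unique(group))
    out
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank chi-square (1 df) with pooled risk sets at
#' tied event times.
#'
#' @param cohort data.frame with `time_months`, `event`.
#' @param labels two-group labels aligned to the cohort.
#' @return List with `statistic` (chi-square), `p`, and per-group
#'   observed/expected event counts.
#' @export
logrankTest <- function(cohort, labels) {
    check_cohort(cohort)
    labels <- factor(labels)
    if (nlevels(labels) != 2L) stop("log-rank test needs exactly two groups")
    if (sum(cohort$event) < 1L) stop("log-rank test needs at least one event")
    sd <- survival::survdiff(
        survival::Surv(cohort$time_months, cohort$event) ~ labels)
    list(statistic = unname(sd$chisq),
         p = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE),
         observed = sd$obs, expected = sd$exp)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with the Efron tie approximation and
#' Wald inference; an optional ridge penalty makes ill-conditioned
#' designs fittable.
#'
#' @param cohort data.frame with `time_months`, `event` and the covariate
#'   columns.
#' @param covariates names of numeric covariate columns.
#' @param penalty ridge weight (0 = unpenalized).
#' @return A [CoxFit-class].
#' @export
coxFit <- function(cohort, covariates, penalty = 0) {
    check_cohort(cohort)
    if (sum(cohort$event) < 1L) stop("Cox fit needs at least one event")
    if (!all(covariates %in% names(cohort)))
        stop("missing covariate columns: ",
             paste(setdiff(covariates, names(cohort)), collapse = ", "))
    dat <- cohort[, c("time_months", "event", covariates), drop = FALSE]
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    rhs <- if (penalty > 0)
        paste0("ridge(", paste(covariates, collapse = ", "),
               ", theta = ", penalty, ", scale = TRUE)")
    else paste(covariates, collapse = " + ")
    fml <- stats::as.formula(paste("Surv(time_months, event) ~", rhs))
    fit <- survival::coxph(fml, data = dat, ties = "efron")
    if (!all(is.finite(coef(fit))))
        stop("Cox fit did not converge; iterations = ", fit$iter)
    b <- coef(fit)
    names(b) <- covariates
    se <- sqrt(diag(fit$var))[seq_along(b)]
    z <- b / se
    new("CoxFit", betas = b, se = unname(se),
        p = unname(2 * stats::pnorm(-abs(z))), hr = unname(exp(b)),
        ci_lower = unname(exp(b - 1.96 * se)),
        ci_upper = unname(exp(b + 1.96 * se)),
        loglik = unname(fit$loglik[length(fit$loglik)]),
        n = as.integer(fit$n), nevent = as.integer(fit$nevent),
        converged = TRUE)
}

#' Time-dependent-covariate check of proportional hazards
#'
#' Augments the Cox model with a `covariate x g(time)` time-dependent
#' interaction (default `g = log`) and reports the Wald test of that
#' term; proportionality is deemed satisfied when the interaction p is
#' at or above 0.05.
#'
#' @param cohort data.frame with `time_months`, `event` and the covariate.
#' @param covariate covariate column name.
#' @param time_transform `"log"` (default) or `"identity"`.
#' @return List with `beta` (interaction coefficient), `p` (its Wald p),
#'   and `satisfied` (`p >= 0.05`).
#' @export
phCheck <- function(cohort, covariate, time_transform = c("log", "identity")) {
    check_cohort(cohort)
    time_transform <- match.arg(time_transform)
    x <- cohort[[covariate]]
    if (is.null(x)) stop("covariate not found: ", covariate)
    if (length(unique(x[!is.na(x)])) < 2L)
        stop("degenerate design: covariate is constant")
    g <- if (time_transform == "log") function(t) log(t) else function(t) t
    dat <- data.frame(time = cohort$time_months, event = cohort$event, x = x)
    dat <- dat[stats::complete.cases(dat) & dat$time > 0, , drop = FALSE]
    fit <- survival::coxph(Surv(time, event) ~ x + tt(x), data = dat,
                           tt = function(x, t, ...) x * g(t))
    b <- coef(fit)
    se <- sqrt(diag(fit$var))
    i <- length(b)   # tt term is last
    p <- 2 * stats::pnorm(-abs(b[i] / se[i]))
    list(beta = unname(b[i]), p = unname(p), satisfied = unname(p >= 0.05))
}

#' Chi-square association of two categorical variables
#'
#' Pearson chi-square without continuity correction, as used for the
#' association tables of group membership versus clinicopathologic
#' categories.
#'
#' @param groups,categorical aligned category labels.
#' @return List with `statistic`, `df`, `p`, and the contingency
#'   `table`.
#' @export
associationTable <- function(groups, categorical) {
    tab <- table(groups, categorical)
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2L || ncol(tab) < 2L)
        stop("degenerate margins: need at least 2 x 2 non-empty categories")
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p = unname(ct$p.value), table = tab)
}

#' One-way ANOVA of a continuous variable across groups
#'
#' @param groups group labels.
#' @param values aligned continuous values.
#' @return List with `F`, `df` (numerator, denominator) and `p`.
#' @export
anovaAcross <- function(groups, values) {
    groups <- factor(groups)
    ok <- !is.na(values) & !is.na(groups)
    groups <- droplevels(groups[ok]); values <- values[ok]
    if (nlevels(groups) < 2L) stop("need at least two groups")
    a <- stats::anova(stats::aov(values ~ groups))
    list(F = a$`F value`[1L], df = c(a$Df[1L], a$Df[2L]),
         p = a$`Pr(>F)`[1L])
}

#' Write Kaplan-Meier step coordinates as CSV
#'
#' One row per step per group, for external plotting.
#'
#' @param curves list of [KMCurve-class] (from [kmEstimate()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeKMCurves <- function(curves, path) {
    df <- do.call(rbind, lapply(curves, function(k)
        data.frame(group = k@group, time = k@time, surv = k@surv,
                   n_risk = k@n_risk, n_event = k@n_event,
                   n_censor = k@n_censor)))
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}
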