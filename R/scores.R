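#' @include AllClasses.R features.R survival.R
NULL

#' Min-max scale features to 0-100 across the cohort
#'
#' Per-feature min-max normalization to `[0, 100]` over non-missing
#' cohort values. Features that are constant (or entirely missing) carry
#' no cohort information and are dropped with a warning.
#'
#' @param x an `ITHExperiment` (or a features x patients numeric matrix).
#' @param ... unused.
#' @return The scaled object with dropped features removed;
#'   `metadata(x)$scaled` set to `TRUE` and `metadata(x)$dropped` naming
#'   the removed features.
#' @export
setGeneric("scaleFeatures", function(x, ...) standardGeneric("scaleFeatures"))

scale_matrix_0_100 <- function(m) {
    rng <- t(apply(m, 1L, function(v) {
        v <- v[!is.na(v)]
        if (!length(v)) c(NA_real_, NA_real_) else range(v)
    }))
    keep <- !is.na(rng[, 1L]) & rng[, 2L] > rng[, 1L]
    scaled <- (m[keep, , drop = FALSE] - rng[keep, 1L]) /
        (rng[keep, 2L] - rng[keep, 1L]) * 100
    list(scaled = scaled, dropped = rownames(m)[!keep])
}

#' @rdname scaleFeatures
#' @export
setMethod("scaleFeatures", "ITHExperiment", function(x, ...) {
    if (isScaled(x)) return(x)
    r <- scale_matrix_0_100(featureValues(x))
    if (length(r$dropped))
        warning(sprintf("dropping %d constant/all-missing feature(s): %s",
                        length(r$dropped),
                        paste(utils::head(r$dropped, 5L), collapse = ", ")))
    out <- x[rownames(r$scaled), ]
    SummarizedExperiment::assay(out, "features") <- r$scaled
    S4Vectors::metadata(out)$scaled <- TRUE
    S4Vectors::metadata(out)$dropped <- r$dropped
    out
})

#' @rdname scaleFeatures
#' @export
setMethod("scaleFeatures", "matrix", function(x, ...) {
    scale_matrix_0_100(x)$scaled
})

#' Family heterogeneity score
#'
#' Mean of the scaled member features of one heterogeneity family
#' (differentiation, stroma or TILs), pairwise-complete per patient; the
#' result lies in `[0, 100]`. A patient with no non-missing member
#' feature receives `NA`.
#'
#' @param x a scaled `ITHExperiment`.
#' @param family `"differentiation"`, `"stroma"` or `"TILs"`.
#' @return Named numeric vector of per-patient scores.
#' @export
familyScore <- function(x, family = c("differentiation", "stroma", "TILs")) {
    stopifnot(is(x, "ITHExperiment"))
    family <- match.arg(family)
    if (!isScaled(x)) stop("scale the feature matrix first (scaleFeatures)")
    member <- SummarizedExperiment::rowData(x)$family == family
    if (!any(member)) stop("no member features for family ", family)
    m <- featureValues(x)[member, , drop = FALSE]
    colMeans(m, na.rm = TRUE) |> (\(v) { v[is.nan(v)] <- NA_real_; v })()
}

#' All three family scores
#'
#' @param x a scaled `ITHExperiment`.
#' @return Patients x 3 matrix of family scores.
#' @export
familyScores <- function(x) {
    fams <- c("differentiation", "stroma", "TILs")
    vapply(fams, function(f) familyScore(x, f), numeric(ncol(x)))
}

#' Univariate screening of features against outcome
#'
#' Fits a univariate Cox proportional-hazards model per feature on the
#' cohort endpoint (complete cases per feature) and retains features with
#' Wald p below `alpha`. Features that are constant on the complete cases
#' or whose fit does not converge are excluded and logged in the result's
#' attributes.
#'
#' @param x a scaled `ITHExperiment` whose `colData` carries
#'   `time_months` and `event`.
#' @param alpha significance level (default 0.05).
#' @return Character vector of retained feature names, with attributes
#'   `p` (named univariate p-values for all testable features) and
#'   `excluded` (features dropped for degeneracy/non-convergence).
#' @export
screenFeatures <- function(x, alpha = 0.05) {
    stopifnot(is(x, "ITHExperiment"))
    cd <- SummarizedExperiment::colData(x)
    if (!all(c("time_months", "event") %in% names(cd)))
        stop("colData must contain time_months and event")
    time <- cd$time_months
    event <- cd$event
    if (sum(event) < 1L) stop("screening requires at least one event")
    m <- featureValues(x)
    p <- setNames(rep(NA_real_, nrow(m)), rownames(m))
    excluded <- character(0)
    for (i in seq_len(nrow(m))) {
        v <- m[i, ]
        ok <- !is.na(v)
        if (length(unique(v[ok])) < 2L || sum(event[ok]) < 1L) {
            excluded <- c(excluded, rownames(m)[i])
            next
        }
        fit <- tryCatch(
            survival::coxph(survival::Surv(time[ok], event[ok]) ~ v[ok]),
            error = function(e) NULL, warning = function(w) NULL)
        if (is.null(fit) || !all(is.finite(coef(fit))) ||
            !all(is.finite(sqrt(diag(fit$var))))) {
            excluded <- c(excluded, rownames(m)[i])
            next
        }
        z <- coef(fit) / sqrt(diag(fit$var))
        p[i] <- 2 * stats::pnorm(-abs(z))
    }
    keep <- names(p)[!is.na(p) & p < alpha]
    structure(keep, p = p, excluded = excluded, alpha = alpha)
}

# Greedy pruning of pairwise correlations above `limit`; of each offending
# pair the feature with the larger univariate p is removed.
prune_collinear <- function(X, univ_p, limit = 0.95) {
    pruned <- character(0)
    repeat {
        if (ncol(X) < 2L) break
        r <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
        diag(r) <- 0
        r[is.na(r)] <- 0
        mx <- which(abs(r) == max(abs(r)), arr.ind = TRUE)[1L, ]
        if (abs(r[mx[1L], mx[2L]]) <= limit) break
        cand <- colnames(X)[mx]
        drop <- cand[which.max(univ_p[cand])]
        pruned <- c(pruned, drop)
        X <- X[, setdiff(colnames(X), drop), drop = FALSE]
    }
    list(X = X, pruned = pruned)
}

#' Fit the Cox-beta-weighted overall ITH model
#'
#' Multivariate Cox regression (Efron ties) of the screened features on
#' the cohort endpoint. The overall heterogeneity score is the linear
#' combination `a + sum(b_i * x_i)` of the feature values with the
#' multivariate betas; the intercept `a` defaults to 0 since the Cox
#' partial likelihood carries no intercept. To keep the procedure total:
#' perfectly collinear features (pairwise |r| > 0.95) are pruned first,
#' keeping the lower univariate p; if the event count is below 10 per
#' retained covariate, or the unpenalized fit fails, a small L2 (ridge)
#' penalty is applied with a warning. Missing feature values are imputed
#' with the per-feature cohort median for the joint fit.
#'
#' @param x a scaled `ITHExperiment`.
#' @param screened features to include (e.g. from [screenFeatures()]).
#' @param intercept constant offset `a` of the score (default 0).
#' @param penalty ridge penalty applied on fallback (default 0.01).
#' @param cor_limit collinearity pruning threshold (default 0.95).
#' @return An [ITHModel-class] (cut-off uncalibrated; see
#'   [optimalCutpoint()] and [calibrateCutoff()]).
#' @export
fitITHModel <- function(x, screened, intercept = 0, penalty = 0.01,
                        cor_limit = 0.95) {
    stopifnot(is(x, "ITHExperiment"))
    scr_p <- attr(screened, "p")
    scr_alpha <- attr(screened, "alpha")
    screened <- as.character(screened)
    if (!length(screened)) stop("screened feature set is empty")
    if (!all(screened %in% rownames(x)))
        stop("screened features missing from the feature matrix")
    cd <- SummarizedExperiment::colData(x)
    time <- cd$time_months
    event <- cd$event
    X <- t(featureValues(x)[screened, , drop = FALSE])
    med <- apply(X, 2L, stats::median, na.rm = TRUE)
    for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- med[j]

    univ_p <- scr_p
    if (is.null(univ_p)) {
        univ_p <- vapply(seq_len(ncol(X)), function(j) {
            f <- tryCatch(survival::coxph(
                survival::Surv(time, event) ~ X[, j]),
                error = function(e) NULL, warning = function(w) NULL)
            if (is.null(f)) 1 else
                2 * stats::pnorm(-abs(coef(f) / sqrt(diag(f$var))))
        }, numeric(1L))
        names(univ_p) <- colnames(X)
    }
    pr <- prune_collinear(X, univ_p, cor_limit)
    X <- pr$X
    feats <- colnames(X)

    dat <- data.frame(time = time, event = event, X, check.names = FALSE)
    safe <- sprintf("f%03d", seq_along(feats))
    names(dat) <- c("time", "event", safe)

    need_pen <- sum(event) < 10L * length(feats)
    fit <- NULL
    used_pen <- 0
    if (!need_pen) {
        fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                       paste(safe, collapse = " + ")))
        fit <- tryCatch(survival::coxph(fml, data = dat),
                        error = function(e) NULL,
                        warning = function(w) NULL)
    }
    if (is.null(fit)) {
        if (need_pen)
            warning(sprintf(
                "events (%d) < 10 x covariates (%d); applying ridge penalty %g",
                sum(event), length(feats), penalty))
        else
            warning(sprintf(
                "unpenalized multivariate fit failed; applying ridge penalty %g",
                penalty))
        used_pen <- penalty
        fml <- stats::as.formula(paste(
            "survival::Surv(time, event) ~ ridge(",
            paste(safe, collapse = ", "),
            ", theta = ", penalty, ", scale = TRUE)"))
        fit <- tryCatch(
            survival::coxph(fml, data = dat),
            error = function(e) NULL, warning = function(w) NULL)
    }
    if (is.null(fit) || !all(is.finite(coef(fit))))
        stop("multivariate Cox fit did not converge (", length(feats),
             " covariates, ", sum(event), " events)")
    betas <- coef(fit)
    names(betas) <- feats
    new("ITHModel", features = feats, betas = betas,
        intercept = intercept, cutoff = NA_real_,
        alpha = if (!is.null(scr_alpha)) scr_alpha else NA_real_,
        medians = med[feats],
        diagnostics = list(converged = TRUE, penalty = used_pen,
                           univariate_p = univ_p, pruned = pr$pruned,
                           n_events = sum(event)))
}

#' Per-patient overall ITH score
#'
#' `a + sum(b_i * x_i)` over the model features; missing feature values
#' are imputed with the training-cohort medians stored in the model.
#'
#' @param model an [ITHModel-class].
#' @param x a scaled `ITHExperiment` (or features x patients matrix)
#'   containing the model features.
#' @return Named numeric vector of scores.
#' @export
ithScore <- function(model, x) {
    stopifnot(is(model, "ITHModel"))
    m <- if (is(x, "ITHExperiment")) featureValues(x) else x
    if (!all(model@features %in% rownames(m)))
        stop("feature matrix lacks model features")
    X <- t(m[model@features, , drop = FALSE])
    for (j in seq_len(ncol(X)))
        X[is.na(X[, j]), j] <- model@medians[model@features[j]]
    setNames(drop(model@intercept + X %*% model@betas), rownames(X))
}

#' Optimal survival cut-point by minimum log-rank p
#'
#' Scans the midpoints between consecutive distinct scores, keeps
#' candidates leaving at least `min_group_frac` of patients in each
#' group, computes the two-group log-rank p at each, and selects the
#' cut-off attaining the minimal p (ties broken toward the lower
#' cut-off) — the X-tile-style optimal cut-point. Because the minimum
#' over candidates is an optimized statistic, the Miller-Siegmund
#' min-p correction is reported alongside the raw minimum.
#'
#' @param scores per-patient scores (NA dropped together with their
#'   cohort rows).
#' @param cohort data.frame with `time_months` and `event` aligned to
#'   `scores`.
#' @param min_group_frac minimum fraction of patients per group
#'   (default 0.1).
#' @return A [CutpointResult-class].
#' @export
optimalCutpoint <- function(scores, cohort, min_group_frac = 0.1) {
    stopifnot(length(scores) == nrow(cohort))
    ok <- !is.na(scores)
    scores <- scores[ok]
    cohort <- cohort[ok, , drop = FALSE]
    n <- length(scores)
    if (length(unique(scores)) < 2L)
        stop("need at least two distinct scores")
    if (sum(cohort$event) < 1L)
        stop("need at least one event")
    s <- sort(unique(scores))
    cand <- (s[-1L] + s[-length(s)]) / 2
    lo <- vapply(cand, function(cc) mean(scores <= cc), numeric(1L))
    keep <- lo >= min_group_frac & (1 - lo) >= min_group_frac
    cand <- cand[keep]
    if (!length(cand))
        stop("no candidate cut-point satisfies the group-size constraint")
    stat <- p <- numeric(length(cand))
    for (i in seq_along(cand)) {
        g <- factor(scores > cand[i], levels = c(FALSE, TRUE),
                    labels = c("low", "high"))
        sd <- survival::survdiff(
            survival::Surv(cohort$time_months, cohort$event) ~ g)
        stat[i] <- sd$chisq
        p[i] <- stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE)
    }
    best <- which(p == min(p))[1L]   # ties -> lower cut-off (cand sorted)
    new("CutpointResult", cutoff = cand[best], candidates = cand,
        statistics = stat, p_values = p, p_min = p[best],
        p_corrected = minpAdjust(p[best], min_group_frac, min_group_frac),
        min_group_frac = min_group_frac)
}

#' Miller-Siegmund correction of a minimum p-value
#'
#' Adjusts the minimal log-rank p obtained by scanning cut-points between
#' the `eps_low` and `1 - eps_high` score quantiles for the optimism of
#' the selection, using the improved Bonferroni-type approximation
#' \deqn{p_{adj} = \varphi(z)(z - 1/z)\log\frac{(1-\epsilon_l)(1-\epsilon_h)}
#' {\epsilon_l \epsilon_h} + 4\varphi(z)/z,} with
#' `z = qnorm(1 - p_min / 2)`. The result is clamped to
#' `[p_min, 1]`.
#'
#' @param p_min raw minimal p-value.
#' @param eps_low,eps_high group-fraction bounds of the scan.
#' @return Corrected p-value.
#' @export
minpAdjust <- function(p_min, eps_low = 0.1, eps_high = 0.1) {
    if (is.na(p_min)) return(NA_real_)
    z <- stats::qnorm(1 - p_min / 2)
    if (!is.finite(z) || z <= 1) return(1)
    adj <- stats::dnorm(z) * (z - 1 / z) *
        log((1 - eps_low) * (1 - eps_high) / (eps_low * eps_high)) +
        4 * stats::dnorm(z) / z
    min(1, max(p_min, adj))
}

#' Dichotomize scores at a cut-off
#'
#' Scores strictly greater than the cut-off form the heterogeneous
#' (`"high"`) group; scores at or below it the `"low"` group.
#'
#' @param scores numeric scores.
#' @param cutoff finite cut-off.
#' @return Factor with levels `low`, `high` (`NA` for missing scores).
#' @export
dichotomize <- function(scores, cutoff) {
    if (!is.finite(cutoff)) stop("cutoff must be finite")
    factor(ifelse(scores > cutoff, "high", "low"), levels = c("low", "high"))
}

#' Calibrate the model cut-off on a cohort
#'
#' Convenience wrapper: computes scores, runs [optimalCutpoint()], and
#' stores the selected cut-off in the model.
#'
#' @param model an [ITHModel-class].
#' @param x a scaled `ITHExperiment` with survival `colData`.
#' @param min_group_frac forwarded to [optimalCutpoint()].
#' @return List with `model` (cut-off filled in), `scores`, `groups` and
#'   `cutpoint` (the [CutpointResult-class]).
#' @export
calibrateCutoff <- function(model, x, min_group_frac = 0.1) {
    sc <- ithScore(model, x)
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    cp <- optimalCutpoint(sc, cd, min_group_frac)
    model@cutoff <- cp@cutoff
    list(model = model, scores = sc, groups = dichotomize(sc, cp@cutoff),
         cutpoint = cp)
}

#' Serialize / restore an ITH model as JSON
#'
#' @param model an [ITHModel-class].
#' @param path file path.
#' @return `writeITHModel` returns `path` invisibly; `readITHModel`
#'   the restored model.
#' @export
writeITHModel <- function(model, path) {
    stopifnot(is(model, "ITHModel"))
    jsonlite::write_json(list(
        features = model@features,
        betas = as.list(model@betas),
        intercept = model@intercept,
        cutoff = model@cutoff,
        alpha = model@alpha,
        medians = as.list(model@medians),
        diagnostics = list(converged = model@diagnostics$converged,
                           penalty = model@diagnostics$penalty,
                           pruned = model@diagnostics$pruned)),
        path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
    invisible(path)
}

#' @rdname writeITHModel
#' @export
readITHModel <- function(path) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    feats <- as.character(j$features)
    new("ITHModel", features = feats,
        betas = setNames(as.numeric(unlist(j$betas)), feats),
        intercept = as.numeric(j$intercept),
        cutoff = if (is.null(j$cutoff)) NA_real_ else as.numeric(j$cutoff),
        alpha = if (is.null(j$alpha)) NA_real_ else as.numeric(j$alpha),
        medians = setNames(as.numeric(unlist(j$medians)), feats),
        diagnostics = list(converged = isTRUE(j$diagnostics$converged),
                           penalty = as.numeric(j$diagnostics$penalty),
                           univariate_p = numeric(0),
                           pruned = as.character(unlist(
                               j$diagnostics$pruned))))
}
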