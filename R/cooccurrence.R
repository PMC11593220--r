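#' @include AllClasses.R
NULL

#' Build a normalized symmetric co-occurrence matrix
#'
#' Accumulates neighbour-level counts over unit offsets between valid
#' patches of a patch-level integer map. With `directions = 8` the four
#' offset vectors (E, S, SE, NE) are scanned and each ordered pair is
#' counted in both orders, so every unordered neighbour pair contributes
#' twice; the accumulated counts are divided by 2 (each unordered pair
#' once) and normalized to sum 1, yielding a symmetric probability matrix
#' p(i, j). `NA` entries (invalid patches) are excluded from all pairs.
#'
#' @param level_map integer matrix of patch levels; `NA` marks invalid
#'   patches.
#' @param distance neighbour offset in patches (default 1).
#' @param directions 8 (default; axial + diagonal) or 4 (axial only).
#' @return A [CoocMatrix-class].
#' @examples
#' m <- matrix(c(1L, 2L), 1, 2)
#' coocProb(buildCoocMatrix(m))   # p(1,2) = p(2,1) = 0.5
#' @export
buildCoocMatrix <- function(level_map, distance = 1L, directions = 8L) {
    stopifnot(is.matrix(level_map))
    if (!directions %in% c(4L, 8L)) stop("directions must be 4 or 8")
    d <- as.integer(distance)
    if (d < 1L) stop("distance must be >= 1")
    lv <- sort(unique(as.vector(level_map[!is.na(level_map)])))
    if (!length(lv)) stop("level map has no valid patch")
    L <- length(lv)
    idx <- matrix(match(level_map, lv), nrow(level_map))
    offs <- list(c(0L, d), c(d, 0L))
    if (directions == 8L) offs <- c(offs, list(c(d, d), c(d, -d)))
    counts <- matrix(0, L, L)
    nr <- nrow(idx); nc <- ncol(idx)
    for (off in offs) {
        dr <- off[1L]; dc <- off[2L]
        if (nr <= dr || nc <= abs(dc)) next
        r1 <- seq_len(nr - dr); r2 <- r1 + dr
        if (dc >= 0L) { c1 <- seq_len(nc - dc); c2 <- c1 + dc }
        else { c1 <- seq.int(1L - dc, nc); c2 <- c1 + dc }
        a <- idx[r1, c1, drop = FALSE]
        b <- idx[r2, c2, drop = FALSE]
        ok <- !is.na(a) & !is.na(b)
        if (!any(ok)) next
        tab <- unclass(table(factor(a[ok], levels = seq_len(L)),
                             factor(b[ok], levels = seq_len(L))))
        counts <- counts + tab + t(tab)
    }
    counts <- counts / 2
    total <- sum(counts)
    if (total == 0)
        stop("no valid neighbour pair: co-occurrence matrix is undefined")
    new("CoocMatrix", p = matrix(counts / total, L, L),
        levels = as.numeric(lv),
        distance = d, directions = as.integer(directions))
}

#' Haralick-style texture statistics of a co-occurrence matrix
#'
#' Computes, with i and j the numeric level values:
#' contrast \eqn{\sum p(i,j)(i-j)^2}; dissimilarity
#' \eqn{\sum p(i,j)|i-j|}; homogeneity
#' \eqn{\sum p(i,j)/(1+(i-j)^2)}; heterogeneity `1 - homogeneity`;
#' correlation \eqn{\sum p(i,j)(i-\mu_i)(j-\mu_j)/(\sigma_i \sigma_j)}
#' (0 and flagged degenerate when a marginal variance vanishes);
#' uniformity \eqn{\sum p(i,j)^2}; energy `sqrt(uniformity)`; entropy
#' \eqn{-\sum_{p>0} p \log_2 p}. A constant map therefore has contrast 0,
#' homogeneity 1, heterogeneity 0, uniformity 1 and entropy 0.
#'
#' @param cm a [CoocMatrix-class].
#' @return Named numeric vector with the eight statistics and an attribute
#'   `degenerate` naming statistics that were undefined (correlation on a
#'   constant map).
#' @examples
#' cm <- buildCoocMatrix(matrix(1L, 4, 4))
#' textureStats(cm)[c("contrast", "homogeneity", "uniformity")]
#' @export
textureStats <- function(cm) {
    stopifnot(is(cm, "CoocMatrix"))
    p <- cm@p
    lv <- cm@levels
    D <- outer(lv, lv, `-`)
    contrast <- sum(p * D^2)
    dissimilarity <- sum(p * abs(D))
    homogeneity <- sum(p / (1 + D^2))
    heterogeneity <- 1 - homogeneity
    uniformity <- sum(p^2)
    energy <- sqrt(uniformity)
    pm <- p[p > 0]
    entropy <- -sum(pm * log2(pm))
    mi <- sum(rowSums(p) * lv)
    si <- sqrt(sum(rowSums(p) * (lv - mi)^2))
    degenerate <- character(0)
    if (si > 0) {
        correlation <- sum(p * outer(lv - mi, lv - mi)) / si^2
    } else {
        correlation <- 0
        degenerate <- "correlation"
    }
    out <- c(contrast = contrast, dissimilarity = dissimilarity,
             homogeneity = homogeneity, heterogeneity = heterogeneity,
             correlation = correlation, uniformity = uniformity,
             energy = energy, entropy = entropy)
    attr(out, "degenerate") <- degenerate
    out
}

#' Colocalization of two per-patch fraction layers
#'
#' \eqn{\sum_k \min(a_k, b_k) / \sum_k \max(a_k, b_k)} over the shared
#' valid patches: 0 iff the supports are disjoint (the layers do not
#' colocalize), 1 iff the same fraction of both layers is found together
#' in every patch. When both layers are empty the statistic is undefined;
#' 0 is returned with attribute `missing = TRUE`.
#'
#' @param fracs_a,fracs_b numeric per-patch fraction vectors of equal
#'   length; `NA` patches are dropped pairwise.
#' @return A fraction in `[0, 1]`.
#' @examples
#' colocalization(c(0.2, 0.4), c(0.4, 0.2))  # 0.4 / 0.8 = 0.5
#' @export
colocalization <- function(fracs_a, fracs_b) {
    if (length(fracs_a) != length(fracs_b))
        stop("fraction vectors must have equal length")
    ok <- !is.na(fracs_a) & !is.na(fracs_b)
    a <- fracs_a[ok]; b <- fracs_b[ok]
    lo <- sum(pmin(a, b))
    hi <- sum(pmax(a, b))
    if (hi == 0) {
        out <- 0
        attr(out, "missing") <- TRUE
        return(out)
    }
    out <- lo / hi
    attr(out, "missing") <- FALSE
    out
}
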