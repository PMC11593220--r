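#' @include AllClasses.R cooccurrence.R catalogue.R
NULL

#' Compute the per-patient heterogeneity feature vector
#'
#' Evaluates every catalogue entry on a patch grid. Texture features are
#' computed from the co-occurrence matrix of the layer's presence/absence
#' patch map (patch fraction above the catalogue threshold, levels 0/1);
#' colocalization features from the raw fraction vectors of the layer
#' pair. Undefined statistics — a co-occurrence matrix with no valid
#' neighbour pair, a degenerate correlation, a colocalization of two empty
#' layers — are returned as `NA`: missingness is data, not failure, and is
#' excluded pairwise downstream.
#'
#' @param grid a [PatchGrid-class].
#' @param catalogue a [FeatureCatalogue-class] (default
#'   [defaultCatalogue()]).
#' @param distance,directions co-occurrence offset and direction count.
#' @return Named numeric vector aligned to the catalogue (length 162 for
#'   the default catalogue), `NA` where a statistic is undefined.
#' @export
computeFeatures <- function(grid, catalogue = defaultCatalogue(),
                            distance = 1L, directions = 8L) {
    stopifnot(is(grid, "PatchGrid"), is(catalogue, "FeatureCatalogue"))
    defs <- catalogue@defs
    fr <- grid@fractions
    pdim <- grid@pdim
    out <- setNames(rep(NA_real_, nrow(defs)), defs$name)

    tex <- defs[defs$type == "texture", , drop = FALSE]
    for (ly in unique(tex$layer)) {
        rows <- tex[tex$layer == ly, , drop = FALSE]
        if (!ly %in% colnames(fr)) next
        thr <- rows$threshold[1L]
        lvmap <- matrix(NA_integer_, pdim[1L], pdim[2L])
        f <- fr[, ly]
        lvmap[grid@valid] <- as.integer(f[grid@valid] > thr)
        stats <- tryCatch({
            cm <- buildCoocMatrix(lvmap, distance = distance,
                                  directions = directions)
            textureStats(cm)
        }, error = function(e) NULL)
        if (is.null(stats)) next
        degen <- attr(stats, "degenerate")
        for (i in seq_len(nrow(rows))) {
            st <- rows$statistic[i]
            out[rows$name[i]] <- if (st %in% degen) NA_real_ else stats[[st]]
        }
    }

    col <- defs[defs$type == "coloc", , drop = FALSE]
    for (i in seq_len(nrow(col))) {
        a <- col$layer[i]; b <- col$layer2[i]
        if (!a %in% colnames(fr) || !b %in% colnames(fr)) next
        v <- colocalization(fr[grid@valid, a], fr[grid@valid, b])
        out[col$name[i]] <- if (isTRUE(attr(v, "missing"))) NA_real_
                            else as.numeric(v)
    }
    out
}

#' Cohort feature matrix as a SummarizedExperiment
#'
#' Assembles per-patient feature vectors into an `ITHExperiment`
#' (a [SummarizedExperiment::SummarizedExperiment] subclass): rows are
#' catalogue features (with `rowData` carrying the catalogue definition),
#' columns are patients (with the cohort table in `colData`), and the
#' single assay `"features"` holds the values. `metadata(x)$scaled`
#' records the normalization state.
#'
#' @param stacks list of [simulateLayerStack()] results or
#'   [LayerStack-class] objects (named by patient id), or a precomputed
#'   features x patients numeric matrix.
#' @param catalogue a [FeatureCatalogue-class].
#' @param cohort optional cohort `data.frame` with `patient_id`,
#'   `time_months`, `event` (and extra covariates), matched to the stacks
#'   by id.
#' @param ... passed to [computeFeatures()].
#' @return An `ITHExperiment`.
#' @export
buildFeatureMatrix <- function(stacks, catalogue = defaultCatalogue(),
                               cohort = NULL, ...) {
    if (is.matrix(stacks)) {
        values <- stacks
    } else {
        values <- vapply(stacks, function(s) {
            st <- if (is(s, "LayerStack")) s else s$stack
            computeFeatures(patchify(excludeDCIS(st)), catalogue, ...)
        }, numeric(nrow(catalogue@defs)))
        if (is.null(colnames(values)) && !is.null(names(stacks)))
            colnames(values) <- names(stacks)
    }
    if (is.null(colnames(values)))
        colnames(values) <- sprintf("P%04d", seq_len(ncol(values)))
    cd <- if (is.null(cohort)) {
        S4Vectors::DataFrame(patient_id = colnames(values))
    } else {
        m <- match(colnames(values), cohort$patient_id)
        if (anyNA(m)) stop("cohort table is missing some patient ids")
        S4Vectors::DataFrame(cohort[m, , drop = FALSE])
    }
    rownames(cd) <- colnames(values)
    rd <- if (nrow(values) == nrow(catalogue@defs)) {
        S4Vectors::DataFrame(catalogue@defs, row.names = catalogue@defs$name)
    } else {
        # ad-hoc matrices (e.g. simulated covariates) without a catalogue
        if (is.null(rownames(values)))
            rownames(values) <- sprintf("f%04d", seq_len(nrow(values)))
        S4Vectors::DataFrame(name = rownames(values),
                             row.names = rownames(values))
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(features = values), rowData = rd, colData = cd)
    out <- methods::new("ITHExperiment", se)
    S4Vectors::metadata(out)$scaled <- FALSE
    out
}

#' Experiment container for cohort feature matrices
#'
#' See [buildFeatureMatrix()]. `featureValues()` returns the assay matrix,
#' `isScaled()` the normalization state.
#'
#' @param x an `ITHExperiment`.
#' @param ... unused.
#' @name ITHExperiment
NULL

#' @rdname ITHExperiment
#' @export
setGeneric("featureValues", function(x, ...) standardGeneric("featureValues"))

#' @rdname ITHExperiment
#' @export
setMethod("featureValues", "ITHExperiment", function(x, ...)
    SummarizedExperiment::assay(x, "features"))

#' @rdname ITHExperiment
#' @export
setGeneric("isScaled", function(x, ...) standardGeneric("isScaled"))

#' @rdname ITHExperiment
#' @export
setMethod("isScaled", "ITHExperiment", function(x, ...)
    isTRUE(S4Vectors::metadata(x)$scaled))

#' Write a cohort feature matrix as CSV
#'
#' Patients as rows, catalogue features as columns, missing values as
#' empty fields.
#'
#' @param x an `ITHExperiment`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFeatureMatrix <- function(x, path) {
    m <- t(featureValues(x))
    df <- data.frame(patient_id = rownames(m), m, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, na = "")
    invisible(path)
}
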