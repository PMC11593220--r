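#' @include AllClasses.R
NULL

#' Accessors for ithquant classes
#'
#' Small accessor generics following Bioconductor conventions; use these
#' instead of direct slot access.
#'
#' @param x an ithquant object.
#' @param ... unused.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("labelGrid", function(x, ...) standardGeneric("labelGrid"))
#' @rdname accessors
#' @export
setMethod("labelGrid", "LabelMap", function(x, ...) x@grid)

#' @rdname accessors
#' @export
setGeneric("classCodes", function(x, ...) standardGeneric("classCodes"))
#' @rdname accessors
#' @export
setMethod("classCodes", "LabelMap", function(x, ...) x@class_codes)

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x, ...) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setMethod("pixelSize", "LabelMap", function(x, ...) x@pixel_size_um)
#' @rdname accessors
#' @export
setMethod("pixelSize", "LayerStack", function(x, ...) x@pixel_size_um)

#' @rdname accessors
#' @export
setGeneric("stackLayers", function(x, ...) standardGeneric("stackLayers"))
#' @rdname accessors
#' @export
setMethod("stackLayers", "LayerStack", function(x, ...) x@layers)

#' @rdname accessors
#' @export
setGeneric("dcisMask", function(x, ...) standardGeneric("dcisMask"))
#' @rdname accessors
#' @export
setMethod("dcisMask", "LayerStack", function(x, ...) x@dcis_mask)

#' @rdname accessors
#' @export
setGeneric("patchFractions", function(x, ...)
    standardGeneric("patchFractions"))
#' @rdname accessors
#' @export
setMethod("patchFractions", "PatchGrid", function(x, ...) x@fractions)

#' @rdname accessors
#' @export
setGeneric("validPatches", function(x, ...) standardGeneric("validPatches"))
#' @rdname accessors
#' @export
setMethod("validPatches", "PatchGrid", function(x, ...) x@valid)

#' @rdname accessors
#' @export
setGeneric("coocProb", function(x, ...) standardGeneric("coocProb"))
#' @rdname accessors
#' @export
setMethod("coocProb", "CoocMatrix", function(x, ...) x@p)

#' @rdname accessors
#' @export
setGeneric("catalogueDefs", function(x, ...) standardGeneric("catalogueDefs"))
#' @rdname accessors
#' @export
setMethod("catalogueDefs", "FeatureCatalogue", function(x, ...) x@defs)

#' @rdname accessors
#' @export
setGeneric("modelBetas", function(x, ...) standardGeneric("modelBetas"))
#' @rdname accessors
#' @export
setMethod("modelBetas", "ITHModel", function(x, ...) x@betas)

#' @rdname accessors
#' @export
setGeneric("modelCutoff", function(x, ...) standardGeneric("modelCutoff"))
#' @rdname accessors
#' @export
setMethod("modelCutoff", "ITHModel", function(x, ...) x@cutoff)

#' @rdname accessors
#' @export
setGeneric("screenedFeatures", function(x, ...)
    standardGeneric("screenedFeatures"))
#' @rdname accessors
#' @export
setMethod("screenedFeatures", "ITHModel", function(x, ...) x@features)

setMethod("show", "LabelMap", function(object) {
    cat(sprintf("LabelMap: %d x %d px (%.3g um/px), classes: %s\n",
        nrow(object@grid), ncol(object@grid), object@pixel_size_um,
        paste(object@class_codes, collapse = ", ")))
})

setMethod("show", "CellPointSet", function(object) {
    cat(sprintf("CellPointSet: %d nuclei in %d x %d frame\n",
        nrow(object@points), object@frame_dim[1L], object@frame_dim[2L]))
    if (nrow(object@points))
        print(table(object@points$class))
})

setMethod("show", "LayerStack", function(object) {
    d <- dim(object@layers[[1L]])
    cat(sprintf("LayerStack: %d layers on %d x %d px grid (%.3g um/px)\n",
        length(object@layers), d[1L], d[2L], object@pixel_size_um))
    cat("  layers:", paste(names(object@layers), collapse = ", "), "\n")
    cat(sprintf("  DCIS pixels: %d; tissue pixels: %d\n",
        sum(object@dcis_mask), sum(object@tissue_mask)))
})

setMethod("show", "PatchGrid", function(object) {
    cat(sprintf(
        "PatchGrid: %d x %d patches (%d px side), %d/%d valid, %d layers\n",
        object@pdim[1L], object@pdim[2L], object@patch_px,
        sum(object@valid), length(object@valid), ncol(object@fractions)))
})

setMethod("show", "CoocMatrix", function(object) {
    cat(sprintf("CoocMatrix: %d levels, distance %d, %d directions\n",
        nrow(object@p), object@distance, object@directions))
    print(round(object@p, 4))
})

setMethod("show", "FeatureCatalogue", function(object) {
    cat(sprintf("FeatureCatalogue: %d features (%s)\n", nrow(object@defs),
        paste(sprintf("%s: %d", names(table(object@defs$family)),
                      table(object@defs$family)), collapse = ", ")))
})

setMethod("show", "ITHModel", function(object) {
    cat(sprintf(
        "ITHModel: %d screened features (alpha = %.3g), cutoff = %s\n",
        length(object@features), object@alpha,
        ifelse(is.na(object@cutoff), "uncalibrated",
               format(object@cutoff, digits = 4))))
})

setMethod("show", "CutpointResult", function(object) {
    cat(sprintf(
        "CutpointResult: cutoff %.4g (min p = %.3g, corrected p = %.3g, %d candidates)\n",
        object@cutoff, object@p_min, object@p_corrected,
        length(object@candidates)))
})

setMethod("show", "CoxFit", function(object) {
    cat(sprintf("CoxFit: n = %d, events = %d, converged = %s\n",
        object@n, object@nevent, object@converged))
    print(data.frame(beta = object@betas, se = object@se, HR = object@hr,
        lower95 = object@ci_lower, upper95 = object@ci_upper, p = object@p))
})

setMethod("show", "KMCurve", function(object) {
    cat(sprintf("KMCurve [%s]: %d time points, final S = %.3f\n",
        object@group, length(object@time),
        if (length(object@surv)) utils::tail(object@surv, 1L) else 1))
})

setMethod("show", "SyntheticParams", function(object) {
    cat(sprintf(
        "SyntheticParams: n = %d, map %d px @ %.3g um/px, theta ~ Beta(%.3g, %.3g), seed %d\n",
        object@n_patients, object@map_side_px, object@pixel_size_um,
        object@theta_dist[1L], object@theta_dist[2L], object@seed))
})
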