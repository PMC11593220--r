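#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Spatial label map
#'
#' A single-channel 2D grid of integer class codes with a physical pixel
#' size. Code 0 is background; every non-zero code must be declared in
#' `class_codes`. The grid follows the usual raster convention: pixel
#' (row 1, col 1) is the top-left corner, indices are 1-based in R but all
#' point coordinates handled by [rasterizeCells()] are 0-based pixel
#' positions, matching the convention of the upstream segmentation outputs.
#'
#' @slot grid integer matrix of class codes (0 = background).
#' @slot pixel_size_um physical side of one pixel in micrometres.
#' @slot class_codes named character vector mapping code (name, as a
#'   character integer) to class label.
#' @exportClass LabelMap
setClass("LabelMap",
    representation(grid = "matrix", pixel_size_um = "numeric",
                   class_codes = "character"))

setValidity("LabelMap", function(object) {
    g <- object@grid
    if (length(g) == 0L || any(dim(g) < 1L))
        return("grid must have positive dimensions")
    v <- unique(as.vector(g))
    v <- v[!is.na(v) & v != 0]
    if (length(v) && !all(as.character(v) %in% names(object@class_codes)))
        return("grid contains codes absent from class_codes")
    if (length(object@pixel_size_um) != 1L || object@pixel_size_um <= 0)
        return("pixel_size_um must be a single positive number")
    TRUE
})

#' Classified nucleus centroids
#'
#' Point set of detected nuclei with class labels, in 0-based pixel
#' coordinates of a reference frame (typically the full-resolution frame
#' that is 5x finer than the region label map).
#'
#' @slot points data.frame with columns `x_px`, `y_px`, `class`.
#' @slot frame_dim integer vector (rows, cols) of the reference frame.
#' @slot pixel_size_um pixel size of the reference frame.
#' @exportClass CellPointSet
setClass("CellPointSet",
    representation(points = "data.frame", frame_dim = "integer",
                   pixel_size_um = "numeric"))

setValidity("CellPointSet", function(object) {
    p <- object@points
    need <- c("x_px", "y_px", "class")
    if (!all(need %in% names(p)))
        return("points must have columns x_px, y_px, class")
    if (length(object@frame_dim) != 2L || any(object@frame_dim < 1L))
        return("frame_dim must be two positive integers (rows, cols)")
    if (nrow(p)) {
        if (any(p$x_px < 0 | p$x_px >= object@frame_dim[2L] |
                p$y_px < 0 | p$y_px >= object@frame_dim[1L]))
            return("point coordinates outside the reference frame")
    }
    TRUE
})

#' Registered stack of binary analysis layers
#'
#' All layers share one grid; `dcis_mask` marks in-situ (DCIS) areas to be
#' excluded from analysis, `tissue_mask` marks tissue. After
#' [excludeDCIS()] no analysis layer intersects the DCIS mask.
#'
#' @slot layers named list of logical matrices.
#' @slot dcis_mask logical matrix.
#' @slot tissue_mask logical matrix.
#' @slot pixel_size_um pixel size in micrometres.
#' @slot patch_side_um side of the analysis patch in micrometres.
#' @exportClass LayerStack
setClass("LayerStack",
    representation(layers = "list", dcis_mask = "matrix",
                   tissue_mask = "matrix", pixel_size_um = "numeric",
                   patch_side_um = "numeric"))

setValidity("LayerStack", function(object) {
    if (!length(object@layers)) return("layers must be non-empty")
    d <- dim(object@layers[[1L]])
    ok <- vapply(object@layers, function(m)
        is.logical(m) && identical(dim(m), d), logical(1L))
    if (!all(ok)) return("all layers must be logical matrices of one shape")
    if (!identical(dim(object@dcis_mask), d) ||
        !identical(dim(object@tissue_mask), d))
        return("dcis_mask and tissue_mask must match layer shape")
    if (is.null(names(object@layers)) || anyDuplicated(names(object@layers)))
        return("layers must be uniquely named")
    TRUE
})

#' Patch grid of per-patch layer fractions
#'
#' Non-overlapping square patches tiling a [LayerStack] from the top-left.
#' `fractions[k, layer]` is the labelled-pixel fraction of patch k (patches
#' ordered column-major over the patch grid). Invalid patches (tissue
#' coverage below threshold or any DCIS overlap) never enter feature sums.
#'
#' @slot fractions numeric matrix, patches x layers.
#' @slot pdim integer (patch rows, patch cols).
#' @slot valid logical vector, one flag per patch.
#' @slot tissue_frac numeric per-patch tissue coverage.
#' @slot level_maps named list of integer patch matrices (dominant level
#'   per patch for graded layers), NA on invalid patches.
#' @slot patch_px patch side in pixels.
#' @slot patch_side_um patch side in micrometres.
#' @exportClass PatchGrid
setClass("PatchGrid",
    representation(fractions = "matrix", pdim = "integer", valid = "logical",
                   tissue_frac = "numeric", level_maps = "list",
                   patch_px = "integer", patch_side_um = "numeric"))

setValidity("PatchGrid", function(object) {
    np <- prod(object@pdim)
    if (nrow(object@fractions) != np) return("fractions rows != patch count")
    if (length(object@valid) != np) return("valid length != patch count")
    f <- object@fractions[object@valid, , drop = FALSE]
    f <- f[!is.na(f)]
    if (length(f) && (min(f) < -1e-9 || max(f) > 1 + 1e-9))
        return("fractions must lie in [0, 1]")
    TRUE
})

#' Normalized symmetric co-occurrence matrix
#'
#' Probabilities p(i, j) that patch levels i and j are neighbours at the
#' given offset distance, accumulated over the configured directions,
#' divided by two (each unordered pair once) and normalized to sum 1.
#'
#' @slot p numeric square matrix of probabilities.
#' @slot levels numeric level values labelling rows/columns.
#' @slot distance offset in patches.
#' @slot directions number of accumulation directions (8 or 4).
#' @exportClass CoocMatrix
setClass("CoocMatrix",
    representation(p = "matrix", levels = "numeric", distance = "integer",
                   directions = "integer"))

setValidity("CoocMatrix", function(object) {
    p <- object@p
    if (nrow(p) != ncol(p)) return("p must be square")
    if (length(object@levels) != nrow(p))
        return("levels length must match p dimension")
    if (any(p < -1e-12)) return("p must be non-negative")
    if (abs(sum(p) - 1) > 1e-12) return("p must sum to 1")
    if (max(abs(p - t(p))) > 1e-12) return("p must be symmetric")
    TRUE
})

#' Heterogeneity feature catalogue
#'
#' Ordered definition of the per-patient feature vector: texture statistics
#' of single layers and colocalization of layer pairs, each assigned to one
#' heterogeneity family (differentiation, stroma, TILs). The default
#' catalogue ([defaultCatalogue()]) has 162 entries.
#'
#' @slot defs data.frame with columns `name`, `type` ("texture" or
#'   "coloc"), `layer`, `layer2`, `statistic`, `family`, `threshold`.
#' @exportClass FeatureCatalogue
setClass("FeatureCatalogue", representation(defs = "data.frame"))

setValidity("FeatureCatalogue", function(object) {
    d <- object@defs
    need <- c("name", "type", "layer", "layer2", "statistic", "family",
              "threshold")
    if (!all(need %in% names(d))) return("defs missing required columns")
    if (anyDuplicated(d$name)) return("feature names must be unique")
    if (!all(d$family %in% c("differentiation", "stroma", "TILs")))
        return("family must be differentiation, stroma or TILs")
    if (!all(d$type %in% c("texture", "coloc")))
        return("type must be texture or coloc")
    TRUE
})

#' Cohort feature matrix container
#'
#' `ITHExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment]: one assay `"features"`
#' (catalogue features x patients), the catalogue definition in
#' `rowData`, the cohort table in `colData`, and the normalization state
#' in `metadata(x)$scaled`. Construct with [buildFeatureMatrix()].
#'
#' @seealso [buildFeatureMatrix()], [scaleFeatures()], [familyScore()]
#' @exportClass ITHExperiment
setClass("ITHExperiment", contains = "SummarizedExperiment")

#' Fitted overall ITH score model
#'
#' Univariately screened features, their multivariate Cox betas, the
#' constant offset of the linear score, and (once calibrated) the optimal
#' survival cut-point dichotomizing the score into low/high heterogeneity.
#'
#' @slot features screened feature names.
#' @slot betas named multivariate Cox coefficients (one per feature).
#' @slot intercept constant offset `a` of the score.
#' @slot cutoff dichotomization cut-point (NA until calibrated).
#' @slot alpha univariate screening significance level.
#' @slot medians per-feature medians used to impute missing values.
#' @slot diagnostics list: convergence flag, penalty used, per-feature
#'   univariate p, pruned collinear features.
#' @exportClass ITHModel
setClass("ITHModel",
    representation(features = "character", betas = "numeric",
                   intercept = "numeric", cutoff = "numeric",
                   alpha = "numeric", medians = "numeric",
                   diagnostics = "list"))

setValidity("ITHModel", function(object) {
    if (!identical(names(object@betas), object@features))
        return("betas must be named by the screened features")
    TRUE
})

#' Optimal cut-point search result
#'
#' @slot cutoff selected cut-point (argmin of the log-rank p over the
#'   candidate grid, ties broken toward the lower cut-off).
#' @slot candidates scanned candidate cut-points.
#' @slot statistics per-candidate log-rank chi-square.
#' @slot p_values per-candidate log-rank p.
#' @slot p_min minimal (uncorrected) p.
#' @slot p_corrected Miller-Siegmund min-p-corrected p.
#' @slot min_group_frac group-size constraint used.
#' @exportClass CutpointResult
setClass("CutpointResult",
    representation(cutoff = "numeric", candidates = "numeric",
                   statistics = "numeric", p_values = "numeric",
                   p_min = "numeric", p_corrected = "numeric",
                   min_group_frac = "numeric"))

#' Cox proportional-hazards fit summary
#'
#' @slot betas named coefficients.
#' @slot se standard errors.
#' @slot p Wald p-values.
#' @slot hr hazard ratios exp(beta).
#' @slot ci_lower,ci_upper 95% Wald confidence limits of the HR.
#' @slot loglik partial log-likelihood at the optimum.
#' @slot n,nevent subjects and events used.
#' @slot converged logical convergence flag.
#' @exportClass CoxFit
setClass("CoxFit",
    representation(betas = "numeric", se = "numeric", p = "numeric",
                   hr = "numeric", ci_lower = "numeric", ci_upper = "numeric",
                   loglik = "numeric", n = "integer", nevent = "integer",
                   converged = "logical"))

#' Kaplan-Meier curve
#'
#' Product-limit estimate for one group: stepwise survival probabilities at
#' the observed event times, with at-risk counts and censoring marks.
#'
#' @slot time event/censoring times.
#' @slot surv survival probability after each time.
#' @slot n_risk,n_event,n_censor risk-set and event/censor counts.
#' @slot group group label.
#' @exportClass KMCurve
setClass("KMCurve",
    representation(time = "numeric", surv = "numeric", n_risk = "numeric",
                   n_event = "numeric", n_censor = "numeric",
                   group = "character"))

setValidity("KMCurve", function(object) {
    s <- object@surv
    if (length(s) && (any(diff(s) > 1e-12) || any(s < -1e-12 | s > 1 + 1e-12)))
        return("survival must be non-increasing within [0, 1]")
    TRUE
})

#' Synthetic cohort parameters
#'
#' Conditions of the simulated study: per-patient spatial label-map stacks
#' with a latent heterogeneity level theta in [0, 1] and survival outcomes
#' whose hazard increases with theta. See [syntheticParams()] for defaults
#' and units.
#'
#' @slot n_patients cohort size.
#' @slot map_side_px side of the (already 5x-downsampled) label maps, px.
#' @slot pixel_size_um physical pixel size of those maps, micrometres.
#' @slot patch_side_um analysis patch side, micrometres.
#' @slot theta_dist Beta shape parameters of the theta prior.
#' @slot class_props region class proportions (tumor, tumor-associated
#'   stroma, other), summing to 1.
#' @slot grade_props,pleo_props level proportions for digital grade and
#'   pleomorphism (levels 1-3).
#' @slot nuclei_density expected nuclei per label-map pixel, named by
#'   nucleus class (tumor, immune, connective, nepith).
#' @slot cluster_scale_px spatial correlation length, px.
#' @slot dcis_frac fraction of tissue covered by simulated DCIS blobs.
#' @slot baseline_hazard exponential baseline hazard, 1/months.
#' @slot log_hr_per_theta true log hazard ratio per unit theta.
#' @slot censor_rate independent exponential censoring rate, 1/months.
#' @slot max_followup administrative censoring horizon, months.
#' @slot seed integer master seed.
#' @exportClass SyntheticParams
setClass("SyntheticParams",
    representation(n_patients = "integer", map_side_px = "integer",
                   pixel_size_um = "numeric", patch_side_um = "numeric",
                   theta_dist = "numeric", class_props = "numeric",
                   grade_props = "numeric", pleo_props = "numeric",
                   nuclei_density = "numeric", cluster_scale_px = "numeric",
                   dcis_frac = "numeric", baseline_hazard = "numeric",
                   log_hr_per_theta = "numeric", censor_rate = "numeric",
                   max_followup = "numeric", seed = "integer"))

setValidity("SyntheticParams", function(object) {
    chkprop <- function(p, what) {
        if (any(p < 0 | p > 1)) return(sprintf("%s must lie in [0, 1]", what))
        if (abs(sum(p) - 1) > 1e-8) return(sprintf("%s must sum to 1", what))
        TRUE
    }
    for (nm in c("class_props", "grade_props", "pleo_props")) {
        r <- chkprop(slot(object, nm), nm)
        if (!isTRUE(r)) return(r)
    }
    if (length(object@theta_dist) != 2L || any(object@theta_dist <= 0))
        return("theta_dist must be two positive Beta shape parameters")
    if (object@n_patients < 0L) return("n_patients must be >= 0")
    if (object@baseline_hazard < 0 || object@censor_rate < 0)
        return("rates must be non-negative")
    if (object@max_followup < 0) return("max_followup must be >= 0")
    if (any(object@nuclei_density < 0))
        return("nuclei densities must be non-negative")
    patch_px <- round(object@patch_side_um / object@pixel_size_um)
    if (object@map_side_px < patch_px)
        return("map_side_px must be at least one patch side")
    TRUE
})
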