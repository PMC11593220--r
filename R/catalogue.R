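#' @include AllClasses.R
NULL

# The 18 default analysis layers and their heterogeneity families.
default_layers <- function() {
    data.frame(
        layer = c("region_tumor", "region_tas", "region_other",
                  "nuclei_tumor", "nuclei_immune_intra",
                  "nuclei_immune_stromal", "nuclei_connective",
                  "nuclei_nepith",
                  "grade_g1", "grade_g2", "grade_g3",
                  "pleo_p1", "pleo_p2", "pleo_p3",
                  "diff_tubule", "diff_mitosis", "diff_cellularity",
                  "diff_discohesive"),
        family = c("stroma", "stroma", "stroma",
                   "differentiation", "TILs", "TILs", "stroma",
                   "differentiation",
                   rep("differentiation", 6L),
                   rep("differentiation", 4L)),
        # presence threshold on the patch fraction; nuclei layers are
        # sparse centroid rasters, so their threshold is lower
        threshold = c(rep(0.1, 3L), rep(0.01, 5L), rep(0.1, 10L)),
        stringsAsFactors = FALSE)
}

# The 18 default colocalization pairs and their families.
default_coloc_pairs <- function() {
    pair <- function(a, b, fam) data.frame(layer = a, layer2 = b,
                                           family = fam,
                                           stringsAsFactors = FALSE)
    rbind(
        pair("region_tumor", "nuclei_immune_intra", "TILs"),
        pair("region_tumor", "nuclei_immune_stromal", "TILs"),
        pair("region_tas", "nuclei_immune_stromal", "TILs"),
        pair("nuclei_tumor", "nuclei_immune_intra", "TILs"),
        pair("grade_g3", "nuclei_immune_intra", "TILs"),
        pair("grade_g3", "nuclei_immune_stromal", "TILs"),
        pair("nuclei_immune_intra", "nuclei_immune_stromal", "TILs"),
        pair("pleo_p3", "nuclei_immune_intra", "TILs"),
        pair("region_tumor", "region_tas", "stroma"),
        pair("region_tumor", "region_other", "stroma"),
        pair("region_tas", "region_other", "stroma"),
        pair("region_tas", "nuclei_connective", "stroma"),
        pair("region_other", "nuclei_connective", "stroma"),
        pair("nuclei_tumor", "region_tas", "stroma"),
        pair("grade_g1", "grade_g3", "differentiation"),
        pair("pleo_p1", "pleo_p3", "differentiation"),
        pair("diff_tubule", "diff_mitosis", "differentiation"),
        pair("nuclei_tumor", "nuclei_nepith", "differentiation"))
}

#' Default heterogeneity feature catalogue (162 features)
#'
#' Eight texture statistics (contrast, dissimilarity, homogeneity,
#' heterogeneity, correlation, uniformity, energy, entropy) for each of
#' the 18 default analysis layers (144 features) plus 18 designated
#' colocalization pairs, for a total of 162 features per patient. Each
#' feature belongs to one heterogeneity family: tumor-differentiation
#' layers (digital grade, pleomorphism, differentiation components, tumor
#' and normal-epithelial nuclei) map to `differentiation`, region and
#' connective-tissue layers to `stroma`, and immune-nuclei layers to
#' `TILs`.
#'
#' Texture statistics are computed on presence/absence patch maps obtained
#' by thresholding each layer's patch fraction (threshold 0.1; 0.01 for
#' the sparse nuclei centroid layers), colocalization directly on the
#' fraction vectors.
#'
#' @return A [FeatureCatalogue-class] with 162 entries.
#' @examples
#' cat162 <- defaultCatalogue()
#' nrow(catalogueDefs(cat162))
#' table(catalogueDefs(cat162)$family)
#' @export
defaultCatalogue <- function() {
    stats <- c("contrast", "dissimilarity", "homogeneity", "heterogeneity",
               "correlation", "uniformity", "energy", "entropy")
    ly <- default_layers()
    tex <- do.call(rbind, lapply(seq_len(nrow(ly)), function(i) {
        data.frame(name = paste0(ly$layer[i], "__", stats),
                   type = "texture", layer = ly$layer[i],
                   layer2 = NA_character_, statistic = stats,
                   family = ly$family[i], threshold = ly$threshold[i],
                   stringsAsFactors = FALSE)
    }))
    cp <- default_coloc_pairs()
    col <- data.frame(name = paste0("coloc__", cp$layer, "__", cp$layer2),
                      type = "coloc", layer = cp$layer, layer2 = cp$layer2,
                      statistic = "colocalization", family = cp$family,
                      threshold = NA_real_, stringsAsFactors = FALSE)
    new("FeatureCatalogue", defs = rbind(tex, col))
}

#' Read / write a feature catalogue as YAML
#'
#' @param x a [FeatureCatalogue-class].
#' @param path file path.
#' @return `readCatalogue` returns a [FeatureCatalogue-class];
#'   `writeCatalogue` returns `path` invisibly.
#' @export
writeCatalogue <- function(x, path) {
    stopifnot(is(x, "FeatureCatalogue"))
    yaml::write_yaml(lapply(seq_len(nrow(x@defs)), function(i)
        as.list(x@defs[i, ])), path)
    invisible(path)
}

#' @rdname writeCatalogue
#' @export
readCatalogue <- function(path) {
    lst <- yaml::read_yaml(path)
    defs <- do.call(rbind, lapply(lst, function(e) {
        e$layer2 <- if (is.null(e$layer2)) NA_character_ else e$layer2
        e$threshold <- if (is.null(e$threshold)) NA_real_ else e$threshold
        as.data.frame(e, stringsAsFactors = FALSE)
    }))
    new("FeatureCatalogue", defs = defs)
}
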