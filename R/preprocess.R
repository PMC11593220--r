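#' @include AllClasses.R utils.R
NULL

#' Build a tissue mask from a label map
#'
#' Takes the union of all non-background labels, applies a morphological
#' closing with a disc brush, and removes connected components smaller
#' than `min_object_px` (8-connectivity), mirroring the thresholding +
#' morphology step that precedes all downstream analysis.
#'
#' @param map a [LabelMap-class].
#' @param min_object_px smallest connected component kept, in pixels.
#' @param closing_radius_px radius of the closing brush; 0 skips closing.
#' @return A logical matrix of the same shape as the input grid.
#' @examples
#' g <- matrix(0L, 8, 8); g[3:6, 3:6] <- 1L
#' m <- new("LabelMap", grid = g, pixel_size_um = 2,
#'          class_codes = c(`1` = "tumor"))
#' sum(tissueMask(m, min_object_px = 4, closing_radius_px = 1))
#' @export
tissueMask <- function(map, min_object_px = 64L, closing_radius_px = 2L) {
    stopifnot(is(map, "LabelMap"))
    g <- labelGrid(map)
    mask <- g != 0L
    if (!any(mask)) {
        warning("label map contains no tissue; returning empty mask")
        return(mask)
    }
    if (closing_radius_px > 0) {
        brush <- EBImage::makeBrush(2L * as.integer(closing_radius_px) + 1L,
                                    shape = "disc")
        mask <- EBImage::closing(mask * 1, brush) > 0.5
    }
    if (min_object_px > 1L) {
        lab <- EBImage::bwlabel(mask * 1)
        sizes <- tabulate(lab[lab > 0])
        keep <- which(sizes >= min_object_px)
        mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
    }
    mask
}

#' Exclude DCIS areas from all analysis layers
#'
#' Zeroes every analysis layer inside the stack's DCIS mask. Areas
#' identified as in-situ disease are thereby removed from all subsequent
#' processing; [patchify()] additionally invalidates any patch the mask
#' touches. The operation is idempotent.
#'
#' @param stack a [LayerStack-class].
#' @return The stack with all layers zeroed inside the DCIS mask.
#' @export
excludeDCIS <- function(stack) {
    stopifnot(is(stack, "LayerStack"))
    d <- stack@dcis_mask
    if (!identical(dim(d), dim(stack@layers[[1L]])))
        stop("DCIS mask is not registered to the layers")
    if (!any(d)) return(stack)
    stack@layers <- lapply(stack@layers, function(m) m & !d)
    stack
}

#' Rasterize classified nuclei onto a down-sampled grid
#'
#' Assigns each nucleus to the pixel at its centroid in a `downsample`x
#' down-sampled frame: output grid is `ceiling(frame / downsample)` and a
#' point at 0-based coordinates (x, y) lands on down-sampled pixel
#' `(floor(x / downsample), floor(y / downsample))`. When several nuclei
#' map to one pixel, points are processed in (y, x, class code) order and
#' the last writer wins, which makes the raster bit-exact reproducible.
#'
#' @param cells a [CellPointSet-class].
#' @param downsample integer down-sampling factor (>= 1; default 5).
#' @return A [LabelMap-class] of nucleus class codes (tumor = 1,
#'   immune = 2, connective = 3, nepith = 4).
#' @examples
#' cs <- new("CellPointSet",
#'     points = data.frame(x_px = 12, y_px = 7, class = "tumor"),
#'     frame_dim = c(20L, 20L), pixel_size_um = 0.4)
#' labelGrid(rasterizeCells(cs, 5))[2, 3]
#' @export
rasterizeCells <- function(cells, downsample = 5L) {
    stopifnot(is(cells, "CellPointSet"))
    if (downsample < 1L) stop("downsample must be >= 1")
    codes <- c(tumor = 1L, immune = 2L, connective = 3L, nepith = 4L)
    p <- cells@points
    out_dim <- as.integer(ceiling(cells@frame_dim / downsample))
    g <- matrix(0L, out_dim[1L], out_dim[2L])
    if (nrow(p)) {
        bad <- p$x_px < 0 | p$x_px >= cells@frame_dim[2L] |
            p$y_px < 0 | p$y_px >= cells@frame_dim[1L]
        if (any(bad))
            stop(sprintf("point %d at (%g, %g) lies outside the frame",
                         which(bad)[1L], p$x_px[which(bad)[1L]],
                         p$y_px[which(bad)[1L]]))
        if (!all(p$class %in% names(codes)))
            stop("unknown nucleus class: ",
                 paste(setdiff(unique(p$class), names(codes)),
                       collapse = ", "))
        code <- codes[p$class]
        ord <- order(p$y_px, p$x_px, code)
        xd <- floor(p$x_px[ord] / downsample) + 1L
        yd <- floor(p$y_px[ord] / downsample) + 1L
        g[cbind(yd, xd)] <- code[ord]
    }
    new("LabelMap", grid = g,
        pixel_size_um = cells@pixel_size_um * downsample,
        class_codes = c(`1` = "tumor", `2` = "immune", `3` = "connective",
                        `4` = "nepith"))
}

#' Tile a layer stack into a patch grid of layer fractions
#'
#' Non-overlapping square patches of side
#' `round(patch_side_um / pixel_size_um)` pixels tile the grid from the
#' top-left (right/bottom remainders are dropped). For each patch k and
#' layer, `f(k, layer)` is the labelled-pixel fraction. Patches with
#' tissue coverage below `min_tissue_frac` or any DCIS overlap are marked
#' invalid and never enter feature computations. Graded layer groups
#' (`grade_g1..g3`, `pleo_p1..p3`) are additionally summarized as a
#' dominant level per patch, ties broken toward the lower level.
#'
#' @param stack a [LayerStack-class].
#' @param min_tissue_frac minimum tissue coverage of a valid patch
#'   (default 0.5).
#' @return A [PatchGrid-class].
#' @export
patchify <- function(stack, min_tissue_frac = 0.5) {
    stopifnot(is(stack, "LayerStack"))
    patch_px <- as.integer(round(stack@patch_side_um / stack@pixel_size_um))
    if (patch_px < 1L)
        stop("patch side is smaller than one pixel at this resolution")
    d <- dim(stack@layers[[1L]])
    if (any(d %/% patch_px < 1L))
        stop("grid is smaller than one patch")
    area <- patch_px^2
    fr <- vapply(stack@layers,
                 function(m) as.vector(patch_block_sums(m, patch_px)) / area,
                 numeric((d[1L] %/% patch_px) * (d[2L] %/% patch_px)))
    fr <- as.matrix(fr)
    pdim <- c(d[1L] %/% patch_px, d[2L] %/% patch_px)
    tissue <- as.vector(patch_block_sums(stack@tissue_mask, patch_px)) / area
    dcis <- as.vector(patch_block_sums(stack@dcis_mask, patch_px))
    valid <- tissue >= min_tissue_frac & dcis == 0
    fr[!valid, ] <- NA_real_

    level_maps <- list()
    for (grp in list(grade = c("grade_g1", "grade_g2", "grade_g3"),
                     pleo = c("pleo_p1", "pleo_p2", "pleo_p3"))) {
        if (all(grp %in% colnames(fr))) {
            sub <- fr[, grp, drop = FALSE]
            lv <- apply(sub, 1L, function(x) {
                if (anyNA(x) || all(x == 0)) NA_integer_
                else which.max(x)  # which.max takes the first (lower) tie
            })
            nm <- if (grp[1L] == "grade_g1") "grade" else "pleo"
            level_maps[[nm]] <- matrix(as.integer(lv), pdim[1L], pdim[2L])
        }
    }
    new("PatchGrid", fractions = fr, pdim = as.integer(pdim),
        valid = valid, tissue_frac = tissue, level_maps = level_maps,
        patch_px = patch_px, patch_side_um = stack@patch_side_um)
}
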