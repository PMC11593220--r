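#' @include AllClasses.R
NULL

#' Read and write label maps as single-channel images
#'
#' Label maps are stored as single-channel 8-bit PNG (or TIFF) images
#' whose pixel values are the integer class codes, with a sidecar JSON
#' file (`<image>.json`) recording the class-code map and the pixel size.
#'
#' @param map a [LabelMap-class].
#' @param path image path ending in `.png` or `.tif`/`.tiff`.
#' @return `writeLabelMap` returns `path` invisibly; `readLabelMap` a
#'   [LabelMap-class].
#' @export
writeLabelMap <- function(map, path) {
    stopifnot(is(map, "LabelMap"))
    g <- labelGrid(map)
    if (max(g) > 255L) stop("class codes above 255 cannot be stored as 8-bit")
    ext <- tolower(tools::file_ext(path))
    if (ext == "png") {
        png::writePNG(g / 255, path)
    } else if (ext %in% c("tif", "tiff")) {
        if (!requireNamespace("tiff", quietly = TRUE))
            stop("the tiff package is required for TIFF output")
        tiff::writeTIFF(g / 255, path, bits.per.sample = 8L)
    } else stop("unsupported image extension: ", ext)
    jsonlite::write_json(list(pixel_size_um = map@pixel_size_um,
                              class_codes = as.list(map@class_codes)),
                         paste0(path, ".json"), auto_unbox = TRUE)
    invisible(path)
}

#' @rdname writeLabelMap
#' @export
readLabelMap <- function(path) {
    ext <- tolower(tools::file_ext(path))
    img <- if (ext == "png") png::readPNG(path)
    else if (ext %in% c("tif", "tiff")) {
        if (!requireNamespace("tiff", quietly = TRUE))
            stop("the tiff package is required for TIFF input")
        tiff::readTIFF(path)
    } else stop("unsupported image extension: ", ext)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    g <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
    side <- paste0(path, ".json")
    if (file.exists(side)) {
        j <- jsonlite::read_json(side, simplifyVector = TRUE)
        new("LabelMap", grid = g, pixel_size_um = j$pixel_size_um,
            class_codes = unlist(j$class_codes))
    } else {
        v <- sort(setdiff(unique(as.vector(g)), 0L))
        new("LabelMap", grid = g, pixel_size_um = 1,
            class_codes = setNames(as.character(v), v))
    }
}

#' Read and write nuclei point tables
#'
#' CSV with columns `patient_id`, `x_px`, `y_px`, `class` (0-based
#' full-resolution pixel coordinates).
#'
#' @param cells a [CellPointSet-class].
#' @param patient_id identifier written with the points.
#' @param path CSV path.
#' @param frame_dim,pixel_size_um frame geometry for `readCellPoints`.
#' @return `writeCellPoints` returns `path` invisibly; `readCellPoints`
#'   a [CellPointSet-class].
#' @export
writeCellPoints <- function(cells, patient_id, path) {
    stopifnot(is(cells, "CellPointSet"))
    p <- cells@points
    df <- data.frame(patient_id = rep(patient_id, nrow(p)),
                     x_px = p$x_px, y_px = p$y_px, class = p$class)
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeCellPoints
#' @export
readCellPoints <- function(path, frame_dim, pixel_size_um = 1) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    new("CellPointSet",
        points = df[, c("x_px", "y_px", "class")],
        frame_dim = as.integer(frame_dim), pixel_size_um = pixel_size_um)
}

#' Write a patch grid as a compressed tabular file
#'
#' One row per patch (row, col, validity, tissue fraction, one column per
#' layer fraction), gzip-compressed CSV.
#'
#' @param grid a [PatchGrid-class].
#' @param path output path (a `.csv.gz` suffix is conventional).
#' @return `path`, invisibly.
#' @export
writePatchGrid <- function(grid, path) {
    stopifnot(is(grid, "PatchGrid"))
    np <- prod(grid@pdim)
    df <- data.frame(
        patch_row = rep(seq_len(grid@pdim[1L]), times = grid@pdim[2L]),
        patch_col = rep(seq_len(grid@pdim[2L]), each = grid@pdim[1L]),
        valid = grid@valid, tissue_frac = grid@tissue_frac,
        grid@fractions, check.names = FALSE)
    con <- gzfile(path, "w")
    on.exit(close(con))
    utils::write.csv(df, con, row.names = FALSE, na = "")
    invisible(path)
}

#' Read and write cohort tables
#'
#' CSV with `patient_id`, `time_months`, `event` and any further
#' covariate columns.
#'
#' @param cohort cohort data.frame.
#' @param path CSV path.
#' @return `writeCohort` returns `path` invisibly; `readCohort` the
#'   data.frame.
#' @export
writeCohort <- function(cohort, path) {
    utils::write.csv(cohort, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
    utils::read.csv(path, stringsAsFactors = FALSE)
}
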