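#' @include AllClasses.R utils.R
NULL

#' Synthetic cohort parameters
#'
#' Constructs the parameter set of the synthetic study: per-patient spatial
#' label-map stacks whose intermixing is controlled by a latent
#' heterogeneity level theta in `[0, 1]`, and exponential
#' proportional-hazards survival whose log hazard increases linearly with
#' theta.
#'
#' Maps are generated at the working resolution of the analysis (the
#' 5x-downsampled frame on which nuclei are rasterized); nuclei centroids
#' are simulated in the 5x finer full-resolution frame and rasterized with
#' [rasterizeCells()]. At `theta = 0` every class occupies a single
#' contiguous block; at `theta = 1` patch labels are independently drawn
#' from the class proportions; intermediate values interpolate by
#' resampling a Bernoulli(theta) subset of patches in correlated
#' super-blocks whose side shrinks from `cluster_scale_px` to one patch.
#'
#' @param n_patients cohort size (default 100).
#' @param map_side_px label-map side in pixels (default 372; with the
#'   default 2 um pixels and 62 um patches this is a 12 x 12 patch grid).
#' @param pixel_size_um pixel size of the label maps, micrometres
#'   (default 2).
#' @param patch_side_um analysis patch side, micrometres (default 62).
#' @param theta_dist Beta shape parameters of the theta prior (default
#'   `c(1.5, 1.5)`: cohorts contain both homogeneous and heterogeneous
#'   tumors).
#' @param class_props region proportions (tumor, tumor-associated stroma,
#'   other), default `c(0.45, 0.30, 0.25)`.
#' @param grade_props,pleo_props digital grade / pleomorphism level
#'   proportions, default `c(0.25, 0.50, 0.25)`.
#' @param nuclei_density expected nuclei per label-map pixel by class,
#'   default `c(tumor = 0.030, immune = 0.012, connective = 0.010,
#'   nepith = 0.004)`.
#' @param cluster_scale_px spatial correlation length in pixels
#'   (default 62, i.e. two patches).
#' @param dcis_frac fraction of tissue covered by simulated DCIS blobs
#'   (default 0.04).
#' @param baseline_hazard exponential baseline hazard in 1/months
#'   (default 0.01).
#' @param log_hr_per_theta true log hazard ratio per unit theta
#'   (default 1).
#' @param censor_rate independent exponential censoring rate in 1/months
#'   (default 0.003).
#' @param max_followup administrative censoring horizon in months
#'   (default 240).
#' @param seed integer master seed; fixed seed gives bit-identical output.
#' @return A [SyntheticParams-class] object.
#' @examples
#' p <- syntheticParams(n_patients = 5, seed = 1)
#' p
#' @export
syntheticParams <- function(n_patients = 100L,
                            map_side_px = 372L,
                            pixel_size_um = 2,
                            patch_side_um = 62,
                            theta_dist = c(1.5, 1.5),
                            class_props = c(tumor = 0.45, tas = 0.30,
                                            other = 0.25),
                            grade_props = c(0.25, 0.50, 0.25),
                            pleo_props = c(0.25, 0.50, 0.25),
                            nuclei_density = c(tumor = 0.030,
                                               immune = 0.012,
                                               connective = 0.010,
                                               nepith = 0.004),
                            cluster_scale_px = 62,
                            dcis_frac = 0.04,
                            baseline_hazard = 0.01,
                            log_hr_per_theta = 1,
                            censor_rate = 0.003,
                            max_followup = 240,
                            seed = 1L) {
    new("SyntheticParams",
        n_patients = as.integer(n_patients),
        map_side_px = as.integer(map_side_px),
        pixel_size_um = pixel_size_um,
        patch_side_um = patch_side_um,
        theta_dist = theta_dist,
        class_props = class_props,
        grade_props = grade_props,
        pleo_props = pleo_props,
        nuclei_density = nuclei_density,
        cluster_scale_px = cluster_scale_px,
        dcis_frac = dcis_frac,
        baseline_hazard = baseline_hazard,
        log_hr_per_theta = log_hr_per_theta,
        censor_rate = censor_rate,
        max_followup = max_followup,
        seed = as.integer(seed))
}

# Patch-level categorical field with theta-controlled intermixing.
# theta = 0: contiguous column-major blocks with exact proportions.
# theta = 1: i.i.d. labels. In between: a Bernoulli(theta) subset of
# patches is resampled, the resampled labels drawn on super-blocks of side
# c = max(1, round((1 - theta) * cluster_scale / patch_px)) patches.
mix_field <- function(pr, pc, props, theta, super_patches) {
    n <- pr * pc
    k <- length(props)
    counts <- diff(round(cumsum(c(0, props)) * n))
    base <- matrix(rep.int(seq_len(k), counts), pr, pc)
    if (theta <= 0) return(base)
    cs <- max(1L, as.integer(round((1 - theta) * super_patches)))
    sr <- ceiling(pr / cs)
    sc <- ceiling(pc / cs)
    slab <- matrix(sample.int(k, sr * sc, replace = TRUE, prob = props),
                   sr, sc)
    resampled <- slab[rep(seq_len(sr), each = cs)[seq_len(pr)],
                      rep(seq_len(sc), each = cs)[seq_len(pc)],
                      drop = FALSE]
    pick <- matrix(stats::runif(n) < theta, pr, pc)
    base[pick] <- resampled[pick]
    base
}

# Random disc blobs covering roughly frac of an nr x nc grid.
blob_mask <- function(nr, nc, frac, radius) {
    m <- matrix(FALSE, nr, nc)
    if (frac <= 0) return(m)
    radius <- max(3L, as.integer(round(radius)))
    nblob <- stats::rpois(1L, frac * nr * nc / (pi * radius^2))
    if (nblob == 0L) return(m)
    cr <- sample.int(nr, nblob, replace = TRUE)
    cc <- sample.int(nc, nblob, replace = TRUE)
    off <- seq(-radius, radius)
    disc <- outer(off, off, function(a, b) a^2 + b^2 <= radius^2)
    for (b in seq_len(nblob)) {
        rr <- cr[b] + off
        cj <- cc[b] + off
        okr <- rr >= 1L & rr <= nr
        okc <- cj >= 1L & cj <= nc
        m[rr[okr], cj[okc]] <- m[rr[okr], cj[okc]] | disc[okr, okc]
    }
    m
}

# Expand a patch-level label map to pixels with a smooth random
# displacement of the patch boundaries (piecewise-constant shifts of up
# to `w` px, shared period 8 px). Patch interiors stay pure; boundaries
# become wiggly like real region segmentations, so patches straddling a
# boundary carry mixed fractions.
warp_expand <- function(pm, patch_px, w = 6L) {
    pr <- nrow(pm); pc <- ncol(pm)
    side_r <- pr * patch_px; side_c <- pc * patch_px
    per <- 8L
    dy <- rep(sample.int(2L * w + 1L, ceiling(side_c / per),
                         replace = TRUE) - w - 1L, each = per)[seq_len(side_c)]
    dx <- rep(sample.int(2L * w + 1L, ceiling(side_r / per),
                         replace = TRUE) - w - 1L, each = per)[seq_len(side_r)]
    R <- matrix(seq_len(side_r), side_r, side_c)
    C <- matrix(seq_len(side_c), side_r, side_c, byrow = TRUE)
    DY <- matrix(dy, side_r, side_c, byrow = TRUE)
    DX <- matrix(dx, side_r, side_c)
    i <- pmin(pmax((R - 1L - DY) %/% patch_px + 1L, 1L), pr)
    j <- pmin(pmax((C - 1L - DX) %/% patch_px + 1L, 1L), pc)
    matrix(pm[cbind(as.vector(i), as.vector(j))], side_r, side_c)
}

# Sample n points uniformly (optionally weighted) from TRUE pixels of a
# mask; returns full-resolution 0-based coordinates (5x finer frame).
sample_points <- function(mask, n, weight = NULL) {
    idx <- which(mask)
    if (!length(idx) || n <= 0L)
        return(data.frame(x_px = numeric(0), y_px = numeric(0)))
    w <- if (is.null(weight)) NULL else weight[idx]
    pick <- sample(idx, n, replace = TRUE, prob = w)
    r <- (pick - 1L) %% nrow(mask) + 1L
    c <- (pick - 1L) %/% nrow(mask) + 1L
    data.frame(x_px = (c - 1L) * 5L + sample.int(5L, n, replace = TRUE) - 1L,
               y_px = (r - 1L) * 5L + sample.int(5L, n, replace = TRUE) - 1L)
}

#' Simulate one patient's layer-map stack
#'
#' Generates a registered set of label maps for one synthetic patient: a
#' region map (tumor / tumor-associated stroma / other), a nuclei point set
#' (simulated in the 5x finer frame and rasterized back at 5x
#' down-sampling), patch-level digital grade and pleomorphism maps, four
#' differentiation-component layers, and a DCIS blob mask — together with
#' the patient's latent heterogeneity level theta.
#'
#' @param params a [SyntheticParams-class] object.
#' @param patient_index 1-based patient index, `<= n_patients`.
#' @return A list with elements `stack` ([LayerStack-class] with the 18
#'   default analysis layers), `region` ([LabelMap-class]), `cells`
#'   ([CellPointSet-class]), `nuclei` (rasterized [LabelMap-class]),
#'   `grade` and `pleo` (patch-level integer matrices), and `theta`.
#' @examples
#' sim <- simulateLayerStack(syntheticParams(n_patients = 2), 1)
#' sim$theta
#' sim$stack
#' @export
simulateLayerStack <- function(params, patient_index) {
    stopifnot(is(params, "SyntheticParams"))
    validObject(params)
    if (patient_index < 1L || patient_index > params@n_patients)
        stop("patient_index must be in 1..n_patients")
    withr::with_seed(derive_seed(params@seed, patient_index, salt = 0L), {
        patch_px <- as.integer(round(params@patch_side_um /
                                     params@pixel_size_um))
        pr <- params@map_side_px %/% patch_px
        pc <- pr
        side <- pr * patch_px
        theta <- stats::rbeta(1L, params@theta_dist[1L],
                              params@theta_dist[2L])
        super <- params@cluster_scale_px / patch_px

        region_p <- mix_field(pr, pc, params@class_props, theta, super)
        grade_p <- mix_field(pr, pc, params@grade_props, theta, super)
        pleo_p <- mix_field(pr, pc, params@pleo_props, theta, super)

        flip <- function(m, p = 0.1) xor(m, matrix(stats::runif(length(m)) < p,
                                                   nrow(m)))
        tubule_p <- flip(grade_p == 1L)
        mitosis_p <- flip(grade_p == 3L)
        cellularity_p <- flip(pleo_p >= 2L)
        discohesive_p <- flip(pleo_p == 3L)

        # region segmentation boundaries are pixel-level, not patch-
        # aligned: warp them; grade/pleomorphism are patch-wise
        # predictions and stay aligned to the patch grid
        region <- warp_expand(region_p, patch_px)
        tumor <- region == 1L
        tas <- region == 2L
        other <- region == 3L

        dcis <- blob_mask(side, side, params@dcis_frac,
                          params@cluster_scale_px / 2)

        # nuclei: homogeneous Poisson within the permitted region classes,
        # immune density tripled in a 3-px band at the tumor-stroma border
        band <- (tumor & dilate4(tas, 3L)) | (tas & dilate4(tumor, 3L))
        dens <- params@nuclei_density
        masks <- list(tumor = tumor, immune = tumor | tas,
                      connective = tas | other, nepith = other)
        pts <- lapply(names(masks), function(cl) {
            m <- masks[[cl]]
            n <- stats::rpois(1L, dens[[cl]] * sum(m))
            w <- if (cl == "immune") 1 + 2 * band else NULL
            p <- sample_points(m, n, w)
            if (nrow(p)) p$class <- cl
            p
        })
        pts <- do.call(rbind, pts[vapply(pts, nrow, 1L) > 0])
        if (is.null(pts))
            pts <- data.frame(x_px = numeric(0), y_px = numeric(0),
                              class = character(0))
        cells <- new("CellPointSet", points = pts,
                     frame_dim = c(side * 5L, side * 5L),
                     pixel_size_um = params@pixel_size_um / 5)

        nuclei <- rasterizeCells(cells, downsample = 5L)
        ng <- labelGrid(nuclei)

        layers <- list(
            region_tumor = tumor,
            region_tas = tas,
            region_other = other,
            nuclei_tumor = ng == 1L,
            nuclei_immune_intra = ng == 2L & tumor,
            nuclei_immune_stromal = ng == 2L & !tumor,
            nuclei_connective = ng == 3L,
            nuclei_nepith = ng == 4L,
            grade_g1 = expand_patches(grade_p == 1L, patch_px),
            grade_g2 = expand_patches(grade_p == 2L, patch_px),
            grade_g3 = expand_patches(grade_p == 3L, patch_px),
            pleo_p1 = expand_patches(pleo_p == 1L, patch_px),
            pleo_p2 = expand_patches(pleo_p == 2L, patch_px),
            pleo_p3 = expand_patches(pleo_p == 3L, patch_px),
            diff_tubule = expand_patches(tubule_p, patch_px),
            diff_mitosis = expand_patches(mitosis_p, patch_px),
            diff_cellularity = expand_patches(cellularity_p, patch_px),
            diff_discohesive = expand_patches(discohesive_p, patch_px))

        stack <- new("LayerStack", layers = layers, dcis_mask = dcis,
                     tissue_mask = matrix(TRUE, side, side),
                     pixel_size_um = params@pixel_size_um,
                     patch_side_um = params@patch_side_um)

        region_map <- new("LabelMap", grid = region,
                          pixel_size_um = params@pixel_size_um,
                          class_codes = c(`1` = "tumor", `2` = "tas",
                                          `3` = "other"))
        list(stack = stack, region = region_map, cells = cells,
             nuclei = nuclei, grade = grade_p, pleo = pleo_p, theta = theta)
    })
}

#' Simulate survival outcomes from heterogeneity levels
#'
#' Event times follow an exponential proportional-hazards model with
#' hazard `baseline_hazard * exp(log_hr_per_theta * theta)`; subjects are
#' censored by an independent exponential mechanism at `censor_rate` and
#' administratively at `max_followup` months.
#'
#' @param theta_values per-patient heterogeneity levels in `[0, 1]`.
#' @param params a [SyntheticParams-class] object.
#' @param patient_id optional identifiers (default `P0001`, ...).
#' @return A cohort `data.frame` with columns `patient_id`, `time_months`,
#'   `event` (1 = death, 0 = censored) and `theta`.
#' @examples
#' p <- syntheticParams(n_patients = 4, seed = 2)
#' simulateSurvival(c(0.1, 0.4, 0.6, 0.9), p)
#' @export
simulateSurvival <- function(theta_values, params, patient_id = NULL) {
    stopifnot(is(params, "SyntheticParams"))
    validObject(params)
    if (length(theta_values) &&
        (any(theta_values < 0) || any(theta_values > 1)))
        stop("theta values must lie in [0, 1]")
    n <- length(theta_values)
    if (is.null(patient_id)) patient_id <- sprintf("P%04d", seq_len(n))
    withr::with_seed(derive_seed(params@seed, 0L, salt = 1L), {
        rate <- params@baseline_hazard *
            exp(params@log_hr_per_theta * theta_values)
        t_event <- ifelse(rate > 0, stats::rexp(n, pmax(rate, 1e-300)), Inf)
        t_cens <- if (params@censor_rate > 0)
            stats::rexp(n, params@censor_rate) else rep(Inf, n)
        horizon <- pmin(t_cens, params@max_followup)
        time <- pmin(t_event, horizon)
        event <- as.integer(t_event <= horizon)
        data.frame(patient_id = patient_id, time_months = time,
                   event = event, theta = theta_values,
                   stringsAsFactors = FALSE)
    })
}

#' Generate a full synthetic cohort
#'
#' Simulates `n_patients` layer-map stacks and an aligned cohort table with
#' survival outcomes driven by each patient's latent heterogeneity level.
#'
#' @param params a [SyntheticParams-class] object.
#' @return A list with `stacks` (list of [simulateLayerStack()] results,
#'   named by patient id) and `cohort` (the [simulateSurvival()] table).
#' @examples
#' cohort <- generateCohort(syntheticParams(n_patients = 3, seed = 5))
#' names(cohort$stacks)
#' cohort$cohort
#' @export
generateCohort <- function(params) {
    stopifnot(is(params, "SyntheticParams"))
    validObject(params)
    n <- params@n_patients
    ids <- sprintf("P%04d", seq_len(n))
    stacks <- lapply(seq_len(n), function(i) simulateLayerStack(params, i))
    names(stacks) <- ids
    thetas <- vapply(stacks, function(s) s$theta, numeric(1L))
    cohort <- simulateSurvival(unname(thetas), params, patient_id = ids)
    list(stacks = stacks, cohort = cohort)
}
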