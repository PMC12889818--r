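#' Generate a synthetic per-cell measurement table with ground truth
#'
#' Emulates the measured-cell stage of a multiplexed lung imaging
#' experiment. For each mouse (sample) a log-scale random intercept is
#' drawn; lesion sizes are zero-truncated negative binomial with the
#' genotype mean scaled by that intercept; lesion centers are placed with a
#' minimum separation (default 450 um) so planted lesions correspond 1:1 to
#' proximity-graph components at the 200 um radius; tumor cells scatter
#' isotropically around their center; each lesion receives a Poisson number
#' of immune cells, placed within 150 um of a randomly chosen tumor cell of
#' the lesion, with types drawn from the lesion's niche profile; background
#' immune cells are placed uniformly (with a small minimum separation so
#' nuclei do not coincide) with types drawn uniformly. Per-cell MFIs are
#' type-conditional log-normals with a configurable fold separation between
#' expected-positive and expected-negative markers; Ki67 ("any" sign) is
#' enriched in tumor cells of proliferative lesions.
#'
#' The generator is fully deterministic for a fixed config (including its
#' seed).
#'
#' @param config a \linkS4class{SimConfig}.
#' @param backgroundMinSeparation minimum distance (um) between background
#'   immune nuclei; default 4 (a nuclear diameter).
#' @return list with \code{cells} (data.frame: cell_id, sample_id, genotype,
#'   x_um, y_um, area_px, one MFI column per marker) and \code{truth}
#'   (a \linkS4class{SimTruth}).
#' @examples
#' sim <- generateCellTable(simConfig(nSamplesPerGenotype = 1,
#'                                    lesionsPerSample = 3, seed = 1))
#' head(sim$cells[, 1:6])
#' trueLesions(sim$truth)
#' @export
generateCellTable <- function(config, backgroundMinSeparation = 4) {
    stopIfNot(is(config, "SimConfig"), "config must be a SimConfig")
    validObject(config)
    set.seed(deriveSeed(config@seed, 11))
    panel <- config@panel
    imm <- immuneTypes(panel)
    fw <- config@fieldSize[1]; fh <- config@fieldSize[2]

    nPer <- config@nSamplesPerGenotype
    sampleIds <- paste0(rep(config@genotypes, each = nPer), "_",
                        rep(seq_len(nPer), 2))
    genoOf <- rep(config@genotypes, each = nPer)
    names(genoOf) <- sampleIds
    intercepts <- stats::rnorm(length(sampleIds), 0, config@sampleRandomSD)
    names(intercepts) <- sampleIds

    lesionRows <- list(); cellRows <- list()
    typeOut <- list(); lesOut <- list()
    nextLesion <- 0L
    margin <- max(3 * config@lesionSpatialSD + 160, 200)
    for (s in sampleIds) {
        nl <- config@lesionsPerSample
        centers <- placeCenters(nl, fw, fh, config@minLesionSeparation,
                                margin)
        mu <- exp(log(config@ztnbMu[[genoOf[[s]]]]) + intercepts[[s]])
        sizes <- if (nl > 0) rztnb(nl, mu, config@ztnbTheta) else integer()
        niche <- if (nl > 0) {
            if (config@nicheSizeLinked)
                ifelse(sizes <= config@nicheSizeCutoff, "niche2", "niche1")
            else sample(c("niche1", "niche2"), nl, replace = TRUE)
        } else character()
        for (l in seq_len(nl)) {
            nextLesion <- nextLesion + 1L
            lesionRows[[nextLesion]] <- data.frame(
                lesion_id = nextLesion, sample_id = s,
                genotype = genoOf[[s]], size = sizes[l], niche = niche[l],
                stringsAsFactors = FALSE)
            # tumor cells
            tx <- stats::rnorm(sizes[l], centers[l, 1],
                               config@lesionSpatialSD)
            ty <- stats::rnorm(sizes[l], centers[l, 2],
                               config@lesionSpatialSD)
            cellRows[[length(cellRows) + 1L]] <- data.frame(
                sample_id = s, genotype = genoOf[[s]], x_um = tx, y_um = ty,
                stringsAsFactors = FALSE)
            typeOut[[length(typeOut) + 1L]] <- rep(tumorType(panel),
                                                   sizes[l])
            lesOut[[length(lesOut) + 1L]] <- rep(nextLesion, sizes[l])
            # immune cells attached to this lesion
            ni <- stats::rpois(1, config@immuneCellsPerLesion)
            if (ni > 0) {
                prof <- config@nicheProfiles[niche[l], imm]
                itypes <- sample(imm, ni, replace = TRUE, prob = prof)
                anchor <- sample.int(sizes[l], ni, replace = TRUE)
                r <- 150 * sqrt(stats::runif(ni))
                a <- stats::runif(ni, 0, 2 * pi)
                cellRows[[length(cellRows) + 1L]] <- data.frame(
                    sample_id = s, genotype = genoOf[[s]],
                    x_um = tx[anchor] + r * cos(a),
                    y_um = ty[anchor] + r * sin(a),
                    stringsAsFactors = FALSE)
                typeOut[[length(typeOut) + 1L]] <- itypes
                lesOut[[length(lesOut) + 1L]] <- rep(nextLesion, ni)
            }
        }
        # background immune cells, uniform, with nuclear-scale separation
        nb <- stats::rpois(1, config@backgroundImmuneDensity *
                                 fw * fh / 1e6)
        if (nb > 0) {
            bg <- placePoints(nb, fw, fh, backgroundMinSeparation)
            cellRows[[length(cellRows) + 1L]] <- data.frame(
                sample_id = s, genotype = genoOf[[s]],
                x_um = bg[, 1], y_um = bg[, 2], stringsAsFactors = FALSE)
            typeOut[[length(typeOut) + 1L]] <-
                sample(imm, nrow(bg), replace = TRUE)
            lesOut[[length(lesOut) + 1L]] <- rep(NA_integer_, nrow(bg))
        }
    }

    cells <- do.call(rbind, cellRows)
    if (is.null(cells))
        cells <- data.frame(sample_id = character(), genotype = character(),
                            x_um = numeric(), y_um = numeric())
    types <- unlist(typeOut); lesionIds <- as.integer(unlist(lesOut))
    n <- nrow(cells)
    cells$x_um <- pmin(pmax(cells$x_um, 0), fw)
    cells$y_um <- pmin(pmax(cells$y_um, 0), fh)
    cells <- cbind(cell_id = sprintf("cell_%06d", seq_len(n)), cells)
    cells$area_px <- pmax(round(stats::rlnorm(n, log(60), 0.25)), 20)

    lesState <- if (length(lesionRows)) {
        lt0 <- do.call(rbind, lesionRows)
        ifelse(lt0$size <= config@nicheSizeCutoff, "dormant",
               "proliferative")[match(lesionIds, lt0$lesion_id)]
    } else rep(NA_character_, n)
    mfi <- simulateMFI(types, lesState, config)
    cells <- cbind(cells, mfi)
    rownames(cells) <- NULL

    lt <- if (length(lesionRows)) do.call(rbind, lesionRows) else
        data.frame(lesion_id = integer(), sample_id = character(),
                   genotype = character(), size = integer(),
                   niche = character())
    truth <- new("SimTruth", cellType = as.character(types),
                 lesionId = lesionIds, lesionTable = lt,
                 sampleIntercepts = intercepts)
    list(cells = cells, truth = truth)
}

# Lesion centers with minimum pairwise separation, by rejection sampling.
placeCenters <- function(n, fw, fh, minSep, margin) {
    if (n == 0) return(matrix(numeric(), 0, 2))
    if (fw - 2 * margin <= 0 || fh - 2 * margin <= 0 ||
        n * minSep^2 * 0.5 > (fw - 2 * margin) * (fh - 2 * margin))
        stop("field too small to place ", n, " lesions ", minSep,
             " um apart: enlarge fieldSize or reduce lesionsPerSample",
             call. = FALSE)
    pts <- matrix(NA_real_, n, 2)
    placed <- 0L; attempts <- 0L
    while (placed < n) {
        attempts <- attempts + 1L
        if (attempts > 2000L * n)
            stop("field too small to place ", n, " lesions ", minSep,
                 " um apart: enlarge fieldSize or reduce lesionsPerSample",
                 call. = FALSE)
        p <- c(stats::runif(1, margin, fw - margin),
               stats::runif(1, margin, fh - margin))
        if (placed == 0L ||
            min((pts[seq_len(placed), 1] - p[1])^2 +
                (pts[seq_len(placed), 2] - p[2])^2) >= minSep^2) {
            placed <- placed + 1L
            pts[placed, ] <- p
        }
    }
    pts
}

# Uniform points with a (small) minimum separation, inset from the field
# edge by the same distance so nuclei lie wholly inside the imaged field.
placePoints <- function(n, fw, fh, minSep) {
    pts <- matrix(NA_real_, n, 2)
    placed <- 0L; attempts <- 0L
    while (placed < n && attempts < 200L * n + 1000L) {
        attempts <- attempts + 1L
        p <- c(stats::runif(1, minSep, fw - minSep),
               stats::runif(1, minSep, fh - minSep))
        if (minSep <= 0 || placed == 0L ||
            min((pts[seq_len(placed), 1] - p[1])^2 +
                (pts[seq_len(placed), 2] - p[2])^2) >= minSep^2) {
            placed <- placed + 1L
            pts[placed, ] <- p
        }
    }
    pts[seq_len(placed), , drop = FALSE]
}

# Type-conditional log-normal MFIs; Ki67 follows lesion state for tumor
# cells.
simulateMFI <- function(types, lesState, config) {
    panel <- config@panel
    markers <- markerNames(panel)
    n <- length(types)
    baseNeg <- 2
    basePos <- baseNeg * config@foldSeparation
    mfi <- matrix(0, n, length(markers), dimnames = list(NULL, markers))
    if (n == 0) return(as.data.frame(mfi))
    signRows <- panel@signs[types, , drop = FALSE]
    for (m in markers) {
        s <- signRows[, m]
        mean0 <- ifelse(s > 0, log(basePos), log(baseNeg))
        if (any(s == 0)) {
            # "any" markers: Ki67-like; positive for tumor cells of
            # proliferative lesions, occasionally positive elsewhere
            pPos <- ifelse(types == tumorType(panel) & !is.na(lesState) &
                               lesState == "proliferative", 0.7, 0.05)
            isPos <- s == 0 & stats::runif(n) < pPos
            mean0[s == 0] <- log(baseNeg)
            mean0[isPos] <- log(basePos)
        }
        mfi[, m] <- stats::rlnorm(n, mean0, config@mfiSdLog)
    }
    as.data.frame(mfi)
}

#' Write / read the cell-table CSV interface
#'
#' Column layout: cell_id, sample_id, genotype, x_um, y_um, area_px, then
#' one MFI column per marker.
#'
#' @param cells cell table data.frame.
#' @param path CSV path.
#' @export
writeCellTable <- function(cells, path) {
    utils::write.csv(cells, path, row.names = FALSE)
    invisible(path)
}

#' @describeIn writeCellTable read and validate a cell-table CSV.
#' @param markers optional character vector of required MFI columns.
#' @export
readCellTable <- function(path, markers = NULL) {
    cells <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("cell_id", "sample_id", "genotype", "x_um", "y_um", "area_px")
    miss <- setdiff(need, names(cells))
    if (length(miss))
        stop("cell table is missing required columns: ",
             paste(miss, collapse = ", "), call. = FALSE)
    if (!is.null(markers)) {
        miss <- setdiff(markers, names(cells))
        if (length(miss))
            stop("cell table is missing MFI columns: ",
                 paste(miss, collapse = ", "), call. = FALSE)
    }
    cells
}

#' Write a simulation (cells + ground truth) to disk
#'
#' Cell table and per-cell truth as CSV, lesion truth as CSV, and the
#' generating parameters as JSON.
#'
#' @param sim result of \code{\link{generateCellTable}}.
#' @param config the \linkS4class{SimConfig} used.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeSimulation <- function(sim, config, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeCellTable(sim$cells, file.path(dir, "cells.csv"))
    utils::write.csv(data.frame(cell_id = sim$cells$cell_id,
                                true_type = sim$truth@cellType,
                                true_lesion_id = sim$truth@lesionId),
                     file.path(dir, "truth_cells.csv"), row.names = FALSE)
    utils::write.csv(sim$truth@lesionTable,
                     file.path(dir, "truth_lesions.csv"), row.names = FALSE)
    params <- list(seed = config@seed,
                   genotypes = config@genotypes,
                   nSamplesPerGenotype = config@nSamplesPerGenotype,
                   lesionsPerSample = config@lesionsPerSample,
                   ztnbMu = as.list(config@ztnbMu),
                   ztnbTheta = config@ztnbTheta,
                   sampleRandomSD = config@sampleRandomSD,
                   sampleIntercepts = as.list(sim$truth@sampleIntercepts),
                   pixelSize = config@pixelSize)
    jsonlite::write_json(params, file.path(dir, "params.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}
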