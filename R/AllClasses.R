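#' @import methods
#' @importFrom stats coef
NULL

#' Multi-channel image stack
#'
#' Holds one 2-D intensity grid per marker, all of identical shape, together
#' with the physical pixel size and a membrane/nuclear flag per marker.
#' Membrane markers are smoothed before per-cell quantification so that the
#' membrane stain overlaps the segmented nucleus; nuclear markers (e.g. Ki67
#' and GFP-class markers) are measured on the unsmoothed channel.
#'
#' @slot channels named list of numeric matrices, one per marker.
#' @slot pixelSize physical x-y pixel size in micrometres.
#' @slot membrane named logical vector; \code{TRUE} for membrane markers.
#'
#' @exportClass ChannelStack
setClass("ChannelStack",
    slots = c(channels = "list", pixelSize = "numeric", membrane = "logical"))

setValidity("ChannelStack", function(object) {
    ch <- object@channels
    if (length(ch) == 0L) return("stack must contain at least one channel")
    if (is.null(names(ch)) || anyDuplicated(names(ch)))
        return("channels must be uniquely named")
    if (!all(vapply(ch, is.matrix, logical(1))))
        return("all channels must be matrices")
    dims <- vapply(ch, dim, integer(2))
    if (any(dims != dims[, 1]))
        return("all channels must share one shape")
    if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
        return("pixelSize must be a single positive number")
    if (!setequal(names(object@membrane), names(ch)))
        return("membrane flags must be named after the channels")
    TRUE
})

#' Marker panel: expected sign profiles for known cell types
#'
#' The panel declares, for every known cell type, the expected
#' positive/negative expression of each marker (+1 positive, -1 negative,
#' 0 "any"), which markers are nuclear rather than membrane stains, which
#' type is the tumor type, and which types are excluded from downstream
#' analysis. After the exact-match gating stage the representative
#' quantitative profile of each type (per-marker mean MFI over the matched
#' cells) is filled into \code{profiles}.
#'
#' @slot markers character vector of marker names (panel order).
#' @slot signs numeric matrix, types x markers, entries in \{-1, 0, 1\}.
#' @slot nuclear named logical; \code{TRUE} for nuclear (unsmoothed) markers.
#' @slot tumorType name of the tumor cell type.
#' @slot excludeTypes types dropped from analysis after phenotyping.
#' @slot profiles types x markers matrix of representative MFIs (0-row until
#'   filled by \code{\link{representativeProfiles}}).
#'
#' @exportClass MarkerPanel
setClass("MarkerPanel",
    slots = c(markers = "character", signs = "matrix", nuclear = "logical",
              tumorType = "character", excludeTypes = "character",
              profiles = "matrix"))

setValidity("MarkerPanel", function(object) {
    if (!identical(colnames(object@signs), object@markers))
        return("signs columns must match markers")
    if (is.null(rownames(object@signs)))
        return("signs rows must be named by cell type")
    if (!all(object@signs %in% c(-1, 0, 1)))
        return("signs must be -1, 0 or +1")
    if (!setequal(names(object@nuclear), object@markers))
        return("nuclear flags must be named after the markers")
    if (length(object@tumorType) != 1L ||
        !(object@tumorType %in% rownames(object@signs)))
        return("tumorType must name one row of signs")
    def <- object@signs != 0
    key <- apply(ifelse(def, object@signs, 0), 1, paste, collapse = ",")
    if (anyDuplicated(key))
        return("expected sign profiles must be pairwise distinct")
    TRUE
})

#' Simulation configuration
#'
#' Study conditions for the synthetic-data generator: two genotypes with
#' several mice (samples) per genotype, per-sample random intercepts on the
#' log scale, lesion sizes drawn zero-truncated negative binomial with a
#' genotype-specific mean, immune cells attached to each lesion with a
#' composition drawn from one of two niche profiles (linked to lesion size
#' by default), plus uniform background immune cells, and optional rendering
#' to a multi-channel image stack.
#'
#' Construct with \code{\link{simConfig}}, which supplies defaults and
#' validates the result.
#'
#' @exportClass SimConfig
setClass("SimConfig",
    slots = c(nSamplesPerGenotype = "integer", genotypes = "character",
              lesionsPerSample = "integer", ztnbMu = "numeric",
              ztnbTheta = "numeric", sampleRandomSD = "numeric",
              nicheProfiles = "matrix", nicheSizeCutoff = "numeric",
              nicheSizeLinked = "logical", immuneCellsPerLesion = "numeric",
              lesionSpatialSD = "numeric", minLesionSeparation = "numeric",
              fieldSize = "numeric", backgroundImmuneDensity = "numeric",
              pixelSize = "numeric", foldSeparation = "numeric",
              mfiSdLog = "numeric", noisePoissonScale = "numeric",
              spillover = "matrix", panel = "MarkerPanel", seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (any(object@ztnbMu <= 0) || object@ztnbTheta <= 0)
        msg <- c(msg, "ztnb mean and dispersion must be positive")
    if (object@sampleRandomSD < 0)
        msg <- c(msg, "sampleRandomSD must be nonnegative")
    if (nrow(object@nicheProfiles) != 2L)
        msg <- c(msg, "exactly two niche profiles are required")
    if (any(object@nicheProfiles < 0) ||
        any(abs(rowSums(object@nicheProfiles) - 1) > 1e-9))
        msg <- c(msg, "niche profiles must each sum to 1 within 1e-9")
    if (any(object@fieldSize <= 0) || object@pixelSize <= 0)
        msg <- c(msg, "field size and pixel size must be positive")
    if (object@backgroundImmuneDensity < 0)
        msg <- c(msg, "background immune density must be nonnegative")
    if (object@lesionSpatialSD * 10 > min(object@fieldSize))
        msg <- c(msg, "field too small: lesionSpatialSD must be << field edge")
    if (length(object@genotypes) != 2L || anyDuplicated(object@genotypes))
        msg <- c(msg, "exactly two distinct genotype labels are required")
    if (length(object@ztnbMu) != 2L ||
        !setequal(names(object@ztnbMu), object@genotypes))
        msg <- c(msg, "ztnbMu must be named by the two genotypes")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Ground truth of a simulated dataset
#'
#' @slot cellType character, the true type of every cell (cell order of the
#'   generated table).
#' @slot lesionId integer, the true lesion id per cell (NA for background
#'   immune cells; tumor cells always have exactly one lesion id).
#' @slot lesionTable data.frame: lesion_id, sample_id, genotype, size, niche.
#' @slot sampleIntercepts named numeric, realized per-sample random effects.
#'
#' @exportClass SimTruth
setClass("SimTruth",
    slots = c(cellType = "character", lesionId = "integer",
              lesionTable = "data.frame", sampleIntercepts = "numeric"))

setValidity("SimTruth", function(object) {
    lt <- object@lesionTable
    if (nrow(lt) && any(lt$size < 1))
        return("lesion sizes must be >= 1")
    TRUE
})

#' A set of tumor lesions with attached immune cells
#'
#' Lesions are the connected components of the proximity graph over tumor
#' cells in which two tumor cells are neighbors iff their centroid distance
#' is at most \code{radius} micrometres (inclusive). Every tumor cell
#' belongs to exactly one lesion; a non-tumor cell is a member of every
#' lesion that contains a tumor cell within \code{radius} of it (zero, one,
#' or several). A lesion is dormant iff its tumor-cell count is at most
#' \code{dormancyCutoff}, proliferative otherwise.
#'
#' @slot lesions data.frame: lesion_id, sample_id, genotype, size, state.
#' @slot tumorCells data.frame: cell_id, lesion_id (one row per tumor cell).
#' @slot immuneMembers data.frame: lesion_id, cell_id, type (one row per
#'   membership; a cell may appear under several lesions).
#' @slot radius neighborhood radius in micrometres.
#' @slot dormancyCutoff maximum tumor-cell count of a dormant lesion.
#'
#' @exportClass LesionSet
setClass("LesionSet",
    slots = c(lesions = "data.frame", tumorCells = "data.frame",
              immuneMembers = "data.frame", radius = "numeric",
              dormancyCutoff = "numeric"))

setValidity("LesionSet", function(object) {
    ls <- object@lesions
    if (nrow(ls)) {
        if (any(ls$size < 1)) return("every lesion must have size >= 1")
        ok <- ifelse(ls$size <= object@dormancyCutoff, "dormant",
                     "proliferative")
        if (!identical(as.character(ls$state), ok))
            return("state must be dormant iff size <= dormancyCutoff")
    }
    if (anyDuplicated(object@tumorCells$cell_id))
        return("a tumor cell may belong to exactly one lesion")
    TRUE
})

#' Lesion x immune-type composition matrix
#'
#' A \linkS4class{SummarizedExperiment} with immune types as rows and
#' lesions as columns, carrying three assays: raw \code{counts}, centered
#' log-ratios (\code{clr}, computed per lesion after adding a pseudocount),
#' and per-type standardized CLRs (\code{zclr}, each type z-scored across
#' lesions). Lesion metadata (sample, genotype, size, state) lives in
#' \code{colData}.
#'
#' @exportClass CompositionMatrix
setClass("CompositionMatrix", contains = "SummarizedExperiment")

setValidity("CompositionMatrix", function(object) {
    a <- SummarizedExperiment::assayNames(object)
    need <- c("counts", "clr", "zclr")
    if (!all(need %in% a))
        return("assays counts, clr and zclr are required")
    clr <- SummarizedExperiment::assay(object, "clr")
    if (ncol(clr) && max(abs(colSums(clr))) > 1e-9)
        return("each lesion's CLR vector must sum to 0 within 1e-9")
    z <- SummarizedExperiment::assay(object, "zclr")
    if (ncol(z) >= 2) {
        if (max(abs(rowMeans(z))) > 1e-9)
            return("standardized CLR rows must have mean 0")
        sds <- apply(z, 1, stats::sd)
        if (max(abs(sds - 1)) > 1e-9)
            return("standardized CLR rows must have SD 1")
    }
    TRUE
})

#' A fitted mixed-effects model
#'
#' Result container for the three random-intercept models: binomial
#' (cell-level tumor status ~ genotype), zero-truncated negative binomial
#' (lesion size ~ genotype) and Gaussian (PC1 ~ size * genotype), each with
#' a per-sample random intercept marginalized by adaptive Gauss-Hermite
#' quadrature (Gaussian: closed-form marginal likelihood).
#'
#' @slot family one of "binomial", "ztnb", "gaussian".
#' @slot coefficients named fixed-effect estimates.
#' @slot se standard errors (Wald, from the observed information).
#' @slot z Wald z statistics.
#' @slot p two-sided Wald p-values.
#' @slot sigmaU random-intercept SD.
#' @slot theta NB dispersion (ztnb) or residual SD (gaussian); NA for
#'   binomial.
#' @slot logLik maximized marginal log-likelihood.
#' @slot converged logical convergence flag.
#' @slot nObs,nGroups observation and group counts.
#' @slot notes character diagnostics (boundary fits, degraded fits).
#'
#' @exportClass MixedModelFit
setClass("MixedModelFit",
    slots = c(family = "character", coefficients = "numeric", se = "numeric",
              z = "numeric", p = "numeric", sigmaU = "numeric",
              theta = "numeric", logLik = "numeric", converged = "logical",
              nObs = "integer", nGroups = "integer", notes = "character"))

setValidity("MixedModelFit", function(object) {
    if (!object@family %in% c("binomial", "ztnb", "gaussian"))
        return("unknown family")
    if (length(object@sigmaU) && object@sigmaU < -1e-12)
        return("sigmaU must be nonnegative")
    if (any(object@p < -1e-12 | object@p > 1 + 1e-12, na.rm = TRUE))
        return("p-values must lie in [0, 1]")
    if (!is.finite(object@logLik))
        return("log-likelihood must be finite at the reported optimum")
    TRUE
})
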