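#' @rdname ChannelStack-class
#' @export
setMethod("channelNames", "ChannelStack", function(x) names(x@channels))

#' @rdname ChannelStack-class
#' @export
setMethod("pixelSize", "ChannelStack", function(x) x@pixelSize)

#' @rdname ChannelStack-class
#' @export
setMethod("getChannel", "ChannelStack", function(x, marker) {
    if (!marker %in% names(x@channels))
        stop("marker '", marker, "' is not in the stack", call. = FALSE)
    x@channels[[marker]]
})

#' @rdname ChannelStack-class
#' @export
setMethod("dim", "ChannelStack", function(x) dim(x@channels[[1]]))

setMethod("show", "ChannelStack", function(object) {
    d <- dim(object)
    cat("ChannelStack:", length(object@channels), "channels,",
        d[1], "x", d[2], "px @", object@pixelSize, "um/px\n")
    cat("  markers:", paste(names(object@channels), collapse = ", "), "\n")
    cat("  membrane:", paste(names(which(object@membrane)), collapse = ", "),
        "\n")
})

#' @rdname MarkerPanel-class
#' @export
setMethod("markerNames", "MarkerPanel", function(x) x@markers)

#' @rdname MarkerPanel-class
#' @export
setMethod("cellTypes", "MarkerPanel", function(x) rownames(x@signs))

#' @rdname MarkerPanel-class
#' @export
setMethod("tumorType", "MarkerPanel", function(x) x@tumorType)

#' @rdname MarkerPanel-class
#' @export
setMethod("immuneTypes", "MarkerPanel", function(x)
    setdiff(rownames(x@signs), c(x@tumorType, x@excludeTypes)))

setMethod("show", "MarkerPanel", function(object) {
    cat("MarkerPanel:", length(object@markers), "markers,",
        nrow(object@signs), "cell types (tumor:", object@tumorType, ")\n")
    if (length(object@excludeTypes))
        cat("  excluded types:",
            paste(object@excludeTypes, collapse = ", "), "\n")
    cat("  representative profiles:",
        if (nrow(object@profiles)) "filled" else "not yet filled", "\n")
})

#' @rdname LesionSet-class
#' @export
setMethod("lesionTable", "LesionSet", function(x) x@lesions)

#' @rdname LesionSet-class
#' @export
setMethod("immuneMembers", "LesionSet", function(x) x@immuneMembers)

#' @rdname LesionSet-class
#' @export
setMethod("length", "LesionSet", function(x) nrow(x@lesions))

setMethod("show", "LesionSet", function(object) {
    ls <- object@lesions
    cat("LesionSet:", nrow(ls), "lesions over",
        length(unique(ls$sample_id)), "samples (radius",
        object@radius, "um, dormancy cutoff", object@dormancyCutoff, ")\n")
    if (nrow(ls)) {
        cat(sprintf("  dormant %d / proliferative %d; size range %d-%d\n",
            sum(ls$state == "dormant"), sum(ls$state == "proliferative"),
            min(ls$size), max(ls$size)))
        cat("  immune memberships:", nrow(object@immuneMembers), "\n")
    }
})

#' @rdname SimTruth-class
#' @export
setMethod("trueLesions", "SimTruth", function(x) x@lesionTable)

#' @rdname SimTruth-class
#' @export
setMethod("trueTypes", "SimTruth", function(x) x@cellType)

setMethod("show", "SimTruth", function(object) {
    cat("SimTruth:", length(object@cellType), "cells,",
        nrow(object@lesionTable), "lesions,",
        length(object@sampleIntercepts), "samples\n")
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", 2 * object@nSamplesPerGenotype, "samples (",
        paste(object@genotypes, collapse = " vs "), "),",
        object@lesionsPerSample, "lesions/sample\n")
    cat("  lesion size ~ ZTNB(mu = ",
        paste(sprintf("%s: %.1f", names(object@ztnbMu), object@ztnbMu),
              collapse = ", "),
        "; theta = ", object@ztnbTheta, "), sample SD ",
        object@sampleRandomSD, "\n", sep = "")
    cat("  field", paste(object@fieldSize, collapse = " x "), "um, pixel",
        object@pixelSize, "um, seed", object@seed, "\n")
})

#' @rdname MixedModelFit-class
#' @param object a \linkS4class{MixedModelFit}
#' @export
setMethod("coef", "MixedModelFit", function(object) object@coefficients)

#' @rdname MixedModelFit-class
#' @export
setMethod("logLik", "MixedModelFit", function(object) object@logLik)

setMethod("show", "MixedModelFit", function(object) {
    fam <- c(binomial = "Binomial (logit link)",
             ztnb = "Zero-truncated negative binomial (log link)",
             gaussian = "Gaussian (identity link)")[object@family]
    cat(fam, "mixed model with per-sample random intercept\n")
    cat(sprintf("  n = %d observations, %d groups; logLik = %.3f%s\n",
        object@nObs, object@nGroups, object@logLik,
        if (object@converged) "" else "  [NOT CONVERGED]"))
    tab <- data.frame(Estimate = object@coefficients, `Std.Error` = object@se,
                      z = object@z, `p` = signif(object@p, 3),
                      check.names = FALSE)
    print(tab, digits = 4)
    cat(sprintf("  random-intercept SD: %.4f\n", object@sigmaU))
    if (object@family == "ztnb")
        cat(sprintf("  dispersion theta: %.4f\n", object@theta))
    if (object@family == "gaussian")
        cat(sprintf("  residual SD: %.4f\n", object@theta))
    if (length(object@notes) && nzchar(object@notes[1]))
        cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})
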