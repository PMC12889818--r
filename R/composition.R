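#' Lesion x immune-type count matrix
#'
#' Counts each immune type's members per lesion (excluded panel types are
#' dropped; multi-lesion members count once in every lesion they belong
#' to). Returned in Bioconductor orientation: immune types as rows,
#' lesions as columns, columns ordered by lesion id and rows in panel
#' order — stable across runs. Lesions with no immune members keep an
#' all-zero column.
#'
#' @param lesionSet a \linkS4class{LesionSet}.
#' @param panel a \linkS4class{MarkerPanel}.
#' @return integer matrix, types x lesions.
#' @export
lesionCounts <- function(lesionSet, panel) {
    types <- immuneTypes(panel)
    lids <- lesionTable(lesionSet)$lesion_id
    mem <- immuneMembers(lesionSet)
    mem <- mem[mem$type %in% types, , drop = FALSE]
    tab <- table(factor(mem$type, levels = types),
                 factor(mem$lesion_id, levels = lids))
    m <- matrix(as.integer(tab), nrow = length(types),
                dimnames = list(types, as.character(lids)))
    m
}

#' Centered log-ratio transform with per-type standardization
#'
#' Re-expresses each lesion's immune composition as centered log-ratios —
#' \eqn{clr_i = \ln(c_i + pc) - \frac{1}{K}\sum_k \ln(c_k + pc)} — to
#' remove the unit-sum constraint of compositional data, then z-scores
#' each type across lesions so that differences in total abundance across
#' cell types do not dominate downstream correlation and PCA.
#'
#' @param counts types x lesions count matrix
#'   (\code{\link{lesionCounts}}).
#' @param pseudocount added before the log (default 0.5); must be positive
#'   when zeros are present.
#' @param lesionData optional data.frame of per-lesion metadata (one row
#'   per column of \code{counts}) stored in \code{colData}.
#' @return a \linkS4class{CompositionMatrix} with assays \code{counts},
#'   \code{clr} and \code{zclr}.
#' @examples
#' cm <- clrStandardize(matrix(rpois(60, 5) + 1, 6,
#'                      dimnames = list(letters[1:6], NULL)))
#' SummarizedExperiment::assay(cm, "clr")[, 1:3]
#' @export
clrStandardize <- function(counts, pseudocount = 0.5, lesionData = NULL) {
    stopIfNot(is.matrix(counts) && all(counts >= 0),
              "counts must be a nonnegative matrix")
    if (any(counts == 0) && pseudocount <= 0)
        stop("pseudocount must be positive when zero counts are present",
             call. = FALSE)
    if (is.null(colnames(counts)))
        colnames(counts) <- as.character(seq_len(ncol(counts)))
    lc <- log(counts + pseudocount)
    clr <- sweep(lc, 2, colMeans(lc))
    if (ncol(counts) >= 2) {
        sds <- apply(clr, 1, stats::sd)
        flat <- sds < 1e-12
        if (any(flat))
            stop("type(s) constant across lesions (SD = 0): ",
                 paste(rownames(counts)[flat], collapse = ", "),
                 call. = FALSE)
        zclr <- (clr - rowMeans(clr)) / sds
    } else {
        zclr <- clr * 0
    }
    cd <- if (is.null(lesionData))
        S4Vectors::DataFrame(row.names = colnames(counts))
    else S4Vectors::DataFrame(lesionData, row.names = colnames(counts))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts, clr = clr, zclr = zclr),
        colData = cd,
        metadata = list(pseudocount = pseudocount))
    new("CompositionMatrix", se)
}

#' Correlation modules of co-occurring immune types
#'
#' Pearson correlations between the standardized CLR profiles of the
#' immune types across lesions, clustered by average-linkage hierarchical
#' clustering on distance 1 - r and cut into exactly two modules. Module 1
#' is the module containing the tumor-proximal reference type (the T-cell
#' niche of proliferative lesions); ties broken lexicographically.
#'
#' @param cm a \linkS4class{CompositionMatrix} (at least 3 lesions).
#' @param referenceType immune type anchoring module 1 (default
#'   \code{"CD8_T"}).
#' @param method correlation flavor, "pearson" (default) or "spearman".
#' @param nModules number of modules to cut (default 2).
#' @return list: \code{correlation} (types x types, unit diagonal),
#'   \code{modules} (named integer vector, 1 = reference module).
#' @export
correlationModules <- function(cm, referenceType = "CD8_T",
                               method = c("pearson", "spearman"),
                               nModules = 2) {
    method <- match.arg(method)
    z <- SummarizedExperiment::assay(cm, "zclr")
    if (ncol(z) < 3)
        stop("at least 3 lesions are required for correlation modules",
             call. = FALSE)
    r <- stats::cor(t(z), method = method)
    hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
    cut <- stats::cutree(hc, k = nModules)
    if (!referenceType %in% names(cut))
        referenceType <- sort(names(cut))[1]
    refMod <- cut[[referenceType]]
    ord <- c(refMod, sort(setdiff(unique(cut), refMod)))
    modules <- match(cut, ord)
    names(modules) <- names(cut)
    list(correlation = r, modules = modules)
}

#' PCA of the standardized CLR matrix
#'
#' Singular value decomposition of the lesions x types standardized CLR
#' matrix (already column-centered and scaled by construction). Loadings
#' are orthonormal; within each component the loading of largest magnitude
#' is made positive, pinning the otherwise arbitrary signs. PC1 scores
#' order lesions along the dominant axis of immune-composition variation.
#'
#' @param cm a \linkS4class{CompositionMatrix} (at least 3 lesions, 2
#'   types).
#' @return list: \code{loadings} (types x components), \code{scores}
#'   (lesions x components), \code{varExplained} (fraction per
#'   component), \code{pc1} (named by lesion).
#' @export
pcaScores <- function(cm) {
    z <- SummarizedExperiment::assay(cm, "zclr")
    if (ncol(z) < 3 || nrow(z) < 2)
        stop("PCA needs at least 3 lesions and 2 immune types",
             call. = FALSE)
    X <- t(z)  # lesions x types
    sv <- svd(X)
    if (max(sv$d) <= 1e-12)
        stop("degenerate input: standardized CLR matrix has rank 0",
             call. = FALSE)
    keep <- sv$d > max(sv$d) * 1e-12
    U <- sv$u[, keep, drop = FALSE]
    D <- sv$d[keep]
    V <- sv$v[, keep, drop = FALSE]
    flip <- vapply(seq_len(ncol(V)), function(j)
        V[which.max(abs(V[, j])), j] < 0, logical(1))
    V[, flip] <- -V[, flip]
    U[, flip] <- -U[, flip]
    scores <- U %*% diag(D, nrow = length(D))
    rownames(V) <- rownames(z)
    rownames(scores) <- colnames(z)
    colnames(V) <- colnames(scores) <- paste0("PC", seq_along(D))
    list(loadings = V, scores = scores,
         varExplained = D^2 / sum(sv$d^2),
         pc1 = stats::setNames(scores[, 1], colnames(z)))
}

#' Full niche analysis of a lesion set
#'
#' Counts, CLR + standardization, correlation modules, and PCA in one
#' call.
#'
#' @inheritParams lesionCounts
#' @inheritParams clrStandardize
#' @inheritParams correlationModules
#' @return list: \code{composition} (\linkS4class{CompositionMatrix}),
#'   \code{correlation}, \code{modules}, \code{pca}.
#' @export
nicheAnalysis <- function(lesionSet, panel, pseudocount = 0.5,
                          referenceType = "CD8_T") {
    counts <- lesionCounts(lesionSet, panel)
    cm <- clrStandardize(counts, pseudocount,
                         lesionData = lesionTable(lesionSet))
    mods <- correlationModules(cm, referenceType)
    pca <- pcaScores(cm)
    list(composition = cm, correlation = mods$correlation,
         modules = mods$modules, pca = pca)
}
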