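#' Elbow threshold of a marker's expression distribution
#'
#' Separates positive from negative expression at the "elbow" of the
#' sorted-value curve: values are sorted ascending, plotted on a log1p
#' scale against rank (both axes normalized to [0, 1]), and the knee is
#' the point of maximum perpendicular distance from the chord joining the
#' curve's endpoints (the kneedle construction; the last point within 1\%
#' of the maximum when the distance plateaus). The threshold is drawn
#' midway, on the log1p scale, between the knee value and the next sorted
#' value — inside the expression gap when one exists. A cell is positive
#' iff its value exceeds the threshold. Deterministic and robust to
#' rescaling of the values (up to the mild distortion of log1p).
#'
#' @param values numeric MFI sample for one marker (at least 50 values).
#' @return the threshold, on the original MFI scale.
#' @examples
#' v <- c(rlnorm(900, log(0.1), 0.7), rlnorm(100, log(10), 0.4))
#' elbowThreshold(v)
#' @export
elbowThreshold <- function(values) {
    stopIfNot(length(values) >= 50,
              "need at least 50 values for a stable elbow")
    if (max(values) - min(values) <= 0)
        stop("marker uninformative: all values equal", call. = FALSE)
    srt <- sort(values)
    n <- length(srt)
    y <- log1p(srt - srt[1])
    y <- y / y[n]
    x <- (seq_len(n) - 1) / (n - 1)
    # perpendicular distance to the y = x chord is |x - y|/sqrt(2); the
    # knee may lie below the chord (minority-positive marker) or above it
    # (majority-positive marker). Along a near-flat distance plateau the
    # knee is taken at its upper end (last index within 1% of the max),
    # and the threshold is drawn midway (log1p scale) between the knee
    # value and the next sorted value, i.e. in the gap that separates
    # negative from positive expression when one exists.
    d <- abs(x - y)
    k <- max(which(d > max(d) - 0.01))
    if (k >= n) k <- n - 1L
    expm1((log1p(srt[k]) + log1p(srt[k + 1])) / 2)
}

#' Gate cells and match exact expected sign profiles
#'
#' Computes each cell's +/- profile from the per-marker thresholds and
#' assigns a cell to a known type iff its profile satisfies exactly one
#' template's expected signs on all definite-sign markers ("any" markers
#' are ignored). Cells whose profile satisfies zero or several templates
#' remain unmatched and flow to the regression stage.
#'
#' @param cells cell table with one MFI column per marker.
#' @param thresholds named numeric, one threshold per definite-sign marker.
#' @param panel a \linkS4class{MarkerPanel}.
#' @return data.frame: cell_id, stage ("matched"/"unmatched"), type.
#' @export
gateAndMatch <- function(cells, thresholds, panel) {
    signs <- panel@signs
    def <- colnames(signs)[apply(signs != 0, 2, any)]
    miss <- setdiff(def, names(thresholds))
    if (length(miss))
        stop("missing thresholds for definite-sign marker(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    pos <- vapply(def, function(m) cells[[m]] > thresholds[[m]],
                  logical(nrow(cells)))
    pos <- matrix(pos, nrow = nrow(cells), dimnames = list(NULL, def))
    nmatch <- integer(nrow(cells))
    type <- rep(NA_character_, nrow(cells))
    for (t in rownames(signs)) {
        s <- signs[t, def]
        d <- s != 0
        ok <- rowSums(pos[, def[d], drop = FALSE] !=
                      rep(s[d] > 0, each = nrow(cells))) == 0
        type[ok & nmatch == 0L] <- t
        nmatch <- nmatch + ok
    }
    matched <- nmatch == 1L
    data.frame(cell_id = cells$cell_id,
               stage = ifelse(matched, "matched", "unmatched"),
               type = ifelse(matched, type, NA_character_),
               stringsAsFactors = FALSE)
}

#' Representative quantitative expression profiles
#'
#' Fills each type's representative profile with the per-marker mean MFI
#' over its exactly-matched cells. Types supported by fewer than
#' \code{minSupport} matched cells are an error: their profile would be
#' too noisy to serve as a regression predictor.
#'
#' @param cells cell table with MFI columns.
#' @param matches result of \code{\link{gateAndMatch}}.
#' @param panel a \linkS4class{MarkerPanel}.
#' @param minSupport minimum matched cells per type (default 20).
#' @return the panel with its \code{profiles} slot filled.
#' @export
representativeProfiles <- function(cells, matches, panel,
                                   minSupport = 20) {
    types <- cellTypes(panel)
    markers <- markerNames(panel)
    counts <- table(factor(matches$type, levels = types))
    low <- names(counts)[counts < minSupport]
    if (length(low))
        stop("type(s) below minimum matched-cell support (", minSupport,
             "): ", paste(low, collapse = ", "), call. = FALSE)
    prof <- matrix(NA_real_, length(types), length(markers),
                   dimnames = list(types, markers))
    for (t in types) {
        idx <- which(matches$stage == "matched" & matches$type == t)
        prof[t, ] <- colMeans(as.matrix(cells[idx, markers, drop = FALSE]))
    }
    panel@profiles <- prof
    validObject(panel)
    panel
}

#' Regression-mixture assignment of unmatched cells
#'
#' Models each unmatched cell's MFI-across-markers vector as a linear
#' mixture of the representative type profiles (ordinary least squares,
#' intercept included, one predictor column per known type). Among type
#' coefficients that are positive and significant (two-sided t-test,
#' \code{p < alpha}), the largest estimate wins; a cell with no qualifying
#' coefficient stays uncategorized.
#'
#' @param cells cell table with MFI columns (the unmatched cells).
#' @param panel panel with filled representative profiles.
#' @param alpha significance level for a contribution (default 0.05).
#' @return data.frame: cell_id, stage ("regression"/"uncategorized"),
#'   type, coef (winning contribution), p (its p-value).
#' @export
regressionAssign <- function(cells, panel, alpha = 0.05) {
    prof <- panel@profiles
    stopIfNot(nrow(prof) > 0, "panel profiles are not filled; run ",
              "representativeProfiles() first")
    markers <- markerNames(panel)
    types <- cellTypes(panel)
    stopIfNot(length(markers) > length(types) + 1,
              "model not identifiable: need more markers than types + 1")
    X <- cbind(`(Intercept)` = 1, t(prof))
    qra <- qr(X)
    if (qra$rank < ncol(X)) {
        aliased <- colnames(X)[qra$pivot[seq(qra$rank + 1, ncol(X))]]
        cc <- stats::cor(t(prof))
        diag(cc) <- 0
        pair <- arrayInd(which.max(abs(cc)), dim(cc))
        stop("collinear template profiles: ",
             rownames(cc)[pair[1]], " and ", rownames(cc)[pair[2]],
             " (aliased: ", paste(aliased, collapse = ", "), ")",
             call. = FALSE)
    }
    Y <- t(as.matrix(cells[, markers, drop = FALSE]))  # markers x cells
    B <- qr.coef(qra, Y)                               # (1+k) x cells
    res <- Y - X %*% B
    dfres <- length(markers) - ncol(X)
    s2 <- colSums(res^2) / dfres
    xtxinv <- chol2inv(qr.R(qra))
    se <- sqrt(outer(diag(xtxinv), s2))                # (1+k) x cells
    tv <- B / se
    pv <- 2 * stats::pt(-abs(tv), dfres)
    Bt <- B[-1, , drop = FALSE]                        # drop intercept
    pt_ <- pv[-1, , drop = FALSE]
    qual <- Bt > 0 & pt_ < alpha
    Bq <- ifelse(qual, Bt, -Inf)
    win <- apply(Bq, 2, which.max)
    any_ <- colSums(qual) > 0
    data.frame(cell_id = cells$cell_id,
               stage = ifelse(any_, "regression", "uncategorized"),
               type = ifelse(any_, types[win], NA_character_),
               coef = ifelse(any_, Bt[cbind(win, seq_along(win))],
                             NA_real_),
               p = ifelse(any_, pt_[cbind(win, seq_along(win))], NA_real_),
               stringsAsFactors = FALSE)
}

#' k-means inspection of uncategorized cells
#'
#' Clusters the leftover cells on standardized MFIs (k-means++-style
#' multi-start initialization under a fixed seed) and reports, per
#' cluster, the markers whose cluster mean exceeds the global mean by more
#' than two standard deviations — the signature of single-marker image
#' noise rather than a genuine unexpected cell type.
#'
#' @param cells uncategorized cell table with MFI columns.
#' @param panel a \linkS4class{MarkerPanel}.
#' @param k number of clusters (default 5).
#' @param seed RNG seed for initialization.
#' @return list with \code{labels} (integer per cell) and \code{report}
#'   (list of marker-name vectors, one per cluster).
#' @export
clusterUnassigned <- function(cells, panel, k = 5, seed = 1) {
    markers <- markerNames(panel)
    M <- as.matrix(cells[, markers, drop = FALSE])
    if (nrow(M) < k)
        stop("fewer cells (", nrow(M), ") than clusters (", k, ")",
             call. = FALSE)
    Z <- scale(M)
    Z[, attr(Z, "scaled:scale") == 0] <- 0
    Z <- matrix(as.numeric(Z), nrow(M), ncol(M),
                dimnames = list(NULL, markers))
    km <- withSeed(seed,
        stats::kmeans(Z, centers = min(k, nrow(unique(Z))),
                      nstart = 10, iter.max = 100))
    report <- lapply(seq_len(max(km$cluster)), function(cl)
        markers[km$centers[cl, ] > 2])
    list(labels = km$cluster, report = report)
}

#' Finalize assignments and summarize
#'
#' Uncategorized cells and cells of configured exclusion types get stage
#' "excluded"; the summary reports the uncategorized fraction and the
#' per-type fractions of all cells.
#'
#' @param assignments combined assignment data.frame (stages matched,
#'   regression, uncategorized).
#' @param excludeTypes character vector of types to exclude.
#' @return list with \code{assignments} (stage updated) and \code{summary}
#'   (fractionUncategorized, perTypeFraction).
#' @export
finalizeAssignments <- function(assignments, excludeTypes = character()) {
    absent <- setdiff(excludeTypes, assignments$type)
    if (length(absent))
        warning("exclusion type(s) absent from assignments: ",
                paste(absent, collapse = ", "))
    a <- assignments
    fracUncat <- mean(a$stage == "uncategorized")
    perType <- prop.table(table(a$type[a$stage %in%
                                           c("matched", "regression")]))
    drop <- a$stage == "uncategorized" |
        (!is.na(a$type) & a$type %in% excludeTypes)
    a$stage[drop] <- "excluded"
    a$type[drop] <- NA_character_
    list(assignments = a,
         summary = list(fractionUncategorized = fracUncat,
                        perTypeFraction = perType))
}

#' Phenotype a cell table end to end
#'
#' Orchestrates the two-stage assignment: per-marker elbow thresholds,
#' exact sign-profile matching, representative profiles, regression
#' assignment of the remainder, optional k-means inspection of leftovers,
#' and final exclusions.
#'
#' @param cells cell table with MFI columns for the panel markers.
#' @param panel a \linkS4class{MarkerPanel}.
#' @param alpha regression significance level.
#' @param minSupport minimum matched cells per type.
#' @param k leftover clustering k (set 0 to skip).
#' @param seed seed for leftover clustering.
#' @return list: assignments (cell_id, stage, type, coef, p), panel (with
#'   profiles), thresholds, summary, leftoverClusters.
#' @export
phenotypeCells <- function(cells, panel, alpha = 0.05, minSupport = 20,
                           k = 5, seed = 1) {
    markers <- markerNames(panel)
    miss <- setdiff(markers, names(cells))
    if (length(miss))
        stop("cell table lacks MFI column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    def <- markers[apply(panel@signs != 0, 2, any)]
    thresholds <- vapply(def, function(m) elbowThreshold(cells[[m]]),
                         numeric(1))
    matches <- gateAndMatch(cells, thresholds, panel)
    panel <- representativeProfiles(cells, matches, panel, minSupport)
    unk <- matches$stage == "unmatched"
    reg <- if (any(unk))
        regressionAssign(cells[unk, , drop = FALSE], panel, alpha)
    else
        data.frame(cell_id = character(), stage = character(),
                   type = character(), coef = numeric(), p = numeric())
    a <- data.frame(cell_id = cells$cell_id, stage = matches$stage,
                    type = matches$type, coef = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
    a[unk, c("stage", "type", "coef", "p")] <-
        reg[, c("stage", "type", "coef", "p")]
    leftovers <- NULL
    nUncat <- sum(a$stage == "uncategorized")
    if (k > 0 && nUncat >= k)
        leftovers <- clusterUnassigned(
            cells[a$stage == "uncategorized", , drop = FALSE], panel,
            k = k, seed = seed)
    fin <- finalizeAssignments(a, panel@excludeTypes)
    c(fin, list(panel = panel, thresholds = thresholds,
                leftoverClusters = leftovers))
}
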