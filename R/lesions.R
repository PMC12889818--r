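#' Define tumor lesions from a proximity graph
#'
#' Two tumor cells are neighbors iff their Euclidean centroid distance is
#' at most \code{radius} micrometres (inclusive); lesions are the
#' connected components of this graph, computed per sample (no edges
#' across samples). A grid spatial index keeps the neighbor search near
#' linear; the result is contractually identical to brute-force all-pairs
#' union-find.
#'
#' @param tumorCells data.frame with cell_id, sample_id, genotype, x_um,
#'   y_um for tumor cells only.
#' @param radius neighborhood radius in micrometres (default 200).
#' @return data.frame: cell_id, sample_id, genotype, lesion_id (lesion ids
#'   are globally unique integers).
#' @examples
#' tc <- data.frame(cell_id = c("a", "b", "c"), sample_id = "s1",
#'                  genotype = "control",
#'                  x_um = c(0, 150, 300), y_um = 0)
#' defineLesions(tc)  # one chain-connected lesion
#' @export
defineLesions <- function(tumorCells, radius = 200) {
    stopIfNot(all(is.finite(tumorCells$x_um)) &&
              all(is.finite(tumorCells$y_um)),
              "coordinates must be finite")
    out <- tumorCells[, c("cell_id", "sample_id", "genotype")]
    out$lesion_id <- NA_integer_
    offset <- 0L
    for (s in unique(tumorCells$sample_id)) {
        idx <- which(tumorCells$sample_id == s)
        comp <- proximityComponents(tumorCells$x_um[idx],
                                    tumorCells$y_um[idx], radius)
        out$lesion_id[idx] <- comp + offset
        offset <- offset + max(comp, 0L)
    }
    out
}

# Connected components of the <= radius proximity graph, via grid binning
# + igraph. Returns component ids 1..k in order of first appearance.
proximityComponents <- function(x, y, radius) {
    n <- length(x)
    if (n == 0) return(integer())
    gx <- floor(x / radius); gy <- floor(y / radius)
    key <- paste(gx, gy)
    cellsOf <- split(seq_len(n), key)
    edges <- list()
    for (b in names(cellsOf)) {
        ij <- as.integer(strsplit(b, " ")[[1]])
        here <- cellsOf[[b]]
        # neighbors: same bin and the 4 "forward" bins (avoid double work)
        for (d in list(c(0, 0), c(1, 0), c(-1, 1), c(0, 1), c(1, 1))) {
            nb <- cellsOf[[paste(ij[1] + d[1], ij[2] + d[2])]]
            if (is.null(nb)) next
            if (d[1] == 0 && d[2] == 0) {
                if (length(here) < 2) next
                pr <- utils::combn(here, 2)
                a <- pr[1, ]; b2 <- pr[2, ]
            } else {
                a <- rep(here, each = length(nb))
                b2 <- rep(nb, times = length(here))
            }
            keep <- (x[a] - x[b2])^2 + (y[a] - y[b2])^2 <= radius^2
            if (any(keep))
                edges[[length(edges) + 1L]] <- cbind(a[keep], b2[keep])
        }
    }
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (length(edges))
        g <- igraph::add_edges(g, t(do.call(rbind, edges)))
    memb <- igraph::components(g)$membership
    # renumber in order of first appearance for determinism
    as.integer(factor(memb, levels = unique(memb)))
}

#' Attach immune cells to lesions
#'
#' A non-tumor cell joins every lesion that contains at least one tumor
#' cell within \code{radius} micrometres of it (inclusive bound, same
#' sample only); membership is independent across lesions, so a cell can
#' belong to zero, one, or several lesions.
#'
#' @param lesionAssign result of \code{\link{defineLesions}}.
#' @param tumorCells the tumor-cell table used for
#'   \code{\link{defineLesions}}.
#' @param immuneCells data.frame with cell_id, sample_id, x_um, y_um, type
#'   for non-tumor cells.
#' @param radius attachment radius in micrometres (default 200).
#' @return data.frame: lesion_id, cell_id, type (one row per membership).
#' @export
attachImmuneCells <- function(lesionAssign, tumorCells, immuneCells,
                              radius = 200) {
    members <- list()
    for (s in unique(immuneCells$sample_id)) {
        ti <- which(tumorCells$sample_id == s)
        ii <- which(immuneCells$sample_id == s)
        if (!length(ti) || !length(ii)) next
        tx <- tumorCells$x_um[ti]; ty <- tumorCells$y_um[ti]
        les <- lesionAssign$lesion_id[ti]
        # grid over tumor cells; each immune cell probes its 3x3 bins
        gx <- floor(tx / radius); gy <- floor(ty / radius)
        binOf <- split(seq_along(ti), paste(gx, gy))
        for (i in ii) {
            px <- immuneCells$x_um[i]; py <- immuneCells$y_um[i]
            bx <- floor(px / radius); by <- floor(py / radius)
            cand <- unlist(lapply(-1:1, function(dx)
                lapply(-1:1, function(dy)
                    binOf[[paste(bx + dx, by + dy)]])), use.names = FALSE)
            if (!length(cand)) next
            hit <- (tx[cand] - px)^2 + (ty[cand] - py)^2 <= radius^2
            if (any(hit)) {
                lid <- unique(les[cand[hit]])
                members[[length(members) + 1L]] <- data.frame(
                    lesion_id = lid, cell_id = immuneCells$cell_id[i],
                    type = immuneCells$type[i], stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(members))
        return(data.frame(lesion_id = integer(), cell_id = character(),
                          type = character()))
    out <- do.call(rbind, members)
    rownames(out) <- NULL
    out
}

#' Dormant / proliferative call for a lesion
#'
#' A lesion of 1-8 tumor cells is dormant; more than \code{cutoff}
#' (default 8) is proliferative.
#'
#' @param size tumor-cell count(s), all \eqn{\ge 1}.
#' @param cutoff dormancy cutoff (default 8).
#' @return character vector, "dormant" or "proliferative".
#' @export
classifyLesionState <- function(size, cutoff = 8) {
    stopIfNot(all(size >= 1), "lesion size must be >= 1")
    ifelse(size <= cutoff, "dormant", "proliferative")
}

#' Build a LesionSet from assignments and coordinates
#'
#' Runs \code{\link{defineLesions}} on the tumor cells,
#' \code{\link{attachImmuneCells}} on the non-excluded immune cells, and
#' calls each lesion's dormant/proliferative state.
#'
#' @param cells full cell table (cell_id, sample_id, genotype, x_um, y_um).
#' @param assignments finalized assignment data.frame (cell_id, stage,
#'   type).
#' @param panel a \linkS4class{MarkerPanel} (declares the tumor type).
#' @param radius neighborhood/attachment radius, micrometres.
#' @param dormancyCutoff dormancy size cutoff.
#' @param dedupeImmune if \code{TRUE}, a multi-member immune cell is kept
#'   only in its nearest lesion (sensitivity toggle; default \code{FALSE},
#'   counting a cell once in each lesion it belongs to).
#' @return a \linkS4class{LesionSet}.
#' @export
buildLesionSet <- function(cells, assignments, panel, radius = 200,
                           dormancyCutoff = 8, dedupeImmune = FALSE) {
    a <- assignments[match(cells$cell_id, assignments$cell_id), ]
    keep <- a$stage %in% c("matched", "regression")
    isTumor <- keep & a$type == tumorType(panel)
    isImmune <- keep & a$type != tumorType(panel)
    tc <- cells[isTumor, c("cell_id", "sample_id", "genotype", "x_um",
                           "y_um")]
    ic <- cells[isImmune, c("cell_id", "sample_id", "x_um", "y_um")]
    ic$type <- a$type[isImmune]
    la <- defineLesions(tc, radius)
    mem <- attachImmuneCells(la, tc, ic, radius)
    if (dedupeImmune && nrow(mem)) {
        cx <- cells$x_um[match(mem$cell_id, cells$cell_id)]
        cy <- cells$y_um[match(mem$cell_id, cells$cell_id)]
        lcx <- tapply(tc$x_um, la$lesion_id, mean)
        lcy <- tapply(tc$y_um, la$lesion_id, mean)
        d <- (cx - lcx[as.character(mem$lesion_id)])^2 +
             (cy - lcy[as.character(mem$lesion_id)])^2
        ord <- order(mem$cell_id, d)
        mem <- mem[ord, ][!duplicated(mem$cell_id[ord]), ]
        rownames(mem) <- NULL
    }
    if (nrow(la)) {
        sizes <- as.integer(table(la$lesion_id))
        lid <- sort(unique(la$lesion_id))
        first <- match(lid, la$lesion_id)
        lesions <- data.frame(
            lesion_id = lid, sample_id = la$sample_id[first],
            genotype = la$genotype[first], size = sizes,
            state = classifyLesionState(sizes, dormancyCutoff),
            stringsAsFactors = FALSE)
    } else {
        lesions <- data.frame(lesion_id = integer(),
                              sample_id = character(),
                              genotype = character(), size = integer(),
                              state = character())
    }
    new("LesionSet", lesions = lesions,
        tumorCells = la[, c("cell_id", "lesion_id")],
        immuneMembers = mem, radius = radius,
        dormancyCutoff = dormancyCutoff)
}

#' Per-sample lesion summary
#'
#' For each sample: the tumor-cell fraction among non-excluded cells, the
#' lesion count, the lesion sizes, and the dormant fraction.
#'
#' @param lesionSet a \linkS4class{LesionSet}.
#' @param cells full cell table.
#' @param assignments finalized assignments.
#' @param panel a \linkS4class{MarkerPanel}.
#' @return data.frame with one row per sample plus a \code{sizes} list
#'   column.
#' @export
summarizeLesions <- function(lesionSet, cells, assignments, panel) {
    a <- assignments[match(cells$cell_id, assignments$cell_id), ]
    keep <- a$stage %in% c("matched", "regression")
    samples <- unique(cells$sample_id)
    ls <- lesionTable(lesionSet)
    rows <- lapply(samples, function(s) {
        inS <- cells$sample_id == s
        nKeep <- sum(keep & inS)
        if (nKeep == 0)
            stop("sample ", s, " has zero non-excluded cells",
                 call. = FALSE)
        nTumor <- sum(keep & inS & a$type == tumorType(panel))
        sl <- ls[ls$sample_id == s, ]
        data.frame(sample_id = s,
                   genotype = cells$genotype[which(inS)[1]],
                   tumor_fraction = nTumor / nKeep,
                   n_lesions = nrow(sl),
                   dormant_fraction = if (nrow(sl))
                       mean(sl$state == "dormant") else NA_real_,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$sizes <- lapply(samples, function(s)
        ls$size[ls$sample_id == s])
    out
}

#' Write the lesion tables CSV interface
#'
#' Lesion table with one count column per immune type, plus the
#' lesion-membership edge list.
#'
#' @param lesionSet a \linkS4class{LesionSet}.
#' @param panel a \linkS4class{MarkerPanel}.
#' @param dir output directory.
#' @export
writeLesionTables <- function(lesionSet, panel, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    counts <- lesionCounts(lesionSet, panel)
    tab <- cbind(lesionTable(lesionSet), t(counts))
    utils::write.csv(tab, file.path(dir, "lesions.csv"), row.names = FALSE)
    utils::write.csv(immuneMembers(lesionSet)[, c("lesion_id", "cell_id")],
                     file.path(dir, "lesion_members.csv"),
                     row.names = FALSE)
    invisible(dir)
}
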