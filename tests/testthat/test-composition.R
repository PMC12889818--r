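# Build a LesionSet-like fixture directly from a membership table.
fakeLesionSet <- function(counts, panel, genotype = NULL, sizes = NULL) {
    nl <- ncol(counts)
    if (is.null(genotype))
        genotype <- rep(c("control", "knockout"), length.out = nl)
    if (is.null(sizes)) sizes <- rep(10L, nl)
    mem <- do.call(rbind, lapply(seq_len(nl), function(j) {
        reps <- rep(rownames(counts), counts[, j])
        if (!length(reps)) return(NULL)
        data.frame(lesion_id = j, cell_id = sprintf("l%d_i%d", j,
                                                    seq_along(reps)),
                   type = reps, stringsAsFactors = FALSE)
    }))
    if (is.null(mem))
        mem <- data.frame(lesion_id = integer(), cell_id = character(),
                          type = character())
    lesions <- data.frame(lesion_id = seq_len(nl),
                          sample_id = paste0("s", seq_len(nl)),
                          genotype = genotype, size = sizes,
                          state = classifyLesionState(sizes))
    new("LesionSet", lesions = lesions,
        tumorCells = data.frame(cell_id = character(),
                                lesion_id = integer()),
        immuneMembers = mem, radius = 200, dormancyCutoff = 8)
}

test_that("lesion counts keep panel order, zero rows and multiplicity", {
    panel <- defaultPanel()
    imm <- immuneTypes(panel)
    counts <- matrix(0L, length(imm), 3, dimnames = list(imm, NULL))
    counts["NK", 1] <- 3L; counts["Monocyte", 1] <- 2L
    ls <- fakeLesionSet(counts, panel)
    got <- lesionCounts(ls, panel)
    expect_identical(rownames(got), imm)
    expect_equal(got["NK", 1], 3L)
    expect_equal(got["Monocyte", 1], 2L)
    expect_equal(sum(got[, 2]), 0L)          # empty lesion retained
    expect_identical(lesionCounts(ls, panel), got)  # stable across runs
})

test_that("CLR rows sum to zero and match the hand-computed example", {
    cm <- clrStandardize(matrix(c(2, 2, 2, 2), 4,
                                dimnames = list(letters[1:4], NULL)),
                         pseudocount = 0.7)
    expect_equal(as.numeric(SummarizedExperiment::assay(cm, "clr")),
                 rep(0, 4))
    # counts (1, 4) with pseudocount 0: ln x - mean ln x
    cm2 <- clrStandardize(matrix(c(1, 4, 2, 2), 2,
                                 dimnames = list(c("u", "v"), NULL)),
                          pseudocount = 0)
    expect_equal(SummarizedExperiment::assay(cm2, "clr")[, 1],
                 c(u = -0.6931, v = 0.6931), tolerance = 1e-4)
    set.seed(6)
    counts <- matrix(rpois(11 * 30, 8), 11,
                     dimnames = list(paste0("t", 1:11), NULL))
    cm3 <- clrStandardize(counts)
    clr <- SummarizedExperiment::assay(cm3, "clr")
    expect_lt(max(abs(colSums(clr))), 1e-9)
    z <- SummarizedExperiment::assay(cm3, "zclr")
    expect_lt(max(abs(rowMeans(z))), 1e-9)
    expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-9)
})

test_that("CLR guards: zeros need a pseudocount, constant types are refused", {
    z <- matrix(c(0, 1, 2, 3), 2, dimnames = list(c("a", "b"), NULL))
    expect_error(clrStandardize(z, pseudocount = 0), "pseudocount")
    # lesions that are scalar multiples of each other have constant CLRs
    cst <- outer(c(1, 2, 4), c(1, 2, 3))
    dimnames(cst) <- list(c("t1", "t2", "t3"), NULL)
    expect_error(clrStandardize(cst, pseudocount = 0), "t1")
})

test_that("CLR is invariant to per-lesion scaling when pseudocount is 0", {
    set.seed(12)
    counts <- matrix(rpois(5 * 8, 20) + 1, 5,
                     dimnames = list(paste0("t", 1:5), NULL))
    a <- SummarizedExperiment::assay(
        clrStandardize(counts, pseudocount = 0), "clr")
    scaled <- sweep(counts, 2, c(2, 3, 1, 5, 4, 2, 7, 10), "*")
    b <- SummarizedExperiment::assay(
        clrStandardize(scaled, pseudocount = 0), "clr")
    expect_equal(a, b, tolerance = 1e-12)
})

test_that("planted correlation blocks are recovered as two modules", {
    set.seed(41)
    n <- 120
    f1 <- rnorm(n); f2 <- -0.6 * f1 + rnorm(n, 0, 0.8)
    types <- paste0("t", 1:8)
    z <- sapply(1:8, function(j) {
        base <- if (j <= 4) f1 else f2
        base * 0.9 + rnorm(n, 0, 0.45)
    })
    counts <- round(exp(z + 3))
    dimnames(counts) <- list(NULL, types)
    cm <- clrStandardize(t(counts))
    mods <- correlationModules(cm, referenceType = "t1")
    expect_equal(diag(mods$correlation), rep(1, 8), ignore_attr = TRUE)
    expect_true(isSymmetric(mods$correlation))
    expect_equal(unname(mods$modules), rep(c(1L, 2L), each = 4))
    # lesion (row) order must not matter
    perm <- sample(ncol(SummarizedExperiment::assay(cm, "zclr")))
    cmP <- clrStandardize(t(counts)[, perm])
    modsP <- correlationModules(cmP, referenceType = "t1")
    expect_identical(mods$modules, modsP$modules)
    tiny <- clrStandardize(t(counts)[, 1:2])
    expect_error(correlationModules(tiny), "3 lesions")
})

test_that("PCA loadings are orthonormal, sign-pinned and capture planted axes", {
    set.seed(99)
    n <- 150
    axis <- rnorm(7); axis <- axis / sqrt(sum(axis^2))
    sc <- rnorm(n, 0, 3)
    z <- outer(sc, axis) + matrix(rnorm(n * 7, 0, 0.1), n)
    counts <- round(exp(z * 0.8 + 5.5))
    cm <- clrStandardize(t(counts) + 0)
    rownames(cm) <- paste0("t", 1:7)
    pca <- pcaScores(cm)
    L <- pca$loadings
    expect_equal(crossprod(L), diag(ncol(L)), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_gte(pca$varExplained[1], 0.90)
    for (j in seq_len(ncol(L)))
        expect_gt(L[which.max(abs(L[, j])), j], 0)
    # flipping the input flips scores but (under the convention) not
    # loadings
    z2 <- SummarizedExperiment::assay(cm, "zclr")
    cmF <- cm
    SummarizedExperiment::assay(cmF, "zclr") <- -z2
    pcaF <- pcaScores(cmF)
    expect_equal(pcaF$loadings[, 1], pca$loadings[, 1], tolerance = 1e-8)
    expect_equal(pcaF$pc1, -pca$pc1, tolerance = 1e-8)
    degenerate <- cm
    SummarizedExperiment::assay(degenerate, "zclr") <- z2 * 0
    expect_error(pcaScores(degenerate), "rank 0")
})

test_that("PC1 separates the planted niches under the size-linked rule", {
    cfg <- simConfig(seed = 63)
    sim <- generateCellTable(cfg)
    ta <- data.frame(cell_id = sim$cells$cell_id, stage = "matched",
                     type = sim$truth@cellType)
    ls <- buildLesionSet(sim$cells, ta, cfg@panel)
    na <- nicheAnalysis(ls, cfg@panel)
    lt <- lesionTable(ls)
    tumor <- sim$truth@cellType == "Tumor"
    rec2true <- tapply(sim$truth@lesionId[tumor],
                       ls@tumorCells$lesion_id[
                           match(sim$cells$cell_id[tumor],
                                 ls@tumorCells$cell_id)],
                       function(v) v[1])
    niche <- trueLesions(sim$truth)$niche[
        match(rec2true[as.character(lt$lesion_id)],
              trueLesions(sim$truth)$lesion_id)]
    r <- cor(na$pca$pc1[as.character(lt$lesion_id)],
             as.integer(factor(niche)))
    expect_gte(abs(r), 0.8)
})
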