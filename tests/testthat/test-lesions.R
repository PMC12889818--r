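tumorDf <- function(x, y, sample = "s1") {
    data.frame(cell_id = sprintf("t%03d", seq_along(x)),
               sample_id = sample, genotype = "control",
               x_um = x, y_um = y, stringsAsFactors = FALSE)
}

test_that("proximity components follow chain transitivity at the inclusive bound", {
    l1 <- defineLesions(tumorDf(c(0, 150, 300), c(0, 0, 0)))
    expect_equal(length(unique(l1$lesion_id)), 1)
    l2 <- defineLesions(tumorDf(c(0, 250), c(0, 0)))
    expect_equal(length(unique(l2$lesion_id)), 2)
    l3 <- defineLesions(tumorDf(c(0, 200), c(0, 0)))
    expect_equal(length(unique(l3$lesion_id)), 1)  # exactly 200: neighbors
    expect_equal(nrow(defineLesions(tumorDf(5, 5))), 1)
})

test_that("partitions equal brute-force union-find on random point sets", {
    set.seed(88)
    for (i in 1:30) {
        n <- sample(20:400, 1)
        span <- runif(1, 500, 6000)
        x <- runif(n, 0, span); y <- runif(n, 0, span)
        got <- defineLesions(tumorDf(x, y))$lesion_id
        want <- bruteForceComponents(x, y, 200)
        expect_equal(randIndex(got, want), 1)
    }
})

test_that("samples are isolated: identical coordinates never merge across samples", {
    a <- tumorDf(c(0, 100), c(0, 0), "s1")
    b <- tumorDf(c(0, 100), c(0, 0), "s2")
    b$cell_id <- c("u1", "u2")
    l <- defineLesions(rbind(a, b))
    expect_equal(length(unique(l$lesion_id)), 2)
    expect_equal(length(unique(l$lesion_id[l$sample_id == "s1"])), 1)
})

test_that("immune attachment is inclusive at 200 um and supports multi-membership", {
    tc <- tumorDf(c(0, 500), c(0, 0))
    la <- defineLesions(tc)
    expect_equal(length(unique(la$lesion_id)), 2)
    ic <- data.frame(cell_id = c("near", "boundary", "far", "between"),
                     sample_id = "s1",
                     x_um = c(150, 200, 0, 340),
                     y_um = c(0, 0, 250, 0),
                     type = "NK", stringsAsFactors = FALSE)
    mem <- attachImmuneCells(la, tc, ic)
    # near (150) and boundary (exactly 200, inclusive) join lesion 1;
    # between is 340 from lesion 1 but 160 from lesion 2; far joins none
    expect_setequal(mem$cell_id[mem$lesion_id == la$lesion_id[1]],
                    c("near", "boundary"))
    expect_setequal(mem$cell_id[mem$lesion_id == la$lesion_id[2]],
                    "between")
    expect_false("far" %in% mem$cell_id)
    # a cell 150 um from tumor cells of two lesions joins both
    tc2 <- tumorDf(c(0, 300), c(0, 0))
    la2 <- defineLesions(tc2)
    ic2 <- data.frame(cell_id = "both", sample_id = "s1", x_um = 150,
                      y_um = 0, type = "NK")
    mem2 <- attachImmuneCells(la2, tc2, ic2)
    expect_equal(nrow(mem2), 2)
    expect_setequal(mem2$lesion_id, unique(la2$lesion_id))
})

test_that("the dormancy cutoff is 1-8 dormant, greater than 8 proliferative", {
    expect_equal(classifyLesionState(c(1, 8, 9)),
                 c("dormant", "dormant", "proliferative"))
    expect_error(classifyLesionState(0), ">= 1")
})

test_that("lesion sets recover the planted partition exactly on default geometry", {
    cfg <- smallSimConfig(seed = 14)
    sim <- generateCellTable(cfg)
    truthAssign <- data.frame(cell_id = sim$cells$cell_id,
                              stage = "matched",
                              type = sim$truth@cellType)
    ls <- buildLesionSet(sim$cells, truthAssign, cfg@panel)
    lt <- lesionTable(ls)
    expect_equal(nrow(lt), nrow(trueLesions(sim$truth)))
    tumor <- sim$truth@cellType == "Tumor"
    got <- ls@tumorCells$lesion_id[match(sim$cells$cell_id[tumor],
                                         ls@tumorCells$cell_id)]
    expect_equal(randIndex(got, sim$truth@lesionId[tumor]), 1)
    # states agree with the truth table through the cutoff
    want <- classifyLesionState(trueLesions(sim$truth)$size)
    byTruth <- tapply(got, sim$truth@lesionId[tumor], unique)
    sizes <- lt$size[match(as.integer(byTruth), lt$lesion_id)]
    expect_equal(unname(classifyLesionState(sizes)), unname(want))
})

test_that("per-sample summaries report fractions and survive permutation", {
    cfg <- smallSimConfig(seed = 9)
    sim <- generateCellTable(cfg)
    ta <- data.frame(cell_id = sim$cells$cell_id, stage = "matched",
                     type = sim$truth@cellType)
    ls <- buildLesionSet(sim$cells, ta, cfg@panel)
    s1 <- summarizeLesions(ls, sim$cells, ta, cfg@panel)
    perm <- sample(nrow(sim$cells))
    s2 <- summarizeLesions(ls, sim$cells[perm, ], ta, cfg@panel)
    ord <- match(s1$sample_id, s2$sample_id)
    expect_equal(s1$tumor_fraction, s2$tumor_fraction[ord])
    expect_equal(s1$dormant_fraction, s2$dormant_fraction[ord])
    lt <- lesionTable(ls)
    for (s in unique(lt$sample_id)) {
        expect_equal(s1$dormant_fraction[s1$sample_id == s],
                     mean(lt$state[lt$sample_id == s] == "dormant"))
    }
    tumorN <- sum(sim$truth@cellType == "Tumor" &
                  sim$cells$sample_id == s1$sample_id[1])
    expect_equal(s1$tumor_fraction[1],
                 tumorN / sum(sim$cells$sample_id == s1$sample_id[1]))
})

test_that("immune de-duplication keeps one membership per cell", {
    tc <- tumorDf(c(0, 300), c(0, 0))
    cells <- rbind(cbind(tc, area_px = 30),
                   data.frame(cell_id = "i1", sample_id = "s1",
                              genotype = "control", x_um = 140, y_um = 0,
                              area_px = 30))
    a <- data.frame(cell_id = cells$cell_id, stage = "matched",
                    type = c("Tumor", "Tumor", "NK"))
    panel <- defaultPanel()
    ls <- buildLesionSet(cells, a, panel)
    expect_equal(nrow(immuneMembers(ls)), 2)
    ls2 <- buildLesionSet(cells, a, panel, dedupeImmune = TRUE)
    expect_equal(nrow(immuneMembers(ls2)), 1)
})
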