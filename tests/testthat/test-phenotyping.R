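test_that("elbow threshold lands in the gap of a bimodal marker", {
    set.seed(311)
    lab <- c(rep(FALSE, 900), rep(TRUE, 100))
    v <- c(rlnorm(900, log(0.1), 0.3), rlnorm(100, log(10), 0.4))
    th <- elbowThreshold(v)
    expect_gt(th, 0.5)
    expect_lt(th, 5)
    expect_gte(mean((v > th) == lab), 0.99)
    expect_error(elbowThreshold(rep(3, 100)), "uninformative")
    expect_error(elbowThreshold(c(1, 2, 3)), "at least 50")
})

test_that("elbow threshold is scale equivariant up to log1p distortion", {
    set.seed(202)
    v <- c(rlnorm(850, log(2), 0.45), rlnorm(150, log(16), 0.45))
    th <- elbowThreshold(v)
    for (c0 in c(2, 3, 7)) {
        thc <- elbowThreshold(c0 * v)
        expect_lt(abs(thc - c0 * th) / (c0 * th), 0.05)
    }
})

test_that("exact profile matching handles identity, ambiguity and null profiles", {
    panel <- toyPanel()
    cells <- data.frame(cell_id = c("nk", "amb", "neg"),
                        A = c(10, 10, 1), B = c(1, 10, 1), C = c(1, 1, 1))
    th <- c(A = 5, B = 5, C = 5)
    m <- gateAndMatch(cells, th, panel)
    expect_equal(m$stage, c("matched", "unmatched", "unmatched"))
    expect_equal(m$type[1], "T1")
    # A+B+ satisfies neither template exactly; all-negative matches none
    expect_true(all(is.na(m$type[2:3])))
    expect_error(gateAndMatch(cells, c(A = 5), panel),
                 "missing thresholds")
})

test_that("representative profiles are per-type MFI means, order invariant", {
    panel <- toyPanel()
    cells <- data.frame(
        cell_id = sprintf("c%02d", 1:80),
        A = c(rep(10, 40), rep(1, 40)), B = c(rep(1, 40), rep(10, 40)),
        C = rep(1, 80))
    m <- gateAndMatch(cells, c(A = 5, B = 5, C = 5), panel)
    cells2 <- cells[sample(nrow(cells)), ]
    m2 <- gateAndMatch(cells2, c(A = 5, B = 5, C = 5), panel)
    p1 <- representativeProfiles(cells, m, panel)
    p2 <- representativeProfiles(cells2, m2, panel)
    expect_equal(p1@profiles, p2@profiles)
    expect_equal(unname(p1@profiles["T1", ]), c(10, 1, 1))
    # hand check: two cells with MFIs (2, 4) and (4, 8) average to (3, 6)
    sub <- data.frame(cell_id = c("a", "b"), A = c(2, 4), B = c(4, 8),
                      C = c(1, 1))
    subm <- data.frame(cell_id = c("a", "b"), stage = "matched",
                       type = "T1")
    expect_error(representativeProfiles(sub, subm, panel, minSupport = 20),
                 "T2")
    pp <- representativeProfiles(
        rbind(sub, transform(sub, cell_id = c("c", "d"), A = c(1, 1),
                             B = c(1, 1))),
        rbind(subm, data.frame(cell_id = c("c", "d"), stage = "matched",
                               type = "T2")),
        panel, minSupport = 2)
    expect_equal(unname(pp@profiles["T1", c("A", "B")]), c(3, 6))
})

test_that("regression assignment recovers mixtures and flags pure noise", {
    set.seed(77)
    panel <- defaultPanel()
    k <- length(cellTypes(panel))
    m <- length(markerNames(panel))
    prof <- matrix(rlnorm(k * m, log(4), 1), k, m,
                   dimnames = list(cellTypes(panel), markerNames(panel)))
    panel@profiles <- prof
    # identity: a cell equal to a template gets coefficient ~1 on it
    cells <- data.frame(cell_id = "t3", t(prof[3, ]) + 0)
    a <- regressionAssign(cells, panel)
    expect_equal(a$stage, "regression")
    expect_equal(a$type, cellTypes(panel)[3])
    expect_equal(a$coef, 1, tolerance = 1e-6)
    # 0.7 / 0.3 mixture with tiny noise: largest contribution wins
    mix <- 0.7 * prof[1, ] + 0.3 * prof[2, ] + rnorm(m, 0, 1e-6)
    a2 <- regressionAssign(data.frame(cell_id = "mix", t(mix)), panel)
    expect_equal(a2$type, cellTypes(panel)[1])
    expect_equal(a2$coef, 0.7, tolerance = 1e-3)
    # residual orthogonalized against all templates: uncategorized
    X <- cbind(1, t(prof))
    noise <- rnorm(m, 0, 5)
    resid <- as.numeric(noise - X %*% solve(crossprod(X),
                                            crossprod(X, noise)))
    names(resid) <- markerNames(panel)
    a3 <- regressionAssign(data.frame(cell_id = "n", t(resid)), panel)
    expect_equal(a3$stage, "uncategorized")
    # collinear templates are refused with the pair named
    panel2 <- panel
    panel2@profiles[2, ] <- 2 * panel2@profiles[1, ]
    expect_error(regressionAssign(cells, panel2), "collinear")
})

test_that("regression coefficients match the normal-equations oracle", {
    set.seed(1234)
    panel <- defaultPanel()
    k <- length(cellTypes(panel)); m <- length(markerNames(panel))
    for (i in 1:50) {
        prof <- matrix(rlnorm(k * m, log(4), 1), k, m,
                       dimnames = list(cellTypes(panel),
                                       markerNames(panel)))
        panel@profiles <- prof
        y <- stats::setNames(rlnorm(m, log(4), 1), markerNames(panel))
        a <- regressionAssign(data.frame(cell_id = "c", t(y)), panel)
        X <- cbind(1, t(prof))
        beta <- solve(crossprod(X), crossprod(X, y))
        if (a$stage == "regression") {
            j <- match(a$type, cellTypes(panel)) + 1
            expect_equal(a$coef, beta[j], tolerance = 1e-8)
        }
    }
})

test_that("leftover k-means recovers planted blobs deterministically", {
    set.seed(5)
    panel <- toyPanel()
    blob <- rbind(matrix(rnorm(150, 0), 50), matrix(rnorm(150, 8), 50))
    cells <- data.frame(cell_id = sprintf("c%03d", 1:100),
                        A = blob[, 1], B = blob[, 2], C = blob[, 3])
    cl <- clusterUnassigned(cells, panel, k = 2, seed = 42)
    expect_equal(adjustedRand(cl$labels, rep(1:2, each = 50)), 1)
    cl2 <- clusterUnassigned(cells, panel, k = 2, seed = 42)
    expect_identical(cl$labels, cl2$labels)
    expect_equal(length(unique(clusterUnassigned(cells, panel, k = 1,
                                                 seed = 1)$labels)), 1)
    expect_error(clusterUnassigned(cells[1:3, ], panel, k = 5), "fewer")
})

test_that("finalization excludes uncategorized and configured types", {
    a <- data.frame(cell_id = sprintf("c%03d", 1:100),
                    stage = c(rep("matched", 80), rep("regression", 12),
                              rep("uncategorized", 8)),
                    type = c(rep("T1", 50), rep("T2", 42), rep(NA, 8)))
    f <- finalizeAssignments(a)
    expect_equal(f$summary$fractionUncategorized, 0.08)
    expect_equal(sum(f$assignments$stage == "excluded"), 8)
    f2 <- finalizeAssignments(a, "T2")
    expect_equal(sum(f2$assignments$stage == "excluded"), 50)
    expect_warning(finalizeAssignments(a, "gdT"), "absent")
    # stages partition the cells
    expect_true(all(table(f2$assignments$stage) > 0))
    expect_equal(sum(table(f2$assignments$stage)), 100)
})

test_that("default synthetic tables are phenotyped accurately", {
    cfg <- smallSimConfig(seed = 31)
    sim <- generateCellTable(cfg)
    ph <- phenotypeCells(sim$cells, cfg@panel)
    a <- ph$assignments
    expect_setequal(unique(a$stage),
                    c("matched", "regression", "excluded"))
    assigned <- a$stage %in% c("matched", "regression")
    acc <- mean(a$type[assigned] == sim$truth@cellType[assigned])
    expect_gte(acc, 0.95)
    expect_lte(ph$summary$fractionUncategorized, 0.10)
})
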