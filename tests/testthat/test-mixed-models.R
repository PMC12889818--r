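# Shared simulators for the mixed-model checks.
simBinomial <- function(nGroups, nPer, b0, b1, sigmaU) {
    geno <- rep(rep(c("control", "knockout"), each = nGroups / 2),
                each = nPer)
    grp <- rep(sprintf("s%02d", seq_len(nGroups)), each = nPer)
    u <- rnorm(nGroups, 0, sigmaU)
    eta <- b0 + b1 * (geno == "knockout") + u[as.integer(factor(grp))]
    data.frame(is_tumor = rbinom(nGroups * nPer, 1, plogis(eta)),
               genotype = geno, sample_id = grp)
}

simZTNB <- function(nGroups, nPer, b0, b1, theta, sigmaU) {
    geno <- rep(rep(c("control", "knockout"), each = nGroups / 2),
                each = nPer)
    grp <- rep(sprintf("s%02d", seq_len(nGroups)), each = nPer)
    u <- rnorm(nGroups, 0, sigmaU)
    mu <- exp(b0 + b1 * (geno == "knockout") +
                  u[as.integer(factor(grp))])
    data.frame(size = rztnb(length(mu), mu, theta), genotype = geno,
               sample_id = grp)
}

test_that("binomial fit reduces to the saturated 2x2 log-odds-ratio", {
    # genotype A: 30/100 tumor cells, B: 10/100, no sample heterogeneity
    d <- data.frame(
        is_tumor = c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90)),
        genotype = rep(c("A", "B"), each = 100),
        sample_id = rep(c("a1", "a2", "b1", "b2"), each = 50))
    # split so each sample holds half its genotype's successes
    d <- d[order(d$genotype, d$is_tumor), ]
    d$sample_id <- c(rep(c("a1", "a2"), 50), rep(c("b1", "b2"), 50))
    fit <- fitBinomialMixed(d)
    lor <- log((30 / 70) / (10 / 90))
    expect_equal(unname(coef(fit)["genotype"]), -lor, tolerance = 1e-3)
    expect_lt(fit@sigmaU, 0.02)
    expect_true(fit@converged)
})

test_that("fixed-effects reduction agrees with glm", {
    set.seed(71)
    d <- simBinomial(8, 60, -1, 0.8, 0.4)
    fit <- fitBinomialMixed(d, sigmaU = 0)
    ref <- glm(is_tumor ~ I(genotype == "knockout"), binomial, d)
    expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-4)
    expect_equal(fit@logLik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("binomial mixed fit recovers a planted genotype effect", {
    set.seed(301)
    est <- replicate(100, {
        d <- simBinomial(20, 500, -1.5, 1.0, 0.5)
        coef(fitBinomialMixed(d, restarts = 1))["genotype"]
    })
    expect_lt(abs(mean(est) - 1.0), 0.1)
})

test_that("ztnb mixed fit matches glmmTMB on a shared dataset", {
    skip_if_not_installed("glmmTMB")
    set.seed(11)
    d <- simZTNB(10, 30, log(3.8), 1.2, 2, 0.5)
    fit <- fitZTNBMixed(d)
    m <- glmmTMB::glmmTMB(
        size ~ I(genotype == "knockout") + (1 | sample_id),
        family = glmmTMB::truncated_nbinom2, data = d)
    expect_equal(unname(coef(fit)),
                 unname(glmmTMB::fixef(m)$cond), tolerance = 1e-2)
    expect_equal(fit@theta, glmmTMB::sigma(m), tolerance = 0.02)
    # AGQ(15) must never fall below the Laplace optimum materially
    expect_gte(fit@logLik, as.numeric(stats::logLik(m)) - 0.5)
})

test_that("single-genotype ztnb matches a 1-D likelihood grid", {
    set.seed(5)
    y <- rztnb(400, 3.8, 2)
    d <- data.frame(size = y, genotype = "g1",
                    sample_id = rep(c("s1", "s2"), 200))
    fit <- fitZTNBMixed(d, sigmaU = 0)
    grid <- seq(log(2), log(8), length.out = 4001)
    ll <- vapply(grid, function(b)
        sum(ztnbLogPmf(y, exp(b), fit@theta)), numeric(1))
    expect_equal(unname(coef(fit)["(Intercept)"]), grid[which.max(ll)],
                 tolerance = 1e-3)
})

test_that("reported ztnb optimum dominates random perturbations", {
    set.seed(23)
    d <- simZTNB(8, 25, log(4), 1, 2, 0.4)
    fit <- fitZTNBMixed(d)
    par0 <- c(unname(coef(fit)), log(fit@theta),
              log(max(fit@sigmaU, 1e-4)))
    atOpt <- ztnbMarginalLogLik(d, par0[1:2], exp(par0[3]), exp(par0[4]))
    expect_equal(atOpt, fit@logLik, tolerance = 1e-6)
    perturbed <- replicate(100, {
        p <- par0 + rnorm(4, 0, 0.25)
        ztnbMarginalLogLik(d, p[1:2], exp(p[3]), exp(p[4]))
    })
    expect_true(all(perturbed <= fit@logLik + 1e-6))
})

test_that("ztnb degenerate inputs are refused", {
    d <- data.frame(size = rep(3, 40), genotype = rep(c("a", "b"), 20),
                    sample_id = rep(c("s1", "s2"), each = 20))
    expect_error(fitZTNBMixed(d), "degenerate")
    d2 <- data.frame(size = c(2.5, 3), genotype = c("a", "b"),
                     sample_id = c("s1", "s2"))
    expect_error(fitZTNBMixed(d2), "integers")
})

test_that("gaussian mixed model recovers noise-free coefficients exactly", {
    set.seed(8)
    n <- 120
    d <- data.frame(size = sample(1:30, n, TRUE),
                    genotype = rep(c("control", "knockout"),
                                   each = n / 2),
                    sample_id = rep(sprintf("s%d", 1:6), each = n / 6))
    d$pc1 <- 0.5 * d$size + 1.0 * (d$genotype == "knockout")
    fit <- fitGaussianMixed(d)
    expect_equal(unname(coef(fit)),
                 c(0, 0.5, 1.0, 0), tolerance = 1e-5)
    # permutation invariance
    fit2 <- fitGaussianMixed(d[sample(n), ])
    expect_equal(coef(fit), coef(fit2), tolerance = 1e-6)
})

test_that("gaussian mixed model agrees with lme4 maximum likelihood", {
    skip_if_not_installed("lme4")
    set.seed(19)
    n <- 200
    d <- data.frame(size = rpois(n, 10) + 1,
                    genotype = rep(c("control", "knockout"),
                                   each = n / 2),
                    sample_id = rep(sprintf("s%d", 1:8), each = n / 8))
    u <- rnorm(8, 0, 0.6)
    d$pc1 <- -0.5 + 0.1 * d$size + 0.8 * (d$genotype == "knockout") +
        0.08 * d$size * (d$genotype == "knockout") +
        u[as.integer(factor(d$sample_id))] + rnorm(n)
    fit <- fitGaussianMixed(d)
    ref <- lme4::lmer(pc1 ~ size * I(genotype == "knockout") +
                          (1 | sample_id), d, REML = FALSE)
    expect_equal(unname(coef(fit)), unname(lme4::fixef(ref)),
                 tolerance = 1e-4)
    expect_equal(fit@logLik, as.numeric(stats::logLik(ref)),
                 tolerance = 1e-4)
    expect_equal(fit@sigmaU,
                 as.numeric(attr(lme4::VarCorr(ref)$sample_id,
                                 "stddev")), tolerance = 1e-3)
})

test_that("gaussian interaction recovery over replicates", {
    set.seed(402)
    est <- replicate(100, {
        n <- 200
        d <- data.frame(size = rpois(n, 8) + 1,
                        genotype = rep(c("control", "knockout"),
                                       each = n / 2),
                        sample_id = rep(sprintf("s%d", 1:8),
                                        each = n / 8))
        u <- rnorm(8, 0, 0.5)
        d$pc1 <- 0.2 * d$size - 0.5 * (d$genotype == "knockout") +
            0.8 * d$size * (d$genotype == "knockout") +
            u[as.integer(factor(d$sample_id))] + rnorm(n)
        coef(fitGaussianMixed(d, restarts = 1))["size:genotype"]
    })
    expect_lt(abs(mean(est) - 0.8) / 0.8, 0.15)
})

test_that("rank-deficient gaussian designs name the aliased term", {
    d <- data.frame(pc1 = rnorm(20), size = rpois(20, 5) + 1,
                    genotype = "control",
                    sample_id = rep(c("s1", "s2"), 10))
    expect_error(fitGaussianMixed(d), "aliased")
})

test_that("likelihood-ratio test is consistent with nested fits", {
    set.seed(55)
    d <- simZTNB(8, 25, log(4), 1.4, 2, 0.3)
    full <- fitZTNBMixed(d)
    d0 <- d; d0$genotype <- "one"
    reduced <- fitZTNBMixed(d0)
    lr <- lrTest(full, reduced)
    expect_equal(lr$df, 1)
    expect_gte(lr$statistic, 0)
    expect_lt(lr$p, 0.05)
})
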