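# Random-intercept mixed models fitted by maximizing the exact marginal
# likelihood, with the per-group integral approximated by adaptive
# Gauss-Hermite quadrature (AGQ): for group j with conditional
# log-likelihood g_j(u) (data terms plus the N(0, sigma_u^2) prior), the
# mode u_j and curvature h_j = -g_j''(u_j) are found by a safeguarded
# Newton iteration vectorized over groups, and
#   log L_j ~= log sum_k w_k exp(x_k^2) exp(g_j(u_j + s_j x_k)) + log s_j,
# with s_j = sqrt(2 / h_j) and (x_k, w_k) the Gauss-Hermite rule. One node
# recovers the Laplace approximation; 15+ nodes are used by default.

ghRule <- function(n) pracma::gaussHermite(n)

# Vectorized safeguarded Newton for per-group posterior modes.
# gradFun(u) returns the per-group gradient of g; curvature is numeric.
newtonModes <- function(gradFun, nGroups, maxIter = 30, tol = 1e-8,
                        u0 = NULL) {
    u <- if (is.null(u0)) numeric(nGroups) else u0
    for (it in seq_len(maxIter)) {
        gr <- gradFun(u)
        gr[!is.finite(gr)] <- 0
        h <- (gradFun(u + 1e-5) - gr) / 1e-5
        h[!is.finite(h) | h > -1e-8] <- -1e-8
        step <- gr / h
        u <- u - pmax(pmin(step, 1), -1)
        if (max(abs(gr)) < tol) break
    }
    h <- -(gradFun(u + 1e-5) - gradFun(u - 1e-5)) / 2e-5
    h[!is.finite(h)] <- 1e-10
    list(u = u, h = pmax(h, 1e-10))
}

# AGQ marginal log-likelihood given per-group value/gradient closures.
# `cache` (an environment) carries the previous modes as a warm start
# across nearby evaluations during optimization.
agqLogLik <- function(valueFun, gradFun, nGroups, sigma, gh,
                      cache = NULL) {
    u0 <- if (!is.null(cache) && !is.null(cache$u) &&
              length(cache$u) == nGroups && all(is.finite(cache$u)))
        cache$u else NULL
    md <- newtonModes(gradFun, nGroups, u0 = u0)
    if (!is.null(cache)) cache$u <- md$u
    s <- sqrt(2 / md$h)
    lw <- vapply(seq_along(gh$x), function(k)
        valueFun(md$u + s * gh$x[k]) + gh$x[k]^2 + log(gh$w[k]),
        numeric(nGroups))
    lw <- matrix(lw, nGroups)
    m <- apply(lw, 1, max)
    sum(log(s) + m + log(rowSums(exp(lw - m)))) -
        nGroups * log(sqrt(2 * pi) * sigma)
}

# Multi-start BFGS + Nelder-Mead polish; returns best optim result.
optimizeMixed <- function(nll, start, restarts = 5, seed = 1,
                          jitter = 0.3) {
    starts <- withSeed(deriveSeed(seed, 37),
        c(list(start), lapply(seq_len(restarts - 1), function(i)
            start + stats::rnorm(length(start), 0, jitter))))
    best <- NULL
    lastErr <- ""
    for (s0 in starts) {
        f <- tryCatch(
            stats::optim(s0, nll, method = "BFGS",
                         control = list(maxit = 500, reltol = 1e-10)),
            error = function(e) {
                lastErr <<- conditionMessage(e)
                NULL
            })
        if (!is.null(f) && (is.null(best) || f$value < best$value))
            best <- f
    }
    if (is.null(best))
        stop("mixed-model optimization failed from every start (last ",
             "error: ", lastErr, ")", call. = FALSE)
    polish <- stats::optim(best$par, nll, method = "Nelder-Mead",
                           control = list(maxit = 1500, reltol = 1e-12))
    if (polish$value <= best$value) best <- polish
    best
}

# Wald table from a numeric Hessian of the negative log-likelihood.
waldFromHessian <- function(nll, par, betaIdx, betaNames) {
    H <- tryCatch(stats::optimHess(par, nll), error = function(e) NULL)
    se <- rep(NA_real_, length(betaIdx))
    if (!is.null(H)) {
        V <- tryCatch(solve(H), error = function(e) NULL)
        if (!is.null(V)) {
            d <- diag(V)[betaIdx]
            se <- ifelse(d > 0, sqrt(d), NA_real_)
        }
    }
    beta <- par[betaIdx]
    z <- beta / se
    list(beta = stats::setNames(beta, betaNames),
         se = stats::setNames(se, betaNames),
         z = stats::setNames(z, betaNames),
         p = stats::setNames(2 * stats::pnorm(-abs(z)), betaNames))
}

# 0/1 genotype coding with the first factor level (or first unique value)
# as the reference; returns list(code, labels).
codeGenotype <- function(genotype) {
    # alphabetical reference level: stable under row permutation
    f <- if (is.factor(genotype)) genotype else factor(genotype)
    if (nlevels(f) > 2)
        stop("at most two genotype levels are supported (got ",
             nlevels(f), ")", call. = FALSE)
    labels <- levels(f)
    if (length(labels) == 1) labels <- c(labels, NA_character_)
    list(code = as.numeric(f) - 1, labels = labels)
}

#' Binomial mixed model: tumor-cell status ~ genotype + (1 | sample)
#'
#' Cell-level logistic regression of the binary tumor-cell indicator on
#' genotype with a per-sample random intercept, fitted by maximizing the
#' AGQ-marginalized likelihood (15 nodes by default). Genotype is coded
#' 0/1 with the first level as reference; the coefficient is the
#' log-odds-ratio of being a tumor cell in the second level. Inference is
#' a Wald z test from the observed information.
#'
#' @param data data.frame of cells.
#' @param response name of the 0/1 (or logical) tumor indicator column.
#' @param genotype,group column names of the genotype and sample-id.
#' @param nAGQ number of quadrature nodes (1 = Laplace).
#' @param sigmaU fix the random-intercept SD (e.g. 0 for a fixed-effects
#'   fit) instead of estimating it.
#' @param restarts optimizer restarts from jittered starts.
#' @param seed seed for the restart jitter.
#' @return a \linkS4class{MixedModelFit}.
#' @export
fitBinomialMixed <- function(data, response = "is_tumor",
                             genotype = "genotype", group = "sample_id",
                             nAGQ = 15, sigmaU = NULL, restarts = 5,
                             seed = 1) {
    y <- as.numeric(data[[response]])
    stopIfNot(all(y %in% c(0, 1)), "response must be binary 0/1")
    gcode <- codeGenotype(data[[genotype]])
    stopIfNot(length(unique(gcode$code)) == 2,
              "both genotypes must be present")
    grp <- factor(data[[group]], levels = unique(data[[group]]))
    notes <- character()
    if (nlevels(grp) < 2 && is.null(sigmaU)) {
        warning("fewer than 2 groups: random effect inestimable, ",
                "fitting fixed effects only")
        notes <- "fixed-only (single group)"
        sigmaU <- 0
    }
    # aggregate to sufficient statistics per (group, genotype) stratum
    strat <- interaction(grp, gcode$code, drop = TRUE)
    succ <- as.numeric(rowsum(y, strat))
    tot <- as.numeric(rowsum(rep(1, length(y)), strat))
    sgrp <- as.integer(tapply(as.integer(grp), strat, `[`, 1))
    sgen <- as.numeric(tapply(gcode$code, strat, `[`, 1))
    nGroups <- nlevels(grp)
    gh <- ghRule(nAGQ)
    condVal <- function(beta, u) {
        eta <- beta[1] + beta[2] * sgen + u[sgrp]
        as.numeric(rowsum(succ * eta - tot * log1pexp(eta), sgrp))
    }
    condGrad <- function(beta, u) {
        eta <- beta[1] + beta[2] * sgen + u[sgrp]
        as.numeric(rowsum(succ - tot * stats::plogis(eta), sgrp))
    }
    estSigma <- is.null(sigmaU)
    cache <- new.env(parent = emptyenv())
    nllFull <- function(par) {
        if (any(!is.finite(par))) return(1e10)
        beta <- par[1:2]
        sg <- if (estSigma) exp(par[3]) else sigmaU
        val <- if (sg < 1e-8) {
            eta <- beta[1] + beta[2] * sgen
            -sum(succ * eta - tot * log1pexp(eta))
        } else {
            vf <- function(u) condVal(beta, u) - u^2 / (2 * sg^2)
            gf <- function(u) condGrad(beta, u) - u / sg^2
            -agqLogLik(vf, gf, nGroups, sg, gh, cache)
        }
        if (!is.finite(val)) 1e10 else val
    }
    pbar <- sum(succ) / sum(tot)
    start <- c(stats::qlogis(min(max(pbar, 0.01), 0.99)), 0,
               if (estSigma) log(0.3))
    opt <- optimizeMixed(nllFull, start, restarts, seed)
    sgHat <- if (estSigma) exp(opt$par[3]) else sigmaU
    if (estSigma && sgHat < 1e-4) {
        notes <- c(notes, "sigma_u at boundary (0)")
        # profile out the flat variance direction for stable SEs
        nllB <- function(b) nllFull(c(b, opt$par[3]))
        wald <- waldFromHessian(nllB, opt$par[1:2], 1:2,
                                c("(Intercept)", "genotype"))
        sgHat <- 0
    } else {
        wald <- waldFromHessian(nllFull, opt$par, 1:2,
                                c("(Intercept)", "genotype"))
    }
    notes <- c(notes, paste0("genotype coding: ", gcode$labels[1],
                             " = 0 (reference), ", gcode$labels[2], " = 1"))
    new("MixedModelFit", family = "binomial",
        coefficients = wald$beta, se = wald$se, z = wald$z, p = wald$p,
        sigmaU = sgHat, theta = NA_real_, logLik = -opt$value,
        converged = opt$convergence == 0, nObs = length(y),
        nGroups = nGroups, notes = notes)
}

#' Zero-truncated negative binomial mixed model: lesion size ~ genotype
#'
#' Log-link ZTNB regression of lesion size (tumor-cell count, at least 1)
#' on genotype with a per-sample random intercept. The NB dispersion theta
#' is estimated jointly; the random intercept is marginalized by AGQ.
#'
#' @inheritParams fitBinomialMixed
#' @param size name of the lesion-size column (integers >= 1).
#' @return a \linkS4class{MixedModelFit}.
#' @export
fitZTNBMixed <- function(data, size = "size", genotype = "genotype",
                         group = "sample_id", nAGQ = 15, sigmaU = NULL,
                         restarts = 5, seed = 1) {
    y <- as.numeric(data[[size]])
    stopIfNot(all(y >= 1) && all(y == floor(y)),
              "lesion sizes must be integers >= 1")
    if (max(y) == min(y))
        stop("degenerate fit: all lesion sizes are equal", call. = FALSE)
    gcode <- codeGenotype(data[[genotype]])
    grp <- factor(data[[group]], levels = unique(data[[group]]))
    notes <- character()
    if (nlevels(grp) < 2 && is.null(sigmaU)) {
        warning("fewer than 2 groups: random effect inestimable, ",
                "fitting fixed effects only")
        notes <- "fixed-only (single group)"
        sigmaU <- 0
    }
    gi <- as.integer(grp)
    geno <- gcode$code
    nGroups <- nlevels(grp)
    oneGeno <- length(unique(geno)) < 2
    gh <- ghRule(nAGQ)
    # group sums by cumsum over a group-sorted permutation: rowsum()
    # re-derives the group set on every call, which dominates the
    # simulation-scale fitting cost
    perm <- order(gi)
    ends <- cumsum(tabulate(gi, nGroups))
    gsum <- function(x) {
        cs <- cumsum(x[perm])
        diff(c(0, cs[ends]))
    }
    lgy1 <- lgamma(y + 1)
    logpmfFast <- function(mu, theta) {
        lp0 <- -theta * log1p(mu / theta)
        lgamma(y + theta) - lgamma(theta) - lgy1 + lp0 +
            y * (log(mu) - log(theta + mu)) - log1mexp(lp0)
    }
    condVal <- function(beta, theta, u) {
        mu <- exp(clampEta(beta[1] + beta[2] * geno + u[gi]))
        gsum(logpmfFast(mu, theta))
    }
    condGrad <- function(beta, theta, u) {
        mu <- exp(clampEta(beta[1] + beta[2] * geno + u[gi]))
        lp0 <- -theta * log1p(mu / theta)
        dmu <- y / mu - (y + theta) / (theta + mu) -
            theta * exp(lp0) / ((theta + mu) * (1 - exp(lp0)))
        gsum(dmu * mu)
    }
    estSigma <- is.null(sigmaU)
    cache <- new.env(parent = emptyenv())
    nllFull <- function(par) {
        if (any(!is.finite(par))) return(1e10)
        beta <- c(par[1], if (oneGeno) 0 else par[2])
        theta <- min(exp(par[if (oneGeno) 2 else 3]), 1e7)
        sg <- if (estSigma) exp(par[length(par)]) else sigmaU
        val <- if (sg < 1e-8) {
            mu <- exp(clampEta(beta[1] + beta[2] * geno))
            -sum(logpmfFast(mu, theta))
        } else {
            vf <- function(u) condVal(beta, theta, u) - u^2 / (2 * sg^2)
            gf <- function(u) condGrad(beta, theta, u) - u / sg^2
            -agqLogLik(vf, gf, nGroups, sg, gh, cache)
        }
        if (!is.finite(val)) 1e10 else val
    }
    start <- c(log(mean(y[geno == 0])),
               if (!oneGeno) log(mean(y[geno == 1]) /
                                 mean(y[geno == 0])),
               log(2), if (estSigma) log(0.3))
    opt <- optimizeMixed(nllFull, start, restarts, seed)
    thIdx <- if (oneGeno) 2L else 3L
    thetaHat <- exp(opt$par[thIdx])
    sgHat <- if (estSigma) exp(opt$par[length(opt$par)]) else sigmaU
    if (thetaHat > 1e6) notes <- c(notes, "theta at boundary (large)")
    bIdx <- if (oneGeno) 1L else 1:2
    bNames <- if (oneGeno) "(Intercept)" else c("(Intercept)", "genotype")
    if (estSigma && sgHat < 1e-4) {
        notes <- c(notes, "sigma_u at boundary (0)")
        fixTail <- opt$par[(max(bIdx) + 1):length(opt$par)]
        nllB <- function(b) nllFull(c(b, fixTail))
        wald <- waldFromHessian(nllB, opt$par[bIdx], seq_along(bIdx),
                                bNames)
        sgHat <- 0
    } else {
        wald <- waldFromHessian(nllFull, opt$par, bIdx, bNames)
    }
    notes <- c(notes, paste0("genotype coding: ", gcode$labels[1],
                             " = 0 (reference), ", gcode$labels[2], " = 1"))
    new("MixedModelFit", family = "ztnb",
        coefficients = wald$beta, se = wald$se, z = wald$z, p = wald$p,
        sigmaU = sgHat, theta = thetaHat, logLik = -opt$value,
        converged = opt$convergence == 0, nObs = length(y),
        nGroups = nGroups, notes = notes)
}

#' Evaluate the ZTNB mixed-model marginal log-likelihood
#'
#' Computes the AGQ-marginalized log-likelihood at user-supplied
#' parameters, without fitting; useful for profiling and for verifying
#' that a reported optimum dominates its neighborhood.
#'
#' @inheritParams fitZTNBMixed
#' @param beta fixed effects c(intercept, genotype).
#' @param theta NB dispersion.
#' @param sigmaU random-intercept SD (0 collapses to the fixed model).
#' @return the marginal log-likelihood (a single number).
#' @export
ztnbMarginalLogLik <- function(data, beta, theta, sigmaU, size = "size",
                               genotype = "genotype",
                               group = "sample_id", nAGQ = 15) {
    y <- as.numeric(data[[size]])
    gcode <- codeGenotype(data[[genotype]])
    grp <- factor(data[[group]], levels = unique(data[[group]]))
    gi <- as.integer(grp)
    geno <- gcode$code
    eta0 <- beta[1] + beta[2] * geno
    if (sigmaU < 1e-8)
        return(sum(ztnbLogPmf(y, exp(eta0), theta)))
    gh <- ghRule(nAGQ)
    nGroups <- nlevels(grp)
    vf <- function(u)
        as.numeric(rowsum(ztnbLogPmf(y, exp(eta0 + u[gi]), theta), gi)) -
            u^2 / (2 * sigmaU^2)
    gf <- function(u) {
        mu <- exp(clampEta(eta0 + u[gi]))
        lp0 <- -theta * log1p(mu / theta)
        dmu <- y / mu - (y + theta) / (theta + mu) -
            theta * exp(lp0) / ((theta + mu) * (1 - exp(lp0)))
        as.numeric(rowsum(dmu * mu, gi)) - u / sigmaU^2
    }
    agqLogLik(vf, gf, nGroups, sigmaU, gh)
}

#' Gaussian mixed model: PC1 ~ size * genotype + (1 | sample)
#'
#' Linear mixed model of a lesion-level response (PC1 of the standardized
#' CLR composition) on lesion size, genotype, and their interaction, with
#' a per-sample random intercept. The random-intercept structure gives a
#' closed-form marginal likelihood (compound-symmetric per-group
#' covariance), profiled over the GLS fixed effects and maximized over the
#' two variance parameters. Maximum likelihood by default (likelihoods
#' comparable across fixed-effect specifications); REML available.
#'
#' @inheritParams fitBinomialMixed
#' @param response,size column names of the response and lesion size.
#' @param logSize model log(size) instead of size.
#' @param REML use the REML criterion instead of ML.
#' @return a \linkS4class{MixedModelFit}.
#' @export
fitGaussianMixed <- function(data, response = "pc1", size = "size",
                             genotype = "genotype", group = "sample_id",
                             logSize = FALSE, REML = FALSE, restarts = 5,
                             seed = 1) {
    yy <- as.numeric(data[[response]])
    sz <- as.numeric(data[[size]])
    if (logSize) sz <- log(sz)
    gcode <- codeGenotype2(data[[genotype]])
    grp <- factor(data[[group]], levels = unique(data[[group]]))
    X <- cbind(`(Intercept)` = 1, size = sz, genotype = gcode$code,
               `size:genotype` = sz * gcode$code)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
        aliased <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
        stop("rank-deficient fixed-effect design; aliased term(s): ",
             paste(aliased, collapse = ", "), call. = FALSE)
    }
    notes <- character()
    singleGroup <- nlevels(grp) < 2
    if (singleGroup) {
        warning("fewer than 2 groups: random effect inestimable, ",
                "fitting fixed effects only")
        notes <- "fixed-only (single group)"
    }
    gi <- as.integer(grp)
    nG <- nlevels(grp)
    n <- length(yy)
    p <- ncol(X)
    ng <- tabulate(gi, nG)
    gls <- function(su2, se2) {
        # Woodbury for V_j = se2 I + su2 J within each group:
        # V_j^-1 = (I - w_j J) / se2 with w_j = su2 / (se2 + n_j su2)
        w <- su2 / (se2 + ng * su2)
        Xg <- rowsum(X, gi)
        yg <- as.numeric(rowsum(yy, gi))
        XtVX <- (crossprod(X) - t(Xg * w) %*% Xg) / se2
        XtVy <- (crossprod(X, yy) - t(Xg * w) %*% yg) / se2
        beta <- solve(XtVX, XtVy)
        r <- yy - X %*% beta
        rg <- as.numeric(rowsum(r, gi))
        quad <- (sum(r^2) - sum(w * rg^2)) / se2
        logdet <- (n - nG) * log(se2) + sum(log(se2 + ng * su2))
        ll <- -0.5 * (n * log(2 * pi) + logdet + quad)
        if (REML)
            ll <- ll - 0.5 * as.numeric(determinant(XtVX)$modulus)
        list(ll = ll, beta = beta, cov = solve(XtVX))
    }
    nll <- function(par) {
        # keep variances inside a numerically safe box; exact-fit data
        # would otherwise drive the residual variance to 0 and the
        # likelihood to +Inf
        par <- pmax(pmin(par, 10), -12)
        su2 <- if (singleGroup) 0 else exp(2 * par[1])
        se2 <- exp(2 * par[length(par)])
        -gls(su2, se2)$ll
    }
    sdy <- stats::sd(yy)
    start <- c(if (!singleGroup) log(max(sdy / 2, 1e-3)),
               log(max(sdy, 1e-3)))
    opt <- optimizeMixed(nll, start, restarts, seed)
    opt$par <- pmax(pmin(opt$par, 10), -12)
    su2 <- if (singleGroup) 0 else exp(2 * opt$par[1])
    se2 <- exp(2 * opt$par[length(opt$par)])
    fit <- gls(su2, se2)
    beta <- as.numeric(fit$beta)
    se <- sqrt(diag(fit$cov))
    z <- beta / se
    pv <- 2 * stats::pnorm(-abs(z))
    names(beta) <- names(se) <- names(z) <- names(pv) <- colnames(X)
    notes <- c(notes, paste0("genotype coding: ", gcode$labels[1],
                             " = 0 (reference), ", gcode$labels[2],
                             " = 1"),
               if (REML) "REML criterion" else "ML criterion",
               if (logSize) "size entered on the log scale")
    new("MixedModelFit", family = "gaussian",
        coefficients = beta, se = se, z = z, p = pv,
        sigmaU = sqrt(su2), theta = sqrt(se2), logLik = -opt$value,
        converged = opt$convergence == 0, nObs = n,
        nGroups = nG, notes = notes)
}

# like codeGenotype but demands both levels present (interaction model)
codeGenotype2 <- function(genotype) {
    g <- codeGenotype(genotype)
    if (length(unique(g$code)) < 2)
        stop("rank-deficient fixed-effect design; aliased term(s): ",
             "genotype, size:genotype (single genotype present)",
             call. = FALSE)
    g
}

#' Likelihood-ratio test between two nested mixed-model fits
#'
#' @param full,reduced \linkS4class{MixedModelFit}s fitted by ML on the
#'   same data, the reduced model nested in the full one.
#' @param df degrees of freedom of the comparison (default: difference in
#'   fixed-effect counts).
#' @return list with statistic, df and p.
#' @export
lrTest <- function(full, reduced, df = NULL) {
    if (is.null(df))
        df <- length(full@coefficients) - length(reduced@coefficients)
    stat <- 2 * (full@logLik - reduced@logLik)
    list(statistic = stat, df = df,
         p = stats::pchisq(max(stat, 0), df, lower.tail = FALSE))
}

#' Export a fit as a JSON-ready record
#'
#' @param fit a \linkS4class{MixedModelFit}.
#' @return a named list (coefficients, SEs, p-values, sigma_u, theta,
#'   logLik, convergence, n).
#' @export
fitRecord <- function(fit) {
    list(family = fit@family,
         coefficients = as.list(fit@coefficients),
         se = as.list(fit@se), p = as.list(fit@p),
         sigma_u = fit@sigmaU, theta = fit@theta, logLik = fit@logLik,
         converged = fit@converged, n_obs = fit@nObs,
         n_groups = fit@nGroups, notes = fit@notes)
}
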