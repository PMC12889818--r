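# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (igraph components, EBImage convolution, the
# AGQ fitters) so agreement is a genuine cross-check.

# Brute-force all-pairs union-find partition of the <= radius proximity
# graph. Returns component id per point (1..k, order of first appearance).
bruteForceComponents <- function(x, y, radius) {
    n <- length(x)
    parent <- seq_len(n)
    find <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    r2 <- radius^2
    for (i in seq_len(max(n - 1, 0))) {
        d2 <- (x[(i + 1):n] - x[i])^2 + (y[(i + 1):n] - y[i])^2
        for (j in which(d2 <= r2) + i) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[rj] <- ri
        }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    as.integer(factor(roots, levels = unique(roots)))
}

# Rand index between two partitions (label vectors over the same items).
randIndex <- function(a, b) {
    n <- length(a)
    if (n < 2) return(1)
    same_a <- outer(a, a, "==")
    same_b <- outer(b, b, "==")
    ut <- upper.tri(same_a)
    mean(same_a[ut] == same_b[ut])
}

# Adjusted Rand index (for k-means planted-partition checks).
adjustedRand <- function(a, b) {
    tab <- table(a, b)
    nij <- sum(choose(tab, 2))
    ai <- sum(choose(rowSums(tab), 2))
    bj <- sum(choose(colSums(tab), 2))
    nn <- choose(sum(tab), 2)
    exp_ <- ai * bj / nn
    (nij - exp_) / ((ai + bj) / 2 - exp_)
}

# Direct (brute force) 2-D Gaussian convolution with reflective boundary;
# quadratic-time reference for the package's FFT/filter-based smoothing.
directGaussianSmooth <- function(img, sigma) {
    hw <- ceiling(4 * sigma)
    ker <- outer(stats::dnorm(-hw:hw, sd = sigma),
                 stats::dnorm(-hw:hw, sd = sigma))
    ker <- ker / sum(ker)
    nr <- nrow(img); nc <- ncol(img)
    # symmetric (edge-including) reflection, the package's convention
    reflect <- function(i, n) {
        i[i < 1] <- 1 - i[i < 1]
        i[i > n] <- 2 * n - i[i > n] + 1
        i
    }
    out <- matrix(0, nr, nc)
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
        ri <- reflect(r + (-hw:hw), nr)
        ci <- reflect(cc + (-hw:hw), nc)
        out[r, cc] <- sum(ker * img[ri, ci])
    }
    out
}

# Zero-truncated NB cdf via the closed-form pmf (direct summation).
ztnbCdfOracle <- function(q, mu, theta) {
    p0 <- (theta / (theta + mu))^theta
    ys <- seq_len(max(q))
    pmf <- stats::dnbinom(ys, mu = mu, size = theta) / (1 - p0)
    cum <- cumsum(pmf)
    ifelse(q < 1, 0, cum[pmin(q, max(q))])
}

# A small, quick simulation configuration for module tests.
smallSimConfig <- function(seed = 1, ...) {
    simConfig(nSamplesPerGenotype = 2, lesionsPerSample = 6,
              fieldSize = c(2000, 2000), seed = seed, ...)
}

# Tiny three-marker panel used for hand-checkable gating fixtures.
toyPanel <- function() {
    markers <- c("A", "B", "C")
    signs <- rbind(T1 = c(1, -1, -1), T2 = c(-1, 1, -1))
    colnames(signs) <- markers
    new("MarkerPanel", markers = markers, signs = signs,
        nuclear = c(A = TRUE, B = FALSE, C = FALSE), tumorType = "T1",
        excludeTypes = character(),
        profiles = matrix(numeric(), 0, 3,
                          dimnames = list(NULL, markers)))
}

# Render a disk on a matrix (used by segmentation fixtures).
drawDisk <- function(img, cx, cy, r, value) {
    xs <- matrix(rep(seq_len(nrow(img)) - 1, ncol(img)), nrow(img))
    ys <- matrix(rep(seq_len(ncol(img)) - 1, each = nrow(img)), nrow(img))
    img[(xs - cx)^2 + (ys - cy)^2 <= r^2] <- value
    img
}
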