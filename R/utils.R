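# Internal helpers shared across modules.

# Derive a stage seed from the global seed; keeps results < 2^31 so the
# value is always a valid R integer.
deriveSeed <- function(seed, offset) {
    as.integer((as.numeric(seed) + offset * 1000003) %% 2147483647)
}

logSumExp <- function(x) {
    m <- max(x)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(x - m)))
}

# log(1 - exp(a)) for a < 0, stable near both ends
log1mexp <- function(a) {
    out <- a
    hi <- a >= -0.6931472
    out[!hi] <- log1p(-exp(a[!hi]))
    out[hi] <- log(-expm1(a[hi]))
    out
}

# Round half to even, then clamp to [0, 255] integers.
roundHalfEven <- function(x) {
    r <- round(x)  # R rounds half to even
    pmin(pmax(r, 0), 255)
}

stopIfNot <- function(cond, ...) {
    if (!isTRUE(cond)) stop(..., call. = FALSE)
}

# Numerically safe log(1 + exp(x)).
log1pexp <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

# Keep linear predictors inside a range where exp() cannot under/overflow.
clampEta <- function(eta) pmax(pmin(eta, 40), -40)

# Run expr under a local RNG seed, restoring the caller's RNG state so
# internal seeding never perturbs user-level simulation loops.
withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
        get(".Random.seed", globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, globalenv())
    })
    set.seed(seed)
    expr
}
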