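# Independent oracles and small fixtures used across the suite.

# Exhaustive Otsu: scan every candidate threshold of the binned histogram
# and return the gray value (bin center) maximizing between-class variance.
otsuExhaustive <- function(gray, levels = 256) {
    rng <- range(gray)
    bin <- pmin(floor((gray - rng[1]) / diff(rng) * levels), levels - 1)
    h <- tabulate(bin + 1L, nbins = levels)
    p <- h / sum(h)
    mids <- (seq_len(levels) - 0.5) / levels
    best <- -Inf; bestt <- NA
    for (t in seq_len(levels - 1)) {
        w0 <- sum(p[1:t]); w1 <- 1 - w0
        if (w0 == 0 || w1 == 0) next
        mu0 <- sum(p[1:t] * mids[1:t]) / w0
        mu1 <- sum(p[(t + 1):levels] * mids[(t + 1):levels]) / w1
        v <- w0 * w1 * (mu0 - mu1)^2
        if (v > best) { best <- v; bestt <- t }
    }
    rng[1] + (bestt / levels) * diff(rng)
}

# Exhaustive minimum-SSE bipartition of n points (n <= ~12).
bestBipartitionSSE <- function(X) {
    X <- as.matrix(X)
    n <- nrow(X)
    sse <- function(idx) {
        if (length(idx) == 0) return(0)
        M <- X[idx, , drop = FALSE]
        sum(sweep(M, 2, colMeans(M))^2)
    }
    best <- Inf
    for (code in 1:(2^(n - 1) - 1)) {
        g <- as.logical(bitwAnd(rep(code, n), 2^(seq_len(n) - 1)))
        best <- min(best, sse(which(g)) + sse(which(!g)))
    }
    best
}

# Tiny season configurations used throughout (desk-scale).
tinyConfig <- function(...) {
    syntheticConfig(n_weeks = 1L, trays_per_week = 2L, ...)       # 48 olives
}
smallConfig <- function(...) {
    syntheticConfig(n_weeks = 2L, trays_per_week = 5L, ...)       # 240 olives
}

# Two well-separated Gaussian blobs in p dims (for clustering tests).
twoBlobs <- function(n_per = 30, p = 2, sep = 20, sd = 0.5, seed = 1) {
    withr::with_seed(seed, {
        rbind(matrix(rnorm(n_per * p, 0, sd), n_per, p),
              matrix(rnorm(n_per * p, sep, sd), n_per, p))
    })
}
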