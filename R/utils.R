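# Seed fan-out: every stochastic component takes an explicit seed derived
# from the global run seed, so whole pipelines are reproducible and
# components stay independently re-runnable. Kept below 2^31 - 1.

#' Derive a child seed from a parent seed
#'
#' Deterministic integer hash used to fan a global run seed out to
#' per-component seeds (generator, per-restart clustering inits, per-repeat
#' splits, SA proposals). Distinct offsets give effectively independent
#' streams.
#'
#' @param seed integer parent seed.
#' @param offset integer stream offset.
#' @return an integer seed in [1, 2^31 - 2].
#' @export
deriveSeed <- function(seed, offset = 0) {
    s <- (abs(as.numeric(seed)) * 48271 + as.numeric(offset) * 16807 + 1)
    as.integer(s %% 2147483646 + 1)
}

# Evaluate expr with a temporary RNG state seeded at `seed`, restoring the
# caller's state afterwards.
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(expr)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
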