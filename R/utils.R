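# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. Keeps package operations reproducible without
# clobbering the user's random stream.
withSeed <- function(seed, expr) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        runif(1)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    expr
}

# Deterministic numeric formatting that round-trips through as.numeric for
# the dose component of condition keys.
.formatDose <- function(d) {
    vapply(d, function(x) format(x, trim = TRUE, digits = 15,
                                  scientific = FALSE), character(1))
}

.asMatrixRow <- function(x, n) {
    if (is.matrix(x)) x else matrix(x, nrow = 1, ncol = n)
}
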