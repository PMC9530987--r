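## Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

## Derive a per-unit RNG stream seed from (master seed, unit index),
## kept inside 32-bit integer range.
.deriveSeed <- function(seed, index) {
    as.integer((as.numeric(seed) * 10007 + as.numeric(index)) %% 2147483647)
}
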