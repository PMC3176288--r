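# internal helpers shared across modules

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs code in the current stream.
withSeed <- function(seed, code) {
    if (is.null(seed))
        return(force(code))
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        stats::runif(1L)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
    force(code)
}

# Uniform argument coercion: accept a character scalar, DNAString or a
# length-1 DNAStringSet and return an uppercase character scalar.
asDnaCharacter <- function(x, what = "sequence") {
    if (methods::is(x, "DNAStringSet")) {
        if (length(x) != 1L)
            stop("expected a single ", what, ", got ", length(x), " sequences")
        x <- x[[1L]]
    }
    if (methods::is(x, "XString"))
        x <- as.character(x)
    if (!is.character(x) || length(x) != 1L || is.na(x))
        stop("'", what, "' must be a single DNA string")
    toupper(x)
}

stopIfNegative <- function(x, what) {
    if (any(!is.finite(x) | x < 0))
        stop("'", what, "' must be finite and non-negative")
    invisible(x)
}
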