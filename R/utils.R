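# Internal helpers shared across modules.

# Stable 31-based string hash on UTF-8 bytes, kept inside 31 bits so the
# XOR with a user seed remains a valid R integer.
hashString <- function(s) {
    bytes <- as.integer(utf8ToInt(s))
    h <- 0
    for (b in bytes) h <- (h * 31 + b) %% 2147483647
    as.integer(h)
}

# Per-target seed: stable hash of the assay id XOR the global seed, so a
# target's model is unaffected by which other targets are trained.
deriveSeed <- function(global_seed, id) {
    bitwAnd(bitwXor(as.integer(global_seed), hashString(id)), 2147483647L)
}

# Pearson r that returns NA (rather than erroring or warning) when either
# vector has zero variance; pairwise-complete on NA.
safePearson <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L) return(NA_real_)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
}

# Column-bound replacement matrix builder preserving dimnames.
sameShape <- function(template, values) {
    dimnames(values) <- dimnames(template)
    values
}

stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}
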