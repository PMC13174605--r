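# Independent oracles and tiny fixture builders used across the suite.

toyEM <- function(values, platform = "B_pea", scale = "standardized",
                  samples = NULL, assays = NULL) {
    if (is.null(samples)) samples <- sprintf("s%02d", seq_len(nrow(values)))
    if (is.null(assays)) assays <- sprintf("a%02d", seq_len(ncol(values)))
    dimnames(values) <- list(samples, assays)
    ExpressionMatrix(values, platform = platform, scale = scale)
}

# Direct covariance-formula Pearson r, independent of stats::cor.
bruteForcePearson <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    mx <- sum(x) / length(x); my <- sum(y) / length(y)
    num <- sum((x - mx) * (y - my))
    den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
    num / den
}

# Exhaustive nearest-neighbor imputation oracle: recomputes, for every
# missing cell, the per-pair scaled Euclidean distances and the k-nearest
# observed assays by full enumeration.
bruteForceKnn <- function(v, k) {
    p <- ncol(v)
    ids <- colnames(v)
    out <- v
    for (i in seq_len(nrow(v))) for (j in seq_len(p)) {
        if (!is.na(v[i, j])) next
        cand <- setdiff(seq_len(p), j)
        dist_j <- vapply(cand, function(b) {
            sh <- !is.na(v[, j]) & !is.na(v[, b])
            if (!any(sh)) return(Inf)
            sqrt(sum((v[sh, j] - v[sh, b])^2) / sum(sh))
        }, numeric(1))
        usable <- cand[is.finite(dist_j) & !is.na(v[i, cand])]
        if (!length(usable)) {
            out[i, j] <- mean(v[, j], na.rm = TRUE)
        } else {
            ord <- usable[order(dist_j[match(usable, cand)], ids[usable])]
            nb <- ord[seq_len(min(k, length(ord)))]
            out[i, j] <- mean(v[i, nb])
        }
    }
    out
}

# Small paired-platform simulation shared by a few tests.
smallSimConfig <- function(n = 300, p = 24, seed = 42, ...) {
    SimConfig(n_samples = n, n_proteins = p,
              block_sizes = rep(4L, p / 4), seed = seed, ...)
}

# Harmonize a simulated pair end-to-end: returns standardized matrices,
# split and overlap, as the pipeline would produce them.
harmonizeSim <- function(truth, seed = truth@config@seed, fraction = 0.75) {
    rawA <- measurePlatform(truth, "A_aptamer")
    rawB <- measurePlatform(truth, "B_pea")
    impB <- knnImpute(qcMissingness(rawB), k = 10)
    shared <- intersect(sampleIDs(rawA), sampleIDs(impB))
    split <- splitSamples(shared, fraction, seed = seed)
    list(
        emA = log2Standardize(rawA[shared, ],
                              fit_subset = split@train_ids)$matrix,
        emB = log2Standardize(impB[shared, ],
                              fit_subset = split@train_ids)$matrix,
        split = split,
        overlap = buildOverlap(simAssayMap(truth, "A_aptamer"),
                               simAssayMap(truth, "B_pea")))
}
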