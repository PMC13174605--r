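test_that("readMatrix parses masks, preserves order and rejects bad files", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("sample_id\tzeta\talpha", "s1\t1.5\t2", "s2\t3\tNA",
                 "s3\t4\t5"), f)
    em <- readMatrix(f, platform = "B_pea", scale = "log2")
    expect_identical(assayIDs(em), c("zeta", "alpha"))  # column order kept
    expect_identical(sum(missingMask(em)), 1L)
    expect_true(missingMask(em)["s2", "alpha"])

    dup_s <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("sample_id\ta", "s1\t1", "s1\t2"), dup_s)
    expect_error(readMatrix(dup_s, "B_pea"), "duplicate sample ids")

    dup_a <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("sample_id\ta\ta", "s1\t1\t2"), dup_a)
    expect_error(readMatrix(dup_a, "B_pea"), "duplicated assay")

    ragged <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("sample_id\ta\tb", "s1\t1\t2", "s2\t3"), ragged)
    expect_error(readMatrix(ragged, "B_pea"))

    rt <- withr::local_tempfile(fileext = ".tsv")
    writeMatrix(em, rt)
    expect_equal(values(readMatrix(rt, "B_pea", scale = "log2")), values(em),
                 tolerance = 1e-12)
})

test_that("liftPanel applies per-assay affine transforms and keeps r invariant", {
    m <- toyEM(matrix(c(3.5, 1, 2, 4, 5, 6), 3, 2), platform = "A_aptamer",
               scale = "raw", assays = c("a1", "a2"))
    ident <- data.frame(assay_id = c("a1", "a2"), scale = 1, offset = 0)
    expect_equal(values(liftPanel(m, ident)), values(m))

    lift <- data.frame(assay_id = c("a1", "a2"), scale = c(2, 3),
                       offset = c(0, 1))
    lifted <- liftPanel(m, lift)
    expect_equal(values(lifted)["s01", "a1"], 7.0)
    expect_equal(values(lifted)[, "a2"], 3 * values(m)[, "a2"] + 1,
                 ignore_attr = TRUE)

    # positive-affine lifts leave Pearson correlations unchanged
    set.seed(1)
    big <- toyEM(matrix(rexp(60) + 1, 12, 5), platform = "A_aptamer",
                 scale = "raw")
    rlift <- data.frame(assay_id = assayIDs(big),
                        scale = runif(5, 0.5, 3), offset = runif(5, -2, 2))
    expect_equal(cor(values(liftPanel(big, rlift))), cor(values(big)),
                 tolerance = 1e-12)

    expect_error(liftPanel(m, data.frame(assay_id = "a1", scale = -1,
                                         offset = 0)), "non-positive")
    expect_warning(liftPanel(m, data.frame(assay_id = "a1", scale = 1,
                                           offset = 0)), "absent")
})

test_that("log2Standardize matches the hand-computed golden column", {
    em <- toyEM(matrix(c(8, 16, 32), 3, 1), platform = "A_aptamer",
                scale = "raw", assays = "a1")
    std <- log2Standardize(em)
    # log2 -> (3, 4, 5); sample-SD (n-1) z-scores -> (-1, 0, 1)
    expect_equal(unname(values(std$matrix)[, 1]), c(-1, 0, 1),
                 tolerance = 1e-12)
    expect_identical(scaleOf(std$matrix), "standardized")

    # applying a scaler to its own fit subset gives mean 0, sd 1
    set.seed(2)
    big <- toyEM(matrix(rexp(80) + 0.5, 16, 5), platform = "A_aptamer",
                 scale = "raw")
    fit_ids <- sampleIDs(big)[1:10]
    std2 <- log2Standardize(big, fit_subset = fit_ids)
    sub <- values(std2$matrix)[fit_ids, ]
    expect_equal(unname(colMeans(sub)), rep(0, 5), tolerance = 1e-12)
    expect_equal(unname(apply(sub, 2, sd)), rep(1, 5), tolerance = 1e-12)

    # held-out samples reuse the training-era parameters
    held <- applyScaler(big[sampleIDs(big)[11:16], ], std2$scaler)
    expect_equal(values(held), values(std2$matrix)[11:16, ],
                 tolerance = 1e-12)

    # double-transform guard and degenerate inputs
    expect_error(log2Standardize(std$matrix), "already standardized")
    expect_error(log2Standardize(toyEM(matrix(c(-1, 2, 3), 3, 1),
                                       platform = "A_aptamer",
                                       scale = "raw")), "non-positive")
    const <- toyEM(matrix(rep(4, 3), 3, 1), platform = "A_aptamer",
                   scale = "raw", assays = "flat")
    expect_error(log2Standardize(const), "flat")

    # standardization leaves assay-pair correlations unchanged
    expect_equal(cor(values(std2$matrix)), cor(log2(values(big))),
                 tolerance = 1e-12)
})

test_that("missingness QC drops by strict > threshold, assays first", {
    v <- matrix(rnorm(40), 10, 4)
    v[1:2, 1] <- NA          # assay 20% missing -> dropped
    v[3, 2] <- NA            # assay 10% missing -> retained (strict >)
    em <- toyEM(v, platform = "B_pea", scale = "log2")
    qc <- qcMissingness(em, threshold = 0.10)
    expect_identical(assayIDs(qc), c("a02", "a03", "a04"))
    # the sample pass runs on the retained assays: s03 is now 1/3 missing
    expect_identical(sampleIDs(qc), setdiff(sampleIDs(em), "s03"))

    # no missingness: identity
    full <- toyEM(matrix(rnorm(20), 5, 4), platform = "B_pea",
                  scale = "log2")
    expect_identical(values(qcMissingness(full)), values(full))

    # sample pass runs after the assay pass
    v2 <- matrix(rnorm(40), 10, 4)
    v2[1, ] <- NA                       # sample fully missing
    v2[, 4] <- NA; v2[2:10, 4] <- rnorm(9)  # assay 10% missing, retained
    em2 <- toyEM(v2, platform = "B_pea", scale = "log2")
    qc2 <- qcMissingness(em2, threshold = 0.10)
    expect_false("s01" %in% sampleIDs(qc2))
    expect_true("a04" %in% assayIDs(qc2))

    all_na <- toyEM(matrix(NA_real_, 4, 2), platform = "B_pea",
                    scale = "log2")
    expect_error(qcMissingness(all_na), "every assay")
})

test_that("knnImpute fills holes from assay neighbors and matches the oracle", {
    # twin-assay toy: the hole copies the identical twin at distance 0
    v <- cbind(c(1, 2, 3, 4), c(-5, 0, 7, 2), c(1, 2, NA, 4))
    em <- toyEM(v, platform = "B_pea", scale = "log2")
    out1 <- knnImpute(em, k = 1)
    expect_equal(values(out1)["s03", "a03"], 3)

    # observed entries are untouched and the result is complete
    expect_identical(values(out1)[-3, ], v[-3, ], ignore_attr = TRUE)
    expect_false(anyNA(values(out1)))

    # no missingness: identity
    full <- toyEM(matrix(rnorm(12), 4, 3), platform = "B_pea",
                  scale = "log2")
    expect_identical(values(knnImpute(full)), values(full))

    # oracle equivalence on random <= 10 x 10 matrices with scattered holes
    for (seed in 1:4) {
        set.seed(seed)
        n <- sample(5:10, 1); p <- sample(4:10, 1)
        v <- matrix(rnorm(n * p), n, p)
        holes <- sample(length(v), round(0.15 * length(v)))
        v[holes] <- NA
        keep <- colMeans(is.na(v)) < 1
        v <- v[, keep, drop = FALSE]
        em <- toyEM(v, platform = "B_pea", scale = "log2")
        k <- sample(1:3, 1)
        expect_equal(values(knnImpute(em, k = k)),
                     bruteForceKnn(values(em), k),
                     tolerance = 1e-12, label = paste("seed", seed))
    }

    # k clamping warns; fully missing assay errors
    v3 <- cbind(c(1, NA, 3), c(2, 3, 4))
    expect_warning(knnImpute(toyEM(v3, platform = "B_pea", scale = "log2"),
                             k = 10), "exceeds")
    v4 <- cbind(c(NA, NA, NA), c(1, 2, 3))
    expect_error(knnImpute(toyEM(v4, platform = "B_pea", scale = "log2")),
                 "fully missing")
})

test_that("QC then imputation leaves no missing entries (simulated panel)", {
    tr <- simulateLatent(smallSimConfig(n = 150, p = 12, seed = 31,
                                        lod_quantile = 0.08))
    b <- measurePlatform(tr, "B_pea")
    expect_true(anyNA(values(b)))
    done <- knnImpute(qcMissingness(b), k = 10)
    expect_false(anyNA(values(done)))
})

test_that("duplicate PEA assays resolve by lowest pre-imputation missingness", {
    v <- cbind(c(1, 2, 3, 4, NA), c(1.1, 2.1, NA, NA, 5), rnorm(5))
    em <- toyEM(v, platform = "B_pea", scale = "log2",
                assays = c("olk1", "olk1_2", "other"))
    map <- assayMap(c("olk1", "olk1_2", "other"), "B_pea",
                    c("p1", "p1", "p2"))
    out <- resolveDuplicates(em, map)
    expect_identical(assayIDs(out), c("olk1", "other"))  # 20% vs 40% missing

    # equal missingness: lexicographically first wins
    v2 <- cbind(c(1, NA, 3), c(2, NA, 4))
    em2 <- toyEM(v2, platform = "B_pea", scale = "log2",
                 assays = c("b_assay", "a_assay"))
    map2 <- assayMap(c("b_assay", "a_assay"), "B_pea", c("p1", "p1"))
    expect_identical(assayIDs(resolveDuplicates(em2, map2)), "a_assay")

    # no duplicates: identity; aptamer platform untouched
    expect_identical(assayIDs(resolveDuplicates(em[, "other"], map)),
                     "other")
    emA <- toyEM(v, platform = "A_aptamer", scale = "raw",
                 assays = c("x", "x_2", "y"))
    expect_identical(assayIDs(resolveDuplicates(emA, map)), c("x", "x_2", "y"))
})

test_that("buildOverlap matches aptamer multiplicity and reports coverage", {
    mA <- assayMap(c("som1", "som1_2", "som2", "som3"), "A_aptamer",
                   c("p1", "p1", "p2", "p4"))
    mB <- assayMap(c("olk1", "olk9"), "B_pea", c("p1", "p3"))
    ov <- buildOverlap(mA, mB)
    expect_identical(nrow(ov), 2L)                 # 2 aptamer rows
    expect_identical(attr(ov, "summary")$n_overlap, 1L)  # 1 distinct protein
    expect_identical(unique(ov$assay_id_B), "olk1")

    # disjoint panels: empty overlap
    mB2 <- assayMap("olkZ", "B_pea", "p9")
    expect_identical(nrow(buildOverlap(mA, mB2)), 0L)

    # unresolved PEA duplicates are rejected
    mBdup <- assayMap(c("o1", "o2"), "B_pea", c("p1", "p1"))
    expect_error(buildOverlap(mA, mBdup), "resolveDuplicates")
})
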