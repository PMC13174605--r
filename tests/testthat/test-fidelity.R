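test_that("pairwise correlations match the brute-force formula oracle", {
    set.seed(8)
    vA <- matrix(rnorm(15), 5, 3)
    vB <- cbind(vA[, 1], -vA[, 2], rnorm(5))
    emA <- toyEM(vA, platform = "A_aptamer")
    emB <- toyEM(vB, platform = "B_pea", assays = c("b1", "b2", "b3"))
    ov <- data.frame(protein_id = c("p1", "p2", "p3"),
                     assay_id_A = c("a01", "a02", "a03"),
                     assay_id_B = c("b1", "b2", "b3"))
    base <- baselineCorrelation(emA, emB, ov)
    expect_equal(base$baseline_r[1], 1)
    expect_equal(base$baseline_r[2], -1)
    expect_equal(base$baseline_r[3],
                 bruteForcePearson(vA[, 3], vB[, 3]), tolerance = 1e-12)

    # 6-sample model-performance fixture against the same oracle
    set.seed(9)
    imp <- toyEM(matrix(rnorm(12), 6, 2), platform = "B_pea",
                 assays = c("b1", "b2"))
    meas <- toyEM(matrix(rnorm(12), 6, 2), platform = "B_pea",
                  assays = c("b1", "b2"))
    perf <- modelPerformance(imp, meas)
    for (j in 1:2)
        expect_equal(perf$model_r[j],
                     bruteForcePearson(values(imp)[, j], values(meas)[, j]),
                     tolerance = 1e-12)

    # zero-variance columns flag undefined with a warning
    vB[, 3] <- 5
    emBc <- toyEM(vB, platform = "B_pea", assays = c("b1", "b2", "b3"))
    expect_warning(bc <- baselineCorrelation(emA, emBc, ov), "undefined")
    expect_true(is.na(bc$baseline_r[3]))
})

test_that("post-imputation correlation uses held-out samples only", {
    set.seed(10)
    n <- 40
    src <- toyEM(matrix(rnorm(n * 2), n, 2), platform = "A_aptamer")
    imp <- toyEM(values(src) + matrix(rnorm(n * 2, sd = 0.1), n, 2),
                 platform = "B_pea", samples = sampleIDs(src),
                 assays = c("b1", "b2"))
    ov <- data.frame(protein_id = c("p1", "p2"),
                     assay_id_A = c("a01", "a02"),
                     assay_id_B = c("b1", "b2"))
    test_ids <- sampleIDs(src)[31:40]
    p0 <- postImputationCorrelation(imp, src, ov, samples = test_ids)

    # identical counterpart: r = 1
    ident <- toyEM(values(src), platform = "B_pea",
                   samples = sampleIDs(src), assays = c("b1", "b2"))
    expect_equal(postImputationCorrelation(ident, src, ov,
                                           samples = test_ids)$post_r,
                 c(1, 1))

    # changing training-sample values leaves the result unchanged
    v2 <- values(src)
    v2[1:30, ] <- matrix(rnorm(60), 30, 2)
    src2 <- toyEM(v2, platform = "A_aptamer", samples = sampleIDs(src))
    expect_equal(postImputationCorrelation(imp, src2, ov,
                                           samples = test_ids)$post_r,
                 p0$post_r)

    # independent imputations decorrelate
    set.seed(11)
    noise <- toyEM(matrix(rnorm(2000 * 1), 2000, 1), platform = "B_pea",
                   assays = "b1")
    srcbig <- toyEM(matrix(rnorm(2000 * 1), 2000, 1),
                    platform = "A_aptamer", samples = sampleIDs(noise))
    ov1 <- data.frame(protein_id = "p1", assay_id_A = "a01",
                      assay_id_B = "b1")
    expect_lt(abs(postImputationCorrelation(noise, srcbig, ov1)$post_r), 0.1)
})

test_that("correlation gain is the post-minus-baseline difference", {
    expect_equal(correlationGain(0.21, 0.61)$gain, 0.40, tolerance = 1e-12)
    expect_equal(correlationGain(0.40, 0.75)$gain, 0.35, tolerance = 1e-12)
    expect_equal(correlationGain(0.5, 0.5)$gain, 0)
    # antisymmetry and magnitude gain for sign-distorted proteins
    expect_equal(correlationGain(0.3, 0.8)$gain,
                 -correlationGain(0.8, 0.3)$gain)
    g <- correlationGain(-0.4, -0.50)
    expect_equal(g$gain, -0.1, tolerance = 1e-12)
    expect_equal(g$magnitude_gain, 0.1, tolerance = 1e-12)
    expect_true(is.na(correlationGain(NA, 0.5)$gain))
})

test_that("tier rules partition the correlation plane exhaustively", {
    expect_identical(assignTier(0.21, 0.61), 2L)
    expect_identical(assignTier(-0.4, -0.50), 4L)
    expect_identical(assignTier(0.8, 0.9), 1L)
    expect_identical(assignTier(0.05, 0.02), 4L)
    expect_identical(assignTier(0.3, 0.35), 3L)
    # boundary conventions: >= for t_high and t_mid, <= for t_low
    expect_identical(assignTier(0.7, 0.7), 1L)
    expect_identical(assignTier(0.1, 0.1), 4L)
    expect_identical(assignTier(0.1, 0.4), 2L)
    expect_true(is.na(assignTier(NA, 0.5)))

    # dense-grid partition: every point gets exactly one defined tier
    g <- seq(-1, 1, length.out = 401)
    grid <- expand.grid(b = g, p = g)
    tiers <- assignTier(grid$b, grid$p)
    expect_false(anyNA(tiers))
    expect_true(all(tiers %in% 1:4))
    # and the rules reproduce themselves region by region
    rules_ok <- ifelse(grid$b >= 0.7 & grid$p >= 0.7, 1L,
                ifelse(grid$b <= 0.1 & grid$p <= 0.1, 4L,
                ifelse(grid$p >= 0.4, 2L, 3L)))
    expect_identical(tiers, rules_ok)
})

test_that("consensus summarizes cross-direction tier agreement", {
    r1 <- data.frame(protein_id = c("p1", "p2", "p3", "p4"),
                     tier = c(1L, 2L, 3L, 4L))
    r2 <- data.frame(protein_id = c("p1", "p2", "p3", "p4"),
                     tier = c(1L, 2L, 4L, 4L))
    cons <- consensusTiers(r1, r2)
    expect_equal(cons$overall_pct_agree, 75)
    expect_identical(cons$per_protein$agree, c(TRUE, TRUE, FALSE, TRUE))

    expect_equal(consensusTiers(r1, r1)$overall_pct_agree, 100)
    r3 <- r2; r3$tier <- c(2L, 3L, 4L, 1L)
    expect_equal(consensusTiers(r1, r3)$overall_pct_agree, 0)
    expect_error(consensusTiers(r1, r2[1:3, ]), "different protein sets")
})

test_that("tier report emits a consistent table and distribution", {
    set.seed(12)
    rec <- data.frame(protein_id = sprintf("p%02d", 1:10),
                      assay_id_A = sprintf("a%02d", 1:10),
                      assay_id_B = sprintf("b%02d", 1:10),
                      direction = "A2B",
                      baseline_r = runif(10, -1, 1),
                      post_r = runif(10, -1, 1))
    rec$gain <- rec$post_r - rec$baseline_r
    rec$magnitude_gain <- abs(rec$post_r) - abs(rec$baseline_r)
    rec$model_r <- NA_real_
    rec$tier <- assignTier(rec$baseline_r, rec$post_r)
    tsv <- withr::local_tempfile(fileext = ".tsv")
    js <- withr::local_tempfile(fileext = ".json")
    rep <- tierReport(rec, tsv_path = tsv, json_path = js)
    d <- rep$distribution$A2B
    expect_identical(sum(unlist(d$counts)), 10L)
    expect_equal(sum(unlist(d$fractions)), 1)
    back <- read.delim(tsv)
    expect_identical(nrow(back), 10L)
    expect_equal(back$post_r, rec$post_r, tolerance = 1e-6)
    meta <- jsonlite::read_json(js)
    expect_true(meta$metadata$boundary_convention$signed)
})

test_that("multi-aptamer proteins report per pair and roll up by best post_r", {
    rec <- data.frame(protein_id = c("p1", "p1", "p2"),
                      assay_id_A = c("s1", "s1_2", "s2"),
                      assay_id_B = c("o1", "o1", "o2"),
                      direction = "A2B",
                      baseline_r = c(0.2, 0.5, 0.8),
                      post_r = c(0.45, 0.75, 0.9),
                      model_r = NA_real_, gain = NA_real_,
                      magnitude_gain = NA_real_,
                      tier = c(2L, 2L, 1L))
    roll <- rollupBestAptamer(rec)
    expect_identical(nrow(roll), 2L)
    expect_identical(roll$assay_id_A[roll$protein_id == "p1"], "s1_2")
})
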