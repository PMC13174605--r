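test_that("latent draw honours the block-exchangeable correlation", {
    # independence when within_block_corr = 0
    t0 <- simulateLatent(SimConfig(n_samples = 3000, n_proteins = 8,
                                   block_sizes = c(4L, 4L),
                                   within_block_corr = 0, seed = 3))
    cc <- cor(latentMatrix(t0))
    expect_lt(max(abs(cc[upper.tri(cc)])), 0.08)

    # within-block empirical r tracks the configured value
    t8 <- simulateLatent(SimConfig(n_samples = 5000, n_proteins = 5,
                                   block_sizes = 5L,
                                   within_block_corr = 0.8, seed = 3))
    cc <- cor(latentMatrix(t8))
    expect_equal(mean(cc[upper.tri(cc)]), 0.8, tolerance = 0.05 / 0.8)

    # marginal scale is standard normal-ish
    expect_equal(mean(apply(latentMatrix(t8), 2, sd)), 1, tolerance = 0.05)
})

test_that("simulation is deterministic under a fixed seed and validates config", {
    cfg <- smallSimConfig(n = 80, p = 8, seed = 9)
    t1 <- simulateLatent(cfg); t2 <- simulateLatent(cfg)
    expect_identical(latentMatrix(t1), latentMatrix(t2))
    expect_identical(classLabels(t1), classLabels(t2))
    m1 <- measurePlatform(t1, "B_pea"); m2 <- measurePlatform(t2, "B_pea")
    expect_identical(values(m1), values(m2))

    expect_error(SimConfig(n_proteins = 10, block_sizes = c(4L, 4L)),
                 "block_sizes")
    expect_error(SimConfig(within_block_corr = 1), "within_block_corr")
    expect_error(SimConfig(class_proportions = c(faithful = 0.5,
                                                 recoverable = 0.5,
                                                 ambivalent = 0.2,
                                                 irreconcilable = -0.2)),
                 "class_proportions")
})

test_that("platform measurement reflects the fidelity classes", {
    # all-faithful, near-zero noise: cross-platform r -> 1
    cfg <- SimConfig(n_samples = 400, n_proteins = 8, block_sizes = c(4L, 4L),
                     class_proportions = c(faithful = 1, recoverable = 0,
                                           ambivalent = 0,
                                           irreconcilable = 0),
                     noise_sd_by_class = c(faithful = 1e-3, recoverable = 1,
                                           ambivalent = 1,
                                           irreconcilable = 1),
                     lod_quantile = 0, seed = 5)
    tr <- simulateLatent(cfg)
    a <- log2(values(measurePlatform(tr, "A_aptamer")))
    b <- values(measurePlatform(tr, "B_pea"))
    r <- vapply(seq_len(8), function(j) cor(a[, j], b[, j]), numeric(1))
    expect_true(all(r > 0.999))

    # off-target proteins decorrelate the platforms
    cfg2 <- SimConfig(n_samples = 2000, n_proteins = 8,
                      block_sizes = c(4L, 4L), within_block_corr = 0,
                      class_proportions = c(faithful = 0, recoverable = 0,
                                            ambivalent = 0,
                                            irreconcilable = 1),
                      lod_quantile = 0, seed = 5)
    tr2 <- simulateLatent(cfg2)
    mech <- tr2@distortion_params$mechanism
    a <- log2(values(measurePlatform(tr2, "A_aptamer")))
    b <- values(measurePlatform(tr2, "B_pea"))
    off <- which(mech == "offtarget_A")
    r_off <- vapply(off, function(j) cor(a[, j], b[, j]), numeric(1))
    expect_true(all(abs(r_off) < 0.1))

    # epitope proteins show the sign-distorted (negative) baseline r
    epi <- which(mech == "epitope")
    r_epi <- vapply(epi, function(j) cor(a[, j], b[, j]), numeric(1))
    expect_true(all(r_epi < -0.2))
})

test_that("LOD censoring yields the configured missing fraction on platform B", {
    cfg <- smallSimConfig(n = 1000, p = 8, seed = 2, lod_quantile = 0.05)
    m <- measurePlatform(simulateLatent(cfg), "B_pea")
    frac <- colMeans(missingMask(m))
    expect_true(all(abs(frac - 0.05) < 0.02))
    # censoring is left-censoring: missing entries sat below every observed one
    v <- values(m)
    expect_true(all(!missingMask(measurePlatform(
        simulateLatent(smallSimConfig(n = 100, p = 8, seed = 2,
                                      lod_quantile = 0)), "B_pea"))))
})

test_that("phenotype generation follows the configured effects", {
    # null effects: proteins explain nothing
    cfg <- smallSimConfig(n = 800, p = 8, seed = 7, effect_sizes = 0,
                          survival_effect_sizes = 0)
    tr <- simulateLatent(cfg)
    ph <- simulatePhenotypes(tr)
    fit <- lm(ph$outcome ~ latentMatrix(tr))
    expect_lt(summary(fit)$r.squared, 0.05)

    # zero censoring: every subject has an event
    cfg0 <- smallSimConfig(n = 100, p = 8, seed = 7, censoring_rate = 0)
    ph0 <- simulatePhenotypes(simulateLatent(cfg0))
    expect_true(all(ph0$event == 1L))

    # censoring rate is roughly honoured at a null linear predictor
    cfgc <- smallSimConfig(n = 2000, p = 8, seed = 7, effect_sizes = 0,
                           survival_effect_sizes = 0, censoring_rate = 0.3)
    phc <- simulatePhenotypes(simulateLatent(cfgc))
    expect_equal(mean(phc$event == 0L), 0.3, tolerance = 0.1)

    # a single beta = log(1.5) is recovered at large n
    cfg1 <- SimConfig(n_samples = 5000, n_proteins = 4, block_sizes = 4L,
                      within_block_corr = 0, phenotype_sparsity = 1,
                      survival_effect_sizes = log(1.5),
                      censoring_rate = 0.3, seed = 13)
    tr1 <- simulateLatent(cfg1)
    ph1 <- simulatePhenotypes(tr1)
    causal <- names(which(tr1@survival_coefs != 0))
    fit <- survival::coxph(survival::Surv(ph1$time, ph1$event) ~
                               latentMatrix(tr1)[, causal])
    expect_equal(unname(exp(coef(fit))), 1.5, tolerance = 0.07)
})

test_that("fixtures round-trip through writeFixture/readMatrix", {
    cfg <- smallSimConfig(n = 30, p = 8, seed = 21, lod_quantile = 0.1)
    tr <- simulateLatent(cfg)
    mats <- list(platform_A = measurePlatform(tr, "A_aptamer"),
                 platform_B = measurePlatform(tr, "B_pea"))
    ph <- simulatePhenotypes(tr)
    dir <- withr::local_tempdir()
    writeFixture(tr, mats, ph, dir)

    back <- readMatrix(file.path(dir, "platform_B.tsv"), platform = "B_pea",
                       scale = "log2")
    expect_equal(values(back), values(mats$platform_B), tolerance = 1e-12)
    # injected missingness encodes as the NA token and survives
    expect_identical(missingMask(back), missingMask(mats$platform_B))

    truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                                 simplifyVector = TRUE)
    expect_length(truth$class_labels, 8L)
    expect_true(all(unlist(truth$class_labels) %in%
                    c("faithful", "recoverable", "ambivalent",
                      "irreconcilable")))
})
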