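#' Configure a paired-platform simulation
#'
#' Builds a \linkS4class{SimConfig} describing a synthetic cohort measured
#' on both an aptamer-like platform (A, raw RFU scale) and a PEA-like
#' platform (B, NPX/log2 scale with below-LOD censoring). Proteins belong
#' to one of four fidelity classes that determine how each platform
#' distorts the shared latent concentration:
#' \describe{
#'   \item{faithful}{positive affine transform of the latent plus mild
#'     noise on both platforms — high cross-platform concordance.}
#'   \item{recoverable}{a monotone cubic distortion \eqn{g(x)=x+0.4x^3} on
#'     platform A only, plus substantial noise on both — modest baseline
#'     concordance that a flexible regressor can largely recover.}
#'   \item{ambivalent}{latent plus heavy noise on both platforms —
#'     concordance low before and after imputation.}
#'   \item{irreconcilable}{either platform A binds an independent
#'     off-target analyte, or a carrier genotype shifts the two platforms'
#'     signals in opposite directions (epitope artifact), driving the
#'     cross-platform correlation negative.}
#' }
#' Default class proportions (0.20, 0.35, 0.25, 0.20) echo the tier shares
#' observed on real paired panels.
#'
#' @param n_samples cohort size (default 2000).
#' @param n_proteins panel size (default 120).
#' @param block_sizes sizes of correlated "biological neighbor" blocks;
#'   must sum to \code{n_proteins} (default blocks of 4).
#' @param within_block_corr exchangeable latent correlation inside a block
#'   (default 0.5).
#' @param class_proportions named fractions over the four fidelity classes.
#' @param noise_sd_by_class named per-class measurement noise SDs.
#' @param lod_quantile left-censoring quantile on platform B (default 0.05).
#' @param epitope_effect_size genotype shift, applied with opposite signs
#'   on the two platforms (default 2.5).
#' @param epitope_carrier_freq carrier allele frequency (default 0.3).
#' @param phenotype_sparsity number of causal proteins (default 10,
#'   capped at \code{n_proteins}).
#' @param effect_sizes continuous-outcome effects, recycled over causal
#'   proteins (default 0.5).
#' @param survival_effect_sizes log hazard ratios per SD, recycled over
#'   causal proteins (default log(1.5)).
#' @param censoring_rate independent censoring fraction (default 0.3).
#' @param seed RNG seed (default 1).
#' @return A validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- SimConfig(n_samples = 100, n_proteins = 12,
#'                  block_sizes = rep(4L, 3), seed = 7)
#' cfg
#' @export
SimConfig <- function(n_samples = 2000L, n_proteins = 120L,
                      block_sizes = NULL, within_block_corr = 0.5,
                      class_proportions = c(faithful = 0.20,
                                            recoverable = 0.35,
                                            ambivalent = 0.25,
                                            irreconcilable = 0.20),
                      noise_sd_by_class = c(faithful = 0.3,
                                            recoverable = 1.0,
                                            ambivalent = 2.5,
                                            irreconcilable = 0.3),
                      lod_quantile = 0.05, epitope_effect_size = 2.5,
                      epitope_carrier_freq = 0.3,
                      phenotype_sparsity = min(10L, n_proteins),
                      effect_sizes = 0.5,
                      survival_effect_sizes = log(1.5),
                      censoring_rate = 0.3, seed = 1L) {
    if (is.null(block_sizes)) {
        nb <- n_proteins %/% 4L
        block_sizes <- rep(4L, nb)
        if (n_proteins %% 4L) block_sizes <- c(block_sizes, n_proteins %% 4L)
    }
    new("SimConfig", n_samples = as.integer(n_samples),
        n_proteins = as.integer(n_proteins),
        block_sizes = as.integer(block_sizes),
        within_block_corr = within_block_corr,
        class_proportions = class_proportions,
        noise_sd_by_class = noise_sd_by_class,
        lod_quantile = lod_quantile,
        epitope_effect_size = epitope_effect_size,
        epitope_carrier_freq = epitope_carrier_freq,
        phenotype_sparsity = as.integer(phenotype_sparsity),
        effect_sizes = effect_sizes,
        survival_effect_sizes = survival_effect_sizes,
        censoring_rate = censoring_rate, seed = as.integer(seed))
}

protein_ids <- function(p) sprintf("P%03d", seq_len(p))
sample_ids <- function(n) sprintf("S%05d", seq_len(n))

# Deterministic class counts from proportions: largest-remainder rounding.
classCounts <- function(proportions, p) {
    raw <- proportions[FIDELITY_CLASSES] * p
    cnt <- floor(raw)
    rem <- p - sum(cnt)
    if (rem > 0) {
        extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
        cnt[extra] <- cnt[extra] + 1
    }
    stats::setNames(as.integer(cnt), FIDELITY_CLASSES)
}

#' Simulate the latent proteome and its ground truth
#'
#' Draws a zero-mean, unit-variance latent concentration matrix with
#' block-exchangeable correlation (\code{within_block_corr} inside each
#' block, 0 across blocks), assigns every protein a fidelity class
#' (largest-remainder counts from \code{class_proportions}, seeded random
#' placement across blocks), fixes the per-platform distortion parameters,
#' carrier genotypes and the sparse phenotype/survival coefficients.
#' Everything downstream of the same \code{config} is reproducible.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return A \linkS4class{SimTruth}.
#' @examples
#' truth <- simulateLatent(SimConfig(n_samples = 50, n_proteins = 8,
#'                                   block_sizes = c(4L, 4L), seed = 1))
#' table(classLabels(truth))
#' @export
simulateLatent <- function(config) {
    validObject(config)
    n <- config@n_samples; p <- config@n_proteins
    rho <- config@within_block_corr
    withSeed(config@seed, {
        # Block-exchangeable MVN: X = sqrt(rho) * block factor + sqrt(1-rho) * noise
        latent <- matrix(0, n, p)
        col <- 0L
        for (m in config@block_sizes) {
            f <- stats::rnorm(n)
            eps <- matrix(stats::rnorm(n * m), n, m)
            latent[, col + seq_len(m)] <- sqrt(rho) * f + sqrt(1 - rho) * eps
            col <- col + m
        }
        dimnames(latent) <- list(sample_ids(n), protein_ids(p))

        cnt <- classCounts(config@class_proportions, p)
        labels <- sample(rep(FIDELITY_CLASSES, cnt))
        names(labels) <- colnames(latent)

        # Irreconcilable mechanisms alternate: off-target, epitope, ...
        irr <- which(labels == "irreconcilable")
        mechanism <- rep(NA_character_, p)
        mechanism[labels == "recoverable"] <- "nonlinear_A"
        if (length(irr))
            mechanism[irr] <- rep(c("offtarget_A", "epitope"),
                                  length.out = length(irr))

        dp <- data.frame(
            protein_id = colnames(latent),
            class = unname(labels),
            mechanism = mechanism,
            scale_A = stats::runif(p, 0.8, 1.25),
            offset_A = stats::runif(p, -1, 1),
            base_A = stats::runif(p, 8, 14),
            scale_B = stats::runif(p, 0.8, 1.25),
            offset_B = stats::runif(p, -1, 1),
            base_B = stats::runif(p, 0, 6),
            noise_sd = unname(config@noise_sd_by_class[labels]),
            offtarget_source = ifelse(!is.na(mechanism) &
                                      mechanism == "offtarget_A",
                                      paste0("OT_", colnames(latent)),
                                      NA_character_),
            stringsAsFactors = FALSE)

        genotypes <- stats::setNames(
            stats::rbinom(n, 2L, config@epitope_carrier_freq),
            rownames(latent))

        causal <- sort(sample.int(p, config@phenotype_sparsity))
        pheno_coefs <- stats::setNames(numeric(p), colnames(latent))
        pheno_coefs[causal] <- rep(config@effect_sizes,
                                   length.out = length(causal))
        surv_coefs <- stats::setNames(numeric(p), colnames(latent))
        surv_coefs[causal] <- rep(config@survival_effect_sizes,
                                  length.out = length(causal))

        new("SimTruth", latent = latent, class_labels = labels,
            distortion_params = dp, genotypes = genotypes,
            phenotype_coefs = pheno_coefs, survival_coefs = surv_coefs,
            config = config)
    })
}

#' Measure the latent proteome on one platform
#'
#' Applies the class-specific measurement model to the latent matrix.
#' On the log2 signal scale: faithful and ambivalent proteins are positive
#' affine transforms of the latent plus class noise; recoverable proteins
#' pass through the monotone cubic \eqn{g(x)=x+0.4x^3} on platform A only;
#' off-target irreconcilable proteins replace platform A's analyte with an
#' independent latent; epitope irreconcilable proteins receive the carrier
#' genotype shift with opposite signs on the two platforms. Platform A is
#' returned on the raw RFU scale (\code{2^(base + signal)}); platform B is
#' returned on the NPX/log2 scale with values below the per-assay
#' \code{lod_quantile} left-censored to \code{NA}.
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param platform \code{"A_aptamer"} or \code{"B_pea"}.
#' @param config optional \linkS4class{SimConfig}; defaults to the one
#'   stored in \code{truth}.
#' @return An \linkS4class{ExpressionMatrix} (assay ids are
#'   \code{"A_<protein>"} or \code{"B_<protein>"}).
#' @examples
#' truth <- simulateLatent(SimConfig(n_samples = 60, n_proteins = 8,
#'                                   block_sizes = c(4L, 4L), seed = 1))
#' measurePlatform(truth, "B_pea")
#' @export
measurePlatform <- function(truth, platform = c("A_aptamer", "B_pea"),
                            config = truth@config) {
    platform <- match.arg(platform)
    validObject(truth)
    latent <- truth@latent
    n <- nrow(latent); p <- ncol(latent)
    dp <- truth@distortion_params
    stopIfNot(all(dp$class %in% FIDELITY_CLASSES), "unknown class label")
    G <- truth@genotypes[rownames(latent)]
    isA <- platform == "A_aptamer"

    withSeed(deriveSeed(config@seed, platform), {
        signal <- matrix(0, n, p)
        for (j in seq_len(p)) {
            x <- latent[, j]
            cls <- dp$class[j]
            mech <- dp$mechanism[j]
            sdj <- dp$noise_sd[j]
            a <- if (isA) dp$scale_A[j] else dp$scale_B[j]
            b <- if (isA) dp$offset_A[j] else dp$offset_B[j]
            core <- if (cls == "recoverable" && isA) {
                x + 0.4 * x^3          # monotone distortion, platform A only
            } else if (cls == "irreconcilable" && mech == "offtarget_A" && isA) {
                stats::rnorm(n)        # independent off-target analyte
            } else if (cls == "irreconcilable" && mech == "epitope") {
                ee <- config@epitope_effect_size
                x + (if (isA) -ee else ee) * G
            } else {
                x
            }
            signal[, j] <- a * core + b + stats::rnorm(n, sd = sdj)
        }
        prefix <- if (isA) "A_" else "B_"
        dimnames(signal) <- list(rownames(latent),
                                 paste0(prefix, colnames(latent)))
        if (isA) {
            rfu <- 2^(sweep(signal, 2, dp$base_A, "+"))
            ExpressionMatrix(rfu, platform = "A_aptamer", scale = "raw")
        } else {
            npx <- sweep(signal, 2, dp$base_B, "+")
            if (config@lod_quantile > 0) {
                lod <- apply(npx, 2, stats::quantile,
                             probs = config@lod_quantile, names = FALSE)
                npx[sweep(npx, 2, lod, "<")] <- NA_real_
            }
            ExpressionMatrix(npx, platform = "B_pea", scale = "log2")
        }
    })
}

#' Simulate linked continuous and time-to-event phenotypes
#'
#' The continuous outcome is a sparse linear combination of the latent
#' causal proteins plus covariate effects (age, sex, group) and Gaussian
#' noise. Event times follow an exponential proportional-hazards model
#' with linear predictor \code{latent \%*\% survival_coefs}; censoring is
#' an independent exponential calibrated so that, at a null linear
#' predictor, the expected censored fraction equals \code{censoring_rate}.
#' Covariates are generated independent of the proteins.
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param config optional \linkS4class{SimConfig} override.
#' @return A data.frame with columns \code{sample_id}, \code{outcome},
#'   \code{age}, \code{sex}, \code{group}, \code{time}, \code{event}.
#' @examples
#' truth <- simulateLatent(SimConfig(n_samples = 50, n_proteins = 8,
#'                                   block_sizes = c(4L, 4L), seed = 1))
#' head(simulatePhenotypes(truth))
#' @export
simulatePhenotypes <- function(truth, config = truth@config) {
    validObject(truth)
    latent <- truth@latent
    n <- nrow(latent)
    stopIfNot(config@phenotype_sparsity <= ncol(latent),
              "phenotype_sparsity exceeds the number of proteins")
    withSeed(deriveSeed(config@seed, "phenotypes"), {
        age <- stats::rnorm(n, 60, 10)
        sex <- stats::rbinom(n, 1L, 0.5)
        group <- sample(c("g1", "g2", "g3"), n, replace = TRUE)
        outcome <- drop(latent %*% truth@phenotype_coefs) +
            0.02 * (age - 60) + 0.5 * sex + stats::rnorm(n)

        lp <- drop(latent %*% truth@survival_coefs)
        lambda0 <- 0.1
        t_event <- stats::rexp(n, rate = lambda0 * exp(lp))
        cr <- config@censoring_rate
        if (cr > 0) {
            t_cens <- stats::rexp(n, rate = lambda0 * cr / (1 - cr))
            event <- as.integer(t_event <= t_cens)
            time <- pmin(t_event, t_cens)
        } else {
            event <- rep(1L, n)
            time <- t_event
        }
        data.frame(sample_id = rownames(latent), outcome = outcome,
                   age = age, sex = sex, group = group,
                   time = time, event = event, stringsAsFactors = FALSE)
    })
}

#' Assay-to-protein map for a simulated platform
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param platform platform tag.
#' @return An assay map data.frame (\code{assay_id}, \code{platform},
#'   \code{protein_id}, \code{duplicate_rank}).
#' @export
simAssayMap <- function(truth, platform = c("A_aptamer", "B_pea")) {
    platform <- match.arg(platform)
    prefix <- if (platform == "A_aptamer") "A_" else "B_"
    pid <- colnames(truth@latent)
    assayMap(assay_id = paste0(prefix, pid), platform = platform,
             protein_id = pid)
}

#' Write a simulated dataset to plain-text files
#'
#' Writes wide TSV matrices (first column \code{sample_id}, \code{NA} as
#' the missing token), the assay-to-protein mapping table, the phenotype
#' table and a JSON truth sidecar (class labels, distortion mechanisms and
#' phenotype/survival coefficients). Matrices round-trip losslessly
#' through \code{\link{readMatrix}}.
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param matrices named list of \linkS4class{ExpressionMatrix} objects
#'   (names become file stems, e.g. \code{platform_A.tsv}).
#' @param phenotypes phenotype data.frame from
#'   \code{\link{simulatePhenotypes}}.
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
writeFixture <- function(truth, matrices, phenotypes, dir) {
    if (!dir.exists(dir))
        dir.create(dir, recursive = TRUE)
    stopIfNot(dir.exists(dir), sprintf("cannot create directory '%s'", dir))
    paths <- character()
    for (nm in names(matrices)) {
        em <- matrices[[nm]]
        stopIfNot(identical(sampleIDs(em), rownames(truth@latent)),
                  "matrix sample ids do not match the truth object")
        f <- file.path(dir, paste0(nm, ".tsv"))
        writeMatrix(em, f)
        paths <- c(paths, f)
    }
    map <- rbind(simAssayMap(truth, "A_aptamer"),
                 simAssayMap(truth, "B_pea"))
    f <- file.path(dir, "assay_map.tsv")
    utils::write.table(map, f, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, f)
    if (!is.null(phenotypes)) {
        stopIfNot(identical(phenotypes$sample_id, rownames(truth@latent)),
                  "phenotype sample ids do not match the truth object")
        f <- file.path(dir, "phenotypes.tsv")
        utils::write.table(phenotypes, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        paths <- c(paths, f)
    }
    sidecar <- list(
        class_labels = as.list(truth@class_labels),
        mechanism = stats::setNames(as.list(truth@distortion_params$mechanism),
                                    truth@distortion_params$protein_id),
        phenotype_coefs = as.list(truth@phenotype_coefs),
        survival_coefs = as.list(truth@survival_coefs),
        seed = truth@config@seed)
    f <- file.path(dir, "truth.json")
    jsonlite::write_json(sidecar, f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, f)
    invisible(paths)
}
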