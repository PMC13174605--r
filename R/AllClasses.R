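#' @import methods
NULL

PLATFORMS <- c("A_aptamer", "B_pea")
SCALES <- c("raw", "log2", "standardized")
FIDELITY_CLASSES <- c("faithful", "recoverable", "ambivalent", "irreconcilable")

#' ExpressionMatrix: a sample x assay measurement grid
#'
#' The lingua franca of every pipeline stage: a numeric matrix with samples
#' in rows and assays in columns, tagged with the platform that produced it
#' (\code{"A_aptamer"} for RFU-scale aptamer panels, \code{"B_pea"} for
#' NPX-scale proximity-extension panels) and with the value scale the matrix
#' is currently on (\code{"raw"}, \code{"log2"} or \code{"standardized"}).
#' Missing values (e.g. below-LOD PEA measurements) are stored as \code{NA};
#' the missingness mask is recovered with \code{\link{missingMask}}.
#'
#' @slot values numeric matrix, rownames = sample ids, colnames = assay ids.
#' @slot platform character(1), one of \code{"A_aptamer"}, \code{"B_pea"}.
#' @slot scale character(1), one of \code{"raw"}, \code{"log2"},
#'   \code{"standardized"}.
#'
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix",
    representation(values = "matrix", platform = "character",
                   scale = "character"))

setValidity("ExpressionMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (!is.numeric(v))
        msg <- c(msg, "'values' must be a numeric matrix")
    if (is.null(rownames(v)) || is.null(colnames(v)))
        msg <- c(msg, "'values' must carry sample ids (rownames) and assay ids (colnames)")
    else {
        if (anyDuplicated(rownames(v)))
            msg <- c(msg, "duplicate sample ids")
        if (anyDuplicated(colnames(v)))
            msg <- c(msg, "duplicate assay ids")
    }
    if (length(object@platform) != 1L || !object@platform %in% PLATFORMS)
        msg <- c(msg, sprintf("'platform' must be one of: %s",
                              paste(PLATFORMS, collapse = ", ")))
    if (length(object@scale) != 1L || !object@scale %in% SCALES)
        msg <- c(msg, sprintf("'scale' must be one of: %s",
                              paste(SCALES, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, samples x assays, with rownames and colnames.
#' @param platform \code{"A_aptamer"} or \code{"B_pea"}.
#' @param scale value scale: \code{"raw"}, \code{"log2"} or
#'   \code{"standardized"}.
#' @return An \linkS4class{ExpressionMatrix}.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(paste0("s", 1:3), paste0("a", 1:2)))
#' ExpressionMatrix(m, platform = "B_pea", scale = "log2")
#' @export
ExpressionMatrix <- function(values, platform, scale) {
    new("ExpressionMatrix", values = values, platform = platform,
        scale = scale)
}

#' Simulation configuration for the paired-platform generator
#'
#' Defines the study conditions of a synthetic two-platform proteomic
#' experiment: cohort size, a block-exchangeable latent correlation
#' structure ("biological neighbor" blocks), the mixture of per-protein
#' fidelity classes, class-specific measurement noise, below-LOD censoring
#' on the PEA-like platform, an epitope-artifact effect, and sparse linear
#' links from the latent proteome to a continuous and a time-to-event
#' phenotype.
#'
#' @slot n_samples integer(1) samples.
#' @slot n_proteins integer(1) proteins.
#' @slot block_sizes integer vector summing to \code{n_proteins}.
#' @slot within_block_corr numeric(1) in [0, 1): exchangeable correlation
#'   inside each block, 0 across blocks.
#' @slot class_proportions named numeric(4) over the fidelity classes
#'   faithful / recoverable / ambivalent / irreconcilable, summing to 1.
#' @slot noise_sd_by_class named numeric(4), per-class measurement noise SD.
#' @slot lod_quantile numeric(1) in [0, 1): per-assay left-censoring
#'   quantile on the PEA-like platform.
#' @slot epitope_effect_size numeric(1): genotype shift applied with
#'   opposite sign on the two platforms for epitope-artifact proteins.
#' @slot epitope_carrier_freq numeric(1): carrier allele frequency.
#' @slot phenotype_sparsity integer(1): number of causal proteins.
#' @slot effect_sizes numeric: recycled over causal proteins (continuous
#'   outcome).
#' @slot survival_effect_sizes numeric: log hazard ratios per SD, recycled
#'   over causal proteins.
#' @slot censoring_rate numeric(1) in [0, 1).
#' @slot seed integer(1).
#'
#' @exportClass SimConfig
setClass("SimConfig",
    representation(n_samples = "integer", n_proteins = "integer",
                   block_sizes = "integer", within_block_corr = "numeric",
                   class_proportions = "numeric",
                   noise_sd_by_class = "numeric",
                   lod_quantile = "numeric",
                   epitope_effect_size = "numeric",
                   epitope_carrier_freq = "numeric",
                   phenotype_sparsity = "integer",
                   effect_sizes = "numeric",
                   survival_effect_sizes = "numeric",
                   censoring_rate = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@n_samples < 2L) msg <- c(msg, "n_samples must be >= 2")
    if (sum(object@block_sizes) != object@n_proteins)
        msg <- c(msg, "block_sizes must sum to n_proteins")
    if (object@within_block_corr < 0 || object@within_block_corr >= 1)
        msg <- c(msg, "within_block_corr must be in [0, 1)")
    cp <- object@class_proportions
    if (!identical(sort(names(cp)), sort(FIDELITY_CLASSES)))
        msg <- c(msg, "class_proportions must be named over the four fidelity classes")
    else if (abs(sum(cp) - 1) > 1e-9 || any(cp < 0))
        msg <- c(msg, "class_proportions must be non-negative and sum to 1")
    ns <- object@noise_sd_by_class
    if (!identical(sort(names(ns)), sort(FIDELITY_CLASSES)) || any(ns <= 0))
        msg <- c(msg, "noise_sd_by_class must be positive and named over the four classes")
    if (object@lod_quantile < 0 || object@lod_quantile >= 1)
        msg <- c(msg, "lod_quantile must be in [0, 1)")
    if (object@epitope_carrier_freq < 0 || object@epitope_carrier_freq > 1)
        msg <- c(msg, "epitope_carrier_freq must be in [0, 1]")
    if (object@phenotype_sparsity > object@n_proteins)
        msg <- c(msg, "phenotype_sparsity exceeds n_proteins")
    if (object@censoring_rate < 0 || object@censoring_rate >= 1)
        msg <- c(msg, "censoring_rate must be in [0, 1)")
    if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated paired-platform dataset
#'
#' @slot latent numeric matrix, samples x proteins: the true (z-scale)
#'   concentrations every downstream recovery test is scored against.
#' @slot class_labels named character: fidelity class per protein; for
#'   irreconcilable proteins the mechanism is recorded in
#'   \code{distortion_params}.
#' @slot distortion_params data.frame, one row per protein: per-platform
#'   affine scale/offset, nonlinearity id, off-target source id, and
#'   epitope flag.
#' @slot genotypes named numeric: carrier genotype (0/1/2) per sample, used
#'   by the epitope artifact.
#' @slot phenotype_coefs named numeric: per-protein effects on the
#'   continuous outcome.
#' @slot survival_coefs named numeric: per-protein log hazard ratios.
#' @slot config the generating \linkS4class{SimConfig}.
#'
#' @exportClass SimTruth
setClass("SimTruth",
    representation(latent = "matrix", class_labels = "character",
                   distortion_params = "data.frame", genotypes = "numeric",
                   phenotype_coefs = "numeric", survival_coefs = "numeric",
                   config = "SimConfig"))

setValidity("SimTruth", function(object) {
    msg <- character()
    p <- ncol(object@latent)
    if (length(object@class_labels) != p)
        msg <- c(msg, "one class label per protein required")
    if (!all(object@class_labels %in% FIDELITY_CLASSES))
        msg <- c(msg, "unknown fidelity class label")
    dp <- object@distortion_params
    if (nrow(dp) != p)
        msg <- c(msg, "distortion_params must have one row per protein")
    if ("offtarget_source" %in% names(dp)) {
        bad <- !is.na(dp$offtarget_source) &
            dp$offtarget_source == dp$protein_id
        if (any(bad))
            msg <- c(msg, "off-target source must differ from the protein itself")
    }
    if (length(msg)) msg else TRUE
})

#' Train/test partition of samples
#'
#' @slot train_ids character: training sample ids.
#' @slot test_ids character: held-out sample ids.
#' @slot train_fraction numeric(1).
#' @slot seed integer(1).
#' @exportClass SplitSpec
setClass("SplitSpec",
    representation(train_ids = "character", test_ids = "character",
                   train_fraction = "numeric", seed = "integer"))

setValidity("SplitSpec", function(object) {
    if (length(intersect(object@train_ids, object@test_ids)))
        return("train and test sample sets must be disjoint")
    TRUE
})

#' Regressor family and hyperparameters for per-target imputation models
#'
#' Defaults describe a histogram-binned gradient-boosted tree ensemble:
#' 255 histogram bins, learning rate 0.1, at most 300 boosting iterations
#' with early stopping monitored on a 10\% validation slice carved from the
#' training split. The per-target RNG seed is derived by a stable hash of
#' the target assay id XOR'd with the global seed, so adding or removing
#' targets does not perturb the models of the others.
#'
#' @slot family character(1), currently \code{"hist_gbt"}.
#' @slot max_bin integer(1) histogram bins.
#' @slot learning_rate numeric(1).
#' @slot max_iter integer(1) boosting-round cap.
#' @slot max_depth integer(1) per-tree depth cap.
#' @slot early_stopping logical(1).
#' @slot validation_fraction numeric(1): slice of the training split held
#'   out for early stopping.
#' @exportClass ModelSpec
setClass("ModelSpec",
    representation(family = "character", max_bin = "integer",
                   learning_rate = "numeric", max_iter = "integer",
                   max_depth = "integer", early_stopping = "logical",
                   validation_fraction = "numeric"))

setValidity("ModelSpec", function(object) {
    msg <- character()
    if (object@family != "hist_gbt")
        msg <- c(msg, "unknown regressor family")
    if (object@learning_rate <= 0) msg <- c(msg, "learning_rate must be > 0")
    if (object@max_iter < 1L) msg <- c(msg, "max_iter must be >= 1")
    if (object@validation_fraction <= 0 || object@validation_fraction >= 0.5)
        msg <- c(msg, "validation_fraction must be in (0, 0.5)")
    if (length(msg)) msg else TRUE
})

#' Construct a ModelSpec
#'
#' @param max_bin histogram bin count (default 255).
#' @param learning_rate shrinkage (default 0.1).
#' @param max_iter boosting-round cap (default 300).
#' @param max_depth tree depth cap (default 6).
#' @param early_stopping monitor a validation slice (default TRUE).
#' @param validation_fraction slice of the training split used for early
#'   stopping (default 0.1).
#' @return A \linkS4class{ModelSpec}.
#' @export
ModelSpec <- function(max_bin = 255L, learning_rate = 0.1, max_iter = 300L,
                      max_depth = 6L, early_stopping = TRUE,
                      validation_fraction = 0.1) {
    new("ModelSpec", family = "hist_gbt", max_bin = as.integer(max_bin),
        learning_rate = learning_rate, max_iter = as.integer(max_iter),
        max_depth = as.integer(max_depth), early_stopping = early_stopping,
        validation_fraction = validation_fraction)
}

#' A direction-tagged set of fitted per-target imputation models
#'
#' One fitted regressor per destination assay, all sharing the identical
#' source-panel feature list (the entire opposite platform); carries the
#' split, model spec and seed needed to reproduce training.
#'
#' @slot direction character(1), \code{"A2B"} or \code{"B2A"}.
#' @slot feature_ids character: source-panel assay ids (model input order).
#' @slot models named list of raw xgboost model payloads, one per target
#'   assay.
#' @slot split the \linkS4class{SplitSpec} used for training.
#' @slot spec the \linkS4class{ModelSpec}.
#' @slot seed integer(1) global seed.
#' @slot source_platform,target_platform character(1) platform tags.
#' @exportClass ImputationModelSet
setClass("ImputationModelSet",
    representation(direction = "character", feature_ids = "character",
                   models = "list", split = "SplitSpec", spec = "ModelSpec",
                   seed = "integer", source_platform = "character",
                   target_platform = "character"))

setValidity("ImputationModelSet", function(object) {
    msg <- character()
    if (!object@direction %in% c("A2B", "B2A"))
        msg <- c(msg, "direction must be 'A2B' or 'B2A'")
    if (is.null(names(object@models)) || anyDuplicated(names(object@models)))
        msg <- c(msg, "models must be uniquely named by target assay id")
    if (length(msg)) msg else TRUE
})

#' Thresholds of the four-tier measurement-fidelity classification
#'
#' Tier 1 ("robust"): baseline and post-imputation r both at or above
#' \code{t_high}. Tier 4 ("irreconcilable"): both at or below \code{t_low}.
#' Of the remainder, tier 2 ("model recoverable") has post-imputation r at
#' or above \code{t_mid}, tier 3 ("ambivalent") below. Comparisons use
#' signed correlations.
#'
#' @slot t_high numeric(1), default 0.7.
#' @slot t_mid numeric(1), default 0.4.
#' @slot t_low numeric(1), default 0.1.
#' @exportClass TierRules
setClass("TierRules",
    representation(t_high = "numeric", t_mid = "numeric", t_low = "numeric"))

setValidity("TierRules", function(object) {
    if (!(object@t_low < object@t_mid && object@t_mid < object@t_high))
        return("thresholds must satisfy t_low < t_mid < t_high")
    TRUE
})

#' Construct tier rules
#'
#' @param t_high tier-1 threshold on both correlations (default 0.7).
#' @param t_mid tier-2 threshold on post-imputation r (default 0.4).
#' @param t_low tier-4 threshold on both correlations (default 0.1).
#' @return A \linkS4class{TierRules}.
#' @examples
#' assignTier(0.8, 0.9, TierRules())  # 1
#' @export
TierRules <- function(t_high = 0.7, t_mid = 0.4, t_low = 0.1) {
    new("TierRules", t_high = t_high, t_mid = t_mid, t_low = t_low)
}
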