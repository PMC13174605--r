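#' Split samples into training and held-out sets
#'
#' Seeded uniform shuffle; the training set takes the first
#' \code{round(fraction * n)} samples.
#'
#' @param ids character sample ids (>= 4).
#' @param fraction training fraction in (0, 1), default 0.75.
#' @param seed RNG seed.
#' @return A \linkS4class{SplitSpec}.
#' @examples
#' sp <- splitSamples(sprintf("s%d", 1:8), seed = 1)
#' length(sp@train_ids)  # 6
#' @export
splitSamples <- function(ids, fraction = 0.75, seed = 1L) {
    stopIfNot(length(ids) >= 4L, "need at least 4 samples to split")
    stopIfNot(fraction > 0 && fraction < 1, "fraction must be in (0, 1)")
    stopIfNot(!anyDuplicated(ids), "duplicate sample ids")
    withSeed(seed, {
        shuffled <- sample(ids)
        n_train <- round(fraction * length(ids))
        new("SplitSpec", train_ids = shuffled[seq_len(n_train)],
            test_ids = shuffled[-seq_len(n_train)],
            train_fraction = fraction, seed = as.integer(seed))
    })
}

directionOf <- function(source_platform) {
    if (source_platform == "A_aptamer") "A2B" else "B2A"
}

# Fit one histogram-binned gradient-boosted regressor. Deterministic:
# single thread, fixed per-target seed; the early-stopping validation
# slice is carved from the training rows only (no test leakage).
fitOneTarget <- function(Xtr, ytr, spec, target_seed) {
    params <- xgboost::xgb.params(
        tree_method = "hist", max_bin = spec@max_bin,
        learning_rate = spec@learning_rate, max_depth = spec@max_depth,
        nthread = 1, seed = target_seed)
    if (spec@early_stopping && nrow(Xtr) >= 20L) {
        n <- nrow(Xtr)
        n_val <- max(1L, ceiling(spec@validation_fraction * n))
        val_idx <- withSeed(target_seed, sample.int(n, n_val))
        dtr <- xgboost::xgb.DMatrix(Xtr[-val_idx, , drop = FALSE],
                                    label = ytr[-val_idx], nthread = 1)
        dva <- xgboost::xgb.DMatrix(Xtr[val_idx, , drop = FALSE],
                                    label = ytr[val_idx], nthread = 1)
        fit <- xgboost::xgb.train(params = params, data = dtr,
                                  nrounds = spec@max_iter,
                                  evals = list(val = dva),
                                  early_stopping_rounds = 10L, verbose = 0)
    } else {
        dtr <- xgboost::xgb.DMatrix(Xtr, label = ytr, nthread = 1)
        fit <- xgboost::xgb.train(params = params, data = dtr,
                                  nrounds = spec@max_iter, verbose = 0)
    }
    xgboost::xgb.save.raw(fit)
}

predictRaw <- function(raw, X) {
    fit <- xgboost::xgb.load.raw(raw)
    unname(stats::predict(fit, X))
}

#' Train per-target cross-platform imputation models for one direction
#'
#' For every destination assay, fits one gradient-boosted regressor using
#' the entire source panel as features, on training samples only. Targets
#' are independent: each gets its own deterministic seed derived from the
#' global seed and the target assay id, so fits can run in any order (or
#' subset) with identical results.
#'
#' @param source standardized, fully imputed source-platform
#'   \linkS4class{ExpressionMatrix}.
#' @param target standardized, fully imputed destination-platform
#'   \linkS4class{ExpressionMatrix}, sample-aligned with \code{source}.
#' @param split a \linkS4class{SplitSpec} over the shared samples.
#' @param spec a \linkS4class{ModelSpec}.
#' @param seed global seed for per-target seed derivation.
#' @param targets optional subset of destination assay ids to fit
#'   (default: all).
#' @return An \linkS4class{ImputationModelSet}.
#' @export
trainDirection <- function(source, target, split, spec = ModelSpec(),
                           seed = 1L, targets = NULL) {
    stopIfNot(scaleOf(source) == "standardized" &&
              scaleOf(target) == "standardized",
              "both matrices must be standardized")
    stopIfNot(platformOf(source) != platformOf(target),
              "source and target must be different platforms")
    stopIfNot(identical(sampleIDs(source), sampleIDs(target)),
              "source and target are not sample-aligned")
    if (anyNA(values(source)) || anyNA(values(target)) ||
        any(!is.finite(values(source))) || any(!is.finite(values(target))))
        stop("non-finite values: impute and standardize before training",
             call. = FALSE)
    all_ids <- sampleIDs(source)
    stopIfNot(all(c(split@train_ids, split@test_ids) %in% all_ids),
              "split refers to unknown sample ids")
    if (is.null(targets)) targets <- assayIDs(target)
    stopIfNot(all(targets %in% assayIDs(target)), "unknown target assay id")

    Xtr <- values(source)[split@train_ids, , drop = FALSE]
    models <- vector("list", length(targets))
    names(models) <- targets
    for (t in targets) {
        ytr <- values(target)[split@train_ids, t]
        models[[t]] <- fitOneTarget(Xtr, ytr, spec,
                                    deriveSeed(seed, t))
    }
    new("ImputationModelSet", direction = directionOf(platformOf(source)),
        feature_ids = assayIDs(source), models = models, split = split,
        spec = spec, seed = as.integer(seed),
        source_platform = platformOf(source),
        target_platform = platformOf(target))
}

#' Impute destination-platform values from a source-platform matrix
#'
#' @param models an \linkS4class{ImputationModelSet}.
#' @param source standardized source-platform matrix whose assays are a
#'   superset of the model feature list (standardized with the
#'   training-era scaler).
#' @param samples optional sample ids to impute (default: all rows of
#'   \code{source}).
#' @return An \linkS4class{ExpressionMatrix} on the destination platform,
#'   with imputation provenance attached as attributes of the value
#'   matrix.
#' @export
imputeValues <- function(models, source, samples = NULL) {
    stopIfNot(is(models, "ImputationModelSet"), "not an ImputationModelSet")
    stopIfNot(scaleOf(source) == "standardized",
              "source must be standardized with the training-era scaler")
    absent <- setdiff(models@feature_ids, assayIDs(source))
    if (length(absent))
        stop("source is missing feature assay(s): ",
             paste(absent, collapse = ", "), call. = FALSE)
    if (is.null(samples)) samples <- sampleIDs(source)
    X <- values(source)[samples, models@feature_ids, drop = FALSE]
    out <- matrix(NA_real_, nrow(X), length(models@models),
                  dimnames = list(samples, names(models@models)))
    for (t in names(models@models))
        out[, t] <- predictRaw(models@models[[t]], X)
    attr(out, "imputed_by") <- sprintf("proteoBridge %s direction=%s seed=%d",
                                       as.character(utils::packageVersion("proteoBridge")),
                                       models@direction, models@seed)
    ExpressionMatrix(out, platform = models@target_platform,
                     scale = "standardized")
}

MODEL_BUNDLE_VERSION <- 1L

#' Save / load an imputation model bundle
#'
#' The bundle is a directory holding one serialized model file per target
#' assay plus a JSON manifest (direction, feature list, split, model spec,
#' seed, format version). \code{loadModels} refuses bundles written with a
#' different format version; round-tripping preserves predictions exactly.
#'
#' @param models an \linkS4class{ImputationModelSet}.
#' @param path bundle directory.
#' @return \code{saveModels}: invisibly, \code{path}; \code{loadModels}:
#'   the restored \linkS4class{ImputationModelSet}.
#' @name model-bundle
#' @export
saveModels <- function(models, path) {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    manifest <- list(
        format_version = MODEL_BUNDLE_VERSION,
        package_version = as.character(utils::packageVersion("proteoBridge")),
        direction = models@direction,
        source_platform = models@source_platform,
        target_platform = models@target_platform,
        feature_ids = models@feature_ids,
        targets = names(models@models),
        seed = models@seed,
        split = list(train_ids = models@split@train_ids,
                     test_ids = models@split@test_ids,
                     train_fraction = models@split@train_fraction,
                     seed = models@split@seed),
        spec = list(family = models@spec@family, max_bin = models@spec@max_bin,
                    learning_rate = models@spec@learning_rate,
                    max_iter = models@spec@max_iter,
                    max_depth = models@spec@max_depth,
                    early_stopping = models@spec@early_stopping,
                    validation_fraction = models@spec@validation_fraction))
    jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (t in names(models@models)) {
        con <- file.path(path, paste0("model_", hashString(t), "_",
                                      make.names(t), ".ubj"))
        writeBin(models@models[[t]], con)
    }
    invisible(path)
}

#' @rdname model-bundle
#' @export
loadModels <- function(path) {
    mf <- file.path(path, "manifest.json")
    stopIfNot(file.exists(mf), sprintf("no manifest at %s", path))
    manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
    if (is.null(manifest$format_version) ||
        manifest$format_version != MODEL_BUNDLE_VERSION)
        stop(sprintf("model bundle format %s does not match this code (%d)",
                     as.character(manifest$format_version %||% "unknown"),
                     MODEL_BUNDLE_VERSION), call. = FALSE)
    models <- lapply(manifest$targets, function(t) {
        f <- file.path(path, paste0("model_", hashString(t), "_",
                                    make.names(t), ".ubj"))
        stopIfNot(file.exists(f), sprintf("missing model file for %s", t))
        raw <- readBin(f, what = "raw", n = file.size(f))
        tryCatch({
            xgboost::xgb.load.raw(raw)  # validates payload
            raw
        }, error = function(e)
            stop(sprintf("corrupted model file for target %s", t),
                 call. = FALSE))
    })
    names(models) <- manifest$targets
    split <- new("SplitSpec", train_ids = manifest$split$train_ids,
                 test_ids = manifest$split$test_ids,
                 train_fraction = manifest$split$train_fraction,
                 seed = as.integer(manifest$split$seed))
    spec <- ModelSpec(max_bin = manifest$spec$max_bin,
                      learning_rate = manifest$spec$learning_rate,
                      max_iter = manifest$spec$max_iter,
                      max_depth = manifest$spec$max_depth,
                      early_stopping = manifest$spec$early_stopping,
                      validation_fraction = manifest$spec$validation_fraction)
    new("ImputationModelSet", direction = manifest$direction,
        feature_ids = manifest$feature_ids, models = models, split = split,
        spec = spec, seed = as.integer(manifest$seed),
        source_platform = manifest$source_platform,
        target_platform = manifest$target_platform)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
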