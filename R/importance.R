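# Squared Pearson correlation between prediction and truth; 0 when the
# correlation is undefined (e.g. constant prediction) so drops remain
# comparable. The squared-Pearson convention (not 1 - SSE/SST) is fixed
# package-wide; the two differ for biased predictions.
pearsonR2 <- function(pred, obs) {
    r <- safePearson(pred, obs)
    if (is.na(r)) 0 else r^2
}

resolvePredictor <- function(model, target = NULL) {
    if (is.function(model)) return(model)
    if (is(model, "ImputationModelSet")) {
        stopIfNot(!is.null(target) && target %in% names(model@models),
                  "specify a target assay present in the model set")
        raw <- model@models[[target]]
        feats <- model@feature_ids
        return(function(X) predictRaw(raw, X[, feats, drop = FALSE]))
    }
    stop("model must be a prediction function or an ImputationModelSet",
         call. = FALSE)
}

#' Permutation feature importance on held-out data
#'
#' For each feature, the feature's column of the held-out design matrix is
#' randomly shuffled (seeded), predictions are recomputed and the drop in
#' squared Pearson r relative to the unpermuted baseline is recorded; this
#' is repeated \code{n_repeats} times and summarized by mean and SD.
#' Results are sorted by descending mean drop (ties: descending SD, then
#' feature id).
#'
#' @param model a prediction function \code{f(X) -> numeric} or an
#'   \linkS4class{ImputationModelSet} (with \code{target}).
#' @param X_test held-out feature matrix (colnames = feature ids; >= 3
#'   rows).
#' @param y_test held-out response.
#' @param n_repeats permutation repeats per feature (default 5).
#' @param seed RNG seed.
#' @param target target assay id when \code{model} is a model set.
#' @param features optional subset of features to score (default: all
#'   columns of \code{X_test}).
#' @return data.frame (\code{feature}, \code{mean_drop}, \code{sd_drop},
#'   \code{n_repeats}) with the baseline r-squared as attribute
#'   \code{"baseline_r2"}.
#' @export
permutationImportance <- function(model, X_test, y_test, n_repeats = 5L,
                                  seed = 1L, target = NULL,
                                  features = colnames(X_test)) {
    stopIfNot(nrow(X_test) >= 3L,
              "permutation importance needs at least 3 test samples")
    stopIfNot(!is.null(colnames(X_test)), "X_test must have column names")
    predictor <- resolvePredictor(model, target)
    base_r2 <- pearsonR2(predictor(X_test), y_test)
    n <- nrow(X_test)
    res <- withSeed(seed, {
        lapply(features, function(f) {
            drops <- vapply(seq_len(n_repeats), function(rep) {
                Xp <- X_test
                Xp[, f] <- Xp[sample.int(n), f]
                base_r2 - pearsonR2(predictor(Xp), y_test)
            }, numeric(1))
            c(mean = mean(drops), sd = stats::sd(drops))
        })
    })
    out <- data.frame(feature = features,
                      mean_drop = vapply(res, `[[`, numeric(1), "mean"),
                      sd_drop = vapply(res, `[[`, numeric(1), "sd"),
                      n_repeats = as.integer(n_repeats),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$mean_drop, -out$sd_drop, out$feature), ,
               drop = FALSE]
    rownames(out) <- NULL
    attr(out, "baseline_r2") <- base_r2
    out
}

#' First-K feature retraining curve
#'
#' Retrains the target's model on the top-K ranked features only (training
#' samples, original hyperparameters and per-target seed) and evaluates,
#' on the held-out samples, the model performance r (imputed vs measured
#' destination) and — when a source-platform counterpart assay is given —
#' the cross-platform r (imputed vs measured source counterpart).
#'
#' @param source standardized source-platform
#'   \linkS4class{ExpressionMatrix}.
#' @param target standardized destination-platform matrix.
#' @param target_assay destination assay to model.
#' @param ranked_features feature ids in importance order (e.g. from
#'   \code{\link{permutationImportance}}).
#' @param split a \linkS4class{SplitSpec}.
#' @param spec a \linkS4class{ModelSpec}.
#' @param K_list K values (default \code{c(1:5, seq(50, 300, 50))});
#'   values above the feature count are clamped with a warning.
#' @param counterpart_assay optional source-platform assay measuring the
#'   same protein (enables \code{cross_r}).
#' @param seed global seed (per-target seed derivation as in training).
#' @return data.frame (\code{K}, \code{model_r}, \code{cross_r}).
#' @export
firstKCurve <- function(source, target, target_assay, ranked_features,
                        split, spec = ModelSpec(),
                        K_list = c(1:5, seq(50, 300, by = 50)),
                        counterpart_assay = NULL, seed = 1L) {
    stopIfNot(all(ranked_features %in% assayIDs(source)),
              "ranked_features must be source assays")
    K_list <- sort(unique(as.integer(K_list)))
    if (any(K_list > length(ranked_features))) {
        warning("K value(s) exceeding the feature count clamped")
        K_list <- unique(pmin(K_list, length(ranked_features)))
    }
    y <- values(target)[, target_assay]
    ytr <- y[split@train_ids]
    yte <- y[split@test_ids]
    target_seed <- deriveSeed(seed, target_assay)
    rows <- lapply(K_list, function(K) {
        feats <- ranked_features[seq_len(K)]
        Xtr <- values(source)[split@train_ids, feats, drop = FALSE]
        Xte <- values(source)[split@test_ids, feats, drop = FALSE]
        raw <- fitOneTarget(Xtr, ytr, spec, target_seed)
        pred <- predictRaw(raw, Xte)
        cross <- if (is.null(counterpart_assay)) NA_real_ else
            safePearson(pred,
                        values(source)[split@test_ids, counterpart_assay])
        data.frame(K = K, model_r = safePearson(pred, yte), cross_r = cross)
    })
    do.call(rbind, rows)
}
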