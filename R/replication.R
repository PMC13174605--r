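covariateDesign <- function(covariates) {
    stopIfNot(is.data.frame(covariates), "covariates must be a data.frame")
    mm <- stats::model.matrix(~ ., data = covariates)[, -1L, drop = FALSE]
    mm
}

#' Penalized continuous-outcome model with unpenalized covariates
#'
#' Elastic-net regression of a continuous outcome on a protein matrix with
#' covariates carried unpenalized (penalty factor 0). The mixing parameter
#' alpha and penalty strength lambda are tuned by \code{cv_folds}-fold
#' cross-validation on the full analytic set; the final model is refit on
#' an \code{eval_split} training fraction and scored on the remaining
#' hold-out by squared Pearson r between predicted and observed outcome,
#' where per-protein permutation importance is also computed. A
#' \code{leakage_mode = "strict"} variant tunes on the training split
#' only.
#'
#' @param proteins \linkS4class{ExpressionMatrix} or numeric matrix
#'   (samples x proteins).
#' @param covariates data.frame of covariates, row-aligned with
#'   \code{proteins} (no missing values; impute first).
#' @param outcome numeric outcome; samples with missing outcome are
#'   removed.
#' @param cv_folds CV folds for tuning (default 10).
#' @param eval_split training fraction of the final fit (default 0.8).
#' @param seed RNG seed (folds, split, permutations).
#' @param alpha_grid elastic-net mixing grid (default 0.1 to 1 by 0.1).
#' @param n_repeats permutation-importance repeats (default 5).
#' @param leakage_mode \code{"as_published"} (tune on the full analytic
#'   set) or \code{"strict"} (tune on the training split only).
#' @return list: \code{fit} (glmnet), \code{alpha}, \code{lambda},
#'   \code{r2} (hold-out squared Pearson), \code{importance} (per-protein
#'   permutation importance), \code{coefficients}, \code{n} (analytic
#'   sample count).
#' @export
fitPenalizedLinear <- function(proteins, covariates, outcome,
                               cv_folds = 10L, eval_split = 0.8, seed = 1L,
                               alpha_grid = seq(0.1, 1, by = 0.1),
                               n_repeats = 5L,
                               leakage_mode = c("as_published", "strict")) {
    leakage_mode <- match.arg(leakage_mode)
    P <- if (is(proteins, "ExpressionMatrix")) values(proteins) else proteins
    stopIfNot(!is.null(colnames(P)), "protein matrix must have column names")
    stopIfNot(nrow(P) == length(outcome) && nrow(P) == nrow(covariates),
              "proteins, covariates and outcome are not row-aligned")
    if (anyNA(covariates))
        stop("missing covariates: impute them first (e.g. knnImputeCovariates)",
             call. = FALSE)
    keep <- !is.na(outcome)
    P <- P[keep, , drop = FALSE]
    covariates <- covariates[keep, , drop = FALSE]
    y <- outcome[keep]
    zerovar <- apply(P, 2, stats::sd) == 0
    if (any(zerovar)) {
        warning("dropping zero-variance protein(s): ",
                paste(colnames(P)[zerovar], collapse = ", "))
        P <- P[, !zerovar, drop = FALSE]
    }
    C <- covariateDesign(covariates)
    X <- cbind(P, C)
    pf <- c(rep(1, ncol(P)), rep(0, ncol(C)))
    n <- nrow(X)

    withSeed(seed, {
        train_idx <- sample.int(n, round(eval_split * n))
        tune_rows <- if (leakage_mode == "as_published") seq_len(n) else
            train_idx
        foldid <- sample(rep_len(seq_len(cv_folds), length(tune_rows)))
        tuning <- lapply(alpha_grid, function(a) {
            cv <- glmnet::cv.glmnet(X[tune_rows, , drop = FALSE],
                                    y[tune_rows], alpha = a,
                                    penalty.factor = pf, foldid = foldid)
            list(alpha = a, lambda = cv$lambda.min,
                 cvm = min(cv$cvm))
        })
        best <- tuning[[which.min(vapply(tuning, `[[`, numeric(1), "cvm"))]]
        fit <- glmnet::glmnet(X[train_idx, , drop = FALSE], y[train_idx],
                              alpha = best$alpha, lambda = best$lambda,
                              penalty.factor = pf)
        hold <- setdiff(seq_len(n), train_idx)
        predictor <- function(Z) drop(stats::predict(fit, newx = Z))
        pred <- predictor(X[hold, , drop = FALSE])
        r2 <- pearsonR2(pred, y[hold])
        imp <- permutationImportance(predictor, X[hold, , drop = FALSE],
                                     y[hold], n_repeats = n_repeats,
                                     seed = seed, features = colnames(P))
        list(fit = fit, alpha = best$alpha, lambda = best$lambda, r2 = r2,
             importance = imp,
             coefficients = stats::setNames(
                 as.numeric(stats::coef(fit)),
                 rownames(stats::coef(fit))),
             n = n)
    })
}

#' KNN imputation of missing covariates
#'
#' Sample-neighbor KNN on standardized numeric covariates: each missing
#' entry is filled with the mean of that covariate over the k nearest
#' samples (Euclidean distance across the covariates observed for both
#' samples, scaled by their count).
#'
#' @param covariates data.frame of numeric covariates.
#' @param k neighbors (default 10).
#' @return The completed data.frame.
#' @export
knnImputeCovariates <- function(covariates, k = 10L) {
    num <- vapply(covariates, is.numeric, logical(1))
    stopIfNot(all(num | !vapply(covariates, anyNA, logical(1))),
              "non-numeric covariates with missing values are not supported")
    if (!anyNA(covariates)) return(covariates)
    M <- as.matrix(covariates[, num, drop = FALSE])
    Z <- scale(M)
    Z[is.nan(Z)] <- 0
    n <- nrow(M)
    for (i in which(rowSums(is.na(M)) > 0)) {
        diffs <- sweep(Z, 2, Z[i, ], "-")
        shared <- !is.na(diffs)
        d <- sqrt(rowSums(diffs^2, na.rm = TRUE) / pmax(rowSums(shared), 1))
        d[i] <- Inf
        d[rowSums(shared) == 0] <- Inf
        for (j in which(is.na(M[i, ]))) {
            donors <- order(d)[!is.na(M[order(d), j])]
            donors <- donors[is.finite(d[donors])]
            if (!length(donors)) {
                M[i, j] <- mean(M[, j], na.rm = TRUE)
            } else {
                M[i, j] <- mean(M[donors[seq_len(min(k, length(donors)))], j])
            }
        }
    }
    covariates[, num] <- as.data.frame(M)
    covariates
}

#' Proteome-wide proportional-hazards association scan
#'
#' One Cox proportional-hazards fit per protein: the protein (log2-scale
#' input, standardized to mean 0, SD 1 inside its model) plus all
#' covariates, Breslow tie handling. Reports the hazard ratio per 1 SD,
#' Wald 95\% CI and p value, and Bonferroni-adjusted p over the converged
#' fits (the denominator is recorded as an attribute). Missing covariates
#' are KNN-imputed (k = \code{covariate_knn_k}) before fitting.
#'
#' @param proteins \linkS4class{ExpressionMatrix} or matrix (samples x
#'   proteins), values on the log2 scale.
#' @param covariates data.frame, row-aligned.
#' @param time follow-up durations (> 0).
#' @param event binary event indicators (at least one event required).
#' @param covariate_knn_k neighbors for covariate imputation (default 10).
#' @param adjust multiple-testing method (default \code{"bonferroni"}).
#' @return data.frame (\code{protein_id}, \code{hr}, \code{ci_lo},
#'   \code{ci_hi}, \code{p}, \code{p_adj}, \code{converged}) with
#'   attribute \code{"n_tests"}.
#' @export
phScan <- function(proteins, covariates, time, event,
                   covariate_knn_k = 10L, adjust = "bonferroni") {
    P <- if (is(proteins, "ExpressionMatrix")) values(proteins) else proteins
    stopIfNot(!is.null(colnames(P)), "protein matrix must have column names")
    stopIfNot(all(time > 0), "follow-up times must be positive")
    if (sum(event) == 0)
        stop("no events observed; cannot fit proportional-hazards models",
             call. = FALSE)
    if (anyNA(covariates))
        covariates <- knnImputeCovariates(covariates, k = covariate_knn_k)
    C <- covariateDesign(covariates)
    surv <- survival::Surv(time, event)
    rows <- lapply(colnames(P), function(pid) {
        z <- P[, pid]
        s <- stats::sd(z)
        if (is.na(s) || s == 0)
            return(data.frame(protein_id = pid, hr = NA_real_,
                              ci_lo = NA_real_, ci_hi = NA_real_,
                              p = NA_real_, converged = FALSE))
        z <- (z - mean(z)) / s
        df <- data.frame(z = z, C)
        fit <- tryCatch(
            survival::coxph(surv ~ ., data = df, ties = "breslow"),
            error = function(e) NULL, warning = function(w) NULL)
        if (is.null(fit) || is.na(stats::coef(fit)["z"]))
            return(data.frame(protein_id = pid, hr = NA_real_,
                              ci_lo = NA_real_, ci_hi = NA_real_,
                              p = NA_real_, converged = FALSE))
        beta <- stats::coef(fit)["z"]
        se <- sqrt(diag(stats::vcov(fit))["z"])
        data.frame(protein_id = pid, hr = exp(beta),
                   ci_lo = exp(beta - stats::qnorm(0.975) * se),
                   ci_hi = exp(beta + stats::qnorm(0.975) * se),
                   p = 2 * stats::pnorm(-abs(beta / se)),
                   converged = TRUE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    n_tests <- sum(out$converged)
    if (n_tests < nrow(out))
        warning(nrow(out) - n_tests,
                " non-converging fit(s) excluded from the adjustment denominator")
    out$p_adj <- NA_real_
    out$p_adj[out$converged] <- stats::p.adjust(
        out$p[out$converged], method = adjust)
    attr(out, "n_tests") <- n_tests
    out
}

#' Agreement between two importance rankings
#'
#' Spearman rank correlation of the mean importance over the shared
#' feature set, plus the overlap fraction of the two top-k sets.
#'
#' @param resultsA,resultsB importance tables from
#'   \code{\link{permutationImportance}} (columns \code{feature},
#'   \code{mean_drop}).
#' @param top_k size of the compared top sets (default 10, clamped to the
#'   shared-set size).
#' @return list (\code{rank_correlation}, \code{topk_overlap},
#'   \code{n_shared}).
#' @examples
#' a <- data.frame(feature = c("x", "y", "z"), mean_drop = c(3, 2, 1))
#' compareImportance(a, a, top_k = 2)$rank_correlation  # 1
#' @export
compareImportance <- function(resultsA, resultsB, top_k = 10L) {
    shared <- intersect(resultsA$feature, resultsB$feature)
    if (!length(shared))
        stop("no shared features between the two importance tables",
             call. = FALSE)
    a <- resultsA$mean_drop[match(shared, resultsA$feature)]
    b <- resultsB$mean_drop[match(shared, resultsB$feature)]
    top_k <- min(top_k, length(shared))
    topA <- shared[order(-a, shared)][seq_len(top_k)]
    topB <- shared[order(-b, shared)][seq_len(top_k)]
    list(rank_correlation = suppressWarnings(
             stats::cor(a, b, method = "spearman")),
         topk_overlap = length(intersect(topA, topB)) / top_k,
         n_shared = length(shared))
}
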