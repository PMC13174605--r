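correlationByPairs <- function(vx, vy, pairs_x, pairs_y, samples) {
    vapply(seq_along(pairs_x), function(i) {
        safePearson(vx[samples, pairs_x[i]], vy[samples, pairs_y[i]])
    }, numeric(1))
}

#' Baseline cross-platform correlation
#'
#' Pearson r between the two platforms' measured values for each
#' overlapping (aptamer assay, PEA assay) pair, computed on the training
#' samples. A protein with multiple aptamers yields one r per pair.
#' Zero-variance columns give an undefined (NA) r with a warning.
#'
#' @param matA,matB standardized, sample-aligned
#'   \linkS4class{ExpressionMatrix} objects for the two platforms.
#' @param overlap overlap table from \code{\link{buildOverlap}}.
#' @param samples sample ids to use (conventionally the training split).
#' @return \code{overlap} with a \code{baseline_r} column.
#' @export
baselineCorrelation <- function(matA, matB, overlap,
                                samples = sampleIDs(matA)) {
    r <- correlationByPairs(values(matA), values(matB),
                            overlap$assay_id_A, overlap$assay_id_B, samples)
    if (anyNA(r))
        warning(sum(is.na(r)), " pair(s) with undefined baseline correlation")
    out <- overlap
    out$baseline_r <- r
    out
}

#' Post-imputation cross-platform correlation
#'
#' Pearson r between the model-imputed destination-platform values and the
#' measured source-platform counterpart, on held-out samples only.
#'
#' @param imputed imputed destination-platform
#'   \linkS4class{ExpressionMatrix}.
#' @param counterpart measured source-platform matrix.
#' @param overlap overlap table; the destination assay column is matched
#'   against \code{imputed}, the other against \code{counterpart}.
#' @param samples held-out sample ids.
#' @return \code{overlap} with a \code{post_r} column.
#' @export
postImputationCorrelation <- function(imputed, counterpart, overlap,
                                      samples = sampleIDs(imputed)) {
    if (platformOf(imputed) == "B_pea") {
        dest <- overlap$assay_id_B; src <- overlap$assay_id_A
    } else {
        dest <- overlap$assay_id_A; src <- overlap$assay_id_B
    }
    r <- correlationByPairs(values(imputed), values(counterpart),
                            dest, src, samples)
    if (anyNA(r))
        warning(sum(is.na(r)), " pair(s) with undefined post-imputation correlation")
    out <- overlap
    out$post_r <- r
    out
}

#' Model performance on the destination platform
#'
#' Pearson r between imputed and measured values of the same destination
#' platform on held-out samples; defined for every destination assay, not
#' only the overlap.
#'
#' @param imputed imputed destination-platform matrix.
#' @param measured measured destination-platform matrix.
#' @param samples held-out sample ids.
#' @return data.frame (\code{assay_id}, \code{model_r}).
#' @export
modelPerformance <- function(imputed, measured,
                             samples = sampleIDs(imputed)) {
    stopIfNot(platformOf(imputed) == platformOf(measured),
              "model performance compares matrices of the same platform")
    assays <- intersect(assayIDs(imputed), assayIDs(measured))
    r <- correlationByPairs(values(imputed), values(measured),
                            assays, assays, samples)
    if (anyNA(r))
        warning(sum(is.na(r)), " assay(s) with undefined model performance")
    data.frame(assay_id = assays, model_r = r, stringsAsFactors = FALSE)
}

#' Correlation gain
#'
#' The difference between post-imputation and baseline Pearson r, together
#' with the magnitude gain \code{|post| - |baseline|} (relevant for
#' sign-distorted proteins). Undefined inputs propagate.
#'
#' @param baseline_r,post_r numeric vectors.
#' @return data.frame (\code{gain}, \code{magnitude_gain}).
#' @examples
#' correlationGain(0.21, 0.61)$gain  # 0.40
#' @export
correlationGain <- function(baseline_r, post_r) {
    data.frame(gain = post_r - baseline_r,
               magnitude_gain = abs(post_r) - abs(baseline_r))
}

#' Assign fidelity tiers
#'
#' Signed correlations are compared directly (no absolute value): tier 1
#' if both baseline and post-imputation r are at or above \code{t_high};
#' otherwise tier 4 if both are at or below \code{t_low}; otherwise tier 2
#' if post-imputation r is at or above \code{t_mid}; otherwise tier 3.
#' The four rules partition \eqn{[-1,1]^2} exhaustively and mutually
#' exclusively. Undefined correlations yield \code{NA} (no tier).
#'
#' @param baseline_r,post_r numeric vectors (recycled to equal length).
#' @param rules a \linkS4class{TierRules}.
#' @return Integer tier vector in \{1, 2, 3, 4\} with \code{NA} for
#'   undefined inputs.
#' @examples
#' assignTier(0.21, 0.61)    # 2
#' assignTier(-0.4, -0.50)   # 4
#' @export
assignTier <- function(baseline_r, post_r, rules = TierRules()) {
    n <- max(length(baseline_r), length(post_r))
    b <- rep_len(baseline_r, n); p <- rep_len(post_r, n)
    tier <- rep(NA_integer_, n)
    ok <- !is.na(b) & !is.na(p)
    tier[ok & b >= rules@t_high & p >= rules@t_high] <- 1L
    t4 <- ok & is.na(tier) & b <= rules@t_low & p <= rules@t_low
    tier[t4] <- 4L
    t2 <- ok & is.na(tier) & p >= rules@t_mid
    tier[t2] <- 2L
    tier[ok & is.na(tier)] <- 3L
    tier
}

#' Assemble per-protein fidelity records for one direction
#'
#' Joins baseline, post-imputation and model-performance correlations into
#' the per-(protein, aptamer-pair) fidelity table and assigns tiers.
#'
#' @param baseline output of \code{\link{baselineCorrelation}}.
#' @param post output of \code{\link{postImputationCorrelation}} on the
#'   same overlap table.
#' @param model_perf output of \code{\link{modelPerformance}} (optional).
#' @param direction \code{"A2B"} or \code{"B2A"}.
#' @param rules a \linkS4class{TierRules}.
#' @return data.frame with columns \code{protein_id}, \code{assay_id_A},
#'   \code{assay_id_B}, \code{direction}, \code{baseline_r}, \code{post_r},
#'   \code{model_r}, \code{gain}, \code{magnitude_gain}, \code{tier}.
#' @export
fidelityRecords <- function(baseline, post, model_perf = NULL,
                            direction = c("A2B", "B2A"),
                            rules = TierRules()) {
    direction <- match.arg(direction)
    key <- c("protein_id", "assay_id_A", "assay_id_B")
    stopIfNot(identical(baseline[key], post[key]),
              "baseline and post tables cover different overlap rows")
    rec <- baseline[key]
    rec$direction <- direction
    rec$baseline_r <- baseline$baseline_r
    rec$post_r <- post$post_r
    if (!is.null(model_perf)) {
        dest <- if (direction == "A2B") rec$assay_id_B else rec$assay_id_A
        rec$model_r <- model_perf$model_r[match(dest, model_perf$assay_id)]
    } else {
        rec$model_r <- NA_real_
    }
    g <- correlationGain(rec$baseline_r, rec$post_r)
    rec$gain <- g$gain
    rec$magnitude_gain <- g$magnitude_gain
    rec$tier <- assignTier(rec$baseline_r, rec$post_r, rules)
    rec
}

#' Protein-level rollup over multiple aptamers
#'
#' When a protein carries several aptamer pairs, keeps the record with the
#' highest post-imputation r ("best aptamer") for protein-level reporting.
#'
#' @param records fidelity table from \code{\link{fidelityRecords}}.
#' @return One row per protein.
#' @export
rollupBestAptamer <- function(records) {
    picked <- do.call(rbind, lapply(split(records, records$protein_id),
        function(d) d[order(-d$post_r, d$assay_id_A)[1L], , drop = FALSE]))
    rownames(picked) <- NULL
    picked[order(picked$protein_id), , drop = FALSE]
}

#' Bidirectional tier consensus
#'
#' Compares the two training directions' tier assignments protein by
#' protein and summarizes per-tier agreement.
#'
#' @param records1,records2 protein-level fidelity tables (one row per
#'   protein) for the two directions.
#' @return list with \code{per_protein} (tier pair + agreement flag) and
#'   \code{per_tier} (count and percent agreeing, by direction-1 tier).
#' @export
consensusTiers <- function(records1, records2) {
    p1 <- sort(records1$protein_id); p2 <- sort(records2$protein_id)
    if (!identical(p1, p2))
        stop("the two directions cover different protein sets", call. = FALSE)
    r1 <- records1[order(records1$protein_id), ]
    r2 <- records2[order(records2$protein_id), ]
    per_protein <- data.frame(protein_id = r1$protein_id,
                              tier_dir1 = r1$tier, tier_dir2 = r2$tier,
                              agree = r1$tier == r2$tier,
                              stringsAsFactors = FALSE)
    per_tier <- do.call(rbind, lapply(1:4, function(t) {
        idx <- which(per_protein$tier_dir1 == t)
        data.frame(tier = t, n = length(idx),
                   n_agree = sum(per_protein$agree[idx], na.rm = TRUE),
                   pct_agree = if (length(idx))
                       100 * mean(per_protein$agree[idx], na.rm = TRUE)
                   else NA_real_)
    }))
    list(per_protein = per_protein, per_tier = per_tier,
         overall_pct_agree = 100 * mean(per_protein$agree, na.rm = TRUE))
}

#' Tier report: table plus distribution summary
#'
#' @param records fidelity table (any number of directions stacked).
#' @param tsv_path optional path for the per-record TSV.
#' @param json_path optional path for the JSON distribution summary.
#' @return list with \code{table} and \code{distribution} (per-direction
#'   tier counts and fractions, plus the boundary conventions used).
#' @export
tierReport <- function(records, tsv_path = NULL, json_path = NULL) {
    dist <- lapply(split(records, records$direction), function(d) {
        ok <- !is.na(d$tier)
        counts <- as.list(table(factor(d$tier[ok], levels = 1:4)))
        list(n = nrow(d), n_tiered = sum(ok),
             counts = stats::setNames(counts, paste0("tier", 1:4)),
             fractions = stats::setNames(
                 as.list(as.numeric(table(factor(d$tier[ok],
                                                 levels = 1:4))) / sum(ok)),
                 paste0("tier", 1:4)))
    })
    meta <- list(boundary_convention = list(
        tier1 = "baseline_r >= t_high AND post_r >= t_high",
        tier4 = "baseline_r <= t_low AND post_r <= t_low",
        tier2 = "otherwise post_r >= t_mid", tier3 = "otherwise",
        signed = TRUE))
    out <- list(table = records,
                distribution = c(dist, list(metadata = meta)))
    if (!is.null(tsv_path))
        utils::write.table(records, tsv_path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    if (!is.null(json_path))
        jsonlite::write_json(out$distribution, json_path,
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out
}
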