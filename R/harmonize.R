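#' Subset an ExpressionMatrix
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @param i sample ids or indices.
#' @param j assay ids or indices.
#' @param ... ignored.
#' @param drop ignored (never drops).
#' @return An \linkS4class{ExpressionMatrix}.
#' @export
setMethod("[", "ExpressionMatrix", function(x, i, j, ..., drop = FALSE) {
    v <- x@values
    if (!missing(i)) v <- v[i, , drop = FALSE]
    if (!missing(j)) v <- v[, j, drop = FALSE]
    ExpressionMatrix(v, platform = x@platform, scale = x@scale)
})

#' Read a wide sample x assay matrix from TSV/CSV
#'
#' Expects a header row, a first column of sample ids, and one column per
#' assay; column order is preserved and missing entries use the declared
#' NA token.
#'
#' @param path file path.
#' @param platform platform tag to attach.
#' @param scale value-scale flag of the stored values (default
#'   \code{"raw"}).
#' @param sep field separator (default tab).
#' @param na_token string encoding missing values (default \code{"NA"}).
#' @return An \linkS4class{ExpressionMatrix}.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("sample_id\ta1\ta2", "s1\t1\t2", "s2\t3\tNA"), f)
#' readMatrix(f, platform = "B_pea", scale = "log2")
#' @export
readMatrix <- function(path, platform, scale = "raw", sep = "\t",
                       na_token = "NA") {
    stopIfNot(file.exists(path), sprintf("file not found: %s", path))
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            na.strings = na_token, check.names = FALSE,
                            stringsAsFactors = FALSE, fill = FALSE)
    stopIfNot(ncol(df) >= 2L, "matrix file needs a sample_id column plus assays")
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids))
        stop("duplicate sample ids in ", path, call. = FALSE)
    assays <- colnames(df)[-1L]
    if (anyDuplicated(assays))
        stop("duplicated assay column(s): ",
             paste(unique(assays[duplicated(assays)]), collapse = ", "),
             call. = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m))
        stop("non-numeric values in ", path, call. = FALSE)
    rownames(m) <- ids
    ExpressionMatrix(m, platform = platform, scale = scale)
}

#' Write an ExpressionMatrix as wide TSV
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @param path output file.
#' @param sep field separator.
#' @param na_token missing-value token.
#' @return Invisibly, \code{path}.
#' @export
writeMatrix <- function(x, path, sep = "\t", na_token = "NA") {
    df <- data.frame(sample_id = sampleIDs(x), x@values,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE,
                       row.names = FALSE, na = na_token)
    invisible(path)
}

#' Build and validate an assay-to-protein map
#'
#' One row per assay; multi-aptamer proteins get \code{duplicate_rank}
#' 1, 2, ... in assay-id order within each (platform, protein).
#'
#' @param assay_id character assay ids.
#' @param platform platform tag(s), recycled.
#' @param protein_id canonical protein ids.
#' @return A data.frame with columns \code{assay_id}, \code{platform},
#'   \code{protein_id}, \code{duplicate_rank}.
#' @export
assayMap <- function(assay_id, platform, protein_id) {
    df <- data.frame(assay_id = as.character(assay_id),
                     platform = rep(platform, length.out = length(assay_id)),
                     protein_id = as.character(protein_id),
                     stringsAsFactors = FALSE)
    stopIfNot(all(df$platform %in% PLATFORMS), "unknown platform tag")
    if (anyDuplicated(df[, c("assay_id", "platform")]))
        stop("duplicate (assay_id, platform) rows in assay map", call. = FALSE)
    df <- df[order(df$platform, df$protein_id, df$assay_id), , drop = FALSE]
    df$duplicate_rank <- stats::ave(seq_len(nrow(df)),
                                    df$platform, df$protein_id,
                                    FUN = seq_along)
    rownames(df) <- NULL
    df
}

#' Apply per-assay panel-version lift
#'
#' A panel lift maps raw measurements between panel versions by a
#' per-assay linear transform \code{value' = scale * value + offset}.
#' Assays absent from the lift table pass through unchanged with a
#' warning.
#'
#' @param x an \linkS4class{ExpressionMatrix} on the raw scale.
#' @param lift data.frame with columns \code{assay_id}, \code{scale}
#'   (positive), \code{offset}.
#' @return The lifted \linkS4class{ExpressionMatrix} (mask unchanged).
#' @export
liftPanel <- function(x, lift) {
    stopIfNot(scaleOf(x) == "raw", "liftPanel expects a raw-scale matrix")
    stopIfNot(all(c("assay_id", "scale", "offset") %in% names(lift)),
              "lift table needs assay_id, scale, offset columns")
    if (any(lift$scale <= 0))
        stop("non-positive lift scale for assay(s): ",
             paste(lift$assay_id[lift$scale <= 0], collapse = ", "),
             call. = FALSE)
    v <- x@values
    idx <- match(colnames(v), lift$assay_id)
    if (anyNA(idx)) {
        warning("assay(s) absent from lift table left unchanged: ",
                paste(colnames(v)[is.na(idx)], collapse = ", "))
    }
    sc <- ifelse(is.na(idx), 1, lift$scale[idx])
    off <- ifelse(is.na(idx), 0, lift$offset[idx])
    v <- sweep(sweep(v, 2, sc, "*"), 2, off, "+")
    ExpressionMatrix(v, platform = x@platform, scale = x@scale)
}

#' Per-assay centering/scaling parameters
#'
#' @slot center named numeric per-assay means.
#' @slot scale named numeric per-assay SDs (n-1 convention).
#' @slot fit_ids sample ids the parameters were estimated on.
#' @slot log_applied whether a log2 step preceded estimation.
#' @exportClass Scaler
setClass("Scaler",
    representation(center = "numeric", scale = "numeric",
                   fit_ids = "character", log_applied = "logical"))

setValidity("Scaler", function(object) {
    if (any(object@scale <= 0)) return("Scaler SDs must be > 0")
    TRUE
})

setMethod("show", "Scaler", function(object) {
    cat(sprintf("Scaler: %d assays, fit on %d samples (log2 step: %s)\n",
                length(object@center), length(object@fit_ids),
                if (object@log_applied) "yes" else "no"))
})

#' Log2-transform and standardize a matrix
#'
#' Raw-scale matrices are log2-transformed first; log2-scale matrices
#' (e.g. NPX) skip straight to standardization. Each assay is then
#' z-scored using the mean and sample (n-1) SD estimated on
#' \code{fit_subset} only, so the same \linkS4class{Scaler} can be applied
#' to held-out samples without leakage (see \code{\link{applyScaler}}).
#'
#' @param x an \linkS4class{ExpressionMatrix} on the raw or log2 scale.
#' @param fit_subset sample ids used to estimate means/SDs (default: all).
#' @return A list with elements \code{matrix} (standardized
#'   \linkS4class{ExpressionMatrix}) and \code{scaler}.
#' @examples
#' m <- matrix(c(8, 16, 32), 3, 1, dimnames = list(paste0("s", 1:3), "a1"))
#' em <- ExpressionMatrix(m, "A_aptamer", "raw")
#' values(log2Standardize(em)$matrix)  # (-1, 0, 1)
#' @export
log2Standardize <- function(x, fit_subset = sampleIDs(x)) {
    if (scaleOf(x) == "standardized")
        stop("matrix is already standardized (double-transform guard)",
             call. = FALSE)
    v <- x@values
    log_applied <- scaleOf(x) == "raw"
    if (log_applied) {
        if (any(v <= 0, na.rm = TRUE))
            stop("non-positive values cannot be log2-transformed",
                 call. = FALSE)
        v <- log2(v)
    }
    stopIfNot(all(fit_subset %in% rownames(v)),
              "fit_subset contains unknown sample ids")
    fit <- v[fit_subset, , drop = FALSE]
    ctr <- colMeans(fit, na.rm = TRUE)
    sds <- apply(fit, 2, stats::sd, na.rm = TRUE)
    if (any(!is.finite(sds) | sds == 0))
        stop("zero-variance assay(s) in fit subset: ",
             paste(colnames(v)[!is.finite(sds) | sds == 0], collapse = ", "),
             call. = FALSE)
    scaler <- new("Scaler", center = ctr, scale = sds,
                  fit_ids = fit_subset, log_applied = log_applied)
    z <- sweep(sweep(v, 2, ctr, "-"), 2, sds, "/")
    list(matrix = ExpressionMatrix(z, platform = x@platform,
                                   scale = "standardized"),
         scaler = scaler)
}

#' Apply a previously fitted Scaler
#'
#' Reuses training-era standardization parameters on new (e.g. held-out)
#' samples.
#'
#' @param x an \linkS4class{ExpressionMatrix} on the scale the scaler was
#'   fit for.
#' @param scaler a \linkS4class{Scaler} from \code{\link{log2Standardize}}.
#' @return A standardized \linkS4class{ExpressionMatrix}.
#' @export
applyScaler <- function(x, scaler) {
    if (scaleOf(x) == "standardized")
        stop("matrix is already standardized (double-transform guard)",
             call. = FALSE)
    v <- x@values
    if (scaler@log_applied) {
        stopIfNot(scaleOf(x) == "raw",
                  "scaler was fit with a log2 step; expected a raw-scale matrix")
        if (any(v <= 0, na.rm = TRUE))
            stop("non-positive values cannot be log2-transformed",
                 call. = FALSE)
        v <- log2(v)
    }
    miss <- setdiff(colnames(v), names(scaler@center))
    stopIfNot(!length(miss),
              paste("assay(s) unknown to scaler:", paste(miss, collapse = ", ")))
    ctr <- scaler@center[colnames(v)]
    sds <- scaler@scale[colnames(v)]
    z <- sweep(sweep(v, 2, ctr, "-"), 2, sds, "/")
    ExpressionMatrix(z, platform = x@platform, scale = "standardized")
}

#' Missingness quality control
#'
#' Drops assays whose missing fraction strictly exceeds \code{threshold},
#' then samples whose missing fraction over the retained assays strictly
#' exceeds it (assays-first order is fixed).
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @param threshold maximum tolerated missing fraction (default 0.10).
#' @return The filtered \linkS4class{ExpressionMatrix}.
#' @export
qcMissingness <- function(x, threshold = 0.10) {
    v <- x@values
    keep_a <- colMeans(is.na(v)) <= threshold
    if (!any(keep_a))
        stop("missingness QC removed every assay", call. = FALSE)
    v <- v[, keep_a, drop = FALSE]
    keep_s <- rowMeans(is.na(v)) <= threshold
    if (!any(keep_s))
        stop("missingness QC removed every sample", call. = FALSE)
    ExpressionMatrix(v[keep_s, , drop = FALSE], platform = x@platform,
                     scale = x@scale)
}

# Assay-pair distance used by knnImpute: Euclidean over samples where both
# assays are observed, scaled by the shared-sample count (root mean squared
# difference); Inf when no sample is shared.
assayDistance <- function(v) {
    p <- ncol(v)
    obs <- !is.na(v)
    d <- matrix(Inf, p, p, dimnames = list(colnames(v), colnames(v)))
    for (a in seq_len(p)) {
        for (b in seq_len(p)) {
            if (b <= a) next
            sh <- obs[, a] & obs[, b]
            ns <- sum(sh)
            if (ns > 0)
                d[a, b] <- d[b, a] <-
                    sqrt(sum((v[sh, a] - v[sh, b])^2) / ns)
        }
        d[a, a] <- 0
    }
    d
}

#' K-nearest-neighbor imputation over assays
#'
#' Each missing entry is filled with the unweighted mean of the k nearest
#' assays (feature-wise neighbors) that are observed for that sample.
#' Distance between two assays is the Euclidean distance over the samples
#' where both are observed, scaled by the shared-sample count; ties are
#' broken by assay id order. An entry with no usable neighbor falls back
#' to the assay mean; a fully missing assay is an error.
#'
#' @param x a post-QC \linkS4class{ExpressionMatrix}.
#' @param k number of neighbors (default 10; clamped with a warning when
#'   fewer assays are available).
#' @return A complete \linkS4class{ExpressionMatrix}.
#' @export
knnImpute <- function(x, k = 10L) {
    v <- x@values
    if (!anyNA(v)) return(x)
    fully_missing <- colnames(v)[colMeans(is.na(v)) == 1]
    if (length(fully_missing))
        stop("assay(s) fully missing, cannot impute: ",
             paste(fully_missing, collapse = ", "), call. = FALSE)
    if (k > ncol(v) - 1L) {
        warning(sprintf("k=%d exceeds available neighbor assays; using %d",
                        k, ncol(v) - 1L))
        k <- ncol(v) - 1L
    }
    d <- assayDistance(v)
    col_means <- colMeans(v, na.rm = TRUE)
    # Neighbor preference per target assay: distance, then assay id.
    ids <- colnames(v)
    for (j in which(colSums(is.na(v)) > 0)) {
        cand <- setdiff(seq_len(ncol(v)), j)
        ord <- cand[order(d[cand, j], ids[cand])]
        for (i in which(is.na(v[, j]))) {
            usable <- ord[is.finite(d[ord, j]) & !is.na(x@values[i, ord])]
            if (!length(usable)) {
                v[i, j] <- col_means[j]
            } else {
                nb <- usable[seq_len(min(k, length(usable)))]
                v[i, j] <- mean(x@values[i, nb])
            }
        }
    }
    ExpressionMatrix(v, platform = x@platform, scale = x@scale)
}

#' Resolve duplicate PEA assays per protein
#'
#' For PEA-platform proteins measured by multiple assays, keeps the assay
#' with the lowest pre-imputation missing fraction (detectability proxy),
#' ties broken by assay id. Aptamer-platform duplicates are retained as
#' distinct measurements.
#'
#' @param x an \linkS4class{ExpressionMatrix} whose \code{NA} pattern still
#'   reflects pre-imputation missingness.
#' @param map assay map from \code{\link{assayMap}}.
#' @return The de-duplicated \linkS4class{ExpressionMatrix}.
#' @export
resolveDuplicates <- function(x, map) {
    if (platformOf(x) != "B_pea") return(x)
    map <- map[map$platform == "B_pea" & map$assay_id %in% assayIDs(x), ,
               drop = FALSE]
    missfrac <- colMeans(is.na(x@values))
    keep <- vapply(split(map$assay_id, map$protein_id), function(a) {
        a[order(missfrac[a], a)][1L]
    }, character(1))
    unmapped <- setdiff(assayIDs(x), map$assay_id)
    sel <- assayIDs(x)[assayIDs(x) %in% c(keep, unmapped)]
    x[, sel]
}

#' Cross-platform overlap table
#'
#' One row per (protein, aptamer assay) pair matched to the protein's
#' single PEA assay, plus summary statistics: the count of distinct
#' overlapping proteins and the percentage of each panel's proteins
#' covered (exact, with conventionally rounded integer companions).
#'
#' @param mapA aptamer-platform assay map.
#' @param mapB PEA-platform assay map (post duplicate resolution: one
#'   assay per protein).
#' @return A data.frame (\code{protein_id}, \code{assay_id_A},
#'   \code{assay_id_B}) with a \code{"summary"} attribute.
#' @examples
#' mA <- assayMap(c("x", "x_2", "y"), "A_aptamer", c("p1", "p1", "p2"))
#' mB <- assayMap(c("ox", "oz"), "B_pea", c("p1", "p3"))
#' ov <- buildOverlap(mA, mB)
#' attr(ov, "summary")$n_overlap  # 1 protein, 2 aptamer rows
#' @export
buildOverlap <- function(mapA, mapB) {
    stopIfNot(all(mapA$platform == "A_aptamer"),
              "mapA must be the aptamer platform")
    stopIfNot(all(mapB$platform == "B_pea"), "mapB must be the PEA platform")
    if (anyDuplicated(mapB$protein_id))
        stop("mapB has multiple assays per protein; run resolveDuplicates first",
             call. = FALSE)
    shared <- intersect(mapA$protein_id, mapB$protein_id)
    a <- mapA[mapA$protein_id %in% shared, c("protein_id", "assay_id")]
    b <- mapB[match(a$protein_id, mapB$protein_id), "assay_id"]
    ov <- data.frame(protein_id = a$protein_id, assay_id_A = a$assay_id,
                     assay_id_B = b, stringsAsFactors = FALSE)
    ov <- ov[order(ov$protein_id, ov$assay_id_A), , drop = FALSE]
    rownames(ov) <- NULL
    nA <- length(unique(mapA$protein_id))
    nB <- length(unique(mapB$protein_id))
    n_overlap <- length(shared)
    attr(ov, "summary") <- list(
        n_overlap = n_overlap,
        coverage_A_pct = 100 * n_overlap / nA,
        coverage_B_pct = 100 * n_overlap / nB,
        coverage_A_pct_int = as.integer(round(100 * n_overlap / nA)),
        coverage_B_pct_int = as.integer(round(100 * n_overlap / nB)))
    ov
}
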