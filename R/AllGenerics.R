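#' Accessors for ExpressionMatrix and friends
#'
#' \code{values} returns the numeric sample x assay matrix; \code{sampleIDs}
#' and \code{assayIDs} its dimnames; \code{platformOf} and \code{scaleOf}
#' the platform tag and value-scale flag; \code{missingMask} the logical
#' mask that is \code{TRUE} exactly where a value is undefined.
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @return See the individual descriptions.
#' @name ExpressionMatrix-accessors
#' @aliases values sampleIDs assayIDs platformOf scaleOf missingMask
#' @examples
#' m <- matrix(c(1, NA, 3, 4, 5, 6), 3, 2,
#'             dimnames = list(paste0("s", 1:3), c("a1", "a2")))
#' em <- ExpressionMatrix(m, "B_pea", "log2")
#' sum(missingMask(em))  # 1
NULL

#' @rdname ExpressionMatrix-accessors
#' @export
setGeneric("values", function(x) standardGeneric("values"))
#' @rdname ExpressionMatrix-accessors
#' @export
setMethod("values", "ExpressionMatrix", function(x) x@values)

#' @rdname ExpressionMatrix-accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))
#' @rdname ExpressionMatrix-accessors
#' @export
setMethod("sampleIDs", "ExpressionMatrix", function(x) rownames(x@values))

#' @rdname ExpressionMatrix-accessors
#' @export
setGeneric("assayIDs", function(x) standardGeneric("assayIDs"))
#' @rdname ExpressionMatrix-accessors
#' @export
setMethod("assayIDs", "ExpressionMatrix", function(x) colnames(x@values))

#' @rdname ExpressionMatrix-accessors
#' @export
setGeneric("platformOf", function(x) standardGeneric("platformOf"))
#' @rdname ExpressionMatrix-accessors
#' @export
setMethod("platformOf", "ExpressionMatrix", function(x) x@platform)

#' @rdname ExpressionMatrix-accessors
#' @export
setGeneric("scaleOf", function(x) standardGeneric("scaleOf"))
#' @rdname ExpressionMatrix-accessors
#' @export
setMethod("scaleOf", "ExpressionMatrix", function(x) x@scale)

#' @rdname ExpressionMatrix-accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))
#' @rdname ExpressionMatrix-accessors
#' @export
setMethod("missingMask", "ExpressionMatrix", function(x) is.na(x@values))

setMethod("show", "ExpressionMatrix", function(object) {
    v <- object@values
    cat(sprintf("ExpressionMatrix: %d samples x %d assays [%s, %s scale]\n",
                nrow(v), ncol(v), object@platform, object@scale))
    nmiss <- sum(is.na(v))
    cat(sprintf("  missing: %d (%.1f%%)\n", nmiss, 100 * nmiss / length(v)))
})

setMethod("show", "SimConfig", function(object) {
    cat(sprintf("SimConfig: %d samples x %d proteins, %d blocks (rho=%.2f)\n",
                object@n_samples, object@n_proteins,
                length(object@block_sizes), object@within_block_corr))
    cp <- object@class_proportions[FIDELITY_CLASSES]
    cat("  class proportions:",
        paste(sprintf("%s=%.2f", names(cp), cp), collapse = ", "), "\n")
    cat(sprintf("  LOD quantile %.2f, censoring rate %.2f, seed %d\n",
                object@lod_quantile, object@censoring_rate, object@seed))
})

setMethod("show", "SimTruth", function(object) {
    tab <- table(factor(object@class_labels, levels = FIDELITY_CLASSES))
    cat(sprintf("SimTruth: %d samples x %d proteins\n",
                nrow(object@latent), ncol(object@latent)))
    cat("  classes:", paste(sprintf("%s=%d", names(tab), tab),
                            collapse = ", "), "\n")
})

setMethod("show", "ImputationModelSet", function(object) {
    cat(sprintf("ImputationModelSet [%s]: %d per-target models, %d features\n",
                object@direction, length(object@models),
                length(object@feature_ids)))
    cat(sprintf("  %s -> %s; train n=%d, test n=%d, seed %d\n",
                object@source_platform, object@target_platform,
                length(object@split@train_ids), length(object@split@test_ids),
                object@seed))
})

setMethod("show", "TierRules", function(object) {
    cat(sprintf(paste0("TierRules (signed r): tier1 both >= %.2f; ",
                       "tier4 both <= %.2f; else tier2 if post >= %.2f, ",
                       "tier3 otherwise\n"),
                object@t_high, object@t_low, object@t_mid))
})

#' Class labels of a simulated truth object
#'
#' @param truth a \linkS4class{SimTruth}.
#' @return Named character vector of per-protein fidelity classes.
#' @export
classLabels <- function(truth) {
    stopifnot(is(truth, "SimTruth"))
    truth@class_labels
}

#' Latent concentration matrix of a simulated truth object
#'
#' @param truth a \linkS4class{SimTruth}.
#' @return Numeric samples x proteins matrix.
#' @export
latentMatrix <- function(truth) {
    stopifnot(is(truth, "SimTruth"))
    truth@latent
}
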