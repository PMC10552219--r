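.asExprSE <- function(expr) {
    if (methods::is(expr, "SummarizedExperiment"))
        return(expr)
    mat <- as.matrix(expr)
    if (is.null(rownames(mat)) || is.null(colnames(mat)))
        stop("expression matrix needs gene rownames and sample colnames")
    SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = mat), metadata = list(centered = FALSE))
}

#' Mean-center an expression matrix per gene
#'
#' Subtracts each gene's across-sample mean, the required preprocessing
#' before signature evaluation. Idempotent: centering a centered matrix
#' changes nothing. Centering is done jointly over all provided samples;
#' to center within a subset, subset first.
#'
#' @param expr a `SummarizedExperiment` (assay `exprs`) or a numeric
#'   genes x samples matrix with dimnames.
#' @return A `SummarizedExperiment` with centered `exprs` and
#'   `metadata(.)$centered = TRUE`.
#' @export
#' @examples
#' m <- matrix(c(1, 3), 1, dimnames = list("g1", c("s1", "s2")))
#' SummarizedExperiment::assay(meanCenter(m))  # -1, 1
meanCenter <- function(expr) {
    se <- .asExprSE(expr)
    mat <- SummarizedExperiment::assay(se, "exprs")
    if (anyDuplicated(rownames(mat)))
        stop("duplicate gene ids")
    if (anyDuplicated(colnames(mat)))
        stop("duplicate sample ids")
    if (ncol(mat) < 2)
        stop("mean-centering needs at least 2 samples")
    mat <- mat - rowMeans(mat)
    SummarizedExperiment::assay(se, "exprs") <- mat
    md <- S4Vectors::metadata(se)
    md$centered <- TRUE
    S4Vectors::metadata(se) <- md
    se
}

#' Is an expression container mean-centered?
#'
#' @param expr a `SummarizedExperiment` or matrix.
#' @param tol tolerance on per-gene means.
#' @return logical.
#' @export
isCentered <- function(expr, tol = 1e-9) {
    se <- .asExprSE(expr)
    flag <- isTRUE(S4Vectors::metadata(se)$centered)
    mat <- SummarizedExperiment::assay(se, "exprs")
    flag && all(abs(rowMeans(mat)) <= tol)
}

#' Score one signature on a centered expression matrix
#'
#' The signature score of a sample is the unweighted mean, over signature
#' genes present in the matrix, of `weight * centered expression`
#' (direction weights +1/-1 default to +1). Signature genes absent from
#' the matrix are dropped with a warning; when no signature gene is
#' present the score is `NA` for all samples (with a warning, not an
#' error).
#'
#' @param expr a mean-centered `SummarizedExperiment` or matrix
#'   (see [meanCenter()]).
#' @param sig a [SignatureDef-class].
#' @return named numeric, one score per sample.
#' @export
scoreSignature <- function(expr, sig) {
    stopifnot(methods::is(sig, "SignatureDef"))
    se <- .asExprSE(expr)
    if (!isCentered(se))
        stop("expression must be mean-centered; run meanCenter() first")
    mat <- SummarizedExperiment::assay(se, "exprs")
    present <- sig@genes %in% rownames(mat)
    if (!any(present)) {
        warning("no genes of signature '", sig@name,
                "' present in the expression matrix; score is NA")
        out <- rep(NA_real_, ncol(mat))
        names(out) <- colnames(mat)
        return(out)
    }
    if (any(!present))
        warning(sum(!present), " gene(s) of signature '", sig@name,
                "' absent from the expression matrix and dropped: ",
                paste(utils::head(sig@genes[!present], 5), collapse = ", "))
    sub <- mat[sig@genes[present], , drop = FALSE]
    w <- sig@weights[present]
    colMeans(sub * w)
}

#' Score all signatures into a per-sample table
#'
#' @param expr mean-centered expression (see [meanCenter()]).
#' @param sigs list of [SignatureDef-class] objects with unique names.
#' @return data.frame with `sample_id` and one column per signature.
#' @export
scoreSignatures <- function(expr, sigs) {
    se <- .asExprSE(expr)
    nms <- vapply(sigs, function(s) s@name, character(1))
    if (anyDuplicated(nms))
        stop("duplicate signature names: ",
             paste(unique(nms[duplicated(nms)]), collapse = ", "))
    out <- data.frame(sample_id = colnames(SummarizedExperiment::assay(se)),
                      stringsAsFactors = FALSE)
    for (sig in sigs)
        out[[sig@name]] <- unname(scoreSignature(se, sig))
    out
}
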