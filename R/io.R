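#' Read a per-cell segmentation table
#'
#' CSV with columns `sample_id`, `cell_id`, `x_um`, `y_um` (coordinates in
#' micrometers), one 0/1 column per marker and optionally `phenotype`.
#' Missing required columns and non-binary marker calls are reported by
#' name and row.
#'
#' @param path CSV file path.
#' @param markers marker column names; default: recognized panel columns
#'   present in the file.
#' @return A [CellTable-class].
#' @export
readCellTable <- function(path, markers = NULL) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    for (col in c("sample_id", "cell_id", "x_um", "y_um"))
        if (!col %in% names(df))
            stop("missing column ", col)
    CellTable(df, markers = markers)
}

#' Write a CellTable to CSV
#'
#' Missing values are written as empty fields.
#'
#' @param cells a [CellTable-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeCellTable <- function(cells, path) {
    stopifnot(methods::is(cells, "CellTable"))
    utils::write.csv(cells@cells, path, row.names = FALSE, na = "")
    invisible(path)
}

#' Read a clinical table
#'
#' CSV with `patient_id`, `os_months`, `death_event` and optional
#' `rcr`, `er_positive`, `sample_type`, `pair_id`, `stils_percent` and
#' precomputed index columns. Empty fields become NA.
#'
#' @param path CSV file path.
#' @return data.frame of clinical records.
#' @export
readClinicalTable <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
    for (col in c("patient_id", "os_months", "death_event"))
        if (!col %in% names(df))
            stop("missing column ", col)
    if (any(df$os_months < 0, na.rm = TRUE))
        stop("negative os_months")
    if (!all(df$death_event %in% c(0, 1, NA)))
        stop("death_event must be 0/1")
    df
}

#' Read a genes-by-samples expression matrix (TSV)
#'
#' Tab-delimited, header row of sample ids, first column gene ids.
#'
#' @param path TSV file path.
#' @return A `SummarizedExperiment` with assay `exprs`, uncentered.
#' @export
readExpressionMatrix <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    genes <- df[[1]]
    if (anyDuplicated(genes))
        stop("duplicate gene ids in ", path)
    mat <- as.matrix(df[, -1, drop = FALSE])
    rownames(mat) <- genes
    SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = mat), metadata = list(centered = FALSE))
}

#' Write an expression matrix to TSV
#'
#' @param expr `SummarizedExperiment` or matrix.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(expr, path) {
    se <- .asExprSE(expr)
    mat <- SummarizedExperiment::assay(se, "exprs")
    df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    invisible(path)
}

#' Read gene signatures in GMT format
#'
#' One signature per line: name, description, then gene ids, tab
#' separated. An optional weights sidecar (TSV with columns `signature`,
#' `gene`, `weight`) supplies +1/-1 direction weights; unlisted genes
#' default to +1.
#'
#' @param path GMT file path.
#' @param weightsPath optional weights TSV path.
#' @return list of [SignatureDef-class] objects.
#' @export
readGMT <- function(path, weightsPath = NULL) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    w <- NULL
    if (!is.null(weightsPath))
        w <- utils::read.delim(weightsPath, stringsAsFactors = FALSE)
    lapply(lines, function(ln) {
        parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
        if (length(parts) < 3)
            stop("malformed GMT line: ", substr(ln, 1, 40))
        name <- parts[1]
        genes <- parts[-(1:2)]
        genes <- genes[nzchar(genes)]
        weights <- rep(1, length(genes))
        if (!is.null(w)) {
            ws <- w[w$signature == name, , drop = FALSE]
            idx <- match(ws$gene, genes)
            weights[idx[!is.na(idx)]] <- ws$weight[!is.na(idx)]
        }
        signatureDef(name, genes, weights)
    })
}

#' Read phenotype gating rules from YAML
#'
#' A YAML list of mappings with keys `name`, `positive`, optional
#' `negative` and `priority`.
#'
#' @param path YAML file path.
#' @return list of [PhenotypeRule-class] objects.
#' @export
readPhenotypeRules <- function(path) {
    spec <- yaml::read_yaml(path)
    lapply(spec, function(r) {
        phenotypeRule(r$name, unlist(r$positive),
                      unlist(r$negative) %||% character(),
                      r$priority %||% 0L)
    })
}

#' Read a score table written by the pipeline
#'
#' @param path CSV file path.
#' @return data.frame keyed by `sample_id`.
#' @export
readScoreTable <- function(path) {
    utils::read.csv(path, stringsAsFactors = FALSE,
                    na.strings = c("", "NA"))
}

#' Write a score or result table to CSV
#'
#' Missing values become empty fields so round-trips are lossless.
#'
#' @param x data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeScoreTable <- function(x, path) {
    utils::write.csv(x, path, row.names = FALSE, na = "")
    invisible(path)
}
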