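#' PhenotypeRule: a marker gate defining one phenotype
#'
#' A cell satisfies a rule when every `requiredPositive` marker call is 1
#' and every `requiredNegative` call is 0. Rules are resolved by priority:
#' each cell receives the highest-priority rule it satisfies.
#'
#' @slot name phenotype label.
#' @slot requiredPositive,requiredNegative disjoint marker sets.
#' @slot priority integer; higher wins.
#' @export
setClass("PhenotypeRule",
    slots = c(name = "character", requiredPositive = "character",
              requiredNegative = "character", priority = "integer"))

setValidity("PhenotypeRule", function(object) {
    if (length(intersect(object@requiredPositive, object@requiredNegative)))
        return("requiredPositive and requiredNegative must be disjoint")
    if (!length(object@requiredPositive))
        return("a rule needs at least one positive marker")
    TRUE
})

#' Construct a PhenotypeRule
#'
#' @param name phenotype label.
#' @param positive markers required positive.
#' @param negative markers required negative.
#' @param priority integer tie-break; higher-priority rules win.
#' @return A [PhenotypeRule-class].
#' @export
#' @examples
#' phenotypeRule("Treg", c("CD3", "FoxP3"), "CD8", priority = 90)
phenotypeRule <- function(name, positive, negative = character(),
                          priority = 0L) {
    methods::new("PhenotypeRule", name = name,
                 requiredPositive = as.character(positive),
                 requiredNegative = as.character(negative),
                 priority = as.integer(priority))
}

setMethod("show", "PhenotypeRule", function(object) {
    neg <- if (length(object@requiredNegative))
        paste0(" ", paste0(object@requiredNegative, "-", collapse = " "))
    else ""
    cat(sprintf("PhenotypeRule '%s' (priority %d): %s%s\n", object@name,
                object@priority,
                paste0(object@requiredPositive, "+", collapse = " "), neg))
})

#' Default phenotype gates
#'
#' Ships the standard immune/tumor gates: tumor = CK+; cytotoxic T =
#' CD3+CD8+; helper T = CD3+CD8-; Treg = CD3+FoxP3+CD8-; FoxP3- T =
#' CD3+FoxP3-; PD1+ T = CD3+PD1+; B cell = CD20+; macrophage = CD68+;
#' NK = CD56+. Priorities place tumor above all immune gates (so CK+ cells
#' are excluded from immune phenotypes when `excludeTumor = TRUE`, the
#' default) and Treg above cytotoxic/helper T. Panel-specific sets restrict
#' the gates to markers stained on that section: panel 1 (CD3, CD20, FoxP3,
#' CK, Ki-67) has no CD8, so its Treg gate is CD3+FoxP3+; panel 2 (CD3,
#' CD8, CD68, PD1, PDL1, CK) carries the T-cell subset gates.
#'
#' @param panel `"combined"`, `"panel1"` or `"panel2"`.
#' @param excludeTumor if TRUE, immune gates additionally require CK-.
#' @return list of [PhenotypeRule-class] objects.
#' @export
defaultPhenotypeRules <- function(panel = c("combined", "panel1", "panel2"),
                                  excludeTumor = TRUE) {
    panel <- match.arg(panel)
    ckNeg <- if (excludeTumor) "CK" else character()
    rules <- switch(panel,
        combined = list(
            phenotypeRule("tumor", "CK", priority = 100L),
            phenotypeRule("Treg", c("CD3", "FoxP3"), c("CD8", ckNeg), 90L),
            phenotypeRule("cytotoxic_T", c("CD3", "CD8"), ckNeg, 80L),
            phenotypeRule("helper_T", "CD3", c("CD8", ckNeg), 70L),
            phenotypeRule("PD1_T", c("CD3", "PD1"), ckNeg, 60L),
            phenotypeRule("FoxP3neg_T", "CD3", c("FoxP3", ckNeg), 50L),
            phenotypeRule("B_cell", "CD20", ckNeg, 40L),
            phenotypeRule("macrophage", "CD68", ckNeg, 30L),
            phenotypeRule("NK", "CD56", ckNeg, 20L)),
        panel1 = list(
            phenotypeRule("tumor", "CK", priority = 100L),
            phenotypeRule("Treg", c("CD3", "FoxP3"), ckNeg, 90L),
            phenotypeRule("FoxP3neg_T", "CD3", c("FoxP3", ckNeg), 50L),
            phenotypeRule("B_cell", "CD20", ckNeg, 40L)),
        panel2 = list(
            phenotypeRule("tumor", "CK", priority = 100L),
            phenotypeRule("cytotoxic_T", c("CD3", "CD8"), ckNeg, 80L),
            phenotypeRule("helper_T", "CD3", c("CD8", ckNeg), 70L),
            phenotypeRule("PD1_T", c("CD3", "PD1"), ckNeg, 60L),
            phenotypeRule("macrophage", "CD68", ckNeg, 30L)))
    rules
}

#' Assign phenotypes from binary marker calls
#'
#' Each cell receives the highest-priority rule it satisfies; cells
#' satisfying no rule are labeled `"other"`. Two distinct rules matching
#' the same cell at equal priority are an ambiguous gate and raise an
#' error. Assignment is idempotent: the phenotype column is recomputed
#' from markers alone.
#'
#' @param cells a [CellTable-class].
#' @param rules list of [PhenotypeRule-class]; default
#'   [defaultPhenotypeRules()].
#' @return The [CellTable-class] with its `phenotype` column filled in.
#' @export
#' @examples
#' df <- data.frame(sample_id = "s", cell_id = "c1", x_um = 0, y_um = 0,
#'                  CD3 = 1, CD8 = 1, CK = 0)
#' cellData(assignPhenotypes(CellTable(df)))$phenotype
assignPhenotypes <- function(cells, rules = defaultPhenotypeRules()) {
    stopifnot(methods::is(cells, "CellTable"))
    df <- cells@cells
    ruleMarkers <- unique(unlist(lapply(rules, function(r)
        c(r@requiredPositive, r@requiredNegative))))
    missing <- setdiff(ruleMarkers, cells@markers)
    if (length(missing))
        stop("missing marker column(s): ", paste(missing, collapse = ", "))
    if (!nrow(df)) {
        cells@cells$phenotype <- character(0)
        return(cells)
    }
    match1 <- function(r) {
        ok <- rep(TRUE, nrow(df))
        for (m in r@requiredPositive) ok <- ok & df[[m]] == 1
        for (m in r@requiredNegative) ok <- ok & df[[m]] == 0
        ok
    }
    matches <- vapply(rules, match1, logical(nrow(df)))
    matches <- matrix(matches, nrow = nrow(df))
    prios <- vapply(rules, function(r) r@priority, integer(1))
    labels <- vapply(rules, function(r) r@name, character(1))

    assigned <- rep("other", nrow(df))
    prioMat <- sweep(matches, 2, prios, "*")
    prioMat[!matches] <- -Inf
    best <- apply(prioMat, 1, max)
    hit <- is.finite(best)
    if (any(hit)) {
        nBest <- rowSums(prioMat == best & matches)
        amb <- hit & nBest > 1
        if (any(amb)) {
            i <- which(amb)[1]
            ties <- labels[matches[i, ] & prioMat[i, ] == best[i]]
            stop("ambiguous gate: rules ", paste(ties, collapse = " and "),
                 " match cell ", df$cell_id[i], " at equal priority")
        }
        idx <- apply(prioMat[hit, , drop = FALSE], 1, which.max)
        assigned[hit] <- labels[idx]
    }
    cells@cells$phenotype <- assigned
    cells
}

#' Summarize per-sample phenotype abundance
#'
#' Counts cells per sample and phenotype and converts them to densities
#' (cells per mm^2) using the analyzed window area.
#'
#' @param cells a [CellTable-class] with phenotypes assigned.
#' @param windowAreaMm2 analyzed area per sample in mm^2 (> 0).
#' @param phenotypes phenotype labels to report (zero counts included);
#'   defaults to the labels present.
#' @return data.frame with columns `sample_id`, `phenotype`, `count`,
#'   `density_mm2`.
#' @export
summarizeAbundance <- function(cells, windowAreaMm2,
                               phenotypes = NULL) {
    stopifnot(methods::is(cells, "CellTable"))
    if (windowAreaMm2 <= 0)
        stop("windowAreaMm2 must be > 0")
    df <- cells@cells
    if (is.null(phenotypes))
        phenotypes <- sort(unique(df$phenotype))
    samples <- unique(df$sample_id)
    grid <- expand.grid(sample_id = samples, phenotype = phenotypes,
                        stringsAsFactors = FALSE)
    counts <- table(factor(df$sample_id, levels = samples),
                    factor(df$phenotype, levels = phenotypes))
    grid$count <- as.integer(counts[cbind(grid$sample_id, grid$phenotype)])
    grid$density_mm2 <- grid$count / windowAreaMm2
    grid[order(grid$sample_id, grid$phenotype), , drop = FALSE]
}
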