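#' @import methods
NULL

#' Canonical marker panel
#'
#' Marker names recognized by the default phenotype rules. Panels correspond
#' to two separately stained sections: panel 1 carries CD3, CD20, FoxP3, CK
#' and Ki-67; panel 2 carries CD3, CD8, CD68, PD1, PDL1 and CK.
#'
#' @param panel One of `"combined"`, `"panel1"`, `"panel2"`.
#' @return Character vector of marker names.
#' @export
#' @examples
#' markerPanel("panel2")
markerPanel <- function(panel = c("combined", "panel1", "panel2")) {
    panel <- match.arg(panel)
    switch(panel,
        panel1 = c("CD3", "CD20", "FoxP3", "CK", "Ki67"),
        panel2 = c("CD3", "CD8", "CD68", "PD1", "PDL1", "CK"),
        combined = c("CD3", "CD8", "CD20", "CD56", "CD68",
                     "FoxP3", "PD1", "PDL1", "CK", "Ki67"))
}

#' CellTable: per-cell coordinates, marker calls and phenotypes
#'
#' Container for segmented-cell tables from multiplex immunofluorescence.
#' Each row is one cell with micrometer coordinates, binary (0/1) marker
#' calls and an assigned phenotype label (`"unassigned"` until
#' [assignPhenotypes()] is run).
#'
#' @slot cells data.frame with columns `sample_id`, `cell_id`, `x_um`,
#'   `y_um`, one 0/1 column per marker, and `phenotype`.
#' @slot markers character vector naming the marker columns.
#' @export
setClass("CellTable",
    slots = c(cells = "data.frame", markers = "character"))

setValidity("CellTable", function(object) {
    df <- object@cells
    required <- c("sample_id", "cell_id", "x_um", "y_um", "phenotype")
    missing <- setdiff(c(required, object@markers), names(df))
    if (length(missing))
        return(paste("missing column(s):", paste(missing, collapse = ", ")))
    if (nrow(df)) {
        if (!all(is.finite(df$x_um)) || !all(is.finite(df$y_um)))
            return("coordinates must be finite")
        for (m in object@markers) {
            v <- df[[m]]
            if (!all(v %in% c(0, 1)))
                return(sprintf("marker '%s' has non-binary values (rows %s)",
                               m, paste(utils::head(which(!v %in% c(0, 1)), 5),
                                        collapse = ", ")))
        }
        dup <- tapply(df$cell_id, df$sample_id, anyDuplicated)
        if (any(unlist(dup) > 0))
            return("cell_id must be unique within sample")
    }
    TRUE
})

#' Construct a CellTable
#'
#' @param cells data.frame with `sample_id`, `cell_id`, `x_um`, `y_um`,
#'   binary marker columns and optionally `phenotype`.
#' @param markers Marker column names; by default every column of `cells`
#'   that matches the combined panel ([markerPanel()]).
#' @return A [CellTable-class] object.
#' @export
#' @examples
#' df <- data.frame(sample_id = "s1", cell_id = "c1", x_um = 10, y_um = 20,
#'                  CD3 = 1, CD8 = 1)
#' CellTable(df)
CellTable <- function(cells, markers = NULL) {
    cells <- as.data.frame(cells)
    if (is.null(markers))
        markers <- intersect(markerPanel("combined"), names(cells))
    if (!"phenotype" %in% names(cells))
        cells$phenotype <- rep("unassigned", nrow(cells))
    cells$sample_id <- as.character(cells$sample_id)
    cells$cell_id <- as.character(cells$cell_id)
    methods::new("CellTable", cells = cells, markers = markers)
}

setMethod("show", "CellTable", function(object) {
    df <- object@cells
    cat("CellTable with", nrow(df), "cells in",
        length(unique(df$sample_id)), "sample(s)\n")
    cat("  markers:", paste(object@markers, collapse = ", "), "\n")
    ph <- table(df$phenotype)
    if (length(ph))
        cat("  phenotypes:",
            paste(sprintf("%s(%d)", names(ph), ph), collapse = " "), "\n")
})

#' QuadratCounts: aligned per-square counts of two cell types
#'
#' Counts of two phenotypes over a fixed square grid anchored at the
#' bounding-box minimum of all cells in one sample. Cells are binned with
#' half-open intervals [k*s, (k+1)*s) so each falls in exactly one square;
#' partial edge squares are kept.
#'
#' @slot sampleId sample identifier.
#' @slot typeA,typeB phenotype labels counted in `countsA`/`countsB`.
#' @slot squareSizeUm side length of a square in micrometers.
#' @slot origin numeric(2), grid origin (minimum x and y) in micrometers.
#' @slot countsA,countsB integer matrices of identical dimension
#'   (rows = y bins, columns = x bins).
#' @export
setClass("QuadratCounts",
    slots = c(sampleId = "character", typeA = "character",
              typeB = "character", squareSizeUm = "numeric",
              origin = "numeric", countsA = "matrix", countsB = "matrix"))

setValidity("QuadratCounts", function(object) {
    if (!identical(dim(object@countsA), dim(object@countsB)))
        return("count grids must have identical shape")
    if (any(object@countsA < 0) || any(object@countsB < 0))
        return("counts must be non-negative")
    if (length(object@squareSizeUm) != 1 || object@squareSizeUm <= 0)
        return("squareSizeUm must be a single positive length")
    if (length(object@origin) != 2)
        return("origin must be numeric(2)")
    TRUE
})

setMethod("show", "QuadratCounts", function(object) {
    cat(sprintf("QuadratCounts [%s] %s vs %s: %d x %d squares of %g um\n",
                object@sampleId, object@typeA, object@typeB,
                nrow(object@countsA), ncol(object@countsA),
                object@squareSizeUm))
    cat(sprintf("  totals: %d (%s), %d (%s)\n",
                sum(object@countsA), object@typeA,
                sum(object@countsB), object@typeB))
})

#' GFunctionCurve: empirical nearest-neighbor distance distribution
#'
#' G(r) is the fraction of reference-type cells whose nearest target-type
#' neighbor lies within Euclidean distance r (self excluded when the two
#' types coincide). No edge correction is applied by default.
#'
#' @slot radii ordered radii in micrometers.
#' @slot g empirical G values in [0, 1], non-decreasing.
#' @slot typeA reference phenotype (cells measured from).
#' @slot typeB target phenotype (nearest neighbor sought).
#' @slot nA,nB number of reference / target cells.
#' @export
setClass("GFunctionCurve",
    slots = c(radii = "numeric", g = "numeric", typeA = "character",
              typeB = "character", nA = "integer", nB = "integer"))

setValidity("GFunctionCurve", function(object) {
    if (length(object@radii) != length(object@g))
        return("radii and g must have equal length")
    if (is.unsorted(object@radii, strictly = TRUE))
        return("radii must be strictly increasing")
    if (any(object@g < -1e-12) || any(object@g > 1 + 1e-12))
        return("G values must lie in [0, 1]")
    if (is.unsorted(object@g))
        return("G must be non-decreasing")
    TRUE
})

setMethod("show", "GFunctionCurve", function(object) {
    cat(sprintf("GFunctionCurve %s -> %s (nA = %d, nB = %d), r in [%g, %g] um\n",
                object@typeA, object@typeB, object@nA, object@nB,
                min(object@radii), max(object@radii)))
})

#' SimulationConfig: parameters of the two-type clustered point process
#'
#' Parameters for a Thomas-style cluster process in a rectangular window
#' emulating a tissue-microarray core: Poisson parents, Poisson offspring
#' counts, isotropic Gaussian displacements, and a fraction of parents
#' shared by the two cell types. `sharedParentFraction = 1` yields a fully
#' colocalized pattern, `0` independent (segregated) clusters. Offspring
#' falling outside the window are discarded, as at a physical core boundary.
#'
#' @slot windowWidthUm,windowHeightUm window size in micrometers.
#' @slot parentIntensity parents per mm^2 (per type; shared parents count
#'   toward both types).
#' @slot offspringMeanA,offspringMeanB expected offspring per parent.
#' @slot offspringSdUm standard deviation of Gaussian displacements (um).
#' @slot sharedParentFraction fraction of parents spawning both types.
#' @slot backgroundIntensityPerType uniform background cells per mm^2.
#' @slot seed integer seed.
#' @export
setClass("SimulationConfig",
    slots = c(windowWidthUm = "numeric", windowHeightUm = "numeric",
              parentIntensity = "numeric", offspringMeanA = "numeric",
              offspringMeanB = "numeric", offspringSdUm = "numeric",
              sharedParentFraction = "numeric",
              backgroundIntensityPerType = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
    if (object@windowWidthUm <= 0 || object@windowHeightUm <= 0)
        return("window dimensions must be positive")
    nonneg <- c(object@parentIntensity, object@offspringMeanA,
                object@offspringMeanB, object@offspringSdUm,
                object@backgroundIntensityPerType)
    if (any(nonneg < 0))
        return("intensities, offspring means and sd must be >= 0")
    f <- object@sharedParentFraction
    if (f < 0 || f > 1)
        return("sharedParentFraction must lie in [0, 1]")
    TRUE
})

#' Construct a SimulationConfig
#'
#' Defaults describe a moderately infiltrated 600 x 600 um core: 10 parent
#' clusters per mm^2, 30 expected offspring per parent, 20 um cluster
#' spread, half the parents shared between the two types, and a 50 cells
#' per mm^2 uniform background.
#'
#' @param windowWidthUm,windowHeightUm window size in micrometers.
#' @param parentIntensity parents per mm^2.
#' @param offspringMeanA,offspringMeanB expected offspring per parent.
#' @param offspringSdUm Gaussian displacement scale in micrometers.
#' @param sharedParentFraction fraction of parents spawning both types.
#' @param backgroundIntensityPerType background cells per mm^2 (each type).
#' @param seed integer seed.
#' @return A [SimulationConfig-class] object.
#' @export
#' @examples
#' simulationConfig(sharedParentFraction = 1, seed = 7)
simulationConfig <- function(windowWidthUm = 600, windowHeightUm = 600,
                             parentIntensity = 10, offspringMeanA = 30,
                             offspringMeanB = 30, offspringSdUm = 20,
                             sharedParentFraction = 0.5,
                             backgroundIntensityPerType = 50,
                             seed = 1L) {
    methods::new("SimulationConfig",
        windowWidthUm = windowWidthUm, windowHeightUm = windowHeightUm,
        parentIntensity = parentIntensity, offspringMeanA = offspringMeanA,
        offspringMeanB = offspringMeanB, offspringSdUm = offspringSdUm,
        sharedParentFraction = sharedParentFraction,
        backgroundIntensityPerType = backgroundIntensityPerType,
        seed = as.integer(seed))
}

#' OutcomeModel: generating model for simulated clinical endpoints
#'
#' Survival times follow a proportional-hazards model with Weibull baseline
#' (exponential when `weibullShape = 1`): h(t) = scale * shape * t^(shape-1)
#' * exp(sum beta * z), administratively censored at `censoringTimeMonths`.
#' Radiological complete response is Bernoulli with a logistic link.
#'
#' @slot baselineHazardScale events per month (> 0).
#' @slot logHazardCoefficients named numeric, log-hazard per unit of each
#'   named score.
#' @slot censoringTimeMonths administrative censoring time (> 0).
#' @slot logisticIntercept,logisticCoefficients logistic model for rCR.
#' @slot weibullShape Weibull shape (1 = exponential baseline).
#' @slot seed integer seed.
#' @export
setClass("OutcomeModel",
    slots = c(baselineHazardScale = "numeric",
              logHazardCoefficients = "numeric",
              censoringTimeMonths = "numeric",
              logisticIntercept = "numeric",
              logisticCoefficients = "numeric",
              weibullShape = "numeric", seed = "integer"))

setValidity("OutcomeModel", function(object) {
    if (object@baselineHazardScale <= 0)
        return("baselineHazardScale must be > 0")
    if (object@censoringTimeMonths <= 0)
        return("censoringTimeMonths must be > 0")
    if (object@weibullShape <= 0)
        return("weibullShape must be > 0")
    TRUE
})

#' Construct an OutcomeModel
#'
#' Defaults give a median survival near 35 months under the null and
#' censoring at 120 months, in the range seen for metastatic breast-cancer
#' cohorts with long follow-up.
#'
#' @param baselineHazardScale events per month.
#' @param logHazardCoefficients named numeric vector (score -> log hazard).
#' @param censoringTimeMonths administrative censoring time in months.
#' @param logisticIntercept,logisticCoefficients rCR logistic model.
#' @param weibullShape baseline shape, 1 for exponential.
#' @param seed integer seed.
#' @return An [OutcomeModel-class] object.
#' @export
#' @examples
#' outcomeModel(logHazardCoefficients = c(treg_density = log(2)))
outcomeModel <- function(baselineHazardScale = 0.02,
                         logHazardCoefficients = numeric(),
                         censoringTimeMonths = 120,
                         logisticIntercept = -1.5,
                         logisticCoefficients = numeric(),
                         weibullShape = 1, seed = 1L) {
    methods::new("OutcomeModel",
        baselineHazardScale = baselineHazardScale,
        logHazardCoefficients = logHazardCoefficients,
        censoringTimeMonths = censoringTimeMonths,
        logisticIntercept = logisticIntercept,
        logisticCoefficients = logisticCoefficients,
        weibullShape = weibullShape, seed = as.integer(seed))
}

#' SignatureDef: a named gene signature with optional direction weights
#'
#' @slot name signature name.
#' @slot genes character vector of gene identifiers (unique, non-empty).
#' @slot weights numeric weights aligned with `genes` (+1/-1 directions;
#'   defaults to +1).
#' @export
setClass("SignatureDef",
    slots = c(name = "character", genes = "character", weights = "numeric"))

setValidity("SignatureDef", function(object) {
    if (!length(object@genes))
        return("gene list must be non-empty")
    if (anyDuplicated(object@genes))
        return("duplicate genes within a signature")
    if (length(object@weights) != length(object@genes))
        return("weights must align with genes")
    TRUE
})

#' Construct a SignatureDef
#'
#' @param name signature name.
#' @param genes character vector of gene ids.
#' @param weights direction weights aligned with `genes`; default +1.
#' @return A [SignatureDef-class] object.
#' @export
#' @examples
#' signatureDef("tcell", c("CD3D", "CD3E", "CD2"))
signatureDef <- function(name, genes, weights = rep(1, length(genes))) {
    methods::new("SignatureDef", name = name, genes = as.character(genes),
                 weights = as.numeric(weights))
}

setMethod("show", "SignatureDef", function(object) {
    cat(sprintf("SignatureDef '%s': %d genes\n", object@name,
                length(object@genes)))
})
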