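#' Marker calls implied by a phenotype label
#'
#' Used by the simulator so generated cells carry marker columns consistent
#' with their generating phenotype; labels outside the default gate set get
#' all-zero markers.
#' @noRd
.markersForPhenotype <- function(phenotype, markers) {
    map <- list(
        tumor        = c("CK"),
        cytotoxic_T  = c("CD3", "CD8"),
        helper_T     = c("CD3"),
        Treg         = c("CD3", "FoxP3"),
        PD1_T        = c("CD3", "PD1"),
        B_cell       = c("CD20"),
        macrophage   = c("CD68"),
        NK           = c("CD56"))
    out <- matrix(0, nrow = length(phenotype), ncol = length(markers),
                  dimnames = list(NULL, markers))
    for (ph in unique(phenotype)) {
        pos <- intersect(map[[ph]], markers)
        if (length(pos))
            out[phenotype == ph, pos] <- 1
    }
    out
}

#' Simulate a two-type clustered cell pattern
#'
#' Draws a marked point pattern from a Thomas-style cluster process inside a
#' rectangular window: Poisson parents (a `sharedParentFraction` of them
#' common to both types, the rest type-exclusive so that each type's parent
#' intensity equals `parentIntensity` regardless of sharing), Poisson
#' offspring counts, isotropic Gaussian displacements, plus an independent
#' uniform Poisson background per type. Offspring landing outside the window
#' are discarded. Identical config and seed reproduce the identical table.
#'
#' @param config a [SimulationConfig-class].
#' @param typeNames length-2 character, phenotype labels for types A and B.
#' @return A [CellTable-class] with one sample (`sample_id = "sim1"`),
#'   phenotypes assigned and marker columns consistent with the labels.
#' @export
#' @examples
#' cfg <- simulationConfig(sharedParentFraction = 1, seed = 42)
#' simulateCellPattern(cfg)
simulateCellPattern <- function(config,
                                typeNames = c("tumor", "cytotoxic_T")) {
    stopifnot(methods::is(config, "SimulationConfig"))
    methods::validObject(config)
    stopifnot(length(typeNames) == 2)
    set.seed(config@seed)
    W <- config@windowWidthUm
    H <- config@windowHeightUm
    areaMm2 <- W * H / 1e6
    f <- config@sharedParentFraction

    rParents <- function(n) {
        cbind(x = stats::runif(n, 0, W), y = stats::runif(n, 0, H))
    }
    nShared <- stats::rpois(1, f * config@parentIntensity * areaMm2)
    nAonly <- stats::rpois(1, (1 - f) * config@parentIntensity * areaMm2)
    nBonly <- stats::rpois(1, (1 - f) * config@parentIntensity * areaMm2)
    shared <- rParents(nShared)
    parentsA <- rbind(shared, rParents(nAonly))
    parentsB <- rbind(shared, rParents(nBonly))

    spawn <- function(parents, meanOff) {
        if (!nrow(parents) || meanOff <= 0)
            return(matrix(numeric(0), ncol = 2,
                          dimnames = list(NULL, c("x", "y"))))
        nOff <- stats::rpois(nrow(parents), meanOff)
        idx <- rep(seq_len(nrow(parents)), nOff)
        n <- length(idx)
        cbind(x = parents[idx, "x"] + stats::rnorm(n, 0, config@offspringSdUm),
              y = parents[idx, "y"] + stats::rnorm(n, 0, config@offspringSdUm))
    }
    background <- function() {
        n <- stats::rpois(1, config@backgroundIntensityPerType * areaMm2)
        cbind(x = stats::runif(n, 0, W), y = stats::runif(n, 0, H))
    }
    ptsA <- rbind(spawn(parentsA, config@offspringMeanA), background())
    ptsB <- rbind(spawn(parentsB, config@offspringMeanB), background())
    inWin <- function(p) {
        p[p[, 1] >= 0 & p[, 1] <= W & p[, 2] >= 0 & p[, 2] <= H, ,
          drop = FALSE]
    }
    ptsA <- inWin(ptsA)
    ptsB <- inWin(ptsB)

    phenotype <- c(rep(typeNames[1], nrow(ptsA)),
                   rep(typeNames[2], nrow(ptsB)))
    xy <- rbind(ptsA, ptsB)
    markers <- markerPanel("combined")
    df <- data.frame(sample_id = rep("sim1", length(phenotype)),
                     cell_id = sprintf("c%06d", seq_along(phenotype)),
                     x_um = xy[, 1], y_um = xy[, 2],
                     stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(.markersForPhenotype(phenotype, markers)))
    df$phenotype <- phenotype
    CellTable(df, markers = markers)
}

#' Simulate standardized per-sample scores
#'
#' Convenience generator of z-scored independent normal features, the form
#' in which scores enter the simulated outcome models (so log-hazard
#' coefficients are per standard deviation).
#'
#' @param n number of samples.
#' @param scoreNames character vector of feature names.
#' @param seed integer seed.
#' @return data.frame with `sample_id` and one standardized column per name.
#' @export
simulateScores <- function(n, scoreNames = c("score1"), seed = 1L) {
    set.seed(as.integer(seed))
    out <- data.frame(sample_id = sprintf("s%04d", seq_len(n)))
    for (nm in scoreNames) {
        v <- stats::rnorm(n)
        out[[nm]] <- as.numeric(scale(v))
    }
    out
}

#' Simulate clinical outcomes tied to per-sample scores
#'
#' Survival times are drawn from the proportional-hazards model of an
#' [OutcomeModel-class] (Weibull baseline, exponential when shape is 1) and
#' administratively censored; radiological complete response (rCR) is
#' Bernoulli through a logistic link. ER status is drawn Bernoulli(0.55),
#' matching a mixed ER+/ER- metastatic cohort, so adjusted analyses have a
#' covariate to use.
#'
#' @param scores data.frame with `sample_id` and numeric score columns.
#' @param model an [OutcomeModel-class].
#' @return data.frame of clinical records: `patient_id`, `os_months`,
#'   `death_event`, `rcr`, `er_positive`, `sample_type`, `pair_id`.
#' @export
#' @examples
#' sc <- simulateScores(50, "treg_density", seed = 3)
#' simulateClinical(sc, outcomeModel(seed = 3))
simulateClinical <- function(scores, model) {
    stopifnot(methods::is(model, "OutcomeModel"))
    methods::validObject(model)
    usedNames <- union(names(model@logHazardCoefficients),
                       names(model@logisticCoefficients))
    unknown <- setdiff(usedNames, names(scores))
    if (length(unknown))
        stop("unknown score name(s) in coefficients: ",
             paste(unknown, collapse = ", "))
    for (nm in usedNames)
        if (anyNA(scores[[nm]]))
            stop("missing values in score '", nm, "'")
    n <- nrow(scores)
    set.seed(model@seed)

    lp <- function(coefs) {
        if (!length(coefs)) return(rep(0, n))
        as.numeric(as.matrix(scores[names(coefs)]) %*% coefs)
    }
    eta <- lp(model@logHazardCoefficients)
    u <- stats::runif(n)
    # inverse-CDF draw from S(t) = exp(-scale * t^shape * exp(eta))
    t <- (-log(u) / (model@baselineHazardScale * exp(eta)))^
        (1 / model@weibullShape)
    cens <- model@censoringTimeMonths
    osMonths <- pmin(t, cens)
    event <- as.integer(t <= cens)

    pRcr <- stats::plogis(model@logisticIntercept +
                          lp(model@logisticCoefficients))
    rcr <- stats::rbinom(n, 1, pRcr)
    er <- stats::rbinom(n, 1, 0.55)

    data.frame(patient_id = scores$sample_id,
               os_months = osMonths, death_event = event, rcr = rcr,
               er_positive = er,
               sample_type = rep("primary", n),
               pair_id = rep(NA_character_, n),
               stringsAsFactors = FALSE)
}

#' Simulate an expression matrix with signature-correlated latent structure
#'
#' Background genes are i.i.d. standard normal; genes belonging to a
#' signature additionally receive `effect * latent * weight`, where the
#' latent factor is one standard-normal draw per sample and signature.
#' Signature scores on the result therefore correlate with the latent
#' factor, with strength governed by the effect size.
#'
#' @param nGenes total number of genes; names are `gene_0001`, ... Signature
#'   genes must be a subset of this universe.
#' @param sampleIds character vector of sample ids.
#' @param signatures list of [SignatureDef-class] objects.
#' @param effectMap named numeric, latent effect size per signature name;
#'   signatures not named get effect 0.
#' @param seed integer seed.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `exprs`; `metadata(se)$latentFactors` is the signatures x samples
#'   matrix of generating factors and `metadata(se)$centered` is FALSE.
#' @export
#' @examples
#' sig <- signatureDef("tcell", c("gene_0001", "gene_0002"))
#' se <- simulateExpression(50, c("s1", "s2"), list(sig),
#'                          c(tcell = 2), seed = 9)
simulateExpression <- function(nGenes, sampleIds, signatures = list(),
                               effectMap = numeric(), seed = 1L) {
    stopifnot(nGenes >= 1, length(sampleIds) >= 1)
    if (anyDuplicated(sampleIds))
        stop("duplicate sample ids")
    genes <- sprintf("gene_%04d", seq_len(nGenes))
    if (anyDuplicated(genes))
        stop("duplicate gene names")
    set.seed(as.integer(seed))
    n <- length(sampleIds)
    mat <- matrix(stats::rnorm(nGenes * n), nrow = nGenes,
                  dimnames = list(genes, sampleIds))
    latents <- matrix(numeric(0), nrow = 0, ncol = n,
                      dimnames = list(NULL, sampleIds))
    for (sig in signatures) {
        stopifnot(methods::is(sig, "SignatureDef"))
        outside <- setdiff(sig@genes, genes)
        if (length(outside))
            stop("signature '", sig@name, "' has genes outside the ",
                 "generated universe: ", paste(outside, collapse = ", "))
        effect <- if (sig@name %in% names(effectMap))
            effectMap[[sig@name]] else 0
        l <- stats::rnorm(n)
        idx <- match(sig@genes, genes)
        mat[idx, ] <- mat[idx, ] +
            effect * outer(sig@weights, l)
        latents <- rbind(latents, matrix(l, nrow = 1, ncol = n))
        rownames(latents)[nrow(latents)] <- sig@name
    }
    SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = mat),
        metadata = list(centered = FALSE, latentFactors = latents))
}
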