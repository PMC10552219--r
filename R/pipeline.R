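.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full scoring and association pipeline
#'
#' Executes phenotype gating, spatial scoring, signature scoring and the
#' association screen on tabular inputs, writing a per-sample score table,
#' the association results, the dot-plot table, optional tertile
#' Kaplan-Meier tables and a JSON run manifest (package version, seed,
#' parameter hash and an MD5 content hash per output). Re-running with
#' identical inputs and seed reproduces byte-identical CSVs.
#'
#' @param config list (or YAML path, see [yaml::read_yaml]) with elements:
#'   `cells` (cell-table CSV path), `clinical` (clinical CSV path),
#'   optional `expression` (TSV) and `signatures` (GMT path), optional
#'   `rules` (phenotype-rule YAML), `pairs` (list of length-2 phenotype
#'   vectors for spatial scores), `square_size_um` (default 100),
#'   `r_max_um` (default 50), `radii_step_um` (default 1),
#'   `window_area_mm2` (default 0.36), and `plan` (screen plan, see
#'   [runAssociationScreen()]; `plan$km_variables` adds tertile KM
#'   tables).
#' @param outDir output directory, created if needed.
#' @param seed integer seed recorded in the manifest and applied before
#'   any stage.
#' @return invisibly, a list with the score table, association results
#'   and manifest.
#' @export
runPipeline <- function(config, outDir, seed = 1L) {
    if (is.character(config) && length(config) == 1)
        config <- yaml::read_yaml(config)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    set.seed(as.integer(seed))

    cells <- .stage("phenotype", {
        ct <- readCellTable(config$cells)
        if (!nrow(cellData(ct)))
            stop("empty cell table")
        rules <- if (!is.null(config$rules))
            readPhenotypeRules(config$rules) else defaultPhenotypeRules()
        assignPhenotypes(ct, rules)
    })

    scores <- .stage("spatial", {
        areaMm2 <- config$window_area_mm2 %||% 0.36
        ab <- summarizeAbundance(cells, areaMm2)
        wide <- stats::reshape(
            ab[, c("sample_id", "phenotype", "density_mm2")],
            idvar = "sample_id", timevar = "phenotype",
            direction = "wide")
        names(wide) <- sub("^density_mm2\\.", "density_", names(wide))
        pairs <- config$pairs %||%
            list(c("tumor", "cytotoxic_T"), c("tumor", "Treg"))
        sp <- spatialScoreTable(cells, pairs,
            squareSizeUm = config$square_size_um %||% 100,
            rMaxUm = config$r_max_um %||% 50,
            radiiStepUm = config$radii_step_um %||% 1)
        merge(wide, sp, by = "sample_id", all = TRUE)
    })

    if (!is.null(config$expression) && !is.null(config$signatures)) {
        scores <- .stage("signatures", {
            expr <- meanCenter(readExpressionMatrix(config$expression))
            sigs <- readGMT(config$signatures)
            sigScores <- scoreSignatures(expr, sigs)
            merge(scores, sigScores, by = "sample_id", all = TRUE)
        })
    }

    records <- .stage("associate", readClinicalTable(config$clinical))
    plan <- config$plan
    if (is.null(plan$variables))
        plan$variables <- setdiff(
            names(scores)[vapply(scores, is.numeric, logical(1))],
            "sample_id")
    results <- .stage("associate",
        runAssociationScreen(scores, records, plan))
    dot <- dotPlotTable(results)

    kmTables <- NULL
    if (length(plan$km_variables)) {
        kmTables <- .stage("associate", {
            merged <- merge(scores, records, by.x = "sample_id",
                            by.y = "patient_id")
            do.call(rbind, lapply(plan$km_variables, function(v) {
                grp <- tertileSplit(merged[[v]])
                km <- kmCurvesByGroup(merged, grp)
                cbind(variable = v, km$curves,
                      logrank_p = km$logrank_p)
            }))
        })
    }

    paths <- c(scores = file.path(outDir, "scores.csv"),
               associations = file.path(outDir, "associations.csv"),
               dotplot = file.path(outDir, "dotplot.csv"))
    writeScoreTable(scores, paths["scores"])
    writeScoreTable(results, paths["associations"])
    writeScoreTable(dot, paths["dotplot"])
    if (!is.null(kmTables)) {
        paths["km_curves"] <- file.path(outDir, "km_curves.csv")
        writeScoreTable(kmTables, paths["km_curves"])
    }

    cfgJson <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
    tmp <- tempfile()
    writeLines(cfgJson, tmp)
    manifest <- list(
        package = "spatialTME",
        version = as.character(utils::packageVersion("spatialTME")),
        seed = as.integer(seed),
        parameter_hash = unname(tools::md5sum(tmp)),
        outputs = lapply(seq_along(paths), function(i) {
            list(name = names(paths)[i], file = basename(paths[[i]]),
                 md5 = unname(tools::md5sum(paths[[i]])))
        }))
    unlink(tmp)
    manifestPath <- file.path(outDir, "manifest.json")
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         pretty = TRUE)
    invisible(list(scores = scores, results = results,
                   manifest = manifest))
}
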