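#' Per-unit Cox proportional-hazards association with overall survival
#'
#' Fits a Cox model (Efron tie handling) of overall survival on one
#' variable of interest, optionally adjusted for covariates, and reports
#' the hazard ratio per unit increase together with a likelihood-ratio
#' p-value: twice the log partial-likelihood difference between the models
#' with and without the variable, on 1 degree of freedom, both fitted on
#' the same complete cases.
#'
#' @param records data.frame with `os_months`, `death_event`, the variable
#'   and any covariates.
#' @param variable name of the column tested.
#' @param covariates character vector of adjustment columns.
#' @param subgroup label carried into the result (filtering happens
#'   upstream, see [runAssociationScreen()]).
#' @param standardize if TRUE the variable is z-scored first, so the
#'   estimate is per standard deviation.
#' @return one-row data.frame (an association result): `variable`,
#'   `endpoint`, `subgroup`, `covariates`, `estimate` (HR), `se_log`
#'   (standard error of the log estimate), `lr_p`, `bh_adjusted_p` (NA
#'   until [bhAdjust()] over a screen), `n`, `n_events`, `note`.
#' @export
coxPerUnit <- function(records, variable, covariates = character(),
                       subgroup = "all", standardize = FALSE) {
    cols <- c("os_months", "death_event", variable, covariates)
    missing <- setdiff(cols, names(records))
    if (length(missing))
        stop("missing column(s): ", paste(missing, collapse = ", "))
    d <- records[stats::complete.cases(records[cols]), cols, drop = FALSE]
    if (sum(d$death_event) == 0)
        stop("zero events")
    v <- d[[variable]]
    if (length(unique(v)) < 2)
        stop("constant variable: ", variable)
    if (standardize)
        d[[variable]] <- as.numeric(scale(v))
    rhs <- paste(c(sprintf("`%s`", variable),
                   sprintf("`%s`", covariates)), collapse = " + ")
    full <- .fitOrDiagnose(survival::coxph(
        stats::as.formula(paste("survival::Surv(os_months, death_event) ~",
                                rhs)),
        data = d, ties = "efron"), variable)
    if (length(covariates)) {
        red <- survival::coxph(stats::as.formula(
            paste("survival::Surv(os_months, death_event) ~",
                  paste(sprintf("`%s`", covariates), collapse = " + "))),
            data = d, ties = "efron")
        lrStat <- 2 * (full$loglik[2] - red$loglik[2])
    } else {
        lrStat <- 2 * diff(full$loglik)
    }
    # the tested variable is the first term in the formula
    beta <- unname(full$coefficients[1])
    se <- sqrt(diag(full$var))[1]
    data.frame(variable = variable, endpoint = "OS", subgroup = subgroup,
               covariates = paste(covariates, collapse = "+"),
               estimate = exp(beta), se_log = se,
               lr_p = stats::pchisq(lrStat, df = 1, lower.tail = FALSE),
               bh_adjusted_p = NA_real_, n = nrow(d),
               n_events = sum(d$death_event), note = NA_character_,
               stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.fitOrDiagnose <- function(expr, variable) {
    fit <- withCallingHandlers(expr,
        warning = function(w) {
            if (grepl("did not converge|infinite", conditionMessage(w)))
                stop("model for '", variable, "' did not converge: ",
                     conditionMessage(w), call. = FALSE)
            invokeRestart("muffleWarning")
        })
    if (any(!is.finite(stats::coef(fit))))
        stop("model for '", variable, "' did not converge: ",
             "non-finite coefficient")
    fit
}

#' Per-unit logistic association with radiological complete response
#'
#' Maximum-likelihood logistic regression of a binary endpoint on one
#' variable of interest, optionally covariate-adjusted; the odds ratio per
#' unit increase is reported with a likelihood-ratio (deviance) p-value on
#' 1 degree of freedom. Complete separation is raised as an error.
#'
#' @param records data.frame containing the outcome, variable, covariates.
#' @param variable name of the column tested.
#' @param covariates adjustment columns.
#' @param outcome binary outcome column (default `"rcr"`).
#' @inheritParams coxPerUnit
#' @return one-row data.frame as in [coxPerUnit()], with `endpoint =
#'   "rCR"`, `estimate` an odds ratio and `n_events` the responder count.
#' @export
logisticPerUnit <- function(records, variable, covariates = character(),
                            outcome = "rcr", subgroup = "all",
                            standardize = FALSE) {
    cols <- c(outcome, variable, covariates)
    missing <- setdiff(cols, names(records))
    if (length(missing))
        stop("missing column(s): ", paste(missing, collapse = ", "))
    d <- records[stats::complete.cases(records[cols]), cols, drop = FALSE]
    y <- d[[outcome]]
    if (length(unique(y)) < 2)
        stop("single class: outcome '", outcome,
             "' has no variation in this subgroup")
    v <- d[[variable]]
    if (length(unique(v)) < 2)
        stop("constant variable: ", variable)
    if (standardize)
        d[[variable]] <- as.numeric(scale(v))
    rhs <- paste(sprintf("`%s`", c(variable, covariates)), collapse = " + ")
    sep <- FALSE
    full <- withCallingHandlers(
        stats::glm(stats::as.formula(paste(outcome, "~", rhs)),
                   data = d, family = stats::binomial()),
        warning = function(w) {
            if (grepl("fitted probabilities numerically 0 or 1",
                      conditionMessage(w)))
                sep <<- TRUE
            invokeRestart("muffleWarning")
        })
    if (sep && (full$deviance < 1e-6 ||
                any(abs(stats::coef(full)) > 15)))
        stop("complete separation for variable '", variable, "'")
    red <- stats::glm(stats::as.formula(paste(outcome, "~",
        if (length(covariates))
            paste(sprintf("`%s`", covariates), collapse = " + ")
        else "1")), data = d, family = stats::binomial())
    lrStat <- red$deviance - full$deviance
    beta <- unname(stats::coef(full)[2])  # after the intercept
    se <- unname(sqrt(diag(stats::vcov(full)))[2])
    data.frame(variable = variable, endpoint = "rCR", subgroup = subgroup,
               covariates = paste(covariates, collapse = "+"),
               estimate = exp(beta), se_log = se,
               lr_p = stats::pchisq(lrStat, df = 1, lower.tail = FALSE),
               bh_adjusted_p = NA_real_, n = nrow(d),
               n_events = sum(y), note = NA_character_,
               stringsAsFactors = FALSE)
}

#' Median follow-up by the reverse Kaplan-Meier method
#'
#' Product-limit estimate of follow-up time with the censoring indicator
#' as the event (deaths are treated as censored); the median of that curve
#' is the reported follow-up.
#'
#' @param records data.frame with `os_months` and `death_event`.
#' @return numeric median follow-up in months; `NA` with attribute
#'   `not_reached = TRUE` when the reversed curve never crosses 0.5.
#' @export
reverseKMMedian <- function(records) {
    stopifnot(nrow(records) >= 1)
    fit <- survival::survfit(
        survival::Surv(os_months, 1 - death_event) ~ 1, data = records)
    med <- unname(summary(fit)$table["median"])
    if (is.na(med)) {
        out <- NA_real_
        attr(out, "not_reached") <- TRUE
        return(out)
    }
    med
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment across a family of p-values;
#' `NA` entries pass through.
#'
#' @param p numeric p-values in [0, 1].
#' @return adjusted p-values in the original order.
#' @export
bhAdjust <- function(p) {
    bad <- !is.na(p) & (p < 0 | p > 1)
    if (any(bad))
        stop("p-values outside [0, 1] at position(s): ",
             paste(which(bad), collapse = ", "))
    stats::p.adjust(p, method = "BH")
}

#' Split values into tertile groups
#'
#' Groups by the empirical 1/3 and 2/3 quantiles; values tied with a cut
#' point go to the lower group. With all values identical every sample
#' lands in T1 (with a warning).
#'
#' @param values numeric; NA allowed (returned as NA group).
#' @return factor with levels T1, T2, T3.
#' @export
tertileSplit <- function(values) {
    v <- values[!is.na(values)]
    if (length(v) < 3)
        stop("tertile split needs >= 3 non-missing values")
    q <- stats::quantile(v, c(1 / 3, 2 / 3), names = FALSE, type = 7)
    out <- rep(NA_character_, length(values))
    out[!is.na(values)] <- ifelse(v <= q[1], "T1",
                                  ifelse(v <= q[2], "T2", "T3"))
    if (q[1] == q[2] && length(unique(v)) == 1)
        warning("all values identical; every sample assigned to T1")
    factor(out, levels = c("T1", "T2", "T3"))
}

#' Kaplan-Meier curves by group with a log-rank test
#'
#' @param records data.frame with `os_months`, `death_event`.
#' @param groups factor/character grouping aligned with `records` rows.
#' @return list: `curves` (data.frame `group`, `time`, `n_risk`,
#'   `n_event`, `surv`), `logrank_p` (NA with a single group).
#' @export
kmCurvesByGroup <- function(records, groups) {
    stopifnot(nrow(records) == length(groups))
    keep <- !is.na(groups)
    d <- records[keep, , drop = FALSE]
    g <- droplevels(factor(groups[keep]))
    if (!nlevels(g))
        stop("no non-missing groups")
    fit <- survival::survfit(
        survival::Surv(os_months, death_event) ~ g, data = d)
    if (nlevels(g) == 1) {
        curves <- data.frame(group = levels(g), time = fit$time,
                             n_risk = fit$n.risk, n_event = fit$n.event,
                             surv = fit$surv)
        return(list(curves = curves, logrank_p = NA_real_))
    }
    strat <- rep(sub("^g=", "", names(fit$strata)), fit$strata)
    curves <- data.frame(group = strat, time = fit$time,
                         n_risk = fit$n.risk, n_event = fit$n.event,
                         surv = fit$surv)
    sd <- survival::survdiff(
        survival::Surv(os_months, death_event) ~ g, data = d)
    p <- stats::pchisq(sd$chisq, df = nlevels(g) - 1, lower.tail = FALSE)
    list(curves = curves, logrank_p = p)
}

# Exact two-sided signed-rank p by sign enumeration (average ranks on
# tied |differences|); used for small paired contrasts where the exact
# null distribution is enumerable.
.signedRankExactP <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    if (!n) return(1)
    r <- rank(abs(d))
    v <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vs <- as.numeric(signs %*% r)
    pLow <- mean(vs <= v)
    pHigh <- mean(vs >= v)
    min(1, 2 * min(pLow, pHigh))
}

#' Primary-versus-metastasis contrast per feature
#'
#' Compares each feature between metastatic and primary samples. Unpaired
#' mode uses a Mann-Whitney U test and reports the mean difference
#' (metastasis minus primary). Paired mode uses a Wilcoxon signed-rank
#' test on within-pair differences; for 12 or fewer informative pairs the
#' p-value is exact by sign enumeration, otherwise the normal
#' approximation is used.
#'
#' @param scores data.frame with `sample_id`, feature columns,
#'   `sample_type` (`"primary"`/`"metastasis"`) and, for paired mode,
#'   `pair_id`.
#' @param features feature column names; default all numeric columns.
#' @param paired logical.
#' @return data.frame: `feature`, `n`, `mean_difference`, `p`, `method`,
#'   `note` (reason when a feature is not testable).
#' @export
primaryMetContrast <- function(scores, features = NULL, paired = FALSE) {
    stopifnot("sample_type" %in% names(scores))
    if (!all(c("primary", "metastasis") %in% scores$sample_type))
        stop("both sample types must be present")
    if (is.null(features))
        features <- setdiff(names(scores)[vapply(scores, is.numeric,
                                                 logical(1))],
                            c("sample_id", "pair_id"))
    rows <- lapply(features, function(f) {
        prim <- scores[scores$sample_type == "primary", ]
        met <- scores[scores$sample_type == "metastasis", ]
        if (paired) {
            if (!"pair_id" %in% names(scores))
                stop("paired mode needs a pair_id column")
            m <- merge(prim[!is.na(prim$pair_id), c("pair_id", f)],
                       met[!is.na(met$pair_id), c("pair_id", f)],
                       by = "pair_id", suffixes = c("_prim", "_met"))
            m <- m[stats::complete.cases(m), , drop = FALSE]
            if (!nrow(m))
                stop("no complete pairs for feature '", f, "'")
            d <- m[[paste0(f, "_met")]] - m[[paste0(f, "_prim")]]
            nz <- d[d != 0]
            p <- if (length(nz) == 0) 1
                else if (length(nz) <= 12) .signedRankExactP(d)
                else suppressWarnings(
                    stats::wilcox.test(m[[paste0(f, "_met")]],
                                       m[[paste0(f, "_prim")]],
                                       paired = TRUE, exact = FALSE)$p.value)
            data.frame(feature = f, n = nrow(m), mean_difference = mean(d),
                       p = p, method = "wilcoxon_signed_rank",
                       note = NA_character_, stringsAsFactors = FALSE)
        } else {
            x <- met[[f]][!is.na(met[[f]])]
            y <- prim[[f]][!is.na(prim[[f]])]
            if (!length(x) || !length(y))
                return(data.frame(feature = f, n = length(x) + length(y),
                                  mean_difference = NA_real_, p = NA_real_,
                                  method = "mann_whitney_u",
                                  note = "feature missing in one group",
                                  stringsAsFactors = FALSE))
            p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
            data.frame(feature = f, n = length(x) + length(y),
                       mean_difference = mean(x) - mean(y), p = p,
                       method = "mann_whitney_u", note = NA_character_,
                       stringsAsFactors = FALSE)
        }
    })
    do.call(rbind, rows)
}

#' Spearman correlation matrix with hierarchical clustering
#'
#' Pairwise-complete Spearman correlations between features, with
#' per-pair p-values, star annotation tiers (`*` p < 0.05, `**` p < 0.01,
#' `***` p < 0.001) and an average-linkage clustering on distance 1 - rho
#' giving the display leaf order. Features with fewer than 3 non-missing
#' values are dropped with a warning.
#'
#' @param scores data.frame; numeric columns are the features.
#' @param features feature names; default all numeric columns.
#' @return list: `rho`, `p`, `stars` (matrices), `order` (leaf order of
#'   feature names), `hclust`.
#' @export
correlationClusterMap <- function(scores, features = NULL) {
    if (is.null(features))
        features <- names(scores)[vapply(scores, is.numeric, logical(1))]
    if (length(features) < 2)
        stop("need at least 2 features")
    ok <- vapply(features, function(f) sum(!is.na(scores[[f]])) >= 3,
                 logical(1))
    if (any(!ok)) {
        warning("dropping feature(s) with < 3 non-missing values: ",
                paste(features[!ok], collapse = ", "))
        features <- features[ok]
    }
    if (length(features) < 2)
        stop("fewer than 2 usable features remain")
    m <- as.matrix(scores[features])
    if (nrow(m) < 3)
        stop("need at least 3 samples")
    rho <- stats::cor(m, method = "spearman",
                      use = "pairwise.complete.obs")
    k <- length(features)
    p <- matrix(NA_real_, k, k, dimnames = dimnames(rho))
    diag(p) <- 0
    for (i in seq_len(k - 1)) {
        for (j in (i + 1):k) {
            cc <- stats::complete.cases(m[, c(i, j)])
            if (sum(cc) >= 3) {
                pv <- suppressWarnings(stats::cor.test(
                    m[cc, i], m[cc, j], method = "spearman"))$p.value
                p[i, j] <- p[j, i] <- pv
            }
        }
    }
    stars <- matrix("", k, k, dimnames = dimnames(rho))
    stars[!is.na(p) & p < 0.05] <- "*"
    stars[!is.na(p) & p < 0.01] <- "**"
    stars[!is.na(p) & p < 0.001] <- "***"
    dmat <- 1 - rho
    dmat[is.na(dmat)] <- 1
    hc <- stats::hclust(stats::as.dist(dmat), method = "average")
    list(rho = rho, p = p, stars = stars,
         order = features[hc$order], hclust = hc)
}

#' Rank-based group comparison with automatic dispatch
#'
#' Mann-Whitney U for two groups, Kruskal-Wallis for more than two; when
#' the second argument is itself continuous (numeric), a Spearman
#' correlation test is used instead.
#'
#' @param values numeric response.
#' @param grouping factor/character groups, or a numeric covariate.
#' @return list: `method`, `statistic`, `p`.
#' @export
groupComparisons <- function(values, grouping) {
    stopifnot(length(values) == length(grouping))
    if (is.numeric(grouping)) {
        ct <- suppressWarnings(stats::cor.test(values, grouping,
                                               method = "spearman"))
        return(list(method = "spearman", statistic = unname(ct$estimate),
                    p = ct$p.value))
    }
    g <- factor(grouping)
    sizes <- table(g)
    if (any(sizes == 0) || nlevels(g) < 2)
        stop("need >= 2 non-empty groups (empty group present)")
    if (nlevels(g) == 2) {
        sp <- split(values, g)
        ht <- suppressWarnings(stats::wilcox.test(sp[[1]], sp[[2]]))
        list(method = "mann_whitney_u", statistic = unname(ht$statistic),
             p = ht$p.value)
    } else {
        ht <- stats::kruskal.test(values, g)
        list(method = "kruskal_wallis", statistic = unname(ht$statistic),
             p = ht$p.value)
    }
}

.subgroupFilter <- function(d, subgroup) {
    switch(subgroup,
        "all" = d,
        "ER+" = d[!is.na(d$er_positive) & d$er_positive == 1, ],
        "ER-" = d[!is.na(d$er_positive) & d$er_positive == 0, ],
        "rCR" = d[!is.na(d$rcr) & d$rcr == 1, ],
        "no-rCR" = d[!is.na(d$rcr) & d$rcr == 0, ],
        "primary" = d[!is.na(d$sample_type) & d$sample_type == "primary", ],
        "metastasis" = d[!is.na(d$sample_type) &
                         d$sample_type == "metastasis", ],
        stop("unknown subgroup: ", subgroup))
}

#' Run a full association screen
#'
#' Executes every (variable, endpoint, subgroup, covariate-set) cell of a
#' screen plan: Cox models for overall survival, logistic models for rCR,
#' each reporting a per-unit estimate with a likelihood-ratio p-value.
#' Cells that cannot be estimated (zero events, single outcome class,
#' constant variable, separation) are flagged `not estimable` and kept,
#' never dropped. Benjamini-Hochberg adjustment is applied across the
#' whole screen family, and each result is assigned the dot-plot
#' significance tier (`p<0.05`, `0.05<=p<0.10`, `p>=0.10`).
#'
#' @param scores data.frame with `sample_id` and feature columns.
#' @param records clinical data.frame (`patient_id`, `os_months`,
#'   `death_event`, `rcr`, `er_positive`, `sample_type`, ...).
#' @param plan list with `variables` (character), `endpoints` (subset of
#'   `c("OS", "rCR")`), `subgroups` (subset of `c("all", "ER+", "ER-",
#'   "rCR", "no-rCR", "primary", "metastasis")`), `covariateSets` (named
#'   list of character vectors; e.g. `list(unadjusted = character(),
#'   adjusted = c("er_positive", "rcr"))`).
#' @param standardize passed through to the per-unit fits.
#' @return data.frame of association results with `bh_adjusted_p` and
#'   `tier` filled in.
#' @export
runAssociationScreen <- function(scores, records, plan,
                                 standardize = FALSE) {
    stopifnot(is.list(plan), length(plan$variables) >= 1)
    endpoints <- plan$endpoints %||% c("OS", "rCR")
    subgroups <- plan$subgroups %||% "all"
    covSets <- plan$covariateSets %||% list(unadjusted = character())
    d <- merge(scores, records, by.x = "sample_id", by.y = "patient_id")
    rows <- list()
    for (v in plan$variables) {
        for (ep in endpoints) {
            for (sg in subgroups) {
                dd <- .subgroupFilter(d, sg)
                for (csName in names(covSets)) {
                    covs <- covSets[[csName]]
                    # outcome cannot adjust for itself; rCR subgroups
                    # cannot adjust for rCR either
                    if (ep == "rCR" || sg %in% c("rCR", "no-rCR"))
                        covs <- setdiff(covs, "rcr")
                    if (sg %in% c("ER+", "ER-"))
                        covs <- setdiff(covs, "er_positive")
                    res <- tryCatch({
                        if (ep == "OS")
                            coxPerUnit(dd, v, covs, subgroup = sg,
                                       standardize = standardize)
                        else
                            logisticPerUnit(dd, v, covs, subgroup = sg,
                                            standardize = standardize)
                    }, error = function(e) {
                        data.frame(variable = v, endpoint = ep,
                                   subgroup = sg,
                                   covariates = paste(covs, collapse = "+"),
                                   estimate = NA_real_, se_log = NA_real_,
                                   lr_p = NA_real_,
                                   bh_adjusted_p = NA_real_,
                                   n = nrow(dd), n_events = NA_integer_,
                                   note = paste("not estimable:",
                                                conditionMessage(e)),
                                   stringsAsFactors = FALSE)
                    })
                    res$adjustment <- csName
                    rows[[length(rows) + 1]] <- res
                }
            }
        }
    }
    out <- do.call(rbind, rows)
    out$bh_adjusted_p <- bhAdjust(out$lr_p)
    out$tier <- cut(out$lr_p, breaks = c(-Inf, 0.05, 0.10, Inf),
                    labels = c("p<0.05", "0.05<=p<0.10", "p>=0.10"),
                    right = FALSE)
    out$tier <- as.character(out$tier)
    out
}

#' Long-format dot-plot table from screen results
#'
#' Adds the display encoding used for association dot plots: direction
#' (estimate above/below 1), dot size (larger for smaller p) and the
#' background tier color (white p < 0.05, light gray 0.05-0.10, gray
#' otherwise).
#'
#' @param results data.frame from [runAssociationScreen()].
#' @return data.frame with `direction`, `dot_size`, `background` added.
#' @export
dotPlotTable <- function(results) {
    results$direction <- ifelse(is.na(results$estimate), NA_character_,
                                ifelse(results$estimate >= 1,
                                       "unfavorable", "favorable"))
    results$dot_size <- ifelse(is.na(results$lr_p), NA_real_,
                               pmin(3, -log10(pmax(results$lr_p, 1e-10))))
    results$background <- ifelse(is.na(results$tier), NA_character_,
        c("p<0.05" = "white", "0.05<=p<0.10" = "lightgray",
          "p>=0.10" = "gray")[results$tier])
    results
}
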