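toySurvival <- function() {
    # six subjects, tied event times, binary covariate
    data.frame(os_months = c(1, 1, 2, 3, 4, 5),
               death_event = c(1, 1, 1, 0, 1, 1),
               x = c(1, 0, 1, 1, 0, 0))
}

test_that("Cox per-unit estimate matches the Efron partial-likelihood grid oracle", {
    d <- toySurvival()
    fit <- coxPerUnit(d, "x")
    oracle <- gridMaxEfron(d$os_months, d$death_event, d$x)
    expect_lt(abs(log(fit$estimate) - oracle), 1e-4)
    expect_identical(fit$n_events, 5)
    # second configuration with heavier ties
    d2 <- data.frame(os_months = c(2, 2, 2, 5, 5, 7, 9, 9),
                     death_event = c(1, 1, 0, 1, 1, 1, 0, 1),
                     x = c(0.5, -1, 2, 0, 1, -0.5, 1.5, 0))
    oracle2 <- gridMaxEfron(d2$os_months, d2$death_event, d2$x)
    expect_lt(abs(log(coxPerUnit(d2, "x")$estimate) - oracle2), 1e-4)
})

test_that("Cox preconditions are enforced", {
    d <- toySurvival()
    d$death_event <- 0
    expect_error(coxPerUnit(d, "x"), "zero events")
    d2 <- toySurvival()
    d2$x <- 1
    expect_error(coxPerUnit(d2, "x"), "constant variable")
    expect_error(coxPerUnit(toySurvival(), "nope"), "missing column")
})

test_that("logistic per-unit estimates odds ratios with LR p-values", {
    # balanced 2x2 table: no association
    d <- data.frame(rcr = rep(c(1, 0), each = 20),
                    x = rep(c(1, 0, 1, 0), each = 10))
    expect_equal(logisticPerUnit(d, "x")$estimate, 1, tolerance = 1e-8)
    # (20,10,10,20): OR = 20*20 / (10*10) = 4
    d2 <- data.frame(rcr = rep(c(1, 0), each = 30),
                     x = c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20)))
    expect_equal(logisticPerUnit(d2, "x")$estimate, 4, tolerance = 1e-6)
    # single outcome class
    d3 <- data.frame(rcr = 1, x = rnorm(10))
    expect_error(logisticPerUnit(d3, "x"), "single class")
    # complete separation is flagged
    d4 <- data.frame(rcr = rep(c(0, 1), each = 10),
                     x = c(rnorm(10, -5), rnorm(10, 5)))
    expect_error(logisticPerUnit(d4, "x"), "separation")
})

test_that("reverse Kaplan-Meier median follow-up matches hand computation", {
    # all alive, last contact at 60 months
    allAlive <- data.frame(os_months = rep(60, 5), death_event = 0)
    expect_equal(as.numeric(reverseKMMedian(allAlive)), 60)
    # all dead: the reversed curve never drops
    allDead <- data.frame(os_months = c(10, 20, 30), death_event = 1)
    out <- reverseKMMedian(allDead)
    expect_true(is.na(out))
    expect_true(attr(out, "not_reached"))
    # mixed 8-record product-limit calculation done by hand:
    # reversed events at 20, 40, 60 with risk sets 7, 5, 3 give
    # S = 6/7, then 24/35, then 16/35 < 0.5 at t = 60
    mixed <- data.frame(os_months = c(10, 20, 30, 40, 50, 60, 70, 80),
                        death_event = c(1, 0, 1, 0, 1, 0, 0, 0))
    expect_equal(as.numeric(reverseKMMedian(mixed)), 60)
})

test_that("BH adjustment reproduces the step-up computed by hand", {
    # by hand: m=3; sorted p (.01,.02,.03) -> min_j>=i m p_j / j all 0.03
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bhAdjust(0.2), 0.2)
    expect_equal(bhAdjust(rep(0.04, 5)), rep(0.04, 5))
    expect_error(bhAdjust(c(0.5, 1.2)), "outside")
    # monotone and order preserving
    p <- c(0.001, 0.5, 0.03, 0.2, 0.0004)
    adj <- bhAdjust(p)
    expect_true(all(adj >= p))
    expect_identical(order(adj[order(p)]), seq_along(p))
})

test_that("tertile splits partition values with ties to the lower group", {
    expect_equal(as.integer(table(tertileSplit(1:9))), c(3L, 3L, 3L))
    sizes <- table(tertileSplit(1:10))
    expect_lte(max(sizes) - min(sizes), 1L)
    expect_identical(sum(sizes), 10L)
    expect_warning(allT1 <- tertileSplit(rep(2, 6)), "identical")
    expect_identical(as.integer(table(allT1)), c(6L, 0L, 0L))
    expect_error(tertileSplit(c(1, 2)), ">= 3")
    withNA <- tertileSplit(c(1:6, NA))
    expect_true(is.na(withNA[7]))
    expect_identical(sum(!is.na(withNA)), 6L)
})

test_that("KM curves and log-rank behave at the exchangeable and separated extremes", {
    d <- data.frame(os_months = c(5, 10, 15, 20), death_event = c(1, 0, 1, 1))
    dup <- rbind(d, d)
    km <- kmCurvesByGroup(dup, rep(c("g1", "g2"), each = 4))
    expect_gt(km$logrank_p, 0.99)  # identical groups
    # extreme separation at n = 20 per group
    sep <- data.frame(os_months = rep(c(1, 10), each = 20),
                      death_event = 1)
    kmSep <- kmCurvesByGroup(sep, rep(c("early", "late"), each = 20))
    expect_lt(kmSep$logrank_p, 0.01)
    # product-limit curve is 1 before the first event
    d2 <- data.frame(os_months = c(2, 5, 8), death_event = c(0, 1, 1))
    km2 <- kmCurvesByGroup(d2, rep("g", 3))
    expect_equal(km2$curves$surv[km2$curves$time == 2], 1)
    expect_true(is.na(km2$logrank_p))  # single group: no test
})

test_that("primary-metastasis contrasts match exact paired enumeration", {
    sc <- data.frame(sample_id = paste0("s", 1:16),
                     f = c(1:8, 1:8 + 10),
                     sample_type = rep(c("primary", "metastasis"), each = 8),
                     pair_id = rep(paste0("p", 1:8), 2))
    res <- primaryMetContrast(sc, "f", paired = TRUE)
    expect_equal(res$mean_difference, 10)
    expect_equal(res$p, 2 * (1 / 2)^8)  # exact sign enumeration
    # identical pairs: difference 0, p = 1
    same <- sc
    same$f <- rep(1:8, 2)
    resSame <- primaryMetContrast(same, "f", paired = TRUE)
    expect_equal(resSame$mean_difference, 0)
    expect_equal(resSame$p, 1)
    # no complete pairs in paired mode
    broken <- sc
    broken$pair_id[broken$sample_type == "metastasis"] <- NA
    expect_error(primaryMetContrast(broken, "f", paired = TRUE),
                 "no complete pairs")
    # unpaired mode flags a feature absent from one group
    sc$g <- ifelse(sc$sample_type == "metastasis", NA, 1)
    resG <- primaryMetContrast(sc, "g")
    expect_true(is.na(resG$p))
    expect_match(resG$note, "missing")
})

test_that("correlation maps recover duplicates, negations and null structure", {
    set.seed(9)
    sc <- data.frame(sample_id = paste0("s", 1:30), a = rnorm(30))
    sc$b <- sc$a                     # duplicate
    sc$c <- -sc$a                    # negation
    suppressWarnings(cm <- correlationClusterMap(sc, c("a", "b", "c")))
    expect_equal(cm$rho["a", "b"], 1)
    expect_equal(cm$rho["a", "c"], -1)
    # duplicated features cluster adjacent
    ord <- match(c("a", "b"), cm$order)
    expect_equal(abs(diff(ord)), 1)
    # feature with < 3 non-missing values is dropped with a warning
    sc$d <- c(1, 2, rep(NA, 28))
    expect_warning(correlationClusterMap(sc, c("a", "b", "d")), "dropping")
    # independent features: small correlations almost everywhere
    set.seed(10)
    nul <- as.data.frame(matrix(rnorm(200 * 10), ncol = 10))
    cmN <- correlationClusterMap(nul)
    off <- abs(cmN$rho[upper.tri(cmN$rho)])
    expect_gte(mean(off < 0.2), 0.95)
})

test_that("group comparisons dispatch by grouping structure", {
    x <- rnorm(60)
    dup <- groupComparisons(c(x[1:30], x[1:30]),
                            rep(c("g1", "g2"), each = 30))
    expect_identical(dup$method, "mann_whitney_u")
    expect_gt(dup$p, 0.9)
    three <- groupComparisons(rnorm(30), rep(c("a", "b", "c"), 10))
    expect_identical(three$method, "kruskal_wallis")
    set.seed(11)
    shifted <- groupComparisons(c(rnorm(30), rnorm(30, 3)),
                                rep(c("lo", "hi"), each = 30))
    expect_lt(shifted$p, 0.01)
    cont <- groupComparisons(rnorm(20), rnorm(20))
    expect_identical(cont$method, "spearman")
    g <- factor(rep("a", 10), levels = c("a", "b"))
    expect_error(groupComparisons(rnorm(10), g), "empty group")
})

test_that("the association screen runs every plan cell and flags the rest", {
    sc <- simulateScores(120, c("v1", "v2"), seed = 15)
    clin <- simulateClinical(sc, outcomeModel(seed = 15))
    plan1 <- list(variables = "v1", endpoints = "OS", subgroups = "all",
                  covariateSets = list(unadjusted = character()))
    res1 <- runAssociationScreen(sc, clin, plan1)
    expect_identical(nrow(res1), 1L)
    # an all-censored subgroup is kept and flagged, never dropped
    clin2 <- clin
    clin2$death_event[clin2$er_positive == 1] <- 0
    clin2$os_months[clin2$er_positive == 1] <- 200
    plan2 <- list(variables = "v1", endpoints = "OS",
                  subgroups = c("all", "ER+"),
                  covariateSets = list(unadjusted = character()))
    res2 <- runAssociationScreen(sc, clin2, plan2)
    flagged <- res2[res2$subgroup == "ER+", ]
    expect_match(flagged$note, "not estimable")
    expect_identical(nrow(res2), 2L)
    # BH column is the screen-family adjustment of the raw column
    expect_equal(res2$bh_adjusted_p, bhAdjust(res2$lr_p))
})

test_that("a null screen is calibrated: ~5% raw and ~0 BH-significant", {
    nVar <- 100
    sc <- simulateScores(200, sprintf("v%03d", 1:nVar), seed = 19)
    clin <- simulateClinical(sc, outcomeModel(seed = 19))
    plan <- list(variables = sprintf("v%03d", 1:nVar), endpoints = "OS",
                 subgroups = "all",
                 covariateSets = list(unadjusted = character()))
    res <- runAssociationScreen(sc, clin, plan)
    expect_identical(nrow(res), as.integer(nVar))
    nRaw <- sum(res$lr_p < 0.05)
    expect_gte(nRaw, 1L)
    expect_lte(nRaw, 12L)
    expect_lte(sum(res$bh_adjusted_p < 0.05), 1L)
})

test_that("dot-plot export mirrors the tier and direction encoding", {
    sc <- simulateScores(80, "v", seed = 23)
    clin <- simulateClinical(sc, outcomeModel(seed = 23))
    res <- runAssociationScreen(sc, clin,
        list(variables = "v", endpoints = c("OS", "rCR"),
             subgroups = "all",
             covariateSets = list(unadjusted = character())))
    dot <- dotPlotTable(res)
    expect_true(all(dot$background[dot$tier == "p<0.05"] == "white",
                    na.rm = TRUE))
    expect_true(all(dot$background[dot$tier == "p>=0.10"] == "gray",
                    na.rm = TRUE))
    expect_true(all(dot$direction %in% c("favorable", "unfavorable", NA)))
})
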