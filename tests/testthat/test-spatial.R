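cellsFromDf <- function(df) CellTable(df)

simplePattern <- function(x, y, phenotype) {
    data.frame(sample_id = "s", cell_id = sprintf("c%03d", seq_along(x)),
               x_um = x, y_um = y, CD3 = 0L, phenotype = phenotype,
               stringsAsFactors = FALSE)
}

test_that("quadrat binning follows the half-open grid convention", {
    df <- simplePattern(c(0, 200, 150, 100), c(0, 200, 50, 150),
                        c("A", "A", "B", "B"))
    q <- quadratCounts(cellsFromDf(df), "A", "B", 100)
    # bounding box [0,200] on both axes: indices 0,1,2 -> 3 bins per axis
    expect_identical(dim(q@countsA), c(3L, 3L))
    # cell at (150, 50): x index 1, y index 0 -> row 1, column 2
    expect_identical(q@countsB[1, 2], 1L)
    # boundary cell at x = 100 goes to the higher-index square (half-open)
    expect_identical(q@countsB[2, 2], 1L)
    expect_identical(q@countsB[2, 1], 0L)
    expect_identical(sum(q@countsB), 2L)
    expect_identical(sum(q@countsA), 2L)
    expect_error(quadratCounts(cellsFromDf(df[0, ]), "A", "B"), "empty")
})

test_that("a 200 um span tiles into a 2 x 2 grid", {
    df <- simplePattern(c(0, 199, 0, 199), c(0, 199, 199, 0),
                        c("A", "A", "B", "B"))
    q <- quadratCounts(cellsFromDf(df), "A", "B", 100)
    expect_identical(dim(q@countsA), c(2L, 2L))
})

test_that("Morisita-Horn matches its closed form and handles edge cases", {
    expect_equal(morisitaHorn(c(2, 1), c(1, 2)), 0.8)
    expect_equal(morisitaHorn(c(2, 0), c(0, 2)), 0)
    expect_equal(morisitaHorn(c(3, 1, 4), c(3, 1, 4)), 1)
    expect_error(morisitaHorn(c(1, 2), c(1, 2, 3)), "mismatched")
    out <- morisitaHorn(c(0, 0), c(1, 2))
    expect_true(is.na(out))
    expect_match(attr(out, "reason"), "absent")
})

test_that("Morisita-Horn is symmetric, bounded and exact vs brute force", {
    for (i in 1:40) {
        df <- randomPattern(50, seed = 100 + i)
        ct <- cellsFromDf(df)
        okA <- any(df$phenotype == "A")
        okB <- any(df$phenotype == "B")
        if (!okA || !okB) next
        q <- quadratCounts(ct, "A", "B", 100)
        qr <- quadratCounts(ct, "B", "A", 100)
        mh <- as.numeric(morisitaHorn(q))
        expect_equal(mh, as.numeric(morisitaHorn(qr)))  # symmetry
        expect_gte(mh, 0)
        expect_lte(mh, 1 + 1e-12)
        expect_equal(mh, bruteMH(df, "A", "B"))          # oracle
        self <- quadratCounts(ct, "A", "A", 100)
        expect_equal(as.numeric(morisitaHorn(self)), 1)  # MH(A, A) = 1
    }
})

test_that("G(r) matches the exhaustive nearest-neighbor oracle", {
    # hand-checkable configuration
    df <- simplePattern(c(0, 3, 10), c(0, 0, 0), c("A", "B", "B"))
    g <- gFunction(cellsFromDf(df), "A", "B", radii = 0:10)
    expect_equal(gValues(g)[gRadii(g) == 5], 1)
    expect_equal(gValues(g)[gRadii(g) == 2], 0)
    # two reference cells at nearest distances 1 and 9
    df2 <- simplePattern(c(0, 20, 1, 29), c(0, 0, 0, 0),
                         c("A", "A", "B", "B"))
    g2 <- gFunction(cellsFromDf(df2), "A", "B", radii = 0:10)
    expect_equal(gValues(g2)[gRadii(g2) == 5], 0.5)
    # randomized oracle equivalence, including self-exclusion when A = B
    for (i in 1:20) {
        df <- randomPattern(40, seed = 300 + i)
        if (!all(c("A", "B") %in% df$phenotype)) next
        radii <- seq(0, 200, by = 10)
        g <- gFunction(cellsFromDf(df), "A", "B", radii = radii)
        expect_equal(gValues(g), bruteG(df, "A", "B", radii))
        gaa <- gFunction(cellsFromDf(df), "A", "A", radii = radii)
        if (sum(df$phenotype == "A") >= 2)
            expect_equal(gValues(gaa), bruteG(df, "A", "A", radii))
        expect_false(is.unsorted(gValues(g)))  # monotone
    }
})

test_that("missing cell types yield a missing curve with a reason", {
    df <- simplePattern(c(0, 1), c(0, 0), c("A", "A"))
    out <- gFunction(cellsFromDf(df), "A", "B")
    expect_true(!methods::is(out, "GFunctionCurve") && is.na(out))
    expect_match(attr(out, "reason"), "B")
})

test_that("SPS is the normalized area under G with exact ramp value", {
    ramp <- methods::new("GFunctionCurve", radii = as.numeric(0:50),
                         g = seq(0, 1, length.out = 51), typeA = "A",
                         typeB = "B", nA = 5L, nB = 5L)
    expect_equal(spatialProximityScore(ramp, 50), 0.5)
    ones <- methods::new("GFunctionCurve", radii = as.numeric(0:50),
                         g = rep(1, 51), typeA = "A", typeB = "B",
                         nA = 2L, nB = 2L)
    expect_equal(spatialProximityScore(ones, 50), 1)
    zeros <- methods::new("GFunctionCurve", radii = as.numeric(0:50),
                          g = rep(0, 51), typeA = "A", typeB = "B",
                          nA = 2L, nB = 2L)
    expect_equal(spatialProximityScore(zeros, 50), 0)
    expect_error(spatialProximityScore(ramp, 0), "> 0")
    expect_error(spatialProximityScore(ramp, 60), "radii range")
})

test_that("G and SPS are translation invariant; MH invariant after re-anchoring", {
    df <- randomPattern(40, seed = 900)
    shifted <- df
    shifted$x_um <- df$x_um + 137.5
    shifted$y_um <- df$y_um - 42.25
    radii <- 0:50
    g1 <- gFunction(cellsFromDf(df), "A", "B", radii = radii)
    g2 <- gFunction(cellsFromDf(shifted), "A", "B", radii = radii)
    expect_equal(gValues(g1), gValues(g2))
    expect_equal(spatialProximityScore(g1, 50), spatialProximityScore(g2, 50))
    # grid origin re-anchors at the bounding-box minimum, so MH is unchanged
    m1 <- morisitaHorn(quadratCounts(cellsFromDf(df), "A", "B", 100))
    m2 <- morisitaHorn(quadratCounts(cellsFromDf(shifted), "A", "B", 100))
    expect_equal(as.numeric(m1), as.numeric(m2))
})

test_that("Ecoscore classifies by mean SPS dominance with a tie rule", {
    expect_identical(ecoscore(0.8, 0.2)$category, "anti-tumor")
    expect_identical(ecoscore(0.2, 0.8)$category, "pro-tumor")
    expect_identical(ecoscore(0.5, 0.5)$category, "indeterminate")
    miss <- ecoscore(0.5, NA_real_)
    expect_identical(miss$category, "indeterminate")
    expect_match(miss$reason, "missing")
    # margin widens the indeterminate band
    expect_identical(ecoscore(0.55, 0.5, margin = 0.2)$category,
                     "indeterminate")
})

test_that("spatialScoreTable computes one row per sample", {
    tabs <- lapply(1:3, function(i) {
        df <- cellData(simulateCellPattern(simulationConfig(seed = 40 + i)))
        df$sample_id <- paste0("s", i)
        df
    })
    ct <- CellTable(do.call(rbind, tabs))
    st <- spatialScoreTable(ct, list(c("tumor", "cytotoxic_T")))
    expect_identical(nrow(st), 3L)
    expect_true(all(c("MH_tumor_cytotoxic_T", "SPS_tumor_cytotoxic_T")
                    %in% names(st)))
    expect_true(all(st$MH_tumor_cytotoxic_T >= 0 &
                    st$MH_tumor_cytotoxic_T <= 1))
})
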