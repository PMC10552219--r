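# Independent brute-force oracles used across the suite. These deliberately
# take different code paths from the package (dictionary keys instead of
# matrix binning, explicit double loops instead of vectorized distances).

# Morisita-Horn via per-square hash keys and the raw formula.
bruteMH <- function(df, typeA, typeB, squareSize = 100) {
    ox <- min(df$x_um)
    oy <- min(df$y_um)
    key <- paste(floor((df$x_um - ox) / squareSize),
                 floor((df$y_um - oy) / squareSize))
    squares <- unique(key)
    x <- vapply(squares, function(k)
        sum(key == k & df$phenotype == typeA), numeric(1))
    y <- vapply(squares, function(k)
        sum(key == k & df$phenotype == typeB), numeric(1))
    X <- sum(x)
    Y <- sum(y)
    if (X == 0 || Y == 0) return(NA_real_)
    2 * sum(x * y) / ((sum(x^2) / X^2 + sum(y^2) / Y^2) * X * Y)
}

# Nearest-neighbor G(r) by exhaustive O(n^2) looping.
bruteG <- function(df, typeA, typeB, radii) {
    a <- df[df$phenotype == typeA, , drop = FALSE]
    b <- df[df$phenotype == typeB, , drop = FALSE]
    nn <- vapply(seq_len(nrow(a)), function(i) {
        d <- Inf
        for (j in seq_len(nrow(b))) {
            if (a$cell_id[i] == b$cell_id[j]) next
            d <- min(d, sqrt((a$x_um[i] - b$x_um[j])^2 +
                             (a$y_um[i] - b$y_um[j])^2))
        }
        d
    }, numeric(1))
    vapply(radii, function(r) mean(nn <= r), numeric(1))
}

# Efron log partial likelihood for a single covariate.
efronLogLik <- function(beta, time, status, x) {
    ll <- 0
    for (t in sort(unique(time[status == 1]))) {
        D <- which(time == t & status == 1)
        R <- which(time >= t)
        d <- length(D)
        sumD <- sum(exp(beta * x[D]))
        sumR <- sum(exp(beta * x[R]))
        ll <- ll + beta * sum(x[D]) -
            sum(vapply(0:(d - 1), function(l)
                log(sumR - (l / d) * sumD), numeric(1)))
    }
    ll
}

# Iteratively refined grid maximization of the Efron partial likelihood.
gridMaxEfron <- function(time, status, x, lo = -5, hi = 5) {
    b <- 0
    for (iter in 1:6) {
        bs <- seq(lo, hi, length.out = 201)
        ll <- vapply(bs, efronLogLik, numeric(1),
                     time = time, status = status, x = x)
        b <- bs[which.max(ll)]
        w <- (hi - lo) / 200
        lo <- b - 2 * w
        hi <- b + 2 * w
    }
    b
}

# Random two-type pattern with <= nMax cells in a 400 x 400 um window.
randomPattern <- function(nMax = 50, seed = 1, types = c("A", "B")) {
    set.seed(seed)
    n <- sample(2:nMax, 1)
    data.frame(sample_id = "r",
               cell_id = sprintf("c%03d", seq_len(n)),
               x_um = runif(n, 0, 400), y_um = runif(n, 0, 400),
               CD3 = 0L,
               phenotype = sample(types, n, replace = TRUE),
               stringsAsFactors = FALSE)
}

# Mean MH and SPS for a tumor/cytotoxic-T pair over simulation replicates.
simMeanScores <- function(nrep, baseSeed, ...) {
    vals <- vapply(seq_len(nrep), function(i) {
        cfg <- simulationConfig(seed = baseSeed + i, ...)
        ct <- simulateCellPattern(cfg)
        if (!nrow(cellData(ct)))
            return(c(NA_real_, NA_real_))
        q <- quadratCounts(ct, "tumor", "cytotoxic_T", 100)
        g <- gFunction(ct, "tumor", "cytotoxic_T", radii = 0:50)
        sps <- if (methods::is(g, "GFunctionCurve"))
            spatialProximityScore(g, 50) else NA_real_
        c(as.numeric(morisitaHorn(q)), sps)
    }, numeric(2))
    c(mh = mean(vals[1, ], na.rm = TRUE), sps = mean(vals[2, ], na.rm = TRUE))
}
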