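#' Quadrat counts of two phenotypes on a fixed square grid
#'
#' Divides the sample's bounding box into non-overlapping squares (default
#' 100 um x 100 um), anchored at the bounding-box minimum corner of all
#' cells in the sample, and counts cells of each phenotype per square.
#' Cells are binned half-open, [k*s, (k+1)*s), so a cell exactly on a
#' square boundary belongs to the higher-index square; partial edge squares
#' are included.
#'
#' @param cells a [CellTable-class] holding exactly one sample, phenotypes
#'   assigned.
#' @param typeA,typeB phenotype labels to count.
#' @param squareSizeUm square side length in micrometers.
#' @return A [QuadratCounts-class].
#' @export
#' @examples
#' df <- data.frame(sample_id = "s", cell_id = c("a", "b"),
#'                  x_um = c(0, 150), y_um = c(0, 150), CD3 = c(0, 1),
#'                  phenotype = c("tumor", "helper_T"))
#' quadratCounts(CellTable(df), "tumor", "helper_T")
quadratCounts <- function(cells, typeA, typeB, squareSizeUm = 100) {
    stopifnot(methods::is(cells, "CellTable"))
    if (squareSizeUm <= 0)
        stop("squareSizeUm must be > 0")
    df <- cells@cells
    if (!nrow(df))
        stop("empty pattern")
    if (length(unique(df$sample_id)) != 1)
        stop("quadratCounts expects a single sample; see subsetSample()")
    origin <- c(min(df$x_um), min(df$y_um))
    ix <- floor((df$x_um - origin[1]) / squareSizeUm)
    iy <- floor((df$y_um - origin[2]) / squareSizeUm)
    nx <- max(ix) + 1
    ny <- max(iy) + 1
    grid <- function(type) {
        sel <- df$phenotype == type
        m <- matrix(0L, nrow = ny, ncol = nx)
        if (any(sel)) {
            tab <- table(factor(iy[sel], levels = 0:(ny - 1)),
                         factor(ix[sel], levels = 0:(nx - 1)))
            m <- matrix(as.integer(tab), nrow = ny, ncol = nx)
        }
        m
    }
    methods::new("QuadratCounts", sampleId = unique(df$sample_id),
                 typeA = typeA, typeB = typeB,
                 squareSizeUm = squareSizeUm, origin = origin,
                 countsA = grid(typeA), countsB = grid(typeB))
}

#' Morisita-Horn colocalization index from quadrat counts
#'
#' With per-square counts x_i and y_i and totals X and Y, the index is
#' \deqn{MH = \frac{2 \sum_i x_i y_i}{(\sum_i x_i^2 / X^2 +
#'   \sum_i y_i^2 / Y^2) \, X Y}.}
#' It ranges from 0 (each square holds only one of the two types: complete
#' segregation) to 1 (the two types share the same spatial distribution),
#' and is symmetric in the two types. When either type is absent the index
#' is undefined and `NA` is returned (with a `reason` attribute) rather
#' than 0, which would falsely assert observed segregation.
#'
#' @param q a [QuadratCounts-class], or a numeric vector of per-square
#'   counts for type A (then `y` must give type B on the same squares).
#' @param y per-square counts for type B when `q` is a vector.
#' @return numeric in [0, 1], or `NA` when a type is absent.
#' @export
#' @examples
#' morisitaHorn(c(2, 1), c(1, 2))  # 0.8
morisitaHorn <- function(q, y = NULL) {
    if (methods::is(q, "QuadratCounts")) {
        x <- as.numeric(q@countsA)
        y <- as.numeric(q@countsB)
    } else {
        x <- as.numeric(q)
        y <- as.numeric(y)
        if (length(x) != length(y))
            stop("mismatched grid shapes")
    }
    X <- sum(x)
    Y <- sum(y)
    if (X == 0 || Y == 0) {
        out <- NA_real_
        attr(out, "reason") <- "at least one cell type absent"
        return(out)
    }
    2 * sum(x * y) / ((sum(x^2) / X^2 + sum(y^2) / Y^2) * X * Y)
}

#' Nearest-neighbor distance distribution G(r)
#'
#' G(r) is the fraction of type-A cells whose nearest type-B neighbor
#' (Euclidean distance; a cell is never its own neighbor when A = B) lies
#' within distance r. No edge correction is applied by default; with
#' `border = "reduced"` (minus sampling) the estimate at each r uses only
#' A cells at least r from the window boundary, which removes the downward
#' bias near the edge at the cost of a possibly non-monotone raw estimate,
#' so the reduced-sample curve is reported cumulatively.
#'
#' @param cells a [CellTable-class] holding one sample.
#' @param typeA reference phenotype (cells measured from).
#' @param typeB target phenotype (nearest neighbor sought).
#' @param radii increasing radii in micrometers (default 0:50).
#' @param border `"none"` (default) or `"reduced"`.
#' @param window numeric(4) `c(xmin, xmax, ymin, ymax)` for the reduced
#'   border correction; defaults to the bounding box of all cells.
#' @return A [GFunctionCurve-class], or `NA` with a `reason` attribute when
#'   either type has no cells.
#' @export
#' @examples
#' df <- data.frame(sample_id = "s", cell_id = c("a", "b", "c"),
#'                  x_um = c(0, 3, 10), y_um = 0, CD3 = c(1, 0, 0),
#'                  phenotype = c("A", "B", "B"))
#' g <- gFunction(CellTable(df), "A", "B", radii = 0:5)
#' gValues(g)[gRadii(g) == 5]  # 1
gFunction <- function(cells, typeA, typeB, radii = 0:50,
                      border = c("none", "reduced"), window = NULL) {
    stopifnot(methods::is(cells, "CellTable"))
    border <- match.arg(border)
    if (is.unsorted(radii, strictly = TRUE))
        stop("radii must be strictly increasing")
    df <- cells@cells
    a <- df[df$phenotype == typeA, , drop = FALSE]
    b <- df[df$phenotype == typeB, , drop = FALSE]
    if (!nrow(a) || !nrow(b)) {
        out <- NA
        attr(out, "reason") <- sprintf("no cells of type %s",
            if (nrow(a)) typeB else typeA)
        return(out)
    }
    # nearest type-B distance for each type-A cell, excluding identity
    d2 <- outer(a$x_um, b$x_um, "-")^2 + outer(a$y_um, b$y_um, "-")^2
    same <- outer(a$cell_id, b$cell_id, "==")
    d2[same] <- Inf
    nn <- sqrt(apply(d2, 1, min))
    if (border == "none") {
        g <- vapply(radii, function(r) mean(nn <= r), numeric(1))
    } else {
        if (is.null(window))
            window <- c(min(df$x_um), max(df$x_um),
                        min(df$y_um), max(df$y_um))
        bdist <- pmin(a$x_um - window[1], window[2] - a$x_um,
                      a$y_um - window[3], window[4] - a$y_um)
        g <- numeric(length(radii))
        for (i in seq_along(radii)) {
            keep <- bdist >= radii[i]
            g[i] <- if (any(keep)) mean(nn[keep] <= radii[i]) else NA_real_
        }
        g[is.na(g)] <- max(0, g[!is.na(g)], na.rm = TRUE)
        g <- cummax(g)
    }
    methods::new("GFunctionCurve", radii = as.numeric(radii), g = g,
                 typeA = typeA, typeB = typeB,
                 nA = nrow(a), nB = nrow(b))
}

#' Spatial Proximity Score: normalized area under G(r)
#'
#' SPS = (1 / r_max) * integral of G(r) from 0 to r_max, evaluated by the
#' trapezoidal rule on the curve's radii grid. 1 means every reference cell
#' has a target neighbor essentially at distance zero; 0 means no target
#' cell within r_max of any reference cell.
#'
#' @param curve a [GFunctionCurve-class].
#' @param rMaxUm upper integration limit in micrometers (default 50); must
#'   lie within the curve's radii range.
#' @return numeric in [0, 1].
#' @export
spatialProximityScore <- function(curve, rMaxUm = 50) {
    stopifnot(methods::is(curve, "GFunctionCurve"))
    if (rMaxUm <= 0)
        stop("rMaxUm must be > 0")
    r <- curve@radii
    g <- curve@g
    if (rMaxUm > max(r))
        stop("rMaxUm outside the radii range of the curve")
    if (!rMaxUm %in% r) {
        # interpolate the endpoint onto the grid
        gEnd <- stats::approx(r, g, xout = rMaxUm)$y
        keep <- r < rMaxUm
        r <- c(r[keep], rMaxUm)
        g <- c(g[keep], gEnd)
    } else {
        keep <- r <= rMaxUm
        r <- r[keep]
        g <- g[keep]
    }
    if (r[1] > 0) {
        r <- c(0, r)
        g <- c(0, g)
    }
    auc <- sum(diff(r) * (utils::head(g, -1) + utils::tail(g, -1)) / 2)
    auc / rMaxUm
}

#' Ecoscore: pro-tumor versus anti-tumor microenvironment classification
#'
#' Compares the mean Spatial Proximity Score of anti-tumor cell classes to
#' tumor cells against that of pro-tumor classes. The microenvironment is
#' called `anti-tumor` when mean(anti) exceeds mean(pro) by more than the
#' relative margin, `pro-tumor` in the reverse case, and `indeterminate`
#' on a tie or when either side is entirely missing. Default class
#' memberships: anti-tumor = cytotoxic T cells; pro-tumor = Tregs and
#' macrophages.
#'
#' @param spsAnti numeric SPS values of anti-tumor classes (NA allowed).
#' @param spsPro numeric SPS values of pro-tumor classes (NA allowed).
#' @param margin relative margin for a call (default 0).
#' @param sampleId optional sample label carried through.
#' @return list with `sample_id`, `category` (one of `"anti-tumor"`,
#'   `"pro-tumor"`, `"indeterminate"`), `mean_anti`, `mean_pro`, `reason`.
#' @export
#' @examples
#' ecoscore(0.8, 0.2)$category  # "anti-tumor"
ecoscore <- function(spsAnti, spsPro, margin = 0, sampleId = NA_character_) {
    spsAnti <- spsAnti[!is.na(spsAnti)]
    spsPro <- spsPro[!is.na(spsPro)]
    if (!length(spsAnti) || !length(spsPro)) {
        return(list(sample_id = sampleId, category = "indeterminate",
                    mean_anti = if (length(spsAnti)) mean(spsAnti) else NA_real_,
                    mean_pro = if (length(spsPro)) mean(spsPro) else NA_real_,
                    reason = "required SPS values missing"))
    }
    a <- mean(spsAnti)
    p <- mean(spsPro)
    category <- if (a > p * (1 + margin)) "anti-tumor"
        else if (p > a * (1 + margin)) "pro-tumor"
        else "indeterminate"
    list(sample_id = sampleId, category = category,
         mean_anti = a, mean_pro = p,
         reason = if (category == "indeterminate") "within margin" else NA_character_)
}

#' Per-sample spatial score table for phenotype pairs
#'
#' Convenience wrapper running [quadratCounts()]/[morisitaHorn()] and
#' [gFunction()]/[spatialProximityScore()] for each requested phenotype
#' pair in every sample of a [CellTable-class].
#'
#' @param cells a [CellTable-class] with phenotypes assigned.
#' @param pairs list of length-2 character vectors (reference, target).
#' @param squareSizeUm quadrat size for Morisita-Horn (default 100).
#' @param rMaxUm SPS integration limit (default 50).
#' @param radiiStepUm radii step for G(r) (default 1).
#' @return data.frame with one row per sample and columns
#'   `MH_<a>_<b>` and `SPS_<a>_<b>` per pair (NA when undefined).
#' @export
spatialScoreTable <- function(cells, pairs, squareSizeUm = 100,
                              rMaxUm = 50, radiiStepUm = 1) {
    stopifnot(methods::is(cells, "CellTable"))
    radii <- seq(0, rMaxUm, by = radiiStepUm)
    samples <- sampleIds(cells)
    out <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
    for (pr in pairs) {
        mhCol <- sprintf("MH_%s_%s", pr[1], pr[2])
        spsCol <- sprintf("SPS_%s_%s", pr[1], pr[2])
        mh <- sps <- rep(NA_real_, length(samples))
        for (i in seq_along(samples)) {
            one <- subsetSample(cells, samples[i])
            if (!nrow(one@cells)) next
            q <- quadratCounts(one, pr[1], pr[2], squareSizeUm)
            mh[i] <- as.numeric(morisitaHorn(q))
            g <- gFunction(one, pr[1], pr[2], radii = radii)
            if (methods::is(g, "GFunctionCurve"))
                sps[i] <- spatialProximityScore(g, rMaxUm)
        }
        out[[mhCol]] <- mh
        out[[spsCol]] <- sps
    }
    out
}
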