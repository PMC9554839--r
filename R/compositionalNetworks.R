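#' Centered log-ratio (CLR) transform
#'
#' Sequencing counts are compositional: only relative information is
#' meaningful. The CLR transform maps each sample's counts onto real
#' coordinates whose rows sum to zero: with `m` features and pseudo-count
#' `1/m^2` (the default, small relative to any observed count yet keeping
#' zeros finite), `clr_j = ln(x_j + 1/m^2) - mean_k ln(x_k + 1/m^2)`.
#'
#' @param counts numeric matrix samples x features, non-negative, with at
#'   least 2 features.
#' @param pseudoCount pseudo-count added to every entry; default `1/m^2`.
#' @return numeric matrix of the same shape; each row sums to 0. The
#'   pseudo-count used is attached as attribute `"pseudo_count"`.
#' @examples
#' clrTransform(matrix(c(1, 2, 4), 1))
#' @export
clrTransform <- function(counts, pseudoCount = NULL) {
    stopifnot(is.matrix(counts))
    m <- ncol(counts)
    if (m < 2) stop("CLR needs at least 2 features")
    if (any(counts < 0)) stop("negative counts")
    if (is.null(pseudoCount)) pseudoCount <- 1 / m^2
    y <- log(counts + pseudoCount)
    out <- y - rowMeans(y)
    attr(out, "pseudo_count") <- pseudoCount
    out
}

#' Aitchison distance
#'
#' The natural distance between compositions: Euclidean distance on
#' CLR-transformed rows.
#'
#' @param a,b numeric vectors, CLR-transformed sample rows over the same
#'   features.
#' @return non-negative real; 0 iff the CLR rows are identical.
#' @export
aitchisonDistance <- function(a, b) {
    if (length(a) != length(b)) stop("dimension mismatch")
    sqrt(sum((a - b)^2))
}

#' Aitchison distance matrix for a counts table
#'
#' @param counts samples x features counts matrix.
#' @param pseudoCount see [clrTransform()].
#' @return a `dist` over samples.
#' @export
aitchisonDist <- function(counts, pseudoCount = NULL) {
    stats::dist(clrTransform(counts, pseudoCount))
}

#' Rho proportionality between two CLR feature vectors
#'
#' Proportionality is the compositionally valid analogue of correlation:
#' `rho = 1 - var(x - y) / (var(x) + var(y))`, algebraically equal to
#' `2 cov(x, y) / (var(x) + var(y))`, bounded in \[-1, 1\], reaching 1 for
#' identical and -1 for sign-opposite CLR profiles. Unbiased (n-1)
#' variance/covariance estimators throughout.
#'
#' @param x,y numeric vectors: one feature's CLR values across the same
#'   >= 3 samples.
#' @return rho in \[-1, 1\]; `NA` with a warning when both variances are 0.
#' @export
rhoProportionality <- function(x, y) {
    if (length(x) != length(y)) stop("dimension mismatch")
    if (length(x) < 3) stop("need at least 3 samples")
    v <- var(x) + var(y)
    if (v == 0) {
        warning("zero total variance: rho undefined")
        return(NA_real_)
    }
    1 - var(x - y) / v
}

# All pairwise rho values from a CLR matrix (samples x features).
.rhoMatrixFromClr <- function(clr) {
    C <- cov(clr)
    v <- diag(C)
    denom <- outer(v, v, "+")
    r <- 2 * C / denom
    r[denom == 0] <- NA_real_
    diag(r) <- 1
    # clamp numerical spill past the algebraic bounds
    r[] <- pmin(pmax(r, -1), 1)
    r
}

#' Ensemble co-occurrence network
#'
#' Co-occurrence structure for one condition: in each iteration the
#' samples are bootstrap-resampled with replacement, the resample is
#' CLR-transformed, and all pairwise rho proportionality values are
#' computed; the final network is the element-wise mean over iterations
#' (entries undefined in an iteration, e.g. a feature constant across the
#' resample, are dropped from that entry's mean). Deterministic given
#' `seed`. With `nIterations = 1` and `resample = FALSE` this degenerates
#' to the plain pairwise-rho network.
#'
#' @param counts samples x features counts matrix with >= 4 samples.
#' @param nIterations ensemble size (default 1000).
#' @param seed integer RNG seed (required when resampling).
#' @param condition condition label stored on the network.
#' @param resample bootstrap the samples? (`FALSE` only sensible with
#'   `nIterations = 1`.)
#' @param pseudoCount see [clrTransform()].
#' @return An [AssociationNetwork-class].
#' @export
ensembleNetwork <- function(counts, nIterations = 1000, seed = NULL,
                            condition = "condition", resample = TRUE,
                            pseudoCount = NULL) {
    stopifnot(is.matrix(counts))
    if (nrow(counts) < 4) stop("need at least 4 samples")
    nIterations <- as.integer(nIterations)
    stopifnot(nIterations >= 1)
    if (!resample) {
        r <- .rhoMatrixFromClr(clrTransform(counts, pseudoCount))
        return(new("AssociationNetwork", condition = condition, rho = r,
                   nIterations = nIterations,
                   seed = if (is.null(seed)) NA_integer_ else as.integer(seed)))
    }
    if (is.null(seed)) stop("resampling requires a seed")
    set.seed(as.integer(seed))
    n <- nrow(counts)
    acc <- matrix(0, ncol(counts), ncol(counts))
    cnt <- matrix(0L, ncol(counts), ncol(counts))
    for (it in seq_len(nIterations)) {
        idx <- sample.int(n, n, replace = TRUE)
        r <- .rhoMatrixFromClr(clrTransform(counts[idx, , drop = FALSE],
                                            pseudoCount))
        ok <- !is.na(r)
        acc[ok] <- acc[ok] + r[ok]
        cnt <- cnt + ok
    }
    mean_r <- acc / cnt
    mean_r[cnt == 0] <- NA_real_
    dimnames(mean_r) <- list(colnames(counts), colnames(counts))
    diag(mean_r) <- 1
    new("AssociationNetwork", condition = condition, rho = mean_r,
        nIterations = nIterations, seed = as.integer(seed))
}

#' Differential co-occurrence edges between two conditions
#'
#' Differential connectivity `D = rho_a - rho_b` per feature pair, keeping
#' only edges with a positive association in *both* conditions (negative
#' proportionality is non-trivial to interpret compositionally) and
#' `|D| >= minDiff` (default 0.1). The sign of `D` is preserved, so
#' condition-a-strengthened and condition-b-strengthened edges are both
#' reported.
#'
#' @param netA,netB [AssociationNetwork-class] objects over identical
#'   feature sets.
#' @param minDiff minimum absolute differential connectivity.
#' @return `data.frame` with columns `source`, `target`, `rho_a`,
#'   `rho_b`, `diff`.
#' @export
differentialNetwork <- function(netA, netB, minDiff = 0.1) {
    ra <- rhoMatrix(netA); rb <- rhoMatrix(netB)
    if (!identical(rownames(ra), rownames(rb)))
        stop("networks must share one feature set")
    feats <- rownames(ra)
    idx <- which(upper.tri(ra), arr.ind = TRUE)
    out <- data.frame(
        source = feats[idx[, 1]], target = feats[idx[, 2]],
        rho_a = ra[idx], rho_b = rb[idx], stringsAsFactors = FALSE)
    out$diff <- out$rho_a - out$rho_b
    keep <- !is.na(out$rho_a) & !is.na(out$rho_b) &
        out$rho_a > 0 & out$rho_b > 0 & abs(out$diff) >= minDiff
    res <- out[keep, , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Prevalence filter for counts features
#'
#' Removes features present (count > 0) in fewer than `minPrevalence` of
#' the samples (default 40 percent, boundary inclusive).
#'
#' @param counts samples x features counts matrix.
#' @param minPrevalence fraction in \[0, 1\].
#' @return the filtered counts matrix.
#' @export
prevalenceFilter <- function(counts, minPrevalence = 0.4) {
    stopifnot(minPrevalence >= 0, minPrevalence <= 1)
    keep <- colMeans(counts > 0) >= minPrevalence
    counts[, keep, drop = FALSE]
}

#' Rho dissimilarity and average-linkage feature clustering
#'
#' Dissimilarity representation of proportionality, `1 - rho` (in
#' \[0, 2\]), with average-linkage agglomerative clustering of the
#' features — the standard input for clustered abundance heatmaps.
#'
#' @param network An [AssociationNetwork-class].
#' @return list with `dissimilarity` (matrix) and `tree`
#'   ([stats::hclust] object).
#' @export
rhoDissimilarityLinkage <- function(network) {
    r <- rhoMatrix(network)
    if (any(!is.finite(r)))
        stop("network contains non-finite entries")
    d <- 1 - r
    list(dissimilarity = d,
         tree = hclust(as.dist(d), method = "average"))
}

#' Write a differential edge table as TSV
#'
#' @param edges `data.frame` from [differentialNetwork()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeEdgeTable <- function(edges, file) {
    utils::write.table(edges, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}
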