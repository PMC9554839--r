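#' Aggregate a counts matrix along a feature grouping
#'
#' Sums counts feature-wise with respect to a grouping (contig -> MAG,
#' MAG -> SLC, ORF -> SSO, SLC -> taxon label, ...): the output feature
#' axis is the set of groups and each cell is the sum of its members'
#' counts. When every feature is grouped, per-sample totals are conserved.
#' With `dropUngrouped = TRUE` features absent from the grouping are
#' silently excluded (the convention for ORF -> SSO aggregation, where
#' unclustered ORFs do not enter functional features); otherwise an
#' ungrouped feature is an error.
#'
#' @param counts numeric matrix, samples x features (non-negative), with
#'   dimnames. Integer read counts and coverage-normalised real counts are
#'   both accepted.
#' @param grouping named character vector feature id -> group id.
#' @param dropUngrouped drop features missing from `grouping`?
#' @return numeric matrix samples x groups (group columns in sorted order).
#' @examples
#' m <- matrix(c(3, 4), 1, dimnames = list("s1", c("c1", "c2")))
#' aggregateCounts(m, c(c1 = "m1", c2 = "m1"))
#' @export
aggregateCounts <- function(counts, grouping, dropUngrouped = FALSE) {
    stopifnot(is.matrix(counts))
    if (any(counts < 0)) stop("negative counts")
    feats <- colnames(counts)
    if (is.null(feats) || anyDuplicated(feats))
        stop("counts must have unique feature (column) names")
    ungrouped <- setdiff(feats, names(grouping))
    if (length(ungrouped)) {
        if (!dropUngrouped)
            stop("feature(s) without a group: ",
                 paste(ungrouped, collapse = ", "))
        counts <- counts[, setdiff(feats, ungrouped), drop = FALSE]
        feats <- colnames(counts)
    }
    if (!length(feats))
        return(counts[, 0, drop = FALSE])
    g <- grouping[feats]
    out <- t(rowsum(t(counts), group = g))
    rownames(out) <- rownames(counts)
    out
}

#' Feature compression ratio
#'
#' The FCR quantifies how much clustering reduces dimensionality:
#' `FCR = 1 - nClusters / nFeatures`. 200 MAGs collapsing into 50 SLCs
#' give an FCR of 0.75 — the clusters encode roughly the same information
#' in 75 percent fewer dimensions. High FCR indicates heavy redundancy
#' (many strain variants of few species).
#'
#' @param nFeatures number of original features (> 0).
#' @param nClusters number of clustered features (0 < nClusters <=
#'   nFeatures).
#' @return ratio in \[0, 1).
#' @examples
#' fcr(200, 50)   # 0.75
#' fcr(219, 154)  # 0.296803653
#' @export
fcr <- function(nFeatures, nClusters) {
    if (nFeatures <= 0) stop("nFeatures must be positive")
    if (nClusters <= 0 || nClusters > nFeatures)
        stop("need 0 < nClusters <= nFeatures")
    1 - nClusters / nFeatures
}

#' Functional feature compression ratio
#'
#' FCR over ORFs and SLC-specific orthogroups, with the one distinction
#' that only clustered ORFs enter the denominator: unclustered ORFs must
#' already be excluded from `nClusteredOrfs`. With 1100 ORFs of which 1000
#' cluster into 100 SSOs, the functional FCR is `1 - 100/1000 = 0.9`.
#'
#' @param nClusteredOrfs number of ORFs placed in SSOs (> 0).
#' @param nSsos number of SSOs (0 < nSsos <= nClusteredOrfs).
#' @return ratio in \[0, 1).
#' @examples
#' functionalFcr(1000, 100)  # 0.9
#' @export
functionalFcr <- function(nClusteredOrfs, nSsos) {
    fcr(nClusteredOrfs, nSsos)
}

#' Render a ratio as a percent string
#'
#' One-decimal (by default) percent rendering with half-even rounding,
#' matching how compression ratios are reported in prose (0.296803653
#' becomes `"29.7%"`).
#'
#' @param x ratio in \[0, 1\].
#' @param digits decimal places (default 1).
#' @return character vector like `"77.9%"`.
#' @export
formatPercent <- function(x, digits = 1) {
    paste0(formatC(round(x * 100, digits), format = "f", digits = digits),
           "%")
}

#' Aggregate species-level clusters into labelled taxa
#'
#' Domain-specific relabelling used before network analysis: prokaryotic
#' SLCs grouped by genus-level taxonomy, viral SLCs by their viral
#' orthologous-group classification, etc. A thin wrapper over
#' [aggregateCounts()] with the label map as grouping (the label map must
#' be total).
#'
#' @param slcCounts numeric matrix samples x SLCs.
#' @param labels named character vector SLC id -> taxon label.
#' @return numeric matrix samples x labels.
#' @export
aggregateTaxonFeatures <- function(slcCounts, labels) {
    aggregateCounts(slcCounts, labels, dropUngrouped = FALSE)
}

#' Read / write counts tables
#'
#' Counts TSVs are stored features x samples (the layout emitted by
#' read-counting tools, first column = feature id) and transposed to the
#' internal samples x features orientation on read.
#'
#' @param file TSV path.
#' @param counts samples x features matrix (for `writeCountsMatrix`).
#' @return `readCountsMatrix` returns a samples x features numeric matrix.
#' @export
readCountsMatrix <- function(file) {
    tab <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab[[1]]
    t(m)
}

#' @rdname readCountsMatrix
#' @export
writeCountsMatrix <- function(counts, file) {
    tab <- data.frame(feature_id = colnames(counts), t(counts),
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tab, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}
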