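#' @import methods
#' @importFrom stats cov var sd hclust as.dist setNames rlnorm rgamma rnorm
#'   rmultinom runif
#' @importFrom utils head
NULL

.DOMAIN_TAGS <- c("P", "E", "V")

#' Canonical genome (MAG) name
#'
#' Genomes recovered from sample-specific binning carry a structured name
#' encoding the source sample, the binning algorithm, a domain tag
#' (`P` prokaryotic, `E` eukaryotic, `V` viral), the binning iteration
#' (prokaryotic/eukaryotic only) and the local bin name, rendered as
#' `Sample_Algorithm_P.1_bin.1` or `Sample_Algorithm_Virus.1`.
#' The underscore is the reserved field separator and is rejected inside
#' the sample and algorithm fields so that names parse unambiguously.
#'
#' @slot sampleId character(1), source sample identifier.
#' @slot algorithm character(1), binning algorithm label (e.g. `"METABAT2"`).
#' @slot domainTag character(1), one of `"P"`, `"E"`, `"V"`.
#' @slot iteration integer(1), binning iteration (>= 1); `NA` for viral names.
#' @slot localName character(1), algorithm-local bin name (e.g. `"bin.1"`).
#'
#' @seealso [GenomeName()], [renderGenomeName()], [parseGenomeName()]
#' @export
setClass("GenomeName",
    representation(
        sampleId  = "character",
        algorithm = "character",
        domainTag = "character",
        iteration = "integer",
        localName = "character"
    )
)

setValidity("GenomeName", function(object) {
    msg <- character()
    for (f in c("sampleId", "algorithm", "domainTag", "localName")) {
        v <- slot(object, f)
        if (length(v) != 1L || is.na(v) || !nzchar(v))
            msg <- c(msg, sprintf("'%s' must be a non-empty string", f))
    }
    if (length(msg)) return(msg)
    if (!object@domainTag %in% .DOMAIN_TAGS)
        msg <- c(msg, "'domainTag' must be one of \"P\", \"E\", \"V\"")
    if (grepl("_", object@sampleId, fixed = TRUE) ||
        grepl("_", object@algorithm, fixed = TRUE))
        msg <- c(msg, "separator '_' is reserved; not allowed in sampleId or algorithm")
    if (object@domainTag %in% c("P", "E")) {
        if (is.na(object@iteration) || object@iteration < 1L)
            msg <- c(msg, "P/E names require a positive 'iteration'")
    } else if (!is.na(object@iteration)) {
        msg <- c(msg, "viral (V) names carry no iteration")
    }
    # keep V local names from masquerading as a P/E iteration field
    if (object@domainTag == "V" &&
        grepl("^[PE]\\.[0-9]+_", object@localName))
        msg <- c(msg, "viral localName may not start with a 'P.<n>_'/'E.<n>_' field")
    if (length(msg)) msg else TRUE
})

#' Bin-level taxonomic domain prediction
#'
#' Result of aggregating per-contig domain prediction probabilities into a
#' single call for a bin: summed log-probability logits per category, their
#' softmax-normalised probabilities, and the argmax call.
#'
#' @slot binId character(1).
#' @slot logits named numeric, one aggregated logit per domain category.
#' @slot probabilities named numeric, softmax of the logits (sums to 1).
#' @slot call character(1), the winning category.
#'
#' @seealso [aggregateBinDomain()]
#' @export
setClass("BinDomainPrediction",
    representation(
        binId         = "character",
        logits        = "numeric",
        probabilities = "numeric",
        call          = "character"
    )
)

setValidity("BinDomainPrediction", function(object) {
    msg <- character()
    if (is.null(names(object@logits)) || is.null(names(object@probabilities)))
        msg <- c(msg, "logits and probabilities must be named by category")
    else if (!identical(names(object@logits), names(object@probabilities)))
        msg <- c(msg, "logits and probabilities must share category names")
    if (abs(sum(object@probabilities) - 1) > 1e-9)
        msg <- c(msg, "probabilities must sum to 1")
    if (length(object@call) != 1L || !object@call %in% names(object@probabilities))
        msg <- c(msg, "'call' must be one of the categories")
    if (length(msg)) msg else TRUE
})

#' Feature-to-cluster assignment map
#'
#' A total map from features (genomes, proteins, contigs) to dense,
#' deterministically numbered cluster identifiers sharing one prefix
#' (`PSLC`/`ESLC`/`VSLC` for prokaryotic/eukaryotic/viral species-level
#' clusters). Singleton features get their own cluster.
#'
#' @slot assignments named character; names are feature ids, values cluster ids.
#' @slot prefix character(1) cluster-id prefix.
#'
#' @seealso [clusterSLC()], [clusterIds()], [clusterMembers()]
#' @export
setClass("ClusterMap",
    representation(assignments = "character", prefix = "character")
)

setValidity("ClusterMap", function(object) {
    msg <- character()
    if (length(object@assignments) &&
        (is.null(names(object@assignments)) ||
         anyDuplicated(names(object@assignments))))
        msg <- c(msg, "assignments must be uniquely named by feature id")
    if (length(object@assignments) &&
        !all(startsWith(object@assignments, object@prefix)))
        msg <- c(msg, "all cluster ids must carry the declared prefix")
    if (length(msg)) msg else TRUE
})

#' Co-occurrence association network
#'
#' A symmetric feature-by-feature matrix of rho proportionality values for
#' one condition, optionally the element-wise mean over bootstrap
#' resamples of the samples.
#'
#' @slot condition character(1) condition label.
#' @slot rho symmetric numeric matrix in \[-1, 1\] with unit diagonal.
#' @slot nIterations integer(1), number of ensemble iterations used.
#' @slot seed integer(1), RNG seed (`NA` when no resampling was done).
#'
#' @seealso [ensembleNetwork()], [differentialNetwork()]
#' @export
setClass("AssociationNetwork",
    representation(
        condition   = "character",
        rho         = "matrix",
        nIterations = "integer",
        seed        = "integer"
    )
)

setValidity("AssociationNetwork", function(object) {
    m <- object@rho
    msg <- character()
    if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
        msg <- c(msg, "rho must be square with matching dimnames")
    fin <- m[is.finite(m)]
    if (length(fin) && (max(fin) > 1 + 1e-9 || min(fin) < -1 - 1e-9))
        msg <- c(msg, "rho entries must lie in [-1, 1]")
    if (max(abs(m - t(m)), na.rm = TRUE) > 1e-9)
        msg <- c(msg, "rho must be symmetric")
    if (any(abs(diag(m) - 1) > 1e-9, na.rm = TRUE))
        msg <- c(msg, "rho diagonal must be 1")
    if (object@nIterations < 1L)
        msg <- c(msg, "nIterations must be >= 1")
    if (length(msg)) msg else TRUE
})

setMethod("show", "GenomeName", function(object) {
    cat("GenomeName:", renderGenomeName(object), "\n")
})

setMethod("show", "BinDomainPrediction", function(object) {
    cat("BinDomainPrediction for bin", sQuote(object@binId), "\n")
    cat("  call:", object@call,
        sprintf("(p = %.4f)\n", object@probabilities[[object@call]]))
    cat("  probabilities:",
        paste(sprintf("%s=%.4f", names(object@probabilities),
                      object@probabilities), collapse = ", "), "\n")
})

setMethod("show", "ClusterMap", function(object) {
    n <- length(object@assignments)
    k <- length(unique(object@assignments))
    cat(sprintf("ClusterMap: %d features in %d clusters (prefix %s)\n",
                n, k, sQuote(object@prefix)))
    if (n) {
        sizes <- sort(table(object@assignments), decreasing = TRUE)
        cat("  largest:", paste(sprintf("%s (%d)", names(head(sizes, 3L)),
                                        head(sizes, 3L)), collapse = ", "), "\n")
    }
})

setMethod("show", "AssociationNetwork", function(object) {
    cat(sprintf(
        "AssociationNetwork %s: %d features, %d iteration(s)\n",
        sQuote(object@condition), nrow(object@rho), object@nIterations))
})

#' @describeIn ClusterMap-class Cluster identifiers in dense order.
#' @param x,object A `ClusterMap`.
#' @export
clusterIds <- function(x) {
    stopifnot(is(x, "ClusterMap"))
    ord <- unique(x@assignments)
    ord[order(as.integer(sub(x@prefix, "", ord, fixed = TRUE)))]
}

#' @describeIn ClusterMap-class Feature ids belonging to one cluster.
#' @param clusterId character(1) cluster id.
#' @export
clusterMembers <- function(x, clusterId) {
    stopifnot(is(x, "ClusterMap"))
    sort(names(x@assignments)[x@assignments == clusterId])
}

#' @describeIn ClusterMap-class Assignments as a named character vector
#'   (feature id -> cluster id).
#' @export
clusterAssignments <- function(x) {
    stopifnot(is(x, "ClusterMap"))
    x@assignments
}

#' @export
#' @describeIn AssociationNetwork-class The rho matrix.
rhoMatrix <- function(x) {
    stopifnot(is(x, "AssociationNetwork"))
    x@rho
}

#' Coerce a ClusterMap to a data.frame
#'
#' @param x A `ClusterMap`.
#' @param row.names,optional,... Ignored; present for S3 consistency.
#' @return `data.frame` with columns `feature_id`, `cluster_id`.
#' @method as.data.frame ClusterMap
#' @export
as.data.frame.ClusterMap <- function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(
        feature_id = names(x@assignments),
        cluster_id = unname(x@assignments),
        stringsAsFactors = FALSE
    )
}
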