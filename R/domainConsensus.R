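#' Aggregate per-contig domain predictions to a bin-level call
#'
#' Contig-level taxonomic domain prediction probabilities (one probability
#' per category, rows summing to 1) are aggregated into a single bin-level
#' prediction: per-category logits are the (optionally length-weighted) sums
#' of natural-log probabilities over member contigs, and a softmax
#' transformation rescales the logits into bin-level probabilities. The call
#' is the argmax category; exact ties go to the earlier category in column
#' order.
#'
#' With `weighting = "length"` each contig's log-probability term is
#' multiplied by `length / mean(length)`, so longer contigs carry
#' proportionally more evidence while the logit scale stays comparable to
#' the uniform case.
#'
#' @param probabilities numeric matrix or data.frame, contigs x categories;
#'   rows must sum to 1 (tolerance 1e-6). Row names are contig ids.
#' @param binId character(1) bin identifier.
#' @param weighting `"uniform"` (default) or `"length"`.
#' @param lengths contig lengths (bp), required for length weighting.
#' @param epsilon probability floor guarding `log(0)`.
#' @return A [BinDomainPrediction-class].
#' @examples
#' p <- rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.6, 0.4))
#' colnames(p) <- c("prokaryota", "eukaryota")
#' aggregateBinDomain(p, "bin.1")
#' @export
aggregateBinDomain <- function(probabilities, binId = "bin",
                               weighting = c("uniform", "length"),
                               lengths = NULL, epsilon = 1e-10) {
    weighting <- match.arg(weighting)
    p <- as.matrix(probabilities)
    if (nrow(p) == 0L)
        stop("empty bin: no contig predictions")
    if (is.null(colnames(p)))
        stop("probability columns must be named by domain category")
    if (any(!is.finite(p)))
        stop("non-finite probability")
    if (any(abs(rowSums(p) - 1) > 1e-6))
        stop("per-contig probabilities must sum to 1")
    w <- if (weighting == "length") {
        if (is.null(lengths) || length(lengths) != nrow(p))
            stop("length weighting requires one length per contig")
        lengths / mean(lengths)
    } else rep(1, nrow(p))
    logits <- colSums(w * log(pmax(p, epsilon)))
    z <- exp(logits - max(logits))
    probs <- z / sum(z)
    call <- names(probs)[which.max(probs)]
    new("BinDomainPrediction", binId = binId, logits = logits,
        probabilities = probs, call = call)
}

#' Partition bins into eukaryotic / prokaryotic / undetermined
#'
#' Domain prediction is applied at the bin level rather than the contig
#' level so that organelle and misclassified contigs are captured with
#' their host bin: a bin is eukaryotic when the probability mass over the
#' eukaryote-side categories (typically `eukarya` plus `organelle`) reaches
#' `minProbability`, prokaryotic when the complementary mass does, and
#' undetermined otherwise. At an exact 50/50 split with
#' `minProbability = 0.5` the eukaryotic rule is tested first.
#'
#' @param bins list of [BinDomainPrediction-class] objects.
#' @param eukaryoteCategories character vector of categories counted toward
#'   the eukaryotic mass.
#' @param minProbability threshold in \[0, 1\] (default 0.5).
#' @return named character vector (`"eukaryotic"`, `"prokaryotic"`,
#'   `"undetermined"`) indexed by bin id.
#' @export
classifyBinsByDomain <- function(bins, eukaryoteCategories,
                                 minProbability = 0.5) {
    if (!length(eukaryoteCategories))
        stop("empty eukaryote category set")
    stopifnot(minProbability >= 0, minProbability <= 1)
    out <- vapply(bins, function(b) {
        stopifnot(is(b, "BinDomainPrediction"))
        eukMass <- sum(b@probabilities[
            names(b@probabilities) %in% eukaryoteCategories])
        if (eukMass >= minProbability) "eukaryotic"
        else if (1 - eukMass >= minProbability) "prokaryotic"
        else "undetermined"
    }, character(1))
    names(out) <- vapply(bins, function(b) b@binId, character(1))
    out
}

#' Read a contig domain-probability table
#'
#' TSV layout: `contig_id` column plus one probability column per domain
#' category (the layout emitted by contig-level domain predictors).
#'
#' @param file TSV path.
#' @return numeric matrix contigs x categories with contig-id rownames.
#' @export
readDomainProbabilities <- function(file) {
    tab <- utils::read.delim(file, stringsAsFactors = FALSE)
    m <- as.matrix(tab[, setdiff(names(tab), "contig_id"), drop = FALSE])
    rownames(m) <- tab$contig_id
    m
}
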