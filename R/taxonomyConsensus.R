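#' Leniency scaling factors for consensus taxonomy
#'
#' An array of N scaling factors, one per taxonomic level (level 1 =
#' coarsest), controlling how strongly deeper assignments are rewarded:
#' `s_i = i^(1/leniency)`. At `leniency = 1` the weights are `1, 2, ..., N`
#' (linear reward for depth); as `leniency` grows the weights flatten
#' toward 1, so high leniency biases assignments toward coarser
#' (higher-order) ranks.
#'
#' @param nLevels number of taxonomic levels N (>= 1).
#' @param leniency positive real leniency parameter.
#' @return numeric vector of length `nLevels`, strictly increasing.
#' @examples
#' leniencyWeights(3, 1)    # 1 2 3
#' leniencyWeights(2, 10)   # 1 1.0718
#' @export
leniencyWeights <- function(nLevels, leniency) {
    stopifnot(nLevels >= 1)
    if (!is.numeric(leniency) || length(leniency) != 1L || leniency <= 0)
        stop("leniency must be a positive real")
    seq_len(nLevels)^(1 / leniency)
}

# Split semicolon-delimited lineages into a list of label vectors.
.splitLineage <- function(lineage) {
    if (is.list(lineage)) return(lineage)
    strsplit(as.character(lineage), ";", fixed = TRUE)
}

# Score every observed lineage prefix of one genome's hits and return the
# full score table. Hits is a data.frame with list-column `lineage` already
# split, and numeric `score`.
.prefixScores <- function(lineages, scores, leniency) {
    depth <- max(lengths(lineages))
    w <- leniencyWeights(depth, leniency)
    tab <- new.env(parent = emptyenv())
    for (h in seq_along(lineages)) {
        lin <- lineages[[h]]
        key <- ""
        for (i in seq_along(lin)) {
            key <- if (nzchar(key)) paste(key, lin[[i]], sep = ";") else lin[[i]]
            prev <- if (is.null(tab[[key]])) 0 else tab[[key]]
            tab[[key]] <- prev + w[[i]] * scores[[h]]
        }
    }
    keys <- ls(tab)
    data.frame(
        prefix = keys,
        level = lengths(strsplit(keys, ";", fixed = TRUE)),
        score = vapply(keys, function(k) tab[[k]], numeric(1)),
        row.names = NULL, stringsAsFactors = FALSE)
}

#' Consensus taxonomy for a genome from per-protein lineage hits
#'
#' Each protein hit carries an ordered lineage (coarsest to finest) and an
#' alignment score (bitscore or percent identity). For every lineage prefix
#' P at level i observed among the hits, the prefix score is
#' `s_i * sum(scores of hits whose lineage begins with P)` with `s_i` from
#' [leniencyWeights()]; the genome is assigned to the highest-scoring
#' prefix. Exact score ties back off to the coarsest tied prefix (then
#' lexicographic), so an even split between two genera resolves to their
#' shared family rather than an arbitrary genus. Hits
#' scoring below their marker's noise cutoff are discarded before scoring;
#' a genome whose hits are all filtered out is returned flagged
#' unclassified rather than raising an error.
#'
#' @param hits `data.frame` with columns `genome_id`, `lineage`
#'   (semicolon-delimited string or list of character vectors), `score`
#'   (>= 0), optional `marker_id`.
#' @param leniency positive real; higher values favour coarser ranks.
#' @param scoreCutoffs optional named numeric vector of per-marker noise
#'   thresholds; hits with `score < scoreCutoffs[marker_id]` are dropped.
#' @return `data.frame` with one row per genome: `genome_id`, `lineage`
#'   (semicolon-joined winning prefix, `NA` if unclassified), `level`,
#'   `score`, `classified` (logical).
#' @examples
#' hits <- data.frame(genome_id = "g1",
#'                    lineage = c("F1;G1", "F1;G2"),
#'                    score = c(100, 50))
#' consensusGenomeClassification(hits, leniency = 1)   # F1;G1
#' consensusGenomeClassification(hits, leniency = 10)  # F1
#' @export
consensusGenomeClassification <- function(hits, leniency = 1,
                                          scoreCutoffs = NULL) {
    stopifnot(all(c("genome_id", "lineage", "score") %in% names(hits)))
    if (any(hits$score < 0)) stop("scores must be non-negative")
    keep <- rep(TRUE, nrow(hits))
    if (!is.null(scoreCutoffs) && "marker_id" %in% names(hits)) {
        cut <- scoreCutoffs[hits$marker_id]
        keep <- is.na(cut) | hits$score >= cut
    }
    genomes <- unique(hits$genome_id)
    res <- lapply(genomes, function(g) {
        sel <- keep & hits$genome_id == g
        if (!any(sel))
            return(data.frame(genome_id = g, lineage = NA_character_,
                              level = 0L, score = NA_real_,
                              classified = FALSE, stringsAsFactors = FALSE))
        tab <- .prefixScores(.splitLineage(hits$lineage[sel]),
                             hits$score[sel], leniency)
        # argmax; ties -> coarsest level, then lexicographic
        ord <- order(-tab$score, tab$level, tab$prefix)
        top <- tab[ord[1L], ]
        data.frame(genome_id = g, lineage = top$prefix,
                   level = as.integer(top$level), score = top$score,
                   classified = TRUE, stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
}

#' Full prefix score table for one genome
#'
#' Diagnostic companion to [consensusGenomeClassification()]: the complete
#' weighted running-sum table over all observed lineage prefixes.
#'
#' @inheritParams consensusGenomeClassification
#' @return `data.frame` with columns `prefix`, `level`, `score`.
#' @export
consensusScoreTable <- function(hits, leniency = 1) {
    stopifnot(all(c("lineage", "score") %in% names(hits)))
    .prefixScores(.splitLineage(hits$lineage), hits$score, leniency)
}

#' Consensus taxonomy for genome clusters
#'
#' Pools the protein hits of all member genomes of each cluster (or,
#' with `method = "vote"`, takes each member's own assignment as a single
#' equal-weight pseudo-hit) and applies
#' [consensusGenomeClassification()] per cluster.
#'
#' @param hits per-protein hit table as in
#'   [consensusGenomeClassification()].
#' @param clusterMap [ClusterMap-class] over the genome ids.
#' @param leniency positive real.
#' @param method `"pool"` (default) or `"vote"`.
#' @return `data.frame` as from [consensusGenomeClassification()] with
#'   `genome_id` replaced by `cluster_id`.
#' @export
consensusClusterClassification <- function(hits, clusterMap, leniency = 1,
                                           method = c("pool", "vote")) {
    method <- match.arg(method)
    asg <- clusterAssignments(clusterMap)
    unknown <- setdiff(unique(hits$genome_id), names(asg))
    if (length(unknown))
        stop("genomes missing from cluster map: ",
             paste(unknown, collapse = ", "))
    if (method == "vote") {
        per <- consensusGenomeClassification(hits, leniency)
        per <- per[per$classified, , drop = FALSE]
        hits <- data.frame(genome_id = per$genome_id, lineage = per$lineage,
                           score = 1, stringsAsFactors = FALSE)
    }
    pooled <- hits
    pooled$genome_id <- unname(asg[hits$genome_id])
    out <- consensusGenomeClassification(pooled, leniency)
    names(out)[names(out) == "genome_id"] <- "cluster_id"
    out
}

#' Consensus habitat annotation for a genome cluster
#'
#' Plurality vote over member habitat labels; missing labels (`NA`) are
#' excluded from the vote. Ties resolve to the lexicographically first
#' label and are flagged.
#'
#' @param memberHabitats character vector of habitat labels (`NA` allowed).
#' @return list with `habitat` (label or `NA`), `support` (winning count /
#'   non-missing total), `tie` (logical), `known` (logical, `FALSE` when
#'   every label was missing).
#' @examples
#' consensusHabitat(c("marine", "marine", "host"))
#' @export
consensusHabitat <- function(memberHabitats) {
    if (!length(memberHabitats))
        stop("empty habitat list")
    lab <- memberHabitats[!is.na(memberHabitats)]
    if (!length(lab))
        return(list(habitat = NA_character_, support = NA_real_,
                    tie = FALSE, known = FALSE))
    tab <- table(lab)
    top <- max(tab)
    winners <- sort(names(tab)[tab == top])
    list(habitat = winners[[1L]], support = unname(top) / length(lab),
         tie = length(winners) > 1L, known = TRUE)
}

#' Read a protein lineage hit table
#'
#' TSV columns: `protein_id`, `genome_id`, `lineage` (semicolon-delimited,
#' coarsest first), `score`, optional `marker_id`.
#'
#' @param file TSV path.
#' @return `data.frame`.
#' @export
readProteinHits <- function(file) {
    utils::read.delim(file, stringsAsFactors = FALSE)
}
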