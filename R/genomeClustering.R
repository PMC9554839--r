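#' Species-level clustering of genomes from pairwise ANI
#'
#' Builds a graph whose nodes are genomes and whose edges are average
#' nucleotide identity (ANI) values, keeps edges at or above the threshold
#' (default 95 percent, the standard species boundary), and takes connected
#' components as species-level clusters (SLCs). Asymmetric ANI pairs
#' (a->b differing from b->a, as alignment-based ANI tools produce) are
#' symmetrized by the maximum before thresholding. Isolated genomes become
#' singleton clusters. Cluster ids are dense and deterministic: clusters
#' are numbered from 0 in order of decreasing size, ties broken by the
#' lexicographically smallest member (e.g. `PSLC0`, `PSLC1`, ...).
#'
#' @param genomes character vector of genome ids (the clustering universe).
#' @param edges `data.frame` with columns `genome_a`, `genome_b`, `ani`
#'   (percent, 0-100). Self-edges are ignored.
#' @param threshold ANI threshold in (0, 100], inclusive (edge qualifies
#'   when symmetrized ANI >= threshold).
#' @param prefix cluster-id prefix, conventionally `"PSLC"`, `"ESLC"` or
#'   `"VSLC"` by domain.
#' @return A [ClusterMap-class] over all input genomes.
#' @examples
#' edges <- data.frame(genome_a = "A", genome_b = "B", ani = 96)
#' clusterSLC(c("A", "B", "C"), edges)
#' @export
clusterSLC <- function(genomes, edges, threshold = 95, prefix = "PSLC") {
    stopifnot(threshold > 0, threshold <= 100)
    if (anyDuplicated(genomes)) stop("duplicate genome ids")
    if (nrow(edges)) {
        unknown <- setdiff(c(edges$genome_a, edges$genome_b), genomes)
        if (length(unknown))
            stop("edge references unknown genome(s): ",
                 paste(unique(unknown), collapse = ", "))
        edges <- edges[edges$genome_a != edges$genome_b, , drop = FALSE]
    }
    # symmetrize asymmetric pairs by the maximum ANI
    if (nrow(edges)) {
        key <- ifelse(edges$genome_a < edges$genome_b,
                      paste(edges$genome_a, edges$genome_b, sep = "\r"),
                      paste(edges$genome_b, edges$genome_a, sep = "\r"))
        ani <- tapply(edges$ani, key, max)
        pairs <- do.call(rbind, strsplit(names(ani), "\r", fixed = TRUE))
        keep <- ani >= threshold
        el <- pairs[keep, , drop = FALSE]
    } else {
        el <- matrix(character(), ncol = 2)
    }
    g <- igraph::graph_from_data_frame(
        data.frame(from = el[, 1], to = el[, 2]),
        directed = FALSE,
        vertices = data.frame(name = genomes))
    comp <- igraph::components(g)
    membership <- comp$membership[genomes]

    # deterministic numbering: size desc, then smallest member
    comps <- split(genomes, membership)
    sizes <- lengths(comps)
    firsts <- vapply(comps, function(m) min(m), character(1))
    ord <- order(-sizes, firsts)
    rank <- integer(length(comps))
    rank[ord] <- seq_along(ord) - 1L
    ids <- paste0(prefix, rank[match(membership, as.integer(names(comps)))])
    names(ids) <- genomes
    new("ClusterMap", assignments = ids, prefix = prefix)
}

#' Partition proteins by species-level cluster
#'
#' Splits a protein universe by the SLC of each protein's source genome,
#' yielding the per-SLC panproteomes on which orthogroup inference runs.
#'
#' @param proteinToGenome named character vector protein id -> genome id.
#' @param clusterMap [ClusterMap-class] over the genomes.
#' @return named list cluster id -> character vector of protein ids; a
#'   disjoint cover of all proteins.
#' @export
partitionProteinsBySLC <- function(proteinToGenome, clusterMap) {
    if (!length(proteinToGenome)) return(structure(list(), names = character()))
    asg <- clusterAssignments(clusterMap)
    orphan <- setdiff(unique(proteinToGenome), names(asg))
    if (length(orphan))
        stop("protein(s) from unclustered genome(s): ",
             paste(orphan, collapse = ", "))
    split(names(proteinToGenome), asg[proteinToGenome])
}

#' Assign globally unique SSO identifiers
#'
#' SLC-specific orthogroups (SSOs) are computed independently within each
#' SLC, so their local labels collide across clusters. Global SSO ids are
#' `"<cluster_id>_<local label>"`. Proteins placed in no orthogroup are
#' flagged unclustered, not assigned (they are excluded from functional
#' feature compression).
#'
#' @param orthogroups named list cluster id -> named character vector
#'   protein id -> local orthogroup label.
#' @param proteins optional character vector of the full protein universe;
#'   when given, `unclustered` lists the proteins absent from every
#'   orthogroup.
#' @return list with `sso` (named character vector protein -> SSO id) and
#'   `unclustered` (character vector).
#' @export
assignSsoIds <- function(orthogroups, proteins = NULL) {
    sso <- character()
    for (cl in names(orthogroups)) {
        local <- orthogroups[[cl]]
        if (!length(local)) next
        if (anyDuplicated(names(local)))
            stop("cluster ", sQuote(cl), ": protein assigned to multiple ",
                 "orthogroups")
        ids <- paste0(cl, "_", local)
        names(ids) <- names(local)
        overlap <- intersect(names(ids), names(sso))
        if (length(overlap))
            stop("protein(s) present in multiple clusters: ",
                 paste(overlap, collapse = ", "))
        sso <- c(sso, ids)
    }
    unclustered <- if (is.null(proteins)) character()
                   else setdiff(proteins, names(sso))
    list(sso = sso, unclustered = unclustered)
}

#' Filter a genome-by-marker presence matrix for phylogeny input
#'
#' Two-stage filter preparing concatenated marker alignments: first,
#' non-informative markers present in fewer than `minGenomesRatio` of the
#' genomes are removed; then, poor-quality genomes containing fewer than
#' `minMarkersRatio` of the *retained* markers are removed. One pass, in
#' that order (no iteration to a fixpoint).
#'
#' @param presence logical (or 0/1) matrix, genomes x markers, with
#'   dimnames.
#' @param minMarkersRatio fraction in \[0, 1\]: minimum share of retained
#'   markers a genome must carry.
#' @param minGenomesRatio fraction in \[0, 1\]: minimum share of genomes a
#'   marker must occur in.
#' @return list with `genomes` and `markers` (character vectors of kept
#'   ids) and the filtered `presence` matrix.
#' @export
markerMatrixFilter <- function(presence, minMarkersRatio = 0.5,
                               minGenomesRatio = 0.5) {
    stopifnot(minMarkersRatio >= 0, minMarkersRatio <= 1,
              minGenomesRatio >= 0, minGenomesRatio <= 1)
    if (!nrow(presence) || !ncol(presence))
        stop("empty presence matrix")
    m <- presence != 0
    keepMarkers <- colMeans(m) >= minGenomesRatio
    m2 <- m[, keepMarkers, drop = FALSE]
    keepGenomes <- if (ncol(m2)) rowMeans(m2) >= minMarkersRatio
                   else rep(FALSE, nrow(m2))
    list(genomes = rownames(m2)[keepGenomes],
         markers = colnames(m2),
         presence = presence[keepGenomes, keepMarkers, drop = FALSE])
}

#' Read an ANI edge list
#'
#' Three-or-more-column TSV `(query, reference, ani)` as emitted by
#' whole-genome ANI tools; extra columns are ignored. No header expected.
#'
#' @param file TSV path.
#' @return `data.frame` with columns `genome_a`, `genome_b`, `ani`.
#' @export
readAniEdges <- function(file) {
    tab <- utils::read.delim(file, header = FALSE, stringsAsFactors = FALSE)
    data.frame(genome_a = tab[[1]], genome_b = tab[[2]],
               ani = as.numeric(tab[[3]]), stringsAsFactors = FALSE)
}
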