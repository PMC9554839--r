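# Independent brute-force oracles used across the suite.

# Connected components by transitive closure over an adjacency matrix;
# independent of the graph-library route used by clusterSLC().
bruteForceComponents <- function(genomes, edges, threshold) {
  n <- length(genomes)
  adj <- diag(TRUE, n)
  dimnames(adj) <- list(genomes, genomes)
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      a <- edges$genome_a[i]; b <- edges$genome_b[i]
      if (a != b && edges$ani[i] >= threshold) {
        adj[a, b] <- TRUE
        adj[b, a] <- TRUE
      }
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj > 0)) break
    adj <- nxt
  }
  # canonical label: smallest member of each closure row
  apply(adj, 1, function(r) min(genomes[r]))
}

# Exhaustive prefix-score enumerator for consensus taxonomy: scores every
# prefix by looping over hits directly (no shared code with the package).
bruteForcePrefixScores <- function(lineages, scores, leniency) {
  lins <- strsplit(lineages, ";", fixed = TRUE)
  depth <- max(lengths(lins))
  w <- seq_len(depth)^(1 / leniency)
  allPrefixes <- unique(unlist(lapply(lins, function(l)
    vapply(seq_along(l), function(i) paste(l[1:i], collapse = ";"),
           character(1)))))
  out <- vapply(allPrefixes, function(p) {
    lev <- length(strsplit(p, ";", fixed = TRUE)[[1]])
    s <- 0
    for (h in seq_along(lins)) {
      l <- lins[[h]]
      if (length(l) >= lev &&
          paste(l[1:lev], collapse = ";") == p)
        s <- s + w[lev] * scores[h]
    }
    s
  }, numeric(1))
  data.frame(prefix = allPrefixes, score = unname(out),
             stringsAsFactors = FALSE)
}

# N50 by literal definition: largest L in the multiset such that the sum of
# lengths >= L covers at least half the total.
bruteForceN50 <- function(lengths) {
  total <- sum(lengths)
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) {
    if (sum(lengths[lengths >= L]) >= total / 2) return(L)
  }
  min(lengths)
}

# A deterministic synthetic binner: groups contigs into bins of `size`
# members in pool order, optionally leaving a fraction unassigned.
makeChunkBinner <- function(name, size = 5L, assignFraction = 1) {
  binnerAdapter(name, function(contigs, coverage, seed) {
    ids <- contigs$contig_id
    nAssign <- floor(length(ids) * assignFraction)
    if (nAssign == 0L) return(setNames(character(), character()))
    ids <- ids[seq_len(nAssign)]
    labels <- paste0("bin.", ceiling(seq_along(ids) / size))
    setNames(labels, ids)
  })
}
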