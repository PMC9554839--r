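#' Fixture generation parameters
#'
#' Bundle of planted-structure parameters consumed by the `make*Fixture`
#' generators. Every generator is a pure function of its spec (seed
#' included): the same spec reproduces the same fixture byte-for-byte.
#'
#' @param seed integer RNG seed.
#' @param nSamples samples per condition.
#' @param nGenomes number of genomes (or planted clusters x members, see
#'   the individual generators).
#' @param nContigsPerGenome contigs per genome.
#' @param nFeatures feature count for counts fixtures.
#' @param domainWeights named numeric mixture weights over planted domain
#'   categories (summing to 1).
#' @param dirichletConcentration concentration of the planted domain in
#'   each contig's probability vector (larger = cleaner predictions).
#' @param withinAniRange,betweenAniRange numeric length-2 ANI ranges
#'   (percent) for intra-/inter-cluster edges; must not overlap.
#' @param latentCorrelation log-scale correlation of planted proportional
#'   feature pairs.
#' @param lineageDepth depth of planted lineages (>= 2).
#' @param meanLogLength,sdLogLength log-normal contig length parameters
#'   (natural log of bp).
#' @param depth sequencing depth (reads per sample) for counts fixtures.
#' @return list of class `"FixtureSpec"`.
#' @export
fixtureSpec <- function(seed = 1L, nSamples = 40L, nGenomes = 12L,
                        nContigsPerGenome = 10L, nFeatures = 20L,
                        domainWeights = c(prokaryota = 0.7, eukaryota = 0.3),
                        dirichletConcentration = 20,
                        withinAniRange = c(96, 99),
                        betweenAniRange = c(80, 90),
                        latentCorrelation = 0.9,
                        lineageDepth = 5L,
                        meanLogLength = 8.5, sdLogLength = 1,
                        depth = 1e5) {
    spec <- list(seed = as.integer(seed), nSamples = as.integer(nSamples),
                 nGenomes = as.integer(nGenomes),
                 nContigsPerGenome = as.integer(nContigsPerGenome),
                 nFeatures = as.integer(nFeatures),
                 domainWeights = domainWeights,
                 dirichletConcentration = dirichletConcentration,
                 withinAniRange = withinAniRange,
                 betweenAniRange = betweenAniRange,
                 latentCorrelation = latentCorrelation,
                 lineageDepth = as.integer(lineageDepth),
                 meanLogLength = meanLogLength, sdLogLength = sdLogLength,
                 depth = depth)
    counts <- c("nSamples", "nGenomes", "nContigsPerGenome", "nFeatures",
                "lineageDepth")
    if (any(vapply(spec[counts], function(x) x < 1L, logical(1))))
        stop("all counts must be positive")
    if (abs(sum(domainWeights) - 1) > 1e-9)
        stop("domainWeights must sum to 1")
    if (abs(latentCorrelation) > 1)
        stop("latentCorrelation must lie in [-1, 1]")
    structure(spec, class = "FixtureSpec")
}

.dirichlet <- function(n, alpha) {
    x <- matrix(rgamma(n * length(alpha), shape = alpha), n, byrow = TRUE)
    x / rowSums(x)
}

#' Synthetic contig set with per-contig domain probabilities
#'
#' Contigs with log-normal lengths; each contig is assigned a planted
#' domain drawn from `domainWeights`, and its prediction probability
#' vector is Dirichlet with concentration mass on the planted domain
#' (`dirichletConcentration` on the truth, 1 elsewhere), emulating a
#' contig-level domain predictor's output.
#'
#' @param spec A [fixtureSpec()].
#' @return list with `contigs` (`data.frame`: `contig_id`, `sample_id`,
#'   `length`, `true_domain`) and `domainProbabilities` (matrix contigs x
#'   categories).
#' @export
makeContigSet <- function(spec) {
    stopifnot(inherits(spec, "FixtureSpec"))
    set.seed(spec$seed)
    n <- spec$nGenomes * spec$nContigsPerGenome
    cats <- names(spec$domainWeights)
    truth <- sample(cats, n, replace = TRUE, prob = spec$domainWeights)
    probs <- matrix(NA_real_, n, length(cats),
                    dimnames = list(NULL, cats))
    for (i in seq_len(n)) {
        alpha <- rep(1, length(cats))
        alpha[match(truth[i], cats)] <- spec$dirichletConcentration
        probs[i, ] <- .dirichlet(1, alpha)
    }
    ids <- sprintf("contig_%04d", seq_len(n))
    rownames(probs) <- ids
    contigs <- data.frame(
        contig_id = ids, sample_id = "S1",
        length = pmax(1L, as.integer(round(rlnorm(
            n, spec$meanLogLength, spec$sdLogLength)))),
        true_domain = truth, stringsAsFactors = FALSE)
    list(contigs = contigs, domainProbabilities = probs)
}

#' Synthetic ANI edge list with planted species clusters
#'
#' Genomes are partitioned into equally sized planted clusters; all
#' intra-cluster pairs get ANI drawn uniformly from `withinAniRange` and
#' all inter-cluster pairs from `betweenAniRange`. Because the ranges must
#' be disjoint (within strictly above between), any threshold separating
#' them recovers the planted partition exactly.
#'
#' @param spec A [fixtureSpec()]; `nGenomes` must be divisible by
#'   `nClusters`.
#' @param nClusters number of planted clusters.
#' @return list with `genomes`, `edges` (`data.frame`), and `truth`
#'   (named integer vector genome -> planted cluster index).
#' @export
makeAniFixture <- function(spec, nClusters = 3L) {
    stopifnot(inherits(spec, "FixtureSpec"))
    if (min(spec$withinAniRange) <= max(spec$betweenAniRange))
        stop("within-cluster ANI range must lie strictly above the ",
             "between-cluster range")
    if (spec$nGenomes %% nClusters != 0)
        stop("nGenomes must be divisible by nClusters")
    set.seed(spec$seed)
    genomes <- sprintf("G%03d", seq_len(spec$nGenomes))
    truth <- rep(seq_len(nClusters), each = spec$nGenomes / nClusters)
    names(truth) <- genomes
    pairs <- t(utils::combn(genomes, 2))
    same <- truth[pairs[, 1]] == truth[pairs[, 2]]
    ani <- numeric(nrow(pairs))
    ani[same] <- runif(sum(same), spec$withinAniRange[1],
                       spec$withinAniRange[2])
    ani[!same] <- runif(sum(!same), spec$betweenAniRange[1],
                        spec$betweenAniRange[2])
    list(genomes = genomes,
         edges = data.frame(genome_a = pairs[, 1], genome_b = pairs[, 2],
                            ani = ani, stringsAsFactors = FALSE),
         truth = truth)
}

#' Synthetic two-condition counts matrices with planted proportional pairs
#'
#' Log-normal abundance profiles closed to a fixed sequencing depth per
#' sample (multinomial draw), emulating compositional count data. Selected
#' feature pairs share a latent log-scale factor with correlation
#' `latentCorrelation` in condition A only; in condition B all features
#' are independent. These pairs are the planted differential
#' co-occurrence signal.
#'
#' @param spec A [fixtureSpec()].
#' @param nPlantedPairs number of planted pairs (disjoint features, taken
#'   from the front of the feature axis).
#' @return list with `countsA`, `countsB` (samples x features integer
#'   matrices) and `plantedPairs` (2-column matrix of feature ids).
#' @export
makeCountsFixture <- function(spec, nPlantedPairs = 1L) {
    stopifnot(inherits(spec, "FixtureSpec"))
    m <- spec$nFeatures
    if (2L * nPlantedPairs > m)
        stop("too many planted pairs for the feature count")
    set.seed(spec$seed)
    feats <- sprintf("F%03d", seq_len(m))
    r <- spec$latentCorrelation

    drawCondition <- function(planted) {
        logAbund <- matrix(rnorm(spec$nSamples * m), spec$nSamples, m)
        if (planted) {
            for (k in seq_len(nPlantedPairs)) {
                i <- 2L * k - 1L; j <- 2L * k
                z <- rnorm(spec$nSamples)
                logAbund[, i] <- sqrt(abs(r)) * z +
                    sqrt(1 - abs(r)) * rnorm(spec$nSamples)
                logAbund[, j] <- sign(r) * sqrt(abs(r)) * z +
                    sqrt(1 - abs(r)) * rnorm(spec$nSamples)
            }
        }
        # feature-specific baselines, then close to fixed depth
        base <- rnorm(m, sd = 1)
        intensity <- exp(sweep(logAbund, 2, base, "+"))
        counts <- t(apply(intensity, 1, function(p)
            rmultinom(1, size = spec$depth, prob = p)[, 1]))
        dimnames(counts) <- list(sprintf("sample_%02d", seq_len(spec$nSamples)),
                                 feats)
        counts
    }
    countsA <- drawCondition(TRUE)
    countsB <- drawCondition(FALSE)
    planted <- cbind(feats[seq(1, by = 2, length.out = nPlantedPairs)],
                     feats[seq(2, by = 2, length.out = nPlantedPairs)])
    colnames(planted) <- c("feature_a", "feature_b")
    list(countsA = countsA, countsB = countsB, plantedPairs = planted)
}

#' Synthetic protein lineage hit table with a planted consensus lineage
#'
#' Generates per-protein lineage hits for one genome: a majority of the
#' score mass follows the planted lineage to full depth, while
#' contamination hits diverge at a chosen level onto a decoy branch.
#' Scores are gamma-distributed around a bitscore-like scale. With low
#' contamination the planted lineage is recovered at leniency 1.
#'
#' @param spec A [fixtureSpec()].
#' @param genomeId genome identifier for the hit table.
#' @param nHits number of protein hits.
#' @param contamination fraction of hits on the decoy branch.
#' @param divergeLevel lineage level (1-based) at which decoy hits branch
#'   off; levels above it are shared.
#' @return list with `hits` (`data.frame`: `protein_id`, `genome_id`,
#'   `lineage`, `score`) and `plantedLineage` (semicolon string).
#' @export
makeAnnotationFixture <- function(spec, genomeId = "G001", nHits = 50L,
                                  contamination = 0.1, divergeLevel = NULL) {
    stopifnot(inherits(spec, "FixtureSpec"))
    depth <- spec$lineageDepth
    if (depth < 2) stop("lineage depth must be >= 2")
    if (is.null(divergeLevel)) divergeLevel <- depth
    stopifnot(divergeLevel >= 2, divergeLevel <= depth)
    set.seed(spec$seed)
    planted <- paste0("T", seq_len(depth), ".a")
    decoy <- planted
    decoy[divergeLevel:depth] <- paste0("T", divergeLevel:depth, ".b")
    nDecoy <- round(nHits * contamination)
    lineages <- c(rep(paste(planted, collapse = ";"), nHits - nDecoy),
                  rep(paste(decoy, collapse = ";"), nDecoy))
    hits <- data.frame(
        protein_id = sprintf("%s_p%04d", genomeId, seq_len(nHits)),
        genome_id = genomeId,
        lineage = sample(lineages),
        score = rgamma(nHits, shape = 20, rate = 0.1),
        stringsAsFactors = FALSE)
    list(hits = hits, plantedLineage = paste(planted, collapse = ";"))
}

#' Write a contig fixture as FASTA plus a domain-probability TSV
#'
#' Convenience exporter for the file-based interfaces: random sequences of
#' the recorded lengths (capped for practicality) and the probability
#' table in the contig-predictor TSV layout.
#'
#' @param fixture result of [makeContigSet()].
#' @param dir output directory (created if needed).
#' @param maxSeqLength cap on written sequence length (bp).
#' @return invisible character vector of the files written.
#' @export
writeContigFixture <- function(fixture, dir, maxSeqLength = 2000L) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    lens <- pmin(fixture$contigs$length, maxSeqLength)
    seqs <- vapply(lens, function(L)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
              collapse = ""), character(1))
    dna <- Biostrings::DNAStringSet(seqs)
    names(dna) <- fixture$contigs$contig_id
    fa <- file.path(dir, "contigs.fasta")
    Biostrings::writeXStringSet(dna, fa)
    tsv <- file.path(dir, "domain_probabilities.tsv")
    utils::write.table(
        data.frame(contig_id = rownames(fixture$domainProbabilities),
                   fixture$domainProbabilities, check.names = FALSE),
        tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(fa, tsv))
}
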