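#' Construct a GenomeName
#'
#' @param sampleId Source sample identifier (no underscores).
#' @param algorithm Binning algorithm label (no underscores).
#' @param domainTag `"P"` (prokaryotic), `"E"` (eukaryotic) or `"V"` (viral).
#' @param iteration Binning iteration, required for `"P"`/`"E"`, must be
#'   absent (`NA`) for `"V"`.
#' @param localName Algorithm-local bin name, e.g. `"bin.1"`.
#' @return A [GenomeName-class] object.
#' @examples
#' nm <- GenomeName("SRR17458623", "METABAT2", "P", 1, "bin.1")
#' renderGenomeName(nm)
#' @export
GenomeName <- function(sampleId, algorithm, domainTag, iteration = NA, localName) {
    new("GenomeName",
        sampleId = as.character(sampleId),
        algorithm = as.character(algorithm),
        domainTag = as.character(domainTag),
        iteration = as.integer(iteration),
        localName = as.character(localName))
}

#' Render a genome name to its canonical string
#'
#' Prokaryotic/eukaryotic scheme: `Sample_Algorithm_<P|E>.<iteration>_Name`.
#' Viral scheme: `Sample_Algorithm_Name` (no iteration field, since viral
#' detection is single-pass).
#'
#' @param name A [GenomeName-class].
#' @return character(1) canonical name; `parseGenomeName(renderGenomeName(x))`
#'   reproduces `x`.
#' @export
renderGenomeName <- function(name) {
    stopifnot(is(name, "GenomeName"))
    validObject(name)
    if (name@domainTag == "V") {
        paste(name@sampleId, name@algorithm, name@localName, sep = "_")
    } else {
        paste(name@sampleId, name@algorithm,
              paste0(name@domainTag, ".", name@iteration, "_", name@localName),
              sep = "_")
    }
}

#' Parse a canonical genome name string
#'
#' @param x character(1) rendered genome name.
#' @return A [GenomeName-class].
#' @export
parseGenomeName <- function(x) {
    stopifnot(is.character(x), length(x) == 1L)
    m <- regmatches(x, regexec(
        "^([^_]+)_([^_]+)_(?:([PE])\\.([0-9]+)_(.+)|(.+))$", x))[[1]]
    if (!length(m))
        stop("cannot parse genome name: ", sQuote(x))
    if (nzchar(m[4L])) {
        GenomeName(m[2L], m[3L], m[4L], as.integer(m[5L]), m[6L])
    } else {
        GenomeName(m[2L], m[3L], "V", NA, m[7L])
    }
}

#' Simplify eukaryotic gene identifiers
#'
#' Exon-aware gene callers emit long, parser-hostile identifiers; downstream
#' counting wants short stable ones. Genes are renamed to
#' `ContigID_GeneStart:GeneEnd(strand)`. Exact duplicates (identical contig,
#' coordinates and strand occurring more than once) receive a deterministic
#' `.k` suffix, `k` being the 1-based occurrence index, so no two emitted
#' identifiers collide.
#'
#' @param contigId character vector of contig ids.
#' @param start,end integer vectors, 1-based inclusive gene coordinates,
#'   `start <= end`.
#' @param strand character vector of `"+"`/`"-"`.
#' @return character vector of unique simplified gene ids.
#' @examples
#' simplifyEukaryoticGeneId("k127_001", 100, 900, "+")
#' @export
simplifyEukaryoticGeneId <- function(contigId, start, end, strand) {
    start <- as.integer(start); end <- as.integer(end)
    if (any(start > end))
        stop("gene start must not exceed end")
    if (!all(strand %in% c("+", "-")))
        stop("strand must be '+' or '-'")
    ids <- sprintf("%s_%d:%d(%s)", contigId, start, end, strand)
    occ <- stats::ave(seq_along(ids), ids, FUN = seq_along)
    dup <- occ > 1L
    ids[dup] <- sprintf("%s.%d", ids[dup], occ[dup])
    ids
}

.checkGeneTable <- function(tab, what) {
    need <- c("contig_id", "gene_id", "start", "end", "strand")
    if (!all(need %in% names(tab)))
        stop(what, " gene table must have columns: ",
             paste(need, collapse = ", "))
    if (nrow(tab)) {
        if (any(tab$start > tab$end))
            stop(what, ": start > end")
        if (!all(tab$strand %in% c("+", "-")))
            stop(what, ": invalid strand")
    }
    tab
}

#' Harmonize eukaryotic and prokaryotic gene models
#'
#' Merges gene tables from an exon-aware eukaryotic caller and a prokaryotic
#' caller into one GFF3-ready [GenomicRanges::GRanges] stream whose records
#' all expose the gene and contig identifiers under the shared attribute key
#' `gene_id` (the default attribute consumed by read-counting tools), so one
#' counting pass covers both domains.
#'
#' @param eukGenes,prokGenes `data.frame`s with columns `contig_id`,
#'   `gene_id`, `start`, `end`, `strand` (1-based inclusive coordinates).
#'   Either may be empty.
#' @param contigLengths optional named integer vector; when supplied, genes
#'   extending past their contig raise an error.
#' @return A `GRanges` with metadata columns `source`, `type`, `gene_id`,
#'   `contig_id`; write it with [exportGff3()].
#' @export
harmonizeGeneModels <- function(eukGenes, prokGenes, contigLengths = NULL) {
    euk  <- .checkGeneTable(eukGenes,  "eukaryotic")
    prok <- .checkGeneTable(prokGenes, "prokaryotic")
    tab <- rbind(
        if (nrow(euk))  cbind(euk[ , c("contig_id", "gene_id", "start", "end",
                                       "strand")], source = "euk")  else NULL,
        if (nrow(prok)) cbind(prok[, c("contig_id", "gene_id", "start", "end",
                                       "strand")], source = "prok") else NULL)
    if (is.null(tab))
        tab <- data.frame(contig_id = character(), gene_id = character(),
                          start = integer(), end = integer(),
                          strand = character(), source = character())
    if (anyDuplicated(tab$gene_id))
        stop("duplicate gene ids after merging")
    if (!is.null(contigLengths) && nrow(tab)) {
        len <- contigLengths[tab$contig_id]
        bad <- !is.na(len) & tab$end > len
        if (any(bad))
            stop("gene(s) extend past contig end: ",
                 paste(tab$gene_id[bad], collapse = ", "))
    }
    gr <- GenomicRanges::GRanges(
        seqnames = tab$contig_id,
        ranges   = IRanges::IRanges(start = tab$start, end = tab$end),
        strand   = tab$strand)
    S4Vectors::mcols(gr)$source    <- tab$source
    S4Vectors::mcols(gr)$type      <- "gene"
    S4Vectors::mcols(gr)$gene_id   <- tab$gene_id
    S4Vectors::mcols(gr)$contig_id <- tab$contig_id
    names(gr) <- tab$gene_id
    gr
}

#' Write harmonized gene models as GFF3
#'
#' @param gr `GRanges` from [harmonizeGeneModels()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
exportGff3 <- function(gr, file) {
    rtracklayer::export(gr, file, format = "GFF3")
    invisible(file)
}

#' Assembly summary statistics
#'
#' N50, contig count, total size, GC fraction and coding density for one
#' assembly. N50 is the smallest contig length L such that contigs of length
#' >= L jointly cover at least half of the assembly. GC counts only
#' unambiguous A/C/G/T in both numerator and denominator. Coding density is
#' the fraction of assembled bases covered by the union of coding spans
#' (overlaps are merged, not double-counted).
#'
#' @param lengths positive integer vector of contig lengths (bp).
#' @param sequences optional character vector or
#'   [Biostrings::DNAStringSet] of contig sequences (for GC content).
#' @param codingSpans optional `data.frame` with columns `contig_id`,
#'   `start`, `end` (1-based inclusive) of coding regions; `contig_id`
#'   must index into `names(lengths)` when lengths are named.
#' @return list with `n50`, `n_contigs`, `total_bp`, `gc_fraction`
#'   (`NA` without sequences), `coding_density` (`NA` without spans).
#' @examples
#' assemblyStats(c(6, 5, 4, 3, 2))$n50  # 5
#' @export
assemblyStats <- function(lengths, sequences = NULL, codingSpans = NULL) {
    if (!length(lengths))
        stop("empty assembly")
    if (any(lengths <= 0))
        stop("contig lengths must be positive")
    lens <- sort(as.numeric(lengths), decreasing = TRUE)
    total <- sum(lens)
    n50 <- lens[which(cumsum(lens) >= total / 2)[1L]]

    gc <- NA_real_
    if (!is.null(sequences)) {
        if (!is(sequences, "DNAStringSet"))
            sequences <- Biostrings::DNAStringSet(sequences)
        counts <- Biostrings::letterFrequency(sequences, c("A", "C", "G", "T"))
        tot <- colSums(counts)
        gc <- unname((tot[["G"]] + tot[["C"]]) / sum(tot))
    }

    cd <- NA_real_
    if (!is.null(codingSpans)) {
        if (nrow(codingSpans) == 0L) {
            cd <- 0
        } else {
            spans <- split(
                IRanges::IRanges(codingSpans$start, codingSpans$end),
                codingSpans$contig_id)
            covered <- sum(vapply(
                spans, function(x) sum(IRanges::width(IRanges::reduce(x))),
                numeric(1)))
            cd <- covered / total
        }
    }

    list(n50 = n50, n_contigs = length(lengths), total_bp = total,
         gc_fraction = gc, coding_density = cd)
}

#' Read / write identifier-map tables
#'
#' Tiered feature-to-parent tables (contig -> MAG -> SLC; ORF -> SSO) kept
#' as TSV with a header row `feature_id`, `parent_id`, `tier`.
#'
#' @param maps named list of `data.frame`s with columns `feature_id`,
#'   `parent_id`; names are tier labels.
#' @param file TSV path.
#' @return `readIdentifierMap` returns the named list of per-tier tables.
#' @export
writeIdentifierMap <- function(maps, file) {
    tab <- do.call(rbind, lapply(names(maps), function(tier) {
        m <- maps[[tier]]
        if (anyDuplicated(m$feature_id))
            stop("tier ", sQuote(tier), ": a feature maps to multiple parents")
        data.frame(feature_id = m$feature_id, parent_id = m$parent_id,
                   tier = tier, stringsAsFactors = FALSE)
    }))
    utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' @rdname writeIdentifierMap
#' @export
readIdentifierMap <- function(file) {
    tab <- utils::read.delim(file, stringsAsFactors = FALSE)
    split(tab[, c("feature_id", "parent_id")], tab$tier)
}
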