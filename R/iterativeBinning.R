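#' Deterministic per-iteration seed policy
#'
#' Each binning iteration runs under its own random seed state so that
#' recycled unbinned contigs face a fresh stochastic start. The policy is a
#' pure function: `(baseSeed + iteration * 104729) mod (2^31 - 1)` (104729
#' is prime), giving distinct, replayable seeds across iterations.
#'
#' @param baseSeed integer base seed.
#' @param iteration iteration number (>= 1).
#' @return integer seed.
#' @export
seedPolicy <- function(baseSeed, iteration) {
    stopifnot(iteration >= 1)
    as.integer((as.numeric(baseSeed) + as.numeric(iteration) * 104729) %%
               2147483647)
}

#' Construct a binner adapter
#'
#' Wraps an external (or synthetic) binning algorithm behind the adapter
#' contract used by [runIterativeBinning()]: `fun(contigs, coverage, seed)`
#' must return a named character vector mapping a subset of
#' `contigs$contig_id` to local bin labels (unassigned contigs omitted)
#' and be deterministic given its inputs and seed.
#'
#' @param name algorithm label (no underscores; it becomes the algorithm
#'   field of accepted genome names).
#' @param fun the binning function.
#' @return list with class `"BinnerAdapter"`.
#' @export
binnerAdapter <- function(name, fun) {
    stopifnot(is.character(name), length(name) == 1L, nzchar(name),
              !grepl("_", name, fixed = TRUE), is.function(fun))
    structure(list(name = name, bin = fun), class = "BinnerAdapter")
}

#' Greedy consensus dereplication of candidate bins
#'
#' Built-in stand-in for an external consensus dereplication tool: candidate
#' bins from all binners are accepted greedily in descending quality score
#' (ties by bin key, lexicographic, for determinism); a bin is accepted only
#' if none of its contigs is already claimed by an accepted bin. The result
#' is a partial partition of the contigs.
#'
#' @param candidates named list (one element per binner) of named character
#'   vectors contig_id -> local bin label.
#' @param scores named numeric vector keyed by `"<binner>:<label>"`; every
#'   candidate bin must be scored.
#' @return `data.frame` with columns `binner`, `label`, `contig_id` for the
#'   accepted bins.
#' @export
dereplicateCandidateBins <- function(candidates, scores) {
    bins <- list()
    for (binner in names(candidates)) {
        asg <- candidates[[binner]]
        for (label in unique(asg)) {
            key <- paste0(binner, ":", label)
            bins[[key]] <- list(binner = binner, label = label,
                                contigs = names(asg)[asg == label])
        }
    }
    if (!length(bins))
        return(data.frame(binner = character(), label = character(),
                          contig_id = character(), stringsAsFactors = FALSE))
    missing <- setdiff(names(bins), names(scores))
    if (length(missing))
        stop("unscored candidate bin(s): ", paste(missing, collapse = ", "))
    ord <- names(bins)[order(-scores[names(bins)], names(bins))]
    claimed <- character()
    out <- list()
    for (key in ord) {
        b <- bins[[key]]
        if (!any(b$contigs %in% claimed)) {
            claimed <- c(claimed, b$contigs)
            out[[key]] <- data.frame(binner = b$binner, label = b$label,
                                     contig_id = b$contigs,
                                     stringsAsFactors = FALSE)
        }
    }
    if (!length(out))
        return(data.frame(binner = character(), label = character(),
                          contig_id = character(), stringsAsFactors = FALSE))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Iterative consensus binning
#'
#' The iterative recovery loop: at each iteration all binner adapters run
#' on the remaining contig pool under a fresh seed from [seedPolicy()],
#' their candidate bins are consensus-dereplicated, the quality gate is
#' applied, and accepted bins — named `Sample_Binner_<tag>.<iteration>_label`
#' — have their contigs removed from the pool before the next round.
#' Unbinned contigs are thus recycled with a separate random seed state
#' until `nIter` is reached or an iteration accepts nothing (early stop,
#' since deterministic adapters would repeat themselves; `forceAllIterations`
#' overrides this).
#'
#' @param contigs `data.frame` with columns `contig_id`, `length`; all
#'   contigs entering the procedure.
#' @param coverage opaque coverage object handed to each binner.
#' @param binners list of [binnerAdapter()] objects.
#' @param qc function(binContigs data.frame) -> logical; the per-bin
#'   quality gate (runs after dereplication, before contig removal, so
#'   rejected bins recycle).
#' @param nIter maximum number of iterations (>= 1).
#' @param baseSeed integer base seed.
#' @param sampleId sample identifier for genome naming.
#' @param domainTag `"P"` (default) or `"E"`.
#' @param scoreFun function(binContigs) -> numeric quality score used by
#'   the dereplicator (default: total bp).
#' @param dereplicator consensus dereplication function with the signature
#'   of [dereplicateCandidateBins()].
#' @param forceAllIterations run all `nIter` iterations even when an
#'   iteration accepts no bins.
#' @return list with `genomes` (named list genome name -> contig id
#'   vector), `unbinned` (contig ids), `records` (`data.frame` with one
#'   row per executed iteration: `iteration`, `seed`, `bins_accepted`,
#'   `contigs_binned`, `contigs_remaining`), and `identifierMap`
#'   (`data.frame` contig -> genome).
#' @export
runIterativeBinning <- function(contigs, coverage = NULL, binners, qc,
                                nIter = 3, baseSeed = 0,
                                sampleId = "S1", domainTag = c("P", "E"),
                                scoreFun = function(b) sum(b$length),
                                dereplicator = dereplicateCandidateBins,
                                forceAllIterations = FALSE) {
    domainTag <- match.arg(domainTag)
    stopifnot(nIter >= 1, length(binners) >= 1)
    stopifnot(all(c("contig_id", "length") %in% names(contigs)))
    if (anyDuplicated(contigs$contig_id))
        stop("duplicate contig ids")

    pool <- contigs
    genomes <- list()
    records <- list()
    for (t in seq_len(nIter)) {
        if (!nrow(pool)) break
        seed <- seedPolicy(baseSeed, t)
        entering <- nrow(pool)

        candidates <- list()
        for (b in binners) {
            asg <- tryCatch(b$bin(pool, coverage, seed), error = function(e)
                stop("binner ", sQuote(b$name), " failed at iteration ", t,
                     ": ", conditionMessage(e)))
            if (length(asg)) {
                stray <- setdiff(names(asg), pool$contig_id)
                if (length(stray))
                    stop("binner ", sQuote(b$name),
                         " assigned contigs absent from the pool: ",
                         paste(stray, collapse = ", "))
                candidates[[b$name]] <- asg
            }
        }

        scores <- numeric()
        for (binner in names(candidates)) {
            asg <- candidates[[binner]]
            for (label in unique(asg)) {
                members <- pool[pool$contig_id %in% names(asg)[asg == label], ,
                                drop = FALSE]
                scores[[paste0(binner, ":", label)]] <- scoreFun(members)
            }
        }

        consensus <- dereplicator(candidates, scores)
        acceptedNames <- character()
        binnedIds <- character()
        if (nrow(consensus)) {
            keys <- unique(paste0(consensus$binner, ":", consensus$label))
            for (key in keys) {
                sel <- paste0(consensus$binner, ":", consensus$label) == key
                members <- pool[pool$contig_id %in% consensus$contig_id[sel], ,
                                drop = FALSE]
                if (isTRUE(qc(members))) {
                    nm <- renderGenomeName(GenomeName(
                        sampleId, consensus$binner[sel][1L], domainTag, t,
                        consensus$label[sel][1L]))
                    genomes[[nm]] <- members$contig_id
                    acceptedNames <- c(acceptedNames, nm)
                    binnedIds <- c(binnedIds, members$contig_id)
                }
            }
        }

        pool <- pool[!pool$contig_id %in% binnedIds, , drop = FALSE]
        records[[t]] <- data.frame(
            iteration = t, seed = seed,
            bins_accepted = length(acceptedNames),
            contigs_binned = length(binnedIds),
            contigs_remaining = nrow(pool), stringsAsFactors = FALSE)
        stopifnot(length(binnedIds) + nrow(pool) == entering)
        if (!length(acceptedNames) && !forceAllIterations) break
    }

    idMap <- if (length(genomes)) {
        data.frame(
            feature_id = unlist(genomes, use.names = FALSE),
            parent_id = rep(names(genomes), lengths(genomes)),
            stringsAsFactors = FALSE)
    } else {
        data.frame(feature_id = character(), parent_id = character(),
                   stringsAsFactors = FALSE)
    }
    list(genomes = genomes, unbinned = pool$contig_id,
         records = do.call(rbind, records), identifierMap = idMap)
}

#' Build a pseudo-coassembly from unbinned contigs
#'
#' The pseudo-coassembly is the union of contigs from all samples that
#' could not be binned sample-specifically; it serves as a multi-sample
#' reference for one more binning pass, on the premise that each sample
#' holds incomplete fragments of the same genomes. Contig ids are prefixed
#' with their sample id (separator `"__"`) so they parse back to their
#' source sample, and the standard contig length filter is applied.
#'
#' @param unbinnedPerSample named list sample id -> `data.frame` with
#'   columns `contig_id`, `length` (and optionally `sequence`).
#' @param minLength minimum contig length in bp (default 1500).
#' @return `data.frame` with columns `contig_id` (prefixed), `sample_id`,
#'   `source_contig_id`, `length` (and `sequence` when present).
#' @export
buildPseudoCoassembly <- function(unbinnedPerSample, minLength = 1500) {
    if (anyDuplicated(names(unbinnedPerSample)))
        stop("sample ids must be unique")
    parts <- lapply(names(unbinnedPerSample), function(s) {
        tab <- unbinnedPerSample[[s]]
        if (!nrow(tab)) return(NULL)
        out <- data.frame(
            contig_id = paste0(s, "__", tab$contig_id),
            sample_id = s,
            source_contig_id = tab$contig_id,
            length = tab$length, stringsAsFactors = FALSE)
        if ("sequence" %in% names(tab)) out$sequence <- tab$sequence
        out
    })
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (!length(parts))
        return(data.frame(contig_id = character(), sample_id = character(),
                          source_contig_id = character(), length = numeric(),
                          stringsAsFactors = FALSE))
    ref <- do.call(rbind, parts)
    if (anyDuplicated(ref$contig_id))
        stop("prefixed contig id collision")
    rownames(ref) <- NULL
    filterContigsByLength(ref, minLength)
}

#' Parse a pseudo-coassembly contig id back to its source
#'
#' @param contigId prefixed id from [buildPseudoCoassembly()].
#' @return list with `sample_id` and `contig_id`.
#' @export
parsePseudoCoassemblyId <- function(contigId) {
    parts <- regmatches(contigId, regexec("^(.+?)__(.+)$", contigId))[[1L]]
    if (!length(parts))
        stop("not a pseudo-coassembly id: ", sQuote(contigId))
    list(sample_id = parts[2L], contig_id = parts[3L])
}

#' Write iteration records as JSON lines
#'
#' @param records `data.frame` from [runIterativeBinning()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeIterationLog <- function(records, file) {
    con <- file(file, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(records)))
        writeLines(jsonlite::toJSON(as.list(records[i, ]),
                                    auto_unbox = TRUE), con)
    invisible(file)
}
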