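#' Prokaryotic genome quality filter
#'
#' Removes poor-quality genomes by completeness/contamination: with the
#' defaults a genome fails when completeness <= 50 or contamination > 10
#' (i.e. it passes iff completeness > `minCompleteness` and contamination
#' <= `maxContamination`). Boundary semantics are configurable because
#' published wordings differ between lineages: `completenessInclusive =
#' TRUE` passes completeness == threshold, and `contaminationInclusive =
#' FALSE` additionally rejects contamination == threshold. The
#' `"high_quality"` preset (completeness >= 70, contamination < 2) is
#' available via [qcPreset()].
#'
#' @param assessments `data.frame` with columns `genome_id`,
#'   `completeness` (percent, 0-100), `contamination` (percent, >= 0).
#' @param minCompleteness,maxContamination percent thresholds.
#' @param completenessInclusive pass completeness equal to the threshold?
#' @param contaminationInclusive pass contamination equal to the threshold?
#' @return list with `pass` and `fail` `data.frame`s (same columns as the
#'   input) and the logical vector `passed`.
#' @examples
#' qa <- data.frame(genome_id = c("a", "b"),
#'                  completeness = c(50, 80), contamination = c(5, 10))
#' filterProkaryotic(qa)$passed  # FALSE TRUE
#' @export
filterProkaryotic <- function(assessments, minCompleteness = 50,
                              maxContamination = 10,
                              completenessInclusive = FALSE,
                              contaminationInclusive = TRUE) {
    stopifnot(minCompleteness >= 0, minCompleteness <= 100,
              maxContamination >= 0)
    if (!nrow(assessments))
        return(list(pass = assessments, fail = assessments,
                    passed = logical()))
    compOk <- if (completenessInclusive)
        assessments$completeness >= minCompleteness
    else assessments$completeness > minCompleteness
    contOk <- if (contaminationInclusive)
        assessments$contamination <= maxContamination
    else assessments$contamination < maxContamination
    passed <- compOk & contOk
    list(pass = assessments[passed, , drop = FALSE],
         fail = assessments[!passed, , drop = FALSE],
         passed = passed)
}

#' Named quality-filter presets
#'
#' `"default"` mirrors the standard gate (completeness > 50,
#' contamination <= 10); `"high_quality"` the strict gate used for
#' publication-grade genome sets (completeness >= 70, contamination < 2).
#'
#' @param name preset name.
#' @return list of arguments for [filterProkaryotic()].
#' @export
qcPreset <- function(name = c("default", "high_quality")) {
    switch(match.arg(name),
        default = list(minCompleteness = 50, maxContamination = 10,
                       completenessInclusive = FALSE,
                       contaminationInclusive = TRUE),
        high_quality = list(minCompleteness = 70, maxContamination = 2,
                            completenessInclusive = TRUE,
                            contaminationInclusive = FALSE))
}

#' Candidate phyla radiation (CPR) quality re-assessment
#'
#' CPR bacteria carry reduced marker sets, so standard completeness
#' estimates under-call them. Genomes whose classified lineage falls under
#' a CPR lineage are re-scored through a caller-supplied adapter (wrapping
#' the external CPR-specific assessment workflow), their `marker_set` is
#' recorded as `"CPR"`, and the standard filter is then re-applied to the
#' full genome set. Non-CPR genomes are untouched. Adapter failures are
#' collected per genome instead of aborting the run.
#'
#' @param assessments quality table as in [filterProkaryotic()] (an
#'   optional `marker_set` column is added/updated).
#' @param classifications named character vector genome_id -> lineage
#'   (semicolon-delimited).
#' @param cprLineages character vector of lineage labels (default
#'   `"Patescibacteria"`); a genome is CPR when any label occurs among its
#'   lineage components.
#' @param cprProvider function(genome_id) returning a list/row with
#'   `completeness` and `contamination`.
#' @param ... passed to [filterProkaryotic()] for the re-filter.
#' @return list with `assessments` (updated table), `pass`, `fail`,
#'   `passed`, and `errors` (data.frame genome_id/message).
#' @export
cprAdjust <- function(assessments, classifications,
                      cprLineages = "Patescibacteria", cprProvider, ...) {
    if (!"marker_set" %in% names(assessments))
        assessments$marker_set <- "default"
    lin <- classifications[assessments$genome_id]
    isCpr <- vapply(lin, function(l) {
        if (is.na(l)) return(FALSE)
        any(strsplit(l, ";", fixed = TRUE)[[1L]] %in% cprLineages)
    }, logical(1))
    errors <- data.frame(genome_id = character(), message = character(),
                         stringsAsFactors = FALSE)
    for (i in which(isCpr)) {
        upd <- tryCatch(cprProvider(assessments$genome_id[i]),
                        error = function(e) e)
        if (inherits(upd, "error")) {
            errors <- rbind(errors, data.frame(
                genome_id = assessments$genome_id[i],
                message = conditionMessage(upd), stringsAsFactors = FALSE))
        } else {
            assessments$completeness[i]  <- upd$completeness
            assessments$contamination[i] <- upd$contamination
            assessments$marker_set[i]    <- "CPR"
        }
    }
    refiltered <- filterProkaryotic(assessments, ...)
    c(list(assessments = assessments, errors = errors), refiltered)
}

.QUALITY_TIERS_OK <- c("medium-quality", "high-quality", "complete")

#' Viral contig quality filter
#'
#' Four-criterion gate on candidate viral contigs, applied after the
#' candidate probability cut (`candidate_p < candidateAlpha`, default
#' 0.05): a candidate passes iff (1) viral genes >= 5 x host genes;
#' (2) completeness >= 50 percent; (3) quality tier is medium-quality,
#' high-quality or complete; and (4) the MIUViG tier likewise. Proviruses
#' are excluded unless `includeProviruses = TRUE`.
#'
#' @param assessments `data.frame` with columns `contig_id`,
#'   `candidate_p`, `n_viral_genes`, `n_host_genes`, `completeness`,
#'   `quality_tier`, `miuvig_tier`, `is_provirus`. Tiers come from
#'   `c("complete", "high-quality", "medium-quality", "low-quality",
#'   "not-determined")`.
#' @param candidateAlpha candidate probability threshold.
#' @param includeProviruses pass proviral candidates too?
#' @return list with `pass`, `fail`, `passed` as in
#'   [filterProkaryotic()].
#' @export
filterViral <- function(assessments, candidateAlpha = 0.05,
                        includeProviruses = FALSE) {
    tiers <- c(.QUALITY_TIERS_OK, "low-quality", "not-determined")
    bad <- setdiff(unique(c(assessments$quality_tier,
                            assessments$miuvig_tier)), tiers)
    if (length(bad))
        stop("unknown quality tier(s): ", paste(bad, collapse = ", "))
    if (any(assessments$n_viral_genes < 0 | assessments$n_host_genes < 0))
        stop("gene counts must be non-negative")
    passed <- assessments$candidate_p < candidateAlpha &
        assessments$n_viral_genes >= 5 * assessments$n_host_genes &
        assessments$completeness >= 50 &
        assessments$quality_tier %in% .QUALITY_TIERS_OK &
        assessments$miuvig_tier %in% .QUALITY_TIERS_OK &
        (includeProviruses | !assessments$is_provirus)
    list(pass = assessments[passed, , drop = FALSE],
         fail = assessments[!passed, , drop = FALSE],
         passed = passed)
}

#' Eukaryotic bin size filter
#'
#' Eukaryotic bins below a minimum total assembly size are discarded
#' (default 2,000,000 bp, inclusive).
#'
#' @param binSizes named numeric vector bin id -> total bp (>= 0).
#' @param minGenomeSize minimum size in bp.
#' @return list with `pass` and `fail` character vectors of bin ids and
#'   the logical vector `passed`.
#' @export
filterEukaryoticBins <- function(binSizes, minGenomeSize = 2e6) {
    stopifnot(all(binSizes >= 0))
    passed <- binSizes >= minGenomeSize
    list(pass = names(binSizes)[passed], fail = names(binSizes)[!passed],
         passed = passed)
}

#' Contig length filter
#'
#' Retains contigs with length >= `minLength` (default 1500 bp, the
#' standard pre-mapping size filter).
#'
#' @param contigs `data.frame` with a `length` column (bp), or a numeric
#'   vector of lengths.
#' @param minLength minimum length in bp (inclusive).
#' @return the retained rows (or vector elements).
#' @export
filterContigsByLength <- function(contigs, minLength = 1500) {
    lens <- if (is.data.frame(contigs)) contigs$length else contigs
    stopifnot(all(lens >= 0))
    keep <- lens >= minLength
    if (is.data.frame(contigs)) contigs[keep, , drop = FALSE]
    else contigs[keep]
}
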