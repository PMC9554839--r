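---
title: "Methods: consensus binning bookkeeping, genome clustering, and compositional networks"
author: "magkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus binning bookkeeping, genome clustering, and compositional networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magkit)
```

# Scope

`magkit` implements the computational layer that sits *between* the heavy
external tools of a metagenome-assembled genome (MAG) recovery workflow:
the binning algorithms, quality estimators, ANI calculators and orthogroup
finders are adapters supplying tables, while this package owns the
decisions made on top of those tables — domain consensus, consensus
taxonomy, quality gates, the iterative binning loop, species-level
clustering, feature compression, and compositional co-occurrence
networks. Everything is testable on seeded synthetic fixtures; no
sequencing data or databases are required.

# Genome naming and identifier plumbing

Genomes carry structured names
(`Sample_Algorithm_P.<iteration>_<name>` for prokaryotes, `E.` for
eukaryotes, and no iteration field for viruses, which are detected
per-contig in a single pass). The underscore is the reserved separator:
it is rejected inside the sample and algorithm fields so every rendered
name parses back losslessly. Viral local names additionally may not begin
with a `P.<n>_`-shaped field, which removes the one parse ambiguity the
grammar would otherwise admit.

Eukaryotic gene callers emit long, punctuation-heavy identifiers; we
rename genes to `Contig_Start:End(strand)`. Exact duplicates receive a
deterministic `.k` suffix with `k` the 1-based occurrence index — a
choice the upstream convention leaves open; any injective, stable rule
would do. Harmonized gene models from both domains are exported as GFF3
with gene and contig ids under the single attribute key `gene_id`, the
default key consumed by read-counting tools; internal coordinates are
handled 1-based inclusive end to end since both input tables and GFF3 use
that convention.

Assembly statistics follow their textbook definitions. N50 is the
smallest contig length such that contigs at least that long cover half
the assembly. GC content ignores ambiguity codes in numerator and
denominator, so an assembly padded with `N` runs does not dilute its GC.
Coding density merges overlapping coding spans per contig before summing,
so overlapping gene calls are not double-counted.

# Bin-level domain consensus

Contig-level domain predictors output a probability vector per contig.
Deciding the domain at the *bin* level (rather than per contig) keeps
organelle contigs and isolated misclassifications attached to their host
genome. Per-category logits are sums of natural-log probabilities over
member contigs — the log-likelihood of the bin under an independence
model — and a softmax converts them back to bin-level probabilities. A
floor of `1e-10` guards `log(0)` from over-confident predictors. Exact
ties take the first category in column order, documented and
deterministic. An optional length weighting multiplies each contig's log
term by `length / mean(length)`: evidence proportional to sequence
length, with the logit scale unchanged on average. Uniform weighting is
the default; both modes are exposed because the convention is not settled
upstream.

A bin is called eukaryotic when the probability mass over the
eukaryote-side categories (typically `eukarya` + `organelle`) reaches
`minProbability` (default 0.5), prokaryotic when the complement does, and
undetermined otherwise; at an exact 0.5/0.5 split the eukaryotic rule is
evaluated first.

# Consensus taxonomy and the leniency parameter

Per-protein lineage hits (each with an alignment score: bitscore or
percent identity) are combined into one genome assignment by prefix
scoring: every lineage prefix `P` at depth `i` accumulates
`s_i * sum(scores of hits beginning with P)`, and the best-scoring prefix
wins. The scaling array is `s_i = i^(1/leniency)`:

* `leniency = 1` rewards depth linearly (1, 2, 3, ...), so specific
  assignments win whenever a majority of score mass agrees;
* `leniency -> Inf` flattens the array toward 1, so coarser (higher-order)
  ranks win — high leniency yields conservative, shallow assignments.

The functional form of the array is this package's own choice: it is the
simplest one-parameter family that is strictly increasing in depth at any
finite leniency and collapses to constant weights in the limit. Other
tools implementing a leniency-style parameter may scale differently, so
absolute scores should not be compared across implementations.

Exact score ties back off to the *coarsest* tied prefix, then
lexicographic. This is deliberate: an even split between two genera
carries no evidence for either, and the shared family is the only
defensible consensus; unanimity is unaffected because the weights are
strictly increasing at finite leniency, so a unanimous lineage always
wins at full depth. Per-marker noise cutoffs discard hits before scoring;
a genome losing all hits is returned flagged unclassified rather than
erroring, so batch runs proceed.

Cluster-level consensus pools member genomes' hits by default (`"pool"`);
a `"vote"` mode treating each member's own assignment as one equal-weight
pseudo-hit is available, since either reading is defensible and the
choice matters only for unbalanced clusters.

# Quality gates

Prokaryotic genomes fail at completeness ≤ 50 % or contamination > 10 %
by default. Published wordings disagree on whether completeness exactly
at the threshold is removed (`≤ 50` vs `< 50` appear side by side in the
literature this mirrors); we default to the stricter reading (remove at
`≤`) and expose `completenessInclusive` / `contaminationInclusive` flags
rather than guessing. The `"high_quality"` preset (completeness ≥ 70,
contamination < 2) matches the stricter gate used for publication-grade
sets.

Candidate phyla radiation (CPR) bacteria carry reduced marker sets that
standard completeness estimation under-calls, so basal bacteria are
allowed through intermediate checks and re-scored through a
CPR-specific adapter once classified; the updated table is then
re-filtered as a whole. The CPR lineage set is configuration (default
`Patescibacteria`, the current nomenclature for the radiation).
Per-genome adapter failures are collected, not fatal.

Viral candidates pass a conjunction of five conditions: candidate
probability `< 0.05`, viral genes ≥ 5 × host genes, completeness ≥ 50 %,
and both the assessment quality tier and the MIUViG tier at
medium-quality or better; proviruses are excluded unless requested.
Eukaryotic bins below 2 Mbp are dropped (smaller bins cannot represent a
credible microeukaryotic genome), and contigs below 1500 bp are excluded
before coverage mapping. All printed thresholds are treated as inclusive
(`≥`) where the convention leaves the operator unstated.

# The iterative binning loop

Each iteration runs every binner adapter on the remaining contig pool
under a fresh seed from the pure policy
`seed(base, t) = (base + t * 104729) mod (2^31 - 1)`, consensus-
dereplicates the candidate bins, applies the quality gate, and removes
only the contigs of *accepted* bins — rejected bins' contigs recycle into
the next round with a different random seed state. The loop stops at
`nIter` or as soon as an iteration accepts nothing: under deterministic
adapters further rounds would repeat themselves exactly, so early
stopping changes no output (a `forceAllIterations` flag restores the
fixed-count behaviour). Three invariants are enforced and tested:
accepted contig sets are pairwise disjoint, accepted ∪ remaining equals
the input pool at every step, and identical inputs plus base seed
reproduce identical genomes, names, and records. Running with
`nIter = 1` is exactly the non-iterative consensus-binning baseline.

The built-in dereplicator is a deliberately naive greedy stand-in for
external consensus tools: bins are accepted in descending quality score
(ties lexicographic on the bin key), and a bin is skipped if any of its
contigs is already claimed. Real workflows plug their consensus tool in
through the same adapter signature.

Unbinned contigs from several samples can be concatenated into a
*pseudo-coassembly* — a multi-sample reference built on the premise that
each sample holds incomplete fragments of the same genomes. Ids are
prefixed `sample__contig` (double underscore, to stay clear of the
genome-name grammar) and remain parseable back to their source sample;
the 1500 bp filter applies.

# Species-level clustering and orthogroup bookkeeping

Genomes become nodes of a graph with ANI-weighted edges; connected
components over edges at ≥ 95 % ANI (the standard species boundary, and
adjustable) are the species-level clusters (SLCs). Asymmetric ANI pairs
are symmetrized by the maximum, so one qualifying direction suffices —
the generous reading, chosen because alignment-fraction asymmetries
routinely depress one direction. Cluster ids are dense and deterministic:
numbered from 0 by decreasing size, ties broken by the lexicographically
smallest member (`PSLC0`, `PSLC1`, ...; `ESLC`/`VSLC` for the other
domains). The implementation is cross-checked against a brute-force
transitive-closure oracle on random graphs in the test suite.

Proteins partition by the SLC of their source genome; orthogroups
inferred within each SLC get globally unique SSO ids
`<cluster>_<local label>`. Proteins placed in no orthogroup are flagged
unclustered and excluded from functional feature compression.

The phylogeny input filter drops non-informative markers first (present
in fewer than `minGenomesRatio` of genomes) and then poor-quality genomes
(carrying fewer than `minMarkersRatio` of the *retained* markers), one
pass in that order; iterating to a fixpoint would couple the two
thresholds in ways that are hard to reason about, and a single pass is
what the filter's parameters describe.

# Feature compression

Counts aggregate along the hierarchy (contig → MAG → SLC; ORF → SSO) by
summation; per-sample totals are conserved whenever the grouping is
total, and aggregation composes: contig → MAG → SLC equals contig → SLC.
The feature compression ratio `FCR = 1 - nClusters/nFeatures` summarises
the dimensionality removed — an FCR of 0.75 for 200 MAGs in 50 SLCs means
the clusters carry roughly the same information in 75 % fewer features, a
direct measure of strain redundancy in the dataset. The functional FCR is
identical in form but counts only clustered ORFs. Ratios are reported at
full precision; percent rendering rounds half-even to one decimal.

# Compositional networks

Counts are compositional, so association analysis runs on centered
log-ratio (CLR) coordinates with pseudo-count `1/m²` (`m` features):
small relative to any observed count yet keeping zeros finite, and
shrinking as the feature space grows. Aitchison distance is Euclidean
distance on CLR rows. Association is rho proportionality,
`1 - var(x - y)/(var(x) + var(y)) = 2 cov(x, y)/(var(x) + var(y))`,
bounded in [-1, 1]; both algebraic forms use the unbiased (n−1)
estimator and agree to 1e−12 in the tests.

The ensemble network bootstrap-resamples the samples with replacement
`nIterations` times (default 1000), computes all pairwise rho on each
resample's CLR, and averages element-wise. Bootstrap-with-mean is this
package's documented stand-in for ensemble schemes whose exact
resampling unit is not published; with `nIterations = 1` and resampling
off it degenerates to the plain pairwise-rho network, and the ensemble
mean converges to the plain network as iterations grow. Features
constant within a resample yield undefined rho for that iteration and
are dropped from that entry's mean.

Differential connectivity between conditions is `D = rho_a - rho_b` per
pair, keeping edges positive in *both* conditions (negative
proportionality is non-trivial to interpret for compositions) with
`|D| ≥ 0.1`; the sign of `D` is kept so edges strengthened in either
condition are distinguishable. Features present in fewer than 40 % of
samples are removed beforehand. For interpretability, SLC features can
first be re-aggregated to genus-level (prokaryotes) or viral-group
labels. Feature clustering for heatmaps uses `1 - rho` dissimilarity
(range [0, 2]) with average linkage.

One caveat the test suite makes explicit: a pair associated in only one
condition has near-zero association in the other, with sign determined
by noise (and a slight negative bias of order `var/m` induced by CLR
closure). The positive-in-both edge filter therefore drops such a pair
roughly half the time even when its differential signal `|D|` is large —
detecting one-condition signals reliably requires examining `|D|`
directly, not only the filtered edge table. The acceptance suite records
this honestly: the magnitude check passes essentially always, the
filtered-retention check does not.

# Synthetic fixtures

The generators are pure functions of a `fixtureSpec` (seed included) and
emulate exactly the statistical structure the methods consume:

* contig sets with log-normal lengths (meanlog 8.5, sdlog 1 — median
  ~5 kbp, a realistic assembled-contig scale) and Dirichlet domain
  probability vectors concentrated on a planted domain;
* ANI fixtures with disjoint within-cluster (96–99) and between-cluster
  (80–90) ranges, so any separating threshold recovers the planted
  partition exactly;
* two-condition counts with log-normal abundances closed to a fixed
  depth by multinomial sampling, and planted pairs sharing a latent
  log-scale factor (correlation 0.9 by default) in condition A only —
  40 samples per condition by default, matching the regime the network
  procedure targets;
* annotation tables whose score mass follows a planted lineage, with a
  contamination fraction diverging at a chosen level.

What passing these fixtures does *not* show: real metagenomes have
uneven coverage, chimeric contigs, correlated (not independent)
community structure, and ANI distributions without a clean gap. The
fixtures validate the bookkeeping and the statistics, not the upstream
biology.

# Problem sizes and determinism

The test suite runs at deliberately small scale — graphs of ≤ 50
genomes, counts matrices of ≤ 60 × 20, 100-replicate detection loops at
12 features — sizes at which the brute-force oracles are exact and the
whole suite completes in well under a minute. All randomness flows
through explicit seeds: fixture specs carry one, the binning loop derives
per-iteration seeds from a pure policy, and ensemble networks require
one when resampling.

# Known limitations

* The leniency scaling array and the ensemble resampling scheme are
  documented package choices; numerical agreement with other tools'
  implementations of the same ideas is not guaranteed.
* The greedy dereplicator ignores partial bin overlap quality trade-offs;
  it exists so the loop is testable, not as a replacement for consensus
  binning tools.
* `cprAdjust` trusts its adapter's scores; it performs no plausibility
  check beyond the standard filter.
* Orthogroup inference, ANI computation, and completeness estimation are
  out of scope by design — adapters supply them.
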