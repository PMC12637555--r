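---
title: "Methods: target-centered analysis of pachytene piRNA regulons"
author: "piregulon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: target-centered analysis of pachytene piRNA regulons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem this package addresses

Pachytene piRNAs are 26-31 nt small RNAs loaded onto PIWIL1 (MIWI) during
male meiosis. Individually they show little obvious complementarity to
cellular transcripts, which long obscured their targets. The
target-centered view implemented here asks the question the other way
around: for each mature mRNA, how much of the *collective* piRNA pool
pairs with it antisense and nearly perfectly? Under that lens, swarms of
piRNAs converge on single mRNAs, the piRNAs trace back to discrete
genomic clusters, and within those clusters they arise from inserted
pseudogene fragments (PGFs) of the very genes they silence - a one-to-one
cluster-to-gene "regulon". `piregulon` implements this analysis end to
end, together with a fully seeded synthetic-data generator so that every
stage can be validated against planted ground truth without any external
download.

## The targeting model

A piRNA of sequence $g$ targets an mRNA $m$ at window $[p, p+20)$ iff

$$d_H\big(\mathrm{revcomp}(g_{2..21}),\; m_{p..p+20}\big) \le 1,$$

where $d_H$ is the Hamming distance and $g_{2..21}$ the 20-nt guide core.
Design choices behind this rule:

* **Watson-Crick only.** G:U wobbles count as mismatches; the mismatch
  budget is a Hamming statement, with no indels and no positional
  weighting inside nt 2-21.
* **Position 1 is free.** The 5' nucleotide is excluded from the core,
  consistent with its non-pairing 1U identity in PIWI proteins.
* **Cleavage geometry.** PIWI slicers cut the target phosphate opposite
  guide nt 10/11. We record the predicted site as the 0-based transcript
  index $p+10$ of the nucleotide paired to piRNA nt 11; the scissile
  phosphate is that position's downstream boundary.

The scanner indexes every 10-mer of every mature mRNA. Because a 20-nt
window with at most one mismatch must contain at least one exact 10-mer
half (pigeonhole), exact lookups of the two query halves enumerate a
complete candidate set, which is then verified by direct Hamming
comparison. The test suite holds the indexed scanner identical to an
exhaustive windowed scan on seeded random instances.

### Counting and ranking

Per-gene targeting mass is **read-weighted** by default: a species
contributes its collapsed read count, because abundance is what converts
a small targeting *fraction* into a large molecular dose
(`molecules_per_cell()` exposes the per-cell conversion with the pool
size as an explicit parameter). A `count_mode = "species"` switch is
available. A species hitting several genes contributes its full count to
each (`assign = "all"`); `assign = "best"` (fewest mismatches, longest
covered span, lexicographic gene id) restores exact normalization so that
fractions sum to 1. The top-target set is the minimal rank prefix whose
cumulative fraction reaches `mass_threshold` (default 0.70); the
threshold is a parameter because a percentile-based reading of the same
cut is equally defensible.

One representative transcript per gene (longest CDS, then longest mature
sequence, then lexicographic id) keeps targeting per-gene without
isoform resolution; no isoform policy is implied by the biology, this is
an explicit package decision.

## Origins, clusters, regulons

Perfect full-length genomic matches of every species are found on both
strands (`map_genomic_origins`). A targeting event is *cis* if any
perfect origin overlaps the target gene's genomic span (any strand),
*trans* if all origins lie elsewhere, *unplaced* with no perfect origin.
Read mass is apportioned **equally across a species' origins**; origin
shares inside (merged, disjoint) cluster annotations accrue to those
clusters, the rest to "unassigned". Per gene, the dominant cluster is the
argmax of the resulting shares (lexicographic tie-break), and a
one-to-one regulon is flagged at a dominant share of at least 0.5. Mass
is conserved exactly: per-species weights always sum to 1, including
unplaced species carried as unassigned.

`tiled_coverage` bins apportioned origin starts into 100-nt tiles per
strand in reads per million retained reads; `cluster_expression` ranks
clusters by attributed rpm and cuts at an expression percentile (default
90th, ties included).

## Pseudogene-fragment discovery

Cluster sequences are aligned to mature mRNAs with iterative masked local
alignment (+2 match, -3 mismatch, gap open 5, gap extend 2 - a scheme
tuned for high-identity fragments), on both strands, after a shared
12-mer prescreen. Blocks of at least 50 nt and 80% identity are chained
under strict collinearity in both coordinates; fragments present in both
orientations become separate calls. Overall identity is total matches
over total alignment columns of the chain, and is always reported with
the aligned coverage of both sequences so it cannot be read out of
context (`pairwise_cluster_identity` for cross-species cluster
comparisons).

A chain is promoted to a PGF call at overall identity >= 0.80 over >= 200
aligned mRNA nt. Anatomy annotations:

* **Exon composition** - chain blocks projected onto exon boundaries
  (>= 10 nt overlap to count an exon, guarding against 1-nt spillover).
* **Processed vs partly processed** - the insert region is re-aligned
  against the *unspliced* parental locus; >= 30 nt of intronic alignment
  flips the call to partly processed. Deciding on the unspliced locus
  rather than on exon-junction spanning is robust to short exons.
* **5' truncation** - chain start > 50 nt into the mRNA.
* **TSD** - see below.

### Target-site duplications

`detect_tsd` searches 30-nt flanks for a duplicated 8-25 nt substring
pair, one copy ending at or upstream of the insertion start and one
beginning at or downstream of its end (copies never overlap the given
interval). Two deliberate deviations from a naive "longest pair with <= 1
mismatch" rule, both forced by direct calculation:

1. **Mismatches only for candidates >= 12 nt.** A flat 1-mismatch budget
   at length 8 admits a random hit in roughly a third of insertions
   (about $961 \times 25/4^8$ expected pairs at length 8 alone); gating
   the budget keeps the false-positive rate on random flanks below 5%,
   which the suite verifies over 200 seeded trials.
2. **Ranking by length minus 4 nt per mismatch** (then fewer mismatches,
   then boundary proximity). Under plain longest-first ordering, an exact
   duplication of length $L$ would be displaced by an $(L{+}1)$-mer pair
   using its mismatch on the extension - so a planted exact TSD would
   almost never be reported verbatim. The penalty makes a mismatch pay
   for itself only when it buys more than 4 additional duplicated
   nucleotides.

Because local alignment can wobble a few bases at fragment ends, the
caller shrinks the estimated insertion interval by 3 nt per side before
the TSD search; the search window absorbs the shift.

## Expression response

The expression module is transparent by construction: median-of-ratios
size factors (the classical RNA-seq normalization), per-feature
$\log_2\frac{\bar c_{KO}+1}{\bar c_{WT}+1}$ fold changes, a two-sided
Welch t-test on $\log_2(\text{normalized count}+1)$ across replicates,
and Benjamini-Hochberg adjustment at $\alpha = 0.05$ (via
`stats::p.adjust`). This deliberately is *not* a dispersion-shrinking
count model: the statistic is fully specified here, at the cost of power
at small replicate numbers - with 3-vs-3 replicates and typical
dispersions, a 3-fold change cannot reach a BH-adjusted 0.05 against
hundreds of features (the attainable p of a Welch test at df ~ 4 is
~10^-3), and the test suite therefore demonstrates single-feature
detection at 6 replicates and 4-fold derepression. Target tiers
(top / lower-ranked / non-targets) are compared by ECDFs and the
two-sample Kolmogorov-Smirnov statistic, $D = \sup_x |F_a(x) - F_b(x)|$,
with the asymptotic p-value evaluated at $\sqrt{n_e}\,D$,
$n_e = n_a n_b/(n_a+n_b)$; a signed $D$ is reported, positive when the
first tier is shifted toward up-regulation.

## Sequence signatures

`positional_base_frequency` tabulates per-position base frequencies
(read-weighted by default, species mode available) and reports the 1U
fraction (T at position 1; primary biogenesis hallmark) and the 10A
fraction (A at position 10; its *absence* marks the lack of ping-pong
amplification, which is all this analysis needs - no 5'-overlap z-score
is computed). The `min_count` filter (recommended 2 when estimating
signatures) drops the singleton species that sequencing errors scatter
around abundant piRNAs; without it the species-weighted 1U estimate is
biased low by roughly the error-read fraction, and the read-weighted
estimate carries the sampling noise of the abundance power law.

## The synthetic-data generator

`simulation_config()` defaults *are* the study conditions used by the
validation suite; they are chosen once to emulate the regime the analysis
assumes, not tuned per test:

| parameter | default | what it emulates |
|---|---|---|
| genome | 500 kb, 1 chromosome | compact uniform background |
| genes | 40; 2-8 exons of 80-400 nt; introns 0.1-2 kb | mRNA structure |
| clusters | 6 spanning 5-30 kb | piRNA precursor loci |
| PGF plans | 3 antisense inserts, divergence 0.05/0.08/0.03, 5' truncation 80/60/100 nt, TSDs 12/14/10 nt | cluster-embedded pseudogene fragments |
| piRNA emission | 4,000 species, 200,000 reads, lengths 26-31 peaked at 29, 1U bias 0.8 | pachytene piRNA pool |
| abundance | Pareto tail exponent 1.5, capped | long-tailed species counts |
| background | 5% of species from non-cluster loci | non-cluster small RNAs |
| errors | 0.001 per base per read | sequencing noise before collapsing |
| expression | NB, lognormal means around 200, dispersion 0.05, 3-fold derepression, 3 replicates | KO/WT response |

Reads are substrings of cluster transcripts; a read starts on a U with
probability exactly equal to the 1U bias (start positions are drawn from
the U/non-U position pools). Insertion sites for PGFs are re-drawn until
the flanking context cannot extend the planted duplication, so "TSD
recovered exactly" is well defined. The truth manifest records, per
species, its emission locus, whether it truly targets a gene (verified by
direct string comparison at the planted offset - never by running the
scanner), and its perfect-origin multiplicity, including the two
subtleties that genuinely arise: background reads drawn antisense to a
gene's exons are real cis-targeting events, and such reads can re-occur
verbatim inside the planted PGF copy and thus multimap into the cluster.

What the generator does **not** emulate - and hence what green tests do
not certify on real data: repeats and transposon landscapes (the genome
background is i.i.d. uniform, so off-target matches are rarer than in a
real genome), ping-pong pairs, isoform complexity, read-quality
artifacts beyond uniform substitution errors, and annotation-version
effects on cluster boundaries, which in a real re-analysis shift the
cluster-origin and dominant-share percentages.

## Numerical choices and degenerate inputs

Internal coordinates are 0-based half-open everywhere (GTF converted at
the boundary); U is normalized to T at ingest and all matching runs in
the DNA alphabet. The default library length window 24-34 nt brackets the
26-31 nt pachytene range with margin for untrimmed ends. Ties are broken
deterministically throughout (lexicographic ids after the scoring
criteria), empty inputs yield empty-but-typed results with warnings
rather than errors where the spec of the operation allows it, zero-count
matrices and all-zero features flow through the expression module, and
all outputs are written without timestamps so identical seeds give
byte-identical datasets and pipeline output trees. Every stage of
`run_pipeline` can be re-run standalone from the previous stage's TSVs.

## Problem sizes used by the validation suite

The suite exercises the default conditions where the claim is about the
default conditions (planted-regulon recovery across 50 seeds; 1U
recovery; determinism), and smaller, explicitly parameterized instances
where the claim is structural (oracle equivalence on 9-12 kb
transcriptomes with ~150 guides; PGF anatomy on 200 kb genomes with one
planted fragment per run; null false-discovery calibration over 200
simulations of 250-300 features). These sizes are the package's choice
of smallest instances that make the corresponding failure modes visible.

## Known limitations

* The one-mismatch pigeonhole index does not generalize to larger
  mismatch budgets; `max_mm` is capped at 1 by design.
* Origin mapping is exact-match only; a piRNA one substitution away from
  its true locus (e.g. a sequencing error) is unplaced and its mass
  reported as unassigned.
* The expression module is a transparent stand-in for a count-model DE
  engine; its p-values are not comparable to dispersion-shrinkage
  methods at small replicate numbers.
* Overall PGF identity is chain identity; against a heavily rearranged
  insertion it can differ from a global-alignment identity, which is why
  aligned coverage is always reported next to it.
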