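---
title: "Splicing fidelity and stable intronic RNAs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splicing fidelity and stable intronic RNAs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sisplice)
```

# Scope and model

`sisplice` analyses one multi-exon gene at a time, asking two questions of a
set of spliced RNA-seq alignments: how faithfully is the gene spliced
(exon-skipping rates per junction), and do its introns host stable
polyadenylated transcripts (sisRNAs)? The motivating gene is human *RPE65*
(14 exons, 13 introns), whose splicing is nearly perfect in native retinal
pigment epithelium but degraded in cell culture, and whose introns 9/10 and
13 carry polyadenylated intronic RNAs.

## Coordinates

All internal coordinates are 0-based half-open; GFF3 (1-based inclusive) and
SAM (1-based) are converted at their I/O boundaries only. Exon and intron
numbering is 1-based in every report, matching field usage ("exon 7",
"intron 10"). Minus-strand genes keep genomic `start < end` per interval and
store exons in transcript order; motif scanning operates on explicitly
strand-oriented sequence.

## Junction quantification

Every `N` operation in a CIGAR is one junction observation; the gap
coordinates come from walking the reference-consuming operations (M, D, N,
=, X). An observation whose gap matches the segment between exons *i* and
*i+1* within `tolerance` nt is a correct splice; between *i* and *i+2*, a
single-exon skip; anything else is tallied as `other` and reported, never
silently dropped. Parameters:

* `min_overhang` (default 5 nt): junction observations with fewer aligned
  nucleotides on either side are unreliable junction evidence and are
  excluded. The source analyses state no threshold; 5 nt is a conservative
  middle ground, and the simulator tests run at 1 nt so the truth ledger can
  be matched exactly.
* `tolerance` (default 0 nt): exact boundary matching is the conservative
  reading of "correct splicing"; a small tolerance admits aligner wobble.
* Secondary/supplementary alignments are excluded by default to avoid double
  counting; long reads flow through the same CIGAR walk with no separate
  code path.

The skip fraction is defined as `k / n` with `k` the skip events and
`n = correct + skip` events at that junction — a proper proportion in [0, 1]
and exactly the binomial success fraction the mixture model needs. Published
tables of this quantity are not always consistent: of the widely cited
*RPE65* junction counts, two printed cells (0.073 from 13/178, 0.030 from
937/31,017) follow `skip/correct` instead. The package computes
`skip/(correct + skip)` everywhere and documents the discrepancy rather than
matching those two cells. Whether both mates of a fragment spanning the same
junction count once or twice is likewise unstated in the source analyses;
the package counts per junction observation (per read), and the simulator's
truth ledger uses the same convention.

## Fisher comparison

Per junction pair, the 2x2 table `[[a_correct, a_skip], [b_correct,
b_skip]]` is tested with the two-sided Fisher exact test under the
minimum-likelihood rule (sum over tables with the observed margins whose
point probability does not exceed the observed one). This convention
reproduces the verifiable printed values on the *RPE65* table (0.68 for the
exons 3–4 comparison, 1.00 for exons 11–12); the computation is delegated to
`stats::fisher.test`, and the test suite checks it against an exhaustive
enumeration oracle for every table with N ≤ 30. Zero-margin tables return
p = 1 with a warning. Raw p-values are the primary output (matching the
source analyses); a clearly labelled Bonferroni column is emitted alongside.

## Mixture of binomials

Per-junction observations `(k_i, n_i)` are modelled as a C-class mixture of
binomials with weights `w_c` and class skip rates `q_c`, fitted by EM:

* E-step: `r_ic ∝ w_c Binom(k_i; n_i, q_c)` (computed in log space).
* M-step: `w_c = mean_i r_ic`, `q_c = Σ_i r_ic k_i / Σ_i r_ic n_i`.

The log-likelihood is asserted non-decreasing across iterations; at C = 1
the fit is the closed form `q = Σk / Σn`. Initialization is a deterministic
quantile split of the empirical rates plus random restarts (default 10,
`tol = 1e-8`, explicit seed), so the default behaviour is reproducible. A
class whose weight falls below `1/(10N)` is removed and the model refitted —
necessary for stability on 12-observation datasets.

The number of classes is selected by a parametric-bootstrap likelihood-ratio
test of C vs C+1 (default B = 199 seeded replicates): the naive chi-square
reference for mixture LRTs is invalid at the boundary of the parameter
space, while the bootstrap is calibrated (the suite verifies a >= 95%
C = 1 rate on single-component data). A chi-square dispersion test is
available as a cheaper alternative switch. On the 4-month ARPE-19 *RPE65*
counts the selected model has two classes, and the high-rate class is
exactly the junctions with k ∈ {8, 11, 13} — the junctions flanking exons 2,
3 and 7; membership is inferred from the printed k values, which force it.

## sisRNA detection

Intronic transcription is evidenced by read pairs in which at least one mate
overlaps a single intron by **more than** 10 nt (strictly greater: 11 nt
accepted, 10 rejected — the literal reading of the published rule; the
threshold is configurable). Each accepted pair is attributed to the intron
of maximal overlap, so accepted + rejected = examined and every accepted
pair counts exactly once.

Candidate intervals are maximal runs of accepted-pair coverage with
`depth ≥ min_depth`, tolerating internal gaps up to `max_gap = 50` nt, kept
at `min_length = 100` nt. The source analyses identified candidates by EST
overlap rather than thresholds, so these defaults are this package's own
operationalisation of "enriched in mapped reads": `min_depth` defaults to
5x the median intronic coverage (floored at 2), making the call scale-free
across library depths. Candidates are assumed sense-strand relative to the
host gene. The canonical polyA signal `AATAAA` is scanned (all overlapping
occurrences; `N` never matches) within the final 50 nt of the candidate —
"near the 3' end" quantified as one read-length's margin. Candidate
abundances are compared as simple supporting-pair ratios; a zero denominator
yields an infinite-flag result, not an exception. When the pipeline scans
called candidates it extends the scan 10 nt past the called 3' edge: coverage
erodes at interval boundaries (only fragments ending exactly at the
transcript end cover the final bases), so the called edge can fall a few
nucleotides short of the true cleavage site that the signal precedes.

## Co-expression

Per-sample raw counts (exonic depth, intronic candidate depth, skip events)
are correlated with Pearson's r; two-sided p-values come from the t
transform with n − 2 degrees of freedom. Counts are used raw — the source
analyses correlate "raw numbers of reads" — with an optional, clearly
non-default library-size normalisation switch. One summary row is one
library/replicate.

# The simulator

`sim_config()` defaults define the study conditions the package is tested
under, chosen to mirror the motivating system at desk scale:

* a 14-exon gene (~1.7 kb of exon, ~4.6 kb of intron, longest intron 660 nt
  — a 1:10 scale model of the 6.6 kb intron 10);
* junction-level skip rates 4.0%, 5.5% and 7.0% at exons 2, 3 and 7 and
  0.5% at exons 4 and 12 (the observed cultured-RPE range), zero elsewhere;
* two polyadenylated sisRNAs: a 460 nt candidate at the 5' end of intron 10
  (mirroring the enriched ~460 nt EST-anchored region) at relative abundance
  0.5, and a 150 nt candidate in the last intron at 0.05 — the published
  ~10x contrast;
* 2% unspliced pre-mRNA, 5000 fragments of 250 ± 30 nt, 2 × 100 nt reads
  (the read length of the deepest public libraries analysed).

Fragment lengths are normal (truncated at the read length), fragment starts
uniform within the source transcript, and skip isoforms are single-exon
skips only — the only kind the junction tables quantify. The generator
plants `AATAAA` ending exactly at each polyadenylated candidate's 3' end and
scrubs the hexamer from the rest of that candidate's 3' window, so motif
results are unambiguous by construction. Identical config and seed give
byte-identical SAM output.

What the simulator does **not** emulate: sequencing errors and quality
variation, aligner soft-clipping and mismapping, multi-isoform annotation,
antisense transcription, nanopore error profiles, and biological variation
between replicate libraries beyond the sample-summary generator's lognormal
depth model. Passing tests therefore demonstrate the correctness of the
counting, testing, clustering and detection machinery on clean alignments —
not robustness to alignment artefacts, which an upstream aligner and its
filters must provide.

Test and example problem sizes (hundreds to a few thousand fragments,
16-sample cohorts, B = 99–199 bootstrap replicates) are the package's
desk-scale choices: large enough that the statistical checks (3-SE binomial
agreement, ≥ 90% detection-rate bounds, ± 0.02 parameter recovery) are
meaningful, small enough to run anywhere in minutes.

# Numerical choices and degenerate inputs

* Mixture EM runs in log space (`dbinom(log = TRUE)` with q clamped to
  [1e-12, 1 − 1e-12] only inside likelihood evaluation); reported `q_c` are
  the raw M-step values, so the C = 1 closed form is exact to machine
  precision.
* Class ties in assignment break toward the lower-q class and are flagged.
* All-zero skip counts: C = 1 fits exactly (q = 0); requesting C > 1 on such
  data is flagged degenerate.
* Skip fraction with `correct = skip = 0` is reported missing (NA), not 0.
* Zero-length introns (abutting exons) and overlapping or unsorted exons are
  validation errors naming the offending pair.
* The bootstrap LRT statistic is floored at 0 (numerically tiny negative
  differences can occur when C and C+1 fits coincide).
* `select_classes` marks the returned model `adequate = FALSE` when the
  class cap was reached while the last test still rejected.

# Known limitations

* One gene at a time; no multi-isoform reconciliation or percent-spliced-in
  across annotations (out of scope by design).
* `other`-class junctions (multi-exon skips, novel sites) are counted and
  reported but not further analysed.
* Whether the intron rule should count fragments or reads is ambiguous in
  the source analyses; the package counts fragments (pairs) and exposes the
  threshold, but not the unit, as a parameter.
* The candidate caller reports intervals per contiguous coverage run; a
  sisRNA spanning an exon (as one long nanopore read suggests for the
  intron-9/exon-10/intron-10 candidate) is reported as its coverage shape
  dictates, and merging across exons is left to the user.
* p-values for the Pearson correlations are two-sided; published one-sided-
  looking values are noted but not emulated.
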