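---
title: "Methods: duplication, selection and expression divergence of CRP gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: duplication, selection and expression divergence of CRP gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crpevol)
```

# Scope and data model

crpevol analyses the evolution of a large gene family — written for plant
cysteine-rich peptides (CRPs), but family-agnostic — from four inputs: a
GFF3 annotation, a homolog-pair table (BLAST-tabular or minimal TSV,
screened at E < 0.01), pre-aligned coding-sequence pairs, and RPKM
expression matrices over developmental stages. Family identification
itself (HMM scans, ORF-level searches, signal-peptide prediction) is
upstream: family membership, signal-peptide status and subfamily labels
arrive as annotations.

The coordinate convention is GFF3 throughout: 1-based, inclusive. Every
gene carries a **rank** — its ordinal position among *all* annotated genes
on its chromosome, ordered by start (ties: end, then id). Ranks always
reflect the full annotation and are never recomputed on a family subset:
tandem and proximal duplication are statements about genome-wide
adjacency, and subsetting first would silently turn "nearby in the genome"
into "nearby within the family". Strand is carried but ignored by
clustering and ranking; no strand rule enters any of the analyses here.

# Gene clusters

A cluster is a maximal run of ≥ 2 family genes on one chromosome whose
consecutive genomic distances are all strictly below `max_gap_bp`
(default 10,000 bp). Two choices here were genuinely open:

- **Distance.** "Genomic distance" is taken as the intergenic gap,
  `max(0, start_next − end_prev − 1)`, clamped to zero for overlapping
  genes. Start-to-start distance is available via `gap_mode = "start"` for
  sensitivity analysis; at CRP gene sizes (a few hundred bp) the two rarely
  disagree at a 10 kb threshold.
- **Intervening genes.** Non-family genes between two family members do
  not break a cluster: the rule is purely positional within the family.

The threshold is strict (`<`), so neighbours at exactly 10,000 bp do not
cluster. Census percentages are rounded half-up to two decimals — the
convention that reproduces published census tables digit-for-digit, which
`round()`'s banker's rounding does not.

# Collinear blocks and duplication typing

Homolog pairs become anchors in (rank~A~, rank~B~) space per chromosome
pair. A block is a chain of anchors strictly monotone on both chromosomes
(increasing–increasing = parallel, increasing–decreasing = antiparallel)
with consecutive rank gaps ≤ `max_gap_ranks` (default 25) on both sides.
`chain_anchors()` extracts the maximum-anchor-count chain per chromosome
pair by dynamic programming, reports it if it has ≥ `min_anchors`
(default 5), removes its anchors, and repeats — a greedy iterated
best-chain scheme in the spirit of MCScanX's block finding, with MCScanX's
published defaults as the starting parameters. Ties are resolved
deterministically: earlier rank~A~ start, then parallel orientation, then
lexicographically by the anchor sequence, so reruns are byte-identical and
the implementation can be compared anchor-for-anchor against exhaustive
chain enumeration in the tests. MCScanX's internal block E-value formula
is deliberately not reproduced; the E < 0.01 screen is applied to the
input alignments instead, which is where the published procedure states
its filter.

Duplication classes follow the standard precedence, each gene receiving
exactly one label:

1. **wgd_segmental** — anchors any collinear block. Whole-genome and
   segmental duplication are one class: rank-space collinearity cannot
   distinguish them without cross-species dating, and the census figures
   this package reproduces treat them as one category.
2. **tandem** — a homolog at the adjacent full-annotation rank
   (|Δrank| = 1, same chromosome).
3. **proximal** — a same-chromosome homolog within
   `proximal_window_ranks` ranks (default 20, the MCScanX classifier
   convention; "proximal" has no standard published definition).
4. **dispersed** — any homolog at all.
5. **singleton** — no homolog.

# Ka/Ks by Nei–Gojobori counting

For each codon and position, the fraction of the three one-nucleotide
changes that are synonymous accrues to the synonymous site count S, the
rest to N. Two conventions for changes that create a stop codon are
implemented (`stop_policy`): the default counts them as nonsynonymous,
which keeps S + N = 3·L exactly — a testable invariant — and matches the
treatment of stops as maximally deleterious; `"exclude"` removes them and
splits the codon's three sites by the remaining syn:nonsyn ratio, since
pairwise Ka/Ks tools differ on this point across versions. Site counts for
a pair are averaged over the two sequences.

Differences between aligned codons differing at one position are
classified directly; at two (three) positions, the per-step
classifications are averaged over the 2 (6) mutational pathways with equal
weights. Pathways passing through a stop codon are excluded — the original
counting method's practice — and if every pathway does, all are included
as a defined fallback rather than dropping the codon.

The proportions p~S~ = Sd/S and p~N~ = Nd/N are corrected for multiple
hits with the one-parameter Jukes–Cantor formula
d = −(3/4)·ln(1 − 4p/3). At p ≥ 3/4 the logarithm's argument is
non-positive: the distance is undefined, the pair's Ka or Ks is set to NA
and propagated (such "null value" pairs are excluded from density dating
and rate-group tests but remain countable in reports) — no exception
aborts a genome-scale run over one saturated pair.

Significance of the Ka/Ks contrast is a two-sided Fisher exact test on
[[Sd, Nd], [S−Sd, N−Nd]], the documented choice of the pairwise
Ka/Ks-calculator lineage; fractional pathway-averaged entries are rounded
half-up to integers for the exact test. A pair is called positively
(negatively) selected when ratio > 1 (< 1) at p < α, default α = 0.05 with
no multiple-testing correction — the screening convention this pipeline
mirrors; a Benjamini–Hochberg step can be added by the caller on the
reported p column. The χ² likelihood-ratio arithmetic for nested site
models (M8 vs M7, 2·Δln L on 2 df) consumes externally fitted −ln L
values; codon-model fitting itself is out of scope. Group-wise rate
comparisons use Bartlett's homogeneity-of-variance test via
`stats::bartlett.test`.

## Ks-density dating

Ks values in the open interval (0, `max_ks`) — default 2, beyond which
synonymous saturation makes dating unreliable — enter a Gaussian kernel
density on a 512-point grid with Silverman's rule-of-thumb bandwidth
(`bw.nrd0`; a fixed bandwidth can be supplied). Peaks are strict local
maxima of the gridded density, returned highest first. At least 10 values
are required: a density mode over fewer points is noise. The 512-point
grid bounds peak-location resolution at `max_ks`/512 ≈ 0.004, well inside
the tolerance of any burst-dating claim.

# Expression divergence and coordination

Divergence of a duplicate pair is 1 − ∂ with ∂ the **signed** Pearson
correlation of the raw RPKM profiles across stages, so perfectly
anti-correlated duplicates score the maximal divergence 2 — the natural
reading when divergence is the quantity of interest. Coordination tables
report **|r|** instead, with a two-sided p from
t = r·√((n−2)/(1−r²)) and the star convention (* p < 0.05, ** p < 0.01),
matching how coordinated-expression tables are printed. Both conventions
are explicit in the API rather than flags buried in a config. Raw RPKM is
the default scale (a `log2p1` option exists); zero-variance profiles are
skipped and counted, not errored, since flat profiles are common in
stage-restricted families. qPCR fold changes average replicate Ct values
per condition and return 2^−ΔΔCt.

Class-wise summaries order duplication classes by median divergence and
join classes whose medians differ by < 0.05 with "≈" — the notation used
in comparative statements like "Singleton > Tandem > WGD ≈ Proximal >
Dispersed".

# The synthetic-data generators

The generators produce data with exactly the structure the analyses
assume, plus a truth ledger, so every stage has a recovery test:

- `simulate_genome()` spaces background genes with intergenic gaps uniform
  in [10,001, 50,000] bp — strictly above the cluster threshold, so no
  accidental clusters exist and planted-cluster recovery is exact by
  construction. Planted clusters use a fixed internal gap (default
  2,000 bp); tandem arrays are homolog runs at consecutive ranks (default
  size 3, small enough that the within-array anchor diagonal stays below
  the 5-anchor block threshold); collinear segments are rank-preserving
  duplicated runs on different chromosomes with one anchor per position.
  Structures occupy disjoint gene-index ranges; requests beyond
  chromosome capacity error rather than silently overlap.
- `simulate_codon_pair()` applies each planted edit at a distinct codon,
  one nucleotide each, never creating a stop, so pathway averaging is
  trivial and (Sd, Nd) recovery is exact. Multi-hit codons are exercised
  separately with hand-built fixtures in the tests; the generator
  deliberately does not model them (no rate matrices, no repeated hits),
  because planted truth under multiple hits is no longer a pair of
  integers.
- `simulate_expression()` uses an empirically orthogonalised bivariate
  construction: the partner profile is built from the standardised source
  profile and the standardised residual of an independent draw, so at
  noise 0 the *sample* correlation equals the target exactly, and the
  noise-0 recovery tests can assert divergence = 1 − target to machine
  precision. The finished matrix is shifted and scaled affinely to
  non-negative, RPKM-magnitude values — affine maps preserve Pearson
  correlation, so the planted truth survives verbatim. A log-normal
  transform would look more like real RPKM marginals but provably shifts
  the correlation (exponentiation is not affine), which would break the
  only property the generator exists to plant; realism of marginal
  distributions was traded away for exactness of the planted statistic.

What passing recovery tests therefore shows: the detection, typing,
counting and correlation machinery is correct on data satisfying its
assumptions. What it does not show: robustness to real-data pathologies —
fragmented assemblies, mis-annotated gene models, alignment errors,
multi-hit codon saturation, heteroscedastic expression noise. Those enter
through the inputs, not this code.

# Determinism and numerics

Every stochastic function takes a seed and is a pure function of its
arguments (`withr::with_seed`, no global RNG leakage); `run_pipeline()`
derives stage seeds from one master seed and reruns are byte-identical.
Reported percentages round half-up at two decimals. Fisher tables round
half-up to integers. Chain extraction and cluster output orders are fully
specified (chromosome, then position), so no report depends on input row
order. The GFF reader names the line number of a malformed row; duplicate
gene ids and negative RPKM values are hard errors at read time rather
than downstream surprises.

Test and validation problem sizes were chosen to make the oracles
exhaustive where possible: all 61 sense codons against one-step
enumeration; a {50, 100, 300} × {0..10}² grid of planted codon pairs;
chain enumeration on ≤ 12 anchors over 200 random instances; union-find
cluster components on 500 random 30-gene instances; 1,000 equal-variance
replicates for the Bartlett type-I error (0.05 ± 0.02); 200 pairs × 50
stages for expression-correlation recovery (±0.03). These sizes keep each
oracle exact or tightly bounded while the whole suite stays fast enough
to run on every change.

# Known limitations

- Block finding is a greedy best-chain approximation; it does not
  reproduce MCScanX's block E-value model, and overlapping or nested
  blocks sharing anchors are resolved by removal order. Distinct planted
  segments on the same chromosome pair within the rank-gap window can
  legitimately merge into one chain.
- NG86 is a counting method: no transition/transversion bias, no codon
  frequencies. For borderline selection calls a maximum-likelihood
  estimator should corroborate.
- The 10 kb cluster rule and the 20-rank proximal window are conventions,
  not estimates; both are parameters.
- Site-model fitting (M0/M7/M8 parameters, site posteriors) is consumed
  from upstream tools, never computed.
- Expression divergence treats stages as exchangeable observations;
  autocorrelation along a developmental series is ignored, as in the
  correlation-based convention it implements.
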