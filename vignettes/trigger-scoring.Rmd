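---
title: "Scoring and discovering TDMD trigger sites with tdmdscout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and discovering TDMD trigger sites with tdmdscout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdmdscout)
```

## Background and model

In target-directed miRNA degradation (TDMD), a target RNA with a canonical
seed match and extensive complementarity to the miRNA 3′ region recruits
the ZSWIM8 Cullin-RING ligase to the Argonaute protein, leading to
degradation of the miRNA rather than repression of the target. Known
endogenous triggers share four features: canonical seed pairing, extensive
3′ pairing, high expression, and (often) evolutionary conservation.
`tdmdscout` operationalizes that description as a scanning-and-scoring
pipeline plus the downstream quantification and statistics used to
validate candidate triggers.

The unit of analysis is a *site*: a canonical seed match (6mer core =
reverse complement of miRNA nucleotides 2–7, optionally upgraded by m8
pairing and/or a target A across from position 1) on a 3′ UTR or lncRNA,
together with the window of `window` nucleotides immediately 5′ of the
target nucleotide opposite miRNA position 8. Within that window the
package searches for the pairing configuration — an antiparallel, monotone
set of (miRNA position, target position) pairs over miRNA positions ≥ 9 —
that maximizes a point score.

## The point scheme and its parameters

All parameters live in `score_params()` (points are unitless; `window` is
in nucleotides):

| parameter | default | meaning |
|---|---|---|
| `match_point` | 1 | per WCF pair at miRNA position > 12 |
| `end_bonus` | 0.5 | extra, per WCF pair at the penultimate or third-to-last position |
| `terminal_wobble_bonus` | 0.5 | for a G:U wobble at the last position |
| `interruption_point` | 1 | per gap/mismatch column inside the 3′ duplex |
| `offset_free` | 3 | largest unpenalized \|offset\| |
| `offset_point` | 0.5 | per offset nucleotide beyond `offset_free` |
| `window` | 30 | upstream search width (nt) |
| `three_prime_start` | 9 | first miRNA position allowed to pair |

Pairs at positions 9–12 may form — they help contiguity — but earn no
points; wobbles earn nothing except at the terminal position. Several
readings of this scheme were genuinely open, and the package fixes them as
follows:

* **End bonus distributivity.** "Penultimate or third-to-last" is read
  per-position: WCF pairs at both L−1 and L−2 earn 0.5 each (max +1
  combined). A WCF pair at the very last position earns its match point
  but no end bonus, since the rule names only the two end-proximal
  positions.
* **Interruption cost.** One interruption event with a gap of *g~m~*
  columns on the miRNA side and *g~t~* on the target side costs
  `interruption_point × max(g_m, g_t)`: a 1×1 mismatch is one interrupting
  column and costs 1 (not 2); an *n*-nt bulge costs *n*.
* **Offset.** Defined as the signed difference between the target-side and
  miRNA-side loop lengths between the seed helix (the miRNA position-8
  column) and the first 3′ pair, penalized on absolute value — bulged
  loops on either strand displace the helix equivalently.
* **Terminal overhangs** on either molecule are free; otherwise the
  maximizer would simply trim them and the penalty would be vacuous.

## The search and its correctness

`best_configuration()` maximizes the score by dynamic programming over
cells "(miRNA position, window position) = last pair", with the offset
penalty applied at chain start and the interruption penalty on each
chain step (C++ via Rcpp; cost is O(L²W²) on tiny L and W, microseconds
per site). The empty configuration scores 0, so scores are never negative.
Ties are resolved deterministically — smaller |offset|, then fewer
interruption events, then the 5′-most target start — so repeated runs
produce byte-identical output.

Correctness is defined by `exhaustive_best()`, an independent pure-R
enumeration of every monotone pairing (incrementally scored, guarded to
3′ regions ≤ 10 nt, windows ≤ 14 nt, and 2×10⁶ enumeration nodes). The
test suite checks score equality on 1,000 random instances within the
guard; tie-broken configurations may legitimately differ only when their
scores tie exactly.

## Duplex energy

As an orthogonal ranking metric, `duplex_mfe()` computes the minimum free
energy (kcal/mol) of hybridization between the miRNA 3′ region and the
same window, considering intermolecular pairs only. The embedded model is
a reduced nearest-neighbor set: WCF and G:U stacking energies close to the
standard Turner values, affine bulge and internal-loop penalties, a duplex
initiation term, and a terminal AU/GU penalty, shipped as package TSV
tables. It aims at correct *ranking* (GC-rich, contiguous complementarity
below weak, interrupted complementarity), not thermodynamic fidelity —
dangling ends, coaxial stacking and partition-function ensembles are
deliberately omitted. Energies are reported to 0.01 kcal/mol; when no
arrangement beats the initiation cost, a no-duplex sentinel is recorded
(an empty cell in candidate TSVs). An external `RNAduplex` executable can
be selected (`backend = "external"`) and is then reported verbatim.
Candidate ranking uses the point score; energy is reported alongside and
used only to break score ties.

## Search branches, expression filter, conservation

`run_denovo_branch()` scans every expressed region for all four canonical
site types (configurable; the set of types to include in a de novo scan is
a judgment call — all four are included by default). `run_conserved_branch()`
scores externally annotated sites in place. Gene expression is the mean
TPM across provided samples; genes absent from the expression table count
as unexpressed, and the default candidate threshold is 1 TPM (exposed as
configuration — only the *existence* of an expression filter, not its
cutoff, is pinned down by the approach this package implements).

`score_across_species()` projects both the site and the mature miRNA onto
each species of a MAF block by alignment columns (gaps stripped), then
re-runs the identical scanning and scoring code per species. Species whose
projected mature differs from the reference by more than 2 nt are flagged
low-confidence; fully gapped species are reported as missing rather than
dropped. Species with partial site deletions are scored on the extracted
remnant and flagged. `seed_intact` requires a same-or-stronger site type
than the reference by default (configurable to any canonical type).
`detect_covariation()` reports positions where both the miRNA base and its
aligned target partner differ from the reference, with a flag for whether
the substituted pair still base-pairs (WCF or G:U).

## Small-RNA quantification and repression statistics

Reads are assigned to miRNAs by exact identity of their first 19 nt with a
dictionary prefix; no mismatches are tolerated, and miRNAs sharing a
prefix are quantified as one merged ambiguous group (the assignment rule
is prefix-deterministic, so fractional splitting would be arbitrary).
Spike-ins and markers are tallied separately and excluded from the
counts-per-million denominator, so cpm sums to 10⁶ over miRNA groups per
sample. `cluster_normalize()` divides a miRNA's cpm by the geometric mean
of its co-transcribed partners' cpm (a single partner reduces to a simple
ratio, the passenger-strand normalization), then expresses each sample
relative to the control-group mean; samples with a zero partner cpm are
flagged undefined and excluded from the control mean.

`run_repression()` compares predicted targets of one miRNA family with a
nontarget cohort sampled 1:1, matched on 3′ UTR length by greedy nearest
neighbor in log10 length without replacement, with the target visit order
randomized per iteration (the matching objective is distributional
similarity; greedy nearest-neighbor with randomized order achieves it
without systematic bias and is reproducible under the seed). Genes below
10 TPM mean expression are excluded first ("across samples" is read as the
mean; the all-samples reading is stricter and is available via
configuration). The "top" target set is the ⌈10%⌉ of targets with the
lowest cumulative weighted context++ scores, boundary ties broken by gene
id. Repression is median(nontarget log2FC) − median(target log2FC), so
planted repression yields positive values; significance is a two-sided
Mann–Whitney U (exact by enumeration when min(n, m) ≤ 8 with no ties,
otherwise normal approximation with tie and continuity corrections — the
boundary is documented configuration). The analysis runs 21 iterations
with fresh nontarget draws; the mean repression and median p are reported,
and the iteration attaining the median p of the all-targets set is marked
representative for plotting. The nontarget pool excludes predicted targets
of the family under consideration only, not of all miRNAs.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes, planted with
known truth and byte-identical under a fixed seed:

* `sim_mirnas()` — mature miRNAs of 21–23 nt with unique 19-nt prefixes
  (optionally one deliberate collision pair), and cluster structure that
  wires up co-transcribed normalization partners.
* `plant_trigger_site()` / `sim_transcriptome()` — transcripts whose
  upstream window realizes exactly a requested pairing architecture
  (WCF/wobble positions, offset); window positions opposite the miRNA 3′
  region that are not part of the pattern are forced non-pairing, so the
  planted configuration is realized exactly and its expected score is
  recorded from `score_configuration()`. Background composition is uniform
  by default with configurable GC. Transcript TPMs are log-normal
  (location log 20), floored at 1 so planted transcripts pass the default
  candidate filter.
* `sim_alignment()` — MAF-style blocks with planted substitutions,
  deletions, insertions, and compensatory pairs.
* `sim_reads()` — exact full-length miRNA sequences drawn multinomially
  from an abundance vector, plus fixed-count spike-in reads (spike-ins are
  modeled as counts, not molar amounts).
* `sim_de_table()` — nontarget log2FCs ~ Normal(0, σ), targets ~
  Normal(δ, σ), log-normal 3′ UTR lengths optionally confounded with
  target status to stress the matcher, and context++ scores tracking the
  per-gene effect rank.

These generators emulate the *structure* of real inputs, not their
statistics: no sequencing errors, isomiRs or untemplated additions; no
compositional or secondary-structure biases in UTRs; independent Gaussian
fold changes rather than correlated, mean-variance-coupled estimates; and
uniformly random backgrounds in which strong chance complementarity is
rare. A passing suite therefore demonstrates that the algorithms implement
their definitions and recover planted truth under clean conditions — it
does not certify performance on real transcriptomes, where background 3′
pairing is more structured.

## Numerical choices and degenerate inputs

* Windows truncated by the transcript 5′ end are searched as-is (no
  padding); a zero-length window yields the empty configuration and the
  energy sentinel.
* A seed-only site has expected score 0 by construction; the search may
  still find weak chance complementarity in a random window, so planted
  truth round-trips are asserted exactly only for patterns that dominate
  background (≥ 2-point margin).
* Score comparisons use an absolute tolerance of 1e−9 (scores are sums of
  halves, so this is far below the quantum of 0.5).
* Per-miRNA ranks are a strict permutation 1..n: score descending, then
  energy ascending (sentinel last), then transcript id, then seed start.
* All randomness flows from explicit integer seeds; per-iteration
  sub-seeds in `run_repression()` are drawn once from the main seed.

## Problem sizes used in the tests

The suite exercises: oracle equivalence on 1,000 random small instances
(3′ regions of 8–10 nt, windows of 6–14 nt); planted-trigger recovery on a
200-transcript × 1-kb transcriptome with 10 miRNAs; read-count
conservation at 10⁵ reads plus a per-position mismatch scan; repression
recovery with 200 planted targets (δ = −0.3, σ = 0.2) and a
1,000-simulation null calibration of the matched Mann–Whitney test. These
sizes keep the full suite to a few minutes on one core while leaving each
estimate's sampling error well inside the asserted bounds.

## Known limitations

* The scorer ranks by the point scheme alone; it does not blend energy,
  conservation and expression into a single posterior.
* The energy model is reduced; absolute kcal/mol values should not be
  compared against full Turner-2004 implementations.
* Conservation analysis consumes alignments; it does not build them, nor
  does it reconstruct ancestral states or compute PhyloP-style tracks.
* Differential expression is consumed as a table; count modeling and
  shrinkage are upstream of this package.
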