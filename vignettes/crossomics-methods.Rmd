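---
title: "Methods: a cross-species precision-medicine pipeline on synthetic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a cross-species precision-medicine pipeline on synthetic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossomics)
```

`crossomics` re-implements, as a tested and reusable pipeline, the analysis
workflow of a comparative-oncology precision-medicine case: a dog with
multiple synchronous leiomyosarcomas whose tumors, recurrence,
patient-derived xenograft (PDX) and derived cell line were profiled with a
high-throughput drug screen, whole-exome sequencing, ubiquitin-remnant
(K-&epsilon;-GG) proteomics and an *in vivo* PDX efficacy study. The raw
study data (screens, sequencing reads, spectra) are not desk-scale inputs,
so every stage here is exercised end to end on **synthetic data with
planted ground truth**; the generators are first-class, tested code. This
vignette explains each model, its assumptions, the tunable parameters, the
numerical choices, and what the passing tests do — and do not — show about
real data.

## Drug-screen analysis

**Model.** Cell viability is read out as luminescence, proportional to
live-cell count. For each compound on each replicate plate,

$$\text{killing} = 100 \times \left(1 - \frac{\overline{L}_{\text{drug}}}{\overline{L}_{\text{DMSO}}}\right)\,[\%],$$

where both means are taken within the plate. Normalising per plate (and
per replicate) absorbs plate-to-plate intensity drift; the invariance test
multiplies a whole plate by a constant and requires identical killing.
Replicates are combined by the arithmetic mean. Negative killing (growth
stimulation) is retained, never clipped — it is informative for
clustering.

**Hit calling and vulnerability ranking.** A compound is a hit at
threshold $t$ iff its mean killing is *strictly* greater than $t$
(matching the ">50% inhibition" convention). Targets or pathways are
ranked by the fraction of their drugs above threshold, then by mean
killing, then name — a deterministic order, invariant to input
permutation. Compounds without the grouping annotation are excluded with
a logged count.

**Dose-response.** The four-parameter logistic on log10 dose,

$$y = b + \frac{T - b}{1 + 10^{\,h\,(\log_{10}\mathrm{IC}_{50} - \log_{10} x)}},$$

is fitted by Levenberg–Marquardt least squares from a small multi-start
grid (IC50 starts at the dose quartiles; Hill slopes 0.5, 1, 2 and −1),
keeping the best SSE. The reported IC50 is the *relative* (inflection)
IC50, the standard convention. Responses with variance below $10^{-8}$, or
fits whose span $T-b$ collapses below $10^{-6}$ of the observed range, are
returned with `converged = FALSE` and an undefined IC50. IC50 is reported
in the dose units supplied (nM in the case study), and scales linearly
when the doses are rescaled.

**Clustering** of replicate killing vectors uses Euclidean distance and
average linkage (configurable); compounds are sorted by identifier first
so hierarchical ties break deterministically.

**What the simulator emulates.** `simulate_screen()` draws DMSO wells
around a per-plate baseline and compound wells as
$\text{baseline} \times (1-\text{killing}) \times \text{LN}(cv)$, with a
unit-mean lognormal noise term (positive support — the natural choice for
luminescence) and an optional per-plate lognormal intensity effect
(CV 5% by default). `example_screen_truth()` builds a 2,100-compound
catalog over 140 pathways (3 targets each, so annotated classes average
~15 drugs, the scale of real inhibitor classes), plants one uniformly
sensitive pathway, and draws background effects so that roughly 6.6% of
the library exceeds 50% killing and 4.2% exceeds 75% — the hit-rate
regime of a bioactive library at 1 µM on a sensitive sarcoma line. It does
**not** emulate positional plate effects (edge wells, drift within a
plate), compound carryover, or cytostatic-versus-cytotoxic differences;
passing tests therefore say nothing about B-score-style corrections.

## Somatic-variant heterogeneity

Variant identity is the exact tuple (chrom, pos, ref, alt), 1-based as in
VCF; no left-alignment or normalisation is performed (inputs are assumed
normalised upstream by the caller). Multiallelic records are split into
one key per ALT; FILTER≠PASS rows are dropped by default. SNV filtering
keeps single-base ref/alt only.

"Percent shared mutations" is denominator-dependent, so two statistics
are emitted: the **Jaccard percentage** $100|A\cap B|/|A\cup B|$ (primary)
and the asymmetric containment $100|A\cap B|/|A|$. Two empty sets are
defined 100% similar, with a note. UpSet-style intersection patterns
assign each variant of the union to exactly one membership pattern;
counts always sum to the union size (checked against a per-variant
brute-force tally).

Deleterious gene sets are *read*, not computed: effect prediction is an
upstream input (VEP-like), carried in the `EFF` INFO key or simulator
truth. The default deleterious labels are `stop_gained`, `frameshift`,
`splice_disrupting`, `missense_deleterious`, fully user-overridable. The
PDX gene set is intersected with the cell line's to remove genes called
from residual mouse tissue — the contamination filter.

**Simulator.** `simulate_clonal_variants()` plants trunk variants
(inherited by every sample), branch variants on each internal edge, and
private variants on each terminal edge of a user-supplied rooted tree, so
the binary characters form a perfect phylogeny by construction (no
homoplasy). PDX contaminants draw gene labels from a separate mouse-style
pool (`MUSG…`) and never enter the cell line. Variant keys are unique
over a 38-autosome + X canine-style chromosome set. Mouse *reads* are not
simulated — contamination is modelled at the gene-set level, which is all
the downstream filter consumes.

## Phylogenetics on binary characters

Characters are variant presence/absence, not the nucleotide recoding a
PHYLIP conversion would produce. The biological signal used downstream is
shared-variant structure, and binary characters make the parsimony oracle
exact; this divergence from the nucleotide representation is deliberate.

* **Distance trees**: $d = 1 - \text{Jaccard}$ on the binary rows, then
  standard neighbor joining (exact on additive matrices — tested with
  exact branch lengths). Negative NJ branch lengths are clamped to zero
  with the deficit logged.
* **Parsimony**: our own vectorised Fitch dynamic program (state-set
  bitmasks, intersection/union per internal node). The score is exact for
  binary trees, rooted or unrooted; it is cross-checked against both a
  brute-force enumeration of internal labelings and `phangorn::fitch`.
  Search is exhaustive for ≤ 8 taxa (10,395 topologies — the default cap
  balances exactness against runtime and can be raised), otherwise NNI
  hill climbing from the NJ tree with lexicographic tie-breaking on a
  canonical newick form; all co-optimal trees are returned in canonical
  order.
* **Bootstrap**: columns resampled with replacement; clade support is the
  number of replicate trees containing each bipartition of the reference
  tree; the majority-rule consensus keeps bipartitions above 50%. The
  conventional full analysis uses 1,000 replicates; the package's own
  checks use 100–200, which is ample for the saturated support levels the
  planted signal produces.

The matched normal is representable as an all-absent outgroup row, used
for rooting displays and PHYLIP export only. Trees are computed unrooted
on the tumor samples: under Jaccard the all-zero row is equidistant from
every sample, so its placement in a distance tree carries no signal and
would only destabilise bipartition counts.

## Differential ubiquitination

Site-level abundances (area-under-curve scale) are summed per protein and
sample — AUCs are additive — log2-transformed with a pseudocount (0.5 by
default, ~10⁻⁶ of a typical abundance, so planted effects pass through
essentially unchanged), and median-centred per sample to remove loading
differences. A median-of-sites roll-up is available as an option.

A note on centring: subtracting the per-sample median is neutral only up
to the spacing of the order statistics around the median. Planting shifts
a treated sample's median by one such gap (~0.04 log2 units at 60
proteins), which is negligible against real effects but not literally
zero; the package's exact-recovery checks therefore run with
`center = "none"`, and the default remains `"median"` for real use.

Per protein, a Welch two-sample t-test compares treated to vehicle on the
log2 scale (n = 3 per arm in the case study; Welch is the safe choice
at small, possibly unequal variances, standing in for the vendor
statistic the original analysis used). Benjamini–Hochberg adjustment is
applied across all tested proteins; direction is the fold-change sign at
adjusted p < α. Proteins with fewer than 2 finite values in either group
are excluded and counted; no imputation. Pathway over-representation uses
the upper-tail hypergeometric p within the quantified background, BH
across pathways.

The simulator draws per-site log2 abundances Normal(µ_site, σ) with 1–3
sites per protein and shifts treated samples by ±log2-effect for the
planted sets. It does not emulate missing values, site-level
interference, or identification FDR — inputs are assumed
identification-filtered upstream.

## Integration

Candidates are genes that (a) carry a deleterious mutation in ≥ 1 sample
— with the PDX set pre-filtered by the cell line — and (b) are
differentially ubiquitinated in either direction (the union; per-direction
views are recoverable from the output's direction column). "Identical
somatic mutations across multiple samples" is interpreted as the same
variant key in ≥ 2 samples and exposed as the `require_shared_identical`
flag, since the exact multiplicity criterion is a judgement call. The
output orders by (direction, gene) and carries per-sample presence flags;
it is idempotent, order-invariant and monotone in the differential sets.

## PDX growth analysis

Volume is the standard ellipsoid approximation
$V = \ell w^2/2$ (mm³). Censoring follows the study rules: animals leave
at day 18 or on first reaching 1,500 mm³; the crossing measurement is
kept, later ones dropped and logged. The treatment comparison is a plain
fixed-effects two-way ANOVA on volume with arm and day (categorical) as
factors, on a balanced design; unbalanced inputs are rejected with
guidance rather than silently refitted, and the case study analyses the
common uncensored window to stay balanced.

**Known limitation.** Repeated measures within animals are *not*
modelled — deliberately, to match the plain two-way ANOVA of the original
analysis. With heterogeneous enrollment volumes (100–150 mm³) the
within-animal correlation makes the arm test anticonservative (we observe
~18% type-I at nominal 5% under the null with enrollment spread). The
package's calibration check therefore isolates iid measurement noise
(common enrollment volume), the regime in which the ANOVA is exact; for
real designs with strong animal heterogeneity a mixed model would be the
upgrade, out of scope here.

The growth simulator uses $V(t) = V_0 e^{r m t}$ with rate $r$ per day
and arm multiplier $m$, multiplicative lognormal caliper noise, and
back-solves calipers under the fixed aspect ratio $\ell = 2w$ (so
$V = w^3$); any fixed ratio would do, this one is simply documented.
Default conditions mirror the study: 5 animals per arm, enrollment at
100–150 mm³, measurements three times a week to day 18.

## The end-to-end case study

`run_case_study(seed)` wires everything together under one master seed:
the 2,100-compound triplicate screen (planted sensitive pathway), 4PL
fits of validation curves at 345 nM and 6 nM with 5% response noise, an
11-sample variant design (seven primary tumors on a caterpillar topology,
recurrence, PDX + cell line as a clade with the recurrence, normal
outgroup; trunk 80, 50 variants per internal edge — the strong-signal
bootstrap regime — 40 private per sample, 12 PDX contaminants), VCF
write/read round-trip, NJ bootstrap with 200 replicates, a 3 vs 3
ubiquitinome with 160 up / 130 down planted proteins of which ten are
trunk genes carrying shared deleterious mutations (five up, five down,
planted at log2 effect 4, σ = 0.25 — the regime where per-protein power
exceeds 95%), integration recovering exactly those ten, and the 5 vs 5
efficacy study (multiplier 0.3 vs 1). `scripts/acceptance.R` runs this
and writes the headline numbers as JSON.

## Problem sizes and determinism

Every generator consumes a seed carried inside its truth object and
restores the caller's RNG state; the same truth yields byte-identical
tables. The test suite uses: 200 random Fitch instances on ≤ 6 taxa
against brute force; 100 × 2,000-protein null simulations for FDR
calibration; 500 null ANOVA studies; 200 power simulations for the
treatment effect; 200 IC50 fits at the 6 nM scale; 50 NJ-versus-least-
squares draws; and a single seeded end-to-end run with 200 bootstrap
replicates. These sizes were chosen so Monte-Carlo error is small
relative to each asserted margin while the whole suite stays fast.

## What passing tests do not show

Synthetic data is homoplasy-free, annotation-complete and balanced. Real
screens have positional effects; real variant calls have caller-specific
artefacts, indel-representation ambiguity and subclonal dropout that
break the perfect-phylogeny assumption; real K-GG data have
missing-not-at-random values; real growth studies lose animals. The tests
certify the algorithms and their calibration under the stated models, not
robustness to those failure modes.
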