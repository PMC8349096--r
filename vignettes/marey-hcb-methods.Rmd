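---
title: "Methods: heterochromatin boundaries and recombination rates from Marey maps"
author: "MareyHCB authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heterochromatin boundaries and recombination rates from Marey maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MareyHCB)
```

## The problem and the model

A Marey map plots, for every genetic marker of a chromosome, its genetic
position (cM) against its physical position (Mb).  The local slope of
that curve is the local recombination rate in cM/Mb.  Meiotic
recombination is effectively absent in heterochromatin — the centromere
and the telomeres — so a recombination map should be zero there; but
naive regression of the Marey curve produces biased, often negative,
rates across those regions.  MareyHCB estimates where the
euchromatin–heterochromatin boundaries (HCB) lie, classifies the
chromosome type, and returns a recombination map that is zeroed across
heterochromatin and floored at zero elsewhere.

The pipeline (`mareyHCB()`) is purely statistical and data-driven:

1. **Quality control (Step 0).**  Global marker density $n/L$ (with $L$
   the largest physical position) is compared with a minimum threshold
   of 2 markers/Mb.  Homogeneity of the marker distribution is tested by
   a Pearson $\chi^2$ goodness-of-fit of 1-Mb bin occupancies against
   the uniform expectation, pooling bins left-to-right until every
   expected count reaches 5 (Cochran's rule).  An optional cleaning pass
   computes consecutive genetic gaps $g_i = gen_{i+1} - gen_i$ on the
   physically sorted map, flags gaps above the extreme boxplot fence
   $Q3 + 3\,\mathrm{IQR}$, and removes the downstream marker of each
   flagged gap — largest gaps first, never more than
   $\lceil 0.05\,n \rceil$ markers per pass.
2. **Regression (Step 1).**  Two Marey curves are fitted: a global
   least-squares cubic $g(x) = a_0 + a_1 x + a_2 x^2 + a_3 x^3$, whose
   derivative is evaluated in closed form, and a Loess local regression
   whose derivative is taken by central finite differences on a
   1000-step grid.  Note that R's `loess` fits local polynomials of
   degree at most 2; at span 1.0 the curve degenerates to a single
   weighted quadratic, which is why the package compares Loess against
   the cubic only at moderate spans.
3. **Chromosome type (Step 2).**  The physical position of the smallest
   polynomial-based rate indicates the centromere.  If it falls within
   the outer 10% of the span the chromosome is telocentric (a single
   arm); otherwise it is atelocentric, and it is called metacentric when
   the Loess-based rate minimum lies within 40–60% of the span, not
   metacentric otherwise.  When the two models disagree about the edge
   the subtype is reported undetermined and a user override
   (`chromosomeTypeOverride`) is honoured.
4. **Cumulative fit-quality curves (Step 3).**  Entry $k$ of the
   $R^2$-forward curve is the coefficient of determination of a cubic
   refitted on markers $1..k$; the backward curve mirrors from the other
   end.  Marey maps show visibly degraded marker quality in
   heterochromatin, so these curves rise through euchromatin and stall
   or dip where heterochromatin begins.
5. **Centromeric boundaries (Step 4).**  Starting at the rate minimum, a
   window of size $\max_i |x_{i+1} - x_i|$ (the largest inter-marker
   physical gap) slides outward in steps equal to its size.  On each
   placement the mean of within-window consecutive differences of the
   cumulative curve is tested against zero (positive on the forward
   curve for the left boundary, negative on the backward curve for the
   right); the first window that passes sets the boundary.  With a
   centromeric assembly gap (largest gap ≥ 20× the median gap and
   ≥ 1 Mb), a confirmation additionally requires the accumulated
   point-slopes within the window, added one point at a time, to keep
   the same sign.  Telocentric chromosomes use a single window moving
   away from the centromeric end.
6. **Telomeric boundaries (Step 5).**  The inner edge of a telomere is
   the position of the smallest value of the cumulative curve on the
   flank outside the centromeric interval (forward curve on the left
   flank, backward on the right), taking the outermost position on ties;
   the outer edges are the first and last markers.
7. **Rate adjustment (Step 6).**  The exported map is the Loess
   derivative on a uniform grid, set to exactly 0 inside every detected
   heterochromatin interval and floored at 0 outside.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `span` | 0.15 | Loess span, fraction of markers per local fit (0.05–1) |
| `densityThreshold` | 2 /Mb | minimum global density for DQC |
| `alpha` | 0.05 | significance level of the distribution test |
| `edgeFraction` | 0.10 | outer span fraction that counts as a chromosome end |
| `gapFactor`, `minGapMb` | 20, 1 Mb | centromeric-gap call thresholds |
| `gridPoints` | 1000 | resolution of the exported rate grid |
| `targetFraction` | 0.05 | cap on the fraction of markers removed per cleaning pass |

The 15% span default matches common practice for fly-sized chromosomes;
larger, sparser genomes are usually analysed at ~25%.  The span does not
affect boundary detection (which uses the cubic refits), only the final
rate map.  The gap thresholds and the 10% edge fraction are package
choices — the underlying procedure does not prescribe values — and all
are exposed as arguments and CLI flags.

## Numerical choices

* Prefix cubics are fitted on centred abscissae; $R^2$ is invariant to
  the shift and short windows far from the origin stay well
  conditioned.  Windows of fewer than 5 markers carry the value of the
  first computable window, so forward and backward curves agree exactly
  on the full data.
* A prefix with zero genetic variance gets $R^2 = 1$ by convention.
* Ties in the telomeric argmin are resolved to the outermost position,
  with a $10^{-12}$ tolerance so that float jitter on perfectly fitted
  data still collapses the telomere to the chromosome end (flagged).
* Internal centromeric boundaries are snapped to the nearest marker
  position: reported boundaries are marker-valued, matching how
  external boundaries (first/last marker) are defined.
* A sliding-window instance holding fewer than two markers is widened
  on its far edge until it holds two.
* Degenerate inputs error early: fewer than 2 markers, zero physical
  length, all-equal physical positions (rank-deficient cubic), spans
  below the feasible neighbourhood (minimum `4/n`).
* Markers sharing a physical position but differing genetically are
  kept (local regression tolerates ties; stable input order), with a
  warning; exact duplicates are dropped with a message.

## The synthetic-data generator

`mareyScenario()` + `simulateMap()` generate chromosomes with known
boundaries, emulating two study conditions used throughout the tests:

* **metacentric** — 44 Mb (two concatenated ~22-Mb arms), centromere at
  20–24 Mb, 2-Mb telomeres at both ends, 100 cM; optionally with a
  centromeric assembly gap (no markers in the centromere);
* **telocentric** — a 22-Mb arm with fly-2L-like geometry: 3-Mb
  centromeric heterochromatin on the right, a 0.7-Mb distal telomere,
  50 cM.  (An early draft gave the telomere the same 2-Mb flat extent
  as the centromere, which makes the two chromosome ends statistically
  indistinguishable and breaks side identification for any
  argmin-based rule — real telocentric arms are strongly asymmetric.)

Marker physical positions are uniform within each region at 5/Mb in
euchromatin and 2/Mb in heterochromatin — the documented working range
of the method (accurate HCB around 5/Mb, minimum 2/Mb).  Genetic
positions follow a monotone template: flat inside heterochromatin and a
logistic rise inside each euchromatin block, rises proportional to
block widths and scaled to the genetic length; Gaussian noise
(sd 0.75 cM in euchromatin) is added and truncated at 0 cM — a
documented simplification whose bias is negligible for
sd ≪ genetic length.  Heterochromatic markers receive 3× the noise sd
(`hetNoiseFactor`): degraded marker quality in heterochromatin is the
very feature the cumulative-$R^2$ depletion detects, and a generator
with uniform noise would deprive telomeres of any signature.

What the generator does **not** emulate: assembly errors and
misplacements, non-monotone genetic maps, marker clustering from
genotyping platforms, chromosome-specific interference patterns, or the
long low-density centromeric plateaus of large plant genomes.  Passing
tests therefore show that the statistics recover boundaries under
clean, known-truth conditions — not that every real genome will resolve
equally well.

## Measured resolution and problem sizes

With the default study conditions the pipeline recovers centromeric
boundaries to well under one window size and telomeric inner edges to a
median of ~2 Mb (biased into euchromatin: the prefix $R^2$ keeps
dipping slightly past the boundary until enough clean signal
accumulates).  Pooled over all internal boundaries, the median shift
stays below twice the sliding-window size, with or without a
centromeric gap and for telocentric arms.  Resolution degrades
monotonically as markers are subsampled from 100% down to 30% (30
seeded replicates per fraction), reproducing the density-degradation
behaviour expected of the method.  The test suite and the acceptance
script use 30 seeds/replicates per condition and 100 seeds for the
$\chi^2$ calibration — sizes chosen to keep Monte-Carlo error on a
median or a rate comfortably inside the asserted bounds.

## Known limitations

* Boundary resolution scales with the sliding window, i.e. with the
  largest inter-marker gap: chromosomes with a centromeric assembly gap
  are resolved no finer than the gap's flanks.
* Telomere detection needs a fit-quality contrast; on manually curated
  maps with uniformly excellent fit the telomeres collapse to the
  chromosome ends (flagged, zero width).
* The distribution-homogeneity test sees only the observed marker
  extent: a map whose markers all stop short of the true chromosome
  end cannot be flagged for what it does not contain.
* Submetacentric vs acrocentric subtypes are not distinguished; the
  classification stops at metacentric / not metacentric, with an
  explicit `undetermined` when the two regression models disagree.
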