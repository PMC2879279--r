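---
title: "Dosage-quotient copy-number calling from multiplex amplicon data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosage-quotient copy-number calling from multiplex amplicon data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maqcna)
library(dplyr)
```

## The measurement model

Multiplex amplicon quantification determines relative copy number at a few
dozen genomic loci in a single closed-tube PCR. Every amplicon in a kit has
a unique designed fragment length; after capillary electrophoresis each
fluorescence peak is therefore attributable to one amplicon, and its area is
proportional to the amount of template, i.e. to the locus copy number, times
an amplicon-specific (and unknown) amplification efficiency.

Raw areas are not comparable across amplicons or runs. The dosage quotient
(DQ) removes both nuisance scales with a double ratio. For target amplicon
area `TarA`, reference amplicon area `RefA`, test sample `s` and normal
control `ctr`:

$$\mathrm{DQ} = \frac{\mathrm{TarA}(s) / \mathrm{RefA}(s)}
                     {\mathrm{TarA}(ctr) / \mathrm{RefA}(ctr)}$$

The inner ratio cancels sample-level scale (input DNA amount, injection),
the outer ratio cancels the per-amplicon efficiency, leaving the copy-number
ratio of target to reference, normalized to a two-copy control. On a diploid
background with diploid references, a DQ of 1 means two copies, 0.5 a
single-copy loss, 1.5 a single-copy gain, and values far above 1
amplification. Reference amplicons sit in regions rarely altered in the
tumor type (5q, 13q, 21q, 22q in the neuroblastoma kits).

`aggregate_dq()` computes one DQ per (reference amplicon, control sample)
combination and summarizes them as the arithmetic mean over the full
Cartesian product, with the sample standard deviation (n − 1) as a
stability measure. Two conventions were genuinely open:

* **Flat versus nested averaging.** We average over the full product of
  references × controls. A nested mean (first over references, then over
  controls) coincides with the flat mean whenever no combination is
  missing; with missing data the flat mean weights each valid combination
  equally, which we prefer because each combination is one independent
  realization of the double ratio.
* **Missing data.** Combinations with an absent or non-positive area are
  excluded, never imputed; a target with no valid combination carries no
  data. Zeros are treated as missing because a zero denominator is
  meaningless and a zero target area is indistinguishable from assay
  failure at these scales. Absence is encoded by absent rows, never by
  zero areas, which would silently corrupt the ratios.

An important degeneracy follows directly from the double ratio: if every
locus — references included — has the same copy number (say, a uniformly
triploid genome), all DQs equal 1. Aneuploid genomes therefore mask
whole-chromosome changes to exactly the extent that the reference set
shares them; this is the central difficulty with "numerical" tumors
discussed below.

## Rule-based scoring

Scoring operates on the position-ordered DQs of each region of interest and
is a pure function of the profile and a rule set (`maq_rules()`,
`mlpa_rules()`; both ship as YAML presets under `inst/extdata/`).

**Segmental aberrations** (part of an arm, e.g. 1p deletion or 17q gain):
called when at least 2 *consecutive* loci deviate from 1 by at least 0.2
(MAQ) or 0.25 (MLPA) in the same direction. The MLPA set adds a fraction
clause: more than 75% of a region's loci deviating by at least 0.15 in the
same direction also calls. Numerical choices we fixed and their reasons:

* All "at least" thresholds are inclusive (a DQ of exactly 0.80 calls under
  MAQ); the "more than 75%"/"more than half" clauses are strict. This
  follows the wording of the published rules; where the original software's
  boundary behavior is unknowable we chose the inclusive reading and kept
  it everywhere.
* A locus with missing DQ breaks adjacency: runs never bridge a failed
  amplicon. This is the conservative choice — it cannot create a call from
  two non-adjacent deviants.
* If, pathologically, both a qualifying loss run and a qualifying gain run
  occur in one region, the first run along the arm determines the call.
* The fraction clause is applied per arm region (not per chromosome), the
  natural unit given that regions of interest are arms.

**Whole-chromosome (numerical) changes**: evaluated only for samples with
no segmental call anywhere (global precedence, mirroring a decision cascade
in which the clinically decisive question — is there any segmental
aberration? — is answered first). A chromosome is called lost when at least
75% of the DQs of *both* arms lie below 1 and more than half of all the
chromosome's DQs deviate by at least 0.1; gains are symmetric. The majority
clause is applied to the union of both arms; applying it per arm would
demand a majority twice and is stricter than the published wording.

**MYCN amplification**: scored independently of everything else; amplified
when all designated MYCN-locus DQs (3 must be measurable under MAQ, 2 under
MLPA) show an increase of at least 3, i.e. DQ ≥ 4. We read "increase with
at least 3" as relative to the normal baseline of 1; the alternative
absolute reading (DQ ≥ 3) is available as `mycn_absolute = TRUE`. When
MYCN is amplified its loci are excluded from chromosome-2 whole-chromosome
evaluation — amplification DQs would trivially satisfy the gain clauses and
say nothing about ploidy. The MYCN kit is analyzed separately from the
other kits throughout (amplification interferes with co-amplified loci in
the same reaction), and DQ profiles are never pooled across kits before
scoring.

## Evaluation statistics

`evaluate_performance()` compares direction-matched binarized calls with a
gold-standard table (in the motivating validation, array CGH segmented by
CBS at ±0.3): loss calls count as positive for the loss regions 1p/3p/11q,
gains for 17q, amplification for MYCN, either direction for whole
chromosomes. Pairs with no data on either side are excluded; undefined
ratios (zero denominators) are reported as `NA`, never as 0 or 100.

Two AUCs are exposed. For a binary caller the ROC curve has one operating
point and the area under the two-segment curve is
(sensitivity + specificity)/2 (`binary_auc()`); this is the default for
tabular reports. `continuous_auc()` sweeps a threshold over a continuous
per-region score (the maximal DQ deviation oriented toward the expected
aberration, `region_scores()`) and equals the Mann–Whitney probability with
midpoint tie handling; it exists for genuine ROC curves. The macro-average
AUC is the unweighted mean over regions. Pooled false-positive and
false-negative rates pool confusion counts over all evaluable region-sample
pairs.

Repeatability follows Bland–Altman: for paired replicate DQs,
`bland_altman_cr()` reports the bias, the half-width of the limits of
agreement 1.96 × SD(differences) — the quantity compared against scoring
thresholds — and a conservative coefficient |bias| + 1.96 × SD.

## The synthetic cohort generator

No raw fragment data are published for the motivating study, so the package
ships a generator (`simulate_cohort()`) that reproduces the *structure* of
its validation series and makes every pipeline stage testable end to end.
The defaults are the study conditions and are not tuning knobs:

* 35 segmental and 17 numerical tumors plus 2 diploid controls; 22
  segmental samples MYCN-amplified (the 19 amplified tumors plus 3 of 4
  cell lines); 15 of 35 segmental samples on a near-triploid background.
* Segmental event frequencies (1p 18/35, 3p 10/35, 11q 13/35, 17q 27/35)
  and numerical chromosome frequencies (chr 1: 9/17, 2: 10/17, 3: 13/17,
  11: 14/17, 17: 16/17) reconstructed from the printed per-region
  validation metrics by integer enumeration.
* Peak areas follow `baseline × efficiency(amplicon) × copies/2 ×
  exp(N(0, σ))`. Lognormal multiplicative noise was chosen over additive
  Gaussian because areas are positive and errors scale with signal.
  Per-amplicon efficiencies are drawn once per cohort and held fixed across
  samples, which is exactly why the double ratio cancels them.
* **σ defaults to 0.03**, calibrated in closed form against the assay's
  reported Bland–Altman repeatability: under this design a per-area σ
  yields a per-locus DQ standard deviation of ≈ 1.23 σ and a replicate
  coefficient 1.96·√2·1.23·σ ≈ 3.4 σ, so the reported coefficients of
  0.0987–0.121 imply σ ≈ 0.03. (σ = 0.05 would imply a repeatability
  coefficient near 0.17, outside the reported range.)
* **Numerical attenuation.** A fully clonal one-copy whole-chromosome
  change on a near-triploid background would give DQ 4/3 ≈ 1.33 or
  2/3 ≈ 0.67 — deviations that would *always* fire the ±0.2 segmental
  rule, which is not what the assay's validation observed: numerical
  changes typically barely reach the ±0.1 whole-chromosome threshold and
  essentially never produce segmental calls. The generator therefore
  attenuates numerical events by a clonality factor (default 1/3; observed
  copies 3 ± 1/3, DQ ≈ 1.11/0.89), modelling the combined effect of
  subclonality and admixture that compresses dosage shifts in aneuploid
  tumors. Reference chromosomes are co-aberrant in 94% of numerical
  samples (typically one of the four), as low-level changes at half that
  attenuation — strong same-direction reference shifts would produce
  false-positive storms that the real assay did not show, while low-level
  reference drift reproduces its documented failure mode (missed calls,
  and occasionally a truly aberrant chromosome surfacing as a wrong-scope
  segmental call).
* The gold standard is derived from the generator's own event log, never
  from caller output, and all randomness flows from one seed; cohorts are
  byte-reproducible.

What passing simulated tests does *not* show: the generator has no
electrophoretic stutter, no size-calling jitter, no tumor-cell-content
variation between samples, no small intra-arm events, and its noise is
homoscedastic on the log scale. Results on real capillary data can be
worse in all of those directions; the simulation validates the *logic* of
normalization, scoring and evaluation, not instrument behavior.

## Problem sizes and runtime choices

The bundled analyses run at the study's own scale: 52 tumors + 2 controls
across three kits (≈ 2,500 dosage quotients per rule set), oracle
equivalence on 1,000 random dosage instances, an exhaustive rule-grid scan
at 2–4 loci with seeded random profiles at 5–8 loci (the full 2–8 locus
grid has 10^8 points and adds nothing: every clause depends only on
threshold crossings exercised at the shorter lengths), and 4,000 replicate
pairs for the repeatability check. Everything completes in a few minutes
on one core.

## Known limitations

* Whole-chromosome sensitivity in near-triploid tumors is intentionally
  mediocre (macro AUC ≈ 0.8): that is the documented behavior of
  ratio-normalized assays when the reference set is itself aneuploid, and
  the generator reproduces it rather than hiding it.
* With attenuated numerical deviations sitting ≈ 2–3 noise SDs below the
  segmental threshold, a truly gained/lost chromosome can occasionally
  present two adjacent loci beyond ±0.2 and be recorded as a segmental
  call of matching direction (a scope error, not a phantom aberration);
  about one numerical sample per cohort is affected at default settings.
* Confidence intervals for AUCs are not implemented (no method is defined
  for the two-point construction that matches the published intervals).
* The caller does not localize breakpoints within an arm, estimate ploidy,
  or call regions outside the panel.
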