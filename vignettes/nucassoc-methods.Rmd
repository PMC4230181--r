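---
title: "Methods: the random spatial null model and association scoring"
author: "nucassoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the random spatial null model and association scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucassoc)
```

## The question and the model

Interphase FISH counts how often two labelled chromatin segments sit
together in a nucleus.  Because two sizeable signal areas dropped at random
into a small nucleus touch each other quite often, an observed association
percentage is only interpretable against an explicit spatial null.  The
Random Spatial Distribution (RSD) model supplies that null: disc-shaped
signal areas are placed at random in a virtual nucleus and the pair counts
as associated when the discs are attached or overlapping, i.e. when their
centre distance is at most the sum of their radii.

The model is two-dimensional.  Flow-sorted leaf nuclei are strongly
flattened and signals are scored in projection, so a 2D ellipse captures
the geometry that the scoring actually sees; it also keeps a deterministic
analytic oracle tractable (below).  A 3D ellipsoid variant could sit behind
the same interface but is deliberately not the default.

Three relations are modelled:

* **trans** (segments on different chromosomes): both signal centres
  independent and uniform over the nucleus ellipse.
* **cis** (segments on different arms of one chromosome): both centres
  uniform inside a single *territory disc*, itself placed uniformly over
  the positions at which it fits inside the nucleus.  This is the simplest
  one-parameter expression of the fact that the centromere holds the two
  arm territories together, which is why the cis expectation exceeds the
  trans expectation.
* **homologous**: each centre inside its own, independently placed
  territory disc.

## Parameters, defaults, and calibration

| parameter | default | unit | meaning |
|---|---|---|---|
| `semiMajor`, `semiMinor` | 4.0, 2.5 | µm | semi-axes of the flattened nucleus footprint |
| `territoryRadius` | 1.5 | µm | radius of the arm-territory disc |
| `signalRadius` | 0.5397 (trans), 0.3467 (cis) | µm | radius of one signal area |
| `nTrials` | 1e5 | — | Monte-Carlo sample size |

The published work fixes the 2C random expectations — 9.9% for trans and
17.2% for cis — without publishing the underlying geometry.  The package
therefore treats those constants as *calibration anchors*, not emergent
predictions: the nucleus footprint (4.0 × 2.5 µm, a typical flattened 2C
leaf-nucleus outline, stated as a convention) and the territory radius
(1.5 µm, chosen not to exceed the ellipse's minimal radius of curvature
b²/a ≈ 1.56 µm so the disc fits everywhere along the boundary) are fixed,
and `calibrateSignalRadius()` bisects the signal radius until the simulated
null matches the anchor within 0.2 percentage points.  Because signal
placement does not depend on the signal radius, re-evaluating with a common
seed makes the estimated percentage exactly non-decreasing in the radius,
so the bisection cannot oscillate.  One radius is calibrated per relation
class; `referenceNull()` returns the anchors themselves as pure lookups.

## The analytic oracle

For the trans relation the null probability has a deterministic value:
P(|P₁ − P₂| ≤ t) for two independent uniform points in the ellipse.
`analyticTransNull()` computes it without Monte Carlo through the set
covariance of the ellipse — the overlap area of the ellipse with a shifted
copy of itself, which rescales to the closed-form lens area of two unit
circles — integrated on a dense polar grid (3000 radial × 600 angular
nodes; for a circular nucleus this reproduces the classical inter-point
distance CDF to about 1e-7, far below Monte-Carlo noise at 1e5 trials).
The simulator is validated against this oracle across association
thresholds spanning 0.1–1.9 nucleus radii.

Uniform sampling inside ellipse and disc uses rejection from the bounding
rectangle, in chunks of twice the remaining need — documented so an
independent implementation can reproduce the stream call-for-call.  The
region where a territory disc fits inside the nucleus (the erosion of an
ellipse, which has no closed form) is sampled by rejection with containment
checked on a 180-angle boundary grid; since association depends only on
positions relative to the disc, this approximation affects reported
coordinates but no association probability.

## Scoring conventions

Scored nuclei live in a tidy one-row-per-nucleus × probe × homolog table
(`ScoredNuclei`), with optional 2D positions (µm, image frame; `"x,y"`
pairs joined by semicolons) and categorical flags.  The metrics follow the
field's denominator conventions:

* **association** counts nuclei in which both probes were scored; a
  nucleus is associated when flags say so or, in position mode, when the
  minimal inter-signal distance is at most the threshold (default: the
  signal diameter of the geometry in use).  Flags take precedence because
  visual scoring is the primary channel; the absence of a flag means "not
  associated", so an all-negative categorical table scores 0% rather than
  erroring.  Position mode errors when positions are missing.
* **elongation** counts nuclei with more signals than the ploidy predicts
  (> 2 in 2C, > 4 in 4C; above 4C the ploidy number, a stated convention).
  Mixed-ploidy input must be disambiguated explicitly since the threshold
  is ploidy-specific.
* **cohesion** counts homologs in replicated (≥ 4C) nuclei whose sisters
  appear as one fused signal; undefined in 2C.
* **separation** of adjacent probes (adjacency verified on the BED
  annotation: same chromosome, touching or overlapping intervals) counts
  homologs in 2C and sister chromatids in 4C — each homolog contributes
  two chromatid units and a homolog-level call applies to both sisters.
* **out-looping** counts nuclei with the segment outside its territory.

Percentages are kept at full precision; display rounds half-up to one
decimal, matching the reporting convention (e.g. 2/150 → 1.3%).

## Exact comparison against the null

`compareToNull()` forms the table `[[k, n−k], [k₀, n−k₀]]` with
`k₀ = round(nullPercent·n/100)` — the expected count at the observed sample
size — and applies the two-sided Fisher's exact test: the sum of
hypergeometric point probabilities not exceeding the observed one, with a
relative tie tolerance of 1e-7.  How a simulated proportion becomes the
second row of a 2×2 table is a genuine gap in the source procedure; using
the same *n* mirrors the comparison of two equally sized samples and keeps
the test exact, while `method = "binomial"` exposes the alternative of
testing against a fixed known proportion.  Treating the null as a second
sample is conservative: on populations generated at the null rate
(n = 150) the test suite measures a star rate at the 0.05 level well under
the nominal 5%.  No multiple-testing correction is applied — stars
(\*P < 0.05, \*\*P < 0.01, \*\*\*P < 0.001, strict inequalities) are
per-comparison, matching the reporting they imitate.

## Co-expression

"Mean-normalized" is interpreted gene-wise: each intensity is divided by
the gene's across-sample mean before log2 (the convention of the
developmental expression atlas this mirrors); rank correlations are
unaffected by any monotone per-gene normalization, so this choice only
matters for segment mean levels.  Spearman's r<sub>s</sub> is the Pearson
correlation of average ranks (ties averaged).  Its two-sided p-value uses
the exact permutation distribution for n ≤ 9 (all n! rank permutations,
enumerated once and cached; assumes untied ranks) and the t approximation
`t = r_s·sqrt((n−2)/(1−r_s²))` on n − 2 degrees of freedom beyond; a
perfect correlation in the approximation branch returns the smallest
positive double rather than zero.  The high/low co-expression cutoffs
(r<sub>s</sub> ≥ 0.7 high, |r<sub>s</sub>| ≤ 0.3 low) are explicit package
conventions — no published cutoffs exist — and are arguments everywhere
they are used.  Genes excluded upstream (e.g. splice-variant-bearing ids a
query database cannot accept) are handled by passing an exclusion list;
unknown ids are reported, never silently dropped.

## What the synthetic generator emulates — and what it does not

`genNucleiPopulation()` emulates a flow-sorted, single-ploidy nucleus
population scored for two probes.  With probability `pAssoc` a nucleus's
two primary signals are *forced* together: the first is placed by the RSD
model, the second uniformly within the association threshold of the first
(clipped to the nucleus) — the simplest mechanism with the right marginal.
Otherwise both follow the RSD placement, so at `pAssoc = 0` the population
reproduces the model's own random association rate.  Flags are derived
from the realized positions with the same threshold, which is why
flag-based and position-based scoring agree exactly on generated data.
Cohesion is drawn per homolog, elongation and out-looping per
nucleus × probe, independently; correlated configurations (e.g. the
cohesion–elongation interplay real chromatin shows) are not generated.
Positions are recorded for the first homolog of each probe; second
homologs are scored categorically.  Consequences for validation:

* Recovery tests for `pAssoc` use a point-like signal geometry
  (signal radius 0.01 µm), because with a realistic radius the scored
  frequency is `pAssoc + (1 − pAssoc)·null`, not `pAssoc`; the point-like
  limit isolates the induced-association channel so the exact binomial CI
  of the generating probability applies.  Validation uses n = 500 nuclei
  and 100 seeds per probability.
* Passing tests on this generator show the *calculators* are correct and
  the pipeline recovers known truth; they say nothing about segmentation
  noise, partial associations, optical blur, or scorer disagreement in
  real micrographs, none of which are simulated.

`genExpressionMatrix()` builds blocks of genes sharing a latent per-sample
factor: on the log2 scale a block gene is
`log2(baseline) + λ·F_s + noiseSd·ε` with
`λ = noiseSd·sqrt(ρ/(1−ρ))`, so the within-block Pearson correlation of
log intensities is exactly `ρ = latentCorrelation` and the expected
Spearman correlation is `(6/π)·asin(ρ/2)` — the recovery oracle used in
the tests (n = 500 samples, tolerance 0.05).  With `noiseSd = 0` block
genes are exact monotone copies (r<sub>s</sub> = 1); background genes are
independent noise.

## Numerical choices and degenerate inputs

* Monte-Carlo estimates are bit-identical under identical (config,
  relation, trials, seed); the global RNG state is saved and restored.
* Calibration: bisection with at most 200 halvings, failing loudly when
  the target is unreachable at the trial granularity or radius bounds.
* `estimateNull` refuses zero trials; `RSDConfig` validity enforces
  0 < signal ≤ territory ≤ minor semi-axis ≤ major semi-axis.
* Fisher: tables with a zero margin have a single attainable
  configuration and return p = 1; negative or non-integer entries are
  domain errors.
* Spearman: constant sequences are an error (undefined correlation);
  n < 4 is refused for p-values.
* One-gene segments report sd 0 by convention; empty segments are errors.
* Reports carry `#` header comments with package version, a hash of the
  run configuration, and the seed.

## Validation problem sizes

The test suite validates the simulator against the analytic oracle at 1e5
trials; the exact test against full enumeration for all 2×2 tables with
margins ≤ 10; generator recovery at 500 nuclei × 100 seeds per
probability; and the size of the null comparison on 1000 populations of
150 nuclei.  These sizes were chosen to give the statistical assertions
comfortable power while keeping a routine test run short.

## Known limitations

* The 2D model cannot represent axial (z) separation; two signals stacked
  in z score as associated.
* Partial association (signals touching by less than a full overlap
  criterion under visual scoring) is not modelled — the association call
  is binary.
* The published geometry behind the 9.9%/17.2% anchors is not
  reproduced, only matched by calibration; different (nucleus, territory,
  signal) triples can yield the same nulls.
* Homolog assignment is taken from the input table as given; no automatic
  pairing of signals to homologs is attempted.
* Cohesion scoring equates "one signal" with "cohesive", which cannot
  distinguish true cohesion from sisters separated along the optical
  axis.
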