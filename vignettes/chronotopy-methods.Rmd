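---
title: "Methods: quantifying temporal cohorts and chronotopic organization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying temporal cohorts and chronotopic organization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronotopy)
```

# Overview

Dorsal-horn interneurons of the mouse spinal cord settle into laminae in
the order they are born: developmental time is converted into a
dorsoventral spatial order (chronotopy). `chronotopy` implements the
quantitative machinery needed to establish that claim from section data:

1. **Registration** of per-section cell coordinates onto an idealized
   spinal cord template via 10 manually placed anatomical anchors.
2. **Birthdating**: cumulative EdU co-labeling curves per cell-type
   family, sigmoid fits, and half-maximal birthdate statistics.
3. **Curve similarity**: dynamic-time-warping (DTW) distances between
   composition-versus-time (or ranked-expression) curves, with a
   permutation null.
4. **Spatial quantification**: 2D kernel density estimates with
   highest-density contour levels, 200-bin dorsoventral depth
   histograms, compressed 80-bin genotype-comparison profiles, and
   quintile ANOVA.

Because raw imaging and sequencing data are outside the package's scope,
a synthetic-data module generates every input with known ground truth;
all statements below about accuracy are backed by the test suite run on
those generators.

# Section registration

Each section carries exactly ten anchors: the dorsal-most and
lateral-most extents of both dorsal horns, the base of the dorsal
columns, the lateral-most and ventral-most extents of both ventral
horns, and the dorsoventral junction on the midline. Registration is a
two-step transform:

**Rotation.** The section is translated so the dorsoventral junction
sits at the origin and rotated so the dorsal-column base lies on the
positive y axis. Of the two solutions that make the midline vertical,
this one uniquely fixes dorsal = up. The transform is rigid, so all
inter-cell distances are preserved.

**Template warp.** Each hemisection is stretched onto the ideal diagram:
y is mapped by a monotone piecewise-linear function through six control
pairs — ventral-horn ventral (−2000), ventral-horn lateral (Y_VLAT),
junction (0), dorsal-horn lateral (Y_LAT), dorsal-column base (Y_DC),
dorsal-horn dorsal (+2000) — and x is scaled so the lateral dorsal-horn
anchors land at ±2000, with the scale blended linearly in y between the
dorsal-horn-lateral and ventral-horn-lateral scales and clamped to the
nearer scale outside that band. The blending form is a design choice:
the relevant anchors are known but no functional form is canonical, so
the simplest continuous interpolation was adopted. Template units are
arbitrary; the intermediate control values default to Y_DC = +1200,
Y_LAT = +800, Y_VLAT = −800, |X_VLAT| = 1600 and are overridable per
segment group, because comparisons are only meaningful within a segment
group anyway.

Cells exactly on the midline (x = 0 after rotation) take the mean of
the left and right hemisection maps; hemisection assignment for such
cells is otherwise arbitrary. Outside the outermost control anchors the
terminal linear segments are extended, so slightly out-of-tissue points
do not error.

The section simulator inverts this warp exactly (per-control y scales,
per-level x scales, then a rigid motion), so at zero coordinate jitter
the round trip recovers the template-frame truth to numerical precision
(≤ 1e−6 template units across random rotations in ±60°, tested).
Jitter is applied to cell coordinates only, never to anchors — anchor
placement error is a real phenomenon but would confound the warp's own
correctness test, so it is left to explicit sensitivity analyses.

For genotype overlays, the reference population is reflected to x ≤ 0,
the comparison population to x ≥ 0, and the reference is downsampled
per cell type by the ratio of the two totals (round-half-to-even per
type, sampling without replacement).

# Cumulative EdU birthdating

An EdU pulse at embryonic time t labels, in the simulator's model, every
cell whose birthdate falls in the half-open window [t, t + w), with
w = 0.5 day by default — the spacing between successive pulses in the
emulated design (injections at 12:00 or 0:00, E10.5 through E13.5).
Birthdates are drawn per cell from each family's Gaussian birth wave.

The analysis mirrors the experimental bookkeeping: per-embryo co-labeled
fractions are averaged within litters (litters, not embryos, are the
replicate unit); per-timepoint litter means m_t are normalized to birth
percentages p_t = 100·m_t/Σm; and each litter's cumulative value at
timepoint t is its own normalized fraction plus the mean percentages of
all earlier timepoints. This preserves within-timepoint variation while
forcing the litter mean at the final timepoint to exactly 100% — a
property the tests assert to machine precision. Litter-level curves can
dip locally when a litter sits above the mean at one pulse and below at
the next; only the mean curve is guaranteed monotone.

Sigmoid fits come in three flavours: a self-starting logistic for
per-litter replicate fits (inflection `xmid`, steepness `scal`), and
4PL/5PL dose-response forms (with time as the "concentration" axis) for
the family-level curves. A 4PL fit falls back to the asymmetric 5PL when
it fails to converge or explains less than 95% of the variance — the
situation that arises when substantial neurogenesis before the first
pulse leaves no slow-growth phase. Optimization is bounded
Levenberg–Marquardt least squares with data-driven starts (bottom =
min y, top = max y, midpoint = half-range crossing, slope ±5 by trend),
tolerance 1e−10.

One bookkeeping subtlety: the cumulative value at pulse time t counts
every birth up to the **end** of that pulse's window, so the fitted
half-max on the pulse axis estimates the median birthdate minus w.
`estimate_birthdates()` therefore reports halfmax + w. On the
full synthetic study design (7 half-day pulses, 4 litters × 3 embryos ×
100 cells) with birth waves at E11.5/E12.0/E12.5 (σ = 0.4 d), the
estimator recovers each wave within 0.25 day in 100/100 seeded runs and
preserves the wave ordering in all of them. Waves centred before the
first pulse are left-censored and recover with a late bias — exactly the
regime the 5PL fallback exists for — so recovery claims are only made
for waves inside the sampled range.

Family differences in inflection time and steepness use equal-variance
two-sample t-tests on the per-litter logistic parameters
(Welch available by option), with Benjamini–Hochberg adjustment across
family pairs, separately per statistic.

# DTW curve comparison

Composition-versus-time curves (one per cell type, fractions summing to
1 at each timepoint) are compared pairwise by dynamic time warping:
local cost |a_i − b_j|, unit-weight steps (diagonal, vertical,
horizontal), no window, and the unnormalized accumulated cost as the
distance. This is the plain textbook recurrence, declared in the
result's `local_cost` tag; no step-pattern normalization is applied.

Significance uses a permutation null: the value ordering of both curves
is shuffled independently (a shuffle-second-curve-only mode exists and
is what the exhaustive small-case tests enumerate), the distance is
recomputed, and p is the proportion of permutations with distance
strictly greater than observed. Ties count as not greater, and the
identity ordering is eligible like any other. When the number of
orderings is at most `n_perm`, all orderings are enumerated exactly.
The test is two-sided in interpretation: p near 0 flags curves further
apart than chance; p near 1 flags curves more similar than chance
(identical curves give p = 1 exactly, since the observed distance is 0).
Under a simulated null (both curves i.i.d. shuffles of the same values)
the p-value distribution is uniform to within a Kolmogorov–Smirnov
statistic of 0.05 at 1,000 pairs × 999 permutations (tested). The
default `n_perm` is 100,000 for production use; tests and the analysis
scripts use 999–10,000 to keep runtimes in seconds. The inner loop is
compiled (Rcpp); a pure-R dynamic program with path backtracking is the
reference implementation and the two are cross-checked on random series.

# Spatial quantification

**KDE and contours.** Densities are axis-aligned Gaussian product
kernels on a 100×100 grid; the bandwidth argument is the kernel SD per
axis, with the normal-reference rule as the automatic default, and grid
limits padded by 3.5 kernel SDs so the grid mass integrates to ~1
(within 1%, tested). Contour levels are anchored to *points*, not grid
mass: the threshold for level α is the density of the ⌈αn⌉-th densest
sample point (densities evaluated exactly at the sample points, not
interpolated), with ties included. Levels at the default fractions
(densest 50/25/15/5/2.5%) are nested by construction, and empirical
coverage at n = 2,000 matches α within 2 percentage points.

**Depth histograms.** Template-frame y-coordinates are assigned to 200
half-open bins spanning [−2000, +2000], bin 1 dorsal-most; counts are
conserved exactly, and out-of-range coordinates are clipped into the end
bins with a warning. Optional smoothing is a Gaussian kernel over bins
(SD 3 bins by default) applied for display only — raw counts are always
retained.

**Compressed profiles and quintiles.** Raw image-derived profiles of
arbitrary length are compressed to a common 80 bins by summing with
fractional pro-rating of straddling bins, then normalized to sum to 1
per replicate so bins are proportions of that replicate's signal. The
dorsal-most 56 bins form the plotting view (lamina VI is excluded from
display); quintiles are five equal 16-bin dorsoventral groups. The
common bin count of 80 is a default consistent with those two published
constants and is configurable. Colocalization profiles are the
elementwise product of two thresholded binary profiles. Quintile weights
feed a three-way ANOVA (genotype × quintile × cell-type, all
interactions; classical sums of squares on the balanced designs the
simulator produces) with Tukey HSD post-hoc comparisons per quintile and
cell-type; replicate composition tables use a two-way ANOVA
(cell-type × genotype) with Tukey per cell type. On simulated profiles a
40-bin genotype shift of one peak produces a genotype × quintile
interaction at p < 0.001 while shift-free data stay null (tested).

# Randomness and problem sizes

All generators are pure functions of their configuration, including the
seed; sub-streams per litter and replicate are derived as fixed integer
offsets from the base seed (R lacks a splittable generator; the offsets
are spaced so streams never overlap in practice, and determinism — the
property that matters for reproducibility — is asserted bitwise in the
tests). Litter-level conception-time jitter (±8 h is a realistic
magnitude) is supported but off by default, since it blurs exactly the
quantity the recovery tests measure.

The analysis scripts use 2,000-cell sections, the full EdU study design
(252 count rows), 4 composition types × 13 quarter-day timepoints with
10,000 permutations per pair, and 160-bin profiles in triplicate. These
sizes give stable third-digit results while keeping every script in the
seconds-to-a-minute range; all are plain arguments and scale up
trivially.

# What the synthetic data do and do not show

The generators emulate the *structure* of the real inputs: bilaterally
symmetric sections with consistent anchor geometry, overlapping Gaussian
birth waves sampled through a litter/embryo hierarchy, smooth
composition drifts, and peaked depth profiles with genotype shifts. They
do not emulate segmentation error, anchor mis-placement, lamina-specific
cell density, non-Gaussian birth waves, or transcript-level noise.
Passing tests therefore certify the *procedures* — that the warp is
exactly invertible, the cumulative construction normalizes as claimed,
the permutation null is calibrated, the contour levels cover what they
say — not that any biological conclusion transfers to a given real
dataset.

# Known limitations

- The x-warp blending between the dorsal- and ventral-horn lateral
  scales is an interpolation convention; other monotone blends would
  register anchors equally well but move interior cells by a few
  template units.
- DTW here is univariate and unconstrained; no Sakoe–Chiba band.
- The quintile ANOVA assumes balanced replicate designs; heavily
  unbalanced data should use a mixed model instead.
- Half-max birthdates for waves outside the pulse range are biased and
  flagged rather than corrected; extending the pulse range is the
  experimental fix.
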