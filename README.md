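# chronotopy

Quantitative pipeline for establishing **temporal cohorts** and the
**chronotopic map** of the spinal dorsal horn — the observation that
late-born dorsal interneurons (dIL families) settle into laminae in
birth order, converting developmental time into dorsoventral position.

The package is aimed at developmental neurobiologists quantifying
section-based coordinate data (EdU birthdating counts, spatial
transcriptomics cell positions, thresholded image profiles). It provides
four analysis stages plus synthetic-data generators with known ground
truth, so the whole pipeline is testable end to end without any external
data:

| Stage | What it does |
|---|---|
| `register` | Rotates each section so the midline anchors share an x-coordinate, then stretches each hemisection onto an idealized template: dorsal/ventral extremes at y = ±2000, lateral dorsal-horn anchors at x = ±2000 (arbitrary units), via a monotone piecewise-linear warp through 10 anatomical anchors. Mirrored, ratio-downsampled genotype overlays. |
| `birthdate` | Litter-level EdU co-labeling fractions; cumulative curves normalized so the litter mean at the final pulse is exactly 100%; logistic / 4PL / 5PL sigmoid fits; half-maximal birthdates; pairwise t-tests on inflection and steepness with BH correction. |
| `tempsim` | Dynamic-time-warping distances between composition-vs-time (or ranked-expression) curves — local cost \|a_i − b_j\|, unit-weight steps, unnormalized total — with a permutation null: p = proportion of shuffled-order distances strictly greater than observed (two-sided reading: p ≈ 0 means more different than chance, p ≈ 1 more similar). |
| `density` | 2D Gaussian KDE at resolution 100; highest-density contour levels fitting the densest 50/25/15/5/2.5% of points; 200-bin dorsoventral depth histograms; 80-bin compressed profiles (56-bin dorsal view) and quintile ANOVA (genotype × quintile × cell-type) with Tukey post hoc. |

The core model for birthdating: each family's neurogenesis is a Gaussian
wave N(μ, σ²) in embryonic time; an EdU pulse at time *t* co-labels
births in [t, t + w), w = 0.5 d. The cumulative co-labeling curve is the
birth CDF evaluated at t + w, so the fitted sigmoid half-max plus w
estimates the family's median birthdate μ.

## Worked example

The `analysis/` scripts run the full workflow on synthetic data
(`Rscript analysis/01_simulate.R` … `05_density.R`). Highlights of what
they print:

Registration of a 2,000-cell section simulated 30° off-axis with a
non-trivial section warp recovers the template-frame ground truth and
pins the template anchors:

```
round-trip max error: 1.25e-11 template units
dorsal anchor y: +2000.0   lateral-left anchor x: -2000.0
```

Birthdating of three simulated waves (true medians E11.5/E12.0/E12.5;
4 litters × 3 embryos × 100 cells, 7 half-day pulses):

```
mean cumulative co-labeling at E13.5: 100.0%, 100.0%, 100.0% (per family)
  family halfmax birthdate converged
1     F1   11.00     11.50      TRUE
2     F2   11.49     11.99      TRUE
3     F3   12.00     12.50      TRUE
inflection-time pairs significant at q < 0.05: 3 of 3
```

The half-max birthdates land on the configured waves to two decimals,
and all pairwise inflection-time differences are detected.

DTW on four composition curves peaking 0.5 d apart (10,000 permutations
per pair): adjacent waves are *more similar than chance* (p near 1),
distant waves *more different* (p near 0):

```
adjacent pair T1-T2: D = 1.501, p = 0.998
extreme pair  T1-T4: D = 7.149, p = 0.000
```

Spatial quantification: per-family highest-density contours hold 50.0%
of points at the outermost level; the quintile ANOVA flags a simulated
40-bin ventral shift of the mutant peak as a genotype × quintile
interaction (p ≈ 5e-45) while the genotype main effect is null (the
profiles are normalized per replicate), with post-hoc differences in
quintiles 1–4.

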