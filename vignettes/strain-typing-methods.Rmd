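---
title: "Methods: strain-level typing from MALDI-TOF fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain-level typing from MALDI-TOF fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maldistrain)
```

`maldistrain` reconstructs, as open and tested code, the statistical
workflow used to discriminate closely related bacterial strains from
linear-mode MALDI-TOF fingerprints: spectral preprocessing, discriminant
peak statistics, classification models with external validation, and
main-spectrum-profile (MSP) log-score identification. This vignette is the
package's own account of the models, the parameters that matter, and the
design decisions taken where the underlying vendor software is
undocumented.

## The synthetic data model

Real whole-cell acquisitions are not redistributable, so the package
defines the study conditions through a generator
(`simulate_replicates()`). A strain is a profile: peak positions in
[1,960, 22,000] Da, an apex-intensity law Normal(mean, sd) truncated at
zero, and a peak width. The built-in `reference_profiles()` carry the three
*Paenibacillus polymyxa* reference strains:

* the `"discriminant"` set is the seven quantified biomarkers (2874, 2944,
  2959, 3314, 5505, 7076, 9492 Da) with their published per-strain
  mean ± sd apex intensities;
* the `"extended"` set adds the further characteristic masses reported for
  these strains (2400, 2685, 2987, 3089, 4179, 4748, 5374, 5954, 6413,
  6525, 6631, 6656, 7336, 13305 Da). Only qualitative descriptions exist
  for them, so the package fixes intensities once: "strongly present"
  peaks at 1.5–6 a.u., "low" at 0.15 a.u., "almost absent" at 0.05 a.u.,
  with a 20% relative sd. The low/absent levels sit below the single-
  spectrum detection limit, so each strain exposes a distinct *detected*
  peak set — the property MSP identification exploits in real fingerprints.

Each replicate renders every profile peak as a Gaussian (default full width
at half maximum 0.1% of its *m/z*, linear-TOF-like broadening that keeps
2944 and 2959 Da resolvable), adds a smooth positive baseline (default
amplitude 0.3 a.u., well below the discriminant peak heights, so top-hat
removal is exercised but never dominates), white noise (default sd
0.08 a.u., putting a 0.76 a.u. peak at single-spectrum signal-to-noise
≈ 10 and a 0.15 a.u. peak below the S/N 5 detection limit), and one global
mass shift per replicate drawn uniformly within ±300 ppm — inside the
1,000 ppm recalibration cap by construction. No noise magnitude or baseline
shape is published; these are package choices, exposed in the arguments and
fixed once.

The generator grid is uniform with a 0.25 Da default step: the narrowest
default peaks (FWHM ≈ 2.9 Da at 2944 Da) need ≈ 4 samples per sigma for
the later resampling to read their apexes to well under 1%; a 1 Da grid
would bias apex reads by up to ~8%. Heights use inverse-CDF truncated
Normal sampling (a fixed number of uniforms per call keeps the RNG stream
aligned), so identical seeds give bit-identical batches.
`simulate_peak_matrix()` draws the apex-intensity matrix directly from the
same law — the exact quantity the spectral pipeline recovers — which is the
input scale on which the classifier and discriminant-statistics study
conditions are defined, at a fraction of the cost.

What the generator does **not** emulate: isotopic envelopes, detector
saturation, matrix cluster ions, peak-shape asymmetry, correlated
(chemical) noise, or between-day batch effects. Tests passing on this
model therefore show that the *statistical machinery* behaves as claimed
under the published intensity statistics; they cannot show robustness to
instrumental artefacts absent from the model.

## Preprocessing

**Resolution and the analysis grid.** The vendor setting "resolution = 800"
has no public definition. Interpreting it as a *point count* (an 800-point
uniform grid over 2,000–15,000 Da, ≈ 16 Da spacing) destroys peaks whose
FWHM is ≈ 3 Da, so the package interprets it as resolving power m/Δm: the
analysis grid is geometric (constant relative step
1/(resolution × oversample), default oversample 6, ≈ 9,700 points). On this
grid a peak whose width is a fixed fraction of its *m/z* spans the same
number of points everywhere, so smoothing and apex reading treat every peak
identically; the Savitzky–Golay filter attenuates all apexes by one common
factor and intensity *ratios* are preserved (verified to within 1% by a
noise-free property test; oversample 4 leaves ≈ 1.3% phase-dependent error,
6 gives ≈ 0.5%).

**Quality control.** A spectrum is a flatline when its intensity range does
not exceed `noise_threshold` (default 2) times the range pure noise of that
length would produce (robust noise estimate × the expected extreme range
2√(2 log n)). A comparison against the noise sd alone can never flag a
noisy flatline — the extreme range of 10⁴–10⁵ noise samples is ≈ 9 sd by
itself — hence the extra factor. Outliers are spectra whose maximum exceeds
10× the batch's median per-spectrum maximum.

**Noise and background.** The robust noise estimate is the scaled median
absolute deviation of the trace about a wide running median. A
first-difference estimator is equivalent on raw traces but collapses
(~10×) once smoothing correlates neighbouring samples, which would let
noise maxima through the S/N gate. The same running median (window ≈ 1% of
*m/z*, an order of magnitude wider than the 0.1% peak widths) serves as the
*local background*: apex intensities are read as prominences above it,
which removes the positive pedestal a morphological opening leaves where
noise dominates (the opening subtracts the noise floor's lower envelope,
≈ 2.5 noise sd below zero).

**Baseline.** The top-hat baseline is the morphological opening — erosion
then dilation with a flat structuring element (default 150 Da, far above
peak widths, far below baseline scales) — computed by an O(n)
monotonic-deque running min/max in C++ over a true mass window, so it is
exact on non-uniform grids. The opening never exceeds the trace, so the
corrected spectrum is non-negative and corrected + baseline reconstructs
the input exactly; tests verify equality with a brute-force sliding
min/max oracle.

**Smoothing and normalisation.** Savitzky–Golay (window 9 points, order 3;
the published workflow names smoothing without parameters) and
total-ion-count scaling to a total of 100 (the vendor default reading of
"intensity normalisation"); both exposed.

**Recalibration.** Per spectrum, S/N ≥ 5 maxima are matched to reference
peak centres within 1,000 ppm; if fewer than 30% of reference peaks match,
the spectrum is excluded, otherwise a single multiplicative correction (the
median relative shift) is applied — a global stretch, not per-peak warping,
matching the "maximal peak shift" phrasing and keeping the operation
invertible. Tests inject a +600 ppm shift and verify sub-50 ppm residuals,
and verify exclusion at +2,000 ppm.

## Peak analysis

Peaks are picked on the total average spectrum (every spectrum weighted
equally; a class-balanced mode exists) as local maxima whose prominence
above the local background reaches S/N ≥ 5. Windows run to the flanking
minima, capped at half the distance to the neighbouring peak and at 0.3% of
the centre mass, so they never overlap. Apex positions and heights are
refined by a log-quadratic fit through the three samples around the
maximum — exact for Gaussian peaks on any grid. The matrix entry is the
apex *maximum*, not the area, consistent with apex-read intensity tables;
window construction itself is a package definition, since the vendor's
"peak calculation" defaults are not public.

## Discriminant statistics

Per peak, the Anderson–Darling composite-normality test is evaluated on the
pooled within-class centred residuals; if it rejects at 0.05 the
Wilcoxon (2 classes) / Kruskal–Wallis (≥ 3) test supplies the selection
p-value, otherwise one-way ANOVA does. The gate is per peak by default —
statistically coherent, since normality is a per-peak property — with a
`gate = "global"` option that lets the worst-case AD p switch every peak at
once, reproducing a single-switch reading. With the published per-strain
intensity laws the pooled residuals are a scale mixture (class sds differ
up to 40-fold), so the AD gate routes essentially all biomarkers to the
rank test, as the published analysis reports. The AD statistic uses the
small-sample adjustment A\*² = A²(1 + 0.75/n + 2.25/n²) and the standard
piecewise-exponential p approximation; it is implemented in the package
because the workflow's contract admits n ≥ 5 while the reference
implementation in `nortest` requires n ≥ 8 (tests cross-check both and a
brute-force order-statistic sum). Zero-variance residuals make AD
undefined; such peaks are routed to the rank test, which handles ties.

No multiple-testing correction is applied by default (the published cut-off
is a raw 0.05); Benjamini–Hochberg is available. Log2 fold changes use a
floor of 10⁻⁶ × the matrix maximum to keep absent peaks finite. PCA is
centred and unscaled, on the peak-intensity matrix (consistent with
loading-plot interpretation of peaks); score-space class separation is
checked by a convex-hull disjointness test. The published real-data
variance fractions (PC1 58%, PC2 20%) depend on the real spectra and are
not reproducible desk-side; the property suite checks separation, ordering
and conservation instead.

## Classification

**QC.** Peaks ranked by ascending W/KW p-value, top 4 retained (the size of
the published multiclass QC model); prediction minimises
Σⱼ wⱼ ((xⱼ − μ_cj)/σ_cj)² with weights wⱼ ∝ −log₁₀(pⱼ) normalised to sum 1.
The vendor describes QC as a p-value-sorted weighted classifier; the exact
rule is frozen here. Deterministic.

**SNN.** The vendor network is unpublished. The package realises it as a
prototype classifier in the learning-vector-quantisation family with
Gaussian receptive fields: each prototype carries a position and
per-dimension widths (the class sds), and distance adds the 2Σ log σ
diagonal-Gaussian term. This matters: the per-class variance structure *is*
discriminating information (a class that is tight on a marker peak claims
it strongly), and plain Euclidean prototypes discard it. Peaks enter by
greedy forward selection maximising leave-one-out accuracy (closed-form
leave-one-out downdates of the class statistics), ties broken by the larger
classification margin so the selection pairs complementary marker peaks
rather than redundant ones; the default cap of 3 matches the published SNN
peak count. Prototype positions are refined by LVQ1 updates (10 epochs,
learning rate 0.02 decaying to zero, seeded order), keeping the classifier
seed-deterministic.

**GA_KNN.** Bit-mask chromosomes over peaks (≤ 30 set bits), fitness =
stratified 5-fold cross-validated KNN accuracy, exactly `n_generations`
generations (50 by default; 0 returns the best of the random initial
population). Unpublished GA internals are fixed as: population 64,
tournament selection of size 3, uniform crossover probability 0.7, per-bit
mutation 1/n_peaks, single elitism (which makes the best fitness
non-decreasing, a tested invariant), fitness memoisation. KNN is
implemented in-package because the prescribed deterministic tie-break
(majority vote, then smallest mean distance, then class order) differs from
`class::knn`'s randomised ties; k must be odd, and k = 7 is accepted
alongside the documented 1/3/5.

**Validation.** One-vs-rest confusion counts per class over the pooled
external set; accuracy, sensitivity and specificity are exact rational
arithmetic × 100, rounded to two decimals only for reporting. Model peaks
align to test-matrix columns by nearest mass within 600 ppm; unalignable
masses are an error listing what is missing.

## Identification

`build_msp()` picks peaks per replicate (intensities normalised to sum
100), pools them, clusters by single-linkage chaining at 600 ppm, and keeps
clusters seen in ≥ 25% of replicates, recording mean normalised intensity
and frequency. `log_score()` maps similarity to the 0–3 scale as
3 + log₁₀(s₁·s₂·s₃), clipped to [0, 3], with

* s₁ — frequency-weighted fraction of MSP peaks matched in the query
  (600 ppm tolerance),
* s₂ — intensity-weighted fraction of query peaks matched in the MSP,
* s₃ — intensity agreement over matched peaks,
  exp(−3 × rms of the median-centred log intensity ratios); the median
  centring makes the score invariant to global rescaling of the query.

The commercial log(score) formula is proprietary. A geometric-mean
composite was considered and rejected: with strains sharing most peak
positions, two of three sub-scores saturate at 1 and a geometric mean can
only fall below the 2.00 high-confidence threshold if the remaining
sub-score drops below 10⁻³, which no correlation-type measure of genuinely
related strains does — such a score would call every congener a
high-confidence match. The product form with an exponential intensity
penalty separates the regimes: a same-strain replicate keeps all three
sub-scores near 1 (score ≈ 2.6–3.0), while a different strain loses both
match fractions (distinct detected peak sets) and intensity agreement
(several-fold differences at shared biomarkers), pushing the score well
below 2.00. The construction is calibrated only against the categorical
outcomes (which strain matches which MSP); published numeric log-score
ranges depend on the commercial reference database and are deliberately not
targets. Confidence bands are the standard ones: ≥ 2.00 high, 1.70–1.99
low, otherwise no identification, with exact boundary behaviour tested at
1.999/2.000/1.699.

## Orchestration, determinism and problem sizes

`run_study_replica()` chains the full workflow (15 training and 21/20/20
external replicates by default, matching the published design) and writes a
discriminant-peak table, a per-model performance table, an MSP library and
a per-replicate identification report plus a parameter manifest; one seed
drives every stochastic stage through derived child seeds, and a fixed seed
reproduces the bundle exactly (a tested invariant). The package is an
analysis library: the exported functions and this vignette are its
interface, and the report bundle is plain CSV/JSON.

Test problem sizes are chosen to keep the default suite fast while leaving
the study conditions untouched: the generator-recovery check uses 8 seeded
batches of 15 replicates; classifier and discriminant-recovery claims use
100 seeded runs at the matrix level (the scale on which those conditions
are stated); the identification claim uses 100 seeded spectral runs with
6-replicate libraries and one fresh query per strain; GA property tests run
reduced generation counts. The pipeline determinism test runs a reduced
two-strain configuration.

## Known limitations

* The synthetic model omits instrumental artefacts (see above); agreement
  with the published per-strain statistics does not imply robustness to
  them.
* The QC, SNN and log-score constructions are documented package
  definitions of unpublished vendor algorithms; they reproduce the
  published input/output behaviour, not vendor numerics bit-for-bit.
* Recalibration fits one multiplicative stretch per spectrum; nonlinear
  mass-axis distortion is out of scope.
* The relationship between the spectra-preparation noise threshold (2) and
  the peak-picking signal-to-noise threshold (5) is not documented
  upstream; the package keeps them as two independent settings.
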