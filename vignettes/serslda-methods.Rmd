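---
title: "Discriminating glycoprotein isoforms from SERS spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating glycoprotein isoforms from SERS spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Surface-enhanced Raman scattering (SERS) amplifies the vibrational spectrum
of molecules adsorbed on a nanostructured metal surface enough to record
spectra of individual proteins. When the *same* protein is produced by
different cell types, its amino-acid backbone is identical and the spectra
are nearly indistinguishable by eye: the differences hide in minor
vibrational bands, plausibly contributed by cell-type-specific N-glycans.
The motivating application is angiotensin I-converting enzyme (ACE)
purified from seminal fluid, lung and heart tissue. `serslda` implements
the complete chemometric chain needed to (i) decide whether such spectra
are separable at all, (ii) quantify the separation with standard
classification metrics, and (iii) point back to the wavenumber intervals
that carry the discriminating signal.

Because no public spectral dataset exists for this problem, the package
ships a synthetic-spectrum generator that reproduces the statistical
structure the analysis assumes, so that every stage is testable end to end.

## The synthetic data generator

A spectrum is modelled as

$$ I(\nu) \;=\; b(\nu) \;+\; \sum_j A_j\,
\frac{w_j^2}{(\nu - c_j)^2 + w_j^2} \;+\; \varepsilon(\nu), $$

a smooth background plus Lorentzian vibrational bands plus i.i.d. Gaussian
noise. Lorentzian profiles are the conventional line shape for Raman bands
(a Gaussian option exists). The defaults encode the study conditions:

* **Axis.** 1024 points. The grid step is chosen so that exactly 855
  points fall inside the analysed 300–1800 cm⁻¹ window; after range
  selection the data matrix therefore has the canonical 855 spectral
  features. A generic `wavenumber_axis()` covers arbitrary grids.
* **Classes.** Three profiles named `seminal`, `lung`, `heart`. All three
  share an identical skeleton of 31 major bands taken from the packaged
  assignment table (`band_table()`), with the five strongest lines (766,
  1011, 1348, 1459, 1663 cm⁻¹) at amplitude 1 and the rest at 0.45.
  Keeping the shared skeleton *identical* across classes is deliberate:
  every bit of class information then comes from the planted
  class-exclusive bands, which gives the feature-importance stage an exact
  ground truth. Class-exclusive minor bands (seminal: 453, 492, 572, 591,
  683, 1069, 1095; lung: 1623; heart: 502, 1279, 1600 cm⁻¹) enter at 15%
  of the strongest band — "minor band" scale.
* **Per-spectrum variation.** Band centers jitter with SD 1 cm⁻¹ and
  amplitudes with 10% relative SD (typical acquisition-to-acquisition
  variability on one substrate); the background is a random degree-3
  polynomial; additive noise has SD 0.02 (high-SNR long acquisitions).
* **Sample size.** 197 spectra split 66/66/65. The source study reports
  only the total; the near-even split is a choice.
* **Cosmic rays.** `inject_spikes()` plants 1–3 single-channel spikes of
  20 spectrum-SDs in 6 randomly chosen spectra and returns the affected
  ids, the exact ground truth for the outlier screen. Spikes are drawn
  inside the analysed window excluding its two edge channels, because the
  rubber-band correction pins the window endpoints to zero and would erase
  a spike planted exactly there before the screen ever sees it.

What the generator does **not** emulate: plasmonic enhancement physics,
substrate heterogeneity between drops, wavelength-dependent detector
response, correlated (pink) noise, and real glycan vibrational structure.
Passing tests on this generator therefore demonstrate the correctness and
calibration of the *analysis chain*, not instrument-level realism.

## Preprocessing

`preprocess_spectra()` applies five stages in a fixed order, the order in
which the experimental protocol states them:

1. **Range selection** to 300–1800 cm⁻¹ (all protein bands live here).
2. **Rubber-band baseline correction**: the background estimate is the
   lower convex hull of the spectrum (Andrew's monotone chain), linearly
   interpolated between hull vertices and subtracted. The corrected
   spectrum is non-negative and zero at the hull vertices; the window
   endpoints are always vertices.
3. **Outlier elimination**: at every wavenumber the median and MAD across
   spectra are computed and a spectrum is dropped *entirely* if any of its
   points exceeds median + 8·1.4826·MAD — a cosmic-ray spike has a
   signal-to-noise ratio far above that of true bands at the same
   frequency. Whole-spectrum removal reproduces the 197 → 191 bookkeeping
   of the source protocol. Two guards make the rule well-posed: channels
   whose MAD is exactly zero are skipped (no robust scale exists there),
   and 5 channels at each window edge are skipped because hull pinning
   collapses their cross-spectrum dispersion by an order of magnitude,
   which would otherwise flag legitimate spectra. The original outlier
   algorithm is unpublished; this median/MAD rule is our documented
   stand-in with the same observable behaviour.
4. **Standardization**: each spectrum is normalized to its own mean and
   standard deviation (population convention, dividing by *n*; the
   convention of the original tooling is unspecified, so one was fixed and
   used consistently, including for archetype SDs).
5. **Savitzky–Golay smoothing**, window 11, polynomial order 2. The
   central least-squares coefficients come from `signal::sgolay()`; ends
   are mirror-padded so length is preserved. Rows are *not* re-standardized
   after smoothing; the residual row means are ~1e-4 (edge effects of the
   mirror padding), which is irrelevant downstream because the
   discriminant is translation-invariant.

The per-class **spectral archetype** (`compute_archetype()`) — mean
spectrum with per-wavenumber SD — summarizes reproducibility and feeds the
peak-matching stage.

## The discriminant model

With class sets $D_i$, class means $\bar{x}_i$ and grand mean $\bar{X}$,
the scatter matrices are

$$ S_W = \sum_{i=1}^{c} \sum_{x \in D_i} (x - \bar x_i)(x - \bar x_i)^T,
\qquad
S_B = \sum_{i=1}^{c} (\bar x_i - \bar X)(\bar x_i - \bar X)^T . $$

$S_B$ is used in this *unweighted* form, as the method was originally
stated; a size-weighted option exists (`weighted = TRUE`) and with
near-equal classes the subspace is essentially unchanged. The discriminant
directions are the leading eigenvectors $V$ of $S_W^{-1} S_B$, and scores
are $Z = (X - \bar X)V$ with two components for three classes (at most
$c-1$ eigenvalues are nonzero because $\mathrm{rank}(S_B) \le c-1$).

Two numerical choices deserve notice:

* **Shrinkage.** With 855 features and ~96 training spectra (before
  augmentation), $S_W$ is singular and its printed inverse does not exist.
  We solve the ridge-regularized problem
  $(S_W + \gamma\,\mathrm{tr}(S_W)/p \cdot I)^{-1} S_B$ with
  $\gamma = 10^{-3}$ by default, via Cholesky reduction to a *symmetric*
  eigenproblem (numerically stable, real eigenvalues, descending order
  guaranteed). $\gamma$ is surfaced as a parameter rather than hidden.
  Requesting $\gamma = 0$ on singular data fails with an instructive
  error.
* **Centering and signs.** The projection is anchored at the training
  grand mean so class clouds are centred at the origin (a presentation
  choice; nearest-centroid classification is unaffected). Eigenvector
  columns are unit-norm with the largest-magnitude entry forced positive,
  so refits are reproducible to the bit.

Classification is **nearest centroid in the discriminant plane**
(Euclidean, equal priors) — the canonical linear rule in the reduced
space; ties break toward the lexicographically smallest class name.
`classification_metrics()` reports per-class precision, sensitivity and F
score with supports, overall accuracy and the confusion matrix; a class
absent from the truth yields `NA` with a warning, never a silent zero.

Before fitting, the training half (50:50 stratified split) is augmented
with 2 Gaussian copies per spectrum at 5% of the per-feature training SD.

## Feature importance and intervals

Expanding the nearest-centroid score of class $i$, the part linear in the
spectrum $x$ has gradient $w_i = V \bar z_i$, the class centroid pulled
back into wavenumber space; $|w_{ij}|$ measures how strongly channel $j$
pushes a spectrum toward class $i$. Whether the original analysis derived
its per-class contributions this way or from one-vs-rest coefficients is
not stated; this definition is declared, not inferred. Weights are
normalized to the global maximum absolute value.

* **Filter** (`filter_importance()`): a feature is retained for a class if
  its absolute weight strictly exceeds the class's 95% sample quantile
  (linear-interpolation convention) and lies more than 10 features from
  either window edge (boundary contributions are screened out). On 855
  features this retains ~43 per class and eliminates ≥ 726 for all classes
  — the "~700 filtered" scale.
* **Ranking**: features are ordered by max-over-classes absolute
  normalized weight, descending, ties toward the lower wavenumber. The
  original figures show per-class bars but rank one list; taking the
  max over classes is the reconciling choice.
* **Accuracy curve** (`accuracy_curve()`): for $k = 1, 2, \ldots$ the full
  split → augment → fit → classify chain is rerun on the top-$k$ features
  over 20 seeded random splits, recording mean ± SD accuracy. "Until
  convergence" is made concrete as: stop after the mean has been ≥ 0.999
  for 5 consecutive $k$.
* **Intervals** (`group_intervals()`): the top-$k$ features are attributed
  to the class with the largest absolute weight and merged into maximal
  runs with gaps of at most 2 grid steps, reported in cm⁻¹ with their
  peak importance.

On default synthetic data the planted exclusive bands dominate the top of
the ranking, the curve reaches mean accuracy 1.0 within a handful of
features (well under 25), and the intervals at $k = 25$ bracket the
planted band centers. A selected feature can sit on a band *flank* rather
than its apex, so interval-recovery checks use one half-width at half
maximum as the localization tolerance.

## The band table

`band_table()` ships the 50-row vibrational assignment table (per-class
positions, mode assignments, amino-acid/dipeptide carriers, literature
positions). `pick_peaks()` (prominence-based), `assign_peaks()`
(nearest-row within 5 cm⁻¹, ties to the smaller row index) and
`exclusive_bands()` (three-way or pairwise presence/absence) operate on
it. The table and the narrative description of exclusive bands disagree in
places (the table has two extra seminal-only rows at 435 and 1441 cm⁻¹,
and the lung/heart attribution of 502/1279/1600 vs 1623 cm⁻¹ is swapped
relative to the running text); the packaged table is authoritative and the
discrepancy is documented rather than resolved.

## Reproducibility and problem sizes

`run_sers_pipeline()` drives everything from one root seed, fanned out to
per-stage child seeds by a fixed affine scheme, so identical
(configuration, seed) pairs give byte-identical reports. The test suite
exercises the default scale (197 spectra × 1024 points) where the
headline results live, and reduced scales elsewhere: oracle comparisons
for the eigenproblem run on 20 instances with $n \le 60$, $p \le 10$;
rubber-band correctness is checked against an exhaustive $O(n^3)$ hull
oracle on ≤ 80-point spectra; spike-recovery is verified on 12 seeded
197-spectrum fixtures; interval recovery on 10 seeds of a 36-spectrum,
three-exclusive-band configuration. These sizes are the package's chosen
balance between statistical persuasiveness and a test suite that stays
pleasant to run.

## Known limitations

* The outlier screen assumes each channel's cross-spectrum majority is
  clean and dense-band spectra; sparse-band data with strong
  minority-class-exclusive channels can be mis-flagged at small sample
  sizes (the screen is built for ~200 spectra, its intended regime).
* The importance definition is tied to the nearest-centroid geometry; it
  is not a permutation or Shapley attribution.
* With shrinkage, eigenvalues are those of the regularized problem; they
  converge to the unregularized ones only when $S_W$ is well conditioned.
* The synthetic generator's independence assumptions (i.i.d. noise,
  independent per-band jitter) make the classification task easier than
  correlated real-world drift would; perfect accuracy on the synthetic
  analog should be read as calibration, not as a claim about any real
  instrument.
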