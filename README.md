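# serslda

Classification of surface-enhanced Raman scattering (SERS) spectra of
glycoprotein isoforms by linear discriminant analysis.

## The problem

SERS makes it possible to record vibrational spectra of a single protein
species adsorbed on a nanostructured silver surface. When the same protein
— the motivating case is angiotensin I-converting enzyme (ACE) from
seminal fluid, lung and heart tissue — is produced by different cell
types, the backbone is identical and the spectra differ only in minor
vibrational bands, plausibly contributed by tissue-specific N-glycans.
`serslda` provides the full chemometric chain for deciding whether such
spectra separate, quantifying the separation, and locating the wavenumber
intervals that carry it:

* a seeded **synthetic-spectrum generator** (Lorentzian bands from a
  packaged 50-row assignment table, polynomial background, Gaussian noise,
  cosmic-ray spikes with exact ground truth), since no public dataset
  exists for this problem;
* **preprocessing**: 300–1800 cm⁻¹ range selection, rubber-band (lower
  convex hull) baseline correction, robust per-wavenumber median/MAD
  outlier elimination, per-spectrum standardization, Savitzky–Golay
  smoothing (window 11, order 2);
* **linear discriminant analysis built from scatter matrices**,

  $$S_W = \sum_i \sum_{x \in D_i} (x-\bar x_i)(x-\bar x_i)^T, \quad
    S_B = \sum_i (\bar x_i - \bar X)(\bar x_i - \bar X)^T,$$

  taking the leading eigenvectors $V$ of $S_W^{-1}S_B$ (ridge-shrunken,
  solved as a symmetric generalized eigenproblem) and scores
  $Z = (X-\bar X)V$ with 2 components for 3 classes, followed by
  nearest-centroid classification with per-class precision, sensitivity
  and F score;
* **feature importance**: per-class weights $w_i = V\bar z_i$, 95%-quantile
  filtering with boundary exclusion, a descending-importance
  incremental-feature accuracy experiment over repeated random splits, and
  grouping of the top-ranked wavenumbers into contiguous intervals matched
  against the band table.

Everything is tidyverse-native: spectra travel as long tibbles
(`spectrum_id`, `label`, `wavenumber`, `intensity`), results come back as
tibbles, fitted models support `tidy()`, `glance()`, `predict()` and
`autoplot()`.

## Worked example

```r
library(serslda)

run <- run_sers_pipeline(seed = 1)
print(run)
#> <sers_run> seed 1
#> spectra: 197 -> 191 after outlier removal; 855 features
#> test accuracy: 1
#> # A tibble: 3 × 5
#>   class   precision sensitivity f_score support
#>   <chr>       <dbl>       <dbl>   <dbl>   <int>
#> 1 heart           1           1       1      32
#> 2 lung            1           1       1      32
#> 3 seminal         1           1       1      32
#> smallest k with mean accuracy 1: 4
#> 10 importance intervals at k = 25
```

Reading the output: 197 synthetic spectra were generated (66/66/65 across
the three classes) and 6 cosmic-ray-contaminated spectra were eliminated,
leaving a 191 × 855 matrix. The held-out half of the data (96 spectra) is
classified perfectly — precision, sensitivity and F score of 1.00 for
every class — and the incremental-feature experiment finds that the mean
accuracy over 20 random splits already reaches 1.0 with the top 4
wavenumbers. The reported intervals at k = 25 bracket the planted
class-exclusive bands (e.g. seminal 453, 591, 683, 1095 cm⁻¹; lung 1623;
heart 502, 1279, 1600).

Individual stages compose with the pipe:

```r
spectra <- generate_spectra(seed = 1) |>
  inject_spikes(n_spectra = 6, seed = 2)
mat <- preprocess_spectra(spectra)
parts <- split_spectra(mat, ratio = 0.5, seed = 3)
fit <- fit_sers_lda(augment_spectra(parts$train, seed = 4))
pred <- predict(fit, parts$test)
classification_metrics(pred$label, pred$pred)
autoplot(fit, newdata = parts$test)
```

A thin command-line wrapper lives at `inst/scripts/run_pipeline.R`.

## Documentation

The methods vignette (`vignettes/serslda-methods.Rmd`) describes the
model, the synthetic generator and its limits, and every numerical design
choice (shrinkage, quantile and edge conventions, convergence rules).
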