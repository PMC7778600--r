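# praman

Raman and fluorescence chemometrics for photodynamic theranostics.

`praman` implements the spectral-analysis side of a combined
Raman-spectroscopy / photodynamic-therapy (PDT) workflow: diagnosing
tissue from single-point Raman spectra, monitoring the molecular
response of treated tumours over time, and quantifying the
photosensitiser protoporphyrin IX (PPIX) in tissue from fluorescence
emission spectra. It is aimed at spectroscopists and chemometricians who
need a tested, reproducible implementation of this processing chain
rather than ad hoc scripts.

## What it computes

**Preprocessing.** Raw Raman spectra (counts vs Raman shift, cm⁻¹) are
cropped to the fingerprint region (510–1825 cm⁻¹), the fluorescence
background is removed by asymmetric penalised least squares — the
baseline *z* minimises

```
Σᵢ wᵢ (yᵢ − zᵢ)² + λ Σᵢ (Δ²zᵢ)²,    wᵢ = p if yᵢ > zᵢ, else 1 − p
```

with λ = 10⁵ and asymmetry p = 0.001 — cosmic-ray spikes are removed by
a modified z-score rule on the first differences, spectra are smoothed
with a first-order Savitzky–Golay filter (frame 7) and normalised to
unit area under the curve.

**Diagnosis.** Classification is PLS-DA: NIPALS PLS2 regression of the
one-hot class indicator on the mean-centred spectra with 6 latent
variables, assessed by Venetian-blinds cross-validation with 10 data
splits (fold of sample *i* = *i* mod 10). Quality statistics: replicate
SNR (peak intensity at 1650 cm⁻¹ over the mean channel SD in the silent
1780–1820 cm⁻¹ band) and the mean spectral coefficient of variation.

**Monitoring.** Treatment response is tracked through difference
spectra (mean tumour − mean control tissue) at each timepoint; the
signed extremum in a ±10 cm⁻¹ window around 1440 cm⁻¹, normalised to
day 0, decreases as the tumour signature recedes. Arms are compared by
two-tailed Welch's *t*-tests, with 1.5×IQR outlier screening for
normalised tumour-growth signals.

**PPIX quantification.** Fluorescence emission spectra (450–750 nm) are
blank-subtracted, the tissue autofluorescence is removed with a weak
Whittaker background fit (λ = 10), and the 620–640 nm PPIX emission is
integrated and read against an ordinary least-squares standard curve;
concentrations are reported as ng PPIX per g tissue after the aliquot
dilution (50 µL into 1 mL ⇒ 21×). Dosimetry helpers convert mass
concentrations to molarity and fluence to exposure time.

Every stage is exercised end to end by seeded synthetic-data generators
(`raman_gen_config()`, `generate_classification_dataset()`,
`generate_longitudinal_study()`, `generate_fluorescence_standards()`)
that emit ground-truth sidecars for oracle testing.

## Worked example

```r
library(praman)

# --- diagnosis on synthetic tumour/control spectra ---
ds   <- generate_classification_dataset(raman_gen_config(),
                                        n_per_class = 60, seed = 1)
proc <- preprocess_spectra(ds$collection, preprocess_config())
cv   <- cross_validate(as.matrix(proc), ds$labels,
                       plsda_config(n_lv = 6, cv_splits = 10))
cv
#> <praman_cv> accuracy 1.000 over 120 samples, 10 folds
#>           control tumour
#>   control      60      0
#>   tumour        0     60

# --- PPIX tissue quantification ---
std <- generate_fluorescence_standards(6, slope_truth = 2, seed = 1)
cfg <- fluor_quant_config()
sig <- sapply(std$standards$spectra, function(s)
  integrate_signal(process_fluorescence(s, std$blank, cfg),
                   cfg$signal_band_nm))
(curve <- fit_standard_curve(std$amounts, sig))
#> <standard curve> signal = 1.954 * ng + 32.7 (r^2 = 0.9877, 6 points)

quantify_ppix(sig[3], curve, dilution_factor = 21,
              tumour_mass_g = 0.053)$ng_per_g
#> 25326 ng/g

mass_to_molar(1000, 562.66)   # 1000 ng/mL PPIX  -> 1.78 uM
exposure_time(30, 50)         # 30 J/cm2 at 50 mW/cm2 -> 600 s
```

The cross-validation table reads: all 60 control and all 60 tumour
spectra were assigned to their true class by models that never saw them
during fitting. The standard curve recovers the generator's true
signal-per-ng slope of 2 to within a few percent, and the
back-calculated tissue concentration folds in the 21× aliquot dilution
and the tumour mass.

## Layout

- `R/` — spectra containers and I/O, preprocessing, PLS-DA, quality
  metrics, PPIX quantification, synthetic generators, workflow runners
  (`run_diagnosis()`, `run_monitoring()`, `run_quantification()`).
- `tests/testthat/` — unit, property and acceptance suites.
- `vignettes/praman-methods.Rmd` — the methods vignette: models,
  parameter choices, generator design and limitations.
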