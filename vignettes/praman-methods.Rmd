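---
title: "Methods: spectral models and design choices in praman"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral models and design choices in praman}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(praman)
```

`praman` covers three workflows around a combined Raman-diagnosis /
photodynamic-therapy (PDT) platform: classifying tissue from
single-point Raman spectra, tracking the molecular response of treated
tumours through difference spectra, and quantifying the photosensitiser
protoporphyrin IX (PPIX) in digested tissue from fluorescence emission
spectra. This vignette records the models behind each step, the
parameters that matter, what the synthetic generators do and do not
emulate, and the design decisions taken where more than one defensible
choice existed.

## Raman preprocessing

A raw in vivo Raman spectrum is dominated by a broad tissue
autofluorescence background with the vibrational bands riding on top,
occasional single-channel cosmic-ray hits, and shot/detector noise.
The chain in `preprocess_spectra()` applies, per spectrum and in fixed
order: crop, baseline subtraction, despiking, Savitzky–Golay smoothing,
area normalisation. Each spectrum is processed independently, so the
chain can be applied before any train/test split without information
leakage; mean-centring is deliberately *not* part of the chain — it is
a model parameter and is estimated inside `fit_pls()` on training folds
only.

### Baseline: asymmetric penalised least squares

The "Whittaker filter" used for baseline subtraction is implemented as
asymmetric penalised least squares: the baseline $z$ minimises

$$\sum_i w_i (y_i - z_i)^2 + \lambda \sum_i (\Delta^2 z_i)^2,$$

with second differences taken on the channel index (the grid is 1 cm⁻¹
in practice, and a single scalar $\lambda$ only has a clean meaning on
an index grid). Weights are reweighted iteratively: $w_i = p$ where
$y_i > z_i$ and $1 - p$ otherwise, so points above the running estimate
— the Raman peaks — barely attract the fit and the baseline settles
under them. A plain symmetric Whittaker smoother would track the peaks
themselves and cannot serve as a baseline estimator, which is why the
asymmetric reading is used. Defaults: $\lambda = 10^5$, $p = 0.001$,
10 iterations (the first pass uses unit weights, so `iters = 1`
recovers the symmetric smoother, which the limit tests exploit).

Numerics: the system $(W + \lambda D^\top D)z = Wy$ is solved by sparse
Cholesky factorisation followed by one step of iterative refinement.
$\lambda$ spans twelve orders of magnitude across the package's uses
($10^{-8}$ to $10^{12}$ in the limit tests), and the raw solve loses
roughly $\mathrm{cond}(A)\cdot\varepsilon$ of accuracy; the refinement
residual is evaluated in the structured form
$w(y-z) - \lambda D^\top(Dz)$, where the neighbour differences cancel
exactly in floating point, so constant and affine inputs are recovered
to machine precision rather than to $10^{-7}$.

### Despiking

Cosmic-ray hits are one- or two-channel transients. A channel is
flagged when *every* first difference touching it has a modified
z-score $0.6745\,|d - \tilde d|/\mathrm{MAD}(d)$ above the threshold
(default 8); at the spectrum edges the single existing difference
decides. Requiring both sides keeps the rule local: a spike flips both
of its adjacent differences, while the spike's neighbours each have
only one hot difference and are left bit-identical — the alternative
"flag right of any hot difference" rule would always interpolate one
innocent neighbour. Flagged channels are replaced by linear
interpolation between the nearest unflagged neighbours. The rule is
parameter-light and testable; it is a documented default, not a claim
about what any particular instrument vendor does.

### Smoothing, normalisation

Savitzky–Golay smoothing fits a degree-1 polynomial over a 7-channel
window and keeps the centre value; near the edges the same polynomial
is fitted to the truncated one-sided window, so spectra keep their
length and affine signals are reproduced exactly everywhere. Area
normalisation divides by the trapezoidal integral over the physical
axis, making spectra comparable across integration times and probe
coupling; it is idempotent and scale-invariant by construction.

## PLS-DA with Venetian-blinds cross-validation

Classification is PLS2 regression of the one-hot class indicator on the
spectra, fitted by NIPALS with per-component deflation of both blocks.
NIPALS was chosen over SIMPLS because its full-rank limit is cleanly
testable: with as many latent variables as the rank of the centred
data, fitted values coincide with ordinary least squares, and the test
suite holds the implementation to that identity at $10^{-6}$. Class
assignment is the argmax of the predicted indicator, ties to the lowest
class index; no threshold parameter is introduced. Six latent variables
and 10 splits are the defaults.

Venetian blinds assigns sample $i$ (input order) to fold
$i \bmod \text{splits}$. This follows the convention of the common
chemometrics toolboxes and is deterministic, but it has a documented
hazard: replicate spectra of one subject, supplied adjacently, land in
*different* folds, so subject-level information leaks between training
and test sets and per-spectrum accuracy overstates subject-level
generalisation. `plsda_config(block_by = )` provides a subject-blocked
variant (all replicates share a fold); it is off by default to match
the plain Venetian-blinds protocol being reproduced. Fold-wise
mean-centring is computed on the training fold only. A training fold
that lacks a class is refused with advice to reorder, rather than
silently fitting a one-class model.

## Quality statistics and monitoring

The replicate SNR is the mean windowed maximum near 1650 cm⁻¹ (amide I)
divided by the mean per-channel standard deviation across replicates in
1780–1820 cm⁻¹. That band is biologically silent, so the
across-replicate SD there estimates the noise floor; averaging the SD
over channels before dividing is an interpretive choice, recorded here
because "mean standard deviation" admits more than one reading. Both
SNR and the mean spectral coefficient of variation are invariant to
global intensity scaling, and channels with near-zero mean are excluded
from the CV to keep the ratio stable.

Monitoring works on difference spectra, mean tumour minus mean control
tissue. `peak_intensity()` is a windowed maximum (half-width 10 cm⁻¹ by
default, tolerant of small calibration shifts, and wide enough that a
window centred at 1440 cm⁻¹ covers the 1445 cm⁻¹ CH₂ band). The
monitoring statistic, however, uses the signed *extremum* (largest
absolute value, sign kept) in the window: control tissue has the
greater intensity at 1445 cm⁻¹, so the tumour-minus-control feature
points downwards and a plain maximum would read noise at the window
edge. Each day's extremum is normalised to day 0; signed normalisation
is the default and an absolute variant is available via a flag. Arms
are compared by two-tailed Welch's *t*-tests on per-animal values, and
normalised growth signals are screened with the 1.5×IQR rule using
type-7 (linearly interpolated) quartiles — stated explicitly so the
outlier test is reproducible.

## PPIX tissue quantification

Emission spectra are cropped to 450–750 nm, the solvent blank is
subtracted channelwise, the tissue autofluorescence is removed with the
same asymmetric Whittaker solver at $\lambda = 10$, and the result is
smoothed (SG 1/7) before integrating 620–640 nm around the ~630 nm
PPIX emission maximum — the readout band is a package choice, made once
and fixed. The asymmetry weight for this background fit defaults to
$10^{-5}$, much smaller than the Raman default: with so weak a penalty
the effective smoothing length is $(\lambda/p)^{1/4}$ channels, and at
$p = 10^{-3}$ the background climbs partway into the emission line and
attenuates the integrated signal by 10–20%. Stiffening the fit under
the line (small $p$) keeps the assay's response linear in the injected
amount.

Quantification inverts the least-squares standard curve, multiplies by
the aliquot dilution (50 µL into 1 mL ⇒ 21×, exposed as a parameter)
and divides by the tumour wet mass. Negative back-calculated amounts
are floored at zero with a warning flag — a physical constraint applied
audibly, never silently. `mass_to_molar()` and `exposure_time()` are
exact unit conversions (ng/mL over g/mol is µM directly; fluence over
fluence rate is seconds).

## The synthetic generators

All tests run on seeded generators, pure functions of (config, seed)
that also emit their ground truth (noiseless templates, injected
amounts, spike positions), so every stage can be checked against an
oracle without external data.

Raman spectra are sums of Lorentzian bands at 936, 1078, 1265, 1302,
1445 and 1655 cm⁻¹ (widths 12–18 cm⁻¹ HWHM), a broad Gaussian-plus-
offset fluorescence baseline, optional photosensitiser pedestal (for
PPIX including a small 1550 cm⁻¹ porphyrin band), additive Gaussian
noise, and Bernoulli cosmic spikes of at least 20 noise SDs. The tumour
class lowers the 1265/1302/1445/1655 amplitudes relative to control
while raising the 1655:1445 ratio. Subjects contribute five adjacent
replicates sharing a log-normal per-peak amplitude jitter, and subjects
alternate between classes so index-interleaved folds stay balanced.
Class-effect sizes, jitter (SD 0.06) and noise (SD 4 counts against
peak amplitudes of 45–100) were calibrated once so that the default
two-class problem at $n = 120$ cross-validates at ≈98% — the
documented, frozen surrogate for the high in vitro accuracies the
protocol is known to reach — and not revisited.

The longitudinal generator scales the tumour-vs-control amplitude
deviation by a per-arm, per-day multiplier (day 0 fixed at 1; the
treated arm decreasing to 0.6 and 0.3 at days 3 and 6, the untreated
arm increasing to 1.3 and 1.6), with five animals per arm and eight
replicate spectra per flank per day — a desk-scale rendering of a
20-replicate, five-animal design, chosen so the whole monitoring
workflow runs in seconds while the day-6 Welch test still resolves the
arms.

Fluorescence standards are a broad autofluorescence hump (Gaussian at
540 nm), a solvent background, and a 630 nm Gaussian line whose total
area is `slope_truth` per ng, at 1% relative noise. Two generator
choices are deliberate and worth knowing about. The line is narrow
(σ = 1.5 nm), narrower than a real PPIX emission band: the background
fit removes a fraction of any feature wider than its smoothing length,
and a realistic 20 nm-wide band would make the "recovered slope equals
injected slope" property untestable for reasons that have nothing to do
with estimator bias. And the default standards span 20–120 ng without a
zero-amount member: near the detection limit the asymmetric background
subtraction responds nonlinearly (it rectifies noise upward and clips
small features), which would curve the low end of the standard line;
the blank anchors zero instead. Both effects are real properties of
asymmetric-least-squares baselines that practitioners of this assay
would recognise.

What passing tests therefore show: the estimators recover what the
generator injected, at the stated noise, under this statistical
structure. What they do not show: robustness to wavenumber calibration
drift, detector etaloning, Poisson (rather than additive Gaussian)
noise, instrument response functions, or tissue heterogeneity — none of
which the generators emulate.

## Degenerate inputs and tie-breaks

Fixed behaviours, chosen once: crop is a closed interval and an empty
crop is an error; a spectrum needs ≥ 8 channels, the baseline ≥ 4, the
despiker ≥ 5; a fully-flagged spectrum is a "degenerate spectrum"
error; zero or negative area cannot be normalised; identical replicates
give a "zero noise estimate" error in the SNR rather than an infinity;
Welch's test returns $p = 1$ when both groups are constant and equal
and errors when constant and unequal; duplicated rows with conflicting
labels make the indicator exactly orthogonal to the data and the PLS
fit refuses them as degenerate; argmax ties in prediction go to the
lowest class index; `n_lv` above the achievable rank is an error that
names the rank. Reports written by the workflow runners print numbers
through fixed formats, so identical inputs give bitwise-identical CSVs.

## Problem sizes

The default test and acceptance runs use: 120 spectra × 1316 channels
for classification, 200 spectra for the permutation null, a
2-arm × 3-day × 5-animal × 8-replicate monitoring study (480 tumour +
480 control spectra), 6-point standard curves with 200 seeded
replicates for the slope-bias estimate, and ≤ 500-channel instances for
the dense-solver oracles. These sizes were picked so the full suite
completes in a couple of minutes on a single core while every statistic
stays comfortably inside its tolerance.

## Known limitations

Venetian-blinds fold leakage between replicates is inherited from the
protocol being reproduced (use `block_by` when subject-level
generalisation is the question). The despike rule can clip a genuine
one-channel feature that is eight MADs steeper than everything else in
the spectrum. The PPIX assay's linearity argument holds for emission
lines narrow relative to the background smoothing length; quantifying
broad emitters against a $\lambda = 10$ background fit would need a
different readout (e.g. fitted line shapes). And the package reads only
delimited text; vendor binary formats are out of scope.
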