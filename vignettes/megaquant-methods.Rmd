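---
title: "Edited MEGA-PRESS glutathione quantitation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edited MEGA-PRESS glutathione quantitation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megaquant)
```

## The measurement problem

Glutathione (GSH) is the brain's principal antioxidant, and its depletion in
the cingulate cortex is a candidate marker of the progression from normal
ageing (NC) through mild cognitive impairment (MCI) to Alzheimer's disease
(AD). The cysteine beta-CH2 resonance of GSH near 2.80 ppm is invisible to
conventional single-voxel MRS because it sits under the far larger creatine
peak at 3.03 ppm. J-difference editing (MEGA-PRESS) solves this: a
frequency-selective pulse applied at 4.40 ppm (ON) refocuses the J-coupling
of the coupled GSH spins, while in alternating acquisitions the pulse sits
at 5.00 ppm (OFF) and leaves them untouched. Subtracting averaged-OFF from
averaged-ON cancels every uncoupled singlet (water, creatine, choline, NAA)
and leaves the co-edited GSH signal.

`megaquant` implements the complete analysis for such data: simulation of
interleaved ON/OFF free-induction-decay (FID) series, spectral
preprocessing, baseline and peak fitting with quality control, absolute
quantitation against a phantom calibration line with relaxation and
partial-volume correction, and the group-level statistics and ROC
diagnostics used to evaluate GSH as a biomarker.

## Signal model and the synthetic-data generator

Because the corresponding clinical data are not publicly distributable, the
package ships a first-class generator whose defaults encode the study
conditions it emulates:

* TE = 120 ms, TR = 2,500 ms, 2,048 complex points per FID, 20 interleaved
  dynamics of 16 averages (`acquisition_params()`);
* spectral width 2,000 Hz and transmitter frequency 127.73 MHz — typical
  3 T values, configurable, since an acquisition protocol rarely prints
  them;
* group x region concentration moments for NC/MCI/AD in the anterior and
  posterior cingulate (ACC/PCC), defaulting to the published cohort values
  (e.g. PCC NC 2.3674 +/- 0.4049 mM, `cohort_sim_config()`).

Each resonance is a damped complex exponential
$A\,e^{i(2\pi f t + \phi)}\,d(t)$ with a Gaussian envelope
$d(t) = e^{-(t/\tau)^2}$ by default (Lorentzian available for
model-mismatch experiments). The Gaussian envelope makes the absorption
lineshape an exact Gaussian with $\sigma_f = 1/(\sqrt{2}\pi\tau)$ Hz, so
the Gaussian peak-fit model downstream is well specified. The default
damping of 0.066 s gives ~8 Hz FWHM, matching the reported in vivo line
widths (9.6 +/- 2.7 Hz).

Editing is phenomenological, not quantum-mechanical: the unedited GSH
amplitude (proportional to concentration) appears in both subspectra, and
the ON dynamics add a co-edited component of `editing_efficiency` (default
0.5) times that amplitude. The noiseless ON-OFF difference therefore
contains exactly the edited component, whose analytic absorption area
(amplitude/2, the one-sided FID folding half the energy into dispersion) is
recorded as ground truth. No multiplet structure, chemical-shift
displacement or eddy-current artefacts are simulated; conclusions from
passing tests are about the processing chain, not about sequence physics.

Realism knobs, all exercised by the tests: residual water at 4.67 ppm at
~50x the metabolite scale, a broad lipid resonance at 1.3 ppm, a smooth
macromolecular background (two very fast-decaying components), per-dynamic
zero-order phase jitter (default SD 5 degrees), instrumental frequency
offset, and circular white complex noise. The cohort default
`noise_sd = 0.5` was chosen so that the fitted-model SNR of the edited peak
lands in the low single digits, the regime the study reports
(3.48 +/- 1.86); the recovery benchmarks below use `noise_sd = 0.35`,
which corresponds to fit SNR near 5.

The cohort generator draws per-subject tissue concentrations from the
group x region law truncated at zero, CSF fractions from per-group
truncated normals on [0, 0.6] (means 0.22/0.26/0.30 for NC/MCI/AD —
atrophy increases CSF with disease), and emits series whose edited signal
is proportional to `true_gsh_mm * (1 - vcsf)`: the acquired voxel signal
is diluted by CSF, which is what partial-volume correction must undo. ACC
and PCC concentrations are drawn independently per subject; real
within-subject regional correlation is not modelled.

## Preprocessing chain

`process_series()` applies, in order:

1. **Zero-order autophasing** per dynamic from the phase of the first FID
   point (falling back to the first point above 1e-12 of the maximum if it
   vanishes). Because the first point is the sum of all resonance
   amplitudes, water dominates it and the per-dynamic phase jitter is
   removed almost exactly.
2. **Interleaved averaging** into averaged-ON and averaged-OFF (10 each for
   a 20-dynamic series), then the **edited difference** ON - OFF.
3. **Apodization** by mixed Gaussian/exponential windows. The default is a
   2 Hz Gaussian and no exponential: exponential broadening turns the
   Gaussian lines into Voigt profiles that a Gaussian fit model
   under-integrates by several percent, while Gaussian-on-Gaussian stays
   inside the model family. Both widths are configurable.
4. **Fourier transformation** with 2x zero filling and the trapezoid
   half-first-point correction (without it the one-sided DFT adds a
   constant offset to every bin that biases fitted areas by ~1%).
5. **Frequency referencing**: the water maximum of the averaged-OFF
   spectrum is pinned to 4.67 ppm and the same shift is applied to the ON
   and difference spectra — the difference spectrum has no water peak of
   its own to reference on.
6. **Residual water and lipid removal** by Hankel-SVD (HLSVD): the leading
   512 FID points are embedded in a Hankel matrix, the 25 dominant damped
   complex exponentials are estimated by the state-space method
   (shift-invariance of the left singular subspace), amplitudes are solved
   linearly on the full FID, and the components inside the water
   (+/- 70 Hz) or lipid ((-520, -480) Hz — the printed band ordered low to
   high) band are reconstructed and subtracted in the time domain, before
   the FFT. Growing poles are clamped to unit magnitude. Tests require
   >= 99% in-band energy removal and < 2% perturbation of out-of-band
   fitted areas.

Raw data quality is summarized by a creatine-window SNR: the real spectrum
is smoothed by a level-3 Daubechies-4 (8-tap) periodized wavelet
approximation, its maximum magnitude within 2.85-3.15 ppm is divided by
the standard deviation of the real part over the 500 lowest-ppm bins,
which contain no known metabolite. No wavelet package is available in the
target R environment, so the filter bank is implemented in-package; its
perfect-reconstruction property is verified by test. The noise region is
read as the low-ppm spectral tail (the description "lower end of the
frequency domain" admits a time-domain reading too; the spectral tail is
the one that contains no metabolite by construction). This SNR is a QC
heuristic only — it feeds no quantitation step — so the wavelet family is
a configuration detail, not a scientific commitment.

## Baseline and peak fitting

`fit_peaks()` alternates two steps until the residual norm stabilizes
(relative tolerance 1e-4, at most 10 outer iterations):

* **SSA baseline**: the real spectrum minus the current peak model is
  embedded in a Hankel (trajectory) matrix and the leading 3 components
  are reconstructed by diagonal averaging. Inside the fit loop the window
  is one quarter of the fit-range length — wide enough that ~8 Hz lines
  stay out of the baseline subspace (a narrower window measurably leaks
  peak area into the baseline). The standalone
  `estimate_baseline_ssa()` defaults to a window of length/8 and adds
  peak-clipping iterations (`pmin(values, baseline)` re-estimation) for
  use on spectra whose peaks have *not* been subtracted; clipping is off
  inside the fit loop where the model has been removed.
* **Bounded Gaussian NLLS**: Levenberg-Marquardt (`minpack.lm`) with
  analytic Jacobian fits $\sum_j A_j \exp(-(f-c_j)^2/2\sigma_j^2)$ to the
  baseline-subtracted real spectrum over the fit window, with
  $A_j \ge 0$, centres confined to the prior shift windows
  (+/- 0.1 ppm), and $\sigma$ bounded in [0.8, 20] Hz. Each fit starts
  from a deterministic three-point grid of centre offsets (0, +/- half the
  shift window) and keeps the best-residual solution, so the optimizer has
  no random state. The cost is evaluated in the frequency domain: for
  Gaussian singlets this is Parseval-equivalent to a time-domain cost and
  keeps the baseline handling and the fit on the same axis.

Derived quantities use the Gaussian closed forms: area
$A\sigma\sqrt{2\pi}$, FWHM $2\sqrt{2\ln 2}\,\sigma$. The fitted-model SNR
is the mean absolute fitted model over 1.0-4.0 ppm divided by the residual
SD there (a perfect fit is reported as an infinite sentinel with a
degeneracy flag). The Cramer-Rao lower bound uses the Fisher matrix
$J^TJ/\sigma_n^2$ at the optimum with the delta method for the area
parameterization; the per-bin noise SD defaults to the SD of the linearly
detrended spectrum over the signal-free 4.0-4.4 ppm band. Monte-Carlo
checks (500 white-noise realizations) confirm the CRLB tracks the actual
area spread within a few percent.

**Quality gate.** Fits are rejected when the relative CRLB exceeds 20%
(boundary inclusive) or the optimizer did not converge. The source
protocol prints the rule as rejecting CRLB *below* 20%; the package
implements the standard direction — a larger CRLB means a less reliable
estimate — and leaves the threshold configurable.

## Absolute quantitation

The phantom calibration line `area = m * conc + k` (defaults
m = 0.00245, k = -0.00091, R^2 = 0.994, from a 1-5 mM GSH phantom) converts
areas to concentrations:

$$\mathrm{conc} = \frac{\mathrm{area} - k}{m}\times F_{relax}$$

with the relaxation factor built from
$T_1$ (in vivo 397 ms, phantom 350 ms) and $T_2$ (in vivo 117 ms, phantom
95 ms) at TE = 120 ms, TR = 2,500 ms. The printed orientation of the
factor evaluates to 0.7894; its reciprocal, 1.2668, is the package
default, for two reasons made explicit rather than silently resolved:
physically, the in vivo signal loses more to $T_2$ decay than the phantom,
so the measured area must be scaled *up*; and numerically, the published
paired means (PCC NC area 0.0037 against concentration 2.3674 mM) are
consistent only with the multiplier greater than one. Both orientations
remain available behind an explicit argument. A related printed
inconsistency — tissue-corrected group means *smaller* than the absolute
means, impossible under `pvc = abs / (1 - Vcsf)` — is likewise surfaced:
the package applies the formula as defined, so corrected values are always
at least the absolute ones.

Negative concentrations (area below the intercept) are flagged, not
clipped, so downstream statistics see the raw estimate. Partial-volume
correction divides by `(1 - f_csf)`, with the CSF fraction obtained by
averaging segmented tissue-probability maps over the binary voxel mask
(`tissue_fractions()`); the segmentation itself is out of scope and the
simulator supplies the latent fractions in its truth table.

In simulation round trips the relaxation factor is set to 1: the
generator does not model relaxation differences, and calibrating and
quantifying through the same simulated physics must cancel exactly. The
linearity of the whole chain is what makes the calibration robust: any
multiplicative bias shared by phantom and in vivo fits (apodization
choices, editing efficiency) divides out.

## Statistics and diagnostics

* `one_way_anova()` / `tukey_posthoc()` wrap the standard R decompositions;
  `anova_from_summary()` recomputes F from printed mean +/- SD (N) triples
  and equals the raw-data ANOVA on moment-matched data to 1e-9 — this is
  the bridge that lets published tables be verified without subject data.
* `variance_and_normality_checks()` implements mean-centered Levene
  directly (ANOVA on absolute deviations) and delegates Shapiro-Wilk to
  `stats::shapiro.test()`.
* `fit_glm()` reads "generalized linear model with age and gender as
  covariates" as a Gaussian-identity ANCOVA — the published effect tables
  report mean squares and R^2, which exist only in that reading. Factors
  use sum-to-zero coding with partial (type-III) sums of squares, and
  pairwise group/region contrasts come from estimated marginal means with
  Bonferroni correction (`emmeans`, `car`). Age enters as a numeric
  covariate (1 df); the published table's 24 df for age implies age was
  binned as a factor there, a choice not reproduced because it discards
  the covariate's ordering. The derived whole-cingulate records
  (`add_cingulate()`) are per-subject ACC + PCC sums, which is what makes
  the published cingulate means (~ACC + PCC) coherent.
* `roc_univariate()` computes the Mann-Whitney AUC (ties one half),
  DeLong structural-components variance for the 95% CI and p-value, and
  the Youden-optimal cutoff reported in concentration units, with scores
  negated internally when the diseased class has the lower mean so
  AUC >= 0.5 (depletion marks disease). Ties in the Youden criterion break
  toward higher specificity, making the output deterministic. The
  published "Youden index" values exceeding 1 are evidently cutoffs, not J
  statistics; the package reports both fields explicitly.
  `roc_multivariate()` fits a binary logistic regression (IRLS via
  `stats::glm`) on the supplied features and scores the predicted
  probabilities, flagging complete separation instead of diverging
  silently. Covariates enter only this multivariate path; the univariate
  ROC is covariate-free.

## Numerical choices and degenerate inputs

* All generators are pure functions of (configuration, seed); processing
  is RNG-free.
* An all-zero spectrum fits to zero amplitudes with zero residual; a zero
  noise estimate is floored at 1e-12 of the data scale before the CRLB.
* ANOVA with zero within-group variance and unequal means returns an
  infinite F sentinel (p = 0) rather than a floating-point overflow.
* Degenerate calibration designs (fewer than three distinct
  concentrations) and empty voxel masks are rejected with errors, as are
  broken ON/OFF interleavings and out-of-bandwidth resonances.

## Problem sizes used by the test and acceptance suites

The package's own verification runs at deliberately chosen sizes: 100
seeded acquisitions for the recovery benchmark (median absolute
concentration error < 5% at fit SNR ~5, and a recovered-versus-true slope
within 1 +/- 0.05 after partial-volume correction across a 30-subject
cohort), 500 null cohorts for the type-I calibration of the ANOVA and
ANCOVA group terms (binomial 95% band around 0.05), 500 noise realizations
for the CRLB check (within 15% of the Monte-Carlo SD), and 1-5 mM
five-point phantoms for calibration linearity (R^2 = 1 to 1e-9 noiseless,
> 0.99 at study noise). Unit tests use shorter FIDs (1,024 points, 4
dynamics) where the full protocol adds nothing.

## Known limitations

* Editing is amplitude-level bookkeeping; no density-matrix simulation, so
  editing efficiency is a scale factor that cancels through calibration
  rather than a prediction.
* Singlet Gaussian models only — no metabolite basis sets, no
  macromolecule model beyond the smooth SSA baseline.
* The extended-conformer peak at 2.95 ppm is available as an optional
  out-of-phase second component (`gsh_ex_fraction`,
  `gsh_priors(include_ex = TRUE)`) but no claim of equivalence to the
  published extended-conformer quantitation is made; that signal was
  reported as indistinct under this protocol.
* Frequency-and-phase correction across dynamics is zero-order only; no
  eddy-current correction; tissue segmentation is consumed, not computed.
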