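# megaquant

Absolute quantitation of brain glutathione (GSH) from J-difference edited
MEGA-PRESS magnetic resonance spectroscopy, for spectroscopists and
neuroimaging statisticians studying oxidative stress in ageing, mild
cognitive impairment (MCI) and Alzheimer's disease (AD).

The cysteine beta-CH2 resonance of GSH (~2.80 ppm) hides under the
creatine peak at 3.03 ppm. MEGA-PRESS editing alternates a selective pulse
ON (4.40 ppm) and OFF (5.00 ppm) so that the averaged ON−OFF difference
spectrum cancels every uncoupled singlet and reveals the co-edited GSH
peak. `megaquant` covers the full analysis:

* **Simulation** — seeded, ground-truth-labelled interleaved ON/OFF FID
  series: phantom calibration runs (1–5 mM) and three-group (NC/MCI/AD),
  two-region (anterior/posterior cingulate) cohorts with residual water,
  overlapping Cr/Cho/NAA singlets, baseline, phase jitter and complex
  noise.
* **Preprocessing** — per-dynamic zero-order autophasing, interleaved
  averaging, edited difference, mixed Gaussian/exponential apodization,
  FFT with water referencing at 4.67 ppm, Hankel-SVD (HLSVD) residual
  water/lipid removal, wavelet-based raw SNR.
* **Fitting** — singular-spectrum-analysis (SSA) baseline estimation
  alternating with bounded Gaussian nonlinear least squares; per-peak
  area, FWHM, fitted-model SNR and Cramér–Rao lower bound (CRLB), with a
  CRLB ≤ 20% quality gate.
* **Quantitation** — phantom calibration line `area = m·conc + k`,
  T1/T2 relaxation correction

  `conc = (area − k)/m × [1 − exp(−TR/T1,phant)]/[1 − exp(−TR/T1,vivo)] × exp(−TE/T2,phant)/exp(−TE/T2,vivo)` (or its reciprocal — both orientations are explicit),

  and CSF partial-volume correction `pvc = conc/(1 − Vcsf)`.
* **Statistics** — one-way ANOVA (raw data or published mean ± SD (N)
  summaries), Tukey–Kramer post hocs, Levene/Shapiro–Wilk checks,
  type-III ANCOVA with age/sex covariates and Bonferroni marginal-mean
  contrasts, univariate ROC with DeLong 95% CI and Youden cutoffs, and
  multivariate ROC via binary logistic regression.

## Worked example

Calibrate on a simulated noiseless phantom, then quantify one noisy
in vivo-like acquisition (2.1 mM true tissue GSH, 25% CSF in the voxel):

```r
library(megaquant)
p <- acquisition_params()                 # TE 120 ms, TR 2500 ms, 20 dynamics

phantom <- simulate_phantom_series(1:5, p)
cal <- calibrate_phantom(phantom, 1:5, baseline = FALSE)
cal$curve$r_squared
#> [1] 1

s <- simulate_mega_press(2.1, p, noise_sd = 0.35,
                         phase_jitter_sd = 5 * pi / 180,
                         baseline_amplitude = 1, seed = 42)
q <- quantify_gsh(s, cal$curve, f_csf = 0.25)
q$fit
#> Gaussian peak fit (1 peaks, converged: TRUE, SNR 4.00)
#>     name amplitude center_ppm sigma_hz   area fwhm_hz crlb_percent
#> 1 GSH_cl    0.0591      2.799    3.481 0.5156   8.196       0.7635
c(area = q$area, absolute = q$absolute_mm, pvc = q$pvc_mm)
#>      area  absolute       pvc
#>    0.5156     2.062     2.750
```

The fitted edited peak sits at 2.80 ppm with an 8.2 Hz linewidth and a
CRLB well inside the 20% gate; the calibrated absolute concentration
(2.06 mM) is the CSF-diluted voxel value, and the partial-volume-corrected
estimate (2.75 mM) recovers the tissue concentration scale.

Published summary tables can be tested directly without subject data:

```r
anova_from_summary(means = c(2.3674, 1.7708, 1.7794),
                   sds   = c(0.4049, 0.3444, 0.4361),
                   ns    = c(25, 16, 16))
#> $F        15.52056   # printed value: F(2) = 15.515
#> $p        4.73e-06
```

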