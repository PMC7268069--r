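#' Describe one spectral resonance for simulation
#'
#' A phenomenological singlet: amplitude, centre, damping envelope and phase.
#' `editable` marks resonances that survive the edited ON-OFF difference
#' (co-edited spins); all others are built identically into both subspectra
#' and cancel on subtraction.
#'
#' For a Gaussian envelope `exp(-(t/damping)^2)` the corresponding absorption
#' lineshape is an exact Gaussian with frequency-domain standard deviation
#' `1 / (sqrt(2) * pi * damping)` Hz, so the default damping of 0.066 s gives
#' a full width at half maximum of about 8 Hz at 3 T.
#'
#' @param name Label (e.g. "GSH_cl", "Cr").
#' @param center_ppm Resonance position in ppm.
#' @param amplitude Signal amplitude in arbitrary units (>= 0).
#' @param damping Decay time constant in seconds (> 0).
#' @param shape Envelope: "gaussian" (`exp(-(t/d)^2)`) or "lorentzian"
#'   (`exp(-t/d)`).
#' @param phase_rad Zero-order phase in radians.
#' @param editable Logical; does the peak appear in the edited difference?
#' @return A `peak_truth` object.
#' @export
peak_truth <- function(name, center_ppm, amplitude, damping = 0.066,
                       shape = c("gaussian", "lorentzian"), phase_rad = 0,
                       editable = FALSE) {
  shape <- match.arg(shape)
  stopifnot(amplitude >= 0, damping > 0)
  structure(list(name = name, center_ppm = center_ppm, amplitude = amplitude,
                 damping = damping, shape = shape, phase_rad = phase_rad,
                 editable = editable),
            class = "peak_truth")
}

#' Frequency-domain Gaussian width of a simulated peak
#'
#' @param damping Gaussian decay constant in seconds.
#' @return Standard deviation of the absorption lineshape in Hz.
#' @export
gaussian_sigma_hz <- function(damping) 1 / (sqrt(2) * pi * damping)

#' Default non-edited background resonances
#'
#' Singlets visible in the averaged-OFF spectrum: NAA (2.01 ppm), Cr
#' (3.03 ppm), Cho (3.22 ppm), plus residual water at the reference position
#' (amplitude ~50x a typical glutathione peak, exercising the water filter)
#' and a broad lipid resonance at 1.3 ppm. Amplitudes are arbitrary-unit
#' stand-ins with realistic relative magnitudes; all cancel in the edited
#' difference.
#'
#' @param water,lipid Logical switches for the two nuisance signals.
#' @return List of [peak_truth()] objects.
#' @export
default_nuisance_peaks <- function(water = TRUE, lipid = TRUE) {
  pk <- list(peak_truth("NAA", 2.01, 10), peak_truth("Cr", 3.03, 8),
             peak_truth("Cho", 3.22, 3))
  if (water) pk <- c(pk, list(peak_truth("water", 4.67, 100, damping = 0.045)))
  if (lipid) pk <- c(pk, list(peak_truth("lipid", 1.30, 5, damping = 0.030)))
  pk
}

# render the noiseless complex FID of a peak list onto a time axis
render_fid <- function(peaks, params, t) {
  half_bw <- params$spectral_width_hz / 2
  x <- complex(real = numeric(length(t)), imaginary = numeric(length(t)))
  for (p in peaks) {
    f <- ppm_to_hz(p$center_ppm, params)
    if (abs(f) > half_bw)
      stop(sprintf("peak '%s' at %.2f ppm (%.0f Hz) lies outside +/- %.0f Hz",
                   p$name, p$center_ppm, f, half_bw))
    env <- if (p$shape == "gaussian") exp(-(t / p$damping)^2)
           else exp(-t / p$damping)
    x <- x + p$amplitude * exp(1i * (2 * pi * f * t + p$phase_rad)) * env
  }
  x
}

# very broad (fast-decaying) components standing in for a smooth macroscopic
# background; deterministic given the amplitude
baseline_components <- function(amplitude) {
  if (amplitude <= 0) return(list())
  list(peak_truth("baseline1", 2.0, amplitude, damping = 0.004),
       peak_truth("baseline2", 3.8, 0.7 * amplitude, damping = 0.004))
}

#' Simulate one free induction decay
#'
#' Sum of damped complex exponentials plus an optional smooth background term
#' (two very broad components) and circular white complex noise. Deterministic
#' for a fixed seed.
#'
#' @param peaks List of [peak_truth()] objects; each must lie within
#'   +/- half the spectral width of the reference.
#' @param params An [acquisition_params()] object.
#' @param noise_sd Standard deviation of the real and imaginary noise parts.
#' @param phase0_rad Zero-order phase applied to the whole FID.
#' @param baseline_amplitude Scale of the smooth background term.
#' @param seed Optional integer seed; `NULL` uses the ambient RNG stream.
#' @param condition,index Optional bookkeeping for interleaved series.
#' @return A `fid_dynamic`: list with `samples` (complex vector), `condition`
#'   and `index`.
#' @export
simulate_fid <- function(peaks, params, noise_sd = 0, phase0_rad = 0,
                         baseline_amplitude = 0, seed = NULL,
                         condition = NA_character_, index = NA_integer_) {
  stopifnot(noise_sd >= 0)
  t <- fid_time_axis(params)
  x <- render_fid(c(peaks, baseline_components(baseline_amplitude)), params, t)
  x <- x * exp(1i * phase0_rad)
  if (noise_sd > 0) {
    x <- x + with_seed(seed, complex(real = stats::rnorm(length(t), 0, noise_sd),
                                     imaginary = stats::rnorm(length(t), 0, noise_sd)))
  }
  structure(list(samples = x, condition = condition, index = index),
            class = "fid_dynamic")
}

#' Simulate an interleaved MEGA-PRESS series
#'
#' Builds `n_dynamics` alternating ON/OFF FIDs. The glutathione resonance
#' (default 2.80 ppm, the closed-conformer cysteine beta-CH2 signal) is
#' present unedited in both subspectra with amplitude `amp_per_mm * gsh_mm`;
#' the ON dynamics additionally carry the co-edited component with amplitude
#' `amp_per_mm * gsh_mm * editing_efficiency`, so the noiseless ON-OFF
#' difference contains only that edited component while water, lipid, NAA,
#' Cr and Cho cancel. An optional out-of-phase extended-conformer peak at
#' 2.95 ppm can be added as a fraction of the edited amplitude.
#'
#' The ground-truth edited signal is recorded in `attr(x, "truth")`:
#' `difference_area` is the analytic area of the real absorption peak in the
#' noiseless difference spectrum (`amplitude / 2` for a zero-phase peak,
#' because the one-sided FID folds half the signal energy into the
#' dispersion part).
#'
#' @param gsh_mm Glutathione concentration (mM, >= 0).
#' @param params An [acquisition_params()] object.
#' @param nuisance Non-edited background peaks (see
#'   [default_nuisance_peaks()]).
#' @param editing_efficiency Fraction of the unedited amplitude recovered by
#'   editing, in (0, 1].
#' @param amp_per_mm Arbitrary-unit amplitude per mM of glutathione.
#' @param noise_sd,phase_jitter_sd,baseline_amplitude Noise standard
#'   deviation, per-dynamic zero-order phase spread (radians) and smooth
#'   background scale.
#' @param freq_offset_ppm Instrumental frequency offset applied to every
#'   resonance (exercises water referencing).
#' @param gsh_center_ppm,gsh_damping Position and damping of the edited peak.
#' @param gsh_ex_fraction Amplitude of the extended-conformer peak at
#'   2.95 ppm as a fraction of the edited closed-conformer amplitude
#'   (0 disables it).
#' @param seed Optional integer seed.
#' @return A `mega_series`: list with `params` and `dynamics` (alternating
#'   ON/OFF `fid_dynamic`s), with a `truth` attribute.
#' @export
simulate_mega_press <- function(gsh_mm, params = acquisition_params(),
                                nuisance = default_nuisance_peaks(),
                                editing_efficiency = 0.5, amp_per_mm = 1,
                                noise_sd = 0, phase_jitter_sd = 0,
                                baseline_amplitude = 0, freq_offset_ppm = 0,
                                gsh_center_ppm = 2.80, gsh_damping = 0.066,
                                gsh_ex_fraction = 0, seed = NULL) {
  stopifnot(gsh_mm >= 0, editing_efficiency > 0, editing_efficiency <= 1)
  if (params$n_dynamics %% 2 != 0) stop("n_dynamics must be even")

  shift <- function(p) { p$center_ppm <- p$center_ppm + freq_offset_ppm; p }
  base <- lapply(nuisance, shift)
  unedited <- shift(peak_truth("GSH_cl", gsh_center_ppm,
                               amp_per_mm * gsh_mm, damping = gsh_damping))
  edited <- shift(peak_truth("GSH_cl_edit", gsh_center_ppm,
                             amp_per_mm * gsh_mm * editing_efficiency,
                             damping = gsh_damping, editable = TRUE))
  off_peaks <- c(base, list(unedited))
  on_peaks <- c(off_peaks, list(edited))
  if (gsh_ex_fraction > 0) {
    ex <- shift(peak_truth("GSH_ex_edit", 2.95,
                           gsh_ex_fraction * edited$amplitude,
                           damping = gsh_damping, phase_rad = pi,
                           editable = TRUE))
    on_peaks <- c(on_peaks, list(ex))
  }

  dynamics <- with_seed(seed, {
    lapply(seq_len(params$n_dynamics), function(i) {
      on <- i %% 2 == 1
      ph <- if (phase_jitter_sd > 0) stats::rnorm(1, 0, phase_jitter_sd) else 0
      simulate_fid(if (on) on_peaks else off_peaks, params,
                   noise_sd = noise_sd, phase0_rad = ph,
                   baseline_amplitude = baseline_amplitude,
                   condition = if (on) "ON" else "OFF", index = i)
    })
  })

  structure(list(params = params, dynamics = dynamics),
            class = "mega_series",
            truth = list(gsh_mm = gsh_mm,
                         difference_amplitude = edited$amplitude,
                         difference_area = edited$amplitude / 2,
                         sigma_hz = gaussian_sigma_hz(gsh_damping),
                         center_ppm = gsh_center_ppm + freq_offset_ppm,
                         editing_efficiency = editing_efficiency,
                         amp_per_mm = amp_per_mm))
}

#' @export
print.mega_series <- function(x, ...) {
  tr <- attr(x, "truth")
  cat(sprintf("MEGA-PRESS series: %d dynamics of %d points (GSH %.3g mM)\n",
              length(x$dynamics), length(x$dynamics[[1]]$samples),
              if (is.null(tr)) NA else tr$gsh_mm))
  invisible(x)
}

#' Simulate a phantom calibration series
#'
#' One interleaved series per concentration with identical nuisance content
#' (residual water only, as for an aqueous phantom), so that the noiseless
#' edited peak areas are exactly linear in concentration.
#'
#' @param concs_mm Concentrations in mM (non-empty, >= 0).
#' @param params An [acquisition_params()] object.
#' @param noise_sd Complex noise standard deviation.
#' @param seed Optional integer seed.
#' @param ... Further arguments passed to [simulate_mega_press()].
#' @return Named list of `mega_series`, one per concentration.
#' @export
simulate_phantom_series <- function(concs_mm, params = acquisition_params(),
                                    noise_sd = 0, seed = NULL, ...) {
  if (length(concs_mm) == 0) stop("empty concentration list")
  stopifnot(all(concs_mm >= 0))
  with_seed(seed, {
    out <- lapply(concs_mm, function(conc)
      simulate_mega_press(conc, params = params,
                          nuisance = default_nuisance_peaks(lipid = FALSE),
                          noise_sd = noise_sd, ...))
    names(out) <- sprintf("conc_%g", concs_mm)
    out
  })
}

#' Cohort simulation configuration
#'
#' Defines the group x region truth distributions, nuisance levels and noise
#' regime of a simulated three-group (NC / MCI / AD) two-region (ACC / PCC)
#' glutathione study. Default concentration moments are the tissue-level
#' group means and standard deviations of an elderly cingulate-cortex cohort
#' (NC about 2.0-2.4 mM, depleted by roughly 20-25% in MCI and AD); default
#' CSF fractions increase with disease severity, emulating atrophy.
#'
#' @param gsh_truth Data frame with columns `group`, `region`, `mean`, `sd`
#'   (mM); defaults described above.
#' @param n_subjects Named vector of group sizes (each >= 2).
#' @param vcsf_mean,vcsf_sd Per-group CSF-fraction distribution, truncated to
#'   `vcsf_range`.
#' @param vcsf_range Allowed CSF-fraction interval.
#' @param age_mean,age_sd Per-group age distributions (years).
#' @param p_male Per-group probability of male sex.
#' @param noise_sd,phase_jitter_sd,baseline_amplitude Acquisition noise
#'   regime passed to [simulate_mega_press()]. The default noise gives fitted
#'   glutathione peaks in the low-single-digit SNR range typical of edited
#'   in vivo data.
#' @param editing_efficiency,amp_per_mm Signal scaling (see
#'   [simulate_mega_press()]).
#' @param seed Integer seed driving all sampling.
#' @return A `cohort_config` list.
#' @export
cohort_sim_config <- function(gsh_truth = NULL,
                              n_subjects = c(NC = 27, MCI = 19, AD = 18),
                              vcsf_mean = c(NC = 0.22, MCI = 0.26, AD = 0.30),
                              vcsf_sd = 0.06, vcsf_range = c(0, 0.6),
                              age_mean = c(NC = 68.44, MCI = 70.84, AD = 70.74),
                              age_sd = c(NC = 7.07, MCI = 7.74, AD = 8.33),
                              p_male = c(NC = 16/27, MCI = 16/19, AD = 10/18),
                              noise_sd = 0.5, phase_jitter_sd = 5 * pi / 180,
                              baseline_amplitude = 1,
                              editing_efficiency = 0.5, amp_per_mm = 1,
                              seed = 1) {
  if (is.null(gsh_truth)) {
    gsh_truth <- data.frame(
      group = rep(c("NC", "MCI", "AD"), 2),
      region = rep(c("ACC", "PCC"), each = 3),
      mean = c(1.9502, 1.6224, 1.5624, 2.3674, 1.7708, 1.7794),
      sd = c(0.4223, 0.3865, 0.3407, 0.4049, 0.3444, 0.4361))
  }
  stopifnot(all(c("group", "region", "mean", "sd") %in% names(gsh_truth)),
            all(gsh_truth$sd >= 0), vcsf_sd >= 0, noise_sd >= 0,
            all(gsh_truth$group %in% c("NC", "MCI", "AD")),
            all(gsh_truth$region %in% c("ACC", "PCC")))
  if (any(n_subjects < 2))
    stop("n_subjects must be >= 2 in every group")
  structure(list(gsh_truth = gsh_truth, n_subjects = n_subjects,
                 vcsf_mean = vcsf_mean, vcsf_sd = vcsf_sd,
                 vcsf_range = vcsf_range, age_mean = age_mean,
                 age_sd = age_sd, p_male = p_male, noise_sd = noise_sd,
                 phase_jitter_sd = phase_jitter_sd,
                 baseline_amplitude = baseline_amplitude,
                 editing_efficiency = editing_efficiency,
                 amp_per_mm = amp_per_mm, seed = seed),
            class = "cohort_config")
}

# truncated normal by rejection; vectorised over n
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Simulate a labelled patient cohort
#'
#' Draws per-subject latent tissue concentrations from the configured
#' group x region truncated-normal laws (truncated at zero), per-voxel CSF
#' fractions, ages and sexes, and emits one interleaved MEGA-PRESS series per
#' subject x region. The generated edited signal is proportional to
#' `true_gsh_mm * (1 - vcsf)`, i.e. the acquired voxel signal is diluted by
#' CSF; partial-volume correction downstream should recover the tissue value.
#'
#' @param config A [cohort_sim_config()] object.
#' @param params An [acquisition_params()] object.
#' @param generate_series If `FALSE`, return only the truth table (fast path
#'   for statistical calibration studies).
#' @return List with `truth` (data frame: subject_id, group, region, age,
#'   sex, true_gsh_mm, vcsf, seed) and `series` (named list of `mega_series`,
#'   keyed `subject_region`), or `NULL` series when `generate_series = FALSE`.
#' @export
simulate_cohort <- function(config = cohort_sim_config(),
                            params = acquisition_params(),
                            generate_series = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- names(config$n_subjects)
  regions <- unique(config$gsh_truth$region)

  with_seed(config$seed, {
    subj <- data.frame(
      subject_id = sprintf("S%03d", seq_len(sum(config$n_subjects))),
      group = rep(groups, config$n_subjects), stringsAsFactors = FALSE)
    subj$age <- rtruncnorm(nrow(subj), config$age_mean[subj$group],
                           config$age_sd[subj$group], lower = 55)
    subj$sex <- ifelse(stats::runif(nrow(subj)) < config$p_male[subj$group],
                       "M", "F")

    truth <- do.call(rbind, lapply(regions, function(rg) {
      d <- subj
      d$region <- rg
      d
    }))
    truth <- truth[order(truth$subject_id, truth$region), ]
    mom <- merge(truth, config$gsh_truth, by = c("group", "region"),
                 sort = FALSE)
    mom <- mom[order(mom$subject_id, mom$region), ]
    truth$true_gsh_mm <- rtruncnorm(nrow(mom), mom$mean, mom$sd, lower = 0)
    truth$vcsf <- rtruncnorm(nrow(truth), config$vcsf_mean[truth$group],
                             config$vcsf_sd, lower = config$vcsf_range[1],
                             upper = config$vcsf_range[2])
    truth$seed <- config$seed
    truth <- truth[, c("subject_id", "group", "region", "age", "sex",
                       "true_gsh_mm", "vcsf", "seed")]
    rownames(truth) <- NULL

    series <- NULL
    if (generate_series) {
      series <- lapply(seq_len(nrow(truth)), function(i) {
        simulate_mega_press(
          truth$true_gsh_mm[i] * (1 - truth$vcsf[i]), params = params,
          editing_efficiency = config$editing_efficiency,
          amp_per_mm = config$amp_per_mm, noise_sd = config$noise_sd,
          phase_jitter_sd = config$phase_jitter_sd,
          baseline_amplitude = config$baseline_amplitude)
      })
      names(series) <- paste(truth$subject_id, truth$region, sep = "_")
    }
    list(truth = truth, series = series)
  })
}
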