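#' Quantify glutathione from one interleaved series
#'
#' Convenience wrapper over the full chain: preprocess the series
#' ([process_series()]), fit the edited-difference glutathione peak
#' ([fit_peaks()] over a window around 2.80 ppm), apply the CRLB quality
#' gate, and convert the area to an absolute and (optionally)
#' partial-volume-corrected concentration.
#'
#' @param series A `mega_series`.
#' @param curve A `calibration_curve` mapping areas to mM.
#' @param factor Relaxation correction factor (1 when phantom and in vivo
#'   relaxation match, as in simulations that do not model relaxation).
#' @param f_csf CSF fraction for partial-volume correction (`NA` skips it).
#' @param config A [processing_config()].
#' @param priors Peak priors for the difference spectrum.
#' @param fit_range_ppm Fit window on the difference spectrum.
#' @param gate A [quality_gate()].
#' @param baseline Estimate an SSA baseline during fitting?
#' @return List: `area`, `absolute_mm`, `pvc_mm`, `qc_pass`, `qc_reason`,
#'   `fit` (the `fit_result`), `processed` (the `processed_mrs`).
#' @export
quantify_gsh <- function(series, curve, factor = 1, f_csf = NA,
                         config = processing_config(),
                         priors = gsh_priors(),
                         fit_range_ppm = c(2.4, 3.4),
                         gate = quality_gate(), baseline = TRUE) {
  proc <- process_series(series, config)
  fit <- fit_peaks(proc$diff, priors, fit_range_ppm = fit_range_ppm,
                   baseline = baseline)
  gatej <- qc_gate(fit, gate, peak = "GSH_cl")
  area <- fit$peaks$area[fit$peaks$name == "GSH_cl"]
  absolute <- as.numeric(area_to_concentration(area, curve, factor))
  pvc <- if (is.na(f_csf)) NA_real_ else apply_pvc(absolute, f_csf)
  list(area = area, absolute_mm = absolute, pvc_mm = pvc,
       qc_pass = gatej$pass, qc_reason = gatej$reason,
       fit = fit, processed = proc)
}

#' Calibrate from a simulated phantom series
#'
#' Processes and fits every phantom acquisition and regresses fitted area
#' on the known concentrations.
#'
#' @param phantom Named list of `mega_series` from
#'   [simulate_phantom_series()].
#' @param concs_mm The true concentrations, in series order.
#' @param ... Passed to [quantify_gsh()]-style processing ([fit_peaks()]
#'   settings via `config`, `priors`, `fit_range_ppm`, `baseline`).
#' @inheritParams quantify_gsh
#' @return List with `curve` (a `calibration_curve`) and `areas`.
#' @export
calibrate_phantom <- function(phantom, concs_mm,
                              config = processing_config(),
                              priors = gsh_priors(),
                              fit_range_ppm = c(2.4, 3.4), baseline = TRUE) {
  stopifnot(length(phantom) == length(concs_mm))
  areas <- vapply(phantom, function(series) {
    proc <- process_series(series, config, remove_lipid = FALSE)
    fit <- fit_peaks(proc$diff, priors, fit_range_ppm = fit_range_ppm,
                     baseline = baseline)
    fit$peaks$area[fit$peaks$name == "GSH_cl"]
  }, numeric(1))
  list(curve = fit_calibration(concs_mm, unname(areas)),
       areas = unname(areas))
}

#' Quantify a simulated cohort
#'
#' Runs [quantify_gsh()] for every subject x region series of a simulated
#' cohort and returns a subject-level table ready for the statistics layer,
#' using each record's true CSF fraction for the partial-volume step (the
#' simulator plays the role of the tissue segmentation).
#'
#' @param cohort Output of [simulate_cohort()].
#' @param curve A `calibration_curve`.
#' @param factor Relaxation correction factor.
#' @param ... Passed to [quantify_gsh()].
#' @return Data frame: subject_id, group, region, age, sex, true_gsh_mm,
#'   vcsf, area, absolute_mm, pvc_mm, qc_pass, qc_reason, fit_snr,
#'   crlb_percent.
#' @export
quantify_cohort <- function(cohort, curve, factor = 1, ...) {
  truth <- cohort$truth
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    key <- paste(truth$subject_id[i], truth$region[i], sep = "_")
    q <- quantify_gsh(cohort$series[[key]], curve, factor = factor,
                      f_csf = truth$vcsf[i], ...)
    data.frame(truth[i, c("subject_id", "group", "region", "age", "sex",
                          "true_gsh_mm", "vcsf")],
               area = q$area, absolute_mm = q$absolute_mm,
               pvc_mm = q$pvc_mm, qc_pass = q$qc_pass,
               qc_reason = q$qc_reason, fit_snr = q$fit$fit_snr,
               crlb_percent =
                 q$fit$peaks$crlb_percent[q$fit$peaks$name == "GSH_cl"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
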