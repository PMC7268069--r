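#' Write and read a FID series container
#'
#' One directory per acquisition: `metadata.json` holds every acquisition
#' parameter plus the per-dynamic editing conditions, and `dynamic_NNN.csv`
#' holds one row per complex sample with columns `index`, `real`, `imag`.
#' Values are written with 17 significant digits, so the round trip is
#' bit-exact for doubles.
#'
#' @param series A `mega_series`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fid_series <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- c(unclass(series$params),
            list(conditions = vapply(series$dynamics, `[[`, "", "condition")))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_along(series$dynamics)) {
    x <- series$dynamics[[i]]$samples
    d <- data.frame(index = seq_along(x),
                    real = sprintf("%.17g", Re(x)),
                    imag = sprintf("%.17g", Im(x)))
    utils::write.csv(d, file.path(dir, sprintf("dynamic_%03d.csv", i)),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' @rdname write_fid_series
#' @export
read_fid_series <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  # whole-number doubles come back as integers; restore storage mode
  meta <- lapply(meta, function(v) if (is.integer(v)) as.numeric(v) else v)
  conds <- meta$conditions
  params <- acquisition_params(
    te_ms = meta$te_ms, tr_ms = meta$tr_ms, n_points = meta$n_points,
    spectral_width_hz = meta$spectral_width_hz,
    transmitter_mhz = meta$transmitter_mhz, edit_on_ppm = meta$edit_on_ppm,
    edit_off_ppm = meta$edit_off_ppm, n_dynamics = meta$n_dynamics,
    nsa_per_dynamic = meta$nsa_per_dynamic,
    reference_ppm = meta$reference_ppm)
  files <- sort(list.files(dir, pattern = "^dynamic_\\d+\\.csv$",
                           full.names = TRUE))
  dynamics <- lapply(seq_along(files), function(i) {
    d <- utils::read.csv(files[i])
    structure(list(samples = complex(real = as.numeric(d$real),
                                     imaginary = as.numeric(d$imag)),
                   condition = conds[i], index = i),
              class = "fid_dynamic")
  })
  structure(list(params = params, dynamics = dynamics),
            class = "mega_series")
}

#' Write and read a processed spectrum as CSV
#'
#' Columns `ppm`, `real`, `imag`; a sidecar JSON stores acquisition
#' parameters for provenance.
#'
#' @param spectrum A `spectrum`.
#' @param path Output CSV path (`.json` sidecar written next to it).
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  d <- data.frame(ppm = sprintf("%.17g", spectrum$ppm_axis),
                  real = sprintf("%.17g", Re(spectrum$values)),
                  imag = sprintf("%.17g", Im(spectrum$values)))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(unclass(spectrum$params),
                       sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  d <- utils::read.csv(path)
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  meta <- lapply(meta, function(v) if (is.integer(v)) as.numeric(v) else v)
  params <- do.call(acquisition_params,
                    meta[names(formals(acquisition_params))])
  structure(list(values = complex(real = as.numeric(d$real),
                                  imaginary = as.numeric(d$imag)),
                 ppm_axis = as.numeric(d$ppm), params = params),
            class = "spectrum")
}

#' Write and read a cohort truth table
#'
#' CSV with columns subject_id, group, region, age, sex, true_gsh_mm,
#' vcsf, seed.
#'
#' @param truth Truth data frame from [simulate_cohort()].
#' @param path CSV path.
#' @return `path` / the data frame.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
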