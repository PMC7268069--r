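#' Acquisition parameters for a MEGA-PRESS experiment
#'
#' Container for the pulse-sequence and sampling settings that every
#' simulation, processing and quantitation step consumes. Defaults follow a
#' 3 T single-voxel glutathione editing protocol: TE = 120 ms, TR = 2,500 ms,
#' 2,048 complex points per free induction decay (FID), editing pulse ON at
#' 4.40 ppm and OFF at 5.00 ppm, 20 interleaved dynamics of 16 averages each,
#' water referenced at 4.67 ppm. The spectral width (2,000 Hz) and proton
#' transmitter frequency (127.73 MHz) are typical 3 T values.
#'
#' @param te_ms Echo time in milliseconds; must be positive.
#' @param tr_ms Repetition time in milliseconds; must exceed `te_ms`.
#' @param n_points Complex samples per FID (>= 2).
#' @param spectral_width_hz Sampling bandwidth in Hz.
#' @param transmitter_mhz Proton frequency in MHz (Hz per ppm).
#' @param edit_on_ppm,edit_off_ppm Editing-pulse offsets (ppm); must differ.
#' @param n_dynamics Number of interleaved dynamics (even: equal ON/OFF).
#' @param nsa_per_dynamic Spectral averages accumulated per stored dynamic.
#' @param reference_ppm Chemical shift assigned to the water resonance.
#'
#' @return An object of class `acq_params` (a validated list).
#' @examples
#' p <- acquisition_params()
#' p$te_ms
#' @export
acquisition_params <- function(te_ms = 120, tr_ms = 2500, n_points = 2048,
                               spectral_width_hz = 2000,
                               transmitter_mhz = 127.73,
                               edit_on_ppm = 4.40, edit_off_ppm = 5.00,
                               n_dynamics = 20, nsa_per_dynamic = 16,
                               reference_ppm = 4.67) {
  stopifnot(te_ms > 0, tr_ms > te_ms, n_points >= 2,
            spectral_width_hz > 0, transmitter_mhz > 0,
            n_dynamics >= 2, nsa_per_dynamic >= 1)
  if (n_dynamics %% 2 != 0)
    stop("n_dynamics must be even (interleaved ON/OFF pairs)")
  if (edit_on_ppm == edit_off_ppm)
    stop("edit_on_ppm and edit_off_ppm must differ")
  structure(list(te_ms = te_ms, tr_ms = tr_ms, n_points = n_points,
                 spectral_width_hz = spectral_width_hz,
                 transmitter_mhz = transmitter_mhz,
                 edit_on_ppm = edit_on_ppm, edit_off_ppm = edit_off_ppm,
                 n_dynamics = n_dynamics, nsa_per_dynamic = nsa_per_dynamic,
                 reference_ppm = reference_ppm),
            class = "acq_params")
}

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf("MEGA-PRESS acquisition: TE %g ms, TR %g ms, %d pts @ %g Hz\n",
              x$te_ms, x$tr_ms, x$n_points, x$spectral_width_hz))
  cat(sprintf("  editing ON %g / OFF %g ppm; %d dynamics x %d NSA; ref %g ppm\n",
              x$edit_on_ppm, x$edit_off_ppm, x$n_dynamics,
              x$nsa_per_dynamic, x$reference_ppm))
  invisible(x)
}

#' Convert chemical shift to frequency offset
#'
#' Offsets are relative to the reference (water) position, in Hz; a resonance
#' upfield of water (lower ppm) has a negative offset.
#'
#' @param ppm Chemical shift(s) in ppm.
#' @param params An [acquisition_params()] object.
#' @return Frequency offset(s) in Hz.
#' @export
ppm_to_hz <- function(ppm, params) {
  (ppm - params$reference_ppm) * params$transmitter_mhz
}

#' @rdname ppm_to_hz
#' @param hz Frequency offset(s) in Hz relative to the reference.
#' @export
hz_to_ppm <- function(hz, params) {
  params$reference_ppm + hz / params$transmitter_mhz
}

# time axis (s) for an n-point FID
fid_time_axis <- function(params, n = params$n_points) {
  (seq_len(n) - 1) / params$spectral_width_hz
}

# Evaluate a block of code with a temporary RNG state. A NULL seed leaves the
# global stream untouched (and advances it).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
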