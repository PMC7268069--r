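# shared fixtures: small, fast acquisition settings for unit tests and a
# couple of constructors used across files

test_params <- function(n_points = 1024, n_dynamics = 4, ...) {
  acquisition_params(n_points = n_points, n_dynamics = n_dynamics, ...)
}

# default-size (2048-point, 20-dynamic) protocol for end-to-end checks
full_params <- function() acquisition_params()

unit_curve <- function() calibration_curve(m = 1, k = 0)

# render a noise-free spectrum containing the given Gaussian peaks directly
# on a ppm grid (bypasses the FID route; used as fitting input with known
# truth). peaks: data.frame(amplitude, center_ppm, sigma_hz)
render_spectrum <- function(peaks, params = full_params(), nbins = 2048,
                            baseline = 0) {
  ppm <- seq(hz_to_ppm(params$spectral_width_hz / 2 - 1e-9, params),
             hz_to_ppm(-params$spectral_width_hz / 2, params),
             length.out = nbins)
  f <- ppm_to_hz(ppm, params)
  y <- rep(baseline, length.out = nbins)
  for (i in seq_len(nrow(peaks)))
    y <- y + peaks$amplitude[i] *
      exp(-(f - ppm_to_hz(peaks$center_ppm[i], params))^2 /
            (2 * peaks$sigma_hz[i]^2))
  structure(list(values = complex(real = y, imaginary = 0),
                 ppm_axis = ppm, params = params),
            class = "spectrum")
}

# exhaustive grid-search oracle for Gaussian peak fitting: loops over a
# centre x sigma grid per peak and solves amplitudes linearly; independent
# of the package's optimizer
grid_fit_oracle <- function(spectrum, centers_ppm, center_span_ppm = 0.03,
                            sigma_range_hz = c(2.5, 4.5),
                            n_center = 13, n_sigma = 11,
                            fit_range_ppm = c(2.4, 3.4)) {
  sel <- spectrum$ppm_axis >= fit_range_ppm[1] &
    spectrum$ppm_axis <= fit_range_ppm[2]
  f <- ppm_to_hz(spectrum$ppm_axis[sel], spectrum$params)
  y <- Re(spectrum$values[sel])
  np <- length(centers_ppm)
  cgrids <- lapply(centers_ppm, function(cp)
    ppm_to_hz(seq(cp - center_span_ppm, cp + center_span_ppm,
                  length.out = n_center), spectrum$params))
  sgrid <- seq(sigma_range_hz[1], sigma_range_hz[2], length.out = n_sigma)
  combos <- expand.grid(lapply(seq_len(np), function(j)
    seq_len(n_center * n_sigma)))
  best <- list(rss = Inf)
  for (r in seq_len(nrow(combos))) {
    X <- matrix(0, length(y), np)
    cs <- ss <- numeric(np)
    for (j in seq_len(np)) {
      idx <- combos[r, j]
      ci <- (idx - 1) %% n_center + 1
      si <- (idx - 1) %/% n_center + 1
      cs[j] <- cgrids[[j]][ci]; ss[j] <- sgrid[si]
      X[, j] <- exp(-(f - cs[j])^2 / (2 * ss[j]^2))
    }
    amp <- tryCatch(qr.solve(X, y), error = function(e) NULL)
    if (is.null(amp) || any(amp < 0)) next
    rss <- sum((y - X %*% amp)^2)
    if (rss < best$rss)
      best <- list(rss = rss, amplitude = amp, center_hz = cs, sigma_hz = ss,
                   area = amp * ss * sqrt(2 * pi))
  }
  best
}
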