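# preprocessing chain: autophasing, averaging, difference, apodization,
# Fourier transform + referencing, Hankel-SVD filtering, wavelet SNR

test_that("zero-order autophasing inverts an applied phase and is a
           projection onto real-positive first points", {
  p <- test_params()
  fid <- simulate_fid(list(peak_truth("Cr", 3.03, 5)), p)
  expect_equal(autophase_zero_order(fid)$samples, fid$samples)

  rot <- fid
  rot$samples <- fid$samples * exp(1i * pi / 3)
  expect_equal(autophase_zero_order(rot)$samples, fid$samples,
               tolerance = 1e-12)

  set.seed(31)
  for (i in 1:50) {
    r <- fid
    r$samples <- fid$samples * exp(1i * runif(1, -pi, pi))
    out <- autophase_zero_order(r)
    expect_lt(abs(Im(out$samples[1])), 1e-12 * Mod(out$samples[1]))
    expect_gt(Re(out$samples[1]), 0)
  }
})

test_that("average_dynamics splits an interleaved series 50/50 and is
           idempotent on identical dynamics", {
  p <- full_params()  # 20 dynamics
  s <- simulate_mega_press(0, p)  # ON == OFF exactly when gsh = 0
  conds <- vapply(s$dynamics, function(d) d$condition, character(1))
  expect_equal(sum(conds == "ON"), 10)
  expect_equal(sum(conds == "OFF"), 10)
  av <- average_dynamics(s)
  expect_equal(av$avg_on$samples, s$dynamics[[1]]$samples, tolerance = 1e-12)
  expect_equal(av$avg_off$samples, av$avg_on$samples, tolerance = 1e-12)
})

test_that("average_dynamics rejects broken interleaving", {
  p <- test_params()
  s <- simulate_mega_press(1, p)
  s$dynamics[[2]]$condition <- "ON"
  expect_error(average_dynamics(s), "alternate")
})

test_that("edited difference is an exact sample-wise subtraction", {
  p <- test_params()
  s <- simulate_mega_press(1, p)
  av <- average_dynamics(s)
  d <- edited_difference(av$avg_on, av$avg_off)
  expect_equal(d$samples, av$avg_on$samples - av$avg_off$samples)
  expect_equal(max(Mod(edited_difference(av$avg_on, av$avg_on)$samples)), 0)
  # common additive content drops out
  shift <- av
  shift$avg_on$samples <- av$avg_on$samples + 3 + 2i
  shift$avg_off$samples <- av$avg_off$samples + 3 + 2i
  expect_equal(edited_difference(shift$avg_on, shift$avg_off)$samples,
               d$samples)
  bad <- av$avg_off
  bad$samples <- bad$samples[-1]
  expect_error(edited_difference(av$avg_on, bad), "length")
})

test_that("apodization: identity at zero widths, unit weight at t = 0,
           exponential widening by lb Hz", {
  p <- acquisition_params(n_points = 4096)
  fid <- simulate_fid(list(peak_truth("x", 3.0, 1, damping = 0.2)), p)
  cfg0 <- processing_config(gaussian_apod_hz = 0, exp_apod_hz = 0)
  expect_identical(apodize(fid, cfg0, p)$samples, fid$samples)

  lb <- 6
  cfg <- processing_config(gaussian_apod_hz = 0, exp_apod_hz = lb)
  ap <- apodize(fid, cfg, p)
  expect_equal(ap$samples[1], fid$samples[1])  # window(0) = 1

  # a pure Lorentzian line of width w broadens to exactly w + lb
  lor <- simulate_fid(list(peak_truth("l", 3.0, 1, damping = 1 / (pi * 4),
                                      shape = "lorentzian")), p)
  fwhm_of <- function(f) {
    sp <- to_spectrum(f, processing_config(zero_fill_to = 32768), p)
    re <- Re(sp$values)
    cross <- range(sp$ppm_axis[re > max(re) / 2])
    abs(diff(cross)) * p$transmitter_mhz
  }
  w0 <- fwhm_of(lor)
  w1 <- fwhm_of(apodize(lor, cfg, p))
  bin_hz <- p$spectral_width_hz / 32768
  expect_lt(abs((w1 - w0) - lb), max(2 * bin_hz, 0.05))
})

test_that("to_spectrum preserves energy (Parseval) without zero-fill", {
  p <- test_params()
  fid <- simulate_fid(list(peak_truth("Cr", 3.03, 5)), p, noise_sd = 0.3,
                      seed = 2)
  sp <- to_spectrum(fid, processing_config(zero_fill_to = p$n_points), p,
                    first_point_half = FALSE)
  dt <- 1 / p$spectral_width_hz
  df <- p$spectral_width_hz / p$n_points
  expect_equal(sum(Mod(fid$samples)^2) * dt, sum(Mod(sp$values)^2) * df,
               tolerance = 1e-9)
})

test_that("zero-filling doubles bin density without moving maxima", {
  p <- test_params()
  fid <- simulate_fid(list(peak_truth("Cr", 3.03, 5)), p)
  sp1 <- to_spectrum(fid, processing_config(zero_fill_to = p$n_points), p)
  sp2 <- to_spectrum(fid, processing_config(zero_fill_to = 2 * p$n_points), p)
  expect_equal(length(sp2$values), 2 * length(sp1$values))
  pk1 <- sp1$ppm_axis[which.max(Mod(sp1$values))]
  pk2 <- sp2$ppm_axis[which.max(Mod(sp2$values))]
  bin1 <- abs(diff(sp1$ppm_axis[1:2]))
  expect_lt(abs(pk1 - pk2), bin1 / 2 + 1e-12)
})

test_that("water referencing recovers an instrumental frequency offset", {
  p <- full_params()
  s <- simulate_mega_press(2, p, freq_offset_ppm = 0.1)
  av <- average_dynamics(s)
  sp <- to_spectrum(apodize(av$avg_off, processing_config(), p),
                    processing_config(), p)
  refd <- reference_to_water(sp)
  i <- which.max(Mod(refd$spectrum$values))
  bin_ppm <- abs(diff(sp$ppm_axis[1:2]))
  expect_lt(abs(refd$spectrum$ppm_axis[i] - 4.67), bin_ppm / 2 + 1e-12)
  expect_lt(abs(refd$shift_ppm + 0.1), bin_ppm)
})

test_that("HLSVD removes an in-band component and leaves out-of-band
           signal untouched", {
  p <- full_params()
  cfg <- processing_config()
  # single resonance at 0 Hz (the water position)
  w <- simulate_fid(list(peak_truth("w", 4.67, 10, damping = 0.05,
                                    shape = "lorentzian")), p)
  filt <- hlsvd_filter(w, c(-70, 70), cfg, p)
  expect_lt(sum(Mod(filt$samples)^2) / sum(Mod(w$samples)^2), 0.01)

  # no components in band: near no-op
  m <- simulate_fid(list(peak_truth("NAA", 2.01, 5)), p)
  keep <- hlsvd_filter(m, c(-70, 70), cfg, p)
  expect_lt(sum(Mod(keep$samples - m$samples)^2) / sum(Mod(m$samples)^2),
            0.02)
})

test_that("HLSVD water removal perturbs the metabolite area by < 2%", {
  p <- full_params()
  cfg <- processing_config()
  fit_area <- function(with_water) {
    pk <- list(peak_truth("GSH_cl", 2.80, 1))
    if (with_water)
      pk <- c(pk, list(peak_truth("water", 4.67, 50, damping = 0.05)))
    fid <- simulate_fid(pk, p)
    fid <- apodize(fid, cfg, p)
    if (with_water) fid <- hlsvd_filter(fid, c(-70, 70), cfg, p)
    sp <- to_spectrum(fid, cfg, p)
    f <- fit_peaks(sp, gsh_priors(), fit_range_ppm = c(2.4, 3.4),
                   baseline = FALSE)
    f$peaks$area[1]
  }
  expect_lt(abs(fit_area(TRUE) / fit_area(FALSE) - 1), 0.02)
})

test_that("raw SNR is scale invariant and detects the creatine peak", {
  p <- full_params()
  cfg <- processing_config()
  s <- simulate_mega_press(2, p, noise_sd = 0.5, seed = 13)
  sp <- process_series(s, cfg)$off
  snr <- estimate_raw_snr(sp, cfg)
  expect_gt(snr, 5)
  scaled <- sp
  scaled$values <- sp$values * 7.3
  expect_equal(estimate_raw_snr(scaled, cfg), snr, tolerance = 1e-9)
})

test_that("raw SNR stays below 5 on pure noise in >= 95% of seeds", {
  p <- full_params()
  cfg <- processing_config()
  ppm <- seq(12, -3, length.out = 2048)
  hits <- vapply(1:100, function(seed) {
    set.seed(seed)
    sp <- structure(list(values = complex(real = rnorm(2048),
                                          imaginary = rnorm(2048)),
                         ppm_axis = ppm, params = p), class = "spectrum")
    estimate_raw_snr(sp, cfg) < 5
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the wavelet filter bank reconstructs perfectly", {
  set.seed(4)
  x <- rnorm(512)
  st <- megaquant:::.dwt_step(x)
  expect_equal(megaquant:::.idwt_step(st$a, st$d), x, tolerance = 1e-10)
})

test_that("scaling the raw series scales the difference spectrum linearly", {
  p <- test_params()
  s <- simulate_mega_press(2, p, baseline_amplitude = 1)
  s3 <- s
  s3$dynamics <- lapply(s$dynamics, function(d) {
    d$samples <- d$samples * 3
    d
  })
  d1 <- process_series(s, processing_config(), remove_water = FALSE,
                       remove_lipid = FALSE)$diff
  d3 <- process_series(s3, processing_config(), remove_water = FALSE,
                       remove_lipid = FALSE)$diff
  expect_equal(d3$values, 3 * d1$values, tolerance = 1e-9)
})
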