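test_that("apodisation: zero broadening is the identity, negative is an error", {
  fid <- simulate_fid(ground_truth(noise_sd = 0), mt_condition("control", 0),
                      default_acq)
  expect_equal(apodize(fid, 0)$samples, fid$samples)
  expect_error(apodize(fid, -1), "nonnegative")
})

test_that("exponential apodisation adds exactly its line broadening to the FWHM", {
  acq <- acquisition_config()
  tab <- data.frame(label = "PCr", shift_ppm = 0, amplitude = 1,
                    linewidth_hz = 12)
  tr <- ground_truth(peak_table = tab, baseline_amplitude = 0, noise_sd = 0)
  fid <- simulate_fid(tr, mt_condition("control", 0), acq)
  fit0 <- fit_single_peak(to_spectrum(fid), "PCr", 0, c(-1, 1),
                          baseline_order = 0)
  fit1 <- fit_single_peak(to_spectrum(apodize(fid, 8, "exponential")),
                          "PCr", 0, c(-1, 1), baseline_order = 0)
  hz <- function(ppm) ppm * acq$spectrometer_frequency
  expect_equal(hz(fit1$fwhm) - hz(fit0$fwhm), 8, tolerance = 0.05)
  expect_equal(hz(fit0$fwhm), 12, tolerance = 0.05)
})

test_that("gaussian apodisation raises spectral SNR on noisy data", {
  tr <- ground_truth(noise_sd = 0.1)
  fid <- simulate_fid(tr, mt_condition("control", 30), default_acq,
                      seed = 31)
  snr <- function(sp) {
    re <- Re(sp$intensities)
    edge <- re[sp$ppm > 18 | sp$ppm < -22]
    (max(re[abs(sp$ppm) < 0.5]) - median(re)) / sd(edge)
  }
  expect_gt(snr(to_spectrum(apodize(fid, 5, "gaussian"))),
            1.5 * snr(to_spectrum(fid)))
})

test_that("spectral axis covers bandwidth/frequency ppm, carrier at 0", {
  acq <- acquisition_config(bandwidth = 3000, spectrometer_frequency = 49.9)
  fid <- simulate_fid(ground_truth(noise_sd = 0), mt_condition("control", 0),
                      acq)
  sp <- to_spectrum(fid)
  expect_equal(diff(range(sp$ppm)), 3000 / 49.9 * (1 - 1 / acq$n_points),
               tolerance = 1e-9)
  expect_true(all(diff(sp$ppm) < 0))  # NMR convention: decreasing axis
  # a lone peak at -2.5 ppm lands at -2.5 within one point
  tab <- data.frame(label = "PCr", shift_ppm = 0, amplitude = 0.01,
                    linewidth_hz = 10)
  tab <- rbind(tab, data.frame(label = "gATP", shift_ppm = -2.5,
                               amplitude = 2, linewidth_hz = 15))
  tr <- ground_truth(peak_table = tab, baseline_amplitude = 0, noise_sd = 0)
  sp2 <- to_spectrum(simulate_fid(tr, mt_condition("control", 0), acq))
  step <- 3000 / acq$n_points / 49.9
  expect_lt(abs(sp2$ppm[which.max(Mod(sp2$intensities))] + 2.5), step)
})

test_that("transform preserves energy (Parseval, first point halved)", {
  fid <- simulate_fid(ground_truth(noise_sd = 0.05),
                      mt_condition("control", 30), default_acq, seed = 3)
  sp <- to_spectrum(fid)
  x <- fid$samples
  x[1] <- x[1] / 2
  expect_equal(sum(Mod(sp$intensities)^2),
               length(x) * sum(Mod(x)^2), tolerance = 1e-9)
})

test_that("phase correction is the stated rotation and is invertible", {
  sp <- make_spectrum(seq(5, -5, length.out = 11), rep(1 + 0i, 11))
  expect_equal(phase_correct(sp, 0, 0)$intensities, sp$intensities)
  # phi0 = pi negates a positive peak
  expect_equal(Re(phase_correct(sp, pi, 0)$intensities), rep(-1, 11),
               tolerance = 1e-12)
  rot <- phase_correct(sp, 0.7, 0.12, pivot = 1)
  expect_equal(rot$intensities[6],
               exp(1i * (0.7 + 0.12 * (sp$ppm[6] - 1))) + 0i)
  back <- phase_correct(rot, -0.7, -0.12, pivot = 1)
  expect_equal(back$intensities, sp$intensities, tolerance = 1e-12)
})

test_that("auto_phase round-trips known phase errors within 0.05 rad", {
  acq <- acquisition_config()
  # already phased: returns approximately (0, 0)
  tr0 <- ground_truth(noise_sd = 0)
  sp0 <- to_spectrum(apodize(simulate_fid(tr0, mt_condition("control", 30),
                                          acq), 5, "gaussian"))
  ph0 <- auto_phase(sp0)
  expect_false(ph0$flagged)
  expect_lt(abs(ph0$phi0), 0.05)
  expect_lt(abs(ph0$phi1), 0.05)
  # dephased by known (p0, p1): recovers the negation
  cases <- list(c(0.4, 0.05), c(-1.2, -0.08), c(2.5, 0.1))
  for (pp in cases) {
    tr <- ground_truth(noise_sd = 0, phase0 = pp[1], phase1 = pp[2])
    sp <- to_spectrum(apodize(simulate_fid(tr, mt_condition("control", 30),
                                           acq), 5, "gaussian"))
    ph <- auto_phase(sp)
    wrap <- function(a) atan2(sin(a), cos(a))
    expect_lt(abs(wrap(ph$phi0 + pp[1])), 0.05)
    expect_lt(abs(ph$phi1 + pp[2]), 0.05)
    # applying the correction restores an essentially nonnegative real part
    fixed <- phase_correct(sp, ph$phi0, ph$phi1)
    re <- Re(fixed$intensities)
    expect_lt(-min(re) / max(re), 0.05)
  }
  # pure noise is flagged, not phased
  tabn <- data.frame(label = "PCr", shift_ppm = 0, amplitude = 0,
                     linewidth_hz = 10)
  trn <- ground_truth(peak_table = tabn, baseline_amplitude = 0,
                      noise_sd = 0.1)
  spn <- to_spectrum(simulate_fid(trn, mt_condition("control", 0), acq,
                                  seed = 8))
  phn <- auto_phase(spn)
  expect_true(phn$flagged)
  expect_equal(c(phn$phi0, phn$phi1), c(0, 0))
})

test_that("baseline correction removes representable polynomials exactly", {
  x <- seq(10, -25, length.out = 800)
  poly4 <- 3 - 0.5 * x + 0.02 * x^2 + 0.004 * x^3 - 2e-4 * x^4
  sp <- make_spectrum(x, poly4)
  out <- baseline_correct(sp, order = 4, exclude = list())
  expect_lt(max(abs(Re(out$intensities))), 1e-8 * max(abs(poly4)))
  # order 0 subtracts the mean of non-excluded points
  sp2 <- make_spectrum(x, x * 0 + 5)
  out2 <- baseline_correct(sp2, order = 0, exclude = list(c(-5, 0)))
  expect_equal(Re(out2$intensities), rep(0, length(x)), tolerance = 1e-12)
  expect_error(baseline_correct(sp, 4, exclude = list(c(-30, 15))),
               "too few points")
})

test_that("baseline correction under a peak preserves its area within 1%", {
  x <- seq(10, -25, length.out = 1600)
  peak <- peak_shape(x, 10, 4.9, 0.3)
  quartic <- 2 + 0.1 * x - 0.01 * x^2 + 5e-4 * x^3 - 3e-5 * x^4
  sp <- make_spectrum(x, peak + quartic)
  out <- baseline_correct(sp, order = 4,
                          exclude = default_exclusion_windows())
  fit <- fit_single_peak(out, "Pi_i", 4.9, c(4, 6), baseline_order = 1)
  expect_equal(fit$area, peak_area(10, 0.3), tolerance = 0.01)
})

test_that("processing commutes with scalar rescaling of the input", {
  fid <- simulate_fid(ground_truth(noise_sd = 0.02),
                      mt_condition("control", 30), default_acq, seed = 12)
  fid3 <- fid
  fid3$samples <- 3 * fid$samples
  s1 <- phase_correct(to_spectrum(apodize(fid, 5, "gaussian")), 0.3, 0.01)
  s3 <- phase_correct(to_spectrum(apodize(fid3, 5, "gaussian")), 0.3, 0.01)
  expect_equal(s3$intensities, 3 * s1$intensities, tolerance = 1e-12)
})

test_that("replaying recorded provenance reproduces the spectrum exactly", {
  fid <- simulate_fid(ground_truth(noise_sd = 0.02),
                      mt_condition("control", 30), default_acq, seed = 21)
  sp <- baseline_correct(
    phase_correct(to_spectrum(apodize(fid, 5, "gaussian")), 0.2, -0.01),
    order = 4)
  replayed <- replay_provenance(fid, sp$provenance)
  expect_identical(replayed$intensities, sp$intensities)
  expect_equal(length(sp$provenance), 4)  # apodise, fft, phase, baseline
})

test_that("spectra round-trip through CSV + JSON sidecars", {
  fid <- simulate_fid(ground_truth(noise_sd = 0.02),
                      mt_condition("control", 30), default_acq, seed = 2)
  sp <- to_spectrum(apodize(fid, 5, "gaussian"))
  path <- file.path(tempdir(), "spec_test.csv")
  write_spectrum(sp, path)
  tab <- read.csv(path)
  expect_equal(tab$ppm, sp$ppm, tolerance = 1e-12)
  expect_equal(complex(real = tab$real, imaginary = tab$imag),
               sp$intensities, tolerance = 1e-12)
  prov <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  expect_equal(prov$step, c("apodize", "fft"))
  unlink(c(path, sub("\\.csv$", ".json", path)))
})
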