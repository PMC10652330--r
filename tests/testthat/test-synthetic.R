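test_that("decay_fraction matches the closed form and its limits", {
  # no exchange or no saturation time leaves the signal untouched
  expect_equal(decay_fraction(0, 3.1, 7.4), 1)
  expect_equal(decay_fraction(0, 5, 100), 1)
  expect_equal(decay_fraction(0.3, 2, 0), 1)
  # frozen closed-form value (hand-evaluated independently)
  expect_equal(decay_fraction(0.2, 3.1, 7.4), 0.62528999, tolerance = 1e-7)
  # infinite-saturation plateau 1/(1 + kf*T1)
  expect_equal(decay_fraction(0.2, 3.1, Inf), 1 / (1 + 0.2 * 3.1),
               tolerance = 1e-12)
  expect_error(decay_fraction(0.2, 0, 1), "t1")
  expect_error(decay_fraction(-0.1, 3, 1), "kf")
})

test_that("decay_fraction is monotone nonincreasing in tau and kf, in (0,1]", {
  taus <- seq(0, 12, by = 0.25)
  for (kf in c(0.05, 0.2, 0.5, 1)) {
    v <- decay_fraction(kf, 3.1, taus)
    expect_true(all(diff(v) <= 1e-12))
    expect_true(all(v > 0 & v <= 1))
  }
  for (tau in c(0.5, 3, 7.4)) {
    v <- vapply(seq(0, 1, by = 0.05), decay_fraction, numeric(1),
                t1 = 3.1, tau = tau)
    expect_true(all(diff(v) <= 1e-12))
  }
})

test_that("Bloch-McConnell oracle reproduces the closed form at full saturation", {
  for (kf in c(0, 0.1, 0.4, 1)) for (t1 in c(1, 3.1, 7)) {
    taus <- c(0, 0.5, 2, 5, 10)
    ode <- bloch_mcconnell_decay(kf, t1, taus)
    cf <- decay_fraction(kf, t1, taus)
    expect_lt(max(abs(ode / cf - 1)), 1e-6)
  }
})

test_that("Bloch-McConnell oracle handles partial and absent saturation", {
  expect_equal(bloch_mcconnell_decay(0, 3.1, c(0, 1, 2)), c(1, 1, 1),
               tolerance = 1e-9)
  # unsaturated partner pool: no transfer at all
  expect_equal(bloch_mcconnell_decay(0.3, 3.1, c(1, 5),
                                     saturation_efficiency = 0),
               c(1, 1), tolerance = 1e-8)
  # partial saturation decays strictly less than full saturation
  full <- bloch_mcconnell_decay(0.2, 3.1, 7.4)
  half <- bloch_mcconnell_decay(0.2, 3.1, 7.4, saturation_efficiency = 0.5)
  expect_gt(half, full)
  expect_lt(half, 1)
  expect_error(bloch_mcconnell_decay(0.2, 3.1, numeric(0)), "nonempty")
  expect_error(bloch_mcconnell_decay(0.2, 3.1, 1, saturation_efficiency = 2),
               "efficiency")
})

test_that("saturation times follow the pulse-train arithmetic", {
  acq <- acquisition_config()
  unit <- 0.11429 + 0.005 + 0.050
  expect_equal(saturation_times(acq, 44), 44 * unit)
  expect_equal(44 * unit, 7.449, tolerance = 1e-3)
  # the nominal labels of the seven conditions, within rounding
  labels <- c(0, 0.5, 1.0, 2.0, 3.0, 5.0, 7.4)
  expect_lt(max(abs(saturation_times(acq) - labels)), 0.11)
})

test_that("acquisition invariants are enforced", {
  expect_error(acquisition_config(n_points = 1000), "power of two")
  expect_error(acquisition_config(pulse_counts = c(0, 3, 3)),
               "strictly increasing")
  expect_error(acquisition_config(pulse_counts = c(-1, 3)), "nonnegative")
  expect_equal(acquisition_config(bandwidth = 4000)$dwell_time, 1 / 4000)
})

test_that("simulate_fid is deterministic and places peaks at configured shifts", {
  acq <- acquisition_config()
  tr <- ground_truth()
  f1 <- simulate_fid(tr, mt_condition("control", 30), acq, seed = 42)
  f2 <- simulate_fid(tr, mt_condition("control", 30), acq, seed = 42)
  expect_identical(f1$samples, f2$samples)
  # noiseless, well-separated peaks: the spectrum magnitude has a local
  # maximum at each configured shift within one spectral point
  tab <- data.frame(label = c("Pi_i", "PCr", "gATP", "bATP"),
                    shift_ppm = c(4.9, 0, -2.5, -16),
                    amplitude = c(0.7, 3, 1.2, 1),
                    linewidth_hz = c(14, 16.5, 28, 34))
  tr0 <- ground_truth(peak_table = tab, noise_sd = 0,
                      baseline_amplitude = 0)
  sp <- to_spectrum(simulate_fid(tr0, mt_condition("control", 30), acq))
  step <- acq$bandwidth / acq$n_points / acq$spectrometer_frequency
  re <- Re(sp$intensities)   # absorption channel (phases are zero)
  for (s in tab$shift_ppm) {
    near <- which(abs(sp$ppm - s) <= 0.4)
    j <- near[which.max(re[near])]
    expect_lt(abs(sp$ppm[j] - s), step + 1e-9)
    # genuinely a local maximum
    expect_true(re[j] >= re[j - 1] && re[j] >= re[j + 1])
  }
})

test_that("noiseless single-peak spectrum height equals the discrete Lorentzian sum", {
  acq <- acquisition_config()
  lw <- 20
  tab <- data.frame(label = "PCr", shift_ppm = 0, amplitude = 2,
                    linewidth_hz = lw)
  tr <- ground_truth(peak_table = tab, baseline_amplitude = 0, noise_sd = 0)
  fid <- simulate_fid(tr, mt_condition("control", 0), acq)
  sp <- to_spectrum(fid)
  # closed form: geometric sum of the damped exponential at resonance,
  # with the first point halved
  r <- exp(-pi * lw * acq$dwell_time)
  expected <- 2 * ((1 - r^acq$n_points) / (1 - r) - 0.5)
  h <- max(Re(sp$intensities))
  expect_equal(h, expected, tolerance = 1e-6)
})

test_that("on-resonance saturation scales Pi(i) areas by decay_fraction", {
  acq <- acquisition_config()
  # an uncluttered Pi(i), and a static PCr, so direct integration is clean
  tab <- data.frame(label = c("Pi_i", "PCr"),
                    shift_ppm = c(4.9, 0),
                    amplitude = c(0.7, 3),
                    linewidth_hz = c(14, 16.5))
  tr <- ground_truth(kf_pi = 0.2, kf_pcr = 0, peak_table = tab,
                     noise_sd = 0, baseline_amplitude = 0)
  proc <- function(fid) {
    # integrate the real channel with a local linear background (removes
    # the slowly varying PCr tail under the Pi peak)
    sp <- to_spectrum(apodize(fid, 5, "gaussian"))
    re <- Re(sp$intensities)
    sel <- sp$ppm > 4.3 & sp$ppm < 5.5
    lo <- mean(re[sp$ppm > 4.0 & sp$ppm <= 4.3])
    hi <- mean(re[sp$ppm >= 5.5 & sp$ppm < 5.8])
    bg <- approx(c(4.15, 5.65), c(lo, hi), sp$ppm[sel], rule = 2)$y
    sum(re[sel] - bg)
  }
  ctrl <- proc(simulate_fid(tr, mt_condition("control", 30), acq))
  for (np in c(12, 44)) {
    sat <- proc(simulate_fid(tr, mt_condition("saturation", np), acq))
    tau <- saturation_times(acq, np)
    expect_equal(sat / ctrl, decay_fraction(0.2, 3.1, tau),
                 tolerance = 5e-3)
  }
})

test_that("peaks outside the spectral window are reported by name", {
  acq <- acquisition_config(bandwidth = 1000)  # +/- 10 ppm window
  expect_error(simulate_fid(ground_truth(noise_sd = 0),
                            mt_condition("control", 0), acq),
               "bATP")
})

test_that("phantom cohort has full paired structure and a complete truth table", {
  coh <- make_phantom_cohort(n_subjects = 3, seed = 9)
  expect_length(coh$subjects, 3)
  for (s in coh$subjects) {
    expect_named(s, c("pre", "post"))
    for (ses in s) {
      expect_length(ses, length(default_acq$pulse_counts) + 1)
      expect_true("control" %in% names(ses))
    }
  }
  expect_equal(nrow(coh$truth), 6)
  expect_true(all(c("kf_pi", "kf_pcr", "t1_pi", "noise_sd") %in%
                    names(coh$truth)))
  expect_true(all(coh$truth$kf_pi > 0))
  expect_error(make_phantom_cohort(2, pre_kf_distribution =
                                     list(mean = -0.1, sd = 0.01)),
               "positive mean")
})

test_that("session bundles serialise deterministically and read back", {
  coh1 <- make_phantom_cohort(n_subjects = 1, seed = 5)
  coh2 <- make_phantom_cohort(n_subjects = 1, seed = 5)
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  write_session_bundle(coh1$subjects[[1]]$pre, d1)
  write_session_bundle(coh2$subjects[[1]]$pre, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  back <- read_session_bundle(d1)
  orig <- coh1$subjects[[1]]$pre
  expect_setequal(names(back), names(orig))
  expect_equal(back$sat_44$samples, orig$sat_44$samples, tolerance = 1e-12)
  expect_equal(back$control$tau, orig$control$tau)
  expect_equal(back$control$acquisition$bandwidth, 3000)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("corrupt bundle rows are reported with file and row", {
  coh <- make_phantom_cohort(n_subjects = 1, seed = 5)
  d <- file.path(tempdir(), "bundle_bad")
  write_session_bundle(coh$subjects[[1]]$pre, d)
  f <- file.path(d, "sat_03.csv")
  lines <- readLines(f)
  lines[5] <- "3,not_a_number,0.1"
  writeLines(lines, f)
  expect_error(suppressWarnings(read_session_bundle(d)), "sat_03.csv at row 4")
  unlink(d, recursive = TRUE)
})
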