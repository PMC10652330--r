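#' Fractional signal remaining under saturation transfer
#'
#' Forsen-Hoffman two-site exchange: while one exchange partner (gamma-ATP)
#' is RF-saturated, the observed pool (Pi or PCr) decays from its
#' equilibrium value towards a reduced steady state. The surviving signal
#' fraction after saturation time `tau` is
#' \deqn{S(\tau)/S_0 = k_f T_{app} e^{-\tau/T_{app}} + T_{app}/T_1,}
#' with the apparent decay constant \eqn{1/T_{app} = 1/T_1 + k_f}.
#'
#' @param kf Forward pseudo-first-order exchange rate, 1/s (>= 0).
#' @param t1 Intrinsic longitudinal relaxation time, s (> 0).
#' @param tau Saturation time(s), s (>= 0). Vectorised.
#' @return Fraction(s) in (0, 1]; 1 when `kf = 0` or `tau = 0`.
#' @examples
#' decay_fraction(0.2, 3.1, 7.4)        # ~0.625
#' decay_fraction(0.2, 3.1, Inf)        # 1/(1 + kf*T1) ~0.617
#' @export
decay_fraction <- function(kf, t1, tau) {
  if (any(t1 <= 0)) stop("t1 must be positive")
  if (any(kf < 0)) stop("kf must be nonnegative")
  if (any(tau < 0)) stop("tau must be nonnegative")
  t_app <- 1 / (1 / t1 + kf)
  kf * t_app * exp(-tau / t_app) + t_app / t1
}

#' Two-pool Bloch-McConnell saturation-transfer oracle
#'
#' Integrates the longitudinal two-pool exchange equations with the
#' partner pool (gamma-ATP) clamped at `(1 - saturation_efficiency)` times
#' its equilibrium magnetisation. With perfect saturation this reproduces
#' the closed-form [decay_fraction()]; it is kept as an independent
#' numerical route for validating the closed form, and for exploring
#' imperfect saturation.
#'
#' @param kf Forward exchange rate, 1/s.
#' @param t1 T1 of the observed pool, s.
#' @param tau_grid Saturation times to report, s (nonempty).
#' @param saturation_efficiency Fraction in \[0, 1\]: 1 clamps the partner
#'   pool to zero (ideal saturation), 0 leaves it at equilibrium.
#' @param pool_ratio Equilibrium magnetisation of the partner pool relative
#'   to the observed pool; sets the reverse rate by detailed balance.
#' @return Signal fractions at `tau_grid`.
#' @export
bloch_mcconnell_decay <- function(kf, t1, tau_grid,
                                  saturation_efficiency = 1,
                                  pool_ratio = 1) {
  if (length(tau_grid) == 0) stop("tau_grid must be nonempty")
  if (any(tau_grid < 0)) stop("tau_grid must be nonnegative")
  if (saturation_efficiency < 0 || saturation_efficiency > 1)
    stop("saturation_efficiency must lie in [0, 1]")
  if (t1 <= 0) stop("t1 must be positive")
  if (kf < 0) stop("kf must be nonnegative")
  kr <- if (pool_ratio > 0) kf / pool_ratio else 0
  mb <- (1 - saturation_efficiency) * pool_ratio  # clamped partner pool
  deriv <- function(t, y, parms) {
    list((1 - y[1]) / t1 - kf * y[1] + kr * mb)
  }
  times <- sort(unique(c(0, tau_grid)))
  sol <- deSolve::lsoda(c(M = 1), times = times, func = deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  vals <- setNames(sol[, "M"], format(sol[, "time"], digits = 15))
  unname(vals[format(tau_grid, digits = 15)])
}

peak_frequency_hz <- function(shift_ppm, acq) shift_ppm * acq$spectrometer_frequency

# Broad short-T2* phospholipid component underlying the 31P spectrum
baseline_component <- function(amplitude) {
  data.frame(label = "phospholipid", shift_ppm = 1.5, amplitude = amplitude,
             linewidth_hz = 600, stringsAsFactors = FALSE)
}

#' Simulate one free induction decay
#'
#' Forward model of an in-vivo 31P MT-MRS acquisition: each resonance is a
#' damped complex exponential at its chemical-shift offset with Lorentzian
#' linewidth; a broad short-T2* component models the phospholipid baseline.
#' Under on-resonance saturation (MT train at -2.5 ppm) the Pi(i) and PCr
#' amplitudes are multiplied by [decay_fraction()] at the condition's
#' saturation time, and gamma-ATP is suppressed as `exp(-tau/tau_sat)` with
#' a short `tau_sat` (near-instant full saturation). Additive noise is
#' i.i.d. complex Gaussian per time point; zeroth/first-order phase errors
#' are applied per resonance about the PCr (0 ppm) pivot.
#'
#' @param truth A [ground_truth()].
#' @param condition An [mt_condition()].
#' @param acq An [acquisition_config()].
#' @param seed Optional integer seed; identical seeds give identical
#'   samples. `NULL` draws from the current RNG stream.
#' @param tau_sat Time constant (s) of gamma-ATP suppression onset.
#' @param subject_id,session_label Metadata carried through the pipeline.
#' @return An object of class `fid_series`.
#' @export
simulate_fid <- function(truth, condition, acq, seed = NULL,
                         tau_sat = 0.05,
                         subject_id = "S1", session_label = "pre") {
  if (!is.null(seed)) set.seed(seed)
  half_width <- acq$bandwidth / 2 / acq$spectrometer_frequency
  peaks <- rbind(truth$peak_table,
                 baseline_component(truth$baseline_amplitude))
  bad <- abs(peaks$shift_ppm) >= half_width
  if (any(bad))
    stop("peak(s) outside the spectral window: ",
         paste(peaks$label[bad], collapse = ", "))
  tau <- saturation_times(acq, condition$n_pulses)
  scale <- rep(1, nrow(peaks))
  if (condition$type == "saturation" && tau > 0) {
    scale[peaks$label == "Pi_i"] <- decay_fraction(truth$kf_pi, truth$t1_pi, tau)
    scale[peaks$label == "PCr"] <- decay_fraction(truth$kf_pcr, truth$t1_pcr, tau)
    scale[peaks$label == "gATP"] <- exp(-tau / tau_sat)
  }
  t <- (seq_len(acq$n_points) - 1) * acq$dwell_time
  fid <- complex(real = rep(0, acq$n_points), imaginary = 0)
  for (k in seq_len(nrow(peaks))) {
    f <- peak_frequency_hz(peaks$shift_ppm[k], acq)
    r <- pi * peaks$linewidth_hz[k]            # Lorentzian FWHM = r/pi Hz
    phase <- truth$phase0 + truth$phase1 * peaks$shift_ppm[k]
    fid <- fid + peaks$amplitude[k] * scale[k] *
      exp(complex(imaginary = 2 * pi * f * t + phase) - r * t)
  }
  if (truth$noise_sd > 0)
    fid <- fid + complex(real = rnorm(acq$n_points, 0, truth$noise_sd),
                         imaginary = rnorm(acq$n_points, 0, truth$noise_sd))
  structure(list(
    samples = fid, condition = condition, tau = unname(tau),
    acquisition = acq, subject_id = subject_id,
    session_label = session_label
  ), class = "fid_series")
}

#' @export
print.fid_series <- function(x, ...) {
  cat(sprintf("<fid_series> %s/%s %s (%d pulses, tau = %.2f s), %d points\n",
              x$subject_id, x$session_label, x$condition$type,
              x$condition$n_pulses, x$tau, length(x$samples)))
  invisible(x)
}

#' Simulate a full single-session MT experiment
#'
#' One FID per configured pulse count (MT train on gamma-ATP) plus the
#' off-resonance control (+15 ppm, 30 pulses), which serves as the
#' normalisation reference.
#'
#' @inheritParams simulate_fid
#' @param control_pulses MT pulses in the control condition.
#' @return A list of `fid_series`, named `sat_<n>` and `control`.
#' @export
simulate_session <- function(truth, acq = acquisition_config(), seed = NULL,
                             subject_id = "S1", session_label = "pre",
                             control_pulses = 30L) {
  if (!is.null(seed)) set.seed(seed)
  fids <- lapply(acq$pulse_counts, function(np)
    simulate_fid(truth, mt_condition("saturation", np), acq,
                 subject_id = subject_id, session_label = session_label))
  names(fids) <- sprintf("sat_%02d", acq$pulse_counts)
  fids$control <- simulate_fid(truth, mt_condition("control", control_pulses),
                               acq, subject_id = subject_id,
                               session_label = session_label)
  fids
}

#' Simulate a paired pre/post cohort with known ground truth
#'
#' Emulates a paired photobiomodulation study: each subject has a pre and a
#' post session, all saturation conditions plus the control. Subject rates
#' are sampled with a shared subject effect, so the pre/post difference has
#' mean `post mean - pre mean` and standard deviation `paired_sd` - the
#' within-subject design the paired cohort statistics assume.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param pre_kf_distribution,post_kf_distribution Lists with `mean` and
#'   `sd` (1/s) for the Pi(i) exchange rate in each session.
#' @param acq An [acquisition_config()].
#' @param seed Integer seed; the whole cohort is derived from it.
#' @param paired_sd Subject-level SD of the pre-to-post rate change, 1/s.
#' @param truth_args Extra arguments passed to [ground_truth()] (noise,
#'   phases, peak table) shared by all subjects.
#' @return A list with `subjects` (per subject: `pre`/`post` session FID
#'   lists) and `truth` (data frame of every sampled parameter).
#' @export
make_phantom_cohort <- function(n_subjects = 7,
                                pre_kf_distribution = list(mean = 0.2, sd = 0.05),
                                post_kf_distribution = list(mean = 0.3, sd = 0.05),
                                acq = acquisition_config(),
                                seed = 1,
                                paired_sd = 0.02,
                                truth_args = list()) {
  stopifnot(n_subjects >= 1)
  for (d in list(pre_kf_distribution, post_kf_distribution))
    if (d$mean <= 0 || d$sd < 0)
      stop("rate distribution must have positive mean and nonnegative sd")
  set.seed(seed)
  subj_effect <- rnorm(n_subjects, 0, pre_kf_distribution$sd)
  kf_pre <- pre_kf_distribution$mean + subj_effect
  kf_post <- post_kf_distribution$mean + subj_effect +
    rnorm(n_subjects, 0, paired_sd)
  if (any(kf_pre <= 0) || any(kf_post <= 0))
    stop("sampled a nonpositive exchange rate; narrow the distributions")
  ids <- sprintf("S%02d", seq_len(n_subjects))
  subjects <- vector("list", n_subjects)
  names(subjects) <- ids
  rows <- list()
  for (i in seq_len(n_subjects)) {
    sessions <- list()
    for (ses in c("pre", "post")) {
      kf <- if (ses == "pre") kf_pre[i] else kf_post[i]
      truth <- do.call(ground_truth, c(list(kf_pi = kf), truth_args))
      sessions[[ses]] <- simulate_session(truth, acq, seed = NULL,
                                          subject_id = ids[i],
                                          session_label = ses)
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = ids[i], session = ses, kf_pi = kf,
        kf_pcr = truth$kf_pcr, t1_pi = truth$t1_pi, t1_pcr = truth$t1_pcr,
        noise_sd = truth$noise_sd, phase0 = truth$phase0,
        phase1 = truth$phase1, delta_pi_i = truth$delta_pi_i,
        stringsAsFactors = FALSE)
    }
    subjects[[i]] <- sessions
  }
  list(subjects = subjects, truth = do.call(rbind, rows), seed = seed)
}

#' Write a session bundle to disk
#'
#' One directory per session: a per-condition CSV of `(index, real, imag)`
#' with a JSON sidecar carrying the acquisition, condition, saturation time
#' and subject metadata.
#'
#' @param session A list of `fid_series` (as from [simulate_session()]).
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_session_bundle <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(session)) {
    fid <- session[[nm]]
    write.csv(data.frame(index = seq_along(fid$samples) - 1L,
                         real = Re(fid$samples), imag = Im(fid$samples)),
              file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
    meta <- list(condition = fid$condition, tau = fid$tau,
                 subject_id = fid$subject_id,
                 session_label = fid$session_label,
                 acquisition = unclass(fid$acquisition))
    jsonlite::write_json(meta, file.path(dir, paste0(nm, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a session bundle written by [write_session_bundle()]
#'
#' @param dir Bundle directory.
#' @return A named list of `fid_series`.
#' @export
read_session_bundle <- function(dir) {
  csvs <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (length(csvs) == 0) stop("no condition CSVs found in ", dir)
  session <- list()
  for (f in csvs) {
    nm <- sub("\\.csv$", "", basename(f))
    tab <- read.csv(f)
    if (!all(c("index", "real", "imag") %in% names(tab)))
      stop("malformed condition file (need index, real, imag): ", f)
    tab$real <- suppressWarnings(as.numeric(tab$real))
    tab$imag <- suppressWarnings(as.numeric(tab$imag))
    if (anyNA(tab$real) || anyNA(tab$imag))
      stop("non-numeric FID sample in ", basename(f), " at row ",
           which(is.na(tab$real) | is.na(tab$imag))[1])
    meta <- jsonlite::read_json(file.path(dir, paste0(nm, ".json")),
                                simplifyVector = TRUE)
    acq <- do.call(acquisition_config,
                   meta$acquisition[setdiff(names(meta$acquisition),
                                            "dwell_time")])
    session[[nm]] <- structure(list(
      samples = complex(real = tab$real, imaginary = tab$imag),
      condition = meta$condition, tau = meta$tau,
      acquisition = acq, subject_id = meta$subject_id,
      session_label = meta$session_label
    ), class = "fid_series")
  }
  session
}
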