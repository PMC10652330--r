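#' Analysis configuration
#'
#' Resolved settings for the end-to-end pipeline. Defaults encode the
#' reference analysis: 5 Hz Gaussian apodisation, automatic phasing
#' estimated on the control spectrum, whole-spectrum quartic baseline,
#' two-Lorentzian fit of the 4-6 ppm Pi window, and fixed-T1 kinetic fits
#' (3.1 s for Pi(i), 5.1 s for PCr).
#'
#' @param line_broadening Apodisation line broadening, Hz.
#' @param apod_shape `"gaussian"` or `"exponential"`.
#' @param baseline_order Whole-spectrum baseline polynomial order.
#' @param pi_window Pi fit window, ppm.
#' @param pi_baseline_order In-window baseline order for the Pi fit.
#' @param peak_shape Lineshape for peak fits.
#' @param t1_pi,t1_pcr Fixed T1 values, s.
#' @param t1_mode `"fixed"` or `"float"` (T1 floated within
#'   `t1_bounds`).
#' @param t1_bounds Bounds for floating T1, s.
#' @param auto_phase Estimate phases on the control spectrum and apply to
#'   every condition (`TRUE`), or leave spectra unphased.
#' @return A list of class `run_config`.
#' @export
run_config <- function(line_broadening = 5,
                       apod_shape = "gaussian",
                       baseline_order = 4,
                       pi_window = c(4, 6),
                       pi_baseline_order = 4,
                       peak_shape = "lorentzian",
                       t1_pi = 3.1,
                       t1_pcr = 5.1,
                       t1_mode = "fixed",
                       t1_bounds = c(1, 7),
                       auto_phase = TRUE) {
  structure(as.list(environment()), class = "run_config")
}

process_fid <- function(fid, config, phases = NULL) {
  spec <- to_spectrum(apodize(fid, config$line_broadening,
                              config$apod_shape))
  if (!is.null(phases))
    spec <- phase_correct(spec, phases$phi0, phases$phi1)
  baseline_correct(spec, config$baseline_order)
}

#' Analyse one session: spectra, fits, saturation curves, kinetics
#'
#' Runs the full single-session pipeline on a bundle of FIDs (one per
#' saturation condition plus the off-resonance control): apodisation,
#' Fourier transform, phasing (estimated once on the control), baseline
#' correction, Pi-window and PCr peak fits, normalised saturation curves
#' and fixed-T1 kinetic fits. Deterministic given the data and config.
#'
#' @param session Named list of `fid_series` (`sat_*` conditions plus
#'   `control`), as from [simulate_session()] or
#'   [read_session_bundle()].
#' @param config A [run_config()].
#' @param output_dir Optional directory; when given, processed spectra and
#'   a per-session fit table are written there.
#' @return A list of class `subject_result`: `kf_pi` and `kf_pcr`
#'   (`kinetic_fit`s), `curves`, `ph`, `delta_pi_i`, the per-condition
#'   `fit_table`, and identifying metadata.
#' @export
run_subject <- function(session, config = run_config(), output_dir = NULL) {
  is_control <- vapply(session, function(f) f$condition$type == "control",
                       logical(1))
  if (!any(is_control))
    stop("session bundle has no control condition (off-resonance ",
         "saturation); cannot normalise - add a 'control' entry")
  control_fid <- session[[which(is_control)[1]]]
  sat <- session[!is_control &
                   vapply(session, function(f)
                     f$condition$type == "saturation", logical(1))]
  if (length(sat) < 3)
    stop("need at least 3 saturation conditions, got ", length(sat))
  phases <- NULL
  if (isTRUE(config$auto_phase)) {
    ctrl_spec0 <- to_spectrum(apodize(control_fid, config$line_broadening,
                                      config$apod_shape))
    ph <- auto_phase(ctrl_spec0)
    if (!ph$flagged) phases <- ph
  }
  ctrl_spec <- process_fid(control_fid, config, phases)
  specs <- lapply(sat, process_fid, config = config, phases = phases)
  fit_one <- function(spec) {
    pw <- fit_pi_window(spec, config$pi_window, config$pi_baseline_order,
                        config$peak_shape)
    pcr <- fit_single_peak(spec, "PCr", 0, c(-1, 1), config$peak_shape,
                           config$pi_baseline_order)
    list(pi = pw, pcr = pcr)
  }
  ctrl_fits <- fit_one(ctrl_spec)
  cond_fits <- lapply(specs, fit_one)
  taus <- vapply(sat, function(f) f$tau, numeric(1))
  curve_pi <- build_saturation_curve(
    lapply(cond_fits, function(z) z$pi$pi_i),
    ctrl_fits$pi$pi_i, taus, metabolite = "Pi_i",
    window_width = diff(config$pi_window))
  curve_pcr <- build_saturation_curve(
    lapply(cond_fits, function(z) z$pcr),
    ctrl_fits$pcr, taus, metabolite = "PCr", window_width = 2)
  fitter <- function(curve, t1) {
    if (identical(config$t1_mode, "float"))
      fit_kf_float_t1(curve, config$t1_bounds)
    else fit_kf(curve, t1)
  }
  kf_pi <- fitter(curve_pi, config$t1_pi)
  kf_pcr <- fitter(curve_pcr, config$t1_pcr)
  delta_pi <- ctrl_fits$pi$pi_i$center
  ph_val <- if (!is.na(delta_pi) && delta_pi > 3.08 && delta_pi < 5.57)
    estimate_ph(delta_pi) else NA_real_
  fit_table <- do.call(rbind, lapply(seq_along(cond_fits), function(i) {
    f <- cond_fits[[i]]$pi$pi_i
    data.frame(condition = names(cond_fits)[i], tau = taus[i],
               metabolite = "Pi_i", center = f$center,
               amplitude = f$amplitude, fwhm = f$fwhm, area = f$area,
               rms = f$residual_rms, flagged = f$flagged)
  }))
  out <- structure(list(
    subject_id = control_fid$subject_id,
    session = control_fid$session_label,
    kf_pi = kf_pi, kf_pcr = kf_pcr,
    curves = list(pi = curve_pi, pcr = curve_pcr),
    ph = ph_val, delta_pi_i = delta_pi,
    fit_table = fit_table,
    config = config
  ), class = "subject_result")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    stem <- paste(out$subject_id, out$session, sep = "_")
    write_spectrum(ctrl_spec, file.path(output_dir,
                                        paste0(stem, "_control.csv")))
    write.csv(fit_table, file.path(output_dir, paste0(stem, "_fits.csv")),
              row.names = FALSE)
    write.csv(curve_pi$points,
              file.path(output_dir, paste0(stem, "_curve_pi.csv")),
              row.names = FALSE)
  }
  out
}

#' @export
print.subject_result <- function(x, ...) {
  cat(sprintf("<subject_result> %s/%s: kf(Pi) = %.3f, kf(PCr) = %.3f, pH = %.2f\n",
              x$subject_id, x$session, x$kf_pi$kf, x$kf_pcr$kf, x$ph))
  invisible(x)
}

#' Analyse a paired cohort end to end
#'
#' Runs [run_subject()] on every session of every subject, fits the
#' group-mean saturation curve per session (mean-then-fit) alongside the
#' average of individual fits, and applies the cohort statistics
#' ([run_cohort_analysis()]).
#'
#' @param subjects List of subjects, each a list with `pre` and `post`
#'   session bundles (the `subjects` element of [make_phantom_cohort()]).
#' @param config A [run_config()].
#' @param ages Optional named age vector for the age correlation.
#' @return A list of class `cohort_result`: per-session `results` table,
#'   `subject_results`, group-mean kinetic fits, mean-of-fits summaries
#'   and the `cohort_report`.
#' @export
run_cohort <- function(subjects, config = run_config(), ages = NULL) {
  if (length(subjects) < 2) stop("need at least 2 subjects")
  missing_post <- vapply(subjects,
                         function(s) is.null(s$pre) || is.null(s$post),
                         logical(1))
  if (any(missing_post))
    stop("subject(s) without paired pre/post sessions: ",
         paste(names(subjects)[missing_post], collapse = ", "))
  subject_results <- lapply(subjects, function(s)
    list(pre = run_subject(s$pre, config),
         post = run_subject(s$post, config)))
  rows <- do.call(rbind, lapply(subject_results, function(sr)
    do.call(rbind, lapply(sr, function(r)
      data.frame(subject_id = r$subject_id, session = r$session,
                 kf_pi = r$kf_pi$kf, kf_pcr = r$kf_pcr$kf, ph = r$ph,
                 stringsAsFactors = FALSE)))))
  rownames(rows) <- NULL
  group_fit <- list()
  mean_of_fits <- list()
  for (ses in c("pre", "post")) {
    curves <- lapply(subject_results, function(sr) sr[[ses]]$curves$pi)
    group_fit[[ses]] <- fit_group_mean(curves, t1_fixed = config$t1_pi)
    mean_of_fits[[ses]] <- mean(rows$kf_pi[rows$session == ses])
  }
  report <- run_cohort_analysis(rows, ages = ages)
  structure(list(
    results = rows,
    subject_results = subject_results,
    group_mean_fit = group_fit,
    mean_of_fits = mean_of_fits,
    report = report,
    config = config
  ), class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf(
    "<cohort_result> %d subjects\n  group-mean-curve kf: pre %.3f, post %.3f\n  mean of individual kf: pre %.3f, post %.3f\n",
    length(x$subject_results),
    x$group_mean_fit$pre$kf, x$group_mean_fit$post$kf,
    x$mean_of_fits$pre, x$mean_of_fits$post))
  print(x$report)
  invisible(x)
}
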