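#' Apodise a free induction decay
#'
#' Multiplies the FID by a decaying window to trade resolution for SNR.
#' The Gaussian window `exp(-(pi*lb*t)^2 / (4 ln 2))` convolves the
#' spectrum with a Gaussian of FWHM `lb` Hz; the exponential window
#' `exp(-pi*lb*t)` adds exactly `lb` Hz to every Lorentzian linewidth.
#'
#' @param fid A `fid_series`.
#' @param line_broadening Line broadening in Hz (>= 0; 0 is the identity).
#' @param shape `"gaussian"` (default) or `"exponential"`.
#' @return The apodised `fid_series`, with the step recorded in its
#'   provenance.
#' @export
apodize <- function(fid, line_broadening = 5,
                    shape = c("gaussian", "exponential")) {
  shape <- match.arg(shape)
  if (line_broadening < 0) stop("line_broadening must be nonnegative")
  if (line_broadening > 0) {
    t <- (seq_along(fid$samples) - 1) * fid$acquisition$dwell_time
    w <- switch(shape,
      gaussian = exp(-(pi * line_broadening * t)^2 / (4 * log(2))),
      exponential = exp(-pi * line_broadening * t))
    fid$samples <- fid$samples * w
  }
  fid$provenance <- c(fid$provenance,
                      list(list(step = "apodize", line_broadening = line_broadening,
                                shape = shape)))
  fid
}

#' Fourier transform a FID onto a PCr-referenced ppm axis
#'
#' Discrete Fourier transform with the carrier at 0 ppm (PCr reference) and
#' the axis in ppm decreasing left-to-right, the NMR plotting convention.
#' The first FID point is halved before the transform to suppress the
#' constant baseline offset it would otherwise contribute.
#'
#' @param fid A `fid_series`.
#' @param reference_shift_ppm Additive shift applied to the axis so that
#'   the reference resonance sits at 0 ppm (default 0: the simulator and
#'   in-vivo protocol already place the carrier on PCr).
#' @return An object of class `spectrum31p` with fields `ppm`
#'   (descending), `intensities` (complex) and `provenance`.
#' @export
to_spectrum <- function(fid, reference_shift_ppm = 0) {
  acq <- fid$acquisition
  if (is.null(acq$spectrometer_frequency))
    stop("acquisition metadata must include the spectrometer frequency")
  n <- length(fid$samples)
  x <- fid$samples
  x[1] <- x[1] / 2
  spec <- fft(x)
  shift_idx <- c((n / 2 + 1):n, 1:(n / 2))        # fftshift, n even
  spec <- spec[shift_idx]
  freq_hz <- ((-n / 2):(n / 2 - 1)) * acq$bandwidth / n
  ppm <- freq_hz / acq$spectrometer_frequency + reference_shift_ppm
  ord <- order(ppm, decreasing = TRUE)
  structure(list(
    ppm = ppm[ord],
    intensities = spec[ord],
    acquisition = acq,
    condition = fid$condition,
    tau = fid$tau,
    subject_id = fid$subject_id,
    session_label = fid$session_label,
    provenance = c(fid$provenance,
                   list(list(step = "fft",
                             reference_shift_ppm = reference_shift_ppm)))
  ), class = "spectrum31p")
}

#' @export
print.spectrum31p <- function(x, ...) {
  cat(sprintf("<spectrum31p> %d points, %.1f to %.1f ppm, %d processing steps\n",
              length(x$ppm), max(x$ppm), min(x$ppm), length(x$provenance)))
  invisible(x)
}

#' Zeroth/first-order phase correction
#'
#' Multiplies the spectrum by `exp(i (phi0 + phi1 * (ppm - pivot)))`.
#' Invertible: correcting with `(-phi0, -phi1)` undoes it exactly.
#'
#' @param spec A `spectrum31p`.
#' @param phi0 Zeroth-order phase, rad.
#' @param phi1 First-order phase, rad/ppm.
#' @param pivot Pivot for the first-order term, ppm (default 0 = PCr).
#' @return The phased spectrum.
#' @export
phase_correct <- function(spec, phi0, phi1 = 0, pivot = 0) {
  spec$intensities <- spec$intensities *
    exp(complex(imaginary = phi0 + phi1 * (spec$ppm - pivot)))
  spec$provenance <- c(spec$provenance,
                       list(list(step = "phase", phi0 = phi0, phi1 = phi1,
                                 pivot = pivot)))
  spec
}

# Phase-sensitive single-peak fit on a small window: complex Lorentzian
# (absorption + dispersion locked by a mixing angle theta) plus a complex
# linear local baseline. Returns theta with its standard error.
fit_anchor_phase <- function(spec, j, halfw = 20) {
  win <- max(1, j - halfw):min(length(spec$ppm), j + halfw)
  x <- spec$ppm[win]
  s <- spec$intensities[win]
  xc <- x - spec$ppm[j]
  model <- function(p) {
    u <- 2 * (x - p[2]) / p[3]
    lshape <- (1 - complex(imaginary = u)) / (1 + u^2)
    p[1] * lshape * exp(complex(imaginary = p[4])) +
      complex(real = p[5], imaginary = p[6]) +
      complex(real = p[7], imaginary = p[8]) * xc
  }
  resid <- function(p) { d <- s - model(p); c(Re(d), Im(d)) }
  a0 <- Mod(s[which.max(Mod(s))])
  th0 <- Arg(sum(s - mean(s[c(1, length(s))])))
  start <- c(a0, spec$ppm[j], 0.3, th0, 0, 0, 0, 0)
  fit <- tryCatch(
    minpack.lm::nls.lm(start, fn = resid,
                       lower = c(0, min(x), 0.02, -2 * pi, rep(-Inf, 4)),
                       upper = c(Inf, max(x), 1.5, 2 * pi, rep(Inf, 4)),
                       control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) return(NULL)
  se <- tryCatch({
    s2 <- fit$deviance / max(1, 2 * length(s) - 8)
    sqrt(diag(s2 * solve(fit$hessian)))
  }, error = function(e) rep(NA_real_, 8))
  list(theta = fit$par[4], center = fit$par[2],
       area = fit$par[1] * fit$par[3], theta_se = se[4],
       amplitude = fit$par[1])
}

# Isolated anchor peaks for phasing: local maxima of the magnitude
# spectrum above the noise, separated by at least min_sep ppm (strongest
# kept in each cluster).
find_anchor_peaks <- function(spec, min_sep = 1.2, max_anchors = 6) {
  mag <- Mod(spec$intensities)
  n <- length(mag)
  edge <- c(head(mag, max(4, n %/% 20)), mag[seq(n - max(4, n %/% 20), n)])
  noise <- stats::mad(edge)
  thr <- median(mag) + 6 * (noise + .Machine$double.eps)
  loc <- which(mag > thr)
  loc <- loc[loc > 1 & loc < n]
  loc <- loc[mag[loc] >= mag[loc - 1] & mag[loc] >= mag[loc + 1]]
  if (length(loc) == 0) return(integer(0))
  loc <- loc[order(-mag[loc])]
  keep <- integer(0)
  for (j in loc) {
    if (all(abs(spec$ppm[j] - spec$ppm[keep]) >= min_sep))
      keep <- c(keep, j)
    if (length(keep) >= max_anchors) break
  }
  sort(keep)
}

#' Automatic phasing
#'
#' Automated stand-in for interactive phasing. Isolated peaks of the
#' magnitude spectrum are fitted with a phase-sensitive complex Lorentzian
#' (absorption/dispersion mixing angle theta plus a complex linear local
#' baseline); the per-peak phases are then regressed on chemical shift,
#' `theta(ppm) = phi0_err + phi1_err * ppm`, by weighted least squares
#' with one outlier-trim pass, and the negated coefficients are returned
#' as the correction. Applying the returned phases therefore maximises
#' the absorption-mode (real-part) content of the peak regions.
#'
#' @param spec A `spectrum31p` containing at least one peak above the
#'   noise; pure-noise input is flagged rather than phased.
#' @param min_sep Minimum anchor-peak separation, ppm.
#' @return List with `phi0` (rad), `phi1` (rad/ppm; apply via
#'   [phase_correct()] with pivot 0) and `flagged` (TRUE when no
#'   resolvable peak was found or all anchor fits failed; phases are then
#'   0).
#' @export
auto_phase <- function(spec, min_sep = 1.2) {
  anchors <- find_anchor_peaks(spec, min_sep)
  if (length(anchors) == 0)
    return(list(phi0 = 0, phi1 = 0, flagged = TRUE))
  fits <- Filter(Negate(is.null),
                 lapply(anchors, function(j) fit_anchor_phase(spec, j)))
  if (length(fits) == 0)
    return(list(phi0 = 0, phi1 = 0, flagged = TRUE))
  th <- vapply(fits, `[[`, numeric(1), "theta")
  x <- vapply(fits, `[[`, numeric(1), "center")
  se <- vapply(fits, `[[`, numeric(1), "theta_se")
  area <- vapply(fits, `[[`, numeric(1), "area")
  w <- ifelse(is.finite(se) & se > 0, 1 / se^2, 0)
  if (all(w == 0)) w <- abs(area)
  # unwrap relative to the best-determined anchor
  dom <- which.max(w)
  th <- th[dom] + atan2(sin(th - th[dom]), cos(th - th[dom]))
  coef_fit <- function(idx) {
    if (length(idx) == 1) c(th[idx], 0)
    else unname(coef(lm(th[idx] ~ x[idx], weights = w[idx])))
  }
  cf <- coef_fit(seq_along(th))
  if (length(th) > 2) {   # trim the single worst anchor if it is far off
    res <- abs(th - (cf[1] + cf[2] * x))
    worst <- which.max(res * sqrt(w))
    if (res[worst] > 0.2) cf <- coef_fit(seq_along(th)[-worst])
  }
  list(phi0 = -atan2(sin(cf[1]), cos(cf[1])), phi1 = -cf[2],
       flagged = FALSE)
}

#' Default baseline exclusion windows
#'
#' Closed ppm intervals of half-width `half` around each assigned 31P
#' resonance, protecting the peaks while the whole-spectrum baseline
#' polynomial is fitted.
#'
#' @param shifts Peak positions, ppm.
#' @param half Half-width, ppm.
#' @return A list of `c(low, high)` ppm intervals.
#' @export
default_exclusion_windows <- function(shifts = default_peak_table()$shift_ppm,
                                      half = 0.5) {
  lapply(shifts, function(s) c(s - half, s + half))
}

#' Polynomial baseline correction
#'
#' Fits a polynomial of the given order to the real channel by least
#' squares over all points outside the exclusion windows, and subtracts it
#' across the full axis. Order 0 subtracts the mean of the non-excluded
#' points.
#'
#' @param spec A phased `spectrum31p`.
#' @param order Polynomial order (>= 0; default 4, the quartic used for
#'   broad phospholipid baselines).
#' @param exclude List of `c(low, high)` ppm windows to leave out of the
#'   fit (typically around the metabolite peaks).
#' @return The corrected spectrum; the fitted coefficients (in the
#'   orthogonal-polynomial basis used internally, plus the evaluated
#'   baseline) are appended to the provenance and returned as the
#'   `baseline` attribute.
#' @export
baseline_correct <- function(spec, order = 4,
                             exclude = default_exclusion_windows()) {
  stopifnot(order >= 0)
  keep <- rep(TRUE, length(spec$ppm))
  for (w in exclude)
    keep[spec$ppm >= min(w) & spec$ppm <= max(w)] <- FALSE
  if (sum(keep) <= order + 1)
    stop("exclusion windows leave too few points to fit the baseline")
  x <- spec$ppm
  y <- Re(spec$intensities)
  if (order == 0) {
    base <- rep(mean(y[keep]), length(y))
    coefs <- mean(y[keep])
  } else {
    fit <- lm(y ~ poly(x, order, raw = TRUE), subset = keep)
    base <- drop(cbind(1, outer(x, seq_len(order), `^`)) %*% coef(fit))
    coefs <- unname(coef(fit))
  }
  spec$intensities <- complex(real = y - base, imaginary = Im(spec$intensities))
  spec$provenance <- c(spec$provenance,
                       list(list(step = "baseline", order = order,
                                 coefficients = coefs)))
  attr(spec, "baseline") <- base
  spec
}

#' Replay a recorded processing chain on a raw FID
#'
#' Applies the provenance steps recorded in a processed spectrum to a raw
#' `fid_series`, reproducing the spectrum exactly. Useful for auditing and
#' for verifying that provenance is complete.
#'
#' @param fid The raw `fid_series`.
#' @param provenance A provenance list from a processed `spectrum31p`.
#' @return The reprocessed `spectrum31p`.
#' @export
replay_provenance <- function(fid, provenance) {
  obj <- fid
  for (p in provenance) {
    obj <- switch(p$step,
      apodize = apodize(obj, p$line_broadening, p$shape),
      fft = to_spectrum(obj, p$reference_shift_ppm),
      phase = phase_correct(obj, p$phi0, p$phi1, p$pivot),
      baseline = baseline_correct(obj, p$order,
                                  exclude = attr(provenance, "exclude") %||%
                                    default_exclusion_windows()),
      stop("unknown provenance step: ", p$step))
  }
  obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a processed spectrum as CSV plus JSON provenance
#'
#' @param spec A `spectrum31p`.
#' @param path Output CSV path; the provenance sidecar takes the same stem
#'   with a `.json` extension.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  write.csv(data.frame(ppm = spec$ppm, real = Re(spec$intensities),
                       imag = Im(spec$intensities)),
            path, row.names = FALSE)
  jsonlite::write_json(spec$provenance,
                       sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
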