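# Shared fixtures: small synthetic objects built in code at test time.

default_acq <- acquisition_config()

# A bare spectrum object on a ppm axis, for unit tests that do not need a
# full FID round trip.
make_spectrum <- function(ppm, intensities) {
  structure(list(ppm = ppm, intensities = as.complex(intensities),
                 acquisition = default_acq, provenance = list()),
            class = "spectrum31p")
}

# Ideal real-valued spectrum: sum of analytic lineshapes plus polynomial
# baseline on a descending ppm axis.
ideal_spectrum <- function(peaks, ppm = seq(8, -20, length.out = 1200),
                           baseline = function(x) 0 * x) {
  y <- baseline(ppm)
  for (k in seq_len(nrow(peaks)))
    y <- y + peak_shape(ppm, peaks$amplitude[k], peaks$center[k],
                        peaks$fwhm[k], peaks$shape[k])
  make_spectrum(ppm, y)
}

# Noiseless session with known Pi exchange rate (cached per rate).
noiseless_session <- local({
  cache <- list()
  function(kf = 0.25) {
    key <- format(kf)
    if (is.null(cache[[key]])) {
      tr <- ground_truth(kf_pi = kf, noise_sd = 0)
      cache[[key]] <<- simulate_session(tr, default_acq)
    }
    cache[[key]]
  }
})

# Saturation curve straight from the closed-form decay (area noise sigma).
synthetic_curve <- function(kf, t1 = 3.1, s0 = 1,
                            taus = saturation_times(default_acq),
                            sigma = 0) {
  v <- s0 * decay_fraction(kf, t1, taus)
  if (sigma > 0) v <- v + rnorm(length(taus), 0, sigma)
  data.frame(tau = taus, value = v, error = rep(max(sigma, 1e-6),
                                                length(taus)))
}

# Single uniform slab head-model row for transport tests.
slab_model <- function(mua, mus, g = 0, n = 1, d = Inf, cco = 0) {
  data.frame(layer = "grey_matter", thickness_cm = d, mua = mua, mus = mus,
             g = g, n = n, cco_mua_fraction = cco, wavelength_nm = 670)
}
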