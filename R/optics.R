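#' Load the chromophore absorption library
#'
#' Reads a table of specific absorption spectra (per cm at the reference
#' composition of each chromophore) on a strictly increasing wavelength
#' grid. The shipped table covers 450-1100 nm for melanin (melanosome
#' power law), oxy-/deoxyhaemoglobin (whole blood at 150 g/L), pure water,
#' and an effective cytochrome-c/CCO spectrum at a reference grey-matter
#' concentration (haem band near 695 nm, broad copper band near 830 nm).
#' Values are compiled approximations with literature-shaped spectra,
#' intended for tolerance-level dosimetry, not radiometric calibration.
#'
#' @param path CSV path; default the table shipped with the package.
#' @return Data frame with `wavelength_nm` plus one column per chromophore.
#' @export
load_chromophores <- function(path = system.file("extdata",
                                                 "chromophores.csv",
                                                 package = "mtmrs")) {
  tab <- read.csv(path)
  if (names(tab)[1] != "wavelength_nm" || any(diff(tab$wavelength_nm) <= 0))
    stop("chromophore table needs a strictly increasing wavelength_nm column")
  if (any(tab[-1] < 0)) stop("chromophore absorptions must be nonnegative")
  tab
}

#' Load the layered head-model table
#'
#' Each row is one tissue layer, top to bottom: geometric thickness (cm;
#' empty = semi-infinite terminal layer), refractive index `n`, scattering
#' anisotropy `g`, reduced scattering at 500 nm `musp500` (1/cm) with
#' power-law exponent `mie_b` (so `musp(lambda) = musp500 *
#' (lambda/500)^-mie_b`), and the chromophore volume/concentration
#' fractions composing the absorption coefficient. The default stack is
#' epidermis (0.01 cm, melanin-bearing), dermis (0.39 cm), skull (0.7 cm),
#' CSF (0.2 cm) and semi-infinite grey matter.
#'
#' @param path CSV path; default the shipped table.
#' @return Data frame of layer specifications.
#' @export
load_tissue_table <- function(path = system.file("extdata",
                                                 "tissue_layers.csv",
                                                 package = "mtmrs")) {
  read.csv(path)
}

interp_chromophore <- function(chrom, name, wavelength) {
  rng <- range(chrom$wavelength_nm)
  if (any(wavelength < rng[1] | wavelength > rng[2]))
    stop("wavelength ", paste(wavelength, collapse = ", "),
         " nm outside the chromophore table (", rng[1], "-", rng[2],
         " nm); no extrapolation")
  stats::approx(chrom$wavelength_nm, chrom[[name]], wavelength)$y
}

#' Build the optical head model at one wavelength
#'
#' Composes each layer's absorption coefficient from the chromophore
#' library, `mua = melanin_frac*A_mel + blood_frac*(so2*A_HbO2 +
#' (1-so2)*A_Hb) + water_frac*A_water + cco_frac*A_cco`, and its
#' scattering coefficient from the reduced-scattering power law,
#' `mus = musp500*(lambda/500)^-mie_b / (1-g)`.
#'
#' @param layer_specs Data frame as from [load_tissue_table()].
#' @param chromophores Data frame as from [load_chromophores()].
#' @param wavelength Wavelength, nm (must lie inside the library grid).
#' @param melanin_fraction Optional override of the epidermal melanin
#'   volume fraction (0.04 pale to 0.43 dark skin).
#' @return Data frame of per-layer `mua`, `mus`, `g`, `n`, `thickness_cm`
#'   plus the CCO share of the total absorption (`cco_mua_fraction`).
#' @export
build_head_model <- function(layer_specs = load_tissue_table(),
                             chromophores = load_chromophores(),
                             wavelength = 670,
                             melanin_fraction = NULL) {
  if (nrow(layer_specs) < 1) stop("need at least one layer")
  ls <- layer_specs
  if (!is.null(melanin_fraction)) {
    if (melanin_fraction < 0 || melanin_fraction > 1)
      stop("melanin_fraction must lie in [0, 1]")
    ls$melanin_frac[ls$melanin_frac > 0 | ls$layer == "epidermis"] <-
      melanin_fraction
  }
  a_mel <- interp_chromophore(chromophores, "melanin", wavelength)
  a_hbo <- interp_chromophore(chromophores, "hb_oxy", wavelength)
  a_hb <- interp_chromophore(chromophores, "hb_deoxy", wavelength)
  a_wat <- interp_chromophore(chromophores, "water", wavelength)
  a_cco <- interp_chromophore(chromophores, "cco", wavelength)
  mua_cco <- ls$cco_frac * a_cco
  mua <- ls$melanin_frac * a_mel +
    ls$blood_frac * (ls$blood_so2 * a_hbo + (1 - ls$blood_so2) * a_hb) +
    ls$water_frac * a_wat + mua_cco
  musp <- ls$musp500 * (wavelength / 500)^(-ls$mie_b)
  mus <- musp / (1 - ls$g)
  data.frame(layer = ls$layer,
             thickness_cm = ifelse(is.na(ls$thickness_cm), Inf,
                                   ls$thickness_cm),
             mua = mua, mus = mus, g = ls$g, n = ls$n,
             cco_mua_fraction = ifelse(mua > 0, mua_cco / mua, 0),
             wavelength_nm = wavelength)
}

gm_index <- function(model) {
  i <- grep("grey|gm", model$layer, ignore.case = TRUE)
  if (length(i) == 0) nrow(model) else i[1]
}

#' Run the layered Monte-Carlo transport
#'
#' Pencil beam at normal incidence on the layer stack; photon packets with
#' weighted absorption, Henyey-Greenstein scattering and Fresnel
#' boundaries. Reflectance, transmittance and per-layer absorption sum to
#' unity to floating-point precision on every run (termination deposits
#' residual packet weight rather than playing roulette with it). Results
#' are reproducible given `seed`; tally standard errors (from 20 photon
#' batches) scale as `1/sqrt(n_photons)`.
#'
#' @param model Head model from [build_head_model()] (or any data frame
#'   with `mua`, `mus`, `g`, `n`, `thickness_cm`).
#' @param n_photons Number of photon packets (>= 1).
#' @param seed Integer seed.
#' @return An object of class `photon_tallies`: absorbed fraction per
#'   layer, specular and diffuse reflectance, transmittance, the fraction
#'   of launched light first reaching each layer, grey-matter summaries
#'   normalised to the light transmitted into the head (incident minus
#'   specular), and batch standard errors.
#' @export
run_mc <- function(model, n_photons = 1e5, seed = 1) {
  if (n_photons < 1) stop("n_photons must be >= 1")
  set.seed(seed)
  raw <- .mcml_run(model$mua, model$mus, model$g, model$n,
                   model$thickness_cm, as.integer(n_photons))
  gm <- gm_index(model)
  entered <- 1 - raw$specular  # light transmitted into the head
  gm_abs <- raw$absorbed[gm]
  structure(list(
    wavelength_nm = model$wavelength_nm[1],
    layers = model$layer,
    n_photons = as.integer(n_photons), seed = seed,
    specular = raw$specular,
    diffuse_reflectance = raw$diffuse_reflectance,
    transmittance = raw$transmittance,
    absorbed = setNames(raw$absorbed, model$layer),
    reached = setNames(raw$reached, model$layer),
    gm_reach_fraction = raw$reached[gm] / entered,
    gm_absorbed_fraction = gm_abs / entered,
    cco_absorbed_fraction = gm_abs * model$cco_mua_fraction[gm] / entered,
    se = raw$se
  ), class = "photon_tallies")
}

#' @export
print.photon_tallies <- function(x, ...) {
  cat(sprintf("<photon_tallies> %s nm, %d photons\n",
              format(x$wavelength_nm), x$n_photons))
  cat(sprintf("  R_spec %.4f, R_diff %.4f, T %.4f, absorbed %.4f\n",
              x$specular, x$diffuse_reflectance, x$transmittance,
              sum(x$absorbed)))
  cat(sprintf("  GM: reach %.3f%%, absorbed %.3f%%, CCO %.4f%% (of light entering head)\n",
              100 * x$gm_reach_fraction, 100 * x$gm_absorbed_fraction,
              100 * x$cco_absorbed_fraction))
  invisible(x)
}

#' Wavelength sweep of the dosimetry quantities
#'
#' Runs the transport on a wavelength grid and tabulates the grey-matter
#' reaching, grey-matter absorbed and CCO-absorbed fractions (all relative
#' to the light transmitted into the head).
#'
#' @param layer_specs,chromophores Model inputs (defaults shipped).
#' @param wavelengths Grid in nm, inside the chromophore table.
#' @param n_photons Photons per wavelength (>= 1).
#' @param seed Base seed; wavelength `i` uses `seed + i - 1`.
#' @param melanin_fraction Optional epidermal melanin override.
#' @return Data frame, one row per wavelength.
#' @export
sweep_wavelengths <- function(layer_specs = load_tissue_table(),
                              chromophores = load_chromophores(),
                              wavelengths = seq(450, 1100, by = 25),
                              n_photons = 1e5, seed = 1,
                              melanin_fraction = NULL) {
  if (n_photons < 1) stop("n_photons must be >= 1")
  rows <- lapply(seq_along(wavelengths), function(i) {
    model <- build_head_model(layer_specs, chromophores, wavelengths[i],
                              melanin_fraction)
    t <- run_mc(model, n_photons, seed + i - 1)
    gm <- gm_index(model)
    data.frame(wavelength_nm = wavelengths[i],
               gm_reach = t$gm_reach_fraction,
               gm_absorbed = t$gm_absorbed_fraction,
               cco_absorbed = t$cco_absorbed_fraction,
               gm_reach_se = t$se$reached[gm] / (1 - t$specular),
               gm_absorbed_se = t$se$absorbed[gm] / (1 - t$specular),
               diffuse_reflectance = t$diffuse_reflectance,
               transmittance = t$transmittance)
  })
  do.call(rbind, rows)
}

#' Melanin-fraction sweep at a fixed wavelength
#'
#' Varies the epidermal melanin volume fraction (pale 0.04 to dark 0.43
#' skin tones) and reports the grey-matter and CCO absorbed fractions,
#' plus the relative drop `1 - value(highest) / value(lowest melanin)`.
#'
#' @param layer_specs,chromophores Model inputs.
#' @param wavelength Wavelength, nm (default 670, the treatment light).
#' @param melanin_fractions Fractions in \[0, 1\], swept in given order.
#' @param n_photons Photons per fraction.
#' @param seed Base seed; fraction `i` uses `seed + i - 1`.
#' @return List with `table` (per-fraction dosimetry) and `cco_drop`,
#'   `gm_drop` (relative drops from the smallest to the largest fraction).
#' @export
melanin_sweep <- function(layer_specs = load_tissue_table(),
                          chromophores = load_chromophores(),
                          wavelength = 670,
                          melanin_fractions = c(0.04, 0.1, 0.2, 0.3, 0.43),
                          n_photons = 1e5, seed = 1) {
  if (any(melanin_fractions < 0 | melanin_fractions > 1))
    stop("melanin fractions must lie in [0, 1]")
  rows <- lapply(seq_along(melanin_fractions), function(i) {
    model <- build_head_model(layer_specs, chromophores, wavelength,
                              melanin_fraction = melanin_fractions[i])
    t <- run_mc(model, n_photons, seed + i - 1)
    data.frame(melanin_fraction = melanin_fractions[i],
               gm_reach = t$gm_reach_fraction,
               gm_absorbed = t$gm_absorbed_fraction,
               cco_absorbed = t$cco_absorbed_fraction)
  })
  tab <- do.call(rbind, rows)
  lo <- which.min(tab$melanin_fraction)
  hi <- which.max(tab$melanin_fraction)
  list(table = tab,
       cco_drop = 1 - tab$cco_absorbed[hi] / tab$cco_absorbed[lo],
       gm_drop = 1 - tab$gm_absorbed[hi] / tab$gm_absorbed[lo])
}
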