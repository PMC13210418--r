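#' Linear attenuation coefficient tables
#'
#' Loads one of the bundled linear attenuation tables (15--174 keV, 1 keV
#' grid). Aluminum and PMMA tables are interpolated from standard photon
#' cross-section tabulations (mass attenuation including coherent scatter)
#' at densities 2.699 and 1.18 g/cm^3; the CdTe table comes from the
#' package's synthetic parametric sensor model (piecewise power-law
#' photoelectric term with Cd/Te K-edge jumps plus a Klein--Nishina Compton
#' term) at 5.85 g/cm^3. Off-grid energies are linearly interpolated.
#'
#' @param material one of `"al"`, `"pmma"`, `"cdte"`.
#' @return an object of class `attenuation_table` with fields `material`,
#'   `energies` (keV), `mu` (1/mm) and `density` (g/cm^3).
#' @export
load_attenuation <- function(material = c("al", "pmma", "cdte")) {
  material <- match.arg(material)
  file <- switch(material,
    al = "mu_al.csv", pmma = "mu_pmma.csv", cdte = "mu_cdte_synthetic.csv")
  path <- system.file("extdata", file, package = "pcdrad", mustWork = TRUE)
  tab <- utils::read.csv(path)
  density <- switch(material, al = 2.699, pmma = 1.18, cdte = 5.85)
  structure(
    list(material = material, energies = tab$energy_keV,
         mu = tab$mu_per_mm, density = density),
    class = "attenuation_table")
}

#' Evaluate a linear attenuation coefficient
#'
#' Linear interpolation of `table` at energies `energy_kev`; the tabulated
#' value is returned exactly at grid energies. Energies outside the table
#' range are an error.
#'
#' @param table an [load_attenuation()] table.
#' @param energy_kev numeric vector of energies in keV.
#' @return attenuation in 1/mm.
#' @export
mu_at <- function(table, energy_kev) {
  stopifnot(inherits(table, "attenuation_table"))
  rng <- range(table$energies)
  if (any(energy_kev < rng[1] | energy_kev > rng[2]))
    stop("energy outside tabulated range [", rng[1], ", ", rng[2], "] keV")
  stats::approx(table$energies, table$mu, xout = energy_kev)$y
}

#' Incident x-ray spectrum
#'
#' Loads the bundled 120 kVp tungsten-anode spectrum (12 degree anode angle,
#' 2.0 mm Al inherent filtration, source-to-image distance 1000 mm; the
#' bundled shape is produced by the package's synthetic Kramers thick-target
#' model with tungsten K lines). The fluence is normalized so that the total
#' open-beam fluence per native detector pixel equals `photons_at_reference`
#' at the reference exposure (see [mas_to_photons()]). Filtration beyond the
#' inherent 2.0 mm Al may be requested and is applied by Beer--Lambert
#' attenuation through the bundled Al table.
#'
#' @param kvp tube potential in kV; only the bundled 120 is available.
#' @param al_filtration_mm total Al filtration in mm (>= 2.0).
#' @param reference_mas exposure at which the normalization holds.
#' @param photons_at_reference open-beam photons per native pixel at
#'   `reference_mas`.
#' @return an object of class `xray_spectrum` with fields `energies` (keV),
#'   `fluence` (photons per 1 keV bin per native pixel at `reference_mas`),
#'   `kvp` and `reference_mas`.
#' @export
load_spectrum <- function(kvp = 120, al_filtration_mm = 2.0,
                          reference_mas = 7.5, photons_at_reference = 1e7) {
  if (kvp != 120)
    stop("only the bundled 120 kVp spectrum is available")
  if (al_filtration_mm < 2.0)
    stop("bundled spectrum already contains 2.0 mm Al inherent filtration")
  path <- system.file("extdata", "spectrum_120kvp_synthetic.csv",
                      package = "pcdrad", mustWork = TRUE)
  tab <- utils::read.csv(path)
  fl <- tab$relative_fluence
  if (al_filtration_mm > 2.0) {
    mu_al <- mu_at(load_attenuation("al"), tab$energy_keV)
    fl <- fl * exp(-mu_al * (al_filtration_mm - 2.0))
  }
  fl <- fl / sum(fl) * photons_at_reference
  structure(
    list(energies = tab$energy_keV, fluence = fl, kvp = kvp,
         reference_mas = reference_mas),
    class = "xray_spectrum")
}

#' Polychromatic Beer--Lambert transmission
#'
#' Attenuates a spectrum through `x_al` mm of aluminum and `x_pmma` mm of
#' PMMA: `I(E) = I0(E) exp(-mu_Al(E) x_Al - mu_PMMA(E) x_PMMA)`. The energy
#' grid is unchanged.
#'
#' @param spectrum an [load_spectrum()] object.
#' @param x_al,x_pmma path lengths in mm (scalars, >= 0).
#' @param mu_al,mu_pmma optional pre-loaded attenuation tables.
#' @return the transmitted `xray_spectrum`.
#' @export
transmit <- function(spectrum, x_al, x_pmma,
                     mu_al = load_attenuation("al"),
                     mu_pmma = load_attenuation("pmma")) {
  stopifnot(inherits(spectrum, "xray_spectrum"),
            length(x_al) == 1, length(x_pmma) == 1)
  if (x_al < 0 || x_pmma < 0) stop("thicknesses must be non-negative")
  att <- exp(-mu_at(mu_al, spectrum$energies) * x_al -
               mu_at(mu_pmma, spectrum$energies) * x_pmma)
  spectrum$fluence <- spectrum$fluence * att
  spectrum
}

#' Mean energy of a spectrum
#' @param spectrum an `xray_spectrum`.
#' @return fluence-weighted mean energy in keV.
#' @export
mean_energy <- function(spectrum) {
  sum(spectrum$energies * spectrum$fluence) / sum(spectrum$fluence)
}

# Dose model: open-beam photons per native pixel are proportional to tube
# current-time product, anchored at 1e7 photons <-> 7.5 mAs.
PHOTONS_PER_MAS <- 1e7 / 7.5

#' Convert between photon fluence and tube load
#'
#' The dose scale is linear in tube current-time product, anchored so that
#' 1e7 open-beam photons per native detector pixel correspond to 7.5 mAs.
#'
#' @param n_photons open-beam photons per native pixel (> 0).
#' @return exposure in mAs.
#' @export
photons_to_mas <- function(n_photons) {
  if (any(n_photons <= 0)) stop("photon count must be positive")
  n_photons / PHOTONS_PER_MAS
}

#' @rdname photons_to_mas
#' @param mas exposure in mAs (> 0).
#' @return open-beam photons per native pixel.
#' @export
mas_to_photons <- function(mas) {
  if (any(mas <= 0)) stop("exposure must be positive")
  mas * PHOTONS_PER_MAS
}

#' @export
print.xray_spectrum <- function(x, ...) {
  cat(sprintf(
    "<xray_spectrum> %d kVp, %d energy bins [%d, %d] keV\n", x$kvp,
    length(x$energies), min(x$energies), max(x$energies)))
  cat(sprintf("  total fluence %.4g photons/pixel at %.3g mAs; mean energy %.1f keV\n",
              sum(x$fluence), x$reference_mas, mean_energy(x)))
  invisible(x)
}

#' @export
print.attenuation_table <- function(x, ...) {
  cat(sprintf("<attenuation_table> %s (rho = %.3f g/cm^3), %d energies [%d, %d] keV\n",
              x$material, x$density, length(x$energies),
              min(x$energies), max(x$energies)))
  invisible(x)
}
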