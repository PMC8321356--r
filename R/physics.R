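#' X-ray tube spectrum
#'
#' A tabulated emission spectrum of an X-ray tube: relative intensity per
#' photon-energy bin. Absorption computations treat the tabulation as the
#' quadrature grid (Riemann sum on the spectrum's own grid), which matches how
#' tabulated spectra are used in practice.
#'
#' @param energies Photon energy grid in keV, strictly increasing.
#' @param intensities Nonnegative relative emission per energy bin (arbitrary
#'   units); at least one must be positive.
#' @param voltage Tube voltage in kV. No photon can exceed the tube voltage,
#'   so all `energies` must be `<= voltage`.
#' @return An object of class `dexa_spectrum`.
#' @seealso [make_spectrum()] for a parametric filtered-bremsstrahlung model,
#'   [read_spectrum_csv()] for tabulated spectra on disk.
#' @export
#' @examples
#' s <- spectrum(c(30, 50, 70), c(1, 2, 1), voltage = 90)
spectrum <- function(energies, intensities, voltage) {
  energies <- as.numeric(energies)
  intensities <- as.numeric(intensities)
  if (length(energies) != length(intensities) || length(energies) < 1L)
    stop("energies and intensities must have equal length >= 1")
  if (any(!is.finite(energies)) || any(!is.finite(intensities)))
    stop("spectrum values must be finite")
  if (is.unsorted(energies, strictly = TRUE))
    stop("energies must be strictly increasing")
  if (any(intensities < 0))
    stop("intensities must be nonnegative")
  if (all(intensities == 0))
    stop("invalid spectrum: all intensities are zero")
  if (any(energies > voltage + 1e-9))
    stop("no emission above the tube voltage: energies must be <= voltage")
  structure(
    list(energies = energies, intensities = intensities,
         voltage = as.numeric(voltage)),
    class = "dexa_spectrum"
  )
}

#' @export
print.dexa_spectrum <- function(x, ...) {
  cat(sprintf("<dexa_spectrum> %d bins, %.1f-%.1f keV, tube voltage %g kV\n",
              length(x$energies), min(x$energies), max(x$energies), x$voltage))
  cat(sprintf("  mean energy %.2f keV\n", mean_energy(x)))
  invisible(x)
}

#' Intensity-weighted mean photon energy of a spectrum (keV)
#' @param spec A [spectrum()].
#' @export
mean_energy <- function(spec) {
  stopifnot(inherits(spec, "dexa_spectrum"))
  sum(spec$energies * spec$intensities) / sum(spec$intensities)
}

#' Linear attenuation curve of a material
#'
#' @param energies Photon energy grid, keV.
#' @param mu Linear attenuation coefficient at each energy, 1/cm; must be
#'   positive. For K-edge-free materials over the diagnostic range the curve
#'   is monotonically decreasing.
#' @param material Material label.
#' @return An object of class `dexa_attenuation`.
#' @export
attenuation_curve <- function(energies, mu, material = "unknown") {
  energies <- as.numeric(energies)
  mu <- as.numeric(mu)
  if (length(energies) != length(mu) || length(energies) < 2L)
    stop("energies and mu must have equal length >= 2")
  if (is.unsorted(energies, strictly = TRUE))
    stop("energies must be strictly increasing")
  if (any(mu <= 0)) stop("mu must be positive everywhere")
  structure(
    list(material = as.character(material), energies = energies, mu = mu),
    class = "dexa_attenuation"
  )
}

#' @export
print.dexa_attenuation <- function(x, ...) {
  cat(sprintf("<dexa_attenuation> %s: %d points, %.1f-%.1f keV\n",
              x$material, length(x$energies), min(x$energies), max(x$energies)))
  invisible(x)
}

#' Interpolate an attenuation curve at given energies
#'
#' Log-log linear interpolation (attenuation coefficients of K-edge-free
#' materials are near-linear in log-log coordinates). Energies outside the
#' tabulated range are an error: extrapolating attenuation data is unsafe.
#'
#' @param curve An [attenuation_curve()].
#' @param energies Energies (keV) at which to evaluate.
#' @return Vector of linear attenuation coefficients, 1/cm.
#' @export
mu_at <- function(curve, energies) {
  stopifnot(inherits(curve, "dexa_attenuation"))
  rng <- range(curve$energies)
  if (any(energies < rng[1] - 1e-9) || any(energies > rng[2] + 1e-9))
    stop(sprintf(
      "energy range error: requested %.3g-%.3g keV outside curve '%s' range %.3g-%.3g keV",
      min(energies), max(energies), curve$material, rng[1], rng[2]))
  exp(stats::approx(log(curve$energies), log(curve$mu), xout = log(energies),
                    rule = 1)$y)
}

#' Ordered stack of material layers along a ray
#'
#' @param curves A single [attenuation_curve()] or a list of them.
#' @param thicknesses Layer thicknesses in cm, nonnegative, one per curve.
#' @return An object of class `dexa_stack`.
#' @export
material_stack <- function(curves, thicknesses) {
  if (inherits(curves, "dexa_attenuation")) curves <- list(curves)
  if (!all(vapply(curves, inherits, logical(1), "dexa_attenuation")))
    stop("curves must be attenuation_curve objects")
  thicknesses <- as.numeric(thicknesses)
  if (length(thicknesses) != length(curves))
    stop("one thickness per curve required")
  if (any(thicknesses < 0)) stop("thicknesses must be >= 0")
  structure(list(curves = curves, thicknesses = thicknesses),
            class = "dexa_stack")
}

# Transmitted fraction sum(w * exp(-sum_m mu_m * L_m)) on the spectrum grid.
# thickness_matrix: one column per material, one row per evaluation point.
transmitted_fraction <- function(spec, curves, thickness_matrix) {
  w <- spec$intensities / sum(spec$intensities)
  expo <- matrix(0, nrow = nrow(thickness_matrix), ncol = length(spec$energies))
  for (m in seq_along(curves)) {
    mu <- mu_at(curves[[m]], spec$energies)
    expo <- expo + outer(thickness_matrix[, m], mu)
  }
  as.numeric(exp(-expo) %*% w)
}

#' Polychromatic absorption rate of a material stack
#'
#' Computes the absorption (attenuation) rate
#' \deqn{M = -\ln \frac{\sum_E I(E)\, e^{-\sum_m \kappa_m(E) L_m}}{\sum_E I(E)}}
#' by a Riemann sum on the spectrum's own energy grid. For a monochromatic
#' (single-line) spectrum this reduces exactly to \eqn{\kappa(E_0) L}; for a
#' polychromatic beam the rate grows sublinearly with thickness (beam
#' hardening).
#'
#' @param spec A [spectrum()].
#' @param stack A [material_stack()], or an [attenuation_curve()] combined
#'   with `thickness`.
#' @param thickness Thickness in cm when `stack` is a single curve.
#' @return Dimensionless absorption rate, `>= 0`; `0` at zero thickness.
#' @export
#' @examples
#' mus <- muscle_attenuation()
#' sp <- make_spectrum(90)
#' absorption_rate(sp, mus, thickness = 3)
absorption_rate <- function(spec, stack, thickness = NULL) {
  stopifnot(inherits(spec, "dexa_spectrum"))
  if (inherits(stack, "dexa_attenuation")) {
    if (is.null(thickness)) stop("thickness required with a single curve")
    stack <- material_stack(stack, thickness)
  }
  stopifnot(inherits(stack, "dexa_stack"))
  tf <- transmitted_fraction(spec, stack$curves,
                             matrix(stack$thicknesses, nrow = 1))
  -log(tf)
}

#' Effective attenuation coefficient of a material under a spectrum
#'
#' First-order (thin-object) approximation: the intensity-weighted mean of the
#' attenuation curve over the spectrum. `absorption_rate(L)/L` converges to
#' this value as `L -> 0`.
#'
#' @inheritParams absorption_rate
#' @param curve An [attenuation_curve()].
#' @return Effective linear attenuation coefficient, 1/cm.
#' @export
effective_attenuation <- function(spec, curve) {
  stopifnot(inherits(spec, "dexa_spectrum"), inherits(curve, "dexa_attenuation"))
  w <- spec$intensities / sum(spec$intensities)
  sum(w * mu_at(curve, spec$energies))
}

#' Dual-energy absorption ratio as a function of thickness
#'
#' Evaluates `M1(L)/M2(L)` for a homogeneous slab of one material under two
#' spectra. For two monochromatic beams the ratio is the constant
#' `mu(E1)/mu(E2)`; for polychromatic beams it drifts with thickness — the
#' beam-hardening effect the thickness-correction stage removes from data.
#'
#' @param spec1,spec2 Low- and high-voltage [spectrum()] objects.
#' @param curve An [attenuation_curve()].
#' @param thicknesses Strictly positive thicknesses, cm (the ratio is 0/0 at
#'   `L = 0`).
#' @return Numeric vector of ratios, one per thickness.
#' @export
ratio_curve <- function(spec1, spec2, curve, thicknesses) {
  thicknesses <- as.numeric(thicknesses)
  if (any(thicknesses <= 0)) stop("thicknesses must be > 0 (ratio undefined at L = 0)")
  tm <- matrix(thicknesses, ncol = 1)
  m1 <- -log(transmitted_fraction(spec1, list(curve), tm))
  m2 <- -log(transmitted_fraction(spec2, list(curve), tm))
  m1 / m2
}

#' Parametric filtered-bremsstrahlung tube spectrum
#'
#' Kramers-type bremsstrahlung model, intensity proportional to
#' `(V - E) / E`, hardened by an aluminum filter of the given thickness, and
#' tabulated on a uniform energy grid from `cutoff_kev` to the tube voltage.
#' Characteristic tungsten lines and detector response are not modeled; the
#' dual-energy method only requires two spectra with different mean energies.
#'
#' @param voltage Tube voltage in kV, within \[20, 150\].
#' @param filtration_mm_al Aluminum filtration in mm (default 2.5, a typical
#'   total filtration for an industrial tube).
#' @param grid_step Energy grid step, keV.
#' @param cutoff_kev Low-energy cutoff, keV (photons below are absorbed in the
#'   tube window; also keeps the `1/E` factor bounded).
#' @return A [spectrum()] normalized to unit total intensity.
#' @export
#' @examples
#' lo <- make_spectrum(40)
#' hi <- make_spectrum(90)
#' mean_energy(hi) > mean_energy(lo)
make_spectrum <- function(voltage, filtration_mm_al = 2.5, grid_step = 1,
                          cutoff_kev = 10) {
  if (voltage < 20 || voltage > 150)
    stop("voltage out of range [20, 150] kV")
  if (grid_step <= 0) stop("grid_step must be > 0")
  energies <- seq(cutoff_kev, voltage, by = grid_step)
  if (energies[length(energies)] < voltage - 1e-9)
    energies <- c(energies, voltage)
  intens <- pmax(voltage - energies, 0) / energies
  if (filtration_mm_al > 0) {
    al <- aluminum_attenuation()
    intens <- intens * exp(-mu_at(al, energies) * filtration_mm_al / 10)
  }
  keep <- intens > 0
  # drop the zero-intensity endpoint at E = V but keep at least 1 bin
  if (!any(keep)) stop("degenerate spectrum")
  spectrum(energies[keep], intens[keep] / sum(intens[keep]), voltage)
}

#' Read a tabulated series from a two-column CSV
#'
#' Expects a header row and two columns: energy in keV and the value
#' (intensity or attenuation coefficient).
#'
#' @param path CSV file path.
#' @param voltage Tube voltage in kV for the resulting [spectrum()].
#' @return `read_spectrum_csv()`: a [spectrum()]; `read_attenuation_csv()`:
#'   an [attenuation_curve()].
#' @export
read_spectrum_csv <- function(path, voltage) {
  d <- utils::read.csv(path)
  if (ncol(d) < 2) stop("expected two columns (energy_keV, value)")
  spectrum(d[[1]], d[[2]], voltage)
}

#' @rdname read_spectrum_csv
#' @param material Material label for the curve (defaults to the file name).
#' @export
read_attenuation_csv <- function(path, material = NULL) {
  d <- utils::read.csv(path)
  if (ncol(d) < 2) stop("expected two columns (energy_keV, value)")
  if (is.null(material))
    material <- sub("\\.csv$", "", basename(path))
  attenuation_curve(d[[1]], d[[2]], material)
}

shipped_curve <- function(file, material) {
  read_attenuation_csv(
    system.file("extdata", file, package = "dexafod", mustWork = TRUE),
    material = material)
}

#' Packaged attenuation curves
#'
#' Coarse tabulated linear attenuation coefficients (10-150 keV) for skeletal
#' muscle (ICRU-44 composition, density 1.05 g/cm3), cortical bone (density
#' 1.92 g/cm3) and aluminum (density 2.699 g/cm3), interpolated log-log.
#' Coarse public-constant tables are sufficient here: the detection method is
#' driven by the qualitative low/high-energy contrast between meat and bone,
#' not by absolute attenuation accuracy.
#'
#' @return An [attenuation_curve()].
#' @export
muscle_attenuation <- function() {
  shipped_curve("attenuation_muscle_icru44.csv", "skeletal muscle (ICRU-44)")
}

#' @rdname muscle_attenuation
#' @export
bone_attenuation <- function() {
  shipped_curve("attenuation_bone_cortical.csv", "cortical bone")
}

#' @rdname muscle_attenuation
#' @export
aluminum_attenuation <- function() {
  shipped_curve("attenuation_aluminum.csv", "aluminum")
}
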