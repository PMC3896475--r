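#' Physical constants of a measured ion
#'
#' Bundles the diffusion coefficient, valence and nominal bath concentration
#' of an ion measured by an ion-selective microelectrode. Constants for the
#' two ions supported out of the box are built in: K+ (D = 1.92e-5 cm2/s,
#' bath 3.4 mM) and Na+ (D = 1.55e-5 cm2/s, bath 20 mM, the
#' NMDG-substituted saline used to improve signal:noise during Na+ scans).
#'
#' Bath concentrations are in mmol/L, numerically identical to umol/cm3 —
#' the unit identity the flux calculation relies on.
#'
#' @param name Ion identifier, e.g. `"K"` or `"Na"`.
#' @param diffusion_coefficient Free-solution diffusion coefficient in
#'   cm2 s-1. Defaults to the built-in value for `"K"` or `"Na"`.
#' @param bath_concentration Nominal bath concentration of the ion in
#'   mmol/L. Defaults to the built-in value for `"K"` or `"Na"`.
#' @param valence Ion charge; only +1 (monovalent cations) is supported.
#' @return An object of class `ion_species`.
#' @examples
#' ion_species("K")
#' ion_species("Na")
#' @export
ion_species <- function(name, diffusion_coefficient = NULL,
                        bath_concentration = NULL, valence = 1L) {
  builtin <- list(
    K  = list(diffusion_coefficient = 1.92e-5, bath_concentration = 3.4),
    Na = list(diffusion_coefficient = 1.55e-5, bath_concentration = 20)
  )
  name <- as.character(name)[1L]
  if (is.null(diffusion_coefficient) || is.null(bath_concentration)) {
    if (!name %in% names(builtin))
      stop("no built-in constants for ion '", name,
           "'; supply diffusion_coefficient and bath_concentration",
           call. = FALSE)
    if (is.null(diffusion_coefficient))
      diffusion_coefficient <- builtin[[name]]$diffusion_coefficient
    if (is.null(bath_concentration))
      bath_concentration <- builtin[[name]]$bath_concentration
  }
  if (!identical(as.integer(valence), 1L))
    stop("only monovalent cations (valence +1) are supported", call. = FALSE)
  if (!is.finite(diffusion_coefficient) || diffusion_coefficient <= 0)
    stop("diffusion_coefficient must be positive", call. = FALSE)
  if (!is.finite(bath_concentration) || bath_concentration <= 0)
    stop("bath_concentration must be positive", call. = FALSE)
  structure(
    list(name = name, valence = 1L,
         diffusion_coefficient = diffusion_coefficient,
         bath_concentration = bath_concentration),
    class = "ion_species")
}

#' @export
print.ion_species <- function(x, ...) {
  cat(sprintf("<ion_species> %s+ : D = %.3g cm2/s, bath = %g mM\n",
              x$name, x$diffusion_coefficient, x$bath_concentration))
  invisible(x)
}

#' Fit the Nernst slope from a two-point calibration
#'
#' The slope of an ion-selective microelectrode is the voltage change per
#' tenfold change in ion concentration. With two calibration solutions it is
#' the voltage difference divided by the decade span; when the two solutions
#' span exactly one decade (the usual 15 mM / 150 mM pair) the slope equals
#' the raw voltage difference.
#'
#' @param low_concentration,high_concentration Calibration concentrations in
#'   mmol/L; must be positive and distinct.
#' @param low_voltage,high_voltage Electrode voltages in uV recorded in the
#'   corresponding solutions.
#' @return Slope in uV per decade (positive for a working cation electrode).
#' @examples
#' fit_slope(15, -65600, 150, -10000) # one-decade span: 55600 uV/decade
#' @export
fit_slope <- function(low_concentration, low_voltage,
                      high_concentration, high_voltage) {
  if (!all(is.finite(c(low_concentration, high_concentration))) ||
      low_concentration <= 0 || high_concentration <= 0)
    stop("invalid calibration: concentrations must be positive", call. = FALSE)
  if (low_concentration == high_concentration)
    stop("invalid calibration: calibration concentrations must be distinct",
         call. = FALSE)
  (high_voltage - low_voltage) /
    log10(high_concentration / low_concentration)
}

#' Build an electrode calibration
#'
#' Constructs the voltage-to-concentration mapping of an ion-selective
#' microelectrode from calibration points. Two points give the standard
#' two-point slope; three or more are reduced to a least-squares fit of
#' voltage against log10 concentration. The point at the highest
#' concentration anchors the absolute mapping.
#'
#' Concentrations stand in for activities throughout: the calibration and
#' experimental salines are of similar ionic strength, so the activity
#' coefficients cancel. No activity-coefficient parameter exists anywhere in
#' the package.
#'
#' @param ion An [ion_species()].
#' @param concentrations Calibration concentrations in mmol/L (length >= 2).
#' @param voltages Matching electrode voltages in uV.
#' @return An object of class `electrode_calibration` with elements `ion`,
#'   `low_concentration`, `high_concentration`, `low_voltage`,
#'   `high_voltage`, `slope` (uV/decade) and `n_points`.
#' @examples
#' cal <- electrode_calibration(ion_species("K"), c(15, 150), c(-55600, 0))
#' cal$slope
#' @export
electrode_calibration <- function(ion, concentrations, voltages) {
  stopifnot(inherits(ion, "ion_species"))
  if (length(concentrations) != length(voltages) || length(concentrations) < 2)
    stop("invalid calibration: need >= 2 (concentration, voltage) pairs",
         call. = FALSE)
  if (any(!is.finite(concentrations)) || any(concentrations <= 0))
    stop("invalid calibration: concentrations must be positive", call. = FALSE)
  if (anyDuplicated(concentrations))
    stop("invalid calibration: calibration concentrations must be distinct",
         call. = FALSE)
  o <- order(concentrations)
  concentrations <- concentrations[o]
  voltages <- voltages[o]
  n <- length(concentrations)
  if (n == 2L) {
    slope <- fit_slope(concentrations[1], voltages[1],
                       concentrations[2], voltages[2])
    v_low <- voltages[1]
    v_high <- voltages[2]
  } else {
    fit <- stats::lm(voltages ~ log10(concentrations))
    slope <- unname(stats::coef(fit)[2])
    pred <- unname(stats::predict(
      fit, data.frame(concentrations = range(concentrations))))
    v_low <- pred[1]
    v_high <- pred[2]
  }
  structure(
    list(ion = ion,
         low_concentration = concentrations[1],
         high_concentration = concentrations[n],
         low_voltage = v_low, high_voltage = v_high,
         slope = slope, n_points = n),
    class = "electrode_calibration")
}

#' @export
print.electrode_calibration <- function(x, ...) {
  cat(sprintf(
    "<electrode_calibration> %s+ electrode: slope %.1f uV/decade (%d points, %g-%g mM)\n",
    x$ion$name, x$slope, x$n_points, x$low_concentration,
    x$high_concentration))
  invisible(x)
}

#' Selectivity profile of an ion-selective electrode
#'
#' Ionophore cocktails reject interfering ions imperfectly. Selectivity is
#' stored as log10 of the Nicolsky-Eisenman selectivity coefficient per
#' interferent: log10 k = -3.9 means the electrode responds to the
#' interferent 10^3.9-fold more weakly than to its primary ion. Absent
#' interferents are treated as perfectly rejected (k = 0).
#'
#' @param primary Primary-ion identifier.
#' @param log10_k Named numeric vector of log10 selectivity coefficients,
#'   one entry per interfering ion (negative = good rejection).
#' @return An object of class `selectivity_profile`.
#' @seealso [default_selectivity()]
#' @export
selectivity_profile <- function(primary, log10_k = numeric()) {
  if (length(log10_k) &&
      (is.null(names(log10_k)) || any(!nzchar(names(log10_k)))))
    stop("log10_k must be a named vector of interfering ions", call. = FALSE)
  if (any(!is.finite(log10_k)))
    stop("log10_k entries must be finite", call. = FALSE)
  structure(list(primary = as.character(primary)[1L],
                 log10_k = log10_k),
            class = "selectivity_profile")
}

#' Default selectivity profiles for the K+ and Na+ cocktails
#'
#' The K+ ionophore (cocktail B) prefers K+ over Na+, Ca2+ and Mg2+ by
#' factors of 10^3.9, 10^4.9 and 10^4.9. For the Na+ cocktail only the
#' selectivity of a closely related formulation is available
#' (10^2.6 over K+, 10^3.5 over Ca2+, 10^3.7 over Mg2+); those figures are a
#' documented stand-in, not a measured property of the exact cocktail.
#'
#' @param ion `"K"` or `"Na"`.
#' @return A [selectivity_profile()].
#' @export
default_selectivity <- function(ion) {
  switch(as.character(ion)[1L],
    K  = selectivity_profile("K",  c(Na = -3.9, Ca = -4.9, Mg = -4.9)),
    Na = selectivity_profile("Na", c(K = -2.6, Ca = -3.5, Mg = -3.7)),
    stop("no default selectivity for ion '", ion, "'", call. = FALSE))
}

#' Forward electrode response (Nicolsky-Eisenman)
#'
#' Voltage an ion-selective electrode reads in a mixed solution:
#' `V = V_high + S * log10(C_eff / C_high)` with effective concentration
#' `C_eff = C_primary + sum_j k_j C_j`, where `k_j = 10^log10_k[j]` weights
#' each interfering ion. The calibration's high point fixes the absolute
#' reference, so a pure solution at the high calibration concentration reads
#' exactly `high_voltage`. Used by the synthetic generator; the analysis
#' direction is [voltage_to_concentration()].
#'
#' @param concentrations Named numeric vector (or list) of concentrations in
#'   mmol/L, keyed by ion name; must include the calibration's primary ion.
#'   The primary entry may be a vector (interferents are recycled).
#' @param calibration An [electrode_calibration()].
#' @param selectivity Optional [selectivity_profile()]; interferents without
#'   an entry are perfectly rejected.
#' @return Voltage(s) in uV.
#' @examples
#' cal <- electrode_calibration(ion_species("K"), c(15, 150), c(-55600, 0))
#' electrode_voltage(c(K = 150), cal)  # exactly the high-point voltage
#' @export
electrode_voltage <- function(concentrations, calibration,
                              selectivity = NULL) {
  stopifnot(inherits(calibration, "electrode_calibration"))
  if (is.list(concentrations)) concentrations <- unlist(concentrations)
  primary <- calibration$ion$name
  if (!primary %in% names(concentrations))
    stop("concentrations must include the primary ion '", primary, "'",
         call. = FALSE)
  c_primary <- concentrations[names(concentrations) == primary]
  if (any(c_primary <= 0))
    stop("primary-ion concentration must be positive", call. = FALSE)
  eff <- unname(c_primary)
  if (!is.null(selectivity)) {
    stopifnot(inherits(selectivity, "selectivity_profile"))
    for (j in setdiff(names(concentrations), primary)) {
      kj <- selectivity$log10_k[j]
      if (!is.na(kj)) eff <- eff + 10^unname(kj) * unname(concentrations[j])
    }
  }
  if (any(eff <= 0))
    stop("effective concentration must be positive", call. = FALSE)
  calibration$high_voltage +
    calibration$slope * log10(eff / calibration$high_concentration)
}

#' Convert electrode voltage to concentration
#'
#' Inverts the calibration curve: `C = C_high * 10^((V - V_high) / S)`.
#' Strictly monotone increasing in voltage for a positive (cation) slope.
#' Interfering ions are not — and cannot be — separated out here: in their
#' presence the result overestimates the primary concentration by exactly
#' `sum_j k_j C_j`.
#'
#' @param voltage Voltage(s) in uV.
#' @param calibration An [electrode_calibration()] with nonzero slope.
#' @return Concentration(s) in mmol/L.
#' @examples
#' cal <- electrode_calibration(ion_species("K"), c(15, 150), c(-55600, 0))
#' voltage_to_concentration(0, cal)       # 150
#' voltage_to_concentration(-55600, cal)  # 15
#' @export
voltage_to_concentration <- function(voltage, calibration) {
  stopifnot(inherits(calibration, "electrode_calibration"))
  if (!is.finite(calibration$slope) || calibration$slope == 0)
    stop("invalid calibration: slope is zero or not finite", call. = FALSE)
  calibration$high_concentration *
    10^((voltage - calibration$high_voltage) / calibration$slope)
}
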