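#' Mean voltage gradient of one recording
#'
#' Each move-wait-sample cycle yields one gradient `V_inner - V_outer`; a
#' recording's gradient is the grand mean over all cycles of all its
#' measurements (or the median, for scans disturbed by peristaltic
#' contractions). With the subtraction in this order a cation source at the
#' tissue surface gives a positive gradient.
#'
#' @param samples Sample rows of one recording (see [scan_dataset()]).
#' @param aggregate `"mean"` (default) or `"median"` over cycle gradients.
#' @return Gradient in uV.
#' @examples
#' s <- data.frame(measurement = 1, cycle = 1,
#'                 position = c("inner", "outer"), voltage_uV = c(40, 10))
#' site_gradient(s)  # 30
#' @export
site_gradient <- function(samples, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  cg <- cycle_gradients(samples)
  if (aggregate == "mean") mean(cg) else stats::median(cg)
}

# Per-cycle V_inner - V_outer, validating cycle completeness.
cycle_gradients <- function(samples) {
  key <- paste(samples$measurement, samples$cycle)
  inner <- samples$position == "inner"
  n_in <- tapply(inner, key, sum)
  n_out <- tapply(!inner, key, sum)
  if (any(n_in != 1L) || any(n_out != 1L))
    stop("malformed recording: each cycle needs exactly one inner and one ",
         "outer sample", call. = FALSE)
  v_in <- samples$voltage_uV[inner]
  v_out <- samples$voltage_uV[!inner]
  unname(v_in[order(key[inner])] - v_out[order(key[!inner])])
}

#' Reference-site voltage gradient of a preparation
#'
#' The gradient recorded far from the tissue, where epithelial flux is
#' negligible: in theory zero, in practice a drift/noise signature that is
#' subtracted from every tissue-site gradient. Multiple reference recordings
#' are averaged.
#'
#' @param dataset A [scan_dataset()].
#' @param aggregate Passed to [site_gradient()].
#' @return Gradient in uV.
#' @export
reference_gradient <- function(dataset, aggregate = c("mean", "median")) {
  stopifnot(inherits(dataset, "scan_dataset"))
  refs <- dataset$samples[dataset$samples$is_reference, , drop = FALSE]
  if (!nrow(refs))
    stop("no reference recordings in preparation '",
         dataset$preparation_id, "'", call. = FALSE)
  mean(vapply(split(refs, refs$site_id), site_gradient, numeric(1),
              aggregate = aggregate))
}

#' Reference-correct a tissue-surface gradient
#'
#' @param dv_site Tissue-surface gradient, uV.
#' @param dv_ref Reference-site gradient, uV.
#' @return `dv_site - dv_ref`, uV.
#' @examples
#' correct_gradient(36.3, -13.1)  # 49.4, the corrected control K+ gradient
#' @export
correct_gradient <- function(dv_site, dv_ref) dv_site - dv_ref

#' Background ion concentration of a scan
#'
#' `"measured"` mode converts every voltage sample in the dataset to a
#' concentration through the calibration curve and averages them (the
#' background is the average of the concentrations at all points).
#' `"nominal"` mode returns the nominal bath concentration of the scanned
#' ion instead — the right choice when the recordings lack an absolute
#' calibration anchor and only voltage differences are meaningful.
#'
#' @param dataset A [scan_dataset()].
#' @param mode `"measured"` or `"nominal"`.
#' @return Background concentration C_B in umol cm-3 (numerically mM).
#' @export
background_concentration <- function(dataset,
                                     mode = c("measured", "nominal")) {
  stopifnot(inherits(dataset, "scan_dataset"))
  mode <- match.arg(mode)
  if (mode == "nominal") return(dataset$ion$bath_concentration)
  if (!nrow(dataset$samples)) stop("empty dataset", call. = FALSE)
  mean(voltage_to_concentration(dataset$samples$voltage_uV,
                                dataset$calibration))
}

#' Convert a corrected voltage gradient to a concentration gradient
#'
#' `dC = C_B * (10^(dV / S) - 1)`: the exponential form of the calibration
#' curve applied to the corrected gradient around the background
#' concentration. Strictly increasing in `dv_corrected` for a positive
#' slope.
#'
#' @param dv_corrected Reference-corrected voltage gradient, uV.
#' @param c_b Background concentration C_B, umol cm-3.
#' @param slope Electrode slope, uV/decade.
#' @return Concentration gradient dC in umol cm-3.
#' @examples
#' concentration_gradient(49.4, 3.4, 55600)  # 6.963e-3
#' @export
concentration_gradient <- function(dv_corrected, c_b, slope) {
  if (any(!is.finite(slope)) || any(slope == 0))
    stop("invalid calibration: slope is zero or not finite", call. = FALSE)
  if (any(c_b <= 0)) stop("background concentration must be > 0",
                          call. = FALSE)
  c_b * (10^(dv_corrected / slope) - 1)
}

#' Fick's-first-law flux from a concentration gradient
#'
#' `J = D * dC / dx`, scaled from umol cm-2 s-1 to pmol cm-2 s-1. `dx` is
#' the electrode excursion in centimeters (50 um = 0.005 cm by default).
#'
#' @param dc Concentration gradient in umol cm-3.
#' @param diffusion_coefficient D in cm2 s-1.
#' @param dx_cm Excursion distance in cm.
#' @return Flux in pmol cm-2 s-1 (positive = toward the bath).
#' @examples
#' fick_flux(6.963e-3, 1.92e-5, 0.005)  # 26.7, control ileal K+
#' @export
fick_flux <- function(dc, diffusion_coefficient, dx_cm) {
  if (any(diffusion_coefficient <= 0) || any(dx_cm <= 0))
    stop("diffusion coefficient and excursion must be positive",
         call. = FALSE)
  1e6 * diffusion_coefficient * dc / dx_cm
}

#' Signal-to-noise ratio of a tissue-site gradient
#'
#' Ratio of the tissue-surface gradient magnitude to the reference-site
#' gradient magnitude: the degree of confidence that the signal reflects
#' epithelial transport rather than electrode noise or drift. Undefined
#' (`NA`) when the reference gradient is exactly zero.
#'
#' @param dv_site Tissue-surface gradient, uV.
#' @param dv_ref Reference-site gradient, uV.
#' @return Dimensionless ratio, `NA` where undefined.
#' @examples
#' signal_to_noise(-45.1, -23.1)  # ~2:1, typical of ileal Na+ scans
#' @export
signal_to_noise <- function(dv_site, dv_ref) {
  out <- abs(dv_site) / abs(dv_ref)
  out[dv_ref == 0] <- NA_real_
  out
}

#' Per-site flux estimates for one preparation
#'
#' Runs the full analysis chain on every tissue site: raw gradient,
#' reference correction, background concentration, concentration gradient,
#' Fick's-law flux, transport direction and signal:noise. Direction labels
#' assume measurement at the basal (haemolymph-facing) surface, where a
#' bath-directed flux is absorption; set `surface = "apical"` to flip the
#' labels for lumen-facing scans.
#'
#' @param dataset A [scan_dataset()].
#' @param cb_mode Background-concentration mode, see
#'   [background_concentration()].
#' @param aggregate Cycle aggregation, see [site_gradient()].
#' @param surface `"basal"` or `"apical"`: which epithelial surface the
#'   electrode scanned (affects only the direction label).
#' @return Data frame with one row per tissue site: `preparation_id`,
#'   `treatment`, `site_id`, `ordinal`, `region_hint`, `dv_raw`,
#'   `dv_reference`, `dv_corrected` (uV), `c_b`, `dc` (umol cm-3), `flux`
#'   (pmol cm-2 s-1), `direction`, `signal_to_noise`.
#' @examples
#' tr <- synthetic_truth(c(ileum = 26.7), n_sites = c(ileum = 2, rectum = 0),
#'                       noise_sd_uV = 0, drift_uV_per_min = 0)
#' ds <- simulate_scan(tr, default_calibration("K"),
#'                     selectivity = selectivity_profile("K"), seed = 1)
#' estimate_fluxes(ds)$flux  # ~26.7 at each site
#' @export
estimate_fluxes <- function(dataset, cb_mode = c("measured", "nominal"),
                            aggregate = c("mean", "median"),
                            surface = c("basal", "apical")) {
  stopifnot(inherits(dataset, "scan_dataset"))
  cb_mode <- match.arg(cb_mode)
  aggregate <- match.arg(aggregate)
  surface <- match.arg(surface)
  dv_ref <- reference_gradient(dataset, aggregate = aggregate)
  c_b <- background_concentration(dataset, mode = cb_mode)
  dx_cm <- dataset$protocol$excursion_um * 1e-4
  tissue <- dataset$samples[!dataset$samples$is_reference, , drop = FALSE]
  if (!nrow(tissue))
    stop("no tissue-site recordings in preparation '",
         dataset$preparation_id, "'", call. = FALSE)
  recs <- split(tissue, tissue$site_id)
  # keep input site order
  recs <- recs[unique(tissue$site_id)]
  rows <- lapply(recs, function(rec) {
    dv_raw <- tryCatch(site_gradient(rec, aggregate = aggregate),
      error = function(e) stop("site '", rec$site_id[1],
                               "' in preparation '", dataset$preparation_id,
                               "': ", conditionMessage(e), call. = FALSE))
    dv_c <- correct_gradient(dv_raw, dv_ref)
    dc <- concentration_gradient(dv_c, c_b, dataset$calibration$slope)
    j <- fick_flux(dc, dataset$ion$diffusion_coefficient, dx_cm)
    data.frame(
      preparation_id = dataset$preparation_id,
      treatment = dataset$treatment_label,
      site_id = rec$site_id[1], ordinal = rec$ordinal[1],
      region_hint = rec$region_hint[1],
      dv_raw = dv_raw, dv_reference = dv_ref, dv_corrected = dv_c,
      c_b = c_b, dc = dc, flux = j,
      direction = flux_direction(j, surface),
      signal_to_noise = signal_to_noise(dv_raw, dv_ref))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

flux_direction <- function(j, surface = "basal") {
  lab <- ifelse(j > 0, "absorption", ifelse(j < 0, "secretion", "none"))
  if (surface == "apical")
    lab <- ifelse(lab == "absorption", "secretion",
                  ifelse(lab == "secretion", "absorption", lab))
  lab
}
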