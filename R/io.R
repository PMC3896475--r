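#' Write a scan dataset to CSV
#'
#' One row per voltage sample with columns `preparation_id, treatment, ion,
#' site_id, ordinal, region_hint, is_reference, measurement, cycle,
#' position, time_s, voltage_uV`. Voltages are stored amplified by `gain`
#' (the acquisition system amplifies 1000-fold; in-memory voltages are
#' always de-amplified true electrode uV).
#'
#' @param dataset A [scan_dataset()].
#' @param path Output file path.
#' @param gain Amplifier gain applied on write.
#' @return `path`, invisibly.
#' @export
write_scan_csv <- function(dataset, path, gain = 1) {
  stopifnot(inherits(dataset, "scan_dataset"))
  if (gain <= 0) stop("gain must be > 0", call. = FALSE)
  s <- dataset$samples
  out <- data.frame(
    preparation_id = dataset$preparation_id,
    treatment = dataset$treatment_label,
    ion = dataset$ion$name,
    site_id = s$site_id, ordinal = s$ordinal,
    region_hint = s$region_hint, is_reference = s$is_reference,
    measurement = s$measurement, cycle = s$cycle, position = s$position,
    time_s = s$time_s, voltage_uV = s$voltage_uV * gain)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

scan_csv_cols <- c("preparation_id", "treatment", "ion", "site_id",
                   "ordinal", "region_hint", "is_reference", "measurement",
                   "cycle", "position", "time_s", "voltage_uV")

#' Read scan datasets from CSV
#'
#' Parses the schema written by [write_scan_csv()], de-amplifies the
#' voltages, and validates every structural invariant; a file may hold
#' several preparations (one [scan_dataset()] is returned per
#' `preparation_id`). Parse problems are reported with the offending column
#' or recording named — a schema violation never yields a silent partial
#' dataset.
#'
#' @param path CSV file path.
#' @param calibration An [electrode_calibration()] for the scanned ion.
#' @param protocol A [scan_protocol()] describing how the file was
#'   recorded.
#' @param gain Amplifier gain to divide out on read (1000 for raw
#'   acquisition files).
#' @return List of [scan_dataset()] objects, one per preparation.
#' @export
read_scan_csv <- function(path, calibration, protocol = scan_protocol(),
                          gain = 1) {
  stopifnot(inherits(calibration, "electrode_calibration"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (gain <= 0) stop("gain must be > 0", call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(scan_csv_cols, names(raw))
  if (length(missing_cols))
    stop("scan CSV '", path, "' is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  ions <- unique(raw$ion)
  if (length(ions) != 1)
    stop("scan CSV '", path, "' mixes ions: ",
         paste(ions, collapse = ", "), call. = FALSE)
  if (!identical(ions, calibration$ion$name))
    stop("scan CSV ion '", ions, "' does not match calibration ion '",
         calibration$ion$name, "'", call. = FALSE)
  raw$voltage_uV <- raw$voltage_uV / gain
  raw$is_reference <- as.logical(raw$is_reference)
  lapply(split(raw, raw$preparation_id), function(d) {
    scan_dataset(
      ion = calibration$ion, calibration = calibration,
      protocol = protocol,
      samples = d[, c("site_id", "ordinal", "region_hint", "is_reference",
                      "measurement", "cycle", "position", "time_s",
                      "voltage_uV")],
      treatment_label = d$treatment[1], preparation_id = d$preparation_id[1])
  })
}

#' Write calibration points to CSV
#'
#' Columns `ion, concentration_mM, voltage_uV`, one row per calibration
#' point.
#'
#' @param calibration An [electrode_calibration()], or a data frame already
#'   in the documented schema.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_calibration_csv <- function(calibration, path) {
  if (inherits(calibration, "electrode_calibration")) {
    calibration <- data.frame(
      ion = calibration$ion$name,
      concentration_mM = c(calibration$low_concentration,
                           calibration$high_concentration),
      voltage_uV = c(calibration$low_voltage, calibration$high_voltage))
  }
  stopifnot(is.data.frame(calibration))
  utils::write.csv(calibration, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and fit a calibration from CSV
#'
#' @param path CSV with columns `ion, concentration_mM, voltage_uV`.
#' @param ion Optional [ion_species()]; defaults to the built-in constants
#'   for the ion named in the file.
#' @return An [electrode_calibration()] (least-squares fitted when more
#'   than two points are present).
#' @export
read_calibration_csv <- function(path, ion = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("ion", "concentration_mM", "voltage_uV")
  missing_cols <- setdiff(needed, names(d))
  if (length(missing_cols))
    stop("calibration CSV '", path, "' is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (length(unique(d$ion)) != 1)
    stop("calibration CSV '", path, "' mixes ions", call. = FALSE)
  if (is.null(ion)) ion <- ion_species(d$ion[1])
  electrode_calibration(ion, d$concentration_mM, d$voltage_uV)
}

#' Experiment configuration
#'
#' Analysis settings shared across a run: scanned ion, background
#' concentration mode, amplifier gain, scanned surface, significance
#' threshold and RNG seed. Written to / read from JSON.
#'
#' @param ion `"K"` or `"Na"`.
#' @param cb_mode `"measured"` or `"nominal"` (see
#'   [background_concentration()]).
#' @param gain Amplifier gain of the stored voltages (> 0).
#' @param surface `"basal"` or `"apical"`.
#' @param alpha Significance threshold in (0, 1).
#' @param seed Integer seed for any simulation driven by this config.
#' @param protocol A [scan_protocol()].
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(ion = "K",
                              cb_mode = c("measured", "nominal"),
                              gain = 1, surface = c("basal", "apical"),
                              alpha = 0.05, seed = 1L,
                              protocol = scan_protocol()) {
  cb_mode <- match.arg(cb_mode)
  surface <- match.arg(surface)
  if (gain <= 0) stop("gain must be > 0", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)",
                                     call. = FALSE)
  structure(list(ion = ion, cb_mode = cb_mode, gain = gain,
                 surface = surface, alpha = alpha, seed = as.integer(seed),
                 protocol = protocol),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @param path JSON file path.
#' @param config An `experiment_config` to serialize.
#' @export
write_config_json <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  x <- unclass(config)
  x$protocol <- unclass(x$protocol)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname experiment_config
#' @export
read_config_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  experiment_config(
    ion = x$ion, cb_mode = x$cb_mode, gain = x$gain, surface = x$surface,
    alpha = x$alpha, seed = x$seed,
    protocol = do.call(scan_protocol, x$protocol))
}

#' Run the full analysis on scan files
#'
#' Reads every scan CSV, estimates per-site fluxes, assigns hindgut regions,
#' summarizes per preparation and region, and — when both a control and a
#' treated condition are present — compares them region by region. Per
#' preparation the three QC quantities a SIET report shows are logged:
#' reference gradient, mean tissue gradient, and signal:noise; sites with
#' signal:noise below 1 are retained but flagged.
#'
#' @param scan_paths Character vector of scan CSV paths.
#' @param calibration An [electrode_calibration()] (or path to a
#'   calibration CSV).
#' @param config An [experiment_config()].
#' @param flux_out,report_out Optional TSV output paths for the site-level
#'   flux table and the region comparison report.
#' @param control_label Which treatment label is the control arm.
#' @param verbose Emit per-preparation QC messages.
#' @return List with `fluxes` (site-level table), `prep_means`,
#'   `summaries`, and `comparison` (`NULL` if only one condition present).
#' @export
run_pipeline <- function(scan_paths, calibration,
                         config = experiment_config(),
                         flux_out = NULL, report_out = NULL,
                         control_label = "control", verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.character(calibration))
    calibration <- read_calibration_csv(calibration)
  datasets <- unlist(lapply(scan_paths, read_scan_csv,
                            calibration = calibration,
                            protocol = config$protocol, gain = config$gain),
                     recursive = FALSE)
  est <- lapply(datasets, function(ds) {
    e <- estimate_fluxes(ds, cb_mode = config$cb_mode,
                         surface = config$surface)
    if (verbose) {
      message(sprintf(
        "preparation %s: reference gradient %.1f uV, mean tissue gradient %.1f uV, signal:noise %.2f",
        ds$preparation_id, e$dv_reference[1], mean(e$dv_raw),
        signal_to_noise(mean(e$dv_raw), e$dv_reference[1])))
      low <- e$site_id[!is.na(e$signal_to_noise) & e$signal_to_noise < 1]
      if (length(low))
        message("  flagged (signal:noise < 1, retained): ",
                paste(low, collapse = ", "))
    }
    e
  })
  fluxes <- assign_regions(do.call(rbind, est))
  prep_means <- preparation_means(fluxes)
  summaries <- summarize_regions(prep_means)
  comparison <- NULL
  labels <- unique(prep_means$treatment)
  if (control_label %in% labels && length(labels) == 2) {
    comparison <- compare_treatments(
      prep_means[prep_means$treatment == control_label, ],
      prep_means[prep_means$treatment != control_label, ],
      alpha = config$alpha)
  }
  if (!is.null(flux_out))
    utils::write.table(fluxes, flux_out, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  if (!is.null(report_out) && !is.null(comparison))
    utils::write.table(comparison, report_out, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  list(fluxes = fluxes, prep_means = prep_means, summaries = summaries,
       comparison = comparison)
}

#' Bar chart of mean flux by region and treatment
#'
#' Minimal mean +/- SEM chart of the [summarize_regions()] table.
#'
#' @param summaries Output of [summarize_regions()].
#' @return A ggplot object.
#' @export
plot_region_fluxes <- function(summaries) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_region_fluxes() needs the ggplot2 package", call. = FALSE)
  summaries$region <- factor(
    summaries$region,
    levels = c("ileum", "anterior_rectum", "posterior_rectum"))
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = region, y = mean_flux,
                               fill = treatment)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = mean_flux - sem_flux,
                   ymax = mean_flux + sem_flux),
      position = ggplot2::position_dodge(0.9), width = 0.25) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "flux (pmol cm-2 s-1)",
                  caption = "positive = absorption (basal surface)") +
    ggplot2::theme_minimal()
}
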