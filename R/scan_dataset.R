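#' One preparation's SIET recordings
#'
#' A `scan_dataset` holds everything recorded for one tissue preparation:
#' the electrode calibration, the scan protocol, and a long table of voltage
#' samples covering the reference site(s) and every tissue site. Each scan
#' measures a single ion; K+ and Na+ scans come from separate preparations.
#'
#' `samples` is a data frame with one row per voltage sample and columns:
#' \describe{
#'   \item{site_id}{recording identifier (reference sites included)}
#'   \item{ordinal}{position index along the tissue axis (NA for reference)}
#'   \item{region_hint}{`"ileum"`, `"rectum"` or NA for reference sites}
#'   \item{is_reference}{logical}
#'   \item{measurement, cycle}{indices within the move-wait-sample protocol}
#'   \item{position}{`"inner"` (within 5 um of the surface) or `"outer"`
#'     (excursion distance further out)}
#'   \item{time_s}{seconds from scan start}
#'   \item{voltage_uV}{de-amplified electrode voltage in uV}
#' }
#'
#' @param ion An [ion_species()].
#' @param calibration An [electrode_calibration()] for the same ion.
#' @param protocol A [scan_protocol()].
#' @param samples Sample table as described above.
#' @param treatment_label Condition label, e.g. `"control"` or
#'   `"GPA2/GPB5"`.
#' @param preparation_id Identifier of the preparation.
#' @return An object of class `scan_dataset`.
#' @export
scan_dataset <- function(ion, calibration, protocol, samples,
                         treatment_label = "control",
                         preparation_id = "prep-1") {
  stopifnot(inherits(ion, "ion_species"),
            inherits(calibration, "electrode_calibration"),
            inherits(protocol, "scan_protocol"),
            is.data.frame(samples))
  if (!identical(ion$name, calibration$ion$name))
    stop("calibration ion '", calibration$ion$name,
         "' does not match dataset ion '", ion$name, "'", call. = FALSE)
  x <- structure(
    list(ion = ion, calibration = calibration, protocol = protocol,
         samples = samples,
         treatment_label = as.character(treatment_label)[1L],
         preparation_id = as.character(preparation_id)[1L]),
    class = "scan_dataset")
  validate_scan_dataset(x)
  x
}

needed_sample_cols <- c("site_id", "ordinal", "region_hint", "is_reference",
                        "measurement", "cycle", "position", "time_s",
                        "voltage_uV")

#' Validate a scan dataset
#'
#' Enforces the structural invariants every downstream operation assumes:
#' required columns, at least one reference and one tissue recording, each
#' (measurement, cycle) pair carrying exactly one inner and one outer
#' sample, and strictly increasing sample times within each recording.
#'
#' @param x A [scan_dataset()].
#' @return `x`, invisibly; errors describe the first violation found.
#' @export
validate_scan_dataset <- function(x) {
  stopifnot(inherits(x, "scan_dataset"))
  s <- x$samples
  missing_cols <- setdiff(needed_sample_cols, names(s))
  if (length(missing_cols))
    stop("samples table of preparation '", x$preparation_id,
         "' is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!nrow(s))
    stop("preparation '", x$preparation_id, "' has no samples", call. = FALSE)
  if (!any(s$is_reference))
    stop("preparation '", x$preparation_id,
         "' has no reference recordings", call. = FALSE)
  if (!any(!s$is_reference))
    stop("preparation '", x$preparation_id,
         "' has no tissue-site recordings", call. = FALSE)
  if (!all(s$position %in% c("inner", "outer")))
    stop("position must be 'inner' or 'outer'", call. = FALSE)
  for (id in unique(s$site_id)) {
    rec <- s[s$site_id == id, , drop = FALSE]
    key <- paste(rec$measurement, rec$cycle)
    n_in <- tapply(rec$position == "inner", key, sum)
    n_out <- tapply(rec$position == "outer", key, sum)
    if (any(n_in != 1L) || any(n_out != 1L))
      stop("malformed recording '", id, "' in preparation '",
           x$preparation_id,
           "': each cycle needs exactly one inner and one outer sample",
           call. = FALSE)
    if (is.unsorted(rec$time_s, strictly = TRUE))
      stop("recording '", id, "' in preparation '", x$preparation_id,
           "': sample times must be strictly increasing", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.scan_dataset <- function(x, ...) {
  s <- x$samples
  cat(sprintf(
    "<scan_dataset> %s+ scan, preparation '%s' (%s): %d tissue site(s), %d reference recording(s), %d samples\n",
    x$ion$name, x$preparation_id, x$treatment_label,
    length(unique(s$site_id[!s$is_reference])),
    length(unique(s$site_id[s$is_reference])), nrow(s)))
  invisible(x)
}
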