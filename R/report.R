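SECTION_METRICS <- c("area", "perimeter", "diameter_min", "diameter_max",
                     "diameter_avg", "diameter_area_derived",
                     "diameter_perimeter_derived")

REPORT_FIELDS <- list(
  annulus  = SECTION_METRICS,
  lvot     = SECTION_METRICS,
  sntj     = c("diameter_min", "diameter_max", "diameter_avg"),
  sov      = c("diameter_lcc", "diameter_rcc", "diameter_ncc"),
  coronary = c("height_left", "height_right")
)

report_units <- function(region, field) {
  if (field == "area") "mm^2" else "mm"
}

#' Construct a measurement report
#'
#' Bundles the 22 scalar measurements of the aortic valvular complex —
#' 7 annulus metrics, 7 LVOT metrics, 3 sinotubular-junction diameters,
#' 3 sinus-of-Valsalva diameters and 2 coronary heights — together with the
#' run metadata (input identifiers, effective parameters, QC flags).
#'
#' @param annulus,lvot Named numeric vectors with fields `area`, `perimeter`,
#'   `diameter_min`, `diameter_max`, `diameter_avg`, `diameter_area_derived`,
#'   `diameter_perimeter_derived`.
#' @param sntj Named numeric vector with `diameter_min`, `diameter_max`,
#'   `diameter_avg`.
#' @param sov Named numeric vector with `diameter_lcc`, `diameter_rcc`,
#'   `diameter_ncc`.
#' @param coronary Named numeric vector with `height_left`, `height_right`.
#' @param metadata List of run metadata; `qc_flags` (character vector) is
#'   always present in the result.
#' @param validate Check the report invariants (default `TRUE`).
#' @return Object of class `measurement_report`.
#' @export
measurement_report <- function(annulus, lvot, sntj, sov, coronary,
                               metadata = list(), validate = TRUE) {
  rep <- structure(list(annulus = unlist(annulus)[REPORT_FIELDS$annulus],
                        lvot = unlist(lvot)[REPORT_FIELDS$lvot],
                        sntj = unlist(sntj)[REPORT_FIELDS$sntj],
                        sov = unlist(sov)[REPORT_FIELDS$sov],
                        coronary = unlist(coronary)[REPORT_FIELDS$coronary],
                        metadata = metadata),
                   class = "measurement_report")
  for (region in names(REPORT_FIELDS)) {
    names(rep[[region]]) <- REPORT_FIELDS[[region]]
  }
  if (is.null(rep$metadata$qc_flags)) rep$metadata$qc_flags <- character()
  if (validate) validate_report(rep)
  rep
}

#' Validate a measurement report
#'
#' Checks the structural invariants: exactly 22 finite scalar fields, ordered
#' diameters (`min <= avg <= max`), the isoperimetric relation
#' (`diameter_area_derived <= diameter_perimeter_derived`), and positive
#' areas/perimeters.
#'
#' @param rep A [measurement_report()].
#' @param tol Numerical slack for the ordering checks.
#' @return The report, invisibly; errors on violation.
#' @export
validate_report <- function(rep, tol = 1e-9) {
  vals <- report_values(rep)
  if (length(vals) != 22) {
    stop("report validation: expected 22 measurements, found ", length(vals),
         call. = FALSE)
  }
  if (!all(is.finite(vals))) {
    stop("report validation: non-finite measurement value(s): ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "), call. = FALSE)
  }
  for (region in c("annulus", "lvot", "sntj")) {
    m <- rep[[region]]
    if (!(m["diameter_min"] <= m["diameter_avg"] + tol &&
          m["diameter_avg"] <= m["diameter_max"] + tol)) {
      stop("report validation: ", region, " diameters not ordered min <= avg <= max",
           call. = FALSE)
    }
  }
  for (region in c("annulus", "lvot")) {
    m <- rep[[region]]
    if (m["area"] <= 0 || m["perimeter"] <= 0) {
      stop("report validation: non-positive ", region, " area/perimeter", call. = FALSE)
    }
    if (m["diameter_area_derived"] > m["diameter_perimeter_derived"] + tol) {
      stop("report validation: ", region,
           " violates the isoperimetric inequality (d_area > d_perim)",
           call. = FALSE)
    }
  }
  invisible(rep)
}

# Flat named vector of the 22 measurements ("region.field" names).
report_values <- function(rep) {
  out <- numeric(0)
  for (region in names(REPORT_FIELDS)) {
    v <- rep[[region]]
    names(v) <- paste(region, REPORT_FIELDS[[region]], sep = ".")
    out <- c(out, v)
  }
  out
}

#' @export
print.measurement_report <- function(x, ...) {
  cat("<measurement_report> 22 measurements\n")
  df <- as.data.frame(x)
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-35s %10.3f %s\n", df$name[i], df$value[i], df$units[i]))
  }
  if (length(x$metadata$qc_flags)) {
    cat("  QC flags:", paste(x$metadata$qc_flags, collapse = "; "), "\n")
  } else {
    cat("  QC flags: none\n")
  }
  invisible(x)
}

#' @export
as.data.frame.measurement_report <- function(x, ...) {
  vals <- report_values(x)
  region <- sub("\\..*", "", names(vals))
  field <- sub("^[^.]*\\.", "", names(vals))
  data.frame(name = names(vals), value = unname(vals),
             units = mapply(report_units, region, field, USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

#' Write a measurement report
#'
#' JSON output nests measurements by region plus a `metadata` block and
#' round-trips losslessly through [read_report()]; CSV output has one row per
#' measurement with columns `name,value,units`.
#'
#' @param rep A valid [measurement_report()].
#' @param path Output path.
#' @param format `"json"` or `"csv"`; inferred from the extension when `NULL`.
#' @return `path`, invisibly.
#' @export
write_report <- function(rep, path, format = NULL) {
  validate_report(rep)
  format <- tolower(format %||% tools::file_ext(path))
  if (format == "json") {
    obj <- lapply(unclass(rep)[names(REPORT_FIELDS)], as.list)
    obj$metadata <- rep$metadata
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else if (format == "csv") {
    utils::write.csv(as.data.frame(rep), path, row.names = FALSE, quote = FALSE)
  } else {
    stop("unsupported report format: ", format, call. = FALSE)
  }
  invisible(path)
}

#' Read a measurement report from JSON
#'
#' @param path Path to a JSON report written by [write_report()].
#' @return A [measurement_report()].
#' @export
read_report <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  measurement_report(obj$annulus, obj$lvot, obj$sntj, obj$sov, obj$coronary,
                     metadata = as.list(obj$metadata))
}
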