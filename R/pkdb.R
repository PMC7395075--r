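# PK summary database: schema, I/O, validation, analysis-set selection.
# One row per study x substrate x route x parameter, carrying the summary
# statistics exactly as published (central tendency + dispersion, any of
# AM/SD, AM/SE, AM/CV, GM/GSD) plus the dosing information needed to
# normalise them later.

#' Column order of the canonical PK summary CSV
#'
#' @format Character vector of the 18 column names, in storage order.
#' @export
PK_SCHEMA_COLUMNS <- c(
  "study_id", "substrate_id", "isoform_ids", "route", "parameter",
  "n_subjects", "dose_value", "dose_basis", "body_weight_kg", "bsa_m2",
  "geography", "health_status", "regimen", "central_kind", "central_value",
  "dispersion_kind", "dispersion_value", "value_units"
)

.pk_enums <- list(
  route           = c("oral", "iv"),
  parameter       = c("auc", "clearance", "cmax"),
  dose_basis      = c("total_mg", "mg_per_kg", "mg_per_m2"),
  health_status   = c("healthy", "patient"),
  regimen         = c("single_dose", "repeated_21d"),
  central_kind    = c("AM", "GM"),
  dispersion_kind = c("SD", "SE", "CV_fraction", "GSD")
)

.pk_numeric_cols <- c("n_subjects", "dose_value", "body_weight_kg",
                      "bsa_m2", "central_value", "dispersion_value")

#' Construct a PK summary database
#'
#' A `pk_database` is a thin S3 wrapper around a data frame whose columns
#' follow [PK_SCHEMA_COLUMNS]. Rows are study-level summaries of one
#' pharmacokinetic parameter (AUC, clearance or Cmax) for one probe
#' substrate and route, as reported in the source publication.
#'
#' @param records Data frame with the schema columns (may have zero rows).
#'   Missing optional fields (`body_weight_kg`, `bsa_m2`) are `NA`.
#' @param schema_version Schema version string stored with the object.
#' @return An object of class `pk_database`.
#' @export
pk_database <- function(records = NULL, schema_version = "1.0") {
  if (is.null(records)) {
    records <- as.data.frame(
      c(
        stats::setNames(rep(list(character(0)), 5), PK_SCHEMA_COLUMNS[1:5]),
        list(n_subjects = integer(0), dose_value = numeric(0)),
        list(dose_basis = character(0), body_weight_kg = numeric(0),
             bsa_m2 = numeric(0), geography = character(0),
             health_status = character(0), regimen = character(0),
             central_kind = character(0), central_value = numeric(0),
             dispersion_kind = character(0), dispersion_value = numeric(0),
             value_units = character(0))
      ),
      stringsAsFactors = FALSE
    )
  }
  if (!is.data.frame(records)) stop("'records' must be a data frame")
  missing_cols <- setdiff(PK_SCHEMA_COLUMNS, names(records))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- records[, PK_SCHEMA_COLUMNS, drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records, schema_version = schema_version),
            class = "pk_database")
}

#' @export
print.pk_database <- function(x, ...) {
  cat(sprintf("PK summary database (schema %s): %d record(s)\n",
              x$schema_version, nrow(x$records)))
  if (nrow(x$records) > 0L) {
    tab <- table(x$records$substrate_id, x$records$parameter)
    print(tab)
  }
  invisible(x)
}

#' Number of records in a PK database
#' @param x A `pk_database`.
#' @export
nrecords <- function(x) nrow(x$records)

.stop_cell <- function(row, column, msg) {
  stop(sprintf("row %d, column '%s': %s", row, column, msg), call. = FALSE)
}

.check_cells <- function(records) {
  n <- nrow(records)
  if (n == 0L) return(invisible(NULL))
  for (col in c("study_id", "substrate_id")) {
    bad <- which(is.na(records[[col]]) | !nzchar(records[[col]]))
    if (length(bad)) .stop_cell(bad[1L], col, "must be non-empty")
  }
  for (col in names(.pk_enums)) {
    bad <- which(!(records[[col]] %in% .pk_enums[[col]]))
    if (length(bad)) {
      .stop_cell(bad[1L], col,
                 sprintf("unknown token '%s' (allowed: %s)",
                         records[[col]][bad[1L]],
                         paste(.pk_enums[[col]], collapse = ", ")))
    }
  }
  for (col in .pk_numeric_cols) {
    v <- records[[col]]
    if (!is.numeric(v)) .stop_cell(1L, col, "must be numeric")
    optional <- col %in% c("body_weight_kg", "bsa_m2")
    if (!optional && anyNA(v)) .stop_cell(which(is.na(v))[1L], col, "missing value")
  }
  pos <- function(col, strictly = TRUE) {
    v <- records[[col]]
    bad <- which(!is.na(v) & if (strictly) v <= 0 else v < 0)
    if (length(bad)) {
      .stop_cell(bad[1L], col,
                 if (strictly) "must be > 0" else "must be >= 0")
    }
  }
  pos("n_subjects"); pos("dose_value"); pos("central_value")
  pos("body_weight_kg"); pos("bsa_m2")
  pos("dispersion_value", strictly = FALSE)
  bad <- which(records$n_subjects != round(records$n_subjects))
  if (length(bad)) .stop_cell(bad[1L], "n_subjects", "must be an integer")
  invisible(NULL)
}

#' Read a PK summary database from CSV
#'
#' The file must carry exactly the columns of [PK_SCHEMA_COLUMNS] (in any
#' order); empty strings in `body_weight_kg` / `bsa_m2` denote missing
#' optional values. Any unknown enum token, nonpositive value or missing
#' mandatory column is a hard error naming the offending row and column.
#'
#' @param path Path to a CSV file.
#' @param schema_version Expected schema version (stored on the result).
#' @return A validated [pk_database()], row order preserved.
#' @export
read_pk_database <- function(path, schema_version = "1.0") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(PK_SCHEMA_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(raw), PK_SCHEMA_COLUMNS)
  if (length(extra) > 0L) {
    stop("unknown column(s): ", paste(extra, collapse = ", "))
  }
  raw <- raw[, PK_SCHEMA_COLUMNS, drop = FALSE]
  for (col in .pk_numeric_cols) {
    v <- trimws(raw[[col]])
    v[!nzchar(v)] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad)) .stop_cell(bad[1L], col,
                                sprintf("not a number: '%s'", v[bad[1L]]))
    raw[[col]] <- num
  }
  raw$n_subjects <- as.integer(raw$n_subjects)
  .check_cells(raw)
  pk_database(raw, schema_version = schema_version)
}

#' Write a PK summary database to CSV
#'
#' Inverse of [read_pk_database()]: `read(write(db))` round-trips the
#' records exactly.
#'
#' @param db A `pk_database`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pk_database <- function(db, path) {
  stopifnot(inherits(db, "pk_database"))
  out <- db$records
  for (col in c("body_weight_kg", "bsa_m2")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "", format(out[[col]], digits = 15))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Report invariant violations in a PK database
#'
#' Unlike [read_pk_database()], which raises on malformed input, this
#' checks the domain invariants of already-parsed records and reports
#' rather than raising: `n_subjects >= 1`, positive central values,
#' nonnegative dispersion, GSD >= 1, uniqueness of the
#' study x substrate x route x parameter key, and the restriction of
#' `mg_per_m2` dosing to BSA-normalised substrates.
#'
#' @param db A `pk_database`.
#' @param bsa_substrates Substrates conventionally dosed per body surface
#'   area (default `"SN38"`).
#' @return Data frame with columns `record` (row index), `field`, `rule`;
#'   zero rows iff all invariants hold.
#' @export
validate_records <- function(db, bsa_substrates = "SN38") {
  stopifnot(inherits(db, "pk_database"))
  r <- db$records
  out <- list()
  add <- function(rows, field, rule) {
    if (length(rows)) {
      out[[length(out) + 1L]] <<- data.frame(record = rows, field = field,
                                             rule = rule,
                                             stringsAsFactors = FALSE)
    }
  }
  add(which(r$n_subjects < 1L), "n_subjects", "n_subjects >= 1")
  add(which(r$central_value <= 0), "central_value", "central_value > 0")
  add(which(r$dispersion_value < 0), "dispersion_value", "dispersion_value >= 0")
  add(which(r$dispersion_kind == "GSD" & r$dispersion_value < 1),
      "dispersion_value", "GSD >= 1")
  add(which(r$dose_basis == "mg_per_m2" & !(r$substrate_id %in% bsa_substrates)),
      "dose_basis", "mg_per_m2 only for BSA-normalised substrates")
  key <- paste(r$study_id, r$substrate_id, r$route, r$parameter, sep = "\r")
  add(which(duplicated(key)), "study_id",
      "duplicate study x substrate x route x parameter key")
  if (length(out) == 0L) {
    return(data.frame(record = integer(0), field = character(0),
                      rule = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$record), , drop = FALSE]
}

#' Select the analysis set for one substrate, route and parameter
#'
#' Applies the inclusion rules used when assembling a meta-analysis input:
#' repeated-dosing records are dropped unless `include_repeated` is set
#' (the ethinylestradiol 21-day contraceptive regimen is the one deliberate
#' exception a caller opts into), and patient records are dropped unless
#' `include_patients` is set (needed for compounds such as SN38, for which
#' only patient data exist).
#'
#' @param db A `pk_database`.
#' @param substrate Substrate identifier to keep.
#' @param route `"oral"` or `"iv"`.
#' @param parameter `"auc"`, `"clearance"` or `"cmax"`.
#' @param include_patients Keep `health_status == "patient"` records?
#' @param include_repeated Keep `regimen == "repeated_21d"` records?
#' @return A `pk_database` with the matching subset (possibly empty).
#' @export
select_analysis_set <- function(db, substrate, route, parameter,
                                include_patients = FALSE,
                                include_repeated = FALSE) {
  stopifnot(inherits(db, "pk_database"))
  route <- match.arg(route, .pk_enums$route)
  parameter <- match.arg(parameter, .pk_enums$parameter)
  r <- db$records
  keep <- r$substrate_id == substrate & r$route == route &
    r$parameter == parameter
  if (!include_repeated) keep <- keep & r$regimen != "repeated_21d"
  if (!include_patients) keep <- keep & r$health_status != "patient"
  pk_database(r[keep, , drop = FALSE], schema_version = db$schema_version)
}
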