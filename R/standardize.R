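# Standardisation of reported PK summaries into dose-normalised lognormal
# summaries (lnGM, lnGSD, n).
#
# Published studies report central tendency and dispersion in four flavours
# (AM/SD, AM/SE, AM/CV, GM/GSD). PK values are treated as lognormal, so every
# flavour is mapped to the geometric summaries by moment matching:
#   CV_N = SD / AM,  GM = AM / sqrt(1 + CV_N^2),
#   GSD  = exp(sqrt(log(1 + CV_N^2))).
# Doses are brought to mg/kg body weight (or mg/m^2 body surface area for
# substrates conventionally dosed per BSA), filling in continent-level
# default body weights where the study reports none.

#' Normalisation configuration
#'
#' Holds the defaults used to dose-normalise records: continent-level mean
#' adult body weights (kg) used when a study reports no body weight, the
#' default body surface area used for BSA-dosed substrates, and the list of
#' substrates that are dosed per BSA. The shipped body weights are regional
#' mean adult body masses (Walpole et al. 2012, BMC Public Health 12:439);
#' they are configuration, not constants — override them to match the
#' geography labels of your database.
#'
#' @param continent_body_weights Named numeric vector mapping geography
#'   labels to default body weights in kg.
#' @param default_bsa_m2 Default adult body surface area (m^2) when a
#'   BSA-dosed substrate's record reports none.
#' @param bsa_substrates Substrates whose dose is normalised per m^2 of
#'   body surface area rather than per kg body weight.
#' @return An object of class `normalization_config`.
#' @export
normalization_config <- function(
    continent_body_weights = c(
      Africa = 60.7, Asia = 57.7, Europe = 70.8, `Latin America` = 67.9,
      `North America` = 80.7, Oceania = 74.1, World = 62.0
    ),
    default_bsa_m2 = 1.79,
    bsa_substrates = "SN38") {
  stopifnot(is.numeric(continent_body_weights),
            length(continent_body_weights) > 0L,
            all(continent_body_weights > 0),
            !is.null(names(continent_body_weights)),
            is.numeric(default_bsa_m2), default_bsa_m2 > 0)
  structure(list(continent_body_weights = continent_body_weights,
                 default_bsa_m2 = default_bsa_m2,
                 bsa_substrates = bsa_substrates),
            class = "normalization_config")
}

#' Convert a reported dispersion statistic to a standard deviation
#'
#' SE is scaled back to SD with `sqrt(n)`; a CV (as a fraction) is scaled by
#' the arithmetic mean. A GSD never passes through this path: it already
#' lives on the geometric scale and is taken directly.
#'
#' @param kind One of `"SD"`, `"SE"`, `"CV_fraction"`.
#' @param value The reported dispersion value (nonnegative).
#' @param n Number of subjects (required, `>= 2`, when `kind == "SE"`).
#' @param mean Reported arithmetic mean (required when `kind == "CV_fraction"`).
#' @return The standard deviation on the arithmetic scale.
#' @export
sd_from_dispersion <- function(kind, value, n = NULL, mean = NULL) {
  stopifnot(is.numeric(value), value >= 0)
  switch(kind,
    SD = value,
    SE = {
      if (is.null(n) || n < 2) stop("SE requires n >= 2")
      value * sqrt(n)
    },
    CV_fraction = {
      if (is.null(mean) || mean <= 0) stop("CV requires a positive mean")
      value * mean
    },
    GSD = stop("GSD is already geometric; it does not convert through SD"),
    stop("unknown dispersion kind: ", kind)
  )
}

#' Arithmetic to geometric summaries under lognormality
#'
#' Moment-matches an arithmetic mean and SD to the geometric mean and
#' geometric standard deviation of a lognormal distribution:
#' `GM = AM / sqrt(1 + CV^2)`, `GSD = exp(sqrt(log(1 + CV^2)))` with
#' `CV = SD / AM`.
#'
#' @param am Arithmetic mean (> 0).
#' @param sd Standard deviation (>= 0).
#' @return Named numeric vector `c(gm =, gsd =)` with `gsd >= 1`.
#' @seealso [gm_gsd_to_am_sd()] for the exact inverse.
#' @export
am_sd_to_gm_gsd <- function(am, sd) {
  if (!is.numeric(am) || am <= 0) stop("arithmetic mean must be > 0")
  if (!is.numeric(sd) || sd < 0) stop("sd must be >= 0")
  cv2 <- (sd / am)^2
  c(gm = am / sqrt(1 + cv2), gsd = exp(sqrt(log1p(cv2))))
}

#' Geometric to arithmetic summaries under lognormality
#'
#' Exact inverse of [am_sd_to_gm_gsd()]:
#' `CV = sqrt(exp(log(GSD)^2) - 1)`, `AM = GM * sqrt(1 + CV^2)`,
#' `SD = CV * AM`.
#'
#' @param gm Geometric mean (> 0).
#' @param gsd Geometric standard deviation (>= 1).
#' @return Named numeric vector `c(am =, sd =)`.
#' @export
gm_gsd_to_am_sd <- function(gm, gsd) {
  if (!is.numeric(gm) || gm <= 0) stop("geometric mean must be > 0")
  if (!is.numeric(gsd) || gsd < 1) stop("GSD must be >= 1")
  cv2 <- expm1(log(gsd)^2)
  am <- gm * sqrt(1 + cv2)
  c(am = am, sd = sqrt(cv2) * am)
}

#' Dose-normalise one record
#'
#' Returns the dose per kg body weight (or per m^2 BSA for BSA-dosed
#' substrates). `mg_per_kg` and `mg_per_m2` doses pass through unchanged; a
#' `total_mg` dose is divided by the reported body weight, falling back to
#' the continent default from `config` matched against the record's
#' geography label. For BSA substrates the reported BSA wins over body
#' weight, falling back to `config$default_bsa_m2`.
#'
#' @param record One-row data frame (or list) with the PK schema fields.
#' @param config A [normalization_config()].
#' @return Dose in mg/kg (or mg/m^2), a positive scalar.
#' @export
normalize_dose <- function(record, config = normalization_config()) {
  basis <- record$dose_basis
  if (basis %in% c("mg_per_kg", "mg_per_m2")) return(record$dose_value)
  if (basis != "total_mg") stop("unknown dose basis: ", basis)
  if (record$substrate_id %in% config$bsa_substrates) {
    bsa <- record$bsa_m2
    if (is.null(bsa) || is.na(bsa)) bsa <- config$default_bsa_m2
    return(record$dose_value / bsa)
  }
  bw <- record$body_weight_kg
  if (is.null(bw) || is.na(bw)) {
    bw <- unname(config$continent_body_weights[record$geography])
    if (is.na(bw)) {
      stop(sprintf(
        "record '%s': total_mg dose with no body weight and no default for geography '%s'",
        record$study_id, record$geography))
    }
  }
  record$dose_value / bw
}

# Unit conversion factors to the canonical reporting units:
#   cmax      ng/mL per mg/kg dose
#   auc       ng*h/mL per mg/kg dose
#   clearance mL/min/kg
.unit_factors <- list(
  cmax = c("ng/mL" = 1, "ug/mL" = 1000, "mg/L" = 1000, "ng/L" = 1e-3),
  auc = c("ng*h/mL" = 1, "ug*h/mL" = 1000, "mg*h/L" = 1000,
          "ng*min/mL" = 1 / 60),
  clearance = c("mL/min/kg" = 1, "L/h/kg" = 1000 / 60, "mL/min" = NA,
                "L/h" = NA)
)

#' Canonical reporting units per PK parameter
#' @return Named character vector (parameter -> unit string).
#' @export
canonical_units <- function() {
  c(cmax = "ng/mL per mg/kg", auc = "ng*h/mL per mg/kg",
    clearance = "mL/min/kg")
}

.to_canonical_units <- function(parameter, value_units, value) {
  fac <- .unit_factors[[parameter]][value_units]
  if (is.na(fac)) {
    stop(sprintf("cannot convert unit '%s' for parameter '%s'",
                 value_units, parameter))
  }
  value * fac
}

#' Standardise one record to a normalised lognormal observation
#'
#' Converts the reported central/dispersion pair to (GM, GSD), brings the
#' GM to canonical units, divides concentration-type parameters (AUC, Cmax)
#' by the normalised dose, and returns the log-scale summary feeding the
#' hierarchical model. Clearance is already expressed per kg and is only
#' unit-converted.
#'
#' @param record One-row data frame (or list) with the PK schema fields.
#' @param config A [normalization_config()].
#' @return One-row data frame with columns `substrate_id`, `route`,
#'   `parameter`, `n_subjects`, `ln_gm`, `ln_gsd`, `source_study_id`.
#' @export
normalize_record <- function(record, config = normalization_config()) {
  if (record$central_kind == "GM" && record$dispersion_kind == "GSD") {
    gm <- record$central_value
    gsd <- record$dispersion_value
    if (gsd < 1) stop("GSD must be >= 1")
  } else if (record$central_kind == "AM") {
    if (record$dispersion_kind == "GSD") {
      stop("AM with GSD is not a coherent reporting pair")
    }
    sdv <- sd_from_dispersion(record$dispersion_kind, record$dispersion_value,
                              n = record$n_subjects,
                              mean = record$central_value)
    g <- am_sd_to_gm_gsd(record$central_value, sdv)
    gm <- g[["gm"]]
    gsd <- g[["gsd"]]
  } else {
    stop("GM must be paired with GSD dispersion")
  }
  gm <- .to_canonical_units(record$parameter, record$value_units, gm)
  if (record$parameter %in% c("auc", "cmax")) {
    gm <- gm / normalize_dose(record, config)
  }
  if (!is.finite(gm) || gm <= 0) stop("non-finite normalised GM")
  data.frame(substrate_id = record$substrate_id, route = record$route,
             parameter = record$parameter,
             n_subjects = as.integer(record$n_subjects),
             ln_gm = log(gm), ln_gsd = log(gsd),
             source_study_id = record$study_id, stringsAsFactors = FALSE)
}

#' Standardise every record of a database
#'
#' @param db A `pk_database` (typically the output of
#'   [select_analysis_set()]).
#' @param config A [normalization_config()].
#' @return Data frame of normalised observations, one row per record, in
#'   input order (see [normalize_record()] for columns).
#' @export
normalize_database <- function(db, config = normalization_config()) {
  stopifnot(inherits(db, "pk_database"))
  r <- db$records
  if (nrow(r) == 0L) {
    return(data.frame(substrate_id = character(0), route = character(0),
                      parameter = character(0), n_subjects = integer(0),
                      ln_gm = numeric(0), ln_gsd = numeric(0),
                      source_study_id = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- lapply(seq_len(nrow(r)), function(i) {
    normalize_record(as.list(r[i, , drop = FALSE]), config)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
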