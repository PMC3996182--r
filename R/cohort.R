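## Patient cohort data model and CSV I/O.
##
## A cohort is a plain data.frame with one row per patient and the 16
## canonical columns below. Single-row subsets act as individual patient
## records throughout the package.

#' Canonical cohort column names
#'
#' @return character vector of the 16 cohort columns, in file order.
#' @export
cohort_columns <- function() {
  c("patient_id", "disease",
    "core_body_temperature", "pulse", "arterial_systolic_pressure",
    "diastolic_blood_pressure", "peep", "pso2", "ph", "po2", "pco2",
    "bicarbonate",
    "frequency", "tidal_volume", "fio2", "support_mode")
}

#' Names of the ten network input fields, in model order
#'
#' Order matters: it is the order the feature vector presents them to the
#' network (diagnosis code first, then the nine physiological inputs).
#'
#' @return character vector of length 10.
#' @export
input_fields <- function() {
  c("disease", "core_body_temperature", "pulse",
    "arterial_systolic_pressure", "diastolic_blood_pressure", "peep",
    "pso2", "ph", "pco2", "bicarbonate")
}

#' Names of the four recommended ventilator settings
#'
#' @return character vector: frequency, tidal_volume, fio2, support_mode.
#' @export
output_fields <- function() c("frequency", "tidal_volume", "fio2", "support_mode")

#' Disease labels and their numeric codes
#'
#' The diagnosis enters the network as a single numeric slot, coded
#' COPD = 1, ARDS = 2, CVD = 3.
#'
#' @return named integer vector.
#' @export
disease_codes <- function() c(COPD = 1L, ARDS = 2L, CVD = 3L)

numeric_cohort_fields <- function() {
  setdiff(cohort_columns(), c("patient_id", "disease", "support_mode"))
}

#' Encode a disease label as its numeric code
#'
#' @param disease character vector of labels in `c("COPD","ARDS","CVD")`.
#' @return numeric codes.
#' @export
disease_code <- function(disease) {
  codes <- disease_codes()
  bad <- !(disease %in% names(codes))
  if (any(bad))
    stop_ventdss("unknown disease label: ", paste(unique(disease[bad]), collapse = ", "))
  unname(codes[disease])
}

#' Read a patient cohort from CSV
#'
#' Expects the canonical 16-column header (see [cohort_columns()]). Empty
#' cells denote absent values (typically the four output settings for
#' patients still awaiting a recommendation). FiO2 accepts both dialects
#' found in clinical sources: a fraction in \[0.21, 1\] or a percent
#' (any value > 1 is divided by 100 on input); it is always stored as a
#' fraction.
#'
#' @param file path or connection to a CSV file.
#' @return data.frame with one row per patient, row order preserved.
#' @export
read_cohort <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE, colClasses = "character",
                 check.names = FALSE)
  unknown <- setdiff(names(df), cohort_columns())
  if (length(unknown))
    stop_ventdss("unknown column(s) in cohort file: ", paste(unknown, collapse = ", "))
  missing <- setdiff(cohort_columns(), names(df))
  if (length(missing))
    stop_ventdss("cohort file lacks column(s): ", paste(missing, collapse = ", "))
  df <- df[cohort_columns()]
  for (f in numeric_cohort_fields()) {
    raw <- df[[f]]
    blank <- is.na(raw) | !nzchar(trimws(raw))
    val <- suppressWarnings(as.numeric(raw))
    bad <- !blank & is.na(val)
    if (any(bad))
      stop_ventdss(sprintf("non-numeric value '%s' in column '%s' at data row %d",
                           raw[which(bad)[1]], f, which(bad)[1]))
    val[blank] <- NA_real_
    df[[f]] <- val
  }
  # FiO2 percent dialect: values above 1 are percentages
  pct <- !is.na(df$fio2) & df$fio2 > 1
  df$fio2[pct] <- df$fio2[pct] / 100
  df$disease[!nzchar(trimws(df$disease))] <- NA_character_
  sm <- trimws(df$support_mode)
  sm[!nzchar(sm)] <- NA_character_
  ok <- is.na(sm) | sm %in% c("PS", "VS")
  if (!all(ok))
    stop_ventdss("support_mode must be 'PS' or 'VS', got: ", sm[which(!ok)[1]])
  df$support_mode <- sm
  known <- is.na(df$disease) | df$disease %in% names(disease_codes())
  if (!all(known))
    stop_ventdss("unknown disease label: ", df$disease[which(!known)[1]])
  rownames(df) <- NULL
  df
}

#' Write a patient cohort to CSV
#'
#' Inverse of [read_cohort()]: numbers are written with enough digits that
#' a read/write round trip reproduces them, FiO2 as a fraction, absent
#' values as empty cells.
#'
#' @param cohort cohort data.frame.
#' @param file path or connection.
#' @return `file`, invisibly.
#' @export
write_cohort <- function(cohort, file) {
  missing <- setdiff(cohort_columns(), names(cohort))
  if (length(missing))
    stop_ventdss("cohort lacks column(s): ", paste(missing, collapse = ", "))
  out <- cohort[cohort_columns()]
  for (f in numeric_cohort_fields()) {
    v <- out[[f]]
    s <- vapply(v, function(x) if (is.na(x)) "" else format(x, digits = 15), "")
    out[[f]] <- s
  }
  out$support_mode[is.na(out$support_mode)] <- ""
  out$disease[is.na(out$disease)] <- ""
  write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Default plausibility ranges for patient fields
#'
#' Closed intervals outside which a value is flagged as a possible faulty
#' entry before any recommendation is computed. These are deliberately wide
#' screening bounds (they catch transcription errors, not abnormal
#' physiology) and can be overridden wholesale or per field.
#'
#' @param overrides optional named list of `c(low, high)` pairs replacing
#'   individual defaults.
#' @return named list of numeric `c(low, high)` ranges covering every
#'   numeric patient field.
#' @export
default_plausibility_ranges <- function(overrides = list()) {
  ranges <- list(
    core_body_temperature      = c(30, 43),
    pulse                      = c(20, 220),
    arterial_systolic_pressure = c(50, 260),
    diastolic_blood_pressure   = c(20, 160),
    peep                       = c(0, 25),
    pso2                       = c(40, 100),
    ph                         = c(6.8, 7.8),
    po2                        = c(20, 600),
    pco2                       = c(10, 130),
    bicarbonate                = c(5, 45),
    frequency                  = c(4, 60),
    tidal_volume               = c(100, 1200),
    fio2                       = c(0.21, 1.0)
  )
  for (nm in names(overrides)) {
    r <- overrides[[nm]]
    if (!nm %in% names(ranges))
      stop_ventdss("no plausibility range for unknown field: ", nm)
    if (length(r) != 2L || !is.numeric(r) || r[1] >= r[2])
      stop_ventdss("range for '", nm, "' must be numeric c(low, high) with low < high")
    ranges[[nm]] <- as.numeric(r)
  }
  ranges
}

#' Read plausibility ranges from a JSON file
#'
#' The file holds an object mapping field name to `[low, high]`; fields not
#' mentioned keep their defaults.
#'
#' @param file path to a JSON file.
#' @return named list of ranges as in [default_plausibility_ranges()].
#' @export
read_plausibility_ranges <- function(file) {
  raw <- jsonlite::read_json(file, simplifyVector = TRUE)
  default_plausibility_ranges(overrides = as.list(raw))
}

#' Screen one patient record for implausible values
#'
#' Stage-one gate of the pipeline: every numeric field present in the record
#' is checked against its plausibility interval, and each value strictly
#' outside its bounds produces an alert naming the field, the observed
#' value, and the violated bound. A record with any alert is marked
#' `suspect` and the recommendation stage refuses to run on it unless the
#' physician overrides.
#'
#' @param record single-row cohort data.frame (or coercible named list).
#' @param ranges plausibility ranges, as from [default_plausibility_ranges()].
#' @param require_inputs if TRUE (default) a missing network input field is
#'   a structural error rather than a plausibility alert.
#' @return object of class `validation_report`: list with `patient_id`,
#'   `ok` flag, and a data.frame of `alerts` (field, value, bound, limit).
#' @export
validate_record <- function(record, ranges = default_plausibility_ranges(),
                            require_inputs = TRUE) {
  record <- as_record(record)
  covered <- intersect(numeric_cohort_fields(), names(record))
  lacking <- setdiff(covered, names(ranges))
  if (length(lacking))
    stop_ventdss("ranges lack entries for: ", paste(lacking, collapse = ", "))
  if (require_inputs) {
    need <- setdiff(input_fields(), "disease")
    absent <- need[vapply(need, function(f) is.na(record[[f]]), TRUE)]
    if (length(absent))
      stop_ventdss("record is missing required input field(s): ",
                   paste(absent, collapse = ", "))
  }
  alerts <- list()
  for (f in covered) {
    v <- record[[f]]
    if (is.na(v)) next
    r <- ranges[[f]]
    if (v < r[1]) alerts[[length(alerts) + 1L]] <-
        data.frame(field = f, value = v, bound = "low", limit = r[1])
    else if (v > r[2]) alerts[[length(alerts) + 1L]] <-
        data.frame(field = f, value = v, bound = "high", limit = r[2])
  }
  alerts <- if (length(alerts)) do.call(rbind, alerts) else
    data.frame(field = character(), value = numeric(),
               bound = character(), limit = numeric())
  structure(list(patient_id = record$patient_id %||% NA_character_,
                 ok = nrow(alerts) == 0L, alerts = alerts),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Record %s: %s\n", x$patient_id,
              if (x$ok) "ok" else sprintf("SUSPECT (%d alert(s))", nrow(x$alerts))))
  if (nrow(x$alerts)) {
    for (i in seq_len(nrow(x$alerts)))
      cat(sprintf("  - %s = %g outside %s bound %g\n", x$alerts$field[i],
                  x$alerts$value[i], x$alerts$bound[i], x$alerts$limit[i]))
  }
  invisible(x)
}

as_record <- function(record) {
  if (is.data.frame(record)) {
    if (nrow(record) != 1L)
      stop_ventdss("a patient record must be a single row (got ", nrow(record), ")")
    return(as.list(record))
  }
  if (is.list(record)) return(record)
  stop_ventdss("record must be a single-row data.frame or a named list")
}

#' Fit a per-feature min-max scaler on a training cohort
#'
#' Maps each of the ten input features affinely onto \[-1, 1\] using the
#' training minima and maxima (the disease label is first replaced by its
#' numeric code). Records scored later are transformed with the frozen
#' training ranges, so values outside them map outside \[-1, 1\] — the
#' scaler is always fitted on training folds only. A constant feature maps
#' to 0.
#'
#' @param cohort training cohort data.frame with complete inputs.
#' @param enabled if FALSE, the scaler is the identity map.
#' @return object of class `feature_scaler`.
#' @export
fit_feature_scaler <- function(cohort, enabled = TRUE) {
  X <- raw_feature_matrix(cohort)
  structure(list(min = apply(X, 2, min), max = apply(X, 2, max),
                 enabled = isTRUE(enabled)),
            class = "feature_scaler")
}

#' Identity feature scaler
#'
#' @return a disabled `feature_scaler` that leaves features untouched.
#' @export
identity_scaler <- function() {
  n <- length(input_fields())
  structure(list(min = rep(0, n), max = rep(1, n), enabled = FALSE),
            class = "feature_scaler")
}

raw_feature_matrix <- function(cohort) {
  if (is.data.frame(cohort) && nrow(cohort) == 0L)
    stop_ventdss("cannot build features from an empty cohort")
  fields <- input_fields()
  miss <- setdiff(fields, names(cohort))
  if (length(miss))
    stop_ventdss("cohort lacks input field(s): ", paste(miss, collapse = ", "))
  if (any(is.na(cohort$disease)))
    stop_ventdss("disease label required to encode features")
  X <- cbind(disease = disease_code(cohort$disease),
             as.matrix(cohort[setdiff(fields, "disease")]))
  if (any(is.na(X))) {
    bad <- which(is.na(X), arr.ind = TRUE)
    stop_ventdss("missing value in input field '", colnames(X)[bad[1, 2]],
                 "' (records with incomplete inputs are rejected, not imputed)")
  }
  storage.mode(X) <- "double"
  colnames(X) <- fields
  X
}

#' Encode patient records as network feature matrices
#'
#' Builds the ordered 10-column feature matrix (diagnosis code, core body
#' temperature, pulse, arterial systolic pressure, diastolic blood
#' pressure, PEEP, pSO2, pH, pCO2, bicarbonate) and applies the scaler.
#' Each row depends only on its own record, so permuting cohort rows
#' permutes the output rows identically.
#'
#' @param cohort cohort data.frame (or single-row record).
#' @param scaler a `feature_scaler`; default leaves values unscaled.
#' @return numeric matrix, one row per record, 10 named columns.
#' @export
encode_features <- function(cohort, scaler = identity_scaler()) {
  X <- raw_feature_matrix(cohort)
  if (!inherits(scaler, "feature_scaler"))
    stop_ventdss("scaler must be a feature_scaler")
  if (!scaler$enabled) return(X)
  span <- scaler$max - scaler$min
  for (j in seq_len(ncol(X))) {
    X[, j] <- if (span[j] > 0) 2 * (X[, j] - scaler$min[j]) / span[j] - 1 else 0
  }
  X
}
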