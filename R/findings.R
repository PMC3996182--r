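## Finding taxonomy, binarization rules, and per-disease finding tables.
##
## A "finding" is a binary abnormality flag derived from one patient field.
## Fifteen findings are tracked per disease: four symptom-level vitals, four
## respiratory settings, five blood-gas values, and the two ventilation-mode
## indicators (which are mutually exclusive and together cover the cohort).

#' The fifteen finding names, in canonical table order
#'
#' @return character vector of length 15.
#' @export
finding_names <- function() {
  c("core_body_temperature", "pulse", "arterial_systolic_pressure",
    "diastolic_blood_pressure", "fio2", "frequency", "tidal_volume",
    "peep", "pso2", "ph", "po2", "pco2", "bicarbonate",
    "pressure_support", "volume_support")
}

#' Default binarization thresholds
#'
#' Rules translating a continuous patient field into its abnormality flag.
#' Thresholds are conventional clinical cut-offs (fever above 37.5 degrees C,
#' tachycardia above 100/min, acidosis/alkalosis outside pH 7.35-7.45,
#' supplemental oxygen above room-air FiO2 0.21, and so on); all are
#' package defaults and overridable per finding. Comparisons are strict:
#' a value exactly at a cut-off is normal.
#'
#' Rule kinds: `greater` (abnormal when value > threshold), `less`
#' (value < threshold), `outside` (value < low or > high), `mode_ps` /
#' `mode_vs` (mirrors of the support mode).
#'
#' @param overrides named list of replacement rules, each
#'   `list(kind =, threshold = )`.
#' @return named list of rules, one per finding.
#' @export
default_thresholds <- function(overrides = list()) {
  rules <- list(
    core_body_temperature      = list(kind = "greater", threshold = 37.5),
    pulse                      = list(kind = "greater", threshold = 100),
    arterial_systolic_pressure = list(kind = "outside", threshold = c(90, 140)),
    diastolic_blood_pressure   = list(kind = "greater", threshold = 90),
    fio2                       = list(kind = "greater", threshold = 0.21),
    frequency                  = list(kind = "greater", threshold = 20),
    tidal_volume               = list(kind = "less",    threshold = 400),
    peep                       = list(kind = "greater", threshold = 5),
    pso2                       = list(kind = "less",    threshold = 90),
    ph                         = list(kind = "outside", threshold = c(7.35, 7.45)),
    po2                        = list(kind = "less",    threshold = 80),
    pco2                       = list(kind = "greater", threshold = 45),
    bicarbonate                = list(kind = "outside", threshold = c(22, 26)),
    pressure_support           = list(kind = "mode_ps"),
    volume_support             = list(kind = "mode_vs")
  )
  for (nm in names(overrides)) {
    if (!nm %in% names(rules)) stop_ventdss("unknown finding: ", nm)
    rules[[nm]] <- overrides[[nm]]
  }
  rules
}

apply_rule <- function(rule, value, mode = NULL) {
  switch(rule$kind,
    greater = value > rule$threshold,
    less    = value < rule$threshold,
    outside = value < rule$threshold[1] | value > rule$threshold[2],
    mode_ps = mode == "PS",
    mode_vs = mode == "VS",
    stop_ventdss("unknown rule kind: ", rule$kind)
  )
}

#' Derive the 15 binary findings from a patient record
#'
#' Deterministic application of the threshold rules; the two mode findings
#' mirror `support_mode`, so exactly one of them is TRUE whenever the mode
#' is known.
#'
#' @param record single-row cohort data.frame or named list.
#' @param thresholds rule set, as from [default_thresholds()].
#' @return named logical vector over [finding_names()].
#' @export
binarize_findings <- function(record, thresholds = default_thresholds()) {
  record <- as_record(record)
  out <- logical(length(finding_names()))
  names(out) <- finding_names()
  for (f in finding_names()) {
    rule <- thresholds[[f]]
    if (is.null(rule)) stop_ventdss("no threshold rule for finding: ", f)
    if (rule$kind %in% c("mode_ps", "mode_vs")) {
      mode <- record$support_mode
      if (is.null(mode) || is.na(mode))
        stop_ventdss("support_mode needed for finding '", f, "' is missing")
      out[f] <- apply_rule(rule, NULL, mode)
    } else {
      v <- record[[f]]
      if (is.null(v) || is.na(v))
        stop_ventdss("field '", f, "' needed by its finding rule is missing")
      out[f] <- apply_rule(rule, v)
    }
  }
  out
}

#' Construct a per-disease finding table
#'
#' Holds, for one disease cohort, how many of its `cohort_size` patients
#' showed each of the 15 findings, together with the implied occurrence
#' proportions.
#'
#' @param disease one of "COPD", "ARDS", "CVD".
#' @param counts integer vector of 15 finding counts (names optional but,
#'   if present, must match [finding_names()]).
#' @param cohort_size number of patients in the disease cohort.
#' @return object of class `finding_table` with elements `disease`,
#'   `findings`, `counts`, `cohort_size`, `probabilities`.
#' @export
finding_table <- function(disease, counts, cohort_size) {
  disease <- match.arg(disease, names(disease_codes()))
  if (length(counts) != 15L)
    stop_ventdss("a finding table needs exactly 15 counts, got ", length(counts))
  if (!is.null(names(counts)) && !identical(names(counts), finding_names()))
    stop_ventdss("count names must match finding_names()")
  counts <- as.integer(counts)
  if (any(counts < 0) || any(counts > cohort_size))
    stop_ventdss("counts must lie in [0, cohort_size]")
  ps <- counts[match("pressure_support", finding_names())]
  vs <- counts[match("volume_support", finding_names())]
  if (ps + vs != cohort_size)
    stop_ventdss("pressure- and volume-support counts must sum to the cohort size")
  structure(list(disease = disease,
                 findings = finding_names(),
                 counts = setNames(counts, finding_names()),
                 cohort_size = as.integer(cohort_size),
                 probabilities = setNames(counts / cohort_size, finding_names())),
            class = "finding_table")
}

#' @export
print.finding_table <- function(x, ...) {
  cat(sprintf("Finding table: %s (n = %d)\n", x$disease, x$cohort_size))
  print(data.frame(finding = x$findings, count = unname(x$counts),
                   proportion = round(unname(x$probabilities), 3)))
  invisible(x)
}

#' Recover integer counts behind a column of rounded proportions
#'
#' Given finding proportions printed to three decimals, finds the smallest
#' cohort size `n <= n_max` for which every proportion equals some integer
#' count over `n` after rounding half away from zero to 3 decimals, and
#' returns that size with the counts. This inverts the rounding applied
#' when a frequency table is printed.
#'
#' @param probabilities numeric vector of proportions in \[0, 1\].
#' @param n_max largest cohort size to try.
#' @param digits decimals the proportions were printed to (default 3).
#' @return list with `cohort_size` and integer `counts`.
#' @export
rationalize_column <- function(probabilities, n_max = 200L, digits = 3L) {
  if (!length(probabilities) || any(probabilities < 0 | probabilities > 1))
    stop_ventdss("probabilities must be a nonempty vector in [0, 1]")
  if (n_max < 1) stop_ventdss("n_max must be at least 1")
  for (n in seq_len(n_max)) {
    k <- round(probabilities * n)
    if (all(abs(round_half_away(k / n, digits) - probabilities) < 1e-9))
      return(list(cohort_size = as.integer(n), counts = as.integer(k)))
  }
  stop_ventdss("irrational column: no cohort size up to ", n_max,
               " reproduces all proportions at ", digits, " decimals")
}

#' Reference finding-occurrence proportions for the three diseases
#'
#' The published occurrence proportions (3 decimals) of the 15 findings in
#' historical COPD, ARDS, and CVD cohorts, as used by the stage-1 disease
#' scorer.
#'
#' @return 15 x 3 numeric matrix, rows [finding_names()], columns diseases.
#' @export
reference_finding_probabilities <- function() {
  m <- cbind(
    COPD = c(0.267, 0.167, 0.633, 0.367, 0.933, 0.567, 0.700, 0.600,
             0.700, 0.767, 0.733, 0.567, 0.667, 0.733, 0.267),
    ARDS = c(0.738, 0.631, 0.200, 0.354, 0.769, 0.600, 0.754, 0.662,
             0.738, 0.615, 0.600, 0.585, 0.523, 0.877, 0.123),
    CVD  = c(0.825, 0.873, 0.413, 0.206, 0.778, 0.905, 0.683, 0.683,
             0.857, 0.603, 0.444, 0.683, 0.730, 0.841, 0.159))
  rownames(m) <- finding_names()
  m
}

#' Reference finding tables with reconstructed integer counts
#'
#' Loads the packaged fixture holding the three per-disease finding tables
#' whose integer counts were recovered from the published 3-decimal
#' proportions by [rationalize_column()] (cohort sizes 30, 65, and 63,
#' totalling 158 patients).
#'
#' @param file optional path to an alternative JSON table file.
#' @return named list of three `finding_table` objects (COPD, ARDS, CVD).
#' @export
reference_finding_tables <- function(file = NULL) {
  file <- file %||% system.file("extdata", "reference_finding_tables.json",
                                package = "ventdss", mustWork = TRUE)
  read_finding_tables(file)
}

#' Scale finding tables to a larger cohort
#'
#' Multiplies every count and the cohort size by an integer factor,
#' preserving all occurrence proportions exactly. Useful for generating
#' larger synthetic cohorts with the reference frequency structure, e.g.
#' for parameter-recovery experiments that need more records than free
#' network parameters.
#'
#' @param tables named list of `finding_table` objects.
#' @param factor positive integer multiplier.
#' @return named list of scaled `finding_table` objects.
#' @export
scale_finding_tables <- function(tables, factor) {
  if (factor < 1 || factor != round(factor))
    stop_ventdss("factor must be a positive integer")
  lapply(tables, function(tb)
    finding_table(tb$disease, tb$counts * factor, tb$cohort_size * factor))
}

#' Read finding tables from JSON
#'
#' Format: an array of objects `{disease, cohort_size, findings: [{name,
#' count}, ...]}` in canonical finding order.
#'
#' @param file path to a JSON file.
#' @return named list of `finding_table` objects.
#' @export
read_finding_tables <- function(file) {
  raw <- jsonlite::read_json(file, simplifyVector = FALSE)
  tables <- lapply(raw, function(tb) {
    counts <- vapply(tb$findings, function(f) as.integer(f$count), 1L)
    names(counts) <- vapply(tb$findings, function(f) f$name, "")
    if (!identical(names(counts), finding_names()))
      stop_ventdss("finding table file must list findings in canonical order")
    finding_table(tb$disease, counts, tb$cohort_size)
  })
  names(tables) <- vapply(tables, function(t) t$disease, "")
  tables[intersect(names(disease_codes()), names(tables))]
}

#' Write finding tables to JSON
#'
#' @param tables named list of `finding_table` objects.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_finding_tables <- function(tables, file) {
  payload <- lapply(tables, function(tb) {
    list(disease = tb$disease, cohort_size = tb$cohort_size,
         findings = lapply(seq_along(tb$findings), function(i)
           list(name = tb$findings[i], count = unname(tb$counts[i]))))
  })
  jsonlite::write_json(unname(payload), file, auto_unbox = TRUE, pretty = TRUE)
  invisible(file)
}
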