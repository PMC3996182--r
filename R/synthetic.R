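## Synthetic cohort generator.
##
## Emulates the statistical structure of the reference study cohort: three
## disease groups (default sizes 30 / 65 / 63, totalling 158 patients over
## 60), per-finding abnormality frequencies matching the reference finding
## tables, and rule-generated ventilator-setting targets so the stage-2
## networks have a known, recoverable signal. Only the binarized finding
## frequencies are constrained by the reference tables; the continuous
## value distributions inside each normal/abnormal slice are the package's
## own clinically plausible choices.

# Per-field generation slices: each entry gives (low, high, mean, sd) of a
# truncated normal for the normal range and for the abnormal side(s).
# Bounds respect the strict binarization comparisons with a small margin.
generation_slices <- function() {
  list(
    core_body_temperature = list(
      normal = c(35.8, 37.5, 36.8, 0.5),
      abnormal = list(c(37.6, 41.0, 38.6, 0.8))),
    pulse = list(
      normal = c(55, 100, 80, 12),
      abnormal = list(c(101, 160, 115, 12))),
    arterial_systolic_pressure = list(
      normal = c(90, 140, 115, 12),
      abnormal = list(c(60, 89.5, 80, 8), c(140.5, 200, 160, 15))),
    diastolic_blood_pressure = list(
      normal = c(45, 90, 70, 10),
      abnormal = list(c(90.5, 130, 100, 8))),
    peep = list(
      normal = c(0, 5, 4, 1.5),
      abnormal = list(c(5.5, 18, 8, 2.5))),
    pso2 = list(
      normal = c(90, 100, 95, 3),
      abnormal = list(c(60, 89.5, 82, 6))),
    ph = list(
      normal = c(7.35, 7.45, 7.40, 0.03),
      abnormal = list(c(7.10, 7.34, 7.28, 0.06), c(7.46, 7.65, 7.50, 0.04))),
    po2 = list(
      normal = c(80, 110, 92, 8),
      abnormal = list(c(35, 79.5, 62, 10))),
    pco2 = list(
      normal = c(28, 45, 38, 4),
      abnormal = list(c(45.5, 90, 58, 9))),
    bicarbonate = list(
      normal = c(22, 26, 24, 1),
      abnormal = list(c(12, 21.8, 18, 2.5), c(26.2, 40, 31, 3.5)))
  )
}

# Truncated-normal draw via inverse-CDF; bounds are honored exactly.
rtnorm <- function(n, lo, hi, mean, sd) {
  if (n == 0L) return(numeric(0))
  plo <- stats::pnorm((lo - mean) / sd)
  phi <- stats::pnorm((hi - mean) / sd)
  mean + sd * qnorm(runif(n, plo, phi))
}

#' Ground-truth rule linking physiology to ventilator settings
#'
#' The deterministic signal the generator plants for stage 2 to learn:
#' breath frequency rises with pCO2 from a per-disease base rate, tidal
#' volume falls with PEEP from a per-disease base volume, and FiO2 rises as
#' oxygen saturation drops. The mapping from physiology to settings is
#' exactly what the trained networks are meant to recover, so this rule is
#' a test harness construct, not a clinical protocol.
#'
#' @param frequency_base named per-disease base breath rates (breaths/min).
#' @param tidal_base named per-disease base tidal volumes (mL).
#' @param frequency_slope breaths/min gained per mmHg of pCO2 above 40.
#' @param tidal_slope mL lost per cmH2O of PEEP above 5.
#' @param fio2_slope FiO2 fraction gained per percentage point of pSO2
#'   below 95.
#' @return list of rule constants used by [generate_cohort()].
#' @export
ground_truth_rule <- function(frequency_base = c(COPD = 18, ARDS = 24, CVD = 16),
                              tidal_base = c(COPD = 450, ARDS = 380, CVD = 480),
                              frequency_slope = 0.6,
                              tidal_slope = 15,
                              fio2_slope = 0.012) {
  list(frequency_base = frequency_base, tidal_base = tidal_base,
       frequency_slope = frequency_slope, tidal_slope = tidal_slope,
       fio2_slope = fio2_slope)
}

#' Specification of a synthetic cohort
#'
#' @param sizes named per-disease group sizes; the defaults reproduce the
#'   reference cohort structure (30 COPD, 65 ARDS, 63 CVD; 158 patients).
#' @param mode `"exact_counts"`: for every disease and finding, exactly the
#'   table count of patients carries the abnormal value, so binarizing the
#'   cohort reproduces the tables verbatim. `"bernoulli"`: each patient is
#'   abnormal independently with probability count/n, so frequencies match
#'   in expectation only.
#' @param tables per-disease finding tables supplying the counts
#'   (default: the reconstructed reference tables).
#' @param thresholds binarization rules, shared with the diagnosis stage.
#' @param rule ground-truth output rule, see [ground_truth_rule()].
#' @param noise named per-output noise standard deviations (breaths/min,
#'   mL, FiO2 fraction). Noise is truncated so a patient never crosses its
#'   assigned side of the output threshold, keeping exact counts exact.
#' @param seed generator seed; the same spec and seed give the identical
#'   cohort.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(sizes = c(COPD = 30L, ARDS = 65L, CVD = 63L),
                        mode = c("exact_counts", "bernoulli"),
                        tables = reference_finding_tables(),
                        thresholds = default_thresholds(),
                        rule = ground_truth_rule(),
                        noise = c(frequency = 1.5, tidal_volume = 25, fio2 = 0.03),
                        seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(names(sizes)) || !all(names(sizes) %in% names(disease_codes())))
    stop_ventdss("sizes must be named with disease labels")
  if (any(sizes <= 0)) stop_ventdss("group sizes must be positive")
  if (any(noise < 0)) stop_ventdss("noise standard deviations must be nonnegative")
  structure(list(sizes = sizes, mode = mode, tables = tables,
                 thresholds = thresholds, rule = rule, noise = noise,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Choose which patients are abnormal for one finding.
draw_abnormal_set <- function(n, count, prob, mode) {
  if (mode == "exact_counts") {
    if (count > n)
      stop_ventdss("finding count ", count, " exceeds group size ", n,
                   " in exact_counts mode")
    idx <- logical(n)
    if (count > 0) idx[sample.int(n, count)] <- TRUE
    idx
  } else {
    runif(n) < prob
  }
}

# Fill one continuous field: normal patients from the normal slice,
# abnormal patients from a randomly chosen abnormal slice.
draw_field_values <- function(abnormal, slices) {
  n <- length(abnormal)
  v <- numeric(n)
  nrm <- slices$normal
  v[!abnormal] <- rtnorm(sum(!abnormal), nrm[1], nrm[2], nrm[3], nrm[4])
  k <- sum(abnormal)
  if (k > 0) {
    sides <- slices$abnormal
    pick <- if (length(sides) == 1L) rep(1L, k) else sample.int(length(sides), k, replace = TRUE)
    vals <- numeric(k)
    for (s in seq_along(sides)) {
      sl <- sides[[s]]
      m <- pick == s
      vals[m] <- rtnorm(sum(m), sl[1], sl[2], sl[3], sl[4])
    }
    v[abnormal] <- vals
  }
  v
}

# Monotone order-preserving layout of raw rule scores into a value slice:
# affine map of the subset's raw range onto the interval.
layout_into <- function(raw, interval) {
  if (!length(raw)) return(numeric(0))
  lo <- interval[1]; hi <- interval[2]
  span <- max(raw) - min(raw)
  if (span <= 0) return(rep((lo + hi) / 2, length(raw)))
  lo + (raw - min(raw)) / span * (hi - lo)
}

# Generate one regression output for a disease group: compute the raw rule
# score, assign the abnormal side to the k most extreme patients, lay both
# subsets monotonically into their slices, then add slice-truncated noise.
generate_output <- function(raw, count, prob, mode, abnormal_high, normal_int,
                            abnormal_int, noise_sd) {
  n <- length(raw)
  k <- if (mode == "exact_counts") count else sum(runif(n) < prob)
  k <- min(k, n)
  ord <- order(raw, seq_len(n))           # deterministic tie-break by index
  abnormal <- logical(n)
  if (k > 0)
    abnormal[if (abnormal_high) ord[(n - k + 1L):n] else ord[seq_len(k)]] <- TRUE
  v <- numeric(n)
  v[!abnormal] <- layout_into(raw[!abnormal], normal_int)
  v[abnormal] <- layout_into(raw[abnormal], abnormal_int)
  if (noise_sd > 0) {
    v <- v + rnorm(n, 0, noise_sd)
    v[!abnormal] <- pmin(pmax(v[!abnormal], normal_int[1]), normal_int[2])
    v[abnormal] <- pmin(pmax(v[abnormal], abnormal_int[1]), abnormal_int[2])
  }
  v
}

generate_disease_group <- function(disease, n, spec) {
  table <- spec$tables[[disease]]
  if (is.null(table)) stop_ventdss("no finding table for disease ", disease)
  counts <- table$counts
  probs <- table$probabilities
  g <- data.frame(patient_id = sprintf("%s-%03d", disease, seq_len(n)),
                  disease = disease, stringsAsFactors = FALSE)
  slices <- generation_slices()
  for (f in names(slices)) {
    abnormal <- draw_abnormal_set(n, counts[[f]], probs[[f]], spec$mode)
    g[[f]] <- draw_field_values(abnormal, slices[[f]])
  }
  # support mode: exactly the table count of pressure-support patients
  # (or an independent Bernoulli draw per patient)
  ps_abn <- draw_abnormal_set(n, counts[["pressure_support"]],
                              probs[["pressure_support"]], spec$mode)
  g$support_mode <- ifelse(ps_abn, "PS", "VS")
  rule <- spec$rule
  raw_f <- rule$frequency_base[[disease]] + rule$frequency_slope * (g$pco2 - 40)
  raw_v <- rule$tidal_base[[disease]] - rule$tidal_slope * (g$peep - 5)
  raw_o <- 0.21 + rule$fio2_slope * (95 - g$pso2)
  g$frequency <- generate_output(raw_f, counts[["frequency"]],
                                 probs[["frequency"]], spec$mode,
                                 abnormal_high = TRUE,
                                 normal_int = c(8, 20), abnormal_int = c(20.3, 38),
                                 noise_sd = spec$noise[["frequency"]])
  g$tidal_volume <- generate_output(raw_v, counts[["tidal_volume"]],
                                    probs[["tidal_volume"]], spec$mode,
                                    abnormal_high = FALSE,
                                    normal_int = c(402, 650),
                                    abnormal_int = c(250, 398),
                                    noise_sd = spec$noise[["tidal_volume"]])
  g$fio2 <- generate_output(raw_o, counts[["fio2"]], probs[["fio2"]], spec$mode,
                            abnormal_high = TRUE,
                            normal_int = c(0.21, 0.21),
                            abnormal_int = c(0.215, 0.9),
                            noise_sd = spec$noise[["fio2"]])
  g[cohort_columns()]
}

#' Generate a synthetic patient cohort
#'
#' Draws the three disease groups described by the spec. In
#' `"exact_counts"` mode, binarizing the generated cohort with the same
#' thresholds reproduces every finding-table count exactly — including the
#' four ventilator-setting findings, whose values are laid out monotonically
#' over the ground-truth rule's raw scores so that precisely the required
#' number of patients falls on the abnormal side while the settings remain
#' a deterministic, learnable function of the physiology.
#'
#' @param spec a [cohort_spec()].
#' @return cohort data.frame, one row per patient, groups stacked in
#'   disease order.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "cohort_spec")) stop_ventdss("spec must be a cohort_spec")
  with_seed(spec$seed, {
    groups <- lapply(names(spec$sizes), function(d)
      generate_disease_group(d, as.integer(spec$sizes[[d]]), spec))
    out <- do.call(rbind, groups)
    rownames(out) <- NULL
    out
  })
}

#' Tabulate finding frequencies from a labeled cohort
#'
#' Binarizes every record and counts findings per disease group — the
#' inverse of exact-count generation, and the way a new historical cohort
#' would be turned into stage-1 scoring tables.
#'
#' @param cohort labeled cohort data.frame.
#' @param thresholds binarization rules.
#' @return named list of `finding_table` objects, one per disease present.
#' @export
cohort_to_finding_tables <- function(cohort, thresholds = default_thresholds()) {
  if (any(is.na(cohort$disease)))
    stop_ventdss("all records must carry a disease label")
  diseases <- intersect(names(disease_codes()), unique(cohort$disease))
  if (!length(diseases)) stop_ventdss("cohort holds no labeled records")
  tables <- lapply(diseases, function(d) {
    grp <- cohort[cohort$disease == d, , drop = FALSE]
    if (!nrow(grp)) stop_ventdss("empty disease group: ", d)
    # column-wise application of the same rules binarize_findings uses
    counts <- vapply(finding_names(), function(f) {
      rule <- thresholds[[f]]
      if (is.null(rule)) stop_ventdss("no threshold rule for finding: ", f)
      if (rule$kind %in% c("mode_ps", "mode_vs")) {
        if (any(is.na(grp$support_mode)))
          stop_ventdss("support_mode needed for finding '", f, "' is missing")
        sum(apply_rule(rule, NULL, grp$support_mode))
      } else {
        v <- grp[[f]]
        if (is.null(v) || any(is.na(v)))
          stop_ventdss("field '", f, "' needed by its finding rule is missing")
        sum(apply_rule(rule, v))
      }
    }, 0)
    finding_table(d, counts, nrow(grp))
  })
  names(tables) <- diseases
  tables
}
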