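## Stage-1 disease scoring: the finding-frequency probability model.
##
## Each disease is scored by a self-weighted average of its finding
## occurrence proportions: weights w_i = x_i / sum(x_j) are the normalized
## finding frequencies, and the score is F = sum(w_i * p_i). With p_i =
## count_i / n this collapses to F = sum(p_i^2) / sum(p_i), which lies
## between the smallest and largest proportion scored.

#' Occurrence proportion of one finding
#'
#' @param count patients in the cohort showing the finding.
#' @param cohort_size cohort size (> 0).
#' @return `count / cohort_size`.
#' @export
finding_probability <- function(count, cohort_size) {
  if (length(cohort_size) != 1L || cohort_size <= 0)
    stop_ventdss("cohort_size must be a single positive integer")
  if (any(count < 0) || any(count > cohort_size))
    stop_ventdss("count must lie in [0, cohort_size]")
  count / cohort_size
}

#' Self-normalized finding weights
#'
#' Weight of each finding is its frequency divided by the total frequency,
#' so the weights sum to one and are invariant to rescaling all inputs by
#' a positive constant (counts and proportions give identical weights).
#'
#' @param values nonnegative finding frequencies (counts or proportions).
#' @return weights summing to 1.
#' @export
feature_weights <- function(values) {
  if (!length(values) || any(!is.finite(values)) || any(values < 0))
    stop_ventdss("values must be finite and nonnegative")
  total <- sum(values)
  if (total <= 0) stop_ventdss("at least one value must be positive")
  values / total
}

#' Finding-frequency disease score
#'
#' The weighted sum `F = sum(w_i * p_i)` with self-normalized weights from
#' [feature_weights()]; algebraically `sum(p^2) / sum(p)`. Being a convex
#' combination of the proportions, F always lies in `[min(p), max(p)]`.
#'
#' @param probabilities finding occurrence proportions in \[0, 1\].
#' @return scalar score in \[0, 1\].
#' @export
disease_probability <- function(probabilities) {
  if (any(probabilities < 0 | probabilities > 1))
    stop_ventdss("probabilities must lie in [0, 1]")
  w <- feature_weights(probabilities)
  sum(w * probabilities)
}

#' Total probability from marginals and conditionals
#'
#' `P(D) = sum(P(x_i) * P(D | x_i))` over a finding partition. Exposed for
#' completeness of the probability toolkit; the default scoring pipeline
#' works from occurrence proportions instead because per-finding marginals
#' are rarely tabulated.
#'
#' @param marginals `P(x_i)` values in \[0, 1\].
#' @param conditionals `P(D | x_i)` values in \[0, 1\], same length.
#' @return scalar probability.
#' @export
total_probability <- function(marginals, conditionals) {
  if (length(marginals) != length(conditionals))
    stop_ventdss("marginals and conditionals must have equal length")
  if (any(marginals < 0 | marginals > 1) || any(conditionals < 0 | conditionals > 1))
    stop_ventdss("probabilities must lie in [0, 1]")
  sum(marginals * conditionals)
}

#' Conditional probability from a joint and a marginal
#'
#' `P(D | x) = P(D & x) / P(x)`.
#'
#' @param joint `P(D & x)`.
#' @param marginal `P(x)`, must be positive and at least `joint`.
#' @return scalar in \[0, 1\].
#' @export
conditional_probability <- function(joint, marginal) {
  assert_scalar_number(joint, "joint")
  assert_scalar_number(marginal, "marginal")
  if (marginal <= 0) stop_ventdss("marginal probability must be positive")
  if (joint < 0 || joint > marginal)
    stop_ventdss("joint must lie in [0, marginal]")
  joint / marginal
}

#' Rank candidate diagnoses for one patient
#'
#' Scores each disease with [disease_probability()] restricted to the
#' findings PRESENT in the patient: the table proportions of the present
#' findings are scored with weights renormalized over that subset. When all
#' 15 findings are present the full-column score is recovered. Ties break
#' by the fixed disease order COPD, ARDS, CVD.
#'
#' @param presence logical vector over [finding_names()], as from
#'   [binarize_findings()].
#' @param tables named list of three `finding_table` objects.
#' @return data.frame (disease, score) sorted by decreasing score.
#' @export
rank_diseases <- function(presence, tables = reference_finding_tables()) {
  if (!is.logical(presence) || length(presence) != 15L)
    stop_ventdss("presence must be 15 logicals, one per finding")
  if (!is.null(names(presence)) && !identical(names(presence), finding_names()))
    stop_ventdss("presence names must match finding_names()")
  need <- names(disease_codes())
  if (!all(need %in% names(tables)))
    stop_ventdss("tables must cover all of: ", paste(need, collapse = ", "))
  if (!any(presence))
    stop_ventdss("no finding present: automated scoring is not informative, ",
                 "refer for manual diagnosis")
  scores <- vapply(need, function(d) {
    p <- tables[[d]]$probabilities[presence]
    # a disease that never showed any of the present findings scores 0
    if (all(p == 0)) 0 else disease_probability(p)
  }, 0)
  ord <- order(-scores, match(need, need))
  data.frame(disease = need[ord], score = unname(scores[ord]),
             stringsAsFactors = FALSE)
}
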