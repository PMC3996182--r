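## End-to-end recommendation pipeline: validate -> diagnose -> recommend.

#' Train a full recommender bundle on a labeled cohort
#'
#' Fits the feature scaler, the regression head (frequency, tidal volume,
#' FiO2) and the mode classifier on the whole cohort, and packages them
#' with the finding tables needed for stage-1 scoring.
#'
#' @param cohort labeled training cohort with complete outputs.
#' @param config a [train_config()].
#' @param tables finding tables for the diagnosis stage.
#' @param seed initialization seed.
#' @return object of class `model_bundle`.
#' @export
fit_model_bundle <- function(cohort, config = train_config(),
                             tables = reference_finding_tables(), seed = 1L) {
  fit <- fit_fold_models(cohort, config, derive_seed(seed, 0L))
  structure(c(fit, list(tables = tables, config = config, seed = seed)),
            class = "model_bundle")
}

#' Recommend ventilator settings for one patient
#'
#' Runs the full pipeline on a single record: plausibility screening,
#' stage-1 disease ranking from the binarized findings, then — if the
#' record is plausible or the physician override is set — the stage-2
#' network prediction of the four ventilator settings. A suspect record
#' without override is refused: the report carries the alerts and no
#' settings, mirroring the physician-confirmation gate of the pipeline.
#'
#' The stage-2 networks consume the patient's confirmed diagnosis; by
#' default that is the stage-1 top-ranked disease, which a physician can
#' overrule via `accept_diagnosis`.
#'
#' @param record single-row cohort data.frame (outputs may be absent).
#' @param bundle a [fit_model_bundle()] result.
#' @param ranges plausibility ranges for the screening gate.
#' @param thresholds binarization rules for stage-1 findings. The mode
#'   findings need `support_mode`; records without one are scored on the
#'   13 physiological findings only.
#' @param accept_diagnosis optional disease label confirmed by the
#'   physician; default accepts the stage-1 ranking.
#' @param override if TRUE, a suspect record is processed anyway.
#' @return object of class `recommendation`: validation report, ranked
#'   disease scores, and (unless blocked) the four recommended settings.
#' @export
recommend <- function(record, bundle, ranges = default_plausibility_ranges(),
                      thresholds = default_thresholds(),
                      accept_diagnosis = NULL, override = FALSE) {
  if (!inherits(bundle, "model_bundle"))
    stop_ventdss("bundle must be a model_bundle (see fit_model_bundle)")
  record <- as_record(record)
  validation <- validate_record(record, ranges)
  blocked <- !validation$ok && !override
  # stage 1: score diseases on the findings derivable from the record
  presence <- tryCatch(binarize_findings(record, thresholds), error = function(e) NULL)
  if (is.null(presence)) {
    # settings or mode absent: score on the physiological findings alone
    partial <- thresholds
    known <- !vapply(finding_names(), function(f) {
      rule <- partial[[f]]
      if (rule$kind %in% c("mode_ps", "mode_vs")) is.null(record$support_mode) || is.na(record$support_mode)
      else is.null(record[[f]]) || is.na(record[[f]])
    }, TRUE)
    presence <- logical(15L); names(presence) <- finding_names()
    for (f in finding_names()[known]) {
      rule <- partial[[f]]
      presence[f] <- if (rule$kind %in% c("mode_ps", "mode_vs"))
        apply_rule(rule, NULL, record$support_mode) else apply_rule(rule, record[[f]])
    }
  }
  ranking <- rank_diseases(presence, bundle$tables)
  diagnosis <- accept_diagnosis %||% ranking$disease[1]
  diagnosis <- match.arg(diagnosis, names(disease_codes()))
  settings <- NULL
  if (!blocked) {
    rec <- record
    rec$disease <- diagnosis
    one <- as.data.frame(rec[intersect(names(rec), cohort_columns())],
                         stringsAsFactors = FALSE)
    pred <- predict_fold(bundle, one)
    settings <- list(frequency = unname(pred$regression[1, "frequency"]),
                     tidal_volume = unname(pred$regression[1, "tidal_volume"]),
                     fio2 = unname(pred$regression[1, "fio2"]),
                     support_mode = pred$mode[1],
                     mode_probability = unname(pred$mode_probability[1]))
  }
  structure(list(patient_id = record$patient_id %||% NA_character_,
                 validation = validation, blocked = blocked,
                 diagnosis = diagnosis, ranking = ranking,
                 settings = settings),
            class = "recommendation")
}

#' @export
print.recommendation <- function(x, ...) {
  cat(sprintf("Recommendation for %s\n", x$patient_id))
  print(x$validation)
  cat("Disease ranking:\n")
  for (i in seq_len(nrow(x$ranking)))
    cat(sprintf("  %d. %s (score %.4f)\n", i, x$ranking$disease[i], x$ranking$score[i]))
  if (x$blocked) {
    cat("BLOCKED: suspect record; physician override required for settings.\n")
  } else {
    s <- x$settings
    cat(sprintf(paste0("Settings: frequency %.1f /min, tidal volume %.0f mL, ",
                       "FiO2 %.2f, mode %s (P[PS] = %.3f)\n"),
                s$frequency, s$tidal_volume, s$fio2, s$support_mode,
                s$mode_probability))
  }
  invisible(x)
}

#' Write a run manifest
#'
#' Records command, seed, configuration snapshot, and input/output paths of
#' a pipeline run so deterministic commands can be reproduced bit for bit.
#'
#' @param command name of the command executed.
#' @param seed integer seed used.
#' @param config list snapshot of the configuration.
#' @param inputs,outputs character vectors of paths.
#' @param file output JSON path.
#' @return `file`, invisibly.
#' @export
write_manifest <- function(command, seed, config = list(),
                           inputs = character(), outputs = character(),
                           file) {
  payload <- list(command = command, seed = seed, config = config,
                  inputs = inputs, outputs = outputs,
                  package_version = as.character(utils::packageVersion("ventdss")),
                  timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}
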