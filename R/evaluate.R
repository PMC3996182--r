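## Success metrics, k-fold cross-validation, and benchmark reports.

#' Build a k-fold partition plan
#'
#' Indices 1..n are shuffled with the seeded generator and split into k
#' contiguous blocks whose sizes differ by at most one. The folds are
#' pairwise disjoint and jointly complete.
#'
#' @param n number of samples.
#' @param k number of folds, `2 <= k <= n`.
#' @param seed shuffle seed.
#' @return object of class `fold_plan`: list of k integer index vectors,
#'   with the seed attached as an attribute.
#' @export
kfold_indices <- function(n, k, seed = 1L) {
  if (k > n) stop_ventdss("k (", k, ") cannot exceed n (", n, ")")
  if (k < 2L) stop_ventdss("k must be at least 2")
  perm <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  plan <- lapply(seq_len(k), function(i) sort(perm[starts[i]:ends[i]]))
  structure(plan, class = "fold_plan", seed = as.integer(seed), n = as.integer(n))
}

#' Regression success rate
#'
#' Two definitions are available. The default, `"nmae"`, is the complement
#' of the normalized mean absolute error:
#' `100 * (1 - mean(|pred - truth| / reference_range))`, floored at 0, so a
#' perfect predictor scores 100 and a predictor whose average error equals
#' the reference span scores 0. The alternative, `"within_tolerance"`, is
#' the percentage of predictions within `tolerance * reference_range` of
#' the truth. The reference range should always come from training-fold
#' truths.
#'
#' @param predictions numeric vector of predicted values.
#' @param truths numeric vector of true values, same length.
#' @param reference_range positive span used to normalize errors.
#' @param metric `"nmae"` (default) or `"within_tolerance"`.
#' @param tolerance half-width of the acceptance band for
#'   `"within_tolerance"`, as a fraction of `reference_range`.
#' @return success percentage in \[0, 100\].
#' @export
regression_success <- function(predictions, truths, reference_range,
                               metric = c("nmae", "within_tolerance"),
                               tolerance = 0.05) {
  metric <- match.arg(metric)
  if (length(predictions) != length(truths) || !length(truths))
    stop_ventdss("predictions and truths must be nonempty and equal length")
  if (!is.finite(reference_range) || reference_range <= 0)
    stop_ventdss("reference_range must be positive")
  err <- abs(predictions - truths)
  if (metric == "nmae") max(0, 100 * (1 - mean(err / reference_range)))
  else 100 * mean(err <= tolerance * reference_range)
}

#' Classification success rate
#'
#' @param predicted vector of predicted mode labels.
#' @param truth vector of true mode labels, same length.
#' @return percentage of agreeing positions.
#' @export
classification_success <- function(predicted, truth) {
  if (!length(truth) || length(predicted) != length(truth))
    stop_ventdss("predicted and truth must be nonempty and equal length")
  100 * mean(predicted == truth)
}

#' Aggregate the best per-output success rates
#'
#' The overall accuracy of the recommender is the arithmetic mean of the
#' best achieved success rate for each of the four output parameters
#' (frequency, tidal volume, FiO2, mode classification), rounded half away
#' from zero to two decimals.
#'
#' @param best_rates four percentages in \[0, 100\].
#' @return scalar percentage.
#' @export
overall_accuracy <- function(best_rates) {
  if (length(best_rates) != 4L || any(!is.finite(best_rates)))
    stop_ventdss("best_rates must be four finite percentages")
  if (any(best_rates < 0 | best_rates > 100))
    stop_ventdss("percentages must lie in [0, 100]")
  round_half_away(mean(best_rates), 2)
}

# Train the two heads (regression + mode classifier) on one training set,
# entirely blind to the test fold.
fit_fold_models <- function(train, config, fold_seed) {
  scaler <- fit_feature_scaler(train)
  Xtr <- encode_features(train, scaler)
  reg_targets <- c("frequency", "tidal_volume", "fio2")
  Ytr_raw <- as.matrix(train[reg_targets])
  t_min <- apply(Ytr_raw, 2, min); t_max <- apply(Ytr_raw, 2, max)
  t_span <- pmax(t_max - t_min, 1e-12)
  Ytr <- sweep(sweep(Ytr_raw, 2, t_min), 2, t_span, `/`) * 2 - 1
  reg_model <- init_mlp(c(10L, config$hidden_units, 3L),
                        seed = derive_seed(fold_seed, 1L))
  reg_run <- train_mlp(reg_model, Xtr, Ytr, config)
  cls_model <- init_mlp(c(10L, config$hidden_units, 1L),
                        seed = derive_seed(fold_seed, 2L),
                        output_activation = "logistic")
  Ycls <- matrix(as.numeric(train$support_mode == "PS"), ncol = 1L)
  cls_run <- train_mlp(cls_model, Xtr, Ycls, config)
  list(scaler = scaler, reg = reg_run$model, cls = cls_run$model,
       t_min = t_min, t_span = t_span,
       ranges = setNames(apply(Ytr_raw, 2, function(v) diff(range(v))),
                         reg_targets))
}

predict_fold <- function(models, records) {
  X <- encode_features(records, models$scaler)
  Yhat <- mlp_forward(models$reg, X)
  Yhat <- sweep(sweep((Yhat + 1) / 2, 2, models$t_span, `*`), 2, models$t_min, `+`)
  colnames(Yhat) <- c("frequency", "tidal_volume", "fio2")
  p <- mlp_forward(models$cls, X)[, 1]
  # exact 0.5 resolves to pressure support, the majority mode
  mode <- ifelse(p >= 0.5, "PS", "VS")
  list(regression = Yhat, mode = mode, mode_probability = p)
}

#' k-fold cross-validation of the ventilator-settings recommender
#'
#' For each fold, the feature scaler, the output scaling, the reference
#' ranges, and both network heads are fitted on the k-1 training folds
#' only; the held-out fold is used exclusively for scoring. Per-output
#' success rates are collected across folds and summarized as mean and
#' sample standard deviation.
#'
#' @param cohort labeled cohort data.frame with complete inputs and outputs.
#' @param config a [train_config()].
#' @param k number of folds (default 10).
#' @param seed seed for the fold shuffle and per-fold model
#'   initializations.
#' @param metric,tolerance regression success definition, see
#'   [regression_success()].
#' @param keep_models if TRUE, the per-fold fitted models are attached
#'   (useful for audits; off by default to keep reports small).
#' @return object of class `cv_report` with elements `algorithm`,
#'   `hidden_units`, `k`, `seed`, `folds` (k x 4 matrix of success rates),
#'   and `summary` (per-output mean and sd).
#' @export
cross_validate <- function(cohort, config = train_config(), k = 10L, seed = 1L,
                           metric = c("nmae", "within_tolerance"),
                           tolerance = 0.05, keep_models = FALSE) {
  metric <- match.arg(metric)
  need <- c(input_fields(), output_fields())
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop_ventdss("cohort lacks column(s): ", paste(miss, collapse = ", "))
  if (any(is.na(cohort[need])))
    stop_ventdss("cross-validation needs complete inputs and outputs")
  n <- nrow(cohort)
  plan <- kfold_indices(n, k, seed)
  if (any(lengths(plan) < 2L))
    stop_ventdss("every fold must hold at least 2 records; reduce k")
  outputs <- c("frequency", "tidal_volume", "fio2", "ps_vs")
  folds <- matrix(NA_real_, k, 4L, dimnames = list(NULL, outputs))
  models <- vector("list", k)
  for (i in seq_len(k)) {
    test_idx <- plan[[i]]
    train <- cohort[-test_idx, , drop = FALSE]
    test <- cohort[test_idx, , drop = FALSE]
    fit <- fit_fold_models(train, config, derive_seed(seed, i))
    pred <- predict_fold(fit, test)
    for (o in c("frequency", "tidal_volume", "fio2"))
      folds[i, o] <- regression_success(pred$regression[, o], test[[o]],
                                        fit$ranges[o], metric = metric,
                                        tolerance = tolerance)
    folds[i, "ps_vs"] <- classification_success(pred$mode, test$support_mode)
    if (keep_models) models[[i]] <- fit
  }
  summary <- data.frame(mean = colMeans(folds), sd = apply(folds, 2, sd),
                        row.names = outputs)
  structure(list(algorithm = config$algorithm,
                 hidden_units = config$hidden_units,
                 k = as.integer(k), seed = as.integer(seed),
                 folds = folds, summary = summary,
                 models = if (keep_models) models else NULL),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation: %s, %d hidden units (seed %d)\n",
              x$k, x$algorithm, x$hidden_units, x$seed))
  s <- x$summary
  for (o in rownames(s))
    cat(sprintf("  %-12s %6.2f +/- %.3f\n", o, s[o, "mean"], s[o, "sd"]))
  invisible(x)
}

#' Benchmark several training algorithms by cross-validation
#'
#' Runs [cross_validate()] once per algorithm and assembles the standard
#' benchmark table: one row per algorithm, one `mean +/- s` cell per output
#' parameter.
#'
#' @param cohort labeled cohort with complete outputs.
#' @param algorithms character vector of algorithm names.
#' @param hidden_units hidden-layer width shared by all runs.
#' @param k folds.
#' @param seed seed shared by all runs (folds are identical across
#'   algorithms, making rows comparable).
#' @param ... further [train_config()] arguments.
#' @return list with `reports` (named list of `cv_report`s) and `table`
#'   (formatted data.frame).
#' @export
benchmark_algorithms <- function(cohort,
                                 algorithms = c("lm", "bayes_reg", "oss",
                                                "bfgs", "cyclical", "sequential"),
                                 hidden_units = 10L, k = 10L, seed = 1L, ...) {
  reports <- lapply(algorithms, function(a) {
    cfg <- train_config(algorithm = a, hidden_units = hidden_units,
                        seed = seed, ...)
    cross_validate(cohort, cfg, k = k, seed = seed)
  })
  names(reports) <- algorithms
  list(reports = reports, table = cv_table(reports))
}

#' Format cross-validation reports as a benchmark table
#'
#' @param reports named list of `cv_report` objects.
#' @return data.frame: one row per algorithm, `mean +/- s` strings per
#'   output parameter.
#' @export
cv_table <- function(reports) {
  fmt <- function(rep, o)
    sprintf("%.3f +/- %.3f", rep$summary[o, "mean"], rep$summary[o, "sd"])
  data.frame(algorithm = names(reports),
             frequency = vapply(reports, fmt, "", o = "frequency"),
             tidal_volume = vapply(reports, fmt, "", o = "tidal_volume"),
             fio2 = vapply(reports, fmt, "", o = "fio2"),
             ps_vs = vapply(reports, fmt, "", o = "ps_vs"),
             row.names = NULL)
}

#' Serialize a cv_report to JSON
#'
#' Full dump (per-fold rates, summary, configuration identifiers).
#'
#' @param report a `cv_report`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_cv_report <- function(report, file) {
  payload <- list(algorithm = report$algorithm,
                  hidden_units = report$hidden_units,
                  k = report$k, seed = report$seed,
                  folds = as.data.frame(report$folds),
                  summary = cbind(output = rownames(report$summary),
                                  report$summary))
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(file)
}
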