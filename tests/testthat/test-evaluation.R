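test_that("fold plans are disjoint, complete, and balanced", {
  p10 <- kfold_indices(10, 10, seed = 1)
  expect_true(all(lengths(p10) == 1L))

  p158 <- kfold_indices(158, 10, seed = 1)
  expect_identical(sort(lengths(p158), decreasing = TRUE),
                   c(rep(16L, 8), rep(15L, 2)))

  expect_identical(kfold_indices(158, 10, seed = 3), kfold_indices(158, 10, seed = 3))
  expect_false(identical(kfold_indices(158, 10, seed = 3),
                         kfold_indices(158, 10, seed = 4)))

  set.seed(5)
  for (i in 1:25) {
    n <- sample(10:200, 1); k <- sample(2:min(n, 12), 1)
    plan <- kfold_indices(n, k, seed = i)
    idx <- unlist(plan)
    expect_identical(sort(idx), seq_len(n))          # complete + disjoint
    expect_lte(diff(range(lengths(plan))), 1L)       # balanced
  }
  expect_error(kfold_indices(5, 6, seed = 1), "exceed")
})

test_that("regression success follows the normalized-MAE definition", {
  y <- c(10, 20, 30)
  expect_equal(regression_success(y, y, 50), 100)
  expect_equal(regression_success(5, 15, 10), 0)       # error equals the range
  expect_equal(regression_success(c(0, 5), c(0, 0), 10), 75)  # (0, half-range)
  expect_equal(regression_success(c(0, 0), c(100, 100), 10), 0)  # floored
  expect_error(regression_success(1, 1, 0), "positive")

  # invariance under joint affine rescaling
  set.seed(6)
  for (i in 1:20) {
    truth <- rnorm(10); pred <- truth + rnorm(10, sd = 0.3)
    a <- runif(1, 0.5, 20); b <- rnorm(1)
    s1 <- regression_success(pred, truth, diff(range(truth)))
    s2 <- regression_success(a * pred + b, a * truth + b, a * diff(range(truth)))
    expect_equal(s1, s2, tolerance = 1e-9)
  }

  # within-tolerance variant counts hits inside the band
  expect_equal(regression_success(c(1, 1.04, 2), c(1, 1, 1), 1,
                                  metric = "within_tolerance"),
               100 * 2 / 3)
})

test_that("classification success equals the brute-force agreement count", {
  expect_equal(classification_success(c("PS", "VS"), c("PS", "VS")), 100)
  expect_equal(classification_success(c("PS", "PS", "PS", "VS"),
                                      c("PS", "PS", "PS", "PS")), 75)
  set.seed(8)
  for (i in 1:20) {
    truth <- sample(c("PS", "VS"), 30, replace = TRUE)
    pred <- sample(truth)
    expect_equal(classification_success(pred, truth),
                 100 * sum(pred == truth) / 30)
  }
  expect_error(classification_success(character(), character()), "nonempty")
})

test_that("overall accuracy averages the four best per-output rates", {
  expect_equal(overall_accuracy(c(100, 100, 100, 100)), 100.00)
  expect_equal(overall_accuracy(c(0, 0, 0, 0)), 0.00)
  expect_equal(overall_accuracy(c(100, 99.81, 99.54, 94.40)), 98.44)
  expect_error(overall_accuracy(c(101, 50, 50, 50)), "100")
  expect_error(overall_accuracy(c(90, 90, 90)), "four")
})

test_that("cross-validation is deterministic and self-consistent", {
  co <- generate_cohort(cohort_spec(seed = 6))[seq(1, 158, by = 2), ]
  cfg <- train_config("lm", hidden_units = 4, max_epochs = 12)
  r1 <- cross_validate(co, cfg, k = 4, seed = 9)
  r2 <- cross_validate(co, cfg, k = 4, seed = 9)
  expect_identical(r1$folds, r2$folds)

  # summary is recomputable from the fold lists
  expect_equal(unname(r1$summary$mean), unname(colMeans(r1$folds)),
               tolerance = 1e-9)
  expect_equal(unname(r1$summary$sd), unname(apply(r1$folds, 2, sd)),
               tolerance = 1e-9)
  expect_true(all(r1$folds >= 0 & r1$folds <= 100))
  expect_error(cross_validate(co[1:5, ], cfg, k = 4, seed = 1), "at least 2")
})

test_that("held-out folds never leak into training", {
  co <- generate_cohort(cohort_spec(seed = 7))[1:60, ]
  cfg <- train_config("lm", hidden_units = 3, max_epochs = 10)
  base <- cross_validate(co, cfg, k = 3, seed = 5, keep_models = TRUE)
  plan <- kfold_indices(nrow(co), 3, seed = 5)

  # corrupt the targets of fold 1's held-out rows only
  poisoned <- co
  poisoned[plan[[1]], c("frequency", "tidal_volume", "fio2")] <-
    poisoned[plan[[1]], c("frequency", "tidal_volume", "fio2")] * 10
  poisoned$support_mode[plan[[1]]] <-
    ifelse(poisoned$support_mode[plan[[1]]] == "PS", "VS", "PS")
  again <- cross_validate(poisoned, cfg, k = 3, seed = 5, keep_models = TRUE)

  # fold 1's models were trained without its test rows: identical parameters
  expect_identical(flatten_params(again$models[[1]]$reg),
                   flatten_params(base$models[[1]]$reg))
  expect_identical(flatten_params(again$models[[1]]$cls),
                   flatten_params(base$models[[1]]$cls))
  # but its scores changed, proving the corruption reached the scoring
  expect_false(isTRUE(all.equal(again$folds[1, ], base$folds[1, ])))
})

test_that("benchmark tables carry one row per algorithm", {
  co <- generate_cohort(cohort_spec(seed = 3))[1:40, ]
  bm <- benchmark_algorithms(co, algorithms = c("lm", "sequential"),
                             hidden_units = 3, k = 3, seed = 2, max_epochs = 6)
  expect_identical(bm$table$algorithm, c("lm", "sequential"))
  expect_identical(ncol(bm$table), 5L)
  expect_match(bm$table$frequency[1], "\\+/-")
  f <- withr::local_tempfile(fileext = ".json")
  write_cv_report(bm$reports$lm, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(nrow(back$folds), 3)
  expect_identical(back$algorithm, "lm")
})
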