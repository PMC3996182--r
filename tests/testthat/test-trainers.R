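# Shared toy problem: a noise-free affine law fitted by a bare linear net,
# where the normal equations give the exact answer.
linear_toy <- function(n = 20, seed = 9) {
  set.seed(seed)
  x <- matrix(seq(0, 1, length.out = n), n, 1)
  list(X = x, Y = 2 * x + 1,
       model = init_mlp(c(1, 1), seed = 2, hidden_activation = "identity"))
}

test_that("a zero-epoch budget returns the model untouched", {
  toy <- linear_toy()
  for (alg in c("lm", "bayes_reg", "oss", "bfgs", "cyclical", "sequential")) {
    run <- train_mlp(toy$model, toy$X, toy$Y,
                     train_config(alg, max_epochs = 0))
    expect_identical(flatten_params(run$model), flatten_params(toy$model))
  }
})

test_that("lm recovers the normal-equations solution on a linear problem", {
  toy <- linear_toy()
  run <- train_mlp(toy$model, toy$X, toy$Y,
                   train_config("lm", max_epochs = 100, goal_sse = 0,
                                gradient_tolerance = 1e-14))
  A <- cbind(toy$X, 1)
  sol <- solve(crossprod(A), crossprod(A, toy$Y))
  expect_equal(flatten_params(run$model), drop(sol), tolerance = 1e-8)
  expect_equal(flatten_params(run$model), c(2, 1), tolerance = 1e-8)
})

test_that("lm accepted-step loss history never increases", {
  set.seed(17)
  for (i in 1:5) {
    m <- init_mlp(c(3, 4, 2), seed = i)
    X <- matrix(rnorm(30), 10, 3)
    Y <- matrix(rnorm(20), 10, 2)
    run <- train_mlp(m, X, Y, train_config("lm", max_epochs = 40))
    expect_true(all(diff(run$sse_history) <= 1e-12))
  }
})

test_that("heavily damped lm steps approach the scaled gradient direction", {
  m <- init_mlp(c(3, 4, 2), seed = 3)
  X <- matrix(rnorm(30), 10, 3)
  Y <- matrix(rnorm(20), 10, 2)
  g <- mlp_gradient(m, X, Y)
  lambda <- 1e8
  run <- train_mlp(m, X, Y, train_config("lm", max_epochs = 1,
                                         lm_lambda_init = lambda))
  step <- flatten_params(run$model) - flatten_params(m)
  expect_lt(max(abs(step - (-g / lambda))) / max(abs(g / lambda)), 1e-3)
})

test_that("bfgs solves a convex quadratic within d+5 iterations", {
  set.seed(4)
  X <- matrix(rnorm(500), 50, 10)
  y <- matrix(X %*% rnorm(10) + 0.5, ncol = 1)
  lin <- init_mlp(c(10, 1), seed = 5, hidden_activation = "identity")
  d <- n_params(lin)
  run <- train_mlp(lin, X, y, train_config("bfgs", max_epochs = d + 5,
                                           gradient_tolerance = 0))
  sol <- solve(crossprod(cbind(X, 1)), crossprod(cbind(X, 1), y))
  expect_lt(max(abs(flatten_params(run$model) - sol)), 1e-8)
})

test_that("one-step secant decreases the loss monotonically", {
  m <- init_mlp(c(4, 6, 2), seed = 8)
  X <- matrix(rnorm(60), 15, 4)
  Y <- matrix(rnorm(30), 15, 2)
  run <- train_mlp(m, X, Y, train_config("oss", max_epochs = 60))
  expect_true(all(diff(run$sse_history) <= 1e-12))
  expect_lt(run$sse_history[length(run$sse_history)], run$sse_history[1] / 2)
})

test_that("bayesian regularization keeps gamma in bounds and finds the
           parameter count of a noise-free linear problem", {
  set.seed(4)
  X <- matrix(rnorm(500), 50, 10)
  y <- matrix(X %*% rnorm(10) + 0.5, ncol = 1)
  lin <- init_mlp(c(10, 1), seed = 5, hidden_activation = "identity")
  run <- train_mlp(lin, X, y, train_config("bayes_reg", max_epochs = 200))
  P <- run$n_params_total
  expect_true(all(run$gamma_history >= 0 & run$gamma_history <= P))
  # all 11 parameters of the exactly-parameterized law are well determined
  expect_equal(run$gamma, P, tolerance = 0.05)
  # and the fit itself is tight
  expect_lt(sse_loss(run$model, X, y), 1e-10)
})

test_that("lm and bfgs learn XOR exactly at a fixed seed", {
  X <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2)
  Y <- matrix(c(0, 1, 1, 0), 4, 1)
  for (alg in c("lm", "bfgs")) {
    m <- init_mlp(c(2, 4, 1), seed = 1, output_activation = "logistic")
    run <- train_mlp(m, X, Y, train_config(alg, max_epochs = 2000,
                                           goal_sse = 1e-6))
    pred <- as.numeric(mlp_forward(run$model, X) >= 0.5)
    expect_identical(pred, as.numeric(Y))
  }
})

test_that("cyclical and sequential coincide under the default cycle", {
  co <- generate_cohort(cohort_spec(seed = 2))[1:40, ]
  sc <- fit_feature_scaler(co)
  X <- encode_features(co, sc)
  Y <- scale(as.matrix(co[c("frequency", "tidal_volume", "fio2")]))
  m <- init_mlp(c(10, 5, 3), seed = 6)
  r_cyc <- train_mlp(m, X, Y, train_config("cyclical", max_epochs = 4))
  r_seq <- train_mlp(m, X, Y, train_config("sequential", max_epochs = 4))
  expect_identical(r_cyc$sse_history, r_seq$sse_history)
  expect_identical(flatten_params(r_cyc$model), flatten_params(r_seq$model))
  expect_lt(r_seq$sse_history[5], r_seq$sse_history[1])

  # a custom presentation cycle is honored and validated
  r_perm <- train_mlp(m, X, Y, train_config("cyclical", max_epochs = 4,
                                            cycle_order = rev(seq_len(40))))
  expect_false(identical(flatten_params(r_perm$model),
                         flatten_params(r_cyc$model)))
  expect_error(train_mlp(m, X, Y, train_config("cyclical", max_epochs = 1,
                                               cycle_order = c(1, 1, 2))),
               "permutation")
})

test_that("repeat runs with identical inputs are bitwise identical", {
  co <- generate_cohort(cohort_spec(seed = 2))[1:30, ]
  sc <- fit_feature_scaler(co)
  X <- encode_features(co, sc)
  Y <- scale(as.matrix(co[c("frequency", "tidal_volume", "fio2")]))
  for (alg in c("lm", "bayes_reg", "oss", "bfgs", "sequential")) {
    m <- init_mlp(c(10, 4, 3), seed = 12)
    r1 <- train_mlp(m, X, Y, train_config(alg, max_epochs = 8))
    r2 <- train_mlp(m, X, Y, train_config(alg, max_epochs = 8))
    expect_identical(r1$sse_history, r2$sse_history)
    expect_identical(flatten_params(r1$model), flatten_params(r2$model))
  }
})

test_that("a diverging incremental run reports the epoch of the blow-up", {
  toy <- linear_toy()
  expect_error(train_mlp(toy$model, toy$X * 100, toy$Y * 100,
                         train_config("sequential", max_epochs = 50,
                                      learning_rate = 1e6)),
               "epoch")
})

test_that("hidden-unit sweeps reuse cross_validate row by row", {
  co <- generate_cohort(cohort_spec(seed = 4))[1:60, ]
  sw <- sweep_hidden_units(co, "lm", unit_list = c(3, 3), k = 3, seed = 2,
                           max_epochs = 10)
  expect_identical(nrow(sw), 2L)
  expect_identical(unlist(sw[1, -1]), unlist(sw[2, -1]))   # duplicated entry, identical rows
  direct <- cross_validate(co, train_config("lm", hidden_units = 3, seed = 2,
                                            max_epochs = 10), k = 3, seed = 2)
  expect_equal(sw$frequency[1], direct$summary["frequency", "mean"])
  expect_true(all(unlist(sw[-1]) >= 0 & unlist(sw[-1]) <= 100))
})
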