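## The six training regimes operating on the MLP substrate.
##
## Batch methods (lm, bayes_reg, oss, bfgs) work on the flat parameter
## vector via the loss/gradient/Jacobian routines; the two incremental
## methods (cyclical, sequential) apply per-sample gradient steps. All are
## deterministic given (initial model, data, config).

#' Training configuration
#'
#' @param algorithm one of `"lm"` (Levenberg-Marquardt), `"bayes_reg"`
#'   (Bayesian regularization), `"oss"` (one-step secant), `"bfgs"`
#'   (BFGS quasi-Newton), `"cyclical"` / `"sequential"` (incremental
#'   per-sample weight/bias updates).
#' @param hidden_units hidden-layer width used when a model is built from
#'   this config.
#' @param max_epochs epoch budget; for incremental methods one epoch is one
#'   full presentation of the data (N per-sample updates), keeping the
#'   budget comparable across algorithms.
#' @param goal_sse stop once the loss falls to this value.
#' @param gradient_tolerance stop once the infinity norm of the full-batch
#'   gradient falls below this.
#' @param learning_rate step size of the incremental methods.
#' @param lm_lambda_init,lm_lambda_factor,lm_lambda_max damping schedule of
#'   lm / bayes_reg: initial lambda, multiplicative factor, overflow cap.
#' @param bayes_max_outer outer evidence-update iterations of bayes_reg.
#' @param cycle_order optional presentation order for `"cyclical"`; default
#'   is dataset order, which makes cyclical and sequential coincide.
#' @param seed RNG seed recorded with the run (training itself draws no
#'   random numbers; the seed ties a run to the model initialization).
#' @return object of class `train_config`.
#' @export
train_config <- function(algorithm = c("lm", "bayes_reg", "oss", "bfgs",
                                       "cyclical", "sequential"),
                         hidden_units = 30L, max_epochs = 200L,
                         goal_sse = 0, gradient_tolerance = 1e-10,
                         learning_rate = 0.01,
                         lm_lambda_init = 1e-3, lm_lambda_factor = 10,
                         lm_lambda_max = 1e10,
                         bayes_max_outer = 50L,
                         cycle_order = NULL, seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (hidden_units < 1L) stop_ventdss("hidden_units must be positive")
  if (max_epochs < 0L) stop_ventdss("max_epochs must be nonnegative")
  if (goal_sse < 0 || gradient_tolerance < 0)
    stop_ventdss("goal_sse and gradient_tolerance must be nonnegative")
  if (learning_rate <= 0) stop_ventdss("learning_rate must be positive")
  if (lm_lambda_init <= 0 || lm_lambda_factor <= 1 || lm_lambda_max <= 0)
    stop_ventdss("lambda parameters must be positive (factor > 1)")
  structure(list(algorithm = algorithm, hidden_units = as.integer(hidden_units),
                 max_epochs = as.integer(max_epochs), goal_sse = goal_sse,
                 gradient_tolerance = gradient_tolerance,
                 learning_rate = learning_rate,
                 lm_lambda_init = lm_lambda_init,
                 lm_lambda_factor = lm_lambda_factor,
                 lm_lambda_max = lm_lambda_max,
                 bayes_max_outer = as.integer(bayes_max_outer),
                 cycle_order = cycle_order, seed = as.integer(seed)),
            class = "train_config")
}

new_train_run <- function(model, history, stop_reason, config, extra = list()) {
  structure(c(list(model = model, sse_history = history,
                   stop_reason = stop_reason, epochs = length(history) - 1L,
                   config = config), extra),
            class = "train_run")
}

#' @export
print.train_run <- function(x, ...) {
  cat(sprintf("Training run: %s, %d epoch(s), stop: %s, final SSE %.6g\n",
              x$config$algorithm, x$epochs, x$stop_reason,
              x$sse_history[length(x$sse_history)]))
  invisible(x)
}

check_finite_loss <- function(sse, epoch) {
  if (!is.finite(sse))
    stop_ventdss("non-finite loss at epoch ", epoch,
                 ": training diverged (reduce the learning rate?)")
}

#' Train a network
#'
#' Dispatches on `config$algorithm`:
#' \describe{
#'   \item{lm}{damped Gauss-Newton: solves `(J'J + lambda I) d = -J'r`,
#'     accepts only steps that decrease the loss, shrinking lambda on
#'     success and growing it on rejection, so the recorded loss sequence
#'     never increases. Lambda passing its cap ends the run with stop
#'     reason `lambda_overflow`.}
#'   \item{bayes_reg}{minimizes `beta*ED + alpha*EW` (`ED` = summed squared
#'     residuals, `EW` = summed squared weights) with `alpha`, `beta`
#'     re-estimated each outer iteration from the evidence approximation:
#'     `gamma = P - alpha * tr((beta J'J + alpha I)^-1)`,
#'     `alpha = gamma / (2 EW)`, `beta = (N - gamma) / (2 ED)`. `gamma` is
#'     the effective number of well-determined parameters, reported in the
#'     run.}
#'   \item{oss}{one-step secant: a memory-free quasi-Newton direction built
#'     from the previous step and gradient change, with an Armijo
#'     backtracking line search.}
#'   \item{bfgs}{dense inverse-Hessian BFGS update with a curvature guard
#'     and Armijo backtracking.}
#'   \item{cyclical, sequential}{per-sample gradient descent; sequential
#'     presents samples in dataset order, cyclical in a fixed repeating
#'     cycle (dataset order unless `cycle_order` says otherwise), so with
#'     the default cycle the two coincide.}
#' }
#'
#' @param model initial `mlp_model`.
#' @param X input matrix (rows = samples).
#' @param Y target matrix.
#' @param config a [train_config()].
#' @return object of class `train_run`: the final model, the per-epoch loss
#'   history (element 1 is the initial loss), the stop reason (`goal`,
#'   `gradient`, `max_epochs`, or `lambda_overflow`), and for bayes_reg the
#'   final `alpha`, `beta`, `gamma`.
#' @export
train_mlp <- function(model, X, Y, config = train_config()) {
  if (!inherits(config, "train_config")) stop_ventdss("config must be a train_config")
  X <- as_input_matrix(model, X)
  Y <- as.matrix(Y)
  if (nrow(X) == 0L) stop_ventdss("training data is empty")
  if (nrow(Y) != nrow(X)) stop_ventdss("X and Y row counts differ")
  switch(config$algorithm,
    lm = train_lm(model, X, Y, config),
    bayes_reg = train_bayes_reg(model, X, Y, config),
    oss = train_linesearch(model, X, Y, config, method = "oss"),
    bfgs = train_linesearch(model, X, Y, config, method = "bfgs"),
    cyclical = train_incremental(model, X, Y, config),
    sequential = train_incremental(model, X, Y, config))
}

train_lm <- function(model, X, Y, config) {
  lambda <- config$lm_lambda_init
  sse <- sse_loss(model, X, Y)
  history <- sse
  stop_reason <- "max_epochs"
  epoch <- 0L
  while (epoch < config$max_epochs) {
    epoch <- epoch + 1L
    check_finite_loss(sse, epoch)
    if (sse <= config$goal_sse) { stop_reason <- "goal"; history <- c(history, sse); break }
    J <- mlp_jacobian(model, X)
    r <- mlp_residuals(model, X, Y)
    g <- drop(crossprod(J, r))
    if (max(abs(g)) < config$gradient_tolerance) {
      stop_reason <- "gradient"; history <- c(history, sse); break
    }
    JtJ <- crossprod(J)
    accepted <- FALSE
    while (!accepted) {
      H <- JtJ; diag(H) <- diag(H) + lambda
      delta <- tryCatch(-solve(H, g), error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- unflatten_params(model, flatten_params(model) + delta)
        new_sse <- sse_loss(cand, X, Y)
        if (is.finite(new_sse) && new_sse < sse) {
          model <- cand; sse <- new_sse
          lambda <- max(lambda / config$lm_lambda_factor, 1e-20)
          accepted <- TRUE
        }
      }
      if (!accepted) {
        lambda <- lambda * config$lm_lambda_factor
        if (lambda > config$lm_lambda_max) break
      }
    }
    if (!accepted) { stop_reason <- "lambda_overflow"; history <- c(history, sse); break }
    history <- c(history, sse)
    if (sse <= config$goal_sse) { stop_reason <- "goal"; break }
  }
  new_train_run(model, history, stop_reason, config, list(final_lambda = lambda))
}

train_bayes_reg <- function(model, X, Y, config) {
  N <- nrow(X) * ncol(as.matrix(Y))
  P <- n_params(model)
  alpha <- 0; beta <- 1
  lambda <- config$lm_lambda_init
  history <- sse_loss(model, X, Y)
  gamma <- P
  gamma_history <- numeric(0)
  stop_reason <- "max_epochs"
  epochs_used <- 0L
  for (outer in seq_len(config$bayes_max_outer)) {
    if (epochs_used >= config$max_epochs) break
    # inner loop: damped Gauss-Newton on the regularized objective
    inner_budget <- min(10L, config$max_epochs - epochs_used)
    for (inner in seq_len(inner_budget)) {
      theta <- flatten_params(model)
      J <- mlp_jacobian(model, X)
      r <- mlp_residuals(model, X, Y)
      ed <- sum(r^2); ew <- sum(theta^2)
      obj <- beta * ed + alpha * ew
      check_finite_loss(obj, epochs_used)
      g <- 2 * beta * drop(crossprod(J, r)) + 2 * alpha * theta
      if (max(abs(g)) < config$gradient_tolerance) { stop_reason <- "gradient"; break }
      JtJ <- crossprod(J)
      accepted <- FALSE
      while (!accepted) {
        H <- 2 * beta * JtJ; diag(H) <- diag(H) + 2 * alpha + lambda
        delta <- tryCatch(-solve(H, g), error = function(e) NULL)
        if (!is.null(delta)) {
          cand <- unflatten_params(model, theta + delta)
          cr <- mlp_residuals(cand, X, Y)
          cand_obj <- beta * sum(cr^2) + alpha * sum((theta + delta)^2)
          if (is.finite(cand_obj) && cand_obj < obj) {
            model <- cand
            lambda <- max(lambda / config$lm_lambda_factor, 1e-20)
            accepted <- TRUE
          }
        }
        if (!accepted) {
          lambda <- lambda * config$lm_lambda_factor
          if (lambda > config$lm_lambda_max) break
        }
      }
      epochs_used <- epochs_used + 1L
      history <- c(history, sse_loss(model, X, Y))
      if (!accepted) { stop_reason <- "lambda_overflow"; break }
      if (epochs_used >= config$max_epochs) break
    }
    # evidence re-estimation of alpha, beta
    theta <- flatten_params(model)
    J <- mlp_jacobian(model, X)
    r <- mlp_residuals(model, X, Y)
    ed <- sum(r^2); ew <- sum(theta^2)
    A <- beta * crossprod(J); diag(A) <- diag(A) + alpha
    tr_inv <- tryCatch(sum(diag(solve(A))), error = function(e) NA_real_)
    if (is.finite(tr_inv)) {
      gamma <- P - alpha * tr_inv
      gamma <- min(max(gamma, 0), P)
      gamma_history <- c(gamma_history, gamma)
      alpha <- if (ew > 0) gamma / (2 * ew) else 0
      beta <- if (ed > 0) (N - gamma) / (2 * ed) else beta
    }
    if (stop_reason %in% c("gradient", "lambda_overflow")) break
    if (history[length(history)] <= config$goal_sse) { stop_reason <- "goal"; break }
  }
  new_train_run(model, history, stop_reason, config,
                list(alpha = alpha, beta = beta, gamma = gamma,
                     gamma_history = gamma_history, n_params_total = P))
}

# Armijo backtracking from unit step, with a quadratic-interpolation refinement
# of the first trial (exact line minimization when the objective is quadratic
# along d). Returns NULL when no acceptable step exists.
backtrack <- function(model, X, Y, theta, d, g, sse, c1 = 1e-4, max_trials = 30L) {
  slope <- sum(g * d)
  if (!is.finite(slope) || slope >= 0) return(NULL)
  eval_at <- function(step) {
    cand_theta <- theta + step * d
    cand <- unflatten_params(model, cand_theta)
    list(model = cand, theta = cand_theta, sse = sse_loss(cand, X, Y), step = step)
  }
  unit <- eval_at(1)
  # minimizer of the quadratic through phi(0), phi'(0), phi(1)
  denom <- 2 * (unit$sse - sse - slope)
  if (is.finite(denom) && denom > 0) {
    t_star <- -slope / denom
    if (is.finite(t_star) && t_star > 1e-3 && t_star < 10 && abs(t_star - 1) > 1e-12) {
      refined <- eval_at(t_star)
      if (is.finite(refined$sse) && refined$sse < min(sse, unit$sse) &&
          refined$sse <= sse + c1 * t_star * slope)
        return(refined)
    }
  }
  if (is.finite(unit$sse) && unit$sse <= sse + c1 * slope) return(unit)
  step <- 0.5
  for (trial in seq_len(max_trials)) {
    cand <- eval_at(step)
    if (is.finite(cand$sse) && cand$sse <= sse + c1 * step * slope) return(cand)
    step <- step / 2
  }
  NULL
}

train_linesearch <- function(model, X, Y, config, method) {
  theta <- flatten_params(model)
  P <- length(theta)
  sse <- sse_loss(model, X, Y)
  history <- sse
  g <- mlp_gradient(model, X, Y)
  Hinv <- if (method == "bfgs") diag(P) else NULL
  s_prev <- NULL; y_prev <- NULL; g_prev <- NULL
  stop_reason <- "max_epochs"
  epoch <- 0L
  while (epoch < config$max_epochs) {
    epoch <- epoch + 1L
    check_finite_loss(sse, epoch)
    if (sse <= config$goal_sse) { stop_reason <- "goal"; break }
    if (max(abs(g)) < config$gradient_tolerance) { stop_reason <- "gradient"; break }
    if (method == "bfgs") {
      d <- -drop(Hinv %*% g)
    } else {
      # one-step secant direction from the last step and gradient change
      if (is.null(s_prev) || sum(s_prev * y_prev) <= 1e-12) {
        d <- -g
      } else {
        sty <- sum(s_prev * y_prev)
        A <- -(1 + sum(y_prev^2) / sty) * sum(s_prev * g) / sty +
          sum(y_prev * g) / sty
        B <- sum(s_prev * g) / sty
        d <- -g + A * s_prev + B * y_prev
      }
    }
    ls <- backtrack(model, X, Y, theta, d, g, sse)
    if (is.null(ls) && !identical(d, -g))
      ls <- backtrack(model, X, Y, theta, -g, g, sse)
    if (is.null(ls)) { stop_reason <- "gradient"; break }
    g_prev <- g; s_prev <- ls$theta - theta
    model <- ls$model; theta <- ls$theta; sse <- ls$sse
    g <- mlp_gradient(model, X, Y)
    y_prev <- g - g_prev
    if (method == "bfgs") {
      sty <- sum(s_prev * y_prev)
      if (sty > 1e-10) {            # curvature guard
        if (epoch == 1L) {
          # scale the initial inverse Hessian to the first curvature estimate
          Hinv <- diag(P) * (sty / sum(y_prev^2))
        }
        rho <- 1 / sty
        Hy <- drop(Hinv %*% y_prev)
        Hinv <- Hinv - rho * (outer(s_prev, Hy) + outer(Hy, s_prev)) +
          rho^2 * (sum(y_prev * Hy) + sty) * outer(s_prev, s_prev)
      }
    }
    history <- c(history, sse)
  }
  if (length(history) == epoch) history <- c(history, sse)
  new_train_run(model, history, stop_reason, config)
}

train_incremental <- function(model, X, Y, config) {
  n <- nrow(X)
  order_idx <- if (config$algorithm == "cyclical" && !is.null(config$cycle_order)) {
    idx <- as.integer(config$cycle_order)
    if (!identical(sort(idx), seq_len(n)))
      stop_ventdss("cycle_order must be a permutation of 1..n")
    idx
  } else seq_len(n)
  lr <- config$learning_rate
  sse <- sse_loss(model, X, Y)
  history <- sse
  stop_reason <- "max_epochs"
  epoch <- 0L
  while (epoch < config$max_epochs) {
    epoch <- epoch + 1L
    check_finite_loss(sse, epoch)
    if (sse <= config$goal_sse) { stop_reason <- "goal"; break }
    for (i in order_idx) {
      g <- mlp_gradient(model, X[i, , drop = FALSE], Y[i, , drop = FALSE])
      model <- unflatten_params(model, flatten_params(model) - lr * g)
    }
    sse <- sse_loss(model, X, Y)
    check_finite_loss(sse, epoch)
    history <- c(history, sse)
    if (sse <= config$goal_sse) { stop_reason <- "goal"; break }
    g_full <- mlp_gradient(model, X, Y)
    if (max(abs(g_full)) < config$gradient_tolerance) { stop_reason <- "gradient"; break }
  }
  new_train_run(model, history, stop_reason, config)
}

#' Sweep hidden-layer widths with cross-validation
#'
#' Runs one [cross_validate()] per hidden-unit count and collects the mean
#' success rates per output, mirroring the usual capacity-sweep summary
#' (unit counts such as 5, 10, 15, 20, 30, 50, 100).
#'
#' @param cohort labeled cohort with complete outputs.
#' @param algorithm training algorithm name (see [train_config()]).
#' @param unit_list integer vector of hidden-unit counts.
#' @param k number of folds.
#' @param seed fold/initialization seed.
#' @param ... further arguments passed to [train_config()].
#' @return data.frame with one row per unit count and the mean success per
#'   output parameter.
#' @export
sweep_hidden_units <- function(cohort, algorithm, unit_list, k = 10L,
                               seed = 1L, ...) {
  if (!length(unit_list)) stop_ventdss("unit_list must be nonempty")
  rows <- lapply(unit_list, function(h) {
    cfg <- train_config(algorithm = algorithm, hidden_units = h, seed = seed, ...)
    rep <- tryCatch(cross_validate(cohort, cfg, k = k, seed = seed),
                    error = function(e)
                      stop_ventdss("cross-validation failed at hidden_units = ",
                                   h, ": ", conditionMessage(e)))
    data.frame(hidden_units = h,
               frequency = rep$summary["frequency", "mean"],
               tidal_volume = rep$summary["tidal_volume", "mean"],
               fio2 = rep$summary["fio2", "mean"],
               ps_vs = rep$summary["ps_vs", "mean"])
  })
  do.call(rbind, rows)
}
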