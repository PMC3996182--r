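## Feed-forward network substrate.
##
## Weight matrices are stored (units_out x units_in); the flat parameter
## vector is all weight matrices in layer order (column-major within each),
## followed by all bias vectors in layer order. Hidden activation is
## hyperbolic tangent by default; the output head is identity for the
## regression network and logistic for the mode classifier.

act_fun <- function(name) {
  switch(name,
    tanh     = list(f = tanh, df = function(z) 1 - tanh(z)^2),
    identity = list(f = identity, df = function(z) z * 0 + 1),
    logistic = list(f = function(z) 1 / (1 + exp(-z)),
                    df = function(z) { s <- 1 / (1 + exp(-z)); s * (1 - s) }),
    stop_ventdss("unknown activation: ", name)
  )
}

#' Initialize a multilayer perceptron
#'
#' Weights and biases are drawn independently from the uniform distribution
#' on \[-0.5, 0.5\] using the given seed, so the same seed always yields the
#' identical network.
#'
#' @param layer_sizes integer vector of at least two layer widths,
#'   input first, e.g. `c(10, 30, 3)` for 10 inputs, 30 hidden tanh units,
#'   3 linear outputs. More than one hidden layer is allowed; with exactly
#'   two entries the network is a bare affine map.
#' @param seed integer RNG seed for the draw.
#' @param output_activation `"identity"` (regression) or `"logistic"`
#'   (classification).
#' @param hidden_activation `"tanh"` (default) or `"identity"`.
#' @return object of class `mlp_model`.
#' @export
init_mlp <- function(layer_sizes, seed = 1L,
                     output_activation = c("identity", "logistic"),
                     hidden_activation = c("tanh", "identity")) {
  output_activation <- match.arg(output_activation)
  hidden_activation <- match.arg(hidden_activation)
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L || any(layer_sizes <= 0L))
    stop_ventdss("layer_sizes needs >= 2 positive entries")
  L <- length(layer_sizes) - 1L
  model <- structure(list(layer_sizes = layer_sizes,
                          W = vector("list", L), b = vector("list", L),
                          hidden_activation = hidden_activation,
                          output_activation = output_activation,
                          seed = as.integer(seed)),
                     class = "mlp_model")
  with_seed(seed, {
    for (l in seq_len(L)) {
      n_out <- layer_sizes[l + 1L]; n_in <- layer_sizes[l]
      model$W[[l]] <- matrix(runif(n_out * n_in, -0.5, 0.5), n_out, n_in)
      model$b[[l]] <- runif(n_out, -0.5, 0.5)
    }
  })
  model
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("MLP %s; hidden: %s, output: %s; %d parameters (seed %d)\n",
              paste(x$layer_sizes, collapse = "-"), x$hidden_activation,
              x$output_activation, n_params(x), x$seed))
  invisible(x)
}

#' Number of free parameters of a network
#'
#' @param model an `mlp_model`.
#' @return integer parameter count.
#' @export
n_params <- function(model) {
  s <- model$layer_sizes
  sum(s[-length(s)] * s[-1]) + sum(s[-1])
}

#' Flatten network parameters to a vector
#'
#' Order: every weight matrix in layer order (column-major), then every
#' bias vector in layer order. [unflatten_params()] inverts this exactly.
#'
#' @param model an `mlp_model`.
#' @return numeric vector of length [n_params()].
#' @export
flatten_params <- function(model) {
  c(unlist(lapply(model$W, as.vector)), unlist(model$b))
}

#' Restore network parameters from a flat vector
#'
#' @param model template `mlp_model` giving the shapes.
#' @param theta flat parameter vector in [flatten_params()] order.
#' @return `mlp_model` with the given parameters.
#' @export
unflatten_params <- function(model, theta) {
  if (length(theta) != n_params(model))
    stop_ventdss("parameter vector has length ", length(theta),
                 ", expected ", n_params(model))
  s <- model$layer_sizes; L <- length(s) - 1L
  pos <- 0L
  for (l in seq_len(L)) {
    k <- s[l + 1L] * s[l]
    model$W[[l]] <- matrix(theta[pos + seq_len(k)], s[l + 1L], s[l])
    pos <- pos + k
  }
  for (l in seq_len(L)) {
    k <- s[l + 1L]
    model$b[[l]] <- theta[pos + seq_len(k)]
    pos <- pos + k
  }
  model
}

as_input_matrix <- function(model, X) {
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (ncol(X) != model$layer_sizes[1])
    stop_ventdss("input has ", ncol(X), " columns, network expects ",
                 model$layer_sizes[1])
  storage.mode(X) <- "double"
  X
}

# Forward pass keeping pre-activations (Z) and activations (A) per layer,
# for use by the gradient and Jacobian routines.
forward_pass <- function(model, X) {
  L <- length(model$W)
  A <- vector("list", L + 1L); Z <- vector("list", L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    act <- act_fun(if (l < L) model$hidden_activation else model$output_activation)
    Z[[l]] <- sweep(A[[l]] %*% t(model$W[[l]]), 2L, model$b[[l]], `+`)
    A[[l + 1L]] <- act$f(Z[[l]])
  }
  list(A = A, Z = Z)
}

#' Network forward pass
#'
#' @param model an `mlp_model`.
#' @param X numeric matrix (rows = samples) or a single input vector.
#' @return matrix of outputs, one row per sample.
#' @export
mlp_forward <- function(model, X) {
  X <- as_input_matrix(model, X)
  fp <- forward_pass(model, X)
  fp$A[[length(fp$A)]]
}

#' Sum-of-squares loss
#'
#' One half of the summed squared residuals over all samples and outputs;
#' zero exactly at a perfect fit.
#'
#' @param model an `mlp_model`.
#' @param X input matrix, rows = samples.
#' @param Y target matrix, same row count.
#' @return nonnegative scalar.
#' @export
sse_loss <- function(model, X, Y) {
  X <- as_input_matrix(model, X)
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(X) || ncol(Y) != model$layer_sizes[length(model$layer_sizes)])
    stop_ventdss("target matrix shape does not match the network outputs")
  R <- mlp_forward(model, X) - Y
  0.5 * sum(R * R)
}

# Per-layer activation derivative for layer l of L.
layer_df <- function(model, l, L, Z) {
  act <- act_fun(if (l < L) model$hidden_activation else model$output_activation)
  act$df(Z[[l]])
}

#' Exact gradient of the sum-of-squares loss
#'
#' Backpropagation over the full batch; matches central finite differences
#' to high relative accuracy.
#'
#' @inheritParams sse_loss
#' @return flat gradient vector in [flatten_params()] order.
#' @export
mlp_gradient <- function(model, X, Y) {
  X <- as_input_matrix(model, X)
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(X) || ncol(Y) != model$layer_sizes[length(model$layer_sizes)])
    stop_ventdss("target matrix shape does not match the network outputs")
  fp <- forward_pass(model, X)
  L <- length(model$W)
  delta <- (fp$A[[L + 1L]] - Y) * layer_df(model, L, L, fp$Z)
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- t(delta) %*% fp$A[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1L)
      delta <- (delta %*% model$W[[l]]) * layer_df(model, l - 1L, L, fp$Z)
  }
  c(unlist(lapply(gW, as.vector)), unlist(gb))
}

#' Residuals of a model on a data set
#'
#' Stacked output-major: all samples for output 1, then output 2, ...
#' Matches the row order of [mlp_jacobian()], so `t(J) %*% r` equals
#' [mlp_gradient()].
#'
#' @inheritParams sse_loss
#' @return numeric vector of length `nrow(X) * n_outputs`.
#' @export
mlp_residuals <- function(model, X, Y) {
  as.vector(mlp_forward(model, X) - as.matrix(Y))
}

#' Jacobian of the network outputs
#'
#' Matrix of partial derivatives of every per-sample, per-output prediction
#' with respect to every parameter: rows ordered like [mlp_residuals()]
#' (samples within output, outputs stacked), columns in
#' [flatten_params()] order. Since residuals are predictions minus fixed
#' targets, this is also the residual Jacobian used by Levenberg-Marquardt
#' and Bayesian-regularization training.
#'
#' @param model an `mlp_model`.
#' @param X input matrix, rows = samples.
#' @return numeric matrix `(n_samples * n_outputs) x n_params`.
#' @export
mlp_jacobian <- function(model, X) {
  X <- as_input_matrix(model, X)
  fp <- forward_pass(model, X)
  L <- length(model$W)
  s <- model$layer_sizes
  n <- nrow(X); m <- s[length(s)]
  P <- n_params(model)
  dfL <- layer_df(model, L, L, fp$Z)
  J <- matrix(0, n * m, P)
  w_offsets <- cumsum(c(0L, s[-length(s)] * s[-1]))
  b_base <- sum(s[-length(s)] * s[-1])
  b_offsets <- b_base + cumsum(c(0L, s[-1]))
  for (o in seq_len(m)) {
    rows <- (o - 1L) * n + seq_len(n)
    # seed the backward sweep with d out_o / d z_L
    delta <- matrix(0, n, m)
    delta[, o] <- dfL[, o]
    for (l in rev(seq_len(L))) {
      n_out <- s[l + 1L]; n_in <- s[l]
      A <- fp$A[[l]]
      J[rows, w_offsets[l] + seq_len(n_out * n_in)] <-
        delta[, rep(seq_len(n_out), times = n_in), drop = FALSE] *
        A[, rep(seq_len(n_in), each = n_out), drop = FALSE]
      J[rows, b_offsets[l] + seq_len(n_out)] <- delta
      if (l > 1L)
        delta <- (delta %*% model$W[[l]]) * layer_df(model, l - 1L, L, fp$Z)
    }
  }
  J
}

#' Serialize a network to JSON
#'
#' Full-precision dump of shapes, activations, seed, and the flat parameter
#' vector; [mlp_from_json()] reloads it bit-exactly.
#'
#' @param model an `mlp_model`.
#' @param file optional path; when NULL the JSON string is returned.
#' @return JSON string, or `file` invisibly.
#' @export
mlp_to_json <- function(model, file = NULL) {
  payload <- list(layer_sizes = model$layer_sizes,
                  hidden_activation = model$hidden_activation,
                  output_activation = model$output_activation,
                  seed = model$seed,
                  parameters = flatten_params(model))
  if (is.null(file))
    return(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17))))
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = I(17))
  invisible(file)
}

#' Restore a network serialized by [mlp_to_json()]
#'
#' @param json JSON string or path to a JSON file.
#' @return an `mlp_model`.
#' @export
mlp_from_json <- function(json) {
  payload <- if (file.exists(json[1]) && length(json) == 1L)
    jsonlite::read_json(json, simplifyVector = TRUE)
  else jsonlite::fromJSON(json)
  model <- init_mlp(payload$layer_sizes, seed = payload$seed,
                    output_activation = payload$output_activation,
                    hidden_activation = payload$hidden_activation)
  unflatten_params(model, payload$parameters)
}
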