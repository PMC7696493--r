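# BP (backpropagation) neural network and PSO-BP baselines.
# One hidden layer, sigmoid activations on hidden and output layers,
# squared-error ("global error") loss, full-batch gradient descent with a
# fixed learning rate. The four output nodes correspond to the four phases.

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Hidden-layer size rule
#'
#' `m = round(sqrt(n + l)) + alpha_const` (rule `"sqrt"`, default): with 5
#' inputs, 4 outputs and the constant 3 this gives the stated 6 hidden
#' nodes. The literal sum `m = n + l + alpha_const` is available as rule
#' `"sum"` for comparison.
#'
#' @param n input-layer size (>= 1)
#' @param l output-layer size (>= 1)
#' @param alpha_const additive constant (default 3)
#' @param rule `"sqrt"` or `"sum"`
#' @return hidden-layer size m
#' @export
hidden_size <- function(n, l, alpha_const = 3, rule = c("sqrt", "sum")) {
  rule <- match.arg(rule)
  if (n < 1 || l < 1) stop("n and l must be >= 1")
  if (rule == "sqrt") round(sqrt(n + l)) + alpha_const else n + l + alpha_const
}

#' MLP specification
#'
#' @param n_input input nodes (feature dimension, 5)
#' @param n_hidden hidden nodes (default via [hidden_size()])
#' @param n_output output nodes (number of phases, 4)
#' @param learning_rate fixed gradient step (default 0.7)
#' @param max_epochs epoch cap for BP training
#' @param target_error stop when the mean squared error per sample falls
#'   below this value
#' @param seed RNG seed for the uniform(-0.5, 0.5) weight initialization
#' @return object of class `mlp_spec`
#' @export
mlp_spec <- function(n_input = 5, n_hidden = hidden_size(5, 4), n_output = 4,
                     learning_rate = 0.7, max_epochs = 500,
                     target_error = 1e-3, seed = 1L) {
  if (n_input < 1 || n_hidden < 1 || n_output < 1)
    stop_config("layer sizes must be >= 1")
  structure(list(n_input = as.integer(n_input), n_hidden = as.integer(n_hidden),
                 n_output = as.integer(n_output), learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 target_error = target_error, seed = seed),
            class = "mlp_spec")
}

n_mlp_params <- function(spec)
  spec$n_input * spec$n_hidden + spec$n_hidden +
  spec$n_hidden * spec$n_output + spec$n_output

init_mlp <- function(spec) {
  w <- with_seed(spec$seed, runif(n_mlp_params(spec), -0.5, 0.5))
  unpack_mlp(w, spec)
}

# Flatten / restore weights and node thresholds; the flattened vector is the
# PSO search space for PSO-BP (n*m + m + m*l + l dimensions).
pack_mlp <- function(model)
  c(model$W1, model$b1, model$W2, model$b2)

unpack_mlp <- function(w, spec) {
  n <- spec$n_input; m <- spec$n_hidden; l <- spec$n_output
  if (length(w) != n_mlp_params(spec)) stop("weight vector has wrong length")
  i <- 0
  take <- function(k) { out <- w[i + seq_len(k)]; i <<- i + k; out }
  structure(list(W1 = matrix(take(n * m), n, m), b1 = take(m),
                 W2 = matrix(take(m * l), m, l), b2 = take(l),
                 spec = spec, loss = numeric(0)),
            class = "mlp_model")
}

#' MLP forward pass
#'
#' `H = sigmoid(X W1 + b1)`, `O = sigmoid(H W2 + b2)`.
#'
#' @param model an `mlp_model`
#' @param x feature vector or matrix
#' @return list with `hidden` and `output` activation matrices
#' @export
mlp_forward <- function(model, x) {
  stopifnot(inherits(model, "mlp_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != model$spec$n_input) stop("dimension mismatch")
  H <- sigmoid(sweep(x %*% model$W1, 2, model$b1, "+"))
  O <- sigmoid(sweep(H %*% model$W2, 2, model$b2, "+"))
  list(hidden = H, output = O)
}

one_hot <- function(y, l) {
  m <- matrix(0, length(y), l)
  m[cbind(seq_along(y), y)] <- 1
  m
}

#' Train a BP neural network
#'
#' Full-batch gradient backpropagation on the squared-error loss with a
#' fixed learning rate, from seeded uniform(-0.5, 0.5) initial weights.
#' Stops at the epoch cap or when the global error (mean squared error per
#' sample) falls below `target_error`. `max_epochs = 0` returns the initial
#' network unchanged.
#'
#' @param ds a [labeled_dataset()]
#' @param spec an [mlp_spec()]
#' @return an `mlp_model` with the per-epoch loss in `$loss`
#' @export
train_bp <- function(ds, spec = mlp_spec()) {
  stopifnot(inherits(ds, "labeled_dataset"), inherits(spec, "mlp_spec"))
  train_bp_from(init_mlp(spec), ds, spec)
}

#' Train a PSO-BP neural network
#'
#' PSO (see [pso_optimize()]) searches the flattened vector of connection
#' weights and node thresholds, maximizing classification accuracy on the
#' training set; the best vector is unpacked into the network. With
#' `polish = TRUE` (default) the swarm's best network is then fine-tuned by
#' BP gradient descent, the standard PSO-BP arrangement (swarm escapes the
#' poor initializations gradient descent is prone to; the gradient refines
#' the swarm's coarse optimum).
#'
#' @param ds a [labeled_dataset()]
#' @param spec an [mlp_spec()]
#' @param swarm a [pso_config()]
#' @param weight_bound search box half-width for every weight/threshold;
#'   the default 1 keeps the swarm on the same scale as the uniform
#'   (-0.5, 0.5) BP initialization, away from saturated sigmoids that
#'   gradient polish cannot escape
#' @param polish fine-tune the swarm optimum with BP
#' @return an `mlp_model`; the swarm's fitness trace is in `$tune$trace`
#' @export
train_pso_bp <- function(ds, spec = mlp_spec(), swarm = pso_config(),
                         weight_bound = 1, polish = TRUE) {
  stopifnot(inherits(ds, "labeled_dataset"), inherits(spec, "mlp_spec"))
  d <- n_mlp_params(spec)
  y_true <- ds$y
  fn <- function(w) {
    m <- unpack_mlp(w, spec)
    mean(predict_mlp(m, ds$x) == y_true)
  }
  res <- pso_optimize(fn, rep(-weight_bound, d), rep(weight_bound, d), swarm)
  model <- unpack_mlp(res$par, spec)
  if (polish) model <- train_bp_from(model, ds, spec)
  model$tune <- list(fitness = res$value, trace = res$trace,
                     iterations = res$iterations)
  model
}

# BP gradient refinement from given weights (shared loop with train_bp).
train_bp_from <- function(model, ds, spec) {
  X <- ds$x
  tgt <- one_hot(ds$y, spec$n_output)
  n <- nrow(X)
  eta <- spec$learning_rate
  loss <- numeric(0)
  for (epoch in seq_len(spec$max_epochs)) {
    fw <- mlp_forward(model, X)
    H <- fw$hidden; O <- fw$output
    E <- 0.5 * mean(rowSums((tgt - O)^2))
    if (!is.finite(E)) stop("BP training diverged (non-finite loss)")
    loss <- c(loss, E)
    if (E < spec$target_error) break
    dO <- (O - tgt) * O * (1 - O) / n
    dH <- (dO %*% t(model$W2)) * H * (1 - H)
    model$W2 <- model$W2 - eta * crossprod(H, dO)
    model$b2 <- model$b2 - eta * colSums(dO)
    model$W1 <- model$W1 - eta * crossprod(X, dH)
    model$b1 <- model$b1 - eta * colSums(dH)
  }
  model$loss <- loss
  model
}

#' MLP phase prediction
#'
#' Argmax over the four output activations; exact ties go to the lowest
#' phase index.
#'
#' @param model an `mlp_model`
#' @param x feature vector or matrix
#' @return integer phase labels
#' @export
predict_mlp <- function(model, x) {
  O <- mlp_forward(model, x)$output
  max.col(O, ties.method = "first")
}
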