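# Binary kernel SVM and the three-node binary-tree phase classifier.
#
# The quadratic-programming solver is delegated to e1071 (libsvm); this file
# owns the kernel definitions, the decision function f(P) = sgn(sum_i Q_i
# alpha_i* K(P_i, P) + b*) evaluated as an explicit sum over the support
# vectors, the peeling binary tree, and model serialization.

#' Kernel specification
#'
#' The four kernels of the classical comparison (libsvm `s` codes in
#' parentheses): polynomial `(gamma u.v + coef0)^degree` (s=0), RBF
#' `exp(-gamma ||u-v||^2)` (s=1), linear `u.v` (s=2), sigmoid
#' `tanh(gamma u.v + coef0)` (s=3).
#'
#' @param kind one of `"polynomial"`, `"rbf"`, `"linear"`, `"sigmoid"`
#' @param gamma kernel bandwidth (> 0 for rbf/polynomial/sigmoid)
#' @param degree polynomial degree
#' @param coef0 offset for polynomial/sigmoid
#' @return object of class `kernel_spec`
#' @export
kernel_spec <- function(kind = c("rbf", "linear", "polynomial", "sigmoid"),
                        gamma = 1, degree = 3, coef0 = 0) {
  kind <- match.arg(kind)
  if (kind != "linear" && (!is.numeric(gamma) || gamma <= 0))
    stop("gamma must be > 0 for ", kind, " kernels")
  structure(list(kind = kind, gamma = gamma, degree = as.integer(degree),
                 coef0 = coef0), class = "kernel_spec")
}

#' Kernel evaluation
#'
#' `kernel_eval` evaluates one pair of vectors; `kernel_matrix` evaluates
#' all pairs of the rows of `U` and `V`.
#'
#' @param spec a [kernel_spec()]
#' @param u,v feature vectors of equal dimension
#' @return scalar kernel value
#' @export
kernel_eval <- function(spec, u, v) {
  if (length(u) != length(v)) stop("u and v must have the same dimension")
  drop(kernel_matrix(spec, matrix(u, 1), matrix(v, 1)))
}

#' @rdname kernel_eval
#' @param U,V matrices with observations in rows
#' @return `kernel_matrix`: nrow(U) x nrow(V) matrix
#' @export
kernel_matrix <- function(spec, U, V) {
  stopifnot(inherits(spec, "kernel_spec"))
  U <- as.matrix(U); V <- as.matrix(V)
  if (ncol(U) != ncol(V)) stop("U and V must have the same dimension")
  ip <- tcrossprod(U, V)
  switch(spec$kind,
    linear = ip,
    polynomial = (spec$gamma * ip + spec$coef0)^spec$degree,
    sigmoid = tanh(spec$gamma * ip + spec$coef0),
    rbf = {
      d2 <- outer(rowSums(U^2), rowSums(V^2), "+") - 2 * ip
      exp(-spec$gamma * pmax(d2, 0))
    })
}

e1071_kernel_name <- c(rbf = "radial", linear = "linear",
                       polynomial = "polynomial", sigmoid = "sigmoid")

#' Train a soft-margin binary kernel SVM
#'
#' Fits the dual soft-margin problem (libsvm backend) and stores the model
#' in decision-function form: support vectors, signed coefficients
#' `Q_i alpha_i*` and bias `b*`, oriented so that positive decision values
#' mean class +1 regardless of training-row order.
#'
#' @param x feature matrix
#' @param y labels in {-1, +1}, both classes present
#' @param C penalty factor (> 0)
#' @param kernel a [kernel_spec()]
#' @return object of class `svm_binary` with fields `sv`, `coef`
#'   (= Q_i alpha_i*, so `sum(coef) == 0` and `|coef| <= C`), `b`, `C`,
#'   `kernel`
#' @export
train_binary <- function(x, y, C = 1, kernel = kernel_spec("rbf")) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (!all(y %in% c(-1L, 1L))) stop("y must be in {-1, +1}")
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (C <= 0) stop("C must be > 0")
  m <- e1071::svm(x, factor(y, levels = c("1", "-1")),
                  scale = FALSE, type = "C-classification",
                  kernel = e1071_kernel_name[[kernel$kind]],
                  cost = C, gamma = kernel$gamma, degree = kernel$degree,
                  coef0 = kernel$coef0)
  # libsvm orients decision values toward the first class it encounters
  flip <- m$levels[m$labels[1]] == "-1"
  structure(list(sv = unname(as.matrix(m$SV)),
                 coef = as.vector(if (flip) -m$coefs else m$coefs),
                 b = if (flip) m$rho else -m$rho,
                 C = C, kernel = kernel),
            class = "svm_binary")
}

#' Binary SVM prediction
#'
#' Evaluates the decision function `f(P) = sum_i Q_i alpha_i* K(P_i, P) +
#' b*` and returns its sign, with the tie rule that a decision value of
#' exactly 0 maps to +1.
#'
#' @param model an `svm_binary`
#' @param x feature vector or matrix of rows to classify
#' @return list with `class` (+1/-1 integers) and `decision` values
#' @export
predict_binary <- function(model, x) {
  stopifnot(inherits(model, "svm_binary"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != ncol(model$sv)) stop("dimension mismatch")
  dv <- as.vector(kernel_matrix(model$kernel, x, model$sv) %*% model$coef) + model$b
  list(class = ifelse(dv >= 0, 1L, -1L), decision = dv)
}

#' Train the binary-tree phase classifier
#'
#' Three binary SVMs peel the phases off in fixed order: SVM1 separates
#' pedaling from everything else, SVM2 separates the lower buffer from the
#' remaining two phases, SVM3 separates relaxation from the upper buffer;
#' whatever survives all three is the upper buffer. `scheme = "secondary"`
#' builds the rejected two-stage alternative ({pedaling, lower buffer} vs
#' the rest, then one SVM inside each half) for comparison only.
#'
#' @param ds a [labeled_dataset()] with all four phases present
#' @param C penalty factor(s); length 1 (shared) or 3 (per node)
#' @param gamma kernel bandwidth(s); length 1 or 3
#' @param kind kernel kind (see [kernel_spec()])
#' @param degree,coef0 passed to [kernel_spec()]
#' @param scheme `"binary_tree"` (default) or `"secondary"`
#' @return object of class `phase_tree`
#' @export
train_tree <- function(ds, C = 2, gamma = 1, kind = "rbf", degree = 3,
                       coef0 = 0, scheme = c("binary_tree", "secondary")) {
  stopifnot(inherits(ds, "labeled_dataset"))
  scheme <- match.arg(scheme)
  if (!all(1:4 %in% ds$y)) stop("all four phase labels must be present")
  C <- rep_len(C, 3)
  gamma <- rep_len(gamma, 3)
  fit <- function(rows, pos, i) {
    train_binary(ds$x[rows, , drop = FALSE],
                 ifelse(ds$y[rows] %in% pos, 1L, -1L),
                 C = C[i], kernel = kernel_spec(kind, gamma[i], degree, coef0))
  }
  nodes <- if (scheme == "binary_tree") {
    list(fit(seq_along(ds$y), 1L, 1),
         fit(which(ds$y != 1L), 2L, 2),
         fit(which(ds$y %in% 3:4), 3L, 3))
  } else {
    list(fit(seq_along(ds$y), 1:2, 1),
         fit(which(ds$y %in% 1:2), 1L, 2),
         fit(which(ds$y %in% 3:4), 3L, 3))
  }
  structure(list(scheme = scheme, nodes = nodes), class = "phase_tree")
}

#' Predict phases with the binary tree
#'
#' Sequential evaluation: the first node returning +1 assigns its phase and
#' later nodes are never evaluated for that sample; a sample rejected by all
#' three nodes is the upper buffer.
#'
#' @param model a `phase_tree`
#' @param x feature vector or matrix
#' @return integer phase labels in {1, 2, 3, 4}
#' @export
predict_tree <- function(model, x) {
  stopifnot(inherits(model, "phase_tree"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  n <- nrow(x)
  out <- integer(n)
  if (model$scheme == "binary_tree") {
    rem <- seq_len(n)
    for (k in 1:3) {
      if (!length(rem)) break
      fired <- predict_binary(model$nodes[[k]], x[rem, , drop = FALSE])$class == 1L
      out[rem[fired]] <- k
      rem <- rem[!fired]
    }
    out[rem] <- 4L
  } else {
    top <- predict_binary(model$nodes[[1]], x)$class == 1L
    if (any(top)) {
      p <- predict_binary(model$nodes[[2]], x[top, , drop = FALSE])$class
      out[top] <- ifelse(p == 1L, 1L, 2L)
    }
    if (any(!top)) {
      p <- predict_binary(model$nodes[[3]], x[!top, , drop = FALSE])$class
      out[!top] <- ifelse(p == 1L, 3L, 4L)
    }
  }
  out
}

#' Kernel / parameter grid accuracy report
#'
#' Trains the binary tree for every (kernel, C, gamma) combination on the
#' training set and reports test-set accuracy, mirroring the classical
#' kernel-comparison table.
#'
#' @param train,test [labeled_dataset()]s
#' @param params data frame with columns `C` and `gamma`
#' @param kinds kernel kinds to sweep
#' @return data frame with columns `kernel`, `C`, `gamma`, `accuracy` (%)
#' @export
kernel_grid_report <- function(train, test,
                               params = data.frame(C = c(2, 1, 2, 3),
                                                   gamma = c(1, 1, 0.5, 2)),
                               kinds = c("polynomial", "rbf", "linear", "sigmoid")) {
  out <- expand.grid(kernel = kinds, row = seq_len(nrow(params)),
                     stringsAsFactors = FALSE)
  out$C <- params$C[out$row]
  out$gamma <- params$gamma[out$row]
  out$row <- NULL
  out$accuracy <- vapply(seq_len(nrow(out)), function(i) {
    fitted <- train_tree(train, C = out$C[i], gamma = out$gamma[i],
                         kind = out$kernel[i])
    100 * mean(predict_tree(fitted, test$x) == test$y)
  }, numeric(1))
  out
}

#' Serialize / restore a phase-tree model as JSON
#'
#' Portable structured text: kernel spec, penalty, support vectors, signed
#' coefficients and bias per node.
#'
#' @param model a `phase_tree`
#' @param path file path
#' @return `read_tree_model` returns a `phase_tree`
#' @export
write_tree_model <- function(model, path) {
  stopifnot(inherits(model, "phase_tree"))
  payload <- list(scheme = model$scheme, nodes = lapply(model$nodes, function(nd)
    list(kernel = unclass(nd$kernel), C = nd$C, b = nd$b,
         coef = nd$coef, sv = nd$sv)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tree_model
#' @export
read_tree_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  nodes <- lapply(payload$nodes, function(nd) {
    k <- nd$kernel
    structure(list(sv = do.call(rbind, lapply(nd$sv, function(r) as.numeric(unlist(r)))),
                   coef = as.numeric(unlist(nd$coef)),
                   b = as.numeric(nd$b), C = as.numeric(nd$C),
                   kernel = kernel_spec(k$kind, k$gamma, k$degree, k$coef0)),
              class = "svm_binary")
  })
  structure(list(scheme = payload$scheme, nodes = nodes), class = "phase_tree")
}
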