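# Extreme learning machine: a single-hidden-layer feed-forward network whose
# hidden parameters are random and never trained; only the output weights
# are solved, analytically, by least squares.

elm_activations <- list(
  sigmoid = stats::plogis,
  tanh = base::tanh
)

# Hidden-layer design matrix H = act(X W^T + b)
elm_hidden <- function(X, W, b, activation) {
  act <- elm_activations[[activation]]
  if (is.null(act)) stop("unknown activation", call. = FALSE)
  H <- tcrossprod(X, W)
  H <- H + matrix(b, nrow(H), length(b), byrow = TRUE)
  act(H)
}

# Assemble a fitted model from an explicit hidden layer: output weights are
# the minimum-norm least-squares solution beta = pinv(H) y.
elm_from_layer <- function(X, y, W, b, activation = "sigmoid") {
  H <- elm_hidden(X, W, b, activation)
  beta <- MASS::ginv(H) %*% y
  structure(
    list(input_dim = ncol(X), hidden_count = nrow(W), input_weights = W,
         hidden_biases = b, output_weights = as.vector(beta),
         activation = activation),
    class = "elm_model"
  )
}

#' Fit an extreme learning machine regressor
#'
#' Input weights and hidden biases are drawn uniformly on `[-1, 1]` from a
#' seeded RNG and left untrained; the hidden design matrix
#' `H = act(X W^T + b)` is formed and the output weights are solved
#' analytically as `beta = pinv(H) y` (Moore-Penrose pseudoinverse, so the
#' residual norm is minimal and `beta` has minimum norm among minimizers).
#'
#' @param X numeric matrix, samples by features.
#' @param y numeric target vector (chlorophyll, mg/L).
#' @param hidden_count number of hidden nodes, `>= 1` (default 20).
#' @param seed RNG seed for the hidden layer.
#' @param activation `"sigmoid"` (default) or `"tanh"`.
#' @return An object of class `elm_model`.
#' @examples
#' X <- matrix(rnorm(30), 15, 2)
#' y <- X[, 1] - 2 * X[, 2]
#' m <- elm_fit(X, y, hidden_count = 10, seed = 1)
#' rmse(y, elm_predict(m, X))
#' @export
elm_fit <- function(X, y, hidden_count = 20L, seed = 1L,
                    activation = c("sigmoid", "tanh")) {
  activation <- match.arg(activation)
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (anyNA(X) || any(!is.finite(X)) || anyNA(y) || any(!is.finite(y))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (nrow(X) != length(y)) stop("row/target length mismatch", call. = FALSE)
  hidden_count <- as.integer(hidden_count)
  if (hidden_count < 1L) stop("`hidden_count` must be >= 1", call. = FALSE)
  local_seed(seed, {
    W <- matrix(stats::runif(hidden_count * ncol(X), -1, 1),
                hidden_count, ncol(X))
    b <- stats::runif(hidden_count, -1, 1)
    elm_from_layer(X, y, W, b, activation)
  })
}

#' Predict with an extreme learning machine
#'
#' @param model an `elm_model`.
#' @param X numeric matrix with `model$input_dim` columns.
#' @return Numeric vector of predictions.
#' @export
elm_predict <- function(model, X) {
  stopifnot(inherits(model, "elm_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$input_dim) {
    stop("feature count does not match the model input dimension",
         call. = FALSE)
  }
  H <- elm_hidden(X, model$input_weights, model$hidden_biases,
                  model$activation)
  as.vector(H %*% model$output_weights)
}

#' @export
print.elm_model <- function(x, ...) {
  cat(sprintf("<elm_model> %d -> %d (%s) -> 1\n",
              x$input_dim, x$hidden_count, x$activation))
  invisible(x)
}

#' Serialize an ELM model to JSON
#'
#' @param model an `elm_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_elm_json <- function(model, path) {
  stopifnot(inherits(model, "elm_model"))
  obj <- list(
    input_dim = model$input_dim,
    hidden_count = model$hidden_count,
    input_weights = model$input_weights,
    hidden_biases = model$hidden_biases,
    output_weights = model$output_weights,
    activation = model$activation
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read an ELM model from JSON
#'
#' @param path file written by [write_elm_json()].
#' @return An `elm_model`.
#' @export
read_elm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- as.matrix(obj$input_weights)
  if (nrow(W) != as.integer(obj$hidden_count)) W <- t(W)
  structure(
    list(input_dim = as.integer(obj$input_dim),
         hidden_count = as.integer(obj$hidden_count),
         input_weights = W,
         hidden_biases = as.numeric(obj$hidden_biases),
         output_weights = as.numeric(obj$output_weights),
         activation = obj$activation),
    class = "elm_model"
  )
}
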