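#' Fit an ELM with a particle-swarm-optimized input layer
#'
#' Each particle encodes a full hidden layer: the first
#' `hidden_count * input_dim` entries fill the input-weight matrix
#' (column-major), the remaining `hidden_count` entries are the hidden
#' biases. A particle's fitness is the RMSE on the validation set of the
#' ELM whose input layer it decodes and whose output weights are solved
#' analytically on the training set; the swarm therefore searches only the
#' random part of the ELM while the output layer stays a closed-form least
#' squares solve. The returned model is decoded from the final global best.
#'
#' @param X,y training samples and targets.
#' @param X_val,y_val non-empty validation set scored by the fitness.
#' @param hidden_count hidden nodes (default 20).
#' @param cfg a [pso_config()]; bounds apply to every weight and bias.
#' @param activation hidden activation (see [elm_fit()]).
#' @param init optional matrix of initial particles (e.g. the encoded layer
#'   of a plain ELM).
#' @param fitness_on score particles on `"validation"` (default) or
#'   `"training"` RMSE.
#' @return An `elm_model` with extra fields `val_rmse` (fitness of the
#'   returned model) and `trace` (the swarm's global-best fitness per
#'   iteration).
#' @export
pso_elm_fit <- function(X, y, X_val, y_val, hidden_count = 20L,
                        cfg = pso_config(), activation = "sigmoid",
                        init = NULL, fitness_on = c("validation", "training")) {
  fitness_on <- match.arg(fitness_on)
  X <- as.matrix(X); X_val <- as.matrix(X_val)
  y <- as.numeric(y); y_val <- as.numeric(y_val)
  if (length(y_val) < 1L) stop("validation set is empty", call. = FALSE)
  if (ncol(X_val) != ncol(X)) stop("feature mismatch", call. = FALSE)
  hidden_count <- as.integer(hidden_count)
  d <- ncol(X)
  dim_total <- hidden_count * (d + 1L)

  decode <- function(p) {
    list(W = matrix(p[seq_len(hidden_count * d)], hidden_count, d),
         b = p[hidden_count * d + seq_len(hidden_count)])
  }
  fitness <- function(p) {
    layer <- decode(p)
    model <- elm_from_layer(X, y, layer$W, layer$b, activation)
    if (fitness_on == "training") {
      rmse(y, elm_predict(model, X))
    } else {
      rmse(y_val, elm_predict(model, X_val))
    }
  }

  res <- pso_minimize(fitness, dim_total, cfg, init = init)
  layer <- decode(res$position)
  model <- elm_from_layer(X, y, layer$W, layer$b, activation)
  model$val_rmse <- res$fitness
  model$trace <- res$trace
  model
}

#' Encode an ELM hidden layer as a particle vector
#'
#' Inverse of the decoding used by [pso_elm_fit()]; useful for warm-starting
#' the swarm at an existing model.
#'
#' @param model an `elm_model`.
#' @return Numeric vector of length `hidden_count * (input_dim + 1)`.
#' @export
encode_elm_layer <- function(model) {
  stopifnot(inherits(model, "elm_model"))
  c(as.vector(model$input_weights), model$hidden_biases)
}

#' Sweep the ELM hidden-node count by validation RMSE
#'
#' Utility for choosing the hidden-layer size: fits a seeded plain ELM for
#' each candidate count and reports validation RMSE.
#'
#' @param X,y training data; `X_val,y_val` validation data.
#' @param counts candidate hidden-node counts.
#' @param seed RNG seed shared by all fits.
#' @return Data frame with `hidden_count` and `val_rmse`.
#' @export
sweep_hidden_count <- function(X, y, X_val, y_val,
                               counts = c(5L, 10L, 20L, 40L), seed = 1L) {
  val <- vapply(counts, function(L) {
    m <- elm_fit(X, y, hidden_count = L, seed = seed)
    rmse(y_val, elm_predict(m, as.matrix(X_val)))
  }, numeric(1))
  data.frame(hidden_count = as.integer(counts), val_rmse = val)
}
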