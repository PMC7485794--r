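#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot`. Can be negative for predictions worse than
#' the mean; errors on constant `y_true`.
#'
#' @param y_true observed values (nonconstant, `n >= 2`).
#' @param y_pred predicted values, same length.
#' @return R-squared.
#' @examples
#' r2_score(c(1, 2, 3), c(1, 2, 4))  # 0.5
#' @export
r2_score <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("length mismatch", call. = FALSE)
  }
  if (length(y_true) < 2L) stop("need at least 2 observations", call. = FALSE)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stop("`y_true` is constant", call. = FALSE)
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Root mean square error
#'
#' @param y_true,y_pred numeric vectors of equal length `>= 1`.
#' @return RMSE, in the units of the inputs (mg/L for chlorophyll).
#' @examples
#' rmse(c(0, 0), c(3, 4))  # sqrt(12.5)
#' @export
rmse <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  if (length(y_true) != length(y_pred) || length(y_true) < 1L) {
    stop("inputs must be non-empty and of equal length", call. = FALSE)
  }
  sqrt(mean((y_true - y_pred)^2))
}

#' Build an evaluation report from predictions
#'
#' @param y_true observed chlorophyll (mg/L).
#' @param y_pred predicted chlorophyll (mg/L).
#' @param sample_ids optional identifiers.
#' @return An object of class `evaluation_report`: `r2`, `rmse`, `n` and a
#'   `predictions` data frame (id, true, predicted).
#' @export
evaluate_predictions <- function(y_true, y_pred, sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_along(y_true))
  structure(
    list(r2 = r2_score(y_true, y_pred), rmse = rmse(y_true, y_pred),
         n = length(y_true),
         predictions = data.frame(id = sample_ids, true = y_true,
                                  predicted = y_pred)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n = %d, R^2 = %.3f, RMSE = %.3f mg/L\n",
              x$n, x$r2, x$rmse))
  invisible(x)
}
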