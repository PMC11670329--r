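#' Evaluation metrics: RMSE, MAE, Pearson correlation
#'
#' The three metrics used to evaluate yield predictions:
#' `rmse = sqrt(mean((y - yhat)^2))`, `mae = mean(abs(y - yhat))`, and the
#' Pearson correlation of predictions with observations. `pearson_r` errors
#' on zero-variance input (the correlation is undefined there; a silent 0
#' would corrupt report tables).
#'
#' @param y Observed values.
#' @param yhat Predicted values (same length, finite).
#' @return A single numeric value.
#' @export
rmse <- function(y, yhat) {
  check_metric_input(y, yhat)
  sqrt(mean((y - yhat)^2))
}

#' @rdname rmse
#' @export
mae <- function(y, yhat) {
  check_metric_input(y, yhat)
  mean(abs(y - yhat))
}

#' @rdname rmse
#' @export
pearson_r <- function(y, yhat) {
  check_metric_input(y, yhat)
  cy <- y - mean(y)
  cyh <- yhat - mean(yhat)
  denom <- sqrt(sum(cy^2)) * sqrt(sum(cyh^2))
  abort_if(denom == 0,
           "pearson_r is undefined: at least one input has zero variance")
  sum(cy * cyh) / denom
}

check_metric_input <- function(y, yhat) {
  abort_if(length(y) == 0L, "empty input")
  abort_if(length(y) != length(yhat),
           "length mismatch: ", length(y), " vs ", length(yhat))
  abort_if(any(!is.finite(y)) || any(!is.finite(yhat)),
           "inputs must be finite")
}

#' Evaluation report for one split
#'
#' @param y Observed yields.
#' @param yhat Predicted yields.
#' @param split Split label (e.g. `"test"`).
#' @return Object of class `eval_report`: list with `rmse`, `mae`, `r`, `n`,
#'   `split`.
#' @export
evaluation_report <- function(y, yhat, split = "test") {
  out <- structure(list(rmse = rmse(y, yhat), mae = mae(y, yhat),
                        r = pearson_r(y, yhat), n = length(y), split = split),
                   class = "eval_report")
  abort_if(out$rmse < out$mae, "internal error: RMSE below MAE")
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("[%s] n = %d  RMSE = %.4f  MAE = %.4f  r = %.4f\n",
              x$split, x$n, x$rmse, x$mae, x$r))
  invisible(x)
}
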