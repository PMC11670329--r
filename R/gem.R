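#' Fit Generalized Ensemble Method weights
#'
#' Solves the convex program
#' `min_w (1/n) sum_i (y_i - sum_j w_j yhat_ij)^2` subject to `w_j >= 0` and
#' `sum_j w_j = 1` — a simplex-constrained least-squares combination of base
#' model predictions, fitted on validation-set predictions. The solver
#' enumerates active sets: for every non-empty support it solves the
#' equality-constrained least-squares KKT system and keeps the best feasible
#' solution. The optimum of a convex QP over the simplex is the
#' equality-constrained optimum on its own support, so the enumeration is
#' exact; vertices (single models) are always feasible, which guarantees the
#' fitted ensemble MSE never exceeds the best base model's MSE on the
#' fitting set. Supports are scanned singletons-first in model order, and
#' improvement must be strict, so ties break toward the lower model index.
#'
#' @param predictions Numeric matrix, `n` observations x `k` base models.
#' @param y Numeric vector of true values, length `n`.
#' @param tolerance Relative feasibility tolerance for clipping negligible
#'   negative weights.
#' @return Object of class `gem_weights`: list with `weights` (length `k`,
#'   non-negative, summing to 1), `objective` (achieved mean squared error)
#'   and `model_ids`.
#' @export
fit_gem <- function(predictions, y, tolerance = 1e-8) {
  predictions <- as.matrix(predictions)
  abort_if(!all(is.finite(predictions)) || !all(is.finite(y)),
           "predictions and y must be finite")
  n <- nrow(predictions)
  k <- ncol(predictions)
  abort_if(n < 1L || k < 1L, "need at least one observation and one model")
  abort_if(length(y) != n, "y must align with prediction rows")
  abort_if(k > 15L, "exact active-set enumeration supports at most 15 models")
  ids <- colnames(predictions) %||% paste0("model_", seq_len(k))

  obj <- function(w) mean((y - predictions %*% w)^2)

  # supports ordered by size then lexicographically: singletons first
  supports <- list()
  for (size in seq_len(k)) {
    cmb <- utils::combn(k, size)
    for (j in seq_len(ncol(cmb))) supports[[length(supports) + 1L]] <- cmb[, j]
  }

  best_w <- NULL
  best_obj <- Inf
  for (S in supports) {
    m <- length(S)
    if (m == 1L) {
      w_s <- 1
    } else {
      P <- predictions[, S, drop = FALSE]
      A <- 2 / n * crossprod(P)
      aug <- rbind(cbind(A, 1), c(rep(1, m), 0))
      rhs <- c(2 / n * crossprod(P, y), 1)
      sol <- tryCatch(solve(aug, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      w_s <- sol[seq_len(m)]
      if (any(w_s < -tolerance)) next
      w_s <- pmax(w_s, 0)
      w_s <- w_s / sum(w_s)
    }
    w <- numeric(k)
    w[S] <- w_s
    o <- obj(w)
    if (o < best_obj - 1e-15) {
      best_obj <- o
      best_w <- w
    }
  }

  base_mse <- apply(predictions, 2L, function(p) mean((y - p)^2))
  abort_if(best_obj > min(base_mse) + 1e-9 * (1 + min(base_mse)),
           "internal error: ensemble objective exceeds best base model")

  structure(list(weights = setNames(best_w, ids), objective = best_obj,
                 model_ids = ids),
            class = "gem_weights")
}

#' @export
print.gem_weights <- function(x, ...) {
  cat("GEM weights:", paste(sprintf("%s = %.4f", x$model_ids, x$weights),
                            collapse = ", "),
      sprintf("(validation MSE %.6g)\n", x$objective))
  invisible(x)
}

#' Combine base-model predictions with fitted ensemble weights
#'
#' @param weights A `gem_weights` object (or bare numeric weight vector on
#'   the simplex).
#' @param predictions Numeric matrix, `n` x `k`, columns aligned with the
#'   weights.
#' @return Numeric vector of row-wise weighted sums.
#' @export
gem_predict <- function(weights, predictions) {
  w <- if (inherits(weights, "gem_weights")) weights$weights else weights
  predictions <- as.matrix(predictions)
  abort_if(ncol(predictions) != length(w),
           "dimension mismatch: ", ncol(predictions), " prediction columns vs ",
           length(w), " weights")
  as.vector(predictions %*% w)
}

#' Exhaustive simplex-grid search (verification oracle)
#'
#' Evaluates the GEM objective on a regular grid over the simplex and
#' returns the best grid point. Intended as an independent check of
#' [fit_gem()] at small `k`; not for production fitting.
#'
#' @param predictions Numeric matrix, `n` x `k`, `k <= 3`.
#' @param y True values.
#' @param resolution Grid resolution (>= 100 subdivisions per axis).
#' @return List with `weights` and `objective`.
#' @export
gem_grid_oracle <- function(predictions, y, resolution = 1000L) {
  predictions <- as.matrix(predictions)
  k <- ncol(predictions)
  abort_if(k > 3L, "grid oracle supports at most 3 models")
  abort_if(resolution < 100L, "resolution must be >= 100")
  if (k == 1L) {
    return(list(weights = 1, objective = mean((y - predictions[, 1L])^2)))
  }
  if (k == 2L) {
    w1 <- seq(0L, resolution) / resolution
    W <- rbind(w1, 1 - w1)
  } else {
    ij <- expand.grid(i = 0:resolution, j = 0:resolution)
    ij <- ij[ij$i + ij$j <= resolution, ]
    W <- rbind(ij$i, ij$j, resolution - ij$i - ij$j) / resolution
  }
  pred <- predictions %*% W
  objs <- colMeans((y - pred)^2)
  best <- which.min(objs)
  list(weights = W[, best], objective = objs[best])
}
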