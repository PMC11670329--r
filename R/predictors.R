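#' Ensemble predictor object
#'
#' Couples trained base networks with fitted GEM weights into a single
#' predictor usable wherever a trained model is.
#'
#' @param models Named list of trained `gem_network` objects.
#' @param weights A `gem_weights` object aligned with `models`.
#' @return Object of class `gem_ensemble`.
#' @export
gem_ensemble <- function(models, weights) {
  abort_if(!inherits(weights, "gem_weights"), "weights must come from fit_gem")
  abort_if(length(models) != length(weights$weights),
           "model count does not match weight count")
  abort_if(!all(vapply(models, inherits, logical(1), "gem_network")),
           "models must be gem_network objects")
  structure(list(models = models, weights = weights,
                 prep = models[[1L]]$prep),
            class = "gem_ensemble")
}

#' @export
print.gem_ensemble <- function(x, ...) {
  cat("gem_ensemble of", length(x$models), "base models\n")
  print(x$weights)
  invisible(x)
}

#' Predict yields from an ensemble on feature rows
#'
#' @param object A `gem_ensemble`.
#' @param features A `gem_features` object.
#' @param rows Optional row selector.
#' @param ... Passed to the base-model predict methods.
#' @return Numeric vector of combined predictions.
#' @export
predict.gem_ensemble <- function(object, features, rows = NULL, ...) {
  base <- vapply(object$models,
                 function(m) predict(m, features, rows = rows, ...),
                 numeric(if (is.null(rows)) nrow(features$onehot)
                         else if (is.logical(rows)) sum(rows) else length(rows)))
  if (is.null(dim(base))) base <- matrix(base, nrow = 1L)
  gem_predict(object$weights, base)
}

#' Predict yields directly from trial records
#'
#' Encodes the records with the predictor's stored category registry and
#' normalisation statistics (for networks and ensembles), or evaluates the
#' stored generative mean (for a [truth_predictor()]), and returns one
#' prediction per record.
#'
#' @param object A trained `gem_network`, a `gem_ensemble`, or a
#'   `truth_predictor`.
#' @param records Trial records `data.frame` (wide weather columns; yields
#'   may be absent).
#' @param ... Unused.
#' @return Numeric vector of predicted yields.
#' @export
predict_yield <- function(object, records, ...) UseMethod("predict_yield")

#' @export
predict_yield.gem_network <- function(object, records, ...) {
  abort_if(is.null(object$prep),
           "model carries no preprocessing state; train it first")
  feats <- build_features(records, object$prep$registry,
                          stats = object$prep$stats)
  predict(object, feats)
}

#' @export
predict_yield.gem_ensemble <- function(object, records, ...) {
  base <- vapply(object$models, predict_yield, numeric(nrow(records)), records)
  if (is.null(dim(base))) base <- matrix(base, nrow = 1L)
  gem_predict(object$weights, base)
}

#' Oracle predictor from stored synthetic truth
#'
#' Reconstructs the generative mean of a synthetic dataset — base yield plus
#' genotype, location and year effects, genotype-by-location interaction and
#' window weather effects (standardised with the stored window statistics) —
#' without the residual. On zero-residual data it reproduces the simulated
#' yields exactly, making it the reference predictor for selection-recovery
#' checks.
#'
#' @param truth A `sim_truth` from [simulate_dataset()] or
#'   [read_truth_json()].
#' @return Object of class `truth_predictor`.
#' @export
truth_predictor <- function(truth) {
  abort_if(!inherits(truth, "sim_truth"), "truth must be a sim_truth")
  structure(list(truth = truth), class = "truth_predictor")
}

#' @export
predict_yield.truth_predictor <- function(object, records, ...) {
  tr <- object$truth
  g <- tr$genotype_effects[records$genotype_id]
  l <- tr$location_effects[records$location_id]
  t_ <- tr$year_effects[as.character(records$year)]
  abort_if(any(is.na(g)) || any(is.na(l)) || any(is.na(t_)),
           "records contain categories unknown to the stored truth")
  inter <- tr$interaction_effects[cbind(records$genotype_id,
                                        records$location_id)]
  win <- rep(0, nrow(records))
  for (w in tr$window_coefficients) {
    daily <- as.matrix(records[, paste0(w$variable, "_", seq_len(N_DAYS)),
                               drop = FALSE])
    agg <- aggregate_weather(daily)
    x <- rowMeans(agg[, w$periods, drop = FALSE])
    z <- if (w$sd > 0) (x - w$mean) / w$sd else 0
    win <- win + w$effect * z
  }
  as.vector(tr$base_yield + g + l + t_ + inter + win)
}
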