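#' Define feature groups for permutation importance
#'
#' At `"variable"` granularity the groups are the three categorical one-hot
#' blocks (year, location, genotype), the 7 weather variables (53 aggregated
#' columns each) and, when present, the soil block — 10 groups (11 with
#' soil). At `"period"` granularity, one single-column group per 4-day
#' period of the requested weather variable (53 groups), used to localise a
#' variable's influence within the growing season.
#'
#' @param features A `gem_features` object.
#' @param granularity `"variable"` or `"period"`.
#' @param variable For `"period"` granularity: which weather variable.
#' @return Named list of feature groups, each a list with `name`, `block`
#'   (`"onehot"`, `"weather"` or `"soil"`) and `cols` (column indices within
#'   that block).
#' @export
define_groups <- function(features, granularity = c("variable", "period"),
                          variable = NULL) {
  granularity <- match.arg(granularity)
  abort_if(!inherits(features, "gem_features"), "features must be gem_features")
  if (granularity == "variable") {
    groups <- list()
    for (b in c("year", "location", "genotype")) {
      groups[[b]] <- list(name = b, block = "onehot",
                          cols = features$groups$onehot[[b]])
    }
    for (v in weather_variables()) {
      groups[[v]] <- list(name = v, block = "weather",
                          cols = features$groups$weather[[v]])
    }
    if (!is.null(features$soil)) {
      groups$soil <- list(name = "soil", block = "soil",
                          cols = features$groups$soil)
    }
    return(groups)
  }
  abort_if(is.null(variable), "period granularity needs a weather variable")
  abort_if(!variable %in% weather_variables(),
           "unknown group name: ", variable)
  cols <- features$groups$weather[[variable]]
  groups <- lapply(seq_len(N_PERIODS), function(p) {
    list(name = paste0(variable, "_", p), block = "weather", cols = cols[p])
  })
  names(groups) <- paste0(variable, "_", seq_len(N_PERIODS))
  groups
}

#' Jointly permute a feature group's rows
#'
#' Applies one random row permutation to all columns of the group at once,
#' preserving within-group row coherence (so a permuted one-hot block stays
#' a valid one-hot block); all other columns are untouched and the input
#' object is not modified.
#'
#' @param features A `gem_features` object.
#' @param group One element of [define_groups()].
#' @param seed Integer seed for the permutation.
#' @return A copy of `features` with the group's rows permuted.
#' @export
permute_group <- function(features, group, seed = 1L) {
  set.seed(as.integer(seed))
  n <- nrow(features$onehot)
  perm <- sample.int(n)
  apply_group_permutation(features, group, perm)
}

apply_group_permutation <- function(features, group, perm) {
  out <- features
  block <- group$block
  out[[block]][, group$cols] <- features[[block]][perm, group$cols]
  out
}

# stable per-group seed so results don't depend on evaluation order
group_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.double(seed) + 7919 * h) %% 2147483647) + 1L
}

#' Grouped permutation importance by RMSE change
#'
#' Computes the baseline RMSE `r0` of the predictor on the evaluation rows
#' (by default the whole `features` object — pass the test split), then, for
#' each feature group, re-predicts on copies with the group's rows jointly
#' permuted and records the RMSE increase, averaged over `repetitions`
#' permutations. A larger RMSE change means the group contributed more to
#' the predictions. Each group's permutations are drawn from a seed derived
#' from `seed` and the group name, so results are independent of group
#' order.
#'
#' @param predictor A trained `gem_network` or `gem_ensemble`.
#' @param features A `gem_features` object for the evaluation rows (with
#'   observed yields).
#' @param groups Output of [define_groups()].
#' @param repetitions Permutations per group (>= 1); changes are averaged.
#' @param seed Integer master seed.
#' @return Object of classes `gem_importance`/`data.frame` with columns
#'   `group`, `r0`, `rmse_perm`, `rmse_change`, `reps`, `seed`.
#' @export
rmse_change <- function(predictor, features, groups, repetitions = 10L,
                        seed = 1L) {
  abort_if(repetitions < 1L, "repetitions must be >= 1")
  y <- features$y
  abort_if(any(!is.finite(y)), "evaluation rows must have observed yields")
  n <- length(y)
  r0 <- rmse(y, predict(predictor, features))
  res <- data.frame(group = names(groups), r0 = r0,
                    rmse_perm = NA_real_, rmse_change = NA_real_,
                    reps = as.integer(repetitions), seed = as.integer(seed),
                    stringsAsFactors = FALSE)
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    set.seed(group_seed(seed, g$name))
    perms <- replicate(repetitions, sample.int(n), simplify = FALSE)
    rs <- vapply(perms, function(perm) {
      permuted <- apply_group_permutation(features, g, perm)
      rmse(y, predict(predictor, permuted))
    }, numeric(1))
    res$rmse_perm[gi] <- mean(rs)
    res$rmse_change[gi] <- mean(rs) - r0
  }
  class(res) <- c("gem_importance", "data.frame")
  res
}
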