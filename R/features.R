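#' Assemble the model-ready feature matrix
#'
#' Combines the one-hot categorical blocks (year, location, genotype), the 7
#' standardised 53-period weather blocks (371 columns) and, when soil columns
#' are present on the records, a standardised 66-column soil block, together
#' with the target vector and named column groups. At the real study
#' cardinalities (13 years, 159 locations, 5,838 genotypes) this yields
#' 6,010 + 371 = 6,381 columns (6,447 with soil).
#'
#' @param records Trial records `data.frame` (wide weather columns; soil
#'   columns appended by [merge_soil()] if used).
#' @param registry Category registry, usually built from the training rows
#'   via [build_category_registry()]. Unregistered categories encode as
#'   all-zero rows in their block.
#' @param split Optional `gem_split`; when given and `norm_scope = "train"`,
#'   normalisation statistics are fitted on training rows only.
#' @param norm_scope `"train"` (default; requires `split`) or `"all"`.
#' @param stats Optional pre-fitted `norm_stats` (overrides fitting; used to
#'   encode prediction-time rows with a trained model's statistics).
#'
#' @return Object of class `gem_features`: list with `onehot` (n x categories
#'   binary matrix), `weather` (n x 371 standardised matrix), `soil` (n x 66
#'   or `NULL`), `y` (yields, `NA` when absent), `groups` (named column-index
#'   lists per block), `registry`, `stats` and `meta` (the categorical key
#'   columns).
#' @export
build_features <- function(records, registry, split = NULL,
                           norm_scope = c("train", "all"), stats = NULL) {
  norm_scope <- match.arg(norm_scope)
  n <- nrow(records)
  onehot <- one_hot_encode(records, registry)

  # aggregate daily weather to 4-day periods, variable by variable
  vars <- weather_variables()
  weather <- matrix(0, n, 7L * N_PERIODS)
  wgroups <- list()
  cn <- character(7L * N_PERIODS)
  for (v in seq_along(vars)) {
    daily <- as.matrix(records[, paste0(vars[v], "_", seq_len(N_DAYS))])
    cols <- (v - 1L) * N_PERIODS + seq_len(N_PERIODS)
    weather[, cols] <- aggregate_weather(daily)
    cn[cols] <- paste0(vars[v], "_", seq_len(N_PERIODS))
    wgroups[[vars[v]]] <- cols
  }
  colnames(weather) <- cn

  soil_cols <- soil_column_names(records)
  soil <- if (length(soil_cols) > 0L) {
    as.matrix(records[, soil_cols, drop = FALSE])
  } else NULL

  to_norm <- if (is.null(soil)) weather else cbind(weather, soil)
  if (is.null(stats)) {
    reference <- if (norm_scope == "train") {
      abort_if(is.null(split), "norm_scope = 'train' requires a split")
      split$train
    } else rep(TRUE, n)
    stats <- fit_normalization(to_norm, reference)
  }
  normed <- apply_normalization(to_norm, stats)
  weather <- normed[, seq_len(ncol(weather)), drop = FALSE]
  if (!is.null(soil)) {
    soil <- normed[, ncol(weather) + seq_len(ncol(soil)), drop = FALSE]
  }

  y <- if ("yield" %in% names(records)) records$yield else rep(NA_real_, n)

  structure(list(
    onehot = onehot,
    weather = weather,
    soil = soil,
    y = y,
    groups = list(onehot = attr(onehot, "blocks"), weather = wgroups,
                  soil = if (!is.null(soil)) seq_len(ncol(soil)) else NULL),
    registry = registry,
    stats = stats,
    meta = records[, c("year", "location_id", "state", "genotype_id")]
  ), class = "gem_features")
}

soil_column_names <- function(records) {
  fixed <- c("year", "location_id", "state", "genotype_id", "maturity_group",
             "yield")
  setdiff(names(records), c(fixed, weather_col_names()))
}

#' @export
print.gem_features <- function(x, ...) {
  cat("gem_features:", nrow(x$onehot), "rows,",
      ncol(x$onehot), "one-hot +", ncol(x$weather), "weather",
      if (!is.null(x$soil)) paste("+", ncol(x$soil), "soil") else "",
      "columns\n")
  invisible(x)
}

#' Total feature column count of a feature matrix
#'
#' @param features A `gem_features` object.
#' @return Integer count of one-hot + weather (+ soil) columns.
#' @export
n_feature_columns <- function(features) {
  ncol(features$onehot) + ncol(features$weather) +
    if (!is.null(features$soil)) ncol(features$soil) else 0L
}

# row subset preserving structure (used by importance / evaluation)
subset_features <- function(features, rows) {
  out <- features
  out$onehot <- features$onehot[rows, , drop = FALSE]
  out$weather <- features$weather[rows, , drop = FALSE]
  if (!is.null(features$soil)) out$soil <- features$soil[rows, , drop = FALSE]
  out$y <- features$y[rows]
  out$meta <- features$meta[rows, , drop = FALSE]
  out
}
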