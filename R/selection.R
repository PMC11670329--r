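#' Enumerate the distinct trial environments
#'
#' One environment per distinct (location, year) pair with observed weather.
#' All records of an environment must share one weather block; conflicting
#' weather raises an error.
#'
#' @param records Trial records `data.frame`.
#' @return `data.frame` with `location_id`, `year`, `state` and `row` (the
#'   index of the environment's first record, whose weather columns define
#'   the environment's weather block).
#' @export
enumerate_environments <- function(records) {
  abort_if(nrow(records) == 0L, "records must be non-empty")
  key <- paste(records$location_id, records$year, sep = "::")
  first <- !duplicated(key)
  wcols <- weather_col_names()
  wmat <- as.matrix(records[, wcols])
  # verify shared weather within each environment against its first record
  ref <- match(key, key[first])
  diff <- abs(wmat - wmat[which(first)[ref], , drop = FALSE])
  bad <- which(rowSums(diff) > 1e-8)
  abort_if(length(bad) > 0L,
           "conflicting weather within environment(s): ",
           paste(unique(key[bad]), collapse = ", "))
  data.frame(location_id = records$location_id[first],
             year = records$year[first],
             state = records$state[first],
             row = which(first),
             stringsAsFactors = FALSE)
}

#' Predict yields for every registered genotype in one environment
#'
#' Holds the environment's weather, location and year fixed and varies only
#' the genotype, producing one prediction per genotype in the candidate
#' pool.
#'
#' @param predictor A trained `gem_network`, `gem_ensemble` or
#'   [truth_predictor()].
#' @param env_record A single trial record (1-row `data.frame`) defining the
#'   environment (its genotype column is ignored).
#' @param genotypes Character vector of candidate genotype ids (defaults to
#'   the predictor's full registry).
#' @return Named numeric vector of predicted yields, one per genotype.
#' @export
predict_all_genotypes <- function(predictor, env_record, genotypes = NULL) {
  abort_if(nrow(env_record) != 1L, "env_record must be a single record row")
  if (is.null(genotypes)) {
    genotypes <- candidate_pool(predictor)
    abort_if(is.null(genotypes),
             "no genotype registry available; pass `genotypes`")
  }
  recs <- env_record[rep(1L, length(genotypes)), , drop = FALSE]
  recs$genotype_id <- genotypes
  rownames(recs) <- NULL
  setNames(predict_yield(predictor, recs), genotypes)
}

candidate_pool <- function(predictor) {
  if (inherits(predictor, "truth_predictor")) {
    names(predictor$truth$genotype_effects)
  } else if (!is.null(predictor$prep)) {
    predictor$prep$registry$genotype
  } else NULL
}

#' Select the top-k genotypes by predicted yield
#'
#' Ties are broken by genotype identifier order, so the selection is
#' deterministic and invariant to the enumeration order of the candidates.
#'
#' @param predictions Named numeric vector of per-genotype predictions.
#' @param k Number of genotypes to retain (1 <= k <= length(predictions)).
#' @return List with `genotypes` (character, length `k`) and `mean`
#'   (mean predicted yield of the selected genotypes).
#' @export
select_top_k <- function(predictions, k = 10L) {
  abort_if(k < 1L, "k must be >= 1")
  abort_if(k > length(predictions),
           "k = ", k, " exceeds the ", length(predictions), " candidates")
  ord <- order(-predictions, names(predictions))
  top <- ord[seq_len(k)]
  list(genotypes = names(predictions)[top], mean = mean(predictions[top]))
}

#' Selection gap report: predicted elite yield vs observed yield
#'
#' For every environment, predicts yields for the full candidate pool,
#' selects the top-k genotypes, and reports the gap between their mean
#' predicted yield and the mean observed yield of the genotypes actually
#' planted there. With `group_by = "state_year"` the per-environment gaps
#' are averaged over each state's environments within a year. Gaps are
#' signed: a negative gap (planted genotypes already better than the
#' selection) is reported, not clipped.
#'
#' @param predictor A trained `gem_network`, `gem_ensemble` or
#'   [truth_predictor()].
#' @param records Trial records with observed yields.
#' @param k Genotypes per selection (default 10).
#' @param group_by `"environment"` or `"state_year"`.
#' @param pool `"registry"` (all registered genotypes, default) or
#'   `"planted"` (only genotypes observed in `records`).
#' @return `data.frame` with columns `group`, `n_environments`,
#'   `top_k_genotypes` (`;`-joined, environment grouping only),
#'   `mean_pred_topk`, `mean_observed`, `gap`.
#' @export
selection_gap_report <- function(predictor, records, k = 10L,
                                 group_by = c("environment", "state_year"),
                                 pool = c("registry", "planted")) {
  group_by <- match.arg(group_by)
  pool <- match.arg(pool)
  abort_if(any(is.na(records$yield)), "records must carry observed yields")
  envs <- enumerate_environments(records)
  genotypes <- if (pool == "planted") {
    sort(unique(records$genotype_id))
  } else {
    candidate_pool(predictor) %||% sort(unique(records$genotype_id))
  }
  key <- paste(records$location_id, records$year, sep = "::")
  env_key <- paste(envs$location_id, envs$year, sep = "::")

  per_env <- lapply(seq_len(nrow(envs)), function(i) {
    pred <- predict_all_genotypes(predictor, records[envs$row[i], , drop = FALSE],
                                  genotypes)
    top <- select_top_k(pred, k)
    observed <- mean(records$yield[key == env_key[i]])
    data.frame(group = env_key[i], state = envs$state[i], year = envs$year[i],
               n_environments = 1L,
               top_k_genotypes = paste(top$genotypes, collapse = ";"),
               mean_pred_topk = top$mean, mean_observed = observed,
               gap = top$mean - observed, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_env)

  if (group_by == "state_year") {
    sy <- paste(out$state, out$year, sep = "::")
    agg <- lapply(unique(sy), function(g) {
      rows <- out[sy == g, , drop = FALSE]
      data.frame(group = g, n_environments = nrow(rows),
                 top_k_genotypes = NA_character_,
                 mean_pred_topk = mean(rows$mean_pred_topk),
                 mean_observed = mean(rows$mean_observed),
                 gap = mean(rows$gap), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, agg)
  } else {
    out$state <- NULL
    out$year <- NULL
  }
  out
}
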