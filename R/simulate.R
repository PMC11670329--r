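#' Configuration for the synthetic multi-environment trial generator
#'
#' Defines the generative model for synthetic soybean trials: additive
#' genotype, location and year effects, genotype-by-location (G-by-E)
#' interaction, weather responses localised to short windows of the growing
#' season, and Gaussian residual noise, around a global mean yield. The
#' defaults emulate a moderately unbalanced multi-environment trial (about
#' 45 observed location-year environments, roughly 3,000 records) with a
#' 50.66 bu/ac mean yield and effect scales in line with observed soybean
#' trial variability.
#'
#' @param n_locations Number of trial locations (>= 1).
#' @param n_years Number of trial years (>= 1); calendar years start at 2003.
#' @param n_genotypes Number of distinct genotypes (>= 1).
#' @param availability_fraction Probability that a (location, year) pair is
#'   observed, in (0, 1]. Values below 1 reproduce the unbalanced
#'   location-year availability typical of real trial networks.
#' @param genotypes_per_env Number of genotypes planted per observed
#'   environment (sampled without replacement).
#' @param effect_sds Named numeric vector with standard deviations (bu/ac)
#'   for components `genotype`, `location`, `year`, `interaction`,
#'   `residual`; all >= 0.
#' @param weather_windows List of weather response windows; each element is a
#'   list with `variable` (one of [weather_variables()]), `periods` (integer
#'   vector of 4-day period indices in 1..53) and `effect` (bu/ac per
#'   standardised unit of the window mean). The defaults place a solar
#'   radiation (MDNI) response around period 25 and a precipitation (AP)
#'   response around period 19, the windows where soybean yield is most
#'   weather-sensitive.
#' @param base_yield Global mean yield in bu/ac.
#' @param truncate_at_zero If `TRUE`, simulated yields are floored at 0.
#'   Default `FALSE` (Gaussian tails are left untouched).
#' @param seed Integer seed; all generator randomness derives from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_dataset()], [simulate_weather()]
#' @export
sim_config <- function(n_locations = 15L,
                       n_years = 5L,
                       n_genotypes = 100L,
                       availability_fraction = 0.6,
                       genotypes_per_env = 65L,
                       effect_sds = c(genotype = 5, location = 8, year = 3,
                                      interaction = 2, residual = 7),
                       weather_windows = list(
                         list(variable = "MDNI", periods = 24:26, effect = 3),
                         list(variable = "AP", periods = 18:20, effect = 2)),
                       base_yield = 50.66,
                       truncate_at_zero = FALSE,
                       seed = 1L) {
  abort_if(!is_count(n_locations) || !is_count(n_years) || !is_count(n_genotypes) ||
             !is_count(genotypes_per_env),
           "all counts must be integers >= 1")
  abort_if(!is.numeric(availability_fraction) || length(availability_fraction) != 1L ||
             availability_fraction <= 0 || availability_fraction > 1,
           "availability_fraction must lie in (0, 1]")
  needed <- c("genotype", "location", "year", "interaction", "residual")
  abort_if(!all(needed %in% names(effect_sds)),
           "effect_sds must name components: ", paste(needed, collapse = ", "))
  effect_sds <- effect_sds[needed]
  abort_if(any(!is.finite(effect_sds)) || any(effect_sds < 0),
           "effect_sds must be finite and >= 0")
  abort_if(genotypes_per_env > n_genotypes,
           "genotypes_per_env cannot exceed n_genotypes")
  for (w in weather_windows) {
    abort_if(!is.list(w) || !all(c("variable", "periods", "effect") %in% names(w)),
             "each weather window needs fields variable, periods, effect")
    abort_if(!w$variable %in% weather_variables(),
             "unknown weather variable in window: ", w$variable)
    abort_if(any(w$periods < 1L) || any(w$periods > N_PERIODS),
             "window periods must lie in [1, ", N_PERIODS, "]")
  }
  structure(list(
    n_locations = as.integer(n_locations),
    n_years = as.integer(n_years),
    n_genotypes = as.integer(n_genotypes),
    availability_fraction = availability_fraction,
    genotypes_per_env = as.integer(genotypes_per_env),
    effect_sds = effect_sds,
    weather_windows = weather_windows,
    base_yield = base_yield,
    truncate_at_zero = isTRUE(truncate_at_zero),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# per-variable seasonal baselines: mean level, seasonal amplitude,
# environment-level shift sd, daily noise sd. Units match weather_variables().
# Day-level variability dominates the environment-level shift, as in real
# growing-season weather where synoptic day-to-day swings are much larger
# than seasonal-mean anomalies between site-years; this keeps short-window
# aggregates identifiable rather than collinear across the season.
weather_baselines <- function() {
  data.frame(
    variable = weather_variables(),
    mean = c(450, 0.12, 65, 700, 24, 11, 17),
    amplitude = c(150, 0.04, 8, 200, 9, 8, 8.5),
    env_sd = c(18, 0.012, 1.8, 25, 0.9, 0.9, 0.9),
    noise_sd = c(110, 0.09, 9, 150, 5.5, 5.5, 4.5),
    nonnegative = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Simulate daily growing-season weather blocks
#'
#' Each of the 7 weather variables follows a smooth seasonal sinusoid peaking
#' mid-season, with a variable-specific mean and amplitude, an
#' environment-level random shift, and independent day-level noise. All
#' records sharing a (location, year) environment share one block.
#'
#' @param n_env Number of environments (>= 1).
#' @param seed Integer seed.
#' @param noise_scale Non-negative multiplier on both the environment-level
#'   shift and the daily noise; 0 gives the deterministic seasonal curves.
#'
#' @return Numeric array of dimension `c(n_env, 7, 214)` with dimnames
#'   `(env, variable, day)`.
#' @export
simulate_weather <- function(n_env, seed = 1L, noise_scale = 1) {
  abort_if(!is_count(n_env), "n_env must be an integer >= 1")
  abort_if(!is.numeric(noise_scale) || noise_scale < 0,
           "noise_scale must be >= 0")
  set.seed(as.integer(seed))
  base <- weather_baselines()
  days <- seq_len(N_DAYS)
  season <- sin(pi * days / (N_DAYS + 1))  # peaks mid-season
  out <- array(0, dim = c(n_env, 7L, N_DAYS),
               dimnames = list(NULL, base$variable, NULL))
  for (v in seq_len(7L)) {
    curve <- base$mean[v] + base$amplitude[v] * season
    shift <- rnorm(n_env, 0, base$env_sd[v] * noise_scale)
    noise <- matrix(rnorm(n_env * N_DAYS, 0, base$noise_sd[v] * noise_scale),
                    n_env, N_DAYS)
    block <- matrix(curve, n_env, N_DAYS, byrow = TRUE) + shift + noise
    if (base$nonnegative[v]) block <- pmax(block, 0)
    out[, v, ] <- block
  }
  out
}

# deal genotypes into environment slots so that every genotype is planted at
# least once: shuffled round-robin pass over all genotypes, then fill each
# environment's remaining slots without replacement
assign_genotypes <- function(n_env, per_env, n_genotypes) {
  abort_if(n_genotypes > n_env * per_env,
           "infeasible coverage: ", n_genotypes, " genotypes but only ",
           n_env * per_env, " planting slots")
  slots <- vector("list", n_env)
  dealt <- split(sample.int(n_genotypes),
                 rep_len(seq_len(n_env), n_genotypes))
  for (e in seq_len(n_env)) {
    got <- if (e <= length(dealt)) dealt[[e]] else integer(0)
    need <- per_env - length(got)
    pool <- setdiff(seq_len(n_genotypes), got)
    extra <- if (need > 0L) pool[sample.int(length(pool), need)] else integer(0)
    slots[[e]] <- sort(c(got, extra))
  }
  slots
}

#' Simulate a multi-environment trial dataset with known ground truth
#'
#' Draws genotype, location and year main effects, a genotype-by-location
#' interaction and per-window weather coefficients, samples the observed
#' (location, year) environments, plants `genotypes_per_env` genotypes in
#' each, and generates yields as
#' `base + g + l + t + interaction + sum(window effects) + residual`.
#' Window effects are linear in the standardised mean of the named weather
#' variable over the named 4-day periods (standardised across environments),
#' matching the granularity at which the preprocessing consumes weather.
#'
#' @param config A [sim_config()].
#'
#' @return A list with components `records` (a `data.frame`: one row per
#'   (genotype, location, year) observation with `year`, `location_id`,
#'   `state`, `genotype_id`, `maturity_group`, `yield` and 7 x 214 daily
#'   weather columns `VAR_d`) and `truth` (class `sim_truth`: the generating
#'   effects, window coefficients and standardisation, residual sd and seed).
#' @export
simulate_dataset <- function(config) {
  abort_if(!inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(config$seed)
  sds <- config$effect_sds

  n_loc <- config$n_locations
  n_yr <- config$n_years
  n_g <- config$n_genotypes
  loc_ids <- sprintf("L%03d", seq_len(n_loc))
  years <- 2003L + seq_len(n_yr) - 1L
  geno_ids <- sprintf("G%04d", seq_len(n_g))
  state_pool <- c("IA", "IL", "IN", "MN", "NE", "OH", "MO", "KS",
                  "ND", "SD", "WI", "MI", "AR", "MB", "ON", "LA")
  states <- state_pool[1L + (seq_len(n_loc) - 1L) %% length(state_pool)]

  # observed environments (unbalanced availability); keep at least one
  grid <- expand.grid(loc = seq_len(n_loc), yr = seq_len(n_yr))
  keep <- runif(nrow(grid)) <= config$availability_fraction
  if (!any(keep)) keep[1L] <- TRUE
  envs <- grid[keep, , drop = FALSE]
  n_env <- nrow(envs)

  g_eff <- rnorm(n_g, 0, sds[["genotype"]])
  l_eff <- rnorm(n_loc, 0, sds[["location"]])
  t_eff <- rnorm(n_yr, 0, sds[["year"]])
  gl_eff <- matrix(rnorm(n_g * n_loc, 0, sds[["interaction"]]), n_g, n_loc,
                   dimnames = list(geno_ids, loc_ids))

  weather <- simulate_weather(n_env, seed = derive_seed(config$seed, 1L))

  # window covariates: standardised mean of the 4-day aggregated variable
  # over the window periods, per environment
  win_z <- matrix(0, n_env, length(config$weather_windows))
  win_stats <- list()
  if (length(config$weather_windows) > 0L) {
    for (wi in seq_along(config$weather_windows)) {
      w <- config$weather_windows[[wi]]
      agg <- aggregate_weather(weather[, w$variable, , drop = TRUE])
      if (n_env == 1L) agg <- matrix(agg, nrow = 1L)
      x <- rowMeans(agg[, w$periods, drop = FALSE])
      mu <- mean(x)
      sdev <- sqrt(mean((x - mu)^2))
      win_z[, wi] <- if (sdev > 0) (x - mu) / sdev else 0
      win_stats[[wi]] <- list(variable = w$variable, periods = w$periods,
                              effect = w$effect, mean = mu, sd = sdev)
    }
  }

  planting <- assign_genotypes(n_env, config$genotypes_per_env, n_g)
  n_rec <- n_env * config$genotypes_per_env
  env_of_rec <- rep(seq_len(n_env), each = config$genotypes_per_env)
  g_of_rec <- unlist(planting)

  env_window <- if (length(win_stats) > 0L) {
    as.vector(win_z %*% vapply(config$weather_windows, `[[`, numeric(1), "effect"))
  } else rep(0, n_env)

  resid <- rnorm(n_rec, 0, sds[["residual"]])
  yld <- config$base_yield +
    g_eff[g_of_rec] +
    l_eff[envs$loc[env_of_rec]] +
    t_eff[envs$yr[env_of_rec]] +
    gl_eff[cbind(g_of_rec, envs$loc[env_of_rec])] +
    env_window[env_of_rec] +
    resid
  if (config$truncate_at_zero) yld <- pmax(yld, 0)

  # maturity group assigned per genotype (carried, unused by the models)
  mg <- paste0("MG", 1L + (seq_len(n_g) - 1L) %% 10L)

  wcols <- matrix(0, n_rec, 7L * N_DAYS)
  colnames(wcols) <- weather_col_names()
  for (v in seq_len(7L)) {
    cols <- (v - 1L) * N_DAYS + seq_len(N_DAYS)
    wcols[, cols] <- weather[env_of_rec, v, ]
  }

  records <- data.frame(
    year = years[envs$yr[env_of_rec]],
    location_id = loc_ids[envs$loc[env_of_rec]],
    state = states[envs$loc[env_of_rec]],
    genotype_id = geno_ids[g_of_rec],
    maturity_group = mg[g_of_rec],
    yield = yld,
    stringsAsFactors = FALSE
  )
  records <- cbind(records, as.data.frame(wcols))

  truth <- structure(list(
    seed = config$seed,
    base_yield = config$base_yield,
    genotype_effects = setNames(g_eff, geno_ids),
    location_effects = setNames(l_eff, loc_ids),
    year_effects = setNames(t_eff, as.character(years)),
    interaction_effects = gl_eff,
    window_coefficients = win_stats,
    residual_sd = sds[["residual"]],
    residuals = resid,
    environments = data.frame(location_id = loc_ids[envs$loc],
                              year = years[envs$yr],
                              stringsAsFactors = FALSE),
    config = config
  ), class = "sim_truth")

  list(records = records, truth = truth)
}

#' Write / read the canonical wide trial CSV
#'
#' Columns: `year, location_id, state, genotype_id, maturity_group, yield`,
#' then `VAR_d` daily weather columns for the 7 variables x 214 days.
#'
#' @param records Trial records `data.frame`.
#' @param path Output CSV path.
#' @return `write_trial_csv` returns `path` invisibly; `read_trial_csv`
#'   returns the records `data.frame`.
#' @export
write_trial_csv <- function(records, path) {
  data.table::fwrite(records, path)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  abort_if(!file.exists(path), "no such file: ", path)
  df <- as.data.frame(data.table::fread(path, stringsAsFactors = FALSE))
  key <- c("year", "location_id", "state", "genotype_id", "maturity_group")
  abort_if(!all(key %in% names(df)),
           "not a trial CSV; missing columns: ",
           paste(setdiff(key, names(df)), collapse = ", "))
  missing_w <- setdiff(weather_col_names(), names(df))
  abort_if(length(missing_w) > 0L,
           "trial CSV lacks ", length(missing_w), " weather columns (first: ",
           missing_w[1L], ")")
  df
}

#' Serialise / restore the synthetic ground truth
#'
#' The JSON file stores the generating seed, all effect vectors, the
#' interaction matrix, the window coefficients with their standardisation
#' statistics, and the residual sd, so recovery tests can reconstruct the
#' generative mean exactly.
#'
#' @param truth A `sim_truth` object from [simulate_dataset()].
#' @param path Output JSON path.
#' @return `write_truth_json` returns `path` invisibly; `read_truth_json`
#'   returns a `sim_truth` object (without the stored per-record residuals
#'   and config, which are session artefacts).
#' @export
write_truth_json <- function(truth, path) {
  abort_if(!inherits(truth, "sim_truth"), "truth must be a sim_truth")
  payload <- list(
    seed = truth$seed,
    base_yield = truth$base_yield,
    genotype_effects = as.list(truth$genotype_effects),
    location_effects = as.list(truth$location_effects),
    year_effects = as.list(truth$year_effects),
    interaction_effects = list(
      genotypes = rownames(truth$interaction_effects),
      locations = colnames(truth$interaction_effects),
      values = unname(truth$interaction_effects)
    ),
    window_coefficients = truth$window_coefficients,
    residual_sd = truth$residual_sd
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  inter <- matrix(unlist(p$interaction_effects$values),
                  nrow = length(p$interaction_effects$genotypes),
                  dimnames = list(p$interaction_effects$genotypes,
                                  p$interaction_effects$locations))
  wins <- p$window_coefficients
  if (is.data.frame(wins)) {
    wins <- lapply(seq_len(nrow(wins)), function(i)
      list(variable = wins$variable[i], periods = unlist(wins$periods[i]),
           effect = wins$effect[i], mean = wins$mean[i], sd = wins$sd[i]))
  }
  structure(list(
    seed = p$seed,
    base_yield = p$base_yield,
    genotype_effects = unlist(p$genotype_effects),
    location_effects = unlist(p$location_effects),
    year_effects = unlist(p$year_effects),
    interaction_effects = inter,
    window_coefficients = wins,
    residual_sd = p$residual_sd
  ), class = "sim_truth")
}

#' Descriptive yield summary of a trial dataset
#'
#' @param records Trial records `data.frame` with a `yield` column.
#' @return Named list: `n`, `mean`, `median`, `sd`, `min`, `max`, `q25`, `q75`.
#' @export
yield_summary <- function(records) {
  y <- records$yield
  abort_if(is.null(y) || all(is.na(y)), "records carry no yields")
  y <- y[!is.na(y)]
  list(n = length(y), mean = mean(y), median = stats::median(y),
       sd = stats::sd(y), min = min(y), max = max(y),
       q25 = unname(stats::quantile(y, 0.25)),
       q75 = unname(stats::quantile(y, 0.75)))
}
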