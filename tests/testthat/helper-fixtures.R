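# Shared fixtures. Everything is generated in code; the heavier trained-model
# fixture is memoised so several test files can reuse one training run.

small_config <- function(seed = 7, ...) {
  defaults <- list(n_locations = 5L, n_years = 3L, n_genotypes = 20L,
                   genotypes_per_env = 10L, availability_fraction = 0.8,
                   seed = seed)
  do.call(sim_config, modifyList(defaults, list(...)))
}

prepare_small <- function(seed = 7, split_seed = 3, ...) {
  sim <- simulate_dataset(small_config(seed = seed, ...))
  split <- split_by_combination(sim$records, seed = split_seed)
  registry <- build_category_registry(sim$records[split$train, , drop = FALSE])
  features <- build_features(sim$records, registry, split = split)
  list(sim = sim, split = split, registry = registry, features = features)
}

# desk-scale architecture/training settings used wherever a net must learn
desk_cnn_spec <- function() {
  architecture_spec("cnn", dense_other_units = 64L,
                    dense_combined_units = 64L,
                    dropout_rates = c(0.1, 0.1, 0.05))
}

desk_lstm_spec <- function() {
  architecture_spec("cnn_lstm", lstm_units = 32L, dense_other_units = 64L,
                    dense_combined_units = 64L,
                    dropout_rates = c(0.1, 0.1, 0.1, 0.05))
}

# study-conditions dataset for the recovery checks: ~3,000 records over ~90
# environments, genotype sd 5, one MDNI response window at periods 24-26,
# all other weather variables null
recovery_config <- function(seed = 101) {
  sim_config(n_locations = 25L, n_years = 6L, n_genotypes = 100L,
             genotypes_per_env = 33L, availability_fraction = 0.6,
             effect_sds = c(genotype = 5, location = 3, year = 2,
                            interaction = 1, residual = 1),
             weather_windows = list(
               list(variable = "MDNI", periods = 24:26, effect = 4)),
             seed = seed)
}

.fixture_cache <- new.env(parent = emptyenv())

trained_fixture <- function() {
  if (!is.null(.fixture_cache$trained)) return(.fixture_cache$trained)
  sim <- simulate_dataset(recovery_config())
  split <- split_by_combination(sim$records, seed = 5)
  registry <- build_category_registry(sim$records[split$train, , drop = FALSE])
  features <- build_features(sim$records, registry, split = split)

  cnn <- build_model(desk_cnn_spec(), n_other = ncol(features$onehot),
                     seed = 21)
  cnn <- train_network(cnn, features, split$train,
                       training_config(iterations = 1500L, seed = 21L))
  lstm <- build_model(desk_lstm_spec(), n_other = ncol(features$onehot),
                      seed = 22)
  lstm <- train_network(lstm, features, split$train,
                        training_config(iterations = 1200L, seed = 22L))

  val_preds <- cbind(cnn = predict(cnn, features, rows = split$validation),
                     cnn_lstm = predict(lstm, features, rows = split$validation))
  weights <- fit_gem(val_preds, features$y[split$validation])
  ensemble <- gem_ensemble(list(cnn = cnn, cnn_lstm = lstm), weights)

  .fixture_cache$trained <- list(sim = sim, split = split, features = features,
                                 cnn = cnn, lstm = lstm, weights = weights,
                                 val_preds = val_preds, ensemble = ensemble)
  .fixture_cache$trained
}

random_gem_instance <- function(k, n = 20L) {
  preds <- matrix(rnorm(n * k, 50, 10), n, k)
  y <- rnorm(n, 50, 10)
  list(predictions = preds, y = y)
}
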