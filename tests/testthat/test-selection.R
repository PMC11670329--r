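test_that("environment enumeration deduplicates and matches the generator", {
  prep <- prepare_small(seed = 7, availability_fraction = 1)
  envs <- enumerate_environments(prep$sim$records)
  cfg <- prep$sim$truth$config
  expect_equal(nrow(envs), cfg$n_locations * cfg$n_years)

  half <- prepare_small(seed = 8, availability_fraction = 0.5)
  envs2 <- enumerate_environments(half$sim$records)
  expect_equal(nrow(envs2), nrow(half$sim$truth$environments))
  expect_setequal(paste(envs2$location_id, envs2$year),
                  paste(half$sim$truth$environments$location_id,
                        half$sim$truth$environments$year))

  # conflicting weather within one environment is an error
  recs <- prep$sim$records
  dup <- which(paste(recs$location_id, recs$year) ==
                 paste(recs$location_id[1], recs$year[1]))
  expect_gt(length(dup), 1)
  recs[dup[2], "MDNI_10"] <- recs[dup[2], "MDNI_10"] + 99
  expect_error(enumerate_environments(recs), "conflicting weather")
})

test_that("per-environment genotype prediction is exhaustive and deterministic", {
  prep <- prepare_small(seed = 7)
  oracle <- truth_predictor(prep$sim$truth)
  env_rec <- prep$sim$records[1, , drop = FALSE]
  pred <- predict_all_genotypes(oracle, env_rec)
  expect_length(pred, prep$sim$truth$config$n_genotypes)
  expect_named(pred, names(prep$sim$truth$genotype_effects))
  expect_identical(pred, predict_all_genotypes(oracle, env_rec))
})

test_that("top-k selection is exact, tie-stable and monotone in k", {
  p <- c(A = 3, B = 1, C = 2)
  top <- select_top_k(p, 2)
  expect_setequal(top$genotypes, c("A", "C"))
  expect_equal(top$mean, 2.5)
  expect_equal(select_top_k(p, 1)$genotypes, "A")
  expect_equal(select_top_k(p, 3)$mean, mean(p))
  expect_error(select_top_k(p, 4), "exceeds")
  expect_error(select_top_k(p, 0), ">= 1")
  # invariant to candidate enumeration order
  expect_equal(select_top_k(p[c(2, 3, 1)], 2)$genotypes, top$genotypes)
  # ties broken by genotype id
  expect_equal(select_top_k(c(B = 1, A = 1, C = 1), 2)$genotypes, c("A", "B"))
  # top-k mean is non-increasing in k
  set.seed(6)
  preds <- setNames(rnorm(30), sprintf("G%02d", 1:30))
  means <- vapply(1:30, function(k) select_top_k(preds, k)$mean, numeric(1))
  expect_true(all(diff(means) <= 1e-12))
})

test_that("oracle selection on zero-residual truth reproduces the exact gap", {
  cfg <- sim_config(n_locations = 6, n_years = 3, n_genotypes = 40,
                    genotypes_per_env = 15, availability_fraction = 0.8,
                    effect_sds = c(genotype = 5, location = 3, year = 2,
                                   interaction = 1.5, residual = 0),
                    seed = 55)
  sim <- simulate_dataset(cfg)
  oracle <- truth_predictor(sim$truth)
  report <- selection_gap_report(oracle, sim$records, k = 10)
  envs <- enumerate_environments(sim$records)
  tr <- sim$truth
  key <- paste(sim$records$location_id, sim$records$year, sep = "::")
  for (i in seq_len(nrow(envs))) {
    ek <- paste(envs$location_id[i], envs$year[i], sep = "::")
    rows <- key == ek
    # truth-computed gap: oracle predictions for every genotype in this
    # environment (constant terms cancel into the comparison directly)
    base_rec <- sim$records[envs$row[i], , drop = FALSE]
    pred <- predict_all_genotypes(oracle, base_rec)
    expected_topk <- mean(sort(pred, decreasing = TRUE)[1:10])
    expected_gap <- expected_topk - mean(sim$records$yield[rows])
    got <- report[report$group == ek, ]
    expect_equal(got$gap, expected_gap, tolerance = 1e-6)
    expect_equal(got$mean_pred_topk, expected_topk, tolerance = 1e-9)
    # top-k mean never falls below the candidate-pool mean
    expect_gte(got$mean_pred_topk, mean(pred))
  }
})

test_that("selected genotypes overlap the true elite beyond chance", {
  cfg <- sim_config(n_locations = 6, n_years = 3, n_genotypes = 60,
                    genotypes_per_env = 20, availability_fraction = 0.8,
                    effect_sds = c(genotype = 5, location = 3, year = 2,
                                   interaction = 0.5, residual = 0),
                    seed = 77)
  sim <- simulate_dataset(cfg)
  oracle <- truth_predictor(sim$truth)
  env_rec <- sim$records[1, , drop = FALSE]
  selected <- select_top_k(predict_all_genotypes(oracle, env_rec), 10)$genotypes
  true_top <- names(sort(sim$truth$genotype_effects +
                           sim$truth$interaction_effects[, env_rec$location_id],
                         decreasing = TRUE))[1:10]
  overlap <- length(intersect(selected, true_top))
  # hypergeometric upper tail at the 1% level
  p_value <- 1 - phyper(overlap - 1, 10, cfg$n_genotypes - 10, 10)
  expect_lt(p_value, 0.01)
})

test_that("state-year grouping averages the per-environment gaps", {
  cfg <- sim_config(n_locations = 4, n_years = 2, n_genotypes = 20,
                    genotypes_per_env = 8, availability_fraction = 1,
                    effect_sds = c(genotype = 4, location = 2, year = 1,
                                   interaction = 0, residual = 0),
                    seed = 66)
  sim <- simulate_dataset(cfg)
  oracle <- truth_predictor(sim$truth)
  env_rep <- selection_gap_report(oracle, sim$records, k = 5,
                                  group_by = "environment")
  sy_rep <- selection_gap_report(oracle, sim$records, k = 5,
                                 group_by = "state_year")
  # locations here map 1:1 to states, so each state-year group holds exactly
  # one environment and the two groupings must agree
  expect_equal(nrow(sy_rep), nrow(env_rep))
  expect_equal(sort(sy_rep$gap), sort(env_rep$gap), tolerance = 1e-12)
  expect_true(all(sy_rep$n_environments == 1))
})

test_that("selection restricted to the planted pool uses only observed genotypes", {
  prep <- prepare_small(seed = 7)
  oracle <- truth_predictor(prep$sim$truth)
  rep_planted <- selection_gap_report(oracle, prep$sim$records, k = 3,
                                      pool = "planted")
  tops <- unlist(strsplit(rep_planted$top_k_genotypes, ";"))
  expect_true(all(tops %in% prep$sim$records$genotype_id))
})
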