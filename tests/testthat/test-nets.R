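test_that("learning-rate schedule matches its closed form", {
  expect_equal(lr_schedule(0), 4e-4)
  expect_equal(lr_schedule(2500), 4e-4 * 0.96)
  expect_equal(lr_schedule(2500), 0.000384)
  expect_equal(lr_schedule(5000), 4e-4 * 0.96^2)
})

test_that("architecture defaults follow the published configurations", {
  cnn <- architecture_spec("cnn")
  expect_equal(cnn$dense_other_units, 2048L)
  expect_equal(cnn$dense_combined_units, 3200L)
  expect_equal(cnn$dropout_rates, c(0.5, 0.7, 0.2))
  lstm <- architecture_spec("cnn_lstm")
  expect_equal(lstm$lstm_units, 128L)
  expect_equal(lstm$dense_other_units, 1596L)
  expect_equal(lstm$dense_combined_units, 1280L)
  expect_equal(lstm$dropout_rates, c(0.5, 0.5, 0.7, 0.2))
  soil <- architecture_spec("cnn", soil_branch = TRUE)
  expect_equal(soil$soil_branch$units, 512L)
  expect_equal(soil$soil_branch$dropout, 0.5)
})

test_that("built models expose the declared structure", {
  lstm <- build_model(architecture_spec("cnn_lstm"), n_other = 30, seed = 1)
  # recurrent layer present with 128 units
  expect_equal(ncol(lstm$params$lstm_Wh), 4L * 128L)
  expect_equal(nrow(lstm$params$lstm_Wh), 128L)
  # seven separate conv branches
  expect_length(grep("^b[1-7]_c1_W$", names(lstm$params)), 7L)
  soil <- build_model(architecture_spec("cnn", soil_branch = TRUE),
                      n_other = 30, n_soil = 66, seed = 1)
  expect_equal(dim(soil$params$soil_W), c(66L, 512L))
  expect_error(build_model(architecture_spec("cnn", soil_branch = TRUE),
                           n_other = 30), "n_soil")
  expect_error(build_model(architecture_spec(
    "cnn", conv_stack = list(list(filters = 4, kernel = 60, stride = 1))),
    n_other = 10), "shape mismatch in conv layer 1")
})

test_that("prediction is a deterministic row-wise map with scalar output", {
  prep <- prepare_small(seed = 7)
  f <- prep$features
  for (spec in list(desk_cnn_spec(), desk_lstm_spec())) {
    m <- build_model(spec, n_other = ncol(f$onehot), seed = 4)
    p5 <- predict(m, f, rows = 1:5)
    expect_length(p5, 5)
    expect_true(all(is.finite(p5)))
    expect_identical(p5, predict(m, f, rows = 1:5))
    # permuting rows permutes outputs identically
    perm <- c(3, 1, 5, 2, 4)
    expect_equal(predict(m, f, rows = perm), p5[perm], tolerance = 1e-12)
  }
})

test_that("an unseen genotype (all-zero block) still yields a finite prediction", {
  prep <- prepare_small(seed = 7)
  recs <- prep$sim$records[1, , drop = FALSE]
  recs$genotype_id <- "NOVEL"
  f <- build_features(recs, prep$registry, stats = prep$features$stats)
  expect_equal(sum(f$onehot[1, prep$features$groups$onehot$genotype]), 0)
  m <- build_model(desk_cnn_spec(), n_other = ncol(f$onehot), seed = 4)
  expect_true(is.finite(predict(m, f)))
})

test_that("backpropagated gradients match finite differences", {
  ns <- asNamespace("gemyield")
  prep <- prepare_small(seed = 7)
  f <- prep$features
  n <- 4L
  y <- f$y[seq_len(n)]
  for (variant in c("cnn", "cnn_lstm")) {
    spec <- architecture_spec(
      variant,
      conv_stack = list(list(filters = 3L, kernel = 5L, stride = 2L),
                        list(filters = 4L, kernel = 3L, stride = 2L)),
      lstm_units = 6L, dense_other_units = 5L, dense_combined_units = 7L,
      dropout_rates = rep(0, if (variant == "cnn") 3L else 4L))
    m <- build_model(spec, n_other = ncol(f$onehot), seed = 3)
    # jitter the zero-initialised biases: exact-zero ReLU pre-activations sit
    # on the kink, where subgradient and central difference legitimately differ
    set.seed(8)
    for (nm in grep("_b$", names(m$params), value = TRUE)) {
      m$params[[nm]] <- m$params[[nm]] + rnorm(length(m$params[[nm]]), 0, 0.05)
    }
    inputs <- ns$model_inputs(m, f, seq_len(n))
    lossfn <- function(model) {
      mean((ns$network_forward(model, inputs, train = FALSE)$pred - y)^2)
    }
    fw <- ns$network_forward(m, inputs, train = FALSE)
    grads <- ns$network_backward(m, fw$cache, 2 * (fw$pred - y) / n)
    eps <- 1e-5
    set.seed(9)
    for (nm in names(m$params)) {
      idx <- sample(length(m$params[[nm]]), min(3L, length(m$params[[nm]])))
      for (i in idx) {
        mp <- m; mp$params[[nm]][i] <- m$params[[nm]][i] + eps
        mm <- m; mm$params[[nm]][i] <- m$params[[nm]][i] - eps
        numeric_grad <- (lossfn(mp) - lossfn(mm)) / (2 * eps)
        expect_equal(grads[[nm]][i], numeric_grad, tolerance = 2e-3,
                     label = sprintf("%s grad of %s[%d]", variant, nm, i))
      }
    }
  }
})

test_that("zero training iterations return the initialised model unchanged", {
  prep <- prepare_small(seed = 7)
  f <- prep$features
  m <- build_model(desk_cnn_spec(), n_other = ncol(f$onehot), seed = 4)
  m0 <- train_network(m, f, prep$split$train,
                      training_config(iterations = 0L))
  expect_identical(m0$params, m$params)
})

test_that("training errors on missing yields", {
  prep <- prepare_small(seed = 7)
  f <- prep$features
  f$y[which(prep$split$train)[1]] <- NA_real_
  m <- build_model(desk_cnn_spec(), n_other = ncol(f$onehot), seed = 4)
  expect_error(train_network(m, f, prep$split$train,
                             training_config(iterations = 10L)),
               "finite yields")
})

test_that("short training beats the constant-mean predictor and lowers the loss", {
  fx <- trained_fixture()
  for (model in list(fx$cnn, fx$lstm)) {
    log <- model$log
    expect_lt(log$loss[nrow(log)], log$loss[1])
    tr_rows <- fx$split$train
    pred <- predict(model, fx$features, rows = tr_rows)
    y <- fx$features$y[tr_rows]
    expect_lt(rmse(y, pred), rmse(y, rep(mean(y), length(y))))
  }
})

test_that("trained genotype ranking correlates with the true genotype effects", {
  fx <- trained_fixture()
  env_row <- enumerate_environments(fx$sim$records)$row[1]
  pred <- predict_all_genotypes(fx$ensemble,
                                fx$sim$records[env_row, , drop = FALSE])
  truth <- fx$sim$truth$genotype_effects[names(pred)]
  expect_gt(cor(pred, truth, method = "spearman"), 0.6)
})

test_that("with dropout off the two variants consume identical encoded inputs", {
  prep <- prepare_small(seed = 7)
  f <- prep$features
  cnn <- build_model(architecture_spec("cnn", dense_other_units = 8L,
                                       dense_combined_units = 8L,
                                       dropout_rates = c(0, 0, 0)),
                     n_other = ncol(f$onehot), seed = 4)
  lstm <- build_model(architecture_spec("cnn_lstm", lstm_units = 8L,
                                        dense_other_units = 8L,
                                        dense_combined_units = 8L,
                                        dropout_rates = c(0, 0, 0, 0)),
                      n_other = ncol(f$onehot), seed = 4)
  p_cnn <- predict(cnn, f, rows = 1:6)
  p_lstm <- predict(lstm, f, rows = 1:6)
  # same rows, same encoding, both finite and deterministic; they differ
  # only through the architecture
  expect_true(all(is.finite(c(p_cnn, p_lstm))))
  expect_false(isTRUE(all.equal(p_cnn, p_lstm)))
  expect_identical(p_cnn, predict(cnn, f, rows = 1:6))
})
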