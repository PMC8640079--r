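# Clinical encoders, feature assembly and grid-searched training.

test_that("age encodes to three ordinal classes with left-closed bounds", {
  expect_equal(encode_age(65), -1L)
  expect_equal(encode_age(70), 0L)
  expect_equal(encode_age(79.9), 0L)
  expect_equal(encode_age(80), 1L)
  expect_equal(encode_age(85), 1L)
  expect_equal(encode_age(c(60, 75, 90)), c(-1L, 0L, 1L))
  expect_error(encode_age(-1), "non-negative")
  # custom thresholds
  expect_equal(encode_age(67, thresholds = c(65, 75)), 0L)
})

test_that("APOE encoding is identity by default and groups carriers", {
  expect_equal(encode_apoe(0:2), 0:2)
  expect_equal(encode_apoe(0:2, mode = "binarized"), c(0L, 1L, 1L))
  expect_error(encode_apoe(3), "0, 1 or 2")
})

test_that("feature table holds pair REO columns plus encoded clinical", {
  coh <- small_cohort(seed = 12, m = 40, planted = 5)
  ids <- rownames(coh$expression)
  pairs <- data.frame(mirna_i = ids[1:17], mirna_j = ids[21:37])
  sig <- signature_file(pairs)
  X <- assemble_feature_table(coh$expression, coh$meta, sig,
                              include_clinical = TRUE)
  expect_equal(ncol(X), 19)
  expect_equal(colnames(X)[18:19], c("age_class", "apoe_e4"))
  expect_equal(rownames(X), coh$meta$sample_id)
  expect_true(all(X[, 1:17] %in% c(-1, 0, 1)))
  expect_true(all(X[, "age_class"] %in% c(-1, 0, 1)))
  expect_true(all(X[, "apoe_e4"] %in% 0:2))
  X0 <- assemble_feature_table(coh$expression, coh$meta, sig,
                               include_clinical = FALSE)
  expect_equal(ncol(X0), 17)
  expect_equal(unname(X0), unname(X[, 1:17]))
})

test_that("the four canonical model configurations are reproducible", {
  cfgs <- lapply(1:4, dlb_model_config)
  expect_equal(vapply(cfgs, `[[`, "", "family"),
               c("svm", "logistic", "svm", "logistic"))
  expect_equal(vapply(cfgs, `[[`, "", "feature_set"),
               c("pairs", "pairs", "signature", "signature"))
  expect_equal(cfgs[[1]]$grid$cost, c(0.0002, 0.002, 0.2, 2, 20, 200))
  expect_equal(cfgs[[1]]$grid$gamma, cfgs[[1]]$grid$cost)
  expect_setequal(cfgs[[1]]$grid$kernel, c("rbf", "linear"))
  expect_equal(cfgs[[2]]$grid$C, c(0.0001, 0.001, 0.01, 0.1))
  expect_equal(cfgs[[3]]$cv_folds, 3L)
  expect_error(model_config("svm", grid = list(cost = numeric(0),
                                               gamma = 1, kernel = "rbf")),
               "non-empty")
})

test_that("grid search scores every point by honest CV accuracy", {
  d <- separable_toy(n = 24, seed = 8)
  cfg <- model_config("logistic", "pairs",
                      grid = list(C = c(0.0001, 0.001, 0.01, 0.1)))
  model <- grid_search_train(d$X, d$y, cfg)
  expect_true(model$hyperparameters$C %in% cfg$grid$C)
  expect_equal(length(model$cv_accuracy), 4)
  expect_gte(max(model$cv_accuracy),
             model$cv_accuracy[[which.max(model$cv_accuracy)]])
  # independent recomputation of each grid point's CV accuracy
  y <- factor(d$y, levels = c("control", "case"))
  fold_id <- reosig:::stratified_folds(y, 3, cfg$seed)
  for (gi in seq_along(cfg$grid$C)) {
    accs <- vapply(1:3, function(f) {
      tr <- fold_id != f
      fit <- glmnet::glmnet(d$X[tr, ], y[tr], family = "binomial",
                            alpha = 0,
                            lambda = 1 / (sum(tr) * cfg$grid$C[gi]),
                            standardize = FALSE, maxit = 1e5)
      p <- drop(predict(fit, d$X[!tr, ], type = "response"))
      mean(ifelse(p >= 0.5, "case", "control") == y[!tr])
    }, numeric(1))
    expect_equal(model$cv_accuracy[gi], mean(accs))
  }
  # single-point grid degenerates to a plain fit
  one <- grid_search_train(d$X, d$y,
                           model_config("logistic", grid = list(C = 0.1)))
  expect_equal(one$hyperparameters$C, 0.1)
})

test_that("training is deterministic and prediction is row-equivariant", {
  d <- separable_toy(n = 25, seed = 4)
  cfg <- model_config("svm", "pairs",
                      grid = list(cost = c(0.2, 2), gamma = 0.002,
                                  kernel = c("rbf", "linear")))
  m1 <- grid_search_train(d$X, d$y, cfg)
  m2 <- grid_search_train(d$X, d$y, cfg)
  expect_identical(m1$hyperparameters, m2$hyperparameters)
  expect_identical(predict_score(m1, d$X), predict_score(m2, d$X))
  # separable toy: training accuracy 1
  expect_equal(mean(predict(m1, d$X) == d$y), 1.0)
  # scores and labels are consistent at the 0.5 threshold
  s <- predict_score(m1, d$X)
  expect_true(all(s[predict(m1, d$X) == "case"] >= 0.5))
  expect_true(all(s >= 0 & s <= 1))
  # permuting rows permutes outputs identically
  perm <- rev(seq_len(nrow(d$X)))
  expect_equal(predict_score(m1, d$X[perm, ]), s[perm])
  # column mismatch errors list the differing names
  bad <- d$X
  colnames(bad)[1] <- "renamed"
  expect_error(predict(m1, bad), "signal")
  expect_error(predict(m1, bad), "renamed")
})

test_that("clinical covariates lift signature models over pairs-only", {
  # planted-pair signal is weak; age and APOE carry strong class signal
  acc <- vapply(1:5, function(seed) {
    coh <- simulate_cohort(synthetic_spec(n_case = 60, n_control = 60,
                                          m_mirnas = 20, planted_pairs = 3,
                                          fidelity = 0.65,
                                          age_case_shift = 10,
                                          apoe_p_case = 0.5,
                                          apoe_p_control = 0.05,
                                          seed = seed))
    sig <- signature_file(coh$truth$pairs[, c("mirna_i", "mirna_j")])
    cfg <- model_config("logistic", grid = list(C = 0.1))
    Xp <- assemble_feature_table(coh$expression, coh$meta, sig, FALSE)
    Xs <- assemble_feature_table(coh$expression, coh$meta, sig, TRUE)
    c(pairs = max(grid_search_train(Xp, coh$meta$label, cfg)$cv_accuracy),
      sig = max(grid_search_train(Xs, coh$meta$label, cfg)$cv_accuracy))
  }, numeric(2))
  expect_gt(mean(acc["sig", ]), mean(acc["pairs", ]))
})
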