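# hand-built linear model with identity scaling: decision value equals the
# raw feature, confidence equals plogis(feature)
identity_model <- function() {
  structure(list(
    kernel = "linear", C = 1, gamma = NULL,
    support_vectors = matrix(1), dual_coefs = 1, bias = 0,
    feature_names = "x",
    scaling = tibble::tibble(feature = "x", min = 0, max = 1),
    calibration = list(slope = 1), weights = 1
  ), class = "ts_svm")
}

test_that("a separable toy set is classified perfectly at large C", {
  m <- make_separable_matrix(seed = 51)
  model <- train_svm(m, kernel = "linear", C = 100)
  conf <- predict_confidence(model, m)
  expect_equal(ifelse(conf > 0.5, "ts", "non-ts"), m$class)
})

test_that("XOR separates under the RBF kernel but not the linear one", {
  m <- make_xor_matrix(seed = 52)
  lin <- train_svm(m, kernel = "linear", C = 100)
  lin_acc <- mean((decision_value(lin, m) > 0) == (m$class == "ts"))
  expect_lte(lin_acc, 0.75)
  rbf <- train_svm(m, kernel = "rbf", C = 100, gamma = 1)
  rbf_acc <- mean((decision_value(rbf, m) > 0) == (m$class == "ts"))
  expect_equal(rbf_acc, 1)
})

test_that("duplicating the training set leaves the decision function intact", {
  m <- make_separable_matrix(seed = 53)
  dup <- dplyr::bind_rows(m, dplyr::mutate(m, sample_id = paste0(sample_id, "b")))
  m1 <- train_svm(m, kernel = "linear", C = 100)
  m2 <- train_svm(dup, kernel = "linear", C = 100)
  expect_equal(decision_value(m2, m), decision_value(m1, m),
               tolerance = 1e-6)
})

test_that("decision values equal the explicit kernel sum and libSVM's own", {
  for (kernel in c("linear", "rbf")) {
    m <- make_separable_matrix(seed = 54)
    model <- train_svm(m, kernel = kernel, C = 2, gamma = 0.5)
    dv <- decision_value(model, m)
    expect_equal(dv, brute_decision(model, m), tolerance = 1e-12)
    # independent cross-check against the fitting library's decision values
    feats <- as.matrix(m[model$feature_names])
    rng <- model$scaling$max - model$scaling$min
    xs <- sweep(sweep(feats, 2, model$scaling$min), 2, rng, "/")
    refit <- e1071::svm(x = xs, y = factor(m$class, c("non-ts", "ts")),
                        scale = FALSE, cost = 2, gamma = 0.5,
                        kernel = if (kernel == "linear") "linear" else "radial")
    ref_dv <- as.numeric(attr(predict(refit, xs, decision.values = TRUE),
                              "decision.values"))
    sign_ref <- if (refit$levels[refit$labels[1]] == "ts") 1 else -1
    expect_equal(dv, sign_ref * ref_dv, tolerance = 1e-8)
  }
})

test_that("linear dual and primal forms agree to 1e-9 relative", {
  withr::with_seed(55, {
    for (i in 1:5) {
      m <- make_separable_matrix(n_per_class = 15, seed = 55 + i)
      model <- train_svm(m, kernel = "linear", C = runif(1, 0.5, 20))
      x <- matrix(rnorm(8 * 3), ncol = 3)
      colnames(x) <- model$feature_names
      dual <- decision_value(model, x)
      rng <- model$scaling$max - model$scaling$min
      rng[rng == 0] <- 1
      xs <- sweep(sweep(x, 2, model$scaling$min), 2, rng, "/")
      primal <- as.numeric(xs %*% model$weights + model$bias)
      expect_equal(dual, primal, tolerance = 1e-9)
    }
  })
})

test_that("an RBF model scores its own support vector as dual_coef + bias", {
  model <- structure(list(
    kernel = "rbf", C = 1, gamma = 0.7,
    support_vectors = matrix(c(0.2, 0.8), nrow = 1), dual_coefs = 1.4,
    bias = -0.3, feature_names = c("x1", "x2"),
    scaling = tibble::tibble(feature = c("x1", "x2"), min = 0, max = 1),
    calibration = list(slope = 1)
  ), class = "ts_svm")
  got <- decision_value(model, tibble::tibble(x1 = 0.2, x2 = 0.8))
  expect_equal(got, 1.4 + (-0.3))
})

test_that("confidence is a strictly monotone sigmoid of the margin", {
  model <- identity_model()
  expect_equal(predict_confidence(model, tibble::tibble(x = 0)), 0.5)
  margins <- tibble::tibble(x = seq(-3, 3, by = 0.5))
  conf <- predict_confidence(model, margins)
  expect_true(all(diff(conf) > 0))
  # trained model: label flips exactly at confidence 0.5
  m <- make_separable_matrix(seed = 56)
  fitted <- train_svm(m, kernel = "rbf", C = 4)
  dv <- decision_value(fitted, m)
  expect_equal(predict_confidence(fitted, m) > 0.5, dv > 0)
})

test_that("calibration on a balanced set centres the mean confidence", {
  withr::with_seed(57, {
    m <- tibble::tibble(
      sample_id = sprintf("s%03d", 1:100),
      f1 = c(rnorm(50, 1), rnorm(50, -1)),
      f2 = rnorm(100),
      class = rep(c("ts", "non-ts"), each = 50)
    )
  })
  model <- train_svm(m, kernel = "rbf", C = 1)
  expect_gt(mean(predict_confidence(model, m)), 0.4)
  expect_lt(mean(predict_confidence(model, m)), 0.6)
})

test_that("ranking is by descending confidence with id tie-breaks", {
  model <- identity_model()
  cand <- tibble::tibble(
    sample_id = c("P1-A1_GLY_Scer", "P1-A1_TRP_Scer", "P1-A1_CYS_Scer",
                  "P1-A1_ASP_Scer", "P1-A1_THR_Scer"),
    x = c(2, 1, 0.5, 0.5, -1)
  )
  preds <- rank_predictions(model, cand)
  expect_equal(preds$rank, 1:5)
  expect_true(all(diff(preds$confidence) <= 0))
  # the two tied confidences fall in lexicographic id order
  expect_equal(preds$mutation_id[3:4],
               c("P1-A1_ASP_Scer", "P1-A1_CYS_Scer"))
  expect_equal(nrow(top_k(preds, 3)), 3)
  expect_equal(nrow(rank_predictions(model,
                                     tibble::tibble(sample_id = character(),
                                                    x = numeric()))), 0)
})

test_that("prediction files match the golden ranked-list format exactly", {
  model <- identity_model()
  cand <- tibble::tibble(
    sample_id = c("YBR109C-F140_GLY_Scer", "YBR109C-F140_ASP_Scer",
                  "YBR109C-F140_CYS_Scer", "YBR109C-F140_PRO_Scer",
                  "YBR109C-F140_THR_Scer"),
    x = c(1.650, 1.593, 1.284, 1.243, 1.203)
  )
  preds <- rank_predictions(model, cand)
  f <- withr::local_tempfile(fileext = ".txt")
  write_predictions(preds, f)
  expect_identical(readLines(f), readLines(test_path("golden-predictions.txt")))
})

test_that("svm_seq_view keeps only sequence-derived features", {
  m <- generate_training_set(n_ts = 3, n_nonts = 4, seed = 58)
  seqm <- svm_seq_view(m)
  expect_lte(length(feature_names(seqm)), 9)
  expect_length(intersect(feature_names(seqm),
                          as.vector(outer(rosetta_score_terms(),
                                          paste0("Q", 1:3), paste0))), 0)
  expect_false(any(c("ACCP", "ss_H", "ss_S", "ss_L") %in%
                     feature_names(seqm)))
  expect_identical(svm_seq_view(seqm), seqm)
  expect_error(svm_seq_view(m[c("sample_id", "omegaQ1", "class")]),
               class = "tsmut_empty_error")
})

test_that("feature weights reconstruct from the dual form and rank planted signal", {
  m <- make_separable_matrix(seed = 59)
  model <- train_svm(m, kernel = "linear", C = 10)
  fw <- feature_weights(model)
  expect_equal(fw$feature[1], "signal")
  expect_equal(fw$weight[order(match(fw$feature, model$feature_names))],
               as.numeric(crossprod(model$support_vectors, model$dual_coefs)),
               tolerance = 1e-12)
  expect_equal(fw$weight, fw$weight[order(-abs(fw$weight))])
  rbf <- train_svm(m, kernel = "rbf", C = 10)
  expect_error(feature_weights(rbf), class = "tsmut_unsupported_error")
})

test_that("persisted models reload with identical decision values", {
  for (kernel in c("linear", "rbf")) {
    m <- make_separable_matrix(seed = 60)
    model <- train_svm(m, kernel = kernel, C = 3)
    f <- withr::local_tempfile(fileext = ".json")
    write_ts_svm(model, f)
    back <- read_ts_svm(f)
    expect_identical(decision_value(back, m), decision_value(model, m))
    expect_identical(predict_confidence(back, m),
                     predict_confidence(model, m))
  }
})

test_that("degenerate training inputs raise typed errors", {
  m <- make_separable_matrix(seed = 61)
  single <- dplyr::mutate(m, class = "ts")
  expect_error(train_svm(single), class = "tsmut_training_error")
  bad <- m
  bad$signal[1] <- NA
  expect_error(train_svm(bad), class = "tsmut_integrity_error")
  bad$signal[1] <- Inf
  expect_error(train_svm(bad), class = "tsmut_input_error")
  expect_error(train_svm(m, C = -1), class = "tsmut_input_error")
})
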