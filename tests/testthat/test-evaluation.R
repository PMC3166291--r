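test_that("k-fold splits are disjoint, covering, balanced and stratified", {
  ids <- sprintf("s%03d", 1:205)
  labels <- rep(c("ts", "non-ts"), c(75, 130))
  folds <- kfold_splits(ids, 10, seed = 1, labels = labels)
  expect_length(folds, 10)
  expect_setequal(unlist(folds), ids)
  expect_equal(sum(lengths(folds)), 205)  # disjoint + covering
  expect_true(all(lengths(folds) %in% c(20, 21)))
  ts_per_fold <- vapply(folds, function(f) sum(labels[match(f, ids)] == "ts"),
                        numeric(1))
  expect_true(all(abs(ts_per_fold - 7.5) <= 1))
  expect_identical(kfold_splits(ids, 10, seed = 1, labels = labels), folds)
  expect_false(identical(kfold_splits(ids, 10, seed = 2, labels = labels),
                         folds))
  loo <- kfold_splits(ids[1:8], 8, seed = 3)
  expect_true(all(lengths(loo) == 1))
  expect_error(kfold_splits(ids[1:5], 10), class = "tsmut_input_error")
})

test_that("metric identities hold on the worked example", {
  truth <- c(1, 1, 0, 0)
  conf <- c(0.9, 0.8, 0.2, 0.1)
  expect_equal(auroc(truth, conf), 1)
  expect_equal(point_biserial(truth, conf), 0.98994949366, tolerance = 1e-9)
  expect_equal(point_biserial(truth, conf), cor(conf, truth),
               tolerance = 1e-12)
  expect_equal(point_biserial(truth, rep(0.5, 4)), 0)
  expect_equal(auroc(truth, 1 - conf), 0)
  expect_error(auroc(c(1, 1), c(0.1, 0.2)), class = "tsmut_metric_error")
  expect_equal(ts_precision(truth, conf), 1)
  expect_equal(confusion_counts(truth, conf),
               tibble::tibble(tp = 2L, fp = 0L, tn = 2L, fn = 0L))
})

test_that("AUROC equals the tie-aware Mann-Whitney statistic", {
  withr::with_seed(71, {
    for (i in 1:50) {
      n <- sample(8:30, 1)
      truth <- c(TRUE, FALSE, runif(n - 2) > 0.5)
      conf <- sample(round(runif(n), 1))  # coarse grid forces ties
      expect_equal(auroc(truth, conf), brute_auroc(truth, conf),
                   tolerance = 1e-12)
      expect_equal(point_biserial(truth, conf),
                   cor(conf, as.numeric(truth)), tolerance = 1e-12)
    }
  })
})

test_that("PR curve starts at the top-ranked sample and AUPR is sane", {
  truth <- c(1, 0, 1, 0)
  conf <- c(0.9, 0.8, 0.7, 0.1)
  pts <- pr_points(truth, conf)
  expect_equal(pts$precision[1], 1)
  expect_equal(pts$recall[nrow(pts)], 1)
  expect_equal(aupr(truth, c(0.9, 0.8, 0.85, 0.1)), 1)  # perfect ranking
  roc <- roc_points(truth, conf)
  expect_equal(roc$fpr[1], 0)
  expect_equal(unlist(roc[nrow(roc), ]), c(fpr = 1, tpr = 1))
})

test_that("repeated CV is deterministic and perfect on separable data", {
  m <- make_separable_matrix(n_per_class = 15, seed = 72)
  rep1 <- repeated_cv(m, kernel = "linear", C = 100, k = 5, reps = 3,
                      seed = 7)
  expect_true(all(rep1$per_rep$precision == 1))
  expect_true(all(rep1$aggregate$var >= 0))
  rep2 <- repeated_cv(m, kernel = "linear", C = 100, k = 5, reps = 3,
                      seed = 7)
  expect_identical(rep1$predictions, rep2$predictions)
  expect_equal(nrow(rep1$per_split), 3 * 5)
})

test_that("label-shuffled data scores near-chance AUROC", {
  withr::with_seed(73, {
    m <- tibble::tibble(sample_id = sprintf("s%03d", 1:200),
                        f1 = rnorm(200), f2 = rnorm(200), f3 = rnorm(200),
                        class = sample(rep(c("ts", "non-ts"), each = 100)))
  })
  rep <- repeated_cv(m, kernel = "rbf", C = 1, k = 5, reps = 2, seed = 74)
  pooled <- auroc(rep$predictions$truth, rep$predictions$confidence)
  expect_gt(pooled, 0.4)
  expect_lt(pooled, 0.6)
})

test_that("grid search covers the lattice deterministically with tie rules", {
  m <- make_separable_matrix(n_per_class = 12, seed = 75)
  g1 <- grid_search(m, kernel = "rbf", C_grid = c(1, 4), gamma_grid = c(0.1, 1),
                    k = 4, reps = 1, seed = 9)
  expect_equal(nrow(g1), 4)  # |C grid| x |gamma grid|
  g2 <- grid_search(m, kernel = "rbf", C_grid = c(1, 4), gamma_grid = c(0.1, 1),
                    k = 4, reps = 1, seed = 9)
  expect_identical(tibble::as_tibble(g1), tibble::as_tibble(g2))
  # separable data: a plateau of perfect precision, broken toward smaller C
  best <- grid_best(g1)
  top <- max(g1$precision, na.rm = TRUE)
  plateau <- g1[!is.na(g1$precision) & g1$precision == top, ]
  expect_gte(nrow(plateau), 2)
  expect_equal(best$C, min(plateau$C))
  expect_equal(best$gamma,
               min(plateau$gamma[plateau$C == min(plateau$C)]))
  lin <- grid_search(m, kernel = "linear", C_grid = c(0.5, 2), k = 4,
                     reps = 1, seed = 9)
  expect_equal(nrow(lin), 2)
  expect_error(grid_search(m, C_grid = numeric(0)),
               class = "tsmut_input_error")
})

test_that("leave-out CV partitions samples, never leaks, and pools metrics", {
  m <- make_separable_matrix(n_per_class = 20, seed = 76)
  report <- leaveout_cv(m, kernel = "rbf", C_grid = c(1, 10),
                        gamma_grid = c(0.1, 1), n_splits = 5, k = 4,
                        grid_reps = 1, seed = 11)
  # the five held-out sets are disjoint and cover the sample set
  expect_setequal(report$predictions$sample_id, m$sample_id)
  expect_equal(nrow(report$predictions), nrow(m))
  expect_equal(nrow(report$per_split), 5)
  expect_true(all(report$per_split$tp + report$per_split$fp +
                    report$per_split$tn + report$per_split$fn == 8))
  # planted signal: pooled precision beats the class prior
  expect_gt(report$aggregate$precision, 0.5)
  # median hyperparameters come from the per-split selections (log space)
  expect_equal(report$final_params$C, 2^median(log2(report$per_split$C)))
  expect_equal(report$final_params$gamma,
               2^median(log2(report$per_split$gamma)))
  # a one-point grid forces the median to that point
  one <- leaveout_cv(m, kernel = "rbf", C_grid = 4, gamma_grid = 0.5,
                     n_splits = 5, k = 4, grid_reps = 1, seed = 11)
  expect_equal(one$final_params$C, 4)
  expect_equal(one$final_params$gamma, 0.5)
})

test_that("cv reports expose tidy/glance summaries", {
  m <- make_separable_matrix(n_per_class = 12, seed = 77)
  rep <- repeated_cv(m, kernel = "linear", C = 10, k = 4, reps = 2, seed = 3)
  expect_identical(tidy(rep), rep$per_split)
  g <- glance(rep)
  expect_equal(g$scheme, "10x10fold")
  expect_true(all(c("mean_precision", "mean_auroc") %in% names(g)))
  lo <- leaveout_cv(m, kernel = "linear", C_grid = c(1, 10), n_splits = 4,
                    k = 3, grid_reps = 1, seed = 3)
  gl <- glance(lo)
  expect_true(all(c("precision", "auroc", "final_C") %in% names(gl)))
})
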