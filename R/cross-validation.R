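# run code under a fixed RNG seed, restoring the caller's RNG state
with_rng_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Disjoint cross-validation folds
#'
#' Splits sample ids into k folds whose sizes differ by at most one and
#' whose union is the full set. When labels are supplied the folds are
#' stratified: samples are shuffled within class and dealt round-robin, so
#' every fold carries a near-proportional share of each class. Deterministic
#' given the seed.
#'
#' @param sample_ids Character vector of sample ids.
#' @param k Number of folds; must not exceed the number of samples.
#' @param seed Integer seed.
#' @param labels Optional class labels (same length as `sample_ids`) for
#'   stratification.
#' @return List of k character vectors.
#' @export
kfold_splits <- function(sample_ids, k, seed = 1, labels = NULL) {
  n <- length(sample_ids)
  if (k > n) {
    abort(paste0("k = ", k, " exceeds the number of samples (", n, ")"),
          class = "tsmut_input_error")
  }
  if (k < 2) abort("k must be at least 2", class = "tsmut_input_error")
  with_rng_seed(seed, {
    if (is.null(labels)) {
      ord <- sample(sample_ids)
    } else {
      ord <- unlist(lapply(split(sample_ids, labels), sample),
                    use.names = FALSE)
    }
    fold <- rep_len(seq_len(k), n)
    unname(split(ord, fold))
  })
}

new_cv_report <- function(scheme, per_split, predictions, aggregate,
                          seeds, per_rep = NULL, final_params = NULL) {
  structure(list(scheme = scheme, per_split = per_split,
                 per_rep = per_rep, predictions = predictions,
                 aggregate = aggregate, final_params = final_params,
                 seeds = seeds),
            class = "ts_cv_report")
}

#' @export
print.ts_cv_report <- function(x, ...) {
  cat("<ts_cv_report> scheme: ", x$scheme, "\n", sep = "")
  print(x$aggregate)
  if (!is.null(x$final_params)) {
    cat("final (median) hyperparameters:\n")
    print(x$final_params)
  }
  invisible(x)
}

pooled_metrics <- function(truth, confidence) {
  tibble::tibble(
    precision = suppressWarnings(ts_precision(truth, confidence)),
    point_biserial = point_biserial(truth, confidence),
    auroc = auroc(truth, confidence),
    aupr = aupr(truth, confidence)
  )
}

cv_one_pass <- function(data, kernel, C, gamma, k, seed) {
  folds <- kfold_splits(data$sample_id, k, seed, labels = data$class)
  res <- purrr::imap(folds, function(held, f) {
    test <- data[data$sample_id %in% held, , drop = FALSE]
    train <- data[!data$sample_id %in% held, , drop = FALSE]
    model <- tryCatch(
      train_svm(train, kernel = kernel, C = C, gamma = gamma),
      error = function(e) {
        abort(paste0("training failed on fold ", f, ": ",
                     conditionMessage(e)),
              class = "tsmut_training_error")
      })
    conf <- predict_confidence(model, test)
    list(
      split = dplyr::bind_cols(
        tibble::tibble(fold = as.integer(f), C = C,
                       gamma = gamma %||% NA_real_),
        confusion_counts(test$class, conf)),
      pred = tibble::tibble(sample_id = test$sample_id, truth = test$class,
                            confidence = conf)
    )
  })
  list(per_fold = dplyr::bind_rows(purrr::map(res, "split")),
       predictions = dplyr::bind_rows(purrr::map(res, "pred")))
}

#' Repeated stratified k-fold cross-validation
#'
#' Runs k-fold CV `reps` times with different fold seeds (seed, seed + 1,
#' ...), pooling the held-out confidences within each repetition to compute
#' per-repetition metrics, and reporting their mean and variance across
#' repetitions. The default 10 x 10-fold scheme gives robust aggregate
#' estimates on small sample sets.
#'
#' @param data Labelled feature matrix tibble.
#' @param kernel,C,gamma SVM configuration (see [train_svm()]).
#' @param k Folds per repetition; default 10.
#' @param reps Repetitions; default 10.
#' @param seed Base seed for fold assignment.
#' @return A `ts_cv_report` (scheme `"10x10fold"`).
#' @export
repeated_cv <- function(data, kernel = "rbf", C = 1, gamma = NULL,
                        k = 10, reps = 10, seed = 1) {
  validate_feature_matrix(data)
  if (!"class" %in% names(data)) {
    abort("labelled data required", class = "tsmut_input_error")
  }
  seeds <- seed + seq_len(reps) - 1L
  runs <- purrr::map(seq_len(reps), function(r) {
    pass <- cv_one_pass(data, kernel, C, gamma, k, seeds[r])
    list(
      per_fold = dplyr::mutate(pass$per_fold, rep = r, .before = 1),
      predictions = dplyr::mutate(pass$predictions, rep = r, .before = 1),
      metrics = dplyr::mutate(
        pooled_metrics(pass$predictions$truth, pass$predictions$confidence),
        rep = r, .before = 1)
    )
  })
  per_rep <- dplyr::bind_rows(purrr::map(runs, "metrics"))
  agg <- per_rep |>
    tidyr::pivot_longer(-"rep", names_to = "metric") |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     var = stats::var(.data$value),
                     .by = "metric")
  new_cv_report(
    scheme = "10x10fold",
    per_split = dplyr::bind_rows(purrr::map(runs, "per_fold")),
    predictions = dplyr::bind_rows(purrr::map(runs, "predictions")),
    aggregate = agg, seeds = seeds, per_rep = per_rep
  )
}

#' Hyperparameter grid search by repeated cross-validation
#'
#' Evaluates every point of a log-spaced C x gamma lattice with
#' [repeated_cv()] on the training matrix and scores each point by its mean
#' ts-class precision across repetitions. Ties are broken toward smaller C,
#' then smaller gamma (the least complex near-optimal model).
#'
#' @param data Labelled feature matrix tibble.
#' @param kernel `"linear"` or `"rbf"`.
#' @param C_grid Candidate complexity values; default 2^seq(-5, 15, 2).
#' @param gamma_grid Candidate RBF widths; default 2^seq(-15, 3, 2)
#'   (ignored for the linear kernel).
#' @param k,reps,seed Passed to [repeated_cv()]; `reps` defaults to 2 here
#'   to keep the lattice sweep affordable.
#' @return A `ts_grid`: tibble of `C`, `gamma`, `precision` with attribute
#'   `best` (one-row tibble of the selected point).
#' @export
grid_search <- function(data, kernel = "rbf",
                        C_grid = 2^seq(-5, 15, by = 2),
                        gamma_grid = 2^seq(-15, 3, by = 2),
                        k = 10, reps = 2, seed = 1) {
  if (!length(C_grid) || (kernel == "rbf" && !length(gamma_grid))) {
    abort("empty hyperparameter grid", class = "tsmut_input_error")
  }
  lattice <- if (kernel == "linear") {
    tidyr::crossing(C = sort(C_grid), gamma = NA_real_)
  } else {
    tidyr::crossing(C = sort(C_grid), gamma = sort(gamma_grid))
  }
  prec <- purrr::map2_dbl(lattice$C, lattice$gamma, function(C, g) {
    rep <- repeated_cv(data, kernel = kernel, C = C,
                       gamma = if (is.na(g)) NULL else g,
                       k = k, reps = reps, seed = seed)
    m <- rep$aggregate$mean[rep$aggregate$metric == "precision"]
    if (is.nan(m)) NA_real_ else m
  })
  surface <- dplyr::mutate(lattice, precision = prec)
  ranked <- surface |>
    dplyr::arrange(dplyr::desc(!is.na(.data$precision)),
                   dplyr::desc(.data$precision), .data$C, .data$gamma)
  structure(surface, best = ranked[1, ],
            class = c("ts_grid", class(surface)))
}

#' Selected point of a grid search
#' @param grid A `ts_grid` from [grid_search()].
#' @return One-row tibble `C`, `gamma`, `precision`.
#' @export
grid_best <- function(grid) attr(grid, "best")

#' Nested leave-out cross-validation with hyperparameter tuning
#'
#' The conservative evaluation scheme: the samples are split into five
#' disjoint stratified 20% leave-out sets. For each, a grid search (by
#' repeated CV) runs on the remaining 80% only, the best (C, gamma) is used
#' to retrain on the full 80%, and confidences are recorded on the untouched
#' 20%. Held-out confidences are pooled over the five splits for the
#' aggregate metrics, so no sample is ever scored by a model that saw it or
#' whose hyperparameters it influenced. The final hyperparameters are the
#' component-wise medians of the five selected points, taken in log2 space.
#'
#' @inheritParams grid_search
#' @param n_splits Number of leave-out splits; default 5.
#' @param grid_reps Repetitions of the inner repeated CV per lattice point.
#' @return A `ts_cv_report` (scheme `"5xleaveout"`) whose `final_params`
#'   holds the median hyperparameters and whose `per_split` records the
#'   chosen point and confusion counts per leave-out set.
#' @export
leaveout_cv <- function(data, kernel = "rbf",
                        C_grid = 2^seq(-5, 15, by = 2),
                        gamma_grid = 2^seq(-15, 3, by = 2),
                        n_splits = 5, k = 10, grid_reps = 2, seed = 1) {
  validate_feature_matrix(data)
  if (!"class" %in% names(data)) {
    abort("labelled data required", class = "tsmut_input_error")
  }
  splits <- kfold_splits(data$sample_id, n_splits, seed, labels = data$class)
  res <- purrr::imap(splits, function(held, s) {
    s <- as.integer(s)
    test <- data[data$sample_id %in% held, , drop = FALSE]
    train <- data[!data$sample_id %in% held, , drop = FALSE]
    if (length(unique(train$class)) < 2) {
      warn(paste0("leave-out split ", s,
                  " has a single class in training; skipped"))
      return(NULL)
    }
    grid <- grid_search(train, kernel = kernel, C_grid = C_grid,
                        gamma_grid = gamma_grid, k = k, reps = grid_reps,
                        seed = seed + 1000L * s)
    best <- grid_best(grid)
    model <- train_svm(train, kernel = kernel, C = best$C,
                       gamma = if (is.na(best$gamma)) NULL else best$gamma)
    conf <- predict_confidence(model, test)
    list(
      split = dplyr::bind_cols(
        tibble::tibble(split = s, C = best$C, gamma = best$gamma),
        confusion_counts(test$class, conf)),
      pred = tibble::tibble(split = s, sample_id = test$sample_id,
                            truth = test$class, confidence = conf)
    )
  })
  res <- purrr::compact(res)
  if (!length(res)) {
    abort("every leave-out split was skipped", class = "tsmut_training_error")
  }
  per_split <- dplyr::bind_rows(purrr::map(res, "split"))
  predictions <- dplyr::bind_rows(purrr::map(res, "pred"))
  final <- tibble::tibble(
    C = 2^median(log2(per_split$C)),
    gamma = if (kernel == "rbf") 2^median(log2(per_split$gamma)) else NA_real_
  )
  new_cv_report(
    scheme = "5xleaveout", per_split = per_split,
    predictions = predictions,
    aggregate = pooled_metrics(predictions$truth, predictions$confidence),
    seeds = seed, final_params = final
  )
}

#' @export
tidy.ts_cv_report <- function(x, ...) x$per_split

#' @export
glance.ts_cv_report <- function(x, ...) {
  if (x$scheme == "5xleaveout") {
    dplyr::bind_cols(tibble::tibble(scheme = x$scheme), x$aggregate,
                     dplyr::rename(x$final_params, final_C = "C",
                                   final_gamma = "gamma"))
  } else {
    dplyr::bind_cols(
      tibble::tibble(scheme = x$scheme),
      tidyr::pivot_wider(x$aggregate, names_from = "metric",
                         values_from = c("mean", "var"))
    )
  }
}

#' ROC and PR curves of pooled held-out predictions
#'
#' @param object A `ts_cv_report`.
#' @param ... Unused.
#' @return A ggplot object with ROC and PR panels.
#' @export
autoplot.ts_cv_report <- function(object, ...) {
  pred <- object$predictions
  roc <- dplyr::mutate(roc_points(pred$truth, pred$confidence),
                       curve = "ROC")
  pr <- pr_points(pred$truth, pred$confidence)
  dat <- dplyr::bind_rows(
    dplyr::transmute(roc, x = .data$fpr, y = .data$tpr, curve = "ROC"),
    dplyr::transmute(pr, x = .data$recall, y = .data$precision,
                     curve = "Precision-recall")
  )
  ggplot2::ggplot(dat, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~curve, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0("Held-out performance (", object$scheme, ")")) +
    ggplot2::theme_minimal()
}

#' Precision surface of a hyperparameter grid
#'
#' @param object A `ts_grid` from [grid_search()].
#' @param ... Unused.
#' @return A ggplot tile plot of ts precision over log2(C) x log2(gamma).
#' @export
autoplot.ts_grid <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  best <- grid_best(object)
  if (all(is.na(dat$gamma))) {
    ggplot2::ggplot(dat, ggplot2::aes(log2(.data$C), .data$precision)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "log2 C", y = "ts precision") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(dat, ggplot2::aes(log2(.data$C), log2(.data$gamma),
                                      fill = .data$precision)) +
      ggplot2::geom_tile() +
      ggplot2::geom_point(data = best, colour = "black", shape = 4, size = 3) +
      ggplot2::labs(x = "log2 C", y = "log2 gamma", fill = "ts precision") +
      ggplot2::theme_minimal()
  }
}
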