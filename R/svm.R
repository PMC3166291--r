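#' Train a soft-margin SVM classifier on a labelled feature matrix
#'
#' Fits a two-class support vector machine (via libSVM) on min-max-scaled
#' features. The returned object records everything needed to re-score
#' deterministically: the support vectors, their signed dual weights
#' (alpha_i * y_i with ts as the positive class), the bias, the per-feature
#' scaling fitted on the training data, and a Platt-style sigmoid slope
#' mapping margins to confidences.
#'
#' @param data Labelled feature matrix tibble (`sample_id`, features,
#'   `class` in \{"ts", "non-ts"\}).
#' @param kernel `"linear"` or `"rbf"`.
#' @param C Complexity (soft-margin penalty); larger values fit the training
#'   samples more tightly.
#' @param gamma RBF kernel width; required for `"rbf"`, defaults to
#'   1 / n_features.
#' @param scale Min-max scale features to \[0, 1\] on the training ranges?
#'   Default `TRUE`.
#' @return A `ts_svm` object.
#' @export
train_svm <- function(data, kernel = c("linear", "rbf"), C = 1,
                      gamma = NULL, scale = TRUE) {
  kernel <- match.arg(kernel)
  validate_feature_matrix(data)
  if (!"class" %in% names(data)) {
    abort("training data must have a `class` column",
          class = "tsmut_input_error")
  }
  if (length(unique(data$class)) < 2) {
    abort("training data contains a single class",
          class = "tsmut_training_error")
  }
  if (C <= 0) abort("C must be positive", class = "tsmut_input_error")
  feats <- feature_names(data)
  x <- as.matrix(data[feats])
  if (!all(is.finite(x))) {
    abort("non-finite feature values in training data",
          class = "tsmut_input_error")
  }
  if (is.null(gamma)) gamma <- 1 / length(feats)
  if (kernel == "rbf" && gamma <= 0) {
    abort("gamma must be positive for the rbf kernel",
          class = "tsmut_input_error")
  }
  scaling <- tibble::tibble(
    feature = feats,
    min = if (scale) apply(x, 2, min) else rep(0, length(feats)),
    max = if (scale) apply(x, 2, max) else rep(1, length(feats))
  )
  xs <- minmax_apply(x, scaling)
  y <- factor(data$class, levels = c("non-ts", "ts"))
  fit <- e1071::svm(x = xs, y = y, scale = FALSE,
                    kernel = if (kernel == "linear") "linear" else "radial",
                    cost = C, gamma = gamma)
  dual <- as.numeric(fit$coefs)
  bias <- -fit$rho
  # libSVM's positive decision sign belongs to the first-seen class; flip so
  # that positive margins always mean ts
  positive <- fit$levels[fit$labels[1]]
  if (positive != "ts") {
    dual <- -dual
    bias <- -bias
  }
  model <- structure(
    list(kernel = kernel, C = C,
         gamma = if (kernel == "rbf") gamma else NULL,
         support_vectors = unname(as.matrix(fit$SV)),
         dual_coefs = dual, bias = bias,
         feature_names = feats, scaling = scaling,
         calibration = list(slope = 1)),
    class = "ts_svm"
  )
  if (model$kernel == "linear") {
    model$weights <- as.numeric(crossprod(model$support_vectors, dual))
  }
  margins <- decision_value(model, data)
  model$calibration$slope <- platt_slope(margins, data$class == "ts")
  model
}

minmax_apply <- function(x, scaling) {
  rng <- scaling$max - scaling$min
  rng[rng == 0] <- 1  # constant features map to 0
  sweep(sweep(x, 2, scaling$min), 2, rng, "/")
}

# Platt-style sigmoid with zero intercept: conf = plogis(slope * margin).
# The intercept is pinned at zero so that confidence > 0.5 exactly when the
# decision function is positive (the predicted-label contract). Fitted by
# 1-D likelihood optimisation with Platt's smoothed targets.
platt_slope <- function(margins, is_ts) {
  n_pos <- sum(is_ts)
  n_neg <- sum(!is_ts)
  t <- ifelse(is_ts, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  nll <- function(log_slope) {
    p <- plogis(exp(log_slope) * margins)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(t * log(p) + (1 - t) * log(1 - p))
  }
  exp(optimize(nll, c(log(1e-3), log(1e3)))$minimum)
}

#' @export
print.ts_svm <- function(x, ...) {
  cat("<ts_svm> ", x$kernel, " kernel, C = ", x$C,
      if (!is.null(x$gamma)) paste0(", gamma = ", signif(x$gamma, 4)),
      ", ", length(x$dual_coefs), " support vectors, ",
      length(x$feature_names), " features\n", sep = "")
  invisible(x)
}

model_matrix <- function(model, newdata) {
  if (is.matrix(newdata)) {
    x <- newdata
    if (ncol(x) != length(model$feature_names)) {
      abort("feature dimension mismatch", class = "tsmut_input_error")
    }
  } else {
    missing <- setdiff(model$feature_names, names(newdata))
    if (length(missing)) {
      abort(paste0("candidate data lacks feature(s): ",
                   paste(missing, collapse = ", ")),
            class = "tsmut_input_error")
    }
    x <- as.matrix(newdata[model$feature_names])
  }
  minmax_apply(x, model$scaling)
}

#' Decision-function margin of an SVM
#'
#' Evaluates the kernel expansion sum_i alpha_i y_i K(sv_i, x) + b directly
#' from the stored support vectors; the sign of the margin is the predicted
#' label (positive = ts). For linear models this agrees with the explicit
#' hyperplane w . x + b.
#'
#' @param model A `ts_svm`.
#' @param newdata Feature tibble (or pre-scaled-compatible numeric matrix in
#'   the model's feature order).
#' @return Numeric vector of margins.
#' @export
decision_value <- function(model, newdata) {
  xs <- model_matrix(model, newdata)
  sv <- model$support_vectors
  k <- if (model$kernel == "linear") {
    xs %*% t(sv)
  } else {
    d2 <- outer(rowSums(xs^2), rowSums(sv^2), "+") - 2 * xs %*% t(sv)
    exp(-model$gamma * pmax(d2, 0))
  }
  as.numeric(k %*% model$dual_coefs + model$bias)
}

#' Calibrated ts confidence
#'
#' Maps margins through the model's fitted sigmoid; strictly increasing in
#' the margin, with confidence > 0.5 exactly when the predicted label is ts.
#'
#' @inheritParams decision_value
#' @return Confidences in (0, 1).
#' @export
predict_confidence <- function(model, newdata) {
  plogis(model$calibration$slope * decision_value(model, newdata))
}

#' Rank candidate mutations by ts confidence
#'
#' @param model A `ts_svm`.
#' @param candidates Feature tibble whose `sample_id` column carries the
#'   mutation ids (see [mutation_id()]).
#' @return A `ts_predictions` tibble with columns `rank`, `confidence`,
#'   `mutation_id`, in descending confidence (ties broken by id, so reruns
#'   are byte-identical).
#' @export
rank_predictions <- function(model, candidates) {
  if (!nrow(candidates)) {
    return(structure(tibble::tibble(rank = integer(), confidence = numeric(),
                                    mutation_id = character()),
                     class = c("ts_predictions", class(tibble::tibble()))))
  }
  conf <- predict_confidence(model, candidates)
  out <- tibble::tibble(confidence = conf,
                        mutation_id = candidates$sample_id) |>
    dplyr::arrange(dplyr::desc(.data$confidence), .data$mutation_id) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
  structure(out, class = c("ts_predictions", class(out)))
}

#' Keep the top k ranked predictions
#'
#' @param predictions A `ts_predictions` tibble.
#' @param k Number of predictions to keep; default 5 (the "top 5" list
#'   handed to experimental screening).
#' @return The truncated predictions tibble.
#' @export
top_k <- function(predictions, k = 5) {
  utils::head(predictions, k)
}

#' Format / write ranked predictions
#'
#' The ranked-list text format: header `rank conf id`, then one line per
#' prediction with the rank, the confidence to three decimals, and the
#' mutation id, e.g. `1  0.839 YBR109C-F140_GLY_Scer`.
#'
#' @param predictions A `ts_predictions` tibble.
#' @param path Output path (for `write_predictions()`).
#' @return `format_predictions()` returns a character vector of lines;
#'   `write_predictions()` returns `path` invisibly.
#' @export
format_predictions <- function(predictions) {
  c("rank conf id",
    sprintf("%d  %.3f %s", predictions$rank, predictions$confidence,
            predictions$mutation_id))
}

#' @rdname format_predictions
#' @export
write_predictions <- function(predictions, path) {
  writeLines(format_predictions(predictions), path)
  invisible(path)
}

#' Restrict a feature matrix to sequence-derived features
#'
#' The SVM-seq variant trains on sequence information only: the
#' category-change codes (`aminochange`, `aminochange2`), the PSSM log-odds
#' and frequency features (`pssm_*`, `freq_*`) and the position information
#' content (`info_cont`). All ensemble-derived and structure features
#' (`<term>Q*`, `ACCP`, `ss_*`) are dropped.
#'
#' @param m Feature matrix tibble.
#' @return The restricted feature matrix.
#' @export
svm_seq_view <- function(m) {
  validate_feature_matrix(m)
  seq_pat <- "^(aminochange2?|pssm_(mut|nat|diff)|freq_(mut|nat|diff)|info_cont)$"
  kept <- grep(seq_pat, feature_names(m), value = TRUE)
  if (!length(kept)) {
    abort("no sequence-derived features present", class = "tsmut_empty_error")
  }
  m[c("sample_id", kept, intersect("class", names(m)))]
}

#' Feature weights of a linear SVM
#'
#' The explicit primal weight vector w = sum_i alpha_i y_i x_i, ranked by
#' absolute value; positive weights favour the ts label.
#'
#' @param model A linear-kernel `ts_svm`.
#' @return Tibble with columns `feature`, `weight`, descending |weight|.
#' @export
feature_weights <- function(model) {
  if (model$kernel != "linear") {
    abort("feature weights are only defined for linear kernels",
          class = "tsmut_unsupported_error")
  }
  tibble::tibble(feature = model$feature_names,
                 weight = model$weights) |>
    dplyr::arrange(dplyr::desc(abs(.data$weight)))
}

#' Persist / reload a trained SVM
#'
#' Plain-text (JSON) dump of every model field at full double precision;
#' reloading reproduces decision values exactly.
#'
#' @param model A `ts_svm`.
#' @param path File path.
#' @return `write_ts_svm()` returns `path` invisibly; `read_ts_svm()`
#'   returns the `ts_svm`.
#' @export
write_ts_svm <- function(model, path) {
  payload <- list(
    kernel = model$kernel, C = model$C, gamma = model$gamma,
    support_vectors = model$support_vectors,
    dual_coefs = model$dual_coefs, bias = model$bias,
    feature_names = model$feature_names,
    scaling = as.list(model$scaling),
    calibration = model$calibration,
    weights = model$weights
  )
  # I(17) significant digits: doubles survive the text round-trip exactly
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_ts_svm
#' @export
read_ts_svm <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(kernel = p$kernel, C = p$C, gamma = p$gamma,
         support_vectors = matrix(p$support_vectors,
                                  ncol = length(p$feature_names)),
         dual_coefs = p$dual_coefs, bias = p$bias,
         feature_names = p$feature_names,
         scaling = tibble::as_tibble(p$scaling),
         calibration = as.list(p$calibration),
         weights = p$weights),
    class = "ts_svm"
  )
}

#' @export
tidy.ts_svm <- function(x, ...) {
  if (x$kernel == "linear") {
    feature_weights(x)
  } else {
    tibble::tibble(support_vector = seq_along(x$dual_coefs),
                   dual_coef = x$dual_coefs)
  }
}

#' @export
glance.ts_svm <- function(x, ...) {
  tibble::tibble(kernel = x$kernel, C = x$C,
                 gamma = x$gamma %||% NA_real_,
                 n_support = length(x$dual_coefs),
                 n_features = length(x$feature_names),
                 bias = x$bias,
                 calibration_slope = x$calibration$slope)
}

#' Plot the |weight| ranking of a linear SVM
#'
#' @param object A linear `ts_svm`.
#' @param top Number of features to show; default 15.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ts_svm <- function(object, top = 15, ...) {
  w <- utils::head(feature_weights(object), top)
  w$feature <- factor(w$feature, levels = rev(w$feature))
  ggplot2::ggplot(w, ggplot2::aes(.data$weight, .data$feature,
                                  fill = .data$weight > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "weight (positive favours ts)", y = NULL,
                  title = "Top features by |weight|") +
    ggplot2::theme_minimal()
}
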