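#' Strongly correlated feature pairs
#'
#' All unordered feature pairs whose absolute Pearson correlation reaches
#' the threshold, sorted by descending |r|. Zero-variance features cannot be
#' correlated and are reported separately in the `degenerate` attribute.
#'
#' @param m Feature matrix tibble with at least 3 samples.
#' @param threshold Absolute-correlation cutoff in \[0, 1\]; default 0.9.
#' @return Tibble with columns `feature_a`, `feature_b`, `r`; attribute
#'   `degenerate` lists zero-variance feature names.
#' @export
correlated_pairs <- function(m, threshold = 0.9) {
  validate_feature_matrix(m)
  if (nrow(m) < 3) {
    abort("need at least 3 samples to estimate correlations",
          class = "tsmut_input_error")
  }
  feats <- feature_names(m)
  x <- as.matrix(m[feats])
  degenerate <- feats[apply(x, 2, function(col) diff(range(col)) == 0)]
  keep <- setdiff(feats, degenerate)
  out <- tibble::tibble(feature_a = character(), feature_b = character(),
                        r = numeric())
  if (length(keep) >= 2) {
    r <- stats::cor(x[, keep, drop = FALSE])
    idx <- which(upper.tri(r) & abs(r) >= threshold, arr.ind = TRUE)
    if (nrow(idx)) {
      out <- tibble::tibble(
        feature_a = keep[idx[, 1]],
        feature_b = keep[idx[, 2]],
        r = r[idx]
      ) |>
        dplyr::arrange(dplyr::desc(abs(.data$r)))
    }
  }
  attr(out, "degenerate") <- degenerate
  out
}

#' The shipped redundancy-pruning plan
#'
#' The fixed pruning applied before training: quartile-feature trios of
#' redundant score terms are removed as groups (`fa_atr`, `fa_sol`,
#' `fa_intra_rep` are near-duplicates of the kept `fa_dun` group; `maxsub`
#' duplicates `gdtmm7_4`; `rms` duplicates `gdtmm2_2`; `irms` carries no
#' information, its values being always zero), along with individual
#' features that degraded performance (`ss_H`, `ss_S`, `ss_L`) or duplicate
#' a kept partner (`freq_*` duplicate `pssm_*`; `aminochange` duplicates
#' the kept `aminochange2` — swap via `keep_aminochange2 = FALSE`).
#'
#' @param keep_aminochange2 Keep the seven-category scheme and drop the
#'   four-category one? Default `TRUE`.
#' @param threshold Correlation threshold the plan was derived under.
#' @return A `ts_pruning_plan`: list with `removed_terms`,
#'   `removed_features`, `threshold`.
#' @export
default_pruning_plan <- function(keep_aminochange2 = TRUE, threshold = 0.9) {
  structure(
    list(
      removed_terms = c("fa_atr", "fa_sol", "fa_intra_rep",
                        "maxsub", "rms", "irms"),
      removed_features = c("ss_H", "ss_S", "ss_L",
                           "freq_mut", "freq_nat", "freq_diff",
                           if (keep_aminochange2) "aminochange"
                           else "aminochange2"),
      threshold = threshold
    ),
    class = "ts_pruning_plan"
  )
}

#' @export
print.ts_pruning_plan <- function(x, ...) {
  cat("<ts_pruning_plan>\n",
      " removed terms (Q1-Q3 trios): ",
      paste(x$removed_terms, collapse = ", "), "\n",
      " removed features: ", paste(x$removed_features, collapse = ", "), "\n",
      " correlation threshold: ", x$threshold, "\n", sep = "")
  invisible(x)
}

# all individual feature names a plan removes
plan_removed_features <- function(plan) {
  c(as.vector(t(outer(plan$removed_terms, paste0("Q", 1:3), paste0))),
    plan$removed_features)
}

#' Apply a pruning plan to a feature matrix
#'
#' Drops the plan's removed features (whole Q1–Q3 trios for removed score
#' terms); sample order and non-feature columns are untouched. Names in the
#' plan that are absent from the matrix produce a warning, not an error, so
#' the same plan applies to full and already-reduced matrices (the
#' operation is idempotent).
#'
#' @param m Feature matrix tibble.
#' @param plan A `ts_pruning_plan`, e.g. [default_pruning_plan()].
#' @return The pruned feature matrix.
#' @export
apply_pruning <- function(m, plan = default_pruning_plan()) {
  validate_feature_matrix(m)
  removed <- plan_removed_features(plan)
  absent <- setdiff(removed, feature_names(m))
  if (length(absent)) {
    warn(paste0("plan names absent from matrix (already removed?): ",
                paste(absent, collapse = ", ")))
  }
  kept <- setdiff(feature_names(m), removed)
  if (!length(kept)) {
    abort("pruning would remove every feature", class = "tsmut_empty_error")
  }
  m[c("sample_id", kept, intersect("class", names(m)))]
}
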