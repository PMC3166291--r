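#' Nearest-rank quartiles of an ensemble's score values
#'
#' Sorts the values ascending and takes the elements at 1-based positions
#' `ceiling(p * n)` for p = 0.25, 0.5, 0.75 (nearest-rank convention, so the
#' quartiles are always observed values).
#'
#' @param values Numeric vector of one score term across an ensemble; at
#'   least 4 values.
#' @return Named numeric vector `c(q1, q2, q3)`.
#' @export
#' @examples
#' score_quartiles(1:8)  # c(q1 = 2, q2 = 4, q3 = 6)
score_quartiles <- function(values) {
  if (length(values) < 4) {
    abort("need at least 4 values to compute quartiles",
          class = "tsmut_insufficient_data_error")
  }
  if (anyNA(values)) {
    abort("score values contain NA", class = "tsmut_input_error")
  }
  s <- sort(values)
  n <- length(s)
  idx <- ceiling(c(0.25, 0.5, 0.75) * n)
  setNames(s[idx], c("q1", "q2", "q3"))
}

#' Percentile of a value within a reference ensemble
#'
#' Empirical-CDF position of `x` within `reference`: the sorted reference
#' values are assigned plotting positions (i - 0.5) / n, tied values share
#' the mean of their positions, `x` is mapped by linear interpolation,
#' extrapolated linearly beyond the extremes with the adjacent segment's
#' slope, and clamped to \[0, 1\]. This is the normalization at the heart of
#' the quartile features: it is invariant under any strictly increasing
#' rescaling applied to both ensembles.
#'
#' @param reference Numeric vector (the wild-type ensemble's values for one
#'   term); at least 4 values.
#' @param x Numeric vector of values to locate.
#' @return Fractions in \[0, 1\], one per element of `x`.
#' @export
#' @examples
#' ecdf_percentile(c(10, 20, 30, 40), 25)  # 0.5
ecdf_percentile <- function(reference, x) {
  if (length(reference) < 4) {
    abort("need at least 4 reference values",
          class = "tsmut_insufficient_data_error")
  }
  if (anyNA(reference) || anyNA(x)) {
    abort("values contain NA", class = "tsmut_input_error")
  }
  n <- length(reference)
  s <- sort(reference)
  pp <- (seq_len(n) - 0.5) / n
  # collapse ties to the mean plotting position of the tied block
  ux <- unique(s)
  up <- vapply(split(pp, match(s, ux)), mean, numeric(1))
  if (length(ux) == 1L) {
    out <- ifelse(x < ux, 0, ifelse(x > ux, 1, 0.5))
    return(out)
  }
  out <- stats::approx(ux, up, xout = x, rule = 1)$y
  # linear extrapolation with the end segments' slopes
  k <- length(ux)
  lo <- x < ux[1]
  hi <- x > ux[k]
  slope_lo <- (up[2] - up[1]) / (ux[2] - ux[1])
  slope_hi <- (up[k] - up[k - 1]) / (ux[k] - ux[k - 1])
  out[lo] <- up[1] + (x[lo] - ux[1]) * slope_lo
  out[hi] <- up[k] + (x[hi] - ux[k]) * slope_hi
  pmin(pmax(out, 0), 1)
}

#' Quartile-to-percentile features for a mutant ensemble
#'
#' The core distribution-comparison statistic: for each score term, the
#' mutant ensemble's three quartiles are located as percentiles within the
#' wild-type ensemble's values of the same term, yielding features
#' `<term>Q1`, `<term>Q2`, `<term>Q3` in \[0, 1\]. An undisturbed term maps
#' near (0.25, 0.50, 0.75); destabilization shows up as displacement toward
#' 0 or 1 and clamping marks quartiles that fall outside the wild-type
#' range entirely. Over the standard 31 score terms this yields 93 features.
#'
#' @param mutant,wt Score tables (see [score-table]) sharing the terms in
#'   `terms`.
#' @param terms Score terms to compare; defaults to the terms shared by both
#'   tables, in the mutant table's order.
#' @return A one-row tibble of `3 * length(terms)` feature columns.
#' @export
#' @examples
#' wt <- generate_wt_ensemble(seed = 1)
#' mut <- generate_mutant_ensemble(effect = mutation_effect(delta = 2), seed = 2)
#' dim(quartile_features(mut, wt))  # 1 x 93
quartile_features <- function(mutant, wt, terms = NULL) {
  validate_score_table(mutant)
  validate_score_table(wt)
  if (is.null(terms)) {
    terms <- intersect(score_term_names(mutant), score_term_names(wt))
  }
  missing_mut <- setdiff(terms, score_term_names(mutant))
  missing_wt <- setdiff(terms, score_term_names(wt))
  if (length(missing_mut) || length(missing_wt)) {
    abort(paste0("term(s) missing from ",
                 if (length(missing_mut)) "mutant" else "wt", " table: ",
                 paste(c(missing_mut, missing_wt), collapse = ", ")),
          class = "tsmut_integrity_error")
  }
  feats <- purrr::map(terms, function(term) {
    q <- score_quartiles(mutant[[term]])
    setNames(ecdf_percentile(wt[[term]], q), paste0(term, "Q", 1:3))
  })
  tibble::as_tibble(as.list(unlist(feats)))
}

#' Visualize the quartile-to-percentile mapping for one term
#'
#' Draws the wild-type empirical CDF for one score term with the mutant
#' quartiles marked at their mapped percentiles — the picture behind each
#' `<term>Q*` feature.
#'
#' @param mutant,wt Score tables.
#' @param term Score term to plot.
#' @return A ggplot object.
#' @export
plot_quartile_map <- function(mutant, wt, term) {
  q <- score_quartiles(mutant[[term]])
  p <- ecdf_percentile(wt[[term]], q)
  s <- sort(wt[[term]])
  cdf <- tibble::tibble(value = s,
                        percentile = (seq_along(s) - 0.5) / length(s))
  marks <- tibble::tibble(quartile = c("Q1", "Q2", "Q3"),
                          value = unname(q), percentile = unname(p))
  ggplot2::ggplot(cdf, ggplot2::aes(.data$value, .data$percentile)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = marks, colour = "red", size = 2) +
    ggplot2::geom_text(data = marks,
                       ggplot2::aes(label = .data$quartile),
                       vjust = -0.8, colour = "red") +
    ggplot2::labs(x = term, y = "wild-type percentile",
                  title = paste0("Quartile mapping for ", term)) +
    ggplot2::theme_minimal()
}
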