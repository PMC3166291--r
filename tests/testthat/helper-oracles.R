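# Independent brute-force oracles used to cross-check the package's
# statistics. These deliberately share no code with the implementation.

# nearest-rank quartile: smallest 1-based index i of the ascending sort with
# i >= p * n
brute_quartiles <- function(values) {
  s <- sort(values)
  n <- length(s)
  vapply(c(0.25, 0.5, 0.75), function(p) {
    i <- which(seq_len(n) >= p * n)[1]
    s[i]
  }, numeric(1))
}

# interpolated ECDF percentile via stats::approx with mean-tie handling and
# explicit end-segment extrapolation, then clamping
brute_ecdf_percentile <- function(reference, x) {
  n <- length(reference)
  s <- sort(reference)
  pp <- (seq_len(n) - 0.5) / n
  agg <- stats::aggregate(pp, list(v = s), mean)
  ux <- agg$v
  up <- agg$x
  vapply(x, function(xi) {
    if (length(ux) == 1) {
      return(if (xi < ux) 0 else if (xi > ux) 1 else 0.5)
    }
    y <- if (xi < ux[1]) {
      up[1] + (xi - ux[1]) * (up[2] - up[1]) / (ux[2] - ux[1])
    } else if (xi > ux[length(ux)]) {
      k <- length(ux)
      up[k] + (xi - ux[k]) * (up[k] - up[k - 1]) / (ux[k] - ux[k - 1])
    } else {
      stats::approx(ux, up, xout = xi)$y
    }
    min(max(y, 0), 1)
  }, numeric(1))
}

# tie-aware Mann-Whitney AUROC by exhaustive pair counting
brute_auroc <- function(truth, confidence) {
  pos <- confidence[truth]
  neg <- confidence[!truth]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# decision function by explicit summation over support vectors
brute_decision <- function(model, newdata) {
  x <- as.matrix(newdata[model$feature_names])
  rng <- model$scaling$max - model$scaling$min
  rng[rng == 0] <- 1
  for (j in seq_len(ncol(x))) {
    x[, j] <- (x[, j] - model$scaling$min[j]) / rng[j]
  }
  out <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    acc <- model$bias
    for (s in seq_along(model$dual_coefs)) {
      sv <- model$support_vectors[s, ]
      k <- if (model$kernel == "linear") {
        sum(sv * x[i, ])
      } else {
        exp(-model$gamma * sum((sv - x[i, ])^2))
      }
      acc <- acc + model$dual_coefs[s] * k
    }
    out[i] <- acc
  }
  out
}

# small labelled toy matrix with a linearly separable signal feature
make_separable_matrix <- function(n_per_class = 20, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      sample_id = sprintf("s%03d", seq_len(2 * n_per_class)),
      signal = c(rnorm(n_per_class, 3), rnorm(n_per_class, -3)),
      noise1 = rnorm(2 * n_per_class),
      noise2 = rnorm(2 * n_per_class),
      class = rep(c("ts", "non-ts"), each = n_per_class)
    )
  })
}

# XOR-patterned 2D set: not linearly separable, RBF-separable
make_xor_matrix <- function(reps = 10, jitter = 0.05, seed = 1) {
  withr::with_seed(seed, {
    base <- tibble::tibble(
      x1 = rep(c(0, 1, 0, 1), reps),
      x2 = rep(c(0, 1, 1, 0), reps),
      class = rep(c("ts", "ts", "non-ts", "non-ts"), reps)
    )
    base$x1 <- base$x1 + rnorm(nrow(base), 0, jitter)
    base$x2 <- base$x2 + rnorm(nrow(base), 0, jitter)
    base$sample_id <- sprintf("x%03d", seq_len(nrow(base)))
    base[c("sample_id", "x1", "x2", "class")]
  })
}

# term a quartile feature derives from ("p_aa_ppQ2" -> "p_aa_pp")
feature_term <- function(feature) sub("Q[123]$", "", feature)
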