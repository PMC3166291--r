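#' Synthetic ensemble model
#'
#' Describes the wild-type score-term distributions a relax run would
#' produce: per-term location and spread, the ensemble size (50 decoys, the
#' standard production setting), and the noise family. The default
#' locations/spreads are order-of-magnitude realistic for a small globular
#' protein (large negative total score, moderate per-term energies,
#' similarity fractions near 1, RMS deviations near 1 Angstrom, and an
#' `irms` term that is numerically zero); their exact values are immaterial
#' to the quartile statistic, which is rank-based.
#'
#' @param terms Score-term names; default [rosetta_score_terms()].
#' @param mu,sigma Optional named numeric vectors overriding per-term
#'   location/spread.
#' @param ensemble_size Decoys per ensemble; default 50.
#' @param family `"normal"` or `"lognormal"` noise.
#' @return An `ensemble_model` list.
#' @export
ensemble_model <- function(terms = rosetta_score_terms(), mu = NULL,
                           sigma = NULL, ensemble_size = 50,
                           family = c("normal", "lognormal")) {
  family <- match.arg(family)
  if (ensemble_size < 4) {
    abort("ensemble_size must be at least 4", class = "tsmut_input_error")
  }
  base_mu <- c(
    score = -250, fa_atr = -480, fa_rep = 60, fa_sol = 270,
    fa_intra_rep = 1.5, pro_close = 2, fa_pair = -8, hbond_sr_bb = -25,
    hbond_lr_bb = -15, hbond_bb_sc = -8, hbond_sc = -10, dslf_ss_dst = 0.1,
    dslf_cs_ang = 0.2, dslf_ss_dih = 0.3, dslf_ca_dih = 0.4, rama = -10,
    omega = 34, fa_dun = 160, p_aa_pp = -18, ref = 20,
    Repack_average_score = -245, Repack_stdev_score = 3, gdtmm1_1 = 0.55,
    gdtmm2_2 = 0.8, gdtmm3_3 = 0.9, gdtmm4_3 = 0.92, gdtmm7_4 = 0.97,
    irms = 0, maxsub = 110, "maxsub2.0" = 90, rms = 1.1
  )
  base_sigma <- c(
    score = 8, fa_atr = 6, fa_rep = 5, fa_sol = 5, fa_intra_rep = 0.3,
    pro_close = 0.5, fa_pair = 1, hbond_sr_bb = 2, hbond_lr_bb = 2,
    hbond_bb_sc = 1.5, hbond_sc = 1.5, dslf_ss_dst = 0.05,
    dslf_cs_ang = 0.05, dslf_ss_dih = 0.05, dslf_ca_dih = 0.05, rama = 2,
    omega = 3, fa_dun = 8, p_aa_pp = 2, ref = 0.5,
    Repack_average_score = 8, Repack_stdev_score = 1, gdtmm1_1 = 0.05,
    gdtmm2_2 = 0.04, gdtmm3_3 = 0.03, gdtmm4_3 = 0.03, gdtmm7_4 = 0.02,
    irms = 1e-6, maxsub = 4, "maxsub2.0" = 5, rms = 0.15
  )
  mu_all <- setNames(rep(0, length(terms)), terms)
  sig_all <- setNames(rep(1, length(terms)), terms)
  known <- intersect(terms, names(base_mu))
  mu_all[known] <- base_mu[known]
  sig_all[known] <- base_sigma[known]
  if (!is.null(mu)) mu_all[names(mu)] <- mu
  if (!is.null(sigma)) sig_all[names(sigma)] <- sigma
  if (any(sig_all <= 0)) {
    abort("per-term spreads must be positive", class = "tsmut_input_error")
  }
  structure(list(terms = terms, mu = mu_all, sigma = sig_all,
                 ensemble_size = ensemble_size, family = family),
            class = "ensemble_model")
}

#' Score terms sensitive to destabilizing mutations
#'
#' The terms on which the synthetic generator plants the mutation effect:
#' the overall score and repack-trajectory variability respond to any
#' destabilization, the backbone-statistics term to strained local
#' conformations, and the mid-threshold similarity fractions to overall
#' atom movement away from the native structure.
#'
#' @return Character vector of term names.
#' @export
default_sensitive_terms <- function() {
  c("score", "Repack_stdev_score", "p_aa_pp", "gdtmm4_3", "gdtmm7_4")
}

#' Planted mutation effect
#'
#' The generator's operationalization of the destabilization-window premise:
#' a mutation shifts the sensitive terms' locations by `delta` wild-type
#' spreads and inflates their spread by `kappa`; the planted label is ts
#' exactly when `delta` lies inside `ts_band` — mutations below the band are
#' tolerated, mutations above it are outright loss-of-function.
#'
#' @param delta Location shift in wild-type-spread units.
#' @param kappa Spread inflation factor (>= 1).
#' @param sensitive_terms Terms the effect applies to.
#' @param ts_band Interval of `delta` labelled ts; default \[1.5, 4\].
#' @return A `mutation_effect` list, with an `is_ts` element giving the
#'   planted label.
#' @export
mutation_effect <- function(delta = 0, kappa = 1,
                            sensitive_terms = default_sensitive_terms(),
                            ts_band = c(1.5, 4)) {
  if (kappa < 1) abort("kappa must be >= 1", class = "tsmut_input_error")
  if (ts_band[1] >= ts_band[2]) {
    abort("ts_band must be an increasing interval",
          class = "tsmut_input_error")
  }
  structure(list(delta = delta, kappa = kappa,
                 sensitive_terms = sensitive_terms, ts_band = ts_band,
                 is_ts = delta >= ts_band[1] && delta <= ts_band[2]),
            class = "mutation_effect")
}

# one standardized draw matrix (decoys x terms) from the model's noise family
draw_ensemble_noise <- function(n, p, family) {
  z <- if (family == "normal") {
    rnorm(n * p)
  } else {
    m <- exp(0.5)
    s <- sqrt((exp(1) - 1) * exp(1))
    (exp(rnorm(n * p)) - m) / s
  }
  matrix(z, nrow = n, ncol = p)
}

generate_ensemble_impl <- function(model, ensemble_id, delta = 0, kappa = 1,
                                   sensitive_terms = character()) {
  n <- model$ensemble_size
  terms <- model$terms
  mu <- model$mu[terms]
  sig <- model$sigma[terms]
  shift <- kap <- setNames(rep(0, length(terms)), terms)
  kap[] <- 1
  hit <- intersect(sensitive_terms, terms)
  shift[hit] <- delta
  kap[hit] <- kappa
  z <- draw_ensemble_noise(n, length(terms), model$family)
  vals <- sweep(sweep(z, 2, sig * kap, "*"), 2, mu + shift * sig, "+")
  colnames(vals) <- terms
  tbl <- dplyr::bind_cols(
    tibble::tibble(decoy_tag = sprintf("%s_%04d", ensemble_id, seq_len(n))),
    tibble::as_tibble(as.data.frame(vals, check.names = FALSE))
  )
  new_score_table(tbl, ensemble_id)
}

#' Generate a synthetic wild-type ensemble
#'
#' Independent per-term draws from the ensemble model, with a decoy-tag
#' series `{ensemble_id}_0001` onward.
#'
#' @param model An [ensemble_model()].
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param ensemble_id Identity string for the table; default `"WT"`.
#' @return A score table tibble.
#' @export
generate_wt_ensemble <- function(model = ensemble_model(), seed = NULL,
                                 ensemble_id = "WT") {
  if (is.null(seed)) {
    generate_ensemble_impl(model, ensemble_id)
  } else {
    with_rng_seed(seed, generate_ensemble_impl(model, ensemble_id))
  }
}

#' Generate a synthetic mutant ensemble
#'
#' Like [generate_wt_ensemble()], but the effect's sensitive terms are drawn
#' at location mu + delta * sigma with spread kappa * sigma; untouched terms
#' share the wild-type model.
#'
#' @param model An [ensemble_model()].
#' @param effect A [mutation_effect()].
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param ensemble_id Identity string; default `"MUT"`.
#' @return A score table tibble.
#' @export
generate_mutant_ensemble <- function(model = ensemble_model(),
                                     effect = mutation_effect(),
                                     seed = NULL, ensemble_id = "MUT") {
  run <- function() {
    generate_ensemble_impl(model, ensemble_id, delta = effect$delta,
                           kappa = effect$kappa,
                           sensitive_terms = effect$sensitive_terms)
  }
  if (is.null(seed)) run() else with_rng_seed(seed, run())
}

# integer percents summing to 100 by largest remainder
percent_round <- function(p) {
  raw <- p * 100
  base <- floor(raw)
  short <- 100L - sum(base)
  if (short > 0) {
    add <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

#' Generate a synthetic PSSM for a sequence
#'
#' Per-position observed frequencies concentrate on the native residue
#' according to the conservation profile (fraction of the probability mass
#' on the native residue above a uniform background); log-odds are half-bit
#' integers consistent with the frequencies against the uniform background,
#' and the information content is the Kullback-Leibler divergence from
#' background in bits. Serializes (via [write_pssm()]) to the dialect
#' [parse_pssm()] reads.
#'
#' @param sequence Character vector of one-letter codes (or a single
#'   string).
#' @param conservation Per-position conservation in \[0, 1\] (recycled).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A `ts_pssm`.
#' @export
generate_pssm <- function(sequence, conservation = 0.7, seed = NULL) {
  if (length(sequence) == 1 && nchar(sequence) > 1) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  check_aa(sequence, "sequence")
  conservation <- rep_len(conservation, length(sequence))
  run <- function() {
    aa <- ncbi_aa_order()
    bg <- 1 / 20
    lo <- fr <- matrix(0, nrow = length(sequence), ncol = 20,
                       dimnames = list(NULL, aa))
    info <- numeric(length(sequence))
    for (i in seq_along(sequence)) {
      w <- runif(20, 0.5, 1.5)
      w <- w / sum(w) * (1 - conservation[i])
      p <- setNames(w, aa)
      p[sequence[i]] <- p[sequence[i]] + conservation[i]
      fr[i, ] <- as.numeric(percent_round(p))
      p_eff <- pmax(fr[i, ] / 100, 1e-4)
      lo[i, ] <- round(2 * log2(p_eff / bg))
      p_pos <- fr[i, ] / 100
      info[i] <- round(sum(ifelse(p_pos > 0,
                                  p_pos * log2(p_pos / bg), 0)), 2)
    }
    new_pssm(tibble::tibble(position = seq_along(sequence),
                            native_aa = sequence,
                            info_cont = pmax(info, 0)),
             lo, fr)
  }
  if (is.null(seed)) run() else with_rng_seed(seed, run())
}

#' Generate a synthetic per-residue accessibility table
#'
#' Random sequence with a chosen number of buried sites (accessibility at or
#' below `buried_below`) and random secondary structure.
#'
#' @param n_res Number of residues.
#' @param n_buried Number of buried residues among them.
#' @param buried_below Accessibility ceiling for the buried sites; default
#'   0.10.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return Accessibility tibble (`position`, `aa`, `acc_fraction`, `ss`).
#' @export
generate_accessibility <- function(n_res = 20, n_buried = 4,
                                   buried_below = 0.10, seed = NULL) {
  run <- function() {
    acc <- runif(n_res, buried_below + 0.05, 0.95)
    buried <- sample.int(n_res, n_buried)
    acc[buried] <- runif(n_buried, 0, buried_below)
    tibble::tibble(
      position = seq_len(n_res),
      aa = sample(amino_acids(), n_res, replace = TRUE),
      acc_fraction = acc,
      ss = sample(c("H", "S", "L"), n_res, replace = TRUE)
    )
  }
  if (is.null(seed)) run() else with_rng_seed(seed, run())
}

#' Generate a labelled synthetic training set
#'
#' Emulates the full training-data pipeline end to end: for each sample a
#' destabilization shift `delta` is drawn — inside the ts band for ts
#' samples, outside it (half tolerated, half loss-of-function) for non-ts
#' samples — with spread inflation `kappa = 1 + 0.4 delta^2` (ensembles of
#' severely destabilized structures wander far beyond the wild-type range
#' during relaxation, so spread grows faster than location; the quadratic
#' coupling keeps within-band quartiles inside the wild-type range while
#' pushing loss-of-function quartiles beyond it); a wild-type and
#' a mutant ensemble are generated; and the *real* feature pipeline
#' ([quartile_features()], [aminochange()], [sequence_features()],
#' [structure_features()]) is run on the generated ensembles and synthetic
#' PSSMs. The default 75 ts / 130 non-ts shape mirrors a realistic curated
#' mutation collection. Labels follow the planted rule exactly.
#'
#' @param n_ts,n_nonts Sample counts per class.
#' @param model An [ensemble_model()].
#' @param ts_band Planted ts interval of `delta`; default \[1.5, 4\].
#' @param lethal_span Width of the loss-of-function `delta` range above the
#'   band; default 3.
#' @param sensitive_terms Terms carrying the effect.
#' @param seed Integer seed.
#' @return Labelled feature matrix tibble (`sample_id`, 106 features,
#'   `class`), with the drawn `delta` per sample in attribute `deltas`.
#' @export
generate_training_set <- function(n_ts = 75, n_nonts = 130,
                                  model = ensemble_model(),
                                  ts_band = c(1.5, 4), lethal_span = 3,
                                  sensitive_terms = default_sensitive_terms(),
                                  seed = 1) {
  stopifnot(n_ts >= 1, n_nonts >= 1)
  with_rng_seed(seed, {
    n <- n_ts + n_nonts
    is_ts <- c(rep(TRUE, n_ts), rep(FALSE, n_nonts))
    delta <- numeric(n)
    delta[is_ts] <- runif(n_ts, ts_band[1], ts_band[2])
    tolerated <- runif(n_nonts) < 0.5
    delta[!is_ts] <- ifelse(tolerated,
                            runif(n_nonts, 0, ts_band[1]),
                            runif(n_nonts, ts_band[2],
                                  ts_band[2] + lethal_span))
    rows <- purrr::map(seq_len(n), function(i) {
      eff <- mutation_effect(delta = delta[i],
                             kappa = 1 + 0.4 * delta[i]^2,
                             sensitive_terms = sensitive_terms,
                             ts_band = ts_band)
      wt <- generate_wt_ensemble(model)
      mut <- generate_mutant_ensemble(model, eff)
      residues <- generate_accessibility(n_res = 15, n_buried = 15)
      pos <- sample.int(15, 1)
      native <- residues$aa[pos]
      mutant_aa <- sample(setdiff(amino_acids(), native), 1)
      spec <- tibble::tibble(protein = sprintf("SYN%03d", i),
                             species = "Synt", position = pos,
                             native_aa = native, mutant_aa = mutant_aa)
      pssm <- generate_pssm(residues$aa, conservation = runif(1, 0.2, 0.9))
      mutation_features(mut, wt, residues, pssm, spec, terms = model$terms)
    })
    out <- dplyr::bind_rows(rows)
    out$class <- ifelse(is_ts, "ts", "non-ts")
    attr(out, "deltas") <- delta
    out
  })
}

#' Materialize a complete toy prediction workspace
#'
#' Writes everything `cmd_predict()` consumes for one synthetic protein:
#' the accessibility table, an ASCII PSSM, relax + rescore score-file pairs
#' for the wild type and for every manifest mutation (each mutation gets a
#' random planted destabilization), and a small labelled training matrix.
#'
#' @param dir Output directory (created if needed).
#' @param protein,species Naming for the toy protein.
#' @param n_res,n_buried Residue counts for the accessibility table.
#' @param model Ensemble model for the score files.
#' @param seed Integer seed.
#' @param n_train_ts,n_train_nonts Size of the bundled training matrix.
#' @return `dir`, invisibly.
#' @export
generate_toy_workspace <- function(dir, protein = "TOY1", species = "Scer",
                                   n_res = 12, n_buried = 2,
                                   model = ensemble_model(), seed = 1,
                                   n_train_ts = 15, n_train_nonts = 25) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  with_rng_seed(seed, {
    residues <- generate_accessibility(n_res = n_res, n_buried = n_buried)
    readr::write_tsv(residues, file.path(dir, "accessibility.tsv"),
                     progress = FALSE)
    pssm <- generate_pssm(residues$aa, conservation = runif(1, 0.3, 0.9))
    write_pssm(pssm, file.path(dir, paste0(protein, ".pssm")))
    buried <- select_buried_sites(residues)
    specs <- enumerate_mutations(protein, species, buried, residues)
    manifest <- build_run_manifest(protein, species, specs,
                                   ensemble_size = model$ensemble_size)
    for (i in seq_len(nrow(manifest))) {
      job <- manifest$job[i]
      tbl <- if (manifest$type[i] == "wt") {
        generate_wt_ensemble(model, ensemble_id = job)
      } else {
        d <- runif(1, 0, 6)
        generate_mutant_ensemble(
          model, mutation_effect(delta = d, kappa = 1 + 0.4 * d^2),
          ensemble_id = job)
      }
      relax_terms <- setdiff(model$terms, rescore_terms())
      relax <- tbl[c("decoy_tag", relax_terms)]
      rescore <- tbl[c("decoy_tag", c("score", rescore_terms()))]
      rescore$decoy_tag <- paste0(rescore$decoy_tag, ".pdb.gz")
      write_scorefile(new_score_table(relax, job),
                      file.path(dir, paste0(job, ".sc")))
      write_scorefile(new_score_table(rescore, job),
                      file.path(dir, paste0(job, "rescore.sc")))
    }
    train <- generate_training_set(n_ts = n_train_ts, n_nonts = n_train_nonts,
                                   model = model,
                                   seed = sample.int(1e6, 1))
    write_feature_matrix(train, file.path(dir, "training.tsv"))
  })
  invisible(dir)
}
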