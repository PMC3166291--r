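#' Amino-acid category schemes for the category-change features
#'
#' Two partitions of the 20 canonical amino acids used by the `aminochange`
#' (four categories) and `aminochange2` (seven categories) features. The
#' category idea (large hydrophobic, polar, charged, ...) is standard; the
#' exact memberships here are the package defaults and can be overridden by
#' passing a modified scheme to [aminochange()].
#'
#' @param name `"aminochange"` or `"aminochange2"`.
#' @return A named list of character vectors partitioning the 20 amino
#'   acids.
#' @export
#' @examples
#' names(amino_category_scheme("aminochange2"))
amino_category_scheme <- function(name = c("aminochange", "aminochange2")) {
  name <- match.arg(name)
  schemes <- list(
    aminochange = list(
      nonpolar = c("A", "V", "L", "I", "M", "F", "W", "Y"),
      polar    = c("S", "T", "N", "Q", "C", "H"),
      charged  = c("D", "E", "K", "R"),
      special  = c("G", "P")
    ),
    aminochange2 = list(
      small_nonpolar    = c("A", "V"),
      large_hydrophobic = c("L", "I", "M", "F", "W", "Y"),
      polar             = c("S", "T", "N", "Q", "C"),
      positive          = c("K", "R", "H"),
      negative          = c("D", "E"),
      glycine           = "G",
      proline           = "P"
    )
  )
  schemes[[name]]
}

validate_category_scheme <- function(scheme) {
  members <- unlist(scheme, use.names = FALSE)
  if (anyDuplicated(members) || !setequal(members, amino_acids())) {
    abort("category scheme must partition the 20 canonical amino acids",
          class = "tsmut_input_error")
  }
  invisible(scheme)
}

#' Category-change code for a substitution
#'
#' Codes how much a substitution changes the residue's chemical category:
#' 0 = same amino acid, 1 = different amino acid within the same category,
#' 2 = change of category.
#'
#' @param native_aa,mutant_aa One-letter codes.
#' @param scheme A category partition, e.g. from [amino_category_scheme()].
#' @return Integer vector in \{0, 1, 2\}.
#' @export
#' @examples
#' aminochange("L", "I", amino_category_scheme("aminochange"))  # 1
#' aminochange("D", "L", amino_category_scheme("aminochange2")) # 2
aminochange <- function(native_aa, mutant_aa,
                        scheme = amino_category_scheme("aminochange")) {
  check_aa(native_aa, "native_aa")
  check_aa(mutant_aa, "mutant_aa")
  validate_category_scheme(scheme)
  cat_of <- function(aa) {
    names(scheme)[vapply(scheme, function(g) aa %in% g, logical(1))]
  }
  purrr::map2_int(native_aa, mutant_aa, function(a, b) {
    if (a == b) return(0L)
    if (identical(cat_of(a), cat_of(b))) 1L else 2L
  })
}

ncbi_aa_order <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

new_pssm <- function(positions, log_odds, frequencies) {
  stopifnot(nrow(positions) == nrow(log_odds),
            nrow(positions) == nrow(frequencies),
            ncol(log_odds) == 20, ncol(frequencies) == 20)
  if (any(positions$info_cont < 0)) {
    abort("information content must be non-negative",
          class = "tsmut_input_error")
  }
  structure(list(positions = positions,
                 log_odds = log_odds,
                 frequencies = frequencies),
            class = "ts_pssm")
}

#' @export
print.ts_pssm <- function(x, ...) {
  cat("<ts_pssm> ", nrow(x$positions), " positions\n", sep = "")
  print(utils::head(x$positions, 5))
  invisible(x)
}

#' Parse an NCBI PSI-BLAST ASCII position-specific scoring matrix
#'
#' Reads the `-out_ascii_pssm` layout: a header line of 40 amino-acid column
#' letters (20 log-odds columns then 20 observed-percentage columns — the
#' order is taken from the file, not assumed), followed by one row per
#' position with the position index, native residue, 40 integers, the
#' per-position information content (bits) and, optionally, the relative
#' gapless match weight.
#'
#' @param path Path to the ASCII PSSM file.
#' @return A `ts_pssm` object: `$positions` (tibble of `position`,
#'   `native_aa`, `info_cont`), `$log_odds` and `$frequencies` (position x 20
#'   matrices with amino-acid column names).
#' @export
parse_pssm <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("PSSM file not found: ", path), class = "tsmut_input_error")
  }
  lines <- readLines(path, warn = FALSE)
  toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  is_header <- vapply(toks, function(t) {
    length(t) == 40 && all(t %in% amino_acids())
  }, logical(1))
  h <- which(is_header)
  if (!length(h)) {
    abort(paste0("no 40-column amino-acid header found in ", path),
          class = "tsmut_format_error")
  }
  lo_order <- toks[[h[1]]][1:20]
  fr_order <- toks[[h[1]]][21:40]
  rows <- list()
  for (i in seq_along(toks)[-seq_len(h[1])]) {
    t <- toks[[i]]
    if (!length(t)) next
    if (is.na(suppressWarnings(as.integer(t[1])))) break  # footer reached
    if (length(t) < 43 || length(t) > 44) {
      abort(paste0("truncated PSSM row at position ", t[1], " (line ", i,
                   "): expected 43-44 fields, got ", length(t)),
            class = "tsmut_format_error")
    }
    rows[[length(rows) + 1L]] <- t
  }
  if (!length(rows)) {
    abort(paste0("no PSSM data rows in ", path), class = "tsmut_format_error")
  }
  pos <- as.integer(vapply(rows, `[`, character(1), 1))
  aa <- vapply(rows, `[`, character(1), 2)
  check_aa(aa, "native_aa")
  num <- t(vapply(rows, function(t) as.numeric(t[3:43]), numeric(41)))
  if (anyNA(num)) {
    abort(paste0("non-numeric PSSM value at position ",
                 pos[which(apply(is.na(num), 1, any))[1]]),
          class = "tsmut_format_error")
  }
  lo <- num[, 1:20, drop = FALSE][, match(ncbi_aa_order(), lo_order),
                                  drop = FALSE]
  fr <- num[, 21:40, drop = FALSE][, match(ncbi_aa_order(), fr_order),
                                   drop = FALSE]
  colnames(lo) <- colnames(fr) <- ncbi_aa_order()
  new_pssm(tibble::tibble(position = pos, native_aa = aa,
                          info_cont = num[, 41]),
           lo, fr)
}

#' Serialize a PSSM in the NCBI ASCII dialect
#'
#' Writes the layout [parse_pssm()] reads, so
#' `parse_pssm(write_pssm(p, f))` reproduces `p`.
#'
#' @param pssm A `ts_pssm` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(pssm, path) {
  aa <- ncbi_aa_order()
  lines <- c(
    "",
    paste("Last position-specific scoring matrix computed, weighted",
          "observed percentages rounded down, information per position,",
          "and relative weight of gapless real matches to pseudocounts"),
    paste0("            ", paste(sprintf("%3s", c(aa, aa)), collapse = " "))
  )
  for (i in seq_len(nrow(pssm$positions))) {
    lines <- c(lines, paste0(
      sprintf("%5d %s ", pssm$positions$position[i],
              pssm$positions$native_aa[i]),
      paste(sprintf("%3d", as.integer(pssm$log_odds[i, ])), collapse = " "),
      "  ",
      paste(sprintf("%3d", as.integer(pssm$frequencies[i, ])), collapse = " "),
      sprintf(" %5.2f %5.2f", pssm$positions$info_cont[i], 0)
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Sequence features for one substitution from a PSSM
#'
#' Looks up the PSI-BLAST log-odds and observed frequencies of the native
#' and substituted residues at the mutated position plus the position's
#' information content. The PSSM's native residue must agree with the spec
#' (guards against off-by-one numbering between structure and sequence).
#'
#' @param pssm A `ts_pssm` object.
#' @param spec One-row mutation-spec tibble (see [enumerate_mutations()]).
#' @return One-row tibble with `pssm_mut`, `pssm_nat`, `pssm_diff`,
#'   `freq_mut`, `freq_nat`, `freq_diff`, `info_cont`.
#' @export
sequence_features <- function(pssm, spec) {
  i <- match(spec$position, pssm$positions$position)
  if (is.na(i)) {
    abort(paste0("position ", spec$position, " absent from PSSM"),
          class = "tsmut_lookup_error")
  }
  if (pssm$positions$native_aa[i] != spec$native_aa) {
    abort(paste0("native residue mismatch at position ", spec$position,
                 ": PSSM has ", pssm$positions$native_aa[i],
                 ", mutation spec has ", spec$native_aa),
          class = "tsmut_consistency_error")
  }
  pm <- unname(pssm$log_odds[i, spec$mutant_aa])
  pn <- unname(pssm$log_odds[i, spec$native_aa])
  fm <- unname(pssm$frequencies[i, spec$mutant_aa])
  fn <- unname(pssm$frequencies[i, spec$native_aa])
  tibble::tibble(pssm_mut = pm, pssm_nat = pn, pssm_diff = pm - pn,
                 freq_mut = fm, freq_nat = fn, freq_diff = fm - fn,
                 info_cont = pssm$positions$info_cont[i])
}

#' Non-Rosetta structure features for one substitution
#'
#' Solvent accessibility in percent (`ACCP`) and one-hot secondary-structure
#' indicators (`ss_H`, `ss_S`, `ss_L`) of the mutated position.
#'
#' @param residues Accessibility tibble as from [read_accessibility()].
#' @param spec One-row mutation-spec tibble.
#' @return One-row tibble with `ACCP`, `ss_H`, `ss_S`, `ss_L`.
#' @export
structure_features <- function(residues, spec) {
  i <- match(spec$position, residues$position)
  if (is.na(i)) {
    abort(paste0("position ", spec$position, " absent from residue table"),
          class = "tsmut_lookup_error")
  }
  ss <- residues$ss[i]
  if (!ss %in% c("H", "S", "L")) {
    abort(paste0("unknown secondary-structure code: ", ss),
          class = "tsmut_input_error")
  }
  tibble::tibble(ACCP = residues$acc_fraction[i] * 100,
                 ss_H = as.numeric(ss == "H"),
                 ss_S = as.numeric(ss == "S"),
                 ss_L = as.numeric(ss == "L"))
}

#' Assemble the full feature row for one candidate mutation
#'
#' Combines the 93 quartile-mapping features of the mutation's relax
#' ensemble against the wild-type ensemble with the category-change,
#' PSSM-derived and structure features — the complete per-sample input of
#' the classifiers (106 features over the standard 31 score terms).
#'
#' @param mutant,wt Score tables for the mutation and the wild type.
#' @param residues Accessibility tibble.
#' @param pssm A `ts_pssm`.
#' @param spec One-row mutation-spec tibble.
#' @param terms Score terms for the quartile features; default
#'   [rosetta_score_terms()].
#' @return One-row feature tibble with a `sample_id` column holding the
#'   mutation id.
#' @export
mutation_features <- function(mutant, wt, residues, pssm, spec,
                              terms = rosetta_score_terms()) {
  dplyr::bind_cols(
    tibble::tibble(sample_id = mutation_id(spec)),
    quartile_features(mutant, wt, terms),
    tibble::tibble(
      aminochange = as.numeric(
        aminochange(spec$native_aa, spec$mutant_aa,
                    amino_category_scheme("aminochange"))),
      aminochange2 = as.numeric(
        aminochange(spec$native_aa, spec$mutant_aa,
                    amino_category_scheme("aminochange2")))
    ),
    sequence_features(pssm, spec),
    structure_features(residues, spec)
  )
}
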