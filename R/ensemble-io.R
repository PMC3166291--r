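#' Score tables and feature matrices
#'
#' A *score table* holds one relax ensemble: one row per decoy (relaxed
#' structure), a `decoy_tag` character column, and one numeric column per
#' score term. The ensemble it describes is recorded in the `ensemble_id`
#' attribute (`"WT"` or a mutation job name such as `"YBR109C-F140A"`).
#'
#' A *feature matrix* is a tibble with a `sample_id` character column, one
#' numeric column per feature, and an optional `class` column with values
#' `"ts"` / `"non-ts"`.
#'
#' @name score-table
NULL

new_score_table <- function(records, ensemble_id = "WT") {
  tbl <- tibble::as_tibble(records)
  validate_score_table(tbl)
  attr(tbl, "ensemble_id") <- ensemble_id
  tbl
}

validate_score_table <- function(tbl) {
  if (!"decoy_tag" %in% names(tbl)) {
    abort("score table must have a `decoy_tag` column",
          class = "tsmut_format_error")
  }
  if (nrow(tbl) < 1) {
    abort("score table must have at least one decoy",
          class = "tsmut_format_error")
  }
  if (anyDuplicated(tbl$decoy_tag)) {
    dups <- unique(tbl$decoy_tag[duplicated(tbl$decoy_tag)])
    abort(paste0("duplicate decoy tag(s): ", paste(dups, collapse = ", ")),
          class = "tsmut_integrity_error")
  }
  terms <- setdiff(names(tbl), "decoy_tag")
  not_num <- terms[!vapply(tbl[terms], is.numeric, logical(1))]
  if (length(not_num)) {
    abort(paste0("non-numeric score term column(s): ",
                 paste(not_num, collapse = ", ")),
          class = "tsmut_format_error")
  }
  invisible(tbl)
}

#' Ensemble identity of a score table
#' @param x A score table.
#' @return Its ensemble id string (`"WT"` or a mutation job name).
#' @export
ensemble_id <- function(x) attr(x, "ensemble_id") %||% "WT"

#' Score-term names of a score table
#' @param x A score table.
#' @return Character vector of score-term column names (everything except
#'   `decoy_tag`).
#' @export
score_term_names <- function(x) setdiff(names(x), "decoy_tag")

#' Read a Rosetta-style score file
#'
#' Parses the whitespace-delimited `"SCORE:"` table dialect written by relax
#' and rescore runs: every payload line starts with the literal token
#' `SCORE:`, the first such line is the header, and the last header column
#' (`description`) carries the decoy tag. Lines without the `SCORE:` prefix
#' (e.g. `SEQUENCE:` banners) and blank lines are ignored.
#'
#' @param path Path to the score file.
#' @param ensemble_id Ensemble identity to record; defaults to the file name
#'   without its `.sc` extension.
#' @return A score table tibble (see [score-table]).
#' @export
#' @examples
#' sc <- generate_wt_ensemble(seed = 1)
#' f <- tempfile(fileext = ".sc")
#' write_scorefile(sc, f)
#' identical(score_term_names(read_scorefile(f)), score_term_names(sc))
read_scorefile <- function(path, ensemble_id = NULL) {
  if (!file.exists(path)) {
    abort(paste0("score file not found: ", path), class = "tsmut_input_error")
  }
  lines <- readLines(path, warn = FALSE)
  is_score <- startsWith(trimws(lines), "SCORE:")
  idx <- which(is_score)
  if (length(idx) < 2) {
    abort(paste0("missing SCORE: header or data lines in ", path),
          class = "tsmut_format_error")
  }
  toks <- lapply(lines[idx], function(l) {
    t <- strsplit(trimws(l), "\\s+")[[1]]
    t[-1]  # drop the SCORE: token
  })
  header <- toks[[1]]
  if (length(header) < 2) {
    abort(paste0("score file header must have at least one term plus a ",
                 "description column: ", path),
          class = "tsmut_format_error")
  }
  terms <- header[-length(header)]
  rows <- toks[-1]
  bad_len <- which(lengths(rows) != length(header))
  if (length(bad_len)) {
    abort(paste0("line ", idx[-1][bad_len[1]], " of ", path, " has ",
                 lengths(rows)[bad_len[1]], " columns, expected ",
                 length(header)),
          class = "tsmut_format_error")
  }
  mat <- do.call(rbind, rows)
  vals <- suppressWarnings(matrix(as.numeric(mat[, -ncol(mat), drop = FALSE]),
                                  nrow = nrow(mat)))
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 1, any))[1]
    abort(paste0("non-numeric score value on line ", idx[-1][bad], " of ",
                 path),
          class = "tsmut_format_error")
  }
  colnames(vals) <- terms
  tbl <- tibble::as_tibble(as.data.frame(vals, check.names = FALSE))
  tbl <- dplyr::bind_cols(tibble::tibble(decoy_tag = mat[, ncol(mat)]), tbl)
  if (is.null(ensemble_id)) {
    ensemble_id <- sub("\\.sc$", "", basename(path))
  }
  new_score_table(tbl, ensemble_id)
}

#' Write a score table in the Rosetta-style score-file dialect
#'
#' Numbers are serialized with 17 significant digits so that
#' `read_scorefile(write_scorefile(x))` reproduces `x` exactly.
#'
#' @param x A score table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scorefile <- function(x, path) {
  validate_score_table(x)
  terms <- score_term_names(x)
  header <- paste(c("SCORE:", terms, "description"), collapse = " ")
  vals <- vapply(x[terms],
                 function(col) formatC(col, digits = 17, format = "g"),
                 character(nrow(x)))
  vals <- matrix(vals, nrow = nrow(x))
  body <- apply(cbind("SCORE:", vals, x$decoy_tag), 1, paste, collapse = " ")
  writeLines(c(header, body), path)
  invisible(path)
}

# decoy-tag normalization used to match relax output names against rescore
# output names (the two passes suffix decoys differently)
normalize_decoy_tag <- function(tag) {
  tag <- tolower(tag)
  tag <- sub("\\.gz$", "", tag)
  sub("\\.pdb$", "", tag)
}

#' Merge relax and rescore tables for one ensemble
#'
#' A relax run and its rescore pass write separate score files for the same
#' decoys. This joins them per decoy (tags are matched after lower-casing and
#' stripping `.pdb`/`.gz` suffixes) into one table holding the union of
#' terms. On a term-name collision the rescore value wins, since the rescore
#' pass recomputes structural-comparison terms against the native structure.
#'
#' @param relax,rescore Score tables for the same ensemble.
#' @return A merged score table with the relax table's decoy tags and
#'   ensemble id.
#' @export
merge_relax_rescore <- function(relax, rescore) {
  validate_score_table(relax)
  validate_score_table(rescore)
  key_relax <- normalize_decoy_tag(relax$decoy_tag)
  key_rescore <- normalize_decoy_tag(rescore$decoy_tag)
  orphans <- c(setdiff(key_relax, key_rescore),
               setdiff(key_rescore, key_relax))
  if (length(orphans)) {
    abort(paste0("decoys present in only one table: ",
                 paste(sort(orphans), collapse = ", ")),
          class = "tsmut_integrity_error")
  }
  res <- rescore[match(key_relax, key_rescore), , drop = FALSE]
  out <- relax
  for (term in setdiff(names(rescore), "decoy_tag")) {
    out[[term]] <- res[[term]]
  }
  new_score_table(out, ensemble_id(relax))
}

reserved_feature_cols <- c("sample_id", "class")

#' Feature-name columns of a feature matrix
#' @param m A feature matrix tibble.
#' @return Character vector of feature column names (everything except
#'   `sample_id` and `class`).
#' @export
feature_names <- function(m) setdiff(names(m), reserved_feature_cols)

validate_feature_matrix <- function(m) {
  if (!"sample_id" %in% names(m)) {
    abort("feature matrix must have a `sample_id` column",
          class = "tsmut_format_error")
  }
  if (anyDuplicated(names(m))) {
    abort(paste0("duplicate feature name(s): ",
                 paste(unique(names(m)[duplicated(names(m))]), collapse = ", ")),
          class = "tsmut_format_error")
  }
  if (anyDuplicated(m$sample_id)) {
    abort("duplicate sample_id values", class = "tsmut_integrity_error")
  }
  feats <- feature_names(m)
  if (anyNA(m[c("sample_id", feats)])) {
    abort("feature matrix has missing cells", class = "tsmut_integrity_error")
  }
  if ("class" %in% names(m) && !all(m$class %in% c("ts", "non-ts"))) {
    abort('`class` values must be "ts" or "non-ts"',
          class = "tsmut_format_error")
  }
  invisible(m)
}

#' Read / write a labelled feature matrix
#'
#' Tab-delimited text with one header row; the label column, when present, is
#' named `class` with values `"ts"` / `"non-ts"`. Numbers round-trip at full
#' double precision, so `read_feature_matrix(write_feature_matrix(m))`
#' reproduces `m` exactly.
#'
#' @param m Feature matrix tibble (see [score-table]).
#' @param path File path.
#' @return `write_feature_matrix()` returns `path` invisibly;
#'   `read_feature_matrix()` returns the feature matrix tibble.
#' @export
write_feature_matrix <- function(m, path) {
  validate_feature_matrix(m)
  ord <- c("sample_id", feature_names(m),
           intersect("class", names(m)))
  m <- m[ord]
  cols <- lapply(m, function(col) {
    if (is.numeric(col)) formatC(col, digits = 17, format = "g") else col
  })
  body <- do.call(paste, c(cols, sep = "\t"))
  writeLines(c(paste(ord, collapse = "\t"), body), path)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("feature matrix file not found: ", path),
          class = "tsmut_input_error")
  }
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header)) {
    abort(paste0("duplicate column name(s) in ", path, ": ",
                 paste(unique(header[duplicated(header)]), collapse = ", ")),
          class = "tsmut_format_error")
  }
  classes <- ifelse(header %in% reserved_feature_cols, "character",
                    "numeric")
  # base read.delim parses doubles with strtod, which is correctly rounded,
  # so write -> read is an exact identity
  m <- tibble::as_tibble(utils::read.delim(
    path, header = TRUE, sep = "\t", check.names = FALSE,
    colClasses = classes, stringsAsFactors = FALSE))
  validate_feature_matrix(m)
  m
}
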