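#' Read a per-residue accessibility / secondary-structure table
#'
#' Tab-delimited with columns `position` (1-based residue index, PDB
#' numbering preserved), `aa` (one-letter code), `acc_fraction` (relative
#' side-chain solvent accessibility in \[0, 1\]) and `ss` (secondary
#' structure: `H` helix, `S` sheet, `L` loop).
#'
#' @param path Path to the table.
#' @return A tibble with the four columns above.
#' @export
read_accessibility <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("accessibility table not found: ", path),
          class = "tsmut_input_error")
  }
  res <- readr::read_tsv(path, col_types = readr::cols(
    position = readr::col_integer(),
    aa = readr::col_character(),
    acc_fraction = readr::col_double(),
    ss = readr::col_character()
  ), progress = FALSE)
  validate_accessibility(res)
  res
}

validate_accessibility <- function(res) {
  need <- c("position", "aa", "acc_fraction", "ss")
  missing <- setdiff(need, names(res))
  if (length(missing)) {
    abort(paste0("accessibility table lacks column(s): ",
                 paste(missing, collapse = ", ")),
          class = "tsmut_format_error")
  }
  check_aa(res$aa, "aa")
  if (any(res$acc_fraction < 0 | res$acc_fraction > 1)) {
    abort("acc_fraction must lie in [0, 1]", class = "tsmut_input_error")
  }
  if (!all(res$ss %in% c("H", "S", "L"))) {
    abort("ss codes must be H, S or L", class = "tsmut_input_error")
  }
  if (anyDuplicated(res$position)) {
    abort("duplicate residue positions", class = "tsmut_integrity_error")
  }
  invisible(res)
}

#' Select buried candidate positions
#'
#' Mutations are proposed only at buried sites, where destabilization is most
#' likely to perturb overall protein function rather than a single surface
#' interaction. A site qualifies when its relative side-chain solvent
#' accessibility is at or below the cutoff (10% by default); the comparison
#' is inclusive, controllable via `inclusive` for the strict reading.
#'
#' @param residues Accessibility tibble as from [read_accessibility()].
#' @param cutoff Accessibility cutoff as a fraction in \[0, 1\]; default 0.10.
#' @param inclusive Include sites exactly at the cutoff? Default `TRUE`.
#' @return Integer vector of qualifying positions, ascending.
#' @export
select_buried_sites <- function(residues, cutoff = 0.10, inclusive = TRUE) {
  validate_accessibility(residues)
  if (cutoff < 0 || cutoff > 1) {
    abort("`cutoff` must be a fraction in [0, 1]", class = "tsmut_input_error")
  }
  keep <- if (inclusive) residues$acc_fraction <= cutoff
          else residues$acc_fraction < cutoff
  sort(residues$position[keep])
}

#' Enumerate candidate substitutions at buried sites
#'
#' For each buried position, emits the 19 substitutions to every canonical
#' amino acid other than the native residue.
#'
#' @param protein Protein name (e.g. `"YBR109C"`).
#' @param species Species tag (e.g. `"Scer"`).
#' @param buried Integer vector of buried positions.
#' @param residues Accessibility tibble providing the native residue at each
#'   position.
#' @return A tibble of mutation specs with columns `protein`, `species`,
#'   `position`, `native_aa`, `mutant_aa`, ordered by position then mutant
#'   residue.
#' @export
#' @examples
#' res <- tibble::tibble(position = c(3L, 9L), aa = c("F", "L"),
#'                       acc_fraction = c(0.02, 0.05), ss = c("H", "L"))
#' nrow(enumerate_mutations("TOY1", "Scer", c(3L, 9L), res))
enumerate_mutations <- function(protein, species, buried, residues) {
  validate_accessibility(residues)
  missing <- setdiff(buried, residues$position)
  if (length(missing)) {
    abort(paste0("position(s) absent from residue table: ",
                 paste(missing, collapse = ", ")),
          class = "tsmut_lookup_error")
  }
  if (!length(buried)) {
    return(tibble::tibble(protein = character(), species = character(),
                          position = integer(), native_aa = character(),
                          mutant_aa = character()))
  }
  native <- residues$aa[match(sort(buried), residues$position)]
  tidyr::crossing(
    tibble::tibble(position = as.integer(sort(buried)), native_aa = native),
    mutant_aa = amino_acids()
  ) |>
    dplyr::filter(.data$mutant_aa != .data$native_aa) |>
    dplyr::arrange(.data$position, .data$mutant_aa) |>
    dplyr::mutate(protein = protein, species = species, .before = 1)
}

# job name for one mutation: {protein}-{a}{NNN}{b}, unpadded position
mutation_job_name <- function(specs) {
  paste0(specs$protein, "-", specs$native_aa, specs$position, specs$mutant_aa)
}

#' Ranked-prediction mutation identifier
#'
#' Formats `{protein}-{a}{NNN}_{MUT3}_{species}` with `a` the one-letter
#' native code, `NNN` the unpadded position, and `MUT3` the uppercase
#' three-letter code of the substituted residue, e.g.
#' `"YBR109C-F140_GLY_Scer"`.
#'
#' @param specs Mutation-spec tibble as from [enumerate_mutations()].
#' @return Character vector of mutation ids.
#' @export
mutation_id <- function(specs) {
  paste0(specs$protein, "-", specs$native_aa, specs$position, "_",
         aa_three_letter(specs$mutant_aa), "_", specs$species)
}

relax_cmd_template <- function(job, protein, ensemble_size) {
  paste0("relax.linuxgccrelease -database $MINI_DB -s ", job,
         ".pdb -native ", protein, ".pdb -nstruct ", ensemble_size,
         " -relax:fast -out:file:scorefile ", job, ".sc -out:pdb_gz")
}

rescore_cmd_template <- function(job, protein) {
  paste0("score.linuxgccrelease -database $MINI_DB -s ", job,
         "_????.pdb.gz -in:file:native ", protein,
         ".pdb -in:file:fullatom -out:file:scorefile ", job, "rescore.sc")
}

#' Build the run manifest for a protein
#'
#' One job for the wild-type structure (`{protein}-WT`) plus one per
#' candidate substitution (`{protein}-{a}{NNN}{b}`); each entry records the
#' relax command (ensemble of `ensemble_size` decoys) and the rescore
#' command that together produce the score files the prediction stage
#' consumes. With `n` buried sites the manifest has `19 n + 1` entries.
#'
#' @param protein,species Protein name and species tag.
#' @param specs Mutation-spec tibble from [enumerate_mutations()].
#' @param ensemble_size Decoys per relax run; default 50.
#' @return A tibble with columns `job`, `type` (`"wt"`/`"mutation"`),
#'   `position`, `native_aa`, `mutant_aa`, `relax_cmd`, `rescore_cmd`.
#' @export
build_run_manifest <- function(protein, species, specs, ensemble_size = 50) {
  wt_job <- paste0(protein, "-WT")
  jobs <- c(wt_job, if (nrow(specs)) mutation_job_name(specs))
  if (anyDuplicated(jobs)) {
    abort(paste0("duplicate job name(s): ",
                 paste(unique(jobs[duplicated(jobs)]), collapse = ", ")),
          class = "tsmut_integrity_error")
  }
  tibble::tibble(
    job = jobs,
    type = c("wt", rep("mutation", nrow(specs))),
    position = c(NA_integer_, specs$position),
    native_aa = c(NA_character_, specs$native_aa),
    mutant_aa = c(NA_character_, specs$mutant_aa),
    relax_cmd = vapply(jobs, relax_cmd_template, character(1),
                       protein = protein, ensemble_size = ensemble_size),
    rescore_cmd = vapply(jobs, rescore_cmd_template, character(1),
                         protein = protein)
  )
}

#' Write a run manifest and per-job shell stubs
#'
#' @param manifest Manifest tibble from [build_run_manifest()].
#' @param dir Output directory.
#' @param stubs Also write one executable `.sh` stub per job? Default `TRUE`.
#' @param force Overwrite an existing manifest? Default `FALSE`.
#' @return The manifest file path, invisibly.
#' @export
write_run_manifest <- function(manifest, dir, stubs = TRUE, force = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, "manifest.tsv")
  if (file.exists(path) && !force) {
    abort(paste0(path, " exists; use force = TRUE to overwrite"),
          class = "tsmut_overwrite_error")
  }
  readr::write_tsv(manifest, path, progress = FALSE)
  if (stubs) {
    for (i in seq_len(nrow(manifest))) {
      stub <- file.path(dir, paste0(manifest$job[i], ".sh"))
      writeLines(c("#!/bin/sh", manifest$relax_cmd[i], manifest$rescore_cmd[i]),
                 stub)
      Sys.chmod(stub, "755")
    }
  }
  invisible(path)
}
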