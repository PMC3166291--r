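#' Rosetta score terms tracked per decoy
#'
#' The 31 per-decoy score terms a relax + rescore run pair produces: the
#' weighted total score, its energy components (Lennard-Jones, solvation,
#' hydrogen bonding, disulfide geometry, backbone-torsion statistics, rotamer
#' self-energy, reference energies), repack-trajectory summaries, and
#' structural-similarity terms (gdtmm/maxsub fractions, RMS deviations) from
#' the rescore pass. Each term yields three quartile-mapping features, named
#' `<term>Q1`, `<term>Q2`, `<term>Q3` (93 features in all).
#'
#' @return Character vector of 31 score-term names.
#' @export
#' @examples
#' length(rosetta_score_terms())
rosetta_score_terms <- function() {
  c(
    "score", "fa_atr", "fa_rep", "fa_sol", "fa_intra_rep", "pro_close",
    "fa_pair", "hbond_sr_bb", "hbond_lr_bb", "hbond_bb_sc", "hbond_sc",
    "dslf_ss_dst", "dslf_cs_ang", "dslf_ss_dih", "dslf_ca_dih", "rama",
    "omega", "fa_dun", "p_aa_pp", "ref", "Repack_average_score",
    "Repack_stdev_score", "gdtmm1_1", "gdtmm2_2", "gdtmm3_3", "gdtmm4_3",
    "gdtmm7_4", "irms", "maxsub", "maxsub2.0", "rms"
  )
}

# terms whose values come from the rescore (structure-comparison) pass rather
# than the relax pass; on a term-name collision during merge the rescore wins
rescore_terms <- function() {
  c(
    "gdtmm1_1", "gdtmm2_2", "gdtmm3_3", "gdtmm4_3", "gdtmm7_4",
    "irms", "maxsub", "maxsub2.0", "rms"
  )
}

#' Canonical amino-acid codes
#'
#' @return Character vector of the 20 one-letter canonical amino-acid codes,
#'   in alphabetical order.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# one- to three-letter amino-acid code map (uppercase, as printed in ranked
# prediction ids)
aa_three_letter <- function(aa) {
  map <- c(
    A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
    E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
    M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
    Y = "TYR", V = "VAL"
  )
  out <- unname(map[aa])
  if (anyNA(out)) {
    abort(paste0("non-canonical amino-acid code: ",
                 paste(aa[is.na(out)], collapse = ", ")),
          class = "tsmut_input_error")
  }
  out
}

check_aa <- function(aa, arg = "aa") {
  bad <- !(aa %in% amino_acids())
  if (any(bad)) {
    abort(paste0("`", arg, "` contains non-canonical amino-acid code(s): ",
                 paste(unique(aa[bad]), collapse = ", ")),
          class = "tsmut_input_error")
  }
  invisible(aa)
}
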