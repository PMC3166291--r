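test_that("aminochange codes same-residue, same-class and cross-class", {
  four <- amino_category_scheme("aminochange")
  seven <- amino_category_scheme("aminochange2")
  expect_equal(aminochange("F", "F", four), 0L)
  expect_equal(aminochange("L", "I", four), 1L)
  expect_equal(aminochange("L", "I", seven), 1L)
  expect_equal(aminochange("D", "L", four), 2L)
  expect_equal(aminochange("D", "L", seven), 2L)
  expect_error(aminochange("X", "A", four), class = "tsmut_input_error")
  expect_error(validate_category_scheme(list(a = c("A", "A"))),
               class = "tsmut_input_error")
})

test_that("the cross-class decision is symmetric", {
  withr::with_seed(9, {
    for (scheme in list(amino_category_scheme("aminochange"),
                        amino_category_scheme("aminochange2"))) {
      for (i in 1:40) {
        pair <- sample(amino_acids(), 2)
        expect_equal(aminochange(pair[1], pair[2], scheme) == 2L,
                     aminochange(pair[2], pair[1], scheme) == 2L)
      }
    }
  })
})

test_that("parse_pssm reads the ASCII layout regardless of column order", {
  seqaa <- c("M", "F", "L", "K", "S")
  p <- generate_pssm(seqaa, conservation = 0.6, seed = 31)
  f <- withr::local_tempfile(fileext = ".pssm")
  write_pssm(p, f)
  back <- parse_pssm(f)
  expect_equal(nrow(back$positions), 5)
  expect_equal(dim(back$log_odds), c(5, 20))
  expect_equal(dim(back$frequencies), c(5, 20))
  expect_equal(back$positions, p$positions)
  expect_identical(back$log_odds, p$log_odds)
  expect_identical(back$frequencies, p$frequencies)

  # permute the serialized column order; parsed content must be unchanged
  withr::with_seed(32, {
    perm_lo <- sample(20)
    perm_fr <- sample(20)
  })
  aa <- colnames(p$log_odds)
  header <- paste0("            ",
                   paste(sprintf("%3s", c(aa[perm_lo], aa[perm_fr])),
                         collapse = " "))
  rows <- vapply(seq_len(5), function(i) {
    paste0(sprintf("%5d %s ", i, seqaa[i]),
           paste(sprintf("%3d", p$log_odds[i, perm_lo]), collapse = " "), "  ",
           paste(sprintf("%3d", p$frequencies[i, perm_fr]), collapse = " "),
           sprintf(" %5.2f %5.2f", p$positions$info_cont[i], 0))
  }, character(1))
  f2 <- withr::local_tempfile(fileext = ".pssm")
  writeLines(c("", "header", header, rows), f2)
  permuted <- parse_pssm(f2)
  expect_identical(permuted$log_odds, p$log_odds)
  expect_identical(permuted$frequencies, p$frequencies)
  expect_equal(permuted$positions, p$positions)

  # rows lacking the information-content column are a format error
  short <- vapply(seq_len(5), function(i) {
    paste0(sprintf("%5d %s ", i, seqaa[i]),
           paste(sprintf("%3d", p$log_odds[i, ]), collapse = " "), "  ",
           paste(sprintf("%3d", p$frequencies[i, ]), collapse = " "))
  }, character(1))
  writeLines(c("", "header", header, short), f2)
  expect_error(parse_pssm(f2), class = "tsmut_format_error")
})

test_that("sequence features are direct PSSM lookups", {
  withr::with_seed(33, {
    for (i in 1:10) {
      seqaa <- sample(amino_acids(), 8, replace = TRUE)
      p <- generate_pssm(seqaa, conservation = runif(1, 0.1, 0.9))
      pos <- sample(8, 1)
      mut <- sample(setdiff(amino_acids(), seqaa[pos]), 1)
      spec <- tibble::tibble(protein = "P", species = "Scer",
                             position = pos, native_aa = seqaa[pos],
                             mutant_aa = mut)
      sf <- sequence_features(p, spec)
      expect_equal(sf$pssm_mut, unname(p$log_odds[pos, mut]))
      expect_equal(sf$pssm_nat, unname(p$log_odds[pos, seqaa[pos]]))
      expect_equal(sf$pssm_diff, sf$pssm_mut - sf$pssm_nat)
      expect_equal(sf$freq_diff, sf$freq_mut - sf$freq_nat)
      expect_equal(sf$info_cont, p$positions$info_cont[pos])
    }
  })
})

test_that("a native-residue mismatch is a consistency error", {
  p <- generate_pssm(c("A", "C", "D"), seed = 34)
  spec <- tibble::tibble(protein = "P", species = "Scer", position = 2L,
                         native_aa = "W", mutant_aa = "G")
  expect_error(sequence_features(p, spec), class = "tsmut_consistency_error")
  spec$position <- 99L
  expect_error(sequence_features(p, spec), class = "tsmut_lookup_error")
})

test_that("structure features expose percent accessibility and one-hot ss", {
  res <- tibble::tibble(position = 1:3, aa = c("F", "L", "V"),
                        acc_fraction = c(0.07, 0.5, 0.2),
                        ss = c("H", "L", "S"))
  spec <- tibble::tibble(protein = "P", species = "Scer", position = 1L,
                         native_aa = "F", mutant_aa = "A")
  sf <- structure_features(res, spec)
  expect_equal(sf, tibble::tibble(ACCP = 7, ss_H = 1, ss_S = 0, ss_L = 0))
  for (pos in 1:3) {
    spec$position <- pos
    got <- structure_features(res, spec)
    expect_equal(got$ss_H + got$ss_S + got$ss_L, 1)
  }
  res$ss[1] <- "X"
  spec$position <- 1L
  expect_error(structure_features(res, spec), class = "tsmut_input_error")
})
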