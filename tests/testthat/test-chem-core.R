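# Residue-level mass chemistry: residue masses, neutral masses, sodiated
# adducts and the b/y fragment series.

test_that("residue masses match atomic-mass sums and the ladder block", {
  expect_equal(residue_mass("Aib"), 85.0528, tolerance = 1e-4)
  expect_equal(residue_mass("Gly"), 57.0215, tolerance = 1e-4)
  # the Gln-Aib block that survives ESI fragmentation: nominal 213
  block <- sum(residue_mass(c("Gln", "Aib")))
  expect_equal(block, 213.111, tolerance = 1e-3)
  expect_equal(round(block), 213)
  # library self-consistency: mono mass equals the formula sum to 1e-4
  lib <- residue_library()
  expect_equal(lib$mono_mass, formula_mass(lib$formula), tolerance = 1e-4)
  # alcohol residues carry the reduced carboxyl: parent - O + 2H
  expect_equal(residue_mass("Leuol"), residue_mass("Leu") - 13.979265, tolerance = 1e-5)
  expect_error(residue_mass("Xyz"), class = "peptaibio_unknown_residue")
})

test_that("iso-classes are isobaric and flagged correctly", {
  lib <- residue_library()
  for (cls in c("Lxx", "Vxx", "Lxxol")) {
    members <- lib$code[lib$iso_class == cls]
    expect_true(length(members) >= 3)  # two members plus the class token
    expect_equal(length(unique(lib[members, "formula"])), 1L)
  }
  expect_identical(iso_class(c("Leu", "Ile", "Val", "Iva", "Leuol", "Ala")),
                   c("Lxx", "Lxx", "Vxx", "Vxx", "Lxxol", "Ala"))
  expect_true(all(grepl("ol$", lib$code[lib$terminal_only])))
})

test_that("neutral mass matches the elemental-composition oracle", {
  seq <- parse_peptaibol(TKV)
  # full-molecule composition from free amino acids: C87 H152 N22 O24
  comp <- oracle_composition(seq$residues)
  expect_equal(comp[["C"]], 87)
  expect_equal(comp[["H"]], 152)
  expect_equal(comp[["N"]], 22)
  expect_equal(comp[["O"]], 24)
  expect_equal(neutral_mass(seq), 1889.135, tolerance = 1e-3)
  expect_equal(neutral_mass(seq), oracle_neutral_mass(seq$residues), tolerance = 1e-6)
  # printed observed M of the matching compound (isotope-apex reading)
  expect_lt(abs(neutral_mass(seq) - 1889.3), 0.25)
  # single free glycine
  expect_equal(neutral_mass(peptaibol_sequence("Gly", "H")), 75.032, tolerance = 1e-3)
  expect_error(peptaibol_sequence(character(0)), class = "peptaibio_invalid_sequence")
})

test_that("neutral mass agrees with the oracle on random sequences", {
  set.seed(11)
  for (s in random_sequences(100)) {
    expect_equal(neutral_mass(s), oracle_neutral_mass(s$residues), tolerance = 1e-3)
  }
})

test_that("neutral mass is a composition property (permutation-invariant)", {
  set.seed(12)
  for (s in random_sequences(20)) {
    n <- length(s$residues)
    perm <- c(sample(seq_len(n - 1L)), n)  # keep the alcohol terminal
    s2 <- peptaibol_sequence(s$residues[perm], s$n_cap)
    expect_equal(neutral_mass(s2), neutral_mass(s), tolerance = 1e-9)
  }
})

test_that("isobaric swaps never change a mass", {
  seq <- parse_peptaibol(TKV)
  swapped <- seq$residues
  swapped[swapped == "Ile"] <- "Leu"
  swapped[swapped == "Val"] <- "Iva"
  swapped[swapped == "Leuol"] <- "Ileol"
  s2 <- peptaibol_sequence(swapped, "Ac")
  expect_equal(neutral_mass(s2), neutral_mass(seq), tolerance = 1e-6)
  n <- length(seq$residues)
  expect_equal(b_ion_mz(s2, 1:(n - 1)), b_ion_mz(seq, 1:(n - 1)), tolerance = 1e-6)
  expect_equal(y_ion_mz(s2, 1:n), y_ion_mz(seq, 1:n), tolerance = 1e-6)
})

test_that("sodiated adducts follow the cation arithmetic", {
  expect_equal(adduct_mz(1000, "M+2Na"), 522.989, tolerance = 1e-3)
  expect_error(adduct_mz(0), class = "peptaibio_domain_error")
  expect_error(adduct_mz(-5, "M+2Na"), class = "peptaibio_domain_error")
  # printed-table consistency: [M+2Na]2+ from [M+Na]+
  expect_equal((1913.2 + 22.98922) / 2, 968.1, tolerance = 0.01)
})

test_that("b ladder is additive and matches a prefix-sum oracle", {
  seq <- parse_peptaibol(TKV)
  expect_equal(b_ion_mz(seq, 2) - b_ion_mz(seq, 1), residue_mass(seq$residues[2]),
               tolerance = 1e-9)
  # b12 against the printed observed value
  expect_lt(abs(b_ion_mz(seq, 12) - 1122.5), 0.25)
  set.seed(13)
  for (s in random_sequences(10, min_len = 19, max_len = 19)) {
    n <- length(s$residues)
    oracle <- cumsum(oracle_residue_mass(s$residues))[1:(n - 1)] +
      42.010565 + 1.007276
    expect_equal(b_ion_mz(s, 1:(n - 1)), unname(oracle), tolerance = 1e-3)
  }
  expect_error(b_ion_mz(seq, 19), class = "peptaibio_index_error")
  expect_error(b_ion_mz(seq, 0), class = "peptaibio_index_error")
})

test_that("y ions match the MS2-selected variants and the Gln/Glu shift", {
  # the four canonical y7 families of the 19-residue scaffold
  y_of <- function(r16, r18) {
    y_ion_mz(peptaibol_sequence(c("Pro", "Val", "Aib", r16, "Gln", r18, "Leuol"), "H"), 7)
  }
  expect_equal(y_of("Leu", "Gln"), 768.50, tolerance = 0.005)
  expect_equal(y_of("Val", "Gln"), 754.48, tolerance = 0.005)
  expect_equal(y_of("Val", "Glu") - y_of("Val", "Gln"), 0.984, tolerance = 1e-3)
  expect_error(y_ion_mz(parse_peptaibol(TKV), 20), class = "peptaibio_index_error")
})

test_that("b/y complementarity holds for every split", {
  set.seed(14)
  for (s in c(list(parse_peptaibol(TKV)), random_sequences(10))) {
    n <- length(s$residues)
    M <- neutral_mass(s)
    for (k in 1:(n - 1)) {
      expect_equal(b_ion_mz(s, n - k) + y_ion_mz(s, k) - M, 2.01456, tolerance = 1e-3)
    }
  }
})

test_that("characteristic ions assemble into a consistent record", {
  rec <- characteristic_ions(TKV)
  expect_s3_class(rec, "mass_record")
  expect_equal((rec$m_na + 22.98922) / 2, rec$m_2na, tolerance = 0.01)
  expect_gt(rec$b12, 0)
  expect_gt(rec$y7, 0)
  short <- characteristic_ions(peptaibol_sequence(c("Aib", "Gly", "Leuol")))
  expect_true(is.na(short$b12))
})

test_that("sequence notation round-trips and validates", {
  s <- parse_peptaibol(TKV)
  expect_identical(format(s), TKV)
  expect_identical(format(parse_peptaibol(format(s))), TKV)
  # fused AcAib style heading
  s2 <- parse_peptaibol("AcAib-Gly-Ala")
  expect_identical(s2$n_cap, "Ac")
  expect_identical(s2$residues[1], "Aib")
  expect_error(parse_peptaibol("Ac-Aib-Leuol-Gly"), class = "peptaibio_invalid_sequence")
  cls <- as_iso_class(s)
  expect_identical(cls$residues[5], "Lxx")
  expect_identical(cls$residues[14], "Vxx")
})

test_that("residue library TSV round-trips and extends", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_residue_library(tmp)
  before <- residue_library()
  # re-loading the identical library is a no-op on masses
  load_residue_library(tmp)
  expect_equal(residue_library()$mono_mass, before$mono_mass)
  # extension with a custom residue
  ext <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("code\tformula\tiso_class", "Hyp\tC5H7NO2\tHyp"), ext)
  load_residue_library(ext)
  expect_equal(residue_mass("Hyp"), formula_mass("C5H7NO2"), tolerance = 1e-6)
  # restore the pristine library for later tests
  assign("table", NULL, envir = peptaibio:::.residue_env)
  expect_error(residue_mass("Hyp"), class = "peptaibio_unknown_residue")
})
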