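# Independent oracles used across the test files. These deliberately avoid
# the package's residue library and mass routines: masses come from a local
# atomic-mass table applied to free amino-acid formulas, peptide composition
# from the chemistry of condensation (n residues lose n-1 waters; acetylation
# adds C2H2O; the 1,2-amino alcohol replaces the carboxyl O with 2 H).

TKV <- "Ac-Aib-Gly-Ala-Aib-Ile-Gln-Aib-Aib-Aib-Ser-Leu-Aib-Pro-Val-Aib-Ile-Gln-Gln-Leuol"

.orc_atomic <- c(C = 12.0, H = 1.007825, N = 14.003074, O = 15.994915, S = 31.972071)

# free amino acid / amino alcohol compositions (element counts)
.orc_free <- list(
  Gly = c(C = 2, H = 5, N = 1, O = 2),   Ala = c(C = 3, H = 7, N = 1, O = 2),
  Ser = c(C = 3, H = 7, N = 1, O = 3),   Pro = c(C = 5, H = 9, N = 1, O = 2),
  Val = c(C = 5, H = 11, N = 1, O = 2),  Thr = c(C = 4, H = 9, N = 1, O = 3),
  Leu = c(C = 6, H = 13, N = 1, O = 2),  Ile = c(C = 6, H = 13, N = 1, O = 2),
  Asn = c(C = 4, H = 8, N = 2, O = 3),   Asp = c(C = 4, H = 7, N = 1, O = 4),
  Gln = c(C = 5, H = 10, N = 2, O = 3),  Glu = c(C = 5, H = 9, N = 1, O = 4),
  Phe = c(C = 9, H = 11, N = 1, O = 2),  Tyr = c(C = 9, H = 11, N = 1, O = 3),
  Trp = c(C = 11, H = 12, N = 2, O = 2), Aib = c(C = 4, H = 9, N = 1, O = 2),
  Iva = c(C = 5, H = 11, N = 1, O = 2),
  Lxx = c(C = 6, H = 13, N = 1, O = 2),  Vxx = c(C = 5, H = 11, N = 1, O = 2),
  Leuol = c(C = 6, H = 15, N = 1, O = 1), Ileol = c(C = 6, H = 15, N = 1, O = 1),
  Lxxol = c(C = 6, H = 15, N = 1, O = 1), Pheol = c(C = 9, H = 13, N = 1, O = 1),
  Trpol = c(C = 11, H = 14, N = 2, O = 1)
)

.orc_add <- function(a, b) {
  els <- union(names(a), names(b))
  av <- stats::setNames(numeric(length(els)), els)
  av[names(a)] <- a
  av[names(b)] <- av[names(b)] + b
  av
}

# elemental composition of a capped peptaibol from its token vector
oracle_composition <- function(tokens, n_cap = "Ac") {
  comp <- Reduce(.orc_add, .orc_free[tokens])
  comp["H"] <- comp["H"] - 2 * (length(tokens) - 1)   # n-1 condensations
  comp["O"] <- comp["O"] - (length(tokens) - 1)
  if (n_cap == "Ac") {
    comp["C"] <- comp["C"] + 2
    comp["H"] <- comp["H"] + 2
    comp["O"] <- comp["O"] + 1
  }
  comp
}

oracle_neutral_mass <- function(tokens, n_cap = "Ac") {
  comp <- oracle_composition(tokens, n_cap)
  sum(comp * .orc_atomic[names(comp)])
}

# oracle residue masses (free amino acid minus water), for ladder prefix sums
oracle_residue_mass <- function(tok) {
  vapply(tok, function(t) {
    comp <- .orc_free[[t]]
    sum(comp * .orc_atomic[names(comp)]) - (2 * 1.007825 + 15.994915)
  }, numeric(1))
}

# random class-token peptaibol sequences for property tests
random_sequences <- function(n, min_len = 5, max_len = 19) {
  interior <- c("Gly", "Ala", "Ser", "Pro", "Vxx", "Lxx", "Gln", "Glu",
                "Aib", "Thr", "Phe")
  lapply(seq_len(n), function(i) {
    len <- if (min_len == max_len) min_len else sample(min_len:max_len, 1)
    toks <- c(sample(interior, len - 1, replace = TRUE), "Lxxol")
    peptaibol_sequence(toks, "Ac")
  })
}

table_sequences <- function(tab = peptaibol_tables()) {
  lapply(seq_len(nrow(tab)), function(i) table_row_sequence(tab[i, ]))
}
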