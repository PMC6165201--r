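# Neutral masses, sodiated adducts and the acetyl-capped b / amino-alcohol y
# fragment series that make up the characteristic ions of peptaibols:
# [M+Na]+, [M+2Na]2+, b12 and y7.

#' Neutral (uncharged) mass of a peptaibol
#'
#' Sum of residue masses plus the terminal water, plus the acetyl cap when
#' present. Amino-alcohol C-termini are handled through the residue library
#' (the alcohol residue mass already carries the -O +2H reduction).
#'
#' @param seq a `peptaibol_sequence` or a token string parseable by
#'   [parse_peptaibol()].
#' @param kind `"monoisotopic"` or `"average"`.
#' @return neutral mass in Da.
#' @examples
#' neutral_mass("Ac-Aib-Gly-Ala-Aib-Leuol")
#' @export
neutral_mass <- function(seq, kind = c("monoisotopic", "average")) {
  kind <- .match_kind(kind)
  seq <- .as_sequence(seq)
  m <- sum(residue_mass(seq$residues, kind)) + MASS_WATER[[kind]]
  if (seq$n_cap == "Ac") m <- m + MASS_ACETYL[[kind]]
  m
}

#' Sodiated adduct m/z
#'
#' `[M+Na]+ = M + 22.98922`; `[M+2Na]2+ = (M + 2 x 22.98922) / 2`. The sodium
#' cation mass is atomic Na minus one electron.
#'
#' @param M neutral mass in Da (> 0).
#' @param adduct `"M+Na"` or `"M+2Na"`.
#' @return m/z of the adduct ion.
#' @export
adduct_mz <- function(M, adduct = c("M+Na", "M+2Na")) {
  adduct <- match.arg(adduct)
  if (any(!is.finite(M)) || any(M <= 0)) {
    stop(errorCondition("neutral mass must be positive",
                        class = c("peptaibio_domain_error", "error", "condition")))
  }
  switch(adduct,
         "M+Na" = M + NA_CATION,
         "M+2Na" = (M + 2 * NA_CATION) / 2)
}

.check_positions <- function(n, i, what) {
  if (any(i < 1L) || any(i > n)) {
    stop(errorCondition(sprintf("%s out of range 1..%d", what, n),
                        class = c("peptaibio_index_error", "error", "condition")))
  }
}

#' b-ion m/z (singly charged acylium)
#'
#' `b_n` = sum of residues 1..n, plus the acetyl cap when present, plus one
#' proton. Ladder additivity: `b_{n+1} - b_n` equals the residue mass at
#' position n+1.
#'
#' @param seq sequence (see [neutral_mass()]).
#' @param n prefix length(s), `1 <= n < length(seq)`.
#' @inheritParams neutral_mass
#' @return numeric vector of b-ion m/z values.
#' @export
b_ion_mz <- function(seq, n, kind = c("monoisotopic", "average")) {
  kind <- .match_kind(kind)
  seq <- .as_sequence(seq)
  len <- length(seq$residues)
  .check_positions(len - 1L, n, "b-ion index")
  cum <- cumsum(residue_mass(seq$residues, kind))
  cap <- if (seq$n_cap == "Ac") MASS_ACETYL[[kind]] else 0
  cum[n] + cap + PROTON_MASS
}

#' y-ion m/z (protonated C-terminal fragment)
#'
#' `y_k` = sum of the last k residues, plus water, plus one proton; the
#' amino-alcohol terminus correction is carried by the alcohol residue mass.
#' Complementarity: `b_{n-k} + y_k - M = 2 x 1.00728`.
#'
#' @param seq sequence (see [neutral_mass()]).
#' @param k suffix length(s), `1 <= k <= length(seq)`.
#' @inheritParams neutral_mass
#' @return numeric vector of y-ion m/z values.
#' @export
y_ion_mz <- function(seq, k, kind = c("monoisotopic", "average")) {
  kind <- .match_kind(kind)
  seq <- .as_sequence(seq)
  len <- length(seq$residues)
  .check_positions(len, k, "y-ion suffix length")
  cum <- cumsum(residue_mass(rev(seq$residues), kind))
  cum[k] + MASS_WATER[[kind]] + PROTON_MASS
}

#' Characteristic ions of a peptaibol
#'
#' The five quantities used for de novo identification: neutral M, [M+Na]+,
#' [M+2Na]2+, b12 and y7 (the latter two `NA` for chains too short to
#' produce them).
#'
#' @inheritParams neutral_mass
#' @return an object of class `mass_record`: list with fields `M`, `m_na`,
#'   `m_2na`, `b12`, `y7`, `mass_kind`.
#' @examples
#' characteristic_ions("Ac-Aib-Gly-Ala-Aib-Ile-Gln-Aib-Aib-Aib-Ser-Leu-Aib-Pro-Val-Aib-Ile-Gln-Gln-Leuol")
#' @export
characteristic_ions <- function(seq, kind = c("monoisotopic", "average")) {
  kind <- .match_kind(kind)
  seq <- .as_sequence(seq)
  M <- neutral_mass(seq, kind)
  len <- length(seq$residues)
  structure(list(
    M = M,
    m_na = adduct_mz(M, "M+Na"),
    m_2na = adduct_mz(M, "M+2Na"),
    b12 = if (len > 12L) b_ion_mz(seq, 12L, kind) else NA_real_,
    y7 = if (len >= 7L) y_ion_mz(seq, 7L, kind) else NA_real_,
    mass_kind = kind
  ), class = "mass_record")
}

#' @export
print.mass_record <- function(x, ...) {
  cat(sprintf(
    "<mass_record> (%s)\n  M       %10.4f\n  [M+Na]+ %10.4f\n  [M+2Na]2+ %8.4f\n  b12     %10s\n  y7      %10s\n",
    x$mass_kind, x$M, x$m_na, x$m_2na,
    ifelse(is.na(x$b12), "NA", sprintf("%.4f", x$b12)),
    ifelse(is.na(x$y7), "NA", sprintf("%.4f", x$y7))))
  invisible(x)
}
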