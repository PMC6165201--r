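# Mass constants. Monoisotopic atomic masses are CODATA/IUPAC values for the
# lightest isotope; average masses follow the IUPAC 2021 standard atomic
# weights. All masses in Da.

.atomic_mono <- c(
  H  = 1.007825,
  C  = 12.0,
  N  = 14.003074,
  O  = 15.994915,
  S  = 31.972071,
  Na = 22.989770
)

.atomic_avg <- c(
  H  = 1.008,
  C  = 12.011,
  N  = 14.007,
  O  = 15.999,
  S  = 32.06,
  Na = 22.98977
)

ELECTRON_MASS <- 0.000549
PROTON_MASS   <- 1.007276           # H minus electron
NA_CATION     <- 22.989221          # Na minus electron

MASS_WATER  <- c(monoisotopic = 18.010565, average = 18.015)
MASS_ACETYL <- c(monoisotopic = 42.010565, average = 42.037)  # CH3CO- minus H
# Reduction of the C-terminal carboxyl to a 1,2-amino alcohol: -O +2H
MASS_ALCOHOL_DELTA <- c(monoisotopic = -13.979265, average = -13.983)

GAS_CONSTANT_KCAL <- 1.9872e-3      # kcal mol^-1 K^-1

.match_kind <- function(kind) {
  match.arg(kind, c("monoisotopic", "average"))
}

#' Mass of an elemental formula
#'
#' Sums atomic masses for a compact formula string such as `"C4H7NO"`.
#' Supported elements: C, H, N, O, S, Na.
#'
#' @param formula character vector of formula strings.
#' @param kind `"monoisotopic"` or `"average"`.
#' @return numeric vector of masses in Da.
#' @examples
#' formula_mass("C4H7NO")   # the Aib residue
#' @export
formula_mass <- function(formula, kind = c("monoisotopic", "average")) {
  kind <- .match_kind(kind)
  table <- if (kind == "monoisotopic") .atomic_mono else .atomic_avg
  vapply(formula, function(f) {
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    parts <- regmatches(f, list(m))[[1]]
    parts <- parts[nzchar(parts)]
    total <- 0
    seen <- 0L
    for (p in parts) {
      el <- sub("[0-9]*$", "", p)
      ct <- sub("^[A-Za-z]+", "", p)
      n <- if (nzchar(ct)) as.integer(ct) else 1L
      if (!el %in% names(table)) {
        stop(errorCondition(sprintf("unknown element '%s' in formula '%s'", el, f),
                            class = c("peptaibio_formula_error", "error", "condition")))
      }
      total <- total + table[[el]] * n
      seen <- seen + nchar(p)
    }
    if (seen != nchar(f)) {
      stop(errorCondition(sprintf("could not parse formula '%s'", f),
                          class = c("peptaibio_formula_error", "error", "condition")))
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

# Parse a formula string into a named integer vector of element counts.
.formula_counts <- function(f) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
  parts <- regmatches(f, list(m))[[1]]
  parts <- parts[nzchar(parts)]
  els <- sub("[0-9]*$", "", parts)
  cts <- sub("^[A-Za-z]+", "", parts)
  cts <- ifelse(nzchar(cts), as.integer(cts), 1L)
  stats::setNames(as.integer(cts), els)
}

# Combine element-count vectors into one.
.counts_add <- function(...) {
  all <- list(...)
  els <- unique(unlist(lapply(all, names)))
  out <- stats::setNames(integer(length(els)), els)
  for (v in all) out[names(v)] <- out[names(v)] + v
  out
}
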