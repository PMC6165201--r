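# Residue library for peptaibols: the 20 proteinogenic residues, the
# non-proteinogenic helix formers Aib and Iva, and C-terminal 1,2-amino
# alcohols. Residue formulas are amino acid minus water; amino-alcohol
# residues carry the reduced carboxyl (-O +2H) in their formula, so their
# residue mass already includes the alcohol terminus correction.

.residue_table <- function() {
  df <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
code   formula    iso_class terminal_only
Gly    C2H3NO     Gly       0
Ala    C3H5NO     Ala       0
Ser    C3H5NO2    Ser       0
Pro    C5H7NO     Pro       0
Val    C5H9NO     Vxx       0
Thr    C4H7NO2    Thr       0
Cys    C3H5NOS    Cys       0
Leu    C6H11NO    Lxx       0
Ile    C6H11NO    Lxx       0
Asn    C4H6N2O2   Asn       0
Asp    C4H5NO3    Asp       0
Gln    C5H8N2O2   Gln       0
Lys    C6H12N2O   Lys       0
Glu    C5H7NO3    Glu       0
Met    C5H9NOS    Met       0
His    C6H7N3O    His       0
Phe    C9H9NO     Phe       0
Arg    C6H12N4O   Arg       0
Tyr    C9H9NO2    Tyr       0
Trp    C11H10N2O  Trp       0
Aib    C4H7NO     Aib       0
Iva    C5H9NO     Vxx       0
Leuol  C6H13N     Lxxol     1
Ileol  C6H13N     Lxxol     1
Valol  C5H11N     Valol     1
Pheol  C9H11N     Pheol     1
Trpol  C11H12N2   Trpol     1
Tyrol  C9H11NO    Tyrol     1
Alaol  C3H7N      Alaol     1
Prool  C5H9N      Prool     1
")
  # Iso-class tokens are first-class sequence symbols: members of one class
  # are isobaric, so the class mass is well defined.
  rownames(df) <- df$code
  cls <- df[c("Leu", "Val", "Leuol"), ]
  cls$code <- c("Lxx", "Vxx", "Lxxol")
  df <- rbind(df, cls)
  df$terminal_only <- as.logical(df$terminal_only)
  df$mono_mass <- formula_mass(df$formula, "monoisotopic")
  df$avg_mass <- formula_mass(df$formula, "average")
  rownames(df) <- df$code
  df
}

.residue_env <- new.env(parent = emptyenv())

#' The peptaibol residue library
#'
#' Returns the residue table in use: one row per residue token with its
#' elemental formula (residue = amino acid minus water; amino alcohols carry
#' the reduced carboxyl), monoisotopic and average masses, isobaric class
#' (`Lxx` = Leu/Ile, `Vxx` = Val/Iva, `Lxxol` = Leuol/Ileol) and a flag for
#' terminal-only (alcohol) residues. Iso-class tokens themselves are valid
#' sequence symbols.
#'
#' @return data.frame with columns `code`, `formula`, `iso_class`,
#'   `terminal_only`, `mono_mass`, `avg_mass`.
#' @export
residue_library <- function() {
  if (is.null(.residue_env$table)) .residue_env$table <- .residue_table()
  .residue_env$table
}

#' Extend or replace the residue library from a TSV file
#'
#' The TSV must have columns `code`, `formula`, `iso_class` and optionally
#' `terminal_only` (0/1). New codes are appended; existing codes are replaced.
#'
#' @param path path to a tab-separated file.
#' @return the updated library, invisibly.
#' @export
load_residue_library <- function(path) {
  ext <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("code", "formula", "iso_class")
  if (!all(need %in% names(ext))) {
    stop(errorCondition(
      sprintf("residue library TSV must have columns %s", paste(need, collapse = ", ")),
      class = c("peptaibio_format_error", "error", "condition")))
  }
  if (is.null(ext$terminal_only)) ext$terminal_only <- grepl("ol$", ext$code)
  ext$terminal_only <- as.logical(ext$terminal_only)
  ext$mono_mass <- formula_mass(ext$formula, "monoisotopic")
  ext$avg_mass <- formula_mass(ext$formula, "average")
  lib <- residue_library()
  lib <- lib[!lib$code %in% ext$code, ]
  lib <- rbind(lib, ext[, names(lib)])
  rownames(lib) <- lib$code
  .residue_env$table <- lib
  invisible(lib)
}

#' Write the residue library to TSV
#'
#' @param lib a residue library data.frame (default: the active library).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_residue_library <- function(path, lib = residue_library()) {
  utils::write.table(lib[, c("code", "formula", "iso_class", "terminal_only")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.resolve_residues <- function(codes) {
  lib <- residue_library()
  bad <- setdiff(codes, lib$code)
  if (length(bad)) {
    stop(errorCondition(
      sprintf("unknown residue token(s): %s", paste(unique(bad), collapse = ", ")),
      class = c("peptaibio_unknown_residue", "error", "condition")))
  }
  lib[codes, , drop = FALSE]
}

#' Residue mass
#'
#' Mass of a residue (amino acid minus water). Amino-alcohol residues
#' (`-ol` suffix) return the reduced-carboxyl residue mass (parent residue
#' - O + 2H). Iso-class tokens (`Lxx`, `Vxx`, `Lxxol`) are accepted: class
#' members are isobaric so the mass is well defined.
#'
#' @param code character vector of residue tokens.
#' @param kind `"monoisotopic"` or `"average"`.
#' @return numeric vector of residue masses in Da.
#' @examples
#' residue_mass("Aib")                    # 85.0528
#' residue_mass(c("Gln", "Aib"))          # the 213.11 ladder block
#' @export
residue_mass <- function(code, kind = c("monoisotopic", "average")) {
  kind <- .match_kind(kind)
  rows <- .resolve_residues(code)
  unname(if (kind == "monoisotopic") rows$mono_mass else rows$avg_mass)
}

#' Map residue tokens to their isobaric class
#'
#' @param code character vector of residue tokens.
#' @return character vector of class tokens (`Lxx`, `Vxx`, `Lxxol`, or the
#'   token itself).
#' @export
iso_class <- function(code) {
  rows <- .resolve_residues(code)
  unname(rows$iso_class)
}
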