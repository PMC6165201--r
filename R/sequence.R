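# Peptaibol sequences: an N-terminal cap ("Ac" or "H") plus an ordered chain
# of residue tokens, written in the field's dash-separated token notation,
# e.g. "Ac-Aib-Gly-Ala-...-Leuol". Positions are 1-based.

#' Construct a peptaibol sequence
#'
#' @param residues character vector of residue tokens (library codes or
#'   iso-class tokens), in N-to-C order.
#' @param n_cap `"Ac"` (acetylated, the peptaibol default) or `"H"` (free).
#' @return an object of class `peptaibol_sequence`.
#' @examples
#' peptaibol_sequence(c("Aib", "Gly", "Ala", "Leuol"))
#' @export
peptaibol_sequence <- function(residues, n_cap = "Ac") {
  n_cap <- match.arg(n_cap, c("Ac", "H"))
  residues <- as.character(residues)
  if (length(residues) < 1L) {
    stop(errorCondition("a peptaibol sequence needs at least one residue",
                        class = c("peptaibio_invalid_sequence", "error", "condition")))
  }
  if (length(residues) > 25L) {
    stop(errorCondition("peptaibol sequences longer than 25 residues are not supported",
                        class = c("peptaibio_invalid_sequence", "error", "condition")))
  }
  rows <- .resolve_residues(residues)
  n <- length(residues)
  if (any(rows$terminal_only[-n])) {
    bad <- which(rows$terminal_only[-n])[1]
    stop(errorCondition(
      sprintf("amino-alcohol residue '%s' at interior position %d (alcohols are C-terminal only)",
              residues[bad], bad),
      class = c("peptaibio_invalid_sequence", "error", "condition")))
  }
  structure(list(n_cap = n_cap, residues = residues),
            class = "peptaibol_sequence")
}

#' Parse the dash-separated token notation
#'
#' Grammar: `[Ac-]Tok(-Tok)*` with tokens from the residue library. A
#' leading `Ac-` (or fused `AcAib` style first token) marks the acetyl cap.
#'
#' @param x character vector of sequence strings.
#' @return a `peptaibol_sequence` (or a list of them when `length(x) > 1`).
#' @examples
#' parse_peptaibol("Ac-Aib-Gly-Ala-Aib-Leuol")
#' @export
parse_peptaibol <- function(x) {
  one <- function(s) {
    toks <- strsplit(trimws(s), "-", fixed = TRUE)[[1]]
    toks <- toks[nzchar(toks)]
    n_cap <- "H"
    if (length(toks) && toks[1] == "Ac") {
      n_cap <- "Ac"
      toks <- toks[-1]
    } else if (length(toks) && grepl("^Ac[A-Z]", toks[1])) {
      n_cap <- "Ac"
      toks[1] <- sub("^Ac", "", toks[1])
    }
    peptaibol_sequence(toks, n_cap)
  }
  if (length(x) == 1L) one(x) else lapply(x, one)
}

#' @export
format.peptaibol_sequence <- function(x, ...) {
  core <- paste(x$residues, collapse = "-")
  if (x$n_cap == "Ac") paste0("Ac-", core) else core
}

#' @export
as.character.peptaibol_sequence <- function(x, ...) format(x)

#' @export
print.peptaibol_sequence <- function(x, ...) {
  cat(sprintf("<peptaibol_sequence> %d residues\n  %s\n",
              length(x$residues), format(x)))
  invisible(x)
}

#' @export
length.peptaibol_sequence <- function(x) length(x$residues)

#' Collapse a sequence to isobaric-class resolution
#'
#' Replaces Leu/Ile by `Lxx`, Val/Iva by `Vxx` and Leuol/Ileol by `Lxxol`.
#' MS cannot discriminate class members, so sequencing output and database
#' comparison default to this resolution.
#'
#' @param seq a `peptaibol_sequence`.
#' @return a `peptaibol_sequence` over class tokens.
#' @export
as_iso_class <- function(seq) {
  stopifnot(inherits(seq, "peptaibol_sequence"))
  peptaibol_sequence(iso_class(seq$residues), seq$n_cap)
}

.as_sequence <- function(x) {
  if (inherits(x, "peptaibol_sequence")) x else parse_peptaibol(x)
}
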