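# Packaged data: the two strain compound tables, the known-peptaibol
# comparison database and the curated relation records.

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "peptaibio")
  if (!nzchar(path)) path <- file.path("inst", "extdata", file)  # pre-install
  path
}

#' Packaged peptaibiome compound tables
#'
#' The characteristic ions, retention times, area shares and class-level
#' sequences of the 30 peptaibols detected in the two studied strains
#' (19 from the *T. gamsii* table, 11 Koningiopsins from the
#' *T. koningiopsis* table).
#'
#' @param strain `"gamsii"`, `"koningiopsis"` or `"both"`.
#' @return data.frame with columns `peptide`, `M`, `m_na`, `m_2na`, `b12`,
#'   `y7`, `rt`, `area_percent`, `R1`..`R19`, and `strain`.
#' @export
peptaibol_tables <- function(strain = c("both", "gamsii", "koningiopsis")) {
  strain <- match.arg(strain)
  read1 <- function(f, s) {
    df <- utils::read.delim(.extdata(f), comment.char = "#",
                            stringsAsFactors = FALSE, check.names = FALSE)
    df$strain <- s
    df
  }
  out <- switch(strain,
    gamsii = read1("table1_gamsii.tsv", "gamsii"),
    koningiopsis = read1("table2_koningiopsis.tsv", "koningiopsis"),
    both = rbind(read1("table1_gamsii.tsv", "gamsii"),
                 read1("table2_koningiopsis.tsv", "koningiopsis")))
  out
}

#' Sequence of a packaged table row
#'
#' @param row one row of [peptaibol_tables()].
#' @return a `peptaibol_sequence` (acetyl-capped, class tokens as printed).
#' @export
table_row_sequence <- function(row) {
  toks <- as.character(unlist(row[paste0("R", 1:19)]))
  peptaibol_sequence(toks, n_cap = "Ac")
}

#' Read a known-peptaibol database
#'
#' @param path TSV with columns `name`, `sequence` (token notation),
#'   `source_ref`; defaults to the packaged comparison database.
#' @return data.frame of class `peptaibol_db` with a parsed `seq` list column.
#' @export
read_peptaibol_db <- function(path = .extdata("known_peptaibols.tsv")) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "sequence")
  if (!all(need %in% names(df))) {
    stop(errorCondition("database TSV needs columns name, sequence",
                        class = c("peptaibio_format_error", "error", "condition")))
  }
  if (anyDuplicated(df$name)) {
    stop(errorCondition("database names must be unique",
                        class = c("peptaibio_format_error", "error", "condition")))
  }
  if (is.null(df$source_ref)) df$source_ref <- NA_character_
  df$seq <- lapply(df$sequence, parse_peptaibol)
  class(df) <- c("peptaibol_db", "data.frame")
  df
}

#' Write a known-peptaibol database TSV
#'
#' @param db a `peptaibol_db` or data.frame with `name`, `sequence`,
#'   `source_ref`.
#' @param path output path.
#' @export
write_peptaibol_db <- function(db, path) {
  utils::write.table(db[, c("name", "sequence", "source_ref")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Curated relation records used by the annotation tests.
.expected_relations <- function() {
  utils::read.delim(.extdata("expected_relations.tsv"), comment.char = "#",
                    stringsAsFactors = FALSE)
}
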