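# Annotation of assembled sequences against known peptaibols: position-wise
# comparison at isobaric-class resolution, ranked database matching, and
# elution-order naming with a/b variant letters.

.relation_rank <- c(identical_by_class = 0L, positional_isomer = 1L,
                    exchanges = 2L, different_length = 3L)

#' Compare two peptaibol sequences
#'
#' Position-wise comparison, by default at isobaric-class resolution (the
#' paper's own annotation convention, since MS cannot separate class
#' members). Equal everywhere: `identical_by_class`; equal as multisets but
#' not position-wise: `positional_isomer`; otherwise an exchange list of
#' per-position records `[X]^i -> [Y]^i` (X = subject/database token, Y =
#' query token). Unequal lengths give relation `different_length` with an
#' undefined exchange count.
#'
#' @param query,subject `peptaibol_sequence` objects or token strings.
#' @param strict if `TRUE`, compare literal tokens instead of iso-classes.
#' @return a `match_report`: list with `relation`, `exchanges` (data.frame
#'   `position`, `from`, `to`), `n_exchanges`.
#' @export
compare_peptaibols <- function(query, subject, strict = FALSE) {
  q <- .as_sequence(query)
  s <- .as_sequence(subject)
  qt <- if (strict) q$residues else iso_class(q$residues)
  st <- if (strict) s$residues else iso_class(s$residues)
  if (length(qt) != length(st)) {
    rep <- list(relation = "different_length",
                exchanges = data.frame(position = integer(0), from = character(0),
                                       to = character(0), stringsAsFactors = FALSE),
                n_exchanges = NA_integer_)
    class(rep) <- "match_report"
    return(rep)
  }
  diff <- which(qt != st)
  relation <- if (!length(diff)) {
    "identical_by_class"
  } else if (identical(sort(qt), sort(st))) {
    "positional_isomer"
  } else {
    "exchanges"
  }
  ex <- if (relation == "exchanges") {
    data.frame(position = diff, from = st[diff], to = qt[diff],
               stringsAsFactors = FALSE)
  } else {
    data.frame(position = integer(0), from = character(0), to = character(0),
               stringsAsFactors = FALSE)
  }
  rep <- list(relation = relation, exchanges = ex,
              n_exchanges = if (relation == "exchanges") nrow(ex) else 0L)
  class(rep) <- "match_report"
  rep
}

#' @export
format.match_report <- function(x, ...) {
  if (x$relation == "exchanges") {
    paste(sprintf("[%s]^%d^->[%s]^%d^", x$exchanges$from, x$exchanges$position,
                  x$exchanges$to, x$exchanges$position), collapse = ", ")
  } else {
    x$relation
  }
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report> %s", x$relation))
  if (x$relation == "exchanges") cat(sprintf(" (%d): %s", x$n_exchanges, format(x)))
  cat("\n")
  invisible(x)
}

#' Annotate a sequence against a known-peptaibol database
#'
#' Compares the query with every database entry and ranks hits by relation
#' class (identical < positional isomer < exchanges), then ascending
#' exchange count, then name. Different-length entries and entries with more
#' than `max_exchanges` exchanges are omitted from the ranking. The query is
#' flagged `new` when no identical-by-class hit exists.
#'
#' @param query a `peptaibol_sequence` or token string.
#' @param db a `peptaibol_db` from [read_peptaibol_db()].
#' @param max_exchanges maximum exchange count retained (default `Inf`).
#' @param strict passed to [compare_peptaibols()].
#' @return data.frame of class `peptaibol_annotation`: columns `name`,
#'   `relation`, `n_exchanges`, `exchange_list` plus attributes `new` and
#'   `reports` (the full `match_report` list, named by entry).
#' @export
annotate_against_db <- function(query, db, max_exchanges = Inf, strict = FALSE) {
  if (!nrow(db)) {
    stop(errorCondition("known-peptaibol database is empty",
                        class = c("peptaibio_empty_database", "error", "condition")))
  }
  reports <- lapply(db$seq, function(s) compare_peptaibols(query, s, strict = strict))
  names(reports) <- db$name
  rel <- vapply(reports, function(r) r$relation, character(1))
  nex <- vapply(reports, function(r) ifelse(is.na(r$n_exchanges), Inf, r$n_exchanges), numeric(1))
  keep <- rel != "different_length" & nex <= max_exchanges
  out <- data.frame(name = db$name[keep], relation = rel[keep],
                    n_exchanges = as.integer(nex[keep]),
                    exchange_list = vapply(reports[keep], format, character(1)),
                    stringsAsFactors = FALSE)
  out <- out[order(.relation_rank[out$relation], out$n_exchanges, out$name), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "new") <- !any(rel == "identical_by_class")
  attr(out, "reports") <- reports
  class(out) <- c("peptaibol_annotation", "data.frame")
  out
}

#' @export
print.peptaibol_annotation <- function(x, ...) {
  cat(sprintf("<peptaibol_annotation> %d hit(s); %s\n", nrow(x),
              ifelse(attr(x, "new"), "new compound (no identical match)",
                     "known compound")))
  print.data.frame(x)
  invisible(x)
}

#' Name compounds by elution order
#'
#' Compounds are sorted by retention time and numbered with Roman numerals.
#' Co-eluting compounds that differ in their characteristic-ion family get
#' one shared numeral with letters a, b, ... in ascending y7 mass: a cluster
#' is a maximal elution-ordered run whose consecutive members are within
#' `cluster_window` minutes and strictly ascend in y7 family (families are
#' distinguished at > 0.5 Da, i.e. at least a Gln/Glu step). Singletons get
#' a bare numeral. Ties in rt break deterministically on y7 then b12.
#'
#' @param rt retention times (minutes, finite).
#' @param b12,y7 characteristic fragment m/z per compound.
#' @param prefix string prepended to every label (e.g. `"Pept-"`).
#' @param cluster_window co-elution window in minutes.
#' @return character vector of labels, parallel to the input order.
#' @export
assign_names <- function(rt, b12, y7, prefix = "", cluster_window = 1.2) {
  stopifnot(length(rt) == length(b12), length(rt) == length(y7))
  if (!length(rt)) return(character(0))
  if (any(!is.finite(rt))) {
    stop(errorCondition("all retention times must be finite",
                        class = c("peptaibio_domain_error", "error", "condition")))
  }
  ord <- order(rt, y7, b12)
  r <- rt[ord]; y <- y7[ord]
  n <- length(r)
  cluster <- integer(n)
  cid <- 1L
  cluster[1] <- cid
  for (i in seq_len(n - 1L)) {
    ascending <- (y[i + 1L] - y[i]) > 0.5
    close_rt <- (r[i + 1L] - r[i]) <= cluster_window
    if (ascending && close_rt) cluster[i + 1L] <- cid
    else { cid <- cid + 1L; cluster[i + 1L] <- cid }
  }
  labels_sorted <- character(n)
  for (cl in unique(cluster)) {
    idx <- which(cluster == cl)
    roman <- as.character(utils::as.roman(cl))
    if (length(idx) == 1L) {
      labels_sorted[idx] <- roman
    } else {
      labels_sorted[idx[order(y[idx])]] <- paste0(roman, letters[seq_along(idx)])
    }
  }
  out <- character(n)
  out[ord] <- paste0(prefix, labels_sorted)
  out
}
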