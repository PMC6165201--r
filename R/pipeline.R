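# End-to-end binder: assemble every peak list, annotate against the known
# database, name by elution order, and (optionally) quantify against a
# calibration — producing one compound-table-style report per run.

#' Run the peptaibiome analysis pipeline
#'
#' For each peak list: de novo assembly ([assemble_sequence()]), database
#' annotation ([annotate_against_db()]), elution-order naming
#' ([assign_names()]) and, when a calibration is supplied, quantitation
#' ([quantify_peptaibols()]). Compound "area" is taken as the summed
#' intensity of the precursor adduct peaks.
#'
#' @param peaklists a list of [peak_list()] objects, or a directory path
#'   containing peak CSV files (read with [read_peak_csv()]).
#' @param db a `peptaibol_db` or a path to a database TSV (default: the
#'   packaged known-peptaibol database).
#' @param calibration optional `peptaibol_calibration` or calibration CSV
#'   path.
#' @param tol matching tolerance in Da.
#' @param cluster_window co-elution window in minutes for naming.
#' @param prefix name prefix (e.g. `"Pept-"`).
#' @param out_dir optional directory; when given, writes `report.tsv` and
#'   per-compound assignment TSVs there.
#' @return data.frame of class `peptaibiome_report`: one row per compound
#'   with name, characteristic ions, rt, area percent, content (if
#'   calibrated), sequence tokens R1..R19, best database hit and relation;
#'   attribute `assignments` holds the full `peptaibol_assignment` list.
#' @export
run_pipeline <- function(peaklists, db = read_peptaibol_db(), calibration = NULL,
                         tol = 0.6, cluster_window = 1.2, prefix = "",
                         out_dir = NULL) {
  if (is.character(peaklists) && length(peaklists) == 1L) {
    files <- sort(list.files(peaklists, pattern = "\\.csv$", full.names = TRUE))
    peaklists <- stats::setNames(lapply(files, read_peak_csv),
                                 sub("\\.csv$", "", basename(files)))
  }
  if (is.character(db)) db <- read_peptaibol_db(db)
  if (is.character(calibration)) calibration <- read_calibration_csv(calibration)

  if (!length(peaklists)) {
    out <- data.frame()
    class(out) <- c("peptaibiome_report", "data.frame")
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.table(out, file.path(out_dir, "report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    return(out)
  }

  assignments <- lapply(peaklists, assemble_sequence, tol = tol)
  seqs <- lapply(assignments, assignment_sequence)
  rec <- lapply(seqs, characteristic_ions)

  rt <- vapply(peaklists, function(p) attr(p, "rt"), numeric(1))
  if (any(!is.finite(rt))) {
    warning("peak list(s) without retention time: naming falls back to input order, no co-elution clusters")
    rt <- seq_along(peaklists) * 10  # spaced beyond any clustering window
  }
  area <- vapply(peaklists, function(p) {
    add <- !is.na(p$kind) & p$kind %in% c("MNa", "M2Na")
    if (any(add)) sum(p$intensity[add]) else sum(p$intensity)
  }, numeric(1))

  b12 <- vapply(rec, function(r) r$b12, numeric(1))
  y7 <- vapply(rec, function(r) r$y7, numeric(1))
  label <- assign_names(rt, b12, y7, prefix = prefix,
                        cluster_window = cluster_window)

  ann <- lapply(seqs, annotate_against_db, db = db)
  best_hit <- vapply(ann, function(a) if (nrow(a)) a$name[1] else NA_character_, character(1))
  relation <- vapply(ann, function(a) if (nrow(a)) a$relation[1] else NA_character_, character(1))
  exch <- vapply(ann, function(a) if (nrow(a)) a$exchange_list[1] else NA_character_, character(1))
  is_new <- vapply(ann, function(a) attr(a, "new"), logical(1))

  toks <- t(vapply(seqs, function(s) s$residues, character(19)))
  colnames(toks) <- paste0("R", 1:19)

  out <- data.frame(
    peptide = label,
    M_obs = vapply(assignments, function(a) a$M_obs, numeric(1)),
    M_theor = vapply(rec, function(r) r$M, numeric(1)),
    m_na = vapply(rec, function(r) r$m_na, numeric(1)),
    m_2na = vapply(rec, function(r) r$m_2na, numeric(1)),
    b12 = b12, y7 = y7, rt = rt,
    area = area, area_percent = 100 * area / sum(area),
    closure_residual = vapply(assignments, function(a) a$closure_residual, numeric(1)),
    status = vapply(assignments, function(a) a$status, character(1)),
    toks,
    best_hit = best_hit, relation = relation, exchange_list = exch,
    new = is_new,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL

  if (!is.null(calibration)) {
    q <- quantify_peptaibols(label, area, rep(19L, length(area)), calibration, rt)
    out$content <- q$content[match(label, q$name)]
    attr(out, "total_content") <- attr(q, "total_content")
  }
  attr(out, "assignments") <- assignments
  class(out) <- c("peptaibiome_report", "data.frame")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(as.data.frame(out), file.path(out_dir, "report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (i in seq_along(assignments)) {
      write_assignment_tsv(assignments[[i]],
                           file.path(out_dir, sprintf("assignment_%02d.tsv", i)))
    }
  }
  out
}

#' @export
print.peptaibiome_report <- function(x, ...) {
  cat(sprintf("<peptaibiome_report> %d compound(s)\n", nrow(x)))
  if (nrow(x)) {
    show <- c("peptide", "M_obs", "b12", "y7", "rt", "area_percent",
              "status", "best_hit", "relation", "new")
    print.data.frame(x[, intersect(show, names(x))], digits = 6)
  }
  invisible(x)
}
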