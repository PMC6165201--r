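# De novo assembly of 19-residue peptaibol sequences from characteristic-ion
# peak lists: sodiated-adduct deconvolution, b-ladder walking with composite
# jumps, y7/MS2 family resolution, Aib-Pro-Vxx-Aib motif gap fill and
# mass-closure validation. All residue calls are made at isobaric-class
# resolution: MS cannot discriminate Leu/Ile or Val/Iva.

# Default sequencing alphabet: the residues observed in peptaibols, at class
# resolution. Restricting the alphabet keeps single-residue ladder steps
# unambiguous at unit resolution (minimum pairwise mass gap 0.98 Da,
# Gln/Glu and Asn/Asp); the full library (with e.g. Lys at 0.036 Da from
# Gln) is available via the `alphabet` argument.
PEPTAIBOL_ALPHABET <- c("Gly", "Ala", "Ser", "Pro", "Vxx", "Thr", "Lxx",
                        "Asn", "Asp", "Gln", "Glu", "Aib", "Phe", "Tyr", "Trp")

GLN_AIB_BLOCK <- 213.1113  # the ladder block protected by the Gln6-Aib7 bond

#' Deconvolute sodiated adducts to a neutral mass
#'
#' Uses peaks labelled `MNa` / `M2Na`; for unlabelled peak lists, searches for
#' a mutually consistent [M+Na]+ / [M+2Na]2+ pair. When both adducts are
#' present the [M+Na]+ value wins and the cross-check residual (difference
#' between the two implied neutral masses) is recorded.
#'
#' @param peaks a [peak_list()].
#' @param tol matching tolerance in Da.
#' @return neutral mass M (Da) with attribute `residual` (NA with a single
#'   adduct).
#' @export
deconvolute_adducts <- function(peaks, tol = 0.6) {
  stopifnot(inherits(peaks, "peak_list"))
  mna <- peaks$mz[!is.na(peaks$kind) & peaks$kind == "MNa"]
  m2na <- peaks$mz[!is.na(peaks$kind) & peaks$kind == "M2Na"]
  if (!length(mna) && !length(m2na)) {
    # label-free fallback: look for a consistent pair among unlabelled peaks
    un <- peaks$mz[is.na(peaks$kind)]
    found <- FALSE
    for (i in rev(seq_along(un))) {
      M1 <- un[i] - NA_CATION
      if (M1 <= 0) next
      hit <- which(abs((M1 + 2 * NA_CATION) / 2 - un) <= tol)
      hit <- setdiff(hit, i)
      if (length(hit)) {
        mna <- un[i]; m2na <- un[hit[1]]
        found <- TRUE
        break
      }
    }
    if (!found) {
      stop(errorCondition("no precursor adduct peak ([M+Na]+ or [M+2Na]2+) found",
                          class = c("peptaibio_no_precursor", "error", "condition")))
    }
  }
  M_from_na <- if (length(mna)) mna[1] - NA_CATION else NA_real_
  M_from_2na <- if (length(m2na)) 2 * m2na[1] - 2 * NA_CATION else NA_real_
  residual <- NA_real_
  if (is.finite(M_from_na) && is.finite(M_from_2na)) {
    residual <- M_from_na - M_from_2na
    if (abs(residual) > 2 * tol) {
      stop(errorCondition(
        sprintf("adducts disagree: [M+Na]+ implies M = %.3f, [M+2Na]2+ implies M = %.3f",
                M_from_na, M_from_2na),
        class = c("peptaibio_inconsistent_adducts", "error", "condition")))
    }
  }
  M <- if (is.finite(M_from_na)) M_from_na else M_from_2na
  attr(M, "residual") <- residual
  M
}

# Expand a mass difference into candidate token runs. Returns a list of
# character vectors (each one expansion), ordered by absolute residual;
# composites (length-2 expansions) follow singles. The Gln-Aib block
# (213.11 Da, the bond that survives ESI fragmentation) expands only in
# motif order.
.expand_jump <- function(d, tol, masses, allow_composite = TRUE) {
  out <- list()
  res <- abs(masses - d)
  singles <- names(masses)[res <= tol]
  singles <- singles[order(res[res <= tol])]
  for (s in singles) out[[length(out) + 1L]] <- s
  if (allow_composite) {
    if (abs(d - GLN_AIB_BLOCK) <= tol) {
      out[[length(out) + 1L]] <- c("Gln", "Aib")
    } else {
      toks <- names(masses)
      pair_res <- outer(masses, masses, function(a, b) abs(a + b - d))
      hits <- which(pair_res <= tol, arr.ind = TRUE)
      if (nrow(hits)) {
        ord <- order(pair_res[hits])
        hits <- hits[ord, , drop = FALSE]
        for (r in seq_len(nrow(hits))) {
          out[[length(out) + 1L]] <- c(toks[hits[r, 1]], toks[hits[r, 2]])
        }
      }
    }
  }
  out
}

#' Walk a b-ion ladder
#'
#' Matches consecutive differences of an ascending b-ion series to single
#' residues or two-residue composites (the 213.11 Da difference is expanded
#' as Gln-then-Aib). b1 is assumed absent, so the first observed peak may be
#' any b_n with n <= 3, resolved by composite enumeration against the
#' acetyl+proton offset. Walking stops at the first difference that no
#' single or composite expansion matches (larger gaps are left to motif and
#' y7 evidence downstream).
#'
#' @param b_peaks ascending numeric vector of b-ion m/z values (>= 2 peaks).
#' @param tol matching tolerance in Da.
#' @param alphabet residue tokens used for matching (class tokens); the
#'   default is the peptaibol alphabet.
#' @return list of candidate partial reads, each a list with `tokens`
#'   (character vector for positions 1..m), `provenance`, `composites`
#'   (number of composite jumps used) and `residual` (cumulative absolute
#'   matching residual); ranked by (composites, residual).
#' @export
walk_b_ladder <- function(b_peaks, tol = 0.6, alphabet = PEPTAIBOL_ALPHABET) {
  b_peaks <- sort(as.numeric(b_peaks))
  if (length(b_peaks) < 2L) {
    stop(errorCondition("need at least 2 b-ion peaks to walk a ladder",
                        class = c("peptaibio_insufficient_ladder", "error", "condition")))
  }
  masses <- stats::setNames(residue_mass(alphabet), alphabet)
  offset <- MASS_ACETYL[["monoisotopic"]] + PROTON_MASS

  # head expansions: first peak is b_n, n <= 3
  head_mass <- b_peaks[1] - offset
  heads <- list()
  # n = 1 and 2 via the jump expander, n = 3 via one extra level
  for (e in .expand_jump(head_mass, tol, masses)) {
    heads[[length(heads) + 1L]] <- list(tokens = e,
                                        composites = as.integer(length(e) > 1L),
                                        residual = abs(sum(masses[e]) - head_mass))
  }
  toks <- names(masses)
  if (!length(heads)) {
    # try 3-residue heads only when nothing shorter fits
    grid <- expand.grid(a = toks, b = toks, c = toks, stringsAsFactors = FALSE)
    s <- masses[grid$a] + masses[grid$b] + masses[grid$c]
    hit <- which(abs(s - head_mass) <= tol)
    hit <- hit[order(abs(s[hit] - head_mass))]
    for (i in utils::head(hit, 50L)) {
      heads[[length(heads) + 1L]] <- list(tokens = unlist(grid[i, ], use.names = FALSE),
                                          composites = 1L,
                                          residual = abs(s[i] - head_mass))
    }
  }
  if (!length(heads)) {
    stop(errorCondition(
      sprintf("first b peak %.3f matches no b_n with n <= 3 within %.2f Da", b_peaks[1], tol),
      class = c("peptaibio_insufficient_ladder", "error", "condition")))
  }

  cands <- heads
  used <- 1L
  if (length(b_peaks) > 1L) {
    for (i in seq_len(length(b_peaks) - 1L)) {
      d <- b_peaks[i + 1L] - b_peaks[i]
      exps <- .expand_jump(d, tol, masses)
      if (!length(exps)) break  # unmatched gap: stop the walk here
      used <- i + 1L
      new <- list()
      for (cand in cands) {
        for (e in exps) {
          new[[length(new) + 1L]] <- list(
            tokens = c(cand$tokens, e),
            composites = cand$composites + as.integer(length(e) > 1L),
            residual = cand$residual + abs(sum(masses[e]) - d))
        }
      }
      # rank-prune to keep enumeration bounded
      ord <- order(vapply(new, function(x) x$composites, integer(1)),
                   vapply(new, function(x) x$residual, numeric(1)))
      cands <- new[utils::head(ord, 64L)]
    }
  }
  attr(cands, "peaks_used") <- used
  cands
}

# theoretical y7 family table for the C-terminal scaffold
# Pro13-Vxx14-Aib15-X16-Gln17-Z18-Lxxol19
.y7_families <- function() {
  fam <- expand.grid(r16 = c("Vxx", "Lxx"), r18 = c("Gln", "Glu"),
                     stringsAsFactors = FALSE)
  fam$suffix <- lapply(seq_len(nrow(fam)), function(i)
    c("Pro", "Vxx", "Aib", fam$r16[i], "Gln", fam$r18[i], "Lxxol"))
  fam$y7 <- vapply(fam$suffix, function(s)
    y_ion_mz(peptaibol_sequence(s, "H"), 7L), numeric(1))
  fam
}

#' Resolve the y7 fragment family
#'
#' Assigns the C-terminal scaffold Pro13-Vxx14-Aib15-X16-Gln17-Z18-Lxxol19
#' by nearest-variant matching of the observed y7 m/z against the four
#' canonical families (X16 in {Lxx, Vxx} x Z18 in {Gln, Glu}). MS2 sub-ions
#' (y1..y6 of the suffix), when given, refine positions 16-19 with
#' provenance `"ms2"`; positions 13-15 are always left unresolved for motif
#' fill (the y7-internal ions covering them are not observed).
#'
#' @param y7_mz observed y7 m/z (> 0).
#' @param ms2_subions optional numeric vector of MS2 sub-ion m/z values.
#' @param tol matching tolerance in Da.
#' @return data.frame with columns `position` (13..19), `token`,
#'   `provenance`; attribute `family` gives the (r16, r18) pair and the
#'   matching residual.
#' @export
resolve_y7 <- function(y7_mz, ms2_subions = NULL, tol = 0.6) {
  if (!is.finite(y7_mz) || y7_mz <= 0) {
    stop(errorCondition("y7 m/z must be positive",
                        class = c("peptaibio_domain_error", "error", "condition")))
  }
  fam <- .y7_families()
  res <- abs(fam$y7 - y7_mz)
  best <- which.min(res)
  if (res[best] > tol) {
    stop(errorCondition(
      sprintf("y7 %.3f matches no canonical variant within %.2f Da (nearest: %s16/%s18 at %.3f, residual %.3f)",
              y7_mz, tol, fam$r16[best], fam$r18[best], fam$y7[best], res[best]),
      class = c("peptaibio_unassigned_y7", "error", "condition")))
  }
  suffix <- fam$suffix[[best]]
  prov <- c("unresolved", "unresolved", "unresolved", "ms2", "closure", "ms2", "closure")
  if (length(ms2_subions)) {
    # sub-ions y1..y6 of the suffix confirm the C-terminal residues they span
    sub <- sort(ms2_subions)
    theo <- vapply(1:6, function(k) y_ion_mz(peptaibol_sequence(suffix, "H"), k), numeric(1))
    for (s in sub) {
      k <- which(abs(theo - s) <= tol)
      if (length(k)) {
        k <- k[which.min(abs(theo[k] - s))]
        span <- (7L - k + 1L):7L           # suffix positions covered by y_k
        prov[span[span >= 4L]] <- "ms2"    # refine 16..19 only
        if (k >= 4L) prov[4:7] <- "ms2"
      }
    }
  }
  out <- data.frame(position = 13:19, token = suffix, provenance = prov,
                    stringsAsFactors = FALSE)
  out$token[out$provenance == "unresolved"] <- NA_character_
  attr(out, "family") <- list(r16 = fam$r16[best], r18 = fam$r18[best],
                              residual = fam$y7[best] - y7_mz)
  out
}

#' Fill the Aib-Pro-Vxx-Aib motif gap
#'
#' The b14 fragment is suppressed after the Aib12-Pro13 bond and the
#' y7-internal ions covering positions 13-15 are not observed, so these
#' positions are predicted from the conserved Aib-Pro-Vxx-Aib motif:
#' Pro13, Vxx14, Aib15 with provenance `"motif"`. Observed calls are never
#' overwritten; an observed call that contradicts the motif raises a
#' motif-conflict error.
#'
#' @param assignment a `peptaibol_assignment` (or its `calls` data.frame).
#' @return the assignment with positions 13-15 filled.
#' @export
fill_motif <- function(assignment) {
  calls <- if (inherits(assignment, "peptaibol_assignment")) assignment$calls else assignment
  motif <- c(`13` = "Pro", `14` = "Vxx", `15` = "Aib")
  for (p in 13:15) {
    i <- which(calls$position == p)
    if (!length(i)) next
    tok <- motif[[as.character(p)]]
    if (calls$provenance[i] == "unresolved" || is.na(calls$token[i])) {
      calls$token[i] <- tok
      calls$provenance[i] <- "motif"
    } else if (calls$token[i] != tok) {
      stop(errorCondition(
        sprintf("observed %s at position %d conflicts with the Aib-Pro-Vxx-Aib motif (%s)",
                calls$token[i], p, tok),
        class = c("peptaibio_motif_conflict", "error", "condition")))
    } # equal observed call: left untouched
  }
  if (inherits(assignment, "peptaibol_assignment")) {
    assignment$calls <- calls
    assignment
  } else {
    calls
  }
}

.assignment <- function(calls, M_obs, closure_residual, tol) {
  status <- if (!any(is.na(calls$token)) &&
                !any(calls$provenance == "unresolved") &&
                is.finite(closure_residual) &&
                abs(closure_residual) <= tol) "complete" else "incomplete"
  structure(list(calls = calls, M_obs = M_obs,
                 closure_residual = closure_residual,
                 status = status, tol = tol),
            class = "peptaibol_assignment")
}

#' Assemble a peptaibol sequence from a peak list
#'
#' Full de novo pipeline for the 19-residue acetyl-capped amino-alcohol
#' scaffold: adduct deconvolution, b-ladder walking over positions 1-12,
#' y7 family resolution for positions 16-19, motif fill for 13-15, and
#' mass-closure validation. Ambiguous ladder expansions are ranked by
#' (fewer unresolved positions, fewer composite jumps, smaller absolute
#' closure residual, N-terminal Aib motif support, token string).
#'
#' @param peaks a [peak_list()] containing at least one adduct peak and a
#'   b-ion series; `kind` labels are used when present, otherwise peaks are
#'   classified against the adduct/y7 expectations.
#' @param tol matching tolerance in Da (default 0.6, unit-resolution trap).
#' @return a `peptaibol_assignment`: per-position calls with provenance,
#'   observed neutral mass, closure residual and completion status.
#' @export
assemble_sequence <- function(peaks, tol = 0.6) {
  stopifnot(inherits(peaks, "peak_list"))
  M_obs <- deconvolute_adducts(peaks, tol)

  labelled <- !is.na(peaks$kind)
  b_peaks <- peaks$mz[labelled & peaks$kind == "b"]
  y7_mz <- peaks$mz[labelled & peaks$kind == "y7"]
  ms2 <- peaks$mz[labelled & peaks$kind == "ms2"]

  if (!any(labelled)) {
    # classify unlabelled peaks: adducts out, y7 by family match, rest -> b
    fam <- .y7_families()
    is_add <- abs(peaks$mz - (M_obs + NA_CATION)) <= tol |
      abs(peaks$mz - (M_obs + 2 * NA_CATION) / 2) <= tol
    is_y7 <- !is_add & vapply(peaks$mz, function(m) any(abs(fam$y7 - m) <= tol), logical(1))
    y7_mz <- peaks$mz[is_y7]
    b_peaks <- peaks$mz[!is_add & !is_y7]
  }
  if (length(b_peaks) < 2L) {
    stop(errorCondition("peak list contains no usable b-ion series",
                        class = c("peptaibio_insufficient_ladder", "error", "condition")))
  }

  ladder <- walk_b_ladder(sort(b_peaks), tol)

  y7_calls <- if (length(y7_mz)) resolve_y7(y7_mz[1], ms2, tol) else
    data.frame(position = 13:19, token = NA_character_,
               provenance = "unresolved", stringsAsFactors = FALSE)

  build <- function(cand) {
    tokens <- rep(NA_character_, 19L)
    prov <- rep("unresolved", 19L)
    m <- min(length(cand$tokens), 19L)
    tokens[seq_len(m)] <- cand$tokens[seq_len(m)]
    prov[seq_len(m)] <- "ladder"
    for (i in seq_len(nrow(y7_calls))) {
      p <- y7_calls$position[i]
      if (prov[p] == "unresolved" && !is.na(y7_calls$token[i])) {
        tokens[p] <- y7_calls$token[i]
        prov[p] <- y7_calls$provenance[i]
      }
    }
    calls <- data.frame(position = 1:19, token = tokens, provenance = prov,
                        stringsAsFactors = FALSE)
    calls <- tryCatch(fill_motif(calls), peptaibio_motif_conflict = function(e) calls)
    closure <- if (any(is.na(calls$token))) NA_real_ else
      M_obs - neutral_mass(peptaibol_sequence(calls$token, "Ac"))
    list(calls = calls, closure = closure,
         n_unres = sum(is.na(calls$token)),
         composites = cand$composites,
         aib_start = identical(calls$token[1], "Aib"),
         key = paste(calls$token, collapse = "-"))
  }

  built <- lapply(ladder, build)
  ord <- order(vapply(built, function(x) x$n_unres, numeric(1)),
               vapply(built, function(x) x$composites, numeric(1)),
               # closure compared at 1e-6 Da so isobaric candidates tie exactly
               vapply(built, function(x) ifelse(is.na(x$closure), Inf, round(abs(x$closure), 6)), numeric(1)),
               -vapply(built, function(x) as.numeric(x$aib_start), numeric(1)),
               vapply(built, function(x) x$key, character(1)))
  best <- built[[ord[1]]]

  complete_possible <- !is.na(best$closure) && abs(best$closure) <= tol
  if (!is.na(best$closure) && !complete_possible &&
      all(vapply(built, function(x) is.na(x$closure) || abs(x$closure) > tol, logical(1)))) {
    warning(sprintf("no candidate closes the observed mass within %.2f Da (best residual %.3f)",
                    tol, best$closure))
  }
  out <- .assignment(best$calls, M_obs, best$closure, tol)
  out$adduct_residual <- attr(M_obs, "residual")
  out
}

#' Extract the called sequence from an assignment
#'
#' @param assignment a `peptaibol_assignment` with no unresolved positions.
#' @return a `peptaibol_sequence` (acetyl-capped, class tokens).
#' @export
assignment_sequence <- function(assignment) {
  stopifnot(inherits(assignment, "peptaibol_assignment"))
  if (any(is.na(assignment$calls$token))) {
    stop(errorCondition("assignment has unresolved positions",
                        class = c("peptaibio_invalid_sequence", "error", "condition")))
  }
  peptaibol_sequence(assignment$calls$token, "Ac")
}

#' @export
print.peptaibol_assignment <- function(x, ...) {
  cat(sprintf("<peptaibol_assignment> status: %s\n  M_obs = %.3f, closure residual = %s (tol %.2f)\n",
              x$status, x$M_obs,
              ifelse(is.na(x$closure_residual), "NA", sprintf("%+.3f", x$closure_residual)),
              x$tol))
  seq_str <- paste(ifelse(is.na(x$calls$token), "?", x$calls$token), collapse = "-")
  cat(sprintf("  Ac-%s\n", seq_str))
  prov <- table(x$calls$provenance)
  cat("  provenance:", paste(sprintf("%s=%d", names(prov), prov), collapse = ", "), "\n")
  invisible(x)
}

#' Write an assignment report TSV
#'
#' Columns `position`, `token`, `provenance`, preceded by comment lines
#' carrying the observed neutral mass, closure residual and status.
#'
#' @param assignment a `peptaibol_assignment`.
#' @param path output path.
#' @export
write_assignment_tsv <- function(assignment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# M_obs\t%.4f", assignment$M_obs), con)
  writeLines(sprintf("# closure_residual\t%s",
                     ifelse(is.na(assignment$closure_residual), "NA",
                            sprintf("%.4f", assignment$closure_residual))), con)
  writeLines(sprintf("# status\t%s", assignment$status), con)
  utils::write.table(assignment$calls, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
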