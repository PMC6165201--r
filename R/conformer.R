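# Conformational-ensemble statistics: backbone dihedrals, per-residue
# Ramachandran free-energy surfaces, helix-region classification, backbone
# hydrogen-bond detection with turn-type classes, RMSD-to-average and radius
# of gyration, and 2D free-energy landscapes.
#
# Ensembles follow the bio3d xyz convention: one row per frame, columns
# (x1, y1, z1, x2, ...) over atoms; the atom table holds residue numbers and
# atom names (N, CA, C, O, H).

#' Construct a backbone ensemble
#'
#' @param xyz numeric matrix, one row per frame, `3 * n_atoms` columns.
#' @param atoms data.frame with columns `resno` (residue index) and `elety`
#'   (atom name: N, CA, C, O, H).
#' @param labels optional residue labels (tokens), length `max(resno)`.
#' @return object of class `backbone_ensemble`.
#' @export
backbone_ensemble <- function(xyz, atoms, labels = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(atoms)) {
    stop(errorCondition("xyz columns must equal 3 * number of atoms",
                        class = c("peptaibio_topology_error", "error", "condition")))
  }
  if (any(!is.finite(xyz))) {
    stop(errorCondition("ensemble coordinates must be finite",
                        class = c("peptaibio_topology_error", "error", "condition")))
  }
  if (is.null(labels)) labels <- rep(NA_character_, max(atoms$resno))
  structure(list(xyz = xyz, atoms = atoms, labels = labels),
            class = "backbone_ensemble")
}

#' @export
print.backbone_ensemble <- function(x, ...) {
  cat(sprintf("<backbone_ensemble> %d frame(s), %d residues, %d atoms/frame\n",
              nrow(x$xyz), max(x$atoms$resno), nrow(x$atoms)))
  invisible(x)
}

# coordinates of one frame as an n_atoms x 3 matrix
.frame_coords <- function(ens, frame) {
  matrix(ens$xyz[frame, ], ncol = 3L, byrow = TRUE)
}

# index of a given atom in a given residue (NA if absent)
.atom_index <- function(atoms, resno, elety) {
  i <- which(atoms$resno == resno & atoms$elety == elety)
  if (length(i)) i[1] else NA_integer_
}

#' Read a multi-model PDB into a backbone ensemble
#'
#' Uses MODEL/ENDMDL records (via bio3d); retains backbone atoms
#' N, CA, C, O and amide H.
#'
#' @param path PDB file path.
#' @return a [backbone_ensemble()].
#' @export
read_ensemble <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  keep <- pdb$atom$elety %in% c("N", "CA", "C", "O", "H")
  atoms <- data.frame(resno = pdb$atom$resno[keep], elety = pdb$atom$elety[keep],
                      stringsAsFactors = FALSE)
  # renumber residues 1..n in order of appearance
  atoms$resno <- match(atoms$resno, unique(atoms$resno))
  cols <- as.vector(rbind(3 * which(keep) - 2, 3 * which(keep) - 1, 3 * which(keep)))
  xyz <- pdb$xyz[, cols, drop = FALSE]
  labels <- pdb$atom$resid[keep][!duplicated(atoms$resno)]
  backbone_ensemble(xyz, atoms, labels)
}

#' Write a backbone ensemble as a multi-model PDB
#'
#' @param ens a [backbone_ensemble()].
#' @param path output path.
#' @export
write_ensemble <- function(ens, path) {
  con <- file(path, "w")
  on.exit(close(con))
  lab <- ens$labels
  lab[is.na(lab)] <- "ALA"
  lab3 <- toupper(substr(lab, 1, 3))
  for (f in seq_len(nrow(ens$xyz))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- .frame_coords(ens, f)
    for (a in seq_len(nrow(ens$atoms))) {
      el <- ens$atoms$elety[a]
      writeLines(sprintf("ATOM  %5d %-4s%-4s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                         a, ifelse(nchar(el) < 4, paste0(" ", el), el),
                         lab3[ens$atoms$resno[a]], ens$atoms$resno[a],
                         xyz[a, 1], xyz[a, 2], xyz[a, 3],
                         substr(el, 1, 1)), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# signed dihedral angle (degrees) for points a, b, c, d (rows of matrices)
.torsion <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- -sum(m1 * n2)   # IUPAC sign convention
  atan2(y, x) * 180 / pi
}

#' Backbone dihedral angles of an ensemble
#'
#' Standard torsions: Phi(C_{i-1}, N_i, CA_i, C_i) and
#' Psi(N_i, CA_i, C_i, N_{i+1}), in degrees in (-180, 180]. Phi of residue 1
#' and Psi of the last residue are `NA`.
#'
#' @param ens a [backbone_ensemble()].
#' @return object of class `dihedral_series`: list of matrices `phi`, `psi`
#'   (frames x residues).
#' @export
backbone_dihedrals <- function(ens) {
  stopifnot(inherits(ens, "backbone_ensemble"))
  n_res <- max(ens$atoms$resno)
  n_fr <- nrow(ens$xyz)
  idx <- function(r, el) .atom_index(ens$atoms, r, el)
  for (r in seq_len(n_res)) {
    for (el in c("N", "CA", "C")) {
      if (is.na(idx(r, el))) {
        stop(errorCondition(sprintf("residue %d is missing backbone atom %s", r, el),
                            class = c("peptaibio_topology_error", "error", "condition")))
      }
    }
  }
  phi <- matrix(NA_real_, n_fr, n_res)
  psi <- matrix(NA_real_, n_fr, n_res)
  for (f in seq_len(n_fr)) {
    xyz <- .frame_coords(ens, f)
    for (r in seq_len(n_res)) {
      if (r > 1L) {
        phi[f, r] <- .torsion(xyz[idx(r - 1L, "C"), ], xyz[idx(r, "N"), ],
                              xyz[idx(r, "CA"), ], xyz[idx(r, "C"), ])
      }
      if (r < n_res) {
        psi[f, r] <- .torsion(xyz[idx(r, "N"), ], xyz[idx(r, "CA"), ],
                              xyz[idx(r, "C"), ], xyz[idx(r + 1L, "N"), ])
      }
    }
  }
  structure(list(phi = phi, psi = psi), class = "dihedral_series")
}

# shared free-energy histogram: dG = -RT ln(P / Pmax), empty bins NA
.fes_hist <- function(x, y, xbreaks, ybreaks, temperature) {
  ix <- findInterval(x, xbreaks, rightmost.closed = TRUE)
  iy <- findInterval(y, ybreaks, rightmost.closed = TRUE)
  ok <- ix >= 1 & ix <= length(xbreaks) - 1 & iy >= 1 & iy <= length(ybreaks) - 1
  counts <- matrix(0L, length(xbreaks) - 1L, length(ybreaks) - 1L)
  for (i in which(ok)) counts[ix[i], iy[i]] <- counts[ix[i], iy[i]] + 1L
  p <- counts / sum(counts)
  dG <- matrix(NA_real_, nrow(p), ncol(p))
  occ <- counts > 0L
  dG[occ] <- -GAS_CONSTANT_KCAL * temperature * log(p[occ] / max(p))
  structure(list(x_breaks = xbreaks, y_breaks = ybreaks, dG = dG,
                 counts = counts, temperature = temperature),
            class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  cat(sprintf("<fes_grid> %d x %d bins, T = %g K, occupied %d, max dG %.3f kcal/mol\n",
              nrow(x$dG), ncol(x$dG), x$temperature, sum(!is.na(x$dG)),
              max(x$dG, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.fes_grid <- function(x, xlab = "x", ylab = "y", ...) {
  xm <- (x$x_breaks[-1] + x$x_breaks[-length(x$x_breaks)]) / 2
  ym <- (x$y_breaks[-1] + x$y_breaks[-length(x$y_breaks)]) / 2
  graphics::image(xm, ym, x$dG, xlab = xlab, ylab = ylab,
                  col = grDevices::hcl.colors(24, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}

#' Ramachandran free-energy surface for one residue
#'
#' 2D occupancy histogram over (Phi, Psi) transformed to relative free
#' energy `dG = -RT ln(P / Pmax)` (kcal/mol); the minimum over occupied bins
#' is exactly 0 and empty bins are masked (`NA`).
#'
#' @param dihedrals a `dihedral_series` from [backbone_dihedrals()].
#' @param residue residue index.
#' @param bins number of bins per axis over [-180, 180] (default 72).
#' @param temperature temperature in K (default 300).
#' @return a `fes_grid`.
#' @export
rama_free_energy <- function(dihedrals, residue, bins = 72L, temperature = 300) {
  stopifnot(inherits(dihedrals, "dihedral_series"), bins >= 2L)
  phi <- dihedrals$phi[, residue]
  psi <- dihedrals$psi[, residue]
  ok <- is.finite(phi) & is.finite(psi)
  if (!any(ok)) {
    stop(errorCondition(sprintf("residue %d has no defined (Phi, Psi) pairs (chain terminus?)", residue),
                        class = c("peptaibio_undefined_residue", "error", "condition")))
  }
  br <- seq(-180, 180, length.out = bins + 1L)
  .fes_hist(phi[ok], psi[ok], br, br, temperature)
}

#' Free-energy landscape over two order parameters
#'
#' The same `-RT ln(P / Pmax)` transform as [rama_free_energy()], applied to
#' any pair of equal-length series (canonically RMSD-to-average vs radius of
#' gyration).
#'
#' @param x,y equal-length numeric series.
#' @param bins bins per axis.
#' @param temperature temperature in K.
#' @return a `fes_grid`.
#' @export
fes_2d <- function(x, y, bins = 50L, temperature = 300) {
  if (length(x) != length(y)) {
    stop(errorCondition("series lengths differ",
                        class = c("peptaibio_domain_error", "error", "condition")))
  }
  pad <- function(v) {
    r <- range(v)
    if (diff(r) == 0) r <- r + c(-0.5, 0.5)
    seq(r[1] - 1e-9, r[2] + 1e-9, length.out = bins + 1L)
  }
  .fes_hist(x, y, pad(x), pad(y), temperature)
}

# Ramachandran boxes (degrees). Subset precedence: 3_10 before alpha;
# left-handed helix boxes are point reflections of the right-handed ones.
.region_boxes <- list(
  three10_R = c(-80, -40, -45, -10),
  three10_L = c(40, 80, 10, 45),
  alpha_R   = c(-100, -30, -80, -5),
  alpha_L   = c(30, 100, 5, 80),
  ppII      = c(-90, -20, 120, 180),
  beta      = c(-180, -90, 90, 180)
)

#' Classify a Ramachandran point into a secondary-structure region
#'
#' Rectangular regions: right-/left-handed 3_10 (tested first, as a subset
#' of the alpha boxes), right-/left-handed alpha, polyproline II and beta;
#' anything else is `"other"`. Left-handed helix boxes are the point
#' reflections of the right-handed ones.
#'
#' @param phi,psi angles in degrees (vectorised).
#' @return character vector over `{alpha_R, alpha_L, three10_R, three10_L,
#'   beta, ppII, other}`.
#' @export
classify_region <- function(phi, psi) {
  stopifnot(length(phi) == length(psi))
  out <- rep("other", length(phi))
  for (nm in names(.region_boxes)) {
    b <- .region_boxes[[nm]]
    hit <- out == "other" & !is.na(phi) & !is.na(psi) &
      phi >= b[1] & phi <= b[2] & psi >= b[3] & psi <= b[4]
    out[hit] <- nm
  }
  out[is.na(phi) | is.na(psi)] <- NA_character_
  out
}

# reconstruct the amide H of residue r in one frame: 1.01 A from N along
# the direction opposing the bisector of N->C(prev) and N->CA
.place_amide_h <- function(xyz, atoms, r) {
  iN <- .atom_index(atoms, r, "N")
  iCA <- .atom_index(atoms, r, "CA")
  iCp <- .atom_index(atoms, r - 1L, "C")
  if (is.na(iCp)) return(NULL)
  N <- xyz[iN, ]
  v1 <- xyz[iCp, ] - N; v1 <- v1 / sqrt(sum(v1^2))
  v2 <- xyz[iCA, ] - N; v2 <- v2 / sqrt(sum(v2^2))
  d <- -(v1 + v2); d <- d / sqrt(sum(d^2))
  N + 1.01 * d
}

#' Detect backbone hydrogen bonds and classify turn types
#'
#' A hydrogen bond in a frame is acceptor O(i) ... donor N(j) with
#' heavy-atom N-O distance <= `dist_cut` and N-H...O angle >= `ang_cut`
#' (angle at H). Amide hydrogens are reconstructed geometrically when absent
#' from the input (1.01 A along the bisector-opposed direction); set
#' `reconstruct_h = FALSE` to require explicit H atoms. Statistics are
#' aggregated over frames; the turn class follows the donor-acceptor
#' separation j - i: 2 = gamma turn, 3 = 3_10 helix, 4 = alpha helix,
#' anything else "other".
#'
#' @param ens a [backbone_ensemble()].
#' @param dist_cut heavy-atom N...O cutoff in Angstrom (default 3.5).
#' @param ang_cut minimum N-H...O angle in degrees (default 135).
#' @param reconstruct_h reconstruct missing amide hydrogens (default TRUE).
#' @return data.frame of class `hbond_stats`: `acceptor`, `donor`
#'   (residue indices), `acceptor_label`, `donor_label`, `fraction`
#'   (occurrence over frames), `mean_distance` (A, over bonded frames),
#'   `turn_class`; sorted by descending fraction.
#' @export
detect_hbonds <- function(ens, dist_cut = 3.5, ang_cut = 135, reconstruct_h = TRUE) {
  stopifnot(inherits(ens, "backbone_ensemble"))
  n_res <- max(ens$atoms$resno)
  n_fr <- nrow(ens$xyz)
  has_h <- any(ens$atoms$elety == "H")
  if (!has_h && !reconstruct_h) {
    stop(errorCondition("no amide hydrogens present and reconstruction disabled",
                        class = c("peptaibio_topology_error", "error", "condition")))
  }
  counts <- list()
  for (f in seq_len(n_fr)) {
    xyz <- .frame_coords(ens, f)
    for (j in 2:n_res) {                      # donors (residue 1 has no amide H here)
      iN <- .atom_index(ens$atoms, j, "N")
      iH <- .atom_index(ens$atoms, j, "H")
      H <- if (!is.na(iH)) xyz[iH, ] else if (reconstruct_h)
        .place_amide_h(xyz, ens$atoms, j) else NULL
      if (is.null(H)) next
      N <- xyz[iN, ]
      for (i in seq_len(n_res)) {
        if (abs(j - i) < 2L) next             # exclude self and adjacent
        iO <- .atom_index(ens$atoms, i, "O")
        if (is.na(iO)) next
        O <- xyz[iO, ]
        dNO <- sqrt(sum((N - O)^2))
        if (dNO > dist_cut) next
        vHN <- N - H; vHO <- O - H
        ang <- acos(pmin(1, pmax(-1, sum(vHN * vHO) /
                                   sqrt(sum(vHN^2) * sum(vHO^2))))) * 180 / pi
        if (ang < ang_cut) next
        key <- paste(i, j)
        if (is.null(counts[[key]])) counts[[key]] <- c(0, 0)
        counts[[key]] <- counts[[key]] + c(1, dNO)
      }
    }
  }
  if (!length(counts)) {
    out <- data.frame(acceptor = integer(0), donor = integer(0),
                      acceptor_label = character(0), donor_label = character(0),
                      fraction = numeric(0), mean_distance = numeric(0),
                      turn_class = character(0), stringsAsFactors = FALSE)
    class(out) <- c("hbond_stats", "data.frame")
    return(out)
  }
  ij <- do.call(rbind, lapply(strsplit(names(counts), " "), as.integer))
  n <- vapply(counts, `[`, numeric(1), 1)
  s <- vapply(counts, `[`, numeric(1), 2)
  sep <- ij[, 2] - ij[, 1]
  out <- data.frame(
    acceptor = ij[, 1], donor = ij[, 2],
    acceptor_label = ens$labels[ij[, 1]], donor_label = ens$labels[ij[, 2]],
    fraction = n / n_fr, mean_distance = s / n,
    turn_class = ifelse(sep == 2, "i+2_gamma",
                 ifelse(sep == 3, "i+3_310",
                 ifelse(sep == 4, "i+4_alpha", "other"))),
    stringsAsFactors = FALSE)
  out <- out[order(-out$fraction, out$acceptor), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hbond_stats", "data.frame")
  out
}

#' Write a hydrogen-bond table TSV
#'
#' Columns mirror the published layout: Acceptor, Donor, Fraction,
#' Average Distance, Class.
#'
#' @param hb an `hbond_stats` data.frame.
#' @param path output path.
#' @export
write_hbond_tsv <- function(hb, path) {
  df <- data.frame(
    Acceptor = ifelse(is.na(hb$acceptor_label), hb$acceptor,
                      paste0(hb$acceptor_label, "_", hb$acceptor)),
    Donor = ifelse(is.na(hb$donor_label), hb$donor,
                   paste0(hb$donor_label, "_", hb$donor)),
    Fraction = hb$fraction, `Average.Distance` = hb$mean_distance,
    Class = hb$turn_class, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Kabsch rotation aligning P (n x 3) onto Q (n x 3), both centred
.kabsch_rotation <- function(P, Q) {
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

# selected-atom coordinates per frame, as a list of n_sel x 3 matrices
.selected_frames <- function(ens, atom_selection) {
  sel <- which(ens$atoms$elety %in% atom_selection)
  if (!length(sel)) {
    stop(errorCondition("empty atom selection",
                        class = c("peptaibio_domain_error", "error", "condition")))
  }
  lapply(seq_len(nrow(ens$xyz)), function(f) .frame_coords(ens, f)[sel, , drop = FALSE])
}

#' RMSD of each frame to the ensemble-average structure
#'
#' Frames are centred and superposed (Kabsch, optimal rotation) onto their
#' coordinate average; the average is recomputed once from the superposed
#' frames; per-frame RMSD to that average is returned.
#'
#' @param ens a [backbone_ensemble()] with >= 2 frames.
#' @param atom_selection atom names used (default backbone C, CA, N).
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_to_average <- function(ens, atom_selection = c("C", "CA", "N")) {
  stopifnot(inherits(ens, "backbone_ensemble"))
  if (nrow(ens$xyz) < 2L) {
    stop(errorCondition("need at least 2 frames for RMSD to the average",
                        class = c("peptaibio_insufficient_ensemble", "error", "condition")))
  }
  frames <- .selected_frames(ens, atom_selection)
  centred <- lapply(frames, function(m) sweep(m, 2, colMeans(m)))
  avg <- Reduce(`+`, centred) / length(centred)
  aligned <- lapply(centred, function(m) m %*% .kabsch_rotation(m, avg))
  avg2 <- Reduce(`+`, aligned) / length(aligned)
  vapply(aligned, function(m) sqrt(mean(rowSums((m - avg2)^2))), numeric(1))
}

#' Radius of gyration
#'
#' Root-mean-square distance of the selected atoms from their centre of
#' mass (unit masses).
#'
#' @param ens a [backbone_ensemble()], or a single `n x 3` coordinate matrix.
#' @param atom_selection atom names used when `ens` is an ensemble.
#' @return numeric vector (one value per frame), or a scalar for a matrix.
#' @export
radius_of_gyration <- function(ens, atom_selection = c("C", "CA", "N")) {
  rog1 <- function(m) {
    if (!nrow(m)) {
      stop(errorCondition("empty atom selection",
                          class = c("peptaibio_domain_error", "error", "condition")))
    }
    sqrt(mean(rowSums(sweep(m, 2, colMeans(m))^2)))
  }
  if (is.matrix(ens)) return(rog1(ens))
  stopifnot(inherits(ens, "backbone_ensemble"))
  vapply(.selected_frames(ens, atom_selection), rog1, numeric(1))
}
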