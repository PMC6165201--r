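# Seeded forward models: instrument-like peak lists from sequences, and
# helical backbone ensembles with designed secondary structure. These make
# every analysis stage testable without instrument or trajectory data.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate an ESI-IT peak list from a peptaibol sequence
#'
#' Emits the sodiated adduct peaks, the b-ion series minus the dropout set,
#' the y7 fragment and optionally MS2 y-sub-ions, each perturbed by Gaussian
#' m/z noise. The default dropout reflects the characteristic missing
#' fragments of peptaibol spectra: b1 (single-residue acylium, rarely
#' observed) and b13/b14 (suppressed after the Aib12-Pro13 bond).
#' Intensities are drawn log-uniformly. Deterministic under a fixed seed.
#'
#' @param seq a `peptaibol_sequence` or token string.
#' @param noise_sigma Gaussian m/z noise width in Da (>= 0).
#' @param dropout character vector of fragment labels to omit, e.g.
#'   `c("b1", "b13", "b14")`; `"b*"` drops the whole b series.
#' @param adducts subset of `c("M+Na", "M+2Na")` to emit.
#' @param ms2_depth number of y-sub-ions (y1..y6 of the y7 suffix) to emit.
#' @param rt retention time to stamp on the peak list (minutes).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a [peak_list()] with `kind` labels.
#' @export
simulate_peaklist <- function(seq, noise_sigma = 0.05,
                              dropout = c("b1", "b13", "b14"),
                              adducts = c("M+Na", "M+2Na"),
                              ms2_depth = 0L, rt = NA_real_, seed = NULL) {
  seq <- .as_sequence(seq)
  stopifnot(noise_sigma >= 0)
  n <- length(seq$residues)
  .with_seed(seed, {
    mz <- numeric(0); kind <- character(0)
    M <- neutral_mass(seq)
    if ("M+Na" %in% adducts) { mz <- c(mz, adduct_mz(M, "M+Na")); kind <- c(kind, "MNa") }
    if ("M+2Na" %in% adducts) { mz <- c(mz, adduct_mz(M, "M+2Na")); kind <- c(kind, "M2Na") }
    if (!"b*" %in% dropout) {
      bn <- setdiff(seq_len(n - 1L), as.integer(sub("^b", "", grep("^b[0-9]+$", dropout, value = TRUE))))
      if (length(bn)) {
        mz <- c(mz, b_ion_mz(seq, bn)); kind <- c(kind, rep("b", length(bn)))
      }
    }
    if (n >= 7L && !"y7" %in% dropout) {
      mz <- c(mz, y_ion_mz(seq, 7L)); kind <- c(kind, "y7")
      depth <- min(as.integer(ms2_depth), 6L)
      if (depth > 0L) {
        suffix <- peptaibol_sequence(seq$residues[(n - 6L):n], "H")
        ks <- seq.int(6L, by = -1L, length.out = depth)  # deepest sub-ions first
        mz <- c(mz, vapply(ks, function(k) y_ion_mz(suffix, k), numeric(1)))
        kind <- c(kind, rep("ms2", depth))
      }
    }
    noisy <- mz + stats::rnorm(length(mz), 0, noise_sigma)
    inten <- 10^stats::runif(length(mz), 2, 5)
    peak_list(noisy, inten, kind, rt = rt)
  })
}

# place atom D given A, B, C with bond length |CD|, angle B-C-D (deg) and
# torsion A-B-C-D (deg): standard internal-coordinate (NeRF) construction
.place_atom <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Build one backbone frame (atoms N, CA, C, O per residue) from per-residue
# (phi, psi) vectors. Standard peptide geometry: N-CA 1.458, CA-C 1.525,
# C-N 1.329, C=O 1.231 A; angles C-N-CA 121.7, N-CA-C 111.0, CA-C-N 116.6,
# CA-C-O 120.5 deg; omega fixed at 180.
.build_backbone <- function(phi, psi) {
  n <- length(phi)
  xyz <- matrix(NA_real_, 4L * n, 3L)
  rownames(xyz) <- paste(rep(seq_len(n), each = 4L), c("N", "CA", "C", "O"))
  i <- function(r, el) 4L * (r - 1L) + match(el, c("N", "CA", "C", "O"))
  xyz[i(1, "N"), ] <- c(0, 0, 0)
  xyz[i(1, "CA"), ] <- c(1.458, 0, 0)
  xyz[i(1, "C"), ] <- c(1.458 + 1.525 * cos(pi - 111 * pi / 180),
                        1.525 * sin(pi - 111 * pi / 180), 0)
  for (r in seq_len(n)) {
    if (r > 1L) {
      xyz[i(r, "CA"), ] <- .place_atom(xyz[i(r - 1L, "CA"), ], xyz[i(r - 1L, "C"), ],
                                       xyz[i(r, "N"), ], 1.458, 121.7, 180)
      xyz[i(r, "C"), ] <- .place_atom(xyz[i(r - 1L, "C"), ], xyz[i(r, "N"), ],
                                      xyz[i(r, "CA"), ], 1.525, 111.0, phi[r])
    }
    if (r < n) {
      xyz[i(r + 1L, "N"), ] <- .place_atom(xyz[i(r, "N"), ], xyz[i(r, "CA"), ],
                                           xyz[i(r, "C"), ], 1.329, 116.6, psi[r])
    }
    xyz[i(r, "O"), ] <- .place_atom(xyz[i(r, "N"), ], xyz[i(r, "CA"), ],
                                    xyz[i(r, "C"), ], 1.231, 120.5, psi[r] + 180)
  }
  xyz
}

#' Generate a helical backbone ensemble
#'
#' Builds N/CA/C/O backbone coordinates from the canonical (Phi, Psi) of the
#' chosen helix type and handedness -- alpha: (-57, -47), 3_10: (-49, -26),
#' signs flipped for the left-handed mirror -- with optional per-frame
#' Gaussian jitter on every angle. Deterministic under a fixed seed.
#'
#' @param n_residues chain length (>= 4).
#' @param helix_type `"alpha"` or `"three10"`.
#' @param handedness `"right"` or `"left"`.
#' @param jitter_sigma Gaussian angle jitter in degrees (>= 0).
#' @param n_frames number of frames (>= 1).
#' @param labels optional residue labels stored in the ensemble.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a [backbone_ensemble()].
#' @export
generate_helix_ensemble <- function(n_residues, helix_type = c("alpha", "three10"),
                                    handedness = c("right", "left"),
                                    jitter_sigma = 0, n_frames = 1L,
                                    labels = NULL, seed = NULL) {
  helix_type <- match.arg(helix_type)
  handedness <- match.arg(handedness)
  stopifnot(n_residues >= 4L, n_frames >= 1L, jitter_sigma >= 0)
  canon <- switch(helix_type, alpha = c(-57, -47), three10 = c(-49, -26))
  if (handedness == "left") canon <- -canon
  atoms <- data.frame(resno = rep(seq_len(n_residues), each = 4L),
                      elety = rep(c("N", "CA", "C", "O"), n_residues),
                      stringsAsFactors = FALSE)
  .with_seed(seed, {
    xyz <- matrix(NA_real_, n_frames, 3L * nrow(atoms))
    for (f in seq_len(n_frames)) {
      phi <- canon[1] + stats::rnorm(n_residues, 0, jitter_sigma)
      psi <- canon[2] + stats::rnorm(n_residues, 0, jitter_sigma)
      xyz[f, ] <- as.vector(t(.build_backbone(phi, psi)))
    }
    backbone_ensemble(xyz, atoms, labels)
  })
}
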