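# Ensemble statistics: dihedrals, region classification, free-energy
# surfaces, hydrogen bonds, RMSD and radius of gyration.

mirror_ensemble <- function(ens) {
  xyz <- ens$xyz
  xyz[, seq(3, ncol(xyz), by = 3)] <- -xyz[, seq(3, ncol(xyz), by = 3)]
  backbone_ensemble(xyz, ens$atoms, ens$labels)
}

rigid_move <- function(ens, angle = 0.7, shift = c(5, -3, 2)) {
  R <- matrix(c(cos(angle), -sin(angle), 0, sin(angle), cos(angle), 0, 0, 0, 1), 3, 3)
  xyz <- t(apply(ens$xyz, 1, function(row) {
    m <- matrix(row, ncol = 3, byrow = TRUE)
    as.vector(t(sweep(m %*% R, 2, shift, `+`)))
  }))
  backbone_ensemble(xyz, ens$atoms, ens$labels)
}

test_that("ideal helices measure their canonical dihedrals", {
  ens <- generate_helix_ensemble(10, "alpha", "right")
  d <- backbone_dihedrals(ens)
  expect_true(all(abs(d$phi[1, 2:9] - (-57)) < 1e-6))
  expect_true(all(abs(d$psi[1, 2:9] - (-47)) < 1e-6))
  expect_true(is.na(d$phi[1, 1]))   # Phi undefined at the N-terminus
  expect_true(is.na(d$psi[1, 10]))  # Psi undefined at the C-terminus
  # torsion sign convention agrees with an independent implementation
  skip_if_not_installed("bio3d")
  set.seed(41)
  for (i in 1:10) {
    m <- matrix(rnorm(12), 4, 3)
    expect_equal(peptaibio:::.torsion(m[1, ], m[2, ], m[3, ], m[4, ]),
                 as.numeric(bio3d::torsion.xyz(as.vector(t(m)), atm.inc = 4)),
                 tolerance = 1e-8)
  }
})

test_that("mirroring coordinates flips every dihedral sign", {
  ens <- generate_helix_ensemble(8, "three10", "right", jitter_sigma = 12,
                                 n_frames = 5, seed = 42)
  d <- backbone_dihedrals(ens)
  dm <- backbone_dihedrals(mirror_ensemble(ens))
  expect_equal(dm$phi, -d$phi, tolerance = 1e-8)
  expect_equal(dm$psi, -d$psi, tolerance = 1e-8)
  # and maps the classification between handedness partners
  ok <- !is.na(d$phi) & !is.na(d$psi)
  cls <- classify_region(d$phi[ok], d$psi[ok])
  clsm <- classify_region(-d$phi[ok], -d$psi[ok])
  swap <- c(alpha_R = "alpha_L", alpha_L = "alpha_R", three10_R = "three10_L",
            three10_L = "three10_R")
  for (i in seq_along(cls)) {
    if (cls[i] %in% names(swap)) expect_identical(clsm[i], unname(swap[cls[i]]))
  }
})

test_that("region boxes classify canonical points", {
  expect_identical(classify_region(-57, -47), "alpha_R")
  expect_identical(classify_region(57, 47), "alpha_L")
  expect_identical(classify_region(-49, -26), "three10_R")
  expect_identical(classify_region(49, 26), "three10_L")
  expect_identical(classify_region(-75, 145), "ppII")
  expect_identical(classify_region(-120, 150), "beta")
  expect_identical(classify_region(0, 0), "other")
  expect_true(is.na(classify_region(NA, 10)))
})

test_that("Ramachandran free energy has an exact zero floor and a mask", {
  # equal occupancy over distinct bins: dG identically 0 where occupied
  ens <- generate_helix_ensemble(6, "alpha", "right")
  d0 <- backbone_dihedrals(ens)
  centres <- seq(-175, 175, by = 10)
  d <- list(phi = cbind(NA, matrix(rep(centres, 2), ncol = 2), NA),
            psi = cbind(NA, matrix(rep(centres, 2), ncol = 2), NA))
  class(d) <- "dihedral_series"
  g <- rama_free_energy(d, residue = 2, bins = 36)
  expect_true(all(g$dG[!is.na(g$dG)] == 0))
  expect_true(any(is.na(g$dG)))  # empty bins masked
  # two-state occupancy 0.8 / 0.2 at 300 K
  ang <- c(rep(-57, 80), rep(60, 20))
  d2 <- list(phi = cbind(NA_real_, ang), psi = cbind(NA_real_, ang))
  class(d2) <- "dihedral_series"
  g2 <- rama_free_energy(d2, residue = 2, bins = 72, temperature = 300)
  vals <- sort(unique(g2$dG[!is.na(g2$dG)]))
  expect_equal(vals[1], 0, tolerance = 1e-12)
  expect_equal(vals[2], 0.827, tolerance = 1e-3)   # -RT ln(0.25)
  # terminal residue: no defined pairs
  expect_error(rama_free_energy(d0, residue = 1),
               class = "peptaibio_undefined_residue")
})

test_that("FES is gauge-invariant under duplicating the sample", {
  set.seed(43)
  x <- rnorm(400); y <- rnorm(400)
  g1 <- fes_2d(x, y, bins = 8)
  g2 <- fes_2d(rep(x, 3), rep(y, 3), bins = 8)
  expect_equal(g1$dG, g2$dG, tolerance = 1e-9)
  expect_equal(min(g1$dG, na.rm = TRUE), 0, tolerance = 1e-12)
})

test_that("hydrogen bonds of ideal helices are exclusively the textbook class", {
  for (hd in c("right", "left")) {
    hb_a <- detect_hbonds(generate_helix_ensemble(10, "alpha", hd))
    expect_gt(nrow(hb_a), 0)
    expect_true(all(hb_a$turn_class == "i+4_alpha"))
    hb_3 <- detect_hbonds(generate_helix_ensemble(10, "three10", hd))
    expect_gt(nrow(hb_3), 0)
    expect_true(all(hb_3$turn_class == "i+3_310"))
    # donor residue i+3 -> acceptor i, e.g. residue 5 donating to residue 2
    expect_true(any(hb_3$acceptor == 2 & hb_3$donor == 5))
  }
})

test_that("turn classes follow the donor-acceptor separation", {
  # a C7 (gamma-turn) construction: donor i+2 -> acceptor i
  phi <- c(-120, -79, -120); psi <- c(120, 69, 120)
  xyz <- peptaibio:::.build_backbone(phi, psi)
  at <- data.frame(resno = rep(1:3, each = 4), elety = rep(c("N", "CA", "C", "O"), 3))
  ens <- backbone_ensemble(matrix(as.vector(t(xyz)), 1), at)
  hb <- detect_hbonds(ens, ang_cut = 120)
  expect_true(any(hb$turn_class == "i+2_gamma" & hb$acceptor == 1 & hb$donor == 3))
})

test_that("hydrogen-bond detection honours explicit H atoms and the flag", {
  ens <- generate_helix_ensemble(8, "three10", "left")
  expect_error(detect_hbonds(ens, reconstruct_h = FALSE),
               class = "peptaibio_topology_error")
  # fractions aggregate over frames and distances are physical
  ens5 <- generate_helix_ensemble(8, "three10", "left", jitter_sigma = 3,
                                  n_frames = 10, seed = 44)
  hb <- detect_hbonds(ens5)
  expect_true(all(hb$fraction > 0 & hb$fraction <= 1))
  expect_true(all(hb$mean_distance > 2 & hb$mean_distance <= 3.5))
})

test_that("left-handed 3_10 helix couples i+3 bonding with three10_L dihedrals", {
  ens <- generate_helix_ensemble(12, "three10", "left")
  d <- backbone_dihedrals(ens)
  cls <- classify_region(d$phi[1, 3:10], d$psi[1, 3:10])
  expect_true(all(cls %in% c("three10_L", "alpha_L")))
  hb <- detect_hbonds(ens)
  expect_true(all(hb$turn_class == "i+3_310"))
})

test_that("RMSD to the average obeys its invariances and the bio3d oracle", {
  ens <- generate_helix_ensemble(8, "alpha", "right", jitter_sigma = 8,
                                 n_frames = 12, seed = 45)
  # identical frames: all zero
  same <- backbone_ensemble(ens$xyz[rep(1, 5), ], ens$atoms)
  expect_equal(rmsd_to_average(same), rep(0, 5), tolerance = 1e-8)
  # frames differing only by rigid motion: all zero after superposition
  rigid <- same
  moved <- rigid_move(same)
  rigid$xyz[3, ] <- moved$xyz[3, ]
  rigid$xyz[5, ] <- moved$xyz[5, ]
  expect_equal(rmsd_to_average(rigid), rep(0, 5), tolerance = 1e-6)
  # global rigid motion of the whole ensemble changes nothing
  expect_equal(rmsd_to_average(rigid_move(ens)), rmsd_to_average(ens),
               tolerance = 1e-6)
  expect_equal(radius_of_gyration(rigid_move(ens)), radius_of_gyration(ens),
               tolerance = 1e-8)
  expect_error(rmsd_to_average(same[["xyz"]][1, , drop = FALSE]))
  # independent superposition machinery: bio3d fit.xyz, same two-pass recipe
  skip_if_not_installed("bio3d")
  sel <- which(ens$atoms$elety %in% c("C", "CA", "N"))
  cols <- as.vector(rbind(3 * sel - 2, 3 * sel - 1, 3 * sel))
  xyz <- ens$xyz[, cols]
  avg <- matrix(colMeans(xyz), nrow = 1)
  fitted <- bio3d::fit.xyz(fixed = as.vector(avg), mobile = xyz,
                           fixed.inds = seq_len(ncol(xyz)),
                           mobile.inds = seq_len(ncol(xyz)))
  avg2 <- colMeans(fitted)
  oracle <- apply(fitted, 1, function(fr)
    sqrt(mean(rowSums((matrix(fr - avg2, ncol = 3, byrow = TRUE))^2))))
  expect_equal(rmsd_to_average(ens), unname(oracle), tolerance = 1e-4)
})

test_that("radius of gyration matches closed forms and direct summation", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1, 3)), 0)
  two <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(radius_of_gyration(two), 0.5, tolerance = 1e-12)
  set.seed(46)
  cloud <- matrix(rnorm(150), 50, 3)
  direct <- sqrt(mean(rowSums(sweep(cloud, 2, colMeans(cloud))^2)))
  expect_equal(radius_of_gyration(cloud), direct, tolerance = 1e-10)
  expect_error(radius_of_gyration(cloud[0, , drop = FALSE]),
               class = "peptaibio_domain_error")
})

test_that("the RMSD/RoG landscape behaves like a free-energy surface", {
  # all frames identical: a single occupied bin at dG = 0
  ens <- generate_helix_ensemble(8, "alpha", "right")
  same <- backbone_ensemble(ens$xyz[rep(1, 6), ], ens$atoms)
  g <- fes_2d(rmsd_to_average(same), radius_of_gyration(same), bins = 5)
  expect_identical(sum(!is.na(g$dG)), 1L)
  expect_equal(g$dG[!is.na(g$dG)], 0)
  # two clusters 0.9 / 0.1: ddG = -RT ln(1/9) = 1.310 kcal/mol
  x <- c(rep(1, 90), rep(5, 10)); y <- c(rep(1, 90), rep(5, 10))
  g2 <- fes_2d(x, y, bins = 4, temperature = 300)
  vals <- sort(unique(g2$dG[!is.na(g2$dG)]))
  expect_equal(vals, c(0, 1.310), tolerance = 1e-3)
  expect_error(fes_2d(1:5, 1:4), class = "peptaibio_domain_error")
})

test_that("topology errors name the offending residue", {
  at <- data.frame(resno = c(1, 1, 1, 2, 2), elety = c("N", "CA", "C", "N", "CA"))
  ens <- backbone_ensemble(matrix(rnorm(15), 1), at)
  expect_error(backbone_dihedrals(ens), "residue 2",
               class = "peptaibio_topology_error")
})
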