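test_that("SASA matches closed-form and dense-grid oracles on small systems", {
  # one isolated atom: exactly the full solvent sphere
  one <- make_point_chain(c(0, 0, 0))
  s1 <- compute_sasa(one)
  expect_equal(s1$atom_area, 4 * pi * (1.70 + 1.4)^2, tolerance = 1e-9)

  # two atoms beyond contact: both retain the full sphere
  two_far <- make_point_chain(rbind(c(0, 0, 0), c(10, 0, 0)))
  s2 <- compute_sasa(two_far)
  expect_equal(s2$atom_area, rep(4 * pi * (1.70 + 1.4)^2, 2),
               tolerance = 1e-9)

  # two overlapping atoms: analytic spherical-cap area within 2%
  d <- 3.0
  two <- make_point_chain(rbind(c(0, 0, 0), c(d, 0, 0)))
  s3 <- compute_sasa(two, n_sphere_points = 960)
  r <- 1.70 + 1.4
  expect_equal(s3$atom_area[1], analytic_two_sphere_area(r, r, d),
               tolerance = 0.02)

  # three collinear atoms: middle one loses two independent caps
  three <- make_point_chain(rbind(c(-3, 0, 0), c(0, 0, 0), c(3, 0, 0)))
  s4 <- compute_sasa(three, n_sphere_points = 960)
  expected_mid <- 4 * pi * r^2 -
    2 * (4 * pi * r^2 - analytic_two_sphere_area(r, r, 3))
  expect_equal(s4$atom_area[2], expected_mid, tolerance = 0.02)
  # and against the dense-grid numerical oracle
  xyz <- rbind(c(-3, 0, 0), c(0, 0, 0), c(3, 0, 0))
  expect_equal(s4$atom_area, oracle_sasa_atoms(xyz, rep("C", 3)),
               tolerance = 0.02)

  # an atom enclosed by a tight shell has zero accessible area
  shell <- as.matrix(expand.grid(c(-2, 0, 2), c(-2, 0, 2), c(-2, 0, 2)))
  sh <- compute_sasa(make_point_chain(shell))
  expect_equal(sh$atom_area[14], 0)   # centre of the 3x3x3 grid
})

test_that("free glycine SASA agrees with the dense-grid oracle", {
  gly <- make_ideal_helix(1, letters = "G")
  s <- compute_sasa(gly, n_sphere_points = 960)
  xyz <- as.matrix(gly$atoms[, c("x", "y", "z")])
  expect_equal(s$residue_sasa,
               sum(oracle_sasa_atoms(xyz, gly$atoms$element)),
               tolerance = 0.02)
})

test_that("SASA is non-negative and non-increasing as atoms are added", {
  h <- fix_helix12()
  s_full <- compute_sasa(h)
  expect_true(all(s_full$atom_area >= 0))
  half <- h
  half$atoms <- half$atoms[half$atoms$res_idx <= 6, ]
  s_half <- compute_sasa(half)
  expect_true(all(s_full$atom_area[seq_along(s_half$atom_area)] <=
                    s_half$atom_area + 1e-9))
})

test_that("burial classification uses a strict 7% threshold", {
  ref_a <- 129.0   # Ala reference area
  expect_true(classify_burial(0.069 * ref_a, "A")$buried)
  expect_false(classify_burial(0.070 * ref_a, "A")$buried)
  z <- classify_burial(0, "A")
  expect_equal(z$rel_sasa, 0)
  expect_true(z$buried)
  unk <- classify_burial(10, "XYZ")
  expect_true(is.na(unk$rel_sasa))
  expect_false(unk$buried)
  # boundary recovered by a 0.1%-step scan is exactly the threshold
  rel <- seq(0, 20, by = 0.1)
  buried <- classify_burial(rel / 100 * ref_a, "A")$buried
  expect_equal(max(rel[buried]), 6.9)
  expect_equal(min(rel[!buried]), 7.0)
  # configurable threshold
  expect_false(classify_burial(0.069 * ref_a, "A", threshold_pct = 5)$buried)
})

test_that("secondary structure matches the independent oracle on ideal fixtures", {
  h <- fix_helix12()
  expect_equal(assign_secondary_structure(h), oracle_ss(h))
  expect_true(all(assign_secondary_structure(h)[2:11] == "H"))

  g310 <- make_ideal_helix(10, phi = -49, psi = -26)
  expect_equal(assign_secondary_structure(g310), oracle_ss(g310))
  expect_true(any(assign_secondary_structure(g310) == "G"))

  sheet <- fix_hairpin()
  expect_equal(assign_secondary_structure(sheet), oracle_ss(sheet))
  ss <- assign_secondary_structure(sheet)
  expect_true(all(ss[c(2:5, 9:12)] == "E"))

  # a lone extended strand has no ladder partner -> coil
  lone <- make_ideal_helix(8, phi = -139, psi = 135)
  expect_true(all(assign_secondary_structure(lone) == "C"))

  # chains shorter than 3 residues are all coil
  expect_equal(assign_secondary_structure(make_ideal_helix(2)), c("C", "C"))
})

test_that("phi/psi recover construction torsions and flag positive phi", {
  h <- make_ideal_helix(12, phi = -57, psi = -47)
  tor <- compute_phi_psi(h)
  expect_true(is.na(tor$phi[1]))
  expect_true(is.na(tor$psi[12]))
  expect_equal(tor$phi[2:12], rep(-57, 11), tolerance = 1e-4)
  expect_equal(tor$psi[1:11], rep(-47, 11), tolerance = 1e-4)
  expect_false(any(tor$positive_phi[2:12]))

  left <- make_ideal_helix(8, phi = 57, psi = 47)
  expect_true(all(compute_phi_psi(left)$positive_phi[2:8]))

  single <- make_ideal_helix(1)
  t1 <- compute_phi_psi(single)
  expect_true(is.na(t1$phi) && is.na(t1$psi))
})

test_that("sidechain-mainchain hydrogen bonds respect the distance cutoff", {
  # poly-Ala has no polar sidechain atoms
  h <- fix_helix12()
  hb <- detect_sidechain_mainchain_hbonds(h)
  expect_false(any(hb$hbond_to_amide))
  expect_false(any(hb$hbond_to_carbonyl))

  # place a Ser OG 2.9 A from residue 1's mainchain O, near-linear
  place_ser <- function(dist) {
    s <- make_ideal_helix(4, phi = -139, psi = 135,
                          letters = c("A", "A", "A", "S"))
    o1 <- as.numeric(s$atoms[s$atoms$res_idx == 1 & s$atoms$atom == "O",
                             c("x", "y", "z")])
    og <- o1 + c(0, 0, dist)
    s$atoms <- rbind(s$atoms, data.frame(
      res_idx = 4L, seq_id = "4", resname = "SER", one_letter = "S",
      atom = "OG", element = "O", x = og[1], y = og[2], z = og[3]
    ))
    s$atoms <- s$atoms[order(s$atoms$res_idx), ]
    s
  }
  near <- detect_sidechain_mainchain_hbonds(place_ser(2.9))
  expect_true(near$hbond_to_carbonyl[4])
  far <- detect_sidechain_mainchain_hbonds(place_ser(4.0))
  expect_false(far$hbond_to_carbonyl[4])
})

test_that("residue depth behaves like a surface distance", {
  # single atom: depth equals its probe-sphere radius
  one <- make_point_chain(c(0, 0, 0))
  expect_equal(compute_residue_depth(one), 1.70 + 1.4, tolerance = 1e-6)

  # fully exposed small peptide: all depths near r_vdw + probe
  tri <- make_ideal_helix(3, phi = -139, psi = 135)
  d <- compute_residue_depth(tri)
  expect_true(all(d >= 1.4))
  expect_true(all(d < 3.5))

  # centre of a close-packed cluster is deeper than the shell,
  # via brute-force nearest-surface-distance on the same sampled surface
  shell1 <- as.matrix(expand.grid(c(-2, 0, 2), c(-2, 0, 2), c(-2, 0, 2)))
  cl <- make_point_chain(shell1)
  sasa <- compute_sasa(cl)
  depths <- compute_residue_depth(cl, sasa = sasa)
  centre <- 14
  expect_gt(depths[centre], max(depths[-centre]))
  brute <- apply(structaln:::cross_dist2(shell1, sasa$surface_points), 1,
                 function(r) sqrt(min(r)))
  expect_equal(depths, unname(brute), tolerance = 1e-9)

  # monotonicity: enclosing the cluster in a second shell cannot
  # decrease the centre atom's depth
  shell2 <- as.matrix(expand.grid(c(-4.5, 0, 4.5), c(-4.5, 0, 4.5),
                                  c(-4.5, 0, 4.5)))
  shell2 <- shell2[rowSums(abs(shell2)) > 0, ]
  cl2 <- make_point_chain(rbind(shell1, shell2))
  depths2 <- compute_residue_depth(cl2)
  expect_gte(depths2[centre], depths[centre] - 1e-9)
})

test_that("intra-chain contacts: grid equals brute force, symmetric, irreflexive", {
  h <- fix_helix20()
  got <- compute_intra_contacts(h, 6.0)
  expect_equal(got, oracle_contacts(h, 6.0))
  for (i in seq_along(got)) {
    expect_false(i %in% got[[i]])
    for (j in got[[i]]) expect_true(i %in% got[[j]])
  }
  # the hairpin exercises long-range (inter-strand) contacts
  sheet <- fix_hairpin()
  expect_equal(compute_intra_contacts(sheet, 6.0),
               oracle_contacts(sheet, 6.0))
})

test_that("contact boundary sits exactly at the cutoff", {
  for (d in c(5.9, 6.0, 6.1)) {
    two <- make_point_chain(rbind(c(0, 0, 0), c(d, 0, 0)))
    ct <- compute_intra_contacts(two, 6.0)
    if (d <= 6.0) expect_equal(ct[[1]], 2L) else expect_length(ct[[1]], 0)
  }
})

test_that("chain and ligand interfaces respect the 5 A cutoff", {
  near <- compute_interface_contacts(make_toy_dimer(4.5), 5.0)
  expect_true(any(near$chain_contact == "B", na.rm = TRUE))
  far <- compute_interface_contacts(make_toy_dimer(5.5), 5.0)
  expect_true(all(is.na(far$chain_contact)))

  lig <- compute_interface_contacts(make_toy_ligand_complex(4.9), 5.0)
  expect_true(any(lig$ligand_contact == "LIG", na.rm = TRUE))
  ligf <- compute_interface_contacts(make_toy_ligand_complex(5.1), 5.0)
  expect_true(all(is.na(ligf$ligand_contact)))

  mono <- fix_helix12()
  none <- compute_interface_contacts(mono, 5.0)
  expect_true(all(is.na(none$chain_contact)))
  expect_true(all(is.na(none$ligand_contact)))
})

test_that("annotate_structure assembles a complete coherent track", {
  h <- fix_helix12()
  ann <- annotate_structure(h)
  expect_equal(nrow(ann), 12)
  expect_true(all(ann$ss %in% c("H", "G", "E", "C")))
  # burial flag is consistent with the relative accessibility
  ok <- !is.na(ann$rel_sasa)
  expect_equal(ann$buried[ok], ann$rel_sasa[ok] < 7)
  expect_true(all(ann$depth >= 1.4, na.rm = TRUE))
})
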