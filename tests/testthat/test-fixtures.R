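test_that("the backbone builder recovers its construction torsions", {
  h <- make_ideal_helix(12, phi = -57, psi = -47)
  tor <- compute_phi_psi(h)
  expect_lt(max(abs(tor$phi[-1] + 57)), 0.1)
  expect_lt(max(abs(tor$psi[-12] + 47)), 0.1)
  mixed <- make_ideal_helix(6, phi = c(-57, -57, -139, -139, -57, -57),
                            psi = c(-47, -47, 135, 135, -47, -47))
  expect_equal(compute_phi_psi(mixed)$phi[3], -139, tolerance = 0.1)
  one <- make_ideal_helix(1)
  expect_equal(n_residues(one), 1)
})

test_that("generators are pure functions of their arguments and seed", {
  a <- make_toy_alignment(4, 15, seed = 8, profile = "mixed",
                          with_structures = TRUE, noise_sd = 0.3)
  b <- make_toy_alignment(4, 15, seed = 8, profile = "mixed",
                          with_structures = TRUE, noise_sd = 0.3)
  expect_identical(
    lapply(a$sequences, function(s) s$structure$atoms),
    lapply(b$sequences, function(s) s$structure$atoms)
  )
  c2 <- make_toy_alignment(4, 15, seed = 9, profile = "mixed")
  expect_false(identical(
    vapply(a$sequences, function(s) s$gapped, character(1)),
    vapply(c2$sequences, function(s) s$gapped, character(1))
  ))
  # the global RNG stream is left untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(make_toy_alignment(3, 5, seed = 1))
  expect_identical(rnorm(1), before)
  expect_identical(make_beta_hairpin(4)$atoms, make_beta_hairpin(4)$atoms)
})

test_that("conservation profiles give their designed entropies", {
  cons <- make_toy_alignment(5, 10, seed = 2, profile = "conserved")
  for (i in 1:10) {
    expect_identical(shannon_entropy(column_frequencies(cons, i)), 0)
  }
  diff4 <- make_toy_alignment(4, 10, seed = 2, profile = "all_different")
  for (i in 1:10) {
    expect_equal(shannon_entropy(column_frequencies(diff4, i)), 1)
  }
  expect_error(make_toy_alignment(21, 5, profile = "all_different"),
               "n_seq <= 20")
})

test_that("hinge displacement puts displaced columns in the top RMSD bins", {
  aln <- make_toy_alignment(2, 20, seed = 5, profile = "conserved",
                            with_structures = TRUE, hinge_shift = 10)
  sup <- superpose(aln)
  bins <- rmsd_bin(sup$column_rmsd)
  # displaced half: pairwise distance ~ the 10 A shift -> top bin
  expect_true(all(bins[11:20] == 4))
  expect_true(all(bins[1:10] == 0))
})

test_that("fixture dumps produce a runnable PIR + PDB job", {
  dir <- withr::local_tempdir()
  res <- dump_fixtures(dir, n_struct = 2, n_col = 10, seed = 3)
  expect_true(file.exists(res$alignment))
  expect_length(res$pdbs, 2)
  aln <- read_alignment(res$alignment)
  expect_length(aln$sequences, 3)    # 2 structures + 1 query row
  structs <- lapply(res$pdbs, parse_pdb_chain)
  expect_silent(match_alignment_to_structures(aln, structs))
})
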