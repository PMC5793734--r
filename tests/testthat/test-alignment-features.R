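aln_from_column <- function(letters) {
  parse_fasta(paste(sprintf(">s%d\n%s", seq_along(letters), letters),
                    collapse = "\n"))
}

test_that("column frequencies count residues, gaps and X correctly", {
  a <- aln_from_column(c("A", "A", "C", "-"))
  fr <- column_frequencies(a, 1)
  expect_equal(fr$f[["A"]], 0.5)
  expect_equal(fr$f[["C"]], 0.25)
  expect_equal(fr$f_gap, 0.25)
  expect_equal(sum(fr$f) + fr$f_gap + fr$f_x, 1)

  x <- column_frequencies(aln_from_column(c("X", "A")), 1)
  expect_equal(x$f_x, 0.5)
  expect_equal(sum(x$f), 0.5)

  # frequencies sum to 1 on random columns
  set.seed(7)
  for (k in 1:10) {
    aln <- make_toy_alignment(sample(2:8, 1), 6, seed = k, profile = "mixed")
    for (i in 1:6) {
      fr <- column_frequencies(aln, i)
      expect_equal(sum(fr$f) + fr$f_gap + fr$f_x, 1)
    }
  }
})

test_that("entropy reproduces the closed-form anchor values", {
  conserved <- column_frequencies(aln_from_column(c("A", "A", "A", "A")), 1)
  expect_identical(shannon_entropy(conserved), 0)

  all_diff <- column_frequencies(aln_from_column(c("A", "C", "D", "E")), 1)
  expect_equal(shannon_entropy(all_diff), 1)

  two_pairs <- column_frequencies(aln_from_column(c("A", "A", "C", "C")), 1)
  expect_equal(shannon_entropy(two_pairs), 0.5)

  # high-precision oracle for an asymmetric column: A,A,A,C with n = 4
  freqs <- column_frequencies(aln_from_column(c("A", "A", "A", "C")), 1)
  expected <- -(0.75 * log(0.75, 4) + 0.25 * log(0.25, 4))
  expect_equal(shannon_entropy(freqs), expected, tolerance = 1e-12)
})

test_that("entropy is bounded, permutation-invariant and gap-sensitive", {
  set.seed(11)
  for (k in 1:25) {
    n_seq <- sample(2:12, 1)
    aln <- make_toy_alignment(n_seq, 8, seed = k, profile = "mixed")
    for (i in 1:8) {
      s <- shannon_entropy(column_frequencies(aln, i))
      expect_gte(s, 0)
      expect_lte(s, 1)
    }
    # permuting sequences leaves every column's entropy unchanged
    perm <- new_alignment(sample(aln$sequences))
    i <- sample(8, 1)
    expect_equal(shannon_entropy(column_frequencies(perm, i)),
                 shannon_entropy(column_frequencies(aln, i)))
  }
  # entropy is 0 iff one residue has frequency 1
  expect_identical(
    shannon_entropy(column_frequencies(aln_from_column(c("W", "W", "W")), 1)),
    0)
  # replacing a residue of a conserved column by a gap raises the score
  gapped <- shannon_entropy(column_frequencies(
    aln_from_column(c("A", "A", "A", "-")), 1))
  expect_gt(gapped, 0)
  # single sequence: no log base, entropy 0 by convention
  expect_identical(shannon_entropy(column_frequencies(
    aln_from_column("A"), 1)), 0)
})

test_that("entropy symbols follow the half-open 0.1 intervals with * at 0", {
  expect_equal(entropy_symbol(0), "*")
  expect_equal(entropy_symbol(0.1), "0")
  expect_equal(entropy_symbol(0.1000001), "1")
  expect_equal(entropy_symbol(1), "9")
  # boundary scan on a fine grid
  s <- (1:1000) / 1000
  sym <- entropy_symbol(s)
  changes <- s[which(sym[-1] != sym[-length(sym)]) + 1]
  expect_equal(changes, (1:9 * 100 + 1) / 1000, tolerance = 1e-9)
  expect_false("*" %in% sym)
})

test_that("secondary structure consensus needs 70% of participating rows", {
  mk <- function(n_h, n_total) {
    make_ss_alignment(lapply(seq_len(n_total), function(i)
      if (i <= n_h) "H" else "C"))
  }
  expect_equal(consensus_ss(mk(7, 10), 1), "a")
  expect_equal(consensus_ss(mk(6, 10), 1), "")
  strands <- make_ss_alignment(list("E", "E", "E"))
  expect_equal(consensus_ss(strands, 1), "b")
  g <- make_ss_alignment(list("G", "G", "G"))
  expect_equal(consensus_ss(g, 1), "3")
  # gaps dilute: 3 of 4 rows helix, fourth row gapped at the column
  diluted <- make_ss_alignment(
    list(c("H", "C"), c("H", "C"), c("H", "C"), "C"),
    gapped = list("AA", "AA", "AA", "-A")
  )
  expect_equal(consensus_ss(diluted, 1), "a")   # 3/4 = 75%
  diluted2 <- make_ss_alignment(
    list(c("H", "C"), c("H", "C"), "C", "C"),
    gapped = list("AA", "AA", "-A", "-A")
  )
  expect_equal(consensus_ss(diluted2, 1), "")   # 2/4 = 50%
  # no structure rows at all
  seq_only <- parse_fasta(">a\nAC\n>b\nAC")
  expect_equal(consensus_ss(seq_only, 1), "")
})

test_that("percent identity counts shared columns only", {
  mk2 <- function(a, b) {
    al <- parse_fasta(paste0(">q\n", a, "\n>t\n", b))
    list(q = al$sequences[[1]], t = al$sequences[[2]])
  }
  p <- mk2("ACDE", "ACDE")
  expect_equal(percent_identity(p$q, p$t), 100)
  p <- mk2("ACDE", "ACD-")
  expect_equal(percent_identity(p$q, p$t), 100)
  p <- mk2("ACDE", "ACDK")
  expect_equal(percent_identity(p$q, p$t), 75)
  p <- mk2("AC--", "--DE")
  u <- percent_identity(p$q, p$t)
  expect_equal(as.numeric(u), 0)
  expect_true(attr(u, "undefined"))
  # symmetry and bounds
  p <- mk2("ACDEFG", "AC-EWG")
  expect_equal(percent_identity(p$q, p$t), percent_identity(p$t, p$q))
  expect_lte(percent_identity(p$q, p$t), 100)
})

test_that("pid_table reports the first non-structure row against structures", {
  aln <- make_toy_alignment(3, 10, seed = 2, profile = "mixed",
                            with_structures = TRUE)
  seqs <- aln$sequences
  seqs[[4]] <- aligned_sequence("query1", "sequence", seqs[[1]]$gapped)
  seqs[[5]] <- aligned_sequence("query2", "sequence", seqs[[2]]$gapped)
  aln <- new_alignment(seqs)
  tab <- pid_table(aln)
  expect_equal(tab$structure_id, c("seq01", "seq02", "seq03"))
  expect_equal(tab$pid[1], 100)   # query1 copies row 1
  expect_true(all(tab$pid >= 0 & tab$pid <= 100))
})

test_that("superposition recovers rigid motions to 1e-6 A", {
  aln <- make_toy_alignment(2, 12, seed = 3, profile = "conserved",
                            with_structures = TRUE)
  R <- structaln:::rot_z(73) %*% structaln:::rot_x(21)
  s2 <- aln$sequences[[2]]$structure
  s2$atoms <- structaln:::transform_atoms(s2$atoms, R, c(5, -3, 11))
  aln$sequences[[2]]$structure <- s2
  sup <- superpose(aln)
  expect_lt(max(sup$column_rmsd, na.rm = TRUE), 1e-6)
  # rotations orthonormal with det +1, weights strictly positive
  for (tf in sup$transforms) {
    expect_equal(t(tf$rot) %*% tf$rot, diag(3), tolerance = 1e-9)
    expect_equal(det(tf$rot), 1, tolerance = 1e-9)
  }
  expect_true(all(sup$weights > 0))
})

test_that("superposition is invariant under rigid motion of any input", {
  aln <- make_toy_alignment(3, 10, seed = 9, profile = "conserved",
                            with_structures = TRUE, noise_sd = 0.3)
  base <- superpose(aln)$column_rmsd
  moved <- aln
  s1 <- moved$sequences[[1]]$structure
  s1$atoms <- structaln:::transform_atoms(
    s1$atoms, structaln:::rot_y(131), c(-4, 8, 2))
  moved$sequences[[1]]$structure <- s1
  expect_equal(superpose(moved)$column_rmsd, base, tolerance = 1e-6)
})

test_that("inverse-variance weighting fits the rigid core tighter than
           an unweighted fit on a two-domain hinge", {
  aln <- make_toy_alignment(2, 20, seed = 5, profile = "conserved",
                            with_structures = TRUE, hinge_shift = 10)
  sup <- superpose(aln)
  core <- 1:10
  hinge <- 11:20
  expect_lt(mean(sup$column_rmsd[core]), mean(sup$column_rmsd[hinge]))

  # unweighted Kabsch oracle (bio3d) over the same C-alpha sets
  cas <- structaln:::ca_by_column(aln)
  fitted2 <- oracle_unweighted_fit(cas[[2]], cas[[1]])
  unweighted_core <- sqrt(rowSums((fitted2 - cas[[1]])^2))[core]
  expect_lt(mean(sup$column_rmsd[core]), mean(unweighted_core))
})

test_that("column RMSD equals the brute-force pairwise formula", {
  aln <- make_toy_alignment(3, 10, seed = 13, profile = "conserved",
                            with_structures = TRUE, noise_sd = 0.5)
  sup <- superpose(aln)
  cas <- structaln:::ca_by_column(aln)
  for (i in c(1, 5, 10)) {
    pts <- do.call(rbind, lapply(names(cas), function(id)
      as.vector(structaln:::apply_transform(matrix(cas[[id]][i, ], 1),
                                            sup$transforms[[id]]))))
    expect_equal(sup$column_rmsd[i], oracle_pairwise_rmsd(pts),
                 tolerance = 1e-9)
  }
  # a column where all structures coincide scores 0
  aln0 <- make_toy_alignment(3, 10, seed = 13, profile = "conserved",
                             with_structures = TRUE, noise_sd = 0)
  expect_equal(max(superpose(aln0)$column_rmsd), 0, tolerance = 1e-6)
  # two structures: RMSD reduces to the single pair distance
  two <- make_toy_alignment(2, 10, seed = 1, profile = "conserved",
                            with_structures = TRUE)
  s2 <- two$sequences[[2]]$structure
  sup2 <- superpose(two)
  expect_equal(sup2$column_rmsd[5],
               {
                 p <- vapply(names(structaln:::ca_by_column(two)), function(id)
                   structaln:::apply_transform(
                     matrix(structaln:::ca_by_column(two)[[id]][5, ], 1),
                     sup2$transforms[[id]]), numeric(3))
                 sqrt(sum((p[, 1] - p[, 2])^2))
               },
               tolerance = 1e-9)
})

test_that("superposition fails cleanly with too little shared structure", {
  one <- make_toy_alignment(1, 10, seed = 1, profile = "conserved",
                            with_structures = TRUE)
  expect_error(superpose(one), "superposition-impossible")
})

test_that("RMSD bins split exactly at 2, 4, 6, 8 A", {
  expect_equal(rmsd_bin(1.9), 0)
  expect_equal(rmsd_bin(2.0), 1)
  expect_equal(rmsd_bin(8.0), 4)
  grid <- seq(0, 10, by = 0.05)
  bins <- rmsd_bin(grid)
  edges <- grid[which(diff(bins) != 0) + 1]
  expect_equal(edges, c(2, 4, 6, 8))
})
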