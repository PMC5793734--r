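## Deterministic synthetic-geometry generators: ideal secondary-structure
## elements, toy complexes and toy alignments with known ground truth.
## Everything is a pure function of its arguments (and an explicit seed),
## so the whole pipeline is testable without external data.

## Standard backbone geometry (A / degrees): bond lengths N-CA 1.458,
## CA-C 1.525, C-N 1.329, C=O 1.231, CA-CB 1.521; angles N-CA-C 111.2,
## CA-C-N 116.2, C-N-CA 121.7, CA-C-O 120.5, N-CA-CB 110.4; omega 180.
BACKBONE_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.521,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  a_ca_c_o = 120.5, a_n_ca_cb = 110.4,
  omega = 180, cb_improper = -122.6
)

build_backbone <- function(n_res, phi, psi, with_cb = TRUE) {
  g <- BACKBONE_GEOM
  phi <- rep_len(phi, n_res)
  psi <- rep_len(psi, n_res)
  N <- CA <- C <- O <- CB <- matrix(NA_real_, n_res, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  th <- (180 - g$a_n_ca_c) * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(cos(th), sin(th), 0)
  for (i in seq_len(n_res)[-1]) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         g$b_c_n, g$a_ca_c_n, psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          g$b_n_ca, g$a_c_n_ca, g$omega)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                         g$b_ca_c, g$a_n_ca_c, phi[i])
  }
  for (i in seq_len(n_res)) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         g$b_c_o, g$a_ca_c_o, psi[i] + 180)
    if (with_cb) {
      CB[i, ] <- place_atom(C[i, ], N[i, ], CA[i, ],
                            g$b_ca_cb, g$a_n_ca_cb, g$cb_improper)
    }
  }
  list(N = N, CA = CA, C = C, O = O, CB = if (with_cb) CB else NULL)
}

backbone_to_atoms <- function(bb, letters, first_res_idx = 1L) {
  n <- nrow(bb$N)
  letters <- rep_len(letters, n)
  resnames <- unname(AA1_TO_3[letters])
  rows <- lapply(seq_len(n), function(i) {
    names_i <- c("N", "CA", "C", "O")
    xyz <- rbind(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$O[i, ])
    elem <- c("N", "C", "C", "O")
    if (!is.null(bb$CB) && letters[i] != "G") {
      names_i <- c(names_i, "CB")
      xyz <- rbind(xyz, bb$CB[i, ])
      elem <- c(elem, "C")
    }
    data.frame(
      res_idx = first_res_idx + i - 1L,
      seq_id = as.character(first_res_idx + i - 1L),
      resname = resnames[i], one_letter = letters[i],
      atom = names_i, element = elem,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Build an ideal poly-Ala helix (or any repeated-torsion backbone)
#'
#' Backbone constructed from standard bond lengths and angles at the
#' requested torsions; the default (-57, -47) is the canonical
#' right-handed alpha helix, (-49, -26) gives a 3-10 helix and
#' (-139, 135) an extended beta strand.
#'
#' @param n_res number of residues (>= 1).
#' @param phi,psi backbone torsions in degrees (scalar or per-residue).
#' @param letters one-letter residue codes recycled along the chain.
#' @param source_id,chain_id identifiers of the generated chain.
#' @return A [chain_structure()].
#' @export
#' @examples
#' h <- make_ideal_helix(12)
#' n_residues(h)
make_ideal_helix <- function(n_res, phi = -57, psi = -47, letters = "A",
                             source_id = "helx", chain_id = "A") {
  stopifnot(n_res >= 1)
  bb <- build_backbone(n_res, phi, psi)
  chain_structure(source_id, chain_id, backbone_to_atoms(bb, letters))
}

## Rigidly transform the coordinate columns of an atom table.
transform_atoms <- function(atoms, rot = diag(3), trans = c(0, 0, 0)) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rot)
  atoms$x <- xyz[, 1] + trans[1]
  atoms$y <- xyz[, 2] + trans[2]
  atoms$z <- xyz[, 3] + trans[3]
  atoms
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

#' Build an ideal two-strand antiparallel beta sheet as one chain
#'
#' Two extended strands (phi = -139, psi = 135) are paired by a
#' deterministic registry search.  The first strand is aligned with the
#' x axis and its pleat (carbonyl direction) with y; the second strand
#' is the first rotated 180 degrees about y or z through the strand
#' centroid and translated over an offset grid.  Each placement is
#' scored by the number of inter-strand hydrogen bonds with sound
#' geometry (N...O distance 2.5-3.3 A and N-H...O angle > 130 degrees,
#' with the amide hydrogen rebuilt from the preceding peptide plane);
#' the best-scoring placement wins, ties broken by grid order.  The two
#' strands form one chain with a break between them (a hairpin without
#' the turn residues).
#'
#' @param n_per_strand residues per strand (>= 3).
#' @param source_id,chain_id identifiers of the generated chain.
#' @return A [chain_structure()] with `2 * n_per_strand` residues.
#' @export
make_beta_hairpin <- function(n_per_strand = 6, source_id = "shee",
                              chain_id = "A") {
  stopifnot(n_per_strand >= 3)
  bbA <- build_backbone(n_per_strand, -139, 135)
  atomsA <- backbone_to_atoms(bbA, "A")
  ## align strand axis (mean CA->CA direction) with +x (Rodrigues)
  axis <- unit(colMeans(diff(bbA$CA)))
  v <- c(0, axis[3], -axis[2])
  s <- vnorm(v); cc <- axis[1]
  if (s > 1e-12) {
    vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    R <- diag(3) + vx + vx %*% vx * ((1 - cc) / s^2)
  } else {
    R <- diag(3)
  }
  atomsA <- transform_atoms(atomsA, R)
  ## align the pleat: carbonyl of residue 2 into the +y half-plane
  co <- unlist(atomsA[atomsA$atom == "O" & atomsA$res_idx == 2,
                      c("x", "y", "z")]) -
        unlist(atomsA[atomsA$atom == "C" & atomsA$res_idx == 2,
                      c("x", "y", "z")])
  atomsA <- transform_atoms(atomsA, rot_x(-atan2(co[3], co[2]) * 180 / pi))
  ctr <- colMeans(as.matrix(atomsA[, c("x", "y", "z")]))
  atomsA$x <- atomsA$x - ctr[1]
  atomsA$y <- atomsA$y - ctr[2]
  atomsA$z <- atomsA$z - ctr[3]
  stA <- chain_structure(source_id, chain_id, atomsA)
  bbS <- backbone_xyz(stA)
  HA <- amide_hydrogens(stA, bbS)
  score_hb <- function(N, H, O) {
    ok <- rowSums(is.finite(H)) == 3L
    if (!any(ok)) return(0L)
    N <- N[ok, , drop = FALSE]; H <- H[ok, , drop = FALSE]
    d_no <- sqrt(pmax(0, cross_dist2(N, O)))
    U <- N - H                                # unit N-H vectors (1 A)
    dot <- U %*% t(O) - rowSums(U * H)        # u_i . (O_j - H_i)
    d_ho <- sqrt(pmax(0, cross_dist2(H, O)))
    cosang <- dot / pmax(d_ho, 1e-9)
    sum(d_no >= 2.5 & d_no <= 3.3 & cosang < cos(130 * pi / 180))
  }
  rots <- list(z = rot_z(180), y = rot_y(180))
  pre <- lapply(rots, function(Rb) list(
    N = bbS$N %*% t(Rb), O = bbS$O %*% t(Rb), H = HA %*% t(Rb)
  ))
  eval_grid <- function(hs, ss, zs, best = NULL) {
    for (axn in names(rots)) {
      p <- pre[[axn]]
      for (h in hs) for (sft in ss) for (z in zs) {
        tr <- c(sft, h, z)
        OB <- sweep(p$O, 2, tr, "+")
        NB <- sweep(p$N, 2, tr, "+")
        HB <- sweep(p$H, 2, tr, "+")
        sc <- score_hb(bbS$N, HA, OB) + score_hb(NB, HB, bbS$O)
        if (is.null(best) || sc > best$sc) {
          best <- list(sc = sc, rot = rots[[axn]], tr = tr)
        }
      }
    }
    best
  }
  best <- eval_grid(seq(3.6, 6.0, by = 0.2), seq(-4, 4, by = 0.2),
                    c(-0.4, 0, 0.4))
  b <- best$tr
  best <- eval_grid(seq(b[2] - 0.2, b[2] + 0.2, by = 0.05),
                    seq(b[1] - 0.2, b[1] + 0.2, by = 0.05),
                    seq(b[3] - 0.4, b[3] + 0.4, by = 0.1), best)
  atomsB <- transform_atoms(atomsA, best$rot, best$tr)
  ## renumber strand B to follow strand A (with a numbering gap marking
  ## the missing turn)
  atomsB$res_idx <- atomsB$res_idx + n_per_strand
  atomsB$seq_id <- as.character(atomsB$res_idx + 2L)
  atoms <- rbind(atomsA, atomsB)
  chain_structure(source_id, chain_id, atoms)
}

#' Build a toy two-chain complex at a controlled interface gap
#'
#' Chain A is a short extended peptide; chain B is a copy translated so
#' that the minimum heavy-atom distance between the chains equals `gap`
#' exactly (to 1e-9 A).  Chain B is stored in `other_chains` for
#' interface analysis.
#'
#' @param gap minimum inter-chain heavy-atom distance, A.
#' @param n_res residues per chain.
#' @return A [chain_structure()] (chain A) with `other_chains` populated.
#' @export
make_toy_dimer <- function(gap = 4.5, n_res = 3) {
  a <- make_ideal_helix(n_res, -139, 135, source_id = "dime", chain_id = "A")
  atomsB <- a$atoms
  xyzA <- as.matrix(a$atoms[, c("x", "y", "z")])
  D <- 30
  mdist <- function(D) {
    cand <- xyzA
    cand[, 2] <- cand[, 2] + D
    min_dist(xyzA, cand)
  }
  for (k in 1:60) {
    m <- mdist(D)
    if (abs(m - gap) < 1e-12) break
    D <- D - (m - gap)
  }
  ## land on the gap from below so a cutoff equal to `gap` still hits
  if (mdist(D) > gap) D <- D - (mdist(D) - gap) - 1e-12
  atomsB$y <- atomsB$y + D
  a$other_chains <- list(list(chain_id = "B", atoms = atomsB))
  a
}

#' Build a toy protein-ligand complex at a controlled distance
#'
#' A single-atom hetero group (`LIG`) is placed at exactly `dist` A from
#' its nearest protein atom.
#'
#' @param dist minimum ligand-protein heavy-atom distance, A.
#' @param n_res residues in the chain.
#' @return A [chain_structure()] with one hetero group.
#' @export
make_toy_ligand_complex <- function(dist = 4.9, n_res = 3) {
  a <- make_ideal_helix(n_res, -139, 135, source_id = "ligc", chain_id = "A")
  ## put the topmost atom exactly at the origin so the ligand-protein
  ## minimum distance is `dist` without rounding
  xyz <- as.matrix(a$atoms[, c("x", "y", "z")])
  top <- which.max(xyz[, 2])
  xyz <- sweep(xyz, 2, xyz[top, ])
  a$atoms$x <- xyz[, 1]; a$atoms$y <- xyz[, 2]; a$atoms$z <- xyz[, 3]
  pos <- c(0, dist, 0)
  a$hetero <- list(list(
    name = "LIG",
    atoms = data.frame(atom = "C1", element = "C",
                       x = pos[1], y = pos[2], z = pos[3],
                       stringsAsFactors = FALSE)
  ))
  a
}

#' Generate a toy alignment with a known conservation profile
#'
#' Column letters are drawn per column according to `profile`:
#' `"conserved"` (one letter repeated down the column),
#' `"all_different"` (distinct letters, requires `n_seq <= 20`),
#' `"random"` (uniform over the 20 amino acids) or `"mixed"` (first half
#' conserved, second half random, with gaps inserted at `gap_rate` —
#' never creating an all-gap column).  With `with_structures = TRUE`
#' every row is ungapped and paired with an ideal-helix structure whose
#' residues carry the row's letters, per-atom Gaussian noise of
#' `noise_sd` A and, for every structure after the first, a rigid
#' displacement of `hinge_shift` A applied to the second half of the
#' chain (a two-domain hinge with known ground truth).
#'
#' @param n_seq,n_col alignment dimensions.
#' @param seed integer seed; the generator is a pure function of it.
#' @param profile conservation profile (see above).
#' @param gap_rate per-cell gap probability for `"mixed"`.
#' @param with_structures attach one synthetic structure per row.
#' @param noise_sd per-coordinate Gaussian noise, A.
#' @param hinge_shift rigid x-displacement of the second half, A.
#' @return An [new_alignment()] (structures attached when requested).
#' @export
make_toy_alignment <- function(n_seq = 4, n_col = 20, seed = 1,
                               profile = c("conserved", "all_different",
                                           "random", "mixed"),
                               gap_rate = 0.15,
                               with_structures = FALSE,
                               noise_sd = 0, hinge_shift = 0) {
  profile <- match.arg(profile)
  stopifnot(n_seq >= 1, n_col >= 1)
  if (profile == "all_different" && n_seq > 20) {
    stop("all_different profile needs n_seq <= 20")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  aa <- AMINO_ACIDS
  mat <- matrix("", n_seq, n_col)
  for (j in seq_len(n_col)) {
    mat[, j] <- switch(profile,
      conserved = rep(sample(aa, 1), n_seq),
      all_different = sample(aa, n_seq),
      random = sample(aa, n_seq, replace = TRUE),
      mixed = if (j <= n_col %/% 2) rep(sample(aa, 1), n_seq)
              else sample(aa, n_seq, replace = TRUE)
    )
  }
  if (profile == "mixed" && !with_structures && gap_rate > 0) {
    gaps <- matrix(stats::runif(n_seq * n_col) < gap_rate, n_seq, n_col)
    keep <- apply(gaps, 2, all)
    gaps[1, keep] <- FALSE       # never an all-gap column
    mat[gaps] <- "-"
  }
  ids <- sprintf("seq%02d", seq_len(n_seq))
  seqs <- lapply(seq_len(n_seq), function(i) {
    row <- paste(mat[i, ], collapse = "")
    if (with_structures) {
      s <- make_ideal_helix(n_col, letters = mat[i, ],
                            source_id = ids[i], chain_id = "A")
      xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
      if (noise_sd > 0) {
        xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = noise_sd),
                            ncol = 3)
      }
      if (hinge_shift != 0 && i > 1) {
        sel <- s$atoms$res_idx > n_col %/% 2
        xyz[sel, 1] <- xyz[sel, 1] + hinge_shift
      }
      s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
      aligned_sequence(ids[i], "structure", row, structure = s)
    } else {
      aligned_sequence(ids[i], "sequence", row)
    }
  })
  new_alignment(seqs)
}

#' Write synthetic fixtures to disk as PIR + PDB files
#'
#' Emits a small end-to-end job: a mixed structure/sequence alignment in
#' PIR format plus one PDB file per structure row, suitable as input for
#' [annotate_job()].
#'
#' @param dir output directory (created if absent).
#' @param n_struct number of structure rows.
#' @param n_col alignment columns.
#' @param seed generator seed.
#' @return Invisibly, a list with the alignment path and PDB paths.
#' @export
dump_fixtures <- function(dir, n_struct = 3, n_col = 20, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aln <- make_toy_alignment(n_struct, n_col, seed = seed, profile = "mixed",
                            with_structures = TRUE, noise_sd = 0.15)
  ## append one pure-sequence row (a copy of row 1's letters)
  seqs <- aln$sequences
  seqs[[length(seqs) + 1L]] <-
    aligned_sequence("query1", "sequence", seqs[[1]]$gapped)
  aln <- new_alignment(seqs)
  pir <- file.path(dir, "alignment.pir")
  writeLines(write_pir(aln), pir)
  pdbs <- character(0)
  for (s in aln$sequences) {
    if (!is.null(s$structure)) {
      p <- file.path(dir, paste0(s$seq_id, ".pdb"))
      write_chain_pdb(s$structure, p)
      pdbs <- c(pdbs, p)
    }
  }
  invisible(list(alignment = pir, pdbs = pdbs))
}
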