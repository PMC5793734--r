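## Secondary structure by backbone hydrogen-bond energy patterns
## (Kabsch-Sander style), mainchain torsions, and sidechain-to-mainchain
## hydrogen bond detection.

PEPTIDE_BOND_MAX <- 2.5   # A, C(i-1)-N(i) distance for an intact bond
HB_ENERGY_CUTOFF <- -0.5  # kcal/mol
HB_Q1Q2F <- 0.084 * 332   # electrostatic H-bond energy prefactor

backbone_xyz <- function(struct) {
  list(
    N = residue_atom_xyz(struct, "N"),
    CA = residue_atom_xyz(struct, "CA"),
    C = residue_atom_xyz(struct, "C"),
    O = residue_atom_xyz(struct, "O")
  )
}

peptide_bond_intact <- function(bb) {
  n <- nrow(bb$N)
  if (n < 2) return(logical(0))
  ok <- logical(n - 1)
  for (i in seq_len(n - 1)) {
    ok[i] <- all(is.finite(bb$C[i, ])) && all(is.finite(bb$N[i + 1, ])) &&
      vnorm(bb$N[i + 1, ] - bb$C[i, ]) < PEPTIDE_BOND_MAX
  }
  ok
}

## Amide hydrogen positions: H on N(i), 1.0 A along the direction of the
## previous residue's C=O bond (from O to C), only where the peptide bond
## is intact and the residue is not proline.
amide_hydrogens <- function(struct, bb = backbone_xyz(struct),
                            bonded = peptide_bond_intact(bb)) {
  n <- nrow(bb$N)
  resnames <- struct$atoms$resname[!duplicated(struct$atoms$res_idx)]
  H <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)[-1]) {
    if (!bonded[i - 1] || resnames[i] == "PRO") next
    if (!all(is.finite(c(bb$C[i - 1, ], bb$O[i - 1, ], bb$N[i, ])))) next
    H[i, ] <- bb$N[i, ] + unit(bb$C[i - 1, ] - bb$O[i - 1, ])
  }
  H
}

## Logical matrix hb[i, j]: the amide of residue i donates a hydrogen
## bond to the carbonyl of residue j (electrostatic energy < -0.5
## kcal/mol).
ks_hbond_matrix <- function(struct) {
  bb <- backbone_xyz(struct)
  n <- nrow(bb$N)
  H <- amide_hydrogens(struct, bb)
  hb <- matrix(FALSE, n, n)
  if (n < 3) return(hb)
  for (i in seq_len(n)) {
    if (!all(is.finite(H[i, ]))) next
    for (j in seq_len(n)) {
      if (abs(i - j) < 2) next
      if (!all(is.finite(c(bb$C[j, ], bb$O[j, ])))) next
      if (vnorm(bb$CA[i, ] - bb$CA[j, ]) > 9) next
      d_on <- vnorm(bb$O[j, ] - bb$N[i, ])
      d_ch <- vnorm(bb$C[j, ] - H[i, ])
      d_oh <- vnorm(bb$O[j, ] - H[i, ])
      d_cn <- vnorm(bb$C[j, ] - bb$N[i, ])
      if (min(d_on, d_ch, d_oh, d_cn) < 0.5) next  # clashing geometry
      e <- HB_Q1Q2F * (1 / d_on + 1 / d_ch - 1 / d_oh - 1 / d_cn)
      hb[i, j] <- e < HB_ENERGY_CUTOFF
    }
  }
  hb
}

## Demote runs of `cls` shorter than `min_len` to coil.
enforce_min_run <- function(ss, cls, min_len) {
  r <- rle(ss)
  short <- r$values == cls & r$lengths < min_len
  r$values[short] <- "C"
  inverse.rle(r)
}

#' Assign secondary structure from backbone hydrogen bonds
#'
#' Hydrogen bonds are detected from the electrostatic backbone H-bond
#' energy (bond if E < -0.5 kcal/mol, amide hydrogens rebuilt from the
#' preceding peptide plane).  Two consecutive i -> i+4 bonds make an
#' alpha helix (`H`, minimum segment 4), two consecutive i -> i+3 bonds
#' a 3-10 helix (`G`, minimum 3), ladders of inter-strand bridge
#' patterns make beta strands (`E`, minimum 2); everything else is coil
#' (`C`).  Priority on overlap: H, then E, then G.
#'
#' @param struct a [chain_structure()].
#' @return Character vector over \{H, G, E, C\}, one per residue.
#' @export
assign_secondary_structure <- function(struct) {
  n <- n_residues(struct)
  if (n < 3) return(rep("C", n))
  hb <- ks_hbond_matrix(struct)
  ss <- rep("C", n)

  turn_at <- function(len) {
    v <- rep(FALSE, n)
    for (i in seq_len(max(0, n - len))) v[i] <- hb[i + len, i]
    v
  }
  mark_helix <- function(ss, len, cls) {
    turns <- turn_at(len)
    for (i in seq_len(max(0, n - len - 1))) {
      if (turns[i] && turns[i + 1]) {
        sel <- (i + 1):(i + len)
        sel <- sel[ss[sel] == "C"]
        ss[sel] <- cls
      }
    }
    ss
  }

  ss <- mark_helix(ss, 4, "H")

  ## beta bridges
  hbond <- function(i, j) {
    i >= 1 && j >= 1 && i <= n && j <= n && hb[i, j]
  }
  bridge <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) <= 2) next
      para <- (hbond(i + 1, j) && hbond(j, i - 1)) ||
              (hbond(j + 1, i) && hbond(i, j - 1))
      anti <- (hbond(i, j) && hbond(j, i)) ||
              (hbond(i - 1, j + 1) && hbond(j - 1, i + 1))
      bridge[i, j] <- para || anti
    }
  }
  in_bridge <- rowSums(bridge) > 0 | colSums(bridge) > 0
  ss[in_bridge & ss == "C"] <- "E"
  ss <- enforce_min_run(ss, "E", 2)

  ss <- mark_helix(ss, 3, "G")
  ss <- enforce_min_run(ss, "G", 3)
  ss <- enforce_min_run(ss, "H", 4)
  ss
}

#' Mainchain phi/psi torsions
#'
#' Standard IUPAC torsions in (-180, 180]; a torsion is undefined (`NA`)
#' at chain termini, across chain breaks (C-N distance >= 2.5 A) and
#' where a backbone atom is missing.  `positive_phi` is `phi > 0` (NA
#' where phi is undefined).
#'
#' @param struct a [chain_structure()].
#' @return data.frame with columns `phi`, `psi`, `positive_phi`.
#' @export
compute_phi_psi <- function(struct) {
  bb <- backbone_xyz(struct)
  n <- nrow(bb$N)
  phi <- psi <- rep(NA_real_, n)
  if (n >= 2) {
    bonded <- peptide_bond_intact(bb)
    for (i in seq_len(n)) {
      if (i > 1 && bonded[i - 1] &&
          all(is.finite(c(bb$C[i - 1, ], bb$N[i, ], bb$CA[i, ], bb$C[i, ])))) {
        phi[i] <- dihedral_angle(bb$C[i - 1, ], bb$N[i, ], bb$CA[i, ], bb$C[i, ])
      }
      if (i < n && bonded[i] &&
          all(is.finite(c(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$N[i + 1, ])))) {
        psi[i] <- dihedral_angle(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$N[i + 1, ])
      }
    }
  }
  data.frame(phi = phi, psi = psi,
             positive_phi = ifelse(is.na(phi), NA, phi > 0))
}

## Sidechain nitrogen/oxygen atoms that can hydrogen-bond, by residue.
SIDECHAIN_POLAR <- list(
  SER = "OG", THR = "OG1", TYR = "OH",
  ASN = c("OD1", "ND2"), GLN = c("OE1", "NE2"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
  HIS = c("ND1", "NE2"), TRP = "NE1"
)

#' Detect sidechain-to-mainchain hydrogen bonds
#'
#' A residue is flagged `hbond_to_amide` when one of its polar sidechain
#' N/O atoms lies within the donor-acceptor cutoff of a mainchain amide
#' nitrogen of another residue (with an N-H...acceptor angle > 90 degrees
#' when the amide hydrogen can be rebuilt), and `hbond_to_carbonyl` when
#' a polar sidechain atom lies within the cutoff of another residue's
#' mainchain carbonyl oxygen.
#'
#' @param struct a [chain_structure()].
#' @param cutoff donor-acceptor distance cutoff, A (default 3.5).
#' @return data.frame with logical columns `hbond_to_amide`,
#'   `hbond_to_carbonyl`.
#' @export
detect_sidechain_mainchain_hbonds <- function(struct, cutoff = 3.5) {
  a <- struct$atoms
  n <- n_residues(struct)
  bb <- backbone_xyz(struct)
  H <- amide_hydrogens(struct, bb)
  resnames <- a$resname[!duplicated(a$res_idx)]
  amide <- carbonyl <- rep(FALSE, n)
  for (r in seq_len(n)) {
    polar <- SIDECHAIN_POLAR[[resnames[r]]]
    if (is.null(polar)) next
    rows <- a$res_idx == r & a$atom %in% polar
    if (!any(rows)) next
    sxyz <- as.matrix(a[rows, c("x", "y", "z")])
    for (s in seq_len(n)) {
      if (s == r) next
      ## sidechain acceptor vs mainchain amide N-H of residue s
      if (!amide[r] && all(is.finite(bb$N[s, ]))) {
        d <- sqrt(pmax(0, cross_dist2(sxyz, matrix(bb$N[s, ], 1))))
        hit <- d <= cutoff
        if (any(hit) && all(is.finite(H[s, ]))) {
          for (k in which(hit)) {
            ang <- bond_angle(bb$N[s, ], H[s, ], sxyz[k, ])
            if (ang > 90) { amide[r] <- TRUE; break }
          }
        } else if (any(hit)) {
          amide[r] <- TRUE
        }
      }
      ## sidechain donor vs mainchain carbonyl O of residue s
      if (!carbonyl[r] && all(is.finite(bb$O[s, ]))) {
        d <- sqrt(pmax(0, cross_dist2(sxyz, matrix(bb$O[s, ], 1))))
        if (any(d <= cutoff)) carbonyl[r] <- TRUE
      }
    }
  }
  data.frame(hbond_to_amide = amide, hbond_to_carbonyl = carbonyl)
}
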