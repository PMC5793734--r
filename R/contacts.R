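## Residue-residue contacts (within-chain, cell-list accelerated) and
## chain/ligand interface membership.

## Assign points to integer grid cells of side `cell`.
grid_cells <- function(xyz, cell) {
  floor(sweep(xyz, 2, apply(xyz, 2, min), "-") / cell)
}

#' Intra-chain residue contacts
#'
#' Residues i and j (i != j) are in contact when the minimum heavy-atom
#' pair distance is at or below the cutoff (default 6.0 A); sequence
#' neighbours are included.  A cell list of side = cutoff restricts the
#' pair search to neighbouring cells, giving results identical to the
#' all-pairs scan.
#'
#' @param struct a [chain_structure()].
#' @param cutoff distance cutoff, A.
#' @return List of sorted integer vectors, one per residue; the relation
#'   is symmetric and irreflexive.
#' @export
compute_intra_contacts <- function(struct, cutoff = 6.0) {
  stopifnot(cutoff > 0)
  a <- struct$atoms
  n <- n_residues(struct)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  res <- a$res_idx
  cells <- grid_cells(xyz, cutoff)
  key <- paste(cells[, 1], cells[, 2], cells[, 3], sep = ",")
  atoms_by_cell <- split(seq_len(nrow(xyz)), key)
  cell_index <- unique(data.frame(cells, key = key, stringsAsFactors = FALSE))
  lookup <- stats::setNames(seq_along(atoms_by_cell), names(atoms_by_cell))
  pairs <- new.env(hash = TRUE)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  cut2 <- cutoff^2
  for (ci in seq_len(nrow(cell_index))) {
    base <- as.integer(cell_index[ci, 1:3])
    ai <- atoms_by_cell[[cell_index$key[ci]]]
    for (oi in seq_len(nrow(offsets))) {
      nb_key <- paste(base[1] + offsets[oi, 1], base[2] + offsets[oi, 2],
                      base[3] + offsets[oi, 3], sep = ",")
      aj <- atoms_by_cell[[nb_key]]
      if (is.null(aj)) next
      d2 <- cross_dist2(xyz[ai, , drop = FALSE], xyz[aj, , drop = FALSE])
      hit <- which(d2 <= cut2, arr.ind = TRUE)
      if (nrow(hit)) {
        ri <- res[ai[hit[, 1]]]
        rj <- res[aj[hit[, 2]]]
        keep <- ri != rj
        if (any(keep)) {
          pk <- unique(paste(pmin(ri[keep], rj[keep]),
                             pmax(ri[keep], rj[keep])))
          for (p in pk) assign(p, TRUE, envir = pairs)
        }
      }
    }
  }
  out <- vector("list", n)
  for (p in ls(pairs)) {
    ij <- as.integer(strsplit(p, " ", fixed = TRUE)[[1]])
    out[[ij[1]]] <- c(out[[ij[1]]], ij[2])
    out[[ij[2]]] <- c(out[[ij[2]]], ij[1])
  }
  lapply(out, function(v) sort(unique(v %||% integer(0))))
}

#' Chain and ligand interface membership
#'
#' For each residue of the annotated chain, reports the identifier of a
#' contacting other polymer chain and/or non-water ligand group (minimum
#' heavy-atom distance at or below the cutoff, default 5 A).  When
#' several partners qualify, the one with the smallest minimum distance
#' is kept, so exactly one partner per residue is reported.
#'
#' @param struct a [chain_structure()] with `other_chains` /` hetero`
#'   populated.
#' @param cutoff distance cutoff, A.
#' @return data.frame with character columns `chain_contact`,
#'   `ligand_contact` (NA where no partner is within the cutoff).
#' @export
compute_interface_contacts <- function(struct, cutoff = 5.0) {
  stopifnot(cutoff > 0)
  a <- struct$atoms
  n <- n_residues(struct)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  chain_contact <- ligand_contact <- rep(NA_character_, n)
  chain_best <- ligand_best <- rep(Inf, n)
  nearest_per_residue <- function(partner_xyz) {
    d2 <- cross_dist2(xyz, partner_xyz)
    dmin <- sqrt(pmax(0, apply(d2, 1, min)))
    as.numeric(tapply(dmin, a$res_idx, min))
  }
  for (oc in struct$other_chains) {
    dres <- nearest_per_residue(as.matrix(oc$atoms[, c("x", "y", "z")]))
    upd <- dres <= cutoff & dres < chain_best
    chain_contact[upd] <- oc$chain_id
    chain_best[upd] <- dres[upd]
  }
  for (h in struct$hetero) {
    dres <- nearest_per_residue(as.matrix(h$atoms[, c("x", "y", "z")]))
    upd <- dres <= cutoff & dres < ligand_best
    ligand_contact[upd] <- h$name
    ligand_best[upd] <- dres[upd]
  }
  data.frame(chain_contact = chain_contact, ligand_contact = ligand_contact,
             stringsAsFactors = FALSE)
}
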