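## Domain containers.  A `chain_structure` holds one polymer chain as a flat
## atom table (bio3d-style), plus any non-water hetero groups and the other
## polymer chains of the same file for interface analysis.  An `alignment`
## holds `aligned_sequence` rows; per-residue and per-column annotation
## tracks are plain data frames attached to those objects.

AA3_TO_1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M"
)

AA1_TO_3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL", X = "UNK"
)

AMINO_ACIDS <- sort(unname(AA3_TO_1[setdiff(names(AA3_TO_1), "MSE")]))

#' Default analysis parameters
#'
#' All tunable thresholds of the annotation pipeline with their default
#' values: burial threshold (% relative SASA), solvent probe radius and
#' sphere-sampling density, sidechain H-bond cutoff (A), intra-chain
#' contact cutoff (A), chain/ligand interface cutoff (A), secondary
#' structure consensus fraction, prediction-rendering confidence
#' thresholds, RMSD bin edges (A), the maximum number of sequences
#' accepted in one alignment, and the HTML wrap width.
#'
#' @param ... named overrides of individual defaults.
#' @return Named list of parameters.
#' @export
#' @examples
#' default_params(burial_threshold = 5)$burial_threshold
default_params <- function(...) {
  p <- list(
    burial_threshold = 7,        # % relative SASA below which a residue is buried
    probe_radius = 1.4,          # A, solvent probe
    n_sphere_points = 480,       # sphere-sampling density for SASA/depth
    hbond_cutoff = 3.5,          # A, sidechain-mainchain donor-acceptor
    contact_cutoff = 6.0,        # A, intra-chain residue contacts
    interface_cutoff = 5.0,      # A, chain/ligand interfaces
    consensus_threshold = 0.70,  # fraction for SS consensus
    pred_strong = 0.7,           # SS prediction confidence, strong rendering
    pred_weak = 0.3,             # SS prediction confidence, weak rendering
    disorder_threshold = 8,      # 0-9 scale
    rmsd_bin_edges = c(2, 4, 6, 8), # A
    max_sequences = 25,
    wrap_width = 60,
    seed = 1L
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
  }
  p
}

#' Construct a chain structure
#'
#' @param source_id identifier matching the alignment sequence id.
#' @param chain_id one-character chain identifier.
#' @param atoms data.frame with columns `res_idx` (1-based residue index),
#'   `seq_id` (author residue number + insertion code, character),
#'   `resname` (three-letter), `one_letter`, `atom` (PDB atom name),
#'   `element`, `x`, `y`, `z`.
#' @param hetero list of non-water hetero groups, each
#'   `list(name =, atoms = data.frame(atom, element, x, y, z))`.
#' @param other_chains list of other polymer chains, each
#'   `list(chain_id =, atoms = <atom data.frame>)`.
#' @return Object of class `chain_structure`.
#' @export
chain_structure <- function(source_id, chain_id, atoms,
                            hetero = list(), other_chains = list()) {
  required <- c("res_idx", "seq_id", "resname", "one_letter",
                "atom", "element", "x", "y", "z")
  miss <- setdiff(required, names(atoms))
  if (length(miss)) stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) {
    stop("empty-chain error: chain '", chain_id, "' of '", source_id,
         "' has no polymer residues")
  }
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates in '", source_id, "'")
  }
  if (any(!nzchar(atoms$atom))) stop("atom with empty name in '", source_id, "'")
  if (is.unsorted(atoms$res_idx)) {
    stop("atoms of '", source_id, "' are not grouped by residue order")
  }
  structure(
    list(source_id = source_id, chain_id = chain_id,
         atoms = atoms, hetero = hetero, other_chains = other_chains),
    class = "chain_structure"
  )
}

#' @export
print.chain_structure <- function(x, ...) {
  cat(sprintf(
    "<chain_structure> %s chain %s: %d residues, %d atoms, %d hetero group(s), %d other chain(s)\n",
    x$source_id, x$chain_id, n_residues(x), nrow(x$atoms),
    length(x$hetero), length(x$other_chains)
  ))
  invisible(x)
}

#' Number of residues in a chain structure
#' @param struct a `chain_structure`.
#' @return Integer count.
#' @export
n_residues <- function(struct) length(unique(struct$atoms$res_idx))

#' One-letter sequence observed in a chain structure
#' @param struct a `chain_structure`.
#' @return Character vector, one letter per residue in chain order.
#' @export
chain_sequence <- function(struct) {
  a <- struct$atoms
  a$one_letter[!duplicated(a$res_idx)]
}

## Coordinates of one named atom per residue (NA rows where absent).
residue_atom_xyz <- function(struct, atom_name) {
  a <- struct$atoms
  n <- n_residues(struct)
  out <- matrix(NA_real_, n, 3)
  sel <- a$atom == atom_name
  idx <- a$res_idx[sel]
  keep <- !duplicated(idx)
  out[idx[keep], ] <- as.matrix(a[sel, c("x", "y", "z")])[keep, , drop = FALSE]
  out
}

#' Construct an aligned sequence
#'
#' @param seq_id sequence identifier.
#' @param role one of `"structure"`, `"model"`, `"sequence"`.
#' @param gapped gapped sequence string over amino-acid codes and `-`.
#' @param structure optional attached [chain_structure()] (required for
#'   structure/model roles once matched).
#' @param annotations optional per-residue annotation data.frame.
#' @param prediction optional prediction track (see
#'   [parse_ss_prediction()]).
#' @return Object of class `aligned_sequence`.
#' @export
aligned_sequence <- function(seq_id, role, gapped, structure = NULL,
                             annotations = NULL, prediction = NULL) {
  role <- match.arg(role, c("structure", "model", "sequence"))
  gapped <- toupper(gsub(".", "-", gapped, fixed = TRUE))
  letters_ok <- strsplit(gapped, "")[[1]] %in% c(AMINO_ACIDS, "X", "-")
  if (!all(letters_ok)) {
    stop("sequence '", seq_id, "' contains invalid character(s): ",
         paste(unique(strsplit(gapped, "")[[1]][!letters_ok]), collapse = ""))
  }
  if (role == "sequence" && !is.null(structure)) {
    stop("sequence-role entry '", seq_id, "' cannot carry a structure")
  }
  structure(
    list(seq_id = seq_id, role = role, gapped = gapped,
         structure = structure, annotations = annotations,
         prediction = prediction),
    class = "aligned_sequence"
  )
}

ungapped <- function(aseq) gsub("-", "", aseq$gapped, fixed = TRUE)

#' Construct and validate an alignment
#'
#' Enforces the construction invariants: all gapped strings share one
#' length, the number of sequences is between 1 and `max_sequences`
#' (default 25), identifiers are unique and no column is all gaps.
#'
#' @param sequences list of [aligned_sequence()] objects.
#' @param max_sequences validation limit on the number of rows.
#' @return Object of class `alignment` with elements `sequences` and
#'   `n_columns`.
#' @export
new_alignment <- function(sequences, max_sequences = 25) {
  if (length(sequences) == 0L) stop("empty-input error: alignment has no sequences")
  if (length(sequences) > max_sequences) {
    stop("too-many-sequences error: ", length(sequences),
         " sequences exceed the limit of ", max_sequences)
  }
  lens <- vapply(sequences, function(s) nchar(s$gapped), integer(1))
  ids <- vapply(sequences, function(s) s$seq_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (length(unique(lens)) != 1L) {
    off <- ids[lens != lens[1]][1]
    stop("alignment-shape error: sequence '", off,
         "' has length ", lens[ids == off][1],
         " but the first record has length ", lens[1])
  }
  mat <- alignment_matrix_from_list(sequences)
  all_gap <- which(colSums(mat != "-") == 0L)
  if (length(all_gap)) {
    stop("alignment column ", all_gap[1], " consists entirely of gaps")
  }
  structure(
    list(sequences = sequences, n_columns = unname(lens[1])),
    class = "alignment"
  )
}

alignment_matrix_from_list <- function(sequences) {
  do.call(rbind, lapply(sequences, function(s) strsplit(s$gapped, "")[[1]]))
}

#' Alignment as a character matrix
#' @param aln an `alignment`.
#' @return Character matrix, rows = sequences, columns = alignment columns.
#' @export
alignment_matrix <- function(aln) alignment_matrix_from_list(aln$sequences)

#' @export
print.alignment <- function(x, ...) {
  roles <- vapply(x$sequences, function(s) s$role, character(1))
  cat(sprintf(
    "<alignment> %d sequence(s) x %d column(s) [%d structure, %d model, %d sequence]\n",
    length(x$sequences), x$n_columns,
    sum(roles == "structure"), sum(roles == "model"), sum(roles == "sequence")
  ))
  invisible(x)
}

## Map residue index -> alignment column for one aligned sequence.
residue_columns <- function(aseq) which(strsplit(aseq$gapped, "")[[1]] != "-")

alignment_roles <- function(aln) {
  vapply(aln$sequences, function(s) s$role, character(1))
}

alignment_ids <- function(aln) {
  vapply(aln$sequences, function(s) s$seq_id, character(1))
}

## Empty per-residue annotation track of a given length.
empty_annotation_track <- function(n) {
  data.frame(
    ss = rep(NA_character_, n),
    rel_sasa = rep(NA_real_, n),
    buried = rep(NA, n),
    phi = rep(NA_real_, n),
    psi = rep(NA_real_, n),
    positive_phi = rep(NA, n),
    hbond_to_amide = rep(FALSE, n),
    hbond_to_carbonyl = rep(FALSE, n),
    depth = rep(NA_real_, n),
    chain_contact = rep(NA_character_, n),
    ligand_contact = rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
}
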