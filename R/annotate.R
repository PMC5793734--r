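## The annotation pipeline: per-residue feature computation for one
## chain, then document assembly over the whole alignment.

#' Compute the full per-residue annotation track of one chain
#'
#' Runs all structural feature calculators: secondary structure,
#' solvent accessibility and burial, phi/psi and phi sign,
#' sidechain-to-mainchain hydrogen bonds, residue depth, intra-chain
#' contacts, and chain/ligand interface membership.
#'
#' @param struct a [chain_structure()].
#' @param params parameters from [default_params()].
#' @return data.frame with one row per residue (plus a `contacts`
#'   list-column of residue indices).
#' @export
annotate_structure <- function(struct, params = default_params()) {
  n <- n_residues(struct)
  ann <- empty_annotation_track(n)
  ann$ss <- assign_secondary_structure(struct)
  sasa <- compute_sasa(struct, params$probe_radius, params$n_sphere_points)
  resnames <- struct$atoms$resname[!duplicated(struct$atoms$res_idx)]
  bur <- classify_burial(sasa$residue_sasa, resnames,
                         params$burial_threshold)
  ann$rel_sasa <- bur$rel_sasa
  ann$buried <- bur$buried
  tor <- compute_phi_psi(struct)
  ann$phi <- tor$phi
  ann$psi <- tor$psi
  ann$positive_phi <- tor$positive_phi
  hb <- detect_sidechain_mainchain_hbonds(struct, params$hbond_cutoff)
  ann$hbond_to_amide <- hb$hbond_to_amide
  ann$hbond_to_carbonyl <- hb$hbond_to_carbonyl
  ann$depth <- compute_residue_depth(struct, params$probe_radius, sasa)
  iface <- compute_interface_contacts(struct, params$interface_cutoff)
  ann$chain_contact <- iface$chain_contact
  ann$ligand_contact <- iface$ligand_contact
  ann$contacts <- I(compute_intra_contacts(struct, params$contact_cutoff))
  ann
}

#' Annotate a matched alignment
#'
#' Computes the residue annotation track of every structure/model row,
#' the per-column track (entropy + symbol, SS consensus, C-alpha RMSD +
#' bin when at least two structures are present), the PID table of the
#' first non-structure row, and assembles everything into an
#' [build_document()] with the parameters recorded as provenance.
#' Prediction tracks (named by sequence id) are attached to the rows
#' eligible per [select_predicted_sequences()].
#'
#' @param aln an [new_alignment()] with structures already attached by
#'   [match_alignment_to_structures()].
#' @param params parameters from [default_params()].
#' @param predictions optional named list of [parse_ss_prediction()]
#'   tracks keyed by sequence id.
#' @return An `annotation_document`.
#' @export
annotate_alignment <- function(aln, params = default_params(),
                               predictions = NULL) {
  stopifnot(inherits(aln, "alignment"))
  seqs <- lapply(aln$sequences, function(s) {
    if (!is.null(s$structure)) {
      s$annotations <- annotate_structure(s$structure, params)
    }
    s
  })
  aln <- new_alignment(seqs, max_sequences = max(params$max_sequences,
                                                 length(seqs)))

  if (!is.null(predictions)) {
    eligible <- select_predicted_sequences(aln)
    for (id in names(predictions)) {
      if (!id %in% eligible) {
        warning("prediction for '", id,
                "' ignored: not an eligible row (first sequence-role ",
                "row and model-role rows only)")
        next
      }
      k <- which(alignment_ids(aln) == id)
      track <- predictions[[id]]
      if (!inherits(track, "prediction_track")) {
        track <- parse_ss_prediction(track, ungapped(aln$sequences[[k]]))
      }
      aln$sequences[[k]]$prediction <- track
    }
  }

  n_struct <- sum(vapply(aln$sequences, function(s) !is.null(s$structure),
                         logical(1)))
  sup <- if (n_struct >= 2) superpose(aln) else NULL

  nc <- aln$n_columns
  entropy <- vapply(seq_len(nc), function(i)
    shannon_entropy(column_frequencies(aln, i)), numeric(1))
  cols <- data.frame(
    entropy = entropy,
    entropy_symbol = entropy_symbol(entropy),
    consensus_ss = vapply(seq_len(nc), function(i)
      consensus_ss(aln, i, params$consensus_threshold), character(1)),
    rmsd = if (is.null(sup)) NA_real_ else sup$column_rmsd,
    stringsAsFactors = FALSE
  )
  cols$rmsd_bin <- rmsd_bin(cols$rmsd, params$rmsd_bin_edges)

  build_document(aln, cols, sup, pid_table(aln), params)
}
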