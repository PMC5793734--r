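# Fully annotated document fixture and field-wise equality helper,
# shared by the document/render/acceptance tests.

annotated_doc <- function() {
  cached("doc3", function() {
    aln <- make_toy_alignment(3, 12, seed = 4, profile = "mixed",
                              with_structures = TRUE, noise_sd = 0.2)
    seqs <- aln$sequences
    seqs[[4]] <- aligned_sequence("query1", "sequence", seqs[[1]]$gapped)
    aln <- new_alignment(seqs)
    preds <- list(query1 = parse_ss_prediction(paste(
      c("index residue helix strand coil disorder",
        sprintf("%d %s %.2f %.2f %.2f %.1f", 1:12,
                strsplit(gsub("-", "", seqs[[4]]$gapped), "")[[1]],
                rep(c(0.9, 0.5, 0.1), 4), rep(0.05, 12),
                rep(0.05, 12), rep(c(0.9, 0.2), 6))),
      collapse = "\n")))
    annotate_alignment(aln, default_params(), preds)
  })
}

expect_documents_equal <- function(a, b, tol = 1e-5) {
  expect_equal(alignment_ids(b$alignment), alignment_ids(a$alignment))
  for (k in seq_along(a$alignment$sequences)) {
    sa <- a$alignment$sequences[[k]]
    sb <- b$alignment$sequences[[k]]
    expect_equal(sb$role, sa$role)
    expect_equal(sb$gapped, sa$gapped)
    if (!is.null(sa$annotations)) {
      for (col in c("ss", "rel_sasa", "buried", "phi", "psi",
                    "positive_phi", "hbond_to_amide", "hbond_to_carbonyl",
                    "depth", "chain_contact", "ligand_contact")) {
        expect_equal(sb$annotations[[col]], sa$annotations[[col]],
                     tolerance = tol, label = paste0(sa$seq_id, "$", col))
      }
      expect_equal(lapply(sb$annotations$contacts, as.integer),
                   lapply(sa$annotations$contacts, as.integer))
    }
    if (!is.null(sa$prediction)) {
      expect_equal(as.data.frame(sb$prediction),
                   as.data.frame(sa$prediction), tolerance = tol)
    }
  }
  expect_equal(b$columns$entropy, a$columns$entropy, tolerance = tol)
  expect_equal(b$columns$entropy_symbol, a$columns$entropy_symbol)
  expect_equal(b$columns$consensus_ss, a$columns$consensus_ss)
  expect_equal(b$columns$rmsd, a$columns$rmsd, tolerance = tol)
  expect_equal(b$columns$rmsd_bin, a$columns$rmsd_bin)
  if (!is.null(a$superposition)) {
    expect_equal(names(b$superposition$transforms),
                 names(a$superposition$transforms))
    for (id in names(a$superposition$transforms)) {
      expect_equal(b$superposition$transforms[[id]]$rot,
                   a$superposition$transforms[[id]]$rot, tolerance = tol)
      expect_equal(b$superposition$transforms[[id]]$trans,
                   a$superposition$transforms[[id]]$trans, tolerance = tol)
    }
    expect_equal(b$superposition$shared_columns,
                 a$superposition$shared_columns)
    expect_equal(b$superposition$weights, a$superposition$weights,
                 tolerance = tol)
  }
  expect_equal(b$pid, a$pid, tolerance = tol)
  expect_equal(b$params[names(a$params)],
               lapply(a$params, as.numeric), tolerance = tol)
  expect_equal(b$version, a$version)
}

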