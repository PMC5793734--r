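test_that("residue glyphs encode the typesetting key", {
  ann <- structaln:::empty_annotation_track(1)
  ann$ss <- "H"; ann$buried <- TRUE; ann$rel_sasa <- 3
  ann$positive_phi <- FALSE; ann$depth <- 2
  ctx <- list(mode = "interactive-lite", depth_rng = c(2, 5),
              partner_cols = character(0), pred = NULL)
  g <- render_residue("a", ann[1, , drop = FALSE], "structure", ctx)
  expect_match(g, ">A</span>")               # buried -> uppercase
  expect_match(g, "color:#cc0000")           # alpha helix red
  expect_no_match(g, "pphi")

  ann$buried <- FALSE; ann$ss <- "E"; ann$positive_phi <- TRUE
  ann$hbond_to_amide <- TRUE; ann$hbond_to_carbonyl <- TRUE
  g2 <- render_residue("G", ann[1, , drop = FALSE], "structure", ctx)
  expect_match(g2, ">g</span>")              # exposed -> lowercase
  expect_match(g2, "color:#0000cc")          # strand blue
  expect_match(g2, "pphi")                   # italics class
  expect_match(g2, "hba")
  expect_match(g2, "hbc")

  # sequence-role residues keep their case and get Taylor colours
  g3 <- render_residue("W", NULL, "sequence", ctx)
  expect_match(g3, ">W</span>")
  expect_match(g3, "color:#00CCFF", fixed = TRUE)
})

test_that("rendered metadata parses back to the exact feature flags", {
  doc <- annotated_doc()
  html <- render_document(doc)
  s1 <- doc$alignment$sequences[[1]]
  ann <- s1$annotations
  # pull the first residue span of sequence 1 out of the document
  row <- regmatches(html, regexec(
    sprintf('<div class="row">%s\\s*(<span.*?</span>)',
            s1$seq_id), html))[[1]][2]
  feats <- parse_residue_features(row)
  expect_equal(unname(feats["ss"]), ann$ss[1])
  expect_equal(unname(feats["buried"]), tolower(as.character(ann$buried[1])))
  expect_equal(as.numeric(feats["depth"]), ann$depth[1], tolerance = 1e-5)
  if (length(ann$contacts[[1]])) {
    expect_equal(as.integer(strsplit(feats[["contacts"]], ",")[[1]]),
                 ann$contacts[[1]])
  }
})

test_that("each block renders n_sequences + 3 annotation rows plus a ruler", {
  doc <- annotated_doc()   # has RMSD rows (3 structures)
  html <- render_document(doc)
  n_blocks <- length(gregexpr('<div class="block">', html, fixed = TRUE)[[1]])
  expect_equal(n_blocks, ceiling(doc$alignment$n_columns /
                                   doc$params$wrap_width))
  rows_per_block <- length(
    gregexpr('<div class="row">', html, fixed = TRUE)[[1]]) / n_blocks
  n_seq <- length(doc$alignment$sequences)
  expect_equal(rows_per_block, n_seq + 3 + 1)   # + entropy/consensus/rmsd + ruler
})

test_that("column rows show entropy symbols, consensus and RMSD glyphs", {
  cols <- data.frame(
    entropy = c(0, 0.45, 1), entropy_symbol = c("*", "4", "9"),
    consensus_ss = c("a", "", "b"), rmsd = c(0.5, NA, 9),
    rmsd_bin = c(0L, NA, 4L), stringsAsFactors = FALSE
  )
  rows <- render_column_rows(cols, 1, 3)
  expect_length(rows, 3)
  expect_match(rows[1], "\\*")
  expect_match(rows[2], 'class="cs csa">a<')
  expect_match(rows[3], "█")
  expect_match(rows[3], "_")
  # without any defined RMSD the row is omitted
  cols$rmsd <- NA_real_; cols$rmsd_bin <- NA_integer_
  expect_length(render_column_rows(cols, 1, 3), 2)
})

test_that("rendering is deterministic and modes differ as documented", {
  doc <- annotated_doc()
  h1 <- render_document(doc)
  h2 <- render_document(doc)
  expect_identical(h1, h2)
  pr <- render_document(doc, "print")
  expect_no_match(pr, "data-feat")
  expect_match(h1, "data-feat")
  # both are self-contained (no external resources)
  expect_no_match(h1, "http[s]?://")
  expect_no_match(h1, "<script")
  # PID table appended after the alignment
  expect_match(h1, "Percentage sequence identity")
})

test_that("FASTA extraction reproduces the alignment sequences", {
  doc <- annotated_doc()
  fa <- extract_fasta(doc)
  re <- parse_fasta(fa)
  expect_equal(alignment_ids(re), alignment_ids(doc$alignment))
  expect_equal(vapply(re$sequences, function(s) s$gapped, character(1)),
               vapply(doc$alignment$sequences, function(s) s$gapped,
                      character(1)))
})
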