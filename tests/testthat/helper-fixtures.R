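# Shared fixtures, built once per test session (the sheet registry
# search is the only non-trivial construction).

.fix_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fix_cache[[key]])) .fix_cache[[key]] <- builder()
  .fix_cache[[key]]
}

fix_helix12 <- function() cached("helix12", function() make_ideal_helix(12))
fix_hairpin <- function() cached("hairpin", function() make_beta_hairpin(6))
fix_helix20 <- function() cached("helix20", function() make_ideal_helix(20))

# A chain of single-atom residues at given coordinates (for controlled
# distance scans).
make_point_chain <- function(xyz, resname = "GLY") {
  xyz <- matrix(xyz, ncol = 3)
  atoms <- data.frame(
    res_idx = seq_len(nrow(xyz)),
    seq_id = as.character(seq_len(nrow(xyz))),
    resname = resname,
    one_letter = unname(structaln:::AA3_TO_1[resname]),
    atom = "CA", element = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE
  )
  chain_structure("points", "A", atoms)
}

# Minimal alignment whose structure rows carry hand-set SS annotations
# (for consensus threshold scans without running geometry).
make_ss_alignment <- function(ss_letters_by_row, gapped = NULL) {
  n_row <- length(ss_letters_by_row)
  seqs <- lapply(seq_len(n_row), function(i) {
    ss <- ss_letters_by_row[[i]]
    gp <- gapped[[i]] %||% paste(rep("A", length(ss)), collapse = "")
    s <- aligned_sequence(sprintf("st%02d", i), "structure", gp)
    ann <- structaln:::empty_annotation_track(nchar(gsub("-", "", gp,
                                                         fixed = TRUE)))
    ann$ss <- ss
    s$annotations <- ann
    s
  })
  new_alignment(seqs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
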