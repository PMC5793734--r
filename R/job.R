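## End-to-end job: files in, annotated artifacts out.

#' Run the full annotation pipeline from input files
#'
#' Reads the alignment (FASTA or PIR), parses and matches the PDB
#' structures, computes all annotations, and writes the output bundle
#' into `out_dir`: the normalized PIR alignment, the XML annotation
#' document, the formatted HTML alignment in both modes, a FASTA
#' extraction and — when at least two structures are present — the
#' superposed-PDB archive.  Every parameter and validation action is
#' appended to `job.log`.
#'
#' @param alignment_path path to the alignment file.
#' @param pdb_paths character vector of PDB files, or a single directory
#'   containing `<seq_id>.pdb` files.
#' @param out_dir output directory (created if needed).
#' @param chain_map optional named character vector mapping sequence id
#'   to chain id (default: first polymer chain of each file).
#' @param params parameters from [default_params()].
#' @param prediction_paths optional named character vector of prediction
#'   tables keyed by sequence id.
#' @return Invisibly, a named list of the written artifact paths.
#' @export
annotate_job <- function(alignment_path, pdb_paths = character(0),
                         out_dir = ".", chain_map = NULL,
                         params = default_params(),
                         prediction_paths = NULL) {
  if (!file.exists(alignment_path)) {
    stop("alignment file not found: ", alignment_path)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "job.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("parameters: %s",
       paste(names(params),
             vapply(params, function(v) paste(v, collapse = ","),
                    character(1)),
             sep = "=", collapse = "; "))

  aln <- read_alignment(alignment_path, params$max_sequences)
  logf("alignment: %d sequence(s) x %d column(s) from %s",
       length(aln$sequences), aln$n_columns, alignment_path)

  if (length(pdb_paths) == 1L && dir.exists(pdb_paths)) {
    pdb_paths <- list.files(pdb_paths, pattern = "\\.(pdb|ent)$",
                            full.names = TRUE)
  }
  structs <- lapply(pdb_paths, function(p) {
    sid <- tools::file_path_sans_ext(basename(p))
    st <- parse_pdb_chain(p, chain_id = chain_map[sid][[1]] %||% NULL,
                          source_id = sid)
    logf("structure: %s chain %s, %d residue(s)", sid, st$chain_id,
         n_residues(st))
    st
  })
  aln <- match_alignment_to_structures(aln, structs)
  logf("sequence/structure correspondence validated")

  predictions <- NULL
  if (length(prediction_paths)) {
    predictions <- lapply(seq_along(prediction_paths), function(k) {
      id <- names(prediction_paths)[k]
      i <- which(alignment_ids(aln) == id)
      if (!length(i)) stop("prediction for unknown sequence '", id, "'")
      parse_ss_prediction(prediction_paths[[k]],
                          ungapped(aln$sequences[[i]]))
    })
    names(predictions) <- names(prediction_paths)
    logf("prediction track(s): %s",
         paste(names(prediction_paths), collapse = ", "))
  }

  doc <- annotate_alignment(aln, params, predictions)

  out <- list()
  out$pir <- file.path(out_dir, "alignment.pir")
  writeLines(write_pir(doc$alignment), out$pir)
  out$xml <- file.path(out_dir, "annotation.xml")
  write_annotation_xml(doc, out$xml)
  out$html <- file.path(out_dir, "alignment.html")
  writeLines(render_document(doc, "interactive-lite"), out$html, sep = "")
  out$html_print <- file.path(out_dir, "alignment_print.html")
  writeLines(render_document(doc, "print"), out$html_print, sep = "")
  out$fasta <- file.path(out_dir, "alignment.fasta")
  writeLines(extract_fasta(doc), out$fasta)
  if (!is.null(doc$superposition)) {
    out$superposed <- write_superposed_pdbs(doc$alignment,
                                            doc$superposition, out_dir)
  } else {
    logf("single structure: superposition/RMSD annotation skipped")
  }
  for (nm in names(out)) logf("wrote %s", out[[nm]])
  invisible(out)
}
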