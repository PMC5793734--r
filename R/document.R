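## The aggregate annotation document: alignment + per-residue tracks +
## per-column track + superposition metadata + PID table + provenance,
## with lossless XML round-trip (floats at 6 significant digits).  The
## schema ships as inst/schema/annotated-alignment.xsd and documents are
## validated against it on read.

DOCUMENT_FORMAT_VERSION <- "1.0"

fmt_num <- function(x) {
  ifelse(is.na(x), NA_character_, as.character(signif(x, 6)))
}

#' Assemble the annotation document
#'
#' Aggregates every computed track over one alignment into a single
#' serializable object, recording all analysis parameters as
#' provenance.  Track shapes are validated: the column track must have
#' `n_columns` rows and every structure/model row must carry a complete
#' per-residue annotation track.
#'
#' @param aln an [new_alignment()] whose structure rows carry
#'   `annotations` (and optionally `prediction`) tracks.
#' @param columns data.frame with one row per alignment column (fields
#'   `entropy`, `entropy_symbol`, `consensus_ss`, `rmsd`, `rmsd_bin`).
#' @param sup optional [superpose()] result.
#' @param pids optional PID table from [pid_table()].
#' @param params parameter list from [default_params()].
#' @return Object of class `annotation_document`.
#' @export
build_document <- function(aln, columns, sup = NULL, pids = NULL,
                           params = default_params()) {
  stopifnot(inherits(aln, "alignment"))
  if (nrow(columns) != aln$n_columns) {
    stop("assembly error: column track has ", nrow(columns),
         " rows but the alignment has ", aln$n_columns, " columns")
  }
  for (s in aln$sequences) {
    if (s$role %in% c("structure", "model")) {
      n_res <- nchar(ungapped(s))
      if (is.null(s$annotations)) {
        stop("assembly error: ", s$role, "-role sequence '", s$seq_id,
             "' lacks a residue annotation track")
      }
      if (nrow(s$annotations) != n_res) {
        stop("assembly error: annotation track of '", s$seq_id, "' has ",
             nrow(s$annotations), " rows for ", n_res, " residues")
      }
    }
    if (!is.null(s$prediction) &&
        nrow(s$prediction) != nchar(ungapped(s))) {
      stop("assembly error: prediction track of '", s$seq_id,
           "' does not match its residue count")
    }
  }
  structure(
    list(alignment = aln, columns = columns, superposition = sup,
         pid = pids %||% data.frame(structure_id = character(0),
                                    pid = numeric(0)),
         params = params, version = DOCUMENT_FORMAT_VERSION),
    class = "annotation_document"
  )
}

#' @export
print.annotation_document <- function(x, ...) {
  cat(sprintf(
    "<annotation_document v%s> %d sequence(s) x %d column(s)%s\n",
    x$version, length(x$alignment$sequences), x$alignment$n_columns,
    if (!is.null(x$superposition)) ", superposed" else ""
  ))
  invisible(x)
}

set_attr_maybe <- function(node, name, value) {
  if (length(value) == 1 && !is.na(value)) xml2::xml_set_attr(node, name, value)
}

#' Serialize an annotation document to XML
#'
#' @param doc an [build_document()] result.
#' @param path optional file to write; when `NULL` the XML is returned
#'   as a single string.
#' @return The path (invisibly) or the XML string.
#' @export
write_annotation_xml <- function(doc, path = NULL) {
  stopifnot(inherits(doc, "annotation_document"))
  root <- xml2::xml_new_root("annotated-alignment")
  xml2::xml_set_attr(root, "format-version", doc$version)

  prov <- xml2::xml_add_child(root, "provenance")
  xml2::xml_set_attr(prov, "tool", "structaln")
  xml2::xml_set_attr(prov, "tool-version", tryCatch(
    as.character(utils::packageVersion("structaln")),
    error = function(e) "dev"))
  for (nm in names(doc$params)) {
    p <- xml2::xml_add_child(prov, "param")
    xml2::xml_set_attr(p, "name", nm)
    xml2::xml_set_attr(p, "value",
                       paste(fmt_num(as.numeric(doc$params[[nm]])),
                             collapse = " "))
  }

  alnode <- xml2::xml_add_child(root, "alignment")
  xml2::xml_set_attr(alnode, "n-columns", doc$alignment$n_columns)
  for (s in doc$alignment$sequences) {
    sn <- xml2::xml_add_child(alnode, "sequence")
    xml2::xml_set_attr(sn, "id", s$seq_id)
    xml2::xml_set_attr(sn, "role", s$role)
    if (!is.null(s$structure)) {
      xml2::xml_set_attr(sn, "chain", s$structure$chain_id)
    }
    xml2::xml_add_child(sn, "gapped", s$gapped)
    if (!is.null(s$annotations)) {
      rn <- xml2::xml_add_child(sn, "residues")
      ann <- s$annotations
      letters <- strsplit(ungapped(s), "")[[1]]
      for (k in seq_len(nrow(ann))) {
        r <- xml2::xml_add_child(rn, "residue")
        xml2::xml_set_attr(r, "idx", k)
        xml2::xml_set_attr(r, "aa", letters[k])
        set_attr_maybe(r, "ss", ann$ss[k])
        set_attr_maybe(r, "rel-sasa", fmt_num(ann$rel_sasa[k]))
        set_attr_maybe(r, "buried", tolower(as.character(ann$buried[k])))
        set_attr_maybe(r, "phi", fmt_num(ann$phi[k]))
        set_attr_maybe(r, "psi", fmt_num(ann$psi[k]))
        set_attr_maybe(r, "positive-phi",
                       tolower(as.character(ann$positive_phi[k])))
        set_attr_maybe(r, "hb-amide",
                       tolower(as.character(ann$hbond_to_amide[k])))
        set_attr_maybe(r, "hb-carbonyl",
                       tolower(as.character(ann$hbond_to_carbonyl[k])))
        set_attr_maybe(r, "depth", fmt_num(ann$depth[k]))
        set_attr_maybe(r, "chain-contact", ann$chain_contact[k])
        set_attr_maybe(r, "ligand-contact", ann$ligand_contact[k])
        if (!is.null(ann$contacts) && length(ann$contacts[[k]])) {
          xml2::xml_set_attr(r, "contacts",
                             paste(ann$contacts[[k]], collapse = " "))
        }
      }
    }
    if (!is.null(s$prediction)) {
      pn <- xml2::xml_add_child(sn, "prediction")
      pr <- s$prediction
      for (k in seq_len(nrow(pr))) {
        p <- xml2::xml_add_child(pn, "p")
        xml2::xml_set_attr(p, "idx", k)
        xml2::xml_set_attr(p, "aa", pr$residue[k])
        xml2::xml_set_attr(p, "helix", fmt_num(pr$helix[k]))
        xml2::xml_set_attr(p, "strand", fmt_num(pr$strand[k]))
        xml2::xml_set_attr(p, "coil", fmt_num(pr$coil[k]))
        set_attr_maybe(p, "disorder", pr$disorder[k])
      }
    }
  }

  cn <- xml2::xml_add_child(root, "columns")
  cols <- doc$columns
  for (i in seq_len(nrow(cols))) {
    cl <- xml2::xml_add_child(cn, "column")
    xml2::xml_set_attr(cl, "idx", i)
    xml2::xml_set_attr(cl, "entropy", fmt_num(cols$entropy[i]))
    xml2::xml_set_attr(cl, "symbol", cols$entropy_symbol[i])
    if (!is.na(cols$consensus_ss[i]) && nzchar(cols$consensus_ss[i])) {
      xml2::xml_set_attr(cl, "consensus", cols$consensus_ss[i])
    }
    set_attr_maybe(cl, "rmsd", fmt_num(cols$rmsd[i]))
    set_attr_maybe(cl, "rmsd-bin", cols$rmsd_bin[i])
  }

  if (!is.null(doc$superposition)) {
    sup <- doc$superposition
    sn <- xml2::xml_add_child(root, "superposition")
    xml2::xml_set_attr(sn, "n-iter", sup$n_iter)
    for (id in names(sup$transforms)) {
      st <- xml2::xml_add_child(sn, "structure")
      xml2::xml_set_attr(st, "id", id)
      xml2::xml_add_child(st, "rotation",
                          paste(fmt_num(as.vector(t(sup$transforms[[id]]$rot))),
                                collapse = " "))
      xml2::xml_add_child(st, "translation",
                          paste(fmt_num(sup$transforms[[id]]$trans),
                                collapse = " "))
    }
    xml2::xml_add_child(sn, "shared-columns",
                        paste(sup$shared_columns, collapse = " "))
    xml2::xml_add_child(sn, "weights",
                        paste(fmt_num(sup$weights), collapse = " "))
  }

  pt <- xml2::xml_add_child(root, "pid-table")
  for (i in seq_len(nrow(doc$pid))) {
    p <- xml2::xml_add_child(pt, "pid")
    xml2::xml_set_attr(p, "structure", doc$pid$structure_id[i])
    xml2::xml_set_attr(p, "value", fmt_num(doc$pid$pid[i]))
  }

  if (is.null(path)) {
    as.character(root)
  } else {
    xml2::write_xml(root, path)
    invisible(path)
  }
}

xml_num <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  out[is.na(x) | x == ""] <- NA_real_
  out
}
xml_lgl <- function(x) ifelse(is.na(x), NA, x == "true")

#' Read an annotation document from XML
#'
#' Parses and validates a document written by [write_annotation_xml()]:
#' the file must be well-formed, match the shipped XSD schema, and pass
#' range checks (entropy in [0,1], relative SASA non-negative); a
#' violation raises a validation error with the offending element path.
#' Structure coordinates are not part of the document, so the rebuilt
#' alignment rows carry their annotation tracks but no
#' [chain_structure()].
#'
#' @param path XML file path or literal XML string.
#' @return An `annotation_document`.
#' @export
read_annotation_xml <- function(path) {
  x <- tryCatch(xml2::read_xml(path),
                error = function(e) stop("validation error: not well-formed XML: ",
                                         conditionMessage(e)))
  xsd_path <- system.file("schema", "annotated-alignment.xsd",
                          package = "structaln")
  if (nzchar(xsd_path)) {
    ok <- xml2::xml_validate(x, xml2::read_xml(xsd_path))
    if (!ok) {
      stop("validation error: ", paste(attr(ok, "errors"), collapse = "; "))
    }
  }
  if (xml2::xml_name(x) != "annotated-alignment") {
    stop("validation error at /: root element must be 'annotated-alignment'")
  }

  params <- list()
  for (p in xml2::xml_find_all(x, "./provenance/param")) {
    v <- as.numeric(strsplit(xml2::xml_attr(p, "value"), " ")[[1]])
    params[[xml2::xml_attr(p, "name")]] <- v
  }

  seqs <- lapply(xml2::xml_find_all(x, "./alignment/sequence"), function(sn) {
    gp <- xml2::xml_text(xml2::xml_find_first(sn, "./gapped"))
    res_nodes <- xml2::xml_find_all(sn, "./residues/residue")
    ann <- NULL
    if (length(res_nodes)) {
      at <- function(a) vapply(res_nodes, xml2::xml_attr, character(1), attr = a)
      ent_path <- xml2::xml_path(res_nodes[1])
      ann <- empty_annotation_track(length(res_nodes))
      ann$ss <- at("ss")
      ann$rel_sasa <- xml_num(at("rel-sasa"))
      if (any(ann$rel_sasa < 0, na.rm = TRUE)) {
        stop("validation error at ", ent_path, ": negative rel-sasa")
      }
      ann$buried <- xml_lgl(at("buried"))
      ann$phi <- xml_num(at("phi"))
      ann$psi <- xml_num(at("psi"))
      ann$positive_phi <- xml_lgl(at("positive-phi"))
      ann$hbond_to_amide <- xml_lgl(at("hb-amide")) %in% TRUE
      ann$hbond_to_carbonyl <- xml_lgl(at("hb-carbonyl")) %in% TRUE
      ann$depth <- xml_num(at("depth"))
      ann$chain_contact <- at("chain-contact")
      ann$ligand_contact <- at("ligand-contact")
      ann$contacts <- I(lapply(at("contacts"), function(v) {
        if (is.na(v)) integer(0) else as.integer(strsplit(v, " ")[[1]])
      }))
    }
    pred_nodes <- xml2::xml_find_all(sn, "./prediction/p")
    pred <- NULL
    if (length(pred_nodes)) {
      at <- function(a) vapply(pred_nodes, xml2::xml_attr, character(1), attr = a)
      pred <- data.frame(
        residue = at("aa"), helix = xml_num(at("helix")),
        strand = xml_num(at("strand")), coil = xml_num(at("coil")),
        disorder = suppressWarnings(as.integer(at("disorder"))),
        stringsAsFactors = FALSE
      )
      class(pred) <- c("prediction_track", class(pred))
    }
    aligned_sequence(
      xml2::xml_attr(sn, "id"), xml2::xml_attr(sn, "role"), gp,
      annotations = ann, prediction = pred
    )
  })
  aln <- new_alignment(seqs, max_sequences = max(25, length(seqs)))

  col_nodes <- xml2::xml_find_all(x, "./columns/column")
  at <- function(a) vapply(col_nodes, xml2::xml_attr, character(1), attr = a)
  entropy <- xml_num(at("entropy"))
  bad <- which(entropy < 0 | entropy > 1)
  if (length(bad)) {
    stop("validation error at ", xml2::xml_path(col_nodes[[bad[1]]]),
         ": entropy ", entropy[bad[1]], " outside [0, 1]")
  }
  cols <- data.frame(
    entropy = entropy,
    entropy_symbol = at("symbol"),
    consensus_ss = ifelse(is.na(at("consensus")), "", at("consensus")),
    rmsd = xml_num(at("rmsd")),
    rmsd_bin = suppressWarnings(as.integer(at("rmsd-bin"))),
    stringsAsFactors = FALSE
  )

  sup <- NULL
  sn <- xml2::xml_find_first(x, "./superposition")
  if (!inherits(sn, "xml_missing")) {
    tf_nodes <- xml2::xml_find_all(sn, "./structure")
    tfs <- lapply(tf_nodes, function(st) {
      rot <- matrix(as.numeric(strsplit(
        xml2::xml_text(xml2::xml_find_first(st, "./rotation")), " ")[[1]]),
        3, 3, byrow = TRUE)
      trans <- as.numeric(strsplit(
        xml2::xml_text(xml2::xml_find_first(st, "./translation")), " ")[[1]])
      list(rot = rot, trans = trans)
    })
    names(tfs) <- vapply(tf_nodes, xml2::xml_attr, character(1), attr = "id")
    sup <- structure(list(
      transforms = tfs,
      column_rmsd = cols$rmsd,
      weights = as.numeric(strsplit(
        xml2::xml_text(xml2::xml_find_first(sn, "./weights")), " ")[[1]]),
      shared_columns = as.integer(strsplit(
        xml2::xml_text(xml2::xml_find_first(sn, "./shared-columns")), " ")[[1]]),
      n_iter = as.integer(xml2::xml_attr(sn, "n-iter"))
    ), class = "superposition")
  }

  pid_nodes <- xml2::xml_find_all(x, "./pid-table/pid")
  pids <- data.frame(
    structure_id = vapply(pid_nodes, xml2::xml_attr, character(1),
                          attr = "structure"),
    pid = xml_num(vapply(pid_nodes, xml2::xml_attr, character(1),
                         attr = "value")),
    stringsAsFactors = FALSE
  )

  doc <- build_document(aln, cols, sup, pids, params)
  doc$version <- xml2::xml_attr(x, "format-version")
  doc
}
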