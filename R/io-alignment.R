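## Alignment input/output: FASTA, PIR/ALI (comparative-modelling dialect
## with structure / structureM / sequence role tags, plus the simplified
## dialect where only the first description field is populated), and the
## normalized PIR writer.

read_text_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else if (length(x) == 1L) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(x)
  }
}

#' Parse a FASTA alignment
#'
#' Every record becomes a sequence-role row (roles are upgraded later when
#' a structure is attached by [match_alignment_to_structures()]).  Gap
#' characters `.` are normalized to `-`.
#'
#' @param text FASTA content: a path, a single string, or a character
#'   vector of lines.
#' @param max_sequences validation limit (default 25).
#' @return An [new_alignment()].
#' @export
#' @examples
#' parse_fasta(">A\nAC-D\n>B\nACED")
parse_fasta <- function(text, max_sequences = 25) {
  lines <- read_text_lines(text)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty-input error: no FASTA records found")
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("empty-input error: no FASTA header lines")
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- lapply(seq_along(hdr), function(k) {
    id <- strsplit(sub("^>\\s*", "", lines[hdr[k]]), "\\s+")[[1]][1]
    if (is.na(id) || !nzchar(id)) stop("FASTA record ", k, " has an empty identifier")
    body <- if (ends[k] >= hdr[k] + 1L)
      paste(lines[(hdr[k] + 1L):ends[k]], collapse = "") else ""
    aligned_sequence(id, "sequence", gsub("\\s", "", body))
  })
  new_alignment(seqs, max_sequences = max_sequences)
}

PIR_ROLE_TAGS <- c(
  structure = "structure", structureX = "structure", structureN = "structure",
  structureM = "model", sequence = "sequence"
)

#' Parse a PIR/ALI alignment
#'
#' Accepts the comparative-modelling PIR conventions: each record has a
#' `>P1;id` header, a colon-separated description line whose first field
#' is one of `structure`, `structureX`, `structureN` (all mapped to role
#' `structure`), `structureM` (role `model`) or `sequence`, and a gapped
#' sequence terminated by `*`.  The simplified dialect (only the first
#' description field populated) is accepted as well.
#'
#' @inheritParams parse_fasta
#' @return An [new_alignment()] with roles taken from the description
#'   tags.
#' @export
parse_pir <- function(text, max_sequences = 25) {
  lines <- read_text_lines(text)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty-input error: no PIR records found")
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("empty-input error: no PIR header lines")
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- lapply(seq_along(hdr), function(k) {
    head_line <- lines[hdr[k]]
    id <- sub("^>\\s*(P1;)?\\s*", "", head_line)
    id <- strsplit(id, "\\s+")[[1]][1]
    if (is.na(id) || !nzchar(id)) stop("PIR record ", k, " has an empty identifier")
    if (ends[k] < hdr[k] + 2L) {
      stop("PIR record '", id, "' lacks a description and/or sequence line")
    }
    desc <- lines[hdr[k] + 1L]
    tag <- trimws(strsplit(desc, ":", fixed = TRUE)[[1]][1])
    if (!tag %in% names(PIR_ROLE_TAGS)) {
      stop("unknown PIR role tag '", tag, "' in record '", id, "'")
    }
    body <- paste(lines[(hdr[k] + 2L):ends[k]], collapse = "")
    body <- gsub("\\s", "", body)
    if (!grepl("\\*$", body)) {
      stop("PIR record '", id, "' is missing the '*' terminator")
    }
    body <- sub("\\*$", "", body)
    aligned_sequence(id, unname(PIR_ROLE_TAGS[tag]), body)
  })
  new_alignment(seqs, max_sequences = max_sequences)
}

#' Read an alignment, auto-detecting FASTA vs PIR
#'
#' PIR is recognized by `>P1;`-style headers or by a role-tag description
#' line following the header; anything else is treated as FASTA.
#'
#' @inheritParams parse_fasta
#' @return An [new_alignment()].
#' @export
read_alignment <- function(text, max_sequences = 25) {
  lines <- read_text_lines(text)
  nonempty <- lines[nzchar(trimws(lines))]
  is_pir <- length(nonempty) >= 2 &&
    (grepl("^>\\s*P1;", nonempty[1]) ||
       trimws(strsplit(nonempty[2], ":", fixed = TRUE)[[1]][1]) %in%
         names(PIR_ROLE_TAGS))
  if (is_pir) parse_pir(lines, max_sequences)
  else parse_fasta(lines, max_sequences)
}

#' Write an alignment in PIR format
#'
#' Roles map back to description tags (`structure`, `structureM`,
#' `sequence`); the simplified dialect is emitted (only the first
#' description field populated).  The result re-parses identically in
#' identifiers, roles and gapped sequences.
#'
#' @param aln an [new_alignment()].
#' @param width sequence line wrap width.
#' @return Character vector of lines.
#' @export
write_pir <- function(aln, width = 60) {
  stopifnot(inherits(aln, "alignment"))
  if (length(aln$sequences) == 0L) stop("cannot write an empty alignment")
  tag_of <- c(structure = "structure", model = "structureM",
              sequence = "sequence")
  unlist(lapply(aln$sequences, function(s) {
    body <- paste0(s$gapped, "*")
    chunks <- substring(body, seq(1, nchar(body), width),
                        pmin(seq(1, nchar(body), width) + width - 1, nchar(body)))
    c(paste0(">P1;", s$seq_id),
      paste0(tag_of[[s$role]], ":", s$seq_id, ":::::::0.00:0.00"),
      chunks)
  }))
}

#' Attach parsed structures to their alignment rows
#'
#' Pairs each structure/model-role row with the [chain_structure()] whose
#' `source_id` equals its `seq_id` and verifies that the ungapped
#' alignment sequence is identical to the sequence observed in the
#' coordinate (ATOM) records — the classic SEQRES-vs-ATOM pitfall is
#' reported with the first mismatching position and both letters.  An
#' `X` in the alignment matches any structure residue.  FASTA-derived
#' rows (role `sequence`) that have a matching structure are upgraded to
#' role `structure`; rows without a structure pass through untouched.
#'
#' @param aln an [new_alignment()].
#' @param structs list of [chain_structure()] objects.
#' @return The alignment with structures attached; idempotent.
#' @export
match_alignment_to_structures <- function(aln, structs) {
  stopifnot(inherits(aln, "alignment"))
  by_id <- stats::setNames(structs, vapply(structs, function(s) s$source_id,
                                           character(1)))
  seqs <- lapply(aln$sequences, function(s) {
    st <- by_id[[s$seq_id]]
    if (s$role %in% c("structure", "model")) {
      if (is.null(st) && is.null(s$structure)) {
        stop("no structure provided for ", s$role, "-role sequence '",
             s$seq_id, "'")
      }
      if (is.null(st)) st <- s$structure
    } else if (is.null(st)) {
      return(s)
    } else {
      s$role <- "structure"   # FASTA rows with a matching PDB become structures
    }
    aseq <- strsplit(ungapped(s), "")[[1]]
    sseq <- chain_sequence(st)
    if (length(aseq) != length(sseq)) {
      stop("sequence/structure mismatch for '", s$seq_id, "': alignment has ",
           length(aseq), " residues but the coordinate records have ",
           length(sseq),
           " (check that the alignment follows the ATOM sequence, not SEQRES)")
    }
    diff <- which(aseq != sseq & aseq != "X" & sseq != "X")
    if (length(diff)) {
      stop("sequence/structure mismatch for '", s$seq_id, "' at residue ",
           diff[1], ": alignment has '", aseq[diff[1]],
           "' but the coordinate records have '", sseq[diff[1]],
           "' (check that the alignment follows the ATOM sequence, not SEQRES)")
    }
    s$structure <- st
    s
  })
  new_alignment(seqs, max_sequences = max(25, length(seqs)))
}
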