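## Externally produced secondary-structure and disorder predictions for
## non-structure rows.  Two dialects: the classic .ss2 table (index,
## residue, state, coil/helix/strand confidences in that column order)
## and a named-header TSV with fields index, residue, helix, strand,
## coil, disorder.  Predictions are inputs; nothing is predicted here.

#' Parse a secondary-structure/disorder prediction track
#'
#' @param text path, single string, or lines of a `.ss2`-style table or
#'   the TSV dialect (header `index residue helix strand coil
#'   disorder`).  Disorder confidences on a 0-1 scale are normalized to
#'   the 0-9 integer scale as `floor(10 x conf)` capped at 9.
#' @param sequence optional ungapped sequence to cross-check the
#'   `residue` column against (a mismatch is an error naming the
#'   position).
#' @return data.frame of class `prediction_track` with columns
#'   `residue`, `helix`, `strand`, `coil` (confidences in [0,1]) and
#'   `disorder` (integer 0-9, NA when the dialect lacks it).
#' @export
parse_ss_prediction <- function(text, sequence = NULL) {
  lines <- read_text_lines(text)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty prediction table")
  is_tsv <- grepl("^index\\b", lines[1], ignore.case = TRUE)
  if (is_tsv) {
    hdr <- tolower(strsplit(lines[1], "[\t ]+")[[1]])
    need <- c("index", "residue", "helix", "strand", "coil")
    miss <- setdiff(need, hdr)
    if (length(miss)) {
      stop("prediction table lacks column(s): ", paste(miss, collapse = ", "))
    }
    rows <- strsplit(lines[-1], "[\t ]+")
    get <- function(name) vapply(rows, function(r) r[match(name, hdr)],
                                 character(1))
    track <- data.frame(
      residue = toupper(get("residue")),
      helix = as.numeric(get("helix")),
      strand = as.numeric(get("strand")),
      coil = as.numeric(get("coil")),
      disorder = if ("disorder" %in% hdr) as.numeric(get("disorder"))
                 else NA_real_,
      stringsAsFactors = FALSE
    )
  } else {
    rows <- strsplit(lines, "[\t ]+")
    bad <- which(lengths(rows) < 6)
    if (length(bad)) {
      stop("prediction row ", bad[1],
           " has fewer than 6 fields (index, residue, state, 3 confidences)")
    }
    ## fixed .ss2 column order: coil, helix, strand
    track <- data.frame(
      residue = toupper(vapply(rows, `[`, character(1), 2)),
      helix = as.numeric(vapply(rows, `[`, character(1), 5)),
      strand = as.numeric(vapply(rows, `[`, character(1), 6)),
      coil = as.numeric(vapply(rows, `[`, character(1), 4)),
      disorder = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  if (anyNA(track$helix) || anyNA(track$strand) || anyNA(track$coil)) {
    stop("non-numeric confidence value in prediction table")
  }
  if (any(track$helix < 0 | track$helix > 1 |
          track$strand < 0 | track$strand > 1 |
          track$coil < 0 | track$coil > 1)) {
    stop("secondary-structure confidences must lie in [0, 1]")
  }
  dis <- track$disorder
  if (!all(is.na(dis))) {
    if (all(dis <= 1, na.rm = TRUE)) dis <- pmin(9, floor(10 * dis))
    if (any(dis < 0 | dis > 9, na.rm = TRUE)) {
      stop("disorder confidences must be on a 0-1 or 0-9 scale")
    }
    track$disorder <- as.integer(dis)
  } else {
    track$disorder <- NA_integer_
  }
  if (!is.null(sequence)) {
    seq_letters <- strsplit(gsub("-", "", sequence, fixed = TRUE), "")[[1]]
    if (length(seq_letters) != nrow(track)) {
      stop("track-mismatch error: prediction has ", nrow(track),
           " rows but the sequence has ", length(seq_letters), " residues")
    }
    diff <- which(track$residue != seq_letters & track$residue != "X" &
                  seq_letters != "X")
    if (length(diff)) {
      stop("track-mismatch error at residue ", diff[1],
           ": prediction has '", track$residue[diff[1]],
           "' but the sequence has '", seq_letters[diff[1]], "'")
    }
  }
  class(track) <- c("prediction_track", class(track))
  track
}

#' Rendering class of a secondary-structure prediction
#'
#' The larger of the helix and strand confidences selects the family;
#' confidence >= 0.7 renders strong, in [0.3, 0.7) weak, below 0.3 not
#' at all.  An exact helix/strand tie renders nothing.
#'
#' @param helix_conf,strand_conf confidences in [0, 1] (vectorized).
#' @return Character vector over `strong-helix`, `weak-helix`,
#'   `strong-strand`, `weak-strand`, `none`.
#' @export
#' @examples
#' ss_render_class(0.8, 0.1)   # strong-helix
ss_render_class <- function(helix_conf, strand_conf) {
  stopifnot(all(helix_conf >= 0 & helix_conf <= 1),
            all(strand_conf >= 0 & strand_conf <= 1))
  n <- max(length(helix_conf), length(strand_conf))
  helix_conf <- rep_len(helix_conf, n)
  strand_conf <- rep_len(strand_conf, n)
  fam <- ifelse(helix_conf > strand_conf, "helix",
                ifelse(strand_conf > helix_conf, "strand", "tie"))
  conf <- pmax(helix_conf, strand_conf)
  ifelse(fam == "tie" | conf < 0.3, "none",
         paste0(ifelse(conf >= 0.7, "strong-", "weak-"), fam))
}

#' Should a disorder prediction be rendered?
#'
#' @param disorder_conf integer confidence on the 0-9 scale (vectorized).
#' @return Logical: `TRUE` iff confidence >= 8.
#' @export
disorder_render_class <- function(disorder_conf) {
  stopifnot(all(disorder_conf >= 0 & disorder_conf <= 9, na.rm = TRUE))
  !is.na(disorder_conf) & disorder_conf >= 8
}

#' Rows eligible for prediction tracks
#'
#' The first sequence-role row (only the first is analysed) plus every
#' model-role row, in alignment order.
#'
#' @param aln an [new_alignment()].
#' @return Character vector of sequence ids (possibly empty).
#' @export
select_predicted_sequences <- function(aln) {
  roles <- alignment_roles(aln)
  ids <- alignment_ids(aln)
  first_seq <- which(roles == "sequence")[1]
  sel <- sort(unique(c(which(roles == "model"),
                       if (!is.na(first_seq)) first_seq)))
  ids[sel]
}
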