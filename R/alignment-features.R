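## Column-level alignment features: gap-aware normalized Shannon entropy
## with its symbol row, secondary-structure consensus, and percentage
## sequence identity.

#' Residue and gap frequencies at an alignment column
#'
#' Frequencies are relative to the total number of sequences N (gaps
#' included in the denominator), so amino-acid frequencies plus the gap
#' frequency sum to 1.  Nonstandard `X` is counted in the denominator
#' but reported separately (it takes part in neither the 20-term entropy
#' sum nor the gap term).
#'
#' @param aln an [new_alignment()].
#' @param i 1-based column index.
#' @return List with `f` (named frequencies over the 20 amino acids),
#'   `f_gap`, `f_x` and `n_seqs`.
#' @export
column_frequencies <- function(aln, i) {
  stopifnot(i >= 1, i <= aln$n_columns)
  col <- vapply(aln$sequences, function(s) substr(s$gapped, i, i),
                character(1))
  N <- length(col)
  f <- vapply(AMINO_ACIDS, function(a) sum(col == a) / N, numeric(1))
  list(f = f, f_gap = sum(col == "-") / N, f_x = sum(col == "X") / N,
       n_seqs = N)
}

#' Gap-aware normalized Shannon entropy of a column
#'
#' S = -sum_a f_a log_n f_a + f_gap with n = min(20, N) and 0 log 0 = 0,
#' bounded in [0, 1]: 0 when the column is totally conserved without
#' gaps, 1 when all residues differ.  Gap frequency enters linearly, so
#' gaps in an otherwise conserved column raise the score.  A
#' single-sequence alignment has no defined log base and scores 0 by
#' convention; the result is clamped to [0, 1] against floating-point
#' drift.
#'
#' @param freqs result of [column_frequencies()].
#' @param n_seqs number of sequences (defaults to the count recorded in
#'   `freqs`).
#' @return Entropy in [0, 1].
#' @export
#' @examples
#' a <- parse_fasta(">s1\nA\n>s2\nA\n>s3\nC\n>s4\nC")
#' shannon_entropy(column_frequencies(a, 1))   # 0.5
shannon_entropy <- function(freqs, n_seqs = freqs$n_seqs) {
  n <- min(20, n_seqs)
  if (n < 2) return(0)
  f <- freqs$f[freqs$f > 0]
  s <- -sum(f * log(f, base = n)) + freqs$f_gap
  max(0, min(1, s))
}

#' Symbol for an entropy value
#'
#' `*` marks fully conserved columns (S = 0); other values map to the
#' digits 0-9 over half-open 0.1 intervals: `0` for 0 < S <= 0.1, `1`
#' for 0.1 < S <= 0.2, and so on up to `9` for 0.9 < S <= 1.
#'
#' @param S entropy in [0, 1] (vectorized).
#' @return Character vector of symbols.
#' @export
entropy_symbol <- function(S) {
  stopifnot(all(S >= 0 & S <= 1))
  ## bins (k/10, (k+1)/10]; comparisons against the exact tenth values
  k <- findInterval(S, 1:9 / 10, left.open = TRUE)
  ifelse(S == 0, "*", as.character(k))
}

#' Secondary-structure consensus symbol at a column
#'
#' Only structure/model rows with an assigned secondary structure
#' participate.  The class fraction is counted against all participating
#' rows (a gap at the column dilutes the consensus).  When the winning
#' fraction reaches the threshold (default 0.70) the column gets `a`
#' (alpha helix), `b` (beta strand) or `3` (3-10 helix); otherwise blank.
#'
#' @param aln an [new_alignment()] whose structure rows carry
#'   `annotations$ss`.
#' @param i 1-based column index.
#' @param threshold consensus fraction.
#' @return One of `"a"`, `"b"`, `"3"`, `""`.
#' @export
consensus_ss <- function(aln, i, threshold = 0.70) {
  stopifnot(i >= 1, i <= aln$n_columns)
  participating <- Filter(function(s) {
    s$role %in% c("structure", "model") && !is.null(s$annotations) &&
      "ss" %in% names(s$annotations)
  }, aln$sequences)
  if (length(participating) == 0L) return("")
  classes <- vapply(participating, function(s) {
    cols <- residue_columns(s)
    k <- match(i, cols)
    if (is.na(k)) NA_character_ else s$annotations$ss[k]
  }, character(1))
  denom <- length(participating)
  out <- ""
  for (cls in c("H", "E", "G")) {
    if (sum(classes == cls, na.rm = TRUE) / denom >= threshold) {
      out <- c(H = "a", E = "b", G = "3")[[cls]]
      break
    }
  }
  out
}

#' Percentage sequence identity between two aligned rows
#'
#' PID = 100 x (identical residue pairs) / (columns where both rows have
#' a residue).  Symmetric; when the rows share no columns the value is
#' reported as 0 with attribute `undefined = TRUE`.
#'
#' @param query,target [aligned_sequence()] rows of the same alignment.
#' @return Percentage in [0, 100].
#' @export
percent_identity <- function(query, target) {
  a <- strsplit(query$gapped, "")[[1]]
  b <- strsplit(target$gapped, "")[[1]]
  stopifnot(length(a) == length(b))
  shared <- a != "-" & b != "-"
  if (!any(shared)) {
    return(structure(0, undefined = TRUE))
  }
  100 * sum(a[shared] == b[shared]) / sum(shared)
}

#' PID of the first non-structure row against every structure row
#'
#' @param aln an [new_alignment()].
#' @return data.frame with columns `structure_id` and `pid`, or an empty
#'   data.frame when there is no non-structure row.
#' @export
pid_table <- function(aln) {
  roles <- alignment_roles(aln)
  q <- which(roles == "sequence")[1]
  empty <- data.frame(structure_id = character(0), pid = numeric(0),
                      stringsAsFactors = FALSE)
  if (is.na(q)) return(empty)
  st <- which(roles %in% c("structure", "model"))
  if (!length(st)) return(empty)
  data.frame(
    structure_id = vapply(aln$sequences[st], function(s) s$seq_id,
                          character(1)),
    pid = vapply(aln$sequences[st], function(s)
      as.numeric(percent_identity(aln$sequences[[q]], s)), numeric(1)),
    stringsAsFactors = FALSE
  )
}
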