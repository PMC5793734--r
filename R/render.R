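## HTML rendering of an annotation document: a self-contained formatted
## alignment (inline CSS, no scripts, no network dependencies) in two
## modes — "interactive-lite" with per-residue metadata attributes, and
## "print" without metadata and ink-heavy backgrounds.  Rendering is a
## pure function of the document: identical documents give identical
## bytes.

## Taylor physicochemical colour wheel (canonical published hues).
TAYLOR_COLOURS <- c(
  A = "#CCFF00", C = "#FFFF00", D = "#FF0000", E = "#FF0066",
  F = "#00FF66", G = "#FF9900", H = "#0066FF", I = "#66FF00",
  K = "#6600FF", L = "#33FF00", M = "#00FF00", N = "#CC00FF",
  P = "#FFCC00", Q = "#FF00CC", R = "#0000FF", S = "#FF3300",
  T = "#FF6600", V = "#99FF00", W = "#00CCFF", Y = "#00FFCC"
)

SS_COLOURS <- c(H = "#cc0000", G = "#800000", E = "#0000cc", C = "#000000")

## Partner bars (chain/ligand identity) cycle through this palette.
BAR_PALETTE <- c("#e41a1c", "#377eb8", "#4daf4a", "#984ea3", "#ff7f00",
                 "#a65628", "#f781bf", "#17becf")

DEPTH_LEVELS <- 8
DEPTH_GREYS <- local({
  g <- as.integer(round(seq(255, 120, length.out = DEPTH_LEVELS)))
  sprintf("#%02x%02x%02x", g, g, g)
})

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

## Deterministic partner -> colour assignment over the whole document.
partner_colours <- function(doc) {
  partners <- character(0)
  for (s in doc$alignment$sequences) {
    if (!is.null(s$annotations)) {
      partners <- c(partners, s$annotations$chain_contact,
                    s$annotations$ligand_contact)
    }
  }
  partners <- sort(unique(partners[!is.na(partners)]))
  stats::setNames(BAR_PALETTE[(seq_along(partners) - 1) %% length(BAR_PALETTE) + 1],
                  partners)
}

depth_range <- function(doc) {
  d <- unlist(lapply(doc$alignment$sequences, function(s)
    if (is.null(s$annotations)) NULL else s$annotations$depth))
  d <- d[is.finite(d)]
  if (!length(d)) c(0, 1) else range(d)
}

depth_level <- function(depth, rng) {
  if (!is.finite(depth)) return(NA_integer_)
  if (rng[2] - rng[1] < 1e-9) return(1L)
  lv <- 1L + as.integer(floor((depth - rng[1]) / (rng[2] - rng[1]) *
                                DEPTH_LEVELS))
  min(DEPTH_LEVELS, max(1L, lv))
}

#' Render one residue glyph
#'
#' Applies the typesetting key: case encodes burial (uppercase =
#' buried), colour encodes secondary structure for structure/model rows
#' (alpha red, 3-10 maroon, strand blue, coil black) and the Taylor
#' physicochemical scheme for sequence rows; italics mark positive phi,
#' bold a sidechain-to-amide hydrogen bond, underline a
#' sidechain-to-carbonyl bond; the background grey level encodes depth;
#' coloured borders mark chain (top) and ligand (bottom) partners and
#' prediction classes.  In `interactive-lite` mode every span carries a
#' `data-feat` attribute listing the features textually.
#'
#' @param letter one-letter residue code.
#' @param annotation one-row slice of the annotation track (or `NULL`).
#' @param role sequence role.
#' @param ctx rendering context (depth range, partner colours, mode,
#'   prediction row), as built by [render_document()].
#' @return HTML fragment (character).
#' @export
render_residue <- function(letter, annotation, role,
                           ctx = list(mode = "interactive-lite",
                                      depth_rng = c(0, 1),
                                      partner_cols = character(0),
                                      pred = NULL)) {
  styles <- character(0)
  classes <- character(0)
  feats <- character(0)
  glyph <- letter
  if (!is.null(annotation) && role %in% c("structure", "model")) {
    a <- annotation
    glyph <- if (isTRUE(a$buried)) toupper(letter) else tolower(letter)
    feats <- c(feats, paste0("buried=", tolower(as.character(isTRUE(a$buried)))))
    if (!is.na(a$ss)) {
      styles <- c(styles, paste0("color:", SS_COLOURS[[a$ss]]))
      feats <- c(feats, paste0("ss=", a$ss))
    }
    if (isTRUE(a$positive_phi)) {
      classes <- c(classes, "pphi")
      feats <- c(feats, "positive-phi=true")
    }
    if (isTRUE(a$hbond_to_amide)) {
      classes <- c(classes, "hba")
      feats <- c(feats, "hb-amide=true")
    }
    if (isTRUE(a$hbond_to_carbonyl)) {
      classes <- c(classes, "hbc")
      feats <- c(feats, "hb-carbonyl=true")
    }
    if (is.finite(a$rel_sasa)) {
      feats <- c(feats, sprintf("rel-sasa=%s", fmt_num(a$rel_sasa)))
    }
    if (is.finite(a$depth)) {
      lv <- depth_level(a$depth, ctx$depth_rng)
      if (ctx$mode != "print") classes <- c(classes, paste0("d", lv))
      feats <- c(feats, sprintf("depth=%s", fmt_num(a$depth)))
    }
    if (!is.na(a$chain_contact)) {
      styles <- c(styles, paste0("border-top:2px solid ",
                                 ctx$partner_cols[[a$chain_contact]]))
      feats <- c(feats, paste0("chain-contact=", a$chain_contact))
    }
    if (!is.na(a$ligand_contact)) {
      styles <- c(styles, paste0("border-bottom:2px solid ",
                                 ctx$partner_cols[[a$ligand_contact]]))
      feats <- c(feats, paste0("ligand-contact=", a$ligand_contact))
    }
    if (!is.null(a$contacts) && length(a$contacts[[1]])) {
      feats <- c(feats, paste0("contacts=",
                               paste(a$contacts[[1]], collapse = ",")))
    }
  } else {
    col <- TAYLOR_COLOURS[toupper(letter)]
    if (!is.na(col) && ctx$mode != "print") {
      styles <- c(styles, paste0("color:", col))
    }
    feats <- c(feats, "taylor=true")
  }
  if (!is.null(ctx$pred)) {
    p <- ctx$pred
    cls <- ss_render_class(p$helix, p$strand)
    if (cls != "none" && is.na(annotation$chain_contact %||% NA)) {
      classes <- c(classes, paste0("pr-", cls))
      feats <- c(feats, paste0("prediction=", cls))
    }
    if (!is.na(p$disorder) && disorder_render_class(p$disorder)) {
      classes <- c(classes, "disord")
      feats <- c(feats, "disorder=true")
    }
  }
  sprintf(
    '<span%s%s%s>%s</span>',
    if (length(classes)) paste0(' class="', paste(classes, collapse = " "), '"') else "",
    if (length(styles)) paste0(' style="', paste(styles, collapse = ";"), '"') else "",
    if (ctx$mode != "print" && length(feats))
      paste0(' data-feat="', paste(feats, collapse = ";"), '"') else "",
    html_escape(glyph)
  )
}

ruler_text <- function(from, to) {
  out <- rep(" ", to - from + 1)
  for (i in seq(from, to)) {
    if (i %% 10 == 0) {
      lab <- as.character(i)
      pos <- i - from + 1
      start <- pos - nchar(lab) + 1
      if (start >= 1) out[start:pos] <- strsplit(lab, "")[[1]]
    }
  }
  paste(out, collapse = "")
}

#' Render the per-column annotation rows of one block
#'
#' One row of entropy symbols (`*`, 0-9), one row of consensus symbols
#' (`a`/`b`/`3` on red/blue/orange backgrounds) and, when any column has
#' a defined RMSD, one row of block glyphs of increasing height for the
#' five RMSD bins.
#'
#' @param columns the document's column track (data.frame).
#' @param from,to 1-based column range of the block.
#' @param label_width width of the row-label gutter.
#' @return Character vector of HTML rows.
#' @export
render_column_rows <- function(columns, from, to,
                               label_width = 12) {
  blk <- columns[from:to, , drop = FALSE]
  pad <- function(lab) formatC(lab, width = label_width, flag = "-")
  rows <- character(0)
  rows <- c(rows, paste0(
    '<div class="row">', pad("entropy"),
    paste(vapply(blk$entropy_symbol, function(ch)
      sprintf('<span class="ent">%s</span>', ch), character(1)),
      collapse = ""),
    "</div>"
  ))
  cons <- vapply(seq_len(nrow(blk)), function(k) {
    ch <- blk$consensus_ss[k]
    if (is.na(ch) || !nzchar(ch)) {
      '<span class="cs">&nbsp;</span>'
    } else {
      sprintf('<span class="cs cs%s">%s</span>',
              c(a = "a", b = "b", `3` = "3")[[ch]], ch)
    }
  }, character(1))
  rows <- c(rows, paste0('<div class="row">', pad("consensus"),
                         paste(cons, collapse = ""), "</div>"))
  if (any(is.finite(blk$rmsd))) {
    glyphs <- vapply(seq_len(nrow(blk)), function(k) {
      b <- blk$rmsd_bin[k]
      if (is.na(b)) {
        '<span class="rb">&nbsp;</span>'
      } else {
        sprintf('<span class="rb" title="%s A">%s</span>',
                fmt_num(blk$rmsd[k]), RMSD_GLYPHS[b + 1])
      }
    }, character(1))
    rows <- c(rows, paste0('<div class="row">', pad("rmsd"),
                           paste(glyphs, collapse = ""), "</div>"))
  }
  rows
}

render_format_key <- function() {
  paste0(
    '<details open class="key"><summary>Format key</summary><ul>',
    '<li><b>UPPERCASE</b>: buried (relative accessibility below threshold); ',
    'lowercase: exposed</li>',
    '<li><span style="color:#cc0000">red</span> alpha helix, ',
    '<span style="color:#800000">maroon</span> 3-10 helix, ',
    '<span style="color:#0000cc">blue</span> beta strand (structure rows); ',
    'Taylor physicochemical colours on sequence rows</li>',
    '<li><i>italic</i>: positive mainchain phi</li>',
    '<li><b>bold</b>: sidechain hydrogen bond to a mainchain amide; ',
    '<u>underline</u>: to a mainchain carbonyl</li>',
    '<li>grey background: residue depth (darker = deeper)</li>',
    '<li>coloured top bar: contact with another chain; bottom bar: ',
    'contact with a ligand</li>',
    '<li>prediction bars: dark red/blue = helix/strand confidence &ge; 0.7, ',
    'lighter shade for 0.3&ndash;0.7; light green: disorder confidence ',
    '&ge; 8</li>',
    '<li>entropy row: * fully conserved, digits 0&ndash;9 for 0.1-wide ',
    'entropy intervals</li>',
    '<li>consensus row: a/b/3 where &ge; 70% of structures share the ',
    'class</li>',
    '<li>rmsd row: glyphs _ ', RMSD_GLYPHS[2], " ", RMSD_GLYPHS[3], " ",
    RMSD_GLYPHS[4], " ", RMSD_GLYPHS[5],
    ' for C-alpha RMSD bins &lt;2, &lt;4, &lt;6, &lt;8, &ge;8 A</li>',
    "</ul></details>"
  )
}

document_css <- function(mode) {
  base <- paste0(
    "body{font-family:sans-serif;margin:1em}",
    ".aln{font-family:monospace;white-space:pre;line-height:1.35}",
    ".row{white-space:pre}",
    ".pphi{font-style:italic}",
    ".hba{font-weight:bold}",
    ".hbc{text-decoration:underline}",
    paste0(".d", seq_len(DEPTH_LEVELS), "{background-color:",
           DEPTH_GREYS, "}", collapse = ""),
    ".csa{background-color:#ff9999}",
    ".csb{background-color:#99bbff}",
    ".cs3{background-color:#ffcc66}",
    ".pr-strong-helix{border-top:2px solid #8b0000}",
    ".pr-weak-helix{border-top:2px solid #e88a8a}",
    ".pr-strong-strand{border-top:2px solid #00008b}",
    ".pr-weak-strand{border-top:2px solid #8a8ae8}",
    ".disord{background-color:#ccffcc}",
    ".key ul{margin:0.3em 0}",
    "table{border-collapse:collapse}",
    "td,th{border:1px solid #999;padding:2px 8px}"
  )
  if (mode == "print") {
    base <- paste0(base,
                   ".csa,.csb,.cs3,.disord{background-color:transparent;",
                   "outline:1px solid #999}")
  }
  base
}

#' Render an annotation document as stand-alone HTML
#'
#' One self-contained file: inline CSS, no scripts, no network
#' dependencies.  The alignment is wrapped in blocks of `wrap_width`
#' columns (from the document's provenance, default 60); each block
#' shows a 10-column ruler, one row per sequence, and the entropy /
#' consensus / RMSD annotation rows.  The PID table (when present) and
#' the format key follow the alignment.  `print` mode drops the
#' per-residue metadata attributes and ink-heavy backgrounds.
#'
#' @param doc an `annotation_document`.
#' @param mode `"interactive-lite"` or `"print"`.
#' @return HTML as one character string.
#' @export
render_document <- function(doc, mode = c("interactive-lite", "print")) {
  mode <- match.arg(mode)
  stopifnot(inherits(doc, "annotation_document"))
  aln <- doc$alignment
  wrap <- as.integer(doc$params$wrap_width %||% 60)
  ids <- alignment_ids(aln)
  label_width <- max(nchar(c(ids, "consensus"))) + 2L
  ctx0 <- list(mode = mode, depth_rng = depth_range(doc),
               partner_cols = partner_colours(doc))
  mat <- alignment_matrix(aln)

  blocks <- character(0)
  starts <- seq(1, aln$n_columns, by = wrap)
  for (from in starts) {
    to <- min(from + wrap - 1L, aln$n_columns)
    rows <- paste0('<div class="row">',
                   formatC("", width = label_width, flag = "-"),
                   html_escape(ruler_text(from, to)), "</div>")
    for (si in seq_along(aln$sequences)) {
      s <- aln$sequences[[si]]
      res_cols <- residue_columns(s)
      spans <- vapply(from:to, function(i) {
        ch <- mat[si, i]
        if (ch == "-") return('<span class="gap">-</span>')
        k <- match(i, res_cols)
        ann <- if (!is.null(s$annotations))
          s$annotations[k, , drop = FALSE] else NULL
        ctx <- ctx0
        if (!is.null(s$prediction)) ctx$pred <- s$prediction[k, , drop = FALSE]
        render_residue(ch, ann, s$role, ctx)
      }, character(1))
      rows <- c(rows, paste0(
        '<div class="row">',
        formatC(s$seq_id, width = label_width, flag = "-"),
        paste(spans, collapse = ""), "</div>"
      ))
    }
    rows <- c(rows, render_column_rows(doc$columns, from, to, label_width))
    blocks <- c(blocks, paste0('<div class="block">',
                               paste(rows, collapse = "\n"), "</div>"))
  }

  pid_html <- ""
  if (nrow(doc$pid)) {
    pid_rows <- sprintf("<tr><td>%s</td><td>%.1f</td></tr>",
                        html_escape(doc$pid$structure_id), doc$pid$pid)
    pid_html <- paste0(
      "<h2>Percentage sequence identity</h2>",
      "<table><tr><th>structure</th><th>PID (%)</th></tr>",
      paste(pid_rows, collapse = ""), "</table>"
    )
  }

  prov <- sprintf(
    "<p class=\"prov\">annotated-alignment format %s; parameters: %s</p>",
    doc$version,
    html_escape(paste(names(doc$params),
                      vapply(doc$params, function(v)
                        paste(fmt_num(as.numeric(v)), collapse = ","),
                        character(1)),
                      sep = "=", collapse = "; "))
  )

  paste0(
    "<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\">",
    "<title>annotated alignment</title>",
    "<style>", document_css(mode), "</style></head>\n<body>",
    "<h1>Annotated alignment</h1>\n",
    '<div class="aln">\n', paste(blocks, collapse = "\n<br>\n"), "\n</div>\n",
    pid_html, "\n", render_format_key(), "\n", prov,
    "</body></html>\n"
  )
}

#' Extract the alignment from a document as FASTA
#'
#' @param doc an `annotation_document`.
#' @return Character vector of FASTA lines (gapped sequences unchanged).
#' @export
extract_fasta <- function(doc) {
  unlist(lapply(doc$alignment$sequences, function(s) {
    c(paste0(">", s$seq_id), s$gapped)
  }))
}

#' Parse the feature list of a rendered residue glyph
#'
#' Inverse of the `data-feat` metadata written by [render_residue()];
#' used to verify that rendering preserves the exact feature flags.
#'
#' @param span one rendered `<span>` fragment.
#' @return Named character vector of features (possibly empty).
#' @export
parse_residue_features <- function(span) {
  m <- regmatches(span, regexec('data-feat="([^"]*)"', span))[[1]]
  if (length(m) < 2) return(stats::setNames(character(0), character(0)))
  kv <- strsplit(strsplit(m[2], ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  stats::setNames(vapply(kv, `[`, character(1), 2),
                  vapply(kv, `[`, character(1), 1))
}
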