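## PDB input (through bio3d) and output.  The parser extracts one selected
## polymer chain as the annotation substrate, keeps all other polymer
## chains for interface analysis and all non-water hetero groups as
## ligands.  Heavy atoms only; first alternate location kept; MSE treated
## as methionine; any other nonstandard polymer residue maps to `X`.

WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

#' Parse one polymer chain from a PDB file
#'
#' @param text a file path or PDB-format text.
#' @param chain_id one-character chain to select; `NULL` selects the
#'   first polymer chain in the file.
#' @param source_id identifier recorded on the result; defaults to the
#'   file base name (without extension) so it can be matched against
#'   alignment sequence ids.
#' @return A [chain_structure()] with `hetero` and `other_chains`
#'   populated.
#' @export
parse_pdb_chain <- function(text, chain_id = NULL, source_id = NULL) {
  path <- text
  if (length(text) > 1L || grepl("\n", text[1]) || !file.exists(text[1])) {
    path <- tempfile(fileext = ".pdb")
    writeLines(read_text_lines(text), path)
    on.exit(unlink(path), add = TRUE)
    if (is.null(source_id)) source_id <- "struct"
  }
  if (is.null(source_id)) {
    source_id <- tools::file_path_sans_ext(basename(path))
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = TRUE)
  at <- pdb$atom
  at$chain[is.na(at$chain)] <- " "
  at$insert[is.na(at$insert)] <- ""
  at$elesy[is.na(at$elesy)] <- ""
  ## polymer = ATOM records plus selenomethionine (deposited as HETATM)
  is_polymer <- at$type == "ATOM" | at$resid == "MSE"
  is_water <- at$resid %in% WATER_NAMES
  element <- ifelse(nzchar(at$elesy), at$elesy,
                    substr(gsub("[0-9']", "", at$elety), 1, 1))
  heavy <- !(toupper(element) %in% c("H", "D"))
  polymer_chains <- unique(at$chain[is_polymer])
  if (length(polymer_chains) == 0L) {
    stop("empty-chain error: no polymer residues in '", source_id, "'")
  }
  if (is.null(chain_id)) chain_id <- polymer_chains[1]
  if (!chain_id %in% polymer_chains) {
    stop("missing-chain error: chain '", chain_id, "' not found in '",
         source_id, "' (available: ",
         paste(polymer_chains, collapse = ", "), ")")
  }

  build_polymer <- function(rows) {
    key <- paste(rows$resno, rows$insert, sep = "|")
    res_idx <- match(key, unique(key))
    resname <- ifelse(rows$resid == "MSE", "MET", rows$resid)
    one <- AA3_TO_1[resname]
    one[is.na(one)] <- "X"
    data.frame(
      res_idx = res_idx,
      seq_id = paste0(rows$resno, rows$insert),
      resname = resname,
      one_letter = unname(one),
      atom = ifelse(rows$resid == "MSE" & rows$elety == "SE", "SD", rows$elety),
      element = element[as.integer(rownames(rows))],
      x = rows$x, y = rows$y, z = rows$z,
      stringsAsFactors = FALSE
    )
  }

  rownames(at) <- seq_len(nrow(at))
  sel_main <- is_polymer & heavy & at$chain == chain_id
  if (!any(sel_main)) {
    stop("empty-chain error: chain '", chain_id, "' of '", source_id,
         "' has no polymer residues")
  }
  main_atoms <- build_polymer(at[sel_main, , drop = FALSE])

  other <- lapply(setdiff(polymer_chains, chain_id), function(ch) {
    rows <- at[is_polymer & heavy & at$chain == ch, , drop = FALSE]
    if (nrow(rows) == 0L) return(NULL)
    list(chain_id = ch, atoms = build_polymer(rows))
  })
  other <- Filter(Negate(is.null), other)

  sel_het <- at$type == "HETATM" & !is_water & at$resid != "MSE" & heavy
  hetero <- list()
  if (any(sel_het)) {
    het <- at[sel_het, , drop = FALSE]
    key <- paste(het$resid, het$chain, het$resno, het$insert, sep = "|")
    for (k in unique(key)) {
      rows <- het[key == k, , drop = FALSE]
      hetero[[length(hetero) + 1L]] <- list(
        name = rows$resid[1],
        id = paste0(rows$resid[1], ":", rows$chain[1], rows$resno[1]),
        atoms = data.frame(
          atom = rows$elety,
          element = element[as.integer(rownames(rows))],
          x = rows$x, y = rows$y, z = rows$z,
          stringsAsFactors = FALSE
        )
      )
    }
  }

  chain_structure(source_id, chain_id, main_atoms,
                  hetero = hetero, other_chains = other)
}

#' Write a chain structure as a PDB file
#'
#' Emits fixed-width ATOM records for the chain (and HETATM records for
#' its hetero groups), optionally after applying a rigid transform —
#' used for the superposed-structure output bundle.
#'
#' @param struct a [chain_structure()].
#' @param path output file path.
#' @param rot,trans optional 3x3 rotation and length-3 translation
#'   applied as `x %*% t(rot) + trans` before writing.
#' @return Invisibly, the path.
#' @export
write_chain_pdb <- function(struct, path, rot = NULL, trans = NULL) {
  a <- struct$atoms
  if (!is.null(rot)) a <- transform_atoms(a, rot, trans %||% c(0, 0, 0))
  resno <- suppressWarnings(as.integer(gsub("[^0-9-]", "", a$seq_id)))
  resno[is.na(resno)] <- a$res_idx[is.na(resno)]
  icode <- gsub("[0-9-]", "", a$seq_id)
  icode[!nzchar(icode)] <- " "
  name_fmt <- ifelse(nchar(a$atom) >= 4, sprintf("%-4s", a$atom),
                     sprintf(" %-3s", a$atom))
  lines <- sprintf(
    "ATOM  %5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), name_fmt, a$resname, struct$chain_id,
    resno, substr(icode, 1, 1), a$x, a$y, a$z, 1, 0, a$element
  )
  serial <- nrow(a)
  for (h in struct$hetero) {
    ha <- h$atoms
    if (!is.null(rot)) ha <- transform_atoms(ha, rot, trans %||% c(0, 0, 0))
    hn <- ifelse(nchar(ha$atom) >= 4, sprintf("%-4s", ha$atom),
                 sprintf(" %-3s", ha$atom))
    lines <- c(lines, sprintf(
      "HETATM%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial + seq_len(nrow(ha)), hn, substr(h$name, 1, 3), struct$chain_id,
      9000L, ha$x, ha$y, ha$z, 1, 0, ha$element
    ))
    serial <- serial + nrow(ha)
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
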