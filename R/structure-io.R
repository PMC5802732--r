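#' Read a macromolecular structure from PDB or mmCIF
#'
#' Parses a coordinate file into a [MacroStructure-class]. Waters and other
#' heteroatoms are retained but flagged (`het = TRUE`) and excluded from all
#' geometric operations. Alternate locations are reduced to a single
#' conformer per atom: the highest-occupancy altloc is kept, ties broken by
#' altloc letter order.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return a [MacroStructure-class].
#' @examples
#' pdb <- buildPeptide("AGPA", phi = -57, psi = -47, omega = 180)
#' tf <- tempfile(fileext = ".pdb")
#' writeStructurePDB(pdb, tf)
#' readStructure(tf)
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  atoms <- switch(format,
    pdb = .readAtomsPDB(path),
    mmcif = .readAtomsCIF(path)
  )
  if (!nrow(atoms[!atoms$het, , drop = FALSE]))
    stop("empty structure: no polymer (ATOM) content in ", path)
  atoms <- .collapseAltlocs(atoms)
  atoms <- atoms[order(match(atoms$chain, unique(atoms$chain)),
                       atoms$resno, atoms$icode), , drop = FALSE]
  rownames(atoms) <- NULL
  new("MacroStructure",
      id = sub("\\.[^.]*$", "", basename(path)),
      atoms = atoms,
      meta = list(path = path, format = format))
}

.readAtomsPDB <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
                  error = function(e) stop("unreadable PDB file: ", path,
                                           " (", conditionMessage(e), ")"))
  a <- pdb$atom
  data.frame(
    chain = ifelse(is.na(a$chain), "", a$chain),
    resno = as.integer(a$resno),
    icode = ifelse(is.na(a$insert), "", a$insert),
    resname = a$resid,
    atom = a$elety,
    element = ifelse(is.na(a$elesy), "", a$elesy),
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o),
    b = ifelse(is.na(a$b), 0, a$b),
    altloc = ifelse(is.na(a$alt), "", a$alt),
    het = a$type == "HETATM",
    stringsAsFactors = FALSE
  )
}

# Minimal mmCIF _atom_site loop reader (coordinates only; no installed R
# package parses mmCIF). Quoted values with embedded blanks are supported.
.readAtomsCIF <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loop_at <- grep("^\\s*loop_\\s*$", lines)
  hdr_at <- grep("^\\s*_atom_site\\.", lines)
  if (!length(hdr_at)) stop("unreadable mmCIF file: no _atom_site loop in ", path)
  first <- min(hdr_at)
  fields <- character()
  i <- first
  while (i <= length(lines) && grepl("^\\s*_atom_site\\.", lines[i])) {
    fields <- c(fields, sub("^\\s*_atom_site\\.(\\S+).*$", "\\1", lines[i]))
    i <- i + 1
  }
  rows <- list()
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^\\s*(#|loop_|_)", ln) || !nzchar(trimws(ln))) break
    rows[[length(rows) + 1L]] <- scan(text = ln, what = character(),
                                      quiet = TRUE)
    i <- i + 1
  }
  if (!length(rows)) stop("unreadable mmCIF file: empty _atom_site loop in ", path)
  ok <- lengths(rows) == length(fields)
  tab <- do.call(rbind, rows[ok])
  colnames(tab) <- fields
  getf <- function(nm, alt = NULL, default = NA_character_) {
    for (f in c(nm, alt)) if (!is.null(f) && f %in% fields) return(tab[, f])
    rep(default, nrow(tab))
  }
  dot2 <- function(v, default) ifelse(v %in% c(".", "?") | is.na(v), default, v)
  data.frame(
    chain = dot2(getf("auth_asym_id", "label_asym_id"), ""),
    resno = as.integer(dot2(getf("auth_seq_id", "label_seq_id"), "0")),
    icode = dot2(getf("pdbx_PDB_ins_code"), ""),
    resname = dot2(getf("auth_comp_id", "label_comp_id"), ""),
    atom = dot2(getf("auth_atom_id", "label_atom_id"), ""),
    element = dot2(getf("type_symbol"), ""),
    x = as.numeric(getf("Cartn_x")),
    y = as.numeric(getf("Cartn_y")),
    z = as.numeric(getf("Cartn_z")),
    occ = as.numeric(dot2(getf("occupancy"), "1")),
    b = as.numeric(dot2(getf("B_iso_or_equiv"), "0")),
    altloc = dot2(getf("label_alt_id"), ""),
    het = getf("group_PDB", default = "ATOM") == "HETATM",
    stringsAsFactors = FALSE
  )
}

# One conformer per atom: highest occupancy wins, ties by altloc letter.
.collapseAltlocs <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$resname,
               atoms$atom, sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$occ, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms[!duplicated(key[ord]), , drop = FALSE]
}

#' Write a MacroStructure as PDB text
#'
#' Minimal fixed-width PDB writer (ATOM/HETATM/TER/END records), sufficient
#' to round-trip structures produced by [buildPeptide()].
#'
#' @param x a [MacroStructure-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeStructurePDB <- function(x, path) {
  stopifnot(is(x, "MacroStructure"))
  a <- x@atoms
  lines <- character(0)
  serial <- 0L
  for (ch in unique(a$chain)) {
    sub <- a[a$chain == ch, , drop = FALSE]
    for (j in seq_len(nrow(sub))) {
      serial <- serial + 1L
      nm <- sub$atom[j]
      # atom-name column convention: 1-3 char names start in column 14
      nm_fmt <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
      lines <- c(lines, sprintf(
        "%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        if (sub$het[j]) "HETATM" else "ATOM", serial %% 100000L, nm_fmt,
        substr(sub$altloc[j], 1, 1), sub$resname[j], ch, sub$resno[j] %% 10000L,
        substr(sub$icode[j], 1, 1), sub$x[j], sub$y[j], sub$z[j],
        sub$occ[j], sub$b[j], sub$element[j]))
    }
    lines <- c(lines, "TER")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
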