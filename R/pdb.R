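# PDB structure input/output and chemical perception.
#
# A structure is an S3 object of class "sg_structure":
#   atoms : data.frame with one row per ATOM/HETATM record kept
#           (serial, name, element, x, y, z, resname, resno, inscode,
#            chain, het, occupancy, b)
#   bonds : integer matrix (k x 2) of atom indices, perceived by a
#           covalent-radius distance criterion within residues plus
#           backbone peptide links
#
# Only altloc ' ' or 'A' records are kept (single-conformer model).

#' Parse a PDB-format string into a structure
#'
#' Reads fixed-width ATOM/HETATM records (record parsing is delegated to
#' \code{bio3d}), keeping only alternate location indicators blank or 'A'.
#' The element is taken from columns 77-78 when present, otherwise inferred
#' from the atom name and residue. Covalent bonds between heavy atoms are
#' perceived within each residue (distance no more than 1.3 times the sum of
#' covalent radii) plus backbone peptide C-N links between residues.
#' Hydrogens present in the input are kept in the atom table but ignored by
#' all perception steps.
#'
#' @param text A single string (or character vector of lines) in PDB format.
#' @return An object of class \code{sg_structure}.
#' @seealso [read_pdb()], [write_pdb()], [extract_pocket()]
#' @export
parse_pdb <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM") |
    trimws(rec) %in% c("ATOM", "HETATM")
  idx <- which(is_atom)
  if (length(idx) == 0L) stop("empty structure: no ATOM or HETATM records")
  # validate fixed-width records before handing them to the parser
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54) stop(sprintf("malformed PDB record at line %d: too short", i))
    xyz <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))))
    if (anyNA(xyz) || any(!is.finite(xyz)))
      stop(sprintf("malformed PDB record at line %d: bad coordinate field", i))
  }
  alt <- substr(lines[idx], 17, 17)
  keep <- idx[alt %in% c(" ", "A", "")]
  if (length(keep) == 0L) stop("empty structure: no records with altloc blank or 'A'")

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(c(lines[keep], "END"), tmp)
  pdb <- bio3d::read.pdb(tmp, verbose = FALSE)
  a <- pdb$atom

  het <- a$type == "HETATM"
  elem <- toupper(trimws(a$elesy))
  miss <- is.na(elem) | elem == ""
  if (any(miss)) {
    elem[miss] <- vapply(which(miss), function(i) {
      infer_element(a$elety[i], a$resid[i], het[i])
    }, character(1))
  }
  occ <- a$o
  occ[is.na(occ)] <- 1
  b <- a$b
  b[is.na(b)] <- 0
  atoms <- data.frame(
    serial = a$eleno,
    name = trimws(a$elety),
    element = elem,
    x = a$x, y = a$y, z = a$z,
    resname = trimws(a$resid),
    resno = a$resno,
    inscode = ifelse(is.na(a$insert) | a$insert == "", "", a$insert),
    chain = ifelse(is.na(a$chain) | a$chain == "", " ", a$chain),
    het = het,
    occupancy = occ,
    b = b,
    stringsAsFactors = FALSE
  )
  s <- structure(list(atoms = atoms, bonds = NULL), class = "sg_structure")
  s$bonds <- perceive_bonds(s)
  s
}

#' Read a PDB file
#'
#' @param path Path to a PDB file.
#' @return An \code{sg_structure}; see [parse_pdb()].
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  parse_pdb(readLines(path, warn = FALSE))
}

# Covalent bond perception: heavy-atom pairs in the same residue with
# d <= 1.3 * (rcov_i + rcov_j), plus peptide C-N links between residues.
perceive_bonds <- function(s) {
  a <- s$atoms
  heavy <- which(a$element != "H")
  key <- paste(a$chain, a$resno, a$inscode, sep = "|")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rcov <- covalent_radius(a$element)
  out <- list()
  for (g in split(heavy, key[heavy])) {
    if (length(g) < 2) next
    d <- cross_dist(xyz[g, , drop = FALSE], xyz[g, , drop = FALSE])
    lim <- 1.3 * outer(rcov[g], rcov[g], "+")
    hit <- which(d <= lim & upper.tri(d), arr.ind = TRUE)
    if (nrow(hit)) out[[length(out) + 1L]] <- cbind(g[hit[, 1]], g[hit[, 2]])
  }
  # peptide links: backbone C of one residue to backbone N of another
  ci <- heavy[a$name[heavy] == "C" & !a$het[heavy]]
  ni <- heavy[a$name[heavy] == "N" & !a$het[heavy]]
  if (length(ci) && length(ni)) {
    d <- cross_dist(xyz[ci, , drop = FALSE], xyz[ni, , drop = FALSE])
    lim <- 1.3 * (covalent_radius("C") + covalent_radius("N"))
    hit <- which(d <= lim, arr.ind = TRUE)
    if (nrow(hit)) {
      p <- cbind(ci[hit[, 1]], ni[hit[, 2]])
      p <- p[key[p[, 1]] != key[p[, 2]], , drop = FALSE]
      if (nrow(p)) out[[length(out) + 1L]] <- p
    }
  }
  if (!length(out)) return(matrix(integer(0), 0, 2))
  b <- do.call(rbind, out)
  b <- t(apply(b, 1, sort))
  unique(b)
}

# ---- accessors ------------------------------------------------------------

#' @export
print.sg_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf(
    "sg_structure: %d atoms, %d bonds, %d metal(s), %d water(s), %d het residue(s)\n",
    nrow(a), nrow(x$bonds), length(metal_atoms(x)), length(water_atoms(x)),
    nrow(ligand_residues(x))))
  invisible(x)
}

#' Atom coordinates as a matrix
#' @param s An \code{sg_structure}.
#' @return Numeric matrix (n x 3) of coordinates in Angstrom.
#' @export
coords <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

#' Indices of metal atoms
#' @param s An \code{sg_structure}.
#' @return Integer vector of atom indices flagged metallic.
#' @export
metal_atoms <- function(s) which(is_metal_element(s$atoms$element) & s$atoms$het)

#' Indices of crystallographic water oxygens
#' @param s An \code{sg_structure}.
#' @return Integer vector of indices of O atoms in HOH/WAT residues.
#' @export
water_atoms <- function(s) {
  which(s$atoms$resname %in% c("HOH", "WAT") & s$atoms$element == "O")
}

#' Het residues usable as ligands
#'
#' Groups HETATM records by residue, excluding waters and lone metal ions.
#'
#' @param s An \code{sg_structure}.
#' @return data.frame with columns resname, chain, resno, inscode, n_atoms.
#' @export
ligand_residues <- function(s) {
  a <- s$atoms
  het <- which(a$het & !(a$resname %in% c("HOH", "WAT")))
  if (!length(het)) {
    return(data.frame(resname = character(0), chain = character(0),
                      resno = integer(0), inscode = character(0),
                      n_atoms = integer(0), stringsAsFactors = FALSE))
  }
  key <- paste(a$resname[het], a$chain[het], a$resno[het], a$inscode[het], sep = "|")
  out <- do.call(rbind, lapply(split(het, key), function(g) {
    data.frame(resname = a$resname[g[1]], chain = a$chain[g[1]],
               resno = a$resno[g[1]], inscode = a$inscode[g[1]],
               n_atoms = length(g), all_metal = all(is_metal_element(a$element[g])),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out <- out[!out$all_metal, , drop = FALSE]
  out$all_metal <- NULL
  out
}

# atom indices of one het residue identified by resname[:chain[:resno]]
ligand_atom_indices <- function(s, ligand) {
  a <- s$atoms
  parts <- strsplit(ligand, ":", fixed = TRUE)[[1]]
  sel <- a$het & a$resname == parts[1]
  if (length(parts) >= 2 && nzchar(parts[2])) sel <- sel & a$chain == parts[2]
  if (length(parts) >= 3) sel <- sel & a$resno == as.integer(parts[3])
  idx <- which(sel)
  if (!length(idx)) {
    lig <- ligand_residues(s)
    stop("ligand '", ligand, "' not found; available het residues: ",
         if (nrow(lig)) paste(sprintf("%s:%s:%d", lig$resname, lig$chain, lig$resno),
                              collapse = ", ") else "(none)")
  }
  idx
}

# ---- writing --------------------------------------------------------------

format_pdb_record <- function(rec, serial, name, resname, chain, resno,
                              inscode, x, y, z, occ, b, element) {
  name4 <- if (nchar(name) >= 4 || nchar(element) == 2) {
    sprintf("%-4s", substr(name, 1, 4))
  } else {
    sprintf(" %-3s", name)
  }
  sprintf("%-6s%5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial %% 100000L, name4, resname, substr(chain, 1, 1),
          resno %% 10000L, ifelse(nzchar(inscode), inscode, " "),
          x, y, z, occ, b, sprintf("%2s", element))
}

#' Write a structure in PDB format
#'
#' @param s An \code{sg_structure}.
#' @param path Optional file path; when \code{NULL} the PDB text is returned.
#' @return The PDB-format string, invisibly when written to a file.
#' @export
write_pdb <- function(s, path = NULL) {
  a <- s$atoms
  lines <- vapply(seq_len(nrow(a)), function(i) {
    format_pdb_record(if (a$het[i]) "HETATM" else "ATOM", a$serial[i], a$name[i],
                      a$resname[i], a$chain[i], a$resno[i], a$inscode[i],
                      a$x[i], a$y[i], a$z[i], a$occupancy[i], a$b[i], a$element[i])
  }, character(1))
  txt <- paste(c(lines, "END", ""), collapse = "\n")
  if (is.null(path)) return(txt)
  cat(txt, file = path)
  invisible(txt)
}

#' Write a structure with predicted waters appended
#'
#' Appends one HETATM HOH oxygen record per placed water. The B-factor column
#' carries \code{100 * (1 - average_quality)} so that well-supported waters
#' (quality 1) read 0.00; occupancy is 1.00. Original records are unchanged.
#'
#' @param s An \code{sg_structure}.
#' @param waters A list of placed waters from [place_waters()].
#' @param path Optional output file path.
#' @return The PDB-format string, invisibly when written to a file.
#' @export
write_pdb_with_waters <- function(s, waters, path = NULL) {
  a <- s$atoms
  base <- vapply(seq_len(nrow(a)), function(i) {
    format_pdb_record(if (a$het[i]) "HETATM" else "ATOM", a$serial[i], a$name[i],
                      a$resname[i], a$chain[i], a$resno[i], a$inscode[i],
                      a$x[i], a$y[i], a$z[i], a$occupancy[i], a$b[i], a$element[i])
  }, character(1))
  serial0 <- if (nrow(a)) max(a$serial) else 0L
  resno0 <- if (nrow(a)) max(a$resno) else 0L
  wlines <- character(0)
  if (length(waters)) {
    wlines <- vapply(seq_along(waters), function(i) {
      w <- waters[[i]]
      format_pdb_record("HETATM", serial0 + i, "O", "HOH", "W", resno0 + i, "",
                        w$position[1], w$position[2], w$position[3],
                        1.00, 100 * (1 - w$average_quality), "O")
    }, character(1))
  }
  txt <- paste(c(base, wlines, "END", ""), collapse = "\n")
  if (is.null(path)) return(txt)
  cat(txt, file = path)
  invisible(txt)
}

#' Serialize a structure to JSON
#'
#' @param s An \code{sg_structure}.
#' @return A JSON string with an \code{atoms} array carrying the atom fields.
#' @export
structure_to_json <- function(s) {
  jsonlite::toJSON(list(atoms = s$atoms, n_bonds = nrow(s$bonds)),
                   dataframe = "rows", auto_unbox = TRUE, digits = NA)
}
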