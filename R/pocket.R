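# Ligand-defined binding pocket extraction.

#' Extract the binding pocket around a ligand
#'
#' Selects every amino-acid residue whose minimum heavy-atom distance to any
#' atom of the ligand is at most \code{radius} (default 6.5 Angstrom, boundary
#' inclusive). Waters and other het groups are never pocket members.
#'
#' @param s An \code{sg_structure}.
#' @param ligand Het residue identifier, \code{"RESNAME"} or
#'   \code{"RESNAME:CHAIN"} or \code{"RESNAME:CHAIN:RESNO"}.
#' @param radius Inclusion cutoff in Angstrom.
#' @return An object of class \code{sg_pocket}: list with \code{residues}
#'   (data.frame chain/resno/inscode/resname), \code{ligand},
#'   \code{ligand_atoms} (indices) and \code{radius}.
#' @export
extract_pocket <- function(s, ligand, radius = 6.5) {
  lig_idx <- ligand_atom_indices(s, ligand)
  a <- s$atoms
  lig_xyz <- coords(s)[lig_idx, , drop = FALSE]
  prot <- which(!a$het & a$element != "H")
  residues <- data.frame(chain = character(0), resno = integer(0),
                         inscode = character(0), resname = character(0),
                         stringsAsFactors = FALSE)
  if (length(prot)) {
    d <- cross_dist(coords(s)[prot, , drop = FALSE], lig_xyz)
    mind <- apply(d, 1, min)
    key <- paste(a$chain[prot], a$resno[prot], a$inscode[prot], sep = "|")
    inc <- tapply(mind, key, min) <= radius
    keys <- names(inc)[inc]
    if (length(keys)) {
      first <- prot[match(keys, key)]
      residues <- data.frame(chain = a$chain[first], resno = a$resno[first],
                             inscode = a$inscode[first], resname = a$resname[first],
                             stringsAsFactors = FALSE)
      residues <- residues[order(residues$chain, residues$resno, residues$inscode), ]
      rownames(residues) <- NULL
    }
  }
  structure(list(residues = residues, ligand = ligand,
                 ligand_atoms = lig_idx, radius = radius),
            class = "sg_pocket")
}

#' @export
print.sg_pocket <- function(x, ...) {
  cat(sprintf("sg_pocket: %d residue(s) within %.2f A of ligand %s\n",
              nrow(x$residues), x$radius, x$ligand))
  invisible(x)
}

# logical index over s$atoms: atom belongs to a pocket residue
pocket_member_atoms <- function(s, pocket) {
  a <- s$atoms
  key <- paste(a$chain, a$resno, a$inscode, sep = "|")
  rkey <- paste(pocket$residues$chain, pocket$residues$resno,
                pocket$residues$inscode, sep = "|")
  (key %in% rkey) & !a$het
}
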