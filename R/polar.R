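# Hydrogen-bond donor/acceptor perception from heavy-atom templates.
#
# Roles are assigned from a residue/atom-name table for the standard amino
# acids and water; O/N atoms of unknown residues fall back to connectivity
# rules. Carbon, sulfur and metal atoms never receive a role (only N and O
# carry hydrogen-bond functions here).

# side-chain template: residue -> atom -> c(role, capacity, hybridization)
.sidechain_roles <- list(
  SER = list(OG  = c("both", 3, "sp3")),
  THR = list(OG1 = c("both", 3, "sp3")),
  TYR = list(OH  = c("both", 2, "sp2")),
  ASP = list(OD1 = c("acceptor", 2, "sp2"), OD2 = c("acceptor", 2, "sp2")),
  GLU = list(OE1 = c("acceptor", 2, "sp2"), OE2 = c("acceptor", 2, "sp2")),
  ASN = list(OD1 = c("acceptor", 2, "sp2"), ND2 = c("donor", 2, "sp2")),
  GLN = list(OE1 = c("acceptor", 2, "sp2"), NE2 = c("donor", 2, "sp2")),
  HIS = list(ND1 = c("both", 1, "sp2"), NE2 = c("both", 1, "sp2")),
  LYS = list(NZ  = c("donor", 3, "sp3")),
  ARG = list(NE  = c("donor", 1, "sp2"), NH1 = c("donor", 2, "sp2"),
             NH2 = c("donor", 2, "sp2")),
  TRP = list(NE1 = c("donor", 1, "sp2"))
)

.standard_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

# adjacency: heavy-atom neighbor indices for each atom
neighbor_list <- function(s) {
  n <- nrow(s$atoms)
  adj <- vector("list", n)
  b <- s$bonds
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      i <- b[k, 1]; j <- b[k, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

#' Perceive hydrogen-bond donor/acceptor roles
#'
#' Assigns each polar heavy atom a role (donor, acceptor or both), a capacity
#' (maximum number of simultaneous hydrogen-bond partners) and a
#' hybridization (sp2/sp3), using residue templates for standard amino acids
#' and water (role both, capacity 4) and connectivity-based rules for O/N
#' atoms of other residues. Carbons and metals are never polar.
#'
#' @param s An \code{sg_structure} (bonds perceived at parse time).
#' @return data.frame with columns \code{atom} (index into \code{s$atoms}),
#'   \code{role}, \code{capacity}, \code{hybridization}.
#' @export
perceive_polar_roles <- function(s) {
  a <- s$atoms
  adj <- neighbor_list(s)
  carbox <- find_carboxylates(s)
  carbox_o <- unlist(lapply(carbox, function(t) t[2:3]))
  rows <- list()
  warned <- character(0)
  add <- function(i, role, cap, hyb) {
    rows[[length(rows) + 1L]] <<- data.frame(
      atom = i, role = role, capacity = as.integer(cap), hybridization = hyb,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(a))) {
    el <- a$element[i]
    if (!(el %in% c("N", "O"))) next
    rn <- a$resname[i]
    nm <- a$name[i]
    if (rn %in% c("HOH", "WAT")) {
      add(i, "both", 4, "sp3")
      next
    }
    if (!a$het[i] && rn %in% .standard_aa) {
      if (nm == "N") {
        if (rn != "PRO") add(i, "donor", 1, "sp2")
        next
      }
      if (nm == "O") { add(i, "acceptor", 2, "sp2"); next }
      if (nm == "OXT") { add(i, "acceptor", 2, "sp2"); next }
      tmpl <- .sidechain_roles[[rn]][[nm]]
      if (!is.null(tmpl)) add(i, tmpl[1], as.integer(tmpl[2]), tmpl[3])
      next
    }
    # connectivity fallback (het groups, non-standard residues)
    if (!(rn %in% .standard_aa) && !(rn %in% warned) && !a$het[i]) {
      warning("unknown residue '", rn, "': assigning polar roles by connectivity")
      warned <- c(warned, rn)
    }
    nb <- adj[[i]]
    nb <- nb[a$element[nb] != "H"]
    nn <- length(nb)
    if (el == "O") {
      if (i %in% carbox_o) { add(i, "acceptor", 2, "sp2"); next }
      if (nn == 0) { add(i, "both", 4, "sp3"); next }
      if (nn == 1) {
        d <- vnorm(as.numeric(a[i, c("x", "y", "z")]) -
                     as.numeric(a[nb, c("x", "y", "z")]))
        if (d < 1.28) add(i, "acceptor", 2, "sp2") else add(i, "both", 2, "sp3")
        next
      }
      add(i, "acceptor", 1, "sp3")
    } else { # N
      if (nn == 0) { add(i, "both", 3, "sp3"); next }
      if (nn == 1) { add(i, "donor", 2, "sp2"); next }
      if (nn == 2) { add(i, "donor", 1, "sp2"); next }
      # 3 heavy neighbors: saturated, no role
    }
  }
  if (!length(rows)) {
    return(data.frame(atom = integer(0), role = character(0),
                      capacity = integer(0), hybridization = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Find carboxylate groups
#'
#' A carboxylate is a carbon bonded to exactly two terminal oxygens, each of
#' which is bonded only to that carbon. Covers Asp/Glu side chains, C-terminal
#' carboxylates and ligand carboxylates (treated downstream as potential
#' bidentate metal ligands).
#'
#' @param s An \code{sg_structure}.
#' @return A list of integer triples \code{c(C, O1, O2)} of atom indices.
#' @export
find_carboxylates <- function(s) {
  a <- s$atoms
  adj <- neighbor_list(s)
  out <- list()
  for (i in which(a$element == "C")) {
    nb <- adj[[i]]
    ox <- nb[a$element[nb] == "O"]
    # terminal oxygens: bonded only to this carbon
    ox <- ox[vapply(ox, function(o) {
      heavy <- adj[[o]][a$element[adj[[o]]] != "H"]
      length(heavy) == 1 && heavy == i
    }, logical(1))]
    if (length(ox) == 2) out[[length(out) + 1L]] <- c(i, ox[1], ox[2])
  }
  out
}
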