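# Synthetic-structure generator with known ground truth.
#
# Fixtures are plain PDB text built in code: ideal or jittered metal
# coordination sites for the geometry engine, and toy polar pockets
# (carbonyl/amide/hydroxyl/carboxylate fragments, inert carbon walls,
# planted crystallographic waters, a one-atom dummy ligand) for the water
# engine. Every fixture is deterministic in its seed and round-trips through
# parse_pdb at PDB 3-decimal precision. Ground-truth labels travel as the
# "ground_truth" attribute and as a sidecar JSON via write_fixture().

#' Generate a synthetic metal coordination site
#'
#' Places the metal at the origin and one oxygen partner per vertex of the
#' chosen reference geometry at \code{bond_length} Angstrom, plus isotropic
#' Gaussian jitter of standard deviation \code{jitter_sigma} per coordinate.
#' Partners are embedded in single-atom UNX het residues so any PDB reader
#' accepts the fixture. The last \code{delete_vertices} vertices are omitted
#' to create sites with free coordination sites.
#'
#' @param geometry Name of a geometry in \code{library}.
#' @param metal Metal element symbol (default "ZN").
#' @param bond_length Metal-partner distance in Angstrom (default 2.1).
#' @param jitter_sigma Gaussian jitter per coordinate in Angstrom.
#' @param seed RNG seed (the global RNG state is left untouched).
#' @param delete_vertices Number of trailing vertices to omit.
#' @param library Geometry library.
#' @return An \code{sg_structure} with a \code{ground_truth} attribute.
#' @export
make_metal_site <- function(geometry, metal = "ZN", bond_length = 2.1,
                            jitter_sigma = 0, seed = 1, delete_vertices = 0,
                            library = builtin_geometries()) {
  stopifnot(jitter_sigma >= 0)
  g <- library[[geometry]]
  if (is.null(g)) stop("unknown geometry '", geometry, "'; available: ",
                       paste(names(library), collapse = ", "))
  if (delete_vertices >= g$coordination_number)
    stop("delete_vertices must be smaller than the coordination number")
  v <- g$vertices
  if (delete_vertices > 0) v <- v[seq_len(nrow(v) - delete_vertices), , drop = FALSE]
  pos <- v * bond_length
  if (jitter_sigma > 0) {
    pos <- pos + with_seed(seed, matrix(stats::rnorm(length(pos), 0, jitter_sigma),
                                        nrow(pos), 3))
  }
  metal <- toupper(metal)
  n <- nrow(pos)
  # full-precision in-memory structure; write_pdb() rounds to the PDB
  # format's 3 decimals on serialization
  atoms <- data.frame(
    serial = seq_len(n + 1L),
    name = c(metal, rep("O", n)),
    element = c(metal, rep("O", n)),
    x = c(0, pos[, 1]), y = c(0, pos[, 2]), z = c(0, pos[, 3]),
    resname = c(metal, rep("UNX", n)),
    resno = seq_len(n + 1L),
    inscode = "", chain = "A", het = TRUE, occupancy = 1, b = 0,
    stringsAsFactors = FALSE)
  s <- structure(list(atoms = atoms, bonds = NULL), class = "sg_structure")
  s$bonds <- perceive_bonds(s)
  attr(s, "ground_truth") <- list(
    kind = "metal_site", geometry = geometry, metal = metal,
    bond_length = bond_length, jitter_sigma = jitter_sigma, seed = seed,
    n_partners = nrow(pos), deleted = delete_vertices)
  s
}

# ---- polar-pocket fragments ----------------------------------------------

# each builder returns list(atoms = data.frame(record rows), truth = list)
.fragment_builders <- list(
  carbonyl = function(position, direction) {
    d <- unitv(direction) # C -> O axis
    p <- perp_vector(d)
    O <- position
    C <- O - 1.23 * d
    CA <- C + 1.52 * (cos(2 * pi / 3) * d + sin(2 * pi / 3) * p)
    list(atoms = data.frame(
      rec = "ATOM", name = c("CA", "C", "O"), element = c("C", "C", "O"),
      resname = "GLY", x = c(CA[1], C[1], O[1]), y = c(CA[2], C[2], O[2]),
      z = c(CA[3], C[3], O[3]), stringsAsFactors = FALSE),
      n_directions = 2L)
  },
  amide = function(position, direction) {
    d <- unitv(direction) # N -> H axis
    p <- perp_vector(d)
    N <- position
    n1 <- cos(2 * pi / 3) * d + sin(2 * pi / 3) * p
    n2 <- cos(2 * pi / 3) * d - sin(2 * pi / 3) * p
    CA <- N + 1.46 * n1
    C <- N + 1.33 * n2
    list(atoms = data.frame(
      rec = "ATOM", name = c("N", "CA", "C"), element = c("N", "C", "C"),
      resname = "GLY", x = c(N[1], CA[1], C[1]), y = c(N[2], CA[2], C[2]),
      z = c(N[3], CA[3], C[3]), stringsAsFactors = FALSE),
      n_directions = 1L)
  },
  hydroxyl = function(position, direction) {
    d <- unitv(direction) # OG -> CB axis
    OG <- position
    CB <- OG + 1.43 * d
    list(atoms = data.frame(
      rec = "ATOM", name = c("OG", "CB"), element = c("O", "C"),
      resname = "SER", x = c(OG[1], CB[1]), y = c(OG[2], CB[2]),
      z = c(OG[3], CB[3]), stringsAsFactors = FALSE),
      n_directions = 3L)
  },
  carboxylate = function(position, direction) {
    d <- unitv(direction) # CG -> outward bisector
    p <- perp_vector(d)
    ang <- 63 * pi / 180 # half the O-C-O angle
    CG <- position
    OD1 <- CG + 1.25 * (cos(ang) * d + sin(ang) * p)
    OD2 <- CG + 1.25 * (cos(ang) * d - sin(ang) * p)
    CB <- CG - 1.52 * d
    list(atoms = data.frame(
      rec = "ATOM", name = c("CB", "CG", "OD1", "OD2"),
      element = c("C", "C", "O", "O"), resname = "ASP",
      x = c(CB[1], CG[1], OD1[1], OD2[1]), y = c(CB[2], CG[2], OD1[2], OD2[2]),
      z = c(CB[3], CG[3], OD1[3], OD2[3]), stringsAsFactors = FALSE),
      n_directions = 4L)
  },
  wall = function(position, direction = NULL) {
    list(atoms = data.frame(
      rec = "ATOM", name = "CA", element = "C", resname = "GLY",
      x = position[1], y = position[2], z = position[3],
      stringsAsFactors = FALSE),
      n_directions = 0L)
  },
  hoh = function(position, direction = NULL) {
    list(atoms = data.frame(
      rec = "HETATM", name = "O", element = "O", resname = "HOH",
      x = position[1], y = position[2], z = position[3],
      stringsAsFactors = FALSE),
      n_directions = 0L)
  },
  ligand = function(position, direction = NULL) {
    list(atoms = data.frame(
      rec = "HETATM", name = "C1", element = "C", resname = "LIG",
      x = position[1], y = position[2], z = position[3],
      stringsAsFactors = FALSE),
      n_directions = 0L)
  }
)

#' Assemble a toy polar pocket
#'
#' Builds a structure from rigid fragments placed at specified positions and
#' orientations: \code{carbonyl} (backbone C=O acceptor with CA/C
#' neighbors), \code{amide} (backbone N-H donor triplet), \code{hydroxyl}
#' (Ser-like O-C), \code{carboxylate} (Asp-like CB-CG(OD1)(OD2)),
#' \code{wall} (inert CA carbon), \code{hoh} (planted crystallographic
#' water) and \code{ligand} (one-atom dummy het group for pocket
#' definition). Each recipe entry is \code{list(kind, position, direction)};
#' the direction points along the fragment's interaction axis (C->O for
#' carbonyl, N->H for amide, O->C for hydroxyl, the O-C-O bisector for
#' carboxylate) and is ignored for point fragments.
#'
#' @param recipe List of fragment specifications.
#' @param seed Kept for interface symmetry with [make_metal_site()];
#'   pocket fixtures are fully determined by the recipe.
#' @return An \code{sg_structure} with a \code{ground_truth} attribute
#'   (per-fragment expected free-direction counts).
#' @export
make_polar_pocket <- function(recipe, seed = 1) {
  frames <- list()
  truth <- list()
  for (k in seq_along(recipe)) {
    fr <- recipe[[k]]
    builder <- .fragment_builders[[fr$kind]]
    if (is.null(builder)) stop("unknown fragment kind '", fr$kind, "'")
    built <- builder(fr$position, fr$direction)
    built$atoms$fragment <- k
    frames[[k]] <- built$atoms
    truth[[k]] <- list(kind = fr$kind, n_directions = built$n_directions)
  }
  atoms <- do.call(rbind, frames)
  # inter-fragment overlap check
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(atoms) > 1) {
    d <- cross_dist(xyz, xyz)
    same <- outer(atoms$fragment, atoms$fragment, "==")
    bad <- which(d < 1.5 & !same & upper.tri(d), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("overlapping fragments: atoms %d and %d are %.2f A apart",
                   bad[1, 1], bad[1, 2], d[bad[1, 1], bad[1, 2]]))
  }
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    format_pdb_record(atoms$rec[i], i, atoms$name[i], atoms$resname[i], "A",
                      atoms$fragment[i], "", atoms$x[i], atoms$y[i],
                      atoms$z[i], 1, 0, atoms$element[i])
  }, character(1))
  s <- parse_pdb(c(lines, "END"))
  attr(s, "ground_truth") <- list(kind = "polar_pocket", fragments = truth,
                                  seed = seed)
  s
}

#' Write a fixture with its ground-truth sidecar
#'
#' @param s A fixture \code{sg_structure}.
#' @param path Output PDB path; the ground truth is written next to it as
#'   \code{<path>.json}.
#' @return Invisibly, the PDB path.
#' @export
write_fixture <- function(s, path) {
  write_pdb(s, path)
  gt <- attr(s, "ground_truth")
  if (!is.null(gt)) {
    jsonlite::write_json(gt, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
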