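# Element tables used for bond perception, coordination spheres and clash terms.

# Covalent radii (Angstrom), Cordero-style consensus values.
.covalent_radii <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
  F = 0.57, CL = 1.02, BR = 1.20, I = 1.39, SE = 1.20, B = 0.84,
  LI = 1.28, `NA` = 1.66, K = 2.03, RB = 2.20, CS = 2.44,
  BE = 0.96, MG = 1.41, CA = 1.76, SR = 1.95, BA = 2.15,
  MN = 1.39, FE = 1.32, CO = 1.26, NI = 1.24, CU = 1.32, ZN = 1.22,
  CD = 1.44, HG = 1.32, AL = 1.21, GA = 1.22, MO = 1.54, W = 1.62,
  V = 1.53, CR = 1.39, TI = 1.60
)

# van der Waals radii (Angstrom), Bondi-style; used by the overlap penalty.
.vdw_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90
)
.vdw_default <- 1.70

.metal_elements <- c(
  "LI", "NA", "K", "RB", "CS", "BE", "MG", "CA", "SR", "BA",
  "MN", "FE", "CO", "NI", "CU", "ZN", "CD", "HG", "AL", "GA",
  "MO", "W", "V", "CR", "TI"
)

# Coordination-sphere radii per metal element (Angstrom). Transition metals
# 2.8, alkaline earths 3.0, alkali metals 3.4; spans typical M-O/N bond
# lengths plus tolerance. Overridable via the radii argument / config.
.default_coordination_radii <- c(
  ZN = 2.8, FE = 2.8, CU = 2.8, NI = 2.8, CO = 2.8, MN = 2.8,
  CD = 2.8, HG = 2.8, CR = 2.8, V = 2.8, TI = 2.8, MO = 2.8, W = 2.8,
  MG = 3.0, CA = 3.0, SR = 3.0, BA = 3.0, BE = 3.0,
  `NA` = 3.4, K = 3.4, LI = 3.4, RB = 3.4, CS = 3.4
)
.coordination_radius_default <- 3.0

covalent_radius <- function(element) {
  r <- .covalent_radii[toupper(element)]
  r[is.na(r)] <- 0.76
  unname(r)
}

vdw_radius <- function(element) {
  r <- .vdw_radii[toupper(element)]
  r[is.na(r)] <- .vdw_default
  unname(r)
}

is_metal_element <- function(element) toupper(element) %in% .metal_elements

#' Coordination-sphere radius for a metal element
#'
#' Returns the distance cutoff (in Angstrom) within which O/N/S/Cl atoms are
#' considered part of a metal's coordination sphere. Defaults are 2.8 for
#' transition metals, 3.0 for alkaline-earth and 3.4 for alkali metals; a
#' named numeric vector of overrides may be supplied (e.g. read from a JSON
#' config file).
#'
#' @param element Metal element symbol (case-insensitive).
#' @param radii Optional named numeric vector of per-element overrides.
#' @return A single numeric radius in Angstrom.
#' @export
coordination_radius <- function(element, radii = NULL) {
  el <- toupper(element)
  if (!is.null(radii) && el %in% toupper(names(radii))) {
    return(unname(radii[[match(el, toupper(names(radii)))]]))
  }
  r <- .default_coordination_radii[el]
  if (is.na(r)) .coordination_radius_default else unname(r)
}

# Element inference from a PDB atom name when columns 77-78 are absent.
# Two-letter het elements are recognized when the atom name matches a known
# element and the record is HETATM (e.g. ZN, CL, NA); otherwise the first
# alphabetic character wins (CA in a protein residue is carbon).
infer_element <- function(name, resname, het) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  rn <- toupper(trimws(resname))
  known2 <- c(.metal_elements, "CL", "BR", "SE")
  if (het && nm %in% known2 && (rn == nm || rn %in% known2)) return(nm)
  if (het && nchar(nm) == 2 && nm %in% known2 && nm == rn) return(nm)
  substr(nm, 1, 1)
}
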