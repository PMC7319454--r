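# Run configuration: every tunable threshold in one place.

#' Default run configuration
#'
#' All tunable parameters of the engines with their default values:
#' \describe{
#'   \item{pocket_radius}{6.5 A ligand-to-residue inclusion cutoff.}
#'   \item{ligand_distance}{8.0 A bound for auto-detecting small molecules
#'     as ligands.}
#'   \item{coordination_radii}{named overrides of per-metal sphere radii.}
#'   \item{score_coefficients}{c(rmsd, free_sites, overlap) = c(50, 4, 50).}
#'   \item{probe_radius}{1.4 A overlap probe.}
#'   \item{water}{clash 2.2 A, merge 0.5 A, neighborhood 1.0 A, converge
#'     0.01 A, max_iter 100, quality_cutoff 0.6 (second round), saturation
#'     0.85, donor_distance 2.6 A, acceptor_distance 2.8 A.}
#' }
#'
#' @return A nested list of parameters.
#' @export
default_config <- function() {
  list(
    pocket_radius = 6.5,
    ligand_distance = 8.0,
    coordination_radii = NULL,
    score_coefficients = c(50, 4, 50),
    probe_radius = 1.4,
    water = list(
      clash = 2.2, merge = 0.5, neighborhood = 1.0,
      converge = 0.01, max_iter = 100,
      quality_cutoff = 0.6, saturation = 0.85,
      donor_distance = 2.6, acceptor_distance = 2.8
    )
  )
}

# overlay a partial config (possibly nested) on the defaults
merge_config <- function(config = NULL) {
  base <- default_config()
  if (is.null(config)) return(base)
  for (k in names(config)) {
    if (k == "water" && is.list(config$water)) {
      for (w in names(config$water)) base$water[[w]] <- config$water[[w]]
    } else {
      base[[k]] <- config[[k]]
    }
  }
  if (!is.null(base$coordination_radii))
    base$coordination_radii <- unlist(base$coordination_radii)
  stopifnot(base$pocket_radius > 0, base$water$clash > 0,
            base$water$merge > 0, base$water$neighborhood > 0,
            all(base$score_coefficients >= 0))
  base
}

#' Load a run configuration from a JSON file
#'
#' Values present in the file override the defaults; everything else keeps
#' its default. See [default_config()] for the schema.
#'
#' @param path Path to a JSON config file.
#' @return A complete configuration list.
#' @export
load_config <- function(path) {
  merge_config(jsonlite::fromJSON(path, simplifyVector = TRUE))
}
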