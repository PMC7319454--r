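# Ensemble statistics over sets of structures: coordination-geometry
# frequencies and metal-partner distance distributions.

#' Coordination-geometry frequency table
#'
#' Counts rank-1 geometry assignments per metal element and converts them to
#' fractions (per metal, fractions sum to 1).
#'
#' @param assignments List of rank-1 \code{sg_assignment} objects.
#' @return data.frame with columns metal, geometry, count, fraction.
#' @export
geometry_frequencies <- function(assignments) {
  empty <- data.frame(metal = character(0), geometry = character(0),
                      count = integer(0), fraction = numeric(0),
                      stringsAsFactors = FALSE)
  if (!length(assignments)) return(empty)
  df <- data.frame(
    metal = vapply(assignments, `[[`, character(1), "metal_element"),
    geometry = vapply(assignments, `[[`, character(1), "geometry"),
    stringsAsFactors = FALSE)
  tab <- as.data.frame(table(metal = df$metal, geometry = df$geometry),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  tab$count <- as.integer(tab$Freq)
  tab$Freq <- NULL
  tot <- tapply(tab$count, tab$metal, sum)
  tab$fraction <- tab$count / as.numeric(tot[tab$metal])
  tab <- tab[order(tab$metal, -tab$count, tab$geometry), ]
  rownames(tab) <- NULL
  tab
}

#' Metal-partner distance histogram
#'
#' Bins all metal-partner distances by (metal element, partner element) into
#' half-open bins \code{[lo, lo + bin_width)}.
#'
#' @param sites List of \code{sg_site} objects.
#' @param s_list Parallel list of parent \code{sg_structure} objects (or a
#'   single structure recycled).
#' @param bin_width Bin width in Angstrom (default 0.1).
#' @return data.frame with columns metal, partner_element, bin_lo, bin_hi,
#'   count.
#' @export
distance_distribution <- function(sites, s_list, bin_width = 0.1) {
  stopifnot(bin_width > 0)
  empty <- data.frame(metal = character(0), partner_element = character(0),
                      bin_lo = numeric(0), bin_hi = numeric(0),
                      count = integer(0), stringsAsFactors = FALSE)
  if (!length(sites)) return(empty)
  if (inherits(s_list, "sg_structure")) s_list <- rep(list(s_list), length(sites))
  rows <- list()
  for (k in seq_along(sites)) {
    site <- sites[[k]]
    if (!length(site$partners)) next
    rows[[length(rows) + 1L]] <- data.frame(
      metal = site$metal_element,
      partner_element = s_list[[k]]$atoms$element[site$partners],
      distance = site$distances,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  d <- do.call(rbind, rows)
  d$bin_lo <- floor(d$distance / bin_width) * bin_width
  key <- paste(d$metal, d$partner_element, format(d$bin_lo, nsmall = 6))
  agg <- do.call(rbind, lapply(split(d, key), function(g) {
    data.frame(metal = g$metal[1], partner_element = g$partner_element[1],
               bin_lo = g$bin_lo[1], bin_hi = g$bin_lo[1] + bin_width,
               count = nrow(g), stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$metal, agg$partner_element, agg$bin_lo), ]
  rownames(agg) <- NULL
  agg
}

#' Metal-site statistics over a directory of PDB files
#'
#' Runs sphere detection and geometry assignment on every metal of every
#' \code{.pdb} file in a directory and aggregates frequencies and distance
#' histograms.
#'
#' @param dir Directory containing PDB files.
#' @param metal Optional element symbol restricting the metals analyzed.
#' @param bin_width Histogram bin width in Angstrom.
#' @param radii,coefficients Passed to [assign_geometries()].
#' @return List with \code{frequencies} and \code{distances} data.frames.
#' @export
site_statistics <- function(dir, metal = NULL, bin_width = 0.1,
                            radii = NULL, coefficients = c(50, 4, 50)) {
  files <- list.files(dir, pattern = "\\.pdb$", full.names = TRUE)
  assignments <- list()
  sites <- list()
  slist <- list()
  for (f in files) {
    s <- read_pdb(f)
    for (m in metal_atoms(s)) {
      if (!is.null(metal) && toupper(s$atoms$element[m]) != toupper(metal)) next
      site <- detect_coordination_sphere(s, m, radii)
      if (site$empty) next
      sites[[length(sites) + 1L]] <- site
      slist[[length(slist) + 1L]] <- s
      ranked <- assign_geometries(s, m, top_k = 1, radii = radii,
                                  coefficients = coefficients)
      if (length(ranked)) assignments[[length(assignments) + 1L]] <- ranked[[1]]
    }
  }
  list(frequencies = geometry_frequencies(assignments),
       distances = distance_distribution(sites, slist, bin_width))
}
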