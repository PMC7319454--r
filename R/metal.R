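# Metal coordination-sphere detection and geometry assignment.
#
# Pipeline: detect the coordination sphere (O/N/S/Cl atoms within an
# element-specific radius), pre-screen reference geometries by angle-list
# RMSD, superpose the site onto each surviving reference (optimal proper
# rotation about the metal over all injective partner-to-vertex
# correspondences, vertices radially scaled to the observed bond lengths),
# add a steric overlap penalty for free coordination sites, and score.

#' Detect a metal's coordination sphere
#'
#' Partners are all O, N, S and Cl atoms within the metal-specific
#' coordination radius, excluding atoms of the metal's own residue.
#' Carboxylate groups with both oxygens inside the radius are recorded as
#' potential bidentate groups (both oxygens count as independent partners).
#'
#' @param s An \code{sg_structure}.
#' @param metal Atom index of the metal in \code{s$atoms}.
#' @param radii Optional named numeric vector overriding coordination radii.
#' @return An \code{sg_site}: list with \code{metal} (index),
#'   \code{metal_element}, \code{partners} (indices), \code{distances},
#'   \code{bidentate_groups} (list of C/O1/O2 index triples), \code{radius}
#'   and \code{empty} flag.
#' @export
detect_coordination_sphere <- function(s, metal, radii = NULL) {
  a <- s$atoms
  if (!is_metal_element(a$element[metal]))
    stop("atom ", metal, " (", a$element[metal], ") is not flagged metallic")
  rad <- coordination_radius(a$element[metal], radii)
  mx <- as.numeric(a[metal, c("x", "y", "z")])
  cand <- which(a$element %in% c("O", "N", "S", "CL"))
  own <- paste(a$chain, a$resno, a$inscode, a$resname, sep = "|")
  cand <- cand[own[cand] != own[metal]]
  if (length(cand)) {
    d <- cross_dist(coords(s)[cand, , drop = FALSE], matrix(mx, 1))[, 1]
    keep <- d <= rad
    partners <- cand[keep]
    distances <- d[keep]
  } else {
    partners <- integer(0)
    distances <- numeric(0)
  }
  ord <- order(distances)
  partners <- partners[ord]
  distances <- distances[ord]
  bid <- Filter(function(t) all(t[2:3] %in% partners), find_carboxylates(s))
  structure(list(metal = metal, metal_element = a$element[metal],
                 partners = partners, distances = distances,
                 bidentate_groups = bid, radius = rad,
                 empty = length(partners) == 0L),
            class = "sg_site")
}

#' @export
print.sg_site <- function(x, ...) {
  cat(sprintf("sg_site: %s with %d partner(s) within %.2f A (%d bidentate group(s))\n",
              x$metal_element, length(x$partners), x$radius,
              length(x$bidentate_groups)))
  invisible(x)
}

# sorted pairwise angle list of a vertex subset of a reference geometry
.subset_angle_list <- function(amat, subset) {
  sort(amat[subset, subset][upper.tri(diag(length(subset)))])
}

#' Pre-screen reference geometries by angle-list RMSD
#'
#' For each reference geometry with coordination number at least the number
#' of observed partners, computes the minimum RMSD between the site's sorted
#' angle list and the sorted angle list of any vertex subset of matching
#' size, and ranks geometries by it. With fewer than two partners the screen
#' is skipped and all size-compatible geometries pass.
#'
#' @param site An \code{sg_site}.
#' @param s The parent \code{sg_structure}.
#' @param library Geometry library, default [builtin_geometries()].
#' @param top_k Number of candidates kept (default 5).
#' @return data.frame with columns geometry, cn, angle_rmsd, ranked ascending.
#' @export
prescreen_geometries <- function(site, s, library = builtin_geometries(),
                                 top_k = 5) {
  n <- length(site$partners)
  compat <- Filter(function(g) g$coordination_number >= n, library)
  if (n < 2) {
    return(data.frame(geometry = vapply(compat, `[[`, character(1), "name"),
                      cn = vapply(compat, `[[`, integer(1), "coordination_number"),
                      angle_rmsd = NA_real_, row.names = NULL,
                      stringsAsFactors = FALSE))
  }
  mx <- as.numeric(s$atoms[site$metal, c("x", "y", "z")])
  pts <- coords(s)[site$partners, , drop = FALSE]
  site_angles <- angle_list_of(pts, mx)
  res <- lapply(compat, function(g) {
    cn <- g$coordination_number
    amat <- cross_angles(g$vertices)
    subsets <- utils::combn(cn, n)
    best <- min(vapply(seq_len(ncol(subsets)), function(j) {
      ref <- .subset_angle_list(amat, subsets[, j])
      sqrt(mean((site_angles - ref)^2))
    }, numeric(1)))
    data.frame(geometry = g$name, cn = cn, angle_rmsd = best,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res <- res[order(res$angle_rmsd, res$cn, res$geometry), ]
  rownames(res) <- NULL
  utils::head(res, top_k)
}

# pairwise angle matrix (degrees) of unit row vectors
cross_angles <- function(v) {
  g <- tcrossprod(v)
  g[g > 1] <- 1
  g[g < -1] <- -1
  acos(g) * 180 / pi
}

#' Superpose a coordination site onto a reference geometry
#'
#' Over all injective correspondences of partners to reference vertices,
#' finds the one minimizing the distance RMSD after (i) an optimal proper
#' rotation about the metal (metal fixed at the origin, least-squares
#' fitting) and (ii) radial scaling of each matched vertex to its matched
#' partner's observed metal distance. The RMSD therefore measures angular
#' distortion in Angstrom at the observed bond lengths and is zero for an
#' ideal site regardless of bond length.
#'
#' @param site An \code{sg_site} with at least one partner.
#' @param geom An \code{sg_geometry} with CN >= number of partners.
#' @param s The parent \code{sg_structure}.
#' @return An \code{sg_assignment} (without overlap penalty or score): list
#'   with geometry, cn, correspondence (vertex index per partner), rmsd,
#'   free_sites, rotation and fitted vertex positions.
#' @export
superpose_to_geometry <- function(site, geom, s) {
  n <- length(site$partners)
  cn <- geom$coordination_number
  if (cn < n) stop("geometry ", geom$name, " has CN ", cn, " < ", n, " partners")
  mx <- as.numeric(s$atoms[site$metal, c("x", "y", "z")])
  P <- sweep(coords(s)[site$partners, , drop = FALSE], 2, mx)
  d <- site$distances
  maps <- injective_maps(n, cn)
  fit <- cpp_best_superposition(P, d, geom$vertices, maps)
  R <- fit$rotation
  scale <- rep(mean(d), cn)
  scale[fit$map] <- d
  fitted <- t(R %*% t(geom$vertices * scale)) +
    matrix(mx, cn, 3, byrow = TRUE)
  structure(list(
    geometry = geom$name, cn = cn,
    correspondence = as.integer(fit$map),
    rmsd = fit$rmsd, free_sites = cn - n,
    rotation = R, fitted_vertices = fitted,
    metal = site$metal, metal_element = site$metal_element,
    partners = site$partners,
    overlap_penalty = NA_real_, score = NA_real_
  ), class = "sg_assignment")
}

#' @export
print.sg_assignment <- function(x, ...) {
  cat(sprintf("%s (CN %d): rmsd %.3f A, free sites %d, overlap %s, score %s\n",
              x$geometry, x$cn, x$rmsd, x$free_sites,
              ifelse(is.na(x$overlap_penalty), "?", sprintf("%.3f", x$overlap_penalty)),
              ifelse(is.na(x$score), "?", sprintf("%.2f", x$score))))
  invisible(x)
}

#' Steric overlap penalty at free coordination sites
#'
#' A probe of radius 1.4 Angstrom (a water-sized would-be binding partner) is
#' placed at each free (unmatched) reference vertex, at the mean observed
#' metal-partner distance. The penalty sums the normalized linear clash depth
#' \code{max(0, (r_probe + r_vdw - d) / (r_probe + r_vdw))} over all probes
#' and all non-partner heavy atoms (the metal excluded); it is 0 with no free
#' sites or no contacts.
#'
#' @param s An \code{sg_structure}.
#' @param site The \code{sg_site}.
#' @param assignment An \code{sg_assignment} from [superpose_to_geometry()].
#' @param probe_radius Probe radius in Angstrom (default 1.4).
#' @return Non-negative dimensionless penalty.
#' @export
overlap_penalty <- function(s, site, assignment, probe_radius = 1.4) {
  free <- setdiff(seq_len(assignment$cn), assignment$correspondence)
  if (!length(free)) return(0)
  probes <- assignment$fitted_vertices[free, , drop = FALSE]
  a <- s$atoms
  others <- setdiff(which(a$element != "H"), c(site$metal, site$partners))
  if (!length(others)) return(0)
  d <- cross_dist(probes, coords(s)[others, , drop = FALSE])
  lim <- matrix(probe_radius + vdw_radius(a$element[others]),
                nrow(d), ncol(d), byrow = TRUE)
  sum(pmax(0, (lim - d) / lim))
}

#' Combine RMSD, free sites and overlap into a score
#'
#' \code{score = a * rmsd + b * free_sites + c * overlap} with default
#' coefficients (50, 4, 50); lower is better. The free-site term implements
#' the preference for simple geometries; the default coefficients reproduce
#' published worked-example scores for a zinc site to caption rounding.
#'
#' @param rmsd Distance RMSD in Angstrom.
#' @param free_sites Number of free coordination sites.
#' @param overlap Overlap penalty.
#' @param coefficients Numeric length-3 vector \code{c(rmsd, free, overlap)}.
#' @return Numeric score (lower = better).
#' @export
score_assignment <- function(rmsd, free_sites, overlap,
                             coefficients = c(50, 4, 50)) {
  stopifnot(all(c(rmsd, free_sites, overlap) >= 0), length(coefficients) == 3)
  coefficients[1] * rmsd + coefficients[2] * free_sites + coefficients[3] * overlap
}

#' Assign and rank coordination geometries for a metal
#'
#' Orchestrates sphere detection, angle-list pre-screening, superposition,
#' overlap penalty and scoring; candidates are ranked ascending by score,
#' ties broken by smaller coordination number (preferring simple geometries),
#' then geometry name.
#'
#' @param s An \code{sg_structure}.
#' @param metal Atom index of the metal.
#' @param top_k Number of ranked assignments returned (default 3).
#' @param library Geometry library.
#' @param radii Optional coordination-radius overrides.
#' @param coefficients Score coefficients, see [score_assignment()].
#' @param prescreen_k Candidates surviving the angle-list screen (default 5).
#' @return List of \code{sg_assignment}, best first; empty (with a message)
#'   when the coordination sphere is empty.
#' @export
assign_geometries <- function(s, metal, top_k = 3,
                              library = builtin_geometries(), radii = NULL,
                              coefficients = c(50, 4, 50), prescreen_k = 5) {
  site <- detect_coordination_sphere(s, metal, radii)
  if (site$empty) {
    message("metal atom ", metal, " (", site$metal_element,
            "): no coordinating atoms within ", site$radius, " A")
    return(list())
  }
  cand <- prescreen_geometries(site, s, library, top_k = prescreen_k)
  out <- lapply(cand$geometry, function(gn) {
    asg <- superpose_to_geometry(site, library[[gn]], s)
    asg$overlap_penalty <- overlap_penalty(s, site, asg)
    asg$score <- score_assignment(asg$rmsd, asg$free_sites, asg$overlap_penalty,
                                  coefficients)
    asg
  })
  ord <- order(vapply(out, `[[`, numeric(1), "score"),
               vapply(out, `[[`, integer(1), "cn"),
               vapply(out, `[[`, character(1), "geometry"))
  utils::head(out[ord], top_k)
}
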