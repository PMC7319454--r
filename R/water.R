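# Water placement at unsaturated hydrogen-bond functions.
#
# Pipeline: enumerate ideal interaction directions for pocket/ligand polar
# atoms (sp2/sp3 heavy-atom templates), keep the free ones (unsaturated or
# badly satisfied, geometric score < 0.85), spawn water candidates at the
# ideal hydrogen-bond distances (2.6 A water-accepting-from-donor, 2.8 A
# water-donating-to-acceptor), drop sterically unavailable ones, merge the
# rest by a score-weighted mean-shift self-assembly, locally optimize each
# predicted position, run one extra round over water-water interactions, and
# annotate each prediction with the closest crystallographic water.
#
# Crystallographic waters (HOH) are reference-only throughout: they seed no
# directions, satisfy no donors/acceptors and block no candidates; they are
# used solely by match_crystal_waters().

.TET_DIRS <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)

# Ideal interaction directions for one polar atom given its heavy-neighbor
# unit vectors (origin -> neighbor) and hybridization. Returns a matrix of
# unit row vectors (possibly 0 rows).
template_directions <- function(u_list, hybridization) {
  nn <- length(u_list)
  if (nn == 0L) return(.TET_DIRS)
  if (hybridization == "sp2") {
    if (nn == 1L) {
      u <- u_list[[1]]
      p <- attr(u_list, "plane")
      if (is.null(p)) p <- perp_vector(u)
      return(rbind(-0.5 * u + (sqrt(3) / 2) * p,
                   -0.5 * u - (sqrt(3) / 2) * p))
    }
    return(matrix(unitv(-(u_list[[1]] + u_list[[2]])), 1, 3))
  }
  # sp3
  if (nn == 1L) {
    u <- u_list[[1]]
    p1 <- attr(u_list, "plane")
    if (is.null(p1)) p1 <- perp_vector(u)
    p2 <- cross3(u, p1)
    ct <- -1 / 3
    st <- sqrt(1 - ct^2)
    return(t(vapply(c(0, 2 * pi / 3, 4 * pi / 3), function(phi) {
      ct * u + st * (cos(phi) * p1 + sin(phi) * p2)
    }, numeric(3))))
  }
  if (nn == 2L) {
    b <- unitv(-(u_list[[1]] + u_list[[2]]))
    e <- cross3(u_list[[1]], u_list[[2]])
    if (vnorm(e) < 1e-8) e <- perp_vector(u_list[[1]]) else e <- unitv(e)
    half <- acos(-1 / 3) / 2
    return(rbind(cos(half) * b + sin(half) * e,
                 cos(half) * b - sin(half) * e))
  }
  if (nn == 3L) {
    v <- -(u_list[[1]] + u_list[[2]] + u_list[[3]])
    if (vnorm(v) < 1e-8) return(matrix(numeric(0), 0, 3))
    return(matrix(unitv(v), 1, 3))
  }
  matrix(numeric(0), 0, 3)
}

# unit vectors origin -> heavy neighbors, with an in-plane reference for sp2
neighbor_units <- function(s, i, adj) {
  a <- s$atoms
  oi <- as.numeric(a[i, c("x", "y", "z")])
  nb <- adj[[i]]
  nb <- nb[a$element[nb] != "H"]
  u <- lapply(nb, function(j) unitv(as.numeric(a[j, c("x", "y", "z")]) - oi))
  if (length(u) == 1L) {
    # plane reference from the neighbor's other substituents (sp2 systems)
    j <- nb[1]
    others <- setdiff(adj[[j]][a$element[adj[[j]]] != "H"], i)
    if (length(others)) {
      jo <- as.numeric(a[j, c("x", "y", "z")])
      w <- unitv(as.numeric(a[others[1], c("x", "y", "z")]) - jo)
      p <- w - sum(w * u[[1]]) * u[[1]]
      if (vnorm(p) > 1e-6) attr(u, "plane") <- unitv(p)
    }
  }
  u
}

empty_directions <- function() {
  data.frame(atom = integer(0), wsrc = integer(0),
             ox = numeric(0), oy = numeric(0), oz = numeric(0),
             dx = numeric(0), dy = numeric(0), dz = numeric(0),
             kind = character(0), ideal_distance = numeric(0),
             stringsAsFactors = FALSE)
}

direction_rows <- function(atom, wsrc, origin, dirs, role, capacity,
                           donor_distance = 2.6, acceptor_distance = 2.8) {
  if (nrow(dirs) == 0L) return(empty_directions())
  origin <- unname(as.numeric(origin))
  kind <- switch(role,
    donor = rep("donor-to-water", nrow(dirs)),
    acceptor = rep("acceptor-to-water", nrow(dirs)),
    both = {
      ndon <- min(nrow(dirs), floor(capacity / 2))
      c(rep("donor-to-water", ndon),
        rep("acceptor-to-water", nrow(dirs) - ndon))
    })
  data.frame(atom = atom, wsrc = wsrc,
             ox = origin[1], oy = origin[2], oz = origin[3],
             dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3],
             kind = kind,
             ideal_distance = ifelse(kind == "donor-to-water",
                                     donor_distance, acceptor_distance),
             stringsAsFactors = FALSE)
}

#' Angular geometric score of a point against an interaction direction
#'
#' The deviation angle theta between (point - origin) and the ideal direction
#' maps linearly to a score: 1 on-axis, 0 at 60 degrees or more. Under this
#' form the conventional 0.85 "badly satisfied" threshold corresponds to a
#' 9-degree deviation.
#'
#' @param direction A one-row direction data.frame (or list with numeric
#'   \code{origin} and \code{direction}).
#' @param point 3-vector.
#' @return Score in \code{[0, 1]}.
#' @export
geometric_score <- function(direction, point) {
  if (is.data.frame(direction)) {
    o <- c(direction$ox[1], direction$oy[1], direction$oz[1])
    d <- c(direction$dx[1], direction$dy[1], direction$dz[1])
  } else {
    o <- direction$origin
    d <- direction$direction
  }
  v <- point - o
  if (vnorm(v) < 1e-9) stop("point coincides with the direction origin")
  max(0, 1 - angle_deg(v, d) / 60)
}

# vectorized: score of point against every row of dirs
score_vs_dirs <- function(dirs, point) {
  if (nrow(dirs) == 0L) return(numeric(0))
  vx <- point[1] - dirs$ox; vy <- point[2] - dirs$oy; vz <- point[3] - dirs$oz
  nv <- sqrt(vx^2 + vy^2 + vz^2)
  ca <- (vx * dirs$dx + vy * dirs$dy + vz * dirs$dz) / pmax(nv, 1e-12)
  ca <- pmax(-1, pmin(1, ca))
  pmax(0, 1 - (acos(ca) * 180 / pi) / 60)
}

# Distance quality of a hydrogen bond: 1 on the ideal band [2.6, 2.8] A,
# falling linearly to 0 at 2.2 and 3.6 A.
distance_quality <- function(d) {
  ifelse(d < 2.6, pmax(0, (d - 2.2) / 0.4),
         ifelse(d <= 2.8, 1, pmax(0, (3.6 - d) / 0.8)))
}

#' Find free interaction directions in a pocket
#'
#' Enumerates template ideal directions for every polar atom of the pocket
#' residues and of the defining ligand (sp2: in-plane at 120 degrees from
#' the bonds; sp3: tetrahedral completions of the bonded directions). A
#' direction is emitted iff its atom is unsaturated (fewer well-placed
#' partners than capacity) or has a badly placed partner (geometric score
#' < \code{saturation}), and no existing partner already lies within the
#' saturation score on that direction. An existing partner is a polar atom
#' of complementary role within 3.5 A (same residue and 1-2/1-3 bonded
#' neighbors excluded); crystallographic waters never count.
#'
#' @param s An \code{sg_structure}.
#' @param pocket An \code{sg_pocket}.
#' @param saturation Geometric-score threshold (default 0.85).
#' @param donor_distance,acceptor_distance Ideal hydrogen-bond distances in
#'   Angstrom for water accepting from a donor (2.6) and donating to an
#'   acceptor (2.8).
#' @return data.frame of interaction directions (origin, unit direction,
#'   kind, ideal distance, source atom index).
#' @export
find_free_directions <- function(s, pocket, saturation = 0.85,
                                 donor_distance = 2.6, acceptor_distance = 2.8) {
  if (nrow(pocket$residues) == 0L && length(pocket$ligand_atoms) == 0L)
    stop("pocket is empty: no residues and no ligand atoms")
  a <- s$atoms
  roles <- perceive_polar_roles(s)
  member <- pocket_member_atoms(s, pocket)
  member[pocket$ligand_atoms] <- TRUE
  hoh <- a$resname %in% c("HOH", "WAT")
  roles <- roles[!hoh[roles$atom], , drop = FALSE]
  use <- roles[member[roles$atom], , drop = FALSE]
  if (nrow(use) == 0L) return(empty_directions())
  adj <- neighbor_list(s)
  xyz <- coords(s)
  reskey <- paste(a$chain, a$resno, a$inscode, sep = "|")
  out <- list()
  for (r in seq_len(nrow(use))) {
    i <- use$atom[r]
    oi <- xyz[i, ]
    u <- neighbor_units(s, i, adj)
    dirs <- template_directions(u, use$hybridization[r])
    if (nrow(dirs) == 0L) next
    cand_dirs <- direction_rows(i, NA_integer_, oi, dirs, use$role[r],
                                use$capacity[r], donor_distance, acceptor_distance)
    # existing partners: complementary-role polar atoms within 3.5 A
    comp <- switch(use$role[r],
                   donor = c("acceptor", "both"),
                   acceptor = c("donor", "both"),
                   both = c("donor", "acceptor", "both"))
    near12 <- c(adj[[i]], unlist(adj[adj[[i]]]))
    partners <- roles$atom[roles$role %in% comp]
    partners <- setdiff(partners, c(i, near12))
    partners <- partners[reskey[partners] != reskey[i]]
    if (length(partners)) {
      pd <- cross_dist(matrix(oi, 1), xyz[partners, , drop = FALSE])[1, ]
      partners <- partners[pd <= 3.5]
    }
    if (length(partners)) {
      pscore <- vapply(partners, function(p) {
        max(score_vs_dirs(cand_dirs, xyz[p, ]))
      }, numeric(1))
      good <- sum(pscore >= saturation)
      if (good >= use$capacity[r] && all(pscore >= saturation)) next
      blocked <- vapply(seq_len(nrow(cand_dirs)), function(k) {
        any(vapply(partners, function(p) {
          score_vs_dirs(cand_dirs[k, ], xyz[p, ]) >= saturation
        }, logical(1)))
      }, logical(1))
      cand_dirs <- cand_dirs[!blocked, , drop = FALSE]
    }
    if (nrow(cand_dirs)) out[[length(out) + 1L]] <- cand_dirs
  }
  if (!length(out)) return(empty_directions())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate water candidates on free directions
#'
#' One candidate per direction at \code{origin + ideal_distance * direction};
#' the initial geometric score is 1 (on-axis by construction).
#'
#' @param directions Direction data.frame from [find_free_directions()].
#' @return data.frame with columns x, y, z, score, dir (row index into
#'   \code{directions}).
#' @export
generate_candidates <- function(directions) {
  if (nrow(directions) == 0L) {
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      score = numeric(0), dir = integer(0)))
  }
  data.frame(
    x = directions$ox + directions$ideal_distance * directions$dx,
    y = directions$oy + directions$ideal_distance * directions$dy,
    z = directions$oz + directions$ideal_distance * directions$dz,
    score = 1,
    dir = seq_len(nrow(directions)))
}

#' Remove sterically unavailable candidates
#'
#' A candidate is dropped when any heavy atom other than its own source atom
#' lies nearer than \code{clash} Angstrom (closed boundary: a contact at
#' exactly \code{clash} is kept). Crystallographic waters do not block;
#' additional occupied points (e.g. already-placed waters) can be supplied.
#'
#' @param candidates Candidate data.frame from [generate_candidates()].
#' @param s An \code{sg_structure}.
#' @param directions The direction data.frame the candidates refer to.
#' @param clash Cutoff in Angstrom (default 2.2).
#' @param extra_points Optional matrix (k x 3) of occupied positions.
#' @return The filtered candidate data.frame.
#' @export
filter_available <- function(candidates, s, directions, clash = 2.2,
                             extra_points = NULL) {
  if (nrow(candidates) == 0L) return(candidates)
  a <- s$atoms
  heavy <- which(a$element != "H" & !(a$resname %in% c("HOH", "WAT")))
  pos <- as.matrix(candidates[, c("x", "y", "z")])
  keep <- rep(TRUE, nrow(candidates))
  if (length(heavy)) {
    d <- cross_dist(pos, coords(s)[heavy, , drop = FALSE])
    src <- directions$atom[candidates$dir]
    for (k in seq_len(nrow(candidates))) {
      dk <- d[k, ]
      if (!is.na(src[k])) dk[heavy == src[k]] <- Inf
      if (any(dk < clash)) keep[k] <- FALSE
    }
  }
  if (!is.null(extra_points) && nrow(extra_points)) {
    d <- cross_dist(pos, extra_points)
    wsrc <- directions$wsrc[candidates$dir]
    for (k in seq_len(nrow(candidates))) {
      dk <- d[k, ]
      if (!is.na(wsrc[k])) dk[wsrc[k]] <- Inf
      if (any(dk < clash)) keep[k] <- FALSE
    }
  }
  candidates[keep, , drop = FALSE]
}

# single-linkage clusters at cutoff h over an n x 3 position matrix
single_linkage_clusters <- function(pos, h) {
  n <- nrow(pos)
  if (n == 1L) return(rep(1L, 1))
  cl <- stats::cutree(stats::hclust(stats::dist(pos), method = "single"), h = h)
  as.integer(cl)
}

#' Self-assemble candidates into predicted waters
#'
#' Iterative score-weighted mean shift: every candidate moves to the
#' geometric-score-weighted centroid of the candidates within
#' \code{neighborhood} Angstrom of itself (scores are re-evaluated against
#' each candidate's source direction as it moves), until the largest
#' displacement falls below \code{converge} or \code{max_iter} iterations.
#' The shifted candidates are then merged by single linkage at \code{merge}
#' Angstrom; each cluster yields one water at the weighted centroid, with
#' one partner entry per contributing source atom (pair quality = angular
#' score times distance quality at the final position).
#'
#' @param candidates Candidate data.frame.
#' @param directions The direction data.frame the candidates refer to.
#' @param neighborhood Mean-shift neighborhood radius (default 1.0 A).
#' @param merge Single-linkage merge radius (default 0.5 A).
#' @param converge Convergence displacement (default 0.01 A).
#' @param max_iter Iteration cap (default 100).
#' @return List of placed waters (class \code{sg_water}): position, partners
#'   data.frame (atom, wsrc, quality), average_quality, source_dirs.
#' @export
self_assemble <- function(candidates, directions, neighborhood = 1.0,
                          merge = 0.5, converge = 0.01, max_iter = 100) {
  if (nrow(candidates) == 0L) return(list())
  pos <- as.matrix(candidates[, c("x", "y", "z")])
  n <- nrow(pos)
  w <- rep(1, n)
  for (it in seq_len(max_iter)) {
    for (k in seq_len(n)) {
      w[k] <- max(0.05, score_vs_dirs(directions[candidates$dir[k], ], pos[k, ]))
    }
    d <- cross_dist(pos, pos)
    newpos <- pos
    for (k in seq_len(n)) {
      nb <- which(d[k, ] <= neighborhood)
      newpos[k, ] <- colSums(pos[nb, , drop = FALSE] * w[nb]) / sum(w[nb])
    }
    disp <- sqrt(rowSums((newpos - pos)^2))
    pos <- newpos
    if (max(disp) < converge) break
  }
  cl <- single_linkage_clusters(pos, merge)
  waters <- lapply(split(seq_len(n), cl), function(members) {
    wm <- w[members]
    p <- colSums(pos[members, , drop = FALSE] * wm) / sum(wm)
    dir_idx <- candidates$dir[members]
    make_water(p, dir_idx, directions)
  })
  names(waters) <- NULL
  waters
}

# build an sg_water at position p from the contributing direction rows
make_water <- function(p, dir_idx, directions) {
  dd <- directions[dir_idx, , drop = FALSE]
  key <- ifelse(is.na(dd$atom), paste0("W", dd$wsrc), paste0("A", dd$atom))
  parts <- lapply(split(seq_along(dir_idx), key), function(g) {
    q <- vapply(g, function(k) {
      o <- c(dd$ox[k], dd$oy[k], dd$oz[k])
      score_vs_dirs(dd[k, ], p) * distance_quality(vnorm(p - o))
    }, numeric(1))
    data.frame(atom = dd$atom[g[1]], wsrc = dd$wsrc[g[1]], quality = max(q),
               stringsAsFactors = FALSE)
  })
  partners <- do.call(rbind, parts)
  rownames(partners) <- NULL
  structure(list(position = as.numeric(p), partners = partners,
                 average_quality = mean(partners$quality),
                 source_dirs = dir_idx, nearest_xray = NULL,
                 optimized = FALSE),
            class = "sg_water")
}

#' @export
print.sg_water <- function(x, ...) {
  cat(sprintf("sg_water at (%.2f, %.2f, %.2f): %d partner(s), avg quality %.2f%s\n",
              x$position[1], x$position[2], x$position[3], nrow(x$partners),
              x$average_quality,
              if (!is.null(x$nearest_xray))
                sprintf(", nearest X-ray water %.2f A", x$nearest_xray$distance)
              else ""))
  invisible(x)
}

# objective for one water: mean pair quality, with a steep penalty inside
# the clash cutoff
water_objective <- function(p, water, directions, clash_xyz, clash = 2.2) {
  dd <- directions[water$source_dirs, , drop = FALSE]
  key <- ifelse(is.na(dd$atom), paste0("W", dd$wsrc), paste0("A", dd$atom))
  qual <- vapply(split(seq_len(nrow(dd)), key), function(g) {
    max(vapply(g, function(k) {
      o <- c(dd$ox[k], dd$oy[k], dd$oz[k])
      score_vs_dirs(dd[k, ], p) * distance_quality(vnorm(p - o))
    }, numeric(1)))
  }, numeric(1))
  pen <- 0
  if (nrow(clash_xyz)) {
    d <- cross_dist(matrix(p, 1), clash_xyz)[1, ]
    pen <- 10 * sum(pmax(0, clash - d))
  }
  mean(qual) - pen
}

#' Locally optimize predicted water positions
#'
#' Derivative-free (Nelder-Mead) maximization of the average pair quality
#' (angular score times distance quality) for each water, subject to the
#' clash constraint via a steep penalty. A water already at quality 1 is
#' left untouched; if the optimizer worsens the objective or leaves the
#' feasible region, the pre-optimization position is kept and the water is
#' flagged.
#'
#' @param waters List of \code{sg_water}.
#' @param directions The direction data.frame.
#' @param s An \code{sg_structure}.
#' @param clash Clash cutoff in Angstrom (default 2.2).
#' @return The list of waters with updated positions and qualities.
#' @export
optimize_positions <- function(waters, directions, s, clash = 2.2) {
  if (!length(waters)) return(waters)
  a <- s$atoms
  heavy <- which(a$element != "H" & !(a$resname %in% c("HOH", "WAT")))
  xyz <- coords(s)
  lapply(waters, function(w) {
    partner_atoms <- w$partners$atom[!is.na(w$partners$atom)]
    others <- setdiff(heavy, partner_atoms)
    clash_xyz <- xyz[others, , drop = FALSE]
    f0 <- water_objective(w$position, w, directions, clash_xyz, clash)
    # a water within numerical noise of perfect quality is already at an
    # optimum; moving it along the flat plateau would only add jitter
    if (w$average_quality >= 1 - 1e-5) {
      w$optimized <- TRUE
      return(w)
    }
    opt <- stats::optim(w$position, function(p) {
      -water_objective(p, w, directions, clash_xyz, clash)
    }, method = "Nelder-Mead", control = list(reltol = 1e-10, maxit = 500))
    feasible <- !nrow(clash_xyz) ||
      min(cross_dist(matrix(opt$par, 1), clash_xyz)) >= clash
    if (-opt$value >= f0 && feasible) {
      nw <- make_water(opt$par, w$source_dirs, directions)
      nw$optimized <- TRUE
      nw
    } else {
      w$optimized <- FALSE # optimizer rejected; pre-optimization kept
      w
    }
  })
}

#' Second placement round over water-water interactions
#'
#' Placed waters become polar atoms themselves (role both, capacity 4): free
#' tetrahedral completions of each water's existing partner directions are
#' enumerated, candidates spawned at 2.8 A, filtered against protein, ligand
#' and already-placed waters, self-assembled and optimized. New waters with
#' average quality at least \code{quality_cutoff} and no clash are appended;
#' first-round waters are never removed. Exactly one extra round is run.
#'
#' @param waters First-round list of \code{sg_water}.
#' @param s An \code{sg_structure}.
#' @param pocket The \code{sg_pocket} (unused beyond provenance; directions
#'   come from the waters themselves).
#' @param quality_cutoff Acceptance threshold (default 0.6).
#' @param clash Clash cutoff in Angstrom (default 2.2).
#' @return Augmented list of waters.
#' @export
second_iteration <- function(waters, s, pocket, quality_cutoff = 0.6,
                             clash = 2.2) {
  if (!length(waters)) return(waters)
  wpos <- do.call(rbind, lapply(waters, `[[`, "position"))
  dirs <- list()
  adj <- neighbor_list(s)
  for (k in seq_along(waters)) {
    w <- waters[[k]]
    # existing hydrogen-bond directions of this water: towards its partners
    u <- list()
    pa <- w$partners$atom
    for (r in seq_len(nrow(w$partners))) {
      o <- if (is.na(pa[r])) waters[[w$partners$wsrc[r]]]$position
           else as.numeric(s$atoms[pa[r], c("x", "y", "z")])
      v <- o - w$position
      if (vnorm(v) > 1e-6) u[[length(u) + 1L]] <- unitv(v)
    }
    if (length(u) == 1L) {
      # covariant torsion reference: the first partner's own heavy neighbor
      # (or, for a water partner, that water's first partner origin)
      nb <- NULL
      if (!is.na(pa[1])) {
        hv <- adj[[pa[1]]][s$atoms$element[adj[[pa[1]]]] != "H"]
        if (length(hv)) nb <- as.numeric(s$atoms[hv[1], c("x", "y", "z")])
      } else {
        src <- waters[[w$partners$wsrc[1]]]
        spa <- src$partners$atom[1]
        if (!is.na(spa)) nb <- as.numeric(s$atoms[spa, c("x", "y", "z")])
      }
      if (!is.null(nb)) {
        r <- nb - w$position
        p <- r - sum(r * u[[1]]) * u[[1]]
        if (vnorm(p) > 1e-6) attr(u, "plane") <- unitv(p)
      }
    }
    free <- template_directions(u, "sp3")
    if (nrow(free) == 0L) next
    n_free <- min(nrow(free), max(0, 4 - length(u)))
    if (n_free == 0L) next
    dirs[[length(dirs) + 1L]] <-
      direction_rows(NA_integer_, k, w$position, free[seq_len(n_free), , drop = FALSE],
                     "both", 4, donor_distance = 2.8, acceptor_distance = 2.8)
  }
  if (!length(dirs)) return(waters)
  directions <- do.call(rbind, dirs)
  rownames(directions) <- NULL
  cands <- generate_candidates(directions)
  cands <- filter_available(cands, s, directions, clash = clash,
                            extra_points = wpos)
  if (nrow(cands) == 0L) return(waters)
  new_w <- self_assemble(cands, directions)
  new_w <- optimize_positions(new_w, directions, s, clash = clash)
  new_w <- Filter(function(w) {
    if (w$average_quality < quality_cutoff) return(FALSE)
    ok_struct <- TRUE
    a <- s$atoms
    heavy <- which(a$element != "H" & !(a$resname %in% c("HOH", "WAT")))
    if (length(heavy))
      ok_struct <- min(cross_dist(matrix(w$position, 1),
                                  coords(s)[heavy, , drop = FALSE])) >= clash
    src <- unique(w$partners$wsrc[!is.na(w$partners$wsrc)])
    dw <- cross_dist(matrix(w$position, 1), wpos)[1, ]
    dw[src] <- Inf
    ok_struct && all(dw >= clash)
  }, new_w)
  c(waters, new_w)
}

#' Annotate waters with the nearest crystallographic water
#'
#' @param placed List of \code{sg_water}.
#' @param s An \code{sg_structure} (HOH oxygens are the references).
#' @return The list with \code{nearest_xray} set to \code{list(atom,
#'   distance)} per water, or left \code{NULL} when the input has no waters.
#' @export
match_crystal_waters <- function(placed, s) {
  wi <- water_atoms(s)
  if (!length(wi) || !length(placed)) return(placed)
  wxyz <- coords(s)[wi, , drop = FALSE]
  lapply(placed, function(w) {
    d <- cross_dist(matrix(w$position, 1), wxyz)[1, ]
    j <- which.min(d)
    w$nearest_xray <- list(atom = wi[j], distance = d[j])
    w
  })
}

#' Place water molecules in a binding pocket
#'
#' Full deterministic pipeline: free interaction directions, candidate
#' generation at the ideal hydrogen-bond distances, steric availability
#' filter, score-weighted self-assembly, local position optimization, one
#' second round over water-water interactions, a final clash guarantee and
#' crystallographic-water annotation.
#'
#' @param s An \code{sg_structure}.
#' @param pocket An \code{sg_pocket} from [extract_pocket()].
#' @param config List of thresholds, see [default_config()]; \code{NULL}
#'   uses the defaults.
#' @return List of \code{sg_water}, possibly empty.
#' @export
place_waters <- function(s, pocket, config = NULL) {
  cfg <- merge_config(config)
  wc <- cfg$water
  directions <- find_free_directions(s, pocket, saturation = wc$saturation,
                                     donor_distance = wc$donor_distance,
                                     acceptor_distance = wc$acceptor_distance)
  if (nrow(directions) == 0L) return(list())
  cands <- generate_candidates(directions)
  cands <- filter_available(cands, s, directions, clash = wc$clash)
  if (nrow(cands) == 0L) return(list())
  waters <- self_assemble(cands, directions, neighborhood = wc$neighborhood,
                          merge = wc$merge, converge = wc$converge,
                          max_iter = wc$max_iter)
  waters <- optimize_positions(waters, directions, s, clash = wc$clash)
  waters <- Filter(function(w) w$average_quality > 0, waters)
  waters <- second_iteration(waters, s, pocket,
                             quality_cutoff = wc$quality_cutoff,
                             clash = wc$clash)
  # final guarantee: no placed water below the clash cutoff from any
  # non-partner heavy atom
  a <- s$atoms
  heavy <- which(a$element != "H" & !(a$resname %in% c("HOH", "WAT")))
  waters <- Filter(function(w) {
    partner_atoms <- w$partners$atom[!is.na(w$partners$atom)]
    others <- setdiff(heavy, partner_atoms)
    !length(others) ||
      min(cross_dist(matrix(w$position, 1),
                     coords(s)[others, , drop = FALSE])) >= wc$clash
  }, waters)
  match_crystal_waters(waters, s)
}

#' Placed waters as a data.frame
#'
#' @param waters List of \code{sg_water}.
#' @param s Optional \code{sg_structure} used to label partner atoms.
#' @return data.frame with one row per water: position, number of partners,
#'   average quality, nearest crystallographic-water distance (NA if none).
#' @export
waters_table <- function(waters, s = NULL) {
  if (!length(waters)) {
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      n_partners = integer(0), average_quality = numeric(0),
                      nearest_xray_distance = numeric(0)))
  }
  do.call(rbind, lapply(waters, function(w) {
    data.frame(x = w$position[1], y = w$position[2], z = w$position[3],
               n_partners = nrow(w$partners),
               average_quality = w$average_quality,
               nearest_xray_distance = if (!is.null(w$nearest_xray))
                 w$nearest_xray$distance else NA_real_)
  }))
}
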