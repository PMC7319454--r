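# Independent oracles used to cross-check the engines. These deliberately
# share no code with the package internals: permutations are enumerated with
# a local recursion and the superposition uses a plain SVD fit written here.

# all permutations of a vector (rows)
oracle_permutations <- function(v) {
  if (length(v) == 1) return(matrix(v, 1, 1))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- oracle_permutations(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

# proper-rotation least-squares fit of rows of Q onto rows of P (both n x 3,
# centered at the origin); returns the residual rmsd
oracle_fit_rmsd <- function(P, Q) {
  C <- t(Q) %*% P
  sv <- svd(C)
  d <- sign(det(sv$v %*% t(sv$u)))
  tr <- sv$d[1] + sv$d[2] + d * sv$d[3]
  err <- sum(P^2) + sum(Q^2) - 2 * tr
  sqrt(max(0, err) / nrow(P))
}

# brute-force minimum distance rmsd of a site (P rows, metal at origin,
# observed distances d) against reference unit vertices V, over every
# injective correspondence
oracle_best_rmsd <- function(P, d, V) {
  n <- nrow(P)
  cn <- nrow(V)
  best <- Inf
  subsets <- utils::combn(cn, n)
  for (j in seq_len(ncol(subsets))) {
    perms <- oracle_permutations(subsets[, j])
    for (r in seq_len(nrow(perms))) {
      Q <- V[perms[r, ], , drop = FALSE] * d
      best <- min(best, oracle_fit_rmsd(P, Q))
    }
  }
  best
}

# sorted pairwise angle list by a double loop (independent of angle_list_of)
oracle_angle_list <- function(pts, center) {
  n <- nrow(pts)
  out <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- pts[i, ] - center
      b <- pts[j, ] - center
      ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
      out <- c(out, acos(max(-1, min(1, ca))) * 180 / pi)
    }
  }
  sort(out)
}

# minimum angle-list rmsd of a site against all same-size vertex subsets of
# a reference geometry (independent of prescreen_geometries)
oracle_subset_angle_rmsd <- function(site_angles, V, n) {
  cn <- nrow(V)
  best <- Inf
  subsets <- utils::combn(cn, n)
  for (j in seq_len(ncol(subsets))) {
    ref <- oracle_angle_list(V[subsets[, j], , drop = FALSE], c(0, 0, 0))
    best <- min(best, sqrt(mean((site_angles - ref)^2)))
  }
  best
}

# a deterministic rotation matrix from an axis-angle pair
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) * c_ + s_ * ux + (1 - c_) * (u %o% u)
}

# apply a rigid motion to every atom of a structure
transform_structure <- function(s, R, t) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
  s$atoms$x <- xyz[, 1] + t[1]
  s$atoms$y <- xyz[, 2] + t[2]
  s$atoms$z <- xyz[, 3] + t[3]
  s
}

# toy pocket with one unobstructed amide donor and one unobstructed carbonyl
# acceptor, far enough apart that their candidate waters never interact
donor_acceptor_pocket <- function() {
  make_polar_pocket(list(
    list(kind = "carbonyl", position = c(0, 0, 0), direction = c(-1, 0, 0)),
    list(kind = "amide", position = c(12, 0, 0), direction = c(1, 0, 0)),
    list(kind = "ligand", position = c(6, 2.5, 0))))
}
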