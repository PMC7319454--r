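direction_obj <- function(origin, dir, kind = "acceptor-to-water",
                          dist = 2.8, atom = 1L, wsrc = NA_integer_) {
  data.frame(atom = atom, wsrc = wsrc,
             ox = origin[1], oy = origin[2], oz = origin[3],
             dx = dir[1], dy = dir[2], dz = dir[3],
             kind = kind, ideal_distance = dist, stringsAsFactors = FALSE)
}

test_that("the angular score falls linearly to zero at 60 degrees", {
  d <- direction_obj(c(0, 0, 0), c(1, 0, 0))
  expect_equal(geometric_score(d, c(2.8, 0, 0)), 1.0)
  th60 <- c(cos(pi / 3), sin(pi / 3), 0) * 2.8
  expect_equal(geometric_score(d, th60), 0, tolerance = 1e-9)
  th9 <- c(cos(9 * pi / 180), sin(9 * pi / 180), 0) * 2.8
  expect_equal(geometric_score(d, th9), 0.85, tolerance = 1e-9)
  th90 <- c(0, 1, 0)
  expect_equal(geometric_score(d, th90), 0)
  expect_error(geometric_score(d, c(0, 0, 0)), "coincides")
})

test_that("an isolated carbonyl exposes two in-plane lone-pair directions", {
  s <- make_polar_pocket(list(
    list(kind = "carbonyl", position = c(0, 0, 0), direction = c(1, 0, 0)),
    list(kind = "ligand", position = c(4, 4, 0))))
  p <- extract_pocket(s, "LIG")
  d <- find_free_directions(s, p)
  expect_equal(nrow(d), 2)
  expect_equal(unique(d$kind), "acceptor-to-water")
  expect_equal(unique(d$ideal_distance), 2.8)
  o <- which(s$atoms$name == "O")
  co <- unname(as.numeric(s$atoms[o, c("x", "y", "z")]) -
                 as.numeric(s$atoms[s$atoms$name == "C", c("x", "y", "z")]))
  for (r in 1:2) {
    dir <- c(d$dx[r], d$dy[r], d$dz[r])
    ang <- acos(sum(dir * co / sqrt(sum(co^2)))) * 180 / pi
    expect_equal(ang, 60, tolerance = 0.5) # 120 deg from the O->C bond
    expect_lt(abs(dir[3]), 1e-6)           # in the sp2 plane
  }
})

saturating_partner <- function(o_pos, lp_dir, dist = 2.9) {
  pos <- o_pos + dist * lp_dir
  list(kind = "amide", position = pos, direction = -lp_dir)
}

test_that("well-placed partners saturate a carbonyl; bad geometry reopens it", {
  # lone pairs of a +x carbonyl lie at +-60 degrees in the xy plane
  lp1 <- c(cos(pi / 3), sin(pi / 3), 0)
  lp2 <- c(cos(pi / 3), -sin(pi / 3), 0)
  sat <- make_polar_pocket(list(
    list(kind = "carbonyl", position = c(0, 0, 0), direction = c(1, 0, 0)),
    saturating_partner(c(0, 0, 0), lp1),
    saturating_partner(c(0, 0, 0), lp2),
    list(kind = "ligand", position = c(0, 0, 5))))
  p <- extract_pocket(sat, "LIG")
  expect_equal(nrow(find_free_directions(sat, p)), 0)
  expect_length(place_waters(sat, p), 0)
  # same partner rotated 25 degrees off-axis: geometric score 0.58 < 0.85
  bad_dir <- c(cos(pi / 3 + 25 * pi / 180), sin(pi / 3 + 25 * pi / 180), 0)
  bad <- make_polar_pocket(list(
    list(kind = "carbonyl", position = c(0, 0, 0), direction = c(1, 0, 0)),
    saturating_partner(c(0, 0, 0), bad_dir),
    list(kind = "ligand", position = c(0, 0, 5))))
  pb <- extract_pocket(bad, "LIG")
  db <- find_free_directions(bad, pb)
  expect_gte(nrow(db), 1)
})

test_that("candidates sit at the ideal hydrogen-bond distances", {
  dirs <- rbind(
    direction_obj(c(0, 0, 0), c(1, 0, 0), "donor-to-water", 2.6),
    direction_obj(c(5, 0, 0), c(0, 1, 0), "acceptor-to-water", 2.8))
  cands <- generate_candidates(dirs)
  expect_equal(nrow(cands), 2)
  expect_equal(as.numeric(cands[1, c("x", "y", "z")]), c(2.6, 0, 0))
  expect_equal(as.numeric(cands[2, c("x", "y", "z")]), c(5, 2.8, 0))
  expect_equal(nrow(generate_candidates(dirs[0, ])), 0)
})

test_that("steric filtering removes blocked candidates, boundary closed", {
  blocker <- function(dist) {
    parse_pdb(sprintf(
      "HETATM    1  C1  LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00           C",
      2.6 + dist, 0, 0))
  }
  dirs <- direction_obj(c(0, 0, 0), c(1, 0, 0), "donor-to-water", 2.6, atom = NA)
  cands <- generate_candidates(dirs)
  expect_equal(nrow(filter_available(cands, blocker(3.0), dirs)), 1)
  expect_equal(nrow(filter_available(cands, blocker(1.5), dirs)), 0)
  expect_equal(nrow(filter_available(cands, blocker(2.2), dirs)), 1)
  expect_equal(nrow(filter_available(cands, blocker(2.199), dirs)), 0)
})

test_that("self-assembly merges nearby candidates and keeps distant ones", {
  # one candidate: fixed point of the mean shift
  d1 <- direction_obj(c(0, 0, 0), c(1, 0, 0))
  w1 <- self_assemble(generate_candidates(d1), d1)
  expect_length(w1, 1)
  expect_equal(w1[[1]]$position, c(2.8, 0, 0), tolerance = 1e-9)
  # donor/acceptor pair whose ideal points are 0.4 A apart -> one water
  dirs <- rbind(
    direction_obj(c(0, 0, 0), c(1, 0, 0), "donor-to-water", 2.6, atom = 1L),
    direction_obj(c(5.8, 0, 0), c(-1, 0, 0), "acceptor-to-water", 2.8, atom = 4L))
  merged <- self_assemble(generate_candidates(dirs), dirs)
  expect_length(merged, 1)
  expect_equal(nrow(merged[[1]]$partners), 2)
  expect_true(merged[[1]]$position[1] > 2.6 && merged[[1]]$position[1] < 3.0)
  # far-apart candidates stay separate
  far <- rbind(
    direction_obj(c(0, 0, 0), c(1, 0, 0), atom = 1L),
    direction_obj(c(10, 0, 0), c(1, 0, 0), atom = 2L))
  expect_length(self_assemble(generate_candidates(far), far), 2)
})

test_that("position optimization is an ascent and respects ideal geometry", {
  s <- parse_pdb(
    "ATOM      1  CA  GLY A   1      20.000  20.000  20.000  1.00  0.00           C")
  dirs <- direction_obj(c(0, 0, 0), c(1, 0, 0), atom = NA)
  at_opt <- self_assemble(generate_candidates(dirs), dirs)
  res <- optimize_positions(at_opt, dirs, s)
  expect_equal(res[[1]]$position, c(2.8, 0, 0), tolerance = 1e-3)
  # displaced off-axis: quality strictly increases and lands on the ideal band
  w <- at_opt
  w[[1]]$position <- w[[1]]$position + c(0.05, 0.3, 0)
  w[[1]] <- sitegeom:::make_water(w[[1]]$position, w[[1]]$source_dirs, dirs)
  q0 <- w[[1]]$average_quality
  res2 <- optimize_positions(w, dirs, s)
  expect_gt(res2[[1]]$average_quality, q0)
  d <- sqrt(sum(res2[[1]]$position^2))
  expect_gte(d, 2.6 - 1e-2)
  expect_lte(d, 2.8 + 1e-2)
})

test_that("the second round adds water-water partners but never removes waters", {
  expect_length(second_iteration(list(), make_metal_site("linear"), NULL), 0)
  s <- make_polar_pocket(list(
    list(kind = "carbonyl", position = c(0, 0, 0), direction = c(1, 0, 0)),
    list(kind = "ligand", position = c(3.5, 4, 0))))
  p <- extract_pocket(s, "LIG")
  dirs <- find_free_directions(s, p)
  first <- optimize_positions(self_assemble(
    sitegeom::filter_available(generate_candidates(dirs), s, dirs), dirs), dirs, s)
  more <- second_iteration(first, s, p)
  expect_gte(length(more), length(first))
  for (k in seq_along(first)) {
    expect_equal(more[[k]]$position, first[[k]]$position)
  }
  added <- more[-seq_along(first)]
  expect_gt(length(added), 0) # open cavity: room at 2.8 A
  for (w in added) {
    expect_true(all(!is.na(w$partners$wsrc)))
    expect_gte(w$average_quality, 0.6)
    src_pos <- first[[w$partners$wsrc[1]]]$position
    expect_equal(sqrt(sum((w$position - src_pos)^2)), 2.8, tolerance = 0.05)
  }
})

test_that("crystallographic-water matching is a nearest-neighbor argmin", {
  w <- list(structure(list(position = c(0, 0, 0), average_quality = 1,
                           partners = data.frame(atom = 1L, wsrc = NA, quality = 1)),
                      class = "sg_water"))
  no_hoh <- make_metal_site("linear")
  expect_null(match_crystal_waters(w, no_hoh)[[1]]$nearest_xray)
  hoh_lines <- vapply(seq_len(3), function(i) {
    sprintf("HETATM%5d  O   HOH A%4d    %8.3f%8.3f%8.3f  1.00  0.00           O",
            i, i, c(0.7, 2.5, 4)[i], 0, 0)
  }, character(1))
  s <- parse_pdb(hoh_lines)
  m <- match_crystal_waters(w, s)[[1]]$nearest_xray
  expect_equal(m$distance, 0.7, tolerance = 1e-9)
  expect_equal(s$atoms$resno[m$atom], 1L)
  # brute-force argmin over several placed waters
  ws <- lapply(list(c(1, 1, 0), c(3.1, 0, 0), c(5, -2, 1)), function(p) {
    structure(list(position = p, average_quality = 1,
                   partners = data.frame(atom = 1L, wsrc = NA, quality = 1)),
              class = "sg_water")
  })
  got <- match_crystal_waters(ws, s)
  hoh_xyz <- coords(s)[water_atoms(s), ]
  for (k in seq_along(ws)) {
    dists <- sqrt(rowSums(sweep(hoh_xyz, 2, ws[[k]]$position)^2))
    expect_equal(got[[k]]$nearest_xray$distance, min(dists), tolerance = 1e-9)
  }
})

test_that("full placement is deterministic and clash-free", {
  s <- donor_acceptor_pocket()
  p <- extract_pocket(s, "LIG")
  w1 <- place_waters(s, p)
  w2 <- place_waters(s, p)
  expect_equal(w1, w2)
  expect_gt(length(w1), 0)
  heavy <- which(s$atoms$element != "H")
  for (w in w1) {
    partner_atoms <- w$partners$atom[!is.na(w$partners$atom)]
    others <- setdiff(heavy, partner_atoms)
    dmin <- min(sqrt(rowSums(sweep(coords(s)[others, , drop = FALSE],
                                   2, w$position)^2)))
    expect_gte(dmin, 2.2)
    expect_true(all(w$partners$quality > 0))
    expect_gte(w$average_quality, 0)
    expect_lte(w$average_quality, 1)
    expect_equal(w$average_quality, mean(w$partners$quality), tolerance = 1e-9)
  }
})

test_that("placements rotate covariantly with the input structure", {
  s <- donor_acceptor_pocket()
  p <- extract_pocket(s, "LIG")
  w <- place_waters(s, p)
  R <- rotation_matrix(c(2, -1, 1), 0.8)
  t <- c(3, 4, -5)
  s2 <- transform_structure(s, R, t)
  p2 <- extract_pocket(s2, "LIG")
  w2 <- place_waters(s2, p2)
  expect_equal(length(w2), length(w))
  pos1 <- do.call(rbind, lapply(w, `[[`, "position"))
  pos2 <- do.call(rbind, lapply(w2, `[[`, "position"))
  moved <- pos1 %*% t(R) + matrix(t, nrow(pos1), 3, byrow = TRUE)
  # match waters by nearest neighbor (cluster order may differ); positions on
  # a quality plateau are optimizer-path dependent within its tolerance
  for (k in seq_len(nrow(moved))) {
    expect_lt(min(sqrt(rowSums(sweep(pos2, 2, moved[k, ])^2))), 5e-3)
  }
})

test_that("a pocket with no polar atoms yields no waters", {
  s <- make_polar_pocket(list(
    list(kind = "wall", position = c(0, 0, 0)),
    list(kind = "wall", position = c(4, 0, 0)),
    list(kind = "ligand", position = c(2, 2, 0))))
  p <- extract_pocket(s, "LIG")
  expect_length(place_waters(s, p), 0)
})
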