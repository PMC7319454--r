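test_that("coordination-sphere detection filters by element and radius", {
  s <- make_metal_site("tetrahedral", bond_length = 2.1)
  site <- detect_coordination_sphere(s, metal_atoms(s)[1])
  expect_length(site$partners, 4)
  expect_equal(site$distances, rep(2.1, 4), tolerance = 2e-3)
  expect_false(site$empty)
  # a carbon 2.0 A away is not a partner; an isolated metal is empty-flagged
  lines <- c(
    "HETATM    1 ZN    ZN A   1       0.000   0.000   0.000  1.00  0.00          ZN",
    "HETATM    2  C1  LIG A   2       2.000   0.000   0.000  1.00  0.00           C")
  s2 <- parse_pdb(lines)
  site2 <- detect_coordination_sphere(s2, 1)
  expect_true(site2$empty)
  expect_length(site2$partners, 0)
  expect_error(detect_coordination_sphere(s2, 2), "not flagged metallic")
})

test_that("a chelating acetate contributes two partners and one bidentate group", {
  lines <- c(
    "HETATM    1 ZN    ZN A   1       0.000   0.000   0.000  1.00  0.00          ZN",
    "HETATM    2  C   ACT A   2       2.900   0.000   0.000  1.00  0.00           C",
    "HETATM    3  O1  ACT A   2       2.200   1.000   0.000  1.00  0.00           O",
    "HETATM    4  O2  ACT A   2       2.400  -1.100   0.000  1.00  0.00           O",
    "HETATM    5  CH3 ACT A   2       4.400   0.100   0.000  1.00  0.00           C")
  s <- parse_pdb(lines)
  site <- detect_coordination_sphere(s, 1)
  expect_length(site$partners, 2)
  expect_length(site$bidentate_groups, 1)
  expect_setequal(s$atoms$name[site$bidentate_groups[[1]]], c("C", "O1", "O2"))
})

test_that("angle-list prescreen ranks the generating geometry first", {
  lib <- builtin_geometries()
  s <- make_metal_site("tetrahedral")
  site <- detect_coordination_sphere(s, metal_atoms(s)[1])
  sc <- prescreen_geometries(site, s, lib, top_k = length(lib))
  expect_equal(sc$geometry[1], "tetrahedral")
  expect_lt(sc$angle_rmsd[1], 1e-6)
  expect_gt(sc$angle_rmsd[sc$geometry == "square-planar"], 10)
})

test_that("prescreen angle RMSDs match exhaustive subset enumeration", {
  lib <- builtin_geometries()
  for (seed in 1:4) {
    s <- make_metal_site("tetrahedral", jitter_sigma = 0.15, seed = seed)
    site <- detect_coordination_sphere(s, metal_atoms(s)[1])
    sc <- prescreen_geometries(site, s, lib, top_k = length(lib))
    mx <- as.numeric(s$atoms[site$metal, c("x", "y", "z")])
    site_angles <- oracle_angle_list(coords(s)[site$partners, ], mx)
    for (r in seq_len(nrow(sc))) {
      expect_equal(sc$angle_rmsd[r],
                   oracle_subset_angle_rmsd(site_angles,
                                            lib[[sc$geometry[r]]]$vertices,
                                            length(site$partners)),
                   tolerance = 1e-9)
    }
    expect_false(is.unsorted(sc$angle_rmsd))
  }
})

test_that("superposition is exact for ideal sites and their subsets", {
  lib <- builtin_geometries()
  s <- make_metal_site("tetrahedral", bond_length = 2.3)
  site <- detect_coordination_sphere(s, metal_atoms(s)[1])
  asg <- superpose_to_geometry(site, lib$tetrahedral, s)
  expect_lt(asg$rmsd, 1e-6)
  expect_equal(asg$free_sites, 0)
  # one vertex deleted: still an exact tetrahedral subset, one free site
  s3 <- make_metal_site("tetrahedral", delete_vertices = 1)
  site3 <- detect_coordination_sphere(s3, metal_atoms(s3)[1])
  asg3 <- superpose_to_geometry(site3, lib$tetrahedral, s3)
  expect_lt(asg3$rmsd, 1e-6)
  expect_equal(asg3$free_sites, 1)
})

test_that("superposition equals brute-force correspondence enumeration", {
  lib <- builtin_geometries()
  geoms <- c("tetrahedral", "trigonal-bipyramidal", "octahedral")
  for (seed in 1:6) {
    gname <- geoms[(seed %% 3) + 1]
    s <- make_metal_site(gname, jitter_sigma = 0.2, seed = seed,
                         delete_vertices = seed %% 2)
    site <- detect_coordination_sphere(s, metal_atoms(s)[1])
    mx <- as.numeric(s$atoms[site$metal, c("x", "y", "z")])
    P <- sweep(coords(s)[site$partners, , drop = FALSE], 2, mx)
    for (ref in c("tetrahedral", "trigonal-bipyramidal")) {
      if (lib[[ref]]$coordination_number < length(site$partners)) next
      asg <- superpose_to_geometry(site, lib[[ref]], s)
      expect_equal(asg$rmsd,
                   oracle_best_rmsd(P, site$distances, lib[[ref]]$vertices),
                   tolerance = 1e-9)
    }
  }
})

test_that("superposition rmsd is invariant under rigid motions", {
  lib <- builtin_geometries()
  s <- make_metal_site("square-pyramidal", jitter_sigma = 0.1, seed = 3)
  site <- detect_coordination_sphere(s, metal_atoms(s)[1])
  base <- superpose_to_geometry(site, lib$`square-pyramidal`, s)$rmsd
  R <- rotation_matrix(c(1, 2, 3), 1.1)
  s2 <- transform_structure(s, R, c(5, -7, 2))
  site2 <- detect_coordination_sphere(s2, metal_atoms(s2)[1])
  moved <- superpose_to_geometry(site2, lib$`square-pyramidal`, s2)$rmsd
  expect_equal(moved, base, tolerance = 1e-6)
})

test_that("overlap penalty implements normalized linear clash depth", {
  lib <- builtin_geometries()
  # 3 partners assigned to a tetrahedral reference -> one free vertex
  s <- make_metal_site("tetrahedral", delete_vertices = 1)
  site <- detect_coordination_sphere(s, metal_atoms(s)[1])
  asg <- superpose_to_geometry(site, lib$tetrahedral, s)
  free_vertex <- asg$fitted_vertices[
    setdiff(seq_len(asg$cn), asg$correspondence), ]
  # no atom near the free site -> zero penalty
  expect_equal(overlap_penalty(s, site, asg), 0)
  # full assignment -> empty sum
  s0 <- make_metal_site("tetrahedral")
  site0 <- detect_coordination_sphere(s0, metal_atoms(s0)[1])
  asg0 <- superpose_to_geometry(site0, lib$tetrahedral, s0)
  expect_equal(overlap_penalty(s0, site0, asg0), 0)
  # place a carbon exactly at contact distance, then at half of it
  lim <- 1.4 + 1.7
  for (f in c(1, 0.5)) {
    probe_dir <- free_vertex / sqrt(sum(free_vertex^2))
    cpos <- free_vertex + probe_dir * lim * f - probe_dir * 0 # radial offset
    cpos <- free_vertex + c(lim * f, 0, 0)
    extra <- sprintf(
      "HETATM   99  C9  LIG A  99    %8.3f%8.3f%8.3f  1.00  0.00           C",
      cpos[1], cpos[2], cpos[3])
    s2 <- parse_pdb(c(strsplit(write_pdb(s), "\n")[[1]][1:4], extra))
    site2 <- detect_coordination_sphere(s2, metal_atoms(s2)[1])
    asg2 <- superpose_to_geometry(site2, lib$tetrahedral, s2)
    # same free vertex up to parsing precision
    pen <- overlap_penalty(s2, site2, asg2)
    expect_equal(pen, 1 - f, tolerance = 2e-3)
  }
})

test_that("the score is linear with published-calibration coefficients", {
  expect_equal(score_assignment(0, 0, 0), 0)
  expect_equal(score_assignment(0.190, 0, 0), 9.5)
  expect_equal(score_assignment(0.173, 1, 0), 12.65)
  # strictly increasing in each argument
  base <- score_assignment(0.2, 1, 0.1)
  expect_gt(score_assignment(0.25, 1, 0.1), base)
  expect_gt(score_assignment(0.2, 2, 0.1), base)
  expect_gt(score_assignment(0.2, 1, 0.2), base)
  expect_error(score_assignment(-0.1, 0, 0))
})

test_that("ideal fixtures are assigned their generating geometry at rank 1", {
  s <- make_metal_site("octahedral")
  ranked <- assign_geometries(s, metal_atoms(s)[1])
  expect_equal(ranked[[1]]$geometry, "octahedral")
  expect_lt(ranked[[1]]$rmsd, 1e-9)
  expect_equal(ranked[[1]]$free_sites, 0)
})

test_that("an ideal tetrahedral site yields the published candidate pattern", {
  # candidates of CN 4, 5 and 6 with free sites 0, 1 and 2
  s <- make_metal_site("tetrahedral")
  ranked <- assign_geometries(s, metal_atoms(s)[1], top_k = 10, prescreen_k = 10)
  cn <- vapply(ranked, `[[`, integer(1), "cn")
  free <- vapply(ranked, `[[`, integer(1), "free_sites")
  expect_equal(ranked[[1]]$geometry, "tetrahedral")
  expect_true(all(c(4L, 5L, 6L) %in% cn))
  expect_equal(free[match(c(4L, 5L, 6L), cn)], c(0L, 1L, 2L))
  n <- length(detect_coordination_sphere(s, metal_atoms(s)[1])$partners)
  expect_equal(free, cn - n)
})

test_that("a vertex-deleted tetrahedron keeps an exact tetrahedral candidate", {
  s <- make_metal_site("tetrahedral", delete_vertices = 1)
  ranked <- assign_geometries(s, metal_atoms(s)[1], top_k = 5)
  # rank 1 is the simpler exact-fit trigonal pyramid (free sites 0, score 0);
  # the tetrahedral assignment is present with one free site and rmsd ~ 0
  expect_equal(ranked[[1]]$geometry, "trigonal-pyramidal")
  expect_lt(ranked[[1]]$rmsd, 1e-9)
  tet <- Filter(function(a) a$geometry == "tetrahedral", ranked)
  expect_length(tet, 1)
  expect_equal(tet[[1]]$free_sites, 1)
  expect_lt(tet[[1]]$rmsd, 1e-9)
})

test_that("rank-1 rmsd grows with coordinate noise", {
  mean_rmsd <- function(sigma) {
    vals <- vapply(1:50, function(seed) {
      s <- make_metal_site("tetrahedral", jitter_sigma = sigma, seed = 1000 + seed)
      site <- detect_coordination_sphere(s, metal_atoms(s)[1])
      superpose_to_geometry(site, builtin_geometries()$tetrahedral, s)$rmsd
    }, numeric(1))
    mean(vals)
  }
  m <- vapply(c(0.05, 0.1, 0.2), mean_rmsd, numeric(1))
  expect_true(all(diff(m) > 0))
})
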