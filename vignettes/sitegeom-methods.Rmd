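---
title: "Geometric models behind sitegeom: metal coordination assignment and water placement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric models behind sitegeom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitegeom)
```

sitegeom analyzes protein–ligand binding interfaces at the level of simple,
interpretable geometry: which ideal coordination polyhedron a metal site
realizes, and where water molecules can form good hydrogen bonds. This
vignette explains the two models, every tunable parameter, what the
synthetic fixtures emulate, and the numerical choices made where the design
was genuinely open.

## Structures, perception and pockets

Input is PDB-format text. Only single-conformer content is kept (alternate
location indicator blank or `A`); hydrogens present in the input are carried
in the atom table but ignored by all perception, since protonation is
outside the package's scope and every rule below is defined on heavy atoms.
Covalent bonds are perceived with a distance criterion, $d \le 1.3\,(r_i +
r_j)$ on covalent radii, applied within residues plus backbone peptide C–N
links; this is robust at typical crystallographic coordinate precision.

Binding pockets follow the ligand-centric convention used across
structure-based design: a residue belongs to the pocket of a ligand if any
of its atoms lies within **6.5 Å** (boundary inclusive) of any ligand atom.
The radius is a parameter (`pocket_radius`), 6.5 Å by default. Waters and
other het groups are never pocket members. Small molecules up to 8.0 Å from
the protein are considered ligand candidates (`ligand_distance`).

Hydrogen-bond roles come from residue/atom-name templates for the twenty
standard amino acids (backbone O: acceptor, capacity 2, sp2; backbone N:
donor, capacity 1, sp2; side chains per chemistry; water: both, capacity 4)
with connectivity-based fallback rules for het groups and unknown residues.
Carbon, sulfur and metal atoms never receive a role: only N and O carry the
hydrogen-bond functions modeled here. Carboxylates — a carbon bonded to
exactly two terminal oxygens — are detected once and reused both as sp2
acceptor templates and as potential bidentate metal ligands.

## Metal coordination geometry

A metal's **coordination sphere** is every O, N, S or Cl atom within an
element-specific radius: 2.8 Å for transition metals (Zn, Fe, Cu, Ni, Co,
Mn, …), 3.0 Å for Mg/Ca and other alkaline earths, 3.4 Å for alkali metals,
and 3.0 Å otherwise. These spans cover typical metal–O/N bond lengths plus
tolerance and are overridable per element via a JSON table. Both oxygens of
a chelating carboxylate count as independent partners; the group is
annotated as a bidentate rather than being collapsed, because no further
rule (e.g. a shared virtual vertex) is defensible without side information.

Candidate geometries come from a built-in library of fourteen ideal
polyhedra, CN 2–8: linear, bent (tetrahedral angle), trigonal planar,
trigonal pyramidal (a tetrahedron minus one vertex), T-shaped, tetrahedral,
square planar, trigonal bipyramidal, square pyramidal (an octahedron minus
one vertex), octahedral, trigonal prismatic (square side faces), pentagonal
bipyramidal, square antiprismatic (equal edges, rings rotated 45°) and
cubic. Each stores unit vertex vectors and its sorted list of
vertex–metal–vertex angles. Users can extend the library from JSON.

Assignment proceeds in three stages:

1. **Angle-list pre-screen.** The site's sorted pairwise angle list is
   compared against the angle list of every same-size vertex subset of each
   geometry with CN at least the partner count; geometries are ranked by
   the minimum RMSD over subsets and the best five (`prescreen_k`) go
   forward. The fingerprint is rotation-free, so this is cheap and never
   discards an exact fit. Subset comparison (rather than padding the site)
   is used because missing partners are exactly what free coordination
   sites describe. With fewer than two partners no angles exist and all
   size-compatible geometries pass.
2. **Superposition.** For each candidate, every injective correspondence of
   partners to reference vertices is enumerated (at most $8! = 40320$ maps,
   evaluated in compiled code), the reference vertices are radially scaled
   to the matched partner's observed metal distance, and the proper
   rotation about the metal minimizing the summed squared deviation is
   found by SVD (Kabsch). The reported **distance RMSD** therefore measures
   angular distortion in Å at the observed bond lengths: it is exactly zero
   for an ideal site at any bond length, and a near-ideal zinc site at
   ~2.1 Å bonds lands in the 0.2 Å range.
3. **Scoring.** $\mathrm{score} = 50\,\mathrm{rmsd} + 4\,\mathrm{free} +
   50\,\mathrm{overlap}$, lower is better. Free sites are unmatched
   vertices (CN minus partners), implementing the preference for simple
   geometries. The overlap term places a 1.4 Å probe (a water-sized
   would-be partner) at each free vertex, at the mean observed bond length,
   and sums the normalized linear clash depth $\max(0, (r_p + r_{vdw} -
   d)/(r_p + r_{vdw}))$ over non-partner heavy atoms. The linear form of
   the score is the package's own choice — published tool outputs name the
   three ingredients and print example triples but not a formula — and the
   coefficients were fixed once by solving the linear system those printed
   triples define. All three coefficients are configurable
   (`score_coefficients`). Ties break toward smaller CN, then geometry
   name, for determinism.

A consequence worth knowing: a site that is an exact subset of a larger
ideal geometry (three vertices of a tetrahedron, five of an octahedron) is
ranked under the *smaller* exact-fit geometry first, because the free-site
term penalizes the larger completion. The larger candidates still appear in
the ranked list with their free-site counts.

## Water placement

The model predicts oxygen positions only; hydrogen orientation is out of
scope. Crystallographic waters in the input are treated as reference
observations throughout — they seed no directions, satisfy no donors and
block no candidates — because they are exactly what the method predicts;
each placed water is annotated with its nearest crystallographic water
when any exist.

1. **Free interaction directions.** Each polar atom of the pocket (and of
   the ligand) emits ideal directions from heavy-atom templates: sp2 atoms
   in the plane of their substituents at 120° from the bonds, sp3 atoms at
   tetrahedral completions of their bonded directions. The torsional
   reference for a one-neighbor sp3 atom is taken covariantly from the
   neighbor's own substituents, so output rotates with the input. A
   direction is emitted only if its atom is unsaturated (fewer well-placed
   partners than capacity) or has a badly placed partner, and no existing
   partner already sits within the saturation score on that direction. An
   existing partner is a complementary polar atom within 3.5 Å (same
   residue and 1-2/1-3 neighbors excluded).
2. **Geometric score.** A point's score against a direction falls linearly
   from 1 on-axis to 0 at 60° deviation. Only the deviation-angle
   dependence of the published score is documented; the linear-to-60° form
   is the package's choice, under which the conventional **0.85**
   saturation threshold corresponds to a ≈9° tolerance.
3. **Candidates** are spawned at the ideal hydrogen-bond distances:
   **2.6 Å** for water accepting from a donor, **2.8 Å** for water donating
   to an acceptor. The two published distances come without an explicit
   mapping; this assignment (donor contacts slightly shorter) follows
   small-molecule hydrogen-bond statistics and is configurable. For atoms
   of role "both", template directions are split with
   $\lfloor\mathrm{capacity}/2\rfloor$ donor-type directions first.
4. **Availability.** Candidates with any non-source heavy atom nearer than
   **2.2 Å** are discarded (closed boundary: a contact at exactly 2.2 Å
   survives).
5. **Self-assembly.** Candidates move iteratively to the score-weighted
   centroid of candidates within **1.0 Å**, scores re-evaluated as they
   move (weights floored at 0.05 so a zero-scored candidate cannot drop
   out of its own average), until the largest displacement is below
   **0.01 Å** or 100 iterations. Shifted candidates merge by single
   linkage at **0.5 Å**; each cluster becomes one water at the weighted
   centroid, with one partner entry per contributing source atom. Pair
   quality is the angular score times a distance quality that is 1 on
   [2.6, 2.8] Å and falls linearly to 0 at 2.2 and 3.6 Å.
6. **Optimization.** Each water's average pair quality is maximized by
   Nelder–Mead under the 2.2 Å clash constraint (steep penalty). Waters
   already within numerical noise of quality 1 are left untouched — the
   quality surface is flat on the ideal band, and walking the plateau
   would only add jitter. If the optimizer worsens the objective or exits
   the feasible region the previous position is kept and the water
   flagged.
7. **Second round.** Placed waters become polar atoms (role both, capacity
   4); their free tetrahedral completions (torsion referenced to the
   partner's neighborhood, again for covariance) spawn water–water
   candidates at 2.8 Å, which run once more through filtering, assembly
   and optimization. New waters need average quality ≥ **0.6** and no
   clash; first-round waters are never removed, and exactly one extra
   round is run.

The clustering radii, the convergence threshold, the second-round
acceptance quality and the clash cutoff are not documented for the
published tool; the defaults above are exposed in `default_config()` and
were chosen once on geometric grounds (half a coordination-sphere step for
merging, a tenth of it for convergence, the midpoint of the quality scale
for acceptance).

## Ensemble statistics

Over any set of structures — a directory of PDB files — the package counts
rank-1 geometry assignments per metal element (fractions normalized per
metal) and histograms all metal–partner distances by (metal element,
partner element) in half-open **0.1 Å** bins. Both tables are additive over
disjoint structure sets, which the tests exercise directly. Statistics are
computed over user-supplied files rather than a live database; the
computation is identical whatever the source of the ensemble.

## Synthetic fixtures and what passing means

`make_metal_site()` builds a metal at the origin with one oxygen partner
per vertex of a chosen reference geometry at a given bond length (2.1 Å
default, a typical Zn–O distance), plus isotropic Gaussian jitter of
standard deviation $\sigma$ per coordinate from a seeded, self-contained
RNG stream. In-memory coordinates are kept at full precision; serialization
rounds to the PDB format's three decimals, and fixtures are byte-identical
per seed. `make_polar_pocket()` assembles rigid donor/acceptor fragments,
inert carbon walls, planted crystallographic waters and a one-atom dummy
ligand at prescribed positions, refusing recipes whose fragments come
within 1.5 Å.

The test conditions are: exact recovery (rank 1, rmsd ≤ 1e-6, zero free
sites) for all fourteen unjittered fixtures; agreement to 1e-9 with a
brute-force correspondence enumeration on one hundred jittered 3–5-partner
sites; ≥ 90 % rank-1 recovery over 200 fixtures per geometry at
$\sigma = 0.1$ Å; exact ideal hydrogen-bond distances on an unobstructed
donor/acceptor pocket; and recovery of the 6.5 Å pocket rule by bisection.
These fixtures emulate coordination-sphere geometry and isolated
hydrogen-bond environments with isotropic noise. They do not emulate
correlated anisotropic displacement, partial occupancy, alternate
conformers, unresolved protonation, or the crowding of a real active site,
so passing them demonstrates correctness of the geometric engines, not
crystallographic accuracy on real data.

## Numerical choices and known limitations

* Correspondence search is exhaustive for every CN ≤ 8; no heuristic is
  involved, so the reported RMSD is the global minimum over proper
  rotations and correspondences. Reflections are excluded (proper
  rotations only), as superposing a site onto a reference of opposite
  chirality is chemically meaningless.
* Degenerate inputs: a coordinating atom exactly at the metal position or
  a direction of zero length raise errors; an empty coordination sphere
  returns a flagged empty result, not an exception; a pocket with no polar
  atoms yields zero waters.
* Positions of waters on flat quality plateaus are defined up to the
  optimizer's tolerance; under a rigid motion of the input, outputs agree
  to ~1e-3 Å rather than machine precision when a plateau is involved.
* Atoms with no bonded neighbor and no partners (an isolated non-water
  polar het atom) fall back to a fixed-frame tetrahedral template, which
  is the one deliberate covariance exception.
* The reference library covers CN ≤ 8; higher coordination numbers and
  continuous shape measures (distortion interpolation) are out of scope,
  as are electron-density support values, protonation and metal identity
  prediction.

## Reproducing the headline numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates every fixture
set, runs the engines and writes the measured quantities (identity rate,
oracle deviation, recovery rate, realized hydrogen-bond distances, pocket
cutoff) as JSON; the README shows a worked example with the numbers the
code prints.
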