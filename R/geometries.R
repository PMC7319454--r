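# Built-in library of ideal coordination polyhedra.
#
# Each reference geometry stores unit vectors from the metal to its ideal
# vertices plus the sorted multiset of vertex-metal-vertex angles, which is
# used as an orientation-free fingerprint in the pre-screen.

reference_geometry <- function(name, vertices) {
  vertices <- t(apply(vertices, 1, unitv))
  g <- structure(list(
    name = name,
    coordination_number = nrow(vertices),
    vertices = vertices,
    angle_list = angle_list_of(rows_list(vertices), c(0, 0, 0))
  ), class = "sg_geometry")
  g
}

#' @export
print.sg_geometry <- function(x, ...) {
  cat(sprintf("sg_geometry '%s' (CN %d)\n", x$name, x$coordination_number))
  invisible(x)
}

#' Sorted angle list of a point set about a center
#'
#' Computes all pairwise vertex-center-vertex angles in degrees, sorted
#' ascending. This fingerprint is rotation-invariant and is compared against
#' the reference geometries' angle lists during candidate pre-screening.
#'
#' @param points List of 3-vectors (or an n x 3 matrix).
#' @param center 3-vector.
#' @return Sorted numeric vector of \code{choose(n, 2)} angles in degrees.
#' @export
angle_list_of <- function(points, center = c(0, 0, 0)) {
  if (is.matrix(points)) points <- rows_list(points)
  if (length(points) < 2) stop("need at least 2 points")
  v <- lapply(points, function(p) {
    d <- p - center
    if (vnorm(d) < 1e-9) stop("degenerate site: point coincides with center")
    d
  })
  n <- length(v)
  out <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) out <- c(out, angle_deg(v[[i]], v[[j]]))
  }
  sort(out)
}

.build_geometries <- function() {
  s3 <- sqrt(3)
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / s3
  eq3 <- rbind(c(1, 0, 0), c(-0.5, s3 / 2, 0), c(-0.5, -s3 / 2, 0))
  eq5 <- t(vapply(0:4, function(k) {
    th <- 2 * pi * k / 5
    c(cos(th), sin(th), 0)
  }, numeric(3)))
  bent_half <- acos(-1 / 3) / 2 # half the tetrahedral angle
  # trigonal prism with square side faces: 2h = sqrt(3) * r
  rp <- 2 / sqrt(7); hp <- sqrt(3) / sqrt(7)
  prism_ring <- function(z, phi0, r) t(vapply(0:2, function(k) {
    th <- phi0 + 2 * pi * k / 3
    c(r * cos(th), r * sin(th), z)
  }, numeric(3)))
  # square antiprism with equal edges: h^2 = (sqrt(2)/4) r^2
  ra <- 1 / sqrt(1 + sqrt(2) / 4); ha <- ra * sqrt(sqrt(2) / 4)
  sq_ring <- function(z, phi0, r) t(vapply(0:3, function(k) {
    th <- phi0 + pi * k / 2
    c(r * cos(th), r * sin(th), z)
  }, numeric(3)))

  list(
    reference_geometry("linear", rbind(c(0, 0, 1), c(0, 0, -1))),
    reference_geometry("bent", rbind(
      c(sin(bent_half), 0, cos(bent_half)),
      c(-sin(bent_half), 0, cos(bent_half)))),
    reference_geometry("trigonal-planar", eq3),
    reference_geometry("trigonal-pyramidal", tet[1:3, ]),
    reference_geometry("t-shaped", rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0))),
    reference_geometry("tetrahedral", tet),
    reference_geometry("square-planar", rbind(
      c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))),
    reference_geometry("trigonal-bipyramidal", rbind(eq3, c(0, 0, 1), c(0, 0, -1))),
    reference_geometry("square-pyramidal", rbind(
      c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1))),
    reference_geometry("octahedral", rbind(
      c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))),
    reference_geometry("trigonal-prismatic", rbind(
      prism_ring(hp, 0, rp), prism_ring(-hp, 0, rp))),
    reference_geometry("pentagonal-bipyramidal", rbind(eq5, c(0, 0, 1), c(0, 0, -1))),
    reference_geometry("square-antiprismatic", rbind(
      sq_ring(ha, 0, ra), sq_ring(-ha, pi / 4, ra))),
    reference_geometry("cubic", rbind(tet * s3, -tet * s3) / s3)
  )
}

.geometry_cache <- new.env(parent = emptyenv())

#' Built-in ideal coordination geometries
#'
#' Returns the reference library of ideal coordination polyhedra (CN 2-8):
#' linear, bent (tetrahedral angle), trigonal planar, trigonal pyramidal,
#' T-shaped, tetrahedral, square planar, trigonal bipyramidal, square
#' pyramidal, octahedral, trigonal prismatic, pentagonal bipyramidal, square
#' antiprismatic and cubic. Each entry carries unit vertex vectors and the
#' sorted pairwise angle list.
#'
#' @return A named list of \code{sg_geometry} objects.
#' @export
builtin_geometries <- function() {
  if (is.null(.geometry_cache$lib)) {
    lib <- .build_geometries()
    names(lib) <- vapply(lib, `[[`, character(1), "name")
    .geometry_cache$lib <- lib
  }
  .geometry_cache$lib
}

#' Load additional reference geometries from JSON
#'
#' The file must contain an array of objects with fields \code{name} and
#' \code{vertices} (array of 3-vectors); vertices are normalized on load and
#' the angle list recomputed.
#'
#' @param path Path to a JSON file.
#' @return A named list of \code{sg_geometry} objects.
#' @export
load_geometries <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lib <- lapply(spec, function(g) {
    v <- do.call(rbind, lapply(g$vertices, unlist))
    reference_geometry(g$name, v)
  })
  names(lib) <- vapply(lib, `[[`, character(1), "name")
  lib
}

#' Serialize a geometry library to JSON
#'
#' @param lib A list of \code{sg_geometry} objects.
#' @param path Optional output path.
#' @return JSON string (invisibly when written to a file).
#' @export
geometries_to_json <- function(lib, path = NULL) {
  x <- lapply(unname(lib), function(g) list(
    name = g$name, coordination_number = g$coordination_number,
    vertices = apply(g$vertices, 1, function(v) v, simplify = FALSE)))
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
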