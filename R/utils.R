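# Small 3-vector helpers shared by the geometry engines.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

# Angle in degrees between two 3-vectors.
angle_deg <- function(a, b) {
  ca <- sum(a * b) / (vnorm(a) * vnorm(b))
  ca <- max(-1, min(1, ca))
  acos(ca) * 180 / pi
}

# A deterministic unit vector perpendicular to u.
perp_vector <- function(u) {
  u <- unitv(u)
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unitv(ref - sum(ref * u) * u)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rows of m (n x 3) to list of vectors.
rows_list <- function(m) lapply(seq_len(nrow(m)), function(i) m[i, ])

# Pairwise Euclidean distances between rows of a (n x 3) and rows of b (m x 3).
cross_dist <- function(a, b) {
  a <- matrix(a, ncol = 3)
  b <- matrix(b, ncol = 3)
  sq <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sq[sq < 0] <- 0
  sqrt(sq)
}

# All injective maps of n items into m slots, as a (count x n) index matrix.
# Cached per (n, m) since the enumeration is reused heavily.
.map_cache <- new.env(parent = emptyenv())

injective_maps <- function(n, m) {
  stopifnot(n >= 1, m >= n)
  key <- paste(n, m, sep = "_")
  if (!is.null(.map_cache[[key]])) return(.map_cache[[key]])
  perm_rec <- function(items) {
    if (length(items) == 1) return(matrix(items, 1, 1))
    out <- do.call(rbind, lapply(seq_along(items), function(i) {
      rest <- perm_rec(items[-i])
      cbind(items[i], rest)
    }))
    out
  }
  subsets <- utils::combn(m, n)
  res <- do.call(rbind, lapply(seq_len(ncol(subsets)), function(j) {
    perm_rec(subsets[, j])
  }))
  .map_cache[[key]] <- res
  res
}

# Run code with a private RNG stream; global .Random.seed is untouched.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
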