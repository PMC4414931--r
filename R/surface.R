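# Geometry helpers ----------------------------------------------------------

# squared Euclidean cross-distance matrix between the rows of P and Q
cross_dist2 <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  d2 <- outer(rowSums(P^2), rowSums(Q^2), `+`) - 2 * tcrossprod(P, Q)
  d2[d2 < 0] <- 0   # numerical noise near zero
  d2
}

row_min <- function(M) {
  if (ncol(M) == 0L) return(rep(Inf, nrow(M)))
  do.call(pmin, as.data.frame(M))
}

coords_matrix <- function(atoms) {
  m <- as.matrix(atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

# Icosphere ------------------------------------------------------------------

# unit icosphere vertices at a given subdivision level (10*4^level + 2 rows),
# memoised per level
icosphere_cache <- new.env(parent = emptyenv())

#' Unit icosphere vertices
#'
#' Vertices of a regular icosahedron subdivided `level` times, with all
#' vertices projected onto the unit sphere. The vertex count is
#' `10 * 4^level + 2` (12, 42, 162, 642, ...). These evenly spaced
#' directions generate the solvent-accessible surface dots.
#'
#' @param level non-negative integer subdivision level.
#' @return numeric matrix with 3 columns (unit vectors).
#' @export
icosphere_vertices <- function(level = 2L) {
  stopifnot(level >= 0L, level == round(level))
  key <- as.character(level)
  if (!is.null(icosphere_cache[[key]])) return(icosphere_cache[[key]])
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t,  0), c( 1,  t,  0), c(-1, -t,  0), c( 1, -t,  0),
    c( 0, -1,  t), c( 0,  1,  t), c( 0, -1, -t), c( 0,  1, -t),
    c( t,  0, -1), c( t,  0,  1), c(-t,  0, -1), c(-t,  0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(level)) {
    mid <- new.env(parent = emptyenv())
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      m <- mid[[key]]
      if (!is.null(m)) return(m)
      p <- v[i, ] + v[j, ]
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      mid[[key]] <- nrow(v)
      nrow(v)
    }
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1L]; b <- f[k, 2L]; c <- f[k, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf[4L * k - 3L, ] <- c(a, ab, ca)
      nf[4L * k - 2L, ] <- c(b, bc, ab)
      nf[4L * k - 1L, ] <- c(c, ca, bc)
      nf[4L * k, ]      <- c(ab, bc, ca)
    }
    f <- nf
  }
  dimnames(v) <- NULL
  icosphere_cache[[key]] <- v
  v
}

# Surface sampling -----------------------------------------------------------

#' Sample evenly spaced solvent-accessible surface points
#'
#' Each heavy polymer atom contributes the vertices of a subdivided
#' icosahedron scaled to radius `r_vdw + probe` and centered on the atom;
#' vertices falling strictly inside any other atom's expanded sphere (by more
#' than a 1e-6 Angstrom tolerance) are discarded. The survivors form one
#' solvent-accessible dot layer around the protein; the probe radius of
#' 1.6 Angstrom and tessellation level 2 are the tuned defaults.
#'
#' @param structure a `protein_structure`.
#' @param probe probe radius in Angstrom (default 1.6).
#' @param tess_level icosphere subdivision level (default 2, i.e. 162
#'   candidate vertices per atom).
#' @param tables `property_tables` supplying the vdW radius table.
#' @return data.frame with columns `x`, `y`, `z`, `atom_serial` (the
#'   generating atom). The attribute `exposed_serials` lists atoms with at
#'   least one surviving vertex.
#' @export
sample_sas_points <- function(structure, probe = 1.6, tess_level = 2L,
                              tables = property_tables()) {
  atoms <- structure$atoms
  V <- icosphere_vertices(tess_level)
  A <- coords_matrix(atoms)
  r <- vdw_radius(atoms$element, tables) + probe
  n <- nrow(A)

  # candidate occluders: expanded spheres that can reach each other's surface
  D <- sqrt(cross_dist2(A, A))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    P <- sweep(V * r[i], 2L, A[i, ], `+`)
    nb <- which(D[i, ] < r[i] + r & seq_len(n) != i)
    keep <- rep(TRUE, nrow(P))
    for (j in nb) {
      dj2 <- (P[, 1] - A[j, 1])^2 + (P[, 2] - A[j, 2])^2 + (P[, 3] - A[j, 3])^2
      keep <- keep & dj2 >= (r[j] - 1e-6)^2
      if (!any(keep)) break
    }
    if (any(keep))
      out[[i]] <- cbind(P[keep, , drop = FALSE], atoms$serial[i])
  }
  m <- do.call(rbind, out)
  if (is.null(m)) m <- matrix(numeric(), 0L, 4L)
  pts <- data.frame(x = m[, 1], y = m[, 2], z = m[, 3],
                    atom_serial = as.integer(m[, 4]))
  attr(pts, "exposed_serials") <- unique(pts$atom_serial)
  attr(pts, "probe") <- probe
  attr(pts, "tess_level") <- tess_level
  pts
}

#' Solvent-exposed atoms
#'
#' An atom is exposed iff at least one of its tessellation vertices survives
#' occlusion in [sample_sas_points()] at the same probe radius.
#'
#' @inheritParams sample_sas_points
#' @return integer vector of exposed atom serials.
#' @export
solvent_exposed_atoms <- function(structure, probe = 1.6, tess_level = 2L,
                                  tables = property_tables()) {
  attr(sample_sas_points(structure, probe, tess_level, tables),
       "exposed_serials")
}

#' Select the inner points of a pocket
#'
#' Keeps exactly the surface points whose minimum distance to any heavy
#' member atom of the pocket is at most `belt` Angstrom (closed boundary).
#' These points form the short belt around the pocket surface in which
#' protein-ligand contact happens; they are the classification unit of the
#' whole method. A surface point adjacent to several pockets is retained
#' once per pocket.
#'
#' @param points surface points from [sample_sas_points()].
#' @param pocket a `pocket_prediction`.
#' @param structure the owning `protein_structure`.
#' @param belt belt width in Angstrom (default 4.0, inclusive).
#' @return data.frame of inner points: `x`, `y`, `z`, `atom_serial`,
#'   `pocket_id`, `label` (NA until [label_points()]).
#' @export
select_inner_points <- function(points, pocket, structure, belt = 4.0) {
  if (length(pocket$members) < 1L) stop("pocket has no member atoms")
  resolve_members(pocket$members, structure, pocket$pocket_id)
  M <- coords_matrix(
    structure$atoms[match(pocket$members, structure$atoms$serial), ])
  P <- as.matrix(points[, c("x", "y", "z")])
  keep <- if (nrow(P)) row_min(cross_dist2(P, M)) <= belt^2 else logical()
  inner <- points[keep, c("x", "y", "z", "atom_serial"), drop = FALSE]
  inner$pocket_id <- rep(pocket$pocket_id, nrow(inner))
  inner$label <- rep(NA_character_, nrow(inner))
  rownames(inner) <- NULL
  inner
}

#' Label inner points by ligand proximity
#'
#' A point is `positive` iff its minimum distance to any heavy ligand atom
#' (over all ligands) is at most `threshold` Angstrom, else `negative`. No
#' rebalancing is applied afterwards: the natural class imbalance of pocket
#' points is part of the training conditions.
#'
#' @param points data.frame of inner points.
#' @param ligands list of `ligand` objects (may be empty: all negative).
#' @param threshold labeling distance in Angstrom (default 2.5, inclusive).
#' @return `points` with the `label` column filled.
#' @export
label_points <- function(points, ligands, threshold = 2.5) {
  stopifnot(threshold > 0)
  if (!nrow(points)) { points$label <- character(0); return(points) }
  if (!length(ligands)) { points$label <- "negative"; return(points) }
  L <- do.call(rbind, lapply(ligands, function(l) coords_matrix(l$atoms)))
  d2 <- row_min(cross_dist2(as.matrix(points[, c("x", "y", "z")]), L))
  points$label <- ifelse(d2 <= threshold^2, "positive", "negative")
  points
}
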