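# Inner-point featurization: atom feature vectors (AFVs) projected onto the
# sampled points by distance weighting, concatenated with point-level features.

#' Linear distance weight
#'
#' `w(d) = 1 - d/8` over the chemical-neighborhood radius of 8 Angstrom:
#' an atom touching the point contributes its full feature vector, an atom
#' at the 8 Angstrom boundary contributes nothing.
#'
#' @param d distance(s) in Angstrom, each in `[0, 8]`.
#' @return numeric weight(s) in `[0, 1]`.
#' @export
#' @examples
#' weight_linear(c(0, 4, 8))   # 1.0 0.5 0.0
weight_linear <- function(d) {
  if (any(d < 0 | d > 8)) stop("distance outside the [0, 8] A neighborhood")
  1 - d / 8
}

#' Atomic neighborhood of a point
#'
#' All heavy, solvent-exposed polymer atoms within `radius` Angstrom
#' (inclusive) of the point, with their distances. Buried atoms are excluded
#' even when geometrically close: only the solvent-facing shell carries
#' chemical information about a surface locale.
#'
#' @param point numeric length-3 coordinate.
#' @param exposed integer serials from [solvent_exposed_atoms()].
#' @param structure a `protein_structure`.
#' @param radius neighborhood radius in Angstrom (default 8).
#' @return data.frame: the atom rows plus a `distance` column (may be empty).
#' @export
atomic_neighborhood <- function(point, exposed, structure, radius = 8.0) {
  at <- structure$atoms[structure$atoms$serial %in% exposed, , drop = FALSE]
  d <- sqrt(colSums((t(coords_matrix(at)) - as.numeric(point))^2))
  nb <- at[d <= radius, , drop = FALSE]
  nb$distance <- d[d <= radius]
  rownames(nb) <- NULL
  nb
}

# AFV matrix for a set of atoms: residue-level block || atom-level block.
# Unknown residues get zero residue features; unknown (residue, atom) pairs
# get the zero atomic row. Both fall back silently here; compute_afv() warns.
afv_matrix <- function(atoms, tables) {
  rt <- tables$residue_table; at <- tables$atom_table
  R <- rt[match(atoms$resname, rownames(rt)), , drop = FALSE]
  R[is.na(R)] <- 0
  A <- at[match(paste(atoms$resname, atoms$name, sep = "."), rownames(at)), ,
          drop = FALSE]
  A[is.na(A)] <- 0
  m <- cbind(R, A)
  dimnames(m) <- list(NULL, paste0("agg_", c(colnames(rt), colnames(at))))
  m
}

#' Atom feature vector (AFV)
#'
#' Residue-level features of the atom's residue (inherited by all its atoms)
#' concatenated with the atom-level features of the (residue, atom) pair.
#' Unknown residues or atom names fall back to zero rows with a warning.
#'
#' @param atom a single-row atom data.frame (as inside a `protein_structure`).
#' @param tables a `property_tables` object.
#' @return named numeric vector.
#' @export
compute_afv <- function(atom, tables = property_tables()) {
  if (!atom$resname[1L] %in% rownames(tables$residue_table))
    warning("unknown residue ", atom$resname[1L], ": zero residue features")
  key <- paste(atom$resname[1L], atom$name[1L], sep = ".")
  if (!key %in% rownames(tables$atom_table))
    warning("unknown atom ", key, ": zero atomic features")
  drop(afv_matrix(atom[1L, , drop = FALSE], tables))
}

#' Protrusion index of a point
#'
#' Local convexity measure in the CX style: the ratio of empty to occupied
#' volume inside a sphere of radius `R` around the point,
#' `(V_sphere - N * v_atom) / (N * v_atom)` with a mean atomic volume
#' `v_atom = 20.1` cubic Angstrom and `N` the number of heavy polymer atoms
#' within `R`. Convex bumps score high, concave invaginations low. Capped at
#' `cap` so an empty neighborhood stays finite.
#'
#' @param point numeric length-3 coordinate.
#' @param structure a `protein_structure`.
#' @param R sphere radius in Angstrom (default 10).
#' @param v_atom mean atomic volume in cubic Angstrom (default 20.1).
#' @param cap upper bound on the index (default 15).
#' @return numeric scalar.
#' @export
protrusion_index <- function(point, structure, R = 10.0, v_atom = 20.1,
                             cap = 15.0) {
  d2 <- colSums((t(coords_matrix(structure$atoms)) - as.numeric(point))^2)
  n <- sum(d2 <= R^2)
  protrusion_from_count(n, R, v_atom, cap)
}

protrusion_from_count <- function(n, R = 10.0, v_atom = 20.1, cap = 15.0) {
  vs <- 4 / 3 * pi * R^3
  idx <- ifelse(n > 0, (vs - n * v_atom) / (n * v_atom), cap)
  pmin(idx, cap)
}

#' Point-specific features (FV)
#'
#' Features computed for the point itself from its local neighborhood:
#' number of H-bond donor-typed and acceptor-typed atoms in the 8 Angstrom
#' neighborhood (an atom typed donor_acceptor counts as both), the mean
#' B-factor over the neighborhood (0 when empty) and the protrusion index.
#'
#' @param point numeric length-3 coordinate.
#' @param structure a `protein_structure`.
#' @param neighborhood data.frame from [atomic_neighborhood()].
#' @param tables a `property_tables` object.
#' @return named numeric vector `(donors, acceptors, mean_b, protrusion)`.
#' @export
compute_point_features <- function(point, structure, neighborhood,
                                   tables = property_tables()) {
  pt <- tables$atom_ptype[paste(neighborhood$resname, neighborhood$name,
                                sep = ".")]
  donors <- sum(pt %in% c("donor", "donor_acceptor"), na.rm = TRUE)
  acceptors <- sum(pt %in% c("acceptor", "donor_acceptor"), na.rm = TRUE)
  mean_b <- if (nrow(neighborhood)) mean(neighborhood$b) else 0
  c(donors = donors, acceptors = acceptors, mean_b = mean_b,
    protrusion = protrusion_index(point, structure))
}

#' Aggregate an inner-point feature vector (IFV)
#'
#' The distance-weighted sum of the AFVs of the point's atomic neighborhood,
#' concatenated with the point-specific feature vector:
#' `IFV(P) = sum_i AFV(A_i) * w(dist(P, A_i))  ||  FV(P)`.
#' An empty neighborhood contributes a zero aggregate block.
#'
#' @param neighborhood data.frame from [atomic_neighborhood()] (must carry a
#'   `distance` column with all values at most 8).
#' @param fv point feature vector from [compute_point_features()].
#' @param tables a `property_tables` object.
#' @return named numeric vector of length `length(tables$feature_names)`.
#' @export
aggregate_ifv <- function(neighborhood, fv, tables = property_tables()) {
  n_agg <- length(tables$feature_names) - length(fv)
  agg <- if (nrow(neighborhood)) {
    w <- weight_linear(neighborhood$distance)
    drop(crossprod(afv_matrix(neighborhood, tables), w))
  } else {
    rep(0, n_agg)
  }
  out <- c(agg, fv)
  names(out) <- tables$feature_names
  out
}

# Vectorised featurization of many points against one structure.
# Returns a matrix (points x features) with columns tables$feature_names.
featurize_points <- function(P, structure, exposed, tables,
                             radius = 8.0, protrusion_R = 10.0) {
  P <- as.matrix(P)
  atoms <- structure$atoms
  A <- coords_matrix(atoms)
  D2 <- cross_dist2(P, A)                       # points x all polymer atoms
  exp_mask <- atoms$serial %in% exposed

  # neighborhood membership and weights (exposed atoms within 8 A)
  Nb <- (D2 <= radius^2)
  Nb[, !exp_mask] <- FALSE
  W <- matrix(0, nrow(P), nrow(A))
  W[Nb] <- 1 - sqrt(D2[Nb]) / radius

  AFV <- afv_matrix(atoms, tables)
  agg <- W %*% AFV

  pt <- tables$atom_ptype[paste(atoms$resname, atoms$name, sep = ".")]
  donor_f <- as.numeric(pt %in% c("donor", "donor_acceptor"))
  acc_f <- as.numeric(pt %in% c("acceptor", "donor_acceptor"))
  nnb <- rowSums(Nb)
  donors <- Nb %*% donor_f
  acceptors <- Nb %*% acc_f
  mean_b <- as.numeric(Nb %*% atoms$b) / pmax(nnb, 1)
  mean_b[nnb == 0] <- 0
  prot <- protrusion_from_count(rowSums(D2 <= protrusion_R^2))

  out <- cbind(agg, donors, acceptors, mean_b, prot)
  colnames(out) <- tables$feature_names
  out
}

#' Build a labeled point dataset from a corpus of structures and pockets
#'
#' Runs the full front half of the pipeline for every protein: surface
#' sampling, inner-point selection per pocket, labeling against the
#' protein's ligands, and featurization. One row per retained inner point
#' (a surface point adjacent to two pockets yields two rows).
#'
#' @param corpus list of entries, each a list with elements `structure` (a
#'   `protein_structure`) and `pockets` (list of `pocket_prediction`).
#' @param tables a `property_tables` object.
#' @param probe,tess_level,belt,label_threshold,neighborhood_radius pipeline
#'   parameters; the defaults are the tuned operating point (probe 1.6 A,
#'   tessellation level 2, 4 A inner-point belt, 2.5 A positive label
#'   distance, 8 A chemical neighborhood).
#' @param strict if `FALSE` (default) a protein whose processing fails is
#'   skipped with a warning; if `TRUE` the error propagates.
#' @return object of class `point_dataset`: list with `features` (matrix),
#'   `label` (0/1 integer), `protein_id`, `pocket_id`, `coords`,
#'   `schema_version`, `class_counts`.
#' @export
build_point_dataset <- function(corpus, tables = property_tables(),
                                probe = 1.6, tess_level = 2L, belt = 4.0,
                                label_threshold = 2.5,
                                neighborhood_radius = 8.0, strict = FALSE) {
  rows <- list()
  for (entry in corpus) {
    res <- try({
      st <- entry$structure
      pts <- sample_sas_points(st, probe, tess_level, tables)
      exposed <- attr(pts, "exposed_serials")
      inner <- do.call(rbind, lapply(entry$pockets, function(p)
        select_inner_points(pts, p, st, belt)))
      if (is.null(inner) || !nrow(inner)) NULL else {
        inner <- label_points(inner, st$ligands, label_threshold)
        X <- featurize_points(inner[, c("x", "y", "z")], st, exposed, tables,
                              radius = neighborhood_radius)
        list(X = X, label = as.integer(inner$label == "positive"),
             protein_id = rep(st$id, nrow(inner)), pocket_id = inner$pocket_id,
             coords = as.matrix(inner[, c("x", "y", "z")]))
      }
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      if (strict) stop(attr(res, "condition"))
      warning("skipping protein '", entry$structure$id, "': ",
              conditionMessage(attr(res, "condition")))
      next
    }
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows)) stop("no inner points produced from the corpus")
  ds <- structure(list(
    features = do.call(rbind, lapply(rows, `[[`, "X")),
    label = unlist(lapply(rows, `[[`, "label"), use.names = FALSE),
    protein_id = unlist(lapply(rows, `[[`, "protein_id"), use.names = FALSE),
    pocket_id = unlist(lapply(rows, `[[`, "pocket_id"), use.names = FALSE),
    coords = do.call(rbind, lapply(rows, `[[`, "coords")),
    schema_version = tables$schema_version), class = "point_dataset")
  ds$class_counts <- c(negative = sum(ds$label == 0L),
                       positive = sum(ds$label == 1L))
  ds
}

#' Assemble a point dataset from components
#'
#' @param features numeric matrix, one row per point.
#' @param label 0/1 vector.
#' @param protein_id,pocket_id grouping keys per row.
#' @param schema_version feature schema identifier.
#' @param coords optional point coordinates.
#' @return a `point_dataset`.
#' @export
point_dataset <- function(features, label, protein_id, pocket_id = NULL,
                          schema_version = "custom", coords = NULL) {
  features <- as.matrix(features)
  label <- as.integer(label)
  stopifnot(nrow(features) == length(label), all(label %in% 0:1),
            !anyNA(features), length(protein_id) == length(label))
  if (is.null(pocket_id)) pocket_id <- rep("p1", length(label))
  structure(list(features = features, label = label,
                 protein_id = as.character(protein_id),
                 pocket_id = as.character(pocket_id), coords = coords,
                 schema_version = schema_version,
                 class_counts = c(negative = sum(label == 0L),
                                  positive = sum(label == 1L))),
            class = "point_dataset")
}

#' @export
print.point_dataset <- function(x, ...) {
  cat("Point dataset: ", nrow(x$features), " points, ",
      ncol(x$features), " features [schema ", x$schema_version, "]\n",
      sep = "")
  cat("  classes: ", x$class_counts["negative"], " negative / ",
      x$class_counts["positive"], " positive (",
      length(unique(x$protein_id)), " proteins)\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.point_dataset <- function(x, ...) {
  d <- data.frame(protein_id = x$protein_id, pocket_id = x$pocket_id,
                  stringsAsFactors = FALSE)
  if (!is.null(x$coords)) {
    d$x <- x$coords[, 1]; d$y <- x$coords[, 2]; d$z <- x$coords[, 3]
  }
  d$label <- x$label
  cbind(d, as.data.frame(x$features))
}

#' Write / read a point dataset as CSV
#'
#' The CSV is the training interchange format: one row per point with
#' protein id, pocket id, coordinates, label and named feature columns. The
#' schema version travels in a `# schema:` comment line.
#'
#' @param dataset a `point_dataset`.
#' @param path CSV file.
#' @return `path` (write) or a `point_dataset` (read).
#' @export
write_point_csv <- function(dataset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# schema: ", dataset$schema_version), con)
  write.csv(as.data.frame(dataset), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_point_csv
#' @export
read_point_csv <- function(path) {
  first <- readLines(path, n = 1L)
  schema <- if (startsWith(first, "# schema:"))
    trimws(sub("^# schema:", "", first)) else "unknown"
  d <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  feat <- setdiff(names(d), c("protein_id", "pocket_id", "x", "y", "z", "label"))
  point_dataset(as.matrix(d[, feat, drop = FALSE]), d$label, d$protein_id,
                d$pocket_id, schema_version = schema,
                coords = if (all(c("x", "y", "z") %in% names(d)))
                  as.matrix(d[, c("x", "y", "z")]) else NULL)
}
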