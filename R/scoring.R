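# Pocket scoring and re-ranking, plus the two baseline rankers.

#' Pocket score from point probabilities
#'
#' The cumulative score `sum(p1^2)` over a pocket's inner points. Squaring
#' emphasizes points voted close to 1; the score is deliberately NOT divided
#' by the point count, so an oversized pocket that contains a true site
#' keeps its score, and appending zero-probability points changes nothing.
#'
#' @param p1 numeric vector of positive-class probabilities in `[0, 1]`.
#' @return numeric scalar, 0 for an empty vector.
#' @export
#' @examples
#' pocket_score(c(0.5, 0.5, 1.0))   # 1.5
pocket_score <- function(p1) {
  if (length(p1) && any(p1 < 0 | p1 > 1))
    stop("probabilities must lie in [0, 1]")
  sum(p1^2)
}

ranked_frame <- function(pockets, score, n_points = NA_integer_) {
  d <- data.frame(
    pocket_id = vapply(pockets, `[[`, "", "pocket_id"),
    original_rank = vapply(pockets, `[[`, 1L, "original_rank"),
    pscore = as.numeric(score),
    n_points = as.integer(n_points),
    cx = vapply(pockets, function(p) p$center[1L], 1),
    cy = vapply(pockets, function(p) p$center[2L], 1),
    cz = vapply(pockets, function(p) p$center[3L], 1),
    volume = vapply(pockets, `[[`, 1, "volume"),
    stringsAsFactors = FALSE)
  # decreasing score; ties keep the original order (stable)
  ord <- order(-d$pscore, d$original_rank)
  d <- d[ord, , drop = FALSE]
  d$new_rank <- seq_len(nrow(d))
  rownames(d) <- NULL
  class(d) <- c("ranked_pockets", "data.frame")
  d
}

#' Rescore and re-rank candidate pockets
#'
#' The full chain for one protein: sample surface points, select each
#' pocket's inner points, featurize them, predict per-point ligandability
#' with the trained forest, score each pocket by [pocket_score()] and sort
#' by decreasing score (stable; ties keep the original rank order). The
#' output is a permutation of the input pockets: nothing is discovered,
#' nothing is dropped. A pocket with zero inner points keeps score 0.
#'
#' @param structure a `protein_structure`.
#' @param pockets list of `pocket_prediction` objects.
#' @param model a `ligandability_forest`.
#' @param tables a `property_tables` object (must match the model schema).
#' @param probe,tess_level,belt,neighborhood_radius pipeline parameters (see
#'   [build_point_dataset()]).
#' @return a `ranked_pockets` data.frame with columns `pocket_id`,
#'   `original_rank`, `pscore`, `n_points`, `cx`, `cy`, `cz`, `volume`,
#'   `new_rank`, sorted by `new_rank`.
#' @export
rescore_pockets <- function(structure, pockets, model,
                            tables = property_tables(), probe = 1.6,
                            tess_level = 2L, belt = 4.0,
                            neighborhood_radius = 8.0) {
  check_pocket_list(pockets)
  if (!identical(tables$schema_version, model$schema_version))
    stop("property-table schema ", tables$schema_version,
         " does not match model schema ", model$schema_version)
  pts <- sample_sas_points(structure, probe, tess_level, tables)
  exposed <- attr(pts, "exposed_serials")
  inner <- lapply(pockets, function(p)
    select_inner_points(pts, p, structure, belt))
  n_points <- vapply(inner, nrow, 1L)
  all_inner <- do.call(rbind, inner)
  scores <- numeric(length(pockets))
  if (!is.null(all_inner) && nrow(all_inner)) {
    X <- featurize_points(all_inner[, c("x", "y", "z")], structure, exposed,
                          tables, radius = neighborhood_radius)
    p1 <- predict(model, X)
    idx <- rep(seq_along(pockets), n_points)
    for (i in seq_along(pockets)) scores[i] <- pocket_score(p1[idx == i])
  }
  ranked_frame(pockets, scores, n_points)
}

#' @export
print.ranked_pockets <- function(x, ...) {
  cat("Re-ranked pockets (decreasing score):\n")
  print.data.frame(head(as.data.frame(
    x[, c("new_rank", "pocket_id", "original_rank", "pscore", "n_points")]),
    20L), row.names = FALSE, digits = 4)
  if (nrow(x) > 20L) cat("  ...", nrow(x) - 20L, "more\n")
  invisible(x)
}

#' PLB-index score of a pocket
#'
#' Propensity-for-Ligand-Binding baseline: the mean residue-level
#' ligand-binding propensity over the distinct residues contributing member
#' atoms to the pocket. The bundled propensity table is a documented
#' stand-in with the usual aromatic-rich ordering and is fully replaceable.
#'
#' @param pocket a `pocket_prediction`.
#' @param structure the owning `protein_structure`.
#' @param propensities named numeric vector, residue name to propensity.
#' @return numeric scalar.
#' @export
plb_score <- function(pocket, structure,
                      propensities = property_tables()$plb) {
  at <- structure$atoms[match(pocket$members, structure$atoms$serial), ,
                        drop = FALSE]
  res <- unique(at[, c("chain", "resno", "inscode", "resname")])
  if (!nrow(res)) stop("pocket has no lining residues")
  p <- propensities[res$resname]
  p[is.na(p)] <- 0
  mean(p)
}

#' Volume score of a pocket
#'
#' Volume baseline ranker: the declared pocket volume when present,
#' otherwise the member-atom count as a size proxy.
#'
#' @param pocket a `pocket_prediction`.
#' @return numeric scalar.
#' @export
volume_score <- function(pocket) {
  if (is.finite(pocket$volume)) pocket$volume else length(pocket$members)
}

#' Rank pockets by a baseline criterion
#'
#' Produces the same `ranked_pockets` shape as [rescore_pockets()] using one
#' of the reference rankers: `"plb"` (amino-acid composition),
#' `"volume"` (declared volume or atom-count proxy) or `"original"` (the
#' upstream tool's own order, kept as-is).
#'
#' @param pockets list of `pocket_prediction` objects.
#' @param structure the owning `protein_structure` (needed for `"plb"`).
#' @param method one of `"plb"`, `"volume"`, `"original"`.
#' @param propensities propensity table for `"plb"`.
#' @return a `ranked_pockets` data.frame.
#' @export
rank_pockets <- function(pockets, structure = NULL,
                         method = c("plb", "volume", "original"),
                         propensities = property_tables()$plb) {
  method <- match.arg(method)
  check_pocket_list(pockets)
  score <- switch(method,
    plb = vapply(pockets, plb_score, 1, structure = structure,
                 propensities = propensities),
    volume = vapply(pockets, volume_score, 1),
    original = -vapply(pockets, `[[`, 1L, "original_rank"))
  ranked_frame(pockets, score)
}
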