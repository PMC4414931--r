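# Ligand-centric evaluation of pocket rankings.

#' Pocket-center detection distances
#'
#' `dca()` is the minimal distance between the pocket center and any heavy
#' atom of the ligand — the classical detection criterion. `dcc()` is the
#' distance between the pocket center and the ligand centroid, which
#' compensates for ligand size. A prediction counts as correct when the
#' distance is not greater than the chosen threshold (inclusive).
#'
#' @param pocket_center numeric length-3 coordinate.
#' @param ligand a `ligand` object.
#' @return distance in Angstrom.
#' @export
dca <- function(pocket_center, ligand) {
  if (!nrow(ligand$atoms)) stop("empty ligand")
  sqrt(min(colSums((t(coords_matrix(ligand$atoms)) -
                      as.numeric(pocket_center))^2)))
}

#' @rdname dca
#' @export
dcc <- function(pocket_center, ligand) {
  if (!nrow(ligand$atoms)) stop("empty ligand")
  sqrt(sum((as.numeric(pocket_center) - ligand$center)^2))
}

#' Evaluation criterion descriptor
#'
#' @param kind `"dca"` or `"dcc"`.
#' @param threshold detection threshold in Angstrom (default 4, inclusive).
#' @return object of class `eval_criterion`.
#' @export
eval_criterion <- function(kind = c("dca", "dcc"), threshold = 4.0) {
  kind <- match.arg(kind)
  stopifnot(threshold > 0)
  structure(list(kind = kind, threshold = threshold), class = "eval_criterion")
}

criterion_distance <- function(criterion, center, ligand) {
  switch(criterion$kind, dca = dca(center, ligand), dcc = dcc(center, ligand))
}

#' Is a ligand identified within a rank cutoff?
#'
#' TRUE iff at least one pocket among the first `cutoff` of the ranking (by
#' `new_rank`) passes the detection criterion against this ligand. Use
#' `cutoff = Inf` for "all predicted pockets" (total coverage).
#'
#' @param ranked a `ranked_pockets` data.frame.
#' @param ligand a `ligand` object.
#' @param criterion an `eval_criterion`.
#' @param cutoff positive integer rank cutoff or `Inf`.
#' @return logical scalar.
#' @export
ligand_identified <- function(ranked, ligand, criterion = eval_criterion(),
                              cutoff = Inf) {
  stopifnot(cutoff >= 1)
  d <- as.data.frame(ranked)
  d <- d[order(d$new_rank), , drop = FALSE]
  top <- d[d$new_rank <= cutoff, , drop = FALSE]
  for (i in seq_len(nrow(top))) {
    dist <- criterion_distance(criterion,
                               c(top$cx[i], top$cy[i], top$cz[i]), ligand)
    if (dist <= criterion$threshold) return(TRUE)
  }
  FALSE
}

#' Ligand-centric success rates of a ranking
#'
#' One evaluation case per (protein, relevant ligand) pair: the pair counts
#' as a success at a cutoff when some pocket within that many top ranks
#' passes the criterion for that ligand. The per-protein cutoff n is the
#' number of relevant ligands of that protein, so rates are reported for
#' Top-n, Top-(n+2) and All (total coverage — the ceiling any re-ranker can
#' reach, since re-ranking discovers no new pockets).
#'
#' @param results list of per-protein entries, each a list with elements
#'   `protein_id`, `ligands` (list of `ligand`) and `ranked` (a
#'   `ranked_pockets` data.frame).
#' @param criterion an `eval_criterion`.
#' @return object of class `eval_report`: list with `rates` (named fractions
#'   `top_n`, `top_n_plus_2`, `all`), `outcomes` (per-pair table) and
#'   `criterion`.
#' @export
success_rates <- function(results, criterion = eval_criterion()) {
  if (!length(results)) stop("empty evaluation corpus")
  rows <- list()
  for (entry in results) {
    n <- length(entry$ligands)
    if (n == 0L) next
    for (j in seq_len(n)) {
      lig <- entry$ligands[[j]]
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = entry$protein_id, ligand = j, n_sites = n,
        top_n = ligand_identified(entry$ranked, lig, criterion, n),
        top_n_plus_2 = ligand_identified(entry$ranked, lig, criterion, n + 2L),
        all = ligand_identified(entry$ranked, lig, criterion, Inf),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no (protein, ligand) evaluation pairs")
  outcomes <- do.call(rbind, rows)
  structure(list(
    rates = c(top_n = mean(outcomes$top_n),
              top_n_plus_2 = mean(outcomes$top_n_plus_2),
              all = mean(outcomes$all)),
    outcomes = outcomes, criterion = criterion,
    n_pairs = nrow(outcomes)), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Ligand-centric evaluation (%s <= %.1f A, %d pairs):\n",
              toupper(x$criterion$kind), x$criterion$threshold, x$n_pairs))
  cat(sprintf("  Top-n %.1f%%   Top-(n+2) %.1f%%   All %.1f%%\n",
              100 * x$rates["top_n"], 100 * x$rates["top_n_plus_2"],
              100 * x$rates["all"]))
  invisible(x)
}

#' Success-rate sweep over thresholds
#'
#' Recomputes [success_rates()] over a range of integer thresholds for one
#' or both criteria, as a long table.
#'
#' @param results as in [success_rates()].
#' @param thresholds numeric vector of thresholds in Angstrom.
#' @param kinds criteria to sweep (default both).
#' @return data.frame with columns `criterion`, `threshold`, `cutoff`, `rate`.
#' @export
success_rate_sweep <- function(results, thresholds = 1:10,
                               kinds = c("dca", "dcc")) {
  out <- list()
  for (kind in kinds) for (th in thresholds) {
    r <- success_rates(results, eval_criterion(kind, th))$rates
    out[[length(out) + 1L]] <- data.frame(
      criterion = kind, threshold = th,
      cutoff = c("top_n", "top_n_plus_2", "all"), rate = unname(r),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
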