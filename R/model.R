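# Random-forest point classifier and its evaluation statistics.

#' Fit the ligandability random forest
#'
#' Fits a probability random forest to a labeled inner-point dataset. The
#' forest is trained on the raw, imbalanced data: no resampling and no class
#' weights (rebalancing degrades generalization for this problem, so the
#' natural class ratio is kept). Training is deterministic for a fixed seed.
#'
#' @param dataset a `point_dataset` with both classes present.
#' @param num_trees number of trees (default 100).
#' @param mtry candidate features per split; default `floor(sqrt(p))`.
#' @param seed integer seed; stored in the model metadata.
#' @return object of class `ligandability_forest` with elements `forest`,
#'   `schema_version`, `feature_names`, `meta`.
#' @seealso [predict.ligandability_forest()], [cross_validate_points()]
#' @export
ligandability_forest <- function(dataset, num_trees = 100L, mtry = NULL,
                                 seed = 42L) {
  stopifnot(inherits(dataset, "point_dataset"))
  if (length(unique(dataset$label)) < 2L)
    stop("dataset contains a single class; both positives and negatives are required")
  X <- dataset$features
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  df <- data.frame(.label = factor(dataset$label, levels = c(0L, 1L)),
                   X, check.names = FALSE)
  forest <- ranger::ranger(
    dependent.variable.name = ".label", data = df,
    num.trees = num_trees, mtry = mtry, probability = TRUE,
    min.node.size = 1L,     # fully grown trees
    respect.unordered.factors = "order",
    seed = seed, num.threads = 1L)
  structure(list(
    forest = forest,
    schema_version = dataset$schema_version,
    feature_names = colnames(X),
    meta = list(seed = seed, num_trees = num_trees, mtry = mtry,
                class_counts = dataset$class_counts,
                n_proteins = length(unique(dataset$protein_id)))),
    class = "ligandability_forest")
}

#' @export
print.ligandability_forest <- function(x, ...) {
  cat("Ligandability random forest [schema ", x$schema_version, "]\n", sep = "")
  cat("  trees:", x$meta$num_trees, " mtry:", x$meta$mtry,
      " seed:", x$meta$seed, "\n")
  cat("  trained on ", x$meta$class_counts["negative"], " negative / ",
      x$meta$class_counts["positive"], " positive points from ",
      x$meta$n_proteins, " protein(s)\n", sep = "")
  invisible(x)
}

#' @export
summary.ligandability_forest <- function(object, ...) {
  print(object)
  cat("  OOB prediction error:",
      signif(object$forest$prediction.error, 4), "\n")
  invisible(object)
}

#' Predict positive-class probabilities
#'
#' Returns P1, the probability that each point is ligandable, as voted by
#' the forest (P0 + P1 = 1 by construction). Refuses feature input built
#' under a different property-table schema.
#'
#' @param object a `ligandability_forest`.
#' @param newdata a `point_dataset` or a numeric matrix whose columns are
#'   the model's feature names.
#' @param ... unused.
#' @return numeric vector of P1 values in `[0, 1]`.
#' @export
predict.ligandability_forest <- function(object, newdata, ...) {
  if (inherits(newdata, "point_dataset")) {
    if (!identical(newdata$schema_version, object$schema_version))
      stop("feature schema mismatch: model ", object$schema_version,
           " vs data ", newdata$schema_version)
    X <- newdata$features
  } else {
    X <- as.matrix(newdata)
  }
  if (!identical(colnames(X), object$feature_names))
    stop("feature columns do not match the model's feature names")
  pr <- predict(object$forest, data.frame(X, check.names = FALSE),
                num.threads = 1L)$predictions
  unname(pr[, "1"])
}

#' Save / load a trained model
#'
#' Serialization round-trips predictions bit-exactly; loading checks the
#' object class so a corrupt or foreign file errors out, and any schema
#' mismatch still surfaces at predict time.
#'
#' @param model a `ligandability_forest`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ligandability_forest"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  m <- tryCatch(readRDS(path), error = function(e)
    stop("corrupt model file ", path, ": ", conditionMessage(e)))
  if (!inherits(m, "ligandability_forest"))
    stop("file does not contain a ligandability_forest: ", path)
  m
}

# Classifier statistics ------------------------------------------------------

#' Confusion counts from truth and prediction
#'
#' @param truth,pred 0/1 vectors of equal length.
#' @return object of class `confusion_counts` (named integer vector
#'   TP, TN, FP, FN).
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  stopifnot(length(truth) == length(pred),
            all(truth %in% 0:1), all(pred %in% 0:1))
  structure(c(TP = sum(truth == 1L & pred == 1L),
              TN = sum(truth == 0L & pred == 0L),
              FP = sum(truth == 0L & pred == 1L),
              FN = sum(truth == 1L & pred == 0L)),
            class = "confusion_counts")
}

zero_flagged <- function(num, den) {
  if (den == 0) structure(0, degenerate = TRUE) else num / den
}

#' Precision, recall and Matthews correlation coefficient
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' MCC ranges from +1 (perfect) through 0 (random) to -1 (inverse) and is
#' the statistic of choice under heavy class imbalance. A vanishing
#' denominator returns 0 with attribute `degenerate = TRUE` instead of
#' erroring (degenerate folds do occur in cross-validation).
#'
#' @param c a `confusion_counts` object (or named TP/TN/FP/FN vector).
#' @return numeric scalar.
#' @export
precision_score <- function(c) zero_flagged(c[["TP"]], c[["TP"]] + c[["FP"]])

#' @rdname precision_score
#' @export
recall_score <- function(c) zero_flagged(c[["TP"]], c[["TP"]] + c[["FN"]])

#' @rdname precision_score
#' @export
mcc_score <- function(c) {
  tp <- c[["TP"]]; tn <- c[["TN"]]; fp <- c[["FP"]]; fn <- c[["FN"]]
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(structure(0, degenerate = TRUE))
  (tp * tn - fp * fn) / den
}

#' Grouped cross-validation of the point classifier
#'
#' Folds are split by protein id: all points of a protein land in the same
#' fold, so near-duplicate neighboring points can never straddle the
#' train/test boundary. Metrics use the 0.5 probability threshold.
#'
#' @param dataset a `point_dataset`.
#' @param k number of folds (default 5).
#' @param repeats independent repetitions with reshuffled folds (default 1).
#' @param seed integer seed governing fold assignment and forests.
#' @param num_trees trees per fold model.
#' @return object of class `cv_result`: list with `summary` (mean precision,
#'   recall, MCC), `folds` (per-fold table) and `fold_assignments` (per
#'   repeat, the protein-to-fold map actually used).
#' @export
cross_validate_points <- function(dataset, k = 5L, repeats = 1L, seed = 42L,
                                  num_trees = 100L) {
  stopifnot(k >= 2L)
  groups <- unique(dataset$protein_id)
  if (length(groups) < k)
    stop("fewer protein groups (", length(groups), ") than folds (", k, ")")
  rows <- list()
  assignments <- vector("list", repeats)
  for (rep in seq_len(repeats)) {
    set.seed(seed + rep - 1L)
    fold_of <- setNames(sample(rep_len(seq_len(k), length(groups))), groups)
    assignments[[rep]] <- fold_of
    for (fold in seq_len(k)) {
      test <- dataset$protein_id %in% groups[fold_of[groups] == fold]
      train_ds <- subset_points(dataset, !test)
      test_ds <- subset_points(dataset, test)
      if (length(unique(train_ds$label)) < 2L) next
      m <- ligandability_forest(train_ds, num_trees = num_trees,
                                seed = seed * 1000L + rep * 10L + fold)
      p1 <- predict(m, test_ds)
      cc <- confusion_counts(test_ds$label, as.integer(p1 >= 0.5))
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_ = rep, fold = fold,
        precision = as.numeric(precision_score(cc)),
        recall = as.numeric(recall_score(cc)),
        mcc = as.numeric(mcc_score(cc)),
        n_test = sum(test))
    }
  }
  folds <- do.call(rbind, rows)
  structure(list(
    summary = c(precision = mean(folds$precision), recall = mean(folds$recall),
                mcc = mean(folds$mcc)),
    folds = folds, fold_assignments = assignments,
    k = k, repeats = repeats, seed = seed),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold grouped cross-validation (%d repeat%s):\n",
              x$k, x$repeats, if (x$repeats > 1) "s" else ""))
  cat(sprintf("  precision %.3f  recall %.3f  MCC %.3f\n",
              x$summary["precision"], x$summary["recall"], x$summary["mcc"]))
  invisible(x)
}

# row-subset of a point_dataset
subset_points <- function(dataset, idx) {
  point_dataset(dataset$features[idx, , drop = FALSE], dataset$label[idx],
                dataset$protein_id[idx], dataset$pocket_id[idx],
                schema_version = dataset$schema_version,
                coords = if (!is.null(dataset$coords))
                  dataset$coords[idx, , drop = FALSE] else NULL)
}
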