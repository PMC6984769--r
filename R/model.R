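#' @importFrom randomForest randomForest
NULL

# Accept either an rpi_matrix or a plain numeric matrix + labels.
.as_xy <- function(x, labels = NULL) {
  if (inherits(x, "rpi_matrix")) {
    list(x = x$x, labels = x$labels)
  } else {
    stopifnot(is.matrix(x))
    list(x = x, labels = labels)
  }
}

#' Default mtry grid
#'
#' Roughly log-spaced candidate values in `[1, n]`, always including
#' `floor(sqrt(n))` and `n` itself.
#'
#' @param n Feature dimension.
#' @param length_out Approximate number of grid points.
#' @return Sorted integer vector.
#' @export
default_mtry_grid <- function(n, length_out = 8) {
  stopifnot(n >= 1)
  g <- unique(round(exp(seq(0, log(n), length.out = length_out))))
  sort(unique(c(g, max(1L, floor(sqrt(n))))))
}

#' Train a random-forest interaction classifier
#'
#' Fits a random forest on a labelled feature matrix.  The model's
#' score for a pair is the fraction of trees voting "interacting";
#' `ntree` and `mtry` are the forest size and the number of candidate
#' features tried at each split.
#'
#' @param x An `rpi_matrix` (see [build_matrix()]) or a numeric matrix
#'   with column names.
#' @param labels Binary labels; ignored when `x` is a labelled
#'   `rpi_matrix`.
#' @param ntree Number of trees.
#' @param mtry Features sampled per split; default `floor(sqrt(n))`.
#' @param seed Integer seed; the fit is deterministic given it.
#' @return An object of class `rpi_rf` wrapping the forest together
#'   with the training column names and feature-set name.
#' @export
train_rf <- function(x, labels = NULL, ntree = 500, mtry = NULL, seed = 1) {
  xy <- .as_xy(x, labels)
  if (is.null(xy$labels)) stop("training requires labels")
  y <- as.integer(xy$labels)
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  n <- ncol(xy$x)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(n)))
  if (mtry < 1 || mtry > n) {
    stop("mtry must lie in [1, ", n, "], got ", mtry)
  }
  set.seed(seed)
  fit <- randomForest::randomForest(
    x = xy$x, y = factor(y, levels = c(0, 1)),
    ntree = ntree, mtry = mtry
  )
  structure(
    list(forest = fit,
         columns = colnames(xy$x),
         feature_set = if (inherits(x, "rpi_matrix")) x$feature_set else NA_character_,
         ntree = ntree, mtry = mtry, seed = seed),
    class = "rpi_rf"
  )
}

#' @export
print.rpi_rf <- function(x, ...) {
  cat("<rpi_rf> random forest on ", length(x$columns), " features",
      if (!is.na(x$feature_set)) paste0(" (", x$feature_set, ")"),
      "; ntree = ", x$ntree, ", mtry = ", x$mtry, "\n", sep = "")
  invisible(x)
}

#' Predict interaction scores for new pairs
#'
#' @param object An `rpi_rf` model.
#' @param newdata An `rpi_matrix` or numeric matrix whose columns match
#'   the training columns by name.
#' @param threshold Score at or above which a pair is called
#'   interacting (default 0.5; a score of exactly 0.5 is class 1).
#' @param ... Unused.
#' @return A `data.frame` with columns `score` (vote fraction in
#'   `[0, 1]`) and `class` (0/1).
#' @export
predict.rpi_rf <- function(object, newdata, threshold = 0.5, ...) {
  xy <- .as_xy(newdata)
  if (!identical(colnames(xy$x), object$columns)) {
    if (ncol(xy$x) != length(object$columns)) {
      stop("feature mismatch: model has ", length(object$columns),
           " columns (", object$feature_set, "), data has ", ncol(xy$x))
    }
    bad <- which(colnames(xy$x) != object$columns)[1]
    stop("feature mismatch at column ", bad, ": model '",
         object$columns[bad], "' vs data '", colnames(xy$x)[bad], "'")
  }
  votes <- predict(object$forest, xy$x, type = "prob")[, "1"]
  data.frame(score = unname(votes),
             class = as.integer(votes >= threshold))
}

#' Stratified cross-validation folds
#'
#' Splits samples into `k` folds preserving the class ratio; fold
#' sizes within each class differ by at most one.
#'
#' @param labels Binary labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold assignments in `1..k`.
#' @export
stratified_folds <- function(labels, k = 10, seed = 1) {
  n <- length(labels)
  if (n < k) stop("fewer samples (", n, ") than folds (", k, ")")
  set.seed(seed)
  fold <- integer(n)
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' 10-fold cross-validation of the random-forest classifier
#'
#' Stratified k-fold cross-validation: each fold is held out once, a
#' forest is trained on the rest, and the held-out pairs are scored.
#' Metrics are computed from the out-of-fold confusion counts pooled
#' over folds, and AUC from the pooled out-of-fold scores; per-fold
#' numbers are reported alongside.
#'
#' @inheritParams train_rf
#' @param folds Number of folds (default 10).
#' @param threshold Classification threshold on the vote fraction.
#' @return An object of class `rpi_cv`: list with `pooled` (Sens,
#'   Spec, ACC, MCC, AUC), `per_fold`, `scores`, `labels`, `fold`,
#'   and `config`.
#' @export
cross_validate <- function(x, labels = NULL, ntree = 500, mtry = NULL,
                           folds = 10, seed = 1, threshold = 0.5) {
  xy <- .as_xy(x, labels)
  if (is.null(xy$labels)) stop("cross-validation requires labels")
  y <- as.integer(xy$labels)
  if (min(table(y)) < folds) {
    stop("stratified ", folds, "-fold CV needs at least ", folds,
         " samples per class")
  }
  n_feat <- ncol(xy$x)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(n_feat)))
  fold <- stratified_folds(y, k = folds, seed = seed)
  scores <- numeric(length(y))
  per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    test <- fold == f
    model <- train_rf(xy$x[!test, , drop = FALSE], y[!test],
                      ntree = ntree, mtry = mtry, seed = seed + f)
    pred <- predict(model, xy$x[test, , drop = FALSE], threshold = threshold)
    scores[test] <- pred$score
    cc <- confusion_counts(pred$class, y[test])
    per_fold[[f]] <- list(
      counts = cc,
      AUC = if (length(unique(y[test])) == 2L) auc_rank(pred$score, y[test]) else NA_real_
    )
  }
  pooled_counts <- Reduce(`+`, lapply(per_fold, `[[`, "counts"))
  pooled <- compute_metrics(pooled_counts)
  pooled$AUC <- auc_rank(scores, y)
  structure(
    list(pooled = pooled, per_fold = per_fold, scores = scores,
         labels = y, fold = fold,
         config = list(ntree = ntree, mtry = mtry, folds = folds,
                       seed = seed, threshold = threshold)),
    class = "rpi_cv"
  )
}

#' @export
print.rpi_cv <- function(x, ...) {
  p <- x$pooled
  cat(sprintf(
    "<rpi_cv> %d-fold CV (ntree = %d, mtry = %d)\n  Sens %.4f  Spec %.4f  ACC %.4f  MCC %.4f  AUC %.4f\n",
    x$config$folds, x$config$ntree, x$config$mtry,
    p$Sens, p$Spec, p$ACC, p$MCC, p$AUC))
  invisible(x)
}

#' Grid search over ntree and mtry
#'
#' Evaluates every (ntree, mtry) combination by stratified k-fold
#' cross-validation and returns the configuration with the highest
#' pooled accuracy; ties go to the smaller ntree, then the smaller
#' mtry.  The default grids cover the conventional search ranges
#' (`ntree` in `[300, 500]`, `mtry` in `[1, n]`) at desk scale:
#' `ntree` in steps of 50 and about eight log-spaced `mtry` values
#' including `floor(sqrt(n))`; both are overridable up to full density.
#'
#' @inheritParams cross_validate
#' @param ntree_grid Integer vector of forest sizes.
#' @param mtry_grid Integer vector of mtry values, or `NULL` for
#'   [default_mtry_grid()].
#' @return A list with `best` (ntree, mtry), `cv` (the winning
#'   `rpi_cv`), and `table` (one row per grid point with pooled
#'   metrics).
#' @export
grid_search <- function(x, labels = NULL,
                        ntree_grid = c(300, 350, 400, 450, 500),
                        mtry_grid = NULL, folds = 10, seed = 1) {
  xy <- .as_xy(x, labels)
  if (is.null(xy$labels)) stop("grid search requires labels")
  n_feat <- ncol(xy$x)
  if (is.null(mtry_grid)) mtry_grid <- default_mtry_grid(n_feat)
  if (length(ntree_grid) == 0 || length(mtry_grid) == 0) {
    stop("empty hyperparameter grid")
  }
  if (any(mtry_grid < 1 | mtry_grid > n_feat)) {
    stop("mtry grid must lie in [1, ", n_feat, "]")
  }
  grid <- expand.grid(ntree = sort(as.integer(ntree_grid)),
                      mtry = sort(as.integer(mtry_grid)))
  results <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    results[[i]] <- cross_validate(xy$x, xy$labels,
                                   ntree = grid$ntree[i],
                                   mtry = grid$mtry[i],
                                   folds = folds, seed = seed)
  }
  tab <- cbind(grid, do.call(rbind, lapply(results, function(r) {
    p <- r$pooled
    data.frame(Sens = p$Sens, Spec = p$Spec, ACC = p$ACC,
               MCC = p$MCC, AUC = p$AUC)
  })))
  best_i <- order(-tab$ACC, tab$ntree, tab$mtry)[1]
  list(best = list(ntree = tab$ntree[best_i], mtry = tab$mtry[best_i]),
       cv = results[[best_i]],
       table = tab)
}

#' Save / load a trained model
#'
#' The saved archive embeds the forest, the training column names, the
#' feature-set name and the seed, so a reloaded model refuses matrices
#' from a different feature set.
#'
#' @param model An `rpi_rf`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "rpi_rf"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "rpi_rf")) stop("not an rpiforest model archive: ", path)
  model
}
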