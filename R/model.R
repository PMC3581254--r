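# Run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so package functions never perturb user RNG.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

protein_key <- function(table) paste(table$groups$pdb_id, table$groups$chain_id)

#' SVM training configuration
#'
#' Bundles the C-SVC/RBF hyper-parameter grids and protocol settings. The
#' default grids are the standard libsvm coarse grid: cost
#' \eqn{2^{-5}, 2^{-3}, ..., 2^{15}} and gamma
#' \eqn{2^{-15}, 2^{-13}, ..., 2^{3}}. Tuning maximizes the Matthews
#' correlation coefficient under inner cross-validation.
#'
#' @param cost_grid Positive cost values to search.
#' @param gamma_grid Positive RBF gamma values to search.
#' @param n_folds Folds for both the outer (protein-level) and inner
#'   (tuning) cross-validation, >= 2.
#' @param seed Integer seed controlling subsampling and fold assignment.
#' @param balance Balance training data by subsampling negatives (default
#'   `TRUE`, the protocol for extremely imbalanced catalytic-residue data).
#' @return An `svm_config` list.
#' @export
svm_config <- function(cost_grid = 2^seq(-5, 15, by = 2),
                       gamma_grid = 2^seq(-15, 3, by = 2),
                       n_folds = 5L, seed = 1L, balance = TRUE) {
  stopifnot(length(cost_grid) >= 1L, all(cost_grid > 0),
            length(gamma_grid) >= 1L, all(gamma_grid > 0),
            n_folds >= 2L)
  structure(list(cost_grid = sort(cost_grid), gamma_grid = sort(gamma_grid),
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 balance = isTRUE(balance)),
            class = "svm_config")
}

#' Balanced subsample of a feature table
#'
#' Retains every catalytic (positive) residue and draws, uniformly without
#' replacement, an equal number of noncatalytic residues — the standard
#' counter to the extreme class imbalance of catalytic-site data.
#' Deterministic given `seed`.
#'
#' @param table A `feature_table`.
#' @param seed Integer seed.
#' @return A `feature_table` with exactly 1:1 class counts.
#' @export
balanced_subsample <- function(table, seed) {
  stopifnot(inherits(table, "feature_table"))
  pos <- which(table$y == 1L)
  neg <- which(table$y == 0L)
  if (length(pos) < 1L) stop("no positive residues to subsample around")
  if (length(neg) < length(pos)) {
    stop("fewer negatives (", length(neg), ") than positives (",
         length(pos), ")")
  }
  keep_neg <- with_seed(seed, sample(neg, length(pos)))
  subset_feature_table(table, sort(c(pos, keep_neg)))
}

#' Protein-level cross-validation folds
#'
#' Partitions proteins (not residues) into `n_folds` groups of near-equal
#' protein count; every residue inherits its protein's fold, so no protein
#' ever contributes rows to more than one fold.
#'
#' @param table A `feature_table`.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed for the protein shuffle.
#' @return Integer vector of fold ids (1..n_folds), one per row of `table`.
#' @export
cv_split <- function(table, n_folds = 5L, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  prot <- protein_key(table)
  u <- unique(prot)
  if (length(u) < n_folds) {
    stop("fewer proteins (", length(u), ") than folds (", n_folds, ")")
  }
  shuffled <- with_seed(seed, sample(u))
  fold_of <- rep(seq_len(n_folds), length.out = length(u))
  names(fold_of) <- shuffled
  unname(fold_of[prot])
}

mcc_from_pred <- function(pred, actual) {
  classification_metrics(confusion(pred, actual))$mcc
}

fit_svm <- function(X, y, cost, gamma, probability = FALSE) {
  e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
             type = "C-classification", kernel = "radial",
             cost = cost, gamma = gamma, scale = FALSE,
             probability = probability)
}

#' Tune and train the C-SVC/RBF classifier
#'
#' Grid-searches (cost, gamma) by inner `n_folds`-fold cross-validation on the
#' (balanced) training table, maximizing the Matthews correlation coefficient,
#' then refits on the full table at the best pair with Platt-scaled
#' probability estimates enabled. Ties are broken toward the smallest cost,
#' then the smallest gamma. Inner folds are stratified by class at the
#' residue level.
#'
#' @param train_table A `feature_table`, normally the output of
#'   [balanced_subsample()].
#' @param config An [svm_config()].
#' @return A `trained_model` with elements `fit` (the e1071 svm object),
#'   `cost`, `gamma`, `feature_names`, `tuning` (the full grid with CV MCC),
#'   and `config`.
#' @export
tune_and_train <- function(train_table, config = svm_config()) {
  stopifnot(inherits(train_table, "feature_table"),
            inherits(config, "svm_config"))
  X <- train_table$X
  y <- train_table$y
  if (length(unique(y)) < 2L) stop("training table has a single class")
  k <- config$n_folds
  folds <- with_seed(config$seed + 7L, {
    f <- integer(length(y))
    for (cls in c(0L, 1L)) {
      idx <- sample(which(y == cls))
      f[idx] <- rep(seq_len(k), length.out = length(idx))
    }
    f
  })
  grid <- expand.grid(gamma = config$gamma_grid, cost = config$cost_grid,
                      KEEP.OUT.ATTRS = FALSE)
  # ordered so the first maximum is the smallest cost, then smallest gamma
  grid <- grid[order(grid$cost, grid$gamma), , drop = FALSE]
  grid$mcc <- NA_real_
  # libsvm's probability calibration draws from the R RNG; seed it so that
  # training is a pure function of (data, config)
  with_seed(config$seed + 23L, for (g in seq_len(nrow(grid))) {
    pred <- integer(length(y))
    ok <- TRUE
    for (f in seq_len(k)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L) { ok <- FALSE; break }
      m <- fit_svm(X[tr, , drop = FALSE], y[tr],
                   cost = grid$cost[g], gamma = grid$gamma[g])
      pred[!tr] <- as.integer(as.character(
        stats::predict(m, X[!tr, , drop = FALSE])))
    }
    if (ok) {
      mcc <- mcc_from_pred(pred, y)
      grid$mcc[g] <- if (is.na(mcc)) 0 else mcc
    }
  })
  if (all(is.na(grid$mcc))) stop("all tuning folds were degenerate")
  best <- which.max(grid$mcc)  # first max in (cost, gamma) order
  fit <- with_seed(config$seed + 29L,
                   fit_svm(X, y, cost = grid$cost[best],
                           gamma = grid$gamma[best], probability = TRUE))
  structure(list(fit = fit,
                 cost = grid$cost[best], gamma = grid$gamma[best],
                 feature_names = train_table$feature_names,
                 feature_set = train_table$feature_set,
                 tuning = grid, config = config,
                 n_train = length(y)),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf(
    "<trained_model> C-SVC/RBF on [%s], cost = %g, gamma = %g, %d training rows\n",
    x$feature_set, x$cost, x$gamma, x$n_train))
  invisible(x)
}

#' Predict catalytic-residue probabilities
#'
#' Applies a trained classifier to a feature table, returning per-residue
#' Platt-scaled probabilities of the catalytic class, a hard call at 0.5, and
#' a within-protein rank (1 = most probable catalytic residue). Probability
#' ties are broken by ascending residue number.
#'
#' @param object A `trained_model`.
#' @param table A `feature_table` with the same feature names.
#' @param ... Unused.
#' @return A `prediction_table`: data frame with columns `pdb_id`,
#'   `chain_id`, `res_seq`, `icode`, `aa`, `prob`, `rank`, `pred`, `label`.
#' @export
predict.trained_model <- function(object, table, ...) {
  stopifnot(inherits(table, "feature_table"))
  if (!identical(object$feature_names, table$feature_names)) {
    stop("feature names of table do not match the model (",
         paste(object$feature_names, collapse = ","), " vs ",
         paste(table$feature_names, collapse = ","), ")")
  }
  raw <- stats::predict(object$fit, table$X, probability = TRUE)
  prob <- attr(raw, "probabilities")[, "1"]
  out <- cbind(table$groups,
               data.frame(prob = as.numeric(prob),
                          rank = NA_integer_,
                          pred = as.integer(prob >= 0.5),
                          label = table$y))
  for (p in unique(paste(out$pdb_id, out$chain_id))) {
    i <- which(paste(out$pdb_id, out$chain_id) == p)
    ord <- order(-out$prob[i], out$res_seq[i], out$icode[i])
    out$rank[i[ord]] <- seq_along(i)
  }
  rownames(out) <- NULL
  class(out) <- c("prediction_table", "data.frame")
  out
}

#' Cross-validated evaluation of a feature set
#'
#' The full evaluation protocol: proteins are split into `n_folds`
#' outer folds; for each fold the classifier is tuned and trained on a
#' balanced subsample of the remaining proteins' residues, then applied to
#' the held-out proteins. Two views of the held-out predictions are kept:
#' the unbalanced view (all residues) feeds the per-protein-averaged ROC
#' curve, and a balanced subsample of the test fold feeds the
#' sensitivity/specificity/MCC table, so that headline metrics are computed
#' on data with equal class counts.
#'
#' @param table A `feature_table` covering at least `n_folds` proteins.
#' @param config An [svm_config()].
#' @return An `evaluation_result` list: `metrics` (pooled balanced-mode
#'   sensitivity/specificity/MCC), `counts` (pooled confusion),
#'   `per_fold` (per-fold metrics), `roc` (per-protein-averaged ROC on the
#'   unbalanced predictions), `auc`, `predictions` (all held-out rows), and
#'   `models` (per-fold chosen cost/gamma).
#' @export
evaluate_protocol <- function(table, config = svm_config()) {
  stopifnot(inherits(table, "feature_table"))
  folds <- cv_split(table, n_folds = config$n_folds, seed = config$seed)
  preds <- list()
  bal_pred <- list()
  per_fold <- list()
  models <- list()
  for (f in seq_len(config$n_folds)) {
    train <- subset_feature_table(table, folds != f)
    test <- subset_feature_table(table, folds == f)
    if (config$balance) {
      train <- balanced_subsample(train, seed = config$seed * 1000L + f)
    }
    model <- tune_and_train(train, config)
    models[[f]] <- list(cost = model$cost, gamma = model$gamma)
    pt <- predict(model, test)
    pt$fold <- f
    preds[[f]] <- pt
    bal_test <- balanced_subsample(test, seed = config$seed * 1000L + 500L + f)
    bp <- predict(model, bal_test)
    bp$fold <- f
    bal_pred[[f]] <- bp
    per_fold[[f]] <- classification_metrics(confusion(bp$pred, bp$label))
  }
  predictions <- do.call(rbind, preds)
  class(predictions) <- c("prediction_table", "data.frame")
  balanced <- do.call(rbind, bal_pred)
  counts <- confusion(balanced$pred, balanced$label)
  roc <- per_protein_roc(predictions)
  structure(list(
    metrics = classification_metrics(counts),
    counts = counts,
    per_fold = do.call(rbind, lapply(per_fold, as.data.frame)),
    roc = roc,
    auc = roc_auc(roc),
    predictions = predictions,
    balanced_predictions = balanced,
    models = models,
    feature_set = table$feature_set
  ), class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    paste0("<evaluation_result> [%s] balanced sens = %.3f, spec = %.3f, ",
           "MCC = %.3f; per-protein ROC AUC = %.3f\n"),
    x$feature_set, m$sensitivity, m$specificity, m$mcc, x$auc))
  invisible(x)
}
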