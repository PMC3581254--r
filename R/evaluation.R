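#' Confusion counts
#'
#' Standard 2x2 counts with the catalytic class as positive.
#'
#' @param predicted Binary (0/1 or logical) predicted labels.
#' @param actual Binary actual labels, same length.
#' @return A `confusion_counts` list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(predicted, actual) {
  predicted <- as.integer(predicted)
  actual <- as.integer(actual)
  if (length(predicted) != length(actual)) stop("length mismatch")
  if (!all(predicted %in% c(0L, 1L)) || !all(actual %in% c(0L, 1L))) {
    stop("labels must be binary 0/1")
  }
  structure(list(
    tp = sum(predicted == 1L & actual == 1L),
    fp = sum(predicted == 1L & actual == 0L),
    tn = sum(predicted == 0L & actual == 0L),
    fn = sum(predicted == 0L & actual == 1L)
  ), class = "confusion_counts")
}

#' Sensitivity, specificity and Matthews correlation
#'
#' \deqn{Sens = TP/(TP+FN), \quad Spec = TN/(TN+FP),}
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FN)(TN+FP)}}.}
#' A metric whose denominator is zero is reported as `NA` (undefined), never
#' silently as 0.
#'
#' @param counts A `confusion_counts`.
#' @return List with `sensitivity`, `specificity`, `mcc`.
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  denom2 <- (tp + fp) * (tp + fn) * (tn + fn) * (tn + fp)
  mcc <- if (denom2 > 0) {
    (tp * tn - fp * fn) / sqrt(denom2)
  } else NA_real_
  list(sensitivity = sens, specificity = spec, mcc = mcc)
}

# ROC of a single protein, evaluated on `grid` by linear interpolation of the
# threshold-sweep polyline. Tied probabilities move both counts together (one
# diagonal segment). Vertical segments (several tpr at one fpr) are preserved:
# a grid point sitting exactly on a jump takes the top of the jump, a point
# between two distinct fpr values interpolates from the top of the left jump
# to the bottom of the right one.
single_roc_tpr <- function(prob, label, grid) {
  ord <- order(-prob)
  lab <- label[ord]
  p <- prob[ord]
  np <- sum(lab == 1L)
  nn <- sum(lab == 0L)
  tp <- cumsum(lab == 1L)
  fp <- cumsum(lab == 0L)
  last_of_tie <- c(p[-1] != p[-length(p)], TRUE)
  fpr <- c(0, fp[last_of_tie] / nn)
  tpr <- c(0, tp[last_of_tie] / np)
  ux <- unique(fpr)
  ymax <- vapply(ux, function(x) max(tpr[fpr == x]), numeric(1))
  ymin <- vapply(ux, function(x) min(tpr[fpr == x]), numeric(1))
  k <- findInterval(grid, ux)
  out <- numeric(length(grid))
  exact <- grid == ux[k]
  out[exact] <- ymax[k[exact]]
  mid <- which(!exact)
  if (length(mid)) {
    x0 <- ux[k[mid]]; x1 <- ux[k[mid] + 1L]
    y0 <- ymax[k[mid]]; y1 <- ymin[k[mid] + 1L]
    out[mid] <- y0 + (y1 - y0) * (grid[mid] - x0) / (x1 - x0)
  }
  out
}

#' Per-protein-averaged ROC curve
#'
#' Computes one ROC curve per protein from its own residues' probabilities,
#' then vertically averages: true-positive rates are linearly interpolated
#' onto a common false-positive-rate grid (0 to 1, step 0.01) and averaged
#' across proteins at each grid point. Proteins lacking a positive or a
#' negative residue have an undefined ROC and are excluded with a warning.
#'
#' @param predictions A `prediction_table` (must carry `prob` and `label`).
#' @param grid_step Spacing of the fpr grid (default 0.01).
#' @return A `roc_curve` list: `fpr` (grid), `mean_tpr`, `n_proteins`, and
#'   `per_protein` (matrix of per-protein tpr, proteins in columns).
#' @export
per_protein_roc <- function(predictions, grid_step = 0.01) {
  stopifnot(all(c("prob", "label") %in% names(predictions)))
  grid <- seq(0, 1, by = grid_step)
  prot <- paste(predictions$pdb_id, predictions$chain_id)
  curves <- list()
  skipped <- character(0)
  for (p in unique(prot)) {
    i <- prot == p
    lab <- predictions$label[i]
    if (sum(lab == 1L) == 0L || sum(lab == 0L) == 0L) {
      skipped <- c(skipped, p)
      next
    }
    curves[[p]] <- single_roc_tpr(predictions$prob[i], lab, grid)
  }
  if (length(skipped)) {
    warning(length(skipped), " protein(s) without both classes excluded ",
            "from ROC averaging: ", paste(skipped, collapse = ", "))
  }
  if (!length(curves)) stop("no protein has both classes; ROC undefined")
  per_protein <- do.call(cbind, curves)
  structure(list(fpr = grid,
                 mean_tpr = rowMeans(per_protein),
                 n_proteins = ncol(per_protein),
                 per_protein = per_protein),
            class = "roc_curve")
}

#' Area under an averaged ROC curve
#'
#' Trapezoidal area under the mean true-positive rate on the fpr grid.
#'
#' @param roc A `roc_curve` from [per_protein_roc()].
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  x <- roc$fpr
  y <- roc$mean_tpr
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Rank of each catalytic residue
#'
#' Reports, for every labelled catalytic residue, its within-protein rank by
#' predicted catalytic probability (rank 1 = most probable residue of the
#' protein) — the per-protein ranking used when comparing individual
#' predictions across methods.
#'
#' @param predictions A `prediction_table`.
#' @return Data frame with columns `protein` (`pdb:chain`), `residue`
#'   (one-letter code + residue number), `res_seq`, `rank`, `prob`.
#' @export
rank_report <- function(predictions) {
  stopifnot(all(c("rank", "label") %in% names(predictions)))
  cat_rows <- predictions[predictions$label == 1L, , drop = FALSE]
  out <- data.frame(
    protein = paste0(cat_rows$pdb_id, ":", cat_rows$chain_id),
    residue = paste0(cat_rows$aa, cat_rows$res_seq, cat_rows$icode),
    res_seq = cat_rows$res_seq,
    rank = cat_rows$rank,
    prob = cat_rows$prob,
    stringsAsFactors = FALSE
  )
  out[order(out$protein, out$res_seq), , drop = FALSE]
}

#' Write an averaged ROC curve to TSV
#'
#' @param roc A `roc_curve`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_roc_tsv <- function(roc, path) {
  stopifnot(inherits(roc, "roc_curve"))
  utils::write.table(
    data.frame(fpr = roc$fpr, mean_tpr = roc$mean_tpr,
               n_proteins = roc$n_proteins),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
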