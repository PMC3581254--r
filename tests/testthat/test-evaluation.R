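test_that("confusion counts match hand counts", {
  c1 <- confusion(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(unclass(c1), list(tp = 2L, fp = 0L, tn = 2L, fn = 0L))
  c2 <- confusion(c(0, 1, 0, 1), c(1, 0, 1, 0))
  expect_equal(unclass(c2), list(tp = 0L, fp = 2L, tn = 0L, fn = 2L))
  c3 <- confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unclass(c3), list(tp = 1L, fp = 1L, tn = 1L, fn = 1L))
  expect_error(confusion(c(1, 0), c(1, 0, 0)), "length mismatch")
})

test_that("metrics follow the closed forms, with NA for undefined cases", {
  perfect <- classification_metrics(confusion(c(1, 1, 0, 0), c(1, 1, 0, 0)))
  expect_equal(perfect, list(sensitivity = 1, specificity = 1, mcc = 1))
  chance <- classification_metrics(confusion(c(1, 1, 0, 0), c(1, 0, 1, 0)))
  expect_equal(chance, list(sensitivity = 0.5, specificity = 0.5, mcc = 0))
  # tp=90 fp=10 tn=60 fn=40, hand-computed from the defining formulas
  counts <- structure(list(tp = 90L, fp = 10L, tn = 60L, fn = 40L),
                      class = "confusion_counts")
  m <- classification_metrics(counts)
  expect_equal(m$sensitivity, 0.6923077, tolerance = 1e-6)
  expect_equal(m$specificity, 0.8571429, tolerance = 1e-6)
  expect_equal(m$mcc, 0.5241424, tolerance = 1e-6)
  # no actual positives: sensitivity undefined, not zero
  none <- classification_metrics(confusion(c(0, 0), c(0, 0)))
  expect_true(is.na(none$sensitivity))
  expect_equal(none$specificity, 1)
  expect_true(is.na(none$mcc))
})

test_that("MCC is invariant under a joint class swap", {
  set.seed(31)
  for (i in 1:10) {
    pred <- rbinom(50, 1, 0.4)
    act <- rbinom(50, 1, 0.2)
    m1 <- classification_metrics(confusion(pred, act))
    m2 <- classification_metrics(confusion(1 - pred, 1 - act))
    expect_equal(m1$mcc, m2$mcc)
    expect_equal(m1$sensitivity, m2$specificity)
  }
})

roc_table <- function(prob, label, protein = "P1") {
  structure(data.frame(pdb_id = protein, chain_id = "A",
                       res_seq = seq_along(prob), icode = "", aa = "A",
                       prob = prob, rank = NA_integer_,
                       pred = as.integer(prob >= 0.5), label = label),
            class = c("prediction_table", "data.frame"))
}

test_that("per-protein ROC handles perfect and inverted rankings", {
  perfect <- roc_table(seq(1, 0.1, length.out = 10),
                       c(1, 1, rep(0, 8)))
  roc <- per_protein_roc(perfect)
  expect_equal(roc$mean_tpr[roc$fpr > 0], rep(1, sum(roc$fpr > 0)))
  worst <- roc_table(seq(1, 0.1, length.out = 10), c(rep(0, 9), 1))
  roc_w <- per_protein_roc(worst)
  expect_equal(roc_w$mean_tpr[roc_w$fpr < 1], rep(0, sum(roc_w$fpr < 1)))
  expect_equal(roc_w$mean_tpr[roc_w$fpr == 1], 1)
})

test_that("vertical averaging is the pointwise mean of per-protein curves", {
  set.seed(17)
  a <- roc_table(runif(30), rbinom(30, 1, 0.3), "P1")
  b <- roc_table(runif(40), rbinom(40, 1, 0.3), "P2")
  both <- rbind(a, b)
  class(both) <- c("prediction_table", "data.frame")
  roc_a <- per_protein_roc(a)
  roc_b <- per_protein_roc(b)
  roc_ab <- per_protein_roc(both)
  expect_equal(roc_ab$mean_tpr, (roc_a$mean_tpr + roc_b$mean_tpr) / 2)
  expect_equal(roc_ab$n_proteins, 2L)
  # identical proteins average to any single curve
  twin <- rbind(a, transform(a, pdb_id = "P9"))
  class(twin) <- c("prediction_table", "data.frame")
  expect_equal(per_protein_roc(twin)$mean_tpr, roc_a$mean_tpr)
  # monotone with proper endpoints
  expect_true(all(diff(roc_ab$mean_tpr) >= -1e-12))
  expect_equal(roc_ab$mean_tpr[length(roc_ab$mean_tpr)], 1)
})

test_that("proteins lacking a class are excluded with a warning", {
  a <- roc_table(runif(20), c(rep(1, 3), rep(0, 17)), "P1")
  b <- roc_table(runif(10), rep(0, 10), "P2")
  both <- rbind(a, b)
  class(both) <- c("prediction_table", "data.frame")
  expect_warning(roc <- per_protein_roc(both), "excluded")
  expect_equal(roc$n_proteins, 1L)
  all_neg <- roc_table(runif(5), rep(0, 5))
  expect_error(suppressWarnings(per_protein_roc(all_neg)), "no protein")
})

test_that("interpolated AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  prob <- runif(200)
  label <- rbinom(200, 1, plogis(3 * (prob - 0.5)))
  tab <- roc_table(prob, label)
  auc_pkg <- roc_auc(per_protein_roc(tab))
  auc_ref <- as.numeric(pROC::auc(pROC::roc(label, prob, quiet = TRUE)))
  expect_equal(auc_pkg, auc_ref, tolerance = 0.02)
  expect_gte(auc_pkg, 0)
  expect_lte(auc_pkg, 1)
})

test_that("the rank report lists catalytic residues with their ranks", {
  tab <- roc_table(c(0.9, 0.1, 0.5), c(1, 0, 0))
  tab$rank <- c(1L, 3L, 2L)
  rep_ <- rank_report(tab)
  expect_equal(nrow(rep_), 1L)
  expect_equal(rep_$rank, 1L)
  expect_equal(rep_$protein, "P1:A")
  # ties produce distinct ranks via the residue-number rule
  tied <- roc_table(c(0.7, 0.7, 0.2), c(1, 1, 0))
  tied$rank <- c(1L, 2L, 3L)
  expect_equal(rank_report(tied)$rank, c(1L, 2L))
})
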