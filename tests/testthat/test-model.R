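make_toy_table <- function(X, y, protein = rep("P1", length(y))) {
  structure(list(
    X = X, y = as.integer(y),
    groups = data.frame(pdb_id = protein, chain_id = "A",
                        res_seq = seq_along(y), icode = "",
                        aa = "A", stringsAsFactors = FALSE),
    feature_names = colnames(X), feature_set = "toy", n_dropped = 0L
  ), class = "feature_table")
}

separable_toy <- function(n = 40, seed = 1) {
  set.seed(seed)
  half <- n / 2
  X <- rbind(matrix(rnorm(half * 2, 1, 0.1), ncol = 2),
             matrix(rnorm(half * 2, -1, 0.1), ncol = 2))
  colnames(X) <- c("f1", "f2")
  make_toy_table(X, rep(c(1, 0), each = half))
}

test_that("balanced subsampling yields exact 1:1 counts deterministically", {
  set.seed(2)
  X <- matrix(rnorm(13), ncol = 1, dimnames = list(NULL, "f"))
  tab <- make_toy_table(X, c(rep(1, 3), rep(0, 10)))
  bal <- balanced_subsample(tab, seed = 5)
  expect_equal(length(bal$y), 6L)
  expect_equal(sum(bal$y == 1L), 3L)
  expect_equal(sum(bal$y == 0L), 3L)
  expect_true(all(which(tab$y == 1L) %in% bal$groups$res_seq))
  bal2 <- balanced_subsample(tab, seed = 5)
  expect_identical(bal$X, bal2$X)
  too_few <- make_toy_table(X[1:5, , drop = FALSE], c(1, 1, 1, 0, 0))
  expect_error(balanced_subsample(too_few, 1), "fewer negatives")
})

test_that("negative draws are uniform across seeds", {
  n_pos <- 100; n_neg <- 1000; n_seeds <- 400
  X <- matrix(0, n_pos + n_neg, 1, dimnames = list(NULL, "f"))
  tab <- make_toy_table(X, c(rep(1, n_pos), rep(0, n_neg)))
  counts <- integer(n_neg)
  for (s in seq_len(n_seeds)) {
    bal <- balanced_subsample(tab, seed = s)
    picked <- bal$groups$res_seq[bal$y == 0L] - n_pos
    counts[picked] <- counts[picked] + 1L
  }
  p <- n_pos / n_neg
  se <- sqrt(p * (1 - p) / n_seeds)
  freq <- counts / n_seeds
  expect_true(all(abs(freq - p) <= 4 * se))
  expect_equal(mean(freq), p)  # exactly n_pos drawn per seed
})

test_that("cross-validation folds partition proteins without leakage", {
  tab <- small_feature_table(n_proteins = 10, n_residues = 40)
  folds <- cv_split(tab, n_folds = 5, seed = 3)
  prot <- paste(tab$groups$pdb_id, tab$groups$chain_id)
  fold_of_protein <- tapply(folds, prot, unique)
  expect_true(all(lengths(fold_of_protein) == 1L))  # no protein in two folds
  expect_equal(sort(unique(folds)), 1:5)
  expect_equal(as.integer(table(unlist(fold_of_protein))), rep(2L, 5))
  expect_error(cv_split(tab, n_folds = 11), "fewer proteins")
})

test_that("tuning finds a separator on linearly separable data", {
  tab <- separable_toy(n = 40)
  model <- tune_and_train(tab, fast_config())
  expect_s3_class(model, "trained_model")
  expect_true(model$cost %in% fast_config()$cost_grid)
  expect_true(model$gamma %in% fast_config()$gamma_grid)
  pt <- predict(model, tab)
  expect_equal(mean(pt$pred == pt$label), 1.0)
})

test_that("inner-CV MCC is near zero on label-shuffled data", {
  set.seed(44)
  X <- matrix(rnorm(400), ncol = 2, dimnames = list(NULL, c("f1", "f2")))
  tab <- make_toy_table(X, sample(rep(c(0, 1), each = 100)))
  model <- tune_and_train(tab, fast_config(seed = 44))
  expect_lt(max(model$tuning$mcc, na.rm = TRUE), 0.3)
})

test_that("predictions rank residues per protein with deterministic ties", {
  tab <- separable_toy(n = 20)
  model <- tune_and_train(tab, fast_config())
  two <- small_feature_table(n_proteins = 2, n_residues = 25, seed = 6)
  model2 <- tune_and_train(balanced_subsample(two, 1), fast_config())
  pt <- predict(model2, two)
  for (p in unique(pt$pdb_id)) {
    r <- pt$rank[pt$pdb_id == p]
    expect_setequal(r, seq_along(r))  # a permutation of 1..N within protein
    i <- pt$pdb_id == p
    expect_equal(pt$res_seq[i][order(pt$rank[i])],
                 pt$res_seq[i][order(-pt$prob[i], pt$res_seq[i])])
  }
  expect_true(all(pt$prob >= 0 & pt$prob <= 1))
  # mismatched features are refused
  expect_error(predict(model, two), "feature names")
})

test_that("the evaluation protocol is deterministic given data and seed", {
  tab <- small_feature_table(n_proteins = 6, n_residues = 40, seed = 10)
  cfg <- fast_config(seed = 10)
  r1 <- evaluate_protocol(tab, cfg)
  r2 <- evaluate_protocol(tab, cfg)
  expect_identical(r1$predictions$prob, r2$predictions$prob)
  expect_identical(r1$metrics, r2$metrics)
  # outer folds never mix proteins between train and test by construction;
  # check that every protein appears exactly once in the held-out predictions
  prot <- paste(tab$groups$pdb_id, tab$groups$chain_id)
  expect_setequal(unique(paste(r1$predictions$pdb_id,
                               r1$predictions$chain_id)), unique(prot))
  expect_equal(nrow(r1$predictions), nrow(tab$X))
})
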