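# evaluation: folds, masking, ranking, ROC/AUC, aggregation, run_cv

test_that("make_folds covers all schemes with the right counts", {
  A <- toy_A()  # 4 known pairs
  expect_length(make_folds(A, "global-LOOCV"), 4)

  set.seed(3)
  Av <- matrix(0, 5, 4, dimnames = list(paste0("m", 1:5), paste0("d", 1:4)))
  Av[sample(20, 10)] <- 1
  A10 <- association_matrix(Av)
  f5 <- make_folds(A10, "kfold", k = 5, reps = 1, seed = 1)
  expect_length(f5, 5)
  expect_true(all(vapply(f5, function(f) nrow(f$test_pairs), 0L) == 2))

  # 11 knowns over k = 5: sizes {3,2,2,2,2}, deterministic under the seed
  Av11 <- Av; Av11[which(Av == 0)[1]] <- 1
  A11 <- association_matrix(Av11)
  f11a <- make_folds(A11, "kfold", k = 5, reps = 1, seed = 9)
  sizes <- vapply(f11a, function(f) nrow(f$test_pairs), 0L)
  expect_identical(sort(sizes, decreasing = TRUE), c(3L, 2L, 2L, 2L, 2L))
  f11b <- make_folds(A11, "kfold", k = 5, reps = 1, seed = 9)
  expect_identical(f11a, f11b)
  # folds partition the known pairs
  all_pairs <- do.call(rbind, lapply(f11a, `[[`, "test_pairs"))
  expect_equal(nrow(unique(all_pairs)), 11)

  # LODOCV: one fold per disease with knowns; empty diseases warned + skipped
  Avz <- Av; Avz[, 4] <- 0
  expect_warning(fl <- make_folds(association_matrix(Avz), "global-LODOCV"),
                 "no known pair")
  expect_length(fl, sum(colSums(Avz) > 0))
})

test_that("mask_fold zeroes exactly the test pairs and validates them", {
  A <- toy_A()
  folds <- make_folds(A, "global-LOOCV")
  tr <- mask_fold(A, folds[[1]])
  expect_equal(sum(A$values) - sum(tr$values), 1)
  expect_equal(tr$values[folds[[1]]$test_pairs], 0)
  bad <- folds[[1]]; bad$test_pairs <- matrix(c(1L, 2L), 1)  # (m1,d2) unknown
  expect_error(mask_fold(A, bad), "not known")
  empty <- folds[[1]]; empty$test_pairs <- folds[[1]]$test_pairs[0, , drop = FALSE]
  expect_error(mask_fold(A, empty), "empty test set")
})

test_that("rank_test_pairs uses midranks against original-A unknowns", {
  A <- association_matrix(matrix(c(1, 0, 0, 0), 2, 2,
                                 dimnames = list(c("m1", "m2"), c("d1", "d2"))))
  fold <- list(scheme = "global-LOOCV",
               test_pairs = matrix(c(1L, 1L), 1), rep = 1L, fold = 1L, seed = 1L)
  Sv <- matrix(c(0.9, 0.1, 0.2, 0.3), 2, 2, dimnames = dimnames(A$values))
  S <- score_matrix(Sv)
  rk <- rank_test_pairs(S, fold, A, "global")
  expect_equal(rk$rank, 1)          # above all three unknowns
  expect_equal(rk$n_candidates, 3)  # held-out pair itself is not a candidate
  # tie -> midrank 1.5
  Sv2 <- Sv; Sv2["m2", "d2"] <- 0.9
  rk2 <- rank_test_pairs(score_matrix(Sv2), fold, A, "global")
  expect_equal(rk2$rank, 1.5)
  # local mode restricts candidates to the disease column
  rkl <- rank_test_pairs(score_matrix(Sv2), fold, A, "local")
  expect_equal(rkl$n_candidates, 1)
  expect_equal(rkl$rank, 1)

  # 3-candidate hand case against exhaustive comparison
  set.seed(5)
  for (i in 1:20) {
    sc <- sample(seq(0.1, 0.9, 0.1), 4, replace = TRUE)
    Sv3 <- matrix(c(sc[1], sc[2], sc[3], sc[4]), 2, 2,
                  dimnames = dimnames(A$values))
    rk3 <- rank_test_pairs(score_matrix(Sv3), fold, A, "global")
    cand <- c(Sv3[2, 1], Sv3[1, 2], Sv3[2, 2])
    expect_equal(rk3$rank, 1 + sum(cand > Sv3[1, 1]) + 0.5 * sum(cand == Sv3[1, 1]))
  }
})

test_that("roc_auc matches Mann-Whitney, its own curve, and the oracle", {
  expect_equal(roc_auc(0.9, c(0.1, 0.8))$auc, 1)
  expect_equal(roc_auc(0.5, c(0.5, 0.1))$auc, 0.75)
  expect_equal(roc_auc(c(0.3, 0.3), c(0.3, 0.3, 0.3))$auc, 0.5)
  expect_error(roc_auc(numeric(), 0.5), "empty")

  set.seed(17)
  grid <- seq(0.1, 0.9, 0.1)
  for (i in 1:200) {
    te <- sample(grid, sample(1:6, 1), replace = TRUE)
    ca <- sample(grid, sample(1:6, 1), replace = TRUE)
    r <- roc_auc(te, ca)
    expect_equal(r$auc, oracle_auc(te, ca), tolerance = 1e-15)
    # trapezoidal area under the emitted curve equals the statistic
    area <- sum(diff(r$roc$fpr) * (r$roc$tpr[-nrow(r$roc)] + r$roc$tpr[-1]) / 2)
    expect_equal(area, r$auc, tolerance = 1e-12)
    expect_equal(unlist(r$roc[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(r$roc[nrow(r$roc), ]), c(fpr = 1, tpr = 1))
  }
})

test_that("aggregate_evaluation reports mean and sample sd", {
  a <- aggregate_evaluation(c(0.8, 0.9))
  expect_equal(a$mean, 0.85)
  expect_equal(a$sd, 0.0707107, tolerance = 1e-6)
  one <- aggregate_evaluation(0.8)
  expect_equal(one$sd, 0)
  expect_false(one$sd_defined)
  expect_equal(aggregate_evaluation(c(0.7, 0.7, 0.7))$sd, 0)
})

test_that("run_fold propagates the mask and recovery works across folds", {
  ds <- cached("tiny_world", generate_dataset(
    synthetic_spec(nm = 40, nd = 20, latent_rank = 3, density = 0.12,
                   dag_depth = 2, seed = 0)))
  folds <- make_folds(ds$A, "kfold", k = 3, reps = 1, seed = 1)
  # masking flips the SSM association entries of the test pairs to 0
  tr <- mask_fold(ds$A, folds[[1]])
  sims <- compute_similarities(tr, ds$dags, ds$fs, ds$fs_coverage)
  ssm <- build_ssm(tr, sims$SM)
  expect_true(all(association_block(ssm)[folds[[1]]$test_pairs] == 0))

  # recovery across folds on the standard fixture, seeds 0-4: held-out
  # positives outrank the median unknown pair in at least 70% of folds
  ok <- 0; total <- 0
  for (s in 0:4) {
    world <- generate_dataset(synthetic_spec(seed = s))
    wfolds <- make_folds(world$A, "kfold", k = 3, reps = 1, seed = s)
    for (fold in wfolds) {
      sc <- run_fold(fold, world$A, world$dags, world$fs, world$fs_coverage)
      rk <- rank_test_pairs(sc, fold, world$A, "global")
      u <- 1 - (rk$rank - 1) / rk$n_candidates
      ok <- ok + (median(u) > 0.5)
      total <- total + 1
    }
  }
  expect_gte(ok / total, 0.7)
})

test_that("run_cv is deterministic and degenerate local equals global", {
  ds <- cached("tiny_world", generate_dataset(
    synthetic_spec(nm = 40, nd = 20, latent_rank = 3, density = 0.12,
                   dag_depth = 2, seed = 0)))
  args <- list(A = ds$A, dags = ds$dags, fs = ds$fs,
               fs_coverage = ds$fs_coverage, scheme = "kfold", k = 3,
               reps = 1, seed = 5, epochs = 5, hidden1 = 24,
               latent_dim = 6, hidden3 = 24)
  r1 <- do.call(run_cv, args)
  r2 <- do.call(run_cv, args)
  expect_identical(r1$ranks, r2$ranks)
  expect_identical(r1$auc, r2$auc)
  expect_true(r1$auc >= 0 && r1$auc <= 1)

  # one-disease world: local and global candidate sets coincide
  # (need >= 2 knowns so LOOCV masking never empties the column)
  j <- which(ds$dags$coverage & colSums(ds$A$values) >= 2)[1]
  A1 <- association_matrix(ds$A$values[, j, drop = FALSE])
  dg1 <- ds$dags
  dg1$coverage <- dg1$coverage[j]
  dg1$dags <- dg1$dags[names(dg1$coverage)]
  base <- list(A = A1, dags = dg1, fs = ds$fs, fs_coverage = ds$fs_coverage,
               seed = 7, epochs = 4, hidden1 = 24, latent_dim = 6,
               hidden3 = 24)
  g <- do.call(run_cv, c(base, scheme = "global-LOOCV"))
  l <- do.call(run_cv, c(base, scheme = "local-LOOCV"))
  expect_equal(l$auc, g$auc, tolerance = 1e-12)
})
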