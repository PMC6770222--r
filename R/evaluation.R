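# Cross-validation harness: global/local LOOCV, repeated k-fold,
# global/local leave-one-disease-out, with rank-based ROC/AUC.
#
# Within every fold the held-out associations are zeroed in A and the
# interaction-profile kernels, integrated similarities and spliced matrices
# are recomputed from the masked A before retraining both VAEs, so no test
# label can leak through the similarity side of the features. Candidate
# (negative) pairs for ranking are always the pairs unknown in the ORIGINAL
# adjacency matrix: held-out positives are never counted as negatives.

.SCHEMES <- c("global-LOOCV", "local-LOOCV", "kfold",
              "global-LODOCV", "local-LODOCV")

#' Build cross-validation folds over the known associations
#'
#' * LOOCV: one fold per known pair (5430 folds for the reference dataset).
#' * kfold: `reps` independent seeded random partitions of the known pairs
#'   into `k` near-equal subsets (sizes differ by at most one; 5 x 1086 for
#'   the reference dataset).
#' * LODOCV: one fold per disease, holding out all of that disease's known
#'   pairs; diseases with no known pair are skipped with a warning.
#'
#' @param A an [association_matrix()].
#' @param scheme one of `r paste(.SCHEMES, collapse = ", ")`.
#' @param k number of folds (kfold only).
#' @param reps number of repetitions (kfold only).
#' @param seed partition seed.
#' @return list of fold specs; each has `scheme`, `test_pairs` (two-column
#'   index matrix into `A$values`), `rep`, `fold`, `seed`.
#' @export
make_folds <- function(A, scheme, k = 5, reps = 1, seed = 1L) {
  stopifnot(inherits(A, "association_matrix"))
  scheme <- match.arg(scheme, .SCHEMES)
  known <- which(A$values == 1, arr.ind = TRUE)
  dimnames(known) <- NULL
  if (nrow(known) == 0) stop("make_folds: no known associations")
  # the global/local prefix only changes ranking, not the folds: seed by the
  # scheme family so e.g. global- and local-LOOCV retrain identical models
  family <- sub("^(global|local)-", "", scheme)
  fold_spec <- function(pairs, rep, fold)
    list(scheme = scheme, test_pairs = pairs, rep = rep, fold = fold,
         seed = derive_seed(seed, family, rep, fold))
  if (scheme %in% c("global-LOOCV", "local-LOOCV")) {
    return(lapply(seq_len(nrow(known)), function(i)
      fold_spec(known[i, , drop = FALSE], 1L, i)))
  }
  if (scheme == "kfold") {
    stopifnot(k >= 2)
    folds <- list()
    n <- nrow(known)
    sizes <- rep(n %/% k, k)
    if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
    for (r in seq_len(reps)) {
      set.seed(derive_seed(seed, "partition", r))
      ord <- sample.int(n)          # shuffled pair order
      grp <- integer(n)
      grp[ord] <- rep(seq_len(k), times = sizes)
      for (f in seq_len(k))
        folds[[length(folds) + 1L]] <-
          fold_spec(known[grp == f, , drop = FALSE], r, f)
    }
    return(folds)
  }
  # LODOCV: one fold per disease with at least one known pair
  folds <- list()
  empty <- character()
  for (j in seq_along(A$disease_ids)) {
    pairs <- known[known[, 2] == j, , drop = FALSE]
    if (nrow(pairs) == 0) { empty <- c(empty, A$disease_ids[j]); next }
    folds[[length(folds) + 1L]] <- fold_spec(pairs, 1L, j)
  }
  if (length(empty) > 0)
    warning("make_folds: skipped disease(s) with no known pair: ",
            paste(empty, collapse = ", "))
  folds
}

#' Mask a fold's test pairs out of the adjacency matrix
#'
#' @param A an [association_matrix()].
#' @param fold a fold spec from [make_folds()].
#' @return the training [association_matrix()] with the test entries set 0.
#' @export
mask_fold <- function(A, fold) {
  stopifnot(inherits(A, "association_matrix"))
  if (nrow(fold$test_pairs) == 0) stop("mask_fold: fold has an empty test set")
  vals <- A$values
  if (!all(vals[fold$test_pairs] == 1))
    stop("mask_fold: fold test pairs are not known associations in A")
  vals[fold$test_pairs] <- 0
  association_matrix(vals, A$mirna_ids, A$disease_ids)
}

#' Score one cross-validation fold
#'
#' Masks the fold's test pairs, recomputes kernels/integrated similarities
#' and spliced matrices from the masked matrix, retrains both VAEs with the
#' fold-derived seed, and returns the full score matrix.
#'
#' @param fold fold spec from [make_folds()].
#' @param A the original [association_matrix()].
#' @param dags,fs,fs_coverage similarity inputs, see [mdvae_fit()].
#' @param ... further arguments (hyperparameters) passed to [mdvae_fit()].
#' @return the fold's [score_matrix()].
#' @export
run_fold <- function(fold, A, dags, fs = NULL, fs_coverage = NULL, ...) {
  A_train <- mask_fold(A, fold)
  fit <- mdvae_fit(A_train, dags, fs, fs_coverage, seed = fold$seed, ...)
  fit$scores
}

#' Midrank of each test pair among candidate pairs
#'
#' Candidates are the pairs unknown in the original adjacency matrix —
#' globally, or restricted to the test pair's disease column in local mode.
#' The rank is `1 + #higher-scoring candidates + 0.5 * #ties`, a real number.
#'
#' @param scores a [score_matrix()] (typically from [run_fold()]).
#' @param fold fold spec whose `test_pairs` are ranked.
#' @param A the original [association_matrix()] defining the unknown pairs.
#' @param mode `"global"` or `"local"`.
#' @return data.frame with `mirna`, `disease` (indices), `score`, `rank`,
#'   `n_candidates`.
#' @export
rank_test_pairs <- function(scores, fold, A, mode = c("global", "local")) {
  mode <- match.arg(mode)
  stopifnot(inherits(scores, "score_matrix"), inherits(A, "association_matrix"))
  S <- scores$values
  unknown <- A$values == 0
  pairs <- fold$test_pairs
  out <- vector("list", nrow(pairs))
  if (mode == "global") cand_all <- S[unknown]
  for (i in seq_len(nrow(pairs))) {
    mi <- pairs[i, 1]; dj <- pairs[i, 2]
    cand <- if (mode == "global") cand_all else S[unknown[, dj], dj]
    ts <- S[mi, dj]
    r <- 1 + sum(cand > ts) + 0.5 * sum(cand == ts)
    out[[i]] <- data.frame(mirna = mi, disease = dj, score = ts, rank = r,
                           n_candidates = length(cand))
  }
  do.call(rbind, out)
}

#' Rank-based ROC curve and AUC
#'
#' AUC is the Mann-Whitney statistic `P(test > candidate) + 0.5 P(tie)`;
#' the ROC curve is the threshold sweep over the pooled scores, whose
#' trapezoidal area equals the Mann-Whitney AUC exactly.
#'
#' @param test_scores scores of the positives (held-out known pairs).
#' @param candidate_scores scores of the negatives (unknown pairs).
#' @return list with `auc` and `roc` (data.frame `fpr`, `tpr`, starting at
#'   (0,0) and ending at (1,1)).
#' @export
roc_auc <- function(test_scores, candidate_scores) {
  if (length(test_scores) == 0 || length(candidate_scores) == 0)
    stop("roc_auc: empty score list")
  nt <- length(test_scores); nc <- length(candidate_scores)
  r <- rank(c(test_scores, candidate_scores))  # midranks
  auc <- (sum(r[seq_len(nt)]) - nt * (nt + 1) / 2) / (nt * nc)
  thr <- sort(unique(c(test_scores, candidate_scores)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(test_scores >= t) / nt, 0)
  fpr <- vapply(thr, function(t) sum(candidate_scores >= t) / nc, 0)
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  if (roc$fpr[nrow(roc)] != 1 || roc$tpr[nrow(roc)] != 1)
    roc <- rbind(roc, data.frame(fpr = 1, tpr = 1))
  list(auc = auc, roc = roc)
}

# per-pair U statistic from a midrank: P(test outscores a random candidate)
.rank_to_u <- function(rank, n_candidates) 1 - (rank - 1) / n_candidates

#' Aggregate per-repetition AUCs
#'
#' @param aucs numeric vector of per-repetition AUCs.
#' @return list with `mean`, `sd` (0 with `sd_defined = FALSE` for a single
#'   repetition), `n_reps`, `aucs`.
#' @export
aggregate_evaluation <- function(aucs) {
  stopifnot(length(aucs) >= 1, all(aucs >= 0 & aucs <= 1))
  list(mean = mean(aucs),
       sd = if (length(aucs) > 1) stats::sd(aucs) else 0,
       sd_defined = length(aucs) > 1,
       n_reps = length(aucs),
       aucs = aucs)
}

#' Run a full cross-validation evaluation
#'
#' Builds the folds, retrains the two-VAE model per fold (recomputing
#' kernels and integrated similarities from the masked adjacency matrix),
#' ranks every held-out pair against the unknown pairs of the original
#' matrix, and converts midranks to an AUC per repetition.
#'
#' LOOCV on real-scale data retrains thousands of models; `subsample` limits
#' the evaluation to a seeded random subset of folds for tractability.
#'
#' @param A,dags,fs,fs_coverage inputs as in [mdvae_fit()].
#' @param scheme evaluation scheme, see [make_folds()]; the `global-`/`local-`
#'   prefix selects the candidate set for ranking.
#' @param k,reps k-fold parameters.
#' @param seed root seed (fold seeds are derived from it).
#' @param subsample optional cap on the number of folds evaluated.
#' @param ... VAE/similarity hyperparameters forwarded to [mdvae_fit()].
#' @return list with `scheme`, `auc` (mean), `sd`, `per_rep` AUC vector,
#'   `ranks` (per-pair data.frame with `rep` column), `n_folds`, `seed`.
#' @export
run_cv <- function(A, dags, fs = NULL, fs_coverage = NULL,
                   scheme = "kfold", k = 5, reps = 1, seed = 1L,
                   subsample = NULL, ...) {
  scheme <- match.arg(scheme, .SCHEMES)
  mode <- if (startsWith(scheme, "local")) "local" else "global"
  folds <- make_folds(A, scheme, k = k, reps = reps, seed = seed)
  if (!is.null(subsample) && subsample < length(folds)) {
    set.seed(derive_seed(seed, "subsample"))
    folds <- folds[sort(sample.int(length(folds), subsample))]
  }
  ranks <- vector("list", length(folds))
  failed <- 0L
  for (i in seq_along(folds)) {
    fold <- folds[[i]]
    scores <- tryCatch(
      run_fold(fold, A, dags, fs, fs_coverage, ...),
      error = function(e) {
        warning(sprintf("run_cv: fold %d (rep %d) failed and was excluded: %s",
                        fold$fold, fold$rep, conditionMessage(e)))
        NULL
      })
    if (is.null(scores)) { failed <- failed + 1L; next }
    rk <- rank_test_pairs(scores, fold, A, mode)
    rk$rep <- fold$rep
    ranks[[i]] <- rk
  }
  ranks <- do.call(rbind, ranks)
  if (is.null(ranks)) stop("run_cv: every fold failed")
  ranks$u <- .rank_to_u(ranks$rank, ranks$n_candidates)
  per_rep <- vapply(split(ranks$u, ranks$rep), mean, 0)
  agg <- aggregate_evaluation(unname(per_rep))
  list(scheme = scheme, auc = agg$mean, sd = agg$sd, per_rep = agg$aucs,
       ranks = ranks, n_folds = length(folds), n_failed = failed, seed = seed)
}
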