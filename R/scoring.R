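# Scoring: deterministic reconstruction of the association block by each
# trained VAE (mean latent, no sampling), then averaging the two sides.

#' Association score matrix
#'
#' `nm x nd` matrix of predicted association scores in `(0,1)`, with
#' provenance (the seeds of the two VAEs that produced it, when known).
#'
#' @param values numeric matrix with miRNA rownames and disease colnames.
#' @param provenance optional list (seeds, checkpoints).
#' @return object of class `score_matrix`.
#' @export
score_matrix <- function(values, provenance = list()) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("score_matrix: dimnames required")
  if (any(!is.finite(values)) || any(values <= 0 | values >= 1))
    stop("score_matrix: entries must lie in (0,1)")
  structure(list(values = values, provenance = provenance),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix: %d miRNAs x %d diseases, scores in [%.3f, %.3f]\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Reconstruct the association block with a trained VAE
#'
#' Each input row is encoded to its latent mean (no reparameterisation
#' noise) and decoded; the association columns of the reconstruction are the
#' side's score block. Fully deterministic given the checkpoint.
#'
#' @param model a `trained_vae`.
#' @param data the [spliced_matrix()] the model was trained on (or one with
#'   identical layout).
#' @return score block: `nm x nd` for the miRNA side, `nd x nm` for the
#'   disease side, with dimnames taken from `data`.
#' @export
reconstruct_side <- function(model, data) {
  stopifnot(inherits(model, "trained_vae"), inherits(data, "spliced_matrix"))
  if (model$config$input_dim != ncol(data$values))
    stop("reconstruct_side: model input width does not match data")
  enc <- encode(model, data$values)
  xh <- decode(model, enc$mu)
  block <- xh[, data$assoc_cols, drop = FALSE]
  dimnames(block) <- list(rownames(data$values),
                          colnames(data$values)[data$assoc_cols])
  block
}

#' Average the two score blocks into the final score matrix
#'
#' `S = (s1 + t(s2)) / 2` with no further normalisation.
#'
#' @param s1 miRNA-side block (`nm x nd`).
#' @param s2 disease-side block (`nd x nm`).
#' @param provenance optional provenance list.
#' @return a [score_matrix()].
#' @export
combine_scores <- function(s1, s2, provenance = list()) {
  s1 <- as.matrix(s1); s2 <- as.matrix(s2)
  if (!identical(dim(s1), rev(dim(s2))))
    stop("combine_scores: t(s2) shape does not match s1")
  score_matrix((s1 + t(s2)) / 2, provenance)
}

#' Rank candidate miRNAs for one disease
#'
#' Returns the unknown pairs (not in `known`) of the given disease sorted by
#' descending score, ties broken by miRNA id, truncated to `k`.
#'
#' @param S a [score_matrix()].
#' @param known an [association_matrix()].
#' @param disease disease id.
#' @param k maximum number of candidates.
#' @return data.frame with columns `mirna_id`, `score`.
#' @export
rank_candidates <- function(S, known, disease, k = 50) {
  stopifnot(inherits(S, "score_matrix"), inherits(known, "association_matrix"),
            k >= 1)
  if (!disease %in% colnames(S$values))
    stop("rank_candidates: unknown disease id: ", disease)
  sc <- S$values[, disease]
  unknown <- known$values[, disease] == 0
  sc <- sc[unknown]
  ord <- order(-sc, names(sc), method = "radix")
  out <- data.frame(mirna_id = names(sc)[ord], score = unname(sc[ord]),
                    stringsAsFactors = FALSE)
  utils::head(out, k)
}

# fold-independent seed derivation (kept below 2^31)
derive_seed <- function(seed, ...) {
  s <- as.numeric(seed) %% 2147483647
  for (x in c(...)) {
    v <- sum(utf8ToInt(paste(x)))
    s <- (s * 69069 + v + 1) %% 2147483647
  }
  as.integer(s)
}

#' Fit the full two-VAE association prediction model
#'
#' End-to-end pipeline for one adjacency matrix: recompute interaction
#' profile kernels and integrated similarities from `A`, build both spliced
#' matrices, train the miRNA-side and disease-side VAEs, and average their
#' reconstructed association blocks.
#'
#' @param A an [association_matrix()] (training associations).
#' @param dags a [disease_dag_set()].
#' @param fs functional similarity `similarity_matrix` or `NULL`.
#' @param fs_coverage named logical of functional-similarity coverage.
#' @param seed integer; the two VAE seeds are derived from it.
#' @param epochs,batch_size,learning_rate,epsilon_std,hidden1,latent_dim,hidden3
#'   VAE hyperparameters, see [vae_config()].
#' @param delta,gamma_prime similarity hyperparameters.
#' @return list with `scores` ([score_matrix()]), `vae1`, `vae2`,
#'   `similarities`, `ssm`, `ssd`.
#' @export
mdvae_fit <- function(A, dags, fs = NULL, fs_coverage = NULL, seed = 1L,
                      epochs = 50, batch_size = 20, learning_rate = 0.001,
                      epsilon_std = 1, hidden1 = 300, latent_dim = 100,
                      hidden3 = 300, delta = 0.5, gamma_prime = 1) {
  sims <- compute_similarities(A, dags, fs, fs_coverage, delta, gamma_prime)
  ssm <- build_ssm(A, sims$SM)
  ssd <- build_ssd(A, sims$SD)
  seed1 <- derive_seed(seed, "vae1")
  seed2 <- derive_seed(seed, "vae2")
  cfg1 <- vae_config(ncol(ssm$values), hidden1, latent_dim, hidden3,
                     batch_size, learning_rate, epsilon_std, epochs,
                     seed = seed1)
  cfg2 <- vae_config(ncol(ssd$values), hidden1, latent_dim, hidden3,
                     batch_size, learning_rate, epsilon_std, epochs,
                     seed = seed2)
  vae1 <- train_vae(ssm, cfg1)
  vae2 <- train_vae(ssd, cfg2)
  s1 <- reconstruct_side(vae1, ssm)
  s2 <- reconstruct_side(vae2, ssd)
  scores <- combine_scores(s1, s2,
                           provenance = list(seed = seed, seed_vae1 = seed1,
                                             seed_vae2 = seed2))
  list(scores = scores, vae1 = vae1, vae2 = vae2, similarities = sims,
       ssm = ssm, ssd = ssd)
}

#' Degree-based popularity baseline scores
#'
#' Assigns every pair the training-degree popularity of its miRNA (row mean
#' of `A`). Used as the floor that the VAE pipeline must beat on synthetic
#' recovery benchmarks.
#'
#' @param A an [association_matrix()].
#' @return plain `nm x nd` numeric matrix of baseline scores.
#' @export
popularity_scores <- function(A) {
  stopifnot(inherits(A, "association_matrix"))
  matrix(rowMeans(A$values), nrow(A$values), ncol(A$values),
         dimnames = dimnames(A$values))
}
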