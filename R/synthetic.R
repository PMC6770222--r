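# Synthetic benchmark generator: a planted low-rank bipartite association
# structure plus the two side-information sources the real pipeline consumes
# (a functional-similarity matrix correlated with the miRNA factors, and
# per-disease term DAGs whose sharing reflects the disease factors).

#' Specification of a synthetic miRNA-disease dataset
#'
#' Defaults describe the standard recovery benchmark: 100 miRNAs x 60
#' diseases, rank-4 latent structure, 8% association density, similarity
#' noise 0.1, depth-3 DAG hierarchies, and 10% of diseases/miRNAs lacking
#' DAG/functional-similarity coverage.
#'
#' @param nm,nd numbers of miRNAs and diseases.
#' @param latent_rank rank of the planted factor structure.
#' @param density target mean association probability, in (0,1).
#' @param noise standard deviation of the symmetric noise added to the
#'   functional-similarity matrix.
#' @param dag_depth number of internal hierarchy levels in the disease DAGs.
#' @param fraction_without_dag,fraction_without_fs coverage gaps, in `[0,1)`.
#' @param seed integer seed.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(nm = 100, nd = 60, latent_rank = 4, density = 0.08,
                           noise = 0.1, dag_depth = 3,
                           fraction_without_dag = 0.1,
                           fraction_without_fs = 0.1, seed = 0L) {
  stopifnot(nm >= 2, nd >= 2, latent_rank >= 1, density > 0, density < 1,
            noise >= 0, dag_depth >= 1,
            fraction_without_dag >= 0, fraction_without_dag < 1,
            fraction_without_fs >= 0, fraction_without_fs < 1)
  structure(list(nm = as.integer(nm), nd = as.integer(nd),
                 latent_rank = as.integer(latent_rank), density = density,
                 noise = noise, dag_depth = as.integer(dag_depth),
                 fraction_without_dag = fraction_without_dag,
                 fraction_without_fs = fraction_without_fs,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# affine rescale of a symmetric matrix into [0,1] with unit diagonal
.cosine01 <- function(U) {
  nrm <- sqrt(rowSums(U^2))
  nrm[nrm == 0] <- 1
  C <- tcrossprod(U / nrm)
  S <- (C + 1) / 2
  diag(S) <- 1
  pmin(pmax(S, 0), 1)
}

#' Generate a complete synthetic dataset
#'
#' Draws latent factors `U` (miRNAs) and `V` (diseases) from a standard
#' normal, plants `P = logistic(c * U V' + b)` with `(c, b)` solved so the
#' mean of `P` equals the target density (the slope `c` normalises `U V'` to
#' unit spread), and samples `A ~ Bernoulli(P)`. Functional similarity is the
#' rescaled cosine similarity of the `U` rows plus symmetric Gaussian noise —
#' signal independent of the sampled `A`. Disease DAGs come from a
#' hierarchical clustering of the `V` rows: every disease's DAG is a chain
#' root -> level-1 cluster -> ... -> its own term, so diseases in the same
#' clusters share ancestors in proportion to their latent similarity.
#' Coverage fractions flag `round(fraction * n)` entities as lacking a DAG
#' or functional-similarity rows.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `A` ([association_matrix()]), `fs`
#'   (`similarity_matrix`, covered miRNAs only), `fs_coverage` (named
#'   logical), `dags` ([disease_dag_set()]), `truth` (the planted probability
#'   matrix `P`), `U`, `V`, and the `spec`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  nm <- spec$nm; nd <- spec$nd; r <- spec$latent_rank
  mirna_ids <- sprintf("mir-%03d", seq_len(nm))
  disease_ids <- sprintf("dis-%03d", seq_len(nd))
  U <- matrix(stats::rnorm(nm * r), nm, r)
  V <- matrix(stats::rnorm(nd * r), nd, r)
  M <- tcrossprod(U, V)
  # Logit scale calibrated once against the planted-truth oracle: slope
  # 2/sd(UV') gives the true probabilities a held-out-vs-unknown AUC ~0.9,
  # the predictability scale of the real benchmark data. (The mean
  # constraint below fixes the intercept; the slope is this calibration.)
  cc <- 2 / stats::sd(M)
  b <- stats::uniroot(function(b) mean(stats::plogis(cc * M + b)) - spec$density,
                      interval = c(-50, 50), tol = 1e-10)$root
  P <- stats::plogis(cc * M + b)
  A <- matrix(stats::rbinom(nm * nd, 1, P), nm, nd,
              dimnames = list(mirna_ids, disease_ids))
  # degenerate guard: every disease/miRNA all-zero would break the GIP kernel
  if (sum(A) == 0) stop("generate_dataset: infeasible density, empty A")
  dimnames(P) <- dimnames(A)

  # functional similarity from U (not from A), noised and symmetrised
  FS <- .cosine01(U)
  if (spec$noise > 0) {
    E <- matrix(stats::rnorm(nm * nm, 0, spec$noise), nm, nm)
    E <- (E + t(E)) / 2
    FS <- FS + E
    diag(FS) <- 1
    FS <- pmin(pmax(FS, 0), 1)
  }
  dimnames(FS) <- list(mirna_ids, mirna_ids)
  n_nofs <- round(spec$fraction_without_fs * nm)
  no_fs <- sample(mirna_ids, n_nofs)
  fs_coverage <- stats::setNames(!(mirna_ids %in% no_fs), mirna_ids)
  fs_ids <- mirna_ids[fs_coverage]
  fs <- similarity_matrix(FS[fs_ids, fs_ids, drop = FALSE], fs_ids, "FS")

  # disease DAGs from nested clustering of V
  hc <- stats::hclust(stats::dist(V), method = "ward.D2")
  edges <- rep(list(data.frame(disease = character(0), child = character(0),
                               parent = character(0))), nd)
  parent_term <- rep("ROOT", nd)
  for (lev in seq_len(spec$dag_depth)) {
    kl <- min(nd, 2^lev)
    cl <- stats::cutree(hc, k = kl)
    term <- sprintf("L%dC%02d", lev, cl)
    for (j in seq_len(nd)) {
      edges[[j]] <- rbind(edges[[j]],
                          data.frame(disease = disease_ids[j],
                                     child = term[j], parent = parent_term[j]))
    }
    parent_term <- term
  }
  for (j in seq_len(nd))
    edges[[j]] <- rbind(edges[[j]],
                        data.frame(disease = disease_ids[j],
                                   child = disease_ids[j],
                                   parent = parent_term[j]))
  n_nodag <- round(spec$fraction_without_dag * nd)
  no_dag <- sample(disease_ids, n_nodag)
  dag_list <- lapply(which(!(disease_ids %in% no_dag)), function(j) {
    e <- edges[[j]][c("child", "parent")]
    list(terms = unique(c(disease_ids[j], e$child, e$parent)), edges = e)
  })
  names(dag_list) <- disease_ids[!(disease_ids %in% no_dag)]
  dags <- disease_dag_set(dag_list, disease_ids)

  list(A = association_matrix(A), fs = fs, fs_coverage = fs_coverage,
       dags = dags, truth = P, U = U, V = V, spec = spec)
}

#' Write a synthetic dataset in the pipeline's input formats
#'
#' Emits the association list TSV, the functional-similarity CSV, the DAG
#' edge TSV and a ground-truth probability CSV under `dir`.
#'
#' @param ds a dataset from [generate_dataset()].
#' @param dir output directory (created if missing).
#' @return named character vector of the four file paths.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(associations = file.path(dir, "associations.tsv"),
             fs = file.path(dir, "functional_similarity.csv"),
             dags = file.path(dir, "disease_dags.tsv"),
             truth = file.path(dir, "truth.csv"))
  known <- which(ds$A$values == 1, arr.ind = TRUE)
  known <- known[order(known[, 1], known[, 2]), , drop = FALSE]
  writeLines(paste(ds$A$mirna_ids[known[, 1]], ds$A$disease_ids[known[, 2]],
                   sep = "\t"), paths["associations"])
  write_similarity_matrix(ds$fs, paths["fs"])
  edge_rows <- unlist(lapply(names(ds$dags$dags), function(d) {
    e <- ds$dags$dags[[d]]$edges
    paste(d, e$child, e$parent, sep = "\t")
  }))
  writeLines(edge_rows, paths["dags"])
  dt <- data.table::as.data.table(ds$truth, keep.rownames = "id")
  data.table::fwrite(dt, paths["truth"], sep = ",")
  invisible(paths)
}

#' Hold out a fraction of the known associations
#'
#' Removes `ceiling(fraction * n_known)` known pairs uniformly at random and
#' returns the masked training matrix together with the held-out pair list.
#'
#' @param A an [association_matrix()].
#' @param fraction fraction of known pairs to hold out, in `[0,1]`.
#' @param seed integer seed.
#' @return list with `train` ([association_matrix()]) and `held_out`
#'   (two-column index matrix).
#' @export
holdout_split <- function(A, fraction, seed = 0L) {
  stopifnot(inherits(A, "association_matrix"), fraction >= 0, fraction <= 1)
  known <- which(A$values == 1, arr.ind = TRUE)
  dimnames(known) <- NULL
  n_out <- ceiling(fraction * nrow(known))
  if (n_out == 0)
    return(list(train = A, held_out = known[0, , drop = FALSE]))
  set.seed(seed)
  sel <- sample.int(nrow(known), n_out)
  vals <- A$values
  vals[known[sel, , drop = FALSE]] <- 0
  list(train = association_matrix(vals, A$mirna_ids, A$disease_ids),
       held_out = known[sel, , drop = FALSE])
}
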