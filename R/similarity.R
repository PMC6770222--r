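# Similarity construction: DAG-based disease semantic similarity (two
# models), Gaussian interaction profile kernels, and elementwise fusion into
# the integrated disease (SD) and miRNA (SM) similarity matrices.

# children of each term within one disease DAG: edges are (child, parent)
.dag_children <- function(edges) {
  split(as.character(edges$child), factor(edges$parent,
                                          levels = unique(c(edges$child, edges$parent))))
}

# decayed semantic contribution of every term in T(d) toward disease d:
# D1_d(d) = 1, D1_d(t) = delta * max over children of t in the DAG.
# All DAG nodes are ancestors of d, so every child chain leads to d.
.semantic_contribution_1 <- function(dag, disease, delta) {
  terms <- dag$terms
  kids <- .dag_children(dag$edges)
  memo <- new.env(parent = emptyenv())
  assign(disease, 1, envir = memo)
  rec <- function(t) {
    if (exists(t, envir = memo, inherits = FALSE)) return(get(t, envir = memo))
    ch <- kids[[t]]
    ch <- ch[!is.na(ch)]
    if (is.null(ch) || length(ch) == 0)
      stop("semantic contribution: term ", t, " has no path toward ", disease)
    v <- delta * max(vapply(ch, rec, 0))
    assign(t, v, envir = memo)
    v
  }
  stats::setNames(vapply(terms, rec, 0), terms)
}

#' DAG-decay disease semantic similarity (model 1)
#'
#' Wang-style semantic similarity over per-disease MeSH ancestor DAGs. Each
#' term `t` in `T(d)` contributes `D1_d(t) = delta^depth` (1 for the disease's
#' own term, decaying by `delta` per layer along the steepest child path), the
#' semantic value `DV1(d)` is the sum of contributions, and
#' `SS1(i,j) = sum_(t in T(i) & T(j)) (D1_i(t) + D1_j(t)) / (DV1(i) + DV1(j))`.
#'
#' @param dags a [disease_dag_set()].
#' @param delta contribution decay factor per DAG layer, in (0,1); default 0.5.
#' @return `similarity_matrix` with role `SS1` over the covered diseases.
#' @export
semantic_similarity_model1 <- function(dags, delta = 0.5) {
  stopifnot(inherits(dags, "disease_dag_set"), delta > 0, delta < 1)
  covered <- names(dags$coverage)[dags$coverage]
  contrib <- lapply(covered, function(d)
    .semantic_contribution_1(dags$dags[[d]], d, delta))
  names(contrib) <- covered
  dv <- vapply(contrib, sum, 0)
  n <- length(covered)
  S <- diag(1, n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
      shared <- intersect(names(contrib[[i]]), names(contrib[[j]]))
      if (length(shared) > 0)
        S[i, j] <- S[j, i] <-
          sum(contrib[[i]][shared] + contrib[[j]][shared]) / (dv[i] + dv[j])
    }
  }
  similarity_matrix(pmin(pmax(S, 0), 1), covered, "SS1")
}

#' Frequency-weighted disease semantic similarity (model 2)
#'
#' Variant in which a term's contribution reflects how rare it is across all
#' disease DAGs rather than its depth:
#' `D2(t) = -log(n_DAGs_containing_t / n_diseases)`. Similarity is the same
#' shared-contribution ratio as model 1; the diagonal is 1 by convention and
#' entries are clipped to `[0,1]` against float drift.
#'
#' When two diseases' shared terms all occur in every DAG the ratio is 0/0;
#' it is defined as 1 for identical term sets and 0 otherwise.
#'
#' @param dags a [disease_dag_set()].
#' @param n_diseases denominator of the term frequency; defaults to the number
#'   of covered diseases.
#' @return `similarity_matrix` with role `SS2` over the covered diseases.
#' @export
semantic_similarity_model2 <- function(dags, n_diseases = NULL) {
  stopifnot(inherits(dags, "disease_dag_set"))
  covered <- names(dags$coverage)[dags$coverage]
  if (is.null(n_diseases)) n_diseases <- length(covered)
  stopifnot(n_diseases >= 1)
  term_sets <- lapply(covered, function(d) dags$dags[[d]]$terms)
  names(term_sets) <- covered
  counts <- table(unlist(lapply(term_sets, unique)))
  stopifnot(all(counts >= 1))  # every term occurs in the DAG that defines it
  d2 <- -log(as.numeric(counts) / n_diseases)
  names(d2) <- names(counts)
  dv <- vapply(term_sets, function(ts) sum(d2[ts]), 0)
  n <- length(covered)
  S <- diag(1, n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
      shared <- intersect(term_sets[[i]], term_sets[[j]])
      denom <- dv[i] + dv[j]
      S[i, j] <- S[j, i] <-
        if (denom == 0) as.numeric(setequal(term_sets[[i]], term_sets[[j]]))
        else 2 * sum(d2[shared]) / denom
    }
  }
  similarity_matrix(pmin(pmax(S, 0), 1), covered, "SS2")
}

#' Gaussian interaction profile kernel similarity
#'
#' RBF kernel on the binary interaction profiles (rows or columns of the
#' adjacency matrix): `K(a,b) = exp(-gamma * ||IP(a) - IP(b)||^2)` with the
#' bandwidth normalised by the mean squared profile norm,
#' `gamma = gamma_prime / mean(||IP||^2)`.
#'
#' @param profiles numeric matrix, one interaction profile per row.
#' @param gamma_prime bandwidth scale; the literature default is 1.
#' @param role role label, `"KD"` (disease) or `"KM"` (miRNA).
#' @return `similarity_matrix` of the given role.
#' @export
gip_kernel <- function(profiles, gamma_prime = 1, role = c("KD", "KM")) {
  role <- match.arg(role)
  stopifnot(gamma_prime > 0)
  P <- as.matrix(profiles)
  sq <- rowSums(P^2)
  if (all(sq == 0)) stop("gip_kernel: empty association matrix (all profiles zero)")
  gamma <- gamma_prime / mean(sq)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(P)
  D2[D2 < 0] <- 0
  K <- exp(-gamma * D2)
  diag(K) <- 1
  K <- (K + t(K)) / 2
  similarity_matrix(K, rownames(P), role)
}

#' @describeIn gip_kernel kernel over disease profiles (columns of A).
#' @param A an [association_matrix()].
#' @export
gip_kernel_diseases <- function(A, gamma_prime = 1)
  gip_kernel(t(A$values), gamma_prime, "KD")

#' @describeIn gip_kernel kernel over miRNA profiles (rows of A).
#' @export
gip_kernel_mirnas <- function(A, gamma_prime = 1)
  gip_kernel(A$values, gamma_prime, "KM")

# elementwise fusion shared by both integration directions
.integrate <- function(primary, fallback, covered_ids, role) {
  ids <- fallback$entity_ids
  S <- fallback$values
  cov <- ids %in% covered_ids
  if (any(cov)) {
    sub <- ids[cov]
    S[cov, cov] <- primary[sub, sub]
  }
  diag(S) <- 1
  similarity_matrix(S, ids, role)
}

#' Integrated disease similarity
#'
#' Fuses the two semantic similarity models with the interaction-profile
#' kernel: where both diseases have DAG coverage the entry is
#' `(SS1 + SS2) / 2`, otherwise the kernel value `KD`.
#'
#' @param ss1,ss2 `similarity_matrix` objects over the covered diseases.
#' @param kd `similarity_matrix` (role `KD`) over all diseases.
#' @param coverage named logical of DAG coverage (defaults to diseases present
#'   in `ss1`).
#' @return `similarity_matrix` with role `SD` over all diseases.
#' @export
integrate_disease_similarity <- function(ss1, ss2, kd, coverage = NULL) {
  stopifnot(inherits(ss1, "similarity_matrix"), inherits(ss2, "similarity_matrix"),
            inherits(kd, "similarity_matrix"))
  if (!identical(ss1$entity_ids, ss2$entity_ids))
    stop("integrate_disease_similarity: SS1/SS2 disease sets disagree")
  covered <- if (is.null(coverage)) ss1$entity_ids else names(coverage)[coverage]
  covered <- intersect(covered, ss1$entity_ids)
  if (!all(covered %in% kd$entity_ids))
    stop("integrate_disease_similarity: covered disease missing from KD")
  sem <- (ss1$values + ss2$values) / 2
  .integrate(sem, kd, covered, "SD")
}

#' Integrated miRNA similarity
#'
#' Uses the functional-similarity score where both miRNAs are covered by the
#' functional-similarity resource, and the interaction-profile kernel `KM`
#' otherwise.
#'
#' @param fs `similarity_matrix` (role `FS`) over the covered miRNAs.
#' @param km `similarity_matrix` (role `KM`) over all miRNAs.
#' @param coverage named logical of FS coverage (defaults to miRNAs in `fs`).
#' @return `similarity_matrix` with role `SM` over all miRNAs.
#' @export
integrate_mirna_similarity <- function(fs, km, coverage = NULL) {
  stopifnot(inherits(fs, "similarity_matrix"), inherits(km, "similarity_matrix"))
  covered <- if (is.null(coverage)) fs$entity_ids else names(coverage)[coverage]
  covered <- intersect(covered, fs$entity_ids)
  if (!all(covered %in% km$entity_ids))
    stop("integrate_mirna_similarity: covered miRNA missing from KM")
  .integrate(fs$values, km, covered, "SM")
}

#' Compute all similarity matrices for one adjacency matrix
#'
#' Convenience wrapper running the full similarity stage: semantic models 1
#' and 2 from the DAGs, interaction-profile kernels from `A`, and both
#' integrations. Re-run whenever `A` changes (e.g. inside cross-validation
#' folds) so the kernels never see held-out labels.
#'
#' @param A an [association_matrix()].
#' @param dags a [disease_dag_set()].
#' @param fs functional similarity (`similarity_matrix`, role `FS`) or `NULL`.
#' @param fs_coverage named logical over miRNAs; defaults to membership in `fs`.
#' @param delta,gamma_prime similarity hyperparameters.
#' @return list with elements `SS1`, `SS2`, `KD`, `KM`, `SD`, `SM`.
#' @export
compute_similarities <- function(A, dags, fs = NULL, fs_coverage = NULL,
                                 delta = 0.5, gamma_prime = 1) {
  stopifnot(inherits(A, "association_matrix"))
  kd <- gip_kernel_diseases(A, gamma_prime)
  km <- gip_kernel_mirnas(A, gamma_prime)
  ss1 <- semantic_similarity_model1(dags, delta)
  ss2 <- semantic_similarity_model2(dags)
  sd_ <- integrate_disease_similarity(ss1, ss2, kd, dags$coverage)
  sm <- if (is.null(fs)) {
    similarity_matrix(km$values, km$entity_ids, "SM")
  } else {
    if (is.null(fs_coverage))
      fs_coverage <- stats::setNames(A$mirna_ids %in% fs$entity_ids, A$mirna_ids)
    integrate_mirna_similarity(fs, km, fs_coverage)
  }
  list(SS1 = ss1, SS2 = ss2, KD = kd, KM = km, SD = sd_, SM = sm)
}
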