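# Shared fixture builders and independent oracles. Everything is generated in
# code; expensive objects are memoised per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# tiny deterministic association matrix
toy_A <- function() {
  association_matrix(matrix(c(1, 0, 1, 1, 0, 1), nrow = 3, byrow = TRUE,
                            dimnames = list(c("m1", "m2", "m3"),
                                            c("d1", "d2"))))
}

# DAG set helpers -------------------------------------------------------------

# chain DAG: d <- t1 <- t2 <- ... <- t_depth (edges are (child, parent))
chain_dag <- function(disease, depth, prefix = paste0(disease, "_t")) {
  terms <- c(disease, paste0(prefix, seq_len(depth)))
  edges <- data.frame(child = terms[-length(terms)], parent = terms[-1])
  list(terms = terms, edges = edges)
}

# random DAG in which every term has at least one child on a path to the
# disease: node i >= 2 picks children among nodes 1..i-1 (node 1 = disease)
random_dag <- function(disease, terms, seed) {
  set.seed(seed)
  nodes <- c(disease, sample(terms, sample(2:min(5, length(terms)), 1)))
  edges <- NULL
  for (i in seq_along(nodes)[-1]) {
    kids <- sample(seq_len(i - 1), min(i - 1, sample(1:2, 1)))
    edges <- rbind(edges, data.frame(child = nodes[kids], parent = nodes[i]))
  }
  list(terms = nodes, edges = unique(edges))
}

random_dag_set <- function(n_diseases, seed, n_terms = 8) {
  pool <- sprintf("T%02d", seq_len(n_terms))
  ids <- sprintf("D%02d", seq_len(n_diseases))
  dags <- lapply(seq_len(n_diseases),
                 function(i) random_dag(ids[i], pool, seed + i))
  names(dags) <- ids
  disease_dag_set(dags, ids)
}

# independent similarity oracles ----------------------------------------------

# D1 via shortest child-path distance: D1_d(t) = delta^dist(t -> d)
oracle_d1 <- function(dag, disease, delta) {
  dist <- stats::setNames(rep(Inf, length(dag$terms)), dag$terms)
  dist[disease] <- 0
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(dag$edges))) {
      ch <- dag$edges$child[k]; pa <- dag$edges$parent[k]
      if (dist[ch] + 1 < dist[pa]) { dist[pa] <- dist[ch] + 1; changed <- TRUE }
    }
    if (!changed) break
  }
  delta^dist
}

oracle_ss1 <- function(dags, delta) {
  covered <- names(dags$coverage)[dags$coverage]
  d1 <- lapply(covered, function(d) oracle_d1(dags$dags[[d]], d, delta))
  names(d1) <- covered
  n <- length(covered)
  S <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    sh <- intersect(names(d1[[i]]), names(d1[[j]]))
    S[i, j] <- if (length(sh) == 0) 0 else
      sum(d1[[i]][sh] + d1[[j]][sh]) / (sum(d1[[i]]) + sum(d1[[j]]))
  }
  dimnames(S) <- list(covered, covered)
  S
}

oracle_ss2 <- function(dags) {
  covered <- names(dags$coverage)[dags$coverage]
  sets <- lapply(covered, function(d) dags$dags[[d]]$terms)
  names(sets) <- covered
  all_terms <- unique(unlist(sets))
  cnt <- vapply(all_terms, function(t)
    sum(vapply(sets, function(s) t %in% s, TRUE)), 0)
  d2 <- stats::setNames(-log(cnt / length(covered)), all_terms)
  n <- length(covered)
  S <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    sh <- intersect(sets[[i]], sets[[j]])
    den <- sum(d2[sets[[i]]]) + sum(d2[sets[[j]]])
    S[i, j] <- if (den == 0) as.numeric(setequal(sets[[i]], sets[[j]]))
      else min(1, max(0, 2 * sum(d2[sh]) / den))
  }
  dimnames(S) <- list(covered, covered)
  S
}

oracle_gip <- function(P, gamma_prime = 1) {
  n <- nrow(P)
  gamma <- gamma_prime / (mean(vapply(seq_len(n), function(i) sum(P[i, ]^2), 0)))
  K <- matrix(NA_real_, n, n)
  for (a in seq_len(n)) for (b in seq_len(n))
    K[a, b] <- exp(-gamma * sum((P[a, ] - P[b, ])^2))
  K
}

# exhaustive pairwise-comparison AUC oracle
oracle_auc <- function(test, cand) {
  tot <- 0
  for (t in test) for (c in cand)
    tot <- tot + (t > c) + 0.5 * (t == c)
  tot / (length(test) * length(cand))
}

# zero-parameter VAE (all weights/biases zero, identity batch norm)
zero_vae <- function(input_dim, hidden1 = 4, latent_dim = 3, hidden3 = 4) {
  cfg <- vae_config(input_dim, hidden1, latent_dim, hidden3, seed = 1)
  m <- init_vae(cfg)
  m$par <- lapply(m$par, function(p) p * 0)
  m$par$bn_gamma <- rep(1, hidden1)
  m$running_mean <- numeric(hidden1)
  m$running_var <- rep(1, hidden1)
  m
}

# small synthetic world shared across tests
small_world <- function(seed = 0) {
  cached(paste0("world", seed),
         generate_dataset(synthetic_spec(nm = 50, nd = 30, latent_rank = 3,
                                         density = 0.1, seed = seed)))
}
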