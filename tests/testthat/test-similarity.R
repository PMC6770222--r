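# similarity: semantic models, GIP kernel, integration

test_that("semantic similarity model 1 matches hand evaluation and the path oracle", {
  # shared root: T(d1)={d1,r}, T(d2)={d2,r}, delta = 0.5 -> SS1 = 1/3
  dg <- disease_dag_set(list(
    d1 = list(terms = c("d1", "r"),
              edges = data.frame(child = "d1", parent = "r")),
    d2 = list(terms = c("d2", "r"),
              edges = data.frame(child = "d2", parent = "r"))))
  s <- semantic_similarity_model1(dg, delta = 0.5)
  expect_equal(s$values["d1", "d2"], 1 / 3, tolerance = 1e-12)
  expect_equal(diag(s$values), c(d1 = 1, d2 = 1))

  # identical DAGs -> 1; disjoint DAGs -> 0
  dg2 <- disease_dag_set(list(
    d1 = list(terms = c("d1", "r"), edges = data.frame(child = "d1", parent = "r")),
    d2 = list(terms = c("d2", "q"), edges = data.frame(child = "d2", parent = "q"))))
  expect_equal(semantic_similarity_model1(dg2, 0.5)$values["d1", "d2"], 0)
  dg3 <- disease_dag_set(list(
    d1 = chain_dag("d1", 3, "t"), d2 = chain_dag("d2", 3, "t")))
  s3 <- semantic_similarity_model1(dg3, 0.5)
  # identical ancestor chains share everything except the disease terms
  d1v <- 0.5^(1:3)
  expect_equal(s3$values["d1", "d2"], sum(2 * d1v) / (2 * (1 + sum(d1v))),
               tolerance = 1e-12)

  # chain DAGs of several depths: closed form delta^level via the oracle
  for (depth in c(1, 4, 7)) {
    dgc <- disease_dag_set(list(dA = chain_dag("dA", depth, "s"),
                                dB = chain_dag("dB", depth, "s")))
    got <- semantic_similarity_model1(dgc, 0.5)
    expect_equal(got$values, oracle_ss1(dgc, 0.5), tolerance = 1e-12)
  }

  # random DAG fixtures against the shortest-path oracle
  for (seed in 1:5) {
    dgr <- random_dag_set(6, seed * 100)
    got <- semantic_similarity_model1(dgr, 0.5)
    expect_equal(got$values, oracle_ss1(dgr, 0.5), tolerance = 1e-12)
  }
})

test_that("adding a shared ancestor never decreases model-1 similarity", {
  for (seed in 1:5) {
    dgr <- random_dag_set(4, seed)
    base <- semantic_similarity_model1(dgr, 0.5)$values
    # graft one common new root above every existing DAG
    dags2 <- lapply(names(dgr$dags), function(d) {
      g <- dgr$dags[[d]]
      tops <- setdiff(g$terms, g$edges$child)  # current roots
      list(terms = c(g$terms, "SHARED_ROOT"),
           edges = rbind(g$edges,
                         data.frame(child = tops, parent = "SHARED_ROOT")))
    })
    names(dags2) <- names(dgr$dags)
    grown <- semantic_similarity_model1(disease_dag_set(dags2), 0.5)$values
    expect_true(all(grown - base > -1e-12))
  }
})

test_that("semantic similarity model 2 matches its frequency definition", {
  # r occurs in both DAGs of 2 -> D2(r) = -log(2/2) = 0 -> SS2 = 0
  dg <- disease_dag_set(list(
    d1 = list(terms = c("d1", "r"), edges = data.frame(child = "d1", parent = "r")),
    d2 = list(terms = c("d2", "r"), edges = data.frame(child = "d2", parent = "r"))))
  s <- dg |> semantic_similarity_model2()
  expect_equal(s$values["d1", "d2"], 0)
  expect_equal(diag(s$values), c(d1 = 1, d2 = 1))

  # identical term sets -> 1 (the 0/0 ratio resolved by term-set equality)
  dg2 <- disease_dag_set(list(
    d1 = list(terms = c("d1", "d2", "r"),
              edges = data.frame(child = c("d1", "d2"), parent = c("d2", "r"))),
    d2 = list(terms = c("d1", "d2", "r"),
              edges = data.frame(child = c("d2", "d1"), parent = c("d1", "r")))))
  expect_equal(semantic_similarity_model2(dg2)$values["d1", "d2"], 1)

  for (seed in 1:5) {
    dgr <- random_dag_set(6, seed * 31)
    got <- semantic_similarity_model2(dgr)
    expect_equal(got$values, oracle_ss2(dgr), tolerance = 1e-12)
  }
})

test_that("gip_kernel matches the closed form and the brute-force oracle", {
  # orthogonal unit profiles: gamma = 1, K = exp(-2)
  P <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  K <- gip_kernel(P, 1, "KD")
  expect_equal(K$values["a", "b"], exp(-2), tolerance = 1e-12)
  # doubling gamma_prime squares the off-diagonal
  K2 <- gip_kernel(P, 2, "KD")
  expect_equal(K2$values["a", "b"], exp(-4), tolerance = 1e-12)
  # identical profiles -> 1
  P2 <- rbind(a = c(1, 1, 0), b = c(1, 1, 0))
  expect_equal(gip_kernel(P2, 1, "KM")$values["a", "b"], 1)

  set.seed(11)
  for (rep in 1:5) {
    Q <- matrix(rbinom(100, 1, 0.3), 10,
                dimnames = list(sprintf("p%d", 1:10), NULL))
    if (all(rowSums(Q) == 0)) Q[1, 1] <- 1
    expect_lt(max(abs(gip_kernel(Q, 1, "KD")$values - oracle_gip(Q, 1))), 1e-12)
  }
  expect_error(gip_kernel(matrix(0, 3, 4), 1, "KD"), "empty association")
})

test_that("similarity outputs are symmetric, unit-diagonal and in [0,1]", {
  for (seed in 1:4) {
    dgr <- random_dag_set(7, seed * 7)
    set.seed(seed)
    A <- matrix(rbinom(7 * 9, 1, 0.3), 9, 7,
                dimnames = list(sprintf("m%d", 1:9), names(dgr$coverage)))
    A[1, 1] <- 1  # guard against an all-zero matrix
    Am <- association_matrix(A)
    sims <- compute_similarities(Am, dgr)
    for (s in sims) {
      expect_s3_class(s, "similarity_matrix")
      expect_equal(s$values, t(s$values))
      expect_true(all(diag(s$values) == 1))
      expect_true(all(s$values >= 0 & s$values <= 1))
    }
  }
})

test_that("integration fuses semantic/functional values with kernel fallback", {
  ids <- c("d1", "d2", "d3")
  mk <- function(v, role) {
    M <- matrix(v, 3, 3); M <- (M + t(M)) / 2; diag(M) <- 1
    similarity_matrix(M, ids, role)
  }
  kd <- mk(0.7, "KD")
  covered <- c("d1", "d2")
  ss1 <- similarity_matrix(matrix(c(1, 0.4, 0.4, 1), 2), covered, "SS1")
  ss2 <- similarity_matrix(matrix(c(1, 0.2, 0.2, 1), 2), covered, "SS2")
  cov <- c(d1 = TRUE, d2 = TRUE, d3 = FALSE)
  sd_ <- integrate_disease_similarity(ss1, ss2, kd, cov)
  expect_equal(sd_$values["d1", "d2"], 0.3)       # (0.4 + 0.2) / 2
  expect_equal(sd_$values["d1", "d3"], 0.7)       # KD fallback
  expect_equal(diag(sd_$values), c(d1 = 1, d2 = 1, d3 = 1))

  # full coverage with SS1 = SS2 = KD is a fixed point
  ssf <- mk(0.7, "SS1"); ssf2 <- mk(0.7, "SS2")
  fix <- integrate_disease_similarity(ssf, ssf2, kd,
                                      stats::setNames(rep(TRUE, 3), ids))
  expect_equal(fix$values, kd$values)

  km <- mk(0.6, "KM")
  fs <- similarity_matrix(matrix(c(1, 0.9, 0.9, 1), 2), c("d1", "d2"), "FS")
  sm <- integrate_mirna_similarity(fs, km, cov)
  expect_equal(sm$values["d1", "d2"], 0.9)
  expect_equal(sm$values["d2", "d3"], 0.6)
  # degenerate mask: nothing covered -> SM is exactly KM
  none <- stats::setNames(rep(FALSE, 3), ids)
  expect_equal(integrate_mirna_similarity(fs, km, none)$values, km$values)
})
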