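test_that("top-k neighbors sort by weight, exclude self, drop zeros", {
  M <- matrix(c(1.0, 0.9, 0.2, 0.0,
                0.9, 1.0, 0.1, 0.3,
                0.2, 0.1, 1.0, 0.0,
                0.0, 0.3, 0.0, 1.0), 4, 4, byrow = TRUE)
  comp <- similarity_matrix(M, "drug", "composite")
  nb <- top_k_neighbors(comp, 1, k = 2)
  expect_equal(nb$indices, c(2, 3))
  expect_equal(nb$weights, c(0.9, 0.2))
  # zero-weight entities are not padded in
  nb <- top_k_neighbors(comp, 1, k = 3)
  expect_equal(nb$indices, c(2, 3))
  # all-zero row warns and returns empty
  Z <- matrix(0, 3, 3); diag(Z) <- 1
  Z[1, ] <- 0; Z[, 1] <- 0
  expect_warning(nb <- top_k_neighbors(similarity_matrix(Z, "drug"), 1),
                 "no positive-weight")
  expect_length(nb$indices, 0)
  expect_error(top_k_neighbors(comp, 1, k = 0), "k must be")
})

test_that("top-k equals exhaustive per-row sort on a random composite", {
  set.seed(14)
  M <- matrix(runif(900), 30, 30); M <- (M + t(M)) / 2
  comp <- similarity_matrix(M, "drug")
  for (i in c(1, 7, 30)) {
    nb <- top_k_neighbors(comp, i, k = 5)
    w <- comp$values[i, ]; w[i] <- -Inf
    expect_equal(nb$indices, order(-w)[1:5])
    expect_equal(nb$weights, sort(w, decreasing = TRUE)[1:5])
  }
})

test_that("similarity and path components follow their printed forms", {
  vec <- c(1, -2, 3)
  nb <- list(entity = 1, indices = c(2, 3), weights = c(0.5, 0.5))
  expect_equal(similarity_component(vec, nb), vec) # weights sum to 1
  nb1 <- list(entity = 1, indices = 2, weights = 1)
  expect_equal(similarity_component(vec, nb1), vec)
  empty <- list(entity = 1, indices = integer(), weights = numeric())
  expect_equal(similarity_component(vec, empty), c(0, 0, 0))
  set.seed(2)
  w <- runif(5); v <- rnorm(3)
  nb5 <- list(entity = 1, indices = 2:6, weights = w)
  expect_equal(similarity_component(v, nb5), sum(w) * v)

  net <- rand_network(6, 4, 0.5, seed = 9)
  pv <- rnorm(3)
  nbd <- list(entity = 1, indices = c(2, 4), weights = c(0.8, 0.5))
  expect_equal(path_component(pv, nbd, net, 3, "drug"),
               sum(net$adjacency[c(2, 4), 3]) * pv)
  # no interacting neighbor: zero vector
  A <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("d1", "d2"), c("t1", "t2")))
  net2 <- dti_network(A)
  nb2 <- list(entity = 1, indices = 2, weights = 1)
  expect_equal(path_component(pv, nb2, net2, 1, "target"), 0 * pv) # A[1,2]=0
  expect_equal(path_component(pv, nb2, net2, 2, "drug"), pv)       # A[2,2]=1
})

test_that("pair embeddings equal the straight-from-the-equations oracle", {
  worst <- 0
  for (seed in 1:20) {
    set.seed(seed)
    m <- sample(4:20, 1); n <- sample(4:20, 1); dim <- sample(2:6, 1)
    net <- rand_network(m, n, 0.35, seed = seed + 100)
    U <- matrix(rnorm(m * dim), m, dim, dimnames = list(net$drug_ids, NULL))
    V <- matrix(rnorm(n * dim), n, dim, dimnames = list(net$target_ids, NULL))
    Sd <- matrix(runif(m * m), m, m); Sd <- (Sd + t(Sd)) / 2
    St <- matrix(runif(n * n), n, n); St <- (St + t(St)) / 2
    dt <- list(vectors = U); tt <- list(vectors = V)
    cd <- similarity_matrix(Sd, "drug"); ct <- similarity_matrix(St, "target")
    for (rep in 1:5) {
      d <- sample(m, 1); t <- sample(n, 1)
      got <- build_pair_embedding(d, t, dt, tt, cd, ct, net, k = 5)
      want <- oracle_pair_embedding(d, t, U, V, cd$values, ct$values,
                                    net$adjacency, k = 5)
      worst <- max(worst, max(abs(got - want)))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("build_all_pairs is vectorization-consistent and complete", {
  net <- rand_network(5, 4, 0.4, seed = 31)
  set.seed(31)
  U <- matrix(rnorm(15), 5, 3, dimnames = list(net$drug_ids, NULL))
  V <- matrix(rnorm(12), 4, 3, dimnames = list(net$target_ids, NULL))
  Sd <- rand_similarity(5, "drug", seed = 1)
  St <- rand_similarity(4, "target", seed = 2)
  dt <- list(vectors = U); tt <- list(vectors = V)
  ap <- build_all_pairs(net, dt, tt, Sd, St, k = 2)
  expect_equal(nrow(ap$vectors), 20)
  expect_equal(ncol(ap$vectors), 6)
  for (idx in c(1, 7, 20)) {
    d <- ap$pairs$drug[idx]; t <- ap$pairs$target[idx]
    expect_equal(unname(ap$vectors[idx, ]),
                 unname(build_pair_embedding(d, t, dt, tt, Sd, St, net, k = 2)))
  }
})

test_that("masking all edges reduces pairs to similarity components only", {
  net <- rand_network(5, 4, 0.5, seed = 8)
  set.seed(8)
  U <- matrix(rnorm(10), 5, 2, dimnames = list(net$drug_ids, NULL))
  V <- matrix(rnorm(8), 4, 2, dimnames = list(net$target_ids, NULL))
  Sd <- rand_similarity(5, "drug", seed = 3)
  St <- rand_similarity(4, "target", seed = 4)
  dt <- list(vectors = U); tt <- list(vectors = V)
  all_edges <- which(net$adjacency == 1, arr.ind = TRUE)
  ap <- build_all_pairs(net, dt, tt, Sd, St, k = 2, mask_edges = all_edges)
  for (idx in c(2, 11)) {
    d <- ap$pairs$drug[idx]; t <- ap$pairs$target[idx]
    nd <- top_k_neighbors(Sd, d, 2); nt <- top_k_neighbors(St, t, 2)
    expect_equal(unname(ap$vectors[idx, ]),
                 c(similarity_component(U[d, ], nd),
                   similarity_component(V[t, ], nt)))
  }
})

test_that("masking one edge only perturbs pairs whose neighbor sets touch it", {
  net <- rand_network(8, 6, 0.4, seed = 17)
  set.seed(17)
  U <- matrix(rnorm(24), 8, 3, dimnames = list(net$drug_ids, NULL))
  V <- matrix(rnorm(18), 6, 3, dimnames = list(net$target_ids, NULL))
  Sd <- rand_similarity(8, "drug", seed = 5)
  St <- rand_similarity(6, "target", seed = 6)
  dt <- list(vectors = U); tt <- list(vectors = V)
  edges <- which(net$adjacency == 1, arr.ind = TRUE)
  e <- edges[1, , drop = FALSE]
  base <- build_all_pairs(net, dt, tt, Sd, St, k = 3)
  masked <- build_all_pairs(net, dt, tt, Sd, St, k = 3, mask_edges = e)
  changed <- which(rowSums(abs(base$vectors - masked$vectors)) > 1e-12)
  # full recomputation oracle: a pair may change only if the masked drug is a
  # neighbor of its drug (and its target is the masked target), or vice versa
  nd <- lapply(1:8, function(i) top_k_neighbors(Sd, i, 3)$indices)
  nt <- lapply(1:6, function(j) top_k_neighbors(St, j, 3)$indices)
  allowed <- which(
    (base$pairs$target == e[1, 2] &
       vapply(base$pairs$drug, function(d) e[1, 1] %in% nd[[d]], NA)) |
    (base$pairs$drug == e[1, 1] &
       vapply(base$pairs$target, function(t) e[1, 2] %in% nt[[t]], NA)))
  expect_true(all(changed %in% allowed))
  expect_gt(length(changed), 0)
})

test_that("pair embeddings are linear in the vertex embeddings", {
  net <- rand_network(6, 5, 0.4, seed = 23)
  set.seed(23)
  U <- matrix(rnorm(18), 6, 3, dimnames = list(net$drug_ids, NULL))
  V <- matrix(rnorm(15), 5, 3, dimnames = list(net$target_ids, NULL))
  Sd <- rand_similarity(6, "drug", seed = 7)
  St <- rand_similarity(5, "target", seed = 8)
  a <- build_all_pairs(net, list(vectors = U), list(vectors = V), Sd, St)
  b <- build_all_pairs(net, list(vectors = 3 * U), list(vectors = 3 * V), Sd, St)
  expect_equal(b$vectors, 3 * a$vectors, tolerance = 1e-12)
  z <- build_all_pairs(net, list(vectors = 0 * U), list(vectors = 0 * V), Sd, St)
  expect_true(all(z$vectors == 0))
})

test_that("neighbor-mix variant mixes neighbor embeddings instead", {
  net <- rand_network(5, 4, 0.5, seed = 12)
  set.seed(12)
  U <- matrix(rnorm(10), 5, 2, dimnames = list(net$drug_ids, NULL))
  V <- matrix(rnorm(8), 4, 2, dimnames = list(net$target_ids, NULL))
  Sd <- rand_similarity(5, "drug", seed = 9)
  St <- rand_similarity(4, "target", seed = 10)
  ap <- build_all_pairs(net, list(vectors = U), list(vectors = V), Sd, St,
                        k = 2, neighbor_mix = "neighbor_embeddings")
  d <- ap$pairs$drug[1]; t <- ap$pairs$target[1]
  nd <- top_k_neighbors(Sd, d, 2)
  dsim <- colSums(nd$weights * U[nd$indices, , drop = FALSE])
  expect_equal(unname(ap$vectors[1, 1:2]),
               unname(dsim + sum(net$adjacency[nd$indices, t]) * V[t, ]))
})
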