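test_that("Co-HITS homogeneous matrices count shared partners", {
  net <- toy_network()
  H <- cohits_matrix(net, "drug")$values
  expect_equal(H["Drug1", "Drug2"], 1)
  expect_equal(H["Drug1", "Drug3"], 0)
  expect_equal(H["Drug2", "Drug3"], 1)
  expect_equal(diag(H), c(Drug1 = 1, Drug2 = 2, Drug3 = 1))

  Ht <- cohits_matrix(net, "target")$values
  expect_equal(dim(Ht), c(2, 2))
  expect_equal(Ht["Target1", "Target2"], 1) # shared drug: Drug2

  # all-zero network (constructed directly, constructor would warn)
  z <- structure(list(adjacency = matrix(0, 2, 2),
                      drug_ids = c("a", "b"), target_ids = c("x", "y")),
                 class = "dti_network")
  expect_true(all(cohits_matrix(z, "drug")$values == 0))
})

test_that("Co-HITS equals the brute-force shared-neighbor oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    m <- sample(2:20, 1); n <- sample(2:20, 1)
    A <- matrix(rbinom(m * n, 1, 0.4), m, n)
    net <- structure(list(adjacency = A, drug_ids = paste0("d", 1:m),
                          target_ids = paste0("t", 1:n)),
                     class = "dti_network")
    expect_equal(unname(cohits_matrix(net, "drug")$values), oracle_cohits(A, "drug"))
    expect_equal(unname(cohits_matrix(net, "target")$values), oracle_cohits(A, "target"))
  }
})

test_that("walk degenerate regimes behave as specified", {
  net <- rand_network(6, 4, 0.5, seed = 3)
  hd <- cohits_matrix(net, "drug")
  # restart always fires: sequences contain only their start vertex
  p <- bine_params(restart_prob = 1, stop_prob = 0.3, max_walks = 3)
  corp <- generate_walks(hd, p, seed = 1)
  for (i in seq_along(corp$sequences))
    expect_true(all(corp$sequences[[i]] == corp$starts[i]))
  # immediate stop: every sequence has length 1
  p <- bine_params(stop_prob = 1, max_walks = 3)
  corp <- generate_walks(hd, p, seed = 1)
  expect_true(all(lengths(corp$sequences) == 1L))
  # reproducible under a fixed seed
  p <- bine_params(max_walks = 4)
  expect_identical(generate_walks(hd, p, seed = 9),
                   generate_walks(hd, p, seed = 9))
  expect_error(generate_walks(structure(list(values = matrix(0, 3, 3),
                                             side = "drug"),
                                        class = "cohits_matrix")),
               "no walkable")
})

test_that("walk transitions follow edge-weight proportions", {
  # 3-vertex chain 1-2-3 with equal weights; from vertex 2 both neighbors
  # should be visited equally; restart off, no stopping bias on step 1
  W <- matrix(c(0, 1, 0,
                1, 0, 1,
                0, 1, 0), 3, 3, byrow = TRUE)
  homo <- structure(list(values = W, side = "drug"), class = "cohits_matrix")
  p <- bine_params(stop_prob = 0.15, restart_prob = 0, max_walks = 1,
                   max_walk_len = 50)
  set.seed(11)
  nexts <- integer(0)
  for (r in 1:4000) {
    corp <- generate_walks(homo, p)
    s <- corp$sequences[[which(corp$starts == 2)]]
    if (length(s) >= 2) nexts <- c(nexts, s[2])
  }
  n1 <- sum(nexts == 1); n3 <- sum(nexts == 3)
  phat <- n1 / (n1 + n3)
  se <- sqrt(0.25 / (n1 + n3))
  expect_lt(abs(phat - 0.5), 3 * se)
})

test_that("walk counts scale with centrality within the configured bounds", {
  net <- rand_network(10, 8, 0.3, seed = 5)
  hd <- cohits_matrix(net, "drug")
  p <- bine_params(max_walks = 8, min_walks = 2)
  corp <- generate_walks(hd, p, seed = 1)
  counts <- table(corp$starts)
  expect_true(all(counts >= 2 & counts <= 8))
  W <- hd$values; diag(W) <- 0
  cent <- rowSums(W)
  expect_equal(max(counts), 8) # the most central vertex gets max_walks
  expect_true(counts[[which.max(cent)]] == 8)
})

test_that("explicit update matches its closed form and the gradient oracle", {
  # zero weight and origin fixed points
  u <- c(0.3, -0.2); v <- c(0.1, 0.4)
  expect_equal(explicit_update(u, v, 0, 1, 0.5), list(u = u, v = v))
  z <- c(0, 0)
  expect_equal(explicit_update(z, z, 1, 1, 1), list(u = z, v = z))
  expect_error(explicit_update(u, c(1, 2, 3), 1, 1, 1), "length")

  # update direction equals the analytic gradient of the edge objective
  for (seed in 1:10) {
    set.seed(seed)
    u <- rnorm(4); v <- rnorm(4); w <- runif(1, 0.5, 2); g <- runif(1, 0.5, 2)
    lr <- 1
    up <- explicit_update(u, v, w, g, lr)
    grad_u <- numeric_gradient(function(x) explicit_objective(x, v, w, g), u)
    grad_v <- numeric_gradient(function(x) explicit_objective(u, x, w, g), v)
    expect_equal((up$u - u) / lr, grad_u, tolerance = 1e-5)
    expect_equal((up$v - v) / lr, grad_v, tolerance = 1e-5)
  }
})

test_that("implicit update matches the negative-sampling gradient oracle", {
  # zero weight: no change
  set.seed(1)
  cm <- matrix(rnorm(6), 3, 2)
  r <- implicit_update(c(1, 2), cm, c(1, 0, 0), 0, 0.5)
  expect_equal(r$center, c(1, 2))
  expect_equal(r$contexts, cm)
  # origin fixed point for the center when all context vectors are zero
  r <- implicit_update(c(0, 0), matrix(0, 2, 2), c(1, 0), 1, 1)
  expect_equal(r$center, c(0, 0))

  for (seed in 1:10) {
    set.seed(seed)
    center <- rnorm(5); ctx <- matrix(rnorm(20), 4, 5)
    ind <- c(1, 0, 0, 0); w <- runif(1, 0.1, 1)
    up <- implicit_update(center, ctx, ind, w, lr = 1)
    gc <- numeric_gradient(function(x) implicit_objective(x, ctx, ind, w), center)
    expect_equal(up$center - center, gc, tolerance = 1e-5)
    for (z in 1:4) {
      gz <- numeric_gradient(function(x) {
        cz <- ctx; cz[z, ] <- x
        implicit_objective(center, cz, ind, w)
      }, ctx[z, ])
      expect_equal(up$contexts[z, ] - ctx[z, ], gz, tolerance = 1e-5)
    }
  }
})

test_that("small gradient steps increase the joint objective components", {
  for (seed in 1:5) {
    set.seed(seed)
    u <- rnorm(6); v <- rnorm(6)
    lr <- 1e-6
    up <- explicit_update(u, v, 1, 0.7, lr)
    expect_gt(explicit_objective(up$u, up$v, 1, 0.7),
              explicit_objective(u, v, 1, 0.7) - 1e-15)
    center <- rnorm(6); ctx <- matrix(rnorm(18), 3, 6); ind <- c(1, 0, 0)
    r <- implicit_update(center, ctx, ind, 0.5, lr)
    expect_gte(implicit_objective(r$center, r$contexts, ind, 0.5),
               implicit_objective(center, ctx, ind, 0.5))
  }
})

test_that("training returns the initialization when max_iter = 0", {
  net <- rand_network(6, 4, 0.5, seed = 2)
  p <- bine_params(dim = 4, max_iter = 0, max_walks = 2, seed = 3)
  emb <- train_bine(net, p)
  expect_equal(dim(emb$drugs$vectors), c(6, 4))
  expect_true(all(abs(emb$drugs$vectors) <= 0.5 / 4))
  expect_true(all(emb$drugs$context == 0))
  expect_true(all(emb$targets$context == 0))
})

test_that("pure explicit ascent drives an edge's score toward 1", {
  A <- matrix(c(1, 1, 1, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("d1", "d2"), c("t1", "t2")))
  net <- dti_network(A)
  sigs <- vapply(c(0, 10, 50, 200), function(it) {
    p <- bine_params(dim = 4, max_iter = it, alpha = 0, beta = 0, gamma = 1,
                     lr = 0.5, ns = 0, max_walks = 1, seed = 5)
    emb <- train_bine(net, p)
    1 / (1 + exp(-sum(emb$drugs$vectors["d1", ] * emb$targets$vectors["t1", ])))
  }, 0)
  expect_true(all(diff(sigs) > 0))
  expect_gt(sigs[4], 0.9)
})

test_that("embeddings separate planted blocks and are reproducible", {
  spec <- synthetic_spec(n_drugs = 16, n_targets = 12, n_blocks = 2,
                         p_within = 0.6, p_between = 0.02, seed = 8)
  ds <- generate_dataset(spec)
  p <- bine_params(dim = 16, max_iter = 30, max_walks = 8, seed = 4)
  emb <- train_bine(ds$network, p)
  U <- emb$drugs$vectors
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  blocks <- ds$truth$drug_blocks
  within <- c(); between <- c()
  for (i in 1:15) for (j in (i + 1):16) {
    cs <- cosine(U[i, ], U[j, ])
    if (blocks[i] == blocks[j]) within <- c(within, cs) else between <- c(between, cs)
  }
  expect_gt(mean(within) - mean(between), 0)

  emb2 <- train_bine(ds$network, p)
  expect_identical(emb, emb2)
})

test_that("compiled epoch kernels agree with the exported update functions", {
  # implicit epoch vs sequential implicit_update under the same RNG stream
  set.seed(2)
  emb <- matrix(rnorm(18), 6, 3)
  ctx <- matrix(rnorm(18), 6, 3)
  pairs <- cbind(c(2L, 5L, 1L, 2L), c(3L, 4L, 6L, 1L))
  freq <- rep(1, 6)
  set.seed(7)
  res <- heteroDTI:::run_implicit_epoch(emb, ctx, pairs, freq, 0.3, 0.1, ns = 2)
  set.seed(7)
  ord <- sample.int(nrow(pairs))
  centers <- pairs[ord, 1L]; contexts <- pairs[ord, 2L]
  negs <- heteroDTI:::draw_negatives(centers, contexts, freq, 2L)
  emb_r <- emb; ctx_r <- ctx
  for (p in seq_along(centers)) {
    zs <- c(contexts[p], negs[p, ]); zs <- zs[zs > 0]
    up <- implicit_update(emb_r[centers[p], ], ctx_r[zs, , drop = FALSE],
                          c(1, numeric(length(zs) - 1)), 0.3, 0.1)
    emb_r[centers[p], ] <- up$center
    ctx_r[zs, ] <- up$contexts
  }
  expect_equal(res$emb, emb_r, tolerance = 1e-12)
  expect_equal(res$ctx, ctx_r, tolerance = 1e-12)

  # explicit epoch vs sequential explicit_update
  U <- matrix(rnorm(12), 4, 3); V <- matrix(rnorm(9), 3, 3)
  dr <- c(1L, 3L, 1L); tg <- c(2L, 1L, 2L)
  res2 <- heteroDTI:::sgd_explicit_epoch_cpp(U, V, dr, tg, 0.7, 0.2)
  U_r <- U; V_r <- V
  for (e in seq_along(dr)) {
    up <- explicit_update(U_r[dr[e], ], V_r[tg[e], ], 1, 0.7, 0.2)
    U_r[dr[e], ] <- up$u
    V_r[tg[e], ] <- up$v
  }
  expect_equal(res2$U, U_r, tolerance = 1e-12)
  expect_equal(res2$V, V_r, tolerance = 1e-12)
})

test_that("embedding norms stay finite over training at default rates", {
  net <- rand_network(10, 8, 0.35, seed = 6)
  p <- bine_params(dim = 8, max_iter = 20, max_walks = 4, seed = 1)
  emb <- train_bine(net, p)
  expect_true(all(is.finite(emb$drugs$vectors)))
  expect_true(all(is.finite(emb$targets$vectors)))
  expect_lt(max(abs(emb$drugs$vectors)), 100)
})
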