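# small fixtures built in code

toy_network <- function() {
  # three drugs, two targets: Drug1-{T2}, Drug2-{T1,T2}, Drug3-{T1}
  A <- matrix(c(0, 1,
                1, 1,
                1, 0), 3, 2, byrow = TRUE,
              dimnames = list(c("Drug1", "Drug2", "Drug3"),
                              c("Target1", "Target2")))
  dti_network(A)
}

# random binary bipartite network with every vertex connected
rand_network <- function(m, n, density = 0.3, seed = 1) {
  set.seed(seed)
  repeat {
    A <- matrix(as.numeric(runif(m * n) < density), m, n)
    if (all(rowSums(A) > 0) && all(colSums(A) > 0)) break
  }
  dimnames(A) <- list(paste0("d", seq_len(m)), paste0("t", seq_len(n)))
  dti_network(A)
}

# random symmetric non-negative similarity matrix
rand_similarity <- function(k, side = "drug", name = "rand", seed = 1) {
  set.seed(seed)
  M <- matrix(runif(k * k), k, k)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  similarity_matrix(M, side, name)
}

quick_config <- function(...) {
  hene_config(bine = list(dim = 8, max_iter = 3, max_walks = 4), ...)
}
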