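# Independent oracle implementations, deliberately naive (loops, no shared
# code with the package internals), used to cross-check the vectorized paths.

sigm <- function(x) 1 / (1 + exp(-x))

# shared-partner counts by explicit double loop
oracle_cohits <- function(A, side) {
  if (side == "target") A <- t(A)
  m <- nrow(A)
  H <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m))
    H[i, j] <- sum(A[i, ] * A[j, ])
  H
}

# straight-from-the-equations pair embedding: top-k neighbors by sorted
# weight (self excluded, ties by index), d_sim = (sum w) * u_d,
# d_path = (sum over neighbors z of A[z, t]) * v_t, parts summed then
# concatenated
oracle_pair_embedding <- function(d, t, U, V, Sd, St, A, k = 5) {
  topk <- function(S, i) {
    w <- S[i, ]
    w[i] <- -Inf
    ord <- order(-w, seq_along(w))
    ord <- ord[seq_len(min(k, length(w) - 1))]
    ord[w[ord] > 0]
  }
  nd <- topk(Sd, d)
  nt <- topk(St, t)
  d_sim <- if (length(nd)) sum(Sd[d, nd]) * U[d, ] else 0 * U[d, ]
  t_sim <- if (length(nt)) sum(St[t, nt]) * V[t, ] else 0 * V[t, ]
  d_path <- if (length(nd)) sum(A[nd, t]) * V[t, ] else 0 * V[t, ]
  t_path <- if (length(nt)) sum(A[d, nt]) * U[d, ] else 0 * U[d, ]
  c(d_sim + d_path, t_sim + t_path)
}

# naive similarity network fusion following the documented update equations,
# entry-by-entry loops throughout
oracle_snf <- function(mats, K, t) {
  k <- nrow(mats[[1]])
  full_kernel <- function(W) {
    P <- matrix(0, k, k)
    for (i in seq_len(k)) {
      denom <- sum(W[i, -i])
      if (denom == 0) denom <- 1
      for (j in seq_len(k)) P[i, j] <- if (i == j) 0.5 else W[i, j] / (2 * denom)
    }
    P
  }
  local_kernel <- function(W) {
    S <- matrix(0, k, k)
    for (i in seq_len(k)) {
      w <- W[i, ]
      w[i] <- -Inf
      nn <- order(-w, seq_len(k))[seq_len(K)]
      nn <- nn[W[i, nn] > 0]
      if (length(nn)) for (j in nn) S[i, j] <- W[i, j] / sum(W[i, nn])
    }
    S
  }
  P <- lapply(mats, full_kernel)
  S <- lapply(mats, local_kernel)
  V <- length(mats)
  for (iter in seq_len(t)) {
    Pnew <- vector("list", V)
    for (v in seq_len(V)) {
      avg <- matrix(0, k, k)
      if (V == 1) avg <- P[[1]]
      else for (u in seq_len(V)) if (u != v) avg <- avg + P[[u]] / (V - 1)
      Q <- S[[v]] %*% avg %*% t(S[[v]])
      Pnew[[v]] <- (Q + t(Q)) / 2
    }
    P <- Pnew
  }
  comp <- matrix(0, k, k)
  for (v in seq_len(V)) comp <- comp + P[[v]] / V
  (comp + t(comp)) / 2
}

# objective components of the joint embedding loss, for finite-difference
# gradient checks
explicit_objective <- function(u, v, w, gamma) gamma * w * log(sigm(sum(u * v)))

implicit_objective <- function(center, contexts, is_context, weight) {
  s <- as.vector(contexts %*% center)
  weight * sum(ifelse(as.logical(is_context), log(sigm(s)), log(sigm(-s))))
}

# central-difference gradient of f at x
numeric_gradient <- function(f, x, eps = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + eps
    xm <- x; xm[i] <- x[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
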