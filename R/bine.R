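#' Hyperparameters for bipartite embedding training
#'
#' Defaults follow the nuclear-receptor-scale profile: 64-dimensional
#' embeddings, learning rate 0.1, 4 negative samples per context, window 5,
#' trade-off weights alpha = 0.01 (drug corpus), beta = 0.1 (target corpus),
#' gamma = 0.1 (observed edges), walk stopping probability 0.15 and restart
#' probability 0.7. `max_iter` counts stochastic-gradient-ascent epochs over
#' the edge set and both corpora. `restart_prob = 0` is legal (plain
#' truncated walks).
#'
#' @param dim embedding size (per side; pair embeddings are twice as long).
#' @param max_iter number of training epochs.
#' @param lr learning rate lambda.
#' @param ns negative samples drawn per (center, context) pair.
#' @param ws context window size.
#' @param alpha,beta,gamma trade-off weights of the drug-corpus, target-corpus
#'   and observed-edge objective components.
#' @param stop_prob per-step probability that a truncated walk terminates.
#' @param restart_prob probability that a chosen step is replaced by the walk's
#'   start vertex.
#' @param max_walks,min_walks bounds on walks per start vertex; the count is
#'   scaled by the vertex's Co-HITS centrality (row sum of the walk graph).
#' @param max_walk_len hard cap on walk length (guards `stop_prob = 0`).
#' @param seed RNG seed controlling walks, shuffling, negative sampling and
#'   initialization.
#' @return An object of class `bine_params`.
#' @export
bine_params <- function(dim = 64, max_iter = 100, lr = 0.1, ns = 4, ws = 5,
                        alpha = 0.01, beta = 0.1, gamma = 0.1,
                        stop_prob = 0.15, restart_prob = 0.7,
                        max_walks = 32, min_walks = 1, max_walk_len = 100,
                        seed = 1) {
  p <- list(dim = as.integer(dim), max_iter = as.integer(max_iter), lr = lr,
            ns = as.integer(ns), ws = as.integer(ws), alpha = alpha,
            beta = beta, gamma = gamma, stop_prob = stop_prob,
            restart_prob = restart_prob, max_walks = as.integer(max_walks),
            min_walks = as.integer(min_walks),
            max_walk_len = as.integer(max_walk_len), seed = seed)
  if (p$dim < 1L) stop2("dim must be >= 1")
  if (p$max_iter < 0L) stop2("max_iter must be >= 0")
  if (p$lr <= 0) stop2("lr must be > 0")
  if (p$ns < 0L) stop2("ns must be >= 0")
  if (p$ws < 1L) stop2("ws must be >= 1")
  if (p$stop_prob < 0 || p$stop_prob > 1) stop2("stop_prob must be in [0, 1]")
  if (p$restart_prob < 0 || p$restart_prob > 1) stop2("restart_prob must be in [0, 1]")
  if (any(c(p$alpha, p$beta, p$gamma) < 0)) stop2("alpha, beta, gamma must be >= 0")
  if (p$min_walks < 1L || p$max_walks < p$min_walks)
    stop2("need max_walks >= min_walks >= 1")
  class(p) <- "bine_params"
  p
}

#' Co-HITS implicit-transition matrix
#'
#' Second-type homogeneous network derived from the bipartite adjacency:
#' `G_b %*% t(G_b)` for drugs (m x m) or `t(G_b) %*% G_b` for targets
#' (n x n). With binary weights, entry (i, j) counts the partners shared by
#' entities i and j, modelling the implicit transition strength between
#' same-type vertices ("guilt by association").
#'
#' @param network a [dti_network].
#' @param side `"drug"` or `"target"`.
#' @return An object of class `cohits_matrix` with fields `values` and `side`.
#' @export
cohits_matrix <- function(network, side) {
  side <- check_side(side)
  A <- network$adjacency
  values <- if (side == "drug") tcrossprod(A) else crossprod(A)
  structure(list(values = values, side = side), class = "cohits_matrix")
}

#' Truncated random walks with restart on a homogeneous network
#'
#' Converts a Co-HITS homogeneous network into a corpus of vertex sequences.
#' Each eligible start vertex (non-zero off-diagonal row) receives between
#' `min_walks` and `max_walks` walks, proportional to its centrality (row sum
#' of the walk graph). A walk starts at its start vertex; at each step it
#' terminates with probability `stop_prob`, otherwise the next vertex is drawn
#' among the current vertex's neighbors with probability proportional to edge
#' weight, and the drawn vertex is replaced by the start vertex with
#' probability `restart_prob`. Self-transitions (the diagonal of the Co-HITS
#' matrix) are excluded from the walk graph.
#'
#' @param homo a [cohits_matrix] (any non-negative square matrix accepted).
#' @param params a [bine_params].
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return An object of class `walk_corpus`: list with `side`, `sequences`
#'   (list of integer vectors) and `starts`.
#' @export
generate_walks <- function(homo, params = bine_params(), seed = NULL) {
  W <- if (inherits(homo, "cohits_matrix")) homo$values else as.matrix(homo)
  side <- if (inherits(homo, "cohits_matrix")) homo$side else "drug"
  if (length(W) == 0L) stop2("no walkable vertices: empty matrix")
  diag(W) <- 0
  cent <- rowSums(W)
  eligible <- which(cent > 0)
  if (length(eligible) == 0L) stop2("no walkable vertices")
  skipped <- which(cent == 0)
  if (length(skipped))
    message("generate_walks: skipping ", length(skipped),
            " vertices with no off-diagonal weight")
  nbrs <- lapply(seq_len(nrow(W)), function(i) which(W[i, ] > 0))
  probs <- lapply(seq_len(nrow(W)), function(i) {
    w <- W[i, nbrs[[i]]]
    w / sum(w)
  })
  n_walks <- pmin(params$max_walks,
                  pmax(params$min_walks,
                       ceiling(params$max_walks * cent / max(cent))))
  with_seed(seed, {
    sequences <- vector("list", sum(n_walks[eligible]))
    starts <- integer(length(sequences))
    k <- 0L
    for (v in eligible) {
      for (r in seq_len(n_walks[v])) {
        seqv <- integer(params$max_walk_len)
        seqv[1L] <- v
        len <- 1L
        cur <- v
        while (len < params$max_walk_len) {
          if (stats::runif(1) < params$stop_prob) break
          nb <- nbrs[[cur]]
          if (length(nb) == 0L) break
          nxt <- if (length(nb) == 1L) nb else
            nb[sample.int(length(nb), 1L, prob = probs[[cur]])]
          if (stats::runif(1) < params$restart_prob) nxt <- v
          len <- len + 1L
          seqv[len] <- nxt
          cur <- nxt
        }
        k <- k + 1L
        sequences[[k]] <- seqv[seq_len(len)]
        starts[k] <- v
      }
    }
    structure(list(side = side, sequences = sequences, starts = starts),
              class = "walk_corpus")
  })
}

# All (center, context) pairs within window ws, as a 2-column integer matrix.
corpus_pairs <- function(corpus, ws) {
  pair_list <- lapply(corpus$sequences, function(s) {
    L <- length(s)
    if (L < 2L) return(NULL)
    out <- vector("list", L)
    for (i in seq_len(L)) {
      ctx <- s[max(1L, i - ws):min(L, i + ws)]
      ctx <- ctx[-(i - max(1L, i - ws) + 1L)]
      out[[i]] <- cbind(s[i], ctx)
    }
    do.call(rbind, out)
  })
  pairs <- do.call(rbind, pair_list)
  if (is.null(pairs)) matrix(integer(), 0L, 2L) else pairs
}

# Token frequencies of a corpus (for the unigram^0.75 negative sampler).
corpus_frequencies <- function(corpus, n_vertices) {
  tab <- tabulate(unlist(corpus$sequences), nbins = n_vertices)
  tab
}

#' One explicit-relationship gradient step
#'
#' Ascends the observed-edge component of the joint objective,
#' `gamma * w_ij * log sigma(u'v)`, for a single bipartite edge:
#' `u <- u + lr * gamma * w_ij * (1 - sigma(u'v)) * v` and symmetrically for
#' `v` (both evaluated at the input vectors; inputs are not mutated).
#'
#' @param u,v numeric embedding vectors of equal length.
#' @param w_ij non-negative edge weight (1 for a known interaction).
#' @param gamma trade-off weight of the explicit component.
#' @param lr learning rate.
#' @return list with updated `u` and `v`.
#' @export
explicit_update <- function(u, v, w_ij, gamma, lr) {
  if (length(u) != length(v)) stop2("u and v must have the same length")
  if (w_ij < 0) stop2("w_ij must be >= 0")
  g <- gamma * w_ij * (1 - sigmoid(sum(u * v)))
  list(u = u + lr * g * v, v = v + lr * g * u)
}

#' One implicit-relationship gradient step (skip-gram with negative sampling)
#'
#' Ascends `weight * [log sigma(c' theta_ctx) + sum_neg log sigma(-c' theta_z)]`
#' for one (center, context) pair and its negative samples. The center vector
#' is moved by `lr * sum_z weight * (I_z - sigma(c' theta_z)) * theta_z`
#' where `I_z` is 1 for the true context and 0 for negatives; each context
#' vector receives the symmetric update `lr * weight * (I_z - sigma) * c`.
#' All sigmoids are evaluated at the input state (simultaneous update);
#' inputs are not mutated.
#'
#' @param center_vec embedding vector of the center vertex.
#' @param context_mat matrix whose rows are the context vectors `theta_z` of
#'   the true context and the negative samples.
#' @param is_context logical/0-1 vector marking which rows are true contexts.
#' @param weight alpha (drug corpus) or beta (target corpus).
#' @param lr learning rate.
#' @return list with updated `center` vector and `contexts` matrix.
#' @export
implicit_update <- function(center_vec, context_mat, is_context, weight, lr) {
  context_mat <- rbind(context_mat)
  if (ncol(context_mat) != length(center_vec))
    stop2("context vectors must match the center vector length")
  if (nrow(context_mat) != length(is_context))
    stop2("is_context must flag every context row")
  s <- sigmoid(as.vector(context_mat %*% center_vec))
  coef <- weight * (as.numeric(is_context) - s)
  list(center = center_vec + lr * as.vector(crossprod(context_mat, coef)),
       contexts = context_mat + (lr * coef) %o% center_vec)
}

# Draw ns negatives per pair from freq^0.75, redrawing (up to 5 rounds) any
# draw that collides with its pair's center or true context. Unresolved
# collisions are dropped (returned as 0).
draw_negatives <- function(centers, contexts, freq, ns) {
  npairs <- length(centers)
  if (ns == 0L || npairs == 0L)
    return(matrix(integer(), npairs, 0L))
  prob <- freq^0.75
  pool <- which(prob > 0)
  prob <- prob[pool]
  negs <- matrix(pool[sample.int(length(pool), npairs * ns, replace = TRUE,
                                 prob = prob)],
                 npairs, ns)
  for (round in 1:5) {
    bad <- which(negs == centers | negs == contexts)
    if (length(bad) == 0L) break
    negs[bad] <- pool[sample.int(length(pool), length(bad), replace = TRUE,
                                 prob = prob)]
  }
  bad <- negs == centers | negs == contexts
  negs[bad] <- 0L
  negs
}

# One epoch of implicit (skip-gram) updates over a pair list. Sampling
# (shuffle + negatives) stays in R so the RNG stream defines the run; the
# numeric updates run in the compiled kernel, whose arithmetic is exactly
# implicit_update() applied pair by pair.
run_implicit_epoch <- function(emb, ctx, pairs, freq, weight, lr, ns) {
  ord <- sample.int(nrow(pairs))
  centers <- pairs[ord, 1L]
  contexts <- pairs[ord, 2L]
  negs <- draw_negatives(centers, contexts, freq, ns)
  res <- sgd_implicit_epoch_cpp(emb, ctx, centers, contexts, negs, weight, lr)
  dimnames(res$emb) <- dimnames(emb)
  dimnames(res$ctx) <- dimnames(ctx)
  res
}

#' Train bipartite embeddings
#'
#' Joint stochastic-gradient-ascent training of drug and target embeddings
#' from a bipartite DTI network. The procedure: (1) build the drug and target
#' Co-HITS homogeneous matrices; (2) convert each into a corpus of truncated
#' random walks with restart; (3) initialize embeddings uniformly in
#' `[-0.5/dim, 0.5/dim]` and context vectors at zero; (4) for `max_iter`
#' epochs, apply [explicit_update()] to every observed edge and
#' [implicit_update()] (with `alpha` for the drug corpus, `beta` for the
#' target corpus, and `ns` negative samples drawn from the unigram^0.75
#' distribution of corpus frequencies) to every in-window (center, context)
#' pair. Edge and pair orders are reshuffled every epoch. Fully reproducible
#' under `params$seed`.
#'
#' @param network a [dti_network].
#' @param params a [bine_params].
#' @return list with elements `drugs` and `targets`, each an embedding table:
#'   list with `side`, `vectors` (entities x dim, rownames = ids) and
#'   `context` (the paired context vectors).
#' @export
train_bine <- function(network, params = bine_params()) {
  m <- length(network$drug_ids)
  n <- length(network$target_ids)
  hd <- cohits_matrix(network, "drug")
  ht <- cohits_matrix(network, "target")
  with_seed(params$seed, {
    corp_d <- generate_walks(hd, params)
    corp_t <- generate_walks(ht, params)
    pairs_d <- corpus_pairs(corp_d, params$ws)
    pairs_t <- corpus_pairs(corp_t, params$ws)
    freq_d <- corpus_frequencies(corp_d, m)
    freq_t <- corpus_frequencies(corp_t, n)
    U <- matrix(stats::runif(m * params$dim, -0.5 / params$dim, 0.5 / params$dim),
                m, params$dim, dimnames = list(network$drug_ids, NULL))
    V <- matrix(stats::runif(n * params$dim, -0.5 / params$dim, 0.5 / params$dim),
                n, params$dim, dimnames = list(network$target_ids, NULL))
    TH <- matrix(0, m, params$dim, dimnames = list(network$drug_ids, NULL))
    VTH <- matrix(0, n, params$dim, dimnames = list(network$target_ids, NULL))
    edges <- which(network$adjacency == 1, arr.ind = TRUE)
    for (epoch in seq_len(params$max_iter)) {
      ord <- sample.int(nrow(edges))
      res <- sgd_explicit_epoch_cpp(U, V, edges[ord, 1L], edges[ord, 2L],
                                    params$gamma, params$lr)
      dimnames(res$U) <- dimnames(U); dimnames(res$V) <- dimnames(V)
      U <- res$U; V <- res$V
      if (nrow(pairs_d)) {
        res <- run_implicit_epoch(U, TH, pairs_d, freq_d, params$alpha,
                                  params$lr, params$ns)
        U <- res$emb; TH <- res$ctx
      }
      if (nrow(pairs_t)) {
        res <- run_implicit_epoch(V, VTH, pairs_t, freq_t, params$beta,
                                  params$lr, params$ns)
        V <- res$emb; VTH <- res$ctx
      }
    }
    if (anyNA(U) || anyNA(V) || any(!is.finite(U)) || any(!is.finite(V)))
      stop2("embedding training diverged (non-finite values)")
    list(drugs = structure(list(side = "drug", vectors = U, context = TH),
                           class = "embedding_table"),
         targets = structure(list(side = "target", vectors = V, context = VTH),
                             class = "embedding_table"))
  })
}

#' Dump a walk corpus to plain text (one sequence per line)
#' @param corpus a `walk_corpus`.
#' @param path output file path.
#' @export
write_walk_corpus <- function(corpus, path) {
  writeLines(vapply(corpus$sequences, paste, "", collapse = " "), path)
  invisible(path)
}
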