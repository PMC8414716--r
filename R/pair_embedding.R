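#' Top-k nearest neighbors of an entity in a composite similarity matrix
#'
#' Returns the `k` entities with the largest composite weight to `entity`
#' (the entity itself excluded), ordered by non-increasing weight with ties
#' broken by ascending index. Entities with zero weight are never returned,
#' so fewer than `k` neighbors come back for weakly connected entities (an
#' all-zero row yields an empty set with a warning).
#'
#' @param composite a [similarity_matrix].
#' @param entity entity index (1-based) or id.
#' @param k number of neighbors (default 5).
#' @return list with `entity`, `indices` and `weights` (non-increasing).
#' @export
top_k_neighbors <- function(composite, entity, k = 5) {
  if (k < 1) stop2("k must be >= 1")
  M <- composite$values
  if (is.character(entity)) entity <- match(entity, rownames(M))
  w <- M[entity, ]
  w[entity] <- -Inf
  ord <- order(-w, seq_along(w))[seq_len(min(k, length(w) - 1L))]
  ord <- ord[w[ord] > 0]
  if (length(ord) == 0L)
    warning("entity ", entity, " has no positive-weight neighbors", call. = FALSE)
  list(entity = entity, indices = ord, weights = unname(w[ord]))
}

#' Similarity component of a pair embedding
#'
#' Scales the entity's own embedding by each neighbor weight and sums, i.e.
#' `(sum of neighbor weights) * entity_vec`. An empty neighbor set yields the
#' zero vector.
#'
#' @param entity_vec the entity's embedding vector.
#' @param neighbors a neighbor set from [top_k_neighbors()].
#' @return numeric vector of the same length as `entity_vec`.
#' @export
similarity_component <- function(entity_vec, neighbors) {
  sum(neighbors$weights) * entity_vec
}

#' Path component of a pair embedding
#'
#' Weights the partner's embedding by the bipartite edge weights between the
#' entity's nearest neighbors and the partner, and sums:
#' `sum_z G_b[z, partner] * partner_vec` (drug-side neighbors against a target
#' partner) or `sum_z G_b[partner, z] * partner_vec` (target-side neighbors
#' against a drug partner). With binary weights this is the count of
#' neighbors known to interact with the partner, times the partner's vector.
#'
#' @param partner_vec embedding vector of the partner entity (opposite side
#'   of the neighbors).
#' @param neighbors neighbor set of the entity (same side as the entity).
#' @param network a [dti_network].
#' @param partner partner index (1-based).
#' @param neighbor_side side of the neighbor set: `"drug"` means the
#'   neighbors are drugs and the partner a target; `"target"` the converse.
#' @return numeric vector of the same length as `partner_vec`.
#' @export
path_component <- function(partner_vec, neighbors, network, partner,
                           neighbor_side) {
  neighbor_side <- check_side(neighbor_side)
  A <- network$adjacency
  w <- if (neighbor_side == "drug") A[neighbors$indices, partner]
       else A[partner, neighbors$indices]
  sum(w) * partner_vec
}

#' Fused embedding of one drug-target pair
#'
#' Builds the pair embedding of `(d, t)`: the drug part is the drug's
#' similarity component plus the path component of the target embedding
#' through the drug's nearest neighbors; the target part is symmetric; the
#' two parts are concatenated, giving a vector twice the embedding size.
#'
#' @param d,t drug and target indices (1-based).
#' @param drug_table,target_table embedding tables from [train_bine()].
#' @param drug_composite,target_composite composite [similarity_matrix]
#'   objects from [build_composite()].
#' @param network a [dti_network].
#' @param k neighbors per entity (default 5).
#' @return numeric vector of length `2 * dim`.
#' @export
build_pair_embedding <- function(d, t, drug_table, target_table,
                                 drug_composite, target_composite,
                                 network, k = 5) {
  u <- drug_table$vectors[d, ]
  v <- target_table$vectors[t, ]
  nd <- suppressWarnings(top_k_neighbors(drug_composite, d, k))
  nt <- suppressWarnings(top_k_neighbors(target_composite, t, k))
  d_part <- similarity_component(u, nd) +
    path_component(v, nd, network, t, "drug")
  t_part <- similarity_component(v, nt) +
    path_component(u, nt, network, d, "target")
  c(d_part, t_part)
}

#' Embeddings of every drug-target pair
#'
#' Vectorized construction of the pair embedding for all `m * n` pairs in the
#' drug-major order `(d1,t1), (d1,t2), ..., (dm,tn)`. When `mask_edges` is
#' given (a 2-column matrix of drug/target indices), those bipartite weights
#' are treated as 0 inside the path components -- the leakage control used
#' when embedding test-fold pairs. `neighbor_mix = "neighbor_embeddings"` is
#' a variant where the similarity component mixes the neighbors' own
#' embeddings (`sum_z w_z * vec_z`) instead of scaling the entity's vector.
#'
#' @inheritParams build_pair_embedding
#' @param mask_edges optional 2-column integer matrix (drug, target) of edges
#'   to hide from the path components.
#' @param neighbor_mix `"as_printed"` (default) or `"neighbor_embeddings"`.
#' @return list with `pairs` (data frame: `drug`, `target`, `drug_id`,
#'   `target_id`) and `vectors` (matrix `(m*n) x (2*dim)`).
#' @export
build_all_pairs <- function(network, drug_table, target_table,
                            drug_composite, target_composite, k = 5,
                            mask_edges = NULL,
                            neighbor_mix = c("as_printed", "neighbor_embeddings")) {
  neighbor_mix <- match.arg(neighbor_mix)
  U <- drug_table$vectors
  V <- target_table$vectors
  m <- nrow(U); n <- nrow(V); dim <- ncol(U)
  A <- network$adjacency
  if (!is.null(mask_edges) && nrow(mask_edges)) A[mask_edges] <- 0
  # neighbor indicator matrices carrying the composite weights
  Wd <- matrix(0, m, m)
  for (i in seq_len(m)) {
    nb <- suppressWarnings(top_k_neighbors(drug_composite, i, k))
    Wd[i, nb$indices] <- nb$weights
  }
  Wt <- matrix(0, n, n)
  for (j in seq_len(n)) {
    nb <- suppressWarnings(top_k_neighbors(target_composite, j, k))
    Wt[j, nb$indices] <- nb$weights
  }
  # sim components
  if (neighbor_mix == "as_printed") {
    Dsim <- rowSums(Wd) * U              # m x dim, row d = (sum w) * u_d
    Tsim <- rowSums(Wt) * V
  } else {
    Dsim <- Wd %*% U
    Tsim <- Wt %*% V
  }
  # path weights: P_d[d, t] = sum over d's neighbors z of A[z, t]
  Pd <- (Wd > 0) %*% A                   # m x n
  Pt <- A %*% t(Wt > 0)                  # m x n ; entry (d, t) = sum_z A[d, z]
  grid_d <- rep(seq_len(m), each = n)
  grid_t <- rep(seq_len(n), times = m)
  vectors <- cbind(
    Dsim[grid_d, , drop = FALSE] + Pd[cbind(grid_d, grid_t)] * V[grid_t, , drop = FALSE],
    Tsim[grid_t, , drop = FALSE] + Pt[cbind(grid_d, grid_t)] * U[grid_d, , drop = FALSE]
  )
  rownames(vectors) <- NULL
  stopifnot(ncol(vectors) == 2L * dim)
  list(pairs = data.frame(drug = grid_d, target = grid_t,
                          drug_id = network$drug_ids[grid_d],
                          target_id = network$target_ids[grid_t]),
       vectors = vectors)
}
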