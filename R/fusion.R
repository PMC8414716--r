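#' Collection of similarity matrices for one side
#'
#' @param matrices named list of [similarity_matrix] objects (or plain square
#'   matrices), all of the same dimension and side.
#' @param side `"drug"` or `"target"`.
#' @return An object of class `similarity_collection`.
#' @export
similarity_collection <- function(matrices, side) {
  side <- check_side(side)
  if (length(matrices) < 1L) stop2("need at least one similarity matrix")
  nm <- names(matrices)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop2("matrices must have unique names")
  matrices <- lapply(nm, function(x) {
    s <- matrices[[x]]
    if (!inherits(s, "similarity_matrix")) s <- similarity_matrix(s, side, x)
    if (s$side != side) stop2("matrix '", x, "' belongs to the other side")
    s
  })
  names(matrices) <- nm
  dims <- vapply(matrices, function(s) nrow(s$values), 0L)
  if (length(unique(dims)) != 1L) stop2("matrices have inconsistent dimensions")
  structure(list(matrices = matrices, side = side),
            class = "similarity_collection")
}

#' Shannon entropy of a similarity matrix
#'
#' Flattens the matrix, normalizes the entries to sum to one, and returns
#' the Shannon entropy `-sum(p * log(p))` in nats (`0 * log 0 := 0`). The
#' maximum attainable value is `log(k)` with `k` the number of entries, met by
#' a uniform matrix; a matrix with a single non-zero entry has entropy 0.
#'
#' @param matrix a [similarity_matrix] or non-negative numeric matrix.
#' @return entropy in nats.
#' @export
matrix_entropy <- function(matrix) {
  m <- if (inherits(matrix, "similarity_matrix")) matrix$values else as.matrix(matrix)
  if (any(m < 0)) stop2("matrix must be non-negative")
  s <- sum(m)
  if (s <= 0) stop2("all-zero matrix has no entropy")
  p <- as.vector(m) / s
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Entropy screen of a similarity collection
#'
#' Removes every matrix whose flattened Shannon entropy exceeds
#' `c1 * log(k)`. By default `log(k)` is the maximum possible entropy
#' (`k` = number of entries per matrix); `reference = "max_observed"` instead
#' uses the largest entropy observed in the collection. Near-uniform
#' (uninformative) matrices sit close to the maximum and are removed;
#' structured matrices with concentrated similarity mass survive.
#'
#' @param collection a [similarity_collection].
#' @param c1 screening threshold (default 0.7).
#' @param reference `"max_possible"` or `"max_observed"`.
#' @return list with `retained` (a [similarity_collection]) and `report`
#'   (entropies, threshold, removed names).
#' @export
entropy_screen <- function(collection, c1 = 0.7,
                           reference = c("max_possible", "max_observed")) {
  reference <- match.arg(reference)
  ent <- vapply(collection$matrices, matrix_entropy, 0)
  k <- length(collection$matrices[[1L]]$values)
  href <- if (reference == "max_possible") log(k) else max(ent)
  threshold <- c1 * href
  removed <- names(ent)[ent > threshold]
  kept <- setdiff(names(ent), removed)
  if (length(kept) == 0L)
    stop2("entropy screen removed every matrix (threshold ", signif(threshold, 4),
          "); consider raising c1")
  list(retained = similarity_collection(collection$matrices[kept], collection$side),
       report = list(entropies = ent, entropy_threshold = threshold,
                     entropy_reference = reference, removed_by_entropy = removed))
}

# redundancy index between two matrices: Es = 1 / (1 + Euclidean distance of
# the flattened matrices); Es = 1 iff identical.
redundancy_index <- function(a, b) {
  ma <- if (inherits(a, "similarity_matrix")) a$values else a
  mb <- if (inherits(b, "similarity_matrix")) b$values else b
  1 / (1 + sqrt(sum((ma - mb)^2)))
}

#' Redundancy screen of a similarity collection
#'
#' Orders matrices by ascending entropy (ties broken by name) and walks the
#' list: starting from the lowest-entropy retained matrix, every later
#' still-retained matrix whose redundancy index `Es = 1 / (1 + d)` with the
#' current matrix exceeds `c2` is removed (`d` = Euclidean distance of the
#' flattened matrices); the scan then advances to the next retained matrix
#' until the list is exhausted. A single-matrix collection passes through.
#'
#' @param collection a [similarity_collection].
#' @param c2 redundancy threshold (default 0.6).
#' @param entropies optional named entropy vector (computed if missing).
#' @return list with `retained` (a [similarity_collection]) and `report`
#'   (`es_pairs` data frame of compared pairs, removed names).
#' @export
redundancy_screen <- function(collection, c2 = 0.6, entropies = NULL) {
  nm <- names(collection$matrices)
  if (is.null(entropies))
    entropies <- vapply(collection$matrices, matrix_entropy, 0)
  ord <- nm[order(entropies[nm], nm)]
  alive <- stats::setNames(rep(TRUE, length(ord)), ord)
  es_pairs <- list()
  i <- 1L
  while (i <= length(ord)) {
    if (alive[[ord[i]]]) {
      cur <- ord[i]
      for (j in seq_along(ord)[-seq_len(i)]) {
        cand <- ord[j]
        if (!alive[[cand]]) next
        es <- redundancy_index(collection$matrices[[cur]],
                               collection$matrices[[cand]])
        es_pairs[[length(es_pairs) + 1L]] <-
          data.frame(kept = cur, candidate = cand, Es = es)
        if (es > c2) alive[[cand]] <- FALSE
      }
    }
    i <- i + 1L
  }
  kept <- nm[nm %in% ord[alive]]
  list(retained = similarity_collection(collection$matrices[kept], collection$side),
       report = list(es_pairs = if (length(es_pairs)) do.call(rbind, es_pairs)
                     else data.frame(kept = character(), candidate = character(),
                                     Es = numeric()),
                     removed_by_redundancy = setdiff(nm, kept)))
}

# Full-kernel normalization of one similarity view:
# P[i,j] = W[i,j] / (2 * sum_{l != i} W[i,l]) off-diagonal, P[i,i] = 1/2.
snf_full_kernel <- function(W) {
  D <- rowSums(W) - diag(W)
  D[D == 0] <- 1 # isolated row: keeps off-diagonal zeros, diagonal 1/2
  P <- W / (2 * D)
  diag(P) <- 0.5
  P
}

# K-nearest-neighbor local kernel: row-normalized over each row's K largest
# off-diagonal weights (ties broken by ascending index), zero elsewhere.
snf_local_kernel <- function(W, K) {
  k <- nrow(W)
  S <- matrix(0, k, k, dimnames = dimnames(W))
  for (i in seq_len(k)) {
    w <- W[i, ]
    w[i] <- -Inf
    nn <- order(-w, seq_len(k))[seq_len(K)]
    nn <- nn[W[i, nn] > 0]
    if (length(nn)) S[i, nn] <- W[i, nn] / sum(W[i, nn])
  }
  S
}

#' Similarity network fusion
#'
#' Fuses the views of a collection into one composite matrix by iterative
#' cross-diffusion. Each view `W_v` is converted to a full kernel `P_v`
#' (row-stochastic with half the mass on the diagonal) and a K-nearest-neighbor
#' local kernel `S_v`; then for `t` rounds every view is updated as
#' `P_v <- S_v %*% mean(P_u, u != v) %*% t(S_v)` followed by symmetrization,
#' and the composite is the average of the final views (symmetrized). A
#' single-view collection diffuses against itself, so fusing duplicates of one
#' matrix reproduces its single-view result.
#'
#' @param collection a [similarity_collection].
#' @param K number of nearest neighbors of the local kernel (must be smaller
#'   than the matrix dimension).
#' @param t number of cross-diffusion iterations.
#' @return A [similarity_matrix] named `"composite"`; symmetric, non-negative.
#' @export
snf_fuse <- function(collection, K = 20, t = 20) {
  mats <- lapply(collection$matrices, `[[`, "values")
  k <- nrow(mats[[1L]])
  if (K >= k) stop2("K must be smaller than the matrix dimension (", k, ")")
  if (K < 1L) stop2("K must be >= 1")
  P <- lapply(mats, snf_full_kernel)
  S <- lapply(mats, snf_local_kernel, K = K)
  V <- length(P)
  for (iter in seq_len(t)) {
    Pnew <- vector("list", V)
    for (v in seq_len(V)) {
      avg <- if (V == 1L) P[[1L]] else
        Reduce(`+`, P[-v]) / (V - 1)
      Q <- S[[v]] %*% avg %*% t(S[[v]])
      Pnew[[v]] <- (Q + t(Q)) / 2
    }
    P <- Pnew
  }
  comp <- Reduce(`+`, P) / V
  comp <- (comp + t(comp)) / 2
  dimnames(comp) <- dimnames(mats[[1L]])
  similarity_matrix(comp, collection$side, "composite")
}

#' Screen and fuse a similarity collection into a composite matrix
#'
#' Chains [entropy_screen()], [redundancy_screen()] and [snf_fuse()],
#' recording every decision in a fusion report. `K` is clipped to the matrix
#' dimension minus one so small collections fuse without manual tuning.
#'
#' @param collection a [similarity_collection].
#' @param c1 entropy threshold (default 0.7).
#' @param c2 redundancy threshold (default 0.6).
#' @param K,t SNF neighborhood size and iteration count.
#' @param entropy_reference passed to [entropy_screen()].
#' @return list with `composite` (a [similarity_matrix]) and `report`
#'   (class `fusion_report`).
#' @export
build_composite <- function(collection, c1 = 0.7, c2 = 0.6, K = 20, t = 20,
                            entropy_reference = c("max_possible", "max_observed")) {
  es <- entropy_screen(collection, c1, match.arg(entropy_reference))
  rs <- redundancy_screen(es$retained, c2, es$report$entropies)
  K <- min(K, nrow(rs$retained$matrices[[1L]]$values) - 1L)
  composite <- snf_fuse(rs$retained, K = K, t = t)
  report <- structure(c(es$report, rs$report,
                        list(retained = names(rs$retained$matrices),
                             snf_K = K, snf_t = t)),
                      class = "fusion_report")
  list(composite = composite, report = report)
}

#' @export
print.fusion_report <- function(x, ...) {
  cat("<fusion_report>\n")
  cat("  entropies:", paste(sprintf("%s=%.3f", names(x$entropies), x$entropies),
                            collapse = ", "), "\n")
  cat(sprintf("  entropy threshold: %.3f (%s)\n", x$entropy_threshold,
              x$entropy_reference))
  cat("  removed by entropy:",
      if (length(x$removed_by_entropy)) paste(x$removed_by_entropy, collapse = ", ")
      else "none", "\n")
  cat("  removed by redundancy:",
      if (length(x$removed_by_redundancy)) paste(x$removed_by_redundancy, collapse = ", ")
      else "none", "\n")
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}
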