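#' Bipartite drug-target interaction network
#'
#' Container for the binary bipartite interaction matrix `G_b` together with
#' its drug and target identifier registries. Rows are drugs, columns are
#' targets, and an entry of 1 records a known interaction (all known
#' interactions carry weight 1; unknown pairs carry weight 0 -- there is no
#' missing-value state).
#'
#' @param adjacency numeric matrix with entries in `{0, 1}`; rows = drugs,
#'   columns = targets.
#' @param drug_ids,target_ids character vectors of unique identifiers whose
#'   order defines the row/column indices. Defaults to the dimnames of
#'   `adjacency`.
#' @return An object of class `dti_network` with fields `adjacency`,
#'   `drug_ids`, `target_ids`.
#' @examples
#' net <- dti_network(matrix(c(1, 1, 1, 0), 2, 2, byrow = TRUE),
#'                    c("d1", "d2"), c("t1", "t2"))
#' interaction_stats(net)
#' @export
dti_network <- function(adjacency, drug_ids = rownames(adjacency),
                        target_ids = colnames(adjacency)) {
  adjacency <- as.matrix(adjacency)
  if (is.null(drug_ids) || is.null(target_ids))
    stop2("drug and target ids are required (or supply a matrix with dimnames)")
  drug_ids <- as.character(drug_ids)
  target_ids <- as.character(target_ids)
  if (anyDuplicated(drug_ids)) stop2("duplicate drug ids")
  if (anyDuplicated(target_ids)) stop2("duplicate target ids")
  if (nrow(adjacency) != length(drug_ids) || ncol(adjacency) != length(target_ids))
    stop2("adjacency dimensions do not match the id registries")
  if (nrow(adjacency) < 1L || ncol(adjacency) < 1L)
    stop2("network needs at least one drug and one target")
  if (!all(adjacency %in% c(0, 1)))
    stop2("adjacency entries must be 0 or 1")
  storage.mode(adjacency) <- "double"
  dimnames(adjacency) <- list(drug_ids, target_ids)
  iso_d <- rowSums(adjacency) == 0
  iso_t <- colSums(adjacency) == 0
  if (any(iso_d))
    warning("drugs without any known interaction: ",
            paste(drug_ids[iso_d], collapse = ", "), call. = FALSE)
  if (any(iso_t))
    warning("targets without any known interaction: ",
            paste(target_ids[iso_t], collapse = ", "), call. = FALSE)
  structure(list(adjacency = adjacency, drug_ids = drug_ids,
                 target_ids = target_ids),
            class = "dti_network")
}

#' @export
print.dti_network <- function(x, ...) {
  s <- interaction_stats(x)
  cat(sprintf("<dti_network> %d drugs x %d targets, %d known interactions (%.2f%%)\n",
              s$n_drugs, s$n_targets, s$n_positive, s$pct_positive))
  invisible(x)
}

#' Read a bipartite edge list
#'
#' Parses a tab-separated edge list (no header) with columns
#' `drug_id`, `target_id` and an optional third `weight` column restricted to
#' `{0, 1}`. Lines starting with `#` are comments. Duplicate edges collapse to
#' a single interaction. When registries are not given they are built in
#' first-appearance order from the file.
#'
#' @param path file path.
#' @param drug_ids,target_ids optional fixed registries; entities in the file
#'   must be a subset of them.
#' @return A [dti_network].
#' @export
read_dti_edges <- function(path, drug_ids = NULL, target_ids = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop2("no edges in '", path, "'")
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- nf < 2L
  if (any(bad))
    stop2("malformed edge line ", idx[which(bad)[1L]], " in '", path,
          "': expected at least 2 tab-separated columns")
  d <- vapply(fields, `[[`, "", 1L)
  t <- vapply(fields, `[[`, "", 2L)
  w <- rep(1, length(d))
  has_w <- nf >= 3L
  if (any(has_w)) {
    wraw <- suppressWarnings(as.numeric(vapply(fields[has_w], `[[`, "", 3L)))
    if (anyNA(wraw) || !all(wraw %in% c(0, 1)))
      stop2("edge weights must be 0 or 1 (line ",
            idx[has_w][which(is.na(wraw) | !(wraw %in% c(0, 1)))[1L]], ")")
    w[has_w] <- wraw
  }
  if (is.null(drug_ids)) drug_ids <- unique(d)
  if (is.null(target_ids)) target_ids <- unique(t)
  if (!all(d %in% drug_ids))
    stop2("drug ids not in registry: ",
          paste(unique(setdiff(d, drug_ids)), collapse = ", "))
  if (!all(t %in% target_ids))
    stop2("target ids not in registry: ",
          paste(unique(setdiff(t, target_ids)), collapse = ", "))
  adj <- matrix(0, length(drug_ids), length(target_ids),
                dimnames = list(drug_ids, target_ids))
  pos <- w == 1
  adj[cbind(match(d[pos], drug_ids), match(t[pos], target_ids))] <- 1
  if (!any(adj == 1)) stop2("no edges in '", path, "'")
  dti_network(adj, drug_ids, target_ids)
}

#' Write a bipartite edge list
#'
#' Inverse of [read_dti_edges()]: one `drug_id<TAB>target_id` line per known
#' interaction, in row-major registry order.
#' @param network a [dti_network].
#' @param path output file path.
#' @export
write_dti_edges <- function(network, path) {
  e <- which(t(network$adjacency) == 1, arr.ind = TRUE) # target-major -> row-major on transpose
  lines <- sprintf("%s\t%s", network$drug_ids[e[, 2L]], network$target_ids[e[, 1L]])
  writeLines(lines, path)
  invisible(path)
}

#' Similarity matrix for one side of the network
#'
#' A square, symmetric, non-negative matrix of drug-drug or target-target
#' similarities (a first-type homogeneous network). Asymmetric input is
#' symmetrized by averaging `(M + t(M)) / 2`; a warning is issued when the
#' maximum asymmetry exceeds `1e-8`.
#'
#' @param values square numeric matrix.
#' @param side `"drug"` or `"target"`.
#' @param name label of the similarity source.
#' @return An object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(values, side, name = "similarity") {
  side <- check_side(side)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop2("similarity matrix must be square")
  if (anyNA(values) || any(!is.finite(values)))
    stop2("similarity matrix must be finite")
  asym <- max(abs(values - t(values)))
  if (asym > 1e-8)
    warning(sprintf("asymmetric similarity matrix '%s' (max |M - t(M)| = %.3g); symmetrized by averaging",
                    name, asym), call. = FALSE)
  values <- (values + t(values)) / 2
  structure(list(values = values, side = side, name = name),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> '%s' (%s side), %d x %d, range [%.3g, %.3g]\n",
              x$name, x$side, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Read a similarity matrix from TSV
#'
#' Expects a header row of entity ids and an id-labelled first column. Rows
#' and columns are reordered to match `ids` (the registry order for that
#' side), so files may store entities in any permutation.
#'
#' @param path file path.
#' @param side `"drug"` or `"target"`.
#' @param ids registry ids for that side; the file must contain exactly these.
#' @param name source label; defaults to the file name without extension.
#' @return A [similarity_matrix].
#' @export
read_similarity_matrix <- function(path, side, ids, name = NULL) {
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stop2("similarity matrix in '", path, "' is not square")
  file_ids <- rownames(m)
  missing <- setdiff(ids, file_ids)
  extra <- setdiff(file_ids, ids)
  if (length(missing) || length(extra))
    stop2("ids in '", path, "' do not match the registry",
          if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
          if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ", ")))
  m <- m[ids, ids, drop = FALSE]
  similarity_matrix(m, side, name)
}

#' Write a similarity matrix to TSV
#' @param sim a [similarity_matrix] (or plain matrix with dimnames).
#' @param path output file path.
#' @export
write_similarity_matrix <- function(sim, path) {
  m <- if (inherits(sim, "similarity_matrix")) sim$values else as.matrix(sim)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Min-max normalization of a similarity matrix to [0, 1]
#'
#' Maps every entry by `(x - min) / (max - min)` over all entries, so the
#' output attains both 0 and 1 and all order relations are preserved. The
#' operation is idempotent on its own output.
#'
#' @param x a [similarity_matrix] or plain numeric matrix.
#' @return Same type as the input, normalized.
#' @export
normalize_similarity_01 <- function(x) {
  m <- if (inherits(x, "similarity_matrix")) x$values else as.matrix(x)
  if (anyNA(m) || any(!is.finite(m))) stop2("matrix must be finite")
  rng <- range(m)
  if (rng[2] <= rng[1]) stop2("zero range: constant matrix cannot be 0-1 normalized")
  m <- (m - rng[1]) / (rng[2] - rng[1])
  if (inherits(x, "similarity_matrix")) {
    x$values <- m
    x
  } else m
}

#' Interaction count summary
#'
#' Counts of drugs, targets, pairs, known (positive) and unknown (negative)
#' pairs, and the positive percentage rounded to 2 decimal places.
#'
#' @param network a [dti_network].
#' @return A list with `n_drugs`, `n_targets`, `n_pairs`, `n_positive`,
#'   `n_negative`, `pct_positive`, `pct_negative`.
#' @export
interaction_stats <- function(network) {
  m <- length(network$drug_ids)
  n <- length(network$target_ids)
  pos <- sum(network$adjacency == 1)
  total <- m * n
  list(n_drugs = m, n_targets = n, n_pairs = total,
       n_positive = pos, n_negative = total - pos,
       pct_positive = round(100 * pos / total, 2),
       pct_negative = round(100 * (total - pos) / total, 2))
}

#' Write embedding vectors to TSV
#'
#' One row per entity: id followed by `dim` float columns.
#' @param table an embedding table as returned by [train_bine()] (one side),
#'   or a numeric matrix with row names.
#' @param path output file path.
#' @export
write_embeddings <- function(table, path) {
  m <- if (is.list(table)) table$vectors else as.matrix(table)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  colnames(df) <- c("id", paste0("e", seq_len(ncol(m))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read embedding vectors from TSV
#' @param path file written by [write_embeddings()].
#' @return numeric matrix with entity ids as row names.
#' @export
read_embeddings <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write pair predictions to TSV
#'
#' Emits `drug_id`, `target_id`, `score`, `label` with `label = 1` iff
#' `score >= threshold`.
#' @param pairs data frame with columns `drug_id`, `target_id`.
#' @param scores numeric vector of probabilities in `[0, 1]`.
#' @param path output file path.
#' @param threshold decision threshold for the binary label.
#' @export
write_predictions <- function(pairs, scores, path, threshold = 0.5) {
  stopifnot(nrow(pairs) == length(scores))
  df <- data.frame(drug_id = pairs$drug_id, target_id = pairs$target_id,
                   score = scores, label = as.integer(scores >= threshold))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
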