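#' Specification of a synthetic heterogeneous DTI dataset
#'
#' Describes a planted-block dataset: drugs and targets are assigned to
#' `n_blocks` latent classes; a drug interacts with a target with probability
#' `p_within` when their blocks match and `p_between` otherwise. Each side
#' receives several block-structured similarity matrices (within-block
#' geometric decay profiles, decay rate varying across sources so the sources
#' are informative but not redundant) perturbed by multiplicative truncated
#' Gaussian noise, plus `n_redundant` near-duplicates of the first source and
#' `n_uniform` near-uniform (maximum-entropy) matrices -- the inputs the
#' entropy and redundancy screens are expected to remove. A
#' `holdout_fraction` of realized interactions can be relabelled 0 and
#' recorded as hidden ground truth for retrieval tests.
#'
#' @param n_drugs,n_targets entity counts.
#' @param n_blocks number of planted blocks.
#' @param p_within,p_between interaction probabilities for matched and
#'   unmatched blocks (`0 <= p_between < p_within <= 1`).
#' @param n_drug_sims,n_target_sims informative similarity sources per side.
#' @param sim_noise_sd standard deviation of the multiplicative noise on the
#'   similarity profiles.
#' @param n_redundant near-duplicate matrices injected per side.
#' @param n_uniform near-uniform matrices injected per side.
#' @param holdout_fraction fraction of realized positives hidden from the
#'   network and recorded as ground truth (in `[0, 1)`).
#' @param seed RNG seed; the whole dataset is reproducible from the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_drugs = 60, n_targets = 40, n_blocks = 3,
                           p_within = 0.3, p_between = 0.01,
                           n_drug_sims = 2, n_target_sims = 2,
                           sim_noise_sd = 0.1, n_redundant = 1,
                           n_uniform = 1, holdout_fraction = 0, seed = 1) {
  s <- list(n_drugs = as.integer(n_drugs), n_targets = as.integer(n_targets),
            n_blocks = as.integer(n_blocks), p_within = p_within,
            p_between = p_between, n_drug_sims = as.integer(n_drug_sims),
            n_target_sims = as.integer(n_target_sims),
            sim_noise_sd = sim_noise_sd, n_redundant = as.integer(n_redundant),
            n_uniform = as.integer(n_uniform),
            holdout_fraction = holdout_fraction, seed = seed)
  if (s$n_drugs < 1L || s$n_targets < 1L) stop2("need at least one entity per side")
  if (s$n_blocks < 1L) stop2("n_blocks must be >= 1")
  if (!(s$p_between >= 0 && s$p_between < s$p_within && s$p_within <= 1))
    stop2("need 0 <= p_between < p_within <= 1")
  if (s$holdout_fraction < 0 || s$holdout_fraction >= 1)
    stop2("holdout_fraction must be in [0, 1)")
  if (s$sim_noise_sd < 0) stop2("sim_noise_sd must be >= 0")
  if (s$n_drug_sims < 1L || s$n_target_sims < 1L)
    stop2("need at least one informative similarity source per side")
  class(s) <- "synthetic_spec"
  s
}

# Within-block geometric decay similarity with multiplicative noise.
# Entities of the same block at within-block rank distance r get rho^r;
# cross-block entries stay exactly 0 (noise is multiplicative and truncated
# at zero), keeping the matrix concentrated enough to pass the entropy screen.
block_decay_similarity <- function(blocks, rho, noise_sd) {
  k <- length(blocks)
  pos <- stats::ave(seq_len(k), blocks, FUN = seq_along)
  same <- outer(blocks, blocks, `==`)
  M <- ifelse(same, rho^abs(outer(pos, pos, `-`)), 0)
  if (noise_sd > 0)
    M <- M * pmax(0, 1 + matrix(stats::rnorm(k * k, 0, noise_sd), k, k))
  M <- (M + t(M)) / 2
  (M - min(M)) / (max(M) - min(M))
}

near_uniform_similarity <- function(k, noise_sd = 0.01) {
  M <- matrix(0.5 + stats::rnorm(k * k, 0, noise_sd), k, k)
  M <- (M + t(M)) / 2
  (M - min(M)) / (max(M) - min(M))
}

make_side_sims <- function(blocks, ids, prefix, side, n_sims, n_redundant,
                           n_uniform, noise_sd) {
  k <- length(blocks)
  rhos <- if (n_sims == 1L) 0.25 else seq(0.2, 0.3, length.out = n_sims)
  sims <- list()
  for (s in seq_len(n_sims))
    sims[[paste0(prefix, "_sim", s)]] <-
      block_decay_similarity(blocks, rhos[s], noise_sd)
  for (r in seq_len(n_redundant)) {
    base <- sims[[paste0(prefix, "_sim1")]]
    dup <- base * pmax(0, 1 + matrix(stats::rnorm(k * k, 0, 0.01), k, k))
    # a small half-normal floor keeps the duplicate's entropy strictly above
    # its source's, so the redundancy screen drops the copy, not the original
    dup <- dup + abs(matrix(stats::rnorm(k * k, 0, 0.002), k, k))
    dup <- (dup + t(dup)) / 2
    sims[[paste0(prefix, "_dup", r)]] <- (dup - min(dup)) / (max(dup) - min(dup))
  }
  for (u in seq_len(n_uniform))
    sims[[paste0(prefix, "_uniform", u)]] <- near_uniform_similarity(k)
  sims <- lapply(sims, function(M) {
    dimnames(M) <- list(ids, ids)
    M
  })
  similarity_collection(sims, side)
}

#' Generate a synthetic heterogeneous DTI dataset
#'
#' Draws a dataset from a [synthetic_spec]: block assignments, the Bernoulli
#' bipartite interaction matrix, similarity collections for both sides
#' (informative + redundant + uniform matrices), the held-out positive pairs,
#' and the block labels as ground truth. Held-out positives are removed from
#' the network before anything else sees it. Any entity left without an edge
#' is re-wired with one random interaction so every vertex is reachable by
#' the truncated walks.
#'
#' @param spec a [synthetic_spec].
#' @return An object of class `synthetic_dti`: list with `network`
#'   ([dti_network]), `drug_sims`, `target_sims` ([similarity_collection]s)
#'   and `truth` (list: `drug_blocks`, `target_blocks`, `holdout` data frame).
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  with_seed(spec$seed, {
    m <- spec$n_drugs; n <- spec$n_targets
    drug_blocks <- sort(sample(rep_len(seq_len(spec$n_blocks), m)))
    target_blocks <- sort(sample(rep_len(seq_len(spec$n_blocks), n)))
    same <- outer(drug_blocks, target_blocks, `==`)
    p <- ifelse(same, spec$p_within, spec$p_between)
    A <- matrix(as.numeric(stats::runif(m * n) < p), m, n)
    if (sum(A) == 0) stop2("spec produced an empty edge set; raise p_within")
    drug_ids <- sprintf("d%02d", seq_len(m))
    target_ids <- sprintf("t%02d", seq_len(n))
    dimnames(A) <- list(drug_ids, target_ids)
    # hold out a fraction of realized positives as hidden truth
    pos <- which(A == 1)
    n_hold <- round(spec$holdout_fraction * length(pos))
    hold <- if (n_hold > 0) sort(sample(pos, n_hold)) else integer()
    A[hold] <- 0
    holdout <- data.frame(
      drug_id = drug_ids[(hold - 1L) %% m + 1L],
      target_id = target_ids[(hold - 1L) %/% m + 1L])
    # re-wire isolated vertices (every node must keep at least one edge);
    # held-out pairs are never re-added
    held_d <- (hold - 1L) %% m + 1L
    held_t <- (hold - 1L) %/% m + 1L
    for (i in which(rowSums(A) == 0)) {
      cand <- setdiff(seq_len(n), held_t[held_d == i])
      A[i, if (length(cand) == 1L) cand else sample(cand, 1L)] <- 1
    }
    for (j in which(colSums(A) == 0)) {
      cand <- setdiff(seq_len(m), held_d[held_t == j])
      A[if (length(cand) == 1L) cand else sample(cand, 1L), j] <- 1
    }
    network <- dti_network(A, drug_ids, target_ids)
    drug_sims <- make_side_sims(drug_blocks, drug_ids, "drug", "drug",
                                spec$n_drug_sims, spec$n_redundant,
                                spec$n_uniform, spec$sim_noise_sd)
    target_sims <- make_side_sims(target_blocks, target_ids, "target", "target",
                                  spec$n_target_sims, spec$n_redundant,
                                  spec$n_uniform, spec$sim_noise_sd)
    structure(list(network = network, drug_sims = drug_sims,
                   target_sims = target_sims,
                   truth = list(drug_blocks = drug_blocks,
                                target_blocks = target_blocks,
                                holdout = holdout),
                   spec = spec),
              class = "synthetic_dti")
  })
}

#' Write a synthetic dataset as a plain-text fixture
#'
#' Emits `edges.tsv` (edge list), one `<side>_<name>.tsv` per similarity
#' matrix, and `truth.json` (block labels, held-out pairs, spec). Reading the
#' files back reproduces the matrices exactly.
#'
#' @param dataset a `synthetic_dti` from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_dti_edges(dataset$network, file.path(dir, "edges.tsv"))
  for (nm in names(dataset$drug_sims$matrices))
    write_similarity_matrix(dataset$drug_sims$matrices[[nm]],
                            file.path(dir, paste0(nm, ".tsv")))
  for (nm in names(dataset$target_sims$matrices))
    write_similarity_matrix(dataset$target_sims$matrices[[nm]],
                            file.path(dir, paste0(nm, ".tsv")))
  truth <- list(drug_blocks = dataset$truth$drug_blocks,
                target_blocks = dataset$truth$target_blocks,
                holdout = dataset$truth$holdout,
                spec = unclass(dataset$spec),
                drug_ids = dataset$network$drug_ids,
                target_ids = dataset$network$target_ids,
                drug_sim_names = names(dataset$drug_sims$matrices),
                target_sim_names = names(dataset$target_sims$matrices))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a fixture directory written by [write_fixture()]
#' @param dir fixture directory.
#' @return A `synthetic_dti`-shaped list (network, sims, truth).
#' @export
read_fixture <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  network <- read_dti_edges(file.path(dir, "edges.tsv"),
                            drug_ids = truth$drug_ids,
                            target_ids = truth$target_ids)
  rd <- function(nm, side, ids)
    read_similarity_matrix(file.path(dir, paste0(nm, ".tsv")), side, ids, nm)
  drug_sims <- similarity_collection(
    stats::setNames(lapply(truth$drug_sim_names, rd, "drug", network$drug_ids),
                    truth$drug_sim_names), "drug")
  target_sims <- similarity_collection(
    stats::setNames(lapply(truth$target_sim_names, rd, "target", network$target_ids),
                    truth$target_sim_names), "target")
  structure(list(network = network, drug_sims = drug_sims,
                 target_sims = target_sims,
                 truth = truth[c("drug_blocks", "target_blocks", "holdout")],
                 spec = truth$spec),
            class = "synthetic_dti")
}
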