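#' Entity-wise cross-validation fold plan
#'
#' Partitions the drugs (`task = "SD"`) or targets (`task = "ST"`) into
#' `n_folds` near-equal random groups. Fold i's test set is every pair
#' involving a group-i entity (cold-start splits: a held-out entity's pairs
#' never appear in training), so the test sets partition the full pair space.
#'
#' @param network a [dti_network].
#' @param task `"SD"` (split by drugs) or `"ST"` (split by targets).
#' @param n_folds number of folds (default 10).
#' @param seed RNG seed for the partition.
#' @return An object of class `fold_plan`: list with `task`, `side`,
#'   `groups` (list of entity-index vectors) and `n_folds`.
#' @export
make_folds <- function(network, task = c("SD", "ST"), n_folds = 10, seed = NULL) {
  task <- match.arg(task)
  side <- if (task == "SD") "drug" else "target"
  n_ent <- if (side == "drug") length(network$drug_ids) else length(network$target_ids)
  if (n_ent < n_folds)
    stop2("cannot make ", n_folds, " folds from ", n_ent, " ", side, "s")
  with_seed(seed, {
    perm <- sample.int(n_ent)
    groups <- split(perm, rep_len(seq_len(n_folds), n_ent))
    names(groups) <- NULL
    structure(list(task = task, side = side, groups = groups,
                   n_folds = n_folds),
              class = "fold_plan")
  })
}

# logical mask (length m * n, drug-major pair order) of fold i's test pairs
fold_test_mask <- function(plan, fold, m, n) {
  ents <- plan$groups[[fold]]
  if (plan$side == "drug") rep(seq_len(m), each = n) %in% ents
  else rep(seq_len(n), times = m) %in% ents
}

#' Fit and score a class-weighted random forest
#'
#' Trains a 100-tree random forest (Gini split criterion) on labelled pair
#' embeddings with class weights inversely proportional to the class
#' frequencies of the training labels (`n / (2 * n_class)`), and returns the
#' positive-class probability of each test embedding. Deterministic under
#' `seed` (single-threaded).
#'
#' @param train_x numeric matrix of training pair embeddings.
#' @param train_y binary labels (0/1), both classes required.
#' @param test_x numeric matrix of embeddings to score.
#' @param num_trees number of trees (default 100).
#' @param seed RNG seed passed to the forest.
#' @return numeric vector of positive-class probabilities.
#' @export
fit_score_rf <- function(train_x, train_y, test_x, num_trees = 100, seed = 1) {
  train_y <- as.integer(train_y)
  tab <- table(factor(train_y, levels = c(0L, 1L)))
  if (any(tab == 0L)) stop2("training set must contain both classes")
  cw <- as.numeric(length(train_y) / (2 * tab))
  df <- data.frame(.y = factor(train_y, levels = c(0L, 1L)), train_x,
                   check.names = FALSE)
  fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                        num.trees = num_trees, probability = TRUE,
                        splitrule = "gini", class.weights = cw,
                        min.node.size = 1, # fully grown trees
                        seed = seed, num.threads = 1)
  pred <- stats::predict(fit, data.frame(test_x, check.names = FALSE),
                         num.threads = 1)
  unname(pred$predictions[, "1"])
}

#' Area under the precision-recall curve
#'
#' Average-precision (step-wise) interpolation: walking the distinct score
#' thresholds from high to low, sums `(recall_k - recall_{k-1}) * precision_k`.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1) with at least one of each class.
#' @return PR-AUC in `[0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop2("PR-AUC needs both a positive and a negative")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # evaluate at the last index of each distinct score (threshold boundaries)
  last <- which(c(diff(s) != 0, TRUE))
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / sum(y)
  sum(diff(c(0, rec)) * prec)
}

#' Area under the ROC curve
#'
#' Trapezoidal ROC-AUC of the scores against binary labels (computed through
#' pROC). A perfect ranking gives 1, a perfectly reversed ranking 0.
#'
#' @inheritParams pr_auc
#' @return ROC-AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop2("ROC-AUC needs both a positive and a negative")
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0L, 1L), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Entity-wise cross-validated evaluation
#'
#' Runs the tenfold cold-start protocol on prepared features: for each fold,
#' pair embeddings are rebuilt with the fold's test edges hidden from the
#' path components (when `masking = "honest"`, the default), a class-weighted
#' random forest is fit on the training pairs, the held-out pairs are scored,
#' and PR-AUC / ROC-AUC are computed per fold and averaged.
#' `masking = "transductive"` leaves the full interaction matrix visible to
#' the path components in every fold.
#'
#' @param features a `hene_features` object from [hene_features()].
#' @param task `"SD"` or `"ST"`.
#' @param n_folds number of folds (default from the config).
#' @param shuffle_labels permute the interaction labels over the pair space
#'   before folding (null calibration; scores should fall to prevalence).
#' @param honest_cv retrain the bipartite embeddings per fold on the training
#'   edges only, instead of reusing the transductive embeddings trained on the
#'   full network (the default, which mirrors the method's transductive
#'   stance). Considerably slower.
#' @param seed master seed; defaults to the config's `master_seed`.
#' @return An object of class `evaluation_result`: `per_fold` data frame,
#'   `mean_pr_auc`, `mean_roc_auc`, `prevalence`, `settings`.
#' @export
run_cv <- function(features, task = c("SD", "ST"), n_folds = NULL,
                   shuffle_labels = FALSE, honest_cv = FALSE, seed = NULL) {
  task <- match.arg(task)
  cfg <- features$config
  n_folds <- n_folds %||% cfg$eval$folds
  seed <- seed %||% cfg$master_seed
  net <- features$network
  m <- length(net$drug_ids); n <- length(net$target_ids)
  labels <- as.vector(t(net$adjacency)) # drug-major pair order
  if (shuffle_labels)
    labels <- with_seed(seed + 4L, sample(labels))
  plan <- make_folds(net, task, n_folds, seed = seed + 2L)
  per_fold <- data.frame(fold = seq_len(n_folds), pr_auc = NA_real_,
                         roc_auc = NA_real_)
  for (f in seq_len(n_folds)) {
    test <- fold_test_mask(plan, f, m, n)
    mask <- NULL
    if (cfg$pairing$masking == "honest") {
      idx <- which(test & labels == 1)
      mask <- cbind((idx - 1L) %/% n + 1L, (idx - 1L) %% n + 1L)
      # masking hides *observed* test edges; under shuffled labels the
      # observed network is unchanged, so mask the true test edges instead
      if (shuffle_labels) {
        true_idx <- which(test & as.vector(t(net$adjacency)) == 1)
        mask <- cbind((true_idx - 1L) %/% n + 1L, (true_idx - 1L) %% n + 1L)
      }
    }
    emb <- features$embeddings
    pair_net <- net
    if (honest_cv) {
      adjf <- net$adjacency
      if (!is.null(mask) && nrow(mask)) adjf[mask] <- 0
      pair_net <- suppressWarnings(dti_network(adjf, net$drug_ids, net$target_ids))
      bp <- do.call(bine_params, cfg$bine)
      bp$seed <- bp$seed + f
      emb <- train_bine(pair_net, bp)
      mask <- NULL # test edges already absent from pair_net
    }
    ap <- build_all_pairs(pair_net, emb$drugs, emb$targets,
                          features$drug_composite, features$target_composite,
                          k = cfg$pairing$k_near, mask_edges = mask,
                          neighbor_mix = cfg$pairing$neighbor_mix)
    scores <- fit_score_rf(ap$vectors[!test, , drop = FALSE], labels[!test],
                           ap$vectors[test, , drop = FALSE],
                           num_trees = cfg$rf$num_trees,
                           seed = seed + 3L + f)
    per_fold$pr_auc[f] <- pr_auc(scores, labels[test])
    per_fold$roc_auc[f] <- roc_auc(scores, labels[test])
  }
  structure(list(per_fold = per_fold,
                 mean_pr_auc = mean(per_fold$pr_auc),
                 mean_roc_auc = mean(per_fold$roc_auc),
                 prevalence = mean(labels),
                 settings = list(task = task, n_folds = n_folds,
                                 masking = cfg$pairing$masking,
                                 shuffle_labels = shuffle_labels,
                                 honest_cv = honest_cv,
                                 seed = seed)),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> %s task, %d folds (%s masking)\n",
              x$settings$task, x$settings$n_folds, x$settings$masking))
  cat(sprintf("  mean PR-AUC  %.4f\n  mean ROC-AUC %.4f\n  prevalence   %.4f\n",
              x$mean_pr_auc, x$mean_roc_auc, x$prevalence))
  invisible(x)
}

#' Case-study ranking of unknown pairs
#'
#' The realistic prediction protocol: all known interactions are labelled 1,
#' every other pair 0; the label-0 pairs are split into `n_groups`
#' non-overlapping random groups; for each group the forest is trained on all
#' positives plus the remaining groups' negatives and scores that group. Every
#' unknown pair is scored exactly once and the descending `top_k` pairs are
#' reported.
#'
#' @param features a `hene_features` object.
#' @param n_groups number of negative groups (default 10).
#' @param top_k length of the reported ranking (default 5).
#' @param seed master seed; defaults to the config's `master_seed`.
#' @return An object of class `case_study_ranking`: `scores` data frame over
#'   all unknown pairs and `top_k` data frame.
#' @export
case_study <- function(features, n_groups = 10, top_k = 5, seed = NULL) {
  cfg <- features$config
  seed <- seed %||% cfg$master_seed
  net <- features$network
  if (sum(net$adjacency) < 1) stop2("need at least one known interaction")
  labels <- as.vector(t(net$adjacency))
  ap <- build_all_pairs(net, features$embeddings$drugs,
                        features$embeddings$targets,
                        features$drug_composite, features$target_composite,
                        k = cfg$pairing$k_near,
                        neighbor_mix = cfg$pairing$neighbor_mix)
  neg <- which(labels == 0)
  pos <- which(labels == 1)
  groups <- with_seed(seed + 5L,
                      split(sample(neg), rep_len(seq_len(n_groups), length(neg))))
  scores <- rep(NA_real_, length(labels))
  for (g in seq_len(n_groups)) {
    test_idx <- groups[[g]]
    train_idx <- c(pos, setdiff(neg, test_idx))
    scores[test_idx] <- fit_score_rf(
      ap$vectors[train_idx, , drop = FALSE], labels[train_idx],
      ap$vectors[test_idx, , drop = FALSE],
      num_trees = cfg$rf$num_trees, seed = seed + 10L + g)
  }
  df <- data.frame(drug_id = ap$pairs$drug_id[neg],
                   target_id = ap$pairs$target_id[neg],
                   drug = ap$pairs$drug[neg], target = ap$pairs$target[neg],
                   score = scores[neg])
  ord <- order(-df$score, df$drug, df$target)
  df <- df[ord, ]
  rownames(df) <- NULL
  structure(list(scores = df, top_k = utils::head(df, top_k),
                 n_groups = n_groups, seed = seed),
            class = "case_study_ranking")
}

#' @export
print.case_study_ranking <- function(x, ...) {
  cat(sprintf("<case_study_ranking> %d unknown pairs scored in %d groups; top %d:\n",
              nrow(x$scores), x$n_groups, nrow(x$top_k)))
  print(x$top_k[, c("drug_id", "target_id", "score")], row.names = FALSE)
  invisible(x)
}
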