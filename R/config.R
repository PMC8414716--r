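#' Run configuration with all pipeline hyperparameters
#'
#' Nested configuration covering every stage. The defaults reproduce the
#' small-dataset profile: 64-dimensional embeddings, learning rate 0.1, 4
#' negative samples, window 5, alpha 0.01, beta 0.1, gamma 0.1, stop
#' probability 0.15, restart probability 0.7, 100 epochs; entropy/redundancy
#' thresholds c1 = 0.7, c2 = 0.6 with SNF K = 20, t = 20; 5 nearest neighbors
#' and honest (test-edge-masked) pair construction; a 100-tree Gini forest;
#' and tenfold drug-split evaluation. One master seed derives every stage
#' seed by fixed offsets, so stages are independently reproducible.
#'
#' @param bine named list overriding [bine_params()] fields.
#' @param fusion named list: `c1`, `c2`, `K`, `t`, `entropy_reference`.
#' @param pairing named list: `k_near`, `neighbor_mix`
#'   (`"as_printed"`/`"neighbor_embeddings"`), `masking`
#'   (`"honest"`/`"transductive"`).
#' @param rf named list: `num_trees`, `criterion` (only `"gini"` supported).
#' @param eval named list: `task` (`"SD"`/`"ST"`), `folds`.
#' @param master_seed integer master seed.
#' @return An object of class `hene_config`.
#' @export
hene_config <- function(bine = list(), fusion = list(), pairing = list(),
                        rf = list(), eval = list(), master_seed = 1) {
  defaults <- list(
    bine = list(dim = 64, max_iter = 100, lr = 0.1, ns = 4, ws = 5,
                alpha = 0.01, beta = 0.1, gamma = 0.1, stop_prob = 0.15,
                restart_prob = 0.7, max_walks = 32, min_walks = 1,
                max_walk_len = 100, seed = master_seed + 1),
    fusion = list(c1 = 0.7, c2 = 0.6, K = 20, t = 20,
                  entropy_reference = "max_possible"),
    pairing = list(k_near = 5, neighbor_mix = "as_printed", masking = "honest"),
    rf = list(num_trees = 100, criterion = "gini"),
    eval = list(task = "SD", folds = 10))
  user <- list(bine = bine, fusion = fusion, pairing = pairing, rf = rf,
               eval = eval)
  cfg <- list()
  for (sec in names(defaults)) {
    unknown <- setdiff(names(user[[sec]]), names(defaults[[sec]]))
    if (length(unknown))
      stop2("unknown ", sec, " config key: ", paste(unknown, collapse = ", "))
    cfg[[sec]] <- utils::modifyList(defaults[[sec]], user[[sec]])
  }
  cfg$master_seed <- master_seed
  # validate through the dedicated constructors / checks
  do.call(bine_params, cfg$bine)
  if (!cfg$pairing$neighbor_mix %in% c("as_printed", "neighbor_embeddings"))
    stop2("invalid pairing$neighbor_mix")
  if (!cfg$pairing$masking %in% c("honest", "transductive"))
    stop2("invalid pairing$masking")
  if (!identical(cfg$rf$criterion, "gini"))
    stop2("rf$criterion: only 'gini' is supported")
  if (!cfg$eval$task %in% c("SD", "ST")) stop2("invalid eval$task")
  if (cfg$eval$folds < 2) stop2("eval$folds must be >= 2")
  if (!cfg$fusion$entropy_reference %in% c("max_possible", "max_observed"))
    stop2("invalid fusion$entropy_reference")
  structure(cfg, class = "hene_config")
}

#' Load a run configuration from YAML
#'
#' Unspecified fields fall back to the [hene_config()] defaults; unknown keys
#' raise an error rather than being silently ignored.
#'
#' @param path YAML file; an empty file yields all defaults.
#' @return A `hene_config`.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  known <- c("bine", "fusion", "pairing", "rf", "eval", "master_seed")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop2("unknown config key: ", paste(unknown, collapse = ", "))
  hene_config(bine = y$bine %||% list(), fusion = y$fusion %||% list(),
              pairing = y$pairing %||% list(), rf = y$rf %||% list(),
              eval = y$eval %||% list(),
              master_seed = y$master_seed %||% 1)
}

#' Write a run configuration to YAML
#' @param config a `hene_config`.
#' @param path output file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.hene_config <- function(x, ...) {
  cat("<hene_config>\n")
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}
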