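#' Prepare the feature state shared by evaluation and case-study runs
#'
#' Runs the two expensive upstream stages once: trains the bipartite
#' embeddings on the full known-interaction network (the method is
#' transductive: all entities and the whole pair space are fixed and visible
#' during learning) and screens + fuses each side's similarity collection
#' into its composite matrix. The returned object feeds [run_cv()] and
#' [case_study()], which only rebuild the cheap pair-embedding and forest
#' stages.
#'
#' @param network a [dti_network].
#' @param drug_sims,target_sims [similarity_collection]s (or a single
#'   [similarity_matrix] each).
#' @param config a [hene_config()].
#' @return An object of class `hene_features`: list with `network`,
#'   `embeddings` (`$drugs`, `$targets`), `drug_composite`,
#'   `target_composite`, `fusion_reports`, `config`.
#' @export
hene_features <- function(network, drug_sims, target_sims,
                          config = hene_config()) {
  if (inherits(drug_sims, "similarity_matrix"))
    drug_sims <- similarity_collection(stats::setNames(list(drug_sims),
                                                       drug_sims$name), "drug")
  if (inherits(target_sims, "similarity_matrix"))
    target_sims <- similarity_collection(stats::setNames(list(target_sims),
                                                         target_sims$name), "target")
  bp <- do.call(bine_params, config$bine)
  embeddings <- train_bine(network, bp)
  fd <- build_composite(drug_sims, c1 = config$fusion$c1, c2 = config$fusion$c2,
                        K = config$fusion$K, t = config$fusion$t,
                        entropy_reference = config$fusion$entropy_reference)
  ft <- build_composite(target_sims, c1 = config$fusion$c1, c2 = config$fusion$c2,
                        K = config$fusion$K, t = config$fusion$t,
                        entropy_reference = config$fusion$entropy_reference)
  structure(list(network = network, embeddings = embeddings,
                 drug_composite = fd$composite, target_composite = ft$composite,
                 fusion_reports = list(drug = fd$report, target = ft$report),
                 config = config),
            class = "hene_features")
}

#' @export
print.hene_features <- function(x, ...) {
  cat(sprintf("<hene_features> %d drugs x %d targets, dim %d embeddings\n",
              length(x$network$drug_ids), length(x$network$target_ids),
              ncol(x$embeddings$drugs$vectors)))
  cat("  drug composite from:",
      paste(x$fusion_reports$drug$retained, collapse = ", "), "\n")
  cat("  target composite from:",
      paste(x$fusion_reports$target$retained, collapse = ", "), "\n")
  invisible(x)
}
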