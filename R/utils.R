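#' @keywords internal
#' @useDynLib heteroDTI, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# logistic function used by all gradient steps
sigmoid <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop2 <- function(...) stop(..., call. = FALSE)

check_side <- function(side) match.arg(side, c("drug", "target"))

# linear index of pair (d, t) in the drug-major pair ordering used by
# build_all_pairs: index = (d - 1) * n_targets + t
pair_index <- function(d, t, n_targets) (d - 1L) * n_targets + t
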