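#' @useDynLib rhpcbn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pchisq pnorm cor runif median quantile setNames
#' @importFrom utils combn read.csv write.csv
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  All randomness in the package flows
# through this helper so that user-visible functions are pure in their seed.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

# Deterministic per-replicate seed derivation: master seed plus a counter,
# folded into the 32-bit signed range.
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) + 1000003 * as.double(counter)) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

check_nodes <- function(g, v) {
  bad <- setdiff(v, g$nodes)
  if (length(bad))
    stop_input("unknown node name(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

pair_key <- function(x, y) {
  if (x < y) paste(x, y, sep = "\r") else paste(y, x, sep = "\r")
}
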