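#' Inter-IAMB Markov boundary learner
#'
#' Interleaved Incremental Association Markov Boundary: the forward phase
#' repeatedly adds the candidate showing the strongest dependence with the
#' target given the current estimate (association scored by the test's
#' p-value, ties broken by larger statistic, then by name order); after each
#' addition an interleaved backward phase removes any member `y` with
#' `t` independent of `y` given the rest of the estimate.  Terminates when
#' no candidate can be added.  A test flagged unreliable counts as
#' independence in both phases (the conservative, data-efficient reading).
#'
#' @param t the target column name.
#' @param data a data frame / [ci_data()] (ignored when `test` is already a
#'   tester closure bound to data, e.g. from [ci_tester()]).
#' @param test a tester closure `f(x, y, z)` or a method name
#'   (`"g2"`, `"x2"`, `"fisher_z"`).
#' @param alpha significance level (used when building a tester from a
#'   method name).
#' @param candidates columns to search within; default all columns but `t`.
#' @param cache optional [sepset_cache()] in which declared independencies
#'   are recorded.
#' @return Sorted character vector: the estimated Markov boundary of `t`
#'   within `candidates`.
#' @export
inter_iamb <- function(t, data = NULL, test = "g2", alpha = 0.05,
                       candidates = NULL, cache = NULL) {
  test <- as_tester(test, data, alpha)
  candidates <- resolve_candidates(t, data, test, candidates)
  ct <- cached_test(test, cache)
  mb <- character(0)
  seen <- character(0)
  repeat {
    rem <- setdiff(candidates, mb)
    best <- NULL; best_p <- Inf; best_stat <- -Inf
    for (x in rem) {
      r <- ct(t, x, mb)
      if (r$independent) next
      if (r$p_value < best_p ||
          (r$p_value == best_p && r$statistic > best_stat)) {
        best <- x; best_p <- r$p_value; best_stat <- r$statistic
      }
    }
    if (is.null(best)) break
    mb <- sort(c(mb, best))
    # interleaved backward pass
    repeat {
      dropped <- FALSE
      for (y in mb) {
        r <- ct(t, y, setdiff(mb, y))
        if (r$independent) {
          mb <- setdiff(mb, y)
          dropped <- TRUE
          break
        }
      }
      if (!dropped) break
    }
    key <- paste(mb, collapse = ",")
    if (key %in% seen) break  # guard against add/remove oscillation
    seen <- c(seen, key)
  }
  sort(mb)
}

#' Inter-IAPC parents-and-children learner
#'
#' The weak PC learner: estimates the Markov boundary with [inter_iamb()]
#' and then removes spouses by exhaustive subset search -- a member `x` is
#' discarded when some subset `z` of the boundary (minus `x`) renders `t`
#' independent of `x` given `z`.  Subsets are enumerated in increasing
#' size; only reliable tests can assert the separating independence (an
#' unreliable large-table test is no evidence that a true neighbour can be
#' screened off).  Under reliable tests on a faithful distribution the
#' result equals the true PC set restricted to `candidates`.
#'
#' @inheritParams inter_iamb
#' @param max_subset cap on the separating-subset size searched
#'   (default unlimited; learned boundaries are small).
#' @return Sorted character vector: the estimated parents-and-children set.
#' @export
inter_iapc <- function(t, data = NULL, test = "g2", alpha = 0.05,
                       candidates = NULL, cache = NULL, max_subset = Inf) {
  test <- as_tester(test, data, alpha)
  mb <- inter_iamb(t, data, test, alpha, candidates, cache = cache)
  ct <- cached_test(test, cache)
  pc <- mb
  for (x in mb) {
    others <- setdiff(mb, x)
    if (find_separator(ct, t, x, others, max_subset)) pc <- setdiff(pc, x)
  }
  sort(pc)
}

# Search subsets of `pool` (increasing size, deterministic order) for a set
# rendering t and x independent by a *reliable* test.  TRUE if found; the
# separating set itself reaches the sepset cache through `ct`.
find_separator <- function(ct, t, x, pool, max_subset = Inf) {
  pool <- sort(pool)
  for (size in 0:min(length(pool), max_subset)) {
    subs <- if (size == 0) list(character(0))
            else combn(pool, size, simplify = FALSE)
    for (zc in subs) {
      r <- ct(t, x, zc)
      if (r$independent && r$reliable) return(TRUE)
    }
  }
  FALSE
}

resolve_candidates <- function(t, data, test, candidates) {
  if (is.null(candidates)) {
    nm <- tester_columns(data, test)
    if (is.null(nm))
      stop_input("candidates must be given when data is not supplied")
    candidates <- setdiff(nm, t)
  }
  candidates <- sort(as.character(candidates))
  if (t %in% candidates)
    stop_input("the target must not be among the candidates")
  candidates
}

tester_columns <- function(data, test) {
  if (inherits(data, "ci_data")) return(data$names)
  if (is.data.frame(data)) return(colnames(data))
  if (inherits(data, "dag")) return(data$nodes)
  NULL
}
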