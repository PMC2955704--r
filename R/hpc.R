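#' Data-efficient parents-and-children superset (DE-PCS)
#'
#' First filtering stage of HPC: starts from every other variable and
#' discards `x` when `t` is independent of `x` marginally (pass 1) or given
#' some single variable of the current set (pass 2, iterated to a fixpoint
#' over the shrinking set, scanning in sorted order).  Conditioning sets
#' never exceed size 1 here, keeping the tests maximally reliable; every
#' removal caches its separating set.  Under reliable tests the returned
#' set contains the true PC set.
#'
#' @inheritParams inter_iamb
#' @param cache a [sepset_cache()]; created when `NULL`.
#' @return `list(pcs = <sorted names>, cache = <sepset_cache>)`.
#' @export
de_pcs <- function(t, data = NULL, test = "g2", alpha = 0.05,
                   candidates = NULL, cache = NULL) {
  test <- as_tester(test, data, alpha)
  candidates <- resolve_candidates(t, data, test, candidates)
  cache <- cache %||% sepset_cache()
  ct <- cached_test(test, cache)
  pcs <- candidates
  # pass 1: marginal screen
  for (x in pcs) {
    if (ct(t, x, character(0))$independent) pcs <- setdiff(pcs, x)
  }
  # pass 2: single-variable screen, iterated to a fixpoint.  Each sweep
  # conditions on the set as it stood at the start of the sweep and applies
  # removals at sweep end (the order-independent "stable" formulation:
  # otherwise a variable removed early in a sweep is lost as a separator
  # candidate for the variables scanned after it).
  repeat {
    snapshot <- pcs
    drop <- character(0)
    for (x in snapshot) {
      for (zc in setdiff(snapshot, x)) {
        if (ct(t, x, zc)$independent) {
          drop <- c(drop, x)
          break
        }
      }
    }
    if (!length(drop)) break
    pcs <- setdiff(pcs, drop)
  }
  list(pcs = pcs, cache = cache)
}

#' Data-efficient spouses superset (DE-SPS)
#'
#' Second filtering stage of HPC: for each `x` in the PC superset, a
#' variable `y` outside it becomes a spouse candidate via `x` when
#' conditioning on `dSep(t, y)` plus `x` re-activates the dependence
#' between `t` and `y` (collider activation); a pruning pass then removes
#' `y` when some other candidate `z` via the same `x` gives independence of
#' `t` and `y` given `{x, z}`.  All conditioning sets have size at most 2.
#' Under reliable tests the returned set contains the true spouse set.
#'
#' @inheritParams de_pcs
#' @param pcs,cache the output of [de_pcs()] for the same target.
#' @return Sorted character vector: the spouse superset.
#' @export
de_sps <- function(t, pcs, cache, data = NULL, test = "g2", alpha = 0.05,
                   candidates = NULL) {
  test <- as_tester(test, data, alpha)
  candidates <- resolve_candidates(t, data, test, candidates)
  ct <- cached_test(test, cache)
  others <- setdiff(candidates, pcs)
  sps <- character(0)
  for (x in pcs) {
    sps_x <- character(0)
    for (y in others) {
      ds <- sepset_get(cache, t, y)  # internal error if de_pcs missed it
      if (!ct(t, y, sort(union(ds, x)))$independent)
        sps_x <- c(sps_x, y)
    }
    # prune: a candidate screened off by {x, z} for a sibling candidate z
    for (y in sps_x) {
      for (zc in setdiff(sps_x, y)) {
        if (ct(t, y, sort(c(x, zc)))$independent) {
          sps_x <- setdiff(sps_x, y)
          break
        }
      }
    }
    sps <- union(sps, sps_x)
  }
  sort(sps)
}

#' HPC: hybrid parents-and-children discovery
#'
#' Learns the parents-and-children set of a target node as an ensemble of
#' weak learners.  The supersets PCS (via [de_pcs()]) and SPS (via
#' [de_sps()]) are extracted first with conditioning sets capped at size 2;
#' a first candidate PC set is produced by running [inter_iapc()] on
#' PCS union SPS; the decentralized search then runs the weak learner on
#' every remaining superset member `x` and adds `x` whenever `t` appears in
#' its output -- rescuing false negatives of the weak learner, which is
#' what lets HPC learn large neighbourhoods from few samples.
#'
#' @inheritParams de_pcs
#' @return `list(pc, cache, stats)` where `pc` is the sorted PC estimate,
#'   `cache` the populated [sepset_cache()], and `stats` the number of
#'   tests performed and largest conditioning set used (when `test` was
#'   built by [ci_tester()]).
#' @export
hpc <- function(t, data = NULL, test = "g2", alpha = 0.05,
                candidates = NULL, cache = NULL) {
  test <- as_tester(test, data, alpha)
  candidates <- resolve_candidates(t, data, test, candidates)
  before <- tester_stats(test)
  res <- de_pcs(t, data, test, alpha, candidates, cache = cache)
  pcs <- res$pcs
  cache <- res$cache
  sps <- de_sps(t, pcs, cache, data, test, alpha, candidates)
  cands <- sort(union(pcs, sps))
  pc <- inter_iapc(t, data, test, alpha, candidates = cands, cache = cache)
  for (x in setdiff(cands, pc)) {
    pcx <- inter_iapc(x, data, test, alpha,
                      candidates = sort(setdiff(c(cands, t), x)),
                      cache = cache)
    if (t %in% pcx) pc <- sort(union(pc, x))
  }
  after <- tester_stats(test)
  list(pc = pc, cache = cache,
       stats = list(n_tests = after$n_tests - before$n_tests,
                    max_cond = after$max_cond))
}
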