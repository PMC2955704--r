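ci_result <- function(statistic, dof, p_value, independent, reliable,
                      x, y, z, method) {
  structure(list(statistic = statistic, dof = dof, p_value = p_value,
                 independent = independent, reliable = reliable,
                 x = x, y = y, z = z, method = method),
            class = "ci_test_result")
}

#' @export
print.ci_test_result <- function(x, ...) {
  zs <- if (length(x$z)) paste(x$z, collapse = ",") else "{}"
  cat(sprintf("%s: %s _||_ %s | %s  stat=%.4g dof=%s p=%.4g  %s%s\n",
              x$method, x$x, x$y, zs, x$statistic, format(x$dof), x$p_value,
              if (x$independent) "independent" else "dependent",
              if (x$reliable) "" else " (unreliable)"))
  invisible(x)
}

#' Discrete conditional-independence test (G2 / Pearson chi-squared)
#'
#' Tests `x` independent of `y` given the discrete columns `z`.  The default
#' statistic is the likelihood ratio G2 = 2 * sum o * log(o / e) over all
#' cells of the x-by-y table within each z-stratum (zero observed cells
#' contribute nothing); Pearson's X2 is available via `statistic = "x2"`.
#' Degrees of freedom are the uncorrected
#' (r_x - 1)(r_y - 1) * prod(r_z).  When the sample is too small for the
#' table -- fewer than `min_obs_per_dof` observations per degree of freedom
#' -- the test is flagged unreliable and returns independence, the
#' conventional insufficient-data heuristic of constraint-based learners.
#'
#' @param data a data frame or [ci_data()] with discrete columns.
#' @param x,y column names.
#' @param z character vector of conditioning column names.
#' @param alpha significance level for the independence decision.
#' @param statistic `"g2"` (default) or `"x2"`.
#' @param min_obs_per_dof reliability heuristic threshold (default 10).
#' @return A `"ci_test_result"`: `statistic`, `dof`, `p_value`,
#'   `independent`, `reliable`.
#' @examples
#' d <- data.frame(a = rep(0:1, 50), b = rep(0:1, 50))
#' g2_test(d, "a", "b")$independent
#' @export
g2_test <- function(data, x, y, z = character(0), alpha = 0.05,
                    statistic = c("g2", "x2"), min_obs_per_dof = 10) {
  statistic <- match.arg(statistic)
  data <- ci_data(data)
  z <- as.character(z)
  if (x == y) stop_input("x and y must be distinct")
  if (x %in% z || y %in% z) stop_input("x and y must not belong to z")
  ci_columns(data, c(x, y, z), "discrete")
  rx <- data$arities[[x]]; ry <- data$arities[[y]]
  nz <- if (length(z)) as.integer(prod(data$arities[z])) else 1L
  dof <- as.integer((rx - 1) * (ry - 1)) * nz
  method <- if (statistic == "g2") "G2" else "X2"
  if (dof < 1L)  # a constant column can never show dependence
    return(ci_result(0, 0L, 1, TRUE, FALSE, x, y, z, method))
  if (data$n < min_obs_per_dof * dof)
    return(ci_result(0, dof, 1, TRUE, FALSE, x, y, z, method))
  zi <- z_index(data, z)
  stat <- ct_stat_cpp(data$codes[, x], data$codes[, y], zi$idx, rx, ry,
                      zi$nz, statistic == "x2")
  p <- pchisq(stat, df = dof, lower.tail = FALSE)
  ci_result(stat, dof, p, p > alpha, TRUE, x, y, z, method)
}

#' Fisher's z conditional-independence test for continuous data
#'
#' Computes the partial correlation `r` of `x` and `y` given `z` and the
#' statistic `sqrt(n - |z| - 3) * 0.5 * log((1 + r) / (1 - r))`, compared
#' two-sided against the standard normal.  Degenerate collinearity
#' (|r| = 1 or a singular correlation matrix) is reported as dependence
#' with `p_value = 0` and `reliable = FALSE`.
#'
#' @inheritParams g2_test
#' @return A `"ci_test_result"`.
#' @export
fisher_z_test <- function(data, x, y, z = character(0), alpha = 0.05) {
  data <- ci_data(data)
  z <- as.character(z)
  if (x == y) stop_input("x and y must be distinct")
  if (x %in% z || y %in% z) stop_input("x and y must not belong to z")
  ci_columns(data, c(x, y, z), "continuous")
  if (data$n <= length(z) + 3)
    stop_input("need more than |z| + 3 rows for Fisher's z")
  S <- cor(data$values[, c(x, y, z), drop = FALSE])
  r <- tryCatch({
    P <- solve(S)
    -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  }, error = function(e) NA_real_)
  if (is.na(r) || abs(r) >= 1 - 1e-12)
    return(ci_result(Inf, 0L, 0, FALSE, FALSE, x, y, z, "fisher_z"))
  stat <- sqrt(data$n - length(z) - 3) * 0.5 * log((1 + r) / (1 - r))
  p <- 2 * pnorm(-abs(stat))
  ci_result(abs(stat), 0L, p, p > alpha, TRUE, x, y, z, "fisher_z")
}

#' d-separation oracle test
#'
#' Realizes the reliable-test idealization: given the generating DAG, the
#' returned test function reports independence exactly when `x` and `y` are
#' d-separated by `z`, with conventional p-values 1 (independent) and 0
#' (dependent).  Used to validate the learners against graph theory.
#'
#' @param g a `"dag"`.
#' @return A function `f(x, y, z)` returning a `"ci_test_result"`.
#' @export
oracle_test <- function(g) {
  if (!inherits(g, "dag")) stop_input("oracle_test expects a dag")
  idx <- setNames(seq_along(g$nodes) - 1L, g$nodes)
  pl <- dag_parent_index(g)
  memo <- new.env(parent = emptyenv(), hash = TRUE)
  function(x, y, z = character(0)) {
    z <- as.character(z)
    key <- paste(pair_key(x, y), paste(sort(z), collapse = ","), sep = "|")
    ind <- memo[[key]]
    if (is.null(ind)) {
      ind <- dsep_cpp(pl, idx[[x]], idx[[y]], unname(idx[z]))
      memo[[key]] <- ind
    }
    ci_result(if (ind) 0 else Inf, 0L, if (ind) 1 else 0,
              ind, TRUE, x, y, z, "oracle")
  }
}

#' Build an instrumented conditional-independence tester
#'
#' Binds a dataset (or a DAG, for the oracle) to a test method and returns
#' a closure `f(x, y, z)` suitable for the learners.  The closure counts
#' calls and tracks the largest conditioning set used, retrievable with
#' [tester_stats()] -- this instruments the `|Z| <= 2` restriction of the
#' superset filters.
#'
#' @param data a data frame / `"ci_data"`, or a `"dag"` when
#'   `method = "oracle"`.
#' @param method `"g2"`, `"x2"`, `"fisher_z"`, or `"oracle"`.
#' @param alpha significance level.
#' @param min_obs_per_dof reliability heuristic for the discrete tests.
#' @return A function `f(x, y, z)` returning a `"ci_test_result"`.
#' @export
ci_tester <- function(data, method = c("g2", "x2", "fisher_z", "oracle"),
                      alpha = 0.05, min_obs_per_dof = 10) {
  method <- match.arg(method)
  inner <- switch(method,
    oracle = {
      g <- if (inherits(data, "dag")) data else stop_input("oracle needs a dag")
      oracle_test(g)
    },
    fisher_z = {
      d <- ci_data(data)
      function(x, y, z) fisher_z_test(d, x, y, z, alpha = alpha)
    },
    {
      # fast path: validation is done once here, not per call
      d <- ci_data(data)
      if (any(d$type != "discrete"))
        stop_input("discrete test requires all-discrete data")
      ar <- d$arities
      n <- d$n
      codes <- d$codes
      pearson <- method == "x2"
      mname <- if (pearson) "X2" else "G2"
      function(x, y, z) {
        rx <- ar[[x]]; ry <- ar[[y]]
        nz <- if (length(z)) as.integer(prod(ar[z])) else 1L
        dof <- (rx - 1L) * (ry - 1L) * nz
        if (dof < 1L || n < min_obs_per_dof * dof)
          return(ci_result(0, dof, 1, TRUE, FALSE, x, y, z, mname))
        if (length(z)) {
          idx <- rep(0L, n)
          stride <- 1L
          for (j in seq_along(z)) {
            idx <- idx + (codes[, z[j]] - 1L) * stride
            stride <- stride * ar[[z[j]]]
          }
          idx <- idx + 1L
        } else idx <- rep(1L, n)
        stat <- ct_stat_cpp(codes[, x], codes[, y], idx, rx, ry, nz, pearson)
        p <- pchisq(stat, df = dof, lower.tail = FALSE)
        ci_result(stat, dof, p, p > alpha, TRUE, x, y, z, mname)
      }
    })
  st <- new.env(parent = emptyenv())
  st$n_tests <- 0L
  st$max_cond <- 0L
  f <- function(x, y, z = character(0)) {
    st$n_tests <- st$n_tests + 1L
    if (length(z) > st$max_cond) st$max_cond <- length(z)
    inner(x, y, z)
  }
  attr(f, "stats") <- st
  attr(f, "method") <- method
  f
}

#' @rdname ci_tester
#' @param test an instrumented tester returned by [ci_tester()].
#' @return `tester_stats()` returns `list(n_tests, max_cond)`.
#' @export
tester_stats <- function(test) {
  st <- attr(test, "stats")
  if (is.null(st)) return(list(n_tests = NA_integer_, max_cond = NA_integer_))
  list(n_tests = st$n_tests, max_cond = st$max_cond)
}

#' @rdname ci_tester
#' @export
reset_tester_stats <- function(test) {
  st <- attr(test, "stats")
  if (!is.null(st)) {
    st$n_tests <- 0L
    st$max_cond <- 0L
  }
  invisible(test)
}

# Accept either a ready-made tester closure or a method name.
as_tester <- function(test, data, alpha) {
  if (is.function(test)) return(test)
  ci_tester(data, method = test, alpha = alpha)
}
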