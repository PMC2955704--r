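# data frame realizing a 2x2 contingency table
table_data <- function(counts) {
  xs <- rep(rep(seq_len(nrow(counts)), ncol(counts)), c(counts))
  ys <- rep(rep(seq_len(ncol(counts)), each = nrow(counts)), c(counts))
  data.frame(x = factor(xs), y = factor(ys))
}

test_that("discrete tests reproduce the hand-computed 2x2 oracle", {
  counts <- rbind(c(10, 20), c(20, 10))
  d <- table_data(counts)
  # Pearson oracle: X2 = n (ad - bc)^2 / (r1 r2 c1 c2) = 60 * 90000 / 810000
  px <- g2_test(d, "x", "y", statistic = "x2", min_obs_per_dof = 1)
  expect_equal(px$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(px$dof, 1)
  expect_equal(px$p_value, pchisq(20 / 3, 1, lower.tail = FALSE))
  expect_false(px$independent)
  # G2 from its printed formula, computed directly on the table
  e <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  g2 <- 2 * sum(counts * log(counts / e))
  pg <- g2_test(d, "x", "y", min_obs_per_dof = 1)
  expect_equal(pg$statistic, g2, tolerance = 1e-12)
  expect_false(pg$independent)
  expect_true(pg$reliable)
})

test_that("a duplicated column is detected as perfectly dependent", {
  set.seed(1)
  x <- sample(0:2, 1000, replace = TRUE)
  d <- data.frame(a = factor(x), b = factor(x))
  r <- g2_test(d, "a", "b")
  expect_false(r$independent)
  expect_lt(r$p_value, 1e-12)
})

test_that("dof follows (rx-1)(ry-1)prod(rz) and the reliability guard", {
  set.seed(2)
  d <- data.frame(a = factor(sample(1:2, 4000, TRUE)),
                  b = factor(sample(1:3, 4000, TRUE)),
                  c = factor(sample(1:2, 4000, TRUE)),
                  e = factor(sample(1:3, 4000, TRUE)))
  expect_equal(g2_test(d, "a", "b")$dof, 2)
  expect_equal(g2_test(d, "a", "b", c("c", "e"))$dof, 2 * 6)
  expect_equal(g2_test(d, "b", "e", "a")$dof, 4 * 2)
  # guard: n < 10 * dof flags the test unreliable and returns independence
  small <- d[1:100, ]
  r <- g2_test(small, "a", "b", c("c", "e"))
  expect_false(r$reliable)
  expect_true(r$independent)
  expect_true(g2_test(d, "a", "b", c("c", "e"))$reliable)
})

test_that("discrete tests are symmetric and relabel-invariant", {
  set.seed(3)
  n <- 600
  a <- sample(1:3, n, TRUE)
  b <- ifelse(runif(n) < 0.4, a, sample(1:3, n, TRUE))
  d <- data.frame(a = factor(a), b = factor(b))
  r1 <- g2_test(d, "a", "b")
  r2 <- g2_test(d, "b", "a")
  expect_equal(r1$statistic, r2$statistic)
  expect_identical(r1$independent, r2$independent)
  # permute category labels of both columns
  perm <- c(3, 1, 2)
  d2 <- data.frame(a = factor(perm[a]), b = factor(perm[b]))
  expect_equal(g2_test(d2, "a", "b")$statistic, r1$statistic)
})

test_that("type mismatches and bad arguments are rejected", {
  d <- data.frame(a = factor(c(1, 2, 1, 2)), b = c(0.5, 1.2, 0.1, 0.7))
  expect_error(g2_test(d, "a", "b"), "not discrete")
  expect_error(fisher_z_test(d, "b", "a"), "not continuous")
  expect_error(g2_test(d, "a", "a"), "distinct")
  expect_error(g2_test(d, "a", "q"), "unknown column")
})

test_that("G2 type-I error is calibrated under the null", {
  rej <- 0L
  n_rep <- 400
  set.seed(4)
  for (i in seq_len(n_rep)) {
    d <- data.frame(a = factor(sample(1:2, 500, TRUE), levels = 1:2),
                    b = factor(sample(1:2, 500, TRUE), levels = 1:2))
    if (!g2_test(d, "a", "b")$independent) rej <- rej + 1L
  }
  env <- qbinom(c(0.005, 0.995), n_rep, 0.05)
  expect_gte(rej, env[1])
  expect_lte(rej, env[2])
})

test_that("fisher_z detects dependence, screens common causes, calibrates", {
  set.seed(5)
  n <- 500
  x <- rnorm(n)
  d <- data.frame(x = x, y = x + rnorm(n, sd = 0.2))
  expect_false(fisher_z_test(d, "x", "y")$independent)
  # common cause screened off by conditioning
  n <- 1000
  cc <- rnorm(n)
  d2 <- data.frame(x = cc, y = cc + rnorm(n), w = cc + rnorm(n))
  expect_false(fisher_z_test(d2, "y", "w")$independent)
  expect_true(fisher_z_test(d2, "y", "w", "x")$independent)
  # calibration
  rej <- 0L
  n_rep <- 400
  for (i in seq_len(n_rep)) {
    dd <- data.frame(a = rnorm(300), b = rnorm(300))
    if (!fisher_z_test(dd, "a", "b")$independent) rej <- rej + 1L
  }
  env <- qbinom(c(0.005, 0.995), n_rep, 0.05)
  expect_gte(rej, env[1])
  expect_lte(rej, env[2])
  # degenerate collinearity
  d3 <- data.frame(x = x, y = 2 * x)
  r <- fisher_z_test(d3, "x", "y")
  expect_false(r$independent)
  expect_false(r$reliable)
  expect_equal(r$p_value, 0)
  expect_error(fisher_z_test(d3[1:3, ], "x", "y", character(0)), "rows")
})

test_that("the oracle test mirrors d-separation exactly", {
  coll <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("C", "B")))
  ot <- oracle_test(coll)
  expect_true(ot("A", "C", character(0))$independent)
  expect_equal(ot("A", "C", character(0))$p_value, 1)
  chain <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  expect_false(oracle_test(chain)("A", "C", character(0))$independent)
  g <- random_dag(7, 10, 4, seed = 99)
  ot <- oracle_test(g)
  nodes <- dag_nodes(g)
  for (x in nodes) for (y in nodes) {
    if (x >= y) next
    for (z in list(character(0), setdiff(nodes, c(x, y))[1:2])) {
      expect_identical(ot(x, y, z)$independent, d_separated(g, x, y, z))
    }
  }
})

test_that("ci_tester instruments calls and conditioning sizes", {
  d <- data.frame(a = factor(rep(1:2, 50)), b = factor(rep(1:2, each = 50)),
                  c = factor(rep(1:2, 25)))
  tt <- ci_tester(d, "g2")
  tt("a", "b", character(0))
  tt("a", "b", "c")
  st <- tester_stats(tt)
  expect_equal(st$n_tests, 2L)
  expect_equal(st$max_cond, 1L)
  reset_tester_stats(tt)
  expect_equal(tester_stats(tt)$n_tests, 0L)
})

test_that("CSV reading respects a schema", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(a = c(1, 2, 1, 2), b = c(0.5, 1.25, 0.1, 0.7)),
            path, row.names = FALSE)
  d <- read_ci_csv(path)
  expect_identical(unname(d$type), c("discrete", "continuous"))
  d2 <- read_ci_csv(path, schema = list(a = "continuous", b = "continuous"))
  expect_identical(unname(d2$type), c("continuous", "continuous"))
  d3 <- read_ci_csv(path, schema = list(a = list(discrete = 4)))
  expect_equal(d3$arities[["a"]], 4)
  expect_error(ci_data(data.frame(a = c(1, NA))), "missing values")
})
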