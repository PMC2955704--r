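# Independent oracles used to validate the implementation.  They deliberately
# share no code with the package internals: d-separation is decided by
# exhaustive path enumeration with the per-path blocking rules, and the
# essential graph by brute-force enumeration of the Markov-equivalence class.

bf_descendants <- function(g, v) {
  out <- v
  frontier <- v
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(lapply(frontier, dag_children, g = g))), out)
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

# d-separation by enumerating every simple undirected path and applying the
# blocking rules triple by triple.
bf_dsep <- function(g, x, y, z) {
  nodes <- dag_nodes(g)
  adj <- lapply(setNames(nodes, nodes),
                function(v) union(dag_parents(g, v), dag_children(g, v)))
  is_edge <- function(a, b) b %in% dag_children(g, a)
  paths <- list()
  dfs <- function(path) {
    v <- path[length(path)]
    if (v == y) {
      paths[[length(paths) + 1L]] <<- path
      return()
    }
    for (w in adj[[v]]) if (!(w %in% path)) dfs(c(path, w))
  }
  dfs(x)
  for (p in paths) {
    blocked <- FALSE
    if (length(p) >= 3) {
      for (k in 2:(length(p) - 1)) {
        a <- p[k - 1]; b <- p[k]; c <- p[k + 1]
        if (is_edge(a, b) && is_edge(c, b)) {        # collider on the path
          if (!any(bf_descendants(g, b) %in% z)) { blocked <- TRUE; break }
        } else if (b %in% z) { blocked <- TRUE; break }
      }
    }
    if (!blocked) return(FALSE)
  }
  TRUE
}

bf_vstructs <- function(g) {
  out <- character(0)
  for (b in dag_nodes(g)) {
    pa <- dag_parents(g, b)
    if (length(pa) < 2) next
    for (i in seq_along(pa)) for (j in seq_along(pa)) {
      if (i >= j) next
      a <- min(pa[i], pa[j]); c <- max(pa[i], pa[j])
      if (!(c %in% union(dag_parents(g, a), dag_children(g, a))))
        out <- c(out, paste(a, b, c))
    }
  }
  sort(out)
}

# Enumerate every DAG with the same skeleton and v-structures as g; return
# the list of "from>to" edge-set strings plus the unanimously oriented edges.
bf_equivalence_class <- function(g) {
  nodes <- dag_nodes(g)
  sk <- dag_edges(g)
  sk <- t(apply(sk, 1, sort))
  m <- nrow(sk)
  vs <- bf_vstructs(g)
  members <- list()
  for (bits in 0:(2^m - 1)) {
    em <- matrix(character(0), ncol = 2)
    for (e in seq_len(m)) {
      fwd <- bitwAnd(bits, bitwShiftL(1L, e - 1L)) != 0
      em <- rbind(em, if (fwd) sk[e, ] else rev(sk[e, ]))
    }
    cand <- tryCatch(dag(nodes, em), error = function(e) NULL)
    if (is.null(cand)) next
    if (!identical(bf_vstructs(cand), vs)) next
    members[[length(members) + 1L]] <- cand
  }
  members
}

bf_cpdag_edges <- function(g) {
  members <- bf_equivalence_class(g)
  sk <- t(apply(dag_edges(g), 1, sort))
  directed <- matrix(character(0), ncol = 2)
  undirected <- matrix(character(0), ncol = 2)
  for (e in seq_len(nrow(sk))) {
    a <- sk[e, 1]; b <- sk[e, 2]
    dirs <- vapply(members, function(d) b %in% dag_children(d, a), TRUE)
    if (all(dirs)) directed <- rbind(directed, c(a, b))
    else if (all(!dirs)) directed <- rbind(directed, c(b, a))
    else undirected <- rbind(undirected, c(a, b))
  }
  list(directed = directed, undirected = undirected)
}

# canonical string forms for PDAG comparison
pdag_sig <- function(p) {
  list(directed = sort(paste(p$directed[, 1], p$directed[, 2], sep = ">")),
       undirected = sort(row_keys(p$undirected)))
}

row_keys <- function(m) {
  if (is.null(m) || !nrow(m)) return(character(0))
  apply(m, 1, function(r) paste(sort(r), collapse = "~"))
}

expect_same_pdag <- function(got, want) {
  expect_identical(pdag_sig(got), pdag_sig(want))
}

# the standard fixture suite of random DAGs (deterministic)
dag_suite <- function(n_graphs, n_range, density = 1.5, max_degree = 4) {
  lapply(seq_len(n_graphs), function(i) {
    n <- n_range[1] + (i - 1) %% (diff(range(n_range)) + 1)
    random_dag(n, min(as.integer(density * n), n * (n - 1) / 2,
                      floor(n * max_degree / 2)),
               max_degree = max_degree, seed = 1000 + i)
  })
}

# mirrors the package's replicate-seed counter scheme
derive_seed_for_test <- function(seed, counter) {
  as.integer((as.double(seed) + 1000003 * as.double(counter)) %% 2147483647)
}

# k-node binary Markov chain X1 -> X2 -> ... -> Xk with strong transitions
chain_bn <- function(k = 5, p_flip = 0.1) {
  nodes <- sprintf("X%d", seq_len(k))
  edges <- cbind(nodes[-k], nodes[-1])
  arities <- setNames(rep(2L, k), nodes)
  cpts <- setNames(vector("list", k), nodes)
  cpts[[nodes[1]]] <- matrix(c(0.5, 0.5), 1)
  for (i in 2:k)
    cpts[[nodes[i]]] <- rbind(c(1 - p_flip, p_flip), c(p_flip, 1 - p_flip))
  bayes_net(dag(nodes, edges), arities, cpts)
}

# collider A -> B <- C with strong, non-deterministic CPTs
collider_bn <- function() {
  nodes <- c("A", "B", "C")
  arities <- setNames(c(2L, 2L, 2L), nodes)
  cpts <- list(
    A = matrix(c(0.5, 0.5), 1),
    B = rbind(c(0.9, 0.1), c(0.5, 0.5), c(0.5, 0.5), c(0.1, 0.9)),
    C = matrix(c(0.5, 0.5), 1))
  bayes_net(dag(nodes, rbind(c("A", "B"), c("C", "B"))), arities, cpts)
}
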