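# Orientation machinery shared by essential_graph() and rhpc():
# a PDAG is held as a pair of logical adjacency matrices,
#   D[i, j]  TRUE iff i -> j   (directed)
#   U[i, j]  TRUE iff i -  j   (undirected, symmetric)
# and Meek's orientation-propagation rules are applied to a fixpoint.

meek_closure <- function(D, U) {
  n <- nrow(D)
  adj <- function(A) A | t(A)
  repeat {
    changed <- FALSE
    A <- adj(D) | U
    for (b in seq_len(n)) {
      for (c in seq_len(n)) {
        if (!U[b, c]) next
        # R1: a -> b, b - c, a and c non-adjacent  =>  b -> c
        as <- which(D[, b] & !A[, c] & seq_len(n) != c)
        if (length(as)) {
          D[b, c] <- TRUE; U[b, c] <- U[c, b] <- FALSE
          changed <- TRUE; next
        }
        # R2: b -> k -> c with b - c  =>  b -> c
        if (any(D[b, ] & D[, c])) {
          D[b, c] <- TRUE; U[b, c] <- U[c, b] <- FALSE
          changed <- TRUE; next
        }
        # R3: b - c, b - k1, b - k2, k1 -> c, k2 -> c, k1,k2 non-adjacent
        ks <- which(U[b, ] & D[, c])
        if (length(ks) >= 2) {
          hit <- FALSE
          for (i in seq_along(ks)) {
            for (j in seq_along(ks)) {
              if (i < j && !A[ks[i], ks[j]]) { hit <- TRUE; break }
            }
            if (hit) break
          }
          if (hit) {
            D[b, c] <- TRUE; U[b, c] <- U[c, b] <- FALSE
            changed <- TRUE; next
          }
        }
        # R4: b - c, b - k, k -> l, l -> c, c and k non-adjacent  =>  b -> c
        ks <- which(U[b, ] & !A[, c] & seq_len(n) != c)
        hit <- FALSE
        for (k in ks) {
          if (any(D[k, ] & D[, c])) { hit <- TRUE; break }
        }
        if (hit) {
          D[b, c] <- TRUE; U[b, c] <- U[c, b] <- FALSE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  list(D = D, U = U)
}

matrices_to_pdag <- function(nodes, D, U) {
  di <- which(D, arr.ind = TRUE)
  ui <- which(U & upper.tri(U), arr.ind = TRUE)
  pdag(nodes,
       directed = cbind(nodes[di[, 1]], nodes[di[, 2]]),
       undirected = cbind(nodes[ui[, 1]], nodes[ui[, 2]]))
}

pdag_to_matrices <- function(p) {
  n <- length(p$nodes)
  idx <- setNames(seq_len(n), p$nodes)
  D <- U <- matrix(FALSE, n, n)
  if (nrow(p$directed))
    D[cbind(idx[p$directed[, 1]], idx[p$directed[, 2]])] <- TRUE
  if (nrow(p$undirected)) {
    U[cbind(idx[p$undirected[, 1]], idx[p$undirected[, 2]])] <- TRUE
    U[cbind(idx[p$undirected[, 2]], idx[p$undirected[, 1]])] <- TRUE
  }
  list(D = D, U = U)
}

# v-structures of a DAG: rows (a, b, c) meaning a -> b <- c with a, c
# non-adjacent and a < c lexicographically.
dag_v_structures <- function(g) {
  out <- NULL
  for (b in g$nodes) {
    pa <- g$parents[[b]]
    if (length(pa) < 2) next
    for (i in seq_along(pa)) {
      for (j in seq_along(pa)) {
        if (i >= j) next
        a <- pa[i]; c <- pa[j]
        if (!(c %in% dag_adjacent(g, a)))
          out <- rbind(out, c(a, b, c))
      }
    }
  }
  out %||% matrix(character(0), ncol = 3)
}

#' Essential graph (CPDAG) of a DAG
#'
#' Computes the DAG pattern of the Markov-equivalence class of `g`: the
#' PDAG with the same skeleton in which an edge is directed precisely when
#' it is compelled (oriented identically in every equivalent DAG).
#' V-structures are oriented first and Meek's four orientation-propagation
#' rules are then applied to a fixpoint.
#'
#' @param g a `"dag"`.
#' @return A `"pdag"`.
#' @examples
#' essential_graph(dag(c("A", "B", "C"), rbind(c("A", "B"), c("C", "B"))))
#' @export
essential_graph <- function(g) {
  if (!inherits(g, "dag")) stop_input("essential_graph expects a dag")
  n <- length(g$nodes)
  idx <- setNames(seq_len(n), g$nodes)
  D <- U <- matrix(FALSE, n, n)
  if (nrow(g$edges)) {
    U[cbind(idx[g$edges[, 1]], idx[g$edges[, 2]])] <- TRUE
    U <- U | t(U)
  }
  vs <- dag_v_structures(g)
  for (r in seq_len(nrow(vs))) {
    a <- idx[[vs[r, 1]]]; b <- idx[[vs[r, 2]]]; c <- idx[[vs[r, 3]]]
    D[a, b] <- TRUE; D[c, b] <- TRUE
    U[a, b] <- U[b, a] <- U[c, b] <- U[b, c] <- FALSE
  }
  m <- meek_closure(D, U)
  matrices_to_pdag(g$nodes, m$D, m$U)
}
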