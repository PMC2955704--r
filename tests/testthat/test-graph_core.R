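test_that("dag construction enforces the invariants", {
  expect_error(dag(c("A", "A")), "duplicate node")
  expect_error(dag(c("A", "B"), rbind(c("A", "A"))), "self-loop")
  expect_error(dag(c("A", "B"), rbind(c("A", "B"), c("A", "B"))), "duplicate edge")
  expect_error(dag(c("A", "B"), rbind(c("A", "C"))), "unknown node")
  expect_error(dag(c("A", "B", "C"),
                   rbind(c("A", "B"), c("B", "C"), c("C", "A"))), "cycle")
  g <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("C", "B")))
  expect_identical(dag_parents(g, "B"), c("A", "C"))
  expect_identical(dag_children(g, "A"), "B")
  expect_error(dag_parents(g, "Z"), "unknown node")
})

test_that("pdag construction enforces the invariants", {
  expect_error(pdag("A", undirected = rbind(c("A", "A"))), "self-loop")
  expect_error(pdag(c("A", "B"), directed = rbind(c("A", "B")),
                    undirected = rbind(c("B", "A"))), "both directed and undirected")
  expect_error(pdag(c("A", "B"), directed = rbind(c("A", "B"), c("B", "A"))),
               "both directions")
  expect_error(pdag(c("A", "B", "C"),
                    directed = rbind(c("A", "B"), c("B", "C"), c("C", "A"))),
               "cycle")
  p <- pdag(c("A", "B", "C"), directed = rbind(c("A", "B")),
            undirected = rbind(c("C", "B")))
  expect_equal(nrow(pdag_skeleton(p)), 2)
})

test_that("d_separated matches the hand rules on chains and colliders", {
  chain <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  expect_true(d_separated(chain, "A", "C", "B"))
  expect_false(d_separated(chain, "A", "C"))
  coll <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("C", "B")))
  expect_true(d_separated(coll, "A", "C"))
  expect_false(d_separated(coll, "A", "C", "B"))
  # descendant of a collider also activates it
  g <- dag(c("A", "B", "C", "D"),
           rbind(c("A", "B"), c("C", "B"), c("B", "D")))
  expect_false(d_separated(g, "A", "C", "D"))
  expect_error(d_separated(chain, "A", "Z"), "unknown node")
  expect_error(d_separated(chain, "A", "A"), "distinct")
  expect_error(d_separated(chain, "A", "B", "A"), "must not belong")
})

test_that("d_separated equals the exhaustive path-enumeration oracle", {
  suite <- dag_suite(10, c(5, 8))
  set.seed(11)
  for (g in suite) {
    nodes <- dag_nodes(g)
    for (rep in 1:25) {
      xy <- sample(nodes, 2)
      z <- setdiff(nodes, xy)
      z <- z[runif(length(z)) < 0.4]
      got <- d_separated(g, xy[1], xy[2], z)
      expect_identical(got, bf_dsep(g, xy[1], xy[2], z))
      expect_identical(got, d_separated(g, xy[2], xy[1], z))  # symmetry
    }
  }
})

test_that("true_node_sets reads the local sets off the graph", {
  g <- dag(c("A", "B", "C", "D", "T"),
           rbind(c("A", "T"), c("B", "T"), c("T", "C"), c("D", "C")))
  s <- true_node_sets(g, "T")
  expect_identical(s$pc, c("A", "B", "C"))
  expect_identical(s$spouses, "D")
  expect_identical(s$mb, c("A", "B", "C", "D"))
  iso <- dag(c("T", "X", "Y"), rbind(c("X", "Y")))
  expect_identical(true_node_sets(iso, "T"),
                   list(pc = character(0), spouses = character(0),
                        mb = character(0)))
  expect_error(true_node_sets(g, "Z"), "unknown node")
})

test_that("the Markov boundary shields the target and is minimal", {
  suite <- dag_suite(6, c(5, 8))
  for (g in suite) {
    for (t in dag_nodes(g)) {
      mb <- true_node_sets(g, t)$mb
      for (x in setdiff(dag_nodes(g), c(t, mb)))
        expect_true(d_separated(g, t, x, mb))
      if (length(mb) && length(mb) <= 5) {
        for (drop in mb) {
          sub <- setdiff(mb, drop)
          shields <- all(vapply(setdiff(dag_nodes(g), c(t, sub)),
                                function(x) d_separated(g, t, x, sub), TRUE))
          expect_false(shields)
        }
      }
    }
  }
})

test_that("essential_graph handles the canonical 3-node cases", {
  coll <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("C", "B")))
  eg <- essential_graph(coll)
  expect_identical(pdag_sig(eg)$directed, c("A>B", "C>B"))
  expect_length(pdag_sig(eg)$undirected, 0)
  chain <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  eg2 <- essential_graph(chain)
  expect_length(pdag_sig(eg2)$directed, 0)
  expect_identical(pdag_sig(eg2)$undirected, c("A~B", "B~C"))
  expect_error(essential_graph(pdag(c("A"))), "expects a dag")
})

test_that("essential_graph equals the brute-force equivalence-class oracle", {
  suite <- dag_suite(8, c(4, 6), density = 1.3)
  for (g in suite) {
    eg <- essential_graph(g)
    bf <- bf_cpdag_edges(g)
    expect_identical(pdag_sig(eg)$directed,
                     sort(paste(bf$directed[, 1], bf$directed[, 2], sep = ">")))
    expect_identical(pdag_sig(eg)$undirected, sort(row_keys(bf$undirected)))
    # same skeleton, and every v-structure edge directed
    expect_identical(sort(row_keys(pdag_skeleton(eg))),
                     sort(row_keys(dag_edges(g))))
    # invariance across the whole equivalence class
    for (member in bf_equivalence_class(g))
      expect_same_pdag(essential_graph(member), eg)
  }
})

test_that("random_dag is deterministic and honours its constraints", {
  expect_identical(dag_edges(random_dag(3, 0, 2, seed = 5)),
                   dag_edges(dag(c("V01", "V02", "V03"))))
  g1 <- random_dag(12, 18, 5, seed = 42)
  g2 <- random_dag(12, 18, 5, seed = 42)
  expect_identical(dag_edges(g1), dag_edges(g2))
  expect_equal(nrow(dag_edges(g1)), 18)
  deg <- vapply(dag_nodes(g1),
                function(v) length(union(dag_parents(g1, v),
                                         dag_children(g1, v))), 0L)
  expect_true(all(deg <= 5))
  # insulin-like dimensions with a unique forced hub
  h <- random_dag(35, 52, 13, seed = 7, hub_degree = 13)
  degh <- vapply(dag_nodes(h),
                 function(v) length(union(dag_parents(h, v),
                                          dag_children(h, v))), 0L)
  expect_equal(nrow(dag_edges(h)), 52)
  expect_equal(max(degh), 13)
  expect_equal(sum(degh == 13), 1)
  expect_error(random_dag(4, 10, 4, seed = 1), "too many edges")
  expect_error(random_dag(6, 10, 2, seed = 1), "infeasible")
  expect_error(random_dag(5, 4, 4, seed = 1, hub_degree = 5), "hub_degree infeasible")
})

test_that("PDAG serialization round-trips through JSON and renders DOT", {
  p <- pdag(c("A", "B", "C"), directed = rbind(c("A", "B")),
            undirected = rbind(c("B", "C")))
  expect_same_pdag(pdag_from_json(pdag_to_json(p)), p)
  path <- tempfile(fileext = ".json")
  pdag_to_json(p, path)
  expect_same_pdag(pdag_from_json(path), p)
  dot <- pdag_to_dot(p)
  expect_match(dot, "\"A\" -> \"B\" \\[dir=forward")
  expect_match(dot, "\"B\" -> \"C\" \\[dir=none")
  # empty graph serializes too
  expect_same_pdag(pdag_from_json(pdag_to_json(pdag(c("X", "Y")))),
                   pdag(c("X", "Y")))
})
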