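test_that("graph construction validates its invariants", {
  ap <- data.frame(p = c(1, 2))
  bp <- data.frame(q = 1)
  expect_s3_class(molecular_graph(c("A", "B"), rbind(c("A", "B")), ap, bp),
                  "molecular_graph")
  expect_error(molecular_graph(c("A", "A"), rbind(c("A", "A")), ap, bp),
               "duplicate node")
  expect_error(molecular_graph(c("A", "B"), rbind(c("A", "X")), ap, bp),
               "unknown node")
  expect_error(molecular_graph(c("A", "B"), rbind(c("A", "A")), ap, bp),
               "self-loop")
  expect_error(molecular_graph(c("A", "B"),
                               rbind(c("A", "B"), c("B", "A")), ap,
                               data.frame(q = c(1, 2))),
               "duplicate edges")
  expect_error(molecular_graph(c("A", "B"), rbind(c("A", "B")), ap, bp,
                               metal = "Z"), "not a node")
  # disconnected graphs have no well-defined depths
  expect_error(molecular_graph(c("A", "B", "C"), rbind(c("A", "B")),
                               data.frame(p = 1:3),
                               data.frame(q = 1)), "disconnected")
  # non-finite property values are schema errors naming the element
  expect_error(molecular_graph(c("A", "B"), rbind(c("A", "B")),
                               data.frame(p = c(1, NA)), bp),
               "property 'p'.*B")
  expect_error(molecular_graph(c("A", "B"), rbind(c("A", "B")), ap,
                               data.frame(q = Inf)), "property 'q'")
})

test_that("atom, bond and bond-atom distances follow their definitions", {
  g <- path_abc()
  expect_identical(atom_distance(g, "A", "C"), 2L)
  expect_identical(atom_distance(g, "A", "A"), 0L)
  expect_identical(bond_distance(g, c("A", "B"), c("B", "C")), 1L)
  expect_identical(bond_distance(g, c("A", "B"), c("A", "B")), 0L)
  expect_identical(bond_atom_distance(g, c("A", "B"), "A"), 0L)
  expect_identical(bond_atom_distance(g, c("A", "B"), "C"), 1L)
  g4 <- molecular_graph(LETTERS[1:4],
                        rbind(c("A", "B"), c("B", "C"), c("C", "D")),
                        data.frame(p = 1:4), data.frame(q = 1:3))
  expect_identical(bond_distance(g4, c("A", "B"), c("C", "D")), 2L)
  expect_identical(bond_atom_distance(g4, c("A", "B"), "D"), 2L)
  # opposite nodes of a 6-cycle
  cyc <- molecular_graph(paste0("c", 1:6),
                         cbind(paste0("c", 1:6), paste0("c", c(2:6, 1))),
                         data.frame(p = 1:6), data.frame(q = 1:6))
  expect_identical(atom_distance(cyc, "c1", "c4"), 3L)
  expect_error(atom_distance(g, "A", "nope"), "unknown node")
  expect_error(bond_distance(g, c("A", "C"), c("A", "B")), "unknown edge")
})

test_that("distances agree with Floyd-Warshall / line-graph oracles and are metrics", {
  set.seed(101)
  for (rep in 1:25) {
    g <- rand_graph(n_nodes = sample(4:12, 1), extra_edges = sample(0:4, 1))
    Da <- atom_distance_matrix_for_test(g)
    expect_equal(Da, oracle_atom_dist(g))
    expect_true(all(Da == t(Da)))                       # symmetry
    n <- nrow(Da)
    for (k in seq_len(n))                                # triangle inequality
      expect_true(all(Da <= outer(Da[, k], Da[k, ], "+") + 1e-9))
    expect_equal(bond_distance_matrix_for_test(g), oracle_bond_dist(g))
    Dba <- oracle_bond_atom_dist(g)
    for (e in seq_len(nrow(g$edges)))
      for (j in seq_along(g$nodes))
        expect_identical(
          as.numeric(bond_atom_distance(g, g$edges[e, ], g$nodes[j])),
          Dba[e, j])
  }
})

test_that("JSON and GML writers round-trip losslessly", {
  g <- path_abc()
  fj <- tempfile(fileext = ".json")
  write_graph_file(g, fj)
  g2 <- read_graph_file(fj)
  expect_identical(g2$nodes, g$nodes)
  expect_identical(g2$edges, g$edges)
  expect_equal(g2$atom_props, g$atom_props)
  expect_equal(g2$bond_props, g$bond_props)
  expect_identical(g2$metal, "B")

  fg <- tempfile(fileext = ".gml")
  write_graph_file(g, fg)
  g3 <- read_graph_file(fg)
  expect_identical(g3$nodes, g$nodes)
  expect_equal(g3$atom_props$p, g$atom_props$p)
  expect_equal(g3$bond_props$q, g$bond_props$q)
  expect_identical(g3$metal, "B")
  expect_equal(unname(aabba_one(g3, list(autocorr_spec("AA", "p", "product",
                                                       "full", 2)))),
               unname(aabba_one(g, list(autocorr_spec("AA", "p", "product",
                                                      "full", 2)))))

  set.seed(7)
  g4 <- rand_graph(n_nodes = 9, extra_edges = 3)
  for (f in c(tempfile(fileext = ".json"), tempfile(fileext = ".gml"))) {
    write_graph_file(g4, f)
    g5 <- read_graph_file(f)
    expect_equal(g5$atom_props, g4$atom_props, tolerance = 1e-12)
    expect_identical(g5$metal, g4$metal)
    expect_identical(edge_set_for_test(g5), edge_set_for_test(g4))
  }
})

test_that("malformed graph files produce schema errors naming the culprit", {
  f <- tempfile(fileext = ".json")
  writeLines('{"nodes":[{"id":"A","props":{"p":1}},{"id":"B","props":{"p":2}}],
              "edges":[{"u":"A","v":"Z","props":{"q":5}}],"metal":null}', f)
  expect_error(read_graph_file(f), "unknown node id: Z")
  writeLines('{"nodes":[{"id":"A","props":{"p":1}},{"id":"B","props":{}}],
              "edges":[{"u":"A","v":"B","props":{"q":5}}],"metal":null}', f)
  expect_error(read_graph_file(f), "missing node property 'p' on B")
  expect_error(read_graph_file("no/such/file.json"), "no such file")
})
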