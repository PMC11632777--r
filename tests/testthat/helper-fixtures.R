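# shared fixtures and random-graph generator for property tests

# the three-atom path A-B-C with metal B used throughout the worked examples
path_abc <- function() {
  molecular_graph(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")),
                  data.frame(p = c(1, 2, 3)), data.frame(q = c(2, 5)),
                  metal = "B")
}

# random connected graph: spanning tree + extra edges; strictly positive
# property values so the ratiometric operator is always defined
rand_graph <- function(n_nodes = 8, extra_edges = 2, n_atom_props = 2,
                       n_bond_props = 2, metal = TRUE) {
  stopifnot(n_nodes >= 2)
  nodes <- paste0("n", seq_len(n_nodes))
  edges <- cbind(nodes[vapply(2:n_nodes, function(i)
    sample.int(i - 1L, 1L), integer(1))], nodes[2:n_nodes])
  have <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  for (k in seq_len(extra_edges)) {
    ij <- sample.int(n_nodes, 2L)
    key <- paste(min(nodes[ij]), max(nodes[ij]))
    if (!key %in% have) {
      edges <- rbind(edges, nodes[ij])
      have <- c(have, key)
    }
  }
  ap <- as.data.frame(lapply(seq_len(n_atom_props), function(k)
    runif(n_nodes, 0.5, 3)))
  names(ap) <- paste0("ap", seq_len(n_atom_props))
  bp <- as.data.frame(lapply(seq_len(n_bond_props), function(k)
    runif(nrow(edges), 0.5, 3)))
  names(bp) <- paste0("bp", seq_len(n_bond_props))
  molecular_graph(nodes, edges, ap, bp,
                  metal = if (metal) sample(nodes, 1L) else NULL)
}

# permute node order (and re-express edges) without changing the graph
permute_graph <- function(g, perm = sample(length(g$nodes))) {
  molecular_graph(g$nodes[perm], g$edges,
                  g$atom_props[perm, , drop = FALSE],
                  g$bond_props, g$metal)
}

# small deterministic dataset for model-harness tests
linear_benchmark <- function(n = 200, p = 5, noise = 0, seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- 2 * X[, 1] - 3 * X[, 2] + 0.5 * X[, 3] + rnorm(n, 0, noise)
  list(X = X, y = y)
}

# internal distance matrices, normalized for comparison with the oracles
atom_distance_matrix_for_test <- function(g) {
  D <- aabba:::atom_distance_matrix(g)
  storage.mode(D) <- "double"
  unname(D)
}

bond_distance_matrix_for_test <- function(g) {
  D <- aabba:::bond_distance_matrix(g)
  storage.mode(D) <- "double"
  unname(D)
}

edge_set_for_test <- function(g) {
  sort(paste(pmin(g$edges[, 1], g$edges[, 2]),
             pmax(g$edges[, 1], g$edges[, 2])))
}
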