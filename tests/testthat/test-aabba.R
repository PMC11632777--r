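test_that("compute_block concatenates labeled per-depth profiles", {
  g <- path_abc()
  b <- compute_block(g, autocorr_spec("AA", "p", "product", "full", 1))
  expect_identical(names(b), c("p-0_FA_AA", "p-1_FA_AA"))
  expect_equal(unname(b), c(14, 8))
  b0 <- compute_block(g, autocorr_spec("AA", "p", "product",
                                       "metal_centered", 0))
  expect_equal(unname(b0), 4)   # metal self-term p_M^2
  expect_error(autocorr_spec("AA", character(), "product"), "at least one")
})

test_that("AABBA(I) is the concatenation of its blocks", {
  g <- path_abc()
  specs <- list(autocorr_spec("AA", "p", "product", "full", 1),
                autocorr_spec("BBm", "q", "product", "metal_centered", 1),
                autocorr_spec("BA", c("q", "p"), "product",
                              "metal_centered", 1))
  v <- aabba_one(g, specs)
  blocks <- lapply(specs, function(s) compute_block(g, s))
  expect_identical(unname(v), unname(unlist(blocks)))
  expect_identical(length(v), sum(lengths(blocks)))
  expect_identical(names(v), unlist(lapply(blocks, names)))
  # duplicated blocks would collide label-wise
  expect_error(aabba_one(g, specs[c(1, 1)]), "duplicate feature labels")
})

test_that("merged edge properties follow the recipe componentwise", {
  g <- molecular_graph(c("A", "B"), rbind(c("A", "B")),
                       data.frame(znum = c(1, 3), eneg = c(2, 2),
                                  radius = c(0.7, 0.3)),
                       data.frame(blen = 1.4, border = 2))
  rec <- merge_recipe(mean_props = "znum", absdiff_props = "eneg",
                      geometry = "radius_sum", geometry_prop = "radius",
                      bond_props = "border")
  M <- merge_edge_properties(g, rec)
  expect_identical(colnames(M), c("znum", "eneg_diff", "geom", "border"))
  expect_equal(unname(M[1, ]), c(2, 0, 1.0, 2))   # mean, |diff|, radius sum
  rec1 <- merge_recipe(mean_props = "znum", geometry = "bond",
                       geometry_prop = "blen")
  expect_equal(unname(merge_edge_properties(g, rec1)[1, ]), c(2, 1.4))
  expect_error(merge_recipe(mean_props = "znum", geometry = "bond"),
               "geometry_prop")
  expect_error(merge_edge_properties(g, merge_recipe(mean_props = "oops")),
               "undeclared")
})

test_that("AABBA(II) equals the bond-bond kernel on the merged bond table", {
  set.seed(55)
  for (rep in 1:5) {
    g <- rand_graph(n_nodes = 8, extra_edges = 2, n_atom_props = 3,
                    n_bond_props = 2)
    names(g$atom_props) <- c("znum", "eneg", "radius")
    names(g$bond_props) <- c("blen", "border")
    rec <- aabba2_variant("II3", synth_catalog())
    M <- merge_edge_properties(g, rec)
    # independent route: rebuild the graph with the merged table as bonds
    g2 <- molecular_graph(g$nodes, g$edges, g$atom_props,
                          as.data.frame(M), g$metal)
    for (origin in c("full", "metal_centered")) {
      merge <- if (origin == "full") "none" else "mean"
      direct <- aabba_two(g, rec, "product", origin, merge = "mean",
                          max_depth = 3)
      via_bb <- unlist(lapply(colnames(M), function(cn)
        bb_ac(g2, cn, "product", origin, merge, 3)))
      expect_equal(unname(direct), unname(via_bb), tolerance = 1e-15)
    }
  }
})

test_that("AABBA(II) variants differ only in their declared components", {
  cat <- synth_catalog()
  r1 <- aabba2_variant("II1", cat)
  r2 <- aabba2_variant("II2", cat)
  r3 <- aabba2_variant("II3", cat)
  expect_identical(r1$geometry, "bond")
  expect_identical(r2$geometry, "none")
  expect_identical(r3$geometry, "radius_sum")
  r4 <- aabba2_variant("II4", cat)
  r5 <- aabba2_variant("II5", cat)
  expect_identical(r4$mean_props, cat$atom_property_names)
  expect_lt(length(r5$mean_props), length(r4$mean_props))
})

test_that("maximal vector length matches the closed-form block count", {
  g <- path_abc()   # 1 atom prop, 1 bond prop, metal present
  v <- maximal_vector(g, max_depth = 6)
  # AA: 2 origins x 4 ops x 1 prop x 7 depths = 56; BB: 56; BBm: 28; BA: 56
  expect_identical(length(v), 196L)
  expect_false(anyDuplicated(names(v)) > 0)
  set.seed(66)
  g2 <- rand_graph(n_nodes = 7, extra_edges = 1, n_atom_props = 3,
                   n_bond_props = 2)
  D <- 4
  v2 <- maximal_vector(g2, max_depth = D)
  nA <- 3; nB <- 2; dd <- D + 1
  expect_identical(length(v2),
                   as.integer((2 * 4 * nA + 2 * 4 * nB + 4 * nB +
                               2 * 4 * nA * nB) * dd))
  # no metal: only full-origin AA/BB/BA blocks remain
  g3 <- rand_graph(n_nodes = 7, extra_edges = 1, n_atom_props = 3,
                   n_bond_props = 2, metal = FALSE)
  expect_identical(length(maximal_vector(g3, max_depth = D)),
                   as.integer((4 * nA + 4 * nB + 4 * nA * nB) * dd))
  vw <- maximal_vector(g2, max_depth = 2, include_whole_graph = TRUE)
  expect_true(all(c("wg_natoms", "wg_nbonds", "wg_sum_ap1") %in% names(vw)))
})

test_that("fingerprints are invariant under node relabeling", {
  set.seed(77)
  # ordered operators in full scope depend on the canonical node order by
  # construction, so the invariance claim covers all other blocks
  sym_specs <- function(cat, D = 3) {
    specs <- list()
    for (op in c("product", "summetric"))
      specs <- c(specs, maximal_specs(cat, TRUE, D, operators = op))
    c(specs,
      list(autocorr_spec("AA", cat$atom_property_names, "deltametric",
                         "metal_centered", D),
           autocorr_spec("AA", cat$atom_property_names, "ratiometric",
                         "metal_centered", D)))
  }
  for (rep in 1:8) {
    g <- rand_graph(n_nodes = 8, extra_edges = 2)
    cat <- property_catalog(names(g$atom_props), names(g$bond_props))
    specs <- sym_specs(cat)
    v <- aabba_one(g, specs)
    for (k in 1:4) {
      gp <- permute_graph(g)
      expect_equal(aabba_one(gp, specs), v, tolerance = 1e-12)
    }
  }
})

test_that("redundancy removal drops constants and exact duplicates only", {
  X <- cbind(c0 = c(1, 1), c1 = c(1, 3), c2 = c(2, 6))
  red <- remove_redundant(X)
  expect_identical(red$kept, c("c1", "c2"))   # c2 = 2*c1 is NOT a duplicate
  expect_identical(red$dropped, "c0")
  X2 <- cbind(a = c(1, 2, 3), b = c(4, 5, 7), bdup = c(4, 5, 7))
  red2 <- remove_redundant(X2)
  expect_identical(red2$kept, c("a", "b"))
  expect_identical(unname(red2$duplicate_of["bdup"]), "b")
  # duplicates are exactly recoverable from the kept columns
  expect_identical(X2[, red2$duplicate_of["bdup"]], unname(X2[, "bdup"]))
  # idempotence
  red3 <- remove_redundant(red2$X)
  expect_identical(red3$X, red2$X)
  expect_length(red3$dropped, 0)
  # all-distinct input is untouched
  expect_identical(remove_redundant(X2[, 1:2])$X, X2[, 1:2])
})

test_that("feature matrices round-trip through CSV with their sidecar", {
  set.seed(88)
  graphs <- replicate(3, rand_graph(6, 1), simplify = FALSE)
  names(graphs) <- paste0("g", 1:3)
  X <- featurize_graphs(graphs, max_depth = 2)
  f <- tempfile(fileext = ".csv")
  write_feature_matrix(X, f, meta = list(max_depth = 2))
  X2 <- read_feature_matrix(f)
  expect_equal(unname(`attr<-`(X2, "meta", NULL)), unname(X),
               tolerance = 1e-12)
  expect_identical(colnames(X2), colnames(X))
  expect_identical(rownames(X2), names(graphs))
  expect_identical(attr(X2, "meta")$max_depth, 2L)
})
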