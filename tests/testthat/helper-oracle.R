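# Independent brute-force oracles: distances by Floyd-Warshall on explicit
# adjacency structures, autocorrelations by direct pair enumeration.  These
# deliberately share no code with the package internals.

oracle_op <- function(op, a, b) {
  switch(op, product = a * b, deltametric = a - b,
         ratiometric = a / b, summetric = a + b)
}

# Floyd-Warshall over a boolean adjacency matrix
oracle_fw <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[adj] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_atom_dist <- function(g) {
  n <- length(g$nodes)
  adj <- matrix(FALSE, n, n)
  for (r in seq_len(nrow(g$edges))) {
    i <- match(g$edges[r, 1L], g$nodes)
    j <- match(g$edges[r, 2L], g$nodes)
    adj[i, j] <- adj[j, i] <- TRUE
  }
  oracle_fw(adj)
}

# explicit line graph: vertices = edges of g, adjacency = shared endpoint
oracle_bond_dist <- function(g) {
  m <- nrow(g$edges)
  adj <- matrix(FALSE, m, m)
  for (a in seq_len(m))
    for (b in seq_len(m))
      if (a != b && length(intersect(g$edges[a, ], g$edges[b, ])) > 0)
        adj[a, b] <- TRUE
  oracle_fw(adj)
}

oracle_bond_atom_dist <- function(g) {
  Da <- oracle_atom_dist(g)
  m <- nrow(g$edges)
  D <- matrix(Inf, m, length(g$nodes))
  for (a in seq_len(m)) {
    u <- match(g$edges[a, 1L], g$nodes)
    v <- match(g$edges[a, 2L], g$nodes)
    D[a, ] <- pmin(Da[u, ], Da[v, ])
  }
  D
}

oracle_aa <- function(g, prop, op, origin, D) {
  p <- g$atom_props[[prop]]
  dm <- oracle_atom_dist(g)
  n <- length(p)
  out <- numeric(D + 1)
  if (origin == "full") {
    for (i in seq_len(n)) out[1] <- out[1] + oracle_op(op, p[i], p[i])
    if (n > 1)
      for (i in 1:(n - 1))
        for (j in (i + 1):n) {
          d <- dm[i, j]
          if (d <= D) out[d + 1] <- out[d + 1] + oracle_op(op, p[i], p[j])
        }
  } else {
    m <- match(g$metal, g$nodes)
    out[1] <- oracle_op(op, p[m], p[m])
    for (j in seq_len(n))
      if (j != m && dm[m, j] <= D)
        out[dm[m, j] + 1] <- out[dm[m, j] + 1] + oracle_op(op, p[m], p[j])
  }
  out
}

oracle_bb <- function(g, prop, op, origin, merge, D) {
  q <- g$bond_props[[prop]]
  m <- length(q)
  dm <- oracle_bond_dist(g)
  out <- numeric(D + 1)
  if (origin == "full") {
    for (e in seq_len(m)) out[1] <- out[1] + oracle_op(op, q[e], q[e])
    if (m > 1)
      for (a in 1:(m - 1))
        for (b in (a + 1):m) {
          d <- dm[a, b]
          if (d <= D) out[d + 1] <- out[d + 1] + oracle_op(op, q[a], q[b])
        }
    return(out)
  }
  ml <- which(g$edges[, 1] == g$metal | g$edges[, 2] == g$metal)
  sb <- if (merge == "sum") sum(q[ml]) else mean(q[ml])
  out[1] <- oracle_op(op, sb, sb)
  for (e in setdiff(seq_len(m), ml)) {
    d <- min(dm[e, ml])
    if (d <= D) out[d + 1] <- out[d + 1] + oracle_op(op, sb, q[e])
  }
  out
}

oracle_ba <- function(g, bond_prop, atom_prop, op, origin, D) {
  q <- g$bond_props[[bond_prop]]
  p <- g$atom_props[[atom_prop]]
  dm <- oracle_bond_atom_dist(g)
  edges <- if (origin == "full") seq_along(q) else
    which(g$edges[, 1] == g$metal | g$edges[, 2] == g$metal)
  out <- numeric(D + 1)
  for (e in edges)
    for (j in seq_along(p)) {
      d <- dm[e, j]
      if (d <= D) out[d + 1] <- out[d + 1] + oracle_op(op, q[e], p[j])
    }
  out
}

# compare a package profile against its oracle, all four operators
expect_profiles_match_oracle <- function(g, D = 4, tol = 1e-12) {
  ops <- c("product", "deltametric", "ratiometric", "summetric")
  for (op in ops) {
    for (pr in names(g$atom_props)) {
      expect_equal(unname(aa_ac(g, pr, op, "full", D)),
                   oracle_aa(g, pr, op, "full", D), tolerance = tol)
      if (!is.null(g$metal))
        expect_equal(unname(aa_ac(g, pr, op, "metal_centered", D)),
                     oracle_aa(g, pr, op, "metal_centered", D),
                     tolerance = tol)
    }
    for (pr in names(g$bond_props)) {
      expect_equal(unname(bb_ac(g, pr, op, "full", "none", D)),
                   oracle_bb(g, pr, op, "full", "none", D), tolerance = tol)
      if (!is.null(g$metal)) {
        expect_equal(unname(bb_ac(g, pr, op, "metal_centered", "sum", D)),
                     oracle_bb(g, pr, op, "metal_centered", "sum", D),
                     tolerance = tol)
        expect_equal(unname(bb_ac(g, pr, op, "metal_centered", "mean", D)),
                     oracle_bb(g, pr, op, "metal_centered", "mean", D),
                     tolerance = tol)
      }
    }
    for (bp in names(g$bond_props))
      for (ap in names(g$atom_props)) {
        expect_equal(unname(ba_ac(g, bp, ap, op, "full", D)),
                     oracle_ba(g, bp, ap, op, "full", D), tolerance = tol)
        if (!is.null(g$metal))
          expect_equal(unname(ba_ac(g, bp, ap, op, "metal_centered", D)),
                       oracle_ba(g, bp, ap, op, "metal_centered", D),
                       tolerance = tol)
      }
  }
  invisible(TRUE)
}
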