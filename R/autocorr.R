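AC_OPERATORS <- c("product", "deltametric", "ratiometric", "summetric")
OP_CODES <- c(product = "A", deltametric = "D", ratiometric = "R",
              summetric = "S")

#' Apply an autocorrelation operator
#'
#' The classical Moreau-Broto autocorrelation multiplies the two property
#' values; the deltametric, ratiometric and summetric variants subtract,
#' divide and add instead.  For the ordered operators (deltametric,
#' ratiometric) `a` is the origin-side operand.
#'
#' @param op one of `"product"`, `"deltametric"`, `"ratiometric"`,
#'   `"summetric"`.
#' @param a,b numeric vectors (recycled as usual); `a` is origin-side.
#' @param on_zero_division for the ratiometric operator: `"error"` (default)
#'   stops on a zero divisor, `"skip"` contributes 0 for the offending terms.
#' @return Numeric vector of combined values.
#' @examples
#' apply_operator("product", 2, 3)
#' apply_operator("deltametric", 2, 2)
#' @export
apply_operator <- function(op, a, b, on_zero_division = c("error", "skip")) {
  op <- match.arg(op, AC_OPERATORS)
  switch(op,
    product = a * b,
    deltametric = a - b,
    summetric = a + b,
    ratiometric = {
      on_zero_division <- match.arg(on_zero_division)
      z <- b == 0
      if (any(z)) {
        if (on_zero_division == "error")
          stop("ratiometric autocorrelation over a zero-valued divisor; ",
               "use on_zero_division = \"skip\" to drop such terms")
        out <- a / b
        out[z] <- 0
        return(out)
      }
      a / b
    })
}

# sum `vals` into bins depth 0..D (terms with depth > D are discarded)
sum_by_depth <- function(vals, depth, D) {
  out <- numeric(D + 1L)
  keep <- depth <= D
  if (any(keep)) {
    s <- rowsum(vals[keep], depth[keep])
    out[as.integer(rownames(s)) + 1L] <- s
  }
  out
}

check_origin <- function(g, origin) {
  origin <- match.arg(origin, c("full", "metal_centered"))
  if (origin == "metal_centered" && is.null(g$metal))
    stop("metal-centered origin requested but the graph has no metal center")
  origin
}

#' Atom-atom autocorrelation depth profile
#'
#' For each depth d in 0..`max_depth`, sums `op(p_i, p_j)` over node pairs at
#' shortest-path distance d.  With the full origin, every unordered pair is
#' counted once, the canonical origin-side operand being the node earlier in
#' node order; depth 0 collects one self-term per node.  With the
#' metal-centered origin only pairs rooted at the metal node contribute, and
#' depth 0 is the metal's self-term.
#'
#' @param g a [molecular_graph].
#' @param prop name of a declared atomic property.
#' @param op operator name (see [apply_operator()]).
#' @param origin `"full"` or `"metal_centered"`.
#' @param max_depth maximum depth D (profile has length D + 1).
#' @param on_zero_division passed to [apply_operator()].
#' @return Numeric vector of length `max_depth + 1`, named by depth.
#' @examples
#' g <- molecular_graph(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")),
#'                      data.frame(p = c(1, 2, 3)),
#'                      data.frame(q = c(2, 5)), metal = "B")
#' aa_ac(g, "p", "product", "full", 1)          # 14, 8
#' aa_ac(g, "p", "product", "metal_centered", 1) # 4, 8
#' @export
aa_ac <- function(g, prop, op, origin = "full", max_depth = 3,
                  on_zero_division = "error") {
  origin <- check_origin(g, origin)
  p <- get_atom_prop(g, prop)
  D <- check_depth(max_depth)
  Dm <- atom_distance_matrix(g)
  n <- length(g$nodes)
  if (origin == "full") {
    self <- sum(apply_operator(op, p, p, on_zero_division))
    if (n > 1L) {
      idx <- which(upper.tri(Dm), arr.ind = TRUE)   # row < col = file order
      vals <- apply_operator(op, p[idx[, 1L]], p[idx[, 2L]], on_zero_division)
      out <- sum_by_depth(vals, Dm[idx], D)
    } else out <- numeric(D + 1L)
    out[1L] <- out[1L] + self
  } else {
    m <- node_index(g, g$metal)
    out <- numeric(D + 1L)
    out[1L] <- apply_operator(op, p[m], p[m], on_zero_division)
    j <- setdiff(seq_len(n), m)
    if (length(j))
      out <- out + sum_by_depth(
        apply_operator(op, p[m], p[j], on_zero_division), Dm[m, j], D)
  }
  names(out) <- 0:D
  out
}

#' Bond-bond autocorrelation depth profile
#'
#' Full origin (`merge = "none"`): sums `op(q_e1, q_e2)` over unordered edge
#' pairs at line-graph distance d (origin-side operand = earlier edge in file
#' order); depth 0 collects one self-term per edge.
#'
#' Metal-centered origin: the properties of all metal-ligand bonds are merged
#' into a single "super-bond" by summation (`merge = "sum"`) or averaging
#' (`merge = "mean"`).  Depth 0 is the super-bond self-term; at depth d >= 1
#' the super-bond value is combined with each non-metal bond whose line-graph
#' distance to the nearest metal-ligand bond is d.
#'
#' @inheritParams aa_ac
#' @param prop name of a declared bond property.
#' @param merge `"none"` (full origin) or `"sum"`/`"mean"` (metal-centered).
#' @return Numeric vector of length `max_depth + 1`, named by depth.
#' @export
bb_ac <- function(g, prop, op, origin = "full",
                  merge = if (origin == "full") "none" else "sum",
                  max_depth = 3, on_zero_division = "error") {
  origin <- check_origin(g, origin)
  merge <- match.arg(merge, c("none", "sum", "mean"))
  if (origin == "full" && merge != "none")
    stop("super-bond merging applies only to the metal-centered origin")
  if (origin == "metal_centered" && merge == "none")
    stop("metal-centered bond-bond autocorrelation needs merge \"sum\" or \"mean\"")
  q <- get_bond_prop(g, prop)
  D <- check_depth(max_depth)
  out <- bb_profile(g, q, op, origin, merge, D, on_zero_division)
  names(out) <- 0:D
  out
}

# shared by bb_ac and aabba_two: profile for an arbitrary per-edge vector q
bb_profile <- function(g, q, op, origin, merge, D, on_zero_division) {
  m <- nrow(g$edges)
  Dm <- bond_distance_matrix(g)
  if (origin == "full") {
    out <- numeric(D + 1L)
    if (m > 0L) {
      out[1L] <- sum(apply_operator(op, q, q, on_zero_division))
      if (m > 1L) {
        idx <- which(upper.tri(Dm), arr.ind = TRUE)
        vals <- apply_operator(op, q[idx[, 1L]], q[idx[, 2L]],
                               on_zero_division)
        out <- out + sum_by_depth(vals, Dm[idx], D)
      }
    }
    return(out)
  }
  ml <- metal_edge_indices(g)
  if (length(ml) == 0L)
    stop("metal-centered bond-bond origin: no metal-ligand bonds in graph")
  sb <- if (merge == "sum") sum(q[ml]) else mean(q[ml])
  out <- numeric(D + 1L)
  out[1L] <- apply_operator(op, sb, sb, on_zero_division)
  rest <- setdiff(seq_len(m), ml)
  if (length(rest)) {
    # depth of a non-metal bond: line-graph distance to nearest metal-ligand bond
    depth <- apply(Dm[rest, ml, drop = FALSE], 1L, min)
    out <- out + sum_by_depth(
      apply_operator(op, sb, q[rest], on_zero_division), depth, D)
  }
  out
}

#' Bond-atom autocorrelation depth profile
#'
#' Sums `op(q_e, p_j)` over (bond, atom) pairs whose bond-atom distance (see
#' [bond_atom_distance()]) equals d; the bond-side value is always the first
#' (origin-side) operand.  With the full origin every bond is an origin; with
#' the metal-centered origin only metal-ligand bonds are.
#'
#' @inheritParams aa_ac
#' @param bond_prop name of a declared bond property.
#' @param atom_prop name of a declared atomic property.
#' @return Numeric vector of length `max_depth + 1`, named by depth.
#' @export
ba_ac <- function(g, bond_prop, atom_prop, op, origin = "full",
                  max_depth = 3, on_zero_division = "error") {
  origin <- check_origin(g, origin)
  q <- get_bond_prop(g, bond_prop)
  p <- get_atom_prop(g, atom_prop)
  D <- check_depth(max_depth)
  Dm <- bond_atom_distance_matrix(g)
  edges <- if (origin == "full") seq_len(nrow(g$edges)) else
    metal_edge_indices(g)
  if (origin == "metal_centered" && length(edges) == 0L)
    stop("metal-centered bond-atom origin: no metal-ligand bonds in graph")
  out <- numeric(D + 1L)
  if (length(edges) && length(p)) {
    sub <- Dm[edges, , drop = FALSE]
    ei <- rep(edges, times = ncol(sub))
    ji <- rep(seq_len(ncol(sub)), each = length(edges))
    vals <- apply_operator(op, q[ei], p[ji], on_zero_division)
    out <- sum_by_depth(vals, as.vector(sub), D)
  }
  names(out) <- 0:D
  out
}

get_atom_prop <- function(g, prop) {
  if (!prop %in% names(g$atom_props))
    stop("undeclared atomic property: ", prop)
  g$atom_props[[prop]]
}

get_bond_prop <- function(g, prop) {
  if (!prop %in% names(g$bond_props))
    stop("undeclared bond property: ", prop)
  g$bond_props[[prop]]
}

check_depth <- function(D) {
  if (!is.numeric(D) || length(D) != 1L || D < 0 || D != round(D))
    stop("max_depth must be a single non-negative integer")
  as.integer(D)
}
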