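#' Construct an attributed molecular graph
#'
#' A `molecular_graph` is an undirected, connected graph whose nodes carry a
#' table of real-valued atomic properties and whose edges carry a table of
#' real-valued bond properties.  At most one node may be flagged as the metal
#' center; the flag is required only by metal-centered autocorrelation
#' origins.
#'
#' Node order is significant: it fixes the canonical operand order used by the
#' ordered autocorrelation operators (deltametric, ratiometric) in full-origin
#' mode, and readers preserve file order.
#'
#' @param nodes character vector of unique node identifiers.
#' @param edges two-column matrix (or data.frame) of node identifiers, one row
#'   per undirected edge.  Self-loops and duplicate edges are rejected.
#' @param atom_props data.frame of atomic properties, one row per node, in
#'   node order.  All columns numeric and finite.
#' @param bond_props data.frame of bond properties, one row per edge, in edge
#'   order.  All columns numeric and finite.  Use a zero-column data.frame for
#'   graphs without bond attributes.
#' @param metal optional node identifier of the metal center.
#'
#' @return An object of class `molecular_graph` with fields `nodes`, `edges`
#'   (character matrix), `atom_props`, `bond_props`, `metal`.
#' @examples
#' g <- molecular_graph(
#'   nodes = c("A", "B", "C"),
#'   edges = rbind(c("A", "B"), c("B", "C")),
#'   atom_props = data.frame(p = c(1, 2, 3)),
#'   bond_props = data.frame(q = c(2, 5)),
#'   metal = "B"
#' )
#' atom_distance(g, "A", "C")
#' @export
molecular_graph <- function(nodes, edges, atom_props, bond_props, metal = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node ids: ",
    paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  if (length(nodes) == 0L) stop("graph must have at least one node")
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  }
  if (ncol(edges) != 2L) stop("'edges' must have two columns")
  storage.mode(edges) <- "character"
  unknown <- setdiff(c(edges), nodes)
  if (length(unknown)) stop("edge references unknown node id: ",
    paste(unknown, collapse = ", "))
  if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
  key <- edge_keys(edges, nodes)
  if (anyDuplicated(key)) stop("duplicate edges are not allowed")
  atom_props <- as.data.frame(atom_props)
  bond_props <- as.data.frame(bond_props)
  if (nrow(atom_props) != length(nodes))
    stop("atom_props must have one row per node")
  if (nrow(edges) > 0L && nrow(bond_props) != nrow(edges))
    stop("bond_props must have one row per edge")
  if (nrow(edges) == 0L && nrow(bond_props) != 0L)
    stop("bond_props must have one row per edge")
  check_prop_table(atom_props, nodes, "atomic")
  check_prop_table(bond_props, apply(edges, 1L, paste, collapse = "-"), "bond")
  if (!is.null(metal)) {
    metal <- as.character(metal)
    if (length(metal) != 1L || !(metal %in% nodes))
      stop("metal node '", metal, "' is not a node of the graph")
  }
  g <- structure(
    list(nodes = nodes, edges = edges, atom_props = atom_props,
         bond_props = bond_props, metal = metal,
         cache = new.env(parent = emptyenv())),   # memoized distance matrices
    class = "molecular_graph")
  if (!graph_is_connected(g))
    stop("graph is disconnected; shortest-path depths are undefined")
  g
}

check_prop_table <- function(tab, element_names, what) {
  if (anyDuplicated(names(tab)))
    stop("duplicate ", what, " property names")
  for (nm in names(tab)) {
    v <- tab[[nm]]
    if (!is.numeric(v))
      stop(what, " property '", nm, "' is not numeric")
    bad <- !is.finite(v)
    if (any(bad))
      stop(what, " property '", nm, "' is missing or non-finite for ",
           paste(element_names[bad], collapse = ", "))
  }
  invisible(TRUE)
}

# canonical "i|j" keys with i, j node indices, i < j
edge_keys <- function(edges, nodes) {
  if (nrow(edges) == 0L) return(character())
  u <- match(edges[, 1L], nodes)
  v <- match(edges[, 2L], nodes)
  paste(pmin(u, v), pmax(u, v), sep = "|")
}

as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = length(g$nodes), directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, "name", value = g$nodes)
  if (nrow(g$edges) > 0L)
    ig <- igraph::add_edges(ig, t(matrix(match(g$edges, g$nodes),
                                         ncol = 2L)))
  ig
}

graph_is_connected <- function(g) {
  igraph::is_connected(as_igraph(g))
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("molecular_graph: ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges\n", sep = "")
  cat("  atomic properties: ",
      if (ncol(x$atom_props)) paste(names(x$atom_props), collapse = ", ")
      else "(none)", "\n", sep = "")
  cat("  bond properties:   ",
      if (ncol(x$bond_props)) paste(names(x$bond_props), collapse = ", ")
      else "(none)", "\n", sep = "")
  cat("  metal center:      ",
      if (is.null(x$metal)) "(none)" else x$metal, "\n", sep = "")
  invisible(x)
}

node_index <- function(g, id) {
  i <- match(as.character(id), g$nodes)
  if (anyNA(i)) stop("unknown node id: ",
                     paste(id[is.na(i)], collapse = ", "))
  i
}

edge_index <- function(g, e) {
  e <- as.character(e)
  if (length(e) != 2L) stop("an edge is a pair of node ids")
  key <- edge_keys(matrix(e, ncol = 2L), g$nodes)
  i <- match(key, edge_keys(g$edges, g$nodes))
  if (is.na(i)) stop("unknown edge: ", e[1L], "-", e[2L])
  i
}

#' Shortest-path distances between atoms
#'
#' The autocorrelation depth between two atoms is the number of bonds on a
#' shortest path connecting them; `atom_distance(g, i, i)` is 0.
#'
#' @param g a [molecular_graph].
#' @param i,j node identifiers.
#' @return Non-negative integer distance.
#' @export
atom_distance <- function(g, i, j) {
  D <- atom_distance_matrix(g)
  D[node_index(g, i), node_index(g, j)]
}

graph_cache <- function(g, key, fn) {
  env <- g$cache
  if (is.null(env) || is.null(env[[key]])) {
    val <- fn()
    if (!is.null(env)) env[[key]] <- val
    return(val)
  }
  env[[key]]
}

atom_distance_matrix <- function(g) {
  graph_cache(g, "atom_D", function() {
    D <- igraph::distances(as_igraph(g), algorithm = "unweighted")
    storage.mode(D) <- "integer"
    dimnames(D) <- list(g$nodes, g$nodes)
    D
  })
}

#' Shortest-path distances between bonds
#'
#' Bond-bond depth is the shortest-path distance in the line graph: 0 for a
#' bond with itself, 1 for two bonds sharing an atom.
#'
#' @param g a [molecular_graph].
#' @param e1,e2 edges, each a length-2 vector of node identifiers.
#' @return Non-negative integer distance.
#' @export
bond_distance <- function(g, e1, e2) {
  D <- bond_distance_matrix(g)
  D[edge_index(g, e1), edge_index(g, e2)]
}

# line-graph pairwise distances; m x m for m edges, in edge order
bond_distance_matrix <- function(g) {
  graph_cache(g, "bond_D", function() {
    m <- nrow(g$edges)
    if (m == 0L) return(matrix(integer(), 0L, 0L))
    lg <- igraph::make_line_graph(as_igraph(g))
    D <- igraph::distances(lg, algorithm = "unweighted")
    storage.mode(D) <- "integer"
    D
  })
}

#' Distance from a bond to an atom
#'
#' Bond-atom depth is the smaller of the two endpoint-to-atom distances; an
#' endpoint of the bond itself is at depth 0.
#'
#' @param g a [molecular_graph].
#' @param e an edge (length-2 vector of node identifiers).
#' @param j a node identifier.
#' @return Non-negative integer distance.
#' @export
bond_atom_distance <- function(g, e, j) {
  D <- bond_atom_distance_matrix(g)
  D[edge_index(g, e), node_index(g, j)]
}

# m x n matrix, rows in edge order, cols in node order
bond_atom_distance_matrix <- function(g) {
  graph_cache(g, "ba_D", function() {
    Da <- atom_distance_matrix(g)
    if (nrow(g$edges) == 0L)
      return(matrix(integer(), 0L, length(g$nodes)))
    u <- match(g$edges[, 1L], g$nodes)
    v <- match(g$edges[, 2L], g$nodes)
    D <- pmin(Da[u, , drop = FALSE], Da[v, , drop = FALSE])
    storage.mode(D) <- "integer"
    D
  })
}

# indices (in edge order) of edges incident to the metal node
metal_edge_indices <- function(g) {
  if (is.null(g$metal)) stop("graph has no metal center flagged")
  which(g$edges[, 1L] == g$metal | g$edges[, 2L] == g$metal)
}
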