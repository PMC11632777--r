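#' Read an attributed molecular graph from file
#'
#' Two plain-text formats are supported.  The JSON layout is
#' `{"nodes": [{"id": ..., "props": {...}}, ...],
#'   "edges": [{"u": ..., "v": ..., "props": {...}}, ...],
#'   "metal": id or null}`.
#' GML files use one numeric attribute per property on `node`/`edge` blocks,
#' a `name` attribute for node ids, and a 0/1 `ismetal` node attribute.
#' Node and edge order is the file order and is preserved on round-trip.
#'
#' @param path file to read.
#' @param format `"json"` or `"gml"`; the default guesses from the file
#'   extension.
#' @return A validated [molecular_graph].
#' @seealso [write_graph_file()]
#' @export
read_graph_file <- function(path, format = c("auto", "json", "gml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gml$", path, ignore.case = TRUE)) "gml" else "json"
  }
  if (!file.exists(path)) stop("no such file: ", path)
  switch(format,
         json = read_graph_json(path),
         gml = read_graph_gml(path))
}

#' Write an attributed molecular graph to file
#'
#' @param g a [molecular_graph].
#' @param path destination file.
#' @param format `"json"` or `"gml"` (default guessed from the extension).
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(g, path, format = c("auto", "json", "gml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gml$", path, ignore.case = TRUE)) "gml" else "json"
  }
  switch(format,
         json = write_graph_json(g, path),
         gml = write_graph_gml(g, path))
  invisible(path)
}

read_graph_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$nodes) || length(doc$nodes) == 0L)
    stop("graph JSON has no nodes: ", path)
  ids <- vapply(doc$nodes, function(n) {
    if (is.null(n$id)) stop("node without 'id' in ", path)
    as.character(n$id)
  }, character(1L))
  atom_props <- props_to_frame(lapply(doc$nodes, `[[`, "props"), ids, "node")
  nedge <- length(doc$edges)
  edges <- matrix(character(), ncol = 2L)
  bond_props <- data.frame()
  if (nedge > 0L) {
    edges <- t(vapply(doc$edges, function(e) {
      if (is.null(e$u) || is.null(e$v))
        stop("edge without 'u'/'v' in ", path)
      c(as.character(e$u), as.character(e$v))
    }, character(2L)))
    enames <- paste(edges[, 1L], edges[, 2L], sep = "-")
    bond_props <- props_to_frame(lapply(doc$edges, `[[`, "props"),
                                 enames, "edge")
  }
  metal <- doc$metal
  if (!is.null(metal)) metal <- as.character(metal)
  molecular_graph(ids, edges, atom_props, bond_props, metal)
}

# list of per-element prop lists -> data.frame, erroring on ragged schemas
props_to_frame <- function(plists, element_names, what) {
  keys <- unique(unlist(lapply(plists, names)))
  if (is.null(keys)) keys <- character()
  cols <- lapply(keys, function(k) {
    vapply(seq_along(plists), function(i) {
      v <- plists[[i]][[k]]
      if (is.null(v))
        stop("missing ", what, " property '", k, "' on ", element_names[i])
      if (!is.numeric(v) || length(v) != 1L)
        stop(what, " property '", k, "' on ", element_names[i],
             " is not a scalar number")
      as.numeric(v)
    }, numeric(1L))
  })
  names(cols) <- keys
  if (length(cols) == 0L)
    return(as.data.frame(matrix(nrow = length(plists), ncol = 0L)))
  as.data.frame(cols, optional = TRUE)
}

write_graph_json <- function(g, path) {
  nodes <- lapply(seq_along(g$nodes), function(i) {
    list(id = g$nodes[i], props = as.list(g$atom_props[i, , drop = FALSE]))
  })
  edges <- lapply(seq_len(nrow(g$edges)), function(i) {
    list(u = g$edges[i, 1L], v = g$edges[i, 2L],
         props = as.list(g$bond_props[i, , drop = FALSE]))
  })
  doc <- list(nodes = nodes, edges = edges, metal = g$metal)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
}

read_graph_gml <- function(path) {
  ig <- igraph::read_graph(path, format = "gml")
  va <- igraph::vertex_attr(ig)
  ids <- as.character(va$name)
  if (is.null(va$name)) ids <- as.character(seq_len(igraph::vcount(ig)))
  metal <- NULL
  if (!is.null(va$ismetal)) {
    w <- which(va$ismetal != 0)
    if (length(w) > 1L) stop("more than one metal node in ", path)
    if (length(w) == 1L) metal <- ids[w]
  }
  drop_v <- c("name", "id", "ismetal")
  atom_props <- as.data.frame(va[setdiff(names(va), drop_v)],
                              optional = TRUE)
  if (ncol(atom_props) == 0L)
    atom_props <- as.data.frame(matrix(nrow = length(ids), ncol = 0L))
  el <- igraph::as_edgelist(ig, names = TRUE)
  ea <- igraph::edge_attr(ig)
  bond_props <- as.data.frame(ea, optional = TRUE)
  if (ncol(bond_props) == 0L)
    bond_props <- as.data.frame(matrix(nrow = nrow(el), ncol = 0L))
  molecular_graph(ids, el, atom_props, bond_props, metal)
}

write_graph_gml <- function(g, path) {
  ig <- as_igraph(g)
  for (nm in names(g$atom_props))
    ig <- igraph::set_vertex_attr(ig, nm, value = g$atom_props[[nm]])
  ig <- igraph::set_vertex_attr(ig, "ismetal",
    value = as.integer(!is.null(g$metal) & g$nodes == (g$metal %||% "")))
  for (nm in names(g$bond_props))
    ig <- igraph::set_edge_attr(ig, nm, value = g$bond_props[[nm]])
  igraph::write_graph(ig, path, format = "gml")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a labeled feature matrix with its provenance sidecar
#'
#' The matrix goes to `path` as CSV (header = feature labels, first column
#' `graph_id`); a JSON sidecar `<path>.json` records the property catalog,
#' the specs that produced the columns and, when redundancy removal was
#' applied, the kept/dropped column labels.
#'
#' @param X numeric matrix with column labels and row names.
#' @param path CSV destination.
#' @param meta named list stored verbatim in the sidecar.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(X, path, meta = list()) {
  df <- data.frame(graph_id = rownames(X) %||% as.character(seq_len(nrow(X))),
                   X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(c(list(labels = colnames(X)), meta),
                       paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path CSV file.
#' @return Numeric matrix with labels as column names, graph ids as row names,
#'   with the sidecar (if present) attached as attribute `"meta"`.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  X <- as.matrix(df[, -1L, drop = FALSE])
  rownames(X) <- as.character(df[[1L]])
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    attr(X, "meta") <- jsonlite::fromJSON(sidecar, simplifyVector = TRUE)
  X
}
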