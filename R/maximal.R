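#' Specs for the maximal-dimensionality AABBA(I) vector
#'
#' Enumerates every autocorrelation block of the maximal representation:
#' kernels AA, BB, BBm (averaged super-bond) and BA, full and metal-centered
#' origins, all four operators, depths 0 to `max_depth` (default 6).  The
#' order is deterministic (kernel, then origin F/M, then operator, then
#' property in catalog order, then depth) so that feature positions are
#' stable across runs and saved models stay valid.
#'
#' @param catalog a [property_catalog].
#' @param has_metal if `FALSE`, only full-origin blocks are produced (and the
#'   BBm kernel, which is metal-centered by definition, is omitted).
#' @param max_depth maximum depth for every block.
#' @param operators operator subset, in the order used.
#' @param on_zero_division passed down to the kernels.
#' @return List of [autocorr_spec] objects.
#' @export
maximal_specs <- function(catalog, has_metal = TRUE, max_depth = 6,
                          operators = AC_OPERATORS,
                          on_zero_division = "error") {
  stopifnot(inherits(catalog, "property_catalog"))
  ap <- catalog$atom_property_names
  bp <- catalog$bond_property_names
  ba_pairs <- NULL
  if (length(ap) && length(bp))
    ba_pairs <- unlist(lapply(bp, function(b) lapply(ap, function(a) c(b, a))),
                       recursive = FALSE)
  origins <- if (has_metal) c("full", "metal_centered") else "full"
  specs <- list()
  for (kernel in AC_KERNELS) {
    props <- switch(kernel, AA = ap, BB = bp, BBm = bp, BA = ba_pairs)
    if (length(props) == 0L) next
    orgs <- if (kernel == "BBm") intersect("metal_centered", origins)
            else origins
    for (org in orgs)
      for (op in operators)
        specs[[length(specs) + 1L]] <-
          autocorr_spec(kernel, props, op, org, max_depth, on_zero_division)
  }
  specs
}

#' Maximal-dimensionality AABBA(I) fingerprint of one graph
#'
#' The concatenation of every block enumerated by [maximal_specs()]; this is
#' the representation fed to the gradient-boosting relevance analysis before
#' redundancy removal.  Its length is
#' `sum over blocks of |properties| * (max_depth + 1)`.
#'
#' @param g a [molecular_graph].
#' @param catalog a [property_catalog]; defaults to the graph's own declared
#'   properties.
#' @param max_depth maximum depth (default 6).
#' @param include_whole_graph append whole-graph summary dimensions (node and
#'   edge counts, per-property sums) labeled `wg_*`.
#' @param ... passed to [maximal_specs()].
#' @return Named numeric vector.
#' @export
maximal_vector <- function(g, catalog = NULL, max_depth = 6,
                           include_whole_graph = FALSE, ...) {
  if (is.null(catalog))
    catalog <- property_catalog(names(g$atom_props), names(g$bond_props))
  specs <- maximal_specs(catalog, has_metal = !is.null(g$metal),
                         max_depth = max_depth, ...)
  v <- aabba_one(g, specs)
  if (include_whole_graph) v <- c(v, whole_graph_props(g, catalog))
  v
}

# optional whole-graph block: counts and property sums
whole_graph_props <- function(g, catalog) {
  out <- c(wg_natoms = length(g$nodes), wg_nbonds = nrow(g$edges))
  for (pr in catalog$atom_property_names)
    out[paste0("wg_sum_", pr)] <- sum(get_atom_prop(g, pr))
  for (pr in catalog$bond_property_names)
    out[paste0("wg_sum_", pr)] <- sum(get_bond_prop(g, pr))
  out
}

#' Featurize a set of graphs into a labeled feature matrix
#'
#' @param graphs list of [molecular_graph] objects.
#' @param specs list of [autocorr_spec] objects, or `NULL` to use the maximal
#'   representation over `catalog`.
#' @param catalog needed when `specs` is `NULL`; defaults to the properties
#'   of the first graph.
#' @param max_depth maximal-representation depth when `specs` is `NULL`.
#' @param ... passed to [maximal_vector()] when `specs` is `NULL`.
#' @return Numeric matrix, one row per graph (row names = list names or
#'   indices), columns labeled by the grammar of [format_label()].
#' @export
featurize_graphs <- function(graphs, specs = NULL, catalog = NULL,
                             max_depth = 6, ...) {
  stopifnot(length(graphs) > 0L)
  rows <- lapply(graphs, function(g) {
    if (is.null(specs)) maximal_vector(g, catalog, max_depth, ...)
    else aabba_one(g, specs)
  })
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L)
    stop("graphs yield fingerprints of different lengths; ",
         "use a shared catalog and consistent metal flags")
  X <- do.call(rbind, rows)
  rownames(X) <- names(graphs) %||% as.character(seq_along(graphs))
  X
}

#' Remove redundant fingerprint dimensions across a dataset
#'
#' Drops columns that are constant over the dataset and columns that are
#' exact duplicates of an earlier column (first occurrence kept).  "Exact"
#' means equality after canonical rounding to 12 significant digits, so the
#' operation is reproducible across platforms.  Column order is otherwise
#' preserved, and the operation is idempotent.
#'
#' @param X numeric matrix with column labels (>= 2 rows).
#' @return List with `X` (the reduced matrix), `kept`, `dropped` (labels),
#'   and `duplicate_of` (named character vector mapping each dropped
#'   duplicate to the kept column it equals; constants map to `NA`).
#' @export
remove_redundant <- function(X) {
  stopifnot(is.matrix(X), nrow(X) >= 2L, !is.null(colnames(X)))
  R <- signif(X, 12L)
  keys <- apply(R, 2L, paste, collapse = "\r")
  constant <- apply(R, 2L, function(col) all(col == col[1L]))
  dup_first <- match(keys, keys)          # index of first identical column
  is_dup <- !constant & dup_first < seq_along(keys) & !constant[dup_first]
  keep <- !constant & !is_dup
  duplicate_of <- character(0L)
  if (any(!keep)) {
    duplicate_of <- ifelse(constant[!keep], NA_character_,
                           colnames(X)[dup_first[!keep]])
    names(duplicate_of) <- colnames(X)[!keep]
  }
  list(X = X[, keep, drop = FALSE],
       kept = colnames(X)[keep],
       dropped = colnames(X)[!keep],
       duplicate_of = duplicate_of)
}
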