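#' Recipe for merging atom and bond properties onto edges (AABBA(II))
#'
#' AABBA(II) attaches to every edge a single property vector combining the
#' endpoint atomic properties with the bond properties, and then
#' autocorrelates that vector exactly like a bond-bond kernel.  A recipe
#' names the ingredients:
#'
#' * `mean_props` — atomic properties merged as the endpoint mean,
#' * `absdiff_props` — atomic properties merged as the absolute endpoint
#'   difference (the natural encoding of bond polarity for
#'   electronegativity-like properties); component named `<prop>_diff`,
#' * `geometry` — `"bond"` carries the bond property `geometry_prop`
#'   (e.g. an optimized bond distance), `"radius_sum"` uses the sum of the
#'   endpoint values of the atomic property `geometry_prop` (e.g. covalent
#'   radii, making the fingerprint geometry-agnostic), `"none"` omits the
#'   component; component named `geom`,
#' * `bond_props` — bond properties carried through unchanged.
#'
#' @param mean_props,absdiff_props,bond_props character vectors of property
#'   names (may be empty).
#' @param geometry `"none"`, `"bond"` or `"radius_sum"`.
#' @param geometry_prop property name used by the geometry component.
#' @return An object of class `merge_recipe`.
#' @seealso [aabba2_variant()] for the shipped numbered variants.
#' @export
merge_recipe <- function(mean_props = character(), absdiff_props = character(),
                         geometry = c("none", "bond", "radius_sum"),
                         geometry_prop = NULL, bond_props = character()) {
  geometry <- match.arg(geometry)
  if (geometry != "none" && is.null(geometry_prop))
    stop("geometry component '", geometry, "' needs geometry_prop")
  if (length(mean_props) + length(absdiff_props) + length(bond_props) == 0L &&
      geometry == "none")
    stop("empty merge recipe")
  structure(list(mean_props = as.character(mean_props),
                 absdiff_props = as.character(absdiff_props),
                 geometry = geometry, geometry_prop = geometry_prop,
                 bond_props = as.character(bond_props)),
            class = "merge_recipe")
}

#' Shipped AABBA(II) variant recipes
#'
#' Five numbered variants are provided as defaults; they differ in the
#' electronegativity and geometry components (variants 1-3) or in the subset
#' of properties selected (variants 4-5, intended for electronic-structure
#' catalogs).  The exact compositions are package conventions, configurable
#' through [merge_recipe()]:
#'
#' * `II1`: all atomic properties by endpoint mean, the `eneg_prop` also as an
#'   absolute difference, geometry = the bond property `distance_prop`, plus
#'   the remaining bond properties.
#' * `II2`: as `II1` without the geometry component.
#' * `II3`: as `II1` with geometry = sum of endpoint `radius_prop` values
#'   (geometry-agnostic).
#' * `II4`: all atomic properties by endpoint mean plus all bond properties.
#' * `II5`: the first half of the atomic properties (catalog order) by mean,
#'   plus all bond properties.
#'
#' @param variant `"II1"` to `"II5"`.
#' @param catalog a [property_catalog].
#' @param eneg_prop,radius_prop atomic property names for the
#'   electronegativity-like and covalent-radius-like components (variants
#'   1-3); defaults taken from the catalog when it contains properties named
#'   `eneg`/`radius`.
#' @param distance_prop bond property name for the geometry component of
#'   `II1` (default: first bond property).
#' @return A [merge_recipe].
#' @export
aabba2_variant <- function(variant = c("II1", "II2", "II3", "II4", "II5"),
                           catalog,
                           eneg_prop = intersect("eneg", catalog$atom_property_names)[1L],
                           radius_prop = intersect("radius", catalog$atom_property_names)[1L],
                           distance_prop = catalog$bond_property_names[1L]) {
  variant <- match.arg(variant)
  stopifnot(inherits(catalog, "property_catalog"))
  ap <- catalog$atom_property_names
  bp <- catalog$bond_property_names
  if (variant %in% c("II4", "II5")) {
    sel <- if (variant == "II4") ap else ap[seq_len(ceiling(length(ap) / 2))]
    return(merge_recipe(mean_props = sel, bond_props = bp))
  }
  if (is.na(eneg_prop) || is.na(radius_prop))
    stop("variants II1-II3 need eneg_prop and radius_prop")
  geom <- switch(variant,
                 II1 = list(type = "bond", prop = distance_prop),
                 II2 = list(type = "none", prop = NULL),
                 II3 = list(type = "radius_sum", prop = radius_prop))
  merge_recipe(mean_props = ap,
               absdiff_props = eneg_prop,
               geometry = geom$type, geometry_prop = geom$prop,
               bond_props = setdiff(bp, if (identical(geom$type, "bond"))
                 geom$prop else NULL))
}

#' Merge endpoint atomic properties and bond properties per edge
#'
#' @param g a [molecular_graph].
#' @param recipe a [merge_recipe] (or a variant name, resolved against the
#'   graph's own properties via [aabba2_variant()]).
#' @return Numeric matrix, one row per edge (edge order), one named column
#'   per merged component.
#' @export
merge_edge_properties <- function(g, recipe) {
  if (is.character(recipe))
    recipe <- aabba2_variant(recipe, property_catalog(
      names(g$atom_props), names(g$bond_props)))
  stopifnot(inherits(recipe, "merge_recipe"))
  u <- match(g$edges[, 1L], g$nodes)
  v <- match(g$edges[, 2L], g$nodes)
  cols <- list()
  for (pr in recipe$mean_props) {
    p <- get_atom_prop(g, pr)
    cols[[pr]] <- (p[u] + p[v]) / 2
  }
  for (pr in recipe$absdiff_props) {
    p <- get_atom_prop(g, pr)
    cols[[paste0(pr, "_diff")]] <- abs(p[u] - p[v])
  }
  if (recipe$geometry == "bond") {
    cols[["geom"]] <- get_bond_prop(g, recipe$geometry_prop)
  } else if (recipe$geometry == "radius_sum") {
    p <- get_atom_prop(g, recipe$geometry_prop)
    cols[["geom"]] <- p[u] + p[v]
  }
  for (pr in recipe$bond_props) cols[[pr]] <- get_bond_prop(g, pr)
  if (anyDuplicated(names(cols)))
    stop("merge recipe produces duplicate component names: ",
         paste(unique(names(cols)[duplicated(names(cols))]), collapse = ", "))
  out <- do.call(cbind, cols)
  if (nrow(g$edges) == 0L)
    out <- matrix(numeric(), 0L, length(cols), dimnames = list(NULL, names(cols)))
  out
}

#' AABBA(II) fingerprint
#'
#' Merges atom and bond properties onto every edge (see
#' [merge_edge_properties()]) and autocorrelates the merged vector
#' component-wise with the bond-bond kernel, including super-bond merging for
#' the metal-centered origin.  This yields the final fingerprint directly,
#' without block concatenation.
#'
#' @param g a [molecular_graph].
#' @param recipe a [merge_recipe] or variant name (`"II1"`..`"II5"`).
#' @param op operator name (see [apply_operator()]).
#' @param origin `"full"` or `"metal_centered"`.
#' @param merge super-bond merge for the metal-centered origin (`"sum"` or
#'   `"mean"`); ignored for the full origin.
#' @param max_depth maximum depth.
#' @param on_zero_division passed to [apply_operator()].
#' @return Named numeric vector of length `n_components * (max_depth + 1)`.
#' @export
aabba_two <- function(g, recipe, op, origin = "metal_centered",
                      merge = "sum", max_depth = 3,
                      on_zero_division = "error") {
  merged <- merge_edge_properties(g, recipe)
  g2 <- g
  g2$bond_props <- as.data.frame(merged)
  if (nrow(g$edges) == 0L)
    g2$bond_props <- as.data.frame(matrix(nrow = 0L, ncol = ncol(merged),
      dimnames = list(NULL, colnames(merged))))
  kernel <- if (origin == "full") "BB" else if (merge == "mean") "BBm" else "BB"
  spec <- autocorr_spec(kernel, colnames(merged), op, origin,
                        max_depth, on_zero_division)
  compute_block(g2, spec)
}
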