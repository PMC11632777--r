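#' Declare a property catalog
#'
#' A catalog fixes the atomic and bond property names and their order, which
#' in turn fixes the feature order of every fingerprint built from it.  The
#' paper-style catalogs ("generic" periodic-table properties, NBO electronic
#' properties) are user-supplied; [synth_catalog()] ships the catalog used by
#' the synthetic generator.
#'
#' @param atom_property_names ordered character vector (may be empty).
#' @param bond_property_names ordered character vector (may be empty).
#' @param catalog_id `"generic"`, `"nbo"` or `"custom"`.
#' @return An object of class `property_catalog`.
#' @export
property_catalog <- function(atom_property_names, bond_property_names,
                             catalog_id = c("custom", "generic", "nbo")) {
  catalog_id <- match.arg(catalog_id)
  atom_property_names <- as.character(atom_property_names)
  bond_property_names <- as.character(bond_property_names)
  if (anyDuplicated(atom_property_names) || anyDuplicated(bond_property_names))
    stop("property names must be unique within a catalog")
  if (length(atom_property_names)) check_prop_name(atom_property_names)
  if (length(bond_property_names)) check_prop_name(bond_property_names)
  structure(list(atom_property_names = atom_property_names,
                 bond_property_names = bond_property_names,
                 catalog_id = catalog_id),
            class = "property_catalog")
}

#' Declare one autocorrelation block
#'
#' An `autocorr_spec` describes a contiguous block of fingerprint dimensions:
#' one kernel, one operator, one origin, one or more properties, depths 0 to
#' `max_depth`.  For the BA kernel, `properties` is a list of
#' `c(bond, atom)` pairs (or a single pair).
#'
#' @param kernel `"AA"`, `"BB"`, `"BBm"` or `"BA"`.
#' @param properties character vector of property names, or for `"BA"` a list
#'   of length-2 character vectors `c(bond_prop, atom_prop)`.
#' @param op operator name (see [apply_operator()]).
#' @param origin `"full"` or `"metal_centered"`.  `"BBm"` requires the
#'   metal-centered origin (it is defined via the averaged super-bond).
#' @param max_depth maximum depth.
#' @param on_zero_division passed to [apply_operator()].
#' @return An object of class `autocorr_spec`.
#' @export
autocorr_spec <- function(kernel, properties, op, origin = "full",
                          max_depth = 3, on_zero_division = "error") {
  kernel <- match.arg(kernel, AC_KERNELS)
  op <- match.arg(op, AC_OPERATORS)
  origin <- match.arg(origin, c("full", "metal_centered"))
  if (kernel == "BBm" && origin != "metal_centered")
    stop("kernel \"BBm\" implies the metal-centered origin")
  if (kernel == "BA") {
    if (is.character(properties) && length(properties) == 2L)
      properties <- list(properties)
    if (!is.list(properties) ||
        !all(vapply(properties, function(p)
          is.character(p) && length(p) == 2L, logical(1L))))
      stop("BA properties must be c(bond, atom) pairs")
  } else {
    properties <- as.character(properties)
  }
  if (length(properties) == 0L)
    stop("an autocorrelation block needs at least one property")
  structure(list(kernel = kernel, properties = properties, op = op,
                 origin = origin, max_depth = check_depth(max_depth),
                 on_zero_division = on_zero_division),
            class = "autocorr_spec")
}

#' Compute one labeled fingerprint block
#'
#' Concatenates, property by property, the depth profiles of the kernel named
#' in `spec`; the result has `|properties| * (max_depth + 1)` labeled entries.
#'
#' @param g a [molecular_graph].
#' @param spec an [autocorr_spec].
#' @return Named numeric vector; names follow the label grammar of
#'   [format_label()].
#' @export
compute_block <- function(g, spec) {
  stopifnot(inherits(spec, "autocorr_spec"))
  D <- spec$max_depth
  blocks <- lapply(spec$properties, function(pr) {
    prof <- switch(spec$kernel,
      AA = aa_ac(g, pr, spec$op, spec$origin, D, spec$on_zero_division),
      BB = bb_ac(g, pr, spec$op, spec$origin,
                 merge = if (spec$origin == "full") "none" else "sum",
                 D, spec$on_zero_division),
      BBm = bb_ac(g, pr, spec$op, "metal_centered", merge = "mean",
                  D, spec$on_zero_division),
      BA = ba_ac(g, pr[1L], pr[2L], spec$op, spec$origin, D,
                 spec$on_zero_division))
    lab <- if (spec$kernel == "BA") paste(pr[1L], pr[2L], sep = ".") else pr
    names(prof) <- vapply(0:D, function(d)
      format_label(lab, d, spec$origin, spec$op, spec$kernel), character(1L))
    prof
  })
  unlist(blocks)
}

#' Assemble an AABBA(I) fingerprint
#'
#' Concatenates the blocks of `specs` in order into one labeled vector: the
#' AABBA(I) representation when the specs cover the atom-atom, bond-bond
#' (summed and averaged super-bond) and bond-atom kernels, or any subset of
#' it otherwise.
#'
#' @param g a [molecular_graph].
#' @param specs list of [autocorr_spec] objects (at least one).
#' @return Named numeric vector; an error is raised if two blocks would yield
#'   the same label.
#' @export
aabba_one <- function(g, specs) {
  if (inherits(specs, "autocorr_spec")) specs <- list(specs)
  if (length(specs) == 0L) stop("need at least one autocorr_spec")
  v <- unlist(lapply(specs, function(s) compute_block(g, s)))
  if (anyDuplicated(names(v)))
    stop("duplicate feature labels across blocks: ",
         paste(unique(names(v)[duplicated(names(v))]), collapse = ", "))
  v
}
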