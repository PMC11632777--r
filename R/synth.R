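#' Property catalog used by the synthetic generator
#'
#' Synthetic stand-ins shaped like a generic chemistry catalog (not real
#' chemistry): atomic properties `znum` (integer, atomic-number-like),
#' `eneg` (positive real, electronegativity-like) and `radius` (positive
#' real, covalent-radius-like); bond properties `blen` (distance-like) and
#' `border` (bond-order-like).  All values are strictly positive so that
#' every operator, including the ratiometric, is defined.
#'
#' @return A [property_catalog].
#' @export
synth_catalog <- function() {
  property_catalog(c("znum", "eneg", "radius"), c("blen", "border"),
                   catalog_id = "custom")
}

#' Configuration for the synthetic graph generator
#'
#' Describes a family of metal-complex-like graphs: one metal hub per graph
#' with `n_ligands` tree-shaped ligand branches of bounded depth, and
#' property values drawn from per-property distributions.
#'
#' @param n_graphs number of graphs.
#' @param n_ligands integer range `c(min, max)` of ligand branches per metal.
#' @param ligand_size integer range `c(min, max)` of atoms per ligand branch.
#' @param max_ligand_depth maximum distance (in bonds) from a ligand atom to
#'   the atom of its branch that binds the metal.
#' @param atom_dists,bond_dists named lists of distribution specs, one per
#'   catalog property: `list(dist = "uniform", min =, max =)` or
#'   `list(dist = "normal", mean =, sd =)`.  `znum` is rounded to an
#'   integer.  Defaults give strictly positive values.
#' @param metal_atom_dists overrides for the metal node's atomic properties
#'   (the metal is heavier and larger than the ligand atoms).
#' @param seed integer seed; a fixed seed makes the generated dataset
#'   byte-identical across runs.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_graphs = 100L,
                         n_ligands = c(4L, 6L),
                         ligand_size = c(1L, 6L),
                         max_ligand_depth = 3L,
                         atom_dists = list(
                           znum = list(dist = "uniform", min = 5, max = 18),
                           eneg = list(dist = "uniform", min = 1.8, max = 3.6),
                           radius = list(dist = "uniform", min = 0.4, max = 1.1)),
                         bond_dists = list(
                           blen = list(dist = "uniform", min = 1.0, max = 2.4),
                           border = list(dist = "uniform", min = 0.6, max = 3.0)),
                         metal_atom_dists = list(
                           znum = list(dist = "uniform", min = 40, max = 80),
                           eneg = list(dist = "uniform", min = 1.2, max = 2.4),
                           radius = list(dist = "uniform", min = 1.2, max = 1.7)),
                         seed = 1L) {
  stopifnot(n_graphs >= 1L, length(n_ligands) == 2L, n_ligands[1L] >= 1L,
            n_ligands[2L] >= n_ligands[1L], length(ligand_size) == 2L,
            ligand_size[1L] >= 1L, ligand_size[2L] >= ligand_size[1L],
            max_ligand_depth >= 1L)
  for (d in c(atom_dists, bond_dists, metal_atom_dists)) check_dist(d)
  if (!setequal(names(atom_dists), names(metal_atom_dists)))
    stop("metal_atom_dists must cover the same properties as atom_dists")
  structure(list(n_graphs = as.integer(n_graphs),
                 n_ligands = as.integer(n_ligands),
                 ligand_size = as.integer(ligand_size),
                 max_ligand_depth = as.integer(max_ligand_depth),
                 atom_dists = atom_dists, bond_dists = bond_dists,
                 metal_atom_dists = metal_atom_dists,
                 seed = as.integer(seed)),
            class = "synth_config")
}

check_dist <- function(d) {
  if (!is.list(d) || is.null(d$dist)) stop("malformed distribution spec")
  if (d$dist == "uniform") {
    if (is.null(d$min) || is.null(d$max) || d$min > d$max)
      stop("uniform distribution needs min <= max")
  } else if (d$dist == "normal") {
    if (is.null(d$mean) || is.null(d$sd) || d$sd < 0)
      stop("normal distribution needs mean and sd >= 0")
  } else stop("unknown distribution: ", d$dist)
  invisible(TRUE)
}

draw_dist <- function(d, n) {
  switch(d$dist,
         uniform = stats::runif(n, d$min, d$max),
         normal = stats::rnorm(n, d$mean, d$sd))
}

#' Generate a set of synthetic metal-complex-like graphs
#'
#' Each graph is a star of ligand subtrees around a single metal node: the
#' metal binds the root atom of every ligand branch, and each branch is a
#' random tree whose atoms stay within `max_ligand_depth` bonds of the root.
#' Properties are drawn independently per atom/bond from the configured
#' distributions.  Output is reproducible: the same config (including seed)
#' yields identical graphs.
#'
#' @param cfg a [synth_config].
#' @return Named list of [molecular_graph] objects (`g1`, `g2`, ...).
#' @export
generate_graphs <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    out <- lapply(seq_len(cfg$n_graphs), function(i) synth_one_graph(cfg))
    names(out) <- paste0("g", seq_len(cfg$n_graphs))
    out
  })
}

# sample one value from an inclusive integer range (safe for min == max)
sample_range <- function(lo, hi) {
  if (lo == hi) return(lo)
  sample(lo:hi, 1L)
}

synth_one_graph <- function(cfg) {
  nlig <- sample_range(cfg$n_ligands[1L], cfg$n_ligands[2L])
  parent <- integer(0)          # parent index per non-metal atom; 0 = metal
  depth <- integer(0)           # bonds from the branch root
  branch <- integer(0)
  for (b in seq_len(nlig)) {
    size <- sample_range(cfg$ligand_size[1L], cfg$ligand_size[2L])
    root <- length(parent) + 1L
    parent <- c(parent, 0L); depth <- c(depth, 0L); branch <- c(branch, b)
    for (k in seq_len(size - 1L)) {
      cand <- which(branch == b & depth < cfg$max_ligand_depth)
      at <- if (length(cand) == 1L) cand else sample(cand, 1L)
      parent <- c(parent, at)
      depth <- c(depth, depth[at] + 1L)
      branch <- c(branch, b)
    }
  }
  n_atoms <- length(parent)
  nodes <- c("M1", paste0("a", seq_len(n_atoms)))
  edges <- cbind(ifelse(parent == 0L, "M1", paste0("a", parent)),
                 paste0("a", seq_len(n_atoms)))
  atom_props <- as.data.frame(lapply(cfg$atom_dists, draw_dist, n = n_atoms))
  metal_props <- as.data.frame(lapply(
    cfg$metal_atom_dists[names(cfg$atom_dists)], draw_dist, n = 1L))
  atom_props <- rbind(metal_props, atom_props)
  if ("znum" %in% names(atom_props))
    atom_props$znum <- round(atom_props$znum)
  bond_props <- as.data.frame(lapply(cfg$bond_dists, draw_dist, n = n_atoms))
  molecular_graph(nodes, edges, atom_props, bond_props, metal = "M1")
}

#' Default planted-target recipe for the synthetic benchmark
#'
#' Two informative fingerprint dimensions, one atom-atom and one averaged
#' super-bond bond-bond term, with weights that give the two contributions
#' comparable variance under [synth_config()] defaults.
#'
#' @return data.frame with columns `label` and `weight`.
#' @export
synth_recipe <- function() {
  data.frame(label = c("znum-1_MA_AA", "blen-0_MS_BBm"),
             weight = c(0.001, 3),
             stringsAsFactors = FALSE)
}

#' Planted regression targets for a set of graphs
#'
#' `y = sum_k weight_k * feature_k(graph) + N(0, noise_sd)`, where each
#' feature label is parsed with [parse_label()] and computed on the graph.
#' The noiseless signal is returned alongside for recovery tests.
#'
#' @param graphs list of [molecular_graph] objects.
#' @param recipe data.frame with columns `label`, `weight`.
#' @param noise_sd Gaussian noise standard deviation (absolute).
#' @param noise_frac alternatively, noise as a fraction of the signal's
#'   standard deviation across graphs (overrides `noise_sd`).
#' @param seed integer seed for the noise draw.
#' @return data.frame with columns `graph_id`, `y`, `signal`, plus attribute
#'   `"noise_sd"` (the absolute value used).
#' @export
generate_targets <- function(graphs, recipe = synth_recipe(), noise_sd = 0,
                             noise_frac = NULL, seed = 1L) {
  stopifnot(is.data.frame(recipe), all(c("label", "weight") %in% names(recipe)))
  F <- features_by_label(graphs, recipe$label)
  signal <- as.vector(F %*% recipe$weight)
  if (!is.null(noise_frac)) noise_sd <- noise_frac * stats::sd(signal)
  y <- signal + with_seed(seed, stats::rnorm(length(signal), 0, noise_sd))
  out <- data.frame(graph_id = rownames(F), y = y, signal = signal,
                    stringsAsFactors = FALSE)
  attr(out, "noise_sd") <- noise_sd
  out
}

# evaluate specific labeled fingerprint dimensions on every graph
features_by_label <- function(graphs, labels) {
  cols <- lapply(labels, function(lab) {
    d <- parse_label(lab)
    vapply(graphs, function(g) {
      prof <- switch(d$kernel,
        AA = aa_ac(g, d$prop, d$op, d$origin, d$depth),
        BB = bb_ac(g, d$prop, d$op, d$origin,
                   merge = if (d$origin == "full") "none" else "sum",
                   max_depth = d$depth),
        BBm = bb_ac(g, d$prop, d$op, "metal_centered", merge = "mean",
                    max_depth = d$depth),
        BA = ba_ac(g, d$bond_prop, d$atom_prop, d$op, d$origin, d$depth))
      prof[[d$depth + 1L]]
    }, numeric(1L))
  })
  F <- do.call(cbind, cols)
  colnames(F) <- labels
  rownames(F) <- names(graphs) %||% as.character(seq_along(graphs))
  F
}

#' Write a synthetic dataset to disk
#'
#' Writes one graph JSON per graph, a `targets.csv` and a `manifest.json`
#' capturing the full configuration and seeds, so the dataset can be
#' regenerated from the manifest alone.
#'
#' @param dir output directory (created if needed).
#' @param cfg a [synth_config].
#' @param recipe,noise_sd,noise_frac,target_seed passed to
#'   [generate_targets()].
#' @param format graph file format, `"json"` or `"gml"`.
#' @return The directory path, invisibly.
#' @export
write_synth_dataset <- function(dir, cfg, recipe = synth_recipe(),
                                noise_sd = 0, noise_frac = NULL,
                                target_seed = cfg$seed + 1L,
                                format = c("json", "gml")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  graphs <- generate_graphs(cfg)
  for (nm in names(graphs))
    write_graph_file(graphs[[nm]], file.path(dir, paste0(nm, ".", format)),
                     format)
  targets <- generate_targets(graphs, recipe, noise_sd, noise_frac,
                              target_seed)
  utils::write.csv(targets, file.path(dir, "targets.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(config = unclass(cfg), recipe = recipe,
         noise_sd = attr(targets, "noise_sd"), target_seed = target_seed,
         format = format, n_graphs = length(graphs)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
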