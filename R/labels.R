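AC_KERNELS <- c("AA", "BB", "BBm", "BA")
ORIGIN_CODES <- c(full = "F", metal_centered = "M")

#' Format and parse feature labels
#'
#' Every fingerprint dimension is labeled
#' `<prop>-<depth>_<origin><op>_<kernel>` where origin is `M`
#' (metal-centered) or `F` (full), the operator code is `A` (product,
#' i.e. the classical autocorrelation), `D` (deltametric), `R` (ratiometric)
#' or `S` (summetric), and the kernel is `AA`, `BB`, `BBm` (averaged
#' super-bond bond-bond, rendered "BB-bar" in reports) or `BA`.  Bond-atom
#' blocks cross a bond property with an atomic property; their property field
#' is `<bond>.<atom>`.  `Z-2_FA_AA`, for example, is the full atom-atom
#' autocorrelation of property `Z` at depth 2.
#'
#' `parse_label(format_label(x))` recovers `x` exactly.
#'
#' @param prop property name (or `<bond>.<atom>` pair for the BA kernel).
#' @param depth non-negative integer depth.
#' @param origin `"full"` or `"metal_centered"`.
#' @param op operator name (see [apply_operator()]).
#' @param kernel `"AA"`, `"BB"`, `"BBm"` or `"BA"`.
#' @return `format_label()`: a string.  `parse_label()`: a list with fields
#'   `prop`, `depth`, `origin`, `op`, `kernel` (plus `bond_prop`/`atom_prop`
#'   for BA labels).
#' @examples
#' format_label("Z", 2, "full", "product", "AA")   # "Z-2_FA_AA"
#' parse_label("q_Nat-1_MR_BA")
#' @export
format_label <- function(prop, depth, origin, op, kernel) {
  kernel <- match.arg(kernel, AC_KERNELS)
  op <- match.arg(op, AC_OPERATORS)
  origin <- match.arg(origin, names(ORIGIN_CODES))
  check_prop_name(sub("\\.", "", prop))
  if (kernel == "BBm" && origin != "metal_centered")
    stop("the averaged super-bond kernel (BBm) is metal-centered by definition")
  paste0(prop, "-", check_depth(depth), "_",
         ORIGIN_CODES[[origin]], OP_CODES[[op]], "_", kernel)
}

#' @rdname format_label
#' @param label a label string to parse.
#' @export
parse_label <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  parts <- strsplit(label, "_", fixed = TRUE)[[1L]]
  if (length(parts) < 3L)
    stop("malformed feature label '", label,
         "': expected <prop>-<depth>_<origin><op>_<kernel>")
  kernel <- parts[length(parts)]
  oo <- parts[length(parts) - 1L]
  head <- paste(parts[seq_len(length(parts) - 2L)], collapse = "_")
  if (!kernel %in% AC_KERNELS)
    stop("malformed feature label '", label, "': unknown kernel '", kernel,
         "' at position ", nchar(label) - nchar(kernel) + 1L)
  if (nchar(oo) != 2L)
    stop("malformed feature label '", label,
         "': origin/operator field '", oo, "' must be two characters")
  origin <- names(ORIGIN_CODES)[match(substr(oo, 1L, 1L), ORIGIN_CODES)]
  op <- names(OP_CODES)[match(substr(oo, 2L, 2L), OP_CODES)]
  if (is.na(origin))
    stop("malformed feature label '", label, "': unknown origin code '",
         substr(oo, 1L, 1L), "'")
  if (is.na(op))
    stop("malformed feature label '", label, "': unknown operator code '",
         substr(oo, 2L, 2L), "'")
  dash <- regexpr("-(?=[0-9]+$)", head, perl = TRUE)
  if (dash < 0L)
    stop("malformed feature label '", label,
         "': no '-<depth>' suffix in '", head, "'")
  prop <- substr(head, 1L, dash - 1L)
  depth <- as.integer(substr(head, dash + 1L, nchar(head)))
  out <- list(prop = prop, depth = depth, origin = origin, op = op,
              kernel = kernel)
  if (kernel == "BA") {
    bits <- strsplit(prop, ".", fixed = TRUE)[[1L]]
    if (length(bits) != 2L)
      stop("malformed BA label '", label,
           "': property field must be <bond>.<atom>")
    out$bond_prop <- bits[1L]
    out$atom_prop <- bits[2L]
  }
  out
}

# property names must survive the label grammar: no "-", "_"-safe, ASCII
check_prop_name <- function(nm) {
  ok <- grepl("^[A-Za-z][A-Za-z0-9_]*$", nm)
  if (!all(ok))
    stop("property name(s) not usable in feature labels ",
         "(letters, digits, '_', starting with a letter): ",
         paste(nm[!ok], collapse = ", "))
  invisible(nm)
}
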