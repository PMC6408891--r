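#' Parse a gene tree from Newick text or file
#'
#' Reads a Newick gene tree in which leaf labels encode the source species and
#' a gene identifier (default scheme `SPECIES_geneid`, split at the first
#' separator), internal node labels are interpreted as branch support values
#' in \[0, 1\] (as written by maximum-likelihood programs reporting
#' Shimodaira--Hasegawa-like local support), and branch lengths are in
#' substitutions per site.
#'
#' Polytomies are preserved. Missing branch lengths are kept missing, never
#' coerced to zero.
#'
#' @param x Newick string, or path to a file containing one tree.
#' @param label_sep Separator between the species id and the gene id in leaf
#'   labels; the first occurrence splits the label.
#' @param species Optional character vector of known species ids. When given,
#'   every leaf must parse to one of them.
#' @return An [ape::phylo] object (class `gene_tree`/`phylo`) with attributes
#'   used by downstream functions.
#' @examples
#' tr <- parse_gene_tree("((A_g1:0.1,A_g2:0.1)0.9:0.2,B_g1:0.3);")
#' leaf_species(tr)
#' @export
parse_gene_tree <- function(x, label_sep = "_", species = NULL) {
  stopifnot(is.character(x), length(x) == 1L)
  txt <- if (!grepl("[(;]", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else {
    x
  }
  check_newick_syntax(txt)
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) abort("failed to parse Newick string")
  as_gene_tree(tree, label_sep = label_sep, species = species)
}

# cheap structural pre-check so errors carry a character position,
# which ape::read.tree does not provide
check_newick_syntax <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        abort(sprintf("malformed Newick: unbalanced ')' at position %d", i))
      }
    }
  }
  if (depth != 0L) {
    abort(sprintf(
      "malformed Newick: %d unclosed '(' at end of input (length %d)",
      depth, length(chars)
    ))
  }
  if (!grepl(";", txt)) abort("malformed Newick: missing terminal ';'")
  invisible(TRUE)
}

#' @rdname parse_gene_tree
#' @param tree An [ape::phylo] object to validate and promote.
#' @export
as_gene_tree <- function(tree, label_sep = "_", species = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (ape::Ntip(tree) < 3L) abort("gene tree must have at least 3 leaves")
  sp <- species_from_labels(tree$tip.label, label_sep)
  bad <- tree$tip.label[is.na(sp)]
  if (length(bad) > 0L) {
    abort(paste0(
      "leaf labels not matching the 'SPECIES", label_sep, "gene' scheme: ",
      paste(utils::head(bad, 10L), collapse = ", ")
    ))
  }
  if (!is.null(species)) {
    unknown <- unique(sp[!sp %in% species])
    if (length(unknown) > 0L) {
      abort(paste0("unknown species ids in leaf labels: ",
                   paste(unknown, collapse = ", ")))
    }
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0, na.rm = TRUE)) {
    abort("negative branch lengths are not allowed")
  }
  sup <- node_support(tree)
  if (any(!is.na(sup) & (sup < 0 | sup > 1))) {
    abort("internal node support values must lie in [0, 1]")
  }
  attr(tree, "label_sep") <- label_sep
  class(tree) <- unique(c("gene_tree", class(tree)))
  tree
}

#' Species id of every leaf
#'
#' @param tree A `phylo` gene tree.
#' @param label_sep Separator between species and gene id (defaults to the
#'   one recorded when the tree was parsed).
#' @return Named character vector, one species id per tip label.
#' @export
leaf_species <- function(tree, label_sep = NULL) {
  label_sep <- label_sep %||% attr(tree, "label_sep") %||% "_"
  sp <- species_from_labels(tree$tip.label, label_sep)
  setNames(sp, tree$tip.label)
}

species_from_labels <- function(labels, label_sep = "_") {
  pos <- regexpr(label_sep, labels, fixed = TRUE)
  out <- ifelse(pos > 1L, substr(labels, 1L, pos - 1L), NA_character_)
  out
}

#' Numeric support values for internal nodes
#'
#' @param tree A `phylo` object whose internal node labels hold support
#'   values; unparsable or empty labels give `NA`.
#' @return Numeric vector of length `tree$Nnode`, indexed in ape's internal
#'   node order (node id minus the number of tips).
#' @export
node_support <- function(tree) {
  n_int <- tree$Nnode
  if (is.null(tree$node.label)) {
    return(rep(NA_real_, n_int))
  }
  suppressWarnings(as.numeric(tree$node.label))
}

#' Root a gene tree for clade-direction analyses
#'
#' Trees produced by maximum-likelihood programs are unrooted; lineage
#' restriction of a clade depends on the rooting, so an explicit policy is
#' applied before expansion detection: midpoint rooting (default) or rooting
#' on an outgroup species set.
#'
#' @param tree A `phylo` gene tree.
#' @param method `"asis"` keeps the current (possibly arbitrary) rooting,
#'   `"midpoint"` roots at the midpoint of the longest leaf-to-leaf path,
#'   `"outgroup"` roots on the smallest clade holding all leaves of
#'   `outgroup_species`.
#' @param outgroup_species Species ids used when `method = "outgroup"`.
#' @param label_sep Leaf label separator, see [parse_gene_tree()].
#' @return A rooted `phylo`.
#' @export
root_gene_tree <- function(tree,
                           method = c("midpoint", "outgroup", "asis"),
                           outgroup_species = NULL, label_sep = NULL) {
  method <- match.arg(method)
  if (method == "asis") {
    return(tree)
  }
  if (method == "midpoint") {
    if (is.null(tree$edge.length)) {
      abort("midpoint rooting requires branch lengths")
    }
    return(phangorn::midpoint(tree))
  }
  if (is.null(outgroup_species)) {
    abort("method = 'outgroup' needs `outgroup_species`")
  }
  sp <- leaf_species(tree, label_sep)
  og <- names(sp)[sp %in% outgroup_species]
  if (length(og) == 0L) abort("no leaves belong to the outgroup species")
  ape::root(tree, outgroup = og, resolve.root = TRUE)
}
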