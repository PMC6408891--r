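#' Detect lineage-restricted expansions in a gene tree
#'
#' Scans every internal node of a rooted gene tree for clades whose descendant
#' leaves all belong to a focal set of species (e.g. the cephalopods within a
#' bilaterian-wide GPCR tree). Only *maximal* such nodes are returned -- a
#' lineage-restricted node nested inside a larger lineage-restricted node is
#' absorbed by its ancestor -- so each burst of duplications is counted once.
#' Nodes are ranked by the number of focal-lineage genes they contain
#' (descending, ties broken by post-order node index), kept when the clade
#' holds at least `cutoff` genes, and finally filtered on branch support when
#' `min_support` is given.
#'
#' @param tree A rooted `phylo` gene tree (see [parse_gene_tree()]). Unrooted
#'   trees are rooted first according to `root_method`.
#' @param focal_species Character vector of focal species ids.
#' @param cutoff Minimum number of focal genes in a clade for it to count as
#'   an expansion (>= 2; the GPCR study used 10).
#' @param min_support Optional support threshold applied as a final filter;
#'   nodes without a support value fail a positive threshold.
#' @param label_sep Leaf label separator, see [parse_gene_tree()].
#' @param root_method Rooting policy applied when `tree` is unrooted, see
#'   [root_gene_tree()].
#' @param outgroup_species Passed to [root_gene_tree()] when needed.
#' @return A tibble of class `expansion_set` with one row per expansion:
#'   `group_id` (rank), `node_id`, `size`, `support`, `n_species`, `species`
#'   and `members` (list columns), and `sister` (leaf labels of the closest
#'   sister clade passing `min_support`, as used for outgroup extraction).
#' @examples
#' tr <- parse_gene_tree("(((c1_a:1,c1_b:1)0.9:1,(c2_a:1,c2_b:1)0.9:1)0.95:1,(x1_a:1,x2_a:1)0.8:1);")
#' find_lineage_expansions(tr, focal_species = c("c1", "c2"), cutoff = 3)
#' @export
find_lineage_expansions <- function(tree, focal_species, cutoff = 10,
                                    min_support = NULL, label_sep = NULL,
                                    root_method = "midpoint",
                                    outgroup_species = NULL) {
  if (length(focal_species) == 0L) abort("`focal_species` must be non-empty")
  if (!is.numeric(cutoff) || cutoff < 2) {
    abort("`cutoff` must be a number >= 2")
  }
  if (!ape::is.rooted(tree)) {
    tree <- root_gene_tree(tree, method = root_method,
                           outgroup_species = outgroup_species,
                           label_sep = label_sep)
  }
  sp <- leaf_species(tree, label_sep)
  ntip <- ape::Ntip(tree)
  focal_tip <- unname(sp %in% focal_species)

  desc <- phangorn::Descendants(tree, type = "tips") # all nodes, tip ids
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  focal_only <- vapply(nodes, function(nd) all(focal_tip[desc[[nd]]]),
                       logical(1))
  names(focal_only) <- nodes

  root <- ntip + 1L
  support <- node_support(tree)

  if (all(focal_tip)) {
    warn("all leaves belong to the focal lineage; returning the root as a single degenerate group")
    res <- expansion_row(root, tree, sp, desc, support, ntip,
                         min_support %||% 0)
    out <- new_expansion_set(res[1, ], tree, focal_species, cutoff,
                             min_support)
    attr(out, "degenerate_root") <- TRUE
    return(out)
  }

  parent_of <- integer(ntip + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]

  cand <- nodes[focal_only]
  # maximality: drop any node whose parent is itself lineage-restricted
  maximal <- cand[vapply(cand, function(nd) {
    p <- parent_of[nd]
    p == 0L || !isTRUE(focal_only[as.character(p)])
  }, logical(1))]

  sizes <- vapply(maximal, function(nd) length(desc[[nd]]), integer(1))
  maximal <- maximal[sizes >= cutoff]
  sizes <- sizes[sizes >= cutoff]

  # rank by size desc, stable ties by post-order node index
  po_nodes <- unique(ape::reorder.phylo(tree, "postorder")$edge[, 1])
  po_rank <- match(maximal, po_nodes)
  ord <- order(-sizes, po_rank)
  maximal <- maximal[ord]

  if (!is.null(min_support)) {
    sup <- support[maximal - ntip]
    maximal <- maximal[!is.na(sup) & sup >= min_support | min_support <= 0]
  }

  rows <- lapply(maximal, expansion_row, tree = tree, sp = sp, desc = desc,
                 support = support, ntip = ntip,
                 min_support = min_support %||% 0)
  res <- if (length(rows) > 0L) dplyr::bind_rows(rows) else empty_expansions()
  new_expansion_set(res, tree, focal_species, cutoff, min_support)
}

expansion_row <- function(nd, tree, sp, desc, support, ntip, min_support) {
  members <- tree$tip.label[desc[[nd]]]
  sis <- sister_leaves(tree, nd, min_support)
  tibble(
    node_id = nd,
    size = length(members),
    support = if (nd > ntip) support[nd - ntip] else NA_real_,
    n_species = length(unique(sp[members])),
    species = list(sort(unique(unname(sp[members])))),
    members = list(members),
    sister = list(sis)
  )
}

empty_expansions <- function() {
  tibble(
    node_id = integer(), size = integer(), support = numeric(),
    n_species = integer(), species = list(), members = list(),
    sister = list()
  )
}

new_expansion_set <- function(res, tree, focal_species, cutoff, min_support) {
  res <- dplyr::mutate(res, group_id = dplyr::row_number(), .before = 1L)
  attr(res, "tree") <- tree
  attr(res, "focal_species") <- focal_species
  attr(res, "cutoff") <- cutoff
  attr(res, "min_support") <- min_support
  class(res) <- c("expansion_set", class(res))
  res
}

# leaves of the sister context used for selection analyses: the tips of the
# enclosing well-supported clade that are not in the group itself
sister_leaves <- function(tree, node, min_support) {
  anc <- enclosing_supported_node(tree, node, min_support)
  if (is.na(anc)) {
    return(character())
  }
  all_tips <- unlist(phangorn::Descendants(tree, anc, type = "tips"))
  grp_tips <- unlist(phangorn::Descendants(tree, node, type = "tips"))
  tree$tip.label[setdiff(all_tips, grp_tips)]
}

# first ancestor of `node` whose support passes the threshold; NA when the
# walk hits the root without finding one (root itself is returned as NA_flagged)
enclosing_supported_node <- function(tree, node, min_support) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  support <- node_support(tree)
  parent_of <- integer(ntip + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  qualifies <- function(nd) {
    if (min_support <= 0) return(TRUE)
    s <- support[nd - ntip]
    !is.na(s) && s >= min_support
  }
  if (node == root) {
    return(NA_integer_)
  }
  cand <- parent_of[node]
  while (cand != root && !qualifies(cand)) {
    cand <- parent_of[cand]
  }
  if (cand == root && !qualifies(cand)) {
    attr(cand, "at_root") <- TRUE
    return(cand)
  }
  cand
}

#' Extract an expanded group together with its closest supported outgroup
#'
#' Returns the smallest subtree containing the given group members plus their
#' sister clade, where the subtending node must reach `min_support`; the walk
#' continues rootward past poorly supported nodes until the condition holds
#' (falling back to the root, with a warning, when nothing below qualifies).
#' Branch lengths and node labels are preserved. This mirrors the group +
#' outgroup subsets used as input for codon-model selection tests.
#'
#' @param tree A rooted `phylo` gene tree.
#' @param members Character vector of group leaf labels (or a single row of an
#'   `expansion_set`).
#' @param min_support Support threshold for the enclosing node (0 accepts the
#'   immediate sister unconditionally).
#' @return A `phylo` subtree; attribute `outgroup_genes` lists the non-member
#'   leaves retained.
#' @export
extract_group_subtree <- function(tree, members, min_support = 0.7) {
  if (inherits(members, "expansion_set")) {
    if (nrow(members) != 1L) abort("pass a single expansion row")
    members <- members$members[[1]]
  }
  missing <- setdiff(members, tree$tip.label)
  if (length(missing) > 0L) {
    abort(paste0("group members absent from tree: ",
                 paste(utils::head(missing, 5L), collapse = ", ")))
  }
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  node <- if (length(members) == 1L) {
    match(members, tree$tip.label)
  } else {
    ape::getMRCA(tree, members)
  }
  if (node == root) {
    warn("group spans the root; returning the whole tree")
    anc <- root
  } else {
    anc <- enclosing_supported_node(tree, node, min_support)
    if (isTRUE(attr(anc, "at_root"))) {
      warn("no ancestor below the root reaches the support threshold; returning the whole tree")
    }
  }
  sub <- if (anc == root) tree else ape::extract.clade(tree, as.integer(anc))
  attr(sub, "label_sep") <- attr(tree, "label_sep")
  attr(sub, "members") <- members
  attr(sub, "outgroup_genes") <- setdiff(sub$tip.label, members)
  sub
}

#' Patristic divergence of an expanded group from reference lineages
#'
#' For each group member, computes the patristic (path-sum of branch lengths)
#' distance to its nearest leaf from the reference species set, and summarises
#' the per-member minima by median and quartiles -- the "total branch length"
#' divergence between an expansion and its closest non-focal relatives, in
#' substitutions per site.
#'
#' @param tree A `phylo` with branch lengths.
#' @param members Group leaf labels.
#' @param reference_species Species ids of the reference (non-focal) lineages.
#' @param label_sep Leaf label separator.
#' @return One-row tibble with `n`, `q1`, `median`, `q3`; the per-member
#'   minimum distances are attached as attribute `distances`.
#' @export
patristic_divergence_summary <- function(tree, members, reference_species,
                                         label_sep = NULL) {
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (anyNA(tree$edge.length)) {
    bad <- tree$edge[which(is.na(tree$edge.length))[1], 2]
    lab <- if (bad <= ape::Ntip(tree)) tree$tip.label[bad] else paste0("node ", bad)
    abort(paste0("missing branch length on the branch subtending ", lab))
  }
  sp <- leaf_species(tree, label_sep)
  ref_tips <- names(sp)[sp %in% reference_species]
  if (length(ref_tips) == 0L) abort("no leaves belong to the reference species")
  missing <- setdiff(members, tree$tip.label)
  if (length(missing) > 0L) {
    abort(paste0("group members absent from tree: ",
                 paste(utils::head(missing, 5L), collapse = ", ")))
  }
  dm <- ape::cophenetic.phylo(tree)
  dmin <- apply(dm[members, ref_tips, drop = FALSE], 1L, min)
  qs <- unname(quantile(dmin, c(0.25, 0.5, 0.75)))
  out <- tibble(n = length(dmin), q1 = qs[1], median = qs[2], q3 = qs[3])
  attr(out, "distances") <- dmin
  out
}

#' @export
print.expansion_set <- function(x, ...) {
  cat(sprintf(
    "Lineage-restricted expansions: %d group(s) (cutoff %s, min support %s)\n",
    nrow(x), attr(x, "cutoff"),
    attr(x, "min_support") %||% "none"
  ))
  NextMethod()
}

#' @rdname find_lineage_expansions
#' @param x An `expansion_set`.
#' @param ... Unused.
#' @export
tidy.expansion_set <- function(x, ...) {
  tibble(
    group_id = x$group_id,
    node_id = x$node_id,
    size = x$size,
    support = x$support,
    n_species = x$n_species,
    species = map_chr(x$species, paste, collapse = ","),
    members = map_chr(x$members, paste, collapse = ",")
  )
}

#' @rdname find_lineage_expansions
#' @export
glance.expansion_set <- function(x, ...) {
  tibble(
    n_groups = nrow(x),
    n_genes = sum(x$size),
    largest = if (nrow(x) > 0L) max(x$size) else NA_integer_,
    cutoff = attr(x, "cutoff"),
    min_support = attr(x, "min_support") %||% NA_real_
  )
}

#' Write detected expansions to TSV and JSON
#'
#' @param x An `expansion_set`.
#' @param tsv,json Output paths (either may be `NULL` to skip).
#' @return `x`, invisibly.
#' @export
write_expansions <- function(x, tsv = NULL, json = NULL) {
  flat <- tidy.expansion_set(x)
  if (!is.null(tsv)) readr::write_tsv(flat, tsv)
  if (!is.null(json)) {
    jsonlite::write_json(flat, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(x)
}
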