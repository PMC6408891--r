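# Independent brute-force oracles used to validate the package's
# implementations. These deliberately avoid the code paths under test
# (no phangorn::Descendants, no pruning): clade membership comes from a
# plain recursive walk over the edge table, likelihoods from explicit
# summation over internal-node states, counts from base tapply.

# descendant tip labels of every node, by recursion on the edge table
oracle_tips_below <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  below <- function(nd) {
    if (nd <= ntip) return(tree$tip.label[nd])
    unlist(lapply(kids[[as.character(nd)]], below))
  }
  nodes <- (ntip + 1):(ntip + tree$Nnode)
  setNames(lapply(nodes, below), nodes)
}

# brute-force lineage-expansion detection: enumerate all internal nodes,
# filter by the focal-only predicate and size, reduce to maximal sets by
# pairwise inclusion, rank, then apply the support filter
oracle_expansions <- function(tree, focal, cutoff, min_support = NULL,
                              sep = "_") {
  tipsets <- oracle_tips_below(tree)
  sp_of <- function(labs) sub(paste0(sep, ".*$"), "", labs)
  keep <- Filter(function(ts) all(sp_of(ts) %in% focal) &&
                   length(ts) >= cutoff, tipsets)
  if (length(keep) == 0) return(list())
  is_max <- vapply(names(keep), function(a) {
    !any(vapply(names(keep), function(b) {
      a != b && all(keep[[a]] %in% keep[[b]])
    }, logical(1)))
  }, logical(1))
  keep <- keep[is_max]
  if (!is.null(min_support) && min_support > 0) {
    ntip <- length(tree$tip.label)
    sup <- suppressWarnings(as.numeric(tree$node.label))
    ok <- vapply(names(keep), function(nd) {
      s <- sup[as.integer(nd) - ntip]
      !is.na(s) && s >= min_support
    }, logical(1))
    keep <- keep[ok]
  }
  unname(lapply(keep, sort))
}

# random gene tree with random species assignment over a pool containing
# focal and non-focal species
random_species_tree <- function(n_tips, n_focal_species = 2,
                                n_other_species = 2, p_focal = 0.5) {
  tr <- ape::rtree(n_tips)
  focal <- paste0("f", seq_len(n_focal_species))
  other <- paste0("o", seq_len(n_other_species))
  sp <- ifelse(runif(n_tips) < p_focal, sample(focal, n_tips, replace = TRUE),
               sample(other, n_tips, replace = TRUE))
  tr$tip.label <- paste0(sp, "_g", seq_len(n_tips))
  tr$node.label <- as.character(round(runif(tr$Nnode, 0.3, 1), 3))
  tr$node.label[1] <- "" # root support usually absent
  list(tree = tr, focal = focal)
}

compare_member_sets <- function(got, want) {
  norm <- function(x) sort(vapply(x, function(m) paste(sort(m), collapse = "|"),
                                  character(1)))
  identical(norm(got), norm(want))
}

# brute-force codon log-likelihood by summation over all internal-node
# states; works for trees with <= 3 internal nodes
oracle_codon_loglik <- function(aln, tree, kappa, omega, pi) {
  tabs <- lsexpand:::codon_tables()
  q <- codon_rate_matrix(kappa, omega, pi)
  dec <- lsexpand:::decompose_generator(q, pi)
  tr <- ape::reorder.phylo(tree, "postorder")
  pm <- lapply(seq_len(nrow(tr$edge)),
               function(e) lsexpand:::probability_matrix(dec, tr$edge.length[e]))
  st <- lsexpand:::codon_states(aln)
  ntip <- length(tr$tip.label)
  internal <- (ntip + 1):(ntip + tr$Nnode)
  n_int <- length(internal)
  stopifnot(n_int <= 3)
  nsite <- ncol(st)
  total <- 0
  combos <- as.matrix(expand.grid(rep(list(1:61), n_int)))
  for (s in seq_len(nsite)) {
    like <- rep(0, nrow(combos))
    for (k in seq_len(nrow(combos))) {
      assign_state <- function(nd) {
        if (nd <= ntip) st[tr$tip.label[nd], s] else {
          combos[k, match(nd, internal)]
        }
      }
      l <- pi[combos[k, match(ntip + 1, internal)]]
      for (e in seq_len(nrow(tr$edge))) {
        a <- assign_state(tr$edge[e, 1]); b <- assign_state(tr$edge[e, 2])
        l <- l * pm[[e]][a, b]
      }
      like[k] <- l
    }
    total <- total + log(sum(like))
  }
  total
}

# brute-force per-group scaffold counts with base R
oracle_scaffold_counts <- function(loci, m) {
  out <- list()
  for (g in sort(unique(loci$group))) {
    sub <- loci[loci$group == g, ]
    counts <- table(sub$scaffold)
    out[[g]] <- c(n_scaffolds = length(counts),
                  n_min_m = sum(counts >= m))
  }
  out
}

# brute-force tandem cluster scan by explicit iteration
oracle_tandem_clusters <- function(loci, members, max_intervening) {
  res <- list()
  for (sc in unique(loci$scaffold)) {
    sub <- loci[loci$scaffold == sc, ]
    sub <- sub[order(sub$start, sub$stop), ]
    flags <- sub$gene_id %in% members
    cur <- character()
    gap <- 0
    for (i in seq_len(nrow(sub))) {
      if (flags[i]) {
        if (length(cur) > 0 && gap > max_intervening) {
          if (length(cur) >= 2) res[[length(res) + 1]] <- cur
          cur <- character()
        }
        cur <- c(cur, sub$gene_id[i])
        gap <- 0
      } else {
        gap <- gap + 1
      }
    }
    if (length(cur) >= 2) res[[length(res) + 1]] <- cur
  }
  res
}

random_codon_tree <- function(n_tips, min_bl = 0.05, max_bl = 0.4) {
  tr <- ape::rtree(n_tips)
  tr$edge.length <- runif(nrow(tr$edge), min_bl, max_bl)
  tr
}
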