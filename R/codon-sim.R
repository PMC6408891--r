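#' Simulate a codon alignment along a tree
#'
#' Evolves codon sequences under the Goldman-Yang model: the root sequence is
#' drawn from the stationary frequencies and each branch applies the matrix
#' exponential transition probabilities of its (scaled) generator. dN/dS can
#' be uniform, differ between a foreground clade and the background, or vary
#' across sites in classes -- the same parameterizations the fitting
#' functions estimate, so simulate-and-recover checks are exact. No internal
#' stop codons can arise (the state space is the 61 sense codons).
#'
#' @param tree Rooted or unrooted `phylo` with branch lengths (expected
#'   substitutions per codon).
#' @param n_codons Number of codon sites.
#' @param kappa Transition/transversion ratio.
#' @param omega Background dN/dS ratio.
#' @param pi Codon frequencies (61, summing to 1); default uniform.
#' @param foreground Optional foreground clade (tip labels) or branch child
#'   ids; `omega_fg` then applies to those branches.
#' @param omega_fg Foreground dN/dS.
#' @param site_classes Optional tibble/data frame with columns `weight` and
#'   `omega`: sites are assigned to classes with the given probabilities and
#'   evolve under the class omega (with the shared mixture scaling used by
#'   the site-model fits).
#' @param seed Optional RNG seed for reproducibility.
#' @return List: `aln` (a [codon_alignment()], gapless), `tree`, and `truth`
#'   (parameters used, per-edge omega, and per-site class for site
#'   simulations).
#' @export
simulate_codon_alignment <- function(tree, n_codons, kappa = 2, omega = 0.4,
                                     pi = NULL, foreground = NULL,
                                     omega_fg = NULL, site_classes = NULL,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_codons < 1L) abort("`n_codons` must be >= 1")
  if (is.null(tree$edge.length)) abort("tree needs branch lengths")
  tabs <- codon_tables()
  pi <- pi %||% rep(1 / 61, 61L)
  pi <- pi / sum(pi)

  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tr)
  nedge <- nrow(tr$edge)

  if (!is.null(site_classes)) {
    stopifnot(all(c("weight", "omega") %in% names(site_classes)))
    w <- site_classes$weight / sum(site_classes$weight)
    site_class <- sample.int(nrow(site_classes), n_codons, replace = TRUE,
                             prob = w)
    qs <- lapply(site_classes$omega, function(om) {
      codon_rate_matrix(kappa, om, pi, scale = FALSE)
    })
    rho <- sum(w * vapply(qs, attr, numeric(1), "rate"))
    decs <- lapply(qs, function(q) decompose_generator(q / rho, pi))
    dec_of_edge <- function(e) decs # all classes on every edge
    edge_omega <- rep(NA_real_, nedge)
  } else {
    labels <- rep("bg", nedge)
    if (!is.null(foreground)) {
      if (is.null(omega_fg)) abort("`omega_fg` required with `foreground`")
      fg_children <- foreground_children(tr, foreground)
      labels <- ifelse(tr$edge[, 2L] %in% fg_children, "fg", "bg")
    }
    site_class <- rep(1L, n_codons)
    oms <- c(bg = omega, fg = omega_fg %||% omega)
    decs_lab <- lapply(oms, function(om) {
      decompose_generator(codon_rate_matrix(kappa, om, pi), pi)
    })
    decs_edge <- lapply(seq_len(nedge), function(e) decs_lab[[labels[e]]])
    dec_of_edge <- function(e) list(decs_edge[[e]])
    edge_omega <- unname(oms[labels])
  }

  n_classes <- if (is.null(site_classes)) 1L else nrow(site_classes)
  node_states <- vector("list", ntip + tr$Nnode)
  root <- ntip + 1L
  node_states[[root]] <- sample.int(61L, n_codons, replace = TRUE, prob = pi)
  for (e in rev(seq_len(nedge))) { # preorder: parents before children
    p <- tr$edge[e, 1L]
    v <- tr$edge[e, 2L]
    t_e <- tr$edge.length[e]
    decs_e <- dec_of_edge(e)
    pmats <- lapply(decs_e, function(d) {
      m <- probability_matrix(d, t_e)
      m / rowSums(m)
    })
    parent_state <- node_states[[p]]
    child_state <- integer(n_codons)
    for (cl in seq_len(n_classes)) {
      sites_cl <- which(site_class == cl)
      if (length(sites_cl) == 0L) next
      ps <- parent_state[sites_cl]
      for (s in unique(ps)) {
        idx <- sites_cl[ps == s]
        child_state[idx] <- sample.int(61L, length(idx), replace = TRUE,
                                       prob = pmats[[cl]][s, ])
      }
    }
    node_states[[v]] <- child_state
  }

  seqs <- vapply(seq_len(ntip), function(i) {
    paste(tabs$codons[node_states[[i]]], collapse = "")
  }, character(1))
  names(seqs) <- tr$tip.label
  truth <- list(
    kappa = kappa, omega = omega, omega_fg = omega_fg, pi = pi,
    edge_omega = edge_omega,
    site_class = if (is.null(site_classes)) NULL else site_class,
    site_omega = if (is.null(site_classes)) NULL else {
      site_classes$omega[site_class]
    }
  )
  list(aln = codon_alignment(seqs), tree = tr, truth = truth)
}

#' Translate a codon alignment to protein
#'
#' @param aln A [codon_alignment()].
#' @return Named character vector of gapped protein sequences.
#' @export
translate_codon_alignment <- function(aln) {
  tabs <- codon_tables()
  cm <- codon_matrix_chr(aln$sequences)
  aa <- matrix("-", nrow(cm), ncol(cm))
  hit <- match(cm, tabs$codons)
  aa[!is.na(hit)] <- tabs$aa[hit[!is.na(hit)]]
  aa[is.na(hit) & cm != "---"] <- "X"
  setNames(apply(aa, 1L, paste, collapse = ""), rownames(cm))
}
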