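# Goldman-Yang codon substitution machinery: 61x61 generator with
# transition/transversion ratio kappa and dN/dS ratio omega, stationary
# frequencies pi; reversible, so P(t) comes from a symmetrized eigen
# decomposition. Likelihoods use Felsenstein pruning over compressed site
# patterns with per-node rescaling; gaps are missing data (unit partials).

#' Goldman-Yang codon rate matrix
#'
#' Builds the 61 x 61 generator with entries for codon pairs differing at a
#' single position: \eqn{q_{ij} = \pi_j \kappa^{ti} \omega^{ns}} where `ti`
#' indicates a transition and `ns` a non-synonymous change; all multi-step
#' rates are 0 and rows sum to 0. By default the matrix is rescaled so the
#' expected substitution rate at stationarity,
#' \eqn{-\sum_i \pi_i q_{ii}}, equals 1 (branch lengths are then expected
#' substitutions per codon).
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega dN/dS ratio (>= 0).
#' @param pi Stationary codon frequencies (61 values summing to 1).
#' @param scale Rescale to unit expected rate.
#' @return 61 x 61 generator matrix; the unscaled expected rate is attached
#'   as attribute `rate`.
#' @export
codon_rate_matrix <- function(kappa, omega, pi, scale = TRUE) {
  stopifnot(kappa > 0, omega >= 0, length(pi) == 61L)
  if (abs(sum(pi) - 1) > 1e-9) abort("codon frequencies must sum to 1")
  tabs <- codon_tables()
  q <- matrix(0, 61L, 61L, dimnames = list(tabs$codons, tabs$codons))
  rates <- pi[tabs$pair_j] *
    ifelse(tabs$is_transition, kappa, 1) *
    ifelse(tabs$is_synonymous, 1, omega)
  q[cbind(tabs$pair_i, tabs$pair_j)] <- rates
  diag(q) <- -rowSums(q)
  rate <- -sum(pi * diag(q))
  if (scale) {
    if (rate <= 0) abort("degenerate rate matrix (expected rate <= 0)")
    q <- q / rate
  }
  attr(q, "rate") <- rate
  q
}

# eigen decomposition of a reversible generator via symmetrization
decompose_generator <- function(q, pi) {
  sp <- sqrt(pi)
  b <- q * outer(sp, 1 / sp)
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  list(
    values = e$values,
    left = e$vectors / sp,        # diag(1/sp) %*% U
    right = t(e$vectors * sp)     # t(U) %*% diag(sp)
  )
}

# transition probability matrix P(t) = exp(Qt)
probability_matrix <- function(decomp, t) {
  p <- decomp$left %*% (exp(decomp$values * t) * decomp$right)
  p[p < 0] <- 0
  p
}

# --- tree bookkeeping ------------------------------------------------------

# postorder edge structure used by the likelihood engine
codon_tree_struct <- function(tree, tip_order) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tr)
  edge <- tr$edge
  list(
    tree = tr,
    ntip = ntip,
    nnode = ntip + tr$Nnode,
    root = ntip + 1L,
    edge = edge,
    nedge = nrow(edge),
    tip_index = match(tr$tip.label, tip_order),
    lengths = tr$edge.length %||% rep(0.1, nrow(edge))
  )
}

# compress alignment columns into unique site patterns
site_patterns <- function(states) {
  st <- states
  key <- apply(st, 2L, paste, collapse = ",")
  u <- !duplicated(key)
  pat_of_site <- match(key, key[u])
  list(
    states = st[, u, drop = FALSE],
    weights = as.numeric(tabulate(pat_of_site, nbins = sum(u))),
    pattern_of_site = pat_of_site
  )
}

tip_partial <- function(states_row, npat) {
  m <- matrix(0, 61L, npat)
  obs <- !is.na(states_row)
  m[cbind(states_row[obs], which(obs))] <- 1
  m[, !obs] <- 1 # gap/ambiguous codon: missing data
  m
}

col_max_scale <- function(m) {
  s <- m[cbind(max.col(t(m), ties.method = "first"), seq_len(ncol(m)))]
  s[s <= 0] <- 1 # all-zero column: impossible pattern, leave unscaled
  list(m = m / rep(s, each = 61L), logs = log(s))
}

# --- pruning ---------------------------------------------------------------

# down-pass partial likelihoods for one substitution class.
# pmats: list over edges of 61x61 transition matrices; tipp: precomputed
# tip partial matrices indexed like the alignment rows.
# Returns per-node scaled partials, per-node cumulative log-scalers (per
# pattern), and the per-edge child products M = P %*% D_child for reuse.
peel_down <- function(struct, pmats, tipp) {
  npat <- ncol(tipp[[1L]])
  partial <- vector("list", struct$nnode)
  scal <- vector("list", struct$nnode)
  mlist <- vector("list", struct$nedge)
  for (e in seq_len(struct$nedge)) {
    p <- struct$edge[e, 1L]
    v <- struct$edge[e, 2L]
    if (v <= struct$ntip) {
      d <- tipp[[struct$tip_index[v]]]
      s <- numeric(npat)
    } else {
      # node v is complete here (postorder); rescale before consuming
      sc <- col_max_scale(partial[[v]])
      partial[[v]] <- sc$m
      scal[[v]] <- scal[[v]] + sc$logs
      d <- partial[[v]]
      s <- scal[[v]]
    }
    m <- pmats[[e]] %*% d
    mlist[[e]] <- m
    if (is.null(partial[[p]])) {
      partial[[p]] <- m
      scal[[p]] <- s
    } else {
      partial[[p]] <- partial[[p]] * m
      scal[[p]] <- scal[[p]] + s
    }
  }
  list(partial = partial, scal = scal, mlist = mlist)
}

# per-pattern log-likelihood for one class given its down pass
class_site_loglik <- function(struct, down, pi) {
  l <- colSums(pi * down$partial[[struct$root]])
  log(l) + down$scal[[struct$root]]
}

# log( sum_c w_c exp(ll_c) ) across classes, per pattern
mix_site_loglik <- function(ll_by_class, weights) {
  lw <- log(weights)
  m <- do.call(cbind, ll_by_class)
  m <- sweep(m, 2L, lw, "+")
  top <- apply(m, 1L, max)
  top + log(rowSums(exp(m - top)))
}

# up-pass ("outside") partials for branch-length optimization.
# For edge e = (p, v): F_e = A_p * prod_{siblings} M_sib, with log-scaler
# fscal_e; the edge likelihood is colSums(F_e * (P(t) %*% D_v)) with total
# scaler fscal_e + dscal_v.
peel_up <- function(struct, down, pi, pmats) {
  npat <- length(down$scal[[struct$root]])
  a <- vector("list", struct$nnode)
  ascal <- vector("list", struct$nnode)
  a[[struct$root]] <- matrix(pi, 61L, npat)
  ascal[[struct$root]] <- numeric(npat)
  fpre <- vector("list", struct$nedge)
  fscal <- vector("list", struct$nedge)
  edges_of_parent <- split(seq_len(struct$nedge), struct$edge[, 1L])
  for (e in rev(seq_len(struct$nedge))) { # preorder
    p <- struct$edge[e, 1L]
    v <- struct$edge[e, 2L]
    sibs <- setdiff(edges_of_parent[[as.character(p)]], e)
    f <- a[[p]]
    s <- ascal[[p]]
    for (se in sibs) {
      f <- f * down$mlist[[se]]
      ch <- struct$edge[se, 2L]
      if (ch > struct$ntip) s <- s + down$scal[[ch]]
    }
    sc <- col_max_scale(f)
    fpre[[e]] <- sc$m
    fscal[[e]] <- s + sc$logs
    if (v > struct$ntip) {
      # A_v = t(P_e) %*% F_e, conditioned on the state at v
      a[[v]] <- crossprod(pmats[[e]], fpre[[e]])
      ascal[[v]] <- fscal[[e]]
    }
  }
  list(fpre = fpre, fscal = fscal, a = a, ascal = ascal)
}
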