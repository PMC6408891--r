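# Maximum-likelihood fitting of codon models: M0 (single omega), two-ratio
# branch model (foreground/background omega), and the M1a/M2a site-class
# models, plus likelihood-ratio tests and naive empirical Bayes site
# posteriors. Optimization alternates bounded quasi-Newton steps on
# log/logit-transformed global parameters with Brent sweeps over individual
# branch lengths using cached outside partials.

# --- engine ----------------------------------------------------------------

codon_engine <- function(aln, tree, freq = "f3x4") {
  stopifnot(inherits(aln, "codon_alignment"))
  # reversible model: fit on the unrooted tree. With a rooted binary tree
  # the two root edges are unidentifiable (pulley principle), and labelling
  # one foreground/one background would let the branch model shift
  # substitution mass between omega classes -- an artefactual extra degree
  # of freedom that inflates the LRT.
  if (ape::is.rooted(tree) && ape::Ntip(tree) > 2L) {
    tree <- ape::unroot(tree)
  }
  states <- codon_states(aln)
  ids <- rownames(states)
  if (!setequal(tree$tip.label, ids)) {
    only_tree <- setdiff(tree$tip.label, ids)
    only_aln <- setdiff(ids, tree$tip.label)
    abort(paste0(
      "tree and alignment do not match",
      if (length(only_tree)) paste0("; only in tree: ", paste(only_tree, collapse = ", ")),
      if (length(only_aln)) paste0("; only in alignment: ", paste(only_aln, collapse = ", "))
    ))
  }
  pi <- if (is.numeric(freq)) {
    stopifnot(length(freq) == 61L)
    setNames(freq / sum(freq), codon_tables()$codons)
  } else {
    codon_frequencies(aln, method = freq)
  }
  struct <- codon_tree_struct(tree, ids)
  pat <- site_patterns(states)
  npat <- ncol(pat$states)
  tipp <- lapply(seq_len(nrow(pat$states)),
                 function(i) tip_partial(pat$states[i, ], npat))
  list(struct = struct, pat = pat, tipp = tipp, pi = unname(pi),
       pi_named = pi, aln = aln)
}

# transition matrices and per-edge decompositions for a parameter point.
# Single-class models scale each omega's generator to unit rate
# individually; site mixtures share the proportion-weighted mean rate so
# relative rates between classes are preserved.
prepare_model <- function(eng, kappa, classes, edge_labels, bls) {
  nedge <- eng$struct$nedge
  if (length(classes) == 1L) {
    omegas <- classes[[1L]]$omegas
    decs <- lapply(omegas, function(om) {
      decompose_generator(codon_rate_matrix(kappa, om, eng$pi), eng$pi)
    })
    dec_edge <- list(decs[edge_labels])
    pmats <- list(lapply(seq_len(nedge), function(e) {
      probability_matrix(dec_edge[[1L]][[e]], bls[e])
    }))
  } else {
    qs <- lapply(classes, function(cl) {
      codon_rate_matrix(kappa, cl$omegas[["all"]], eng$pi, scale = FALSE)
    })
    w <- vapply(classes, `[[`, numeric(1), "weight")
    rho <- sum(w * vapply(qs, attr, numeric(1), "rate"))
    decs <- lapply(qs, function(q) decompose_generator(q / rho, eng$pi))
    dec_edge <- lapply(decs, function(d) rep(list(d), nedge))
    pmats <- lapply(decs, function(d) {
      lapply(seq_len(nedge), function(e) probability_matrix(d, bls[e]))
    })
  }
  list(pmats = pmats, dec_edge = dec_edge,
       weights = vapply(classes, `[[`, numeric(1), "weight"))
}

engine_loglik <- function(eng, prep, keep_downs = FALSE) {
  downs <- lapply(prep$pmats, function(pm) peel_down(eng$struct, pm, eng$tipp))
  lls <- lapply(downs, function(d) class_site_loglik(eng$struct, d, eng$pi))
  site_ll <- if (length(lls) == 1L) lls[[1L]] else {
    mix_site_loglik(lls, prep$weights)
  }
  total <- sum(eng$pat$weights * site_ll)
  if (keep_downs) {
    list(loglik = total, downs = downs, site_ll_by_class = lls)
  } else {
    total
  }
}

# one Brent sweep over all branch lengths using cached outside partials
branch_sweep <- function(eng, bls, ll_cur, make_prep, bl_max,
                         brent_tol = 1e-5) {
  prep <- make_prep(bls)
  full <- engine_loglik(eng, prep, keep_downs = TRUE)
  downs <- full$downs
  ups <- lapply(seq_along(downs), function(c) {
    peel_up(eng$struct, downs[[c]], eng$pi, prep$pmats[[c]])
  })
  struct <- eng$struct
  w_pat <- eng$pat$weights
  lw <- log(prep$weights)
  nclass <- length(downs)
  new_bls <- bls
  for (e in seq_len(struct$nedge)) {
    v <- struct$edge[e, 2L]
    dv <- vector("list", nclass)
    dsc <- vector("list", nclass)
    for (c in seq_len(nclass)) {
      if (v <= struct$ntip) {
        dv[[c]] <- eng$tipp[[struct$tip_index[v]]]
        dsc[[c]] <- 0
      } else {
        dv[[c]] <- downs[[c]]$partial[[v]]
        dsc[[c]] <- downs[[c]]$scal[[v]]
      }
    }
    obj <- function(t) {
      lls <- lapply(seq_len(nclass), function(c) {
        p <- probability_matrix(prep$dec_edge[[c]][[e]], t)
        val <- colSums(ups[[c]]$fpre[[e]] * (p %*% dv[[c]]))
        log(val) + ups[[c]]$fscal[[e]] + dsc[[c]]
      })
      site <- if (nclass == 1L) lls[[1L]] else mix_site_loglik(lls, prep$weights)
      sum(w_pat * site)
    }
    new_bls[e] <- optimize(obj, interval = c(1e-8, bl_max),
                           maximum = TRUE, tol = brent_tol)$maximum
  }
  ll_new <- engine_loglik(eng, make_prep(new_bls))
  if (ll_new >= ll_cur) {
    return(list(bls = new_bls, loglik = ll_new))
  }
  damped <- sqrt(bls * new_bls) # simultaneous updates overshot: half-step
  ll_damp <- engine_loglik(eng, make_prep(damped))
  if (ll_damp >= ll_cur) {
    return(list(bls = damped, loglik = ll_damp))
  }
  list(bls = bls, loglik = ll_cur)
}

# --- model definitions -----------------------------------------------------

softmax3 <- function(a, b) {
  z <- exp(c(a, b, 0) - max(a, b, 0))
  z / sum(z)
}

make_model <- function(type, nedge, edge_labels = NULL) {
  edge_labels <- edge_labels %||% rep("all", nedge)
  switch(type,
    M0 = list(
      type = "M0", np_global = 2L, edge_labels = edge_labels,
      init = c(log(2), log(0.5)),
      lower = c(log(0.05), log(1e-4)), upper = c(log(100), log(1e3)),
      par_to_spec = function(th) {
        list(kappa = exp(th[1L]),
             classes = list(list(weight = 1,
                                 omegas = c(all = exp(th[2L])))))
      },
      report = function(th) list(kappa = exp(th[1L]), omega = exp(th[2L]))
    ),
    branch = list(
      type = "branch", np_global = 3L, edge_labels = edge_labels,
      init = c(log(2), log(0.5), log(0.5)),
      lower = c(log(0.05), log(1e-4), log(1e-4)),
      upper = c(log(100), log(1e3), log(1e3)),
      par_to_spec = function(th) {
        list(kappa = exp(th[1L]),
             classes = list(list(weight = 1,
                                 omegas = c(bg = exp(th[2L]),
                                            fg = exp(th[3L])))))
      },
      report = function(th) list(kappa = exp(th[1L]),
                                 omega_background = exp(th[2L]),
                                 omega_foreground = exp(th[3L]))
    ),
    M1a = list(
      type = "M1a", np_global = 3L, edge_labels = edge_labels,
      init = c(log(2), stats::qlogis(0.7), stats::qlogis(0.3)),
      lower = c(log(0.05), -12, stats::qlogis(1e-4)),
      upper = c(log(100), 12, stats::qlogis(1 - 1e-4)),
      par_to_spec = function(th) {
        p0 <- stats::plogis(th[2L])
        w0 <- stats::plogis(th[3L])
        list(kappa = exp(th[1L]),
             classes = list(
               list(weight = p0, omegas = c(all = w0)),
               list(weight = 1 - p0, omegas = c(all = 1))
             ))
      },
      report = function(th) list(kappa = exp(th[1L]),
                                 p0 = stats::plogis(th[2L]),
                                 p1 = 1 - stats::plogis(th[2L]),
                                 omega0 = stats::plogis(th[3L]),
                                 omega1 = 1)
    ),
    M2a = list(
      type = "M2a", np_global = 5L, edge_labels = edge_labels,
      init = c(log(2), log(0.65 / 0.05), log(0.3 / 0.05),
               stats::qlogis(0.3), log(3 - 1)),
      lower = c(log(0.05), -12, -12, stats::qlogis(1e-4), log(1e-4)),
      upper = c(log(100), 12, 12, stats::qlogis(1 - 1e-4), log(999)),
      par_to_spec = function(th) {
        p <- softmax3(th[2L], th[3L])
        w0 <- stats::plogis(th[4L])
        w2 <- 1 + exp(th[5L])
        list(kappa = exp(th[1L]),
             classes = list(
               list(weight = p[1L], omegas = c(all = w0)),
               list(weight = p[2L], omegas = c(all = 1)),
               list(weight = p[3L], omegas = c(all = w2))
             ))
      },
      report = function(th) {
        p <- softmax3(th[2L], th[3L])
        list(kappa = exp(th[1L]), p0 = p[1L], p1 = p[2L], p2 = p[3L],
             omega0 = stats::plogis(th[4L]), omega1 = 1,
             omega2 = 1 + exp(th[5L]))
      }
    ),
    abort(paste0("unknown model type: ", type))
  )
}

# --- core fitting loop -----------------------------------------------------

fit_codon_model <- function(aln, tree, model_type, foreground = NULL,
                            freq = "f3x4", init = NULL, init_bls = NULL,
                            multistart = 1L,
                            control = list()) {
  ctrl <- utils::modifyList(
    list(tol = 1e-6, max_outer = 40L, stall_outer = 5L, bl_max = 20,
         global_maxit_first = 40L, global_maxit = 15L),
    control
  )
  if (length(aln$sequences) < 3L) abort("need at least 3 sequences")
  eng <- codon_engine(aln, tree, freq)
  nedge <- eng$struct$nedge

  edge_labels <- rep("all", nedge)
  fg_children <- NULL
  if (model_type == "branch") {
    if (is.null(foreground)) abort("branch model needs `foreground`")
    fg_children <- foreground_children(eng$struct$tree, foreground)
    is_fg <- eng$struct$edge[, 2L] %in% fg_children
    if (!any(is_fg)) abort("foreground set matches no branches")
    if (all(is_fg)) abort("foreground must be a proper subset of branches")
    edge_labels <- ifelse(is_fg, "fg", "bg")
  }
  model <- make_model(model_type, nedge, edge_labels)

  bls <- init_bls %||% pmin(pmax(eng$struct$lengths, 1e-4), ctrl$bl_max)
  theta <- init %||% model$init
  make_prep <- function(b, th = theta) {
    spec <- model$par_to_spec(th)
    prepare_model(eng, spec$kappa, spec$classes, model$edge_labels, b)
  }
  loglik_at <- function(th, b) {
    engine_loglik(eng, make_prep(b, th))
  }

  run_once <- function(theta0, bls0) {
    th <- theta0
    b <- bls0
    ll <- loglik_at(th, b)
    converged <- FALSE
    iter <- 0L
    gain <- Inf
    prev_gain <- Inf
    while (iter < ctrl$max_outer) {
      iter <- iter + 1L
      ll_start <- ll
      maxit <- if (iter == 1L) ctrl$global_maxit_first else ctrl$global_maxit
      opt <- optim(
        th,
        function(x) {
          val <- loglik_at(x, b)
          if (!is.finite(val)) 1e10 else -val
        },
        method = "L-BFGS-B", lower = model$lower, upper = model$upper,
        control = list(maxit = maxit)
      )
      if (-opt$value > ll) {
        th <- opt$par
        ll <- -opt$value
      }
      # coarse branch-length tolerance early, fine near convergence
      btol <- if (iter <= 2L) 1e-3 else if (gain > 1e-3) 1e-5 else 1e-7
      sw <- branch_sweep(eng, b, ll,
                         make_prep = function(bb) make_prep(bb, th),
                         bl_max = ctrl$bl_max, brent_tol = btol)
      b <- sw$bls
      ll <- sw$loglik
      prev_gain <- gain
      gain <- ll - ll_start
      if (gain < ctrl$tol) {
        converged <- TRUE
        break
      }
      if (iter >= ctrl$stall_outer && gain > 0.5 * prev_gain) {
        # alternation has plateaued (typically an omega/branch-length
        # ridge): finish with one joint quasi-Newton pass
        jp <- joint_polish(th, b, ll)
        th <- jp$theta
        b <- jp$bls
        converged <- jp$converged || (jp$loglik - ll < 10 * ctrl$tol)
        ll <- jp$loglik
        break
      }
    }
    list(theta = th, bls = b, loglik = ll, converged = converged,
         iterations = iter)
  }

  # gradient of the negative log-likelihood in (theta, log branch lengths):
  # analytic for branch lengths (dP/dt from the eigendecomposition),
  # central differences for the few global parameters
  joint_gradient <- function(p, nth) {
    tt <- p[seq_len(nth)]
    bb <- exp(p[-seq_len(nth)])
    spec <- model$par_to_spec(tt)
    prep <- prepare_model(eng, spec$kappa, spec$classes, model$edge_labels,
                          bb)
    full <- engine_loglik(eng, prep, keep_downs = TRUE)
    ups <- lapply(seq_along(full$downs), function(c) {
      peel_up(eng$struct, full$downs[[c]], eng$pi, prep$pmats[[c]])
    })
    nclass <- length(full$downs)
    w_pat <- eng$pat$weights
    gb <- vapply(seq_len(eng$struct$nedge), function(e) {
      v <- eng$struct$edge[e, 2L]
      dens <- nums <- scals <- vector("list", nclass)
      for (c in seq_len(nclass)) {
        if (v <= eng$struct$ntip) {
          dvv <- eng$tipp[[eng$struct$tip_index[v]]]
          dsc <- 0
        } else {
          dvv <- full$downs[[c]]$partial[[v]]
          dsc <- full$downs[[c]]$scal[[v]]
        }
        dec <- prep$dec_edge[[c]][[e]]
        dp <- dec$left %*% ((dec$values * exp(dec$values * bb[e])) *
                              dec$right)
        dens[[c]] <- colSums(ups[[c]]$fpre[[e]] *
                               (prep$pmats[[c]][[e]] %*% dvv))
        nums[[c]] <- colSums(ups[[c]]$fpre[[e]] * (dp %*% dvv))
        scals[[c]] <- ups[[c]]$fscal[[e]] + dsc
      }
      g_pat <- if (nclass == 1L) {
        nums[[1L]] / dens[[1L]]
      } else {
        smat <- do.call(cbind, scals)
        mx <- apply(smat, 1L, max)
        es <- exp(smat - mx)
        den <- rowSums(sweep(do.call(cbind, dens) * es, 2L, prep$weights,
                             "*"))
        num <- rowSums(sweep(do.call(cbind, nums) * es, 2L, prep$weights,
                             "*"))
        num / den
      }
      sum(w_pat * g_pat) * bb[e] # chain rule for log branch length
    }, numeric(1))
    h <- 1e-5
    gth <- vapply(seq_len(nth), function(j) {
      tp <- tt; tp[j] <- tt[j] + h
      tm <- tt; tm[j] <- tt[j] - h
      (loglik_at(tp, bb) - loglik_at(tm, bb)) / (2 * h)
    }, numeric(1))
    -c(gth, gb)
  }

  joint_polish <- function(th, b, ll_cur) {
    nth <- length(th)
    par0 <- c(th, log(pmax(b, 1e-8)))
    opt <- optim(
      par0,
      function(p) {
        val <- loglik_at(p[seq_len(nth)], exp(p[-seq_len(nth)]))
        if (!is.finite(val)) 1e10 else -val
      },
      gr = function(p) joint_gradient(p, nth),
      method = "L-BFGS-B",
      lower = c(model$lower, rep(log(1e-8), length(b))),
      upper = c(model$upper, rep(log(ctrl$bl_max), length(b))),
      control = list(maxit = 40L, factr = 1e7)
    )
    if (-opt$value >= ll_cur) {
      list(theta = opt$par[seq_len(nth)], bls = exp(opt$par[-seq_len(nth)]),
           loglik = -opt$value, converged = opt$convergence == 0L)
    } else {
      list(theta = th, bls = b, loglik = ll_cur, converged = FALSE)
    }
  }

  best <- run_once(theta, bls)
  if (multistart > 1L) {
    for (k in seq_len(multistart - 1L)) {
      jitter <- rnorm(length(theta), 0, 0.7)
      th0 <- pmin(pmax(model$init + jitter, model$lower), model$upper)
      cand <- run_once(th0, bls)
      if (cand$loglik > best$loglik) best <- cand
    }
  }
  if (!best$converged) {
    warn(sprintf("%s fit did not reach the convergence tolerance in %d outer iterations",
                 model_type, ctrl$max_outer))
  }

  fitted_tree <- eng$struct$tree
  fitted_tree$edge.length <- best$bls
  params <- model$report(best$theta)
  branch_tbl <- branch_table(eng$struct, best$bls, model$edge_labels, params)

  structure(list(
    model = model_type,
    log_likelihood = best$loglik,
    kappa = params$kappa,
    params = params,
    frequencies = eng$pi_named,
    tree = fitted_tree,
    branches = branch_tbl,
    foreground = fg_children,
    np_global = model$np_global,
    converged = best$converged,
    iterations = best$iterations,
    n_seq = length(aln$sequences),
    n_codons = length(aln$column_map),
    n_patterns = ncol(eng$pat$states),
    theta = best$theta,
    freq_method = if (is.numeric(freq)) "custom" else freq
  ), class = "codon_fit")
}

branch_table <- function(struct, bls, edge_labels, params) {
  tr <- struct$tree
  child <- struct$edge[, 2L]
  child_label <- ifelse(child <= struct$ntip, tr$tip.label[child],
                        paste0("node", child))
  om <- if (all(edge_labels == "all")) {
    rep(params$omega %||% NA_real_, length(child))
  } else {
    ifelse(edge_labels == "fg", params$omega_foreground,
           params$omega_background)
  }
  tibble(
    parent = struct$edge[, 1L],
    child = child,
    child_label = child_label,
    length = bls,
    label = ifelse(edge_labels == "all", "all", edge_labels),
    omega = om
  )
}

# child node ids of the foreground branches: the side of the tree spanned
# by the given tips, including the stem branch of that group. Works on
# unrooted trees by locating the bipartition, so a foreground group lying
# "across" an arbitrary root is still labelled correctly.
foreground_children <- function(tree, foreground) {
  if (is.numeric(foreground)) {
    return(as.integer(foreground))
  }
  stopifnot(is.character(foreground))
  missing <- setdiff(foreground, tree$tip.label)
  if (length(missing) > 0L) {
    abort(paste0("foreground tips absent from tree: ",
                 paste(utils::head(missing, 5L), collapse = ", ")))
  }
  ntip <- ape::Ntip(tree)
  fg_tips <- match(foreground, tree$tip.label)
  if (length(fg_tips) == 1L) {
    return(fg_tips)
  }
  desc <- phangorn::Descendants(tree, type = "tips")
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  # the foreground forms a clade as drawn: clade plus its stem
  for (nd in nodes) {
    if (length(desc[[nd]]) == length(fg_tips) &&
          setequal(desc[[nd]], fg_tips)) {
      return(as.integer(c(nd, unlist(phangorn::Descendants(tree, nd,
                                                           type = "all")))))
    }
  }
  # the complement forms a clade (possibly a single tip): foreground is
  # everything else plus the shared stem branch
  comp <- setdiff(seq_len(ntip), fg_tips)
  if (length(comp) == 1L) {
    return(as.integer(setdiff(tree$edge[, 2L], comp)))
  }
  for (nd in nodes) {
    if (length(desc[[nd]]) == length(comp) && setequal(desc[[nd]], comp)) {
      bg_side <- c(nd, unlist(phangorn::Descendants(tree, nd, type = "all")))
      fg <- setdiff(tree$edge[, 2L], setdiff(bg_side, nd))
      return(as.integer(fg))
    }
  }
  # not a split: fall back to the smallest spanning clade
  mrca <- ape::getMRCA(tree, foreground)
  inside <- unlist(phangorn::Descendants(tree, mrca, type = "all"))
  tipset <- unlist(phangorn::Descendants(tree, mrca, type = "tips"))
  extra <- setdiff(tree$tip.label[tipset], foreground)
  if (length(extra) > 0L) {
    inform(paste0("foreground clade also spans: ", paste(extra, collapse = ", ")))
  }
  as.integer(c(mrca, inside))
}

#' Parse codeml-style foreground tags from a tree
#'
#' Accepts `#1` suffixes on tip or internal-node labels, marking the branch
#' subtending the labelled node as foreground; tags are stripped from the
#' returned tree.
#'
#' @param tree A `phylo` whose labels may carry `#1` tags.
#' @return List with `tree` (tags removed) and `foreground` (child node ids
#'   of the tagged branches; empty when no tags present).
#' @export
foreground_from_tags <- function(tree) {
  tag <- "\\s*#\\d+\\s*$"
  fg <- integer()
  tips_tagged <- grepl(tag, tree$tip.label)
  fg <- c(fg, which(tips_tagged))
  tree$tip.label <- sub(tag, "", tree$tip.label)
  if (!is.null(tree$node.label)) {
    nodes_tagged <- grepl(tag, tree$node.label)
    fg <- c(fg, ape::Ntip(tree) + which(nodes_tagged))
    tree$node.label <- sub(tag, "", tree$node.label)
  }
  list(tree = tree, foreground = fg)
}

# --- public fits -----------------------------------------------------------

#' Fit the M0 (single-ratio) codon model
#'
#' Maximum-likelihood fit of the Goldman-Yang model with one dN/dS ratio
#' shared by every branch: optimizes omega, kappa and all branch lengths;
#' codon frequencies are fixed empirically (F3x4 by default).
#'
#' @param aln A cleaned [codon_alignment()] with >= 3 sequences.
#' @param tree `phylo` whose tips match the alignment; branch lengths, when
#'   present, seed the optimization.
#' @param freq `"f3x4"`, `"equal"`, or a numeric vector of 61 frequencies.
#' @param multistart Number of optimizer starts (> 1 adds randomly jittered
#'   restarts; results depend on the RNG state).
#' @param control Optimizer control overrides: `tol` (log-likelihood
#'   convergence tolerance, default 1e-6), `max_outer`, `bl_max`.
#' @return A `codon_fit` object; see [tidy.codon_fit()], [glance.codon_fit()].
#' @export
fit_m0 <- function(aln, tree, freq = "f3x4", multistart = 1L,
                   control = list()) {
  fit_codon_model(aln, tree, "M0", freq = freq, multistart = multistart,
                  control = control)
}

#' Fit the two-ratio branch model
#'
#' Estimates separate dN/dS ratios for a set of foreground branches (an
#' expanded clade, including its stem) and the remaining background branches.
#'
#' @inheritParams fit_m0
#' @param foreground Foreground specification: tip labels spanning the
#'   foreground clade (all branches inside the clade plus its stem become
#'   foreground), or integer child-node ids of individual branches (e.g.
#'   from [foreground_from_tags()]).
#' @param m0 Optional [fit_m0()] result on the same data; its estimates seed
#'   the branch-model optimization, which also guarantees the nested
#'   likelihood ordering.
#' @return A `codon_fit` with `omega_foreground`/`omega_background`.
#' @export
fit_branch_model <- function(aln, tree, foreground, m0 = NULL, freq = "f3x4",
                             multistart = 1L, control = list()) {
  init <- NULL
  if (!is.null(m0)) {
    stopifnot(inherits(m0, "codon_fit"), m0$model == "M0")
    init <- c(log(m0$kappa), log(max(m0$params$omega, 1e-4)),
              log(max(m0$params$omega, 1e-4)))
    tree <- m0$tree # optimized branch lengths seed the branch-model fit
  }
  fit_codon_model(aln, tree, "branch", foreground = foreground, freq = freq,
                  init = init, multistart = multistart, control = control)
}

#' Likelihood-ratio test between nested codon model fits
#'
#' The statistic is `2 * (logL_alt - logL_null)`, clamped at zero, referred
#' to a chi-squared distribution with `df` degrees of freedom (the
#' difference in free global parameters, inferred when not given).
#'
#' @param null,alt Nested `codon_fit` objects on the same data.
#' @param df Degrees of freedom; default `alt$np_global - null$np_global`.
#' @return One-row tibble (class `lrt_result`): `statistic`, `df`,
#'   `p_value`, `model_null`, `model_alt`.
#' @export
lrt <- function(null, alt, df = NULL) {
  stopifnot(inherits(null, "codon_fit"), inherits(alt, "codon_fit"))
  df <- df %||% (alt$np_global - null$np_global)
  if (df < 1L) abort("`df` must be >= 1 (is `alt` really the larger model?)")
  delta <- 2 * (alt$log_likelihood - null$log_likelihood)
  if (delta < -1e-4) {
    warn(sprintf(
      "alternative log-likelihood below null by %.3g: optimizer failure suspected; statistic clamped to 0",
      -delta / 2
    ))
  }
  stat <- max(0, delta)
  out <- tibble(
    statistic = stat,
    df = as.integer(df),
    p_value = pchisq(stat, df = df, lower.tail = FALSE),
    model_null = null$model,
    model_alt = alt$model
  )
  class(out) <- c("lrt_result", class(out))
  out
}

#' Fit the M1a/M2a site models and flag positively selected sites
#'
#' M1a ("nearly neutral") mixes a purifying class (omega0 < 1) with a
#' neutral class (omega1 = 1); M2a adds a positive-selection class
#' (omega2 > 1). The two fits are compared by a 2-df likelihood-ratio test,
#' and per-site class posteriors are computed by naive empirical Bayes at
#' the M2a maximum-likelihood estimates; sites are flagged when the
#' posterior probability of the omega2 class is at least `posterior_cutoff`
#' and the estimated omega2 exceeds 1.
#'
#' @inheritParams fit_m0
#' @param posterior_cutoff Posterior probability needed to flag a site.
#' @return List with `m1a`, `m2a` (`codon_fit`s), `lrt` (df = 2), and
#'   `site_posteriors`: tibble with per-site class posteriors
#'   (`p_purifying`, `p_neutral`, `p_positive`), the source protein column
#'   (`protein_column`), and the `selected` flag.
#' @export
fit_sites_models <- function(aln, tree, freq = "f3x4",
                             posterior_cutoff = 0.95, control = list()) {
  m1a <- fit_codon_model(aln, tree, "M1a", freq = freq, control = control)
  # seed M2a at the M1a solution with a small positive-selection class
  p0 <- min(max(m1a$params$p0, 1e-3), 1 - 2e-3)
  p2 <- 0.02
  p1 <- max(1 - p0 * (1 - p2) - p2, 1e-3) # keep proportions in the simplex
  init <- c(log(m1a$kappa),
            log(p0 * (1 - p2) / p2),
            log(max(p1, 1e-4) / p2),
            stats::qlogis(min(max(m1a$params$omega0, 1e-4), 1 - 1e-4)),
            log(2 - 1))
  m2a <- fit_codon_model(aln, m1a$tree, "M2a", freq = freq, init = init,
                         control = control)
  test <- lrt(m1a, m2a, df = 2L)
  post <- neb_site_posteriors(aln, m2a)
  post$selected <- post$p_positive >= posterior_cutoff &
    m2a$params$omega2 > 1
  list(m1a = m1a, m2a = m2a, lrt = test, site_posteriors = post)
}

# naive empirical Bayes: class posteriors at the MLEs
neb_site_posteriors <- function(aln, fit) {
  stopifnot(inherits(fit, "codon_fit"), fit$model %in% c("M1a", "M2a"))
  eng <- codon_engine(aln, fit$tree, fit$frequencies)
  model <- make_model(fit$model, eng$struct$nedge)
  spec <- model$par_to_spec(fit$theta)
  prep <- prepare_model(eng, spec$kappa, spec$classes, model$edge_labels,
                        eng$struct$lengths)
  res <- engine_loglik(eng, prep, keep_downs = TRUE)
  lw <- log(prep$weights)
  m <- do.call(cbind, res$site_ll_by_class)
  m <- sweep(m, 2L, lw, "+")
  top <- apply(m, 1L, max)
  post <- exp(m - top)
  post <- post / rowSums(post)
  site_post <- post[eng$pat$pattern_of_site, , drop = FALSE]
  out <- tibble(
    site = seq_len(nrow(site_post)),
    protein_column = aln$column_map,
    p_purifying = site_post[, 1L],
    p_neutral = site_post[, 2L],
    p_positive = if (ncol(site_post) >= 3L) site_post[, 3L] else 0
  )
  out
}

#' Exclude implausibly high dN/dS estimates
#'
#' Branch (or group) omega estimates above `limit` are discarded from
#' positive-selection reporting -- extreme values typically reflect
#' alignment problems between highly divergent sequences rather than
#' selection. The comparison is strict: an estimate exactly at the limit is
#' retained.
#'
#' @param fits Data frame with an `omega` column (e.g. [tidy.codon_fit()]
#'   rows or per-group estimates).
#' @param limit Exclusion threshold.
#' @return The retained rows; discarded rows are attached as attribute
#'   `discarded` and reported via a message.
#' @export
filter_high_omega <- function(fits, limit = 100) {
  stopifnot(is.data.frame(fits), "omega" %in% names(fits))
  keep <- is.na(fits$omega) | fits$omega <= limit
  discarded <- fits[!keep, , drop = FALSE]
  if (nrow(discarded) > 0L) {
    inform(sprintf("discarded %d estimate(s) with omega > %g", nrow(discarded),
                   limit))
  }
  out <- fits[keep, , drop = FALSE]
  attr(out, "discarded") <- discarded
  out
}

#' Codon-model log-likelihood at fixed parameters
#'
#' Evaluates the Goldman-Yang log-likelihood of a codon alignment on a tree
#' by Felsenstein pruning over the 61 codon states, at the given kappa and
#' omega (optionally with a separate foreground omega on labelled
#' branches). Site patterns are compressed; gap codons are treated as
#' missing data.
#'
#' @inheritParams fit_m0
#' @param kappa Transition/transversion ratio.
#' @param omega Background dN/dS.
#' @param foreground Optional foreground branch specification (see
#'   [fit_branch_model()]).
#' @param omega_fg Foreground dN/dS (required with `foreground`).
#' @return Scalar log-likelihood.
#' @export
codon_log_likelihood <- function(aln, tree, kappa, omega, freq = "f3x4",
                                 foreground = NULL, omega_fg = NULL) {
  eng <- codon_engine(aln, tree, freq)
  nedge <- eng$struct$nedge
  if (is.null(foreground)) {
    classes <- list(list(weight = 1, omegas = c(all = omega)))
    labels <- rep("all", nedge)
  } else {
    if (is.null(omega_fg)) abort("`omega_fg` required with `foreground`")
    fg_children <- foreground_children(eng$struct$tree, foreground)
    labels <- ifelse(eng$struct$edge[, 2L] %in% fg_children, "fg", "bg")
    classes <- list(list(weight = 1, omegas = c(bg = omega, fg = omega_fg)))
  }
  prep <- prepare_model(eng, kappa, classes, labels, eng$struct$lengths)
  engine_loglik(eng, prep)
}

# --- methods ---------------------------------------------------------------

#' @export
print.codon_fit <- function(x, ...) {
  cat(sprintf("Codon model %s: logL = %.4f (%s)\n", x$model,
              x$log_likelihood,
              if (x$converged) "converged" else "NOT converged"))
  pars <- x$params
  cat(paste0("  ", paste(names(pars), signif(unlist(pars), 4), sep = " = ",
                         collapse = ", ")), "\n")
  cat(sprintf("  %d sequences, %d codons (%d patterns), frequencies: %s\n",
              x$n_seq, x$n_codons, x$n_patterns, x$freq_method))
  invisible(x)
}

#' Per-branch table of a codon model fit
#' @param x A `codon_fit`.
#' @param ... Unused.
#' @return Tibble with one row per branch: `parent`, `child`, `child_label`,
#'   `length` (expected substitutions per codon), `label`
#'   (foreground/background) and the branch's `omega`.
#' @export
tidy.codon_fit <- function(x, ...) x$branches

#' One-row summary of a codon model fit
#' @param x A `codon_fit`.
#' @param ... Unused.
#' @export
glance.codon_fit <- function(x, ...) {
  tibble(
    model = x$model,
    log_likelihood = x$log_likelihood,
    kappa = x$kappa,
    omega = x$params$omega %||% NA_real_,
    omega_foreground = x$params$omega_foreground %||% NA_real_,
    omega_background = x$params$omega_background %||% NA_real_,
    np_global = x$np_global,
    converged = x$converged,
    n_seq = x$n_seq,
    n_codons = x$n_codons
  )
}
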