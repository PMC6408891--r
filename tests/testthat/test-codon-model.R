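test_that("rate matrix is a proper reversible generator with unit rate", {
  set.seed(2)
  pi_r <- rgamma(61, 2, 1); pi_r <- pi_r / sum(pi_r)
  for (pars in list(c(2, 0.5), c(1, 1), c(5, 3))) {
    q <- codon_rate_matrix(pars[1], pars[2], pi_r)
    expect_equal(max(abs(rowSums(q))), 0, tolerance = 1e-12)
    # detailed balance: pi_i q_ij = pi_j q_ji
    flux <- pi_r * q
    expect_equal(flux, t(flux), tolerance = 1e-12)
    # expected substitution rate at stationarity is 1 after scaling
    expect_equal(-sum(pi_r * diag(q)), 1, tolerance = 1e-10)
  }
  # kappa = omega = 1 with equal frequencies: all allowed rates equal
  q1 <- codon_rate_matrix(1, 1, rep(1 / 61, 61), scale = FALSE)
  off <- q1[q1 > 0]
  expect_equal(max(off), min(off))
  expect_error(codon_rate_matrix(2, 0.5, rep(1, 61)), "sum to 1")
})

test_that("transition probabilities are stochastic and converge to pi", {
  set.seed(4)
  pi_r <- rgamma(61, 2, 1); pi_r <- pi_r / sum(pi_r)
  q <- codon_rate_matrix(2, 0.5, pi_r)
  dec <- lsexpand:::decompose_generator(q, pi_r)
  for (t in c(0.01, 0.5, 3)) {
    p <- lsexpand:::probability_matrix(dec, t)
    expect_equal(rowSums(p), rep(1, 61), tolerance = 1e-8)
    expect_true(all(p >= 0))
  }
  expect_equal(lsexpand:::probability_matrix(dec, 0), diag(61),
               tolerance = 1e-8)
  # long-time limit: every row approaches the stationary distribution
  plong <- lsexpand:::probability_matrix(dec, 500)
  expect_equal(plong[1, ], pi_r, tolerance = 1e-6)
})

test_that("pruning log-likelihood equals brute-force state enumeration", {
  set.seed(6)
  pi_u <- rep(1 / 61, 61)
  # 3 taxa (1 internal node when unrooted input is kept as a trifurcation)
  tr3 <- ape::read.tree(text = "(a:0.3,b:0.15,c:0.5);")
  sim3 <- simulate_codon_alignment(tr3, 10, kappa = 2.5, omega = 0.5, seed = 7)
  ll <- codon_log_likelihood(sim3$aln, sim3$tree, kappa = 2.5, omega = 0.5,
                             freq = "equal")
  bf <- oracle_codon_loglik(sim3$aln, sim3$tree, 2.5, 0.5, pi_u)
  expect_lt(abs(ll - bf), 1e-8)

  # 4 taxa, rooted binary (3 internal nodes)
  tr4 <- ape::read.tree(text = "((a:0.2,b:0.3):0.15,(c:0.4,d:0.1):0.2);")
  sim4 <- simulate_codon_alignment(tr4, 10, kappa = 1.5, omega = 1.2, seed = 8)
  ll4 <- codon_log_likelihood(sim4$aln, sim4$tree, kappa = 1.5, omega = 1.2,
                              freq = "equal")
  bf4 <- oracle_codon_loglik(sim4$aln, sim4$tree, 1.5, 1.2, pi_u)
  expect_lt(abs(ll4 - bf4), 1e-8)
})

test_that("zero branch lengths with identical sequences give sum log pi", {
  tabs <- lsexpand:::codon_tables()
  tr <- ape::read.tree(text = "(a:0,b:0,c:0);")
  cods <- c("ATG", "GCA", "TTT", "AAA")
  seqs <- setNames(rep(paste(cods, collapse = ""), 3), c("a", "b", "c"))
  aln <- codon_alignment(seqs)
  ll <- codon_log_likelihood(aln, tr, kappa = 2, omega = 0.5, freq = "equal")
  expect_equal(ll, 4 * log(1 / 61), tolerance = 1e-8)
})

test_that("likelihood is invariant to rerooting and taxon order", {
  set.seed(9)
  tr <- random_codon_tree(6)
  sim <- simulate_codon_alignment(tr, 40, kappa = 2, omega = 0.4, seed = 10)
  ll0 <- codon_log_likelihood(sim$aln, sim$tree, 2, 0.4, freq = "equal")
  # reroot (pulley principle for a reversible model)
  rr <- ape::root(ape::unroot(sim$tree), outgroup = sim$tree$tip.label[1],
                  resolve.root = TRUE)
  ll1 <- codon_log_likelihood(sim$aln, rr, 2, 0.4, freq = "equal")
  expect_equal(ll0, ll1, tolerance = 1e-8)
  # permute alignment rows
  perm <- codon_alignment(sim$aln$sequences[sample(names(sim$aln$sequences))])
  ll2 <- codon_log_likelihood(perm, sim$tree, 2, 0.4, freq = "equal")
  expect_equal(ll0, ll2, tolerance = 1e-10)
  # leaf/sequence mismatch errors list the offenders
  bad <- sim$tree; bad$tip.label[1] <- "zzz"
  expect_error(codon_log_likelihood(sim$aln, bad, 2, 0.4), "zzz")
})

test_that("gap codons act as missing data", {
  tr <- ape::read.tree(text = "((a:0.2,b:0.3):0.1,(c:0.4,d:0.1):0.2);")
  sim <- simulate_codon_alignment(tr, 6, seed = 11)
  seqs <- sim$aln$sequences
  # drop one taxon's data entirely via gaps: likelihood equals the
  # 3-taxon likelihood of the remaining data
  gapped <- seqs
  gapped["d"] <- paste(rep("---", 6), collapse = "")
  ll_gap <- codon_log_likelihood(codon_alignment(gapped), tr, 2, 0.5,
                                 freq = "equal")
  tr3 <- ape::drop.tip(tr, "d")
  ll3 <- codon_log_likelihood(codon_alignment(seqs[c("a", "b", "c")]), tr3,
                              2, 0.5, freq = "equal")
  expect_equal(ll_gap, ll3, tolerance = 1e-8)
})

test_that("codon simulation is deterministic and respects omega = 0", {
  tr <- random_codon_tree(5)
  s1 <- simulate_codon_alignment(tr, 25, seed = 20)
  s2 <- simulate_codon_alignment(tr, 25, seed = 20)
  expect_identical(s1$aln$sequences, s2$aln$sequences)
  # omega = 0: no non-synonymous change can occur anywhere
  s0 <- simulate_codon_alignment(tr, 30, omega = 0, seed = 21)
  prots <- translate_codon_alignment(s0$aln)
  expect_equal(length(unique(unname(prots))), 1L)
})

test_that("long-branch simulation converges to stationary codon usage", {
  # chi-squared goodness of fit of simulated codon counts against pi
  star <- ape::read.tree(text = "(a:30,b:30,c:30,d:30);")
  sim <- simulate_codon_alignment(star, 400, kappa = 1, omega = 1, seed = 22)
  st <- lsexpand:::codon_states(sim$aln)
  counts <- tabulate(st, nbins = 61)
  gof <- suppressWarnings(stats::chisq.test(counts, p = rep(1 / 61, 61)))
  expect_gt(gof$p.value, 0.01)
})
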