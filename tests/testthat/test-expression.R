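test_that("Tau matches hand-evaluated cases and behaves at the boundaries", {
  expect_equal(compute_tau(c(1, 0, 0, 0)), 1)
  expect_equal(compute_tau(c(5, 5, 5, 5)), 0)
  # hand evaluation: x_hat = (1, .5, .5, .5); sum(1 - x_hat) = 1.5; / 3 = 0.5
  expect_equal(compute_tau(c(2, 1, 1, 1)), 0.5)
  expect_warning(expect_true(is.na(compute_tau(c(0, 0, 0)))), "all-zero")
  expect_error(compute_tau(c(-1, 2)), "non-negative")
  expect_error(compute_tau(7), "at least 2")
})

test_that("Tau bounds, scale invariance and extremes hold on random vectors", {
  set.seed(21)
  for (i in 1:200) {
    n <- sample(2:15, 1)
    x <- rgamma(n, 1, 0.1)
    tau <- compute_tau(x)
    expect_gte(tau, 0)
    expect_lte(tau, 1)
    expect_equal(compute_tau(x * runif(1, 0.1, 50)), tau)
    expect_equal(compute_tau(sample(x)), tau)
    # tau = 1 iff exactly one nonzero tissue
    y <- rep(0, n); y[sample(n, 1)] <- runif(1, 0.1, 5)
    expect_equal(compute_tau(y), 1)
    if (tau == 1) expect_equal(sum(x > 0), 1L)
    expect_equal(compute_tau(rep(x[1], n)), 0)
  }
})

test_that("specificity classification is strict at the threshold", {
  expect_true(classify_specific(0.81))
  expect_false(classify_specific(0.80)) # 'higher than' is strict
  expect_true(is.na(classify_specific(NA_real_)))
  expect_equal(classify_specific(c(0.5, 0.9), threshold = 0.85),
               c(FALSE, TRUE))
})

test_that("expression proportions divide by the tissue sum", {
  expect_equal(expression_proportions(c(2, 3, 5)), c(0.2, 0.3, 0.5))
  expect_equal(expression_proportions(c(0, 4)), c(0, 1))
  expect_error(expression_proportions(7), "at least 2")
  expect_warning(p <- expression_proportions(c(0, 0)), "all-zero")
  expect_true(all(is.na(p)))
  set.seed(5)
  for (i in 1:50) {
    x <- rgamma(sample(2:12, 1), 1, 1)
    expect_equal(sum(expression_proportions(x)), 1, tolerance = 1e-9)
  }
})

test_that("tau_profile profiles a matrix and flags all-zero genes", {
  expr <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    brain = c(100, 2, 0), gill = c(1, 2, 0), skin = c(1, 2, 0)
  )
  expect_message(prof <- tau_profile(expr), "all-zero")
  expect_equal(prof$gene_id, expr$gene_id)
  expect_true(prof$is_specific[1])
  expect_equal(prof$tau[2], 0)
  expect_true(is.na(prof$tau[3]))
  expect_equal(prof$top_tissue[1], "brain")
  expect_equal(attr(prof, "n_all_zero"), 1L)

  # permuting tissues leaves tau unchanged and permutes proportions
  perm <- expr[, c("gene_id", "skin", "brain", "gill")]
  prof2 <- suppressMessages(tau_profile(perm))
  expect_equal(prof2$tau, prof$tau)
  long <- suppressMessages(proportions_profile(expr))
  long2 <- suppressMessages(proportions_profile(perm))
  j <- dplyr::inner_join(long, long2, by = c("gene_id", "tissue"))
  expect_equal(j$proportion.x, j$proportion.y)
})

test_that("Kruskal-Wallis front end reproduces the hand-derived statistic", {
  # R1 = 6, R2 = 15: H = 12/(6*7) * (36/3 + 225/3) - 3*7 = 27/7
  kw <- kruskal_rank_test(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$statistic, 27 / 7, tolerance = 1e-12)
  expect_equal(kw$df, 1L)

  expect_equal(kruskal_rank_test(list(c(2, 2, 2), c(2, 2)))$statistic, 0)
  expect_equal(kruskal_rank_test(list(c(2, 2, 2), c(2, 2)))$p_value, 1)

  # invariance under strictly monotone transforms
  set.seed(31)
  x <- rnorm(30); g <- rep(1:3, each = 10)
  expect_equal(kruskal_rank_test(exp(x), g)$statistic,
               kruskal_rank_test(x, g)$statistic)
  expect_gte(kruskal_rank_test(x, g)$statistic, 0)
  expect_error(kruskal_rank_test(1:5, rep(1, 5)), "2 groups")
})

test_that("Dunn's test matches an independent mean-rank computation", {
  set.seed(13)
  x <- c(rnorm(8), rnorm(6, 2), rnorm(7, 2), rep(1.5, 3)) # includes ties
  g <- rep(c("a", "b", "c", "a"), c(8, 6, 7, 3))
  got <- dunn_posthoc(x, g)
  # independent computation
  r <- rank(x); N <- length(x)
  ties <- table(x)
  tcorr <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tcorr
  for (k in seq_len(nrow(got))) {
    a <- got$group_a[k]; b <- got$group_b[k]
    z_want <- (mean(r[g == a]) - mean(r[g == b])) /
      sqrt(v0 * (1 / sum(g == a) + 1 / sum(g == b)))
    expect_equal(got$z[k], z_want, tolerance = 1e-12)
    expect_equal(got$p_raw[k], 2 * pnorm(-abs(z_want)), tolerance = 1e-12)
  }
  # Holm adjustment: step-down, monotone, >= raw, capped at 1
  expect_equal(got$p_adj, p.adjust(got$p_raw, "holm"))
  expect_true(all(got$p_adj >= got$p_raw))
  ord <- order(got$p_raw)
  expect_true(all(diff(got$p_adj[ord]) >= -1e-15))
})

test_that("Dunn edge cases: single pair, identical groups, tiny groups", {
  got <- dunn_posthoc(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(nrow(got), 1L)
  expect_equal(got$p_adj, got$p_raw) # single pair: adjusted == raw

  same <- dunn_posthoc(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$z, 0)
  expect_equal(same$p_raw, 1)

  expect_warning(
    skipped <- dunn_posthoc(list(a = 1:5, b = 2, c = 3:7)),
    "fewer than 2"
  )
  expect_false("b" %in% c(skipped$group_a, skipped$group_b))
})

test_that("group comparison object combines KW and Dunn with Holm", {
  set.seed(17)
  tau_tbl <- tibble::tibble(
    gene_id = paste0("g", 1:60),
    tau = c(runif(30, 0, 0.6), runif(30, 0.5, 1))
  )
  groups <- setNames(rep(c("non_expanded", "group1"), each = 30),
                     tau_tbl$gene_id)
  cmp <- compare_tau_groups(tau_tbl, groups)
  expect_s3_class(glance(cmp), "tbl_df")
  expect_equal(glance(cmp)$df, 1L)
  expect_lt(glance(cmp)$p_value, 0.01)
  expect_equal(nrow(tidy(cmp)), 1L)
  expect_true(all(tidy(cmp)$p_adj >= tidy(cmp)$p_raw))
})

test_that("per-group summaries: CIs, mean proportions, planted argmax tissue", {
  # identical tau values: CI width 0
  expr <- tibble::tibble(
    gene_id = paste0("g", 1:4),
    t1 = c(10, 10, 1, 0), t2 = c(0, 0, 1, 1)
  )
  groups <- setNames(c("a", "a", "b", "b"), expr$gene_id)
  s <- summarize_by_group(expr, groups)
  a_row <- dplyr::filter(s$tau, group == "a")
  expect_equal(a_row$ci_lo, a_row$ci_hi)
  expect_equal(a_row$mean_tau, 1)

  # proportions (1,0) and (0,1) average to (0.5, 0.5)
  expr2 <- tibble::tibble(gene_id = c("x", "y"), t1 = c(1, 0), t2 = c(0, 1))
  s2 <- summarize_by_group(expr2, setNames(c("g", "g"), c("x", "y")))
  expect_equal(sort(s2$proportions$mean_proportion), c(0.5, 0.5))

  # planted tissue-specific group: argmax mean proportion = planted tissue
  sim <- simulate_expression(paste0("g", 1:40),
                             groups = setNames(rep(c("group1", "non_expanded"),
                                                   c(20, 20)), paste0("g", 1:40)),
                             fold = 50, dispersion = 0.1, seed = 99)
  planted <- table(sim$truth$dominant_tissue[sim$truth$gene_id %in%
                                               paste0("g", 1:20)])
  home <- names(planted)[which.max(planted)]
  s3 <- summarize_by_group(sim$expr,
                           setNames(rep(c("group1", "non_expanded"), c(20, 20)),
                                    paste0("g", 1:40)))
  top <- s3$proportions |>
    dplyr::filter(group == "group1") |>
    dplyr::slice_max(mean_proportion, n = 1)
  expect_equal(top$tissue, home)

  # empty groups warn and are omitted
  expect_warning(
    summarize_by_group(expr2, c(x = "g", y = "g", zz = "empty")),
    "omitted"
  )

  # bootstrap CI option returns finite bounds
  s4 <- summarize_by_group(sim$expr,
                           setNames(rep(c("group1", "non_expanded"), c(20, 20)),
                                    paste0("g", 1:40)),
                           bootstrap = 200)
  expect_true(all(is.finite(s4$tau$ci_lo)))
  expect_true(all(s4$tau$ci_lo <= s4$tau$ci_hi))
})

test_that("expression matrix validation rejects malformed input", {
  expect_error(tau_profile(tibble::tibble(gene_id = "g", t1 = 1)), "2 tissue")
  bad <- tibble::tibble(gene_id = c("g", "g"), t1 = c(1, 2), t2 = c(3, 4))
  expect_error(tau_profile(bad), "duplicate")
  neg <- tibble::tibble(gene_id = "g", t1 = -1, t2 = 2)
  expect_error(tau_profile(neg), "non-negative")
})
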