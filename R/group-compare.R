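#' Compare Tau distributions between gene groups
#'
#' Non-parametric comparison of tissue-specificity between the non-expanded
#' gene background and each expanded group: a Kruskal--Wallis rank test over
#' all groups, followed by Dunn's pairwise post hoc z tests on mean ranks
#' (tie-corrected pooled variance, two sided) with Holm step-down adjustment
#' over the whole family of pairs.
#'
#' @param tau_tbl A [tau_profile()] result, or any data frame with `gene_id`
#'   and `tau` columns.
#' @param groups Group assignment: a data frame with `gene_id` and `group`
#'   columns, or a named character vector (names = gene ids).
#' @return A `tau_comparison` object; see [tidy.tau_comparison()] and
#'   [glance.tau_comparison()].
#' @export
compare_tau_groups <- function(tau_tbl, groups) {
  stopifnot(all(c("gene_id", "tau") %in% names(tau_tbl)))
  df <- dplyr::inner_join(
    dplyr::select(as_tibble(tau_tbl), "gene_id", "tau"),
    normalize_groups(groups),
    by = "gene_id"
  ) |>
    dplyr::filter(!is.na(.data$tau))
  if (dplyr::n_distinct(df$group) < 2L) {
    abort("need at least 2 groups with non-missing Tau values")
  }
  kw <- kruskal_rank_test(df$tau, df$group)
  pw <- dunn_posthoc(df$tau, df$group, adjust = "holm")
  out <- list(
    kruskal = kw,
    pairwise = pw,
    n = dplyr::count(df, .data$group, name = "n")
  )
  class(out) <- "tau_comparison"
  out
}

#' Kruskal--Wallis rank test on a list or vector of samples
#'
#' Thin, validated front end over [stats::kruskal.test()] (mid-ranks with tie
#' correction, chi-squared reference with k - 1 degrees of freedom). When all
#' observations are identical the statistic is 0 and p = 1 by convention.
#'
#' @param x Numeric values, or a list of numeric group samples.
#' @param g Group labels (ignored when `x` is a list).
#' @return One-row tibble `statistic` (H), `df`, `p_value`, `n_groups`.
#' @export
kruskal_rank_test <- function(x, g = NULL) {
  if (is.list(x) && !is.data.frame(x)) {
    g <- rep(seq_along(x), lengths(x))
    x <- unlist(x, use.names = FALSE)
  }
  if (length(x) != length(g)) abort("`x` and `g` lengths differ")
  g <- factor(g)
  if (nlevels(g) < 2L) abort("need at least 2 groups")
  if (any(tabulate(g) == 0L)) abort("empty group")
  if (length(unique(x)) == 1L) {
    return(tibble(statistic = 0, df = nlevels(g) - 1L, p_value = 1,
                  n_groups = nlevels(g)))
  }
  kt <- kruskal.test(x, g)
  tibble(
    statistic = unname(kt$statistic),
    df = unname(kt$parameter),
    p_value = unname(kt$p.value),
    n_groups = nlevels(g)
  )
}

#' Dunn's post hoc test for all group pairs
#'
#' Pairwise z statistics on mean ranks after a Kruskal--Wallis test, using the
#' tie-corrected pooled variance
#' \deqn{\sigma^2_{ab} = \left(\frac{N(N+1)}{12} -
#'   \frac{\sum_t (t^3 - t)}{12(N-1)}\right)
#'   \left(\frac{1}{n_a} + \frac{1}{n_b}\right)}
#' with two-sided normal p-values, adjusted over the whole family of pairs.
#'
#' @param x Numeric values, or a list of numeric group samples.
#' @param g Group labels (ignored when `x` is a list).
#' @param adjust Multiple-testing adjustment passed to [stats::p.adjust()]
#'   (default Holm step-down).
#' @return Tibble with one row per pair: `group_a`, `group_b`, `z`, `p_raw`,
#'   `p_adj`. Pairs involving a group of fewer than 2 observations are
#'   skipped with a warning.
#' @export
dunn_posthoc <- function(x, g = NULL, adjust = "holm") {
  if (is.list(x) && !is.data.frame(x)) {
    nm <- names(x) %||% as.character(seq_along(x))
    g <- rep(nm, lengths(x))
    x <- unlist(x, use.names = FALSE)
  }
  g <- factor(g)
  if (nlevels(g) < 2L) abort("need at least 2 groups")
  r <- rank(x) # mid-ranks
  N <- length(x)
  tie_sizes <- table(x)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term
  mean_rank <- tapply(r, g, mean)
  n_g <- tabulate(g)
  names(n_g) <- levels(g)

  small <- levels(g)[n_g < 2L]
  if (length(small) > 0L) {
    warn(paste0("group(s) with fewer than 2 observations skipped in pairwise tests: ",
                paste(small, collapse = ", ")))
  }
  keep <- setdiff(levels(g), small)
  if (length(keep) < 2L) abort("fewer than 2 groups usable for pairwise tests")
  pairs <- utils::combn(keep, 2L)
  z <- vapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    se <- sqrt(v0 * (1 / n_g[[a]] + 1 / n_g[[b]]))
    if (se == 0) 0 else (mean_rank[[a]] - mean_rank[[b]]) / se
  }, numeric(1))
  p_raw <- 2 * pnorm(-abs(z))
  p_raw[z == 0] <- 1
  tibble(
    group_a = pairs[1L, ],
    group_b = pairs[2L, ],
    z = z,
    p_raw = p_raw,
    p_adj = p.adjust(p_raw, method = adjust)
  )
}

#' Per-group Tau and expression-proportion summaries
#'
#' For each group: number of genes with defined Tau, mean Tau with a 95%
#' confidence interval, the fraction of tissue-specific genes, and the mean
#' expression proportion per tissue (over genes with defined proportions).
#' The CI uses the normal approximation mean +/- z * se by default; a
#' non-parametric bootstrap of the mean is available.
#'
#' @inheritParams tau_profile
#' @param groups Group assignment as in [compare_tau_groups()].
#' @param threshold Tau specificity threshold.
#' @param conf Confidence level.
#' @param bootstrap Number of bootstrap resamples for the CI; 0 (default)
#'   uses the normal approximation.
#' @return A `group_expression_summary`: list with `$tau` (per-group tibble)
#'   and `$proportions` (group x tissue mean proportions, long tibble).
#'   Genes with all-zero expression are excluded and counted in `$qc`.
#' @export
summarize_by_group <- function(expr, groups, threshold = 0.8, conf = 0.95,
                               bootstrap = 0) {
  prof <- tau_profile(expr, threshold = threshold)
  grp <- normalize_groups(groups)
  df <- dplyr::inner_join(prof, grp, by = "gene_id")
  unassigned <- setdiff(prof$gene_id, grp$gene_id)
  if (length(unassigned) > 0L) {
    inform(sprintf("%d gene(s) without a group assignment were excluded",
                   length(unassigned)))
  }
  empty <- setdiff(unique(grp$group), unique(df$group))
  if (length(empty) > 0L) {
    warn(paste0("empty group(s) omitted: ", paste(empty, collapse = ", ")))
  }
  z <- qnorm(1 - (1 - conf) / 2)
  tau_sum <- df |>
    dplyr::filter(!is.na(.data$tau)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_tau = mean(.data$tau),
      sd_tau = sd(.data$tau),
      prop_specific = mean(.data$is_specific),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      se = dplyr::if_else(.data$n > 1L, .data$sd_tau / sqrt(.data$n), NA_real_),
      ci_lo = .data$mean_tau - z * dplyr::coalesce(.data$se, 0),
      ci_hi = .data$mean_tau + z * dplyr::coalesce(.data$se, 0)
    )
  if (bootstrap > 0) {
    boot_ci <- df |>
      dplyr::filter(!is.na(.data$tau)) |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(ci = list(boot_mean_ci(.data$tau, bootstrap, conf)),
                       .groups = "drop")
    tau_sum$ci_lo <- map_dbl(boot_ci$ci, 1L)
    tau_sum$ci_hi <- map_dbl(boot_ci$ci, 2L)
  }
  props <- proportions_profile(expr) |>
    dplyr::inner_join(grp, by = "gene_id") |>
    dplyr::filter(!is.na(.data$proportion)) |>
    dplyr::group_by(.data$group, .data$tissue) |>
    dplyr::summarise(mean_proportion = mean(.data$proportion),
                     n = dplyr::n(), .groups = "drop")
  out <- list(
    tau = tau_sum,
    proportions = props,
    qc = tibble(
      n_all_zero = attr(prof, "n_all_zero"),
      n_unassigned = length(unassigned)
    )
  )
  class(out) <- "group_expression_summary"
  out
}

boot_mean_ci <- function(x, reps, conf) {
  means <- vapply(seq_len(reps), function(i) mean(sample(x, replace = TRUE)),
                  numeric(1))
  unname(quantile(means, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
}

normalize_groups <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("gene_id", "group") %in% names(groups)))
    out <- as_tibble(groups)[, c("gene_id", "group")]
  } else if (!is.null(names(groups))) {
    out <- tibble(gene_id = names(groups), group = unname(as.character(groups)))
  } else {
    abort("`groups` must be a data frame (gene_id, group) or a named vector")
  }
  if (anyDuplicated(out$gene_id)) abort("duplicate gene ids in group assignment")
  out$group <- as.character(out$group)
  out
}

#' @export
print.tau_comparison <- function(x, ...) {
  kw <- x$kruskal
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.3g\n",
              kw$statistic, kw$df, kw$p_value))
  cat("Dunn's post hoc (Holm adjusted):\n")
  print(as.data.frame(x$pairwise), digits = 4)
  invisible(x)
}

#' Tidy Dunn's pairwise results
#' @param x A `tau_comparison`.
#' @param ... Unused.
#' @export
tidy.tau_comparison <- function(x, ...) x$pairwise

#' One-row Kruskal--Wallis summary
#' @param x A `tau_comparison`.
#' @param ... Unused.
#' @export
glance.tau_comparison <- function(x, ...) x$kruskal

#' @export
print.group_expression_summary <- function(x, ...) {
  cat("Per-group Tau summary:\n")
  print(as.data.frame(x$tau), digits = 4)
  cat("\nTop mean expression proportions per group:\n")
  top <- x$proportions |>
    dplyr::group_by(.data$group) |>
    dplyr::slice_max(.data$mean_proportion, n = 1L) |>
    dplyr::ungroup()
  print(as.data.frame(top), digits = 4)
  invisible(x)
}

#' @export
autoplot.group_expression_summary <- function(object, ...) {
  ggplot2::ggplot(
    object$proportions,
    ggplot2::aes(x = .data$tissue, y = .data$group,
                 fill = .data$mean_proportion)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "mean\nproportion") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Mean expression proportion by group and tissue")
}
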