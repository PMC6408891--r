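#' Tau tissue-specificity index
#'
#' Tau summarises how concentrated a gene's expression is across `n` tissues:
#' \deqn{\tau = \frac{\sum_i (1 - x_i / \max_j x_j)}{n - 1}}
#' It is 0 for perfectly uniform expression, 1 when a single tissue carries
#' all expression, and is invariant to rescaling of the expression vector.
#'
#' @param x Non-negative per-tissue expression vector (length >= 2),
#'   normalized units such as TPM.
#' @return Tau in \[0, 1\]; `NA` (with a warning) for an all-zero vector,
#'   for which specificity is undefined.
#' @examples
#' compute_tau(c(1, 0, 0, 0)) # 1
#' compute_tau(c(5, 5, 5, 5)) # 0
#' compute_tau(c(2, 1, 1, 1)) # 0.5
#' @export
compute_tau <- function(x) {
  if (!is.numeric(x) || length(x) < 2L) {
    abort("`x` must be a numeric vector over at least 2 tissues")
  }
  if (anyNA(x)) abort("`x` contains missing values")
  if (any(x < 0)) abort("expression values must be non-negative")
  m <- max(x)
  if (m == 0) {
    warn("all-zero expression vector: Tau undefined, returning NA")
    return(NA_real_)
  }
  sum(1 - x / m) / (length(x) - 1L)
}

#' Classify a gene as tissue specific
#'
#' Strictly-greater comparison against the threshold (a gene at exactly the
#' threshold is *not* specific); the conventional threshold is 0.8.
#'
#' @param tau Tau value(s) in \[0, 1\] or `NA`.
#' @param threshold Specificity threshold.
#' @return Logical vector; `NA` tau stays unclassified (`NA`).
#' @export
classify_specific <- function(tau, threshold = 0.8) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  ifelse(is.na(tau), NA, tau > threshold)
}

#' Per-tissue expression proportions
#'
#' Divides each tissue's expression by the gene's summed expression over all
#' tissues, so proportions sum to 1 per gene.
#'
#' @param x Non-negative per-tissue vector (length >= 2) with positive sum.
#' @return Vector of proportions summing to 1; all-`NA` (with a warning) for
#'   an all-zero gene.
#' @export
expression_proportions <- function(x) {
  if (!is.numeric(x) || length(x) < 2L) {
    abort("`x` must be a numeric vector over at least 2 tissues")
  }
  if (any(x < 0)) abort("expression values must be non-negative")
  s <- sum(x)
  if (s == 0) {
    warn("all-zero expression vector: proportions undefined, returning NA")
    return(rep(NA_real_, length(x)))
  }
  x / s
}

#' Tissue-specificity profile of an expression matrix
#'
#' Computes Tau, the specificity call, and the dominant tissue for every gene
#' of a gene x tissue expression table.
#'
#' @param expr Expression data: a data frame whose first column is the gene
#'   id and remaining columns are tissues (the TSV layout written by
#'   [read_expression_tsv()]), or a numeric matrix with gene rownames.
#' @param threshold Tau threshold for the specificity call.
#' @param log1p Apply `log1p` to expression values before computing Tau
#'   (kept off by default; raw normalized values are used, but the Tau
#'   literature is split on this).
#' @return Tibble with one row per gene: `gene_id`, `tau`, `is_specific`,
#'   `top_tissue`, `top_proportion`, `n_tissues`. Genes with all-zero
#'   expression carry `NA` tau and are counted in attribute `n_all_zero`.
#' @export
tau_profile <- function(expr, threshold = 0.8, log1p = FALSE) {
  m <- as_expression_matrix(expr)
  vals <- if (log1p) base::log1p(m) else m
  tau <- apply(vals, 1L, function(x) {
    if (max(x) == 0) NA_real_ else sum(1 - x / max(x)) / (length(x) - 1L)
  })
  sums <- rowSums(m)
  top_i <- max.col(m, ties.method = "first")
  out <- tibble(
    gene_id = rownames(m),
    tau = unname(tau),
    is_specific = classify_specific(unname(tau), threshold),
    top_tissue = unname(ifelse(sums > 0, colnames(m)[top_i], NA_character_)),
    top_proportion = unname(
      ifelse(sums > 0, m[cbind(seq_len(nrow(m)), top_i)] / sums, NA_real_)
    ),
    n_tissues = ncol(m)
  )
  n_zero <- sum(sums == 0)
  if (n_zero > 0L) {
    inform(sprintf("%d gene(s) with all-zero expression: Tau undefined", n_zero))
  }
  attr(out, "n_all_zero") <- n_zero
  attr(out, "threshold") <- threshold
  class(out) <- c("tau_profile", class(out))
  out
}

#' Long table of expression proportions for all genes
#'
#' @inheritParams tau_profile
#' @return Long tibble `gene_id`, `tissue`, `proportion`; all-zero genes get
#'   `NA` proportions.
#' @export
proportions_profile <- function(expr) {
  m <- as_expression_matrix(expr)
  s <- rowSums(m)
  p <- m / ifelse(s == 0, NA_real_, s)
  as_tibble(p, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "tissue",
                        values_to = "proportion")
}

as_expression_matrix <- function(expr) {
  if (is.matrix(expr)) {
    m <- expr
    if (is.null(rownames(m))) abort("expression matrix needs gene rownames")
  } else if (is.data.frame(expr)) {
    if (ncol(expr) < 3L) {
      abort("expression table needs a gene id column plus >= 2 tissue columns")
    }
    genes <- as.character(expr[[1L]])
    m <- as.matrix(expr[, -1L, drop = FALSE])
    rownames(m) <- genes
  } else {
    abort("`expr` must be a data frame (gene id + tissues) or a matrix")
  }
  if (!is.numeric(m)) abort("tissue columns must be numeric")
  if (ncol(m) < 2L) abort("need at least 2 tissues")
  if (anyNA(m)) abort("expression values contain NA")
  if (any(m < 0)) abort("expression values must be non-negative")
  if (anyDuplicated(rownames(m))) abort("duplicate gene ids in expression data")
  if (anyDuplicated(colnames(m))) abort("duplicate tissue labels")
  m
}

#' Read a gene x tissue expression TSV
#'
#' First column: gene id; remaining columns: one per tissue, with a header
#' row of tissue labels.
#'
#' @param path TSV file path.
#' @return Tibble in the layout accepted by [tau_profile()].
#' @export
read_expression_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @export
autoplot.tau_profile <- function(object, groups = NULL, ...) {
  df <- object
  thr <- attr(object, "threshold") %||% 0.8
  if (!is.null(groups)) {
    df <- dplyr::left_join(df, normalize_groups(groups), by = "gene_id")
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$tau)) +
      ggplot2::geom_violin(fill = "grey85") +
      ggplot2::geom_jitter(width = 0.12, alpha = 0.4, size = 0.8) +
      ggplot2::geom_hline(yintercept = thr, linetype = 2,
                          colour = "firebrick") +
      ggplot2::labs(y = expression(tau))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$tau)) +
      ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
      ggplot2::geom_vline(xintercept = thr, linetype = 2,
                          colour = "firebrick") +
      ggplot2::labs(x = expression(tau))
  }
  p + ggplot2::labs(title = "Tissue specificity (Tau)")
}
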