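#' Read gene loci from a BED-like TSV
#'
#' Expected columns: `scaffold`, `start`, `stop`, `strand`, `gene_id`, and
#' optionally `group`. Coordinates are stored 0-based half-open internally;
#' tables written 1-based inclusive (a common convention for supplementary
#' coordinate tables) are converted with `one_based = TRUE`, which preserves
#' feature length as `stop - start`.
#'
#' @param x TSV path, or a data frame already holding the columns above.
#' @param one_based Input coordinates are 1-based inclusive.
#' @return Tibble of validated loci (`scaffold`, `start`, `stop`, `strand`,
#'   `gene_id`, and `group` when present).
#' @export
read_loci <- function(x, one_based = FALSE) {
  loci <- if (is.data.frame(x)) as_tibble(x) else {
    readr::read_tsv(x, show_col_types = FALSE)
  }
  need <- c("scaffold", "start", "stop", "strand", "gene_id")
  missing <- setdiff(need, names(loci))
  if (length(missing) > 0L) {
    abort(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (one_based) loci$start <- loci$start - 1L
  bad <- which(loci$start >= loci$stop | loci$start < 0)
  if (length(bad) > 0L) {
    abort(paste0("invalid coordinates (start must be < stop and >= 0) in row(s): ",
                 paste(utils::head(bad, 5L), collapse = ", ")))
  }
  if (!all(loci$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'")
  }
  if (anyDuplicated(loci$gene_id)) {
    dup <- unique(loci$gene_id[duplicated(loci$gene_id)])
    abort(paste0("duplicate gene id(s): ", paste(utils::head(dup, 5L), collapse = ", ")))
  }
  loci
}

#' Scaffold occupancy summary per gene group
#'
#' For each group, counts the scaffolds it occupies and the subset carrying
#' at least `m` group members -- the descriptive statistic used to contrast
#' the scattered non-expanded gene background ("1 scaffold out of 155 with
#' three or more genes") against tandem-expanded groups.
#'
#' @param loci Loci tibble from [read_loci()], with a `group` column (or
#'   supply `groups`).
#' @param groups Optional group assignment (data frame `gene_id`/`group` or
#'   named vector) overriding the `group` column.
#' @param m Member threshold per scaffold.
#' @return A `scaffold_summary`: list with `$by_group` (group, `n_genes`,
#'   `n_scaffolds`, `n_scaffolds_min_m`) and `$by_scaffold` (group, scaffold,
#'   `n_genes`), both sorted deterministically.
#' @export
scaffold_summary <- function(loci, groups = NULL, m = 3) {
  loci <- with_groups(loci, groups)
  by_scaffold <- loci |>
    dplyr::count(.data$group, .data$scaffold, name = "n_genes") |>
    dplyr::arrange(.data$group, .data$scaffold)
  by_group <- by_scaffold |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_scaffolds = dplyr::n(),
      n_scaffolds_min_m = sum(.data$n_genes >= m),
      n_genes = sum(.data$n_genes),
      .groups = "drop"
    ) |>
    dplyr::relocate("n_genes", .after = "group") |>
    dplyr::arrange(.data$group)
  out <- list(by_group = by_group, by_scaffold = by_scaffold, m = m)
  class(out) <- "scaffold_summary"
  out
}

#' @export
print.scaffold_summary <- function(x, ...) {
  cat(sprintf("Scaffold occupancy (threshold m = %d):\n", x$m))
  print(as.data.frame(x$by_group))
  invisible(x)
}

#' Tidy per-group scaffold occupancy
#' @param x A `scaffold_summary`.
#' @param ... Unused.
#' @export
tidy.scaffold_summary <- function(x, ...) x$by_group

#' Detect tandem duplication clusters on scaffolds
#'
#' Within each scaffold, genes are ordered by start coordinate; a cluster is a
#' maximal run of two or more group members in which consecutive members are
#' separated by at most `max_intervening` non-member genes. Strand is ignored
#' for clustering (tandem arrays can contain inversions) but the strand
#' pattern is reported. When `loci` contains only the group's own genes (no
#' background gene complement to count), a distance fallback is used instead:
#' consecutive members at most `max_gap_bp` apart, labelled
#' `method = "distance"`.
#'
#' @param loci All gene loci on the scaffolds (group members plus background
#'   genes), from [read_loci()].
#' @param group Group label whose members are clustered; alternatively
#'   `members` gives gene ids directly.
#' @param members Character vector of member gene ids (overrides `group`).
#' @param max_intervening Maximum number of non-member genes between
#'   consecutive cluster members.
#' @param max_gap_bp Maximum genomic gap for the distance fallback.
#' @return Tibble with one row per cluster: `cluster_id`, `scaffold`,
#'   `n_members`, `members` (list), `start`, `end`, `span_bp`, `strands`,
#'   `n_intervening`, `method`.
#' @export
detect_tandem_clusters <- function(loci, group = NULL, members = NULL,
                                   max_intervening = 5, max_gap_bp = 1e5) {
  if (is.null(members)) {
    if (is.null(group)) abort("give `group` or `members`")
    if (!"group" %in% names(loci)) abort("`loci` has no group column")
    if (!group %in% loci$group) abort(paste0("unknown group label: ", group))
    members <- loci$gene_id[loci$group == group]
  }
  loci <- dplyr::arrange(loci, .data$scaffold, .data$start, .data$stop)
  loci$is_member <- loci$gene_id %in% members
  has_background <- any(!loci$is_member)
  method <- if (has_background) "intervening" else "distance"

  clusters <- loci |>
    dplyr::group_by(.data$scaffold) |>
    dplyr::group_map(~ scan_scaffold(.x, .y$scaffold, max_intervening,
                                     max_gap_bp, method)) |>
    dplyr::bind_rows()
  if (nrow(clusters) == 0L) {
    clusters <- tibble(
      scaffold = character(), n_members = integer(), members = list(),
      start = numeric(), end = numeric(), span_bp = numeric(),
      strands = character(), n_intervening = integer(), method = character()
    )
  }
  clusters |>
    dplyr::arrange(dplyr::desc(.data$n_members), .data$scaffold, .data$start) |>
    dplyr::mutate(cluster_id = dplyr::row_number(), .before = 1L)
}

# one scaffold, genes pre-sorted by start
scan_scaffold <- function(df, scaffold, max_intervening, max_gap_bp, method) {
  idx <- which(df$is_member)
  if (length(idx) < 2L) return(NULL)
  gap_ok <- if (method == "intervening") {
    # non-member genes strictly between consecutive members
    diff(idx) - 1L <= max_intervening
  } else {
    df$start[idx[-1L]] - df$stop[idx[-length(idx)]] <= max_gap_bp
  }
  run_id <- cumsum(c(TRUE, !gap_ok))
  runs <- split(idx, run_id)
  runs <- runs[lengths(runs) >= 2L]
  if (length(runs) == 0L) return(NULL)
  dplyr::bind_rows(lapply(runs, function(ii) {
    tibble(
      scaffold = scaffold,
      n_members = length(ii),
      members = list(df$gene_id[ii]),
      start = min(df$start[ii]),
      end = max(df$stop[ii]),
      span_bp = max(df$stop[ii]) - min(df$start[ii]),
      strands = paste(df$strand[ii], collapse = ""),
      n_intervening = sum(!df$is_member[seq(min(ii), max(ii))]),
      method = method
    )
  }))
}

with_groups <- function(loci, groups) {
  if (!is.null(groups)) {
    loci <- dplyr::select(loci, -dplyr::any_of("group")) |>
      dplyr::inner_join(normalize_groups(groups), by = "gene_id")
  }
  if (!"group" %in% names(loci)) {
    abort("`loci` needs a group column (or pass `groups`)")
  }
  if (anyNA(loci$group)) abort("missing group labels")
  loci
}

#' @export
autoplot.scaffold_summary <- function(object, ...) {
  ggplot2::ggplot(
    object$by_scaffold,
    ggplot2::aes(x = .data$n_genes)
  ) +
    ggplot2::geom_bar(fill = "grey60", colour = "grey20") +
    ggplot2::facet_wrap(~group, scales = "free_y") +
    ggplot2::geom_vline(xintercept = object$m - 0.5, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "genes per scaffold", y = "scaffolds",
                  title = "Scaffold occupancy by group")
}
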