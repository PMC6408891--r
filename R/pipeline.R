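#' Pipeline configuration
#'
#' Collects inputs and thresholds for [run_pipeline()]. Inputs may be file
#' paths (Newick / TSV / FASTA) or in-memory objects; a bundle from
#' [simulate_study()] can be converted directly with
#' [pipeline_config_from_bundle()].
#'
#' @param tree Gene tree: path or `phylo`.
#' @param focal_species Focal lineage species ids.
#' @param expression Optional expression matrix: path or data frame.
#' @param loci Optional gene loci: path or data frame.
#' @param alignments Optional named list; each element a list with `cds`
#'   (path or [codon_alignment()]), optional `protein` (path or named
#'   character; triggers back-translation), optional `tree` (path or
#'   `phylo` for the group's subtree).
#' @param reference_species Species for divergence summaries (default: all
#'   non-focal species in the tree).
#' @param cutoff Expansion size cutoff (default 10 paralogues).
#' @param min_support Branch support threshold (default 0.70).
#' @param tau_threshold Tau specificity threshold (default 0.8).
#' @param alpha Significance level for selection LRTs (default 0.05).
#' @param omega_limit Discard branch omega estimates above this (default 100).
#' @param run_sites Also run the M1a/M2a sites test per group.
#' @param freq Codon frequency model for selection fits.
#' @param m Scaffold co-occupancy threshold (default 3 genes).
#' @param max_intervening Tandem-cluster gap tolerance in genes.
#' @param label_sep Leaf-label separator.
#' @param root_method Rooting policy for unrooted input trees.
#' @param adjust_group_lrts Apply Holm adjustment across the per-group
#'   branch LRT p-values (off by default: groups are reported as separate
#'   tests).
#' @param seed RNG seed recorded and applied at pipeline start.
#' @param out_dir Optional output directory for the report bundle.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(tree, focal_species, expression = NULL,
                            loci = NULL, alignments = NULL,
                            reference_species = NULL, cutoff = 10,
                            min_support = 0.70, tau_threshold = 0.8,
                            alpha = 0.05, omega_limit = 100,
                            run_sites = FALSE, freq = "f3x4", m = 3,
                            max_intervening = 5, label_sep = "_",
                            root_method = "midpoint",
                            adjust_group_lrts = FALSE, seed = NULL,
                            out_dir = NULL) {
  stopifnot(cutoff >= 2, min_support >= 0, min_support <= 1,
            tau_threshold >= 0, tau_threshold <= 1, alpha > 0, alpha < 1,
            omega_limit > 0)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' File paths in the YAML are resolved relative to the YAML's directory.
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments
#'   (alignment entries as a mapping group -> {cds, protein, tree}).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) {
    if (is.null(p)) NULL
    else if (file.exists(p)) p
    else file.path(base, p)
  }
  for (key in c("tree", "expression", "loci")) y[[key]] <- rel(y[[key]])
  if (!is.null(y$alignments)) {
    y$alignments <- lapply(y$alignments, function(a) {
      lapply(a, rel)
    })
  }
  do.call(pipeline_config, y)
}

#' Build a pipeline configuration from a synthetic study bundle
#'
#' @param bundle Result of [simulate_study()].
#' @param ... Overrides passed on to [pipeline_config()].
#' @return A `pipeline_config` running on the in-memory bundle.
#' @export
pipeline_config_from_bundle <- function(bundle, ...) {
  args <- list(
    tree = bundle$tree,
    focal_species = default_species()$focal,
    expression = bundle$expr,
    loci = bundle$loci,
    alignments = bundle$alignments,
    seed = bundle$seed
  )
  do.call(pipeline_config, utils::modifyList(args, list(...)))
}

#' Run the expansion analysis pipeline end to end
#'
#' Stages, in order: expansion detection on the gene tree; per-group
#' subtree extraction and patristic divergence; tissue-specificity and
#' group-comparison analysis of the expression matrix; per-group codon
#' selection tests (M0 vs two-ratio branch model, optional M1a/M2a sites
#' test), with the high-omega post-filter; scaffold co-localization. A
#' failure inside one group's selection fit is caught and recorded without
#' aborting the other groups. Stage outputs land in the returned report
#' (and on disk when `out_dir` is set).
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report`; see [render_report()].
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  results <- list(config = config_echo(config), status = list())

  tree <- load_tree_input(config$tree, config$label_sep)
  if (!ape::is.rooted(tree)) {
    tree <- root_gene_tree(tree, method = config$root_method,
                           label_sep = config$label_sep)
  }
  results$n_leaves <- ape::Ntip(tree)

  # --- detection -----------------------------------------------------------
  expansions <- find_lineage_expansions(
    tree, config$focal_species, cutoff = config$cutoff,
    min_support = config$min_support, label_sep = config$label_sep,
    root_method = "asis"
  )
  results$expansions <- expansions
  results$status$detect <- "ok"
  group_labels <- if (nrow(expansions) > 0L) {
    paste0("group", expansions$group_id)
  } else {
    character()
  }

  sp <- leaf_species(tree, config$label_sep)
  reference <- config$reference_species %||%
    setdiff(unique(sp), config$focal_species)

  gene_groups <- setNames(rep("non_expanded", length(tree$tip.label)),
                          tree$tip.label)
  for (i in seq_len(nrow(expansions))) {
    gene_groups[expansions$members[[i]]] <- group_labels[i]
  }

  if (nrow(expansions) == 0L) {
    inform("no expansions at the configured cutoff; downstream group stages skipped")
  }

  # --- subtrees + divergence ----------------------------------------------
  results$divergence <- purrr::map_dfr(seq_len(nrow(expansions)), function(i) {
    members <- expansions$members[[i]]
    div <- tryCatch(
      patristic_divergence_summary(tree, members, reference,
                                   config$label_sep),
      error = function(e) tibble(n = NA_integer_, q1 = NA_real_,
                                 median = NA_real_, q3 = NA_real_)
    )
    dplyr::mutate(div, group = group_labels[i], .before = 1L)
  })
  results$subtrees <- setNames(
    lapply(seq_len(nrow(expansions)), function(i) {
      extract_group_subtree(tree, expansions$members[[i]],
                            min_support = config$min_support)
    }),
    group_labels
  )
  results$status$subtrees <- "ok"

  # --- expression ----------------------------------------------------------
  if (!is.null(config$expression)) {
    expr <- load_table_input(config$expression, read_expression_tsv)
    expr_groups <- gene_groups[intersect(names(gene_groups), expr[[1L]])]
    absent <- setdiff(unlist(expansions$members), expr[[1L]])
    if (length(absent) > 0L) {
      inform(sprintf(
        "%d expansion gene(s) missing from the expression matrix", length(absent)
      ))
    }
    extra <- setdiff(expr[[1L]], names(gene_groups))
    expr_groups <- c(expr_groups,
                     setNames(rep("non_expanded", length(extra)), extra))
    results$tau <- tau_profile(expr, threshold = config$tau_threshold)
    results$expression_summary <- summarize_by_group(
      expr, expr_groups, threshold = config$tau_threshold
    )
    results$tau_comparison <- tryCatch(
      compare_tau_groups(results$tau, expr_groups),
      error = function(e) {
        results$status$expression <<- paste0("comparison skipped: ",
                                             conditionMessage(e))
        NULL
      }
    )
    results$status$expression <- results$status$expression %||% "ok"
  } else {
    results$status$expression <- "no input"
  }

  # --- selection -----------------------------------------------------------
  if (!is.null(config$alignments) && nrow(expansions) > 0L) {
    results$selection <- list()
    for (i in seq_len(nrow(expansions))) {
      glab <- group_labels[i]
      members <- expansions$members[[i]]
      results$selection[[glab]] <- tryCatch(
        run_group_selection(config, tree, members, glab),
        error = function(e) {
          list(status = paste0("failed: ", conditionMessage(e)))
        }
      )
    }
    if (isTRUE(config$adjust_group_lrts)) {
      ps <- vapply(results$selection, function(s) s$lrt$p_value %||% NA_real_,
                   numeric(1))
      adj <- p.adjust(ps, method = "holm")
      for (g in names(results$selection)) {
        if (!is.null(results$selection[[g]]$lrt)) {
          results$selection[[g]]$lrt$p_adjusted <- adj[[g]]
        }
      }
    }
    results$status$selection <- "ok"
  } else {
    results$status$selection <- "no input"
  }

  # --- co-localization -----------------------------------------------------
  if (!is.null(config$loci)) {
    loci <- load_table_input(config$loci, read_loci)
    loci <- read_loci(loci) # validate whatever came in
    loc_groups <- gene_groups[intersect(names(gene_groups), loci$gene_id)]
    extra <- setdiff(loci$gene_id, names(loc_groups))
    loc_groups <- c(loc_groups,
                    setNames(rep("background", length(extra)), extra))
    loci$group <- unname(loc_groups[loci$gene_id])
    results$scaffolds <- scaffold_summary(loci, m = config$m)
    results$clusters <- purrr::map(
      setNames(group_labels, group_labels),
      function(g) detect_tandem_clusters(loci, group = g,
                                         max_intervening = config$max_intervening)
    )
    results$status$coloc <- "ok"
  } else {
    results$status$coloc <- "no input"
  }

  report <- render_report(results)
  if (!is.null(config$out_dir)) {
    write_report(report, config$out_dir)
  }
  report
}

# selection tests for one detected group
run_group_selection <- function(config, tree, members, glab) {
  entry <- match_alignment_entry(config$alignments, members)
  if (is.null(entry)) {
    return(list(status = "no matching alignment"))
  }
  aln <- load_alignment_entry(entry)
  aln <- clean_alignment(aln)
  ids <- names(aln$sequences)
  fit_tree <- if (!is.null(entry$tree)) {
    load_tree_input(entry$tree, config$label_sep, validate = FALSE)
  } else {
    extract_group_subtree(tree, members, min_support = config$min_support)
  }
  drop <- setdiff(fit_tree$tip.label, ids)
  if (length(drop) > 0L) fit_tree <- ape::drop.tip(fit_tree, drop)
  fg <- intersect(members, ids)
  if (length(fg) == 0L) abort("no group members left after cleaning")
  if (length(setdiff(ids, fg)) == 0L) {
    abort("no background sequences left after cleaning")
  }
  m0 <- fit_m0(aln, fit_tree, freq = config$freq)
  br <- fit_branch_model(aln, fit_tree, foreground = fg, m0 = m0,
                         freq = config$freq)
  test <- lrt(m0, br)
  branches <- filter_high_omega(tidy.codon_fit(br), limit = config$omega_limit)
  positive <- test$p_value < config$alpha &&
    br$params$omega_foreground > 1 &&
    br$params$omega_foreground <= config$omega_limit
  out <- list(
    status = "ok",
    m0 = m0, branch = br, lrt = test,
    branches = branches,
    positive_selection = positive
  )
  if (isTRUE(config$run_sites)) {
    out$sites <- fit_sites_models(aln, fit_tree, freq = config$freq)
  }
  out
}

match_alignment_entry <- function(alignments, members) {
  best <- NULL
  best_ov <- 0
  for (entry in alignments) {
    ids <- alignment_entry_ids(entry)
    ov <- length(intersect(ids, members))
    if (ov > best_ov) {
      best <- entry
      best_ov <- ov
    }
  }
  best
}

alignment_entry_ids <- function(entry) {
  cds <- entry$cds
  if (inherits(cds, "codon_alignment")) return(names(cds$sequences))
  names(as_named_seqs(cds, "DNA"))
}

load_alignment_entry <- function(entry) {
  if (!is.null(entry$protein)) {
    cds <- if (inherits(entry$cds, "codon_alignment")) {
      gsub("-", "", entry$cds$sequences, fixed = TRUE) # unaligned CDS
    } else {
      entry$cds
    }
    return(back_translate(entry$protein, cds))
  }
  if (inherits(entry$cds, "codon_alignment")) return(entry$cds)
  read_codon_alignment(entry$cds)
}

load_tree_input <- function(x, label_sep, validate = TRUE) {
  if (inherits(x, "phylo")) {
    if (validate) as_gene_tree(x, label_sep) else x
  } else if (validate) {
    parse_gene_tree(x, label_sep)
  } else {
    ape::read.tree(x)
  }
}

load_table_input <- function(x, reader) {
  if (is.data.frame(x)) as_tibble(x) else reader(x)
}

config_echo <- function(config) {
  keep <- c("focal_species", "reference_species", "cutoff", "min_support",
            "tau_threshold", "alpha", "omega_limit", "run_sites", "freq",
            "m", "max_intervening", "label_sep", "root_method",
            "adjust_group_lrts", "seed")
  config[keep]
}

#' Assemble the machine-readable pipeline report
#'
#' Combines the stage results into one object with a per-group summary
#' table (size, support, divergence, Tau summary, top tissue, branch LRT,
#' foreground omega with the high-omega filter applied, flagged sites,
#' tandem clusters) plus the full stage outputs and the configuration echo.
#' All fields are present for every group; stages that did not run yield
#' `NA` values.
#'
#' @param results Internal stage results from [run_pipeline()].
#' @return A `pipeline_report` with elements `summary` (tibble), `stages`,
#'   `status`, and `config`.
#' @export
render_report <- function(results) {
  exp <- results$expansions
  glabs <- if (nrow(exp) > 0L) paste0("group", exp$group_id) else character()
  rows <- purrr::map_dfr(seq_along(glabs), function(i) {
    g <- glabs[i]
    sel <- results$selection[[g]]
    tau_row <- if (!is.null(results$expression_summary)) {
      dplyr::filter(results$expression_summary$tau, .data$group == g)
    } else NULL
    top_prop <- if (!is.null(results$expression_summary)) {
      results$expression_summary$proportions |>
        dplyr::filter(.data$group == g) |>
        dplyr::slice_max(.data$mean_proportion, n = 1L, with_ties = FALSE)
    } else NULL
    div <- if (!is.null(results$divergence) && nrow(results$divergence) > 0L) {
      dplyr::filter(results$divergence, .data$group == g)
    } else NULL
    clus <- results$clusters[[g]]
    tibble(
      group = g,
      size = exp$size[i],
      support = exp$support[i],
      n_species = exp$n_species[i],
      divergence_median = div$median %||% NA_real_,
      divergence_q1 = div$q1 %||% NA_real_,
      divergence_q3 = div$q3 %||% NA_real_,
      mean_tau = if (!is.null(tau_row) && nrow(tau_row)) tau_row$mean_tau else NA_real_,
      prop_specific = if (!is.null(tau_row) && nrow(tau_row)) tau_row$prop_specific else NA_real_,
      top_tissue = if (!is.null(top_prop) && nrow(top_prop)) top_prop$tissue else NA_character_,
      lrt_statistic = sel$lrt$statistic %||% NA_real_,
      lrt_p = sel$lrt$p_value %||% NA_real_,
      omega_foreground = sel$branch$params$omega_foreground %||% NA_real_,
      omega_background = sel$branch$params$omega_background %||% NA_real_,
      omega_m0 = sel$m0$params$omega %||% NA_real_,
      positive_selection = sel$positive_selection %||% NA,
      n_selected_sites = if (!is.null(sel$sites)) {
        sum(sel$sites$site_posteriors$selected)
      } else NA_integer_,
      n_tandem_clusters = if (!is.null(clus)) nrow(clus) else NA_integer_,
      n_scaffolds = scaffold_count(results$scaffolds, g)
    )
  })
  if (length(glabs) == 0L) rows <- empty_report_summary()
  out <- list(
    summary = rows,
    stages = results[setdiff(names(results), c("config", "status"))],
    status = results$status,
    config = results$config
  )
  class(out) <- "pipeline_report"
  out
}

scaffold_count <- function(scaffolds, g) {
  if (is.null(scaffolds)) return(NA_integer_)
  row <- dplyr::filter(scaffolds$by_group, .data$group == g)
  if (nrow(row) == 0L) NA_integer_ else row$n_scaffolds
}

empty_report_summary <- function() {
  tibble(
    group = character(), size = integer(), support = numeric(),
    n_species = integer(), divergence_median = numeric(),
    divergence_q1 = numeric(), divergence_q3 = numeric(),
    mean_tau = numeric(), prop_specific = numeric(),
    top_tissue = character(), lrt_statistic = numeric(), lrt_p = numeric(),
    omega_foreground = numeric(), omega_background = numeric(),
    omega_m0 = numeric(), positive_selection = logical(),
    n_selected_sites = integer(), n_tandem_clusters = integer(),
    n_scaffolds = integer()
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Expansion pipeline report: %d group(s)\n", nrow(x$summary)))
  st <- unlist(x$status)
  cat(paste0("  stages: ",
             paste(names(st), st, sep = "=", collapse = ", ")), "\n")
  if (nrow(x$summary) > 0L) {
    print(as.data.frame(x$summary[, c("group", "size", "support", "mean_tau",
                                      "lrt_p", "omega_foreground",
                                      "positive_selection",
                                      "n_tandem_clusters")]),
          digits = 4)
  }
  invisible(x)
}

#' Tidy the per-group pipeline summary
#' @param x A `pipeline_report`.
#' @param ... Unused.
#' @export
tidy.pipeline_report <- function(x, ...) x$summary

# write the report bundle: JSON summary + per-stage TSVs
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$summary, file.path(dir, "summary.tsv"))
  payload <- list(
    config = report$config,
    status = report$status,
    summary = report$summary
  )
  if (!is.null(report$stages$tau_comparison)) {
    payload$kruskal_wallis <- report$stages$tau_comparison$kruskal
    payload$dunn_pairwise <- report$stages$tau_comparison$pairwise
    readr::write_tsv(report$stages$tau_comparison$pairwise,
                     file.path(dir, "dunn_pairwise.tsv"))
  }
  if (!is.null(report$stages$tau)) {
    readr::write_tsv(report$stages$tau, file.path(dir, "tau_per_gene.tsv"))
  }
  if (!is.null(report$stages$expansions)) {
    write_expansions(report$stages$expansions,
                     tsv = file.path(dir, "expansions.tsv"))
  }
  if (!is.null(report$stages$scaffolds)) {
    readr::write_tsv(report$stages$scaffolds$by_group,
                     file.path(dir, "scaffold_summary.tsv"))
  }
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
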