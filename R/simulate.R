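# Synthetic data generators. They emulate the statistical structure of the
# study inputs -- multi-species gene trees carrying lineage-restricted
# duplication bursts, tissue-structured expression matrices, and scaffold
# layouts mixing tandem arrays with dispersed genes -- with machine-readable
# ground truth, so every analysis stage can be validated without external
# downloads. All generators are deterministic under a fixed seed.

default_species <- function() {
  list(
    focal = c("OCTBM", "OCMIN", "ESCOL"),          # cephalopod-like lineage
    outgroup = c("CRAGI", "LOTGI", "MIZYE")        # other molluscs
  )
}

default_tissues <- function() {
  c("sucker", "testes", "embryo", "ova", "skin", "psg", "viscera",
    "sub_brain", "supra_brain", "optic_lobe", "axial_nerve_cord", "retina")
}

#' Simulate a gene tree with planted lineage-restricted expansions
#'
#' Builds a gene family tree over a focal lineage plus outgroup species:
#' background gene families follow the species topology (with occasional
#' within-species duplications, so small focal-only cherries occur
#' naturally), while each planted expansion is a focal-only clade of the
#' requested size grafted next to a background family that acts as its
#' sister outgroup. Internal nodes carry support values; planted stems are
#' well supported. Because every background family contains outgroup
#' leaves and within-family duplications stay small, no non-planted
#' focal-only clade can reach typical expansion cutoffs -- recovery of the
#' planted truth is therefore well defined.
#'
#' @param n_background Number of background gene families.
#' @param planted_sizes Integer vector: leaf count of each planted
#'   focal-only expansion (>= 2).
#' @param focal_species,outgroup_species Species id sets.
#' @param dup_prob Probability that a background gene acquires a
#'   within-species duplicate.
#' @param stem_length Branch length of each planted clade's stem.
#' @param support_range Range of support values for ordinary internal nodes.
#' @param low_support_prob Fraction of ordinary nodes downgraded to low
#'   support (uniform on 0.3--0.7), emulating poorly resolved splits.
#' @param seed Optional RNG seed.
#' @return List: `tree` (a `gene_tree`), `truth` (tibble `clade_id`,
#'   `size`, `members` list column), and `groups` (named vector gene id ->
#'   `group<k>` / `"non_expanded"`).
#' @export
simulate_gene_tree <- function(n_background = 30, planted_sizes = c(12L, 15L),
                               focal_species = default_species()$focal,
                               outgroup_species = default_species()$outgroup,
                               dup_prob = 0.08, stem_length = 0.4,
                               support_range = c(0.75, 1),
                               low_support_prob = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(planted_sizes < 2L)) abort("planted sizes must be >= 2")
  if (n_background < length(planted_sizes) + 1L) {
    abort("need at least one background family per planted clade, plus one")
  }
  rsup <- function(n = 1L) {
    s <- round(runif(n, support_range[1L], support_range[2L]), 3)
    low <- runif(n) < low_support_prob
    s[low] <- round(runif(sum(low), 0.3, 0.7), 3)
    s
  }
  rlen <- function(n = 1L) round(rexp(n, rate = 4) + 0.02, 4)

  # one background family: species topology with length jitter and
  # occasional within-species duplicate cherries
  family_newick <- function(fam) {
    leaf <- function(sp) {
      ids <- paste0(sp, "_", fam, "g", seq_len(1L + rbinom(1L, 1L, dup_prob)))
      if (length(ids) == 1L) {
        sprintf("%s:%s", ids, rlen())
      } else {
        sprintf("(%s:%s,%s:%s)%s:%s", ids[1L], rlen(), ids[2L], rlen(),
                rsup(), rlen())
      }
    }
    clade <- function(members) {
      if (length(members) == 1L) return(members)
      k <- sample.int(length(members) - 1L, 1L)
      sprintf("(%s,%s)%s:%s", clade(members[seq_len(k)]),
              clade(members[-seq_len(k)]), rsup(), rlen())
    }
    focal_part <- clade(vapply(focal_species, leaf, character(1)))
    out_part <- clade(vapply(outgroup_species, leaf, character(1)))
    sprintf("(%s,%s)%s:%s", focal_part, out_part, rsup(), rlen())
  }

  planted_newick <- function(k, size) {
    sp_cycle <- rep_len(focal_species, size)
    tips <- sprintf("%s_exp%dg%d:%s", sp_cycle, k, seq_len(size), rlen(size))
    clade <- function(members) {
      if (length(members) == 1L) return(members)
      cut <- sample.int(length(members) - 1L, 1L)
      sprintf("(%s,%s)%s:%s", clade(members[seq_len(cut)]),
              clade(members[-seq_len(cut)]),
              round(runif(1L, 0.85, 1), 3), rlen())
    }
    inner <- clade(tips)
    # planted stem: well supported, positive length
    sub("(:[0-9.]+)$", "", inner) |>
      (\(x) sprintf("%s:%s", x, stem_length))()
  }

  fams <- vapply(seq_len(n_background), family_newick, character(1))
  slots <- as.list(fams)
  # pair each planted clade with a background family as guaranteed sister
  for (k in seq_along(planted_sizes)) {
    host <- k # families are exchangeable; take the k-th
    slots[[host]] <- sprintf("(%s,%s)%s:%s", planted_newick(k, planted_sizes[k]),
                             slots[[host]], round(runif(1L, 0.9, 1), 3),
                             rlen())
  }
  backbone <- function(items) {
    if (length(items) == 1L) return(items[[1L]])
    k <- sample.int(length(items) - 1L, 1L)
    sprintf("(%s,%s)%s:%s", backbone(items[seq_len(k)]),
            backbone(items[-seq_len(k)]), rsup(), rlen())
  }
  ord <- sample.int(length(slots))
  nwk <- paste0(backbone(slots[ord]), ";")
  tree <- parse_gene_tree(nwk)

  truth <- tibble(
    clade_id = paste0("group", seq_along(planted_sizes)),
    size = as.integer(planted_sizes),
    members = lapply(seq_along(planted_sizes), function(k) {
      grep(paste0("_exp", k, "g"), tree$tip.label, value = TRUE)
    })
  )
  groups <- setNames(rep("non_expanded", length(tree$tip.label)),
                     tree$tip.label)
  for (k in seq_along(planted_sizes)) {
    groups[truth$members[[k]]] <- truth$clade_id[k]
  }
  list(tree = tree, truth = truth, groups = groups)
}

#' Simulate a tissue-structured expression matrix
#'
#' Tissue-specific genes get one dominant tissue whose mean expression is
#' `fold` times the baseline; broadly expressed genes get near-uniform means
#' with mild lognormal variation. Observed values add gamma noise with the
#' given dispersion (variance = dispersion * mean^2), so Tau behaves like it
#' does on normalized transcriptome quantifications. Genes in an expanded
#' group are more often tissue specific and share a group "home" tissue,
#' emulating expansions whose members converge on a novel expression domain.
#'
#' @param gene_ids Character vector of gene ids.
#' @param groups Named group assignment (gene id -> group label); genes of
#'   the same non-background group share a home tissue.
#' @param tissues Tissue labels (>= 2).
#' @param specific_fraction Probability that a gene is tissue specific:
#'   named vector with entries `expanded` and `non_expanded`.
#' @param fold Dominant-tissue fold change over baseline for specific genes.
#' @param dispersion Gamma noise dispersion (0 = noiseless means).
#' @param baseline Baseline mean expression.
#' @param broad_sd Lognormal standard deviation of broad genes' per-tissue
#'   means (0 = exactly uniform means).
#' @param seed Optional RNG seed.
#' @return List: `expr` (tibble, gene_id + one column per tissue) and
#'   `truth` (tibble `gene_id`, `class`, `dominant_tissue`).
#' @export
simulate_expression <- function(gene_ids, groups = NULL,
                                tissues = default_tissues(),
                                specific_fraction = c(expanded = 0.7,
                                                      non_expanded = 0.25),
                                fold = 50, dispersion = 0.2, baseline = 5,
                                broad_sd = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(tissues) < 2L) abort("need at least 2 tissues")
  if (fold <= 1) abort("`fold` must exceed 1")
  groups <- groups %||% setNames(rep("non_expanded", length(gene_ids)),
                                 gene_ids)
  groups <- groups[gene_ids]
  grp_levels <- setdiff(unique(groups), "non_expanded")
  home <- setNames(sample(tissues, length(grp_levels), replace = TRUE),
                   grp_levels)

  n <- length(gene_ids)
  p_spec <- ifelse(groups == "non_expanded",
                   specific_fraction[["non_expanded"]],
                   specific_fraction[["expanded"]])
  is_spec <- runif(n) < p_spec
  dominant <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (!is_spec[i]) next
    dominant[i] <- if (groups[i] != "non_expanded" && runif(1) < 0.7) {
      home[[groups[i]]]
    } else {
      sample(tissues, 1L)
    }
  }
  m <- matrix(0, n, length(tissues), dimnames = list(gene_ids, tissues))
  for (i in seq_len(n)) {
    mu <- if (is_spec[i]) {
      ifelse(tissues == dominant[i], baseline * fold, baseline)
    } else {
      if (broad_sd > 0) baseline * exp(rnorm(length(tissues), 0, broad_sd))
      else rep(baseline, length(tissues))
    }
    m[i, ] <- if (dispersion > 0) {
      rgamma(length(tissues), shape = 1 / dispersion,
             rate = 1 / (mu * dispersion))
    } else {
      mu
    }
  }
  expr <- dplyr::bind_cols(tibble(gene_id = gene_ids),
                           as_tibble(round(m, 4)))
  truth <- tibble(gene_id = gene_ids,
                  class = ifelse(is_spec, "specific", "broad"),
                  dominant_tissue = dominant)
  list(expr = expr, truth = truth)
}

#' Simulate scaffold layouts with planted tandem arrays
#'
#' Selected groups contribute tandem arrays: runs of group genes on one
#' scaffold with a Poisson-distributed number of background filler genes
#' between consecutive members. All remaining genes are scattered across
#' scaffolds at non-overlapping positions.
#'
#' @param gene_ids Gene ids to place.
#' @param groups Named group assignment (gene id -> group).
#' @param cluster_spec Tibble/data frame with columns `group` and `size`:
#'   each row plants one tandem array of `size` members of `group` (sizes
#'   are capped at group membership).
#' @param n_scaffolds Number of scaffolds for scattered genes.
#' @param intervening_rate Poisson mean of filler genes between consecutive
#'   array members.
#' @param gene_length_range,gap_range Uniform ranges (bp) for gene lengths
#'   and intergenic gaps.
#' @param seed Optional RNG seed.
#' @return List: `loci` (tibble as from [read_loci()], including filler
#'   genes labelled group `"background"`) and `truth` (tibble `cluster_id`,
#'   `group`, `scaffold`, `members` list column).
#' @export
simulate_scaffolds <- function(gene_ids, groups,
                               cluster_spec = NULL,
                               n_scaffolds = 40,
                               intervening_rate = 1,
                               gene_length_range = c(1e3, 5e3),
                               gap_range = c(2e3, 2e4),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  groups <- groups[gene_ids]
  rlen_bp <- function(n) round(runif(n, gene_length_range[1L],
                                     gene_length_range[2L]))
  rgap <- function(n) round(runif(n, gap_range[1L], gap_range[2L]))
  rows <- list()
  truth <- list()
  placed <- character()
  filler_i <- 0L
  if (!is.null(cluster_spec)) {
    stopifnot(all(c("group", "size") %in% names(cluster_spec)))
    for (r in seq_len(nrow(cluster_spec))) {
      g <- cluster_spec$group[r]
      avail <- setdiff(gene_ids[groups == g], placed)
      k <- min(cluster_spec$size[r], length(avail))
      if (k < 2L) {
        warn(sprintf("group %s has fewer than 2 unplaced genes; array skipped", g))
        next
      }
      members <- avail[seq_len(k)]
      placed <- c(placed, members)
      scaf <- sprintf("scaffold_T%02d", r)
      pos <- 1e4
      arr <- list()
      for (j in seq_len(k)) {
        if (j > 1L) {
          for (f in seq_len(rpois(1L, intervening_rate))) {
            filler_i <- filler_i + 1L
            len <- rlen_bp(1L)
            arr[[length(arr) + 1L]] <- tibble(
              scaffold = scaf, start = pos, stop = pos + len,
              strand = sample(c("+", "-"), 1L),
              gene_id = sprintf("BG_fill%04d", filler_i),
              group = "background"
            )
            pos <- pos + len + rgap(1L)
          }
        }
        len <- rlen_bp(1L)
        arr[[length(arr) + 1L]] <- tibble(
          scaffold = scaf, start = pos, stop = pos + len,
          strand = sample(c("+", "-"), 1L),
          gene_id = members[j], group = g
        )
        pos <- pos + len + rgap(1L)
      }
      rows <- c(rows, arr)
      truth[[length(truth) + 1L]] <- tibble(
        cluster_id = sprintf("planted%02d", r), group = g, scaffold = scaf,
        members = list(members)
      )
    }
  }
  rest <- setdiff(gene_ids, placed)
  if (length(rest) > 0L) {
    scaf_of <- sample(sprintf("scaffold%03d", seq_len(n_scaffolds)),
                      length(rest), replace = TRUE)
    for (scaf in unique(scaf_of)) {
      ids <- rest[scaf_of == scaf]
      pos <- 1e4
      for (id in ids) {
        len <- rlen_bp(1L)
        rows[[length(rows) + 1L]] <- tibble(
          scaffold = scaf, start = pos, stop = pos + len,
          strand = sample(c("+", "-"), 1L),
          gene_id = id, group = unname(groups[id])
        )
        pos <- pos + len + rgap(1L)
      }
    }
  }
  loci <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$scaffold, .data$start)
  truth <- if (length(truth) > 0L) dplyr::bind_rows(truth) else {
    tibble(cluster_id = character(), group = character(),
           scaffold = character(), members = list())
  }
  list(loci = loci, truth = truth)
}

#' Generate a complete synthetic study bundle
#'
#' Chains the generators into one coherent data set: a gene tree with
#' planted expansions, per-group codon alignments simulated on the extracted
#' group + outgroup subtrees under known foreground/background dN/dS, a
#' tissue expression matrix over all genes, and scaffold loci with planted
#' tandem arrays for the expanded groups. A single root seed spawns
#' independent sub-seeds per generator, so components can be regenerated
#' independently.
#'
#' @param seed Root seed (integer).
#' @param n_background,planted_sizes Passed to [simulate_gene_tree()].
#' @param n_codons Codon alignment length per group.
#' @param omega_bg,omega_fg Background/foreground dN/dS for the per-group
#'   codon alignments (foreground = the planted clade).
#' @param kappa Transition/transversion ratio for codon simulation.
#' @param min_support Support threshold used when extracting group
#'   subtrees for the codon simulations.
#' @param tissues,fold,dispersion Passed to [simulate_expression()].
#' @param cluster_sizes Integer vector: one planted tandem array size per
#'   planted group (recycled).
#' @param dir Optional directory: when given, all components are written as
#'   the plain-text formats the pipeline consumes (Newick, FASTA, TSV) plus
#'   JSON truth tables.
#' @return List with `tree`, `truth`, `groups`, `expr`, `expr_truth`,
#'   `loci`, `loci_truth`, `alignments` (per group: `cds`, `protein`,
#'   `tree`, `foreground`), and `paths` when `dir` was given.
#' @export
simulate_study <- function(seed = 20190227, n_background = 30,
                           planted_sizes = c(12L, 15L), n_codons = 150,
                           omega_bg = 0.2, omega_fg = 1.5, kappa = 2,
                           min_support = 0.7, tissues = default_tissues(),
                           fold = 50, dispersion = 0.2,
                           cluster_sizes = c(4L, 5L), dir = NULL) {
  seeds <- derive_seeds(seed, 4L)
  sim_tree <- simulate_gene_tree(n_background = n_background,
                                 planted_sizes = planted_sizes,
                                 seed = seeds[1L])
  tree <- sim_tree$tree
  groups <- sim_tree$groups

  expr_sim <- simulate_expression(names(groups), groups, tissues = tissues,
                                  fold = fold, dispersion = dispersion,
                                  seed = seeds[2L])

  cluster_spec <- tibble(
    group = sim_tree$truth$clade_id,
    size = rep_len(cluster_sizes, nrow(sim_tree$truth))
  )
  scaf_sim <- simulate_scaffolds(names(groups), groups,
                                 cluster_spec = cluster_spec,
                                 seed = seeds[3L])

  set.seed(seeds[4L])
  alignments <- list()
  for (k in seq_len(nrow(sim_tree$truth))) {
    gid <- sim_tree$truth$clade_id[k]
    members <- sim_tree$truth$members[[k]]
    sub <- extract_group_subtree(tree, members, min_support = min_support)
    # rescale to codon-model-friendly branch lengths
    sub$edge.length <- pmin(sub$edge.length, 1) * 0.5
    sim <- simulate_codon_alignment(sub, n_codons = n_codons, kappa = kappa,
                                    omega = omega_bg, foreground = members,
                                    omega_fg = omega_fg)
    alignments[[gid]] <- list(
      cds = sim$aln,
      protein = translate_codon_alignment(sim$aln),
      tree = sim$tree,
      foreground = members
    )
  }

  out <- list(
    seed = seed,
    tree = tree,
    truth = sim_tree$truth,
    groups = groups,
    expr = expr_sim$expr,
    expr_truth = expr_sim$truth,
    loci = scaf_sim$loci,
    loci_truth = scaf_sim$truth,
    alignments = alignments
  )
  if (!is.null(dir)) {
    out$paths <- write_study_bundle(out, dir)
  }
  out
}

derive_seeds <- function(seed, n) {
  # spread a root seed into distinct 31-bit sub-seeds
  (as.integer(seed) + 104729L * seq_len(n)) %% 2147483647L
}

write_study_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    tree = file.path(dir, "gene_tree.nwk"),
    expression = file.path(dir, "expression.tsv"),
    loci = file.path(dir, "loci.tsv"),
    groups = file.path(dir, "groups.tsv"),
    truth = file.path(dir, "truth.json")
  )
  ape::write.tree(bundle$tree, paths$tree)
  readr::write_tsv(bundle$expr, paths$expression)
  readr::write_tsv(bundle$loci, paths$loci)
  readr::write_tsv(tibble(gene_id = names(bundle$groups),
                          group = unname(bundle$groups)), paths$groups)
  truth <- list(
    planted_clades = lapply(seq_len(nrow(bundle$truth)), function(k) {
      list(clade_id = bundle$truth$clade_id[k],
           size = bundle$truth$size[k],
           members = bundle$truth$members[[k]])
    }),
    expression = bundle$expr_truth,
    clusters = lapply(seq_len(nrow(bundle$loci_truth)), function(k) {
      list(cluster_id = bundle$loci_truth$cluster_id[k],
           group = bundle$loci_truth$group[k],
           scaffold = bundle$loci_truth$scaffold[k],
           members = bundle$loci_truth$members[[k]])
    })
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  aln_dir <- file.path(dir, "alignments")
  dir.create(aln_dir, showWarnings = FALSE)
  for (gid in names(bundle$alignments)) {
    al <- bundle$alignments[[gid]]
    cds_path <- file.path(aln_dir, paste0(gid, "_cds.fasta"))
    prot_path <- file.path(aln_dir, paste0(gid, "_protein.fasta"))
    tree_path <- file.path(aln_dir, paste0(gid, "_subtree.nwk"))
    write_codon_alignment(al$cds, cds_path)
    writeLines(paste0(">", names(al$protein), "\n", unname(al$protein)),
               prot_path)
    ape::write.tree(al$tree, tree_path)
    paths[[paste0("alignment_", gid)]] <- cds_path
  }
  paths
}
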