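test_that("gene tree simulation plants exact focal-only clades deterministically", {
  sim <- simulate_gene_tree(n_background = 12, planted_sizes = c(12L, 10L),
                            seed = 77)
  tree <- sim$tree
  # planted clades exist as exact nodes
  for (k in seq_len(nrow(sim$truth))) {
    members <- sim$truth$members[[k]]
    expect_equal(length(members), sim$truth$size[k])
    mrca <- ape::getMRCA(tree, members)
    below <- tree$tip.label[phangorn::Descendants(tree, mrca, "tips")[[1]]]
    expect_setequal(below, members)
    sp <- unique(sub("_.*$", "", members))
    expect_true(all(sp %in% default_species()$focal))
  }
  # same seed twice: byte-identical Newick
  sim2 <- simulate_gene_tree(n_background = 12, planted_sizes = c(12L, 10L),
                             seed = 77)
  expect_identical(ape::write.tree(sim$tree), ape::write.tree(sim2$tree))
  # different seed: different tree
  sim3 <- simulate_gene_tree(n_background = 12, planted_sizes = c(12L, 10L),
                             seed = 78)
  expect_false(identical(ape::write.tree(sim$tree), ape::write.tree(sim3$tree)))
  # group labels cover every leaf
  expect_setequal(names(sim$groups), tree$tip.label)
  expect_error(simulate_gene_tree(planted_sizes = 1L), ">= 2")
})

test_that("no-expansion and no-focal configurations yield empty detections", {
  sim <- simulate_gene_tree(n_background = 10, planted_sizes = integer(0),
                            seed = 5)
  got <- find_lineage_expansions(sim$tree, default_species()$focal,
                                 cutoff = 10, root_method = "asis")
  expect_equal(nrow(got), 0L)
  got2 <- find_lineage_expansions(sim$tree, "NOSUCH", cutoff = 10,
                                  root_method = "asis")
  expect_equal(nrow(got2), 0L)
})

test_that("expression simulation calibrates Tau by construction", {
  genes <- paste0("g", 1:120)
  groups <- setNames(rep(c("group1", "non_expanded"), c(40, 80)), genes)
  sim <- simulate_expression(genes, groups, seed = 88)
  expect_identical(simulate_expression(genes, groups, seed = 88)$expr,
                   sim$expr)
  prof <- suppressMessages(tau_profile(sim$expr))
  joined <- dplyr::inner_join(prof, sim$truth, by = "gene_id")
  spec_tau <- joined$tau[joined$class == "specific"]
  expect_gte(mean(spec_tau > 0.8, na.rm = TRUE), 0.95)
  # noiseless uniform broad genes: Tau exactly 0
  flat <- simulate_expression(genes[1:20],
                              setNames(rep("non_expanded", 20), genes[1:20]),
                              specific_fraction = c(expanded = 0,
                                                    non_expanded = 0),
                              dispersion = 0, broad_sd = 0, seed = 1)
  expect_equal(tau_profile(flat$expr)$tau, rep(0, 20))
  expect_error(simulate_expression(genes, groups, tissues = "one"),
               "2 tissues")
})

test_that("scaffold simulation is deterministic with exact planted arrays", {
  genes <- paste0("g", 1:40)
  groups <- setNames(rep(c("group1", "non_expanded"), c(15, 25)), genes)
  spec <- tibble::tibble(group = "group1", size = 4)
  s1 <- simulate_scaffolds(genes, groups, cluster_spec = spec, seed = 9)
  s2 <- simulate_scaffolds(genes, groups, cluster_spec = spec, seed = 9)
  expect_identical(s1$loci, s2$loci)
  expect_equal(nrow(s1$truth), 1L)
  expect_equal(length(s1$truth$members[[1]]), 4L)
  # intervals valid and non-overlapping per scaffold
  loci <- read_loci(s1$loci)
  by_scaf <- split(loci, loci$scaffold)
  for (sc in by_scaf) {
    sc <- sc[order(sc$start), ]
    if (nrow(sc) > 1) expect_true(all(sc$start[-1] >= sc$stop[-nrow(sc)]))
  }
  # planted array with zero intervening genes: exact recovery at gap 0
  s0 <- simulate_scaffolds(genes, groups, cluster_spec = spec,
                           intervening_rate = 0, seed = 10)
  got <- detect_tandem_clusters(s0$loci, group = "group1",
                                max_intervening = 0)
  expect_true(any(vapply(got$members, function(m) {
    identical(sort(m), sort(s0$truth$members[[1]]))
  }, logical(1))))
  # all genes scattered: no planted clusters reported
  none <- simulate_scaffolds(genes, groups, cluster_spec = NULL,
                             n_scaffolds = 40, seed = 11)
  expect_equal(nrow(none$truth), 0L)
})

test_that("study bundles are coherent and reproducible end to end", {
  b1 <- simulate_study(seed = 303, n_background = 10,
                       planted_sizes = c(10L, 11L), n_codons = 40)
  b2 <- simulate_study(seed = 303, n_background = 10,
                       planted_sizes = c(10L, 11L), n_codons = 40)
  expect_identical(ape::write.tree(b1$tree), ape::write.tree(b2$tree))
  expect_identical(b1$expr, b2$expr)
  expect_identical(b1$loci, b2$loci)
  expect_identical(b1$alignments$group1$cds$sequences,
                   b2$alignments$group1$cds$sequences)
  # alignments cover the planted members plus outgroup context
  for (k in seq_len(nrow(b1$truth))) {
    gid <- b1$truth$clade_id[k]
    ids <- names(b1$alignments[[gid]]$cds$sequences)
    expect_true(all(b1$truth$members[[k]] %in% ids))
    expect_gt(length(setdiff(ids, b1$truth$members[[k]])), 0L)
  }
  # bundle writes the plain-text formats the pipeline consumes
  dir <- withr::local_tempdir()
  b3 <- simulate_study(seed = 303, n_background = 10,
                       planted_sizes = c(10L, 11L), n_codons = 40, dir = dir)
  expect_true(file.exists(file.path(dir, "gene_tree.nwk")))
  expect_true(file.exists(file.path(dir, "expression.tsv")))
  expect_true(file.exists(file.path(dir, "loci.tsv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  expect_true(file.exists(file.path(dir, "alignments", "group1_cds.fasta")))
  reread <- read_codon_alignment(file.path(dir, "alignments",
                                           "group1_cds.fasta"))
  expect_equal(reread$sequences, b3$alignments$group1$cds$sequences)
})
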