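test_that("Newick parsing reads supports, lengths and polytomies", {
  tr <- parse_gene_tree("((A_g1:0.1,A_g2:0.1)0.9:0.2,B_g1:0.3);")
  expect_s3_class(tr, "gene_tree")
  expect_equal(ape::Ntip(tr), 3L)
  expect_equal(sort(unname(leaf_species(tr))), c("A", "A", "B"))
  sup <- node_support(tr)
  expect_true(0.9 %in% sup)

  # absent branch lengths stay missing, not zero
  tr2 <- parse_gene_tree("((A_g1,A_g2),(B_g1,B_g2));")
  expect_null(tr2$edge.length)

  # polytomies preserved
  tr3 <- parse_gene_tree("(A_g1:1,A_g2:1,B_g1:1,B_g2:1);")
  expect_equal(tr3$Nnode, 1L)

  # round trip: parse -> serialize -> parse is isomorphic with equal lengths
  txt <- ape::write.tree(tr)
  tr_rt <- parse_gene_tree(txt)
  expect_true(ape::all.equal.phylo(tr, tr_rt, use.edge.length = TRUE))
})

test_that("Newick parse errors carry positions; label scheme is enforced", {
  expect_error(parse_gene_tree("((A_g1,B_g1);"), "unclosed")
  expect_error(parse_gene_tree("(A_g1,B_g1))x;"), "position")
  expect_error(parse_gene_tree("((A_g1:1,A_g2:1):1,Bg1:1);"), "Bg1")
  expect_error(parse_gene_tree("((A_g1:1,A_g2:1):1,B_g1:1);",
                               species = c("A")), "unknown species")
  expect_error(as_gene_tree(ape::read.tree(text = "(A_g1:1,B_g1:1);")),
               "at least 3")
})

test_that("lineage expansion detection matches the worked examples", {
  tr <- parse_gene_tree("(((c1_a:1,c1_b:1):1,(c2_a:1,c2_b:1):1):1,(x1_a:1,x2_a:1):1);")
  got <- find_lineage_expansions(tr, c("c1", "c2"), cutoff = 3)
  expect_equal(nrow(got), 1L)
  expect_equal(got$size, 4L)
  expect_setequal(got$members[[1]], c("c1_a", "c1_b", "c2_a", "c2_b"))

  expect_equal(nrow(find_lineage_expansions(tr, c("c1", "c2"), cutoff = 5)), 0L)
  expect_equal(nrow(find_lineage_expansions(tr, "zz", cutoff = 2)), 0L)
  expect_error(find_lineage_expansions(tr, "c1", cutoff = 1), "cutoff")

  # all leaves focal: degenerate root group with a warning
  expect_warning(
    deg <- find_lineage_expansions(tr, c("c1", "c2", "x1", "x2"), cutoff = 2),
    "degenerate"
  )
  expect_equal(deg$size, 6L)
})

test_that("detection equals brute-force node enumeration on random trees", {
  set.seed(42)
  for (i in 1:60) {
    rs <- random_species_tree(sample(8:40, 1))
    cutoff <- sample(2:5, 1)
    ms <- sample(c(NA, 0.7), 1)
    ms <- if (is.na(ms)) NULL else ms
    if (all(sub("_.*$", "", rs$tree$tip.label) %in% rs$focal)) next
    got <- find_lineage_expansions(rs$tree, rs$focal, cutoff = cutoff,
                                   min_support = ms, root_method = "asis")
    want <- oracle_expansions(rs$tree, rs$focal, cutoff, ms)
    expect_true(compare_member_sets(got$members, want),
                info = sprintf("tree %d (cutoff %d)", i, cutoff))
  }
})

test_that("detected groups are maximal and monotone in cutoff and support", {
  set.seed(7)
  for (i in 1:25) {
    rs <- random_species_tree(sample(10:40, 1), p_focal = 0.7)
    if (all(sub("_.*$", "", rs$tree$tip.label) %in% rs$focal)) next
    g2 <- find_lineage_expansions(rs$tree, rs$focal, cutoff = 2)
    # maximality: no returned set nested in another
    if (nrow(g2) > 1) {
      for (a in seq_len(nrow(g2))) {
        for (b in seq_len(nrow(g2))) {
          if (a == b) next
          expect_false(all(g2$members[[a]] %in% g2$members[[b]]))
        }
      }
    }
    # ranking is by size, descending
    expect_true(all(diff(g2$size) <= 0))
    # raising the cutoff never adds groups
    g3 <- find_lineage_expansions(rs$tree, rs$focal, cutoff = 4)
    expect_lte(nrow(g3), nrow(g2))
    keys <- vapply(g2$members, function(m) paste(sort(m), collapse = "|"), "")
    keys3 <- vapply(g3$members, function(m) paste(sort(m), collapse = "|"), "")
    expect_true(all(keys3 %in% keys))
    # raising min_support never adds groups
    gs <- find_lineage_expansions(rs$tree, rs$focal, cutoff = 2,
                                  min_support = 0.8)
    expect_lte(nrow(gs), nrow(g2))
  }
})

test_that("group subtree extraction walks rootward past weak nodes", {
  tr <- parse_gene_tree("(((c1_a:1,c1_b:1)0.95:1,x1_a:1)0.9:1,x2_a:1);")
  sub <- extract_group_subtree(tr, c("c1_a", "c1_b"), min_support = 0.7)
  expect_setequal(sub$tip.label, c("c1_a", "c1_b", "x1_a"))
  expect_setequal(attr(sub, "outgroup_genes"), "x1_a")

  # weak subtending node: walk one node rootward, sister now includes x2_a
  tr2 <- parse_gene_tree("(((c1_a:1,c1_b:1)0.95:1,x1_a:1)0.5:1,x2_a:1);")
  expect_warning(
    sub2 <- extract_group_subtree(tr2, c("c1_a", "c1_b"), min_support = 0.7),
    "root"
  )
  expect_setequal(sub2$tip.label, c("c1_a", "c1_b", "x1_a", "x2_a"))

  # min_support = 0: immediate sister always accepted
  sub3 <- extract_group_subtree(tr2, c("c1_a", "c1_b"), min_support = 0)
  expect_setequal(sub3$tip.label, c("c1_a", "c1_b", "x1_a"))

  # branch lengths preserved
  expect_true(all(sub$edge.length == 1))
})

test_that("patristic divergence summarises per-member minima", {
  # hand path sum: A_g1 -0.5- node -0.5- X_g1
  tr <- ape::read.tree(text = "((A_g1:0.5,X_g1:0.5):0.5,X_g2:3);")
  d <- patristic_divergence_summary(tr, "A_g1", "X")
  expect_equal(d$median, 1.0)
  expect_equal(d$q1, d$q3) # single member: q1 = median = q3
  expect_equal(unname(attr(d, "distances")), 1.0)

  # all branch lengths 0 -> all distances 0
  tr0 <- tr
  tr0$edge.length <- rep(0, length(tr0$edge.length))
  expect_equal(patristic_divergence_summary(tr0, "A_g1", "X")$median, 0)

  # quartile ordering on a larger group
  tr2 <- parse_gene_tree(
    "(((c1_a:0.2,c1_b:0.9)0.9:0.3,(c1_c:1.5,c1_d:0.1)0.8:0.2)0.9:0.4,(x1_a:0.3,x1_b:0.2)0.9:0.1);")
  d2 <- patristic_divergence_summary(tr2, c("c1_a", "c1_b", "c1_c", "c1_d"), "x1")
  expect_true(d2$q1 <= d2$median && d2$median <= d2$q3)
  expect_true(all(attr(d2, "distances") >= 0))

  # missing lengths are an error naming the branch
  trna <- tr
  trna$edge.length[2] <- NA
  expect_error(patristic_divergence_summary(trna, "A_g1", "X"), "branch")
})

test_that("patristic distances are symmetric and satisfy the triangle inequality", {
  set.seed(11)
  for (i in 1:10) {
    tr <- ape::rtree(12)
    dm <- ape::cophenetic.phylo(tr)
    expect_equal(dm, t(dm))
    trip <- sample(tr$tip.label, 3)
    expect_lte(dm[trip[1], trip[2]],
               dm[trip[1], trip[3]] + dm[trip[3], trip[2]] + 1e-12)
  }
})

test_that("rooting policies work and tidy/glance summarise expansions", {
  tr <- ape::read.tree(text = "((c1_a:1,c1_b:1):1,(c1_c:1,x1_a:3):1,x2_a:1);")
  expect_false(ape::is.rooted(tr))
  mid <- root_gene_tree(tr, "midpoint")
  expect_true(ape::is.rooted(mid))
  og <- root_gene_tree(tr, "outgroup", outgroup_species = "x2")
  expect_true(ape::is.rooted(og))

  tr2 <- parse_gene_tree("(((c1_a:1,c1_b:1)0.9:1,(c1_c:1,c1_d:1)0.9:1)0.95:1,(x1_a:1,x2_a:1)0.8:1);")
  ex <- find_lineage_expansions(tr2, "c1", cutoff = 3)
  td <- tidy(ex)
  expect_equal(td$members, paste(ex$members[[1]], collapse = ","))
  gl <- glance(ex)
  expect_equal(gl$n_groups, 1L)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_expansions(ex, tsv = tmp)
  expect_true(file.exists(tmp))
})
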