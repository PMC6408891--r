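toy_loci <- function() {
  tibble::tibble(
    scaffold = c("s1", "s1", "s2"),
    start = c(100, 5000, 200),
    stop = c(1100, 6000, 900),
    strand = c("+", "-", "+"),
    gene_id = c("g1", "g2", "g3"),
    group = c("a", "a", "b")
  )
}

test_that("locus tables are validated and converted between conventions", {
  loci <- read_loci(toy_loci())
  expect_equal(nrow(loci), 3L)

  bad <- toy_loci(); bad$stop[1] <- bad$start[1]
  expect_error(read_loci(bad), "start must be < stop")
  dup <- toy_loci(); dup$gene_id[2] <- "g1"
  expect_error(read_loci(dup), "duplicate")
  odd <- toy_loci(); odd$strand[1] <- "?"
  expect_error(read_loci(odd), "strand")

  # 1-based inclusive input: start shifts down, length stop - start grows by 1
  one <- toy_loci()
  conv <- read_loci(one, one_based = TRUE)
  expect_equal(conv$stop - conv$start, (one$stop - one$start) + 1)
  expect_equal(conv$stop, one$stop)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(toy_loci(), tsv)
  expect_equal(nrow(read_loci(tsv)), 3L)
})

test_that("scaffold summary counts occupied scaffolds per group", {
  loci <- tibble::tibble(
    scaffold = c("s1", "s1", "s1", "s2", "s3"),
    start = c(1, 100, 200, 1, 1) * 1000,
    stop = c(1, 100, 200, 1, 1) * 1000 + 500,
    strand = "+",
    gene_id = paste0("g", 1:5),
    group = c("a", "a", "a", "a", "b")
  )
  s <- scaffold_summary(loci, m = 3)
  a <- dplyr::filter(s$by_group, group == "a")
  expect_equal(a$n_scaffolds, 2L)       # {s1: 3, s2: 1}
  expect_equal(a$n_scaffolds_min_m, 1L) # only s1 has >= 3
  # m = 1: every occupied scaffold counts
  s1 <- scaffold_summary(loci, m = 1)
  expect_equal(s1$by_group$n_scaffolds,
               s1$by_group$n_scaffolds_min_m)
  expect_equal(tidy(s)$n_genes, c(4L, 1L))
  expect_error(scaffold_summary(dplyr::select(loci, -group)), "group")
})

test_that("scaffold summary equals brute-force counting on random layouts", {
  set.seed(50)
  for (i in 1:30) {
    n <- sample(10:60, 1)
    start <- sample.int(1e6, n)
    loci <- tibble::tibble(
      scaffold = sample(paste0("s", 1:8), n, replace = TRUE),
      start = start, stop = start + sample.int(5e3, n),
      strand = sample(c("+", "-"), n, replace = TRUE),
      gene_id = paste0("g", seq_len(n)),
      group = sample(c("a", "b", "non_expanded"), n, replace = TRUE)
    )
    m <- sample(2:4, 1)
    s <- scaffold_summary(loci, m = m)
    want <- oracle_scaffold_counts(loci, m)
    for (g in names(want)) {
      row <- dplyr::filter(s$by_group, group == g)
      expect_equal(row$n_scaffolds, unname(want[[g]]["n_scaffolds"]))
      expect_equal(row$n_scaffolds_min_m, unname(want[[g]]["n_min_m"]))
    }
  }
})

test_that("tandem cluster scan handles gaps, scaffolds and adjacency", {
  # members at sorted ranks 1, 2, 4 with one intervening gene
  loci <- tibble::tibble(
    scaffold = "s1",
    start = c(1, 2, 3, 4) * 1000,
    stop = c(1, 2, 3, 4) * 1000 + 500,
    strand = c("+", "+", "-", "+"),
    gene_id = c("m1", "m2", "x1", "m3"),
    group = c("g", "g", "bg", "g")
  )
  got <- detect_tandem_clusters(loci, members = c("m1", "m2", "m3"),
                                max_intervening = 1)
  expect_equal(nrow(got), 1L)
  expect_setequal(got$members[[1]], c("m1", "m2", "m3"))
  expect_equal(got$n_intervening, 1L)
  expect_equal(got$strands, "+++") # strand pattern of members only

  # max_intervening = 0: the run breaks at the intervening gene
  got0 <- detect_tandem_clusters(loci, members = c("m1", "m2", "m3"),
                                 max_intervening = 0)
  expect_equal(nrow(got0), 1L)
  expect_setequal(got0$members[[1]], c("m1", "m2"))

  # members on different scaffolds never cluster
  split_loci <- loci
  split_loci$scaffold <- c("s1", "s2", "s2", "s3")
  expect_equal(nrow(detect_tandem_clusters(split_loci,
                                           members = c("m1", "m2", "m3"),
                                           max_intervening = 5)), 0L)

  # distance fallback when no background genes are supplied
  only <- dplyr::filter(loci, gene_id != "x1")
  near <- detect_tandem_clusters(only, members = c("m1", "m2", "m3"),
                                 max_gap_bp = 1e5)
  expect_equal(near$method, "distance")
  expect_equal(nrow(near), 1L)
  expect_error(detect_tandem_clusters(loci, group = "zz"), "unknown group")
})

test_that("clusters match brute force, stay disjoint and shrink with stricter gaps", {
  set.seed(51)
  for (i in 1:25) {
    n <- sample(15:50, 1)
    loci <- tibble::tibble(
      scaffold = sort(sample(paste0("s", 1:4), n, replace = TRUE)),
      gene_id = paste0("g", seq_len(n)),
      strand = sample(c("+", "-"), n, replace = TRUE),
      group = sample(c("grp", "bg"), n, replace = TRUE, prob = c(0.4, 0.6))
    )
    loci <- loci |>
      dplyr::group_by(scaffold) |>
      dplyr::mutate(start = cumsum(sample(2e3:2e4, dplyr::n())),
                    stop = start + 1000) |>
      dplyr::ungroup()
    members <- loci$gene_id[loci$group == "grp"]
    k <- sample(0:3, 1)
    got <- detect_tandem_clusters(loci, members = members,
                                  max_intervening = k)
    want <- oracle_tandem_clusters(as.data.frame(loci), members, k)
    expect_true(compare_member_sets(got$members, want),
                info = paste("layout", i))
    # every cluster member belongs to the group; clusters are disjoint
    all_members <- unlist(got$members)
    expect_true(all(all_members %in% members))
    expect_equal(anyDuplicated(all_members), 0L)
    # tightening the gap tolerance never increases cluster membership
    if (k > 0) {
      tight <- detect_tandem_clusters(loci, members = members,
                                      max_intervening = k - 1)
      expect_lte(sum(lengths(tight$members)), sum(lengths(got$members)))
    }
  }
})

test_that("planted tandem arrays are recovered from simulated layouts", {
  set.seed(52)
  hits <- 0; total <- 0
  for (i in 1:5) {
    genes <- paste0("g", 1:30)
    groups <- setNames(rep(c("group1", "non_expanded"), c(10, 20)), genes)
    sim <- simulate_scaffolds(genes, groups,
                              cluster_spec = tibble::tibble(group = "group1",
                                                            size = 5),
                              intervening_rate = 1)
    got <- detect_tandem_clusters(sim$loci, group = "group1",
                                  max_intervening = 5)
    for (r in seq_len(nrow(sim$truth))) {
      total <- total + 1
      planted <- sort(sim$truth$members[[r]])
      if (any(vapply(got$members,
                     function(m) identical(sort(m), planted), logical(1)))) {
        hits <- hits + 1
      }
    }
  }
  expect_equal(hits, total)
})
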