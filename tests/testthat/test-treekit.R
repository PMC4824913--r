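test_that("Newick parsing, validation, and round-trips", {
  tr <- parse_newick("(A,(B,C),D);")
  expect_s3_class(tr, "phylo")
  bp <- bipartitions(tr)
  expect_length(bp, 1L)
  expect_equal(bp[[1]], c("B", "C"))
  expect_error(parse_newick("(A,(B,C,D);"), "unbalanced")
  expect_error(parse_newick("(A,(B,B),D);"), "duplicate leaf")

  tr29 <- simulate_tree(29, "yule", seed = 11)
  back <- parse_newick(write_newick(tr29))
  expect_same_topology(tr29, back)
  # parse-write-parse is idempotent on topology
  again <- parse_newick(write_newick(back))
  expect_same_topology(back, again)

  # multi-tree files: one tree per line
  f <- tempfile(fileext = ".nwk")
  trees <- lapply(1:3, function(s) simulate_tree(8, "yule", seed = s))
  class(trees) <- "multiPhylo"
  write_newick(trees, f)
  rd <- read_newick(f)
  expect_length(rd, 3L)
  expect_same_topology(rd[[2]], trees[[2]])
})

test_that("bipartitions obey the n-3 rule and are representation-invariant", {
  tr29 <- simulate_tree(29, "yule", seed = 3)
  expect_length(bipartitions(tr29), 26L)
  star <- ape::read.tree(text = paste0("(", paste(paste0("t", 1:8),
                                                  collapse = ","), ");"))
  expect_length(bipartitions(star), 0L)
  # all 15 binary 5-leaf topologies: re-drawn representations give equal
  # sets, distinct topologies give distinct sets
  tops <- all_topologies(paste0("t", 1:5))
  expect_length(tops, 15L)
  keys <- vapply(tops, function(t) paste(sort(names(bipartitions(t))),
                                         collapse = ";"), "")
  expect_length(unique(keys), 15L)
  for (t in tops) {
    redrawn <- parse_newick(write_newick(ape::rotateConstr(t, rev(t$tip.label))))
    expect_setequal(names(bipartitions(t)), names(bipartitions(redrawn)))
  }
})

test_that("RF distance is a metric and matches an independent reference", {
  t1 <- simulate_tree(29, "yule", seed = 1)
  t2 <- simulate_tree(29, "yule", seed = 2)
  expect_equal(rf_distance(t1, t1), 0L)
  expect_lte(rf_distance(t1, t2), 2L * (29L - 3L))
  expect_equal(rf_distance(t1, t2), rf_distance(t2, t1))
  t3 <- simulate_tree(29, "yule", seed = 3)
  expect_lte(rf_distance(t1, t3),
             rf_distance(t1, t2) + rf_distance(t2, t3))
  expect_error(rf_distance(t1, simulate_tree(5, "yule", seed = 1)),
               "different leaf sets")
  skip_if_not_installed("phangorn")
  tops <- all_topologies(paste0("t", 1:6))
  set.seed(7)
  pairs <- cbind(sample.int(length(tops), 60, TRUE),
                 sample.int(length(tops), 60, TRUE))
  for (r in seq_len(nrow(pairs))) {
    a <- tops[[pairs[r, 1]]]; b <- tops[[pairs[r, 2]]]
    expect_equal(rf_distance(a, b), as.integer(phangorn::RF.dist(a, b)))
  }
})

test_that("strict consensus keeps exactly the shared bipartitions", {
  tr <- simulate_tree(10, "yule", seed = 9)
  expect_same_topology(strict_consensus(list(tr)), tr)
  # all 15 binary 5-leaf trees agree on nothing: the star
  tops <- all_topologies(paste0("t", 1:5))
  cons <- strict_consensus(tops)
  expect_length(bipartitions(cons), 0L)
  # idempotent and order-independent
  trees <- lapply(1:4, function(s) simulate_tree(9, "yule", seed = s))
  c1 <- strict_consensus(trees)
  c2 <- strict_consensus(rev(trees))
  expect_same_topology(c1, c2)
  expect_same_topology(strict_consensus(list(c1, c1)), c1)
  # consensus splits = intersection of input split sets
  common <- Reduce(intersect, lapply(trees, function(t) names(bipartitions(t))))
  expect_setequal(as.character(names(bipartitions(c1))), as.character(common))
  expect_error(strict_consensus(list()), "no trees")
})

test_that("zero-minimum branch collapsing matches brute force and keeps length", {
  # every split supported by its own character: nothing collapses
  tr <- simulate_tree(8, "yule", seed = 21)
  xs <- split_characters(tr)
  col <- collapse_min_zero(tr, xs)
  expect_same_topology(col, tr)
  # all-constant matrix: any tree collapses to a star
  const <- toy_matrix(rep("000", 6))
  anytree <- simulate_tree(6, "yule", seed = 2, labels = const$taxa)
  expect_length(bipartitions(collapse_min_zero(anytree, const)), 0L)
  # 6-leaf brute force: an edge may collapse iff every character admits an
  # optimal assignment with equal endpoint states
  for (seed in 1:6) {
    x <- random_small_matrix(6, 4, seed = seed)
    tr6 <- simulate_tree(6, "yule", seed = seed, labels = x$taxa)
    po <- ape::reorder.phylo(tr6, "postorder")
    keep_expected <- character(0)
    tb <- morphpars:::tips_below(po)
    n <- 6L
    per_char <- lapply(seq_len(x$n_char), function(j)
      oracle_optimal_assignments(po, x, j))
    for (r in seq_len(nrow(po$edge))) {
      p <- po$edge[r, 1]; ch <- po$edge[r, 2]
      if (ch <= n) next
      zero_all <- all(vapply(per_char, function(oa) {
        any(oa$assignments[, p - n] == oa$assignments[, ch - n])
      }, logical(1)))
      if (!zero_all) {
        side <- sort(po$tip.label[tb$below[[ch]]])
        ref <- sort(po$tip.label)[1]
        if (ref %in% side) side <- sort(setdiff(po$tip.label, side))
        keep_expected <- c(keep_expected, morphpars:::split_key(side))
      }
    }
    col6 <- collapse_min_zero(tr6, x)
    expect_setequal(as.character(names(bipartitions(col6))),
                    unique(keep_expected))
    # an edge has zero minimum length iff contracting it alone leaves the
    # (hard) tree length unchanged; and re-resolving the fully collapsed
    # tree per character can never lengthen it
    L <- fitch_length(tr6, x)
    labs6 <- sort(tr6$tip.label)
    allsp <- bipartitions(tr6)
    for (ksp in seq_along(allsp)) {
      one <- morphpars:::tree_from_clades(unname(allsp[-ksp]), labs6, labs6[1])
      Lh <- fitch_length(one, x, polytomies = "hard")
      if (names(allsp)[ksp] %in% keep_expected)
        expect_gt(Lh, L)   # a supported edge costs length when contracted
      else
        expect_equal(Lh, L)
    }
    expect_lte(fitch_length(col6, x), L)
  }
})

test_that("hard-polytomy scoring matches assignment enumeration and bounds refine", {
  for (seed in 1:4) {
    x <- random_small_matrix(6, 3, seed = 800 + seed)
    tr <- simulate_tree(6, "yule", seed = seed, labels = x$taxa)
    bp <- bipartitions(tr)
    poly <- morphpars:::tree_from_clades(unname(bp[-1]), sort(x$taxa),
                                         sort(x$taxa)[1])
    hard <- fitch_length(poly, x, per_character = TRUE, polytomies = "hard")
    # the exhaustive-assignment oracle scores the multifurcating tree as is
    expect_equal(hard, oracle_fitch(poly, x, per_character = TRUE))
    expect_true(all(fitch_length(poly, x, per_character = TRUE) <= hard))
  }
})

test_that("refinement scoring of polytomies equals enumeration over refinements", {
  for (seed in 1:4) {
    x <- random_small_matrix(6, 3, seed = 100 + seed)
    tr <- simulate_tree(6, "yule", seed = seed, labels = x$taxa)
    # knock out one internal split to create a polytomy
    bp <- bipartitions(tr)
    poly <- morphpars:::tree_from_clades(unname(bp[-1]), sort(x$taxa),
                                         sort(x$taxa)[1])
    expect_equal(fitch_length(poly, x, per_character = TRUE),
                 unname(oracle_refinement_score(poly, x)))
  }
  # star tree: per-character minimum over all topologies
  x <- random_small_matrix(5, 3, seed = 42)
  star <- morphpars:::tree_from_clades(list(), sort(x$taxa), sort(x$taxa)[1])
  tops <- all_topologies(x$taxa)
  best <- apply(vapply(tops, function(t)
    oracle_fitch(t, x, per_character = TRUE), integer(x$n_char)), 1L, min)
  expect_equal(fitch_length(star, x, per_character = TRUE), unname(best))
})
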