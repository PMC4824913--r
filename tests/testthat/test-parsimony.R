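test_that("Fitch length on small trees matches brute-force minimisation", {
  x <- toy_matrix(c("0", "0", "1", "1"), taxa = c("A", "B", "C", "D"))
  t_ab <- parse_newick("((A,B),(C,D));")
  t_ac <- parse_newick("((A,C),(B,D));")
  expect_equal(fitch_length(t_ab, x), 1L)
  expect_equal(fitch_length(t_ac, x), 2L)
  expect_equal(fitch_length(t_ab, x), oracle_fitch(t_ab, x))
  expect_equal(fitch_length(t_ac, x), oracle_fitch(t_ac, x))
  # constant character scores 0 on any tree
  const <- toy_matrix(rep("0", 4), taxa = c("A", "B", "C", "D"))
  expect_equal(fitch_length(t_ab, const), 0L)
})

test_that("Fitch length equals exhaustive assignment minimisation (property)", {
  for (seed in 1:12) {
    nt <- sample(c(5L, 6L), 1L)
    x <- random_small_matrix(nt, 4, k = 3, p_missing = 0.15, p_poly = 0.15,
                             seed = 200 + seed)
    tr <- simulate_tree(nt, "yule", seed = seed, labels = x$taxa)
    expect_equal(fitch_length(tr, x, per_character = TRUE),
                 oracle_fitch(tr, x, per_character = TRUE))
  }
})

test_that("length is invariant to rooting and leaf order; missing adds nothing", {
  x <- load_fixture("composite")
  tr <- simulate_tree(29, "yule", seed = 4, labels = x$taxa)
  L <- fitch_length(tr, x)
  for (og in x$taxa[c(1, 10, 29)]) {
    rooted <- ape::root(tr, og, resolve.root = TRUE)
    expect_equal(fitch_length(rooted, x), L)
  }
  # permuting matrix row order must not matter
  set.seed(1)
  perm <- sample(n_taxa(x))
  xp <- morphpars:::new_char_matrix(x$masks[perm, ], x$taxa[perm])
  expect_equal(fitch_length(tr, xp), L)
  # an all-missing character changes no score
  xm <- morphpars:::new_char_matrix(cbind(x$masks, 0L), x$taxa)
  expect_equal(fitch_length(tr, xm), L)
  expect_error(fitch_length(simulate_tree(5, "yule", seed = 1), x),
               "not in matrix|not in tree")
})

test_that("per-character step minima match their definition", {
  expect_equal(min_steps(toy_matrix(c("0", "1", "2"))), 2L)
  expect_equal(min_steps(toy_matrix(c("?", "?", "?"))), 0L)
  expect_equal(min_steps(toy_matrix(c("[01]", "[01]", "[01]", "[01]"))), 0L)
  # brute force over resolutions at <= 6 taxa: m = min over resolutions of
  # (#distinct states - 1)
  for (seed in 1:8) {
    x <- random_small_matrix(6, 3, seed = 300 + seed)
    m <- min_steps(x)
    for (j in seq_len(x$n_char)) {
      cells <- x$masks[, j]
      cells <- cells[cells > 0L]
      if (!length(cells)) { expect_equal(m[j], 0L); next }
      opts <- lapply(cells, function(cc) which(bitwAnd(cc, 2L^(0:9)) > 0L) - 1L)
      grid <- expand.grid(opts)
      expect_equal(m[j], min(apply(grid, 1L, function(r) length(unique(r)) - 1L)))
    }
  }
})

test_that("per-character step maxima equal the worst-tree length", {
  x20 <- toy_matrix(c(rep("0", 20), rep("1", 9)))
  expect_equal(max_steps(x20), 9L)
  expect_equal(max_steps(toy_matrix(rep("0", 6))), 0L)
  expect_equal(max_steps(toy_matrix(c("[01]", "0", "0", "0"))), 0L)
  # at 6 taxa, g equals the maximum Fitch length over all topologies
  for (seed in 1:4) {
    x <- random_small_matrix(6, 3, k = 2, p_missing = 0.1, p_poly = 0.1,
                             seed = 400 + seed)
    tops <- all_topologies(x$taxa)
    worst <- apply(vapply(tops, function(t)
      oracle_fitch(t, x, per_character = TRUE), integer(x$n_char)), 1L, max)
    expect_equal(max_steps(x), unname(worst))
  }
})

test_that("ensemble indices follow their definitions and bounds", {
  fake <- list(s = c(100, 30), m = c(40, 12), g = c(200, 60))
  idx <- ensemble_indices(fake)  # sums: m 52, s 130, g 260
  expect_equal(idx$ci, 0.40)
  expect_equal(idx$ri, 0.625)
  # homoplasy-free data: CI = RI = 1 on the generating tree
  tr <- simulate_tree(10, "yule", seed = 31)
  xs <- split_characters(tr)
  sc <- tree_score(tr, xs)
  expect_equal(sc$ci, 1)
  expect_equal(sc$ri, 1)
  # degenerate denominators give NA, not errors
  const <- toy_matrix(rep("00", 5))
  tc <- simulate_tree(5, "yule", seed = 1, labels = const$taxa)
  scc <- tree_score(tc, const)
  expect_true(is.na(scc$ci))
  expect_true(is.na(scc$ri))
  # m <= s <= g and total = sum(s) on random data
  for (seed in 1:6) {
    x <- random_small_matrix(8, 6, seed = 500 + seed)
    t8 <- simulate_tree(8, "yule", seed = seed, labels = x$taxa)
    sc8 <- tree_score(t8, x)
    expect_true(all(sc8$m <= sc8$s))
    expect_true(all(sc8$s <= sc8$g))
    expect_equal(sc8$total, sum(sc8$s))
  }
})

test_that("fixture CI/RI at length 186 match the independent reference values", {
  # cross-check values computed with phangorn's CI/RI on an optimal tree
  # (uninformative characters included): 0.3602 and 0.6676
  x <- load_fixture("composite")
  res <- heuristic_search(x, search_config(n_replicates = 30, seed = 7))
  expect_equal(res$best_length, 186L)
  sc <- tree_score(res$mpts_binary[[1]], x)
  expect_equal(sc$ci, 0.3602, tolerance = 1e-3)
  expect_equal(sc$ri, 0.6676, tolerance = 1e-3)
  # every character in this matrix is parsimony-informative, so the
  # adjusted variant coincides here ...
  expect_true(all(informative_characters(x)))
  sc2 <- tree_score(res$mpts_binary[[1]], x, exclude_uninformative = TRUE)
  expect_equal(sc2$ci, sc$ci)
  # ... while on data with an autapomorphy the two variants differ
  xa <- toy_matrix(c("00", "11", "00", "10"))
  ta <- parse_newick("((t1,t2),(t3,t4));")
  full <- tree_score(ta, xa)
  adj <- tree_score(ta, xa, exclude_uninformative = TRUE)
  expect_lt(adj$ci, full$ci)
})

test_that("synapomorphy mapping finds clade-diagnostic changes", {
  # characters 1-2 derived only in clade {C,D}
  x <- toy_matrix(c("00", "00", "11", "11", "00", "00"),
                  taxa = c("A", "B", "C", "D", "E", "F"))
  tr <- parse_newick("((A,B),((C,D),(E,F)));")
  syn <- map_synapomorphies(tr, x, outgroup = "A")
  cd <- syn[syn$clade == "C + D", ]
  expect_equal(nrow(cd), 2L)
  expect_true(all(cd$unambiguous))
  expect_equal(cd$from, c(0L, 0L))
  expect_equal(cd$to, c(1L, 1L))
})

test_that("synapomorphy mapping agrees with enumeration of reconstructions", {
  for (seed in 1:4) {
    x <- random_small_matrix(6, 3, seed = 600 + seed)
    tr <- simulate_tree(6, "yule", seed = seed, labels = x$taxa)
    syn <- map_synapomorphies(tr, x, outgroup = x$taxa[1])
    po <- ape::reorder.phylo(ape::unroot(tr), "postorder")
    tb <- morphpars:::tips_below(po)
    n <- 6L
    for (j in seq_len(x$n_char)) {
      oa <- oracle_optimal_assignments(po, x, j)
      for (r in seq_len(nrow(po$edge))) {
        p <- po$edge[r, 1]; ch <- po$edge[r, 2]
        if (ch <= n) next  # restrict the check to internal edges
        a <- oa$assignments[, p - n]
        b <- oa$assignments[, ch - n]
        always <- all(a != b) && length(unique(paste(a, b))) == 1L
        side <- sort(po$tip.label[tb$below[[ch]]])
        flip <- x$taxa[1] %in% side
        clade <- if (flip) sort(setdiff(po$tip.label, side)) else side
        got <- syn[syn$character == j &
                   syn$clade == paste(clade, collapse = " + ") &
                   syn$unambiguous, ]
        expect_equal(nrow(got) == 1L, always,
                     label = sprintf("seed %d char %d edge %d", seed, j, r))
        if (always) {
          expect_equal(got$from, unname(if (flip) b[1] else a[1]))
          expect_equal(got$to, unname(if (flip) a[1] else b[1]))
        }
      }
    }
  }
})
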