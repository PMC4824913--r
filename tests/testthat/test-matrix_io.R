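test_that("TNT rows parse to the printed cells, including polymorphism", {
  x <- load_fixture("composite")
  rh <- x$masks["Rhineceps nyasaensis", ]
  expect_equal(cell_states(x, "Rhineceps nyasaensis", 14), 1L)
  expect_equal(cell_states(x, "Rhineceps nyasaensis", 38), 1L)
  expect_equal(cell_states(x, "Rhineceps nyasaensis", 54), 1L)
  expect_true(is.na(cell_states(x, "Rhineceps nyasaensis", 56)))
  expect_equal(sum(rh == 0L), 1L)  # only character 56 missing
  expect_equal(unname(rh[setdiff(1:56, c(14, 38, 54, 56))]),
               rep(1L, 52))        # all remaining cells state 0
  expect_equal(cell_states(x, "Edingerella madagascariensis", 7), c(0L, 1L))
  expect_equal(cell_states(x, "Edingerella madagascariensis", 8), 2L)
  # the Stanocephalosaurus birdi row contains a stray internal space in the
  # source; it must still expand to 56 cells
  expect_equal(sum(x$masks["Stanocephalosaurus birdi", ] == 0L), 0L)
})

test_that("parse errors name the offending taxon, count, and symbol", {
  expect_error(parse_matrix(c("tA 0101", "tB 010"), "tnt"),
               "tB.*3 cells, expected 4")
  expect_error(parse_matrix(c("tA 01x1"), "tnt"), "unknown symbol 'x'")
  expect_error(parse_matrix(c("tA 0101", "tA 0011"), "tnt"),
               "duplicate taxon label")
  expect_error(parse_matrix(c("xread 'x' 4 3", "tA 0101", "tB 0011"), "tnt"),
               "declares 3 taxa but 2 rows")
})

test_that("parsing ignores whitespace grouping inside symbol strings", {
  a <- parse_matrix("tA 0101010101", "tnt")
  b <- parse_matrix("tA 01010 10101", "tnt")
  c3 <- parse_matrix("tA\t01 01 01 01 01", "tnt")
  expect_identical(a$masks, b$masks)
  expect_identical(a$masks, c3$masks)
})

test_that("both fixture variants are 29 x 56 with the expected cell domain", {
  comp <- load_fixture("composite")
  holo <- load_fixture("holotype")
  expect_equal(n_taxa(comp), 29L)
  expect_equal(n_characters(comp), 56L)
  expect_equal(n_taxa(holo), 29L)
  expect_equal(n_characters(holo), 56L)
  expect_identical(comp$taxa, holo$taxa)
  # cells restricted to {0},{1},{2},{0,1},{1,2}, missing
  allowed <- c(0L, 1L, 2L, 4L, 3L, 6L)
  expect_true(all(comp$masks %in% allowed))
  expect_true(all(holo$masks %in% allowed))
  # the two variants differ only in the Y. maopingchangensis row
  focal <- "Yuanansuchus maopingchangensis"
  same <- comp$masks[comp$taxa != focal, ] == holo$masks[holo$taxa != focal, ]
  expect_true(all(same))
  expect_equal(cell_states(comp, focal, 11), c(0L, 1L))
  expect_equal(cell_states(holo, focal, 11), 1L)
  # holotype coding is more incomplete in the postcranial character range
  expect_gt(sum(holo$masks[holo$taxa == focal, 40:50] == 0L),
            sum(comp$masks[comp$taxa == focal, 40:50] == 0L))
})

test_that("write/parse round-trips are cell-identical in both dialects", {
  comp <- load_fixture("composite")
  for (d in c("tnt", "nexus")) {
    # fixture labels contain spaces; the NEXUS writer rewrites them with
    # underscores and the parser restores them
    back <- parse_matrix(write_matrix(comp, d), d)
    expect_identical(unname(back$masks), unname(comp$masks))
    expect_identical(back$taxa, comp$taxa)
  }
  tr <- simulate_tree(12, "yule", seed = 5)
  ds <- simulate_matrix(tr, mk_sim_config(n_taxa = 12, n_characters = 20,
                                          seed = 5))
  dg <- degrade_matrix(ds, 0.2, 0.1, seed = 6)
  for (d in c("tnt", "nexus")) {
    back <- parse_matrix(write_matrix(dg, d), d)
    expect_identical(unname(back$masks), unname(dg$masks))
  }
  # explicit polymorphism and missing round-trip
  m <- toy_matrix(c("0[02]?", "1[01]0", "2[12]1"))
  for (d in c("tnt", "nexus")) {
    back <- parse_matrix(write_matrix(m, d), d)
    expect_identical(unname(back$masks), unname(m$masks))
  }
  expect_equal(cell_states(m, "t1", 2), c(0L, 2L))
  expect_true(is.na(cell_states(m, "t1", 3)))
})

test_that("the NEXUS fixture file matches the TNT fixture cell-for-cell", {
  nex <- read_matrix(system.file("extdata", "capitosaur56.nex",
                                 package = "morphpars"), "nexus")
  tnt <- read_matrix(system.file("extdata", "capitosaur56.tnt",
                                 package = "morphpars"), "tnt")
  expect_equal(dim(nex$masks), c(30L, 56L))
  expect_identical(unname(nex$masks), unname(tnt$masks))
})

test_that("matrix_summary classifies characters correctly", {
  m <- toy_matrix(c("001", "001", "011", "010"))  # 4 taxa, 3 chars
  s <- matrix_summary(m)
  expect_false(s$informative[1])               # constant
  expect_equal(s$min_steps[1], 0L)
  expect_true(s$informative[2])                # 2+2 split
  expect_false(s$informative[3])               # autapomorphy (one 0)
  comp <- load_fixture("composite")
  sc <- matrix_summary(comp)
  expect_true(all(sc$n_states <= 3))
  # a polymorphic cell can only back one side of a split at a time
  m2 <- toy_matrix(c("0", "[01]", "1"))
  expect_false(matrix_summary(m2)$informative[1])
  m3 <- toy_matrix(c("0", "[01]", "1", "1"))
  expect_true(matrix_summary(m3)$informative[1])
})
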