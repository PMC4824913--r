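# Shared fixtures and independent brute-force oracles used across the
# suite.  The oracles deliberately avoid the package's scoring path: tree
# length is minimised by enumerating every ancestral state assignment, and
# refinement scores by enumerating every compatible binary topology.

# build a small matrix from rows of symbol strings
toy_matrix <- function(symbols, taxa = NULL) {
  if (is.null(taxa)) taxa <- paste0("t", seq_along(symbols))
  parse_matrix(sprintf("%s %s", taxa, symbols), dialect = "tnt")
}

# all unrooted binary topologies on the given labels (by sequential
# insertion on every edge); n <= 7 expected.  Trees are built as plain
# edge sets (tips 1..n, internals n+1..2n-2) and converted to phylo.
edgeset_to_phylo <- function(E, n, labels) {
  nb <- vector("list", 2L * n - 2L)
  for (r in seq_len(nrow(E))) {
    a <- E[r, 1]; b <- E[r, 2]
    nb[[a]] <- c(nb[[a]], b); nb[[b]] <- c(nb[[b]], a)
  }
  or_edge <- matrix(0L, nrow(E), 2)
  visited <- rep(FALSE, length(nb))
  stack <- n + 1L; visited[n + 1L] <- TRUE; r <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (w in nb[[v]]) if (!visited[w]) {
      visited[w] <- TRUE
      r <- r + 1L
      or_edge[r, ] <- c(v, w)
      stack <- c(stack, w)
    }
  }
  tr <- structure(list(edge = or_edge, Nnode = n - 2L, tip.label = labels),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

all_topologies <- function(labels) {
  n <- length(labels)
  stopifnot(n >= 4, n <= 7)
  base <- rbind(c(n + 1L, 1L), c(n + 1L, 2L), c(n + 1L, 3L))
  pool <- list(base)
  for (k in 4:n) {
    w <- n + k - 2L
    nxt <- list()
    for (E in pool) {
      for (e in seq_len(nrow(E))) {
        a <- E[e, 1]; b <- E[e, 2]
        E2 <- rbind(E[-e, , drop = FALSE], c(a, w), c(w, b), c(w, k))
        nxt[[length(nxt) + 1L]] <- E2
      }
    }
    pool <- nxt
  }
  lapply(pool, edgeset_to_phylo, n = n, labels = labels)
}

# brute-force Fitch length by minimising over every internal-node state
# assignment, per character
oracle_fitch <- function(tree, x, per_character = FALSE) {
  tree <- ape::unroot(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  n <- length(po$tip.label)
  nn <- po$Nnode
  edge <- po$edge
  idx <- match(po$tip.label, x$taxa)
  obs <- sapply(seq_len(x$n_char), function(j) {
    col <- x$masks[, j]
    Reduce(bitwOr, col, 0L)
  })
  obs[obs == 0L] <- 1L
  s <- integer(x$n_char)
  for (j in seq_len(x$n_char)) {
    states <- which(bitwAnd(obs[j], 2L^(0:9)) > 0L) - 1L
    cells <- x$masks[idx, j]
    cells[cells == 0L] <- obs[j]
    k <- length(states)
    grid <- as.matrix(expand.grid(rep(list(states), nn)))
    best <- Inf
    for (g in seq_len(nrow(grid))) {
      asg <- grid[g, ]
      cost <- 0L
      feasible <- TRUE
      state_of <- function(node) {
        if (node <= n) NA else asg[node - n]
      }
      for (r in seq_len(nrow(edge))) {
        p <- edge[r, 1]; ch <- edge[r, 2]
        sp <- asg[p - n]
        if (ch <= n) {
          if (bitwAnd(cells[ch], 2L^sp) == 0L) cost <- cost + 1L
        } else {
          if (asg[ch - n] != sp) cost <- cost + 1L
        }
      }
      if (cost < best) best <- cost
    }
    s[j] <- best
  }
  if (per_character) s else sum(s)
}

# all optimal ancestral assignments (per character) for a small binary tree;
# returns, per character, a matrix of assignments (rows) over internal nodes
oracle_optimal_assignments <- function(tree, x, j) {
  tree <- ape::unroot(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  n <- length(po$tip.label)
  nn <- po$Nnode
  edge <- po$edge
  idx <- match(po$tip.label, x$taxa)
  col <- x$masks[, j]
  obs <- Reduce(bitwOr, col, 0L)
  if (obs == 0L) obs <- 1L
  cells <- x$masks[idx, j]
  cells[cells == 0L] <- obs
  states <- which(bitwAnd(obs, 2L^(0:9)) > 0L) - 1L
  grid <- as.matrix(expand.grid(rep(list(states), nn)))
  costs <- apply(grid, 1L, function(asg) {
    cost <- 0L
    for (r in seq_len(nrow(edge))) {
      p <- edge[r, 1]; ch <- edge[r, 2]
      sp <- asg[p - n]
      if (ch <= n) {
        if (bitwAnd(cells[ch], 2L^sp) == 0L) cost <- cost + 1L
      } else if (asg[ch - n] != sp) cost <- cost + 1L
    }
    cost
  })
  list(tree = po, assignments = grid[costs == min(costs), , drop = FALSE],
       min = min(costs))
}

# minimum length over all binary topologies whose splits contain the given
# (possibly polytomous) tree's splits, per character
oracle_refinement_score <- function(tree, x) {
  labs <- tree$tip.label
  need <- names(bipartitions(tree))
  tops <- all_topologies(labs)
  compat <- Filter(function(t) all(need %in% names(bipartitions(t))), tops)
  percar <- sapply(compat, function(t) oracle_fitch(t, x, per_character = TRUE))
  if (is.null(dim(percar))) percar <- matrix(percar, nrow = 1)
  apply(percar, 1L, min)
}

# random small matrix (cells possibly missing / polymorphic), seeded
random_small_matrix <- function(n_taxa, n_char, k = 3, p_missing = 0.1,
                                p_poly = 0.1, seed = 1) {
  set.seed(seed)
  masks <- matrix(0L, n_taxa, n_char)
  for (j in seq_len(n_char)) {
    for (i in seq_len(n_taxa)) {
      r <- runif(1)
      if (r < p_missing) { masks[i, j] <- 0L; next }
      st <- sample.int(k, 1L) - 1L
      if (r < p_missing + p_poly && k >= 2) {
        others <- setdiff(0:(k - 1L), st)
        st <- c(st, others[sample.int(length(others), 1L)])
      }
      masks[i, j] <- as.integer(sum(2L^st))
    }
    if (all(masks[, j] == 0L)) masks[1, j] <- 1L
  }
  morphpars:::new_char_matrix(masks, paste0("t", seq_len(n_taxa)))
}

# homoplasy-free matrix: one binary character per non-trivial split of the
# given tree (each internal edge supported by exactly one change)
split_characters <- function(tree) {
  labs <- sort(tree$tip.label)
  bp <- bipartitions(tree)
  masks <- matrix(1L, length(labs), length(bp))
  for (j in seq_along(bp)) masks[labs %in% bp[[j]], j] <- 2L
  morphpars:::new_char_matrix(masks, labs)
}

expect_same_topology <- function(t1, t2) {
  expect_setequal(as.character(names(bipartitions(t1))),
                  as.character(names(bipartitions(t2))))
}

# memoised full-scale searches shared by the acceptance blocks
.acc_cache <- new.env(parent = emptyenv())
acc_search <- function(variant) {
  key <- paste0("acc_", variant)
  if (!exists(key, envir = .acc_cache))
    assign(key,
           heuristic_search(load_fixture(variant),
                            search_config(n_replicates = 100, seed = 1)),
           envir = .acc_cache)
  get(key, envir = .acc_cache)
}
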