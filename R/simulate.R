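# Mk-model simulation: random trees, symmetric k-state character evolution
# with known per-character change counts, and degradation (missing data,
# polymorphic cells) emulating fragmentary morphological matrices.

#' Simulation configuration
#'
#' Defaults emulate the shape of the bundled capitosaur matrix: 29 taxa,
#' 56 unordered characters with up to 3 states, roughly 3 expected changes
#' per character, about 20% missing cells and a small fraction of
#' polymorphic cells.
#'
#' @param n_taxa number of leaves (>= 4)
#' @param n_characters number of characters
#' @param n_states number of states per character (2 or 3)
#' @param tree_model `"yule"` (growth by random leaf splitting) or
#'   `"uniform"` (every unrooted binary topology equiprobable; n <= 10)
#' @param expected_changes_per_character rate scaling: the expected total
#'   number of state changes per character across the tree
#' @param missing_fraction probability that a cell is replaced by `?`
#' @param polymorphic_fraction probability that a non-missing cell is
#'   widened to a two-state set containing the true state
#' @param seed integer seed; determines the dataset exactly
#' @return an object of class `mk_sim_config`
#' @export
mk_sim_config <- function(n_taxa = 29L, n_characters = 56L, n_states = 3L,
                          tree_model = c("yule", "uniform"),
                          expected_changes_per_character = 3,
                          missing_fraction = 0.2,
                          polymorphic_fraction = 0.005, seed = 1L) {
  tree_model <- match.arg(tree_model)
  stopifnot(n_taxa >= 4L, n_characters >= 1L, n_states %in% 2:3,
            expected_changes_per_character >= 0,
            missing_fraction >= 0, missing_fraction < 1,
            polymorphic_fraction >= 0, polymorphic_fraction < 1,
            missing_fraction + polymorphic_fraction < 1)
  structure(list(n_taxa = as.integer(n_taxa),
                 n_characters = as.integer(n_characters),
                 n_states = as.integer(n_states), tree_model = tree_model,
                 expected_changes_per_character = expected_changes_per_character,
                 missing_fraction = missing_fraction,
                 polymorphic_fraction = polymorphic_fraction,
                 seed = as.integer(seed)),
            class = "mk_sim_config")
}

# run fn() under a local RNG state seeded by `seed` (NULL = current stream)
with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fn()
}

#' Simulate a random unrooted binary tree
#'
#' `"uniform"` draws every unrooted binary topology with equal probability
#' by sequential random attachment to a uniformly chosen edge (restricted
#' to n <= 10); `"yule"` grows the tree by splitting a uniformly chosen
#' leaf, giving the clumpier shapes typical of birth processes.
#'
#' @param n_taxa number of leaves (>= 4)
#' @param tree_model `"yule"` or `"uniform"`
#' @param seed optional integer seed
#' @param labels optional leaf labels (default `t1..tn`)
#' @return an unrooted binary `phylo`
#' @export
simulate_tree <- function(n_taxa, tree_model = c("yule", "uniform"),
                          seed = NULL, labels = NULL) {
  tree_model <- match.arg(tree_model)
  stopifnot(n_taxa >= 4L)
  if (tree_model == "uniform" && n_taxa > 10L)
    stop("uniform-topology sampling is limited to 10 taxa; use \"yule\"")
  if (is.null(labels)) labels <- paste0("t", seq_len(n_taxa))
  stopifnot(length(labels) == n_taxa)
  with_seed(seed, function() {
    n <- n_taxa
    # adjacency over nodes 1..(2n-2); tips 1..n, internals n+1..
    nb <- vector("list", 2L * n - 2L)
    link <- function(a, b) { nb[[a]] <<- c(nb[[a]], b); nb[[b]] <<- c(nb[[b]], a) }
    cut <- function(a, b) {
      nb[[a]] <<- nb[[a]][nb[[a]] != b]; nb[[b]] <<- nb[[b]][nb[[b]] != a]
    }
    link(n + 1L, 1L); link(n + 1L, 2L); link(n + 1L, 3L)
    edges <- function() {
      out <- NULL
      for (a in seq_along(nb)) for (b in nb[[a]]) if (b > a)
        out <- rbind(out, c(a, b))
      out
    }
    for (k in 4:n) {
      w <- n + k - 2L
      if (tree_model == "uniform") {
        E <- edges()
        e <- E[sample.int(nrow(E), 1L), ]
      } else {
        leaf <- sample.int(k - 1L, 1L)       # split a random extant leaf
        e <- c(leaf, nb[[leaf]][1])
      }
      cut(e[1], e[2]); link(e[1], w); link(w, e[2]); link(w, k)
    }
    edge <- NULL
    for (a in seq_along(nb)) for (b in nb[[a]]) if (b > a)
      edge <- rbind(edge, c(a, b))
    # orient away from internal node n+1
    or_edge <- matrix(0L, nrow(edge), 2)
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
  })
}

#' Simulate characters on a tree under the symmetric Mk model
#'
#' Each character evolves independently along the tree: change events occur
#' as a Poisson process with equal intensity on every branch, scaled so the
#' expected total number of events per character equals
#' `expected_changes_per_character`; each event jumps to a uniformly chosen
#' different state.  The root state is uniform.  The true per-character
#' change counts are retained for validation.
#'
#' @param tree a `phylo` (its topology is the truth; branch lengths are
#'   ignored and treated as equal)
#' @param config an [mk_sim_config()]
#' @return a `sim_dataset`: list with `true_tree`, `matrix` (a
#'   `char_matrix`, before any degradation), `per_character_change_counts`,
#'   and `config`
#' @export
simulate_matrix <- function(tree, config) {
  stopifnot(inherits(config, "mk_sim_config"))
  with_seed(config$seed, function() {
    po <- ape::reorder.phylo(tree, "postorder")
    n <- length(po$tip.label)
    nchar_ <- config$n_characters
    k <- config$n_states
    nE <- nrow(po$edge)
    lambda <- config$expected_changes_per_character / nE
    pre <- nrow(po$edge):1
    root <- po$edge[nrow(po$edge), 1]
    masks <- matrix(0L, n, nchar_)
    changes <- integer(nchar_)
    nodestate <- integer(n + po$Nnode)
    for (j in seq_len(nchar_)) {
      nodestate[root] <- sample.int(k, 1L) - 1L
      nev_total <- 0L
      for (r in pre) {
        p <- po$edge[r, 1]; ch <- po$edge[r, 2]
        s <- nodestate[p]
        nev <- rpois(1L, lambda)
        if (nev > 0L) {
          for (q in seq_len(nev)) {
            others <- setdiff(0:(k - 1L), s)
            s <- others[sample.int(length(others), 1L)]
          }
          nev_total <- nev_total + nev
        }
        nodestate[ch] <- s
      }
      changes[j] <- nev_total
      masks[, j] <- 2L^nodestate[seq_len(n)]
    }
    mat <- new_char_matrix(masks, po$tip.label,
                           metadata = list(source = "mk simulation"))
    structure(list(true_tree = tree, matrix = mat,
                   per_character_change_counts = changes, config = config),
              class = "sim_dataset")
  })
}

#' Degrade a simulated matrix
#'
#' Replaces uniformly random cells by missing (`?`) and widens others to
#' two-state polymorphic sets containing the true state, emulating
#' fragmentary specimens and ambiguous scorings.  The truth is retained in
#' the dataset object.
#'
#' @param dataset a `sim_dataset` (or a `char_matrix`)
#' @param missing_fraction per-cell probability of becoming missing
#' @param polymorphic_fraction per-cell probability (among non-missing
#'   cells) of widening to a two-state set
#' @param seed optional integer seed
#' @return a `char_matrix`
#' @export
degrade_matrix <- function(dataset, missing_fraction,
                           polymorphic_fraction = 0, seed = NULL) {
  x <- if (inherits(dataset, "sim_dataset")) dataset$matrix else dataset
  k <- if (inherits(dataset, "sim_dataset")) dataset$config$n_states else
    max(vapply(seq_len(x$n_char), function(j)
      max(c(mask_to_states(observed_masks(x)[j]), 0L)) + 1L, integer(1)))
  stopifnot(missing_fraction >= 0, missing_fraction < 1,
            polymorphic_fraction >= 0, polymorphic_fraction < 1)
  with_seed(seed, function() {
    masks <- x$masks
    ncell <- length(masks)
    miss <- runif(ncell) < missing_fraction
    poly <- !miss & runif(ncell) < polymorphic_fraction
    masks[miss] <- 0L
    if (any(poly) && k >= 2L) {
      idx <- which(poly)
      for (i in idx) {
        st <- mask_to_states(masks[i])[1]
        others <- setdiff(0:(k - 1L), st)
        other <- others[sample.int(length(others), 1L)]
        masks[i] <- states_to_mask(c(st, other))
      }
    }
    new_char_matrix(masks, x$taxa,
                    metadata = c(x$metadata, list(degraded = TRUE)))
  })
}

#' Write a simulated dataset to files
#'
#' Emits the matrix (chosen dialect), the true tree (Newick) and a JSON
#' truth manifest (config echo and per-character change counts).
#'
#' @param dataset a `sim_dataset`
#' @param dir output directory (created if needed)
#' @param dialect matrix dialect
#' @return invisibly, the file paths
#' @export
write_sim_dataset <- function(dataset, dir, dialect = c("tnt", "nexus")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fm <- file.path(dir, paste0("matrix.", if (dialect == "tnt") "tnt" else "nex"))
  ft <- file.path(dir, "true_tree.nwk")
  fj <- file.path(dir, "truth.json")
  write_matrix(dataset$matrix, dialect, fm)
  write_newick(dataset$true_tree, ft)
  jsonlite::write_json(
    list(config = unclass(dataset$config),
         per_character_change_counts = dataset$per_character_change_counts),
    fj, auto_unbox = TRUE, digits = NA)
  invisible(c(matrix = fm, tree = ft, truth = fj))
}
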