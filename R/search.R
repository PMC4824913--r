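# Tree search: exact exhaustive enumeration, branch-and-bound, and seeded
# random-addition + branch-swapping heuristic search, all returning the
# full set of equally most-parsimonious trees.

#' Search configuration
#'
#' @param n_replicates number of random-addition-sequence starts
#' @param swap branch-swapping neighbourhood: `"tbr"` (default), `"spr"`,
#'   or `"nni"`
#' @param seed integer seed; the seed fully determines the search
#'   trajectory
#' @param max_trees_held cap on the pool of equal-length trees
#' @param collapse collapse zero-minimum-length branches before counting
#'   distinct optimal topologies
#' @param stop_no_improve stop early after this many replicates without
#'   improvement (0 = run all replicates)
#' @return an object of class `search_config`
#' @export
search_config <- function(n_replicates = 100L, swap = c("tbr", "spr", "nni"),
                          seed = 1L, max_trees_held = 10000L,
                          collapse = TRUE, stop_no_improve = 0L) {
  swap <- match.arg(swap)
  stopifnot(n_replicates >= 1L, max_trees_held >= 1L, stop_no_improve >= 0L)
  structure(list(n_replicates = as.integer(n_replicates), swap = swap,
                 seed = as.integer(seed),
                 max_trees_held = as.integer(max_trees_held),
                 collapse = isTRUE(collapse),
                 stop_no_improve = as.integer(stop_no_improve)),
            class = "search_config")
}

edge_to_phylo <- function(edge, taxa) {
  n <- length(taxa)
  tr <- structure(list(edge = edge, Nnode = max(edge) - n,
                       tip.label = taxa), class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

finish_result <- function(raw, x, method, config = NULL, collapse = TRUE) {
  taxa <- x$taxa
  binary <- lapply(raw$trees, edge_to_phylo, taxa = taxa)
  binary <- dedup_trees(binary)
  mpts <- if (collapse)
    dedup_trees(lapply(binary, collapse_min_zero, x = x))
  else binary
  class(mpts) <- class(binary) <- "multiPhylo"
  structure(list(best_length = as.integer(raw$best_length),
                 mpts = mpts, mpts_binary = binary,
                 replicate_log = raw$replicate_log %||% NULL,
                 hit_cap = isTRUE(raw$hit_cap),
                 collapse = collapse, method = method, config = config,
                 n_taxa = length(taxa)),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("<search_result> %s: best length %d, %d distinct MPT(s)%s\n",
              x$method, x$best_length, length(x$mpts),
              if (x$collapse) " (post-collapse)" else ""))
  if (x$hit_cap) cat("  note: tree pool cap was hit; MPT set may be incomplete\n")
  invisible(x)
}

#' Exhaustive parsimony search
#'
#' Scores every unrooted binary topology (enumerable up to 9 taxa:
#' 135,135 trees at n = 9) and returns the exact optimum with the complete
#' set of most-parsimonious trees.
#'
#' @param x a `char_matrix` with at most 9 taxa
#' @param collapse collapse zero-minimum-length branches in the reported
#'   MPT set
#' @return a `search_result`
#' @export
exhaustive_search <- function(x, collapse = TRUE) {
  n <- n_taxa(x)
  if (n > 9)
    stop("exhaustive enumeration is limited to 9 taxa; use branch_and_bound()")
  if (n < 4) stop("need at least 4 taxa")
  masks <- scoring_masks(x)
  raw <- .cpp_bnb(masks, 0:(n - 1L), FALSE, min_steps(x), 1e9, 200000L)
  finish_result(raw, x, "exhaustive", collapse = collapse)
}

#' Branch-and-bound parsimony search
#'
#' Exact search by stepwise taxon insertion with lower-bound pruning: a
#' partial tree is abandoned when its per-character steps, raised to each
#' character's global minimum, already exceed the best complete tree found
#' (initially a greedy addition tree).  Returns the exact optimum and the
#' complete MPT set.
#'
#' @param x a `char_matrix` (practical up to ~15 taxa)
#' @param collapse collapse zero-minimum-length branches in the reported set
#' @param max_nodes safety cap on visited partial trees
#' @return a `search_result`
#' @export
branch_and_bound <- function(x, collapse = TRUE, max_nodes = 5e7) {
  n <- n_taxa(x)
  if (n < 4) stop("need at least 4 taxa")
  if (n > 16)
    stop("branch_and_bound is limited to 16 taxa; use heuristic_search()")
  masks <- scoring_masks(x)
  raw <- .cpp_bnb(masks, 0:(n - 1L), TRUE, min_steps(x), max_nodes, 200000L)
  finish_result(raw, x, "branch_and_bound", collapse = collapse)
}

#' Heuristic parsimony search
#'
#' Random-addition-sequence starting trees followed by branch swapping
#' (TBR by default), accepting equal-or-better trees; all trees at the best
#' length are pooled, themselves swapped to enumerate the tree island, and
#' deduplicated (after optional collapsing of zero-minimum-length
#' branches).  Deterministic given the seed in `config`.
#'
#' @param x a `char_matrix`
#' @param config a [search_config()]
#' @return a `search_result`
#' @export
heuristic_search <- function(x, config = search_config()) {
  stopifnot(inherits(config, "search_config"))
  n <- n_taxa(x)
  if (n < 4) stop("need at least 4 taxa")
  masks <- scoring_masks(x)
  swapcode <- match(config$swap, c("nni", "spr", "tbr")) - 1L
  raw <- .cpp_heuristic_search(masks, config$n_replicates, swapcode,
                               as.double(config$seed),
                               config$max_trees_held,
                               config$stop_no_improve, TRUE)
  finish_result(raw, x, "heuristic", config = config,
                collapse = config$collapse)
}

#' Count distinct most-parsimonious trees
#'
#' Number of distinct post-collapse optimal topologies found by a search.
#' If the search was run without collapsing, the matrix must be supplied so
#' the collapse can be applied here.
#'
#' @param result a `search_result`
#' @param x the `char_matrix` (only needed when the search did not collapse)
#' @return integer count
#' @export
count_mpts <- function(result, x = NULL) {
  if (result$collapse) return(length(result$mpts))
  if (is.null(x))
    stop("search was run without collapsing; supply the matrix")
  length(dedup_trees(lapply(result$mpts_binary, collapse_min_zero, x = x)))
}
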