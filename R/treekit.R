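# Tree handling: Newick I/O (via ape), bipartition machinery, Robinson-
# Foulds distance, strict consensus, and zero-minimum-length branch
# collapsing.  Trees are ape "phylo" objects; scoring and consensus treat
# them as unrooted.

#' Parse / write Newick trees
#'
#' `parse_newick()` reads one or more Newick strings (one tree per line or
#' several separated by `;`) into `phylo` / `multiPhylo` objects, with
#' up-front validation of parenthesis balance and duplicate leaf labels.
#' `write_newick()` is the inverse; round-trips preserve topology.
#'
#' @param text Newick text
#' @return a `phylo`, or a `multiPhylo` if several trees are present
#' @export
parse_newick <- function(text) {
  text <- paste(text, collapse = "\n")
  open <- lengths(regmatches(text, gregexpr("\\(", text)))
  close <- lengths(regmatches(text, gregexpr("\\)", text)))
  if (open != close)
    stop("unbalanced parentheses in Newick text")
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick text")
  check_dup <- function(t) {
    if (anyDuplicated(t$tip.label))
      stop("duplicate leaf label: ", t$tip.label[duplicated(t$tip.label)][1])
    t
  }
  if (inherits(tr, "multiPhylo")) {
    for (t in tr) check_dup(t)
    tr
  } else check_dup(tr)
}

#' @rdname parse_newick
#' @param tree a `phylo` or `multiPhylo`
#' @param file optional output path
#' @return `write_newick()`: the Newick string(s), invisibly when written
#' @export
write_newick <- function(tree, file = NULL) {
  out <- ape::write.tree(tree)
  if (is.null(file)) return(out)
  writeLines(out, file)
  invisible(out)
}

#' @rdname parse_newick
#' @export
read_newick <- function(file) parse_newick(readLines(file, warn = FALSE))

# tips (as index vector into tip.label) below each node, postorder
tips_below <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  below <- vector("list", nn)
  for (i in seq_len(n)) below[[i]] <- i
  for (r in seq_len(nrow(tree$edge))) {
    p <- tree$edge[r, 1]; ch <- tree$edge[r, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  list(tree = tree, below = below)
}

split_key <- function(labels) paste(sort(labels), collapse = "\r")

# canonical non-trivial splits of a tree: for each internal edge, the sorted
# labels of the side not containing the reference leaf (the lexicographically
# smallest label)
#' Non-trivial bipartitions of a tree
#'
#' One canonical bipartition per internal edge: the side of the leaf-set
#' split that does not contain the reference leaf (the lexicographically
#' smallest label).  Trivial (single-leaf) splits are excluded; an unrooted
#' binary tree on n leaves yields exactly n - 3 bipartitions.
#'
#' @param tree a `phylo` (polytomies allowed)
#' @return a list of character vectors (sorted leaf labels), named by a
#'   canonical key
#' @export
bipartitions <- function(tree) {
  labs <- tree$tip.label
  n <- length(labs)
  ref <- labs[order(labs)][1]
  tb <- tips_below(tree)
  tree <- tb$tree
  out <- list()
  for (r in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[r, 2]
    if (ch <= n) next
    side <- labs[tb$below[[ch]]]
    sz <- length(side)
    if (sz < 2 || sz > n - 2) next
    if (ref %in% side) side <- setdiff(labs, side)
    out[[split_key(side)]] <- sort(side)
  }
  out[!duplicated(names(out))]
}

#' Robinson-Foulds distance
#'
#' Size of the symmetric difference between the bipartition sets of two
#' trees over the same leaf set.
#'
#' @param t1,t2 `phylo` objects with identical leaf sets
#' @return non-negative integer
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets: ",
         paste(union(setdiff(t1$tip.label, t2$tip.label),
                     setdiff(t2$tip.label, t1$tip.label)), collapse = ", "))
  k1 <- names(bipartitions(t1))
  k2 <- names(bipartitions(t2))
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

# Build an (unrooted, possibly polytomous) phylo from a compatible set of
# canonical splits.  `clades` are label vectors not containing `ref`.
tree_from_clades <- function(clades, leaves, ref) {
  clades <- clades[!duplicated(vapply(clades, split_key, ""))]
  keep <- lengths(clades) >= 2 & lengths(clades) <= length(leaves) - 2
  clades <- clades[keep]
  n <- length(leaves)
  if (length(clades)) clades <- clades[order(-lengths(clades))]
  nnode <- 1L + length(clades)
  ids <- if (length(clades)) n + 1L + seq_along(clades) else integer(0)
  cl_parent <- rep(n + 1L, length(clades))
  for (i in seq_along(clades)) {
    for (j in rev(seq_len(i - 1L))) {
      if (all(clades[[i]] %in% clades[[j]])) { cl_parent[i] <- ids[j]; break }
    }
  }
  tip_parent <- rep(n + 1L, n)
  for (t in seq_len(n)) {
    lab <- leaves[t]
    if (lab == ref) next
    for (j in rev(seq_along(clades)))
      if (lab %in% clades[[j]]) { tip_parent[t] <- ids[j]; break }
  }
  edge <- rbind(cbind(cl_parent, ids), cbind(tip_parent, seq_len(n)))
  storage.mode(edge) <- "integer"
  colnames(edge) <- NULL
  tr <- structure(list(edge = edge, Nnode = nnode, tip.label = leaves),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

#' Strict consensus tree
#'
#' Returns the tree whose bipartitions are exactly those present in every
#' input tree.
#'
#' @param trees a `multiPhylo` or list of `phylo` over one leaf set
#' @return a `phylo` (polytomies where the inputs disagree)
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) == 0) stop("no trees supplied")
  labs <- trees[[1]]$tip.label
  for (t in trees)
    if (!setequal(t$tip.label, labs)) stop("trees must share one leaf set")
  bp <- lapply(trees, bipartitions)
  common_keys <- Reduce(intersect, lapply(bp, names))
  clades <- bp[[1]][common_keys]
  ref <- sort(labs)[1]
  tree_from_clades(unname(clades), sort(labs), ref)
}

is_binary_tree <- function(tree) {
  n <- length(tree$tip.label)
  tab <- tabulate(tree$edge[, 1], nbins = n + tree$Nnode)
  kids <- tab[(n + 1):(n + tree$Nnode)]
  root_ok <- sum(kids == 3) <= 1
  all(kids %in% c(2, 3)) && root_ok && tree$Nnode == n - 2 ||
    all(kids == 2) && tree$Nnode == n - 1  # rooted binary
}

# masks of a matrix reordered to a tree's tip order
masks_for_tree <- function(tree, x) {
  idx <- match(tree$tip.label, x$taxa)
  if (anyNA(idx))
    stop("tree leaves not in matrix: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "))
  if (length(idx) != length(x$taxa))
    stop("matrix taxa not in tree: ",
         paste(setdiff(x$taxa, tree$tip.label), collapse = ", "))
  scoring_masks(x)[idx, , drop = FALSE]
}

#' Collapse branches of zero minimum length
#'
#' Contracts every internal edge whose minimum number of character-state
#' changes over all most-parsimonious reconstructions is zero, i.e. edges
#' that need not carry any change in any character under any optimal
#' ancestral assignment.  Scored with hard polytomies
#' (`fitch_length(..., polytomies = "hard")`), the contracted tree keeps
#' exactly the original length; under per-character refinement scoring it
#' can only become shorter.  This is the (stricter,
#' reconstruction-independent) rule used to decide when two binary search
#' results are spurious resolutions of the same underlying tree.
#'
#' @param tree a binary `phylo` over the matrix's taxa
#' @param x a `char_matrix`
#' @return a `phylo`, possibly with polytomies
#' @export
collapse_min_zero <- function(tree, x) {
  tree <- ape::unroot(tree)
  if (!is_binary_tree(tree))
    stop("collapse_min_zero() expects a binary tree")
  po <- ape::reorder.phylo(tree, "postorder")
  masks <- masks_for_tree(po, x)
  res <- .cpp_mpr_pairs(po$edge, length(po$tip.label), masks)
  labs <- po$tip.label
  n <- length(labs)
  tb <- tips_below(po)
  keep <- list()
  for (r in seq_len(nrow(po$edge))) {
    ch <- po$edge[r, 2]
    if (ch <= n) next                  # terminal edges never collapse
    if (res$collapse_ok[r]) next       # zero-minimum edge: contract
    side <- labs[tb$below[[ch]]]
    if (length(side) < 2 || length(side) > n - 2) next
    ref0 <- sort(labs)[1]
    if (ref0 %in% side) side <- setdiff(labs, side)
    keep[[length(keep) + 1L]] <- sort(side)
  }
  tree_from_clades(keep, sort(labs), sort(labs)[1])
}

# canonical key of a whole topology (split-set identity)
topology_key <- function(tree) {
  paste(sort(names(bipartitions(tree))), collapse = "\n")
}

# deduplicate a list of trees by split-set identity
dedup_trees <- function(trees) {
  keys <- vapply(trees, topology_key, "")
  trees[!duplicated(keys)]
}
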