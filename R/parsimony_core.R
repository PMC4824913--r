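# Fitch parsimony scoring: tree length, per-character step counts, step
# minima/maxima, ensemble consistency and retention indices, and
# synapomorphy mapping from all most-parsimonious reconstructions.

#' Fitch parsimony length of a tree
#'
#' Minimum number of character-state changes needed to explain the matrix
#' on the given tree, summed over equally weighted unordered characters.
#' Missing cells enter as the full observed state set of their character
#' and therefore never force changes.  Binary trees use a bitmask Fitch
#' pass.  Trees with polytomies are scored, per character, either as the
#' minimum over binary refinements of that character
#' (`polytomies = "refine"`, the default; exact dynamic programme, polytomy
#' degree at most 12) or on the multifurcating tree as given
#' (`polytomies = "hard"`, i.e. a polytomy is a simultaneous divergence).
#' The hard score is never below the refinement score; the two coincide on
#' binary trees.
#'
#' @param tree a `phylo` whose leaves match the matrix taxa
#' @param x a `char_matrix`
#' @param per_character if `TRUE`, return the per-character step vector
#' @param polytomies `"refine"` or `"hard"` (ignored for binary trees)
#' @return total steps (integer), or an integer vector of per-character
#'   steps when `per_character = TRUE`
#' @export
fitch_length <- function(tree, x, per_character = FALSE,
                         polytomies = c("refine", "hard")) {
  polytomies <- match.arg(polytomies)
  po <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  masks <- masks_for_tree(po, x)
  res <- if (is_binary_tree(po))
    .cpp_fitch_edge(po$edge, length(po$tip.label), masks)
  else
    .cpp_refine_score(po$edge, length(po$tip.label), masks, 12L,
                      polytomies == "refine")
  if (per_character) res$s else as.integer(res$total)
}

#' Per-character parsimony step minima
#'
#' The fewest steps character i can require on any tree: one less than the
#' size of the smallest set of states hitting every non-missing cell
#' (polymorphic cells may be satisfied by any member state).  Constant and
#' all-missing characters give 0.
#'
#' @param x a `char_matrix`
#' @return integer vector m, one entry per character
#' @export
min_steps <- function(x) {
  obs <- observed_masks(x)
  vapply(seq_len(x$n_char), function(j) {
    cells <- x$masks[, j]
    cells <- cells[cells > 0L]
    if (!length(cells)) return(0L)
    states <- mask_to_states(obs[j])
    k <- length(states)
    for (r in seq_len(k)) {
      combos <- utils::combn(states, r, simplify = FALSE)
      for (tt in combos) {
        tm <- states_to_mask(tt)
        if (all(bitwAnd(cells, tm) > 0L)) return(r - 1L)
      }
    }
    k - 1L
  }, integer(1))
}

#' Per-character parsimony step maxima
#'
#' The most steps character i can require on any tree (its length on the
#' worst-case/star tree): the number of non-missing cells minus the largest
#' single-state count achievable when polymorphic cells are resolved to
#' favour that state.  Missing cells never contribute.
#'
#' @param x a `char_matrix`
#' @return integer vector g, one entry per character
#' @export
max_steps <- function(x) {
  obs <- observed_masks(x)
  vapply(seq_len(x$n_char), function(j) {
    cells <- x$masks[, j]
    cells <- cells[cells > 0L]
    if (!length(cells)) return(0L)
    states <- mask_to_states(obs[j])
    min(vapply(states, function(s)
      sum(bitwAnd(cells, 2L^s) == 0L), integer(1)))
  }, integer(1))
}

#' Ensemble consistency and retention indices
#'
#' CI = sum(m)/sum(s); RI = (sum(g) - sum(s)) / (sum(g) - sum(m)), where s
#' are observed steps and m, g the per-character minima and maxima.  With a
#' degenerate denominator the statistic is `NA`, not an error.
#'
#' @param score a `tree_score` (see [tree_score()]), or any list carrying
#'   per-character vectors `s`, `m` and `g`
#' @return list with elements `ci` and `ri`
#' @export
ensemble_indices <- function(score) {
  compute_indices(score$s, score$m, score$g)
}

compute_indices <- function(s, m, g, use = TRUE) {
  S <- sum(s[use]); M <- sum(m[use]); G <- sum(g[use])
  ci <- if (S > 0) M / S else NA_real_
  ri <- if (G > M) (G - S) / (G - M) else NA_real_
  list(ci = ci, ri = ri)
}

#' Score a tree against a matrix
#'
#' Computes the full parsimony score report: total length, per-character
#' observed steps s, minima m, maxima g, and the ensemble consistency and
#' retention indices.  By default all characters enter the CI/RI sums (the
#' common default of classic parsimony software); set
#' `exclude_uninformative = TRUE` for the adjusted variants.
#'
#' @inheritParams fitch_length
#' @param exclude_uninformative drop parsimony-uninformative characters
#'   from the CI/RI sums
#' @return an object of class `tree_score`
#' @export
tree_score <- function(tree, x, exclude_uninformative = FALSE) {
  s <- fitch_length(tree, x, per_character = TRUE)
  m <- min_steps(x)
  g <- max_steps(x)
  use <- if (exclude_uninformative) informative_characters(x) else
    rep(TRUE, x$n_char)
  idx <- compute_indices(s, m, g, use)
  structure(list(total = sum(s), s = s, m = m, g = g,
                 ci = idx$ci, ri = idx$ri,
                 exclude_uninformative = exclude_uninformative),
            class = "tree_score")
}

#' @export
print.tree_score <- function(x, ...) {
  cat(sprintf("<tree_score> length %d steps; CI = %s, RI = %s%s\n",
              x$total,
              ifelse(is.na(x$ci), "NA", sprintf("%.2f", x$ci)),
              ifelse(is.na(x$ri), "NA", sprintf("%.2f", x$ri)),
              if (x$exclude_uninformative) " (uninformative excluded)" else ""))
  invisible(x)
}

#' @export
as.data.frame.tree_score <- function(x, ...) {
  data.frame(character = seq_along(x$s), m = x$m, s = x$s, g = x$g)
}

#' Write a score report
#'
#' Emits the per-character m/s/g table as TSV and a JSON summary (total
#' length, CI, RI).
#'
#' @param score a `tree_score`
#' @param tsv,json output paths (either may be `NULL` to skip)
#' @return invisibly, the summary list
#' @export
write_score_report <- function(score, tsv = NULL, json = NULL) {
  if (!is.null(tsv))
    utils::write.table(as.data.frame(score), tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  summ <- list(total_length = score$total, ci = score$ci, ri = score$ri)
  if (!is.null(json))
    jsonlite::write_json(summ, json, auto_unbox = TRUE, digits = NA)
  invisible(summ)
}

decode_pairs <- function(bits) {
  # pair bitmask -> two-column matrix of (parent-side, child-side) states
  out <- NULL
  for (a in 0:4) for (b in 0:4) {
    if (bitwAnd(bits, bitwShiftL(1L, a * 6L + b)) != 0L)
      out <- rbind(out, c(a, b))
  }
  out
}

#' Map synapomorphies onto optimal trees
#'
#' For a set of equally most-parsimonious binary trees, finds every
#' character-state change assigned to a branch by at least one
#' most-parsimonious reconstruction, and flags as unambiguous those changes
#' that appear, with the same states, on the branch subtending the same
#' clade in every reconstruction of every supplied tree ("in all shortest
#' trees").  Clades are read relative to an outgroup leaf.
#'
#' @param trees a `multiPhylo` or list of binary `phylo` objects
#' @param x a `char_matrix`
#' @param outgroup leaf label used to orient changes; defaults to
#'   `"Rhineceps nyasaensis"` when present, otherwise the first taxon
#' @return data frame with columns `character` (1-based), `from`, `to`,
#'   `clade` (labels joined by `" + "`), `clade_size`, `n_trees`,
#'   `unambiguous`
#' @export
map_synapomorphies <- function(trees, x, outgroup = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("no trees supplied")
  if (is.null(outgroup))
    outgroup <- if ("Rhineceps nyasaensis" %in% x$taxa)
      "Rhineceps nyasaensis" else x$taxa[1]
  if (!outgroup %in% x$taxa) stop("unknown outgroup: ", outgroup)
  lens <- vapply(trees, fitch_length, integer(1), x = x)
  if (length(unique(lens)) > 1L)
    warning("supplied trees differ in length (", paste(range(lens), collapse = "-"),
            "); non-optimal trees processed anyway")
  nt <- length(trees)
  recs <- list()
  for (ti in seq_along(trees)) {
    tree <- ape::unroot(trees[[ti]])
    if (!is_binary_tree(tree))
      stop("map_synapomorphies() expects binary trees; collapse afterwards")
    po <- ape::reorder.phylo(tree, "postorder")
    masks <- masks_for_tree(po, x)
    res <- .cpp_mpr_pairs(po$edge, length(po$tip.label), masks)
    labs <- po$tip.label
    n <- length(labs)
    tb <- tips_below(po)
    for (r in seq_len(nrow(po$edge))) {
      ch <- po$edge[r, 2]
      side <- sort(labs[tb$below[[ch]]])
      flip <- outgroup %in% side
      clade <- if (flip) sort(setdiff(labs, side)) else side
      for (j in seq_len(x$n_char)) {
        bits <- res$pairs[r, j]
        if (bits == 0L) next
        P <- decode_pairs(bits)
        changing <- P[P[, 1] != P[, 2], , drop = FALSE]
        if (!nrow(changing)) next
        unamb <- nrow(P) == 1L && nrow(changing) == 1L
        for (q in seq_len(nrow(changing))) {
          a <- changing[q, 1]; b <- changing[q, 2]
          if (flip) { tmp <- a; a <- b; b <- tmp }
          recs[[length(recs) + 1L]] <- data.frame(
            tree = ti, character = j, from = a, to = b,
            clade = paste(clade, collapse = " + "),
            clade_size = length(clade), unamb = unamb)
        }
      }
    }
  }
  if (!length(recs))
    return(data.frame(character = integer(0), from = integer(0),
                      to = integer(0), clade = character(0),
                      clade_size = integer(0), n_trees = integer(0),
                      unambiguous = logical(0)))
  allr <- do.call(rbind, recs)
  key <- paste(allr$character, allr$from, allr$to, allr$clade, sep = "\r")
  agg <- lapply(split(allr, key), function(d) {
    data.frame(character = d$character[1], from = d$from[1], to = d$to[1],
               clade = d$clade[1], clade_size = d$clade_size[1],
               n_trees = length(unique(d$tree)),
               unambiguous = sum(d$unamb[!duplicated(d$tree)]) == nt)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$character, out$clade), ]
}
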