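# End-to-end analysis pipelines with machine-diffable run manifests.
# These functions back the command-line interface in inst/cli/morphpars.R.

md5_of_matrix <- function(x) {
  f <- tempfile(fileext = ".tnt")
  on.exit(unlink(f))
  write_matrix(x, "tnt", f)
  unname(tools::md5sum(f))
}

run_pipeline <- function(x, config, outgroup = NULL, out_dir = NULL,
                         command = "run", extra = list()) {
  t0 <- proc.time()[["elapsed"]]
  res <- heuristic_search(x, config)
  cons <- strict_consensus(res$mpts)
  score <- tree_score(res$mpts_binary[[1]], x)
  syn <- map_synapomorphies(res$mpts_binary, x, outgroup = outgroup)
  wall <- proc.time()[["elapsed"]] - t0
  manifest <- c(list(
    command = command,
    seed = config$seed,
    config = unclass(config),
    matrix_md5 = md5_of_matrix(x),
    n_taxa = n_taxa(x), n_characters = n_characters(x),
    best_length = res$best_length,
    n_mpts = length(res$mpts),
    n_binary_trees = length(res$mpts_binary),
    hit_cap = res$hit_cap,
    ci = score$ci, ri = score$ri,
    consensus_newick = write_newick(cons),
    wall_time_s = round(wall, 3)), extra)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_newick(res$mpts, file.path(out_dir, "mpts.nwk"))
    write_newick(cons, file.path(out_dir, "consensus.nwk"))
    write_score_report(score, tsv = file.path(out_dir, "score.tsv"),
                       json = file.path(out_dir, "score.json"))
    utils::write.table(syn, file.path(out_dir, "synapomorphies.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(manifest = manifest, result = res, consensus = cons, score = score,
       synapomorphies = syn)
}

#' Reproduce the capitosaur analyses
#'
#' Runs the full pipeline on a bundled matrix variant: load, heuristic
#' search, collapse, strict consensus, homoplasy indices, synapomorphy
#' mapping.  The run is checked against the published expectations for that
#' variant: best length 186 with 3 MPTs for the composite coding of
#' *Y. maopingchangensis*, 185 with 2 MPTs for the holotype-only coding,
#' and the presence of the *Yuanansuchus* sister-pair in the consensus.
#' Length and clade presence are hard checks; the MPT count is reported but
#' only flagged on mismatch, since it depends on the branch-collapsing
#' convention of the original program, which is not stated.
#'
#' @param variant `"composite"` or `"holotype"`
#' @param seed search seed
#' @param out_dir optional output directory for manifest, trees and tables
#' @param config optional [search_config()] (its seed is overridden by
#'   `seed`)
#' @param quiet suppress the printed PASS/FLAG summary
#' @return invisibly, a list with `manifest`, `result`, `consensus`,
#'   `score`, `synapomorphies`, and `pass`
#' @export
reproduce_analysis <- function(variant = c("composite", "holotype"),
                               seed = 1L, out_dir = NULL, config = NULL,
                               quiet = FALSE) {
  variant <- match.arg(variant)
  expected <- switch(variant,
                     composite = list(length = 186L, n_mpts = 3L),
                     holotype = list(length = 185L, n_mpts = 2L))
  x <- load_fixture(variant)
  if (is.null(config)) config <- search_config()
  config$seed <- as.integer(seed)
  out <- run_pipeline(x, config, outgroup = "Rhineceps nyasaensis",
                      out_dir = out_dir, command = paste0("reproduce:", variant),
                      extra = list(variant = variant, expected = expected))
  pair <- c("Yuanansuchus laticeps", "Yuanansuchus maopingchangensis")
  in_cons <- split_key(pair) %in% names(bipartitions(out$consensus))
  in_all <- all(vapply(out$result$mpts, function(t)
    split_key(pair) %in% names(bipartitions(t)), logical(1)))
  len_ok <- out$result$best_length == expected$length
  count_ok <- length(out$result$mpts) == expected$n_mpts
  pass <- len_ok && in_cons && in_all
  if (!quiet) {
    msg <- function(ok, what)
      cat(sprintf("  [%s] %s\n", if (ok) "PASS" else "FAIL", what))
    cat(sprintf("reproduce (%s coding):\n", variant))
    msg(len_ok, sprintf("best length %d (expected %d)",
                        out$result$best_length, expected$length))
    msg(in_cons && in_all, "Yuanansuchus sister-pair in all MPTs and consensus")
    cat(sprintf("  [%s] %d distinct MPTs after collapsing (published: %d)%s\n",
                if (count_ok) "PASS" else "FLAG", length(out$result$mpts),
                expected$n_mpts,
                if (count_ok) "" else " - collapse convention dependent"))
  }
  out$pass <- pass
  out$checks <- list(length = len_ok, clade = in_cons && in_all,
                     mpt_count = count_ok)
  invisible(out)
}

#' Run the pipeline on an arbitrary matrix
#'
#' @param x a `char_matrix`, or a path to a matrix file
#' @param config a [search_config()]
#' @param outgroup optional leaf label for orienting synapomorphies
#' @param out_dir optional output directory
#' @param dialect matrix dialect when `x` is a path
#' @return a list with `manifest`, `result`, `consensus`, `score`,
#'   `synapomorphies`
#' @export
run_analysis <- function(x, config = search_config(), outgroup = NULL,
                         out_dir = NULL, dialect = "auto") {
  if (is.character(x)) x <- read_matrix(x, dialect)
  run_pipeline(x, config, outgroup = outgroup, out_dir = out_dir)
}

#' Score a user tree against a matrix
#'
#' @param x a `char_matrix` or path to a matrix file
#' @param tree a `phylo` or path to a Newick file
#' @param dialect matrix dialect when `x` is a path
#' @inheritParams tree_score
#' @return a `tree_score`
#' @export
score_tree <- function(x, tree, dialect = "auto",
                       exclude_uninformative = FALSE) {
  if (is.character(x)) x <- read_matrix(x, dialect)
  if (is.character(tree)) tree <- read_newick(tree)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  tree_score(tree, x, exclude_uninformative = exclude_uninformative)
}
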