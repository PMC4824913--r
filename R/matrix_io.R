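# Character matrix container and readers/writers.
#
# A `char_matrix` stores each cell as a bitmask over state digits 0..9
# (bit s set <=> state s in the cell's state set); 0 encodes "missing".
# Missing cells behave in all scoring as the full set of states observed in
# that character's column, the standard convention of parsimony programs.

SYMBOL_RX <- "^[][0-9?-]+$"  # digits, ?, -, and bracket tokens

new_char_matrix <- function(masks, taxa, char_labels = NULL, metadata = list()) {
  stopifnot(is.matrix(masks), nrow(masks) == length(taxa))
  storage.mode(masks) <- "integer"
  rownames(masks) <- taxa
  structure(
    list(taxa = taxa, n_char = ncol(masks), masks = masks,
         char_labels = char_labels, metadata = metadata),
    class = "char_matrix")
}

#' Number of taxa / characters of a character matrix
#' @param x a `char_matrix`
#' @return integer count
#' @export
n_taxa <- function(x) length(x$taxa)

#' @rdname n_taxa
#' @export
n_characters <- function(x) x$n_char

#' @export
print.char_matrix <- function(x, ...) {
  cat(sprintf("<char_matrix> %d taxa x %d characters\n",
              n_taxa(x), n_characters(x)))
  nm <- sum(x$masks == 0L)
  np <- sum(bit_count(x$masks) > 1L)
  cat(sprintf("  missing cells: %d (%.1f%%), polymorphic cells: %d\n",
              nm, 100 * nm / length(x$masks), np))
  if (!is.null(x$metadata$source))
    cat("  source:", x$metadata$source, "\n")
  invisible(x)
}

bit_count <- function(m) {
  n <- integer(length(m))
  v <- as.integer(m)
  while (any(v > 0L)) {
    n <- n + (v %% 2L)
    v <- v %/% 2L
  }
  dim(n) <- dim(m)
  n
}

mask_to_states <- function(mask) which(bitwAnd(mask, 2L^(0:9)) > 0L) - 1L

states_to_mask <- function(states) as.integer(sum(2L^states))

#' States recorded in one cell
#'
#' @param x a `char_matrix`
#' @param taxon taxon label or row index
#' @param character 1-based character index
#' @return integer vector of state digits, or `NA` for a missing cell
#' @export
cell_states <- function(x, taxon, character) {
  i <- if (is.character(taxon)) match(taxon, x$taxa) else taxon
  if (is.na(i)) stop("unknown taxon: ", taxon)
  m <- x$masks[i, character]
  if (m == 0L) return(NA_integer_)
  mask_to_states(m)
}

# per-character mask of all observed states (0 where a column is all-missing)
observed_masks <- function(x) {
  apply(x$masks, 2L, function(col) Reduce(bitwOr, col, 0L))
}

# masks with missing cells resolved to the full observed state set of the
# column; all-missing columns become state {0} so they score zero anywhere
scoring_masks <- function(x) {
  obs <- observed_masks(x)
  obs[obs == 0L] <- 1L
  m <- x$masks
  for (j in seq_len(ncol(m))) m[m[, j] == 0L, j] <- obs[j]
  storage.mode(m) <- "integer"
  m
}

tokenize_symbols <- function(s, where = "") {
  s <- gsub("[ \t]", "", s)
  chars <- strsplit(s, "")[[1]]
  toks <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= length(chars) && chars[j] != "]") j <- j + 1L
      if (j > length(chars))
        stop("unterminated '[' in ", where)
      toks <- c(toks, paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + 1L
    } else {
      toks <- c(toks, ch)
      i <- i + 1L
    }
  }
  toks
}

token_to_mask <- function(tok, where = "", pos = NA) {
  if (tok %in% c("?", "-")) return(0L)
  digs <- strsplit(tok, "")[[1]]
  if (!all(grepl("^[0-9]$", digs)) || length(digs) < 1L)
    stop(sprintf("unknown symbol '%s' at character %s in %s", tok, pos, where))
  states_to_mask(unique(as.integer(digs)))
}

row_to_masks <- function(sym, taxon, n_char = NULL) {
  toks <- tokenize_symbols(sym, where = taxon)
  if (!is.null(n_char) && length(toks) != n_char)
    stop(sprintf("row for '%s' expands to %d cells, expected %d",
                 taxon, length(toks), n_char))
  vapply(seq_along(toks), function(i)
    token_to_mask(toks[i], where = taxon, pos = i), integer(1))
}

# Split a row line into (label, symbol string).  The label is the leading
# quoted string, or all leading tokens that are not pure symbol runs; the
# remaining tokens are concatenated (Table-1-style 10-column grouping and
# stray internal spaces are typographic, not semantic).
split_row <- function(line) {
  line <- trimws(line)
  if (startsWith(line, "'")) {
    m <- regmatches(line, regexec("^'([^']*)'\\s*(.*)$", line))[[1]]
    if (length(m) < 3L) stop("unterminated quoted label: ", line)
    return(list(label = m[2], symbols = m[3]))
  }
  toks <- strsplit(line, "[ \t]+")[[1]]
  is_sym <- grepl(SYMBOL_RX, toks)
  k <- which(is_sym)[1]
  if (is.na(k) && length(toks) >= 2L)
    k <- length(toks)  # malformed symbols: report them from token_to_mask
  if (is.na(k) || k == 1L)
    stop("cannot split row into label and symbols: ", line)
  list(label = paste(toks[seq_len(k - 1L)], collapse = " "),
       symbols = paste(toks[k:length(toks)], collapse = ""))
}

#' Parse a morphological character matrix
#'
#' Reads a taxa-by-characters matrix of unordered multistate characters from
#' text in either a TNT-style dialect (optional `xread 'comment' nchar ntax`
#' header, one `label  symbols` row per taxon, optional terminating `;`) or
#' a NEXUS subset (`DATA`/`CHARACTERS` block with `DIMENSIONS`, `FORMAT`,
#' `MATRIX`).  `?` (or `-`) is missing; `[ab]` is a polymorphic/ambiguous
#' cell scored as the state set \{a, b\}.  Whitespace inside a row's symbol
#' string is ignored.
#'
#' @param text character vector of lines, or a single string with newlines
#' @param dialect `"tnt"`, `"nexus"`, or `"auto"` (sniff for `#NEXUS`)
#' @return a `char_matrix`
#' @seealso [read_matrix()], [write_matrix()], [load_fixture()]
#' @export
parse_matrix <- function(text, dialect = c("auto", "tnt", "nexus")) {
  dialect <- match.arg(dialect)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  if (dialect == "auto")
    dialect <- if (any(grepl("^\\s*#NEXUS", lines, ignore.case = TRUE)))
      "nexus" else "tnt"
  if (dialect == "tnt") parse_tnt(lines) else parse_nexus(lines)
}

#' Read a character matrix from a file
#' @param file path to a matrix file
#' @inheritParams parse_matrix
#' @return a `char_matrix`
#' @export
read_matrix <- function(file, dialect = c("auto", "tnt", "nexus")) {
  m <- parse_matrix(readLines(file, warn = FALSE), dialect)
  m$metadata$source <- file
  m
}

parse_tnt <- function(lines) {
  lines <- sub("(^|[^'])#.*$", "\\1", lines)  # trailing comments
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  declared <- NULL
  comment <- NULL
  if (length(lines) && grepl("^xread", lines[1], ignore.case = TRUE)) {
    hd <- lines[1]
    cm <- regmatches(hd, regexec("'([^']*)'", hd))[[1]]
    if (length(cm) == 2L) comment <- cm[2]
    hd2 <- gsub("'[^']*'", "", hd)
    nums <- as.integer(regmatches(hd2, gregexpr("[0-9]+", hd2))[[1]])
    if (length(nums) >= 2L) declared <- nums[1:2]  # nchar ntax
    lines <- lines[-1]
  }
  lines <- sub(";\\s*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, split_row)
  labs <- vapply(rows, `[[`, "", "label")
  if (anyDuplicated(labs))
    stop("duplicate taxon label: ", labs[duplicated(labs)][1])
  n_char <- if (!is.null(declared)) declared[1] else
    length(tokenize_symbols(rows[[1]]$symbols, labs[1]))
  if (!is.null(declared) && declared[2] != length(rows))
    stop(sprintf("header declares %d taxa but %d rows found",
                 declared[2], length(rows)))
  cells <- vapply(rows, function(r)
    row_to_masks(r$symbols, r$label, n_char), integer(n_char))
  masks <- if (is.matrix(cells)) t(cells) else matrix(cells, ncol = 1L)
  new_char_matrix(masks, labs,
                  metadata = list(dialect = "tnt", comment = comment))
}

parse_nexus <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  ntax <- as.integer(sub(".*NTAX\\s*=\\s*([0-9]+).*", "\\1", txt,
                         ignore.case = TRUE))
  nchr <- as.integer(sub(".*NCHAR\\s*=\\s*([0-9]+).*", "\\1", txt,
                         ignore.case = TRUE))
  if (is.na(ntax) || is.na(nchr))
    stop("NEXUS input lacks DIMENSIONS NTAX/NCHAR")
  mstart <- grep("^\\s*MATRIX\\s*$", lines, ignore.case = TRUE)
  if (!length(mstart)) stop("NEXUS input lacks a MATRIX block")
  body <- lines[(mstart[1] + 1L):length(lines)]
  semi <- grep("^\\s*;", body)
  if (length(semi)) body <- body[seq_len(semi[1] - 1L)]
  body <- trimws(body)
  body <- body[nzchar(body)]
  body <- gsub("\\(", "[", body)
  body <- gsub("\\)", "]", body)
  body <- gsub("\\{", "[", body)
  body <- gsub("\\}", "]", body)
  rows <- lapply(body, split_row)
  labs <- gsub("_", " ", vapply(rows, `[[`, "", "label"))
  if (anyDuplicated(labs))
    stop("duplicate taxon label: ", labs[duplicated(labs)][1])
  if (length(rows) != ntax)
    stop(sprintf("NTAX=%d but %d matrix rows found", ntax, length(rows)))
  cells <- vapply(rows, function(r)
    row_to_masks(r$symbols, r$label, nchr), integer(nchr))
  masks <- if (is.matrix(cells)) t(cells) else matrix(cells, ncol = 1L)
  new_char_matrix(masks, labs, metadata = list(dialect = "nexus"))
}

mask_to_token <- function(m) {
  if (m == 0L) return("?")
  st <- mask_to_states(m)
  if (length(st) == 1L) as.character(st) else
    paste0("[", paste(st, collapse = ""), "]")
}

#' Write a character matrix
#'
#' Serializes a `char_matrix` so that [parse_matrix()] recovers it
#' cell-for-cell (missing cells as `?`, polymorphic cells as bracket
#' tokens).
#'
#' @param x a `char_matrix`
#' @param dialect `"tnt"` or `"nexus"`
#' @param file optional path; if `NULL` the text is returned invisibly
#' @return character vector of lines (invisibly when written to a file)
#' @export
write_matrix <- function(x, dialect = c("tnt", "nexus"), file = NULL) {
  dialect <- match.arg(dialect)
  symrows <- apply(x$masks, 1L, function(r)
    paste(vapply(r, mask_to_token, ""), collapse = ""))
  if (dialect == "tnt") {
    cmt <- x$metadata$comment %||% "morphological matrix"
    out <- c(sprintf("xread '%s' %d %d", cmt, x$n_char, length(x$taxa)),
             sprintf("'%s'\t%s", x$taxa, symrows), ";")
  } else {
    out <- c("#NEXUS", "BEGIN DATA;",
             sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", length(x$taxa), x$n_char),
             "FORMAT SYMBOLS=\"0123456789\" MISSING=?;", "MATRIX",
             sprintf("%s\t%s", gsub(" ", "_", x$taxa), symrows),
             ";", "END;")
  }
  if (is.null(file)) return(out)
  writeLines(out, file)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load the bundled capitosaur matrix
#'
#' Returns the bundled 29-taxon, 56-character cranial character matrix of
#' capitosaur temnospondyls.  The matrix is stored with 30 rows because the
#' recently erected species *Yuanansuchus maopingchangensis* carries two
#' alternative coding rows: one scored from the holotype skull only, and a
#' composite row scored from all known specimens.  `load_fixture()` resolves
#' the requested variant to a 29-taxon matrix.
#'
#' One taxon label is printed in the source with an evident typo
#' ("Cherninis denwai"); it is preserved verbatim, with the corrected
#' binomial recorded as an alias in `metadata$aliases`.
#'
#' @param variant `"composite"` (all known specimens) or `"holotype"`
#' @return a 29 x 56 `char_matrix`
#' @export
load_fixture <- function(variant = c("composite", "holotype")) {
  variant <- match.arg(variant)
  path <- system.file("extdata", "capitosaur56.tnt", package = "morphpars",
                      mustWork = TRUE)
  m <- read_matrix(path, dialect = "tnt")
  focal <- "Yuanansuchus maopingchangensis"
  keep_row <- paste0(focal, " (", variant, ")")
  drop_row <- paste0(focal, " (",
                     setdiff(c("composite", "holotype"), variant), ")")
  i <- match(keep_row, m$taxa)
  j <- match(drop_row, m$taxa)
  if (is.na(i) || is.na(j)) stop("fixture lacks expected coding rows")
  masks <- m$masks[-j, , drop = FALSE]
  taxa <- m$taxa[-j]
  taxa[taxa == keep_row] <- focal
  new_char_matrix(masks, taxa, metadata = list(
    source = path, variant = variant, dialect = "tnt",
    aliases = c("Cherninia denwai" = "Cherninis denwai")))
}

#' Per-character summary of a matrix
#'
#' For each character: the observed states, how many taxa bear each state
#' (polymorphic cells counted once per member state), the number of missing
#' cells, the parsimony step minimum and maximum, and whether the character
#' is parsimony-informative (at least two states can each be held by at
#' least two taxa under some resolution of polymorphic cells).
#'
#' @param x a `char_matrix`
#' @return a data frame with one row per character
#' @export
matrix_summary <- function(x) {
  obs <- observed_masks(x)
  mm <- min_steps(x)
  gg <- max_steps(x)
  res <- lapply(seq_len(x$n_char), function(j) {
    col <- x$masks[, j]
    st <- mask_to_states(obs[j])
    counts <- vapply(st, function(s)
      sum(bitwAnd(col, 2L^s) > 0L), integer(1))
    data.frame(
      character = j,
      n_states = length(st),
      states = paste(st, collapse = ","),
      counts = paste(counts, collapse = ","),
      n_missing = sum(col == 0L),
      min_steps = mm[j],
      max_steps = gg[j],
      informative = is_informative(col, st))
  })
  do.call(rbind, res)
}

# informative <=> some resolution of polymorphic cells leaves >=2 states
# each in >=2 taxa; checked pairwise (cells holding both focal states can be
# assigned to either side)
is_informative <- function(col, states) {
  if (length(states) < 2L) return(FALSE)
  for (a in states) for (b in states) {
    if (a >= b) next
    ina <- bitwAnd(col, 2L^a) > 0L
    inb <- bitwAnd(col, 2L^b) > 0L
    only_a <- sum(ina & !inb); only_b <- sum(inb & !ina)
    both <- sum(ina & inb)
    for (k in 0:both)
      if (only_a + k >= 2L && only_b + (both - k) >= 2L) return(TRUE)
  }
  FALSE
}

#' Parsimony-informative characters
#' @param x a `char_matrix`
#' @return logical vector, one entry per character
#' @export
informative_characters <- function(x) {
  obs <- observed_masks(x)
  vapply(seq_len(x$n_char), function(j)
    is_informative(x$masks[, j], mask_to_states(obs[j])), logical(1))
}
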