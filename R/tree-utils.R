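# Tree utilities: bipartitions, monophyly, newick I/O. Trees are ape
# "phylo" objects (unrooted, leaf labels = taxon labels; internal node
# labels carry bootstrap supports when present).

# Canonical key of a bipartition side: the side NOT containing the overall
# lexicographically smallest leaf, sorted and pipe-joined.
bipartition_key <- function(side, all_labels) {
  anchor <- min(all_labels)
  if (anchor %in% side) side <- setdiff(all_labels, side)
  paste(sort(side), collapse = "|")
}

#' Nontrivial bipartitions of an unrooted tree
#'
#' Each internal edge of an unrooted tree splits the leaves into two
#' complementary sets. Returns the nontrivial splits (both sides with at
#' least two leaves) in a canonical keyed form usable for comparing trees and
#' counting bootstrap replicates.
#'
#' @param tree An ape `phylo` object.
#' @return Named list: keys are canonical split strings (see details), values
#'   are character vectors holding the keyed side's labels.
#' @export
tree_bipartitions <- function(tree) {
  labs <- tree$tip.label
  pp <- ape::prop.part(tree)
  out <- list()
  for (cl in pp) {
    side <- labs[cl]
    if (length(side) < 2L || length(side) > length(labs) - 2L) next
    key <- bipartition_key(side, labs)
    out[[key]] <- sort(if (min(labs) %in% side) setdiff(labs, side) else side)
  }
  out
}

#' Test monophyly of a taxon set on an unrooted tree
#'
#' A taxon set is monophyletic on an unrooted tree when the set (or,
#' equivalently, its complement) forms one side of some bipartition — i.e. it
#' is a clade under any rooting outside the set. Singletons and the full leaf
#' set are trivially monophyletic.
#'
#' @param tree An ape `phylo` object.
#' @param taxa Character vector of leaf labels.
#' @return `TRUE` or `FALSE`.
#' @export
is_monophyletic <- function(tree, taxa) {
  labs <- tree$tip.label
  unknown <- setdiff(taxa, labs)
  if (length(unknown) > 0L)
    stop(sprintf("unknown label '%s'", unknown[1L]), call. = FALSE)
  taxa <- unique(taxa)
  k <- length(taxa)
  if (k <= 1L || k >= length(labs) - 1L) return(TRUE)
  key <- bipartition_key(taxa, labs)
  key %in% names(tree_bipartitions(tree))
}

needs_quoting <- function(x) grepl("[][ '(){}:;,]", x)

quote_label <- function(x) {
  ifelse(needs_quoting(x),
         paste0("'", gsub("'", "''", x), "'"),
         x)
}

#' Write a tree as newick text
#'
#' Branch lengths are written to 6 decimals and internal-node labels (e.g.
#' bootstrap supports) are preserved; labels containing spaces or newick
#' metacharacters are single-quoted (with embedded quotes doubled), which
#' [read_newick()] undoes on the way back in.
#'
#' @param tree An ape `phylo` object.
#' @param path Optional file path; when `NULL` the newick string is returned.
#' @param digits Decimals for branch lengths.
#' @return The newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, path = NULL, digits = 6L) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  elen <- tree$edge.length
  eidx <- setNames(seq_len(nrow(tree$edge)), tree$edge[, 2L])
  fmt_len <- function(node) {
    if (is.null(elen)) return("")
    sprintf(paste0(":%.", digits, "f"), elen[eidx[[as.character(node)]]])
  }
  node_lab <- function(node) {
    if (is.null(tree$node.label)) return("")
    lab <- tree$node.label[node - ntip]
    if (is.na(lab) || !nzchar(lab)) "" else quote_label(lab)
  }
  serialize <- function(node) {
    if (node <= ntip) return(quote_label(tree$tip.label[node]))
    inner <- paste(vapply(kids[[as.character(node)]], function(k) {
      paste0(serialize(k), fmt_len(k))
    }, ""), collapse = ",")
    paste0("(", inner, ")", node_lab(node))
  }
  txt <- paste0(serialize(root), ";")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a newick tree
#'
#' @param text Newick string (used when `path` is `NULL`).
#' @param path Optional file to read from.
#' @return An ape `phylo` object; surrounding single quotes on labels are
#'   stripped.
#' @export
read_newick <- function(text = NULL, path = NULL) {
  txt <- if (!is.null(path)) paste(readLines(path), collapse = "") else text
  if (is.null(txt) || !nzchar(trimws(txt)))
    stop("empty newick input", call. = FALSE)
  if (!grepl(";", txt, fixed = TRUE))
    stop(sprintf("malformed newick: missing ';' (near character %d)",
                 nchar(txt)), call. = FALSE)
  # shield single-quoted labels (which may hold newick metacharacters) from
  # the structural parser, then restore them afterwards
  qm <- gregexpr("'(?:[^']|'')*'", txt, perl = TRUE)
  quoted <- regmatches(txt, qm)[[1L]]
  if (length(quoted) > 0L) {
    regmatches(txt, qm) <- list(sprintf("QLBL%dX", seq_along(quoted)))
  }
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) {
    bal <- cumsum((strsplit(txt, "")[[1L]] == "(") -
                    (strsplit(txt, "")[[1L]] == ")"))
    off <- if (any(bal < 0)) which(bal < 0)[1L] else nchar(txt)
    stop(sprintf("malformed newick near character %d", off), call. = FALSE)
  }
  restore <- function(x) {
    hit <- regmatches(x, regexec("^QLBL(\\d+)X$", x))
    for (i in seq_along(x)) {
      if (length(hit[[i]]) == 2L) {
        orig <- quoted[as.integer(hit[[i]][2L])]
        x[i] <- gsub("''", "'", substr(orig, 2L, nchar(orig) - 1L))
      }
    }
    x
  }
  tr$tip.label <- restore(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- restore(tr$node.label)
  tr
}
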