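# Pairwise divergence: uncorrected p-distance with optional JC69/K2P
# corrections, and table formatting in the style of published divergence
# tables (percent, lower triangle, 3 decimals).

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of mismatching sites among sites where both residues are
#' determinate (`A/C/G/T`). A gap or ambiguity code at either position skips
#' the site under pairwise deletion; `complete-context` applies the same
#' arithmetic to an alignment the caller has already column-masked.
#'
#' @param x,y Aligned residue strings (or character vectors) of equal length.
#' @param deletion `"pairwise"` (default) or `"complete-context"`.
#' @return A list with `p` (proportion in `[0,1]`) and `comparable` (site
#'   count the proportion is based on).
#' @examples
#' p_distance("ACGT", "ACGA")$p   # 0.25
#' p_distance("AC-T", "ACGT")$p   # 0 over 3 comparable sites
#' @export
p_distance <- function(x, y, deletion = c("pairwise", "complete-context")) {
  match.arg(deletion)
  if (is.character(x) && length(x) == 1L) x <- strsplit(toupper(x), "")[[1L]]
  if (is.character(y) && length(y) == 1L) y <- strsplit(toupper(y), "")[[1L]]
  if (length(x) != length(y))
    stop("sequences must have equal aligned length", call. = FALSE)
  comp <- x %in% DET_BASES & y %in% DET_BASES
  n <- sum(comp)
  if (n == 0L) stop("no comparable sites between the two sequences", call. = FALSE)
  list(p = sum(x[comp] != y[comp]) / n, comparable = n)
}

jc69_correct <- function(p, pair = "pair") {
  arg <- 1 - 4 * p / 3
  if (arg <= 0)
    stop(sprintf("JC69 correction undefined for %s (p = %.4f)", pair, p),
         call. = FALSE)
  -3 / 4 * log(arg)
}

# Kimura 2-parameter distance from transition (P) and transversion (Q)
# proportions: d = -1/2 log((1 - 2P - Q) sqrt(1 - 2Q)).
k2p_correct <- function(P, Q, pair = "pair") {
  a <- 1 - 2 * P - Q
  b <- 1 - 2 * Q
  if (a <= 0 || b <= 0)
    stop(sprintf("K2P correction undefined for %s (P = %.4f, Q = %.4f)",
                 pair, P, Q), call. = FALSE)
  -0.5 * log(a * sqrt(b))
}

PURINES <- c("A", "G")

#' Pairwise divergence matrix
#'
#' All-pairs divergence from an alignment: uncorrected p-distance, optionally
#' corrected with the Jukes-Cantor (`jc69`) or Kimura 2-parameter (`k2p`)
#' model. Under `complete` deletion every column containing a gap or
#' ambiguity in any sequence is removed once before comparison.
#'
#' @param aln A [dna_alignment()] with at least two sequences.
#' @param model `"p"` (default), `"jc69"`, or `"k2p"`.
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return A `divergence_matrix`: list with `labels`, `d` (symmetric numeric
#'   matrix of proportions, zero diagonal), `comparable` (per-pair site
#'   counts), `model`, and `deletion`.
#' @export
distance_matrix <- function(aln, model = c("p", "jc69", "k2p"),
                            deletion = c("pairwise", "complete")) {
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  stopifnot(inherits(aln, "dna_alignment"))
  mat <- aln$seqs
  if (nrow(mat) < 2L) stop("distance matrix requires >= 2 sequences", call. = FALSE)
  if (deletion == "complete") {
    keep <- apply(matrix(mat %in% DET_BASES, nrow = nrow(mat)), 2L, all)
    mat <- mat[, keep, drop = FALSE]
    if (ncol(mat) == 0L)
      stop("no comparable sites remain under complete deletion", call. = FALSE)
  }
  ids <- rownames(mat)
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  comp <- matrix(NA_integer_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      pairlab <- sprintf("'%s' vs '%s'", ids[i], ids[j])
      xi <- mat[i, ]; yj <- mat[j, ]
      ok <- xi %in% DET_BASES & yj %in% DET_BASES
      nc <- sum(ok)
      if (nc == 0L)
        stop(sprintf("no comparable sites between %s", pairlab), call. = FALSE)
      diff <- xi[ok] != yj[ok]
      p <- sum(diff) / nc
      val <- switch(model,
        p = p,
        jc69 = jc69_correct(p, pairlab),
        k2p = {
          ts <- diff & ((xi[ok] %in% PURINES) == (yj[ok] %in% PURINES))
          k2p_correct(sum(ts) / nc, sum(diff & !ts) / nc, pairlab)
        })
      d[i, j] <- d[j, i] <- val
      comp[i, j] <- comp[j, i] <- nc
    }
  }
  structure(list(labels = ids, d = d, comparable = comp,
                 model = model, deletion = deletion),
            class = "divergence_matrix")
}

#' @export
print.divergence_matrix <- function(x, ...) {
  cat(sprintf("<divergence_matrix> %d taxa, model %s, %s deletion\n",
              length(x$labels), x$model, x$deletion))
  print(round(x$d, 5))
  invisible(x)
}

#' @export
as.matrix.divergence_matrix <- function(x, ...) x$d

# Round half away from zero (print convention of published distance tables;
# base round() rounds half to even).
round_half_up <- function(x, digits) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Format a divergence matrix as a lower-triangular table
#'
#' Renders the matrix the way pairwise-divergence tables are printed in the
#' systematics literature: taxa down the rows (from the second taxon),
#' columns for all but the last taxon, percent scale, fixed decimals, halves
#' rounded away from zero.
#'
#' @param m A [distance_matrix()] result or plain symmetric matrix with
#'   dimnames.
#' @param scale `"percent"` (default) or `"proportion"`.
#' @param digits Decimal places (default 3).
#' @return A single string: TSV with a header row, one line per row taxon.
#' @export
format_distance_table <- function(m, scale = c("percent", "proportion"),
                                  digits = 3L) {
  scale <- match.arg(scale)
  d <- if (inherits(m, "divergence_matrix")) m$d else m
  labs <- rownames(d)
  mult <- if (scale == "percent") 100 else 1
  n <- nrow(d)
  fmt <- function(v) sprintf(paste0("%.", digits, "f"),
                             round_half_up(v * mult, digits))
  lines <- c(paste(c("", labs[-n]), collapse = "\t"))
  for (i in seq(2L, n)) {
    cells <- fmt(d[i, seq_len(i - 1L)])
    lines <- c(lines, paste(c(labs[i], cells), collapse = "\t"))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Write a PHYLIP-style square distance matrix
#'
#' @param m A [distance_matrix()] result or plain symmetric matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phylip_matrix <- function(m, path) {
  d <- if (inherits(m, "divergence_matrix")) m$d else m
  labs <- rownames(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste(c(sprintf("%-12s", labs[i]),
                       sprintf("%.6f", d[i, ])), collapse = "  "), con)
  }
  invisible(path)
}

#' Read a PHYLIP-style square distance matrix
#'
#' @param path Path written by [write_phylip_matrix()] (or any square PHYLIP
#'   distance file with whitespace-delimited fields).
#' @return A symmetric numeric matrix with dimnames.
#' @export
read_phylip_matrix <- function(path) {
  ln <- readLines(path)
  n <- as.integer(trimws(ln[1L]))
  rows <- strsplit(trimws(ln[seq(2L, 1L + n)]), "\\s+")
  labs <- vapply(rows, `[[`, "", 1L)
  d <- t(vapply(rows, function(r) as.numeric(r[-1L]), numeric(n)))
  dimnames(d) <- list(labs, labs)
  d
}
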