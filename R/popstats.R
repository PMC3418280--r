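# Alignment summary statistics: haplotypes, diversity, site classification.

#' Collapse an alignment into haplotypes
#'
#' Groups identical sequences. In `indel-aware` mode the full gapped strings
#' are compared (an indel difference separates haplotypes); in
#' `substitutions-only` mode every column containing a gap anywhere in the
#' alignment is ignored before comparing, so sequences differing only by
#' indels collapse together.
#'
#' @param aln A [dna_alignment()].
#' @param mode `"indel-aware"` (default) or `"substitutions-only"`.
#' @return A `haplotype_table` data frame with columns `haplotype`
#'   (representative full-length sequence of the first member), `count`, and
#'   `members` (list column of specimen ids), ordered by first appearance.
#' @export
collapse_haplotypes <- function(aln, mode = c("indel-aware", "substitutions-only")) {
  mode <- match.arg(mode)
  stopifnot(inherits(aln, "dna_alignment"))
  mat <- aln$seqs
  keymat <- mat
  if (mode == "substitutions-only") {
    gapcol <- apply(mat == GAP_CHAR, 2L, any)
    keymat <- mat[, !gapcol, drop = FALSE]
  }
  keys <- apply(keymat, 1L, paste, collapse = "")
  grp <- split(rownames(mat), factor(keys, levels = unique(keys)))
  tab <- data.frame(
    haplotype = vapply(grp, function(m) paste(mat[m[1L], ], collapse = ""), ""),
    count = lengths(grp),
    row.names = NULL, stringsAsFactors = FALSE
  )
  tab$members <- unname(grp)
  attr(tab, "mode") <- mode
  class(tab) <- c("haplotype_table", "data.frame")
  tab
}

#' Haplotype diversity (Nei's unbiased h)
#'
#' `h = n/(n-1) * (1 - sum(p_i^2))`, the unbiased probability that two
#' sequences drawn at random carry different haplotypes.
#'
#' @param counts Vector of positive haplotype counts (or a
#'   `haplotype_table`).
#' @return h in `[0, 1]`; 0 iff the sample is monomorphic.
#' @examples
#' haplotype_diversity(c(2, 1)) # 2/3
#' @export
haplotype_diversity <- function(counts) {
  if (inherits(counts, "haplotype_table")) counts <- counts$count
  counts <- as.numeric(counts)
  stopifnot(all(counts > 0))
  n <- sum(counts)
  if (n < 2) stop("haplotype diversity undefined for fewer than 2 sequences",
                  call. = FALSE)
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

# TRUE where the residue is determinate under the given indel rule.
determinate_mask <- function(mat, gap_is_state = FALSE) {
  ok <- matrix(mat %in% DET_BASES, nrow = nrow(mat))
  if (gap_is_state) ok <- ok | mat == GAP_CHAR
  ok
}

#' Nucleotide diversity (pi)
#'
#' Average proportion of differing sites over all unordered sequence pairs,
#' per comparable site. Ambiguity codes are always missing. With
#' `indels = "exclude"` a site with a gap in either sequence of a pair is
#' skipped, so indel-only variation yields pi = 0; with `"fifth-state"` the
#' gap is an ordinary fifth character state.
#'
#' @param aln A [dna_alignment()] with at least two sequences.
#' @param deletion `"pairwise"` (default; each pair uses its own comparable
#'   sites) or `"complete"` (columns with any missing residue are removed
#'   once, for all pairs).
#' @param indels `"exclude"` (default) or `"fifth-state"`.
#' @return pi, the mean per-site pairwise difference.
#' @export
nucleotide_diversity <- function(aln,
                                 deletion = c("pairwise", "complete"),
                                 indels = c("exclude", "fifth-state")) {
  deletion <- match.arg(deletion)
  indels <- match.arg(indels)
  stopifnot(inherits(aln, "dna_alignment"))
  mat <- aln$seqs
  if (nrow(mat) < 2L) stop("nucleotide diversity requires >= 2 sequences",
                           call. = FALSE)
  ok <- determinate_mask(mat, gap_is_state = indels == "fifth-state")
  if (deletion == "complete") {
    keep <- apply(ok, 2L, all)
    mat <- mat[, keep, drop = FALSE]
    ok <- ok[, keep, drop = FALSE]
  }
  n <- nrow(mat)
  ids <- rownames(mat)
  tot <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      comp <- ok[i, ] & ok[j, ]
      ncomp <- sum(comp)
      if (ncomp == 0L)
        stop(sprintf("no comparable sites between '%s' and '%s'",
                     ids[i], ids[j]), call. = FALSE)
      tot <- tot + sum(mat[i, comp] != mat[j, comp]) / ncomp
    }
  }
  tot / (n * (n - 1) / 2)
}

#' Classify alignment columns
#'
#' Each column is classified as one of `invariant`, `variable-singleton`,
#' `parsimony-informative`, `gap-excluded` (contains a gap under the
#' `exclude-column` policy), or `missing-excluded` (no determinate residue).
#' A column is variable when at least two determinate states are observed,
#' and parsimony-informative when at least two states are each carried by at
#' least two sequences. The segregating-site count equals the variable count.
#' Ambiguity codes are missing and never contribute a state.
#'
#' @param aln A [dna_alignment()].
#' @param gap_policy `"exclude-column"` (default: any gap removes the column
#'   from the counts) or `"fifth-state"` (a gap is an ordinary state).
#' @return A `site_classification` list: `classes` (character vector, one per
#'   column), and counts `invariant`, `variable_singleton`,
#'   `parsimony_informative`, `gap_excluded`, `missing_excluded`, plus
#'   `variable` (= segregating sites) and `length`.
#' @export
classify_sites <- function(aln, gap_policy = c("exclude-column", "fifth-state")) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(inherits(aln, "dna_alignment"))
  mat <- aln$seqs
  gap_is_state <- gap_policy == "fifth-state"
  classes <- character(ncol(mat))
  for (c in seq_len(ncol(mat))) {
    col <- mat[, c]
    if (!gap_is_state && any(col == GAP_CHAR)) {
      classes[c] <- "gap-excluded"
      next
    }
    states <- col[col %in% DET_BASES | (gap_is_state & col == GAP_CHAR)]
    if (length(states) == 0L) {
      classes[c] <- "missing-excluded"
      next
    }
    cnt <- table(states)
    if (length(cnt) < 2L) {
      classes[c] <- "invariant"
    } else if (sum(cnt >= 2L) >= 2L) {
      classes[c] <- "parsimony-informative"
    } else {
      classes[c] <- "variable-singleton"
    }
  }
  out <- list(
    classes = classes,
    invariant = sum(classes == "invariant"),
    variable_singleton = sum(classes == "variable-singleton"),
    parsimony_informative = sum(classes == "parsimony-informative"),
    gap_excluded = sum(classes == "gap-excluded"),
    missing_excluded = sum(classes == "missing-excluded"),
    length = ncol(mat)
  )
  out$variable <- out$variable_singleton + out$parsimony_informative
  class(out) <- "site_classification"
  out
}

#' @export
print.site_classification <- function(x, ...) {
  cat(sprintf(paste0("<site_classification> %d sites: %d variable ",
                     "(%d parsimony-informative), %d invariant, ",
                     "%d gap-excluded, %d missing-excluded\n"),
              x$length, x$variable, x$parsimony_informative, x$invariant,
              x$gap_excluded, x$missing_excluded))
  invisible(x)
}

#' Per-locus summary statistics row
#'
#' One row of the `stats` pipeline table: sample size, alignment length,
#' variable and parsimony-informative sites, haplotype count (indel-aware),
#' haplotype diversity and nucleotide diversity.
#'
#' @param aln A [dna_alignment()].
#' @param gap_policy Passed to [classify_sites()].
#' @return A one-row data frame.
#' @export
alignment_stats <- function(aln, gap_policy = "exclude-column") {
  cls <- classify_sites(aln, gap_policy)
  hap <- collapse_haplotypes(aln, "indel-aware")
  n <- n_seqs(aln)
  data.frame(
    locus = aln$locus_name,
    n_sequences = n,
    length = n_sites(aln),
    variable_sites = cls$variable,
    parsimony_informative = cls$parsimony_informative,
    haplotypes = nrow(hap),
    haplotype_diversity = if (n >= 2) haplotype_diversity(hap) else NA_real_,
    nucleotide_diversity = if (n >= 2) nucleotide_diversity(aln) else NA_real_,
    stringsAsFactors = FALSE
  )
}
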