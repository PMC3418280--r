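# Neighbor-joining (Saitou-Nei agglomeration) with deterministic
# tie-breaking, and nonparametric bootstrap support.

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration under the standard Q criterion. Deterministic:
#' ties on Q are broken by the lexicographically smallest (sorted) label
#' pair. Negative branch-length estimates are clamped to zero with the
#' deficit transferred to the sister edge, so the joined path length is
#' preserved (standard practice; changes printed lengths, never topology).
#'
#' @param m A [distance_matrix()] result, or a symmetric numeric matrix with
#'   dimnames, over at least 3 taxa.
#' @return An unrooted ape `phylo` tree with branch lengths.
#' @export
nj_tree <- function(m) {
  D <- if (inherits(m, "divergence_matrix")) m$d else as.matrix(m)
  labs <- rownames(D)
  n <- nrow(D)
  if (is.null(labs) || n < 3L)
    stop("neighbor-joining requires a labelled matrix with >= 3 taxa",
         call. = FALSE)
  # Each active node carries a newick fragment and the smallest leaf label in
  # its subtree (for deterministic tie-breaking).
  frags <- quote_label(labs)
  minlab <- labs
  fmt <- function(x) sprintf("%.10g", x)
  clamp_pair <- function(a, b) {
    if (a < 0) { b <- b + a; a <- 0 }
    if (b < 0) { a <- max(0, a + b); b <- 0 }
    c(a, b)
  }
  while (n > 3L) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 & upper.tri(Q), arr.ind = TRUE)
    keypair <- apply(cand, 1L, function(ix) {
      paste(sort(c(minlab[ix[1L]], minlab[ix[2L]])), collapse = "\r")
    })
    pick <- cand[order(keypair)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    ll <- clamp_pair(li, lj)
    newfrag <- sprintf("(%s:%s,%s:%s)", frags[i], fmt(ll[1L]),
                       frags[j], fmt(ll[2L]))
    dk <- (D[i, -c(i, j)] + D[j, -c(i, j)] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk),
               c(dk, 0))
    frags <- c(frags[keep], newfrag)
    minlab <- c(minlab[keep], min(minlab[c(i, j)]))
    n <- n - 1L
  }
  # Final three nodes: closed-form star resolution.
  e1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  e2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  e3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  e <- pmax(c(e1, e2, e3), 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frags[1L], fmt(e[1L]),
                 frags[2L], fmt(e[2L]), frags[3L], fmt(e[3L]))
  read_newick(text = nwk)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Nonparametric bootstrap support for the NJ tree
#'
#' Resamples alignment columns with replacement, recomputes the distance
#' matrix and NJ tree per pseudo-replicate, and reports for each internal
#' edge of the full-data tree the percentage of replicates containing the
#' same bipartition. Supports are mapped onto the full-data tree (not a
#' consensus). Replicates in which some pair has no comparable sites are
#' discarded and counted; a warning is issued when more than 1% are dropped.
#'
#' @param aln A [dna_alignment()] with at least 4 sequences.
#' @param n_reps Number of pseudo-replicates (>= 1).
#' @param seed Integer seed; the same seed and inputs reproduce the support
#'   map exactly. Global RNG state is restored on exit.
#' @param model,deletion Passed to [distance_matrix()].
#' @return A list: `tree` (the full-data NJ tree with `node.label` set to
#'   integer support percentages), `support` (named vector, canonical
#'   bipartition key -> percent), `n_kept`, `n_discarded`.
#' @export
bootstrap_support <- function(aln, n_reps, seed,
                              model = "p", deletion = "pairwise") {
  stopifnot(inherits(aln, "dna_alignment"), n_reps >= 1L)
  if (n_seqs(aln) < 4L)
    stop("bootstrap requires at least 4 sequences", call. = FALSE)
  full <- nj_tree(distance_matrix(aln, model, deletion))
  keys <- names(tree_bipartitions(full))
  counts <- setNames(numeric(length(keys)), keys)
  L <- n_sites(aln)
  n_disc <- 0L
  with_seed(seed, {
    for (rep in seq_len(n_reps)) {
      idx <- sample.int(L, L, replace = TRUE)
      baln <- aln
      baln$seqs <- aln$seqs[, idx, drop = FALSE]
      dm <- tryCatch(distance_matrix(baln, model, deletion),
                     error = function(e) NULL)
      if (is.null(dm)) { n_disc <- n_disc + 1L; next }
      bk <- names(tree_bipartitions(nj_tree(dm)))
      hit <- keys %in% bk
      counts[hit] <- counts[hit] + 1
    }
  })
  n_kept <- n_reps - n_disc
  if (n_disc > 0.01 * n_reps)
    warning(sprintf("%d of %d bootstrap replicates discarded (no comparable sites for some pair)",
                    n_disc, n_reps), call. = FALSE)
  if (n_kept == 0L) stop("all bootstrap replicates discarded", call. = FALSE)
  support <- 100 * counts / n_kept
  full <- annotate_supports(full, support)
  list(tree = full, support = support, n_kept = n_kept, n_discarded = n_disc)
}

# Write supports into node.label of the tree they were computed on.
annotate_supports <- function(tree, support) {
  labs <- tree$tip.label
  nlab <- rep("", tree$Nnode)
  pp <- ape::prop.part(tree)
  for (k in seq_along(pp)) {
    side <- labs[pp[[k]]]
    if (length(side) < 2L || length(side) > length(labs) - 2L) next
    key <- bipartition_key(side, labs)
    if (key %in% names(support)) nlab[k] <- sprintf("%d", round(support[[key]]))
  }
  tree$node.label <- nlab
  tree
}
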