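# Fitch parsimony and exact branch-and-bound search for most parsimonious
# trees. Character states are bitmask-coded (A=1, C=2, G=4, T=8); missing
# residues (ambiguity codes, and gaps under the "missing" policy) carry the
# full state set and contribute no cost.

fitch_codes <- function(mat, gap_policy = c("missing", "fifth-state")) {
  gap_policy <- match.arg(gap_policy)
  full <- if (gap_policy == "fifth-state") 31L else 15L
  code <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  X <- matrix(full, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  for (b in names(code)) X[mat == b] <- code[[b]]
  if (gap_policy == "fifth-state") {
    X[mat == GAP_CHAR] <- 16L
    # ambiguity codes denote bases only: they cannot be a gap
    X[mat %in% AMBIG_CODES] <- 15L
  }
  X
}

# Fitch length of a tree given as an undirected edge matrix. Leaves are node
# ids <= nrow(X) (rows of the state-code matrix X); internal ids are larger.
# The tree is rooted at its smallest leaf, which is exact for binary trees.
fitch_score_edges <- function(edges, X) {
  maxid <- max(edges)
  nb <- vector("list", maxid)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1L]; b <- edges[r, 2L]
    nb[[a]] <- c(nb[[a]], b)
    nb[[b]] <- c(nb[[b]], a)
  }
  present <- which(lengths(nb) > 0L)
  root <- min(present[present <= nrow(X)])
  parent <- integer(maxid)
  pre <- integer(0)
  stack <- root
  parent[root] <- 0L
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    pre <- c(pre, v)
    for (w in nb[[v]]) {
      if (w != parent[v]) { parent[w] <- v; stack <- c(stack, w) }
    }
  }
  nsites <- ncol(X)
  S <- matrix(0L, maxid, nsites)
  init <- logical(maxid)
  for (v in present[present <= nrow(X)]) { S[v, ] <- X[v, ]; init[v] <- TRUE }
  cost <- integer(nsites)
  for (v in rev(pre)) {
    p <- parent[v]
    if (p == 0L) next
    sv <- S[v, ]
    if (!init[p]) {
      S[p, ] <- sv
      init[p] <- TRUE
    } else {
      inter <- bitwAnd(S[p, ], sv)
      z <- inter == 0L
      cost[z] <- cost[z] + 1L
      S[p, z] <- bitwOr(S[p, z], sv[z])
      S[p, !z] <- inter[!z]
    }
  }
  sum(cost)
}

#' Fitch parsimony length of a tree
#'
#' Sum over alignment columns of the minimal number of state changes under
#' unordered (Fitch) parsimony. Missing and ambiguous residues carry the full
#' state set at the leaves and contribute no cost; under
#' `gap_policy = "fifth-state"` the gap is a fifth character state.
#'
#' @param aln A [dna_alignment()].
#' @param tree An ape `phylo` tree whose tip labels equal the alignment's
#'   specimen ids.
#' @param gap_policy `"missing"` (default) or `"fifth-state"`.
#' @return Integer tree length. Invariant under rerooting.
#' @export
fitch_length <- function(aln, tree, gap_policy = c("missing", "fifth-state")) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(inherits(aln, "dna_alignment"))
  if (!setequal(tree$tip.label, rownames(aln$seqs)))
    stop("tree tip labels do not match alignment specimen ids", call. = FALSE)
  X <- fitch_codes(aln$seqs[tree$tip.label, , drop = FALSE], gap_policy)
  fitch_score_edges(tree$edge, X)
}

# Column-wise decomposition for the search: parsimony-uninformative columns
# cost the same on every topology ((number of distinct determinate states)
# - 1); only informative columns need rescoring per tree.
split_informative <- function(X, gap_policy) {
  codes <- c(1L, 2L, 4L, 8L)
  if (gap_policy == "fifth-state") codes <- c(codes, 16L)
  const <- 0L
  informative <- logical(ncol(X))
  for (c in seq_len(ncol(X))) {
    cnt <- vapply(codes, function(k) sum(X[, c] == k), 0L)
    if (sum(cnt >= 2L) >= 2L) {
      informative[c] <- TRUE
    } else {
      const <- const + max(0L, sum(cnt > 0L) - 1L)
    }
  }
  list(informative = informative, const = const)
}

insert_taxon <- function(edges, row, newint, leaf) {
  u <- edges[row, 1L]; v <- edges[row, 2L]
  edges[row, ] <- c(u, newint)
  rbind(edges, c(newint, v), c(newint, leaf))
}

edges_to_phylo <- function(edges, labels) {
  nleaf <- length(labels)
  nb <- vector("list", max(edges))
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1L]; b <- edges[r, 2L]
    nb[[a]] <- c(nb[[a]], b)
    nb[[b]] <- c(nb[[b]], a)
  }
  build <- function(v, par) {
    if (v <= nleaf) return(quote_label(labels[v]))
    kids <- setdiff(nb[[v]], par)
    paste0("(", paste(vapply(kids, build, "", par = v), collapse = ","), ")")
  }
  r0 <- nb[[1L]][1L]
  kids <- nb[[r0]]
  nwk <- paste0("(",
                paste(vapply(kids, build, "", par = r0), collapse = ","),
                ");")
  read_newick(text = nwk)
}

#' Exact branch-and-bound maximum parsimony search
#'
#' Finds the globally shortest Fitch tree(s) by stepwise taxon addition
#' (input-row order) with branch-and-bound pruning: a partial tree is
#' abandoned as soon as its length on the taxa placed so far exceeds the best
#' complete length found. The global optimum is guaranteed, and every
#' distinct optimal unrooted topology is returned, deterministically ordered
#' by canonical bipartition key.
#'
#' @param aln A [dna_alignment()] with 4 to 15 sequences (exact search is
#'   exponential; larger inputs need heuristic searches, which are out of
#'   scope).
#' @param gap_policy `"missing"` (default) or `"fifth-state"`.
#' @return A list with `length` (optimal tree length, integer) and `trees`
#'   (list of ape `phylo` objects, one per optimal topology, no branch
#'   lengths).
#' @export
branch_and_bound_mp <- function(aln, gap_policy = c("missing", "fifth-state")) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(inherits(aln, "dna_alignment"))
  n <- n_seqs(aln)
  if (n < 4L)
    stop("branch-and-bound search requires at least 4 taxa", call. = FALSE)
  if (n > 15L)
    stop("more than 15 taxa: exact search infeasible; heuristic search is out of scope",
         call. = FALSE)
  labels <- rownames(aln$seqs)
  X <- fitch_codes(aln$seqs, gap_policy)
  sp <- split_informative(X, gap_policy)
  Xi <- X[, sp$informative, drop = FALSE]
  score <- function(edges) {
    if (ncol(Xi) == 0L) 0L else fitch_score_edges(edges, Xi)
  }
  env <- new.env(parent = emptyenv())
  env$best <- Inf
  env$trees <- list()
  add_taxon <- function(edges, k) {
    if (k > n) {
      L <- score(edges)
      if (L < env$best) {
        env$best <- L
        env$trees <- list(edges)
      } else if (L == env$best) {
        env$trees <- c(env$trees, list(edges))
      }
      return(invisible(NULL))
    }
    for (r in seq_len(nrow(edges))) {
      cand <- insert_taxon(edges, r, n + k - 2L, k)
      if (score(cand) <= env$best) add_taxon(cand, k + 1L)
    }
    invisible(NULL)
  }
  start <- rbind(c(n + 1L, 1L), c(n + 1L, 2L), c(n + 1L, 3L))
  add_taxon(start, 4L)
  trees <- lapply(env$trees, edges_to_phylo, labels = labels)
  keys <- vapply(trees, function(t) {
    paste(sort(names(tree_bipartitions(t))), collapse = ";")
  }, "")
  trees <- trees[order(keys)]
  list(length = as.integer(env$best + sp$const), trees = trees)
}
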