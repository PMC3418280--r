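test_that("NJ resolves the additive 4-taxon case with hand-solved edges", {
  # dAB=3, dCD=7, dAC=5, dAD=6, dBC=6, dBD=7: four-point condition gives
  # split AB|CD with internal edge 1 and leaf edges A=1, B=2, C=3, D=4
  labs <- c("A", "B", "C", "D")
  d <- matrix(0, 4, 4, dimnames = list(labs, labs))
  d["A", "B"] <- d["B", "A"] <- 3
  d["C", "D"] <- d["D", "C"] <- 7
  d["A", "C"] <- d["C", "A"] <- 5
  d["A", "D"] <- d["D", "A"] <- 6
  d["B", "C"] <- d["C", "B"] <- 6
  d["B", "D"] <- d["D", "B"] <- 7
  tr <- nj_tree(d)
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_true(is_monophyletic(tr, c("C", "D")))
  lens <- setNames(tr$edge.length[tr$edge[, 2] <= 4], tr$tip.label[tr$edge[tr$edge[, 2] <= 4, 2]])
  expect_equal(lens[labs], c(A = 1, B = 2, C = 3, D = 4))
  internal <- tr$edge.length[tr$edge[, 2] > 4]
  expect_equal(internal, 1)
})

test_that("NJ on 3 taxa uses the closed-form three-point edges", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[c("a", "b", "c")], c(a = 1, b = 1, c = 3))
  expect_error(nj_tree(d[1:2, 1:2]), ">= 3 taxa")
})

test_that("NJ recovers random additive trees exactly", {
  withr::local_seed(101)
  for (rep in 1:30) {
    n <- sample(5:8, 1L)
    true <- ape::rtree(n, rooted = FALSE)
    true$edge.length <- stats::runif(nrow(true$edge), 0.01, 1)
    d <- ape::cophenetic.phylo(true)
    est <- nj_tree(d[sort(rownames(d)), sort(colnames(d))])
    expect_equal(topo_key(est), topo_key(true))
  }
})

test_that("NJ agrees with ape's implementation on random matrices", {
  withr::local_seed(113)
  for (rep in 1:10) {
    n <- sample(5:8, 1L)
    true <- ape::rtree(n, rooted = FALSE)
    true$edge.length <- stats::runif(nrow(true$edge), 0.05, 1)
    d <- ape::cophenetic.phylo(true)
    expect_equal(topo_key(nj_tree(d)), topo_key(ape::nj(d)))
  }
})

test_that("bipartitions and monophyly follow the unrooted-split definition", {
  tr <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_true(is_monophyletic(tr, c("C", "D")))
  expect_false(is_monophyletic(tr, c("A", "C")))
  expect_true(is_monophyletic(tr, "A"))              # leaf edge
  expect_true(is_monophyletic(tr, c("A", "B", "C"))) # complement of a leaf
  expect_error(is_monophyletic(tr, "Z"), "unknown label")
})

test_that("newick round-trip preserves topology, lengths, supports, and odd labels", {
  nwk <- "(('A fist (CAL)':1.5,B:2)91:0.25,C:1,D:1);"
  tr <- read_newick(text = nwk)
  expect_true("A fist (CAL)" %in% tr$tip.label)
  out <- write_newick(tr)
  back <- read_newick(text = out)
  expect_equal(sort(back$tip.label), sort(tr$tip.label))
  expect_equal(topo_key(back), topo_key(tr))
  expect_equal(sort(back$edge.length), sort(tr$edge.length))
  expect_true("91" %in% back$node.label)
  expect_error(read_newick(text = "((A,B);"), "malformed|parse")
  expect_equal(topo_key(read_newick(text = "(A,B,(C,D));")),
               topo_key(read_newick(text = "((A,B),(C,D));")))
})

test_that("fitch length counts minimal changes and treats missing as free", {
  aln <- make_aln(c(A = "A", B = "A", C = "G", D = "G"))
  ab_cd <- read_newick(text = "((A,B),(C,D));")
  ac_bd <- read_newick(text = "((A,C),(B,D));")
  expect_equal(fitch_length(aln, ab_cd), 1L)
  expect_equal(fitch_length(aln, ac_bd), 2L)
  invar <- make_aln(c(A = "AAA", B = "AAA", C = "AAA", D = "AAA"))
  expect_equal(fitch_length(invar, ab_cd), 0L)
  miss <- make_aln(c(A = "A", B = "N", C = "-", D = "G"))
  expect_equal(fitch_length(miss, ab_cd), 1L)
  expect_error(fitch_length(aln, read_newick(text = "((A,B),(C,E));")),
               "tip labels")
})

test_that("fitch length is invariant under rerooting and leaf permutation", {
  withr::local_seed(211)
  for (rep in 1:15) {
    n <- sample(5:8, 1L)
    tr <- ape::rtree(n, rooted = FALSE)
    mat <- matrix(sample(c("A", "C", "G", "T", "-", "N"), n * 20, TRUE,
                         prob = c(rep(0.22, 4), 0.06, 0.06)), n, 20,
                  dimnames = list(tr$tip.label, NULL))
    aln <- dna_alignment(mat, "sim")
    base <- fitch_length(aln, tr)
    rerooted <- ape::root(tr, outgroup = tr$tip.label[1L], resolve.root = TRUE)
    expect_equal(fitch_length(aln, rerooted), base)
    perm <- sample(n)
    aln2 <- dna_alignment(mat[perm, , drop = FALSE], "sim")
    expect_equal(fitch_length(aln2, tr), base)
  }
})

test_that("fitch length matches phangorn on random instances", {
  skip_if_not_installed("phangorn")
  withr::local_seed(221)
  for (rep in 1:15) {
    n <- sample(4:8, 1L)
    tr <- ape::rtree(n, rooted = FALSE)
    mat <- matrix(sample(c("A", "C", "G", "T", "-"), n * 15, TRUE), n, 15,
                  dimnames = list(tr$tip.label, NULL))
    aln <- dna_alignment(mat, "sim")
    pd <- phangorn::phyDat(mat, type = "DNA")
    expect_equal(fitch_length(aln, tr), phangorn::fitch(tr, pd))
  }
})

test_that("branch-and-bound equals exhaustive search on a 5-taxon toy", {
  skip_if_not_installed("phangorn")
  withr::local_seed(31)
  mat <- matrix(sample(c("A", "C", "G", "T"), 5 * 12, TRUE), 5, 12,
                dimnames = list(letters[1:5], NULL))
  aln <- dna_alignment(mat, "toy")
  mp <- branch_and_bound_mp(aln)
  alltr <- phangorn::allTrees(5, rooted = FALSE, tip.label = letters[1:5])
  pd <- phangorn::phyDat(mat, type = "DNA")
  scores <- vapply(alltr, function(t) phangorn::fitch(t, pd), 0)
  expect_equal(mp$length, min(scores))
  best_keys <- sort(vapply(alltr[scores == min(scores)], topo_key, ""))
  expect_equal(sort(vapply(mp$trees, topo_key, "")), best_keys)
})

test_that("an alignment with no informative signal ties all topologies", {
  aln <- make_aln(c(a = "AAT", b = "AAA", c = "ACA", d = "GAA", e = "AAA"))
  mp <- branch_and_bound_mp(aln)
  expect_length(mp$trees, 15L)  # all unrooted 5-taxon topologies
  expect_equal(mp$length, 3L)
  expect_error(branch_and_bound_mp(make_aln(c(a = "A", b = "A", c = "A"))),
               "at least 4")
  big <- setNames(rep("ACGT", 16), sprintf("t%02d", 1:16))
  expect_error(branch_and_bound_mp(make_aln(big)), "heuristic")
})

test_that("bootstrap supports are deterministic given a seed and certain for clean splits", {
  aln <- make_aln(c(A = "AAAACCCC", B = "AAAACCCC",
                    C = "GGGGCCCC", D = "GGGGCCCC",
                    E = "GGGGTTTT", F = "GGGGTTTT"))
  bs1 <- bootstrap_support(aln, n_reps = 60L, seed = 5L)
  bs2 <- bootstrap_support(aln, n_reps = 60L, seed = 5L)
  expect_identical(bs1$support, bs2$support)
  expect_true(all(bs1$support >= 0 & bs1$support <= 100))
  ab <- names(bs1$support)[vapply(names(bs1$support), function(k) {
    setequal(strsplit(k, "|", fixed = TRUE)[[1L]],
             c("C", "D")) || setequal(strsplit(k, "|", fixed = TRUE)[[1L]],
                                      c("A", "B", "E", "F"))
  }, TRUE)]
  # every column supports AB|CDEF and ABCD|EF style splits around CD
  expect_true(all(bs1$support[ab] == 100))
  expect_equal(bs1$n_discarded, 0L)
})

test_that("bootstrap recovers planted clades with high support", {
  withr::local_seed(300)
  # 6 taxa, two clades of 3, 50 clean synapomorphies per clade
  base <- sample(c("A", "C", "G", "T"), 140, TRUE)
  mat <- matrix(rep(base, each = 6), 6, 140,
                dimnames = list(sprintf("t%d", 1:6), NULL))
  # synapomorphies: clade {t1,t2,t3} at columns 1-50, nested {t1,t2} at 51-100
  mat[1:3, 1:50] <- matrix(rep(chartr("ACGT", "GTAC", base[1:50]), each = 3), 3)
  mat[1:2, 51:100] <- matrix(rep(chartr("ACGT", "CAGT", base[51:100]), each = 2), 2)
  aln <- dna_alignment(mat, "sim")
  bs <- bootstrap_support(aln, n_reps = 200L, seed = 77L)
  k123 <- bipartition_keys_for(bs$support, c("t1", "t2", "t3"), rownames(mat))
  k12 <- bipartition_keys_for(bs$support, c("t1", "t2"), rownames(mat))
  expect_gte(bs$support[[k123]], 95)
  expect_gte(bs$support[[k12]], 95)
})
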