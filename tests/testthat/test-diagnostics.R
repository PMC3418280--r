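two_species_part <- function(x, y) {
  species_partition(setNames(c(rep("X", length(x)), rep("Y", length(y))),
                             c(x, y)))
}

test_that("pure diagnostics are fixed-and-exclusive positions", {
  aln <- make_aln(c(x1 = "ACGT", x2 = "ACGT", y1 = "ACGA", y2 = "ACGC"))
  part <- two_species_part(c("x1", "x2"), c("y1", "y2"))
  res <- find_pure_diagnostics(aln, part)
  # brute-force scan over all 4 columns: only (4, T) is fixed in X and
  # absent from Y; Y is not fixed anywhere it differs from X
  expect_equal(pure_key(res[res$species == "X", ]), "X:4:T")
  expect_equal(sum(res$species == "Y"), 0L)

  ident <- make_aln(c(x1 = "ACGT", y1 = "ACGT"))
  expect_equal(nrow(find_pure_diagnostics(ident, two_species_part("x1", "y1"))), 0L)
})

test_that("ambiguity codes conservatively block fixation and exclusivity", {
  # N in a member blocks fixation
  aln1 <- make_aln(c(x1 = "AT", x2 = "AN", y1 = "AC"))
  part1 <- two_species_part(c("x1", "x2"), "y1")
  expect_equal(nrow(find_pure_diagnostics(aln1, part1)), 0L)
  # N in a non-member could be the candidate state: blocks exclusivity
  # (a species entirely missing at a column warns instead of erroring)
  aln2 <- make_aln(c(x1 = "AT", x2 = "AT", y1 = "AN"))
  part2 <- two_species_part(c("x1", "x2"), "y1")
  expect_warning(res2 <- find_pure_diagnostics(aln2, part2),
                 "entirely missing")
  expect_equal(nrow(res2), 0L)
})

test_that("gap policy controls diagnostic eligibility of gapped columns", {
  aln <- make_aln(c(x1 = "A-G", x2 = "A-G", y1 = "AAG", y2 = "AAG"))
  part <- two_species_part(c("x1", "x2"), c("y1", "y2"))
  expect_equal(nrow(find_pure_diagnostics(aln, part, "exclude-column")), 0L)
  res <- find_pure_diagnostics(aln, part, "fifth-state")
  expect_equal(pure_key(res), c("X:2:-", "Y:2:A"))
})

test_that("composite finder returns exactly the minimal-cardinality sets", {
  # X fixed for G at 2 (shared with Y) and T at 7 (shared with Z); no single
  # non-member carries both. Exhaustive 2- and 3-subset enumeration is the
  # oracle.
  aln <- make_aln(c(x1 = "AAGAAAT", x2 = "AAGAAAT",
                    y1 = "AAGAAAA", y2 = "AAGAAAC",
                    z1 = "AACAAAT", z2 = "AAAAAAT"))
  part <- species_partition(c(x1 = "X", x2 = "X", y1 = "Y", y2 = "Y",
                              z1 = "Z", z2 = "Z"))
  res <- find_composite_diagnostics(aln, part, max_size = 3L)
  xs <- Filter(function(cd) cd$species == "X", res)
  expect_equal(composite_key(xs), "X:3G+7T")
  expect_equal(composite_key(res), composite_key(oracle_composites(aln, part, 3L)))

  # removing either element of the set leaves a matching non-member
  cd <- xs[[1L]]
  for (drop in seq_along(cd$positions)) {
    kept_pos <- cd$positions[-drop]
    kept_state <- cd$states[-drop]
    others <- c("y1", "y2", "z1", "z2")
    match_all <- vapply(others, function(o) {
      all(aln$seqs[o, kept_pos] == kept_state)
    }, TRUE)
    expect_true(any(match_all))
  }
})

test_that("species whose fixed profile is matched by a non-member is undiagnosable", {
  aln <- make_aln(c(x1 = "ACGT", x2 = "ACGT", y1 = "ACGT", z1 = "TTTT"))
  part <- species_partition(c(x1 = "X", x2 = "X", y1 = "Y", z1 = "Z"))
  expect_equal(sum(find_pure_diagnostics(aln, part)$species == "X"), 0L)
  res <- find_composite_diagnostics(aln, part, max_size = 4L)
  expect_false(any(vapply(res, function(cd) cd$species == "X", TRUE)))
  expect_true("X" %in% attr(res, "undiagnosable"))
})

test_that("duplicating a member never changes a species' diagnostics", {
  withr::local_seed(7)
  for (rep in 1:25) {
    inst <- random_diag_instance()
    aln <- inst$aln; part <- inst$part
    sp <- sample(part$species, 1L)
    mem <- intersect(members_of(part, sp), specimen_ids(aln))
    if (length(mem) == 0L) next
    mat2 <- rbind(aln$seqs, dup_zz = aln$seqs[mem[1L], ])
    aln2 <- dna_alignment(mat2, aln$locus_name)
    part2 <- species_partition(c(part$assignment, dup_zz = sp))
    p1 <- suppressWarnings(find_pure_diagnostics(aln, part))
    p2 <- suppressWarnings(find_pure_diagnostics(aln2, part2))
    expect_equal(pure_key(p1[p1$species == sp, ]), pure_key(p2[p2$species == sp, ]))
    c1 <- suppressWarnings(find_composite_diagnostics(aln, part, 3L))
    c2 <- suppressWarnings(find_composite_diagnostics(aln2, part2, 3L))
    expect_equal(composite_key(Filter(function(cd) cd$species == sp, c1)),
                 composite_key(Filter(function(cd) cd$species == sp, c2)))
  }
})

test_that("pure positions never appear in that species' composites", {
  withr::local_seed(13)
  for (rep in 1:40) {
    inst <- random_diag_instance()
    pure <- suppressWarnings(find_pure_diagnostics(inst$aln, inst$part))
    comps <- suppressWarnings(find_composite_diagnostics(inst$aln, inst$part, 3L))
    for (cd in comps) {
      own_pure <- pure$position[pure$species == cd$species]
      expect_length(intersect(cd$positions, own_pure), 0L)
    }
  }
})

test_that("reports merge loci, annotate regions, and assign verdicts", {
  its <- make_aln(c(x1 = "ACGT", x2 = "ACGT", y1 = "ACGA"), "ITS")
  coi <- make_aln(c(x1 = "GG", x2 = "GG", y1 = "GT"), "COI")
  part <- two_species_part(c("x1", "x2"), "y1")
  regions <- list(ITS = region_map(c("ITS1", "ITS2"), c(1L, 3L), c(2L, 4L)))
  rep <- diagnose_species(list(its, coi), part, regions)
  expect_equal(unname(rep$verdicts), c("pure", "pure"))
  x_pure <- rep$pure[rep$pure$species == "X", ]
  expect_equal(x_pure$region[x_pure$locus == "ITS"], "ITS2")
  expect_equal(x_pure$region[x_pure$locus == "COI"], "unassigned")
  # single-specimen species flagged provisional
  expect_equal(rep$provisional, "Y")
  tab <- diagnosis_table(rep)
  expect_true(all(c("locus", "species", "kind", "position", "state", "region")
                  %in% names(tab)))
})

test_that("verdicts distinguish pure, composite-only, and undiagnosable", {
  # sp A diagnosable only by the pair (1,2): each state shared with one other
  aln <- make_aln(c(a1 = "GTAAA", a2 = "GTAAA",
                    b1 = "GAAAA", b2 = "GAAAA",
                    c1 = "CTAAA", c2 = "CTAAA"))
  part <- species_partition(c(a1 = "A", a2 = "A", b1 = "B", b2 = "B",
                              c1 = "C", c2 = "C"))
  rep <- diagnose_species(aln, part)
  expect_equal(unname(rep$verdicts["A"]), "composite-only")
  expect_equal(unname(rep$verdicts["B"]), "pure")  # A at 2 is unique to B
})
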