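test_that("simulation is deterministic and emits byte-identical files", {
  spec <- aplysina_sim_spec()
  a <- simulate_alignments(spec, seed = 3L)
  b <- simulate_alignments(spec, seed = 3L)
  expect_identical(a$alignments, b$alignments)
  expect_identical(a$truth, b$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_alignments(spec, seed = 3L, out_dir = d1)
  simulate_alignments(spec, seed = 3L, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  c_ <- simulate_alignments(spec, seed = 4L)
  expect_false(identical(a$alignments, c_$alignments))
})

test_that("infeasible specs fail before writing anything", {
  loci <- data.frame(name = "L1", length = 5L)
  species <- data.frame(label = c("A", "B", "C"), n = c(2L, 2L, 2L))
  expect_error(
    sim_spec(loci, species,
             private_subs = data.frame(locus = "L1", species = "A", n = 0L),
             composites = data.frame(locus = "L1", species = "A", size = 2L)),
    "unsatisfiable")
  spec <- sim_spec(loci, species,
                   private_subs = data.frame(locus = "L1",
                                             species = c("A", "B", "C"),
                                             n = c(3L, 2L, 2L)))
  out <- file.path(withr::local_tempdir(), "sim")
  expect_error(simulate_alignments(spec, seed = 1L, out_dir = out),
               "exceed length")
  expect_false(dir.exists(out))
})

test_that("the mimic spec realizes the study's structure exactly", {
  sim <- simulate_alignments(aplysina_sim_spec(), seed = 11L)
  its <- sim$alignments$ITS
  coi <- sim$alignments$COI
  expect_equal(n_sites(its), 705L)
  expect_equal(n_sites(coi), 523L)
  expect_equal(n_seqs(its), 15L)

  # COI: exactly one segregating site, diagnostic for A. revillagigedi
  expect_equal(classify_sites(coi)$variable, 1L)
  pure_coi <- find_pure_diagnostics(coi, sim$partition)
  expect_equal(unique(pure_coi$species), "A_revillagigedi")

  # ITS p-distances: exact counts over the 695-site backbone
  dm <- distance_matrix(its)
  g <- members_of(sim$partition, "A_gerardogreeni")[1L]
  r <- members_of(sim$partition, "A_revillagigedi")[1L]
  c_ <- members_of(sim$partition, "A_clathrata")[1L]
  expect_equal(unname(dm$d[c_, r]), 2 / 695)
  expect_equal(unname(dm$d[c_, g]), 5 / 695)
  expect_equal(unname(dm$d[r, g]), 5 / 695)
  expect_equal(unname(dm$comparable[c_, r]), 695L)

  # indel-only intraspecific variation: 2 clathrata haplotypes, h = 0.6, pi = 0
  clat <- dna_alignment(its$seqs[members_of(sim$partition, "A_clathrata"), ],
                        "ITS")
  hap <- collapse_haplotypes(clat)
  expect_equal(sort(hap$count), c(2L, 3L))
  expect_equal(haplotype_diversity(hap), 0.6)
  expect_equal(nucleotide_diversity(clat), 0)
  expect_equal(nrow(collapse_haplotypes(clat, "substitutions-only")), 1L)
})

test_that("planted diagnostics are recovered with no false positives across random specs", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      spec <- random_sim_spec(with_composite = seed %% 2 == 0)
    })
    sim <- simulate_alignments(spec, seed = seed)
    aln <- sim$alignments$L1
    part <- sim$partition
    pure <- suppressWarnings(find_pure_diagnostics(aln, part))
    truth <- sim$truth$pure
    expect_equal(pure_key(pure), pure_key(truth), label = sprintf("seed %d", seed))
    for (ct in sim$truth$composites) {
      found <- suppressWarnings(
        find_composite_diagnostics(aln, part, max_size = ct$size + 1L))
      own <- Filter(function(cd) cd$species == ct$species, found)
      expect_true(length(own) > 0L, label = sprintf("seed %d composite", seed))
      expect_true(all(vapply(own, function(cd) cd$size, 0L) == ct$size),
                  label = sprintf("seed %d cardinality", seed))
      expect_true(composite_key(list(ct)) %in% composite_key(own),
                  label = sprintf("seed %d planted set returned", seed))
    }
    # NJ on the p-distance matrix recovers every planted species as a clade
    multi <- part$species[table(factor(part$assignment, part$species)) >= 1L]
    if (n_seqs(aln) >= 3L) {
      tr <- nj_tree(distance_matrix(aln))
      for (sp in multi) {
        expect_true(is_monophyletic(tr, members_of(part, sp)),
                    label = sprintf("seed %d monophyly of %s", seed, sp))
      }
    }
  }
})

test_that("truth files describe the emitted data", {
  out <- withr::local_tempdir()
  sim <- simulate_alignments(aplysina_sim_spec(), seed = 2L, out_dir = out)
  expect_true(all(file.exists(file.path(
    out, c("ITS.fasta", "COI.fasta", "partition.tsv", "regions.tsv",
           "truth.json")))))
  back <- read_fasta(file.path(out, "ITS.fasta"), "ITS")
  expect_identical(back$seqs, sim$alignments$ITS$seqs)
  part <- read_partition(file.path(out, "partition.tsv"))
  expect_identical(part$assignment, sim$partition$assignment)
  truth <- jsonlite::read_json(file.path(out, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$seed, 2L)
  expect_equal(nrow(truth$pure), nrow(sim$truth$pure))
})
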