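# Shared fixture builders (all data generated in code).

make_aln <- function(seqs, locus = "L1") dna_alignment(seqs, locus)

# Random gapped alignment plus a random species partition; used by the
# oracle-equivalence and corruption property tests.
random_diag_instance <- function(n_max_rows = 8L, n_max_cols = 8L,
                                 p_gap = 0.08, p_amb = 0.05) {
  nr <- sample(4:n_max_rows, 1L)
  nc <- sample(2:n_max_cols, 1L)
  pool <- c("A", "C", "G", "T")
  mat <- matrix(sample(pool, nr * nc, replace = TRUE), nr, nc)
  mat[runif(nr * nc) < p_gap] <- "-"
  amb <- runif(nr * nc) < p_amb
  mat[amb] <- sample(c("N", "R", "Y"), sum(amb), replace = TRUE)
  rownames(mat) <- sprintf("s%02d", seq_len(nr))
  nsp <- sample(2:3, 1L)
  labels <- LETTERS[seq_len(nsp)]
  assign <- sample(labels, nr, replace = TRUE)
  # guarantee every species has a member
  assign[seq_len(nsp)] <- labels
  names(assign) <- rownames(mat)
  list(aln = dna_alignment(mat, "sim"),
       part = species_partition(assign))
}

# Small random spec with planted structure for full-pipeline recovery tests.
random_sim_spec <- function(n_species = sample(3:5, 1L), with_composite = FALSE) {
  labels <- sprintf("sp%d", seq_len(n_species))
  species <- data.frame(label = labels,
                        n = sample(1:8, n_species, replace = TRUE),
                        stringsAsFactors = FALSE)
  priv <- data.frame(locus = "L1", species = labels,
                     n = sample(1:3, n_species, replace = TRUE),
                     stringsAsFactors = FALSE)
  comp <- NULL
  if (with_composite && n_species >= 4L) {
    comp_sp <- labels[n_species]
    priv$n[priv$species == comp_sp] <- 0L
    comp <- data.frame(locus = "L1", species = comp_sp,
                       size = min(3L, n_species - 2L), stringsAsFactors = FALSE)
  }
  sim_spec(loci = data.frame(name = "L1", length = 120L, stringsAsFactors = FALSE),
           species = species, private_subs = priv, composites = comp)
}
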