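# Pipeline driver: stats -> distances -> diagnosis -> trees -> combined
# per-species evidence report, with a reproducible config and a hashed
# output manifest.

#' Published Aplysina ITS divergence matrix
#'
#' The pairwise ITS1-5.8S-ITS2 rDNA divergence (percent uncorrected
#' p-distance) among ten Eastern Pacific and Caribbean *Aplysina* taxa, as
#' printed in the study this package's workflow reproduces, shipped as a
#' plain-text fixture. Useful as a ready-made [nj_tree()] input.
#'
#' @param as_proportion Divide by 100 (default `TRUE`) so entries are plain
#'   proportions.
#' @return Symmetric numeric matrix with taxon dimnames.
#' @export
aplysina_divergence_matrix <- function(as_proportion = TRUE) {
  path <- system.file("extdata", "aplysina_its_pdist_percent.tsv",
                      package = "spdelim", mustWork = TRUE)
  tab <- read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                    check.names = FALSE)
  m <- as.matrix(tab)
  if (as_proportion) m <- m / 100
  m
}

#' Assemble a pipeline run configuration
#'
#' @param alignments Named character vector or list of FASTA paths, keyed by
#'   locus name.
#' @param partition Path to the specimen-to-species TSV.
#' @param regions Optional named list of region-map TSV paths, keyed by locus.
#' @param model,deletion Distance options (see [distance_matrix()]).
#' @param gap_policy Diagnosis/site-classification gap policy.
#' @param max_size Largest composite-diagnostic cardinality searched.
#' @param bootstrap Bootstrap pseudo-replicates for the NJ tree (0 = none).
#' @param mp Also run the exact branch-and-bound parsimony search on loci
#'   with 4-15 distinct taxa.
#' @param seed Integer seed for the bootstrap.
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(alignments, partition, regions = NULL,
                       model = "p", deletion = "pairwise",
                       gap_policy = "exclude-column", max_size = 6L,
                       bootstrap = 0L, mp = FALSE, seed = 1L, out_dir) {
  structure(list(alignments = as.list(alignments), partition = partition,
                 regions = regions, model = model, deletion = deletion,
                 gap_policy = gap_policy, max_size = as.integer(max_size),
                 bootstrap = as.integer(bootstrap), mp = isTRUE(mp),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full delimitation pipeline
#'
#' Executes every stage on the configured inputs and writes, under
#' `config$out_dir`: `stats.tsv` (per-locus summary), per-locus distance
#' tables (`<locus>_distances.tsv`, percent lower-triangle, and
#' `<locus>_distances.phy`), `diagnostics.tsv` and `diagnostics.txt`,
#' per-locus NJ trees (`<locus>_nj.nwk`, with bootstrap supports when
#' requested) and optional MP trees, a per-species-pair evidence report
#' (`report.md`), the serialized `config.json`, and `manifest.tsv` with an
#' md5 content hash per output file. Re-running the same config and seed
#' reproduces every file byte-for-byte.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory stage results (`stats`,
#'   `distances`, `diagnosis`, `trees`, `report_lines`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  part <- read_partition(config$partition)
  alignments <- lapply(names(config$alignments), function(locus) {
    read_fasta(config$alignments[[locus]], locus)
  })
  names(alignments) <- names(config$alignments)
  regions <- NULL
  if (!is.null(config$regions)) {
    regions <- lapply(config$regions, read_region_map)
  }
  outfiles <- character(0)
  emit <- function(name) {
    path <- file.path(config$out_dir, name)
    outfiles <<- c(outfiles, path)
    path
  }

  message(sprintf("[stats] %d locus/loci", length(alignments)))
  stats <- do.call(rbind, lapply(alignments, alignment_stats,
                                 gap_policy = config$gap_policy))
  write.table(stats, emit("stats.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  distances <- list()
  trees <- list()
  for (locus in names(alignments)) {
    aln <- alignments[[locus]]
    if (n_seqs(aln) < 2L) next
    dm <- distance_matrix(aln, config$model, config$deletion)
    distances[[locus]] <- dm
    writeLines(format_distance_table(dm, "percent", 3L),
               emit(paste0(locus, "_distances.tsv")), sep = "")
    write_phylip_matrix(dm, emit(paste0(locus, "_distances.phy")))
    message(sprintf("[distances] %s: %d taxa, model %s", locus,
                    n_seqs(aln), config$model))
    if (n_seqs(aln) >= 3L) {
      if (config$bootstrap > 0L && n_seqs(aln) >= 4L) {
        bs <- bootstrap_support(aln, config$bootstrap,
                                derive_seed(config$seed, locus),
                                config$model, config$deletion)
        trees[[locus]] <- bs$tree
      } else {
        trees[[locus]] <- nj_tree(dm)
      }
      write_newick(trees[[locus]], emit(paste0(locus, "_nj.nwk")))
      message(sprintf("[tree] %s: NJ (%d bootstrap replicates)", locus,
                      config$bootstrap))
      if (config$mp && n_seqs(aln) >= 4L && n_seqs(aln) <= 15L) {
        mp <- branch_and_bound_mp(aln, gap_policy = "missing")
        con <- file(emit(paste0(locus, "_mp.nwk")), "w")
        for (t in mp$trees) writeLines(write_newick(t), con)
        close(con)
        writeLines(sprintf("length\t%d", mp$length),
                   emit(paste0(locus, "_mp_length.tsv")))
        message(sprintf("[tree] %s: MP length %d (%d optimal trees)",
                        locus, mp$length, length(mp$trees)))
      }
    }
  }

  species_present <- unique(part$assignment[unlist(lapply(alignments, specimen_ids))])
  if (length(species_present) >= 2L) {
    diagnosis <- diagnose_species(alignments, part, regions,
                                  config$max_size, config$gap_policy)
    write.table(diagnosis_table(diagnosis), emit("diagnostics.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    txt <- utils::capture.output(print(diagnosis))
    writeLines(txt, emit("diagnostics.txt"))
    message(sprintf("[diagnose] %d pure, %d composite set(s)",
                    nrow(diagnosis$pure), length(diagnosis$composites)))
  } else {
    diagnosis <- NULL
    message("[diagnose] skipped: fewer than two species")
  }

  report <- evidence_report(alignments, part, distances, diagnosis, trees)
  writeLines(report, emit("report.md"))

  # config.json records the run's own parameters (incl. machine-local paths)
  # and is deliberately not part of the hashed result manifest
  jsonlite::write_json(unclass(config), file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- data.frame(file = basename(outfiles),
                         md5 = unname(tools::md5sum(outfiles)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  write.table(manifest, file.path(config$out_dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(stats = stats, distances = distances, diagnosis = diagnosis,
                 trees = trees, report_lines = report, manifest = manifest))
}

# Markdown evidence report: one section per species pair, one
# supported/not-supported flag per line of evidence.
evidence_report <- function(alignments, part, distances, diagnosis, trees) {
  lines <- c("# Species delimitation evidence report", "")
  species <- part$species[part$species %in%
                            unique(part$assignment[unlist(lapply(alignments, specimen_ids))])]
  if (length(species) < 2L) {
    return(c(lines, "No interspecific comparison possible: fewer than two species sampled."))
  }
  pure <- diagnosis$pure
  min_interspecific <- function(locus, a, b) {
    dm <- distances[[locus]]
    if (is.null(dm)) return(NA_real_)
    ma <- intersect(members_of(part, a), dm$labels)
    mb <- intersect(members_of(part, b), dm$labels)
    if (length(ma) == 0L || length(mb) == 0L) return(NA_real_)
    min(dm$d[ma, mb])
  }
  for (i in seq_len(length(species) - 1L)) {
    for (j in seq((i + 1L), length(species))) {
      a <- species[i]; b <- species[j]
      lines <- c(lines, sprintf("## %s vs %s", a, b), "")
      n_support <- 0L
      for (locus in names(alignments)) {
        d <- min_interspecific(locus, a, b)
        if (!is.na(d)) {
          ok <- d > 0
          if (ok) n_support <- n_support + 1L
          lines <- c(lines, sprintf(
            "- distance divergence (%s): minimum interspecific p = %.3f%% [%s]",
            locus, 100 * d, if (ok) "supported" else "not supported"))
        }
      }
      for (sp in c(a, b)) {
        np <- sum(pure$species == sp)
        ok <- np > 0L
        if (ok) n_support <- n_support + 1L
        lines <- c(lines, sprintf(
          "- pure diagnostic characters for %s: %d [%s]",
          sp, np, if (ok) "supported" else "not supported"))
        nc <- sum(vapply(diagnosis$composites, function(cd) cd$species == sp, TRUE))
        lines <- c(lines, sprintf(
          "- composite diagnostic combinations for %s: %d [%s]",
          sp, nc, if (nc > 0L) "supported" else "not supported"))
        if (nc > 0L) n_support <- n_support + 1L
      }
      for (locus in names(trees)) {
        tr <- trees[[locus]]
        for (sp in c(a, b)) {
          mem <- intersect(members_of(part, sp), tr$tip.label)
          if (length(mem) == 0L) next
          ok <- is_monophyletic(tr, mem)
          if (ok) n_support <- n_support + 1L
          lines <- c(lines, sprintf(
            "- monophyly of %s in %s NJ tree [%s]",
            sp, locus, if (ok) "supported" else "not supported"))
        }
      }
      lines <- c(lines, "", sprintf(
        "Independent lines of evidence supporting the distinction: %d", n_support), "")
    }
  }
  if (length(diagnosis$provisional) > 0L) {
    lines <- c(lines, sprintf(
      "Note: species sampled with a single specimen (%s) are provisionally diagnostic.",
      paste(diagnosis$provisional, collapse = ", ")))
  }
  lines
}
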