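# Synthetic multi-species barcode alignments with planted, known truth.
#
# Generator model: per locus, a uniform random root sequence; each species'
# haplotype is derived by substitutions at positions sampled without
# replacement (planted diagnostics first, then the species' private
# substitutions), so pairwise substitution counts are exact counts, not
# expectations. All specimens of a species copy its haplotype; intraspecific
# variation is indel-only, realized as insertion columns carried by a subset
# of specimens and gapped in everyone else (the generator emits pre-aligned
# FASTA). One global seed governs everything; per-locus streams are derived
# by a stable string hash of (seed, locus name).

#' Specify a synthetic multi-species barcode data set
#'
#' @param loci Data frame with columns `name` and `length` (backbone sites
#'   per locus, before insertion columns).
#' @param species Data frame with columns `label` and `n` (specimens).
#' @param private_subs Data frame with columns `locus`, `species`, `n`:
#'   number of substitutions private to that species at that locus. Each
#'   private substitution is a planted pure diagnostic nucleotide.
#' @param composites Optional data frame with columns `locus`, `species`,
#'   `size`: plant one composite-only diagnostic combination of `size`
#'   positions. Feasibility requires `size <= n_species - 2`: each member
#'   state is copied into blocker species so that it is not pure, and every
#'   proper subset is matched by some blocker, making the planted cardinality
#'   minimal. A species with a planted composite receives no private
#'   substitutions.
#' @param indels Optional data frame with columns `locus`, `species`,
#'   `length`, `carriers`: one insertion of `length` columns carried by
#'   `carriers` specimens of the species (indel-only intraspecific
#'   variation).
#' @param regions Optional named list (by locus) of [region_map()]s. Maps are
#'   interpreted on backbone coordinates and shifted across insertions when
#'   the alignment is realized.
#' @return A `sim_spec` object.
#' @export
sim_spec <- function(loci, species, private_subs,
                     composites = NULL, indels = NULL, regions = NULL) {
  stopifnot(all(c("name", "length") %in% names(loci)),
            all(c("label", "n") %in% names(species)),
            all(c("locus", "species", "n") %in% names(private_subs)))
  if (anyDuplicated(loci$name)) stop("duplicate locus name", call. = FALSE)
  if (anyDuplicated(species$label)) stop("duplicate species label", call. = FALSE)
  if (!is.null(composites)) {
    bad <- composites$size > nrow(species) - 2L
    if (any(bad))
      stop(sprintf("composite of size %d unsatisfiable with %d species (needs size <= n_species - 2)",
                   composites$size[bad][1L], nrow(species)), call. = FALSE)
    if (any(composites$size < 2L))
      stop("composite size must be >= 2", call. = FALSE)
    joint <- merge(composites, private_subs, by = c("locus", "species"))
    if (any(joint$n > 0L))
      stop("a species with a planted composite must have no private substitutions at that locus (it would not be composite-only)",
           call. = FALSE)
  }
  structure(list(loci = loci, species = species, private_subs = private_subs,
                 composites = composites, indels = indels, regions = regions),
            class = "sim_spec")
}

# Stable 31-adic string hash folded with the seed, kept below 2^31.
derive_seed <- function(seed, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 2147483647
  as.integer(((seed %% 2147483647) * 7919 + h) %% 2147483647)
}

other_base <- function(b) setdiff(DET_BASES, b)

#' Realize a synthetic data set
#'
#' Generates the alignments described by a [sim_spec()] together with a truth
#' record of every expected analysis output. Deterministic: the same spec and
#' seed reproduce the result bit-for-bit; the caller's RNG state is left
#' untouched.
#'
#' @param spec A [sim_spec()].
#' @param seed Integer seed.
#' @param out_dir Optional directory; when given, writes one FASTA per locus,
#'   `partition.tsv`, `regions.tsv` (if regions were specified), and
#'   `truth.json`.
#' @return A `sim_truth` list: `alignments` (named list of
#'   [dna_alignment()]), `partition` ([species_partition()]), `regions`
#'   (named list of [region_map()] on realized coordinates, or `NULL`), and
#'   `truth` with elements `pure` (expected pure diagnostics: locus, species,
#'   position, state), `composites` (expected minimal sets with positions,
#'   states, size), `pair_subs` (per locus, matrix of interspecific
#'   substitution counts), `comparable_sites` (backbone length per locus),
#'   and `species_members` (specimen ids per species).
#' @export
simulate_alignments <- function(spec, seed, out_dir = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  sp_labels <- spec$species$label
  n_by_sp <- setNames(spec$species$n, sp_labels)
  specimen_ids <- unlist(lapply(sp_labels, function(s) {
    sprintf("%s_%02d", gsub("[^A-Za-z0-9]+", "_", s), seq_len(n_by_sp[[s]]))
  }))
  assignment <- setNames(rep(sp_labels, n_by_sp[sp_labels]), specimen_ids)
  part <- species_partition(assignment)

  alignments <- list()
  regions_out <- list()
  truth_pure <- list()
  truth_comp <- list()
  pair_subs <- list()
  comparable <- list()

  for (li in seq_len(nrow(spec$loci))) {
    locus <- spec$loci$name[li]
    L <- spec$loci$length[li]
    lseed <- derive_seed(seed, locus)
    res <- with_seed(lseed, {
      root <- sample(DET_BASES, L, replace = TRUE)

      priv <- spec$private_subs[spec$private_subs$locus == locus, , drop = FALSE]
      comps <- if (is.null(spec$composites)) NULL
               else spec$composites[spec$composites$locus == locus, , drop = FALSE]
      n_needed <- sum(priv$n) + if (is.null(comps)) 0L else sum(comps$size)
      if (n_needed > L)
        stop(sprintf("locus '%s': %d planted positions exceed length %d",
                     locus, n_needed, L), call. = FALSE)
      pos_pool <- sample.int(L, n_needed)
      nxt <- 0L
      take <- function(k) {
        out <- pos_pool[nxt + seq_len(k)]
        nxt <<- nxt + k
        out
      }

      hap <- matrix(rep(root, each = length(sp_labels)),
                    nrow = length(sp_labels), dimnames = list(sp_labels, NULL))
      pure <- list()
      comp_truth <- list()

      for (r in seq_len(nrow(priv))) {
        if (priv$n[r] == 0L) next
        s <- priv$species[r]
        pos <- sort(take(priv$n[r]))
        states <- vapply(pos, function(p) sample(other_base(root[p]), 1L), "")
        hap[s, pos] <- states
        pure[[length(pure) + 1L]] <- data.frame(
          locus = locus, species = s, position = pos, state = states,
          stringsAsFactors = FALSE)
      }

      if (!is.null(comps)) {
        for (r in seq_len(nrow(comps))) {
          s <- comps$species[r]
          m <- comps$size[r]
          pos <- sort(take(m))
          states <- vapply(pos, function(p) sample(other_base(root[p]), 1L), "")
          hap[s, pos] <- states
          blockers <- setdiff(sp_labels, s)[seq_len(m)]
          # blocker j carries every member state except the j-th, so each
          # member state occurs outside s (never pure) and every proper
          # subset is matched by some blocker (planted cardinality minimal)
          for (j in seq_len(m)) {
            hap[blockers[j], pos[-j]] <- states[-j]
          }
          comp_truth[[length(comp_truth) + 1L]] <- list(
            locus = locus, species = s, positions = pos,
            states = unname(states), size = m)
        }
      }

      seqs <- hap[assignment, , drop = FALSE]
      rownames(seqs) <- specimen_ids

      # insertions: new columns after a random backbone position, bases in
      # carrier specimens, gaps elsewhere
      ins <- if (is.null(spec$indels)) NULL
             else spec$indels[spec$indels$locus == locus, , drop = FALSE]
      shifts <- integer(0)  # backbone position after which an insert sits
      if (!is.null(ins) && nrow(ins) > 0L) {
        for (r in seq_len(nrow(ins))) {
          s <- ins$species[r]
          len <- ins$length[r]
          mem <- members_of(part, s)
          if (ins$carriers[r] >= length(mem))
            stop(sprintf("indel carriers must leave >= 1 non-carrier in species '%s'", s),
                 call. = FALSE)
          carriers <- sort(sample(mem, ins$carriers[r]))
          at <- sample.int(ncol(seqs) - 1L, 1L)  # current coordinates
          block <- matrix(GAP_CHAR, nrow(seqs), len,
                          dimnames = list(rownames(seqs), NULL))
          # one insertion event: every carrier shares the same inserted
          # segment, so intraspecific variation stays indel-only
          block[carriers, ] <- matrix(sample(DET_BASES, len, replace = TRUE),
                                      nrow = length(carriers), ncol = len,
                                      byrow = TRUE)
          seqs <- cbind(seqs[, seq_len(at), drop = FALSE], block,
                        seqs[, seq(at + 1L, ncol(seqs)), drop = FALSE])
          shifts <- c(shifts, at)
          names(shifts)[length(shifts)] <- as.character(len)
        }
      }

      list(root = root, hap = hap, seqs = seqs, pure = pure,
           comp_truth = comp_truth, shifts = shifts)
    })

    # map backbone coordinates to realized alignment coordinates
    to_realized <- function(pos) {
      out <- pos
      if (length(res$shifts) > 0L) {
        # shifts recorded in realized coordinates at insertion time; replay
        for (k in seq_along(res$shifts)) {
          at <- res$shifts[k]
          len <- as.integer(names(res$shifts)[k])
          out <- ifelse(out > at, out + len, out)
        }
      }
      out
    }

    pure_df <- if (length(res$pure) > 0L) do.call(rbind, res$pure) else
      data.frame(locus = character(), species = character(),
                 position = integer(), state = character(),
                 stringsAsFactors = FALSE)
    if (nrow(pure_df) > 0L) pure_df$position <- to_realized(pure_df$position)
    comp_list <- lapply(res$comp_truth, function(ct) {
      ct$positions <- to_realized(ct$positions)
      ct
    })

    aln <- dna_alignment(res$seqs, locus)
    alignments[[locus]] <- aln
    truth_pure[[locus]] <- pure_df
    truth_comp <- c(truth_comp, comp_list)
    comparable[[locus]] <- L

    # exact interspecific substitution counts from the haplotypes
    ns <- length(sp_labels)
    ps <- matrix(0L, ns, ns, dimnames = list(sp_labels, sp_labels))
    for (i in seq_len(ns - 1L)) {
      for (j in seq(i + 1L, ns)) {
        ps[i, j] <- ps[j, i] <- sum(res$hap[i, ] != res$hap[j, ])
      }
    }
    pair_subs[[locus]] <- ps

    rg <- locus_regions(spec$regions, locus)
    if (!is.null(rg)) {
      starts <- to_realized(rg$start)
      ends <- to_realized(rg$end)
      regions_out[[locus]] <- region_map(rg$region, starts, ends)
    }
  }

  truth <- list(
    pure = do.call(rbind, c(truth_pure, list(make.row.names = FALSE))),
    composites = truth_comp,
    pair_subs = pair_subs,
    comparable_sites = comparable,
    species_members = lapply(setNames(sp_labels, sp_labels),
                             function(s) members_of(part, s))
  )
  out <- structure(list(alignments = alignments, partition = part,
                        regions = if (length(regions_out) > 0L) regions_out else NULL,
                        truth = truth, seed = seed),
                   class = "sim_truth")
  if (!is.null(out_dir)) write_sim_truth(out, out_dir)
  out
}

write_sim_truth <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (locus in names(sim$alignments)) {
    write_fasta(sim$alignments[[locus]], file.path(out_dir, paste0(locus, ".fasta")))
  }
  part <- sim$partition
  write.table(data.frame(specimen_id = names(part$assignment),
                         species = unname(part$assignment)),
              file.path(out_dir, "partition.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$regions)) {
    rows <- do.call(rbind, lapply(names(sim$regions), function(locus) {
      rg <- sim$regions[[locus]]
      data.frame(locus = locus, region = rg$region, start = rg$start,
                 end = rg$end, stringsAsFactors = FALSE)
    }))
    write.table(rows, file.path(out_dir, "regions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(seed = sim$seed,
         pure = sim$truth$pure,
         composites = sim$truth$composites,
         pair_subs = lapply(sim$truth$pair_subs, function(m)
           as.data.frame(as.table(m), stringsAsFactors = FALSE)),
         comparable_sites = sim$truth$comparable_sites,
         species_members = sim$truth$species_members),
    file.path(out_dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Synthetic data set shaped like the Eastern Pacific Aplysina study
#'
#' A packaged [sim_spec()] mirroring the structure of the three-species
#' Mexican Pacific *Aplysina* data: an ITS-like nuclear locus with a 695-site
#' comparable backbone plus a 10-column insertion (705 aligned columns
#' total), interspecific substitution counts of 2 and 5 (so p-distances are
#' exactly 2/695 = 0.288% and 5/695 = 0.719% at the printed precision), four
#' pure diagnostic nucleotides for *A. gerardogreeni* and one each for the
#' other species, indel-only intraspecific variation in *A. clathrata* (two
#' haplotypes), and a COI-like 523-site locus whose single segregating site
#' is diagnostic for *A. revillagigedi*. Sample sizes are 6/4/5 specimens.
#'
#' @return A `sim_spec`; realize it with [simulate_alignments()].
#' @export
aplysina_sim_spec <- function() {
  sim_spec(
    loci = data.frame(name = c("ITS", "COI"), length = c(695L, 523L),
                      stringsAsFactors = FALSE),
    species = data.frame(
      label = c("A_gerardogreeni", "A_revillagigedi", "A_clathrata"),
      n = c(6L, 4L, 5L), stringsAsFactors = FALSE),
    private_subs = data.frame(
      locus = c("ITS", "ITS", "ITS", "COI"),
      species = c("A_gerardogreeni", "A_revillagigedi", "A_clathrata",
                  "A_revillagigedi"),
      n = c(4L, 1L, 1L, 1L), stringsAsFactors = FALSE),
    indels = data.frame(locus = "ITS", species = "A_clathrata",
                        length = 10L, carriers = 2L, stringsAsFactors = FALSE),
    regions = list(ITS = region_map(c("ITS1", "ITS2"), c(1L, 102L), c(101L, 695L)))
  )
}
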