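# Character-based species diagnosis (Davis-Nixon characteristic attributes):
# pure diagnostic nucleotides and minimal composite diagnostic combinations.
#
# Conventions shared by both finders:
#  * Coordinates are 1-based alignment positions.
#  * Ambiguity codes (incl. N) are missing data and are handled
#    conservatively: a missing residue in a species member blocks fixation,
#    and a missing residue in a non-member "possibly matches" any base state,
#    blocking exclusivity.
#  * gap_policy "exclude-column": any column containing a gap anywhere in the
#    alignment is removed from consideration. "fifth-state": the gap is an
#    ordinary character state (it matches only itself; ambiguity codes do not
#    possibly-match a gap).

# Columns eligible under the gap policy (logical over columns).
diag_column_mask <- function(mat, gap_policy) {
  if (gap_policy == "exclude-column") {
    !apply(mat == GAP_CHAR, 2L, any)
  } else {
    rep(TRUE, ncol(mat))
  }
}

# Per-column fixed state of a species: the shared determinate state, or NA
# when members disagree or any member is missing there.
species_fixed_states <- function(mat, members, gap_policy) {
  sub <- mat[members, , drop = FALSE]
  first <- sub[1L, ]
  same <- colSums(sub != matrix(first, nrow(sub), ncol(sub), byrow = TRUE)) == 0L
  det <- first %in% DET_BASES | (gap_policy == "fifth-state" & first == GAP_CHAR)
  out <- first
  out[!(same & det)] <- NA_character_
  out
}

# TRUE where residue r could be state s (conservative): exact match, or r is
# an ambiguity code and s is a base.
possibly_matches <- function(r, s) {
  (r == s) | (r %in% AMBIG_CODES & s != GAP_CHAR)
}

#' Find pure diagnostic nucleotides
#'
#' A pure diagnostic character for a species is an alignment position whose
#' state is fixed in every member of the species and not possibly carried by
#' any specimen outside it. Positions are scanned per species over all
#' columns eligible under `gap_policy`.
#'
#' @param aln A [dna_alignment()].
#' @param part A [species_partition()] covering every specimen in `aln`,
#'   with at least two species present in the alignment.
#' @param gap_policy `"exclude-column"` (default) or `"fifth-state"`.
#' @return Data frame with columns `locus`, `species`, `position` (1-based),
#'   `state`, ordered by species (partition order) then position. A species
#'   whose members are entirely missing at some column triggers a warning,
#'   not an error.
#' @export
find_pure_diagnostics <- function(aln, part,
                                  gap_policy = c("exclude-column", "fifth-state")) {
  gap_policy <- match.arg(gap_policy)
  check_partition_covers(aln, part)
  mat <- aln$seqs
  keep <- diag_column_mask(mat, gap_policy)
  out <- list()
  for (sp in species_in_alignment(aln, part)) {
    mem <- intersect(members_of(part, sp), rownames(mat))
    oth <- setdiff(rownames(mat), mem)
    sub <- mat[mem, , drop = FALSE]
    allmiss <- colSums(matrix(sub %in% AMBIG_CODES, nrow(sub))) == nrow(sub)
    if (any(allmiss & keep))
      warning(sprintf("species '%s' is entirely missing at %d column(s)",
                      sp, sum(allmiss & keep)), call. = FALSE)
    fixed <- species_fixed_states(mat, mem, gap_policy)
    cand <- which(keep & !is.na(fixed))
    for (c in cand) {
      if (!any(possibly_matches(mat[oth, c], fixed[c]))) {
        out[[length(out) + 1L]] <- data.frame(
          locus = aln$locus_name, species = sp, position = c,
          state = fixed[c], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(locus = character(), species = character(),
                      position = integer(), state = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

check_partition_covers <- function(aln, part) {
  ids <- rownames(aln$seqs)
  missing <- setdiff(ids, names(part$assignment))
  if (length(missing) > 0L)
    stop(sprintf("specimen '%s' has no species assignment", missing[1L]),
         call. = FALSE)
  if (length(species_in_alignment(aln, part)) < 2L)
    stop("diagnosis requires at least two species in the alignment",
         call. = FALSE)
  invisible(TRUE)
}

species_in_alignment <- function(aln, part) {
  present <- unique(part$assignment[rownames(aln$seqs)])
  part$species[part$species %in% present]
}

#' Find minimal composite diagnostic combinations
#'
#' A composite diagnostic for a species is a set of at least two positions,
#' each fixed within the species but none a pure diagnostic on its own, such
#' that no single specimen outside the species possibly matches all member
#' states simultaneously. The search proceeds by increasing cardinality and,
#' per species, stops at the first cardinality yielding at least one set;
#' every returned set is therefore of minimal cardinality (any proper subset
#' has a cardinality already proven non-diagnostic). Candidate columns are
#' restricted to those mismatched by at least one non-member, which provably
#' leaves the result unchanged: a column every non-member possibly matches
#' excludes no specimen and can never occur in a minimal set.
#'
#' @inheritParams find_pure_diagnostics
#' @param max_size Largest combination cardinality searched (default 6).
#' @return A `composite_diagnostics` list. Each element has `species`,
#'   `positions` (sorted), `states`, `size`, `locus`, `minimal = TRUE`;
#'   elements are ordered by species then lexicographically by positions.
#'   Species for which the search is exhausted without success up to
#'   `max_size` are recorded in `attr(, "undiagnosable")`.
#' @export
find_composite_diagnostics <- function(aln, part, max_size = 6L,
                                       gap_policy = c("exclude-column", "fifth-state")) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(max_size >= 2L)
  check_partition_covers(aln, part)
  mat <- aln$seqs
  keep <- diag_column_mask(mat, gap_policy)
  pure <- find_pure_diagnostics(aln, part, gap_policy)
  out <- list()
  undiag <- character()
  for (sp in species_in_alignment(aln, part)) {
    mem <- intersect(members_of(part, sp), rownames(mat))
    oth <- setdiff(rownames(mat), mem)
    fixed <- species_fixed_states(mat, mem, gap_policy)
    pure_pos <- pure$position[pure$species == sp]
    cand <- setdiff(which(keep & !is.na(fixed)), pure_pos)
    # Exclusion matrix: E[k, o] TRUE when non-member o cannot carry the
    # species state at candidate k. A set is diagnostic iff its rows cover
    # every non-member (set-cover structure).
    E <- vapply(cand, function(c) !possibly_matches(mat[oth, c], fixed[c]),
                logical(length(oth)))
    E <- t(matrix(E, nrow = length(oth), ncol = length(cand)))
    useful <- rowSums(E) > 0L
    cand <- cand[useful]
    E <- E[useful, , drop = FALSE]
    found <- FALSE
    if (length(cand) >= 2L && all(colSums(E) > 0L)) {
      for (m in seq(2L, min(max_size, length(cand)))) {
        combos <- combn(seq_along(cand), m)
        hit <- which(apply(combos, 2L, function(ix) {
          all(colSums(E[ix, , drop = FALSE]) > 0L)
        }))
        if (length(hit) > 0L) {
          for (h in hit) {
            ix <- combos[, h]
            out[[length(out) + 1L]] <- list(
              species = sp, positions = cand[ix],
              states = unname(fixed[cand[ix]]), size = m,
              locus = aln$locus_name, minimal = TRUE)
          }
          found <- TRUE
          break
        }
      }
    }
    if (!found) undiag <- c(undiag, sp)
  }
  structure(out, class = "composite_diagnostics",
            undiagnosable = undiag, max_size = max_size)
}

#' @export
print.composite_diagnostics <- function(x, ...) {
  cat(sprintf("<composite_diagnostics> %d minimal set(s)\n", length(x)))
  for (cd in x) {
    cat(sprintf("  %s [%s]: %s\n", cd$species, cd$locus,
                paste(sprintf("%d%s", cd$positions, cd$states), collapse = " + ")))
  }
  ud <- attr(x, "undiagnosable")
  if (length(ud) > 0L)
    cat(sprintf("  no composite up to size %d for: %s\n",
                attr(x, "max_size"), paste(ud, collapse = ", ")))
  invisible(x)
}

#' Diagnose species across one or more loci
#'
#' Runs [find_pure_diagnostics()] and [find_composite_diagnostics()] on each
#' locus independently (composite sets never span loci), annotates positions
#' with regions, and merges everything into a per-species report with a
#' diagnosability verdict: `"pure"` (at least one pure character),
#' `"composite-only"` (no pure, at least one composite), or
#' `"undiagnosable"` (within `max_size`).
#'
#' @param alignments A single [dna_alignment()] or a list of them (one per
#'   locus).
#' @param part A [species_partition()].
#' @param regions Optional [region_map()], or a named list of region maps
#'   keyed by locus name.
#' @param max_size Largest composite cardinality searched.
#' @param gap_policy Passed to both finders.
#' @return A `diagnosis_report`: list with `pure` (data frame incl. `region`
#'   column), `composites`, `verdicts` (named character vector per species),
#'   and `provisional` (species represented by a single specimen, whose
#'   fixation is trivially satisfied).
#' @export
diagnose_species <- function(alignments, part, regions = NULL, max_size = 6L,
                             gap_policy = c("exclude-column", "fifth-state")) {
  gap_policy <- match.arg(gap_policy)
  if (inherits(alignments, "dna_alignment")) alignments <- list(alignments)
  pure_all <- list()
  comp_all <- list()
  undiag_by_locus <- list()
  species_seen <- character()
  for (aln in alignments) {
    region_for <- locus_regions(regions, aln$locus_name)
    pure <- find_pure_diagnostics(aln, part, gap_policy)
    pure$region <- assign_region(region_for, pure$position)
    comp <- find_composite_diagnostics(aln, part, max_size, gap_policy)
    for (cd in comp) cd$regions <- assign_region(region_for, cd$positions)
    pure_all[[aln$locus_name]] <- pure
    comp_all <- c(comp_all, lapply(comp, function(cd) {
      cd$regions <- assign_region(region_for, cd$positions)
      cd
    }))
    undiag_by_locus[[aln$locus_name]] <- attr(comp, "undiagnosable")
    species_seen <- union(species_seen, species_in_alignment(aln, part))
  }
  pure_df <- do.call(rbind, c(pure_all, list(make.row.names = FALSE)))
  if (is.null(pure_df))
    pure_df <- data.frame(locus = character(), species = character(),
                          position = integer(), state = character(),
                          region = character(), stringsAsFactors = FALSE)
  species_seen <- part$species[part$species %in% species_seen]
  verdicts <- vapply(species_seen, function(sp) {
    if (any(pure_df$species == sp)) "pure"
    else if (any(vapply(comp_all, function(cd) cd$species == sp, TRUE))) "composite-only"
    else "undiagnosable"
  }, "")
  counts <- table(factor(part$assignment, levels = part$species))
  provisional <- species_seen[counts[species_seen] == 1L]
  structure(list(pure = pure_df, composites = comp_all, verdicts = verdicts,
                 provisional = provisional, max_size = max_size),
            class = "diagnosis_report")
}

locus_regions <- function(regions, locus) {
  if (is.null(regions)) return(NULL)
  if (inherits(regions, "region_map")) return(regions)
  regions[[locus]]
}

#' @export
print.diagnosis_report <- function(x, ...) {
  cat("Character-based diagnosis\n=========================\n")
  for (sp in names(x$verdicts)) {
    cat(sprintf("\n%s: %s\n", sp, x$verdicts[[sp]]))
    p <- x$pure[x$pure$species == sp, , drop = FALSE]
    if (nrow(p) > 0L) {
      for (i in seq_len(nrow(p)))
        cat(sprintf("  pure: %s position %d = %s (%s)\n",
                    p$locus[i], p$position[i], p$state[i], p$region[i]))
    }
    for (cd in x$composites) {
      if (cd$species != sp) next
      cat(sprintf("  composite (size %d, %s): %s\n", cd$size, cd$locus,
                  paste(sprintf("%d%s [%s]", cd$positions, cd$states,
                                cd$regions), collapse = " + ")))
    }
  }
  if (length(x$provisional) > 0L)
    cat(sprintf("\nNote: species with a single specimen (%s) are provisionally diagnostic;\nfixation cannot be assessed from n = 1.\n",
                paste(x$provisional, collapse = ", ")))
  invisible(x)
}

#' Tabulate a diagnosis report
#'
#' @param report A [diagnose_species()] result.
#' @return Data frame with columns `locus`, `species`, `kind`
#'   (`pure`/`composite`), `set_id`, `position`, `state`, `region`.
#' @export
diagnosis_table <- function(report) {
  rows <- list()
  p <- report$pure
  if (nrow(p) > 0L) {
    rows[[1L]] <- data.frame(locus = p$locus, species = p$species,
                             kind = "pure", set_id = NA_integer_,
                             position = p$position, state = p$state,
                             region = p$region, stringsAsFactors = FALSE)
  }
  for (k in seq_along(report$composites)) {
    cd <- report$composites[[k]]
    rows[[length(rows) + 1L]] <- data.frame(
      locus = cd$locus, species = cd$species, kind = "composite",
      set_id = k, position = cd$positions, state = cd$states,
      region = cd$regions, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(locus = character(), species = character(),
                      kind = character(), set_id = integer(),
                      position = integer(), state = character(),
                      region = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
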