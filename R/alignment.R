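# Aligned-sequence container and standard-format I/O.

#' Construct a multiple sequence alignment
#'
#' The central data container: a set of equal-length, gapped, uppercase DNA
#' sequences keyed by specimen id, for one locus. Residues must be drawn from
#' `{A,C,G,T,-}` plus the IUPAC ambiguity codes (including `N`), which are
#' treated as missing data by all downstream analyses.
#'
#' @param seqs Named character vector of aligned sequences (one string per
#'   specimen), or a character matrix of single residues with specimen ids as
#'   row names.
#' @param locus_name Single string naming the locus (e.g. `"ITS"`, `"COI"`).
#' @return An object of class `dna_alignment`: a list with elements
#'   `locus_name`, `seqs` (residue matrix, rows = specimens, columns = sites),
#'   and `length` (number of sites).
#' @examples
#' aln <- dna_alignment(c(a = "ACGT", b = "AC-T"), "toy")
#' n_sites(aln)
#' @export
dna_alignment <- function(seqs, locus_name) {
  stopifnot(is.character(locus_name), length(locus_name) == 1L, nzchar(locus_name))
  if (is.matrix(seqs)) {
    mat <- toupper(seqs)
  } else {
    stopifnot(is.character(seqs))
    if (length(seqs) == 0L) stop("empty alignment: no sequences", call. = FALSE)
    ids <- names(seqs)
    if (is.null(ids)) stop("sequences must be named by specimen id", call. = FALSE)
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      bad <- names(seqs)[which(lens != lens[1L])[1L]]
      stop(sprintf("unaligned input: record '%s' has length %d, expected %d",
                   bad, nchar(seqs[bad]), lens[1L]), call. = FALSE)
    }
    mat <- matrix(toupper(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)),
                  nrow = length(seqs), byrow = TRUE,
                  dimnames = list(ids, NULL))
  }
  validate_alignment_matrix(mat)
  structure(list(locus_name = locus_name, seqs = mat, length = ncol(mat)),
            class = "dna_alignment")
}

validate_alignment_matrix <- function(mat) {
  if (nrow(mat) == 0L) stop("empty alignment: no sequences", call. = FALSE)
  if (ncol(mat) < 1L) stop("empty alignment: zero sites", call. = FALSE)
  ids <- rownames(mat)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("specimen ids must be nonempty", call. = FALSE)
  if (anyDuplicated(ids))
    stop(sprintf("duplicate specimen id: '%s'", ids[duplicated(ids)][1L]),
         call. = FALSE)
  bad <- matrix(!(mat %in% ALPHABET), nrow(mat))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("illegal residue '%s' in record '%s' at position %d",
                 mat[idx[1L], idx[2L]], ids[idx[1L]], idx[2L]), call. = FALSE)
  }
  invisible(mat)
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("<dna_alignment> locus '%s': %d sequences x %d sites\n",
              x$locus_name, nrow(x$seqs), x$length))
  invisible(x)
}

#' @rdname dna_alignment
#' @param aln A `dna_alignment`.
#' @export
n_sites <- function(aln) aln$length

#' @rdname dna_alignment
#' @export
n_seqs <- function(aln) nrow(aln$seqs)

#' @rdname dna_alignment
#' @export
specimen_ids <- function(aln) rownames(aln$seqs)

#' Extract sequences as strings
#' @param aln A `dna_alignment`.
#' @return Named character vector of aligned sequence strings.
#' @export
alignment_strings <- function(aln) {
  setNames(apply(aln$seqs, 1L, paste, collapse = ""), rownames(aln$seqs))
}

#' Read an aligned FASTA file
#'
#' Reads a FASTA file of pre-aligned sequences and validates it into a
#' [dna_alignment()]. Sequence order is preserved, residues are uppercased,
#' and the record id is the first whitespace-delimited token of the header.
#'
#' @param path Path to a FASTA file of equal-length records.
#' @param locus_name Locus label attached to the alignment.
#' @return A `dna_alignment`.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path, locus_name) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty alignment: no FASTA records", call. = FALSE)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  dna_alignment(seqs, locus_name)
}

#' Write an alignment to FASTA
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(aln, path))` recovers
#' the identical alignment (ids, order, residues, gaps).
#'
#' @param aln A `dna_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "dna_alignment"))
  if (nrow(aln$seqs) == 0L) stop("empty alignment", call. = FALSE)
  set <- Biostrings::BStringSet(alignment_strings(aln))
  Biostrings::writeXStringSet(set, filepath = path, width = 80L)
  invisible(path)
}

# Species partition ------------------------------------------------------

#' Construct a specimen-to-species partition
#'
#' @param assignment Named character vector: names are specimen ids, values
#'   are species labels. Species order is first-appearance order.
#' @return An object of class `species_partition` with elements `assignment`
#'   and `species` (ordered unique labels).
#' @export
species_partition <- function(assignment) {
  stopifnot(is.character(assignment))
  ids <- names(assignment)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("specimen ids must be nonempty", call. = FALSE)
  if (any(!nzchar(assignment) | is.na(assignment)))
    stop("blank species label", call. = FALSE)
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)]
    for (d in dup) {
      if (length(unique(assignment[ids == d])) > 1L)
        stop(sprintf("specimen '%s' assigned to conflicting species", d),
             call. = FALSE)
    }
    assignment <- assignment[!duplicated(ids)]
    ids <- names(assignment)
  }
  structure(list(assignment = assignment,
                 species = unique(unname(assignment))),
            class = "species_partition")
}

#' @export
print.species_partition <- function(x, ...) {
  cnt <- table(factor(x$assignment, levels = x$species))
  cat(sprintf("<species_partition> %d specimens in %d species:\n",
              length(x$assignment), length(x$species)))
  for (s in x$species) cat(sprintf("  %s: %d\n", s, cnt[[s]]))
  invisible(x)
}

#' Specimens belonging to one species
#' @param part A `species_partition`.
#' @param species Species label.
#' @return Character vector of specimen ids.
#' @export
members_of <- function(part, species) {
  names(part$assignment)[part$assignment == species]
}

#' Read a specimen-to-species partition table
#'
#' Two-column TSV `specimen_id<TAB>species`; a header row is detected when the
#' first field is one of `specimen`, `specimen_id`, `id`, or `sample`
#' (case-insensitive).
#'
#' @param path Path to the TSV file.
#' @return A [species_partition()].
#' @export
read_partition <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tab <- read.table(path, sep = "\t", header = FALSE, colClasses = "character",
                    quote = "", comment.char = "")
  if (ncol(tab) < 2L) stop("partition table must have two columns", call. = FALSE)
  if (tolower(tab[1L, 1L]) %in% c("specimen", "specimen_id", "id", "sample"))
    tab <- tab[-1L, , drop = FALSE]
  if (nrow(tab) == 0L) stop("empty partition table", call. = FALSE)
  species_partition(setNames(tab[[2L]], tab[[1L]]))
}

# Region map -------------------------------------------------------------

#' Construct an alignment region map
#'
#' Named, non-overlapping intervals in 1-based inclusive alignment
#' coordinates, used to annotate diagnostic positions (e.g. ITS1 vs ITS2).
#'
#' @param region Character vector of region names.
#' @param start,end Integer vectors of 1-based inclusive bounds.
#' @return A `region_map` data frame with columns `region`, `start`, `end`,
#'   sorted by `start`.
#' @export
region_map <- function(region, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(region) == length(start), length(start) == length(end))
  if (length(region) == 0L) {
    rm <- data.frame(region = character(), start = integer(), end = integer())
    class(rm) <- c("region_map", "data.frame")
    return(rm)
  }
  if (any(start < 1L) || any(end < start))
    stop("region bounds must satisfy 1 <= start <= end", call. = FALSE)
  o <- order(start)
  region <- region[o]; start <- start[o]; end <- end[o]
  if (length(start) > 1L && any(start[-1L] <= end[-length(end)]))
    stop("regions overlap", call. = FALSE)
  rm <- data.frame(region = region, start = start, end = end,
                   stringsAsFactors = FALSE)
  class(rm) <- c("region_map", "data.frame")
  rm
}

#' Read a region map table
#'
#' Three-column TSV `region<TAB>start<TAB>end` (1-based inclusive); a header
#' row starting with `region` is skipped.
#'
#' @param path Path to the TSV file.
#' @return A [region_map()].
#' @export
read_region_map <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tab <- read.table(path, sep = "\t", header = FALSE, colClasses = "character",
                    quote = "", comment.char = "")
  if (ncol(tab) < 3L) stop("region map must have three columns", call. = FALSE)
  if (tolower(tab[1L, 1L]) == "region") tab <- tab[-1L, , drop = FALSE]
  region_map(tab[[1L]], as.integer(tab[[2L]]), as.integer(tab[[3L]]))
}

#' Annotate alignment positions with region names
#'
#' @param regions A [region_map()] or `NULL`.
#' @param positions Integer vector of 1-based alignment positions.
#' @return Character vector of region names; `"unassigned"` where no region
#'   covers the position (or `regions` is `NULL`/empty).
#' @export
assign_region <- function(regions, positions) {
  out <- rep("unassigned", length(positions))
  if (is.null(regions) || nrow(regions) == 0L) return(out)
  for (i in seq_len(nrow(regions))) {
    hit <- positions >= regions$start[i] & positions <= regions$end[i]
    out[hit] <- regions$region[i]
  }
  out
}
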