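# Independent brute-force oracles for character-based diagnosis. These scan
# every column / every column subset directly from the definitions, with no
# candidate pruning, and are used only to check the package's finders on
# small instances.

.ORACLE_AMB <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
.ORACLE_DET <- c("A", "C", "G", "T")

oracle_eligible_cols <- function(mat, gap_policy) {
  cols <- seq_len(ncol(mat))
  if (gap_policy == "exclude-column") {
    cols <- cols[vapply(cols, function(c) !any(mat[, c] == "-"), TRUE)]
  }
  cols
}

oracle_fixed_state <- function(mat, mem, c, gap_policy) {
  states <- unique(mat[mem, c])
  if (length(states) != 1L) return(NA_character_)
  s <- states
  ok <- s %in% .ORACLE_DET || (gap_policy == "fifth-state" && s == "-")
  if (!ok) return(NA_character_)
  s
}

oracle_could_match <- function(residues, s) {
  residues == s | (residues %in% .ORACLE_AMB & s != "-")
}

oracle_pure <- function(aln, part, gap_policy = "exclude-column") {
  mat <- aln$seqs
  res <- list()
  for (sp in part$species) {
    mem <- intersect(members_of(part, sp), rownames(mat))
    if (length(mem) == 0L) next
    oth <- setdiff(rownames(mat), mem)
    for (c in oracle_eligible_cols(mat, gap_policy)) {
      s <- oracle_fixed_state(mat, mem, c, gap_policy)
      if (is.na(s)) next
      if (!any(oracle_could_match(mat[oth, c], s))) {
        res[[length(res) + 1L]] <- data.frame(species = sp, position = c,
                                              state = s, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0L)
    return(data.frame(species = character(), position = integer(),
                      state = character(), stringsAsFactors = FALSE))
  do.call(rbind, res)
}

# All minimal-cardinality composite sets per species: enumerate every subset
# of the fixed, non-pure columns by increasing size and apply the definition
# (no single non-member could match all states simultaneously).
oracle_composites <- function(aln, part, max_size = 4L,
                              gap_policy = "exclude-column") {
  mat <- aln$seqs
  pure <- oracle_pure(aln, part, gap_policy)
  res <- list()
  for (sp in part$species) {
    mem <- intersect(members_of(part, sp), rownames(mat))
    if (length(mem) == 0L) next
    oth <- setdiff(rownames(mat), mem)
    cand <- c()
    states <- c()
    for (c in oracle_eligible_cols(mat, gap_policy)) {
      s <- oracle_fixed_state(mat, mem, c, gap_policy)
      if (is.na(s)) next
      if (any(pure$species == sp & pure$position == c)) next
      cand <- c(cand, c)
      states <- c(states, s)
    }
    if (length(cand) < 2L) next
    found <- FALSE
    for (m in 2:min(max_size, length(cand))) {
      if (found) break
      combos <- utils::combn(seq_along(cand), m)
      for (k in seq_len(ncol(combos))) {
        ix <- combos[, k]
        matches_all <- rep(TRUE, length(oth))
        for (t in ix) {
          matches_all <- matches_all & oracle_could_match(mat[oth, cand[t]], states[t])
        }
        if (!any(matches_all)) {
          res[[length(res) + 1L]] <- list(species = sp, positions = cand[ix],
                                          states = states[ix], size = m)
          found <- TRUE
        }
      }
    }
  }
  res
}

# Canonical string forms for set comparison.
pure_key <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  sort(sprintf("%s:%d:%s", df$species, df$position, df$state))
}

composite_key <- function(lst) {
  sort(vapply(lst, function(cd) {
    o <- order(cd$positions)
    sprintf("%s:%s", cd$species,
            paste(sprintf("%d%s", cd$positions[o], cd$states[o]), collapse = "+"))
  }, ""))
}

# Canonical topology key for comparing tree sets.
topo_key <- function(tree) paste(sort(names(tree_bipartitions(tree))), collapse = ";")

# Canonical key of the split side|rest, matching the package's convention
# (the side not holding the smallest label, sorted, pipe-joined).
bipartition_keys_for <- function(support, side, all_labels) {
  anchor <- min(all_labels)
  if (anchor %in% side) side <- setdiff(all_labels, side)
  paste(sort(side), collapse = "|")
}
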