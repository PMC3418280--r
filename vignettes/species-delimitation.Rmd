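---
title: "Methods: character-based diagnosis and divergence analysis for species delimitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: character-based diagnosis and divergence analysis for species delimitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spdelim)
```

## The problem

Sponges of the order Verongida (e.g. the genus *Aplysina*) lack mineral
spicules, so the morphological characters classical taxonomy relies on are few
and plastic. Molecular markers — the fast-evolving nuclear ITS1-5.8S-ITS2 rDNA
region and the mitochondrial COI barcode — carry most of the discriminating
signal, but at very low divergence (tenths of a percent between valid
species). At that scale, tree-based methods alone are fragile, and species
delimitation leans on several *independent* lines of molecular evidence:

1. **Quantitative divergence**: uncorrected pairwise p-distances between
   species exceed intraspecific variation.
2. **Character-based diagnosis** (Davis–Nixon characteristic attributes):
   individual alignment positions, or minimal combinations of positions, that
   separate a species from all others.
3. **Phylogenetic structure**: monophyly of each putative species in
   distance (NJ) and parsimony (MP) reconstructions, with bootstrap support.
4. **Population summaries**: haplotype diversity *h* and nucleotide diversity
   π, and the partitioning of variation into substitutions versus indels.

`spdelim` implements this workflow end to end, plus a synthetic-alignment
generator with planted truth so every stage can be validated without any
sequence download.

## Data model and conventions

All analyses operate on a `dna_alignment`: equal-length, uppercase, gapped
sequences over `{A,C,G,T,-}` plus IUPAC ambiguity codes, keyed by specimen id,
one object per locus. A `species_partition` assigns every specimen to exactly
one species; a `region_map` labels 1-based coordinate intervals (e.g. ITS1 vs
ITS2) for reporting. Every coordinate a user sees is 1-based and inclusive.

Two conventions hold everywhere:

* **Ambiguity codes (including `N`) are missing data.** They never count as a
  state in site classification, never contribute to distances, and are
  handled *conservatively* in diagnosis: a missing residue inside a species
  blocks fixation, and a missing residue outside it blocks exclusivity
  (because the unknown base could be the candidate state). This costs a
  little sensitivity and buys zero false diagnostics from incomplete data.
* **Gap policy is explicit.** The default for site classification and
  diagnosis is `exclude-column`: any column containing a gap is set aside
  (gapped columns carry alignment uncertainty, and in the motivating data all
  intraspecific variation is indel-borne, so nucleotide diagnostics should
  not depend on them). `fifth-state` treats the gap as an ordinary character
  for sensitivity analysis.

## Summary statistics

* **Haplotypes** are groups of identical sequences; `indel-aware` mode
  compares full gapped strings, `substitutions-only` first drops every column
  containing a gap, so indel-only variants collapse.
* **Haplotype diversity** is Nei's unbiased estimator
  $h = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)$.
* **Nucleotide diversity** π is the mean over unordered pairs of
  (differences / comparable sites); with the default `indels = "exclude"`,
  a gap at either sequence skips the site, so indel-only variation gives
  exactly π = 0.
* **Site classification**: a column is *variable* (segregating) when ≥ 2
  determinate states are observed and *parsimony-informative* when ≥ 2 states
  each occur in ≥ 2 sequences. Counts of
  invariant/variable/informative/gap-excluded/missing-excluded columns always
  sum to the alignment length.

## Divergence

The uncorrected p-distance between two aligned sequences is the proportion of
mismatches among sites where both residues are determinate. Pairwise deletion
(each pair uses its own comparable sites) is the default; complete deletion
(mask once, all pairs share the site set) is available because published
tables do not always state which was used — on the low-divergence data this
package targets the two differ negligibly. JC69
($d = -\tfrac34\ln(1-\tfrac43 p)$) and K2P corrections are provided; both
inflate the raw p, and on divergences below ~2% the inflation is far below
the printed precision, which is why the workflow reports plain p-distances.
Tables are printed lower-triangular in percent with 3 decimals, halves
rounded away from zero, mirroring the convention of published divergence
tables.

## Character-based diagnosis

A **pure diagnostic character** for species *S* is a position whose state is
fixed in every member of *S* and not possibly carried by any specimen outside
*S*. A **composite diagnostic combination** is a set of ≥ 2 positions, each
fixed in *S* but none diagnostic alone, such that no single outside specimen
possibly matches all of the member states simultaneously; reported sets are
of minimal cardinality.

The composite search exploits a set-cover structure: each candidate column
*excludes* the outside specimens that cannot carry the species state there,
and a set is diagnostic exactly when its columns jointly exclude every
outside specimen. Candidates are restricted to columns excluding at least one
outsider — a column every outsider matches can never appear in a minimal set
(removing it from any diagnostic set leaves a diagnostic set). The search
enumerates subsets by increasing cardinality and stops, per species, at the
first cardinality that succeeds, which makes every returned set minimal by
construction. `max_size` (default 6) caps the cardinality; a species with no
set up to the cap is reported `undiagnosable` within it. The default report
lists all sets at the minimal cardinality; note that a species with pure
diagnostics can also have composite sets (they are reported as additional
evidence, as is conventional).

Species sampled with a single specimen satisfy fixation trivially; the report
flags them as *provisionally diagnostic* rather than suppressing them,
because interspecific polymorphic sites in such data are provisional by
nature.

Correctness is checked two ways: against an independent brute-force
enumerator (all columns, all column subsets, straight from the definitions)
on 1,000 random alignments up to 8 × 8, and by planted-truth recovery on the
synthetic generator's output.

## Trees

**Neighbor-joining** follows Saitou–Nei agglomeration with the standard Q
criterion. Two deterministic choices are made explicit because they matter
for reproducibility on tie-rich low-divergence matrices: ties on Q are broken
by the lexicographically smallest pair of subtree labels, and negative branch
estimates are clamped to zero with the deficit moved to the sister edge (the
joined path length is preserved; topology is never affected). Consistency is
property-tested: NJ exactly recovers 100 random additive trees of 5–8 taxa
from their path-length matrices.

**Bootstrap** resamples columns with replacement, seeded and reproducible,
recomputes distance + NJ per replicate, and maps the percentage of replicates
containing each bipartition onto the full-data tree (not a consensus,
matching how support is usually displayed on a single published tree). A
replicate in which some pair loses all comparable sites is discarded and
counted, with a warning above 1% discarded.

**Parsimony** uses Fitch optimization (bitmask state sets; missing residues
carry the full state set, contributing no cost; ambiguity codes are mapped to
the full determinate set rather than their IUPAC subset, consistent with the
package-wide ambiguity-is-missing policy). Gaps default to missing data, the
common MP practice; `fifth-state` is optional. The exact **branch-and-bound**
search adds taxa in input order, pruning a partial tree as soon as its length
exceeds the best complete tree (ties are kept, so every optimal topology is
returned, deterministically ordered by canonical bipartition key). The search
is guarded to 4–15 taxa: beyond that, exact search is impractical and
heuristic searches are deliberately out of scope. Equivalence with exhaustive
enumeration is tested on 200 random ≤ 6-taxon instances against an
independent implementation (phangorn).

**Monophyly** on an unrooted tree means the taxon set (or its complement)
forms one side of a bipartition, i.e. the set is a clade under any rooting
outside it.

Newick I/O preserves topology, branch lengths (6 decimals), and supports as
internal node labels; labels containing metacharacters are single-quoted.

## The synthetic-data generator

`sim_spec()` + `simulate_alignments()` produce alignments with *known planted
truth*: a uniform random root per locus; per-species private substitutions at
positions sampled without replacement (so pairwise distances are exact counts
k/L, not expectations — each private substitution is a planted pure
diagnostic); optional composite-only plantings; and indel-only intraspecific
variation realized as insertion columns shared by a subset of carrier
specimens and gapped elsewhere. One global seed governs everything; per-locus
streams are derived by a stable string hash, and reruns are byte-identical.

Composite-only planting uses a blocker construction: the m member states are
each copied into a distinct blocker species minus one position, so no member
state is pure and every proper subset of the planted set is matched by some
blocker — the planted cardinality is provably minimal. This requires
m ≤ n_species − 2 (with fewer species, a blocker's background state would
itself become an accidental pure diagnostic); infeasible specs fail before
any file is written. Because other species' private substitutions also
exclude their own members, additional minimal sets of the same cardinality
can exist; truth is therefore asserted on the cardinality and on the planted
set being among those returned.

`aplysina_sim_spec()` packages the study conditions the package was built
around: three species with 6/4/5 specimens; an ITS-like locus with a 695-site
comparable backbone plus a 10-column insertion (705 columns total, the
published alignment length) and substitution counts 4/1/1 private to the
three species, giving pairwise distances of exactly 2/695 = 0.288% and
5/695 = 0.719% and four pure diagnostics for *A. gerardogreeni*; indel-only
variation in *A. clathrata* (two haplotypes, carriers 2 of 5, so h = 0.6 and
π = 0); and a COI-like 523-site locus whose single segregating site is
diagnostic for *A. revillagigedi*. On the published value h = 0.67: that
number corresponds to haplotype counts 2:1 over n = 3, while the specimen
table lists five *A. clathrata* individuals, under which two haplotypes give
h = 0.4 (4:1) or 0.6 (3:2). The generator follows the specimen table (n = 5,
3:2) and reports h as computed rather than forcing the printed value.

What the generator does **not** emulate: substitution-model realism (no
transition/transversion bias, no rate heterogeneity), intraspecific
substitution polymorphism, alignment error, or sequencing artifacts. Passing
the planted-truth tests therefore demonstrates the correctness of the
*computations*, not robustness to alignment-protocol choices — on real data,
counts of variable sites and tree lengths are sensitive to the aligner and
end-clipping rule, which is why the validation surface is built on planted
truth and on the published divergence matrix (shipped in
`inst/extdata/aplysina_its_pdist_percent.tsv`) rather than on re-aligned
sequences.

## Pipeline and reproducibility

`run_pipeline()` wires the stages (stats → distances → diagnosis → trees →
report) over a serializable `run_config`; outputs include per-stage TSVs,
newick trees, a per-species-pair markdown evidence report with explicit
supported / not-supported flags, the config itself, and a manifest of md5
content hashes. Re-running a config with the same seed reproduces every
hashed output byte-for-byte. The bootstrap seed is an explicit input — there
is no hidden RNG state, and library calls restore the caller's RNG.

Validation problem sizes (chosen to exercise each property thoroughly while
keeping the whole suite fast): 1,000 random ≤ 8 × 8 diagnosis instances
against the brute-force oracle; 100 random additive 5–8-taxon matrices for NJ
consistency; 200 random ≤ 6-taxon parsimony instances against exhaustive
search; 10 random planted-truth generator specs plus the packaged mimic spec;
bootstrap determinism and planted-clade recovery at 60–200 replicates.

## Known limitations

* Fixation is strict (every member must share the state): no frequency-based
  ("private allele") relaxation of the CAOS type.
* Composite search cost grows combinatorially with the number of informative
  candidate columns at higher cardinalities; `max_size` is the guard.
* No likelihood or Bayesian inference, no heuristic tree search, no
  composite-likelihood distances: distance and parsimony methods cover the
  delimitation evidence this workflow needs, and on data this shallow the
  topology is insensitive to the distance estimator.
* The pipeline consumes pre-aligned FASTA; alignment itself (and hence all
  alignment-protocol sensitivity) is upstream of the package.
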