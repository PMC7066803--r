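---
title: "Curating a duplicated gene family: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating a duplicated gene family: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famcurate)
```

# The problem

Teleost genomes carry roughly twice as many members of many gene families
as other vertebrates, the legacy of a whole-genome duplication at the base
of the teleosts (~350 Mya).  Databases name the resulting genes
inconsistently: some copies carry Greek-style symbols (`gja1`), some
protein-size symbols (`cx43`), some are `-like` names after a related (and
sometimes wrong) group, and some have no name at all.  famcurate implements
a curation pipeline for such a family — modelled throughout on the connexin
(gap junction protein) family across seven teleosts and mammalian
outgroups — with four stages:

1. **Consensus classification**: infer the orthologous groups by running a
   grid of phylogenetic analyses and keeping only relationships supported
   by a strict majority of them.
2. **Synteny**: separate ohnologs (duplicates from the genome duplication,
   on different chromosomes) from tandem duplicates (same chromosome) using
   chromosome co-occurrence across species.
3. **Nomenclature**: detect naming violations and propose standardized
   names under the amended Greek rules (`a`/`b` for ohnologs, `.1`/`.2`
   for tandems, no `-like`, unique per species).
4. **Assembly QC**: screen an assembly's gene complement against
   cross-species expectations and scan for breakpoints near missing genes.

A fully ground-truthed simulator of the family's evolution makes every
stage testable without any database access.

# Consensus classification

## The analysis grid

Conclusions rest on agreement across analyses, never on a single tree.
One analysis (`analysis_config()`) fixes a reconstruction method
(neighbor-joining, minimum evolution, or maximum parsimony), a data level
(translated conserved domains, or codon positions 1+2 of the nucleotide
alignment — third positions are saturated at teleost–mammal divergences), a
substitution model, and a site filter.  The default grid
(`default_grid()`) spans 21 such analyses, including a complete-deletion
(coverage 1.0) wing next to the default partial deletion at 95% site
coverage.

Distance models are the p-distance, Poisson correction, Jukes–Cantor, and
maximum-likelihood pairwise distances under the Dayhoff and JTT empirical
amino-acid matrices (computed by `phangorn::dist.ml`).  Saturated entries
(`p >= 0.75` for Jukes–Cantor) are flagged rather than silently truncated,
and tree building refuses saturated matrices by naming the offending pairs.

## Trees

`build_nj()` is the Saitou–Nei agglomeration with the Q-criterion.  Ties
in Q are broken by the lexicographically smallest pair of cluster labels
(each cluster labelled by its smallest leaf id), so results are
reproducible to the byte.  Negative branch lengths are clamped to zero.

`search_me()` minimizes the ordinary-least-squares tree length: OLS branch
lengths are fitted on the path-indicator design matrix (`ols_fit()`,
negatives clamped after fitting), and the topology is improved by
first-improving nearest-neighbor-interchange moves in a fixed traversal
order until a local optimum.  `search_mp()` does the same for the Fitch
parsimony score, with gaps treated as missing.  On small taxon sets
(<= 12) the parsimony landscape is proportionally rugged, so the climb is
repeated from a few seeded random starts and the best optimum kept; large
alignments carry enough signal for the single NJ-start climb.

All tree reasoning is unrooted: a *clan* is one side of an edge, and two
sets form a *dichotomy* when each set and their union are clans (i.e. the
sets are sisters).  Bootstrap support (`bootstrap_support()`) resamples
alignment columns with replacement under an explicit seed and scores each
bipartition of the point tree by the percentage of replicate trees
containing it.

## Reading groups off the trees

`tally()` counts, for each clan or dichotomy query, the number of analyses
whose tree satisfies it; a relationship is *robust* when a strict majority
(k/n > 0.5) supports it.  14 of 21 analyses is robust; 10 of 20 is not.

`assign_orthogroups()` reads group membership off each tree the way a
curator does.  Every focal (teleost) gene `g` has a maximal reference-free
clan M(g) — the largest clan containing `g` but no mammalian reference
gene.  The gene votes for reference group R when M(g) and R together form
a clan, i.e. the gene's teleost context is the sister of that mammalian
group.  A lone gene (M(g) = {g}) that attaches at the root of a group's
clade instead falls back to the smallest enclosing clan holding exactly
one reference group: a single rogue is read as a group member, while a
multi-species teleost clade in the same position is treated as potentially
novel.  Analyses whose tree does not resolve a gene's attachment abstain;
the final label is the majority (> 0.5) of the cast votes, with a
two-vote quorum.  Genes that never attach to any reference are clustered
into teleost-only
groups (two genes share a novel group when they fall in the same
reference-free clan in more than half of the trees); genes with split
votes stay unassigned.  Known long-branch-attraction taxa are removed via
a configured exclusion list (`excluded_ids`), never auto-detected.

With a single reference group no discrimination between "member" and
"novel sister group" is possible within one tree; at least two reference
groups are assumed.

# Synteny: ohnologs versus tandems

`classify_duplicates()` classifies the duplicates of one orthologous group
within one species: copies on one chromosome (at any distance) are tandem
duplicates; copies on two chromosomes are candidate ohnologs, confirmed
when (i) at least one other orthologous group spans the same chromosome
pair in that species, or (ii) the group has two-chromosome duplicate pairs
in at least two other species.  These thresholds reproduce the printed
worked examples, including ohnolog pairs sitting on "unexpected"
chromosomes that only cross-species evidence confirms.  Unplaced scaffolds
never confirm or refute a pairing; they propagate as `unplaced`, and an
unplaced partner makes the call ambiguous rather than wrong.

`cooccurrence_groups()` anchors on one species (eel, as the earliest
diverging lineage, in the shipped table) and reports, per anchor
chromosome, the resident groups and the plurality chromosome per other
species; `pairing_consistency()` scores each anchor chromosome's modal
partner chromosome and lists the deviating groups.

The package ships the curated connexin locus table
(`inst/extdata/table2_loci.tsv`) in a wide format: one row per ohnolog
copy slot, slash-joined cells for tandem multiplets, `?` for unplaced.

# Nomenclature

`name_system()` classifies a symbol's system from its shape alone:
`gj[a-e]N` Greek, `cxN(.N)` size, `CXN..` alphabetic, joined Greek–size
mixed, trailing `like`, or none.  Comparisons are case-insensitive;
rendering is styled (mammalian symbols upper-case, teleost lower-case).

`detect_inconsistencies()` reports six violation classes: mixed systems
within one group, different names for evident orthologs, identical names
across distinct groups, `-like` names, names whose own group (via the
translation table) contradicts the assigned group, and non-unique names
within a species.  Wrong size-style names are only detectable through
collisions, since a bare kDa value does not identify a group.

`suggest_names()` proposes standardized names: the mammalian counterpart's
Greek symbol lowercased; `a`/`b` for confirmed ohnolog pairs (`a` to the
copy on the smaller anchor chromosome label — the tie-break is arbitrary
but deterministic and recorded in the rationale); `.1`/`.2` for tandem
pairs by ascending coordinate; table-amended symbols for known
teleost-only groups; and the lowest unoccupied subfamily integer for new
groups, always skipping `gja7` (historically used for Cx45).  No proposal
ever contains `like`, and proposals are unique within each species.

`motif_class()` reports the cysteine spacing of the second
extracellular-loop segment (`C-x(4)-C-x(5)-C` family-wide,
`C-x(5)-C-x(5)-C` as the GJB3 hallmark).  The exact loop boundaries are
taken from the caller's second conserved domain.

# Assembly QC

`expected_complement()` sets the expected copy number of each group in a
target assembly to the mode across the other species/assemblies (ties
resolve to the maximum and are flagged low-confidence).  `find_missing()`
reports each shortfall with the chromosomes where the gene was expected,
read from the synteny matrix.  Presence/absence is taken from the gene
sets given per assembly; homology search against raw assemblies is out of
scope.  Note that real biological loss also produces shortfalls — the
report lists candidates for inspection, not verdicts.

`scan_duplicates()` groups same-species records with CDS identity at or
above a threshold (default 0.99, covering "identical" and "nearly
identical" artifact duplicates); a group is a likely artifact when copies
share a scaffold or another assembly collapses them.  True ohnologs, at
roughly 15–25% divergence, sit far below the threshold.

`anchor_dotplot()` finds exact shared substrings of at least `word_size`
nucleotides (default 256) on both strands by word seeding at `word_size`
step with same-diagonal merging, chains collinear runs, and reports breaks
(query gaps above `gap_threshold`, default 10 kb at chromosome scale) and
inversions (reverse-orientation chains).  Events intersecting an expected
gene window set the report's flag.  Word seeding at step `word_size` can
miss shared regions shorter than twice the word size; at the chromosome
scales screened here that is immaterial.

# The simulator

`simulate_family()` evolves an ancestral gene complement along a fixed
teleost + mammal species tree with divergence times (Mya): teleost–mammal
split 430, whole-genome duplication on the teleost stem 350, eel 300,
herring/zebrafish ancestor 250 then 240, acanthomorphs 150, stickleback
100, pufferfishes 70, human–opossum 160.  Times only scale branch lengths.

Defaults are chosen as the study conditions of the family being emulated:

* 20 ancestral genes on 12 chromosomes (doubled by the duplication to a
  teleost-scale karyotype; the chromosome pairing is the ground-truth
  ohnology);
* per-lineage loss probability 0.2 for each duplicated copy, applied once
  per terminal branch — the high-retention regime this family shows;
  phylogenetically shared early losses are *not* modelled;
* tandem duplication probability 0.1 per gene per branch segment;
* rearrangement probability 0.05 per gene per terminal lineage, moving the
  gene together with its tandem co-copies (relocations are segmental);
* Jukes–Cantor substitutions at 3e-4 substitutions/site/My inside the two
  conserved domains (~0.26 between teleosts and mammals) and 3x that
  outside; codons mutating into stops are reverted, a cheap proxy for
  purifying selection;
* the ancestral paralogs derive from one family ancestor at a 700-My
  radiation depth, so the whole family stays alignable like a real
  conserved-domain set;
* conserved domains of 270 and 300 nt on a 660-nt CDS: with the 15-nt
  extensions, 200 aligned codons — the scale of the real conserved-domain
  alignments.  Substitutions only: the emitted domains are positionally
  homologous and `domain_alignment()` returns them as a gapless codon
  alignment, so alignment construction and alignment error are outside the
  simulator's scope;
* database-style naming noise: 35% Greek, 35% size, 20% `-like`, 10%
  unnamed, with a 5% wrong-group rate, all recorded in the ground truth.

`inject_misassembly()` adds assembly errors on top: deletions (removed
from the assembly view, retained in truth), segmental duplications
(near-identical copies at 0.2% divergence on the same scaffold), and
inversions of a gene-containing interval (asymmetric around the gene, so
coordinates demonstrably move).  `emit_chromosome()` renders a chromosome
as seeded background sequence with the resident CDSs written in, and
`invert_interval()` applies an inversion at sequence level for dot-plot
round trips.

What passing tests on simulated data do **not** show: robustness to
alignment error or indels, to rate heterogeneity beyond the domain/spacer
split, to incomplete lineage sorting, or to real database label
formatting.  The simulator's purpose is exact bookkeeping — every gene's
orthogroup, ohnolog partner, tandem set, true name and injected event is
known — so that classification, synteny, nomenclature and QC logic can be
scored against truth.

# Numerical and interface conventions

* Coordinates are 0-based half-open internally; locus tables are read and
  written 1-based inclusive, and reverse-strand rows given as
  `start > end` are normalized to `start < end` with strand `-`.
  Zero-length loci are rejected with the offending row named.
* Distance ties in NJ, move order in the NNI searches, and the `a`/`b`
  ohnolog assignment are all deterministic; every stochastic step
  (bootstrap, simulator, parsimony restarts) takes an explicit integer
  seed.
* Percent identities are computed at full precision and rounded to two
  decimals only at the reporting surface.  Pairwise comparisons ignore
  columns where either row has a gap or ambiguity.
* OLS fits use the pivoted QR in `lm.fit`; rank-deficient designs warn and
  zero the unresolved branches.

# Experiment sizes

The parameter-recovery experiments reported by `scripts/acceptance.R` and
the test suite use 10 seeded replicates of a 6-group family (~95 genes
across 9 species) analyzed under a 7-cell grid (five NJ variants and both
parsimony levels), a scale chosen so the full suite completes on one CPU
in minutes while exercising every pipeline stage; the 21-cell default grid
is exercised end-to-end on a 12-taxon family and in the grid tests.  The
missing-gene experiments use 10 replicates with 5 injected deletions each,
scored on genes with unambiguous expected counts.

# Known limitations

* Maximum-likelihood tree inference and interior-branch tests are not
  implemented; the grid spans NJ/ME/MP variants and bootstrap is the only
  support measure.
* `search_me()` refits OLS per candidate move, which is comfortable to a
  few hundred taxa but not beyond; the recovery grid therefore leans on NJ
  and MP at family scale.
* Orthogroup assignment assumes at least two mammalian reference groups
  and majority-quality trees; a clade misplaced in most analyses will be
  mis-assigned — by design, since the pipeline reports what the analyses
  collectively support.
* The missing-gene screen cannot separate biological loss from assembly
  error on its own; corroborating assemblies and the breakpoint scan exist
  for exactly that reason.
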