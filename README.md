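# famcurate

Curation tools for duplicated vertebrate gene families, built around the
connexin (gap junction protein) family in teleosts and mammals.

Teleost genomes retain many extra gene copies from the whole-genome
duplication at the base of the teleosts (~350 Mya), and public databases
name those copies chaotically: Greek symbols (`gja1`), protein-size
symbols (`cx43`), `-like` names after related (sometimes wrong) groups,
or no name at all.  famcurate is for curators and comparative genomicists
who need to turn such a family into a clean set of orthologous groups
with consistent names, and to use the family as a probe of assembly
quality.

## What it computes

* **Consensus classification.**  Trees are inferred under a grid of
  analyses — neighbor-joining, minimum evolution (OLS tree length with
  NNI search) and maximum parsimony, at amino-acid and codon-position-1+2
  levels, under p/Poisson/Jukes–Cantor distances and ML distances under
  the Dayhoff and JTT matrices, with partial deletion at 95% site
  coverage — and a relationship (clan or sister dichotomy in the unrooted
  sense) is deemed robust only when a strict majority of analyses
  supports it (k/n > 0.5; 14 of 21 is robust, 10 of 20 is not).
  Orthologous groups are read off each tree as teleost clans sister to a
  mammalian reference group, with a cross-analysis majority vote.
* **Ohnologs versus tandems.**  Within-species duplicates on one
  chromosome are tandem (`.1`/`.2` naming); duplicates on two chromosomes
  are ohnologs (`a`/`b` naming) when corroborated by a co-resident group
  spanning the same chromosome pair or by the same two-chromosome pattern
  in at least two other species.
* **Nomenclature harmonization.**  Detection of mixed naming systems,
  duplicate and wrong-group names, and standardized proposals under the
  amended Greek rules (never `-like`, never the reserved `gja7`, unique
  per species).
* **Assembly QC.**  Expected per-group copy counts as the cross-species
  mode, missing-gene reports with expected chromosomes, near-identical
  duplicate (artifact) scanning, and an exact-match dot plot (word size
  256) that calls breaks and inversions near expected gene positions.
* **Simulation.**  A seeded gene-family evolution simulator (species tree
  with realistic divergence times, whole-genome duplication, loss, tandem
  duplication, segmental rearrangement, two conserved domains, naming
  noise, misassembly injection) with complete ground truth.

See `vignettes/famcurate-methods.Rmd` for the models, parameter meanings
and design decisions.

## Worked example

The package ships the curated connexin locus table (one row per ohnolog
copy slot, one column per species).  Anchoring on eel (`Aj`), the most
connexin-rich chromosome is recovered with its conserved cross-species
co-occurrence, and the ohnolog pairing of eel chromosome 7 shows the two
deviating pairs:

```r
library(famcurate)
lm2 <- read_locus_matrix(system.file("extdata", "table2_loci.tsv",
                                     package = "famcurate"))
co <- cooccurrence_groups(lm2, "Aj")
co[["19"]]$orthogroups
#> [1] "cx28.9" "cx32.2" "cx34.5" "gja1"   "gja10"  "gjb7"   "gjd2*1" "gje1"
subset(co[["19"]]$species, species %in% c("Dr", "Ga"))
#>   species plurality_chr n_on_plurality deviating
#> 2      Dr            20              8
#> 4      Ga            18              8

pc <- pairing_consistency(lm2)
subset(pc, species == "Aj" & anchor_chr == "7")
#>   species anchor_chr partner_chr n_pairs n_consistent     score   deviating
#> 5      Aj          7           4       6            4 0.6666667 gja1,gjd2*1

classify_duplicates(lm2, "cx30.3", "Tn", copy = "A")$class
#> [1] "tandem"
```

Eight connexin genes sit on eel linkage group 19, and the same eight
co-occur on zebrafish chromosome 20 and stickleback chromosome 18.  On
eel chromosome 7, four of the six placed ohnolog pairs point to
chromosome 4; `gja1` and `gjd2*1` deviate (their partners sit on
chromosome 19), and the green spotted pufferfish `cx30.3` triplet on
chromosome 2 is a tandem multiplet.

Screening the herring chromosome-level complement against the
cross-species expectation reports exactly the three lost genes:

```r
exp_ch <- expected_complement(lm2, "Ch")
ch <- subset(lm2, species == "Ch")
drop <- ch$orthogroup == "gjb7" |
  (ch$orthogroup == "gja9" & ch$copy == "B") |
  (ch$orthogroup == "gjb1" & ch$copy == "B")
find_missing(ch[!drop, ], exp_ch, lm2)
#>   orthogroup expected observed expected_chr     corroborating
#> 1       gja9        2        1         7,10 Aj,Dr,Gm,Ga,Fr,Tn
#> 2       gjb1        2        1        14,15 Aj,Dr,Gm,Ga,Fr,Tn
#> 3       gjb7        1        0        14,15 Aj,Dr,Gm,Ga,Fr,Tn
```

The `gjb7` shortfall points at chromosomes 14/15 — the region where the
dot-plot scan (`anchor_dotplot()`, word size 256) is then used to look
for breaks and inversions.

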