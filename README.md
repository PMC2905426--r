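# karyophy

Chromosomal phylogenies from cross-species chromosome painting.

## What this is for

Comparative cytogeneticists map karyotype evolution by hybridizing
whole-chromosome paint probes of one species onto metaphases of another
(ZOO-FISH). Each contiguous painted block is a *hybridization signal*; a
target chromosome carrying material of two or more probe chromosomes is a
*syntenic association* (written `3/20/15/14`). Differences between
species' homology maps reflect rearrangements — centric fusions and
fissions, pericentric and paracentric inversions, tandem fusions,
Y-autosome translocations — and the presence/absence of discrete
chromosome forms can be coded as binary characters and analysed
cladistically.

karyophy takes plain-text homology-map tables and produces the full
downstream analysis:

1. **Synteny analysis** — signal counts per haploid set, conserved-synteny
   classes (`WHOLE` / `ASSOCIATED` / `SPLIT`), association detection, and
   matching against a catalogue of ancestral-karyotype associations.
2. **Character coding** — binary (0/1/?) matrices from per-taxon form
   observations, with NEXUS and TSV serialization.
3. **Maximum parsimony** — Fitch small parsimony with exhaustive
   enumeration of all (2n−5)!! unrooted binary topologies, tree length s,
   minimum m, maximum g, and the indices CI = m/s, RI = (g−s)/(g−m),
   HI = 1−CI; outgroup rooting; character bootstrap with majority-rule
   consensus; Newick I/O.
4. **Simulation** — binary characters evolved by per-branch flips and
   karyotypes evolved by typed rearrangement events on a known tree, for
   end-to-end topology-recovery experiments.

The packaged fixtures transcribe the three published painting experiments
for the saki-uakari monkeys (Pitheciinae): human probes on *Pithecia
irrorata* (PIR) and on *Cacajao calvus rubicundus* (CCR), and *Saguinus
oedipus* probes on CCR, plus a documented partial reconstruction for
*Chiropotes utahicki* (CUT) and a reconstructed 5-taxon character matrix
with *Brachyteles arachnoides* (BAR) and *Cebus apella* (CAP) as
outgroups.

## A worked example

```r
library(karyophy)
maps <- load_painting_maps()

count_signals(maps$hsa_pir)
#> 32 autosomal signals per haploid set (33 incl. sex probes)

detect_associations(maps$hsa_ccr)
#> 9 syntenic association(s)
#>   chromosome 1: 3/20/15/14
#>   chromosome 2: 3/5
#>   chromosome 3: 8/18
#>   chromosome 4: 16/10/16/10
#>   chromosome 5: 16/2
#>   chromosome 6: 1/12
#>   chromosome 7: 10/2
#>   chromosome 19: 3/21
#>   chromosome 21: 5/7
#> sex-linked composite(s): 11/Y (Y)

fx <- pitheciinae_matrix()
exhaustive_search(fx)
#> exhaustive search: 15 topologies examined, 1 MP tree(s) of length 17
#> length s = 17 (m = 15, g = 24)
#> CI = 0.882  RI = 0.778  HI = 0.118

res <- exhaustive_search(fx)
write_newick(root_with_outgroup(res$mp_trees[[1]], c("BAR", "CAP")))
#> [1] "(((CCR,CUT),PIR),(BAR,CAP));"
```

Reading the output: human probes give 32 signals per haploid PIR set; CCR
chromosome 1 is the fusion product 3/20/15/14 and chromosome 4 carries the
alternating 16/10/16/10 pattern left by a pericentric inversion of the
ancestral 10a/16a association; the composite Y carries the human-11
homologue (the Y-autosome translocation behind CCR's X1X2Y sex system).
The single most parsimonious tree over all 15 possible topologies places
CCR and CUT as sister taxa with PIR basal in the ingroup, rooted on the
outgroup pair.

A thin command-line front end with subcommands (`count`, `associations`,
`matrix`, `search`, `bootstrap`, `simulate`, `pipeline`) lives at

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/karyophy-cli.R", package="karyophy"))')" \
  count --map inst/extdata/hsa_pir.tsv
```

and `run_pipeline()` orchestrates the whole analysis into an output
directory (synteny reports, matrix as NEXUS/TSV, MP trees, statistics,
bootstrap table, rooted annotated tree, run log).

## Vignette

`vignettes/chromosome-painting-phylogeny.Rmd` documents the model, the
table-qualifier grammar that reconstructs within-chromosome segment
order, the character-coding conventions, the engine's numerical choices,
what the simulator does and does not emulate, and known limitations.
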