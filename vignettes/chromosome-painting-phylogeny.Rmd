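---
title: "From chromosome painting homology maps to a chromosomal phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From chromosome painting homology maps to a chromosomal phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyophy)
```

## The problem

Cross-species chromosome painting (ZOO-FISH) hybridizes fluorescently
labelled whole-chromosome probes of one species onto metaphase spreads of
another. Each contiguous painted block — a *hybridization signal* — marks a
chromosomal segment homologous to the probe chromosome. Tabulating the
signals per target chromosome gives a *homology map*, and comparing
homology maps across species reveals the rearrangements (centric fusions
and fissions, pericentric and paracentric inversions, tandem fusions,
sex-autosome translocations) that separate their karyotypes. Coding the
presence or absence of discrete chromosome forms as binary characters then
allows an explicit cladistic analysis: a maximum-parsimony tree over the
sampled taxa, rooted with outgroups.

karyophy implements this route end to end for the saki-uakari monkeys
(Pitheciinae: *Pithecia irrorata*, PIR; *Cacajao calvus rubicundus*, CCR;
*Chiropotes utahicki*, CUT), whose three published painting experiments —
human (HSA) probes on PIR and on CCR, and *Saguinus oedipus* (SOE) probes
on CCR — ship as plain-text fixtures. Everything downstream of the wet lab
is computed by the package: signal counts, conserved-synteny classes,
syntenic associations, ancestral-karyotype matching, binary coding,
exhaustive-search Fitch parsimony with tree statistics and bootstrap.

## The homology-map model

A map stores, per target chromosome, an ordered list of probe segments.
The counting unit is the signal: a probe chromosome split over three
target chromosomes contributes three signals; a probe that paints one
entire chromosome contributes one. Two modelling rules matter and both are
forced by internal consistency of the source tables:

* **One table cell, one signal.** A location with a compound positional
  qualifier such as "proximal q + p" describes a single contiguous block.
  Only under this rule do the published haploid totals (32 for HSA on PIR,
  33 for HSA on CCR, 28 for SOE on CCR) reconcile with the row-by-row
  content of the homology table.
* **The X is excluded from autosomal totals**, while a segment of an
  autosomal probe translocated onto the Y (the Y-autosome composite in
  CCR, which makes the male diploid number 45 against the female 46 and
  creates an X1X2Y multiple sex system) counts as one autosomal-probe
  signal. Again, only this convention reproduces all three printed totals.

Positional qualifiers carry the within-chromosome order. The package maps
cytological regions to ranks along the chromosome
(pter → qter: `distal p < p < proximal p < proximal q < q < distal q`),
treats `A + B` as one block (mean rank) and `A- B` as one probe occupying
two separate regions (two ordered tokens). This grammar alone reconstructs
the printed four-token association 3/20/15/14 on CCR chromosome 1 and the
alternating 16/10/16/10 pattern — the product of a pericentric inversion
of the ancestral 10a/16a association — from the bare table qualifiers.
Segments without qualifiers keep table order and sort before ranked
material; no order-dependent inference is made beyond what the qualifiers
state.

## Syntenies, associations and ancestral matching

`classify_synteny()` assigns each autosomal probe one class: `WHOLE`
(single signal painting an entire chromosome), `ASSOCIATED` (single
signal on a chromosome shared with other probes' material), or `SPLIT`
(two or more signals). `detect_associations()` returns every target
chromosome carrying at least two probe tokens. `match_ancestral()`
compares detected associations against a catalogue of ancestral forms —
by default the six human-homologous associations of the inferred
ancestral Platyrrhini karyotype (3a/21, 5/7a, 2b/16b, 8a/18, 14/15a,
10a/16a) — using order-insensitive token multiset containment, with
sub-segment letters compared only when both sides carry one. That
leniency is deliberate: the inverted 16/10/16/10 form still contains the
ancestral 10a/16a association, and published labels alternate freely
between e.g. 15/14 and 14/15a.

One reporting decision deserves explanation. For CCR the source reports
*all nine* association-bearing chromosomes (including derived products
such as 1/12 and 3/5), but for PIR it reports only the *six* chromosomes
whose associations correspond to ancestral Platyrrhini forms, although
PIR too carries nine association-bearing chromosomes (the extra three are
2/10, 13/22 and 1b/15b, each accounted for elsewhere as a derived or
retained form). `detect_associations()` therefore always returns the
complete set, and the package reproduces the published six-item PIR list
as the ancestral-matching subset, which the synteny report annotates
explicitly. No option silently drops associations.

## Character coding

`build_matrix()` turns (taxon, form, state) observations into a binary
matrix over `{0, 1, ?}`: 1 for presence of a chromosome form or
rearrangement, 0 for absence, `?` for unobserved pairs (a `missing_state`
policy of `"0"` is available for simulation pipelines where absence of
evidence is absence). Columns are sorted by form label so the result is
deterministic; contradictory duplicate observations are an error naming
the taxon and form.

`pitheciinae_matrix()` is a documented 21-character reconstruction over
PIR, CCR, CUT and the outgroups *Brachyteles arachnoides* (BAR) and
*Cebus apella* (CAP). Its columns encode the subfamily-wide shared
derived forms (fusion 2a/10b, acrocentric 15/14, acrocentric 19, and the
16a/10a/16a/10a inversion shared with *Callicebus*); three CCR+CUT shared
derived forms (the 5a1/5a2 fission, the 20/15/14 fusion, and the derived
acrocentric state of the 5/7a association); two PIR+CCR shared derived
forms (acrocentric 7b, acrocentric 12); six ancestral-association
retention characters; and per-taxon autapomorphies, each column citing
its source note. The original supplementary matrix behind the published
analysis (about 44 characters, 45 steps) is not deposited anywhere
machine-readable, so this fixture is a reconstruction and is labelled as
such; when the true file is available it is read through `from_nexus()`
or `read_matrix_tsv()` and analysed identically.

Outgroup coding follows the standard cladistic convention and is
switchable (`outgroup_policy`): `"ancestral"` codes outgroups 0 for
ingroup-derived forms and 1 for ancestral retention characters;
`"unknown"` codes them `?`, which leaves rooting entirely to the user.

## The parsimony engine

Characters are unordered and binary; `?` is treated as the full state set
in the Fitch bottom-up pass, so missing data never costs a step (the
behaviour of standard parsimony software). The score is computed by
sequential pairwise union/intersection folding in postorder; folding the
basal trifurcation of an unrooted tree equals rooting on its third edge,
so scores are exactly rooting-invariant (this is asserted against a
brute-force enumeration of all internal labelings in the tests).

`exhaustive_search()` enumerates *all* (2n−5)!! unrooted binary
topologies by stepwise leaf addition over every edge — each topology
produced exactly once — and returns every tree attaining the minimum
length. Enumeration refuses above a cap of 10 taxa
((2·10−5)!! = 2,027,025); heuristic search is deliberately out of scope,
as the target analyses have 15 topologies. Tree statistics follow the
standard definitions over **all** characters, including
parsimony-uninformative autapomorphies (again matching common software
defaults, and the only convention consistent with a consistency index of
0.978 at 45 steps): m = Σ(observed states − 1), g = Σ min(n₀, n₁),
CI = m/s, RI = (g−s)/(g−m), HI = 1−CI. RI is undefined (reported `NA`
with a warning) when g = m while s > m. Printed indices are rounded
half-up to three decimals; a tree of length m has CI = RI = 1 by
convention, including the degenerate all-constant case s = 0.

Bootstrap replicates resample characters with replacement (same count);
each replicate's MP trees contribute fractionally (1/k for k ties) to
bipartition tallies, an unbiased treatment of ties. All resampling
indices are drawn up front from one generator seeded by the single
`seed` argument, so support tables are bit-reproducible.
`majority_rule_consensus()` retains bipartitions with frequency strictly
above the threshold (≥ 0.5, hence pairwise compatible) and assembles the
laminar cluster family directly. Outgroup rooting places the root on the
edge realizing the outgroup bipartition; a non-monophyletic outgroup
triggers a warning and rooting on the best-separating edge.

## What the simulator emulates — and what it does not

`simulate_characters()` evolves each character independently down a known
tree with a symmetric per-branch flip probability p ∈ [0, 0.5) — a
probability per branch, not a rate; this is the simplest process that
exercises homoplasy (reversals and convergence arise naturally) and is
sufficient for recovery testing. `simulate_karyotype_evolution()` applies
Poisson-many typed rearrangement events per branch to a 22-autosome
ancestral karyotype embedding the six catalogue associations (a package
construction, not a scientific claim). Every event permutes segments but
never creates or destroys them, so each leaf karyotype carries exactly
the ancestral segment alphabet — an invariant asserted after every event.
Operand choice is uniform over applicable operands with up to ten
resamples before a draw is skipped and logged.

The simulator does **not** model breakpoint reuse, inversion sizes in
physical coordinates, chromatin context, or realistic event rates, and
leaf maps are expressed against the ancestral segment alphabet rather
than a third-species probe set. Passing recovery tests therefore shows
that the inference machinery is correct and well-behaved under the
assumed generating process, not that real karyotype evolution satisfies
those assumptions.

`recovery_experiment()` defines a run as *recovered* when the generating
topology is the unique MP tree. For character simulations it draws
parsimony-informative characters (rejection sampling per character):
constant columns and autapomorphies carry no topological signal, so an
unconditioned draw at small p mostly measures how often no informative
character hit an internal branch rather than anything about the engine —
with 30 unconditioned characters at p = 0.05 on five taxa, an internal
edge is left without support in roughly a third of runs. Conditioning on
informativeness mirrors the practice of scoring support only over
variable sites. For karyotype simulations, leaves are coded by the
association forms their chromosomes carry (`detect_associations()` +
`build_matrix()` with absence coded 0), the same route a comparative
cytogeneticist takes from painting data.

## Problem sizes and numerical choices

The test suite and the acceptance script run, by design, at these sizes:
exhaustive searches on 5 taxa (15 topologies); Fitch-versus-brute-force
oracle sweeps over 200 random instances of up to 6 taxa and 10 characters
(the oracle enumerates at most 2⁴ internal labelings per character);
enumeration count checks up to 8 taxa (10,395 topologies); 500 bootstrap
replicates on the 21-character fixture; 200 seeded recovery runs at 30
informative characters and p = 0.05; and 100 + 100 karyotype-simulation
runs at 2 versus 8 events per branch for the saturation contrast. Seeds
are fixed integers throughout; every stochastic function takes a `seed`
argument and derives per-run substreams as `seed + run`.

Ties and degenerate inputs: equal-length trees are all returned (no
arbitrary winner); an all-constant matrix ties all topologies at zero
steps; maps with no chromosomes serialize to a header-only table; an
empty association list matches nothing; a map declaring an autosome with
no probe material fails validation rather than silently passing.

## Known limitations

* The within-chromosome segment order is only as good as the positional
  qualifiers in the source table; where a table gives none, order is
  table order and should not be over-interpreted.
* The character fixture is a reconstruction; its tree statistics
  (length 17, CI 0.882 on 21 characters) are not the published 45-step
  figures, which belong to the original ~44-character supplementary
  matrix. The published indices are reproduced exactly by the index
  formulas at the published step counts (CI(45, 44) = 0.978,
  RI(45, 44, 55) = 0.909, HI = 0.022), and the fixture reproduces the
  published topology and its qualitative support structure.
* Exhaustive search is exponential by construction; above ten taxa the
  package refuses rather than silently switching strategy.
* Bootstrap support values on 21 characters are coarse (resolution
  1/500 with the default replicate count used in the acceptance run).

## A worked five-minute session

```{r example, eval = FALSE}
maps <- load_painting_maps()
count_signals(maps$hsa_pir)            # 32 autosomal signals
classify_synteny(maps$hsa_ccr)         # 8 WHOLE + 5 ASSOCIATED + 9 SPLIT
detect_associations(maps$hsa_ccr)      # 9 associations incl. 3/20/15/14
match_ancestral(detect_associations(maps$hsa_pir),
                ancestral_platyrrhini_catalogue())

fx <- pitheciinae_matrix()
res <- exhaustive_search(fx)           # 15 topologies, 1 MP tree
root_with_outgroup(res$mp_trees[[1]], c("BAR", "CAP"))
bootstrap_support(fx, n_replicates = 500, seed = 1)
```
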