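---
title: "Inferring reticulate origins in an apogamous fern complex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring reticulate origins in an apogamous fern complex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reticulator)
```

## The inference problem

An apogamous fern lineage is a clone: sporophytes develop without
fertilization, so the genotype fixed at the lineage's founding
hybridization is transmitted unchanged, heterozygosity and all. A species
complex of such lineages — like the *Pteris cadieri* complex treated
throughout this package — is therefore a static record of the crosses
that created it. Three data layers expose that record: ploidy (flow
cytometry), the biparental nuclear genome (cloned sequences of a
single-copy gene, *PgiC*-like), and the maternal chloroplast genome
(haplotype sequences). The reconstruction problem is to explain every
observed (morph, cytotype) taxon as the product of one cross among a
minimal set of parents.

## Ploidy and reproduction calls

The cytometry model is deliberately minimal. A histogram carries two G1
peaks — the co-run calibration standard (*N. tabacum* 4X, 20.08 pg) and
the sample. Peaks are found on a moving-average smooth (default window 5
bins) as local maxima whose *prominence* — height above the higher of the
two valley minima on the paths to higher terrain — exceeds a fraction of
the histogram maximum (default 0.10). Prominence rather than raw height
suppresses shoulder noise without suppressing a genuinely smaller G1
peak. Peak positions are refined by an intensity-weighted centroid, so
they are not quantised to bin centres. The lowest qualifying peak is the
standard: with reference ratios at or above 1.2 the standard always sits
below the sample.

The ratio maps to ploidy through the reference ratios 1.2, 1.8 and 2.4
(0.6 per genome copy) with tolerance 0.15 — the midpoint between adjacent
references, the widest non-overlapping band. Genome size is exactly
`ratio * 20.08` pg; summaries round to integer picograms, full precision
is kept internally. Spore counts classify reproduction: 64 per
sporangium is sexual (slack 0 by default), 32 or fewer apogamous,
anything in between — never observed in real material — is
*indeterminate* rather than forced; the plant-level call is the
plurality over sporangia with ties indeterminate.

## Allele calling under dosage ambiguity

Clones of one individual collapse by single-linkage at up to 2
substitution differences. Gaps are compared as coded extents, not per
column: clones whose gap-run architectures differ are never linked — an
extent difference is allelic (the 15 bp X/Y deletion being the extreme
case), while polymerase point errors drive linkage. Each cluster takes a
majority-rule consensus; clusters seen only once are flagged as putative
PCR or cloning artefacts and excluded from genotyping by default (the
sequencing protocol accepts an allele only once captured more than once),
though they are persisted for audit.

Major-clade assignment (X vs Y) rests on the diagnostic deletion via
reciprocal overlap (default 0.8); the subgroup within the clade is the
nearest exemplar by p-distance, with a 0.5% separation margin below
which the call is `unassigned` rather than guessed. A genotype is then
*all* multisets of size ploidy containing each observed group at least
once — `choose(ploidy - 1, k - 1)` candidates for `k` groups — with a
star label (X3\*Y) whenever dosage is unresolved. Dosage is never chosen.

## Indel coding and the parsimony engine

Simple indel coding turns each distinct internal gap extent into one
binary character: exact extent 1, no overlapping gap 0, overlapping gap
of different extent missing. Terminal gaps are uncoded and score missing
for characters they overlap, because they usually reflect incomplete
sequencing of primer-bounded fragments (a `coded` switch exists).
Ambiguously aligned regions are removed by an explicit column mask, not
an automatic criterion. Coordinates are 0-based half-open internally,
converted to 1-based inclusive only at I/O boundaries.

The parsimony core works on bitmask-encoded unordered characters
(missing = full alphabet) in C++, as the field's packages do at this
scale. Tree length is Fitch optimisation; per-character bounds m (states
minus one) and g (non-missing taxa minus the largest state class) give
CI = sum(m)/L and RI = (sum(g) - L)/(sum(g) - sum(m)). Searches:
exhaustive enumeration of all unrooted binary topologies to 9 taxa (the
oracle), and random-addition stepwise starts with branch swapping to
convergence — SPR by default, NNI as an option. SPR replaces the
literature's TBR: at complex scale the gain from TBR is marginal and SPR
keeps the search directly testable against the exhaustive oracle. All
equally best trees are retained (MULTREES semantics); ties during
addition and swapping are broken by a seeded RNG, so runs are
deterministic given the seed.

Bootstrap support resamples characters with replacement (reduced search
settings per replicate); a replicate contributes to a split in proportion
to the fraction of its equally best trees containing the split. The ILD
test uses D = L(combined) − L(part1) − L(part2), permutes characters into
pseudo-partitions of the original sizes, and reports the add-one-corrected
upper tail P(D_perm >= D_obs); only parsimony-informative characters enter
by default. Both conventions vary across the literature, so they are
pinned here exactly as stated.

## Maternal mapping and the diploids-first network

Chloroplast haplotypes cluster hierarchically on p-distance (average
linkage by default) with the tree cut at the midpoint of the largest gap
in merge heights — deep, mutually exclusive haplotype clades separate
cleanly there; group labels follow decreasing size. The allele ->
haplotype map is built by deterministic rounds: an allele maps when its
not-yet-explained carriers share one haplotype *and* it is the strictly
preferred candidate (smallest raw haplotype spread) in some carrier;
additions within a round are decided against the round-start map and
applied together. Symmetric ties are reported as ambiguous, and carriers
contradicting an otherwise-consistent allele produce conflict records —
the map never guesses. Taxa with known nuclear/chloroplast disagreement
(morphs 5 and 6 in the shipped table) are exempted from map building.

The network search follows the diploids-first strategy: one homozygous
sexual diploid progenitor per allele lineage; candidate sexual
tetraploids by genome doubling of any diploid genotype and genome
addition between sexual diploids (a known doubling-source haplotype
survives merging with an unknown addition provenance; conflicting known
haplotypes leave it undetermined). Gamete rules: a sexual parent of even
ploidy contributes any half-size sub-multiset (tetrasomic segregation —
the published crosses require heterogenic gametes from tetraploids); an
apogamous parent is functionally male and contributes its full genotype;
ploidy reduction is not an event type. Apogamous intermediates are
depth-limited to one level. The maternal constraint is strict: an
offspring with a known haplotype admits only mothers of that haplotype,
so mothers of unknown haplotype are rejected and taxa without compatible
parents surface as *unexplained* rather than being resolved arbitrarily.
When the constraint is off, sexual-by-sexual crosses are canonicalised to
unordered parent pairs, since nothing then distinguishes mother from
father.

The objective is the number of distinct presumed (unobserved) parent
nodes used across the one-cross-per-taxon assignment, minimised by
exhaustive branch-and-bound; ties break by fewer distinct parent nodes
overall, then lexicographically. All co-optimal networks are retained,
and maternal ambiguity is read off their disagreement — in the shipped
11-taxon table the triploid morph 5 and the tetraploids keep ambiguous
maternal parents, which is the honest answer the field data support.

## The synthetic-data generator

`simulate_complex()` emulates the statistical structure the analysis
assumes, not fern biology at large. Exemplar references evolve on a star
phylogeny with clades under independent per-site substitutions:
within-group 0.5%, between-subgroup 4%, between-clade 8% (clade branches
shortened by the group step so cross-clade pairs sit near the nominal 8%),
with a 15-column deletion in the last clade. Per individual it emits:

- a clone set sampled proportionally to allele dosage times PCR bias
  weight, with per-base errors at 5e-4 (the usual figure for
  non-proofreading Taq over a 30-odd-cycle amplification). Sampling has
  two channels, mirroring the laboratory's primers: a fixed-depth generic
  channel (default 8 clones) and adaptive per-clade channels that
  sequence until every observed allele type is captured more than once
  and the observed set is stable (minimum 6, patience 8, cap 16 clones) —
  the protocol's "sequence until captured more than once" stopping rule.
  Without the clade channels, realistic PCR bias makes polyploid
  genotypes unrecoverable at any fixed depth, which is exactly why the
  original protocol added clade-specific primers;
- a maternal cpDNA sequence with within-group variation;
- a histogram with standard and sample peaks at ratio 0.6 per genome
  copy, Gaussian with CV 3% by default, 4000 events per peak over 1024
  channels;
- spore counts (32 with probability 0.9, else 16 or 28) and
  region/phenology labels.

Ground truth records progenitors, the full event list and per-individual
latent states; every latent genotype is the disjoint union of its
parents' gametes by construction. All draws derive from one mandatory
seed, and equal seeds give identical output.

What the generator does *not* model: recombination (apogamy suppresses
it, and the inference assumes its absence), chromatogram-level
base-calling error structure, cytometry debris and G2/S cell-cycle
peaks, population-genetic drift or selection, and morphology (morph
labels are opaque tags). Passing recovery tests therefore validate the
inference chain under the stated noise model — clean instrument
histograms and independent per-base PCR error — not performance on
degraded real-world chromatograms.

## Validation design and problem sizes

The test suite checks the published arithmetic exactly (peak-ratio
genome sizes; 11 taxa / 5 alleles / 3 haplotype groups; the
five-progenitor hypothesis; the three printed crosses for X2X3Y; the
star-genotype candidate sets), and property suites at sizes chosen to
finish in minutes on one core: 500 random Fitch cases against brute-force
labeling (up to 6 leaves, 4 states) plus an independent library
cross-check; 100 heuristic-vs-exhaustive searches at 8 taxa; 200 random
gappy alignments against a column-wise indel-coding oracle; ILD type-I
calibration over 200 congruent simulations at 199 permutations and power
on maximally conflicting six-taxon partitions; and end-to-end recovery of
ploidy, genotype label and haplotype group on 50 simulated complexes at
benign settings, with progenitor-set recovery on 100 further complexes of
3–5 alleles. Determinism is asserted by byte-identical reruns.

## Known limitations

- Subgroup assignment uses exemplar p-distance, not tree placement; it
  assumes subgroups are well separated (as the deep clades here are).
- The haplotype cut assumes a clear gap between within- and
  between-group merge heights; continuous divergence gradients would
  need an explicit threshold.
- The network search is exhaustive and intended for complex-scale
  problems (about 15 taxa, 8 alleles); it is not a general phylogenetic
  network method and has no likelihood model.
- CI/RI bound counting treats partial ambiguity codes as missing.
- Apogamous lineages are assumed strictly clonal; rare residual
  sexuality would blur the one-cross-per-taxon model.
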