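# reticulator

Multi-evidence reconstruction of reticulate (hybrid and polyploid) origins
in apogamous fern species complexes, built around the *Pteris cadieri*
complex of Hainan and Taiwan.

Apogamous ferns reproduce clonally: sporophytes form without
fertilization, each lineage freezes the genotype of the hybridization
event that created it, and sporangia carry 32 spores instead of the sexual
64. A complex of such lineages is therefore a fossil record of its own
crosses. This package infers that record from four kinds of evidence:

- **Flow cytometry** — ploidy from the sample/standard G1 peak ratio
  against the *Nicotiana tabacum* 4X standard (20.08 pg). Reference ratios
  are 0.6 per genome copy: 1.2 (2X, about 24 pg), 1.8 (3X, about 36 pg),
  2.4 (4X, about 48 pg).
- **Spore counts** — 64 spores per sporangium is sexual; 32 or fewer
  (occasionally 16 or 28) apogamous.
- **Nuclear alleles from clones** — cloned sequences of a single-copy
  nuclear gene collapse into allele calls; a 15 bp diagnostic deletion
  separates two deep allele clades (X vs Y), subgroups (X1..X4) by nearest
  exemplar p-distance. Clone presence/absence cannot reveal dosage, so a
  polyploid genotype is a *set* of candidate multisets with a star label:
  X3\*Y means X3X3Y or X3YY.
- **Chloroplast haplotypes** — maternally inherited; deep clusters
  (alpha, beta, gamma) mark maternal lineages, and alleles whose carriers
  share a haplotype map to it (the allele -> haplotype maternal map).

A compact maximum-parsimony engine supports the sequence analyses: Fitch
lengths over bitmask-encoded unordered characters, CI = sum(m_i)/L and
RI = (sum(g_i) - L)/(sum(g_i) - sum(m_i)), exhaustive search to 9 taxa,
random-addition + SPR/NNI heuristic search with MULTREES semantics,
nonparametric bootstrap, the ILD partition-homogeneity permutation test,
and simple indel coding of alignment gaps (exact extent = 1, no
overlapping gap = 0, different overlapping extent = missing).

The endpoint is a **diploids-first reticulate network**: posit one
homozygous sexual diploid progenitor per allele lineage, derive candidate
sexual tetraploids by genome doubling and genome addition, enumerate
crosses under the gamete rules (sexual parents contribute reduced
gametes; apogamous parents are functionally male and contribute their
full genotype), require the mother's haplotype to match the offspring's,
and pick the cross assignment minimising the number of presumed
(unobserved) taxa. All co-optimal networks are kept; taxa with no
haplotype-compatible parents are reported as unexplained, never forced.

A synthetic-data generator (`simulate_complex()`) emits complete
observation bundles — clone FASTAs, cpDNA sequences, cytometry
histograms, spore counts, metadata — with known ground truth, and is the
basis of the package's recovery validation.

## Worked example

The transcribed 11-taxon observation table of the *P. cadieri* complex is
shipped as `cadieri_observations()`:

```r
library(reticulator)
fx  <- cadieri_observations()
map <- infer_allele_haplotype_map(fx$observations, fx$exempt)
map$map
#>      X1      X3      X4      X2
#> "alpha" "gamma"  "beta" "alpha"
net <- infer_network(fx$observations, map)
net
#> reticulate network: 11 crosses, 7 presumed taxa, 29 co-optimal
head(net$crosses[, 1:5], 3)
#>   offspring mother mother_gamete father father_gamete
#> 1 morph1_2x   X2X2            X2     YY             Y
#> 2 morph2_2x   X4X4            X4     YY             Y
#> 3 morph3_2x   X3X3            X3     YY             Y
```

Reading the output: four alleles map to maternal haplotypes (X1, X2 ->
alpha; X3 -> gamma; X4 -> beta); Y co-occurs with every haplotype and
stays unmapped. The minimal network explains all 11 (morph, cytotype)
taxa with 7 presumed taxa — the five diploid progenitors X1X1..YY plus
the sexual tetraploids X2X2YY and X4X4X4X4 — e.g. morph 1 (X2Y, alpha)
arises from mother X2X2 x father YY. The maternal parent of the triploid
morph 5 and of the tetraploids differs between co-optimal networks, i.e.
their maternal lineages remain ambiguous, matching the field evidence.

## Analysis workflow

Numbered drivers under `analysis/` run a full synthetic study and the
observed-complex reconstruction, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R               # synthetic complex + truth
Rscript analysis/02_cytometry_reproduction.R # ploidy + reproduction table
Rscript analysis/03_allele_typing.R          # alleles + genotypes
Rscript analysis/04_haplotypes_parsimony.R   # haplotype groups, MP, bootstrap
Rscript analysis/05_network.R                # maternal map + network
```

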