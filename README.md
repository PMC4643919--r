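# plastcomp

Comparative analysis of plastid (chloroplast) genomes in R, aimed at the
shallow-divergence regime typical of congeneric land-plant plastomes
(pairwise p-distance ~10⁻³), where the questions are structural and
mutational rather than purely phylogenetic:

* **Quadripartite structure** — detect the inverted repeat as the longest
  pair of disjoint, exactly reverse-complementary repeats (origin-aware),
  partition the circle into LSC / IRb / SSC / IRa, canonicalize the SSC
  orientation isomer against a reference, and report which gene crosses
  each junction and by how many bases it extends into the IR.
* **Divergence profiling** — uncorrected p-distance under pairwise
  deletion, percent variability of noncoding regions
  (100 × (substitution sites + indel events) / aligned length),
  mVISTA-style sliding-window identity, parsimony-informative sites.
* **Polarized mutation spectra** — with an outgroup fixing direction:
  the 12 directed substitution types, Ts/Tv, insertion/deletion calls
  with length spectra, and classification of each indel's repeat context
  (homopolymer / tandem repeat / none), testing the slipped-strand
  mispairing prediction.
* **Genome-size decomposition** — partition two annotated genomes into
  genes, introns and intergenic spacers (one IR copy removed), attribute
  the size difference to matched elements, and account for it with large
  (>100 bp) indels.
* **Tajima's relative rate test** — 3-taxon site-pattern counts under
  complete deletion and the 1-df statistic
  χ² = (m₁ − m₂)² / (m₁ + m₂) on the lineage-specific counts, with
  computed p-values.
* **A known-truth simulator** — plastome-like genomes evolved along a tree
  under a directional spectrum (Ts/Tv = 0.5 with an A→C excess) and a
  slipped-strand indel process, emitting the true alignment, true region
  coordinates and per-branch event logs, so every analysis stage is
  validated against planted parameters.

Inputs are standard formats: GenBank flat files (or FASTA plus a TSV
feature table) for annotated genomes, aligned FASTA for alignments.
Coordinates are 0-based half-open internally and 1-based inclusive in all
reports.

## Worked example

The relative-rate statistic from published lineage-specific site counts
(*Gossypium hirsutum* vs *Tilia mandshurica*, *Theobroma cacao* outgroup;
m₁ = 2456, m₂ = 725):

```r
library(plastcomp)
tajima_test(2456, 725)
#> <rate_test> m1 = 2456, m2 = 725: chi-square = 941.96 (df 1), p < 0.001
```

The ingroup lineage contributed far fewer unique sites, so it is the
significantly slower one. The full workflow runs as numbered scripts over a
simulated quartet (four ingroup genomes plus outgroup at the study
conditions):

```sh
Rscript analysis/01_simulate.R          # ~163 kb quartet + truth fixture
Rscript analysis/02_structure.R         # regions, gene inventory, junctions
Rscript analysis/03_divergence.R        # p-distance, noncoding variability
Rscript analysis/04_spectrum.R          # polarized substitutions + indels
Rscript analysis/05_size_decomposition.R
Rscript analysis/06_relative_rate.R
```

Step 2 prints, per genome, the detected structure and the planted junction
gene:

```
T_mand   162866 bp  LSC 91222  IR 25600  SSC 20444  genes 115 (97 unique)
...
IRb/SSC junction: gene ycf1 extends 36 bp into the IR in every genome
```

i.e. the ycf1-like gene crosses the IRb/SSC boundary with a 36-bp fragment
duplicated inside the IR, recovered identically in all genomes. Step 3
summarises divergence:

```
pairwise p-distance among 4 ingroup genomes: mean 0.0016, range 0.0009-0.0020
noncoding regions >200 bp aligned: 72; variability 0-2.72%
```

and step 4 the polarized spectrum — note the planted A→C excess and the
insertion bias recovered from the called events:

```
transitions 143, transversions 325, Ts/Tv = 0.44
  over-represented: A>C (95 vs 39.0 expected)
polarized indels: 67 insertions, 19 deletions
1-bp fraction: insertions 40%, deletions 63%; longest: 10 / 7 bp
repeat-associated (homopolymer or tandem): 76 of 86
```

Each step writes its tables under `results/` as TSV. The methods vignette
(`vignettes/comparative-plastome-analysis.Rmd`) documents the models,
conventions, defaults and the validation design.

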