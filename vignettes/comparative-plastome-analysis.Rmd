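---
title: "Methods: comparative plastome analysis on known-truth synthetic genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative plastome analysis on known-truth synthetic genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastcomp)
```

# The problem

Plastid genomes of photosynthetic land plants are circular molecules of
roughly 120–170 kb with a strongly conserved quadripartite organisation: a
large and a small single-copy region (LSC, SSC) separated by two identical
inverted repeats (IRa, IRb). Comparative studies of congeneric plastomes —
long-lived trees in particular — operate at very shallow divergence
(p-distance on the order of 10^-3^), where the interesting signal is not a
tree so much as the *anatomy* of the differences: where the IR boundaries
sit and which genes they truncate or duplicate; how variability distributes
over noncoding loci; the direction of substitutions and indels relative to
an outgroup; whether indels cluster at repeats, as the slipped-strand
mispairing model predicts; what sequence elements carry a genome-size
difference; and whether lineages differ in rate.

`plastcomp` implements each of those analyses as ordinary R functions over
two containers — an annotated circular record (`plastome_record`) and an
alignment with per-taxon coordinate maps (`alignment_matrix`) — plus a
sequence-evolution simulator that produces plastome-like genomes *with
known truth* (true alignment, true event logs, true region coordinates), so
that every stage can be validated against planted parameters rather than
against itself. The `analysis/` scripts chain the stages into the full
workflow; `scripts/acceptance.R` recomputes the headline statistics.

# Quadripartite structure

`detect_inverted_repeats()` finds the longest pair of disjoint, exactly
reverse-complementary repeats, by seed-and-extend on the doubled sequence
(so candidates straddling the circular origin are found), with maximal
extension computed by binary search on substring equality. Exact matching
is deliberate: the two IR copies of an assembled plastome are identical by
construction, and a mismatch-tolerant mode would only blur the boundary
definition. Defaults and conventions:

* `min_ir_length = 1000` bp — far below real IR sizes (~25 kb) but above
  the dispersed repeats plastomes accumulate.
* Single-copy labels are assigned by size (LSC is the longer arc); IRb is
  the copy immediately downstream of the LSC, giving the usual junction
  naming JLB, JSB, JSA, JLA.
* Ties between equal-length candidate pairs are broken by maximising the
  shorter single-copy arc, then by position — detection is deterministic.
* The reported IR length is the maximal exact-repeat length. When a
  junction gene (typically *ycf1* at JSB) has a fragment duplicated in the
  IR, that duplication *is* part of the exact repeat, so it is included —
  and `junction_report()` measures it per junction.

`canonicalize_orientation()` addresses the SSC orientation isomerism: a
plastome assembly can legitimately present either SSC strand, and the
difference is a representation artifact, not a gene-order difference. The
record's SSC is scored against a reference SSC in both orientations by
shared k-mer count (k = 15) and flipped when the reverse complement scores
higher. Features wholly inside the SSC are mirrored; a feature straddling a
junction is left untouched with a warning, since mirroring would tear it.
Junction overlap lengths are invariant under the flip, which the suite
checks.

# Divergence profiling

`p_distance()` is the uncorrected proportion of mismatches under pairwise
deletion: only columns where both taxa carry an unambiguous base are
compared. At the depths this package targets (p ≈ 0.001–0.002),
model-corrected distances would differ in the fifth decimal, so they are
out of scope.

`region_variability()` follows the convention of counting *events*, not
columns: substitution sites are columns with ≥ 2 distinct bases among the
chosen taxa, and indels are maximal per-taxon gap runs, de-duplicated by
their exact column extent — a run shared identically by several taxa is a
single event (one mutation, inherited), while overlapping runs of different
extent are distinct events. A run is assigned to the region containing its
first column. The `> 200` bp filter applies to *aligned* length. Percent
variability is `100 × (substitution sites + indel events) / aligned length`.

`sliding_identity()` is an mVISTA-style profile (defaults window 100,
step 25 columns; the `analysis/` driver uses 1000/250 at genome scale):
percent of matching columns among columns where either taxon has a base,
indexed by the reference taxon's ungapped coordinate.
`count_informative_sites()` counts parsimony-informative columns (≥ 2
states each in ≥ 2 taxa; gaps and N are not states), verified against
exhaustive enumeration of all 4^4 single-column patterns.

# Outgroup polarization

`polarize_substitutions()` emits one event per column where direction is
unambiguous: no gap or N in any considered taxon, exactly two states in the
ingroup, and the outgroup carrying one of them. The outgroup state is
ancestral; ingroup taxa with the other state are carriers. A shared derived
state is **one** event — the parsimonious single-origin reading on a
shallow tree — and the per-taxon occurrence tally is reported alongside for
comparison. Columns failing a condition are tallied by reason
(`gap_or_N`, `monomorphic`, `multiallelic`, `outgroup_mismatch`); the
ingroup-monomorphic class is exactly where outgroup-lineage changes land,
so they never masquerade as ingroup events.

`call_and_polarize_indels()` applies the same logic to maximal gap runs. A
run pattern is polarizable when every considered taxon either has exactly
that maximal run or has sequence across the whole interval; the outgroup
side of the partition decides insertion vs deletion. Two classes are
excluded with tallies: genuinely mixed patterns (partially overlapping
runs), and patterns whose carriers would be the *entire* ingroup. The
second exclusion mirrors the monomorphic skip above: a gap separating the
whole ingroup from the outgroup polarises formally, but the event sits on
the outgroup lineage and is not an indel *among* the ingroup genomes —
counting it would, at realistic outgroup depths, swamp the within-ingroup
spectrum with flipped-polarity events.

`classify_indel_context()` implements the slipped-strand predictions with
the minimal definitions that make them testable: *homopolymer* — the event
sequence is a single repeated base inside a mononucleotide run of total
length ≥ 4 (threshold configurable) in the un-gapped neighbourhood;
*tandem repeat* — the event sequence exactly equals the adjacent upstream
or downstream flank of the same length. For events longer than 1 bp the
tandem test runs first. For 1-bp events **only** the homopolymer test
applies: a length-1 "tandem" is nothing but a 2-base mononucleotide run,
below the homopolymer threshold, and counting it would tag ~44% of
context-free 1-bp indels as repeat-associated by chance alone, destroying
the discriminating power of the classification. Flanks are taken from the
sequence the event happened in: the first carrier for insertions, and for
deletions the closest non-carrier ingroup taxon rather than the outgroup —
the outgroup's own accumulated changes would otherwise corrupt the
exact-match tests (using outgroup flanks measurably deflates the
repeat-associated fraction on synthetic truth).

# Genome-size decomposition

`partition_genome()` drops one IR copy and tiles the LSC + IRb + SSC
representation into gene elements (exon unions per feature), introns
(inter-exon gaps) and intergenic spacers (maximal uncovered intervals,
named by flanking genes). Overlapping gene extents are resolved by
assigning overlap bases to the earlier-starting gene, so element lengths
are additive and sum exactly to the representation length — a conservation
invariant the suite asserts. `compare_partitions()` matches elements by
name (spacers by their flanking-gene pair, orientation-insensitively;
rearranged neighbourhoods stay unmatched rather than being force-matched)
and reports per-element deltas, per-class totals, larger-in-A/-B/equal
counts and the large-delta list. `large_indel_accounting()` closes the
loop: polarized indels longer than the threshold (default 100 bp), summed
with sign relative to the focal genome, expressed as a fraction of the
observed size difference.

# Tajima's relative rate test

`site_pattern_counts()` classifies each column of a 3-taxon projection
under complete deletion (any gap or N discards the column): identical,
divergent (all three distinct), or unique to one taxon. The test statistic
is `(m1 − m2)² / (m1 + m2)` on the two ingroup-unique counts, compared to
chi-square with 1 df; p-values are computed, not table-looked-up, and
formatted in the conventional `< 0.001` style. The implementation is
checked three ways: exhaustive 5³ single-column enumeration against a
brute-force classifier, an independent tail-probability oracle
(`2Φ(−√x)`), and a 500-replicate equal-rate simulation whose rejection
rate at α = 0.05 must fall inside the 99% binomial envelope.
`run_rate_tests()` reports the equal-rate limit (χ² = 0, p = 1) when a
pair has no lineage-specific sites at all, rather than erroring as the
bare statistic does.

# The synthetic-data generator

`sim_config()` defaults *are* the study conditions, chosen once:

| parameter | default | reason |
|---|---|---|
| LSC / SSC / IR | 91,000 / 20,400 / 25,600 bp | region magnitudes of sequenced Malvaceae plastomes |
| base frequencies | A = T = 0.3175, C = G = 0.1825 | GC content 36.5% |
| tree | tips 5×10⁻⁴, internal 5×10⁻⁴, stem 0.01, outgroup 0.015 | ingroup p-distance 0.001–0.002, outgroup ~0.025 |
| spectrum | rate(A→C) = 2.5, rate(G→C) = rate(C→G) = 0.4, other transversions 1; each base's transition rate = half its transversion sum | A→C excess and G:C deficit with *exactly* Ts/Tv = 0.5 conditional on an event, independent of composition |
| indel : substitution ratio | 58/208 | observed event ratio at these depths |
| insertion fraction | 41/58 | insertions outnumber deletions ~2.4:1 |
| length distribution | geometric, P(1 bp) = 0.5 | ~half of indels are 1 bp |
| slip fraction | 52/58 | repeat-associated share of indels |
| junction overlap | 36 bp | *ycf1*-like duplication at JSB |

The root genome is drawn i.i.d. from the base frequencies and then seeded
with homopolymer runs (every ~250 bp) and short tandem repeats (every
~800 bp), because a purely random sequence offers the slip process too few
targets; genes (including intron-bearing and IR-duplicated ones, and the
junction-crossing *ycf1*-like gene) are placed non-overlapping. One base at
each single-copy/IR junction is adjusted, if needed, so that the planted IR
is also the *maximal* exact repeat — otherwise a chance complementary flank
would make detection disagree with truth by a base.

Evolution walks the tree in preorder. Substitutions are drawn per site per
branch from the normalised directional matrix (branch lengths are expected
substitutions per site at the configured composition); a change in IRb is
mirrored into IRa, emulating plastid IR copy correction, so every leaf
keeps IRa = revcomp(IRb) exactly. Indel events are then placed sequentially
in the single-copy regions — slip-seeded events duplicate or delete one
base of a homopolymer run, or one copy of an adjacent tandem pair;
context-free events hit uniform positions. Restricting indels to the
single-copy regions keeps the IR copies identical without the considerable
bookkeeping of mirrored coordinate shifts; real plastomes do accumulate
occasional IR indels, which this model does not emulate.

Homology is never re-inferred: every residue carries a sort key, insertions
receive keys strictly between their neighbours', and the true alignment is
the union of leaf keys in order. Replaying the per-branch event logs from
the root must reproduce every leaf byte-for-byte; the suite and
`analysis/01_simulate.R` both assert this.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: alignment error (the truth alignment sidesteps MAFFT
entirely), codon structure and selection, rate heterogeneity along the
genome, IR expansion/contraction, rearrangements, heteroplasmy, and
sequencing/assembly error. Conclusions about those belong to the full-scale
replication on deposited accessions, which consumes externally aligned
FASTA through the same interfaces.

# Validation design and problem sizes

The acceptance suite runs five kinds of check, sized to stay comfortable on
one CPU (~2.5 minutes in total):

1. worked examples recomputed from published summary tables (four
   relative-rate chi-squares to 2 dp; Ts/Tv = 0.52 from 71/137; the
   2495/2311 bp size deltas);
2. exhaustive-pattern oracle equivalence (all 4⁵ polarization columns, all
   5³ site-pattern columns, all 4⁴ informative-site columns);
3. event-replay identity and exact IR recovery on a full-size (~163 kb)
   quartet at the default conditions;
4. end-to-end parameter recovery: Ts/Tv, insertion fraction and
   repeat-associated fraction estimated by the full pipeline must fall in
   the 99% binomial interval of their planted values at ≥ 300 events. To
   accrue 300+ within-ingroup indels on one quartet the indel:substitution
   ratio is raised to 1.0 and the outgroup is placed at ~0.005 rather than
   ~0.025 — at the realistic outgroup depth the outgroup lineage
   contributes thousands of its own indels, and overlapping gap runs
   (which concentrate at the shared repeat targets) would be excluded as
   unpolarizable, preferentially discarding slip-seeded events and biasing
   the recovered fraction downward. The closer outgroup isolates the
   estimator from that multiple-hit confounding while leaving the ingroup
   at study depth;
5. calibration: 500 equal-rate replicates for the rate test's type-I
   error, and a no-false-positive check among the equal-rate simulated
   sister species.

# Known limitations

* GenBank parsing covers single-record flat files with simple,
  `complement()` and `join()` locations — the subset deposited plastomes
  use. Remote references and fuzzy coordinates beyond `<`/`>` are
  rejected, naming the offending line.
* `partition_genome()` clips features that cross the dropped-IR boundary
  and labels a truncated leading fragment of an overlap-resolved gene as
  gene sequence; both biases are at most a few bases per genome.
* The SSC flip does not re-mirror features straddling a junction (warned).
* Event counting is per derived allele; the per-taxon occurrence tally is
  reported alongside, but all spectrum summaries use event counts.
* The simulator's truth for `canonicalize_orientation()` is limited to
  flips constructed in tests; opposite-isomer simulation is not built in.
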