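---
title: "Methods: comparative SSR landscapes with ssrscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative SSR landscapes with ssrscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrscape)
library(dplyr)
```

## The problem

Microsatellites (simple sequence repeats, SSRs) are tandem repetitions of
1–6 nt DNA motifs. Their genomic density, motif composition, preferred
lengths and genic context vary strongly across eukaryotes, and comparing
those patterns across many genomes requires a pipeline that is exhaustive
(every perfect repeat above a length cutoff), canonical (motifs that
describe the same repeat are pooled), and deterministic (so that matrices
built from hundreds of genomes are reproducible). `ssrscape` implements
that pipeline end to end and ships a synthetic-genome generator with
planted ground truth so every stage can be validated without any external
download.

## Repeat classes

A repeat read from a genome can start at any phase of its motif and on
either strand: `TTC`, `TCT`, `CTT`, `GAA`, `AGA` and `AAG` runs all
describe the same underlying repeat. `ssrscape` therefore works with
*repeat classes*: a motif is mapped to the lexicographically smallest
string among the cyclic rotations of itself and of its reverse complement.
Only *primitive* motifs (not themselves a tandem repetition of a shorter
motif, so `AC` but never `ACAC`) name classes. There are 5356 primitive
motifs of length 1–6 and they collapse into 501 classes (2, 4, 10, 33, 102
and 350 for motif sizes 1–6); the class table is enumerated once and its
order (motif size ascending, then alphabetical) fixes the column order of
every downstream table and matrix.

Class GC content is evaluated on the 12 bp string formed by repeating the
motif in tandem — the minimum repeat length — rather than on the bare
motif. The two differ for pentamers, where the 12 bp window truncates the
third unit (`AACCG` has motif GC 0.6 but 12 bp-window GC 0.5). Five GC
groups are used: ≤ 25%, 26–49%, exactly 50%, 51–74% and ≥ 75%; computed at
class level these contain 70, 120, 133, 108 and 70 classes.

## Detection

`scan_sequence()` finds every maximal perfect repeat of a primitive motif
with total length ≥ `min_length` (default 12 bp, i.e. two complete units
of the largest motif size; the cutoff is applied uniformly across motif
sizes, so partial trailing units count toward length and
`units = floor(length/k)`). Coordinates are BED-style 0-based half-open.
`N` breaks runs; lowercase soft-masking is scanned after uppercasing;
IUPAC ambiguity codes other than `N` are demoted to `N` with a message.

Where perfect runs of different motifs abut or nest, some convention must
pick the reported decomposition. `ssrscape` scans left to right greedily:
at each position it takes the longest maximal perfect run starting there
(ties between motif sizes go to the smaller motif), emits it if long
enough, and resumes at its end. The rule is deterministic and
order-independent, and the test suite holds the scanner to exact equality
with an independent character-walk reference that applies the same rule.
One consequence worth knowing: a record's left edge is maximal with
respect to the *unconsumed* sequence — in a junction such as poly-A
followed by `CACACA...`, the dinucleotide record begins where the poly-A
record ended, even though one more `A` on its left would also fit the
period.

## Per-genome attributes

For each organism the package reports SSR frequency (count), base coverage
(summed lengths), density (bases covered per Mb of genome) and SSR GC (GC
fraction of the concatenation of all repeat sequences, computed exactly
from each record's motif and length). Genome size includes `N` bases;
genomic GC is computed over non-`N` bases only. Both choices are recorded
in the run log; they differ only through the assembly's `N` fraction. A
genome with no SSRs reports missing (not zero) SSR GC so correlation
analyses are not polluted. Per-class tables are zero-filled over all 501
classes, and conservation (class sums equal genome totals) is asserted in
the tests.

## Enrichment scores and clade signatures

Within each organism, classes are ranked by density (rank 1 = densest;
ties broken by frequency, then motif, so matrices are reproducible).
Scores are: 3 for ranks 1–10, 2 for 11–25, 1 for 26–100, −1 for the bottom
100 ranks (402–501 of the full 501-class ranking) when frequency ≥ 10, 0
otherwise — and −2 whenever frequency < 10, overriding rank, to damp
sampling noise from near-absent classes. Zero-frequency classes are
therefore always −2, never −1. Columns of the organisms × classes matrix
are ordered by hierarchical clustering on Euclidean distance; the linkage
(default average, configurable) affects display order only, never scores,
so no quantitative result depends on it.

A class is *uniquely abundant* in a clade when it ranks in the top 10 in
every clade member and in no outside organism. Significance uses a
two-sided Welch t-test on the underlying densities (clade vs all others);
Welch was chosen because cross-clade density variances are wildly unequal,
and densities (not ranks) are tested because ranks discard the effect
size the claim is about. Multiple clade×class tests are Bonferroni
adjusted by default. Degenerate inputs (constant densities) report a
missing p-value rather than an error.

## Length preference

For each class, the abundance curve counts SSRs at each exact
complete-unit length ("unit length vs abundance"); bp-binned variants were
rejected because consecutive unit lengths are the natural grid for a
fixed motif. Abundance normally decays with length, so a *length
preference* is a local rise: scanning left to right, an increase between
consecutive unit lengths opens a candidate whose start is the unit length
before the first increase (plateaus do not count as increases); the curve
must climb to a local maximum and then fall, and the peak ends at the
first unit length whose abundance drops strictly below the start
abundance. Peaks must span ≥ 4 consecutive unit lengths (start and end
included) with start abundance > 10; several disjoint peaks per curve are
allowed, scanning resuming after each end.

Two boundary choices were genuinely open. The endpoint comparison is
strict ("drops below", not "at or below"); and a candidate whose abundance
never falls below its start before the histogram ends is discarded rather
than closed at the histogram edge — the conservative reading of "the
endpoint is where abundance goes lower than the start". Under that rule,
appending zero-abundance unit lengths beyond the observed range preserves
every detected peak (it can only add peaks for previously discarded
candidates), which is what the tests assert.

## Genomic annotation

`build_feature_index()` reads GFF3 `gene` and `exon` rows (NCBI-dialect
rows such as `region` are ignored; mRNA rows are not used, so exons are
merged across isoforms before introns are derived as gene span minus
exons). Genes without exon children count as single-exon genes; exons
sticking out of gene spans are clipped with a warning. Each SSR is
assigned exon > intron > intergenic by any-overlap precedence; the
reported exon-overlap percentage keeps boundary-spanning assignments
auditable (on synthetic data planted wholly inside exons, every exonic
record shows 100%). TSS distance is unsigned, measured from the nearest
SSR boundary to the nearest strand-aware gene 5′ end, 0 when the SSR
covers a TSS.

## The synthetic-data generator

The generator is the package's substitute for downloading hundreds of
assemblies: it emulates exactly the statistical structure the analyses
assume, with known truth.

* **Genomes** are i.i.d. backgrounds at a requested GC with perfect
  arrays planted at fixed or random non-overlapping positions (≥ 3 bp
  apart). Array boundaries are padded so each array is exactly maximal,
  and the sequence is rescanned, substituting single background bases,
  until the detector's output equals the truth table *exactly* — so
  "background repeat-free at the 12 bp threshold" is verified, not
  assumed.
* **Cohorts** share a deterministic baseline ladder of repeat classes
  (expected instance counts decaying geometrically, ratio 0.82 from 60
  instances, over 25 classes, with per-organism lognormal noise of
  sd 0.2) so every organism's top-10 set is stable; clades carry their
  signature class at roughly 10× the median baseline class coverage while
  non-members get < 10 trace instances; peak-plan organisms receive a
  class whose unit-length counts are a decaying curve (220 instances at
  the minimum unit length, ratio 0.72) plus a flat bump of configurable
  start, width and height.
* Defaults used by the validation suite: 150 kb genomes (100 kb for the
  12-organism signature cohort, 10 kb sequences for the
  detector-vs-reference comparison), background GC 0.41, 12 organisms in
  3 clades of 4, signature fold 10. These sizes were chosen as the
  smallest at which every planted structure is unambiguous — e.g. a
  signature class must out-dense 10 baseline classes in every clade
  member — while keeping the full suite fast enough to run routinely.

What the generator does *not* emulate: mutational repeat
expansion/contraction dynamics, imperfect repeats, compositional
heterogeneity (isochores), assembly gaps and collapsed arrays. Passing
tests therefore demonstrate algorithmic correctness on clean inputs, not
robustness to real-assembly artefacts; on real data the quantities most
sensitive to those artefacts are the longest-instance statistics.

## Numerical and degenerate-input conventions

Rank ties break by frequency then motif; density uses genome size
including `N`; empty genomes error while zero-SSR genomes return zero
counts with missing GC; constant-density signature tests return missing
p-values; clustering requires ≥ 2 classes; histograms must be contiguous
(the histogram builder zero-fills internal gaps). All cohort randomness
derives from a single seed (per-organism seeds are drawn once from the
cohort seed), and reruns are byte-identical, which the suite checks
file-by-file.

## Limitations

Motifs above 6 nt, imperfect/compound repeats, and promoter/UTR
sub-annotation are out of scope. The greedy junction rule and the peak
endpoint rule are documented conventions validated against this package's
own reference implementations; other tools may decompose junctions
differently, so cross-tool record lists can differ at repeat boundaries
even when both are internally consistent.

## A small worked run

```{r example, eval = FALSE}
library(ssrscape)

co <- generate_cohort(
  n_organisms = 6, clades = list(cladeA = 1:3),
  signature_classes = c(cladeA = "AACAGC"),
  genome_length = 60000, seed = 7)
manifest <- write_cohort(co, tempfile("cohort"))
res <- run_cohort(manifest, tempfile("out"),
                  clades = list(cladeA = manifest$organism_id[1:3]))
res$signatures |>
  dplyr::filter(uniquely_abundant, p_value < 0.05)
autoplot(res$score_matrix,
         class_order = res$class_order$order)
```
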