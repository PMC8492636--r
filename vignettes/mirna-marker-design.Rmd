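---
title: "miRNA-derived and semi-random ISSR markers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{miRNA-derived and semi-random ISSR markers: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirmarker)
```

## The marker system

`mirmarker` implements a functional-marker workflow for linking a
quantitative trait (the motivating case is salt tolerance in pistachio,
*Pistacia vera*) to genotype using two families of PCR markers derived from
trait-responsive sequences rather than anonymous genomic loci:

* **miRNA-derived primers.** A mature miRNA is the ~18–24 nt product
  excised from one arm of its pre-miRNA hairpin. A single such primer can
  amplify across the hairpin (between the mature miRNA and its star
  sequence), which wastes the primer on a fixed-length stem–loop product.
  The design rule therefore orients every primer *outward* from its locus:
  a mature sequence originating from the **5′ arm** is reverse-complemented
  (after U→T substitution), while a **3′-arm** sequence is used unchanged.
  Pairs of such primers amplify the intervening genomic region between
  neighbouring miRNA (or isomiR) loci, so band presence/absence reflects
  both sequence variation in the mature miRNAs and variation in their
  genomic placements.
* **Semi-random anchored ISSR primers.** Transcripts that respond to the
  trait are mined for perfect microsatellites; the most informative motifs
  are turned into primers of the form *motif×n + anchor*. "Semi-random"
  means the 3′ anchor is not arbitrary: it is the most frequent k-mer
  observed immediately 3′ of that motif's tracts in the trait-responsive
  transcripts, excluding k-mers that would merely extend the repeat (first
  base equal to the first motif base). Anchoring at the 3′ end fixes the
  annealing register at the repeat/flank boundary, standard ISSR practice.

Markers are assayed as unordered primer pairs: all `choose(n, 2)` pairs
within the miRNA set plus the full cross-product with the ISSR set (8
miRNA primers give 28 within-set pairs; 8 × 6 gives 48 cross pairs). A
"random subset" of combinations is reproduced as seeded subsampling of the
full cross product.

## Microsatellite mining

`find_ssrs()` detects **perfect** tandem repeats with unit length 2–6,
with per-unit minimum repeat counts `{2:6, 3:5, 4:5, 5:4, 6:4}` — the
standard transcript-mining configuration for this workflow.
Semantics follow the MISA conventions:

* only complete repeat units count (a trailing partial unit is ignored);
* a motif that is itself a repetition of a shorter unit is reported at the
  shorter unit (ATAT×5 is AT×10), so nested-unit reports of one tract
  never coexist;
* the motif is recorded exactly as it occurs at the tract start; merging
  cyclic rotations (AG/GA) is opt-in, and reverse complements are never
  merged because motif selection treats TC and AG as distinct choices;
* N never matches, so an N interrupts a tract;
* two loci within 100 nt are annotated as a compound SSR but always counted
  individually;
* mononucleotide runs are not mined (the threshold table starts at unit 2).

One subtlety: maximal tracts of the *same* unit length can overlap by up
to unit−1 bases (…CCGACCGA│ACGAACGA…, sharing one A). The scanner resumes
its search unit−1 bases before each match end so both tracts are reported;
the unit tests check exact agreement with an independent shift-comparison
oracle on randomised sequences with planted tracts.

Motif selection for ISSR design ranks motifs within each unit length (di-,
tri- and penta-nucleotide by default) by
`w_abund · rank(locus count) + w_act · rank(mean host-gene activity)`.
The published workflow states that abundance and the "activity" of the
host genes both informed selection without giving a formula; the weighted
rank combination here is the package's own declared stand-in, with
activity defaulting to |log2 fold-change| when a differential-expression
table is supplied and to weight 0 otherwise. Ties break by activity, then
lexicographically.

## In-silico PCR

`find_binding_sites()` scans both strands for primer annealing with at
most `max_mismatch` mismatches and an exact 3′-terminal seed
(`seed_len = 3`); N in the template never matches. `predict_amplicons()`
enumerates every convergent site combination — including two sites of the
same primer, i.e. single-primer amplification — with product length in
`[min_len, max_len]` and non-overlapping primer footprints.

Defaults are `max_mismatch = 0`, `seed_len = 3`, `min_len = 100`,
`max_len = 3000`. The wet protocol this emulates used fixed touchdown
programs rather than Tm-matched annealing, so no thermodynamic model is
attempted; exact matching keeps predictions deterministic, and the
100–3000 bp window brackets the 200–1200 bp range typical of these assays
with margin. GC content is reported for information only; Tm, hairpin and
dimer screens are out of scope.

Coordinates are 0-based half-open internally and 1-based inclusive in all
user-facing tables; the BED export converts explicitly.

## Band scoring and statistics

Gel-estimated sizes are approximate, so observed sizes of one primer pair
are clustered by **single linkage with a 2 % relative tolerance**
(`bin_bands()`); each bin is one scored locus with the median size as
representative. A primer pair that fails to amplify at all in a sample is
recorded as NA for the whole pair×sample block — distinct from a genuinely
absent band — and NAs are excluded from every denominator downstream.

PIC is `1 − Σ pᵢ²`. Two modes are provided:

* **multiallelic** (default): each band of a pair is an allele class and
  `pᵢ` is its share of the pair's presence calls. This is the pair-level
  convention under which published values up to 0.88 arise — a dominant
  biallelic locus caps at 0.5, so pair-level values above 0.5 imply the
  pair's bands were treated as one multi-allelic locus.
* **dominant**: per-band biallelic PIC `2p(1−p)` averaged over the pair's
  bands, capped at 0.5 by construction.

A locus is polymorphic when present in ≥1 and absent in ≥1 non-NA sample;
a pair when any of its loci is. Percentages are rounded to one decimal
(20/28 → 71.4) and PIC to two decimals in reports. Transferability of a
marker set to a related species is the percentage of pairs amplifying in
the focal species that also amplify in that species, rounded to the
nearest integer (1 of 3 → 33).

## Clustering and bulked-sample selection

Jaccard similarity `a/(a+b+c)` is computed over pairwise-complete (non-NA)
bands, with `J = 1` when two profiles share no presences at all among
co-scored bands (two blank profiles are indistinguishable). Clustering is
UPGMA on `d = 1 − J` with node height `d/2`, so cophenetic distances equal
the merge distances. Ties between equally close cluster pairs break to the
pair containing the lexicographically smallest sample id, and each merge
places the cluster with the smallest id on the left — together these make
the Newick output byte-reproducible. `cut_clusters()` supports a k-based
cut (default k = 3, the grouping used in the motivating study) and refuses
ambiguous cuts where the boundary merges are tied; a height-threshold cut
can be emulated by choosing k from the `height` vector.

The bulked-sample rule selects bands **present in every tolerant bulk and
absent from every sensitive bulk**. A bulk of several samples presents a
band when at least one member carries it (pooled-DNA semantics). Any NA in
a bulk sample disqualifies the band, which is reported separately rather
than silently dropped. Adding bulks can only shrink the candidate set.

## The synthetic panel generator

No genotype data are released with the motivating study, so
`simulate_panel()` builds panels in which every pipeline stage has known
ground truth. The default configuration mirrors the study design: 18
samples (16 cultivated genotypes and two related wild species), eight
mature miRNAs (four per arm), six selected SSR motifs (TC/AG, GAA/CCA,
GACCA/CTACT) hosted in synthetic trait-responsive transcripts, two
parallel tolerant bulks against one sensitive bulk, and three planted
tolerance-linked loci whose product lengths (988, 687 and 495 bp) equal
the cloned products of the three selected markers in the study.

Genomes are assembled from independent **marker cassettes** — forward
primer site + insert + reverse-complemented primer site — separated by
spacers longer than the PCR window (3.1 kb), so each planted locus
amplifies exactly once and cassettes cannot cross-amplify. For this reason
the genome length is derived from the cassette count and spacer length
(~320 kb per genotype at study scale) rather than being a free parameter.
Background composition is uniform (GC 0.5). Neutral cassettes come in
three types:

* *monomorphic* (~30 %): identical product in all genotypes;
* *group-structured*: insert length varies with a latent genotype group,
  with the tolerant-carrier and sensitive groups sharing lengths;
* *idiosyncratic*: per-genotype lengths from a grid spaced > 2 % apart
  (so bins never chain), with the experimental tolerant and sensitive
  bulk genotypes constrained to share a length.

The two constraints in italics are deliberate: any neutral band present in
all tolerant bulks and absent from the sensitive bulk would be
indistinguishable from a planted tolerance locus, so neutral variation is
generated to never mimic the bulk contrast. This isolates the three
discriminative cassettes — insertions carried only by tolerant-haplotype
genotypes — as the exact expected output of the selection rule, which is
what the parameter-recovery suite verifies (50 seeded noise-free panels,
zero false positives or negatives). Partial cross-species transferability
is modelled by omitting the two miRNA+miRNA selected-marker cassettes from
the *P. atlantica*-like genome (1 of 3 selected markers transferable,
33 %) while the *P. khinjuk*-like genome keeps all three (100 %).

Scoring noise is modelled by `degrade_bands()`: each presence call flips
to absence independently with probability `dropout` (default 0). The
false-negative rate of bulk selection increases monotonically with
dropout; dropout can also create false positives by erasing a sensitive
bulk's band, which is a property of the selection rule, not a bug.

What the generator does **not** emulate: sequence-level mutation and
annealing competition (all variation is presence/absence and insert
length), multi-band stutter within one locus, organellar genomes and
retrotransposon context (the study's annotation of selected products as
mitochondrial/LTR sequences is biological interpretation outside this
package's scope), and population-genetic structure (no allele
frequencies, recombination or selection). Passing tests therefore
demonstrate correctness of the computational pipeline under its own model
of banding data, not performance on real gels.

Determinism: one seed drives the whole panel; identical configurations
give byte-identical FASTA output, and the generator saves and restores the
caller's RNG state. All planted coordinates are re-verified against the
assembled genomes before a panel is returned.

## Problem sizes and numerical choices

The test suite and the acceptance script run at the following scales,
chosen so a complete run stays comfortable on a single CPU: the
study-scale panel (18 genotypes, 76 pairs, ~320 kb per genome) for
end-to-end checks, a compact three-sample demo panel (nine primers, 33
pairs) for repeated-simulation studies such as the 50-panel recovery
suite, 500 random sequences of 200–2000 nt for the SSR oracle comparison,
and 200 replicates for the dropout calibration check.

Other fixed numerical conventions: band-size binning tolerance 2 %
(relative to the smaller size, single linkage); UPGMA tie tolerance 1e-15
on merge distances; Newick branch lengths printed with up to 10
significant digits; percentages rounded to one decimal and PIC to two in
reports; primer minimum length 15 nt with N disallowed in primers (but
allowed in templates, where it never matches).

## Known limitations

* The exact scoring the original authors used to combine motif abundance
  with gene activity is unstated; the weighted-rank scheme here is a
  declared substitute, and with no activity table the choice reduces to
  abundance alone.
* Anchor length and sequence of the published ISSR primers are not
  reproduced in the main text; defaults (anchor 2 nt, target length 18)
  are the package's own and are recorded in each primer's provenance
  fields.
* The published per-pair PIC tables are supplementary-only; the package
  can summarise them (`pic_summary()`) once a user supplies the tables,
  but cannot bundle them.
* One published summary ("PIC values of 33 % of the markers were more
  than 0.50" for 20 markers) is arithmetically inconsistent — no integer
  out of 20 rounds to 33 % — and is intentionally not reproduced.
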