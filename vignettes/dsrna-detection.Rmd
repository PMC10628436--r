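---
title: "Detecting double-stranded RNA regions from region-skipping in long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting double-stranded RNA regions from region-skipping in long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The signal: reverse transcriptases stumble on hairpins

Long double-stranded RNA (dsRNA) — typically formed when two inverted
repeats in the same transcript base-pair into a hairpin — is what cytosolic
innate-immune sensors such as MDA5 recognise. Catalogues of dsRNA are
usually built from A-to-I editing evidence: ADAR enzymes bind duplexes, so
clusters of known editing sites ("editing-enriched regions", EERs) mark
structure. That logic fails exactly where it is most interesting, in
transcripts that are structured but *unedited*.

This package exploits an editing-agnostic signal instead. During library
preparation the reverse transcriptase occasionally switches template across
a stable hairpin, producing a cDNA with an internal deletion that aligns
like a spliced-out intron (a CIGAR `N` run, or a `~` item in minimap2's
`cs` difference string). These artifactual skips differ from real splicing
in three measurable ways:

* they affect only a small fraction of the molecules covering the region,
  whereas splice junctions are used by none or most of them;
* their boundaries wobble from read to read instead of aligning exactly;
* they are not flanked by splice-site motifs (GT...AG).

A random-forest classifier over per-window summaries of these properties
separates dsRNA-induced skipping from splicing and other alignment
artifacts, after which candidate windows are verified thermodynamically
with RNAfold.

## The per-window feature vector

For every 2500-nt window with at least six overlapping reads and at least
one region-skipping read (the *candidate filter*), 38 predictors are
computed from the reads and the reference:

| feature | definition |
|---|---|
| `skip_ratio` | reads with an internal skip / all reads overlapping the window |
| `len_skip` | mean skipped length over skip events (nt) |
| `group_num` | number of skip-boundary groups, averaged between start and end sides |
| `std_start`, `std_end` | population SD of boundary coordinates within a group, averaged over groups |
| `gc_skip` | GC fraction of the skipped reference segment, averaged over events |
| `bp_start_AA` ... `bp_end_TT` | frequencies of the first-two and last-two reference bases of the skipped segment (16 + 16 dinucleotides) |

Conventions worth making explicit:

* Coordinates are 0-based half-open throughout; editing catalogs are
  converted from 1-based on load, BED output is 0-based.
* A skip belongs to a window when its **start** coordinate falls inside it,
  so an event straddling a window edge is counted exactly once.
* Skips shorter than 20 nt (configurable, `min_skip_len`) are treated as
  small deletions rather than region-skipping; the literature gives no
  floor, and without one every 1-nt deletion would count.
* Boundary dinucleotides and GC content are read from the *reference*:
  the skipped bases are absent from the read by definition.
* The population standard deviation (divisor *n*) keeps singleton groups at
  0 rather than undefined.
* `cs` tags take precedence over CIGAR strings when both are present; the
  two encodings of the same alignment are required (and tested) to yield
  identical events.

### Grouping skip boundaries

Skip starts (and, separately, ends) are clustered with two rules: sites
within 100 nt of each other belong to the same cluster (single linkage), and
within a cluster every reported group must have its leftmost and rightmost
coordinates strictly within 100 nt of the group median. The second rule is a
constraint, not an algorithm, and several partitions can satisfy it. We
resolve it as the *coarsest* valid contiguous partition — the fewest groups,
computed by dynamic programming, tie-broken by greedily extending the first
group. Coarseness is the natural reading: the grouping exists to count
distinct skipping event clouds, and any finer split would inflate
`group_num` and deflate the within-group dispersions. A recursive
"split at the largest gap" heuristic was considered and rejected: on dense
random instances it returns more groups than necessary in roughly 40% of
cases, i.e. it fails its own defining property.

## Training data

Positives are EER-derived: catalog editing sites are scanned for at least
three sites within any 50-nt span (strictly, max − min < 50), enriched
intervals are unioned, intervals within 1 kb are merged, and each merged
region is folded and kept only when its structure passes the dsRNA filter
below. Positive intervals narrower than the window size are widened
symmetrically to 2500 nt before feature extraction, so that both classes
are profiled over comparable spans and boundary skips (which start at the
hairpin edge, typically just outside the first edited site) are not lost.

Negatives are uniformly sampled 2500-nt windows that do not share a single
base with any positive, pass the same candidate filter, and are drawn until
the classes balance; sampling is seeded and fails loudly after a bounded
number of attempts.

## The classifier

A random forest with a fixed, externally tuned configuration: 100 trees,
Gini impurity, bootstrap sampling, no depth limit, minimum split size 2,
minimum leaf size 4, and 20% of the features considered per split
(`mtry = floor(0.2 * 38) = 7`). The `randomForest` implementation pins the
remaining behaviour; the mapping (`ntree`, `nodesize`, `mtry`, `replace`)
is recorded in the model object for reproducibility. Gini is that
implementation's only classification criterion, which is exactly the
configured choice. Serialized models embed the feature-name order, the
configuration and a fingerprint of the training rows, and reproduce
probabilities exactly after reloading.

Evaluation is stratified k-fold cross-validation (default k = 20): per-fold
accuracy at the 0.5 threshold, plus one ROC AUC and one area under the
precision-recall curve from the pooled out-of-fold probabilities. The AUPRC
is step-interpolated average precision over distinct thresholds.

Feature contributions are permutation-based: the coefficient of
determination (R²) between the predicted positive-class probability and the
0/1 label is computed on a stratified 20% held-out split, each feature
column is permuted five times, and the contribution is the mean decrease in
R². Applying R² to a classifier requires choosing what to correlate; using
the predicted probability (rather than the hard label) keeps the measure
continuous.

## Structure curation

Candidate sequences are folded with RNAfold (ViennaRNA) behind a narrow
adapter — sequence in, dot-bracket and MFE out — so tests can substitute a
deterministic engine. Three derived metrics drive classification:

* **Adjusted MFE (AMFE)** = MFE / length × 100, kcal/mol per 100 nt. The
  dsRNA filter is AMFE ≤ −35. The literature prints the threshold as
  "−0.35" while defining AMFE with the ×100 factor, under which −0.35 per
  100 nt would be passed by almost any sequence and −0.35 per nt by almost
  none except via the ×100 reading; we therefore read it as −35 kcal/mol
  per 100 nt and expose it as a parameter (`amfe_max`).
* **Stem length**: helices (maximal runs of stacked pairs) are chained into
  a duplex while consecutive helices are separated by interior loops or
  bulges of at most 30 nt per side (configurable); the duplex with the most
  base pairs is reported. RNAfold output does not come with a stem-length
  definition, so this chaining procedure *is* the definition used here —
  it is deterministic and testable against an exhaustive chain enumeration.
* **Mismatch fraction**: the share of positions between the duplex's
  outermost pair that are not paired within the duplex. Note that the
  terminal hairpin loop counts against this budget, so a qualifying dsRNA
  (≥200 bp stem, ≤20% mismatches) needs a loop much shorter than its stem.

All three thresholds are inclusive (≥, ≤). Model-positive windows that fail
any of them are reported as generally "structured RNA" rather than novel
long dsRNA. T is mapped to U and N never pairs; sequences beyond 5 kb are
skipped with a logged reason rather than an error.

## Genome-wide discovery

Chromosomes are tiled with 2500-nt windows at a 1250-nt stride, so every
covered base lands in one or two windows. A trailing partial window is kept
only when strictly longer than one stride: a chromosome of 5000 nt yields
starts {0, 1250, 2500}, not a fourth window of exactly half width.
Candidates pass the read filter, are scored by the model, retained at
probability strictly above 0.5, excluded if they share even one base with a
curated positive region (those are known dsRNA, not discoveries), folded,
and classified. Overlapping positive windows from adjacent strides are
reported as-is rather than merged, keeping the window the unit of account.

The per-region A-to-I editing index is pooled G/(A+G) over catalog sites
covered by more than three reads, counting aligned non-deleted bases;
minus-strand sites count T positions read as C. Regions with no qualifying
site report a missing index, never zero.

## What the synthetic corpus emulates — and what it does not

The generator plants three locus archetypes in a uniform-random genome,
spaced at least one window apart:

* **dsRNA loci**: an inverted repeat (arm 200–600 nt, loop 50–500 nt).
  Each read skips the hairpin independently with a per-locus fraction drawn
  from 0.02–0.2, with boundaries jittered N(0, 30 nt) and no motif — the
  template-switching archetype. Arms receive 10–30 editing sites (a dense
  triple within 50 nt in each arm, as ADAR decorates both strands of the
  duplex), realised as A→G substitutions in a per-site fraction (0.1–0.5)
  of covering reads.
* **splice loci**: a GT...AG intron of 300–1500 nt between 300-nt exons,
  skipped exactly at its junctions with a per-locus probability drawn from
  Beta(0.3, 0.3) — the bimodal inclusion archetype.
* **noise loci**: a fixed, motif-free skip of 100–800 nt present in
  0.3–0.9 of reads — consistent region-skipping from genetic variants,
  alignment artifacts or error hotspots, the documented third population of
  covered control regions in real long-read libraries. Without it, the
  GT/AG dinucleotide features alone would separate the two remaining
  classes perfectly, which no real dataset supports; with it, the skipping
  ratio carries the load, as observed in practice.

Coverage is Poisson with mean 20 reads per locus, comfortably above the
six-read floor. Every record carries a consistent CIGAR and `cs` tag, and
every artifact (FASTA, sorted SAM, truth table, editing catalog, manifest)
is byte-deterministic in the seed.

Deliberately not emulated: sequencing-error profiles beyond the planted
substitutions, isoform structure, multi-intron genes, strand-specific
libraries, reference bias, and dsRNA formed across distant repeats rather
than a single hairpin. Passing tests on this corpus therefore demonstrate
that the pipeline recovers the *mechanisms it models* — low-frequency
jittered motif-free skipping against splicing and consistent artifacts —
not that real-data accuracy will match the synthetic numbers.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen so the
full pipeline executes in minutes on one CPU: corpora of 100 + 100 + 100
loci on a 1.5-Mb genome (about 6000 reads) for corpus-level checks, 30 + 30
+ 30 for discovery recall, and 8 + 8 + 8 for unit fixtures. Structural
verification with the real engine is exercised on short constructed
hairpins and single windows (an RNAfold call on 2500 nt takes seconds);
corpus-level evaluations use EER intervals as positives without per-locus
folding, since planted hairpins are dsRNA by construction and the
structural filter is validated separately against its own oracle.

Other numerical choices: feature TSVs serialise doubles as C17 (`%.17g`)
so round-trips are bit-exact; ties in the grouping DP go to the longest
first group; `group_positions` on a single coordinate returns one singleton
group with zero spread; windows with no qualifying skip events refuse
feature extraction (the candidate filter should have removed them);
probabilities exactly at 0.5 are *not* discoveries ("more than 50%"); a
merge distance of exactly 1 kb merges; coverage of exactly three reads
excludes an editing site ("more than three").

## Limitations

The classifier is only as good as its positive set: EER-derived regions
inherit REDIportal's biases (Alu-dominated, editing-dependent), and the
negative set deliberately contains splicing, so transcripts that are both
spliced and structured are hard calls. The stem/mismatch definitions are
one reasonable concretisation among several; comparisons across tools
should re-derive them from the dot-bracket rather than trust the numbers to
be interchangeable. Folding whole 2500-nt windows ignores that the true
duplex may extend past window edges or pair across windows. Finally, the
editing index pools sites, so one highly covered site can dominate a
region's value.
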