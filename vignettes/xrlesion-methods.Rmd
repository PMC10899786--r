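---
title: "Locating CPD lesions in XR-seq reads and quantifying incision site selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating CPD lesions in XR-seq reads and quantifying incision site selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xrlesion)
```

## The measurement problem

Nucleotide excision repair (NER) excises a short single-stranded fragment
around a helix-distorting lesion.  XR-seq sequences these fragments, so
each read's two ends are direct observations of the 5' and 3' incision
sites — but the lesion inside the fragment is ordinarily invisible, which
makes per-fragment incision geometry (how far each cut lies from the
lesion) unmeasurable.  Cytosine-containing cyclobutane pyrimidine dimers
(CPDs) offer a way in: cytosine deamination, normally extremely slow, is
accelerated by orders of magnitude inside a CPD.  A deaminated C is read
as T, so aligning the fragment back to the genome leaves a C>T mismatch
at the lesion (or CC>TT when both cytosines of a CC dimer deaminate).
This package treats that mismatch as a single-nucleotide lesion tag and
builds the downstream incision-site analyses on it.

Everything is exercised against a simulator with a complete ground-truth
table, so each stage is testable without any sequencing download.

## Coordinate and distance conventions

Read coordinates are 1-based and intervals closed, following
IRanges/GRanges practice; BED input and output converts at the boundary,
and SAM positions are taken as 1-based on ingest.  All read-level
quantities are expressed in read orientation: a minus-strand read's
sequence and flanks are reverse-complemented so that "3' flank" always
means past the read's 3' end.

Cut-site distances are lesion-inclusive: `d5` counts from the 5' read end
to the lesion inclusive, `d3` from the lesion to the 3' end inclusive, so
`d5 + d3 = L + 1` for a read of length `L`.  For a tandem CC>TT event the
lesion is anchored at the half-base between the two cytosines; distances
become half-integers and satisfy the same identity.  A single C>T inside
a CC dimer is genuinely ambiguous (it may be the 5' or the 3' cytosine);
the simulator mirrors this by choosing the deaminated cytosine uniformly
and recording the truth.

On position axes, `-1` denotes the first nucleotide before the 3' cut
site and `+1` the first nucleotide after the 5' cut site.

## The simulator and what it emulates

`sim_config()` / `simulate_xrseq()` generate an i.i.d. random genome and
excised fragments with:

* a lesion dipyrimidine of configurable type (`TT`, `CT`, `TC`, `CC`),
  placed on a uniformly chosen strand at a uniformly chosen genomic
  occurrence;
* a 3' cut-site distance drawn from a categorical distribution over
  5–9 nt (mode 7) and a 5' distance over 15–23 nt (mean ~19.3) — chosen
  to reproduce the reported human geometry of mean distances near 19.4
  and 7.4 nt and fragment lengths of 22–30 nt;
* incision coupling: after drawing `d5`, the 3' distance is set to
  `d3_base - c (d5 - mean(d5))` for a coupling fraction `c`.  The default
  `c = 0.46` is the human estimate recovered by the coupling regression.
  The compensated value is rounded *stochastically* (`floor(x + U)`,
  `U ~ Uniform(0,1)`) and clipped to at least 1.  Stochastic rounding is
  a deliberate design choice: deterministic half-away rounding makes
  `E[d3 | d5]` a staircase whose least-squares slope differs from `-c`
  by up to several percentage points, whereas unbiased rounding keeps the
  configured coupling exactly equal to the regression slope in
  expectation, which is the property the estimator-recovery tests rely
  on.  With the default distance supports the clip at 1 never binds;
* per-lesion deamination (`p_deaminate = 0.5` by default, an appreciable
  per-fragment tagging rate at an early repair timepoint) and tandem
  deamination of CC lesions (`p_tandem = 0.15`);
* a lesion dinucleotide mix of 53% TT, 17% CT, 20% TC and 10% CC,
  following reported CPD frequencies by dipyrimidine class;
* background substitution errors (`seq_error_rate = 0.001`) that never
  hit the lesion dinucleotide, so truth labels stay unambiguous;
* mispriming truncation: with probability `p_misprime`, a fragment with
  an internal adapter-homologous TGG (in read orientation) is truncated
  immediately 5' of its 3'-most TGG that still leaves at least `Lmin`
  bases.  The truncated read then carries a genomic TGG right past its
  new 3' end — exactly the signature the TGG filter removes.  The search
  runs on the actual (possibly deaminated or error-carrying) molecule,
  so a TGG created by an error can, rarely, produce a truncated read
  whose genomic flank is not TGG; that residual imperfection is faithful
  to the mechanism.

What the simulator does *not* model: PCR duplication and amplification
depth, adapter chemistry, UV dose response, repair kinetics over time,
non-uniform genome composition (isochores, repeats) and mappability
structure.  Tests passing on this generator therefore validate the
*bookkeeping and statistics* of the pipeline — coordinate conventions,
filter logic, estimator calibration — not robustness to real-genome
alignment artifacts.

Nucleosome dyads are tiled at a configurable repeat length with uniform
jitter, and an optional boundary modulation adds a configurable shift to
`d5` (compensated through the coupling rule) for lesions in a configurable
distance band from a dyad, emulating incision modulation at nucleosome
edges.

## Read placement and mismatch extraction

The internal placer (`build_index()`, `align_read()`) does exact
occurrence search on both strands with a fallback to a unique
one-substitution placement, preferring exact hits and dropping any read
whose best-scoring placement is not unique ("ambiguous") —
reproducibility is preferred over recall.  It is a deliberately small
stand-in for a production seeded aligner at synthetic-genome scale, and
it shares that aligner's key blind spot by construction: a read with two
adjacent mismatches (tandem deamination) cannot be placed, which is what
motivates the revertant path.  Mismatches are extracted by base-wise
comparison against the reference interval and carry offsets from both
read ends plus the reference trinucleotide context in read-strand
orientation.  A minimal SAM dialect (pure-`M` CIGARs; anything else is
flagged `has_indel` and excluded by the basic filters) supports external
alignments; the importer is cross-checked in the tests against an
independent SAM/BAM reader.

## Read filters

`basic_filters()` applies, in a fixed and reported order: indel reads,
reads with more than one mismatch (these are routed to the tandem path,
not discarded), reads containing N, and reads outside the species read
length range.  Counts are conserved (`removed + retained = input`) and a
read failing several rules is counted under the first.

The species length range can be supplied (presets: human 22–30,
Arabidopsis 24–30, yeast 22–25, E. coli 11–13) or derived from the data:
for each read length, the position relative to the 3' end with maximal
dipyrimidine frequency is found, that frequency is multiplied by the
number of reads to give a score, and the returned range is a maximal
contiguous run of lengths whose score stays at or above a configurable
fraction (default 0.2) of the maximum.  The fraction operationalises a
"sharp decline" that was originally judged by eye, and is documented as a
heuristic.  Among disjoint qualifying runs the one containing the
expected length wins; otherwise longer lengths are favoured, since short
fragments may reflect degradation.

`tgg_filter()` removes reads whose 3-nt genomic 3' flank (read
orientation) is exactly TGG; a `TG` mode gives the stricter variant.  The
filter is applied before every downstream analysis.

## Lesion calling

C>T mismatch positions are tabulated per read length
(`position_matrix()`), and positions are called lesion-enriched when
their within-length frequency is at least four sample standard deviations
above the mean of the ten positions closest to the 5' incision site,
where no CPD is expected (`call_enriched_positions()`).  The two-sided
normal tail at four standard deviations is 6.3e-5, the significance
usually quoted with this rule.  Choices the rule leaves open, decided
here and configurable: the background uses the sample (n−1) standard
deviation; the background is computed within each read length's own
frequency vector (matching the stratified presentation rather than a
pooled one); the threshold is inclusive (at least four); a zero-variance
background is flagged degenerate and requires a strict excess over the
mean; unoccupied integer positions count as zero-frequency cells.
Non-C>T mismatches are kept in a parallel channel as controls rather than
discarded.

## Tandem CC>TT recovery

`enumerate_revertants()` replaces each TT occurrence (overlapping ones
included) by CC; `adjudicate()` calls a tandem event iff exactly one
revertant has an exact genomic occurrence, that occurrence is unique, and
the original read has none.  Occurrence counting is exact matching over
both strands; a variant with two or more occurrences is rejected as
multimapped.  The original-sequence criterion is applied literally on
*exact* hits: a read whose original sequence aligns elsewhere with one
mismatch but no exact hit is still callable.  The reason codes
(`original_aligned`, `no_variant_hit`, `multi_variant_hit`,
`variant_multimapped`) make rejections auditable; `original_aligned` is
checked first because it is the cheapest and most informative diagnosis
for a read that never needed reverting.  The machinery is generalised to
any dinucleotide pair, giving control modes such as GG>AA that should
find nothing in deamination-only data.  Calls then pass the same length
and TGG filters as the single-mismatch channel and yield half-integer
incision records.

## Incision statistics

*Contribution decomposition.*  For each incision side, the mean cut-site
distance is computed per read length; differences from the minimum
length's mean, weighted by read length frequencies and summed per side,
give the two sides' contributions to length variability, normalised to
100%.  Because `d5 + d3 = L + 1`, the two weighted sums always total the
mean length excess over the minimum, so the percentages are a true
decomposition.  A single observed read length yields `NA`.

*Coupling.*  Ordinary least squares (the straightforward reading of a
"standard linear regression") of `d3` on `d5`; the coupling percentage is
−100 times the slope.  The identity `slope(L ~ d5) = 1 + slope(d3 ~ d5)`
holds exactly and is asserted in the tests on every run.  The shuffle
control permutes `d5` across records without replacement and recomputes
`L = d5 + d3 - 1`; it preserves both marginal multisets, destroys the
dependence, and therefore has length-on-`d5` slope 1.00 and coupling 0%
in expectation.  Each read contributes one point to the regression;
whether repeated distance pairs should be deduplicated is left as an open
question by the source material, and weighting by read is the natural
default.

*HYV profile.*  H = not G, Y = C or T, V = not T; the 5' incision falls
between Y and V, so the incision-proximal signal is an HYV with Y on the
last base before the read and V on the first read base.  Frequencies are
computed on genomic context (the read body taken from the reference, as a
coordinate-based sequence extraction would give), reported at the Y base,
with significance from the four-standard-deviation rule against the six
5'-most profile positions.  In cut-distance-stratified profiles,
positions within two bases of the lesion are masked by default because
dipyrimidine-forming sequences bias composition there.

*Composition and information.*  Per-position base frequencies over
flanked contexts, with information content computed as relative entropy
against a background derived from the input's own GC content
(`q_G = q_C = GC/2`), i.e. the normalisation a GC-aware sequence logo
applies.  No small-sample correction is applied; at the read counts this
package targets the correction is negligible, and leaving it out keeps
the quantity a pure relative entropy.

## Nucleosome-proximal profiles

Dyads are first filtered against blacklist regions after extension by
73 bp on either side (the nucleosome core footprint).  Every
(lesion, dyad) pair within 500 bp contributes the record's distances to
the bin at the strand-aligned signed distance (plus strand:
`lesion − dyad`; minus strand: negated), so 5' incisions always point in
the negative direction.  A lesion near two dyads contributes to both
bins, but the grand means count each record once by default
(`grand_per_pair` flips this; the right choice is not determined by the
source material, so it is exposed).  Each bin's sample is compared to the
scalar grand mean by a two-tailed one-sample t-test — the comparison is
against the mean across bins, not against the pooled distribution — with
a fixed cutoff of 5e-5 and no multiple-testing correction; a Welch
two-sample variant would be a trivial extension but is not the default.
A zero-variance bin away from the grand mean is flagged with p reported
as 0.  Note the extreme-tail t reference is exact under normality; with
small bins of strongly discrete distances the realised false-positive
rate can exceed the nominal one, which is why the null-calibration test
uses Gaussian distances to isolate the machinery itself.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on synthetic data:
genomes of 20–200 kb, 10^3–10^5 fragments depending on the precision the
check needs (estimator-recovery checks use 10^5 records so that three
Monte-Carlo standard errors correspond to well under one percentage point
of coupling).  All randomness flows from explicit seeds; rerunning any
stage with the same configuration reproduces byte-identical outputs.

## Known limitations

* The internal placer tolerates at most one substitution and drops
  multi-mapped reads; it is a stand-in, not an emulation, of a seeded
  production aligner, whose seeding heuristics are not reproduced.
* The simulator's i.i.d. genome understates multi-mapping ambiguity and
  contains no repeat structure; recall figures on it are upper bounds.
* Reads with more than one tandem event, or with a tandem and an
  additional single mismatch, are out of scope of the revertant path.
* The per-read mispriming search is sequential; at very large simulated
  depths it is the slowest generator step.
* Graphical logo rendering is intentionally out of scope; the
  composition matrix contains everything a renderer needs.
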