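# xrlesion

Locating UV lesions inside excised DNA-repair fragments, and measuring
how the repair machinery chose its cut sites.

## The problem

Nucleotide excision repair (NER) removes bulky DNA lesions — such as the
cyclobutane pyrimidine dimers (CPDs) produced by UV light — by cutting
the damaged strand on both sides of the lesion and releasing a ~22–30 nt
fragment.  XR-seq sequences those excised fragments, so every read's 5'
and 3' ends are direct observations of the two incision sites.  The
lesion itself, however, is normally invisible, so per-fragment incision
geometry cannot be measured.

Cytosine-containing CPDs betray their position: cytosine deamination is
enormously accelerated inside a CPD, and a deaminated C is sequenced as
T.  Aligning such a read to the reference genome leaves a C>T mismatch
(or a tandem CC>TT) exactly at the lesion.  `xrlesion` turns this
signature into a measurement device for incision-site selection, for
anyone analysing XR-seq (or similar excision-fragment) data.

## What the package computes

With lesion-inclusive cut-site distances `d5` (5' end to lesion) and
`d3` (lesion to 3' end), so that `d5 + d3 = L + 1` for a read of length
`L` (half-integers for tandem CC>TT events, anchored between the two
cytosines):

* **Lesion calling** — C>T mismatch positions per read length, called
  enriched when ≥ 4 standard deviations above a background from the ten
  5'-most positions (two-sided normal tail 6.3e-5); substitution and
  trinucleotide-context spectra with the dipyrimidine fraction.
* **Mispriming filter** — reads whose genomic 3' flank is `TGG` (the
  start of the 3' adapter) are removed as probable PCR-mispriming
  truncations.
* **Tandem recovery** — reads that a one-mismatch aligner drops because
  of tandem CC>TT deamination are aligned by *revertant sequences*: each
  TT is restored to CC in turn, and a call is made iff exactly one
  revertant matches the genome exactly once and the original matches
  nowhere.
* **Contribution decomposition** — the share of fragment-length
  variability attributable to each incision site, from length-weighted
  position differences.
* **Incision coupling** — ordinary least squares of `d3` on `d5`; the
  coupling percentage is `−100 ×` slope, with a 5'-distance shuffle as
  the independence control (slope of length on shuffled `d5` = 1.00,
  coupling 0%).
* **HYV motif and composition** — frequency of the 5'-incision motif HYV
  (H = not G, Y = C/T, V = not T; the cut falls between Y and V) around
  reads, and per-position base composition with GC-normalised relative
  entropy.
* **Nucleosome profiles** — mean `d5`/`d3` by strand-aligned
  lesion-to-dyad distance within ±500 bp, with blacklist filtering and
  per-bin t-tests against the grand mean (cutoff 5e-5).
* **Simulator** — a ground-truth generator for all of the above:
  fragments with configurable cut-distance distributions, coupling,
  deamination, sequencing errors, mispriming truncation, and nucleosome
  boundary modulation, plus FASTA/FASTQ/SAM/BED/TSV export.

## Worked example

```r
library(xrlesion)

cfg    <- sim_config(n_fragments = 5000, seed = 7)
genome <- generate_genome(cfg)
fr     <- generate_fragments(genome, cfg)

mm  <- collapse_tandem(mismatch_table(fr$reads, genome))
mismatch_spectrum(mm)          # C>T dominates: 1177 of ~1275 events (92%)
context_spectrum(mm)$dipyrimidine_fraction
#> 0.994                        # C>T mismatches sit in dipyrimidines

rec <- incision_records(fr$reads, mm, kind = "single_CT")
coupling_regression(rec, "d3_vs_d5")
#>     target      slope intercept       p_value coupling_percent    n
#>   d3_vs_d5 -0.5643742  18.09307 1.672325e-150         56.43742 1150

sh <- shuffle_control(rec, seed = 99)
round(coupling_regression(sh, "read_length_vs_d5")$slope, 2)
#> 0.99                         # independence control: slope ~ 1

ct <- contribution_decomposition(rec)
c(ct$percent_5prime, ct$percent_3prime)
#> 94.6  5.4
```

Read this as: the generator planted lesions whose 3' incision
compensates about half of every 5' shift (configured coupling 0.46); the
single-C>T channel recovers a coupling of ~56% (slightly above the
configured value because the single mismatch only brackets the lesion
within its dipyrimidine), the shuffle control destroys it, and — because
the 3' cut tracks the lesion while the 5' cut varies — most length
variability is attributed to the 5' side.

The full pipeline (simulate → align → filter → call → tandem → incision
→ nucleosome profile), with TSV outputs and a JSON manifest:

```r
run_pipeline(pipeline_config(outdir = "out", seed = 1, n_fragments = 2000))
```

or from a shell via `inst/scripts/xrlesion.R`.

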