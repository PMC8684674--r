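---
title: "Detecting insertion sites of known elements from long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting insertion sites of known elements from long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insertscout)
```

## The problem

Insertional mutagenesis screens (Tnt1 or Ac/Ds transposon tagging, T-DNA
transformation) disrupt genes by scattering copies of a known DNA element
through a genome.  Recovering where each copy landed is the central
bookkeeping task of such a screen: the insertion coordinate identifies the
disrupted gene, and the set of coordinates per line is the line's genotype.
Long reads make this almost direct — a single Nanopore read often covers an
entire element copy together with kilobases of host sequence on both sides —
so the computational job reduces to finding the reads that carry the
element, cutting out the host-derived *flanking sequences*, placing those
flanks back on the reference, and turning the resulting junction
coordinates into a confident, annotated site list.

`insertscout` implements that pipeline as composable, data-frame-first R
functions plus a one-command runner, together with a synthetic-data
generator that makes the whole chain testable end to end, and a
combinatorial barcode-pooling decoder for multiplexed mutant panels.

## The pipeline

Five stages, each exposed as its own function:

1. **Target screen** — `find_tagged_reads()` aligns the element sequence
   against every read (both strands) and reports merged *target spans* per
   read.  Hits are kept at E-value ≤ 10⁻³.
2. **Flank extraction** — `extract_flanks()` cuts out the read segments on
   either side of each span, recording which end of the flank touches the
   element (`junction_end`) and which end of the element it abuts
   (`element_side`, 5′/3′).
3. **Flank mapping** — `map_flanks()` aligns flanks to the reference,
   keeps hits with aligned length strictly greater than 200 bp and
   identity at least 80 %, requires a unique placement, and derives the
   genomic breakpoint from the junction end and the alignment orientation.
4. **Site calling** — `cluster_breakpoints()` groups breakpoints within
   50 bp (single linkage) into insertion sites with read support, extent
   and 5′/3′ side coverage; `annotate_genes()` attaches genes within
   2000 bp; `filter_sites()` applies the minimum read support (default 1).
5. **Significance** — `windowed_counts()` tiles the genome into 1 kb
   windows, `fit_zip()` fits a zero-inflated Poisson to the window read
   counts, and `site_pvalue()` assigns each site the upper-tail
   probability of its support under that background.

### Flank orientation bookkeeping

The junction logic lives in one four-row truth table
(`element_side_of()`, `breakpoint_of()`).  A flank left of its span in the
read touches the element with its *right* end; if the span is on the
read's forward strand that end is the element's 5′ end, otherwise its 3′
end.  Mapping to the genome then sends `junction_end` through the
alignment orientation: a right-junction flank mapped forward puts the
breakpoint at the alignment end, mapped reverse at the alignment start,
and mirror-image for left-junction flanks.  On error-free simulated data
with no target-site duplication, both flanks of a junction-spanning read
land on exactly the planted coordinate — a property the test suite asserts
literally.

## The built-in aligner

The engine is a seed-and-extend local aligner written in C++: exact
*k*-mer seeds on both query strands are grouped into diagonal clusters,
and each cluster is extended with banded affine-gap Smith–Waterman with
full traceback.  Scoring defaults are BLASTN-like (+2/−3, gap open −5,
gap extend −2); E-values use the Karlin–Altschul form
*E = K·m·n·e^(−λS)* with the ungapped nucleotide constants λ = 1.28,
K = 0.46 and search space `query_len × total_subject_len`.  The constants
are an approximation for gapped scores; only the permissive ≤ 10⁻³
thresholding is consumed downstream, so calibration error is tolerable and
deliberately not corrected.

Three design points matter in practice:

* **Seed word length.**  The engine default is k = 13, which is the right
  sensitivity for pairwise work.  The *pipeline* stages default to k = 28 —
  the word size the standard BLASTN binary uses for its default (megablast)
  task — because at genome scale a 13–15 bp chance exact match already
  passes E ≤ 10⁻³ and would fabricate target spans; a 28 bp exact seed is
  still found hundreds of times across a multi-kilobase element even at
  ten percent read error, so sensitivity is not the binding constraint.
* **Adaptive extension.**  The banded DP is first confined to the seeded
  query range plus a pad.  When the optimal alignment ends near a
  restricted row, window or diagonal bound (within 128 bp), the extension
  is re-run with a four-fold pad and doubled band until it ends strictly
  inside.  This matters at high error rates, where the junction-proximal
  stretch of a flank can be seedless for hundreds of bases: without the
  retry the alignment stops short of the junction and the breakpoint
  drifts by the truncated amount, fragmenting true sites into one-sided
  satellites.
* **Exhaustiveness.**  With a band at least as wide as both sequences the
  engine is, by construction, a full Smith–Waterman; the test suite checks
  score equality against an independent exhaustive DP on hundreds of
  random pairs at 0–15 % divergence.

External BLASTN runs are supported through their 12-column tabular output
(`parse_blast_tab()`), converted to the same hit conventions, so both
alignment stages can be driven by either engine.

### Uniqueness of flank placements

"Uniquely aligned" is implemented conservatively: after the length and
identity filters, hits of one flank lying within 1 kb on the same
chromosome and strand are collapsed to their best-scoring representative
(a fragmented alignment of one placement is not multi-mapping evidence),
and the flank is kept only if exactly one such locus remains.  A
bitscore-ratio mode (`unique_mode = "ratio"`, best ≥ 1.2 × second) is
available for repeat-rich genomes where strict uniqueness is too lossy.
Flanks of one read mapping to different chromosomes are kept but flagged
`discordant_pair`.

## The zero-inflated Poisson background

Site support is scored against genome-wide windowed counts.  Most windows
contain no insertion evidence at all — structural zeros — so a plain
Poisson underestimates the zero mass and overstates the significance of
everything else.  The model is the minimal faithful one: an intercept-only
mixture with zero-inflation probability π and Poisson mean λ,

* P(0) = π + (1 − π)·e^(−λ),
* P(k ≥ 1) = (1 − π)·λᵏ·e^(−λ)/k!.

`fit_zip()` maximizes the likelihood by EM over the latent structural-zero
indicator, initialized at π₀ = max(0, zero fraction − e^(−mean of positive
counts)) and λ₀ = mean of positive counts, iterating until the
log-likelihood moves by less than 10⁻⁸ (or 500 iterations; near the π → 0
boundary EM converges slowly and the iteration cap is a legitimate exit).
The log-likelihood trajectory is stored and is non-decreasing — asserted
on every fitted model in the tests.  All-zero input yields a flagged
degenerate model rather than an error.

P-values are the upper tail P(X ≥ count), computed through R's stable
Poisson tail; they are reported raw, with Benjamini–Hochberg adjustment
available behind a flag (`add_site_pvalues(fdr = TRUE)`) but not applied
by default, since the output contract is a per-site P-value.

The count universe is a declared construction: windows of 1 kb
(configurable) over every chromosome, each holding the summed read support
of the sites inside it.  Whether the original tooling fitted windows,
candidate sites, or per-read counts is not recoverable; the construction
is isolated in `windowed_counts()` so alternatives are pluggable.

## Barcode-pooling design and decoding

For multiplexed panels, every sample is sequenced under exactly two
barcodes and every sample gets a distinct pair, so `n` barcodes encode up
to `choose(n, 2)` samples — 13 barcodes suffice for a 56-sample flowcell.
`make_design()` builds such a layout deterministically with a greedy rule
(always the unused pair with least-loaded barcodes, lexicographic ties),
which keeps per-barcode loads within one of each other; any published
layout can instead be loaded verbatim with `read_design()`.  `decode()`
unifies per-barcode calls within 50 bp (the site-clustering tolerance,
reused for consistency) and classifies each unified insertion by its
barcode footprint: exactly one sample's pair → assigned; a single barcode
→ unassigned; three or more barcodes, or a pair no sample carries →
ambiguous, never silently assigned.  The three categories partition the
input, and the decoder is checked against an all-pairs brute-force oracle.

## The synthetic-data generator

`sim_insertion_experiment()` emulates a whole-genome resequencing run of a
mutant line:

* i.i.d. random genome at configurable GC (default 0.42) with
  non-overlapping gene intervals covering ~30 % of it;
* planted element copies at uniform positions with random orientation,
  spaced at least two mean read lengths apart and one mean read length
  from chromosome ends, so single reads can span a junction; optional
  target-site duplication of configurable length (default 0: clean
  junctions, since no duplication length is assumed for the generic
  element);
* log-normal read lengths (defaults: mean 7307 bp, sd 5000 bp, truncated
  at 500 bp), uniform start positions and strands, ~44× depth by default,
  and i.i.d. per-base substitution/insertion/deletion errors (defaults
  4 %/3 %/3 %, Nanopore-like ~10 % total);
* a machine-readable truth table in reference coordinates — the
  coordinate system of the final site table.

Everything is deterministic given the seed.  What the generator does *not*
model — homopolymer-biased errors, chimeric reads, adapter remnants,
repeat-rich reference sequence, enrichment-capture bias — bounds what
passing tests show about real data: they demonstrate the pipeline's logic
and its robustness to uniform noise, not robustness to structured
artifacts, which upstream trimming and the uniqueness filter must absorb.

`evaluate_calls()` matches calls to truth greedily, nearest first, one
truth per call, within a tolerance (default 20 bp), and reports recall,
precision and the median absolute positional error.

## Numerical and convention choices

* Internal coordinates are 0-based half-open; every writer converts to
  1-based inclusive at the boundary.  A site's `position` is the 1-based
  coordinate just right of the junction boundary.
* The site position is the *lower median* of member breakpoints — robust
  to a straggler member and deterministic on ties.
* The aligned-length filter is strict (`> 200`) and the identity filter
  inclusive (`≥ 80`), matching the stated cutoffs' wording; both are
  asserted at their exact boundaries in the tests.
* Clustering output is independent of input order (canonical sort first);
  site tables render P-values with six significant digits so a
  write→read→write cycle is byte-identical.
* "More than one gene involved" is counted over the 2 kb neighborhood,
  not only overlapping genes; the distance is measured from the site
  position to the nearest gene edge.
* The "extent of insertion" column is interpreted as the genomic interval
  spanned by the clustered breakpoints, flagged here as an interpretation
  since no definition is given in the output contract it mirrors.

## Problem sizes used in the checks

The end-to-end checks simulate a 500 kb single-chromosome genome with ten
planted 2 kb element copies and 30× reads of mean length 8 kb — large
enough that every stage (seeding, banding, clustering, background fit) is
exercised at realistic densities, small enough to run in well under a
minute per replicate.  Clean runs must recover every site exactly;
replicated runs at 10 % error must keep recall and precision at or above
0.9 with median positional error within 20 bp.  The aligner is checked
against the exhaustive DP on 200 random pairs up to 500 bp; ZIP recovery
uses 20 replicates of n = 5000 at (π = 0.6, λ = 4); decoding is verified
on 50 random design/truth instances.

## Limitations

* The uniqueness rule discards flanks in unresolvable repeats; insertions
  inside young, high-identity repeat families will be under-called.
* One element family per run; mixed-element screens need one pass per
  element sequence.
* Zygosity (homozygous/heterozygous carriers) is an experimental readout
  and is not computed.
* Target-site-duplication length is not estimated; when a TSD exists the
  5′- and 3′-side breakpoints differ by its length and the site position
  is their lower median.
* The E-value calibration is approximate (ungapped constants); E-values
  should be treated as a filter, not as a calibrated significance measure
  — site-level significance is the ZIP P-value.
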