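---
title: "ribocal: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ribocal: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains what ribocal computes, the assumptions behind each
step, the choices we made where the design was genuinely open, and what the
validation suite does and does not establish.

## The signal model

Elongating ribosomes advance three nucleotides at a time, so the 5′ ends of
ribosome-protected fragments of a given length are enriched at one position
per codon. ribocal treats a library as a collection of per-length 5′-end
count maps (`FivePrimeEndIndex`) and asks two questions of each read length
*L*:

1. Is the summed 5′-end profile over CDS prefixes 3-nt periodic?
2. How far downstream of the 5′ end does the P-site sit?

Both estimators operate on *metaprofiles*: position-wise sums over the
representative transcripts of the highest-coverage protein-coding genes.
The underlying assumptions are that (a) high-coverage genes are dominated
by genuine translation, (b) initiation and termination produce elevated
ribosome occupancy at the first and last codons, giving the metagene
windows a distinct peak, and (c) the offset is constant per read length
within a library.

## Periodicity detection

For length *L* the profile `c[j]`, `j = 0..N-1` (default `N = 150` nt of
CDS prefix) is transformed with `stats::fft`; amplitudes `|C(k)|` are
examined for `k = 1..floor(N/2)`. The zero-frequency (mean) term is
excluded — including it would make every non-negative profile aperiodic —
and no detrending or windowing is applied, since the statistic is computed
on raw summed counts. The length is periodic iff `argmax_k |C(k)|` equals
the period-3 bin `round(N/3)` exactly. This integer-bin equality is the
strictest reading of "highest amplitude at period 3": with `N = 150` the
period-3 bin is `k = 50` and the dominant period must be exactly 3.0 nt.
If `N` is not a multiple of 3 the period-3 bin is only approximate; we
therefore recommend keeping `N` divisible by 3 (the default is).

Degenerate inputs are handled explicitly: all-zero or constant profiles
raise a "no signal" condition which callers convert into a non-periodic
call. Lengths whose profile holds fewer than `minReads` (default 100)
reads are not classified at all — an argmax over a handful of counts is
noise — but stay in the output table, as do lengths classified as noise,
so the user can override the selection.

## P-site calibration

For each periodic length a 41-position metagene window (−30..+10 nt) is
summed around an anchor. The start anchor is the first base of the start
codon. The stop anchor is the first base of the **last sense codon**
(`cdsEndT − 2` in 1-based transcript coordinates): annotation dialects
disagree on whether the stop codon is inside the CDS, and terminating
ribosomes peak on the last codon before stop; anchoring there makes the
offset arithmetic identical for both anchors, so start- and stop-anchored
calibration estimate the same quantity and can be cross-checked.

The change-point statistic is the difference of **segment means**: for
each boundary `b` between adjacent window positions,
`Δ(b) = mean(counts[b+1..41]) − mean(counts[1..b])`, maximized over the 40
boundaries, ties resolved towards the most 5′ position for determinism.
The window position immediately right of the argmax is the inferred 5′ end
of initiating (terminating) ribosomes and the offset is its negated window
coordinate. An alternative reading of "difference of means for each
adjacent position" — the discrete gradient between the two values flanking
each boundary — is available as `changePoint(..., statistic =
"adjacent_pair")` for comparison, but the segment-mean form is what
"maximum shift in means" describes and is the package default. A change
point downstream of the anchor yields a negative offset; it is returned
with a warning rather than silently clamped, because it is diagnostic of a
pathological library.

**Anchor fallback.** Under `anchorPolicy = "auto"` the start anchor is
used when its window shows a clear peak, otherwise the stop anchor is
tried; if neither does, the offset is left undefined (`NA`) with a
warning, and the length is excluded from shifted exports unless manually
overridden. "Clear peak" is operationalized as window peakiness:
`max(counts) / mean(counts) > clarityRatio` (default 5). We initially
evaluated a shift-based criterion (`max Δ` against the mean absolute
`Δ`), but it behaves inversely to intent: on clean windows the initiation
spike inflates the mean absolute shift as much as the maximum, capping the
ratio near 1.5, while diffuse noise windows reach 3–6. Peakiness separates
the two regimes cleanly (phased libraries score in the tens, flat or
diffuse windows near 1–3) and directly expresses "no clear peak defined
over either end".

Offsets are applied by shifting 5′ ends `+offset` nt towards the 3′ end of
the read — rightwards on the genomic plus strand, leftwards on minus —
since the P-site lies downstream of the 5′ end.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `prefixN` | 150 | nt | CDS prefix summed for periodicity; keep divisible by 3 |
| `topFraction` | 0.1 | — | share of highest-coverage coding genes anchoring metaprofiles |
| `minReads` | 100 | reads | minimum profile mass for a periodicity call |
| window | −30..+10 | nt | metagene window around the anchors (fixed) |
| `clarityRatio` | 5 | — | peakiness threshold for auto anchor fallback |
| `multimapperPolicy` | `primary_only` | — | secondary/supplementary handling at ingest |
| `lengthRange` | 20–40 | nt | read lengths considered |

Gene "coverage" for `topFraction` ranking is the all-length 5′-end count
inside the representative CDS; the paper-style definition is not fully
specified anywhere, and CDS-restricted counting keeps the ranking focused
on translation rather than UTR contamination.

## Coordinates, regions and quantification

Internally everything is 1-based and closed, the native convention of
GRanges/IRanges, GTF and wiggle; converting to a single host-ecosystem
convention at the boundaries (BED's half-open 0-based intervals are
converted on read) eliminates the off-by-one class that mixing conventions
invites. Transcript coordinates run 5′→3′ with position 1 at the
transcript 5′ end, so on the minus strand the genomic right end maps to
position 1.

Multi-isoform genes are collapsed to one **representative transcript** per
gene — the longest CDS, ties broken by lexicographic transcript id — for
all metaprofiles, region statistics, tracks and expression tables. Isoform
ambiguity is out of scope; the choice is deterministic and recorded.

Region statistics classify each (optionally shifted) 5′ end against the
representative transcripts: exonic positions become leader/CDS/trailer (or
`noncoding_transcript` on a non-coding representative), positions inside a
representative transcript's genomic span but not exonic are `intron`, the
rest `intergenic`. A P-site shift applied in genomic space can move a read
near an exon boundary into an intron; the statistics report this honestly
rather than re-splicing the shift, matching how the shifted genomic tracks
are written. Transcriptomic tracks map shifted genomic positions through
representative-transcript exons; reads that fall off them are dropped and
counted in a sidecar tally, and positions on several representative
transcripts go to the lexicographically smallest transcript id.

RPKM uses counts in the representative CDS (footprints, P-site-shifted,
selected lengths) or representative exons (RNA-seq, raw 5′ ends), divided
by feature kilobases and by millions of **all reads surviving filtering**
(mask, deselection and — for footprints — length selection). The
conventional whole-library denominator keeps RPKM invariant under uniform
scaling. Translational efficiency is the per-gene ratio of the two RPKMs;
note it therefore carries an exon-kb/CDS-kb factor per gene, which cancels
in comparisons of the same gene across conditions. TE is undefined (not
zero) where RNA RPKM is zero.

## Sessions and determinism

The pipeline contains no sampling: identical inputs and configuration
yield byte-identical outputs, which is what makes the XML session
mechanism meaningful. A session file (schema version attribute on the
root, fixed element order, unknown elements rejected) records inputs,
parameters, selected lengths, offsets with their provenance (anchor used,
change-point position, manual-override flag), deselected genes and export
options. Replaying a session skips detection and calibration and applies
the stored values — the batch workflow: inspect one library, store, apply
to the rest. The XML dialect is this package's own, versioned schema; no
compatibility with any other tool's session format is claimed.

## The synthetic-data generator

`simScenario()` defines a deterministic toy genome (default 30 coding
genes on two chromosomes, alternating strands, every third gene carrying
one intron inside its CDS; 60-nt leaders and trailers, CDS lengths of
100–200 codons) and a footprint library with known ground truth: periodic
lengths 27–29 nt at 5000 reads each, true offsets 11/12/13 nt, 90% of 5′
ends on frame 0, and noise lengths 20–22 nt placed uniformly over
transcripts at 1000 reads each. Gene expression follows a Zipf (1/rank)
weight profile so that "top 10% of genes" is a meaningful selection.

The first and last CDS codons carry a 40× sampling weight. This emulates
the strong initiation/termination pausing of real (CHX-treated) libraries,
whose metagene profiles show start/stop peaks one to two orders of
magnitude above the per-codon baseline — and it is structurally necessary:
a perfectly flat elongation profile has no rising edge at the stop
anchor, so no change-point method could recover a stop-anchored offset
from it. The value 40 was fixed from an expectation-level analysis of the
segment-mean statistic (exact recovery for offsets 10–14 at phase
0.7–1.0 requires ≥ 30× under this geometry) before any end-to-end run,
and not revisited.

Each generation stage (annotation, footprints, RNA-seq) draws from its own
deterministically derived seed in a documented order, so stages are
independently reproducible and repeated calls are byte-identical, BAM
included. The toy genome has no nucleotide sequence — BAM headers only
need sequence names and lengths, so none is emitted and read sequences are
placeholders.

**What passing tests do and do not show.** The generator reproduces the
geometric features the estimators consume: per-length phased 5′ ends,
terminal peaks, uniform noise, spliced alignments on both strands. It does
not model sequence-dependent ligation bias, codon-specific dwell times,
drug-specific artifacts (e.g. harringtonine run-off), UTR translation,
overlapping genes or isoform diversity. Exact recovery on these libraries
validates the estimators' correctness and calibration arithmetic, not
their behaviour on every real-world bias; the auto-fallback and
manual-override paths exist precisely because real libraries deviate.

## Validation sizes and known limitations

The test suite validates estimators against independent brute-force
oracles (direct O(N²) periodogram on 200 random vectors; exhaustive
boundary search on 500 random windows), recovers ground truth exactly on
the reference scenario (5000 reads/length, phase 0.9) for seeds 1–5 on
both anchors, and checks conservation, wiggle round-trips and replay
determinism. Unit tests use reduced instances (1200–2000 reads/length)
of the same scenario; these sizes were chosen as the smallest at which the
metaprofiles are comfortably above the classification thresholds.

Known limitations:

- **Stop-anchor margin at low depth/phasing.** The segment-mean statistic
  compares the terminating-ribosome peak against window-edge boundaries
  whose left segment holds only a position or two; with weak phasing
  (~0.7) and shallow windows (~2000 reads/length before top-gene
  selection) the margin falls within sampling noise and a stop-anchored
  offset can come out wrong while the start anchor remains exact. The
  offset-recovery property is therefore exercised at 4000 reads/length
  for phase 0.7; at the reference conditions both anchors are exact.
- Genomic-space P-site shifting can land near-boundary reads in introns
  (reported as such), and transcriptomic tracks drop reads off
  representative exons (counted, warned).
- The periodic/noise call is a hard argmax rule; a length with a genuine
  but secondary period-3 component is classified noise, by design — the
  table retains it for manual override.
- BED12 input carries no gene grouping; each record becomes its own gene.
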