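---
title: "Detecting single-strand breaks from erroneous end-labelling signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting single-strand breaks from erroneous end-labelling signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steelseq)
```

## The signal and its model

A nick-translating, highly error-prone DNA polymerase loaded at a
single-strand break (SSB) with one dNTP omitted resynthesizes the strand
downstream of the nick. Every template position that calls for the
missing nucleotide is filled with one of the three available bases
(transitions dominate: A→G when dATP is omitted, C→T when dCTP is) or
skipped, producing a deletion. The result, seen in an aligned read, is a
*tract* in which **every** occurrence of the target base is mutated,
while flanking sequence is intact. Detection therefore reduces to a
combinatorial scan, not a probabilistic model:

1. enumerate the reference target-base positions inside the aligned span
   of a read (positions consumed by `M/=/X/D`; `N` gaps excluded);
2. mark each as *mutated* (substituted or deleted) or *intact*;
3. report every maximal run of consecutive mutated target positions that
   has an intact target base immediately flanking it on the *anchor*
   side — 5′ for A/C signatures, 3′ for T/G signatures, because synthesis
   proceeds 5′→3′ on the strand that was nicked.

The break interval for a forward (A) event is
`[anchor + 1, first_mutated + 1)` in 0-based half-open coordinates:
between the last remaining target base and the first replaced one. The
mirror rule `[last_mutated, anchor)` applies to reverse (T) events. Both
strands are always scanned, since either strand of the duplex may have
been sequenced. The `-dCTP` mode applies the identical machinery to C/G.

Runs that touch the alignment edge on the anchor side are discarded: the
"last intact target base" cannot be verified there, and a fragment end is
exactly the artefact this method is designed to exclude. For the same
reason "first mutated nucleotide" is interpreted as the first mutated
*target* base of the run rather than any mismatched base — an isolated
non-target mismatch inside the interval is indistinguishable from a
sequencing error and would only shrink the interval unreliably.

## Filters and their parameters

Sequencing errors can conspire to look like polymerase activity, so four
filters are applied (all thresholds configurable per
`technology_profile()`):

| filter | default | rationale |
|---|---|---|
| per-read error rate | ≤ 0.10 | removes misaligned/chimeric reads; counts substitutions + inserted + deleted bases over the reference span (`M/=/X/D`), the closest reproducible analogue of the `NM` edit distance. The bound is inclusive ("at most 10%"). |
| mutated target bases per event | 5 (pacbio-hifi, nanopore), 3 (illumina-tk6), 4 (illumina-hacat) | chance co-occurrence of k mutated target positions decays geometrically with k; long reads need the larger k because they contain more target positions per read. |
| mean quality of substituted bases | ≥ 10 (phred) | deletions carry no quality, so the mean is taken over substituted positions only; events with zero substitutions skip this filter (they fail the substitution filter instead). When a record carries no qualities (`*`), the filter fails closed unless the profile sets `require_quality = FALSE`. |
| substitutions per event | ≥ 3 for nanopore, ≥ 1 otherwise | homopolymer deletions are the dominant nanopore error mode; requiring substitutions suppresses them. |

Only the Illumina profiles deduplicate calls by
`(chrom, start, end, strand)`: short-read libraries contain PCR
duplicates, whereas each long read is an independent molecule. Ties keep
the call with the highest mapping quality, then the lexicographically
smallest read name, so output is deterministic.

## What the simulator emulates — and what it does not

The generator produces, per molecule (one simulated read = one molecule):
a seeded i.i.d. reference at a chosen GC content with nickase motifs
embedded in random orientation; nicks at motif-derived positions
(`GTCTC` + 6 forward; the mirrored position for reverse-orientation
copies), at a Poisson rate, or at explicit positions; a tract downstream
of each nick on the nicked strand whose target bases are substituted or
deleted according to the spectrum; and an i.i.d. per-base sequencing
error layer. Reads are emitted as spec-conformant SAM with CIGAR/MD/NM
computed from the known edit script, so no aligner runs and alignment is
never a confound. Reads drawn from the unmodified strand of a nicked
duplex carry no signature, as in a real library, which halves the
effective signature coverage.

Default parameters, chosen once as plausible study conditions:

* substitution spectrum with dATP omitted: A→G 0.55, A→T 0.10, A→C 0.10,
  deletion 0.25, insertion 0.01 per tract position. This reproduces the
  qualitative observations (G most frequent, deletions common); the
  exact in-vitro proportions are not published as numbers, so these are
  honest package defaults, not measured values. Inserted bases never
  equal the omitted base — no dATP is available to insert.
* tract length: geometric with mean 50 bp. Only a single design point
  (a hairpin with a 55-nt modified stretch) is known, so the
  distribution is an assumption; `tract_model = "fixed"` is available.
* sequencing error rates: illumina 1e-3 sub / 1e-4 indel (Q35),
  pacbio-hifi 2e-3 / 1e-3 (Q30), nanopore 2e-2 / 2e-2 (Q15) — round
  figures well below the 10% usability bound.

Not modelled: the gap/nick-translation intermediate (molecules are
emitted sealed, as after the gap-filling step of the protocol),
PCR duplicates, chimeric or supplementary long-read alignments,
position-dependent quality, and paired-end layout (every record is
single-end; the detector treats mates independently anyway). Passing
tests on simulated data therefore demonstrate the correctness of the
*computational* pipeline under known truth — they do not validate the
biochemical assumptions on real libraries, where alignment artefacts and
non-uniform error profiles add noise the simulator does not reproduce.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally and in BED output;
  conversion to 1-based closed happens only at Bioconductor container
  boundaries.
* Reference `N` positions are never substitutions and never target
  bases: no truth is available there.
* An event consisting solely of deletions has no substituted-base
  quality; the quality filter is vacuous for it rather than failing,
  so the failure is attributed to the substitution-count filter.
* `ref_span = 0` (fully clipped records) gives an undefined error rate;
  such records are unusable.
* Deduplication and BED emission sort by (chrom, start, end, strand,
  read name) so identical inputs give byte-identical outputs.
* Site/call coincidence uses the window-extension overlap rule: a call
  extended by `w` on both sides must overlap the 1-bp nick-point
  interval under half-open semantics. This matches `bedtools window -w`
  exactly (verified against it on boundary cases). Nickase sites are
  represented as 1-bp nick points rather than recognition-site spans;
  the distance between half-open intervals is gap length, 0 when they
  overlap.
* Recall/precision against truth use any-match at tolerance 10 bp;
  the per-nick hit table uses greedy 1-to-1 matching by increasing
  distance with coordinate tie-breaks. Precision is computed over calls
  as given — deduplicate first when that is the quantity of interest.

## Region annotation

The genomic-region summary re-implements the standard promoter/UTR/exon/
intron annotation as a priority partition: promoter bins (0–1, 1–2,
2–3 kb upstream of the TSS of the longest transcript per gene) >
5′ UTR > 3′ UTR > exon > first intron > other introns > downstream
(≤ 3 kb) > distal intergenic. Each unique call is assigned by its
interval midpoint (calls are at most tens of bp, so the midpoint is a
deterministic and unbiased representative). Call strand is re-expressed
relative to the assigned gene; intergenic calls keep their absolute
strand. Per-region frequencies divide by the partition's bp size by
default; `aligned_nt` optionally scales denominators by mean coverage,
since it is not established whether published region frequencies were
coverage-normalised — both readings are exposed, neither asserted.

## Validation scale

The end-to-end checks simulate a 1 Mbp genome with 200 embedded motifs
nicked on both strands at 30× long-read coverage (~10,000 reads), plus a
matched nick-free control; the event scanner is additionally compared
against a brute-force oracle on 1,000 random ≤200 bp alignments for all
four target bases. These sizes give stable statistics (binomial 3-sd
bands on every stochastic assertion) while a full run of the suite stays
in the minutes range. At this scale the pipeline recovers essentially
all planted nicks, localises every matched call within 10 bp (the
interval construction contains the nick by design), and shows motif
coincidence an order of magnitude above an equally sized random site
track — the random track itself agreeing with the closed-form chance
expectation, computed at the level of merged extended intervals where
the independence assumption actually holds.

## Known limitations

* Breaks with 3′ ends that the polymerase cannot extend (e.g.
  3′-phosphate termini) are invisible to the assay and hence to this
  package.
* Localization is an interval, not a point: its width is the spacing
  between the anchor and the first mutated target base, so resolution
  degrades in target-base-poor sequence.
* A sequencing error that restores the target base inside a long tract
  splits one event into two; the secondary event passes all filters and
  mislocalises by up to the tract length. At default error rates this
  affects on the order of 1% of calls and is the dominant source of
  imprecision.
* The detector ignores supplementary alignments; split long reads are
  counted once at their primary locus.
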