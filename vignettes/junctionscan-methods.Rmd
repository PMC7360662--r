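---
title: "Targeted junction scanning: model, parameters and design choices"
author: "junctionscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted junction scanning: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(junctionscan)
```

## The problem

The KIAA1549:BRAF fusion is the most common driver alteration of pediatric
pilocytic astrocytoma. It arises from a focal tandem duplication at 7q34 and
is expressed as a chimeric transcript, most often joining KIAA1549 exon 16
or 15 to BRAF exon 9 (the "16:9" and "15:9" variants). In routine RNA-Seq,
alignment-based fusion callers miss this fusion surprisingly often: KIAA1549
is weakly expressed, tumor purity of these low-grade gliomas is low, and
the junction-spanning reads that do exist are exactly the reads spliced
aligners handle worst — overlapping paired-end reads over short inserts,
and split reads with a short overhang on one side of the breakpoint. The
evidence is frequently present in the raw FASTQ yet invisible downstream.

`junctionscan` takes the complementary targeted route: for a *known* fusion
it constructs the breakpoint sequence explicitly and searches the raw reads
for it. This is a deliberately narrow tool — a targeted verifier for
curated fusions with high sensitivity at full specificity — not a de novo
fusion discovery method.

## Junction contigs

For a fusion joining exon `e5` of the 5' partner to exon `e3` of the 3'
partner, the junction contig is

    contig = suffix(spliced5, up to end of e5) + prefix(spliced3, from e3)

with the breakpoint offset recorded as the length of the 5' part (0-based
index of the first 3'-partner base). Spliced transcripts are built from a
genome FASTA and GTF exon records, concatenating exons in transcription
order and reverse-complementing per exon stream for minus-strand genes.
Coordinates are 1-based inclusive at the GTF boundary and 0-based
half-open everywhere inside the package.

The tool works on a single exon chain per gene: exon numbers in fusion
variant names refer to a canonical transcript, so multi-transcript
annotations require an explicit `transcript_id` selection rather than a
silent guess. Flanks default to `flank_target = 200` bases, twice the
100 bp read length of the emulated sequencing design, so that every
placement of a read over the breakpoint lies fully inside the contig and
the scanner sees no edge effects. Ambiguous genome bases are kept as `N`
and never match anything.

## The scanner and its contracts

A read supports a junction if some ungapped placement of it (or of its
reverse complement) on the contig

* crosses the breakpoint with at least `min_overhang` aligned bases on
  **each** side (default 10),
* covers at least `min_aligned_fraction` of the read (default 0.5;
  placements may clip at contig ends), and
* has at most `max_mismatches` Hamming mismatches over the aligned span
  (default 2).

The two thresholds mirror the aligner parameters that rescued these reads
in the optimized alignment workflow (`--peOverlapNbasesMin 10`,
`--alignSplicedMateMapLminOverLmate 0.5`); the mismatch budget extends the
original exact-`grep` idea of searching raw FASTQ for breakpoint-spanning
sequence with tolerance for sequencing error. Setting `max_mismatches = 0`
(`--strict-exact` on the command line) recovers exact matching.

Matching is ungapped by design: a junction-spanning cDNA read has no indel
at the splice boundary by construction, and indels elsewhere are out of
scope (they count as mismatch-heavy and the read is dropped). `N` counts
as a mismatch, never as a wildcard. Base qualities are ignored during
matching, as sequence-level search defines the method; they pass through
untouched.

Among qualifying placements the scanner reports the one with fewest
mismatches, breaking ties by smallest contig offset and then forward
orientation before reverse complement — a fixed total order that makes
output deterministic.

### Seeding, and why it cannot change decisions

The implementation is seed-and-verify, in compiled code: exact `seed_length`
k-mers (default 12) of the breakpoint-proximal contig window are indexed,
and candidate diagonals come from k-mer lookups of the read at a fixed
stride. The stride is derived by pigeonhole: a qualifying span of at least
`S_min = max(2 * min_overhang, min_aligned_fraction * read_length)` bases
with at most `m` mismatches contains a mismatch-free run of length
`g = ceil((S_min - m) / (m + 1))`, and if `g >= k` such a run is guaranteed
to contain a k-mer starting at a read offset divisible by `t = g - k + 1`.
Whenever this bound fails (small reads, large mismatch budgets, long
seeds), the scanner transparently evaluates every breakpoint-crossing
diagonal instead — a small set, since qualifying diagonals are confined to
`[b + o - R, b - o]`. Seeding is therefore a pure optimization; the test
suite asserts equality with a brute-force all-offsets oracle over
randomized contigs, reads and parameters.

Support is counted per sequenced **fragment**, not per read: mates of a
short-insert pair frequently both cover the breakpoint, and counting them
twice is precisely the kind of double-dipping that support thresholds are
meant to guard against. PCR duplicates are not collapsed by default (the
method makes no assumption about library complexity); an optional flag
collapses fragments with identical sequence pairs.

A read may hit several junction contigs — the 16:9 and 15:9 variants share
their 3' flank — and is then recorded against every qualifying junction;
the caller resolves variant-level redundancy via the per-pair `primary`
flag rather than discarding evidence early.

## Calling and the one-read rescue rule

Calls are made per junction variant from fragment support `s`:

| condition                                  | status      |
|--------------------------------------------|-------------|
| `s = 0`                                    | `absent`    |
| `s >= min_support`                         | `reported`  |
| `0 < s < min_support`, pair whitelisted    | `reported` (rescued) |
| `0 < s < min_support`, not whitelisted     | `discarded` |

The rescue row is the Arriba v1.2.0 rule — report a fusion with a single
supporting read if it is on a curated known-fusion list — which exists
because one-read KIAA1549:BRAF events had been found and then filtered
away as presumed noise. `min_support` defaults to 2: the observed behavior
that one-read events were discarded implies the general threshold exceeds
one, and we deliberately do not reproduce any caller's full
coverage-dependent confidence model — a fixed threshold keeps the rule
inspectable. Whitelist matching is by ordered gene pair and
exon-variant-agnostic by default, as curated lists are keyed by partners;
`variant_strict = TRUE` narrows matching to listed variants.

## The simulator

`simulate_sample()` emulates the study regime the tool targets: 2 x 100 bp
paired-end reads, a normal insert model (mean 250 bp, sd 30), per-base
substitution errors at 0.001, and a fusion transcript expressed as a small
fraction of fragments. `fusion_fraction` is the single dial that stands in
for the two real detectability drivers — fusion-partner expression and
tumor-cell content — both of which act by diluting fusion-derived
fragments. Wildtype transcripts are sampled length-weighted (fragment-level
mixing), fragment starts uniformly over valid placements, and the fragment
strand is randomized. Every fragment carries a ground-truth record
(source, placement, exact junction overhangs per read), so detection
results can be scored against truth without re-deriving anything.

Deliberate simplifications, and what they imply about test results:
unstranded simulation despite the stranded library protocol (the scanner
is orientation-agnostic, so strandedness cannot change decisions);
substitution-only errors (matching the ungapped scanner; indel robustness
is explicitly out of scope); constant base quality; no PCR/GC bias, no
polyA-capture 3' bias, no FFPE degradation. Passing tests therefore show
correctness of the detection logic under idealized noise, not robustness
to every artifact of real libraries; on real data the practical caveats
are coverage bias near the breakpoint and mismatch clusters from RNA
editing or hypermutation.

The closed form `expected_spanning_fragments()` gives, for fixed fragment
length and an interior breakpoint, the expected number of fragments whose
reads cover the breakpoint with a required overhang — each read window
contributes `R - 2o + 1` fragment starts, with the overlap of the two
start intervals removed exactly. It is the independent calibration oracle
for the simulator: observed spanning counts must sit within binomial error
of it, which the test suite checks over ten seeds.

## Evaluation taxonomy

Per sample, for a target gene pair: a truth-positive sample is `reported`
if any variant is reported, else `discarded` if any variant was found but
filtered, else `missed`; a truth-negative sample is a `false_positive` if
*any* split-read evidence was called or discarded, else a `true_negative`.
"Missed" is the sample-level name for call-level "absent" — two
vocabularies, one mapping. Cohort summaries report counts and relative
frequencies within each truth stratum (to one decimal place, raw counts
always alongside), sensitivity, specificity, and the merged
detected-rate (reported + discarded), since covariate analyses group the
two detected categories together. `compare_cohorts()` emits the
status-by-cohort contingency table; significance testing is left to the
user's statistics environment.

## Synthetic reference and problem sizes

No genome download is assumed anywhere: `synthetic_reference()` generates
a fully synthetic KIAA1549/BRAF-like locus (both genes minus-strand as in
the human genome, 17 and 18 exons, random exon/intron sizes in realistic
ranges, plus a housekeeping filler gene) from a fixed seed, writes it as
FASTA/GTF/whitelist, and re-parses it through the standard path. Sequences
are random DNA; files are labelled synthetic.

The benchmark sizes used by the test suite and the acceptance script —
50-sample negative cohorts and 10-sample cohorts per fusion fraction at
200,000 fragments per sample, calibration at 100,000 fragments over ten
seeds — were chosen so a full run completes on a single CPU in minutes
while keeping binomial error bars far smaller than the effects being
asserted. At 200,000 fragments and fusion fraction 0, the probability of
even one spurious junction-spanning call is negligible under the default
contracts (a random read would need a 50-base near-exact match crossing
the breakpoint), which is what the 100%-specificity property exercises at
reduced scale.

## Numerical and degenerate-input choices

* Tie-breaks in the scanner are total and documented (mismatches, contig
  offset, orientation), so repeated runs are byte-identical.
* Reads shorter than `2 * min_overhang` cannot span and are skipped with a
  counted warning rather than an error.
* Flanks truncate at transcript bounds; a junction whose flank is shorter
  than `min_overhang` triggers an "undetectable" warning at build time.
* Fragment lengths are rounded normal draws clamped to
  `[read_length, transcript length]`; clamping is flagged per fragment in
  the truth table.
* The spanning-count closed form refuses configurations it does not
  describe (variable fragment length, breakpoints near transcript ends)
  instead of extrapolating.
* All RNG is seeded explicitly; simulation outputs for a fixed
  configuration and seed are byte-identical across runs.

## Known limitations

De novo breakpoint discovery, genomic (intronic) breakpoints of the 7q34
duplication, multi-isoform junction enumeration, gapped alignment and
SAM/BAM emission are non-goals. The caller intentionally implements only
the support threshold plus rescue rule, not a full confidence model with
blacklists and read-through detection. Whitelist matching at gene-pair
level may rescue an unlisted exon variant of a listed pair; strict mode
exists where that matters.
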