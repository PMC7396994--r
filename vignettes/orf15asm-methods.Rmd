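---
title: "De novo assembly-based variant calling for a low-complexity amplicon: models and methods"
author: "orf15asm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De novo assembly-based variant calling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orf15asm)
```

## The problem

Exon ORF15 of *RPGR* is a mutation hotspot for X-linked retinitis pigmentosa.
Its sequence is purine-rich and highly repetitive on the coding strand, which
makes the region hard to capture, hard to sequence, and — the part this
package addresses — hard to analyse. Standard secondary analysis (map reads
to the genome, call variants from the pileup) fails in characteristic ways on
deep targeted sequencing of the ~2.1 kb long-range PCR amplicon that spans
the exon: large insertions and deletions (duplications of 15–51 bp are
common real alleles here) are missed outright, and misplaced reads produce
recurrent *heterozygous* SNV calls in male samples — an immediate red flag at
an X-chromosomal locus, where males carry one allele.

`orf15asm` implements the alternative: assemble the amplicon reads *de
novo*, select a single satisfactory contig through a three-round cascade,
align that contig globally to the amplicon reference, and read the variants
off the alignment. A deliberately naive mapping/pileup caller and a
concordance comparator reproduce the standard pipeline's failure class so the
two strategies can be contrasted on the same samples, and a read simulator
generates ORF15-like samples with known truth, since patient reads are not
distributable.

## The pipeline model

### Assembly

Reads are decomposed into k-mers (both strands counted; orientation is fixed
later by base composition, not by the graph). A de Bruijn graph is built per
k; edges seen fewer than `min_kmer_count = 3` times are pruned. Two kinds of
seed sequences modify this:

* **trusted contigs** — their k-mers are exempt from pruning. Feeding the
  amplicon reference as a trusted contig in later rounds lets the graph
  bridge local coverage dropouts with reference sequence while
  read-supported k-mers keep their counts.
* **untrusted contigs** — their k-mers enter with a pseudo-count of one and
  remain prunable; they can rescue borderline k-mers but cannot invent
  sequence on their own.

Simplification is standard: tips (dead-ended unitigs shorter than `2k`) are
clipped; simple bubbles (parallel unitigs between the same junction nodes
whose lengths differ by at most 3) collapse to the higher-coverage branch,
ties broken lexicographically for determinism. Contigs are maximal
non-branching paths; the coverage statistic attached to each contig is the
mean count of its constituent k-mer edges, and reverse-complement twins from
two-strand counting are reported once.

Assembly iterates over an ascending k list, feeding each iteration's contigs
to the next as untrusted contigs. Round 1 uses k = 21, 33, 55, 77, 99, 127
(all below the 151 bp read length). Small k tolerates low coverage but
tangles in repeats; large k resolves repeats up to k-mer span but needs deep
coverage. At the ~1000x depths this amplicon is sequenced to, the final
k = 127 dominates the result.

### Contig selection

The amplicon's plus strand carries well under 7% G (the coding strand is the
G/A-rich one), which gives a cheap two-purpose filter: a contig whose G
fraction is below 15% is accepted as plus-oriented; otherwise its reverse
complement is checked; if both strands fail the contig is discarded as
unrelated sequence. The global aligner never reverse complements, so
selection fixes orientation.

All threshold comparisons are strict: pre-selection keeps contigs with
400 < length < 2300 and mean coverage > 30; a *satisfactory* contig has
2040 < length < 2300. A looser satisfactory lower bound of 2000 is a
defensible alternative for this locus; 2040 is the default because it is
the tighter bound consistent with accepting true full-length haplotypes
(including ones carrying sizeable deletions) while rejecting near-complete
misassemblies, and `selection_thresholds(satisfactory_size=)` exposes it.
Contigs legitimately exceed the 2100 bp amplicon because primer-proximal
fragments are over-represented; the window tolerates up to 2300.

Scoring contigs "by size and coverage" admits many orderings; this package
commits to a fixed lexicographic order — inside the
satisfactory window first, then higher mean coverage, then longer, then id —
chosen because it is deterministic and never prefers an unusable contig over
a satisfactory one.

Three rounds: (1) plain multi-k assembly; (2) the top five ranked contigs
plus the reference as trusted inputs, k = 55, 77, 99, 127; (3) k = 77, 99,
127 with prior top contigs untrusted and the reference alone trusted.
Selection stops at the first satisfactory contig; a sample failing all three
rounds is reported, not raised.

### Alignment and calling

The selected contig is aligned to the reference with an affine-gap global
alignment: match +1, mismatch −2, gap open −12, gap extend −0.5 per base
(gap of length L costs `open + L·extend`). The tiny extension penalty is the
load-bearing choice: in a repeat tract a 27 bp duplication must surface as
*one* contiguous 27-column gap, not be scattered. The end-gap convention is
a standard overlap alignment: terminal gap runs on either sequence are
free. Restricting the free ends to the contig's sides alone would be the
other natural convention; since terminal gap columns are excluded from
calling either way, the two produce identical call sets, and the symmetric
convention also handles contigs that fall slightly short of the reference
ends. Traceback ties prefer the aligned pair, then a gap in the contig row,
then a gap in the reference row, making the alignment deterministic.

Calls are read off maximal runs of non-matching columns: a run without gaps
yields one SNV per mismatch column (the dialect of per-column SNV callers);
a run containing any gap becomes a single event — deletion, insertion, or
delins when both reference and contig bases are present. The run-merging
rule reflects how repeat-tract alleles actually surface in alignments: when
an allele is described from a shifted register, a delins typically lands
immediately adjacent to a long insertion, and reporting the run as one
event keeps such combinations coherent.

Every indel is then expressed twice from the same internal
interval-replacement variant: 3'-shifted on the transcript sense and
dup-classified for HGVS c. nomenclature, and left-aligned with an anchor
base for VCF. The two normalizations genuinely disagree inside repeats,
which is why frequency annotation matches only on the left-aligned VCF key.
A hard invariant is checked on every run: applying the finalized call set to
the reference must reproduce the aligned contig haplotype exactly.

Consequence classes follow frame arithmetic and translation: a coding indel
with net length change not divisible by three is a frameshift (p. notation
from translating the edited coding sequence to the first stop); an SNV
creating a stop is nonsense; the prioritized set is exactly
{frameshift, nonsense}, because essentially all pathogenic alleles reported
at this locus fall in those classes. Everything else stays in the full
report.

### Zygosity

The pipeline selects one contig. The rule implemented: one contig in a male
sample → hemizygous; one contig in a female → unknown (a single contig
cannot distinguish homozygous from a collapsed heterozygote); a second
passing satisfactory contig, when present, is reported as a candidate second
allele. How the original analysis represented heterozygous females is not
stated anywhere; this is the conservative choice.

### The baseline comparator

The baseline exists to reproduce the *failure-mode class* of standard
mapping pipelines on this locus, not to re-implement any particular mapper:
it anchors each read on its first exact 31-mer seed (leftmost read k-mer,
leftmost reference occurrence — the naive choice), extends with a banded
(half-width 30) semi-global alignment whose gap costs (open −18, extend −6
per base) make gaps beyond a few bases uneconomical against mismatching
through a low-complexity tail, and calls variants from allele fractions at
positions with depth ≥ 20: ≥ 0.8 hom/hemi, [0.2, 0.8) heterozygous. Two
documented behaviours follow mechanically: duplications of ≥ 20 bp are never
called (the gap is never opened), and reads whose in-repeat indel junction
sits toward one end align with a shifted, partially matching tail, piling
non-reference bases at the repeat flanks into the heterozygous band — in a
male, an immediate artifact marker, which `flag_het_in_haploid()` applies.
A gap-tolerant extension (e.g. open −6, extend −1 with a wide band) absorbs
such duplications cleanly and shows neither behaviour; the defaults were
chosen so the baseline models the legacy callers that motivated the
assembly approach. All of these knobs are exposed in `baseline_params()`.

Cross-pipeline concordance is keyed on the left-aligned anchored
representation and a variant's call quality is *high* iff its per-sample
presence is identical in both pipelines across the whole cohort — the
complete-concordance rule — else *low*.

## The synthetic data generator

Real patient reads are unavailable, so the generator emulates the documented
properties of the system:

* **Reference** (`synthesize_reference()`): a 2100 bp amplicon whose coding
  strand is built from a Glu/Gly-rich codon pool (GAA, GAG, GGA, AGG, AAG,
  GAT and a 2% admixture of GCA; no stop codons), flanked by 60 bp random
  unique primer-site flanks, with an embedded exact tandem block (default
  27 bp unit x 4 copies, codon-aligned) and a terminal stop codon closing
  the coding segment. The plus strand is the reverse complement, so its G
  fraction is the coding strand's C fraction — about 2%, comfortably below
  the 7% documented for the real locus. The transcript map mirrors ORF15:
  coding segment anchored at c.1753 on the minus strand, an intronic stretch
  5' of it (`c.1753-K` labels), a 3'UTR after it (`c.*N` labels).
* **Reads** (`simulate_sample()`): fragments of normal(273, 40) length
  clamped at the 151 bp read length, uniform starts with a 3x
  over-representation of fragments touching the 25 bp primer spans,
  inward-facing 2x151 mates from both strands, substitution errors at
  0.001 per base, constant Q30 qualities. Coverage defaults to 1000x;
  the expected pair count is `coverage * length / (2 * 151)`. Sequencing
  indel errors default to off so that indel calls are attributable to the
  pipeline, not the error model; an `indel_error_rate` knob exists.
  A note on an internal inconsistency: with the pair count fixed by
  coverage, primer-span read depth cannot exceed interior depth under any
  fragment-start distribution (the terminal 25 bp are covered only by the
  few fragments starting there), so primer over-representation is validated
  against the unboosted simulation at the same positions rather than
  against interior depth.
* **Truth sets** (`spike_standard_truthsets()`): one single-variant set per
  class seen at the real locus — nonsense SNV, 2 bp GG deletion, 4 bp
  deletion, 2 bp delins, in-frame duplications of 15/21/27 bp placed at the
  tandem block's 3' end, and a 51 bp insertion that is deliberately not a
  duplication of its 5' context.

What passing tests on this material do **not** show: performance on real
MiSeq error and quality profiles, PCR stutter/chimeras, amplification
failure, platform-specific biases, or diploid phasing of female carriers —
the generator makes none of these, and the cohort-scale counts reported for
the real study are not reproducible without the patient data.

## Numerical choices and degenerate inputs

* All selection thresholds strict; ranking ties broken by id; bubble ties by
  sequence order; alignment traceback ties by fixed state preference — every
  stage is deterministic, and identical inputs (reads, seed, config)
  reproduce byte-identical outputs.
* Gap cost convention `open + L·extend` in both aligners.
* Overlapping variants in one set are rejected, not merged; two insertions
  at one position are rejected as ambiguous.
* Deletions at position 1 / insertions before position 1 cannot take a VCF
  anchor base and are refused at export.
* Empty read sets, empty graphs and empty call lists flow through as empty
  results; an unresolvable sample after round 3 is a reported failure.
* Whether an insertion should be *named* as a dup or as an ins+delins
  combination in repeat tracts is genuinely underdetermined — automated
  callers and confirmatory sequencing can legitimately describe the same
  allele differently. The package always 3'-shifts and prefers the dup name
  when an exact preceding copy exists, and `sets_equivalent()` is the
  arbiter that two namings describe the same allele.

## Problem sizes used by the test suite

The suite regenerates everything from code: the assembler oracle uses 100
random 300–600 bp references with error-free tiling reads; the alignment
oracle compares the DP against exhaustive enumeration on 500 string pairs of
length ≤ 12; the normalization oracle enumerates all equivalent
representations for 1000 random indels in repeat tracts; end-to-end recovery
runs all eight truth classes at 1000x over 20 seeds each; the failure-mode
property runs 10 seeds of the 27 bp duplication through both pipelines.
These sizes were chosen so the whole suite exercises every claim in minutes
on one CPU.

## Known limitations

* Diploid samples are simulated and flagged, but the selector returns one
  contig; a heterozygous female with two near-equal alleles may assemble a
  mosaic or drop one allele — mirrored honestly by `zygosity = "unknown"`.
* The baseline is a failure-mode model, not a faithful BWA/GATK; its false
  positive *counts* are properties of the simulation, not estimates for any
  real cohort.
* The HGVS dialect covers what the pipeline emits (SNV, del, dup, ins,
  delins, intronic offsets, 3'UTR positions); inversions, alleles and
  protein-level parsing are out of scope.
* Frequency annotation is an exact-key local lookup; there is no liftover
  and no live database access.
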