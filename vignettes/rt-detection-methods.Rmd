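---
title: "Detecting balanced reciprocal translocations from paired-end reads: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting balanced reciprocal translocations from paired-end reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtdetect)
```

# The problem

A balanced reciprocal translocation (RT) is a mutual exchange of
terminal segments between two non-homologous chromosomes with no net
gain or loss of material. Carriers are healthy but produce unbalanced
gametes, so RT screening matters wherever fertility is selected on —
notably in livestock breeding, where karyotype screening of AI boars is
routine. In paired-end short-read data a balanced RT leaves no
read-depth signal; its evidence is (i) discordant read pairs whose
mates map to different chromosomes and (ii) split reads whose alignment
is divided across the two breakpoints, which give base-pair resolution.

`rtdetect` implements the full detection and characterization chain:

1. **Breakend calling** (`call_breakends_from_aln()`): cluster
   discordant pairs by chromosome pair and orientation, group split
   reads by their exact clip boundaries, and merge the two into
   inter-chromosomal breakend (BND) calls with the attributes the
   downstream filters use — PE (discordant-pair support), SR
   (split-read support), MAPQ (median mapping quality of supporting
   fragments), SRQ (mean split-read identity to the assembled
   junction consensus), PRECISE/IMPRECISE, and a connection type.
2. **Tiered filtering** (`basic_filter()`, `strict_filter()`,
   `relaxed_filter()`) and **reciprocal-pair matching**
   (`match_reciprocal_pairs()`).
3. **Breakpoint-pattern classification** (`classify_breakend()`):
   automation of the visual read-pattern triage that separates RT-like
   loci from repeat artifacts.
4. **Junction characterization** (`characterize_junction()`,
   `compute_bases_lost()`, `derive_chromosomes()`, `gene_context()`):
   microhomology / blunt / micro-insertion calls, bases lost, derived
   chromosome arithmetic, gene context.
5. A **diploid carrier simulator** (`make_reference()`,
   `plant_translocation()`, `simulate_read_pairs()`,
   `emit_truth_alignments()`) so the whole chain is testable with
   known truth and without any external data.

# Coordinates, connection types and junction orientation

All coordinates are 1-based inclusive. The *head* of a chromosome with
breakpoint `bp` is bases `1..bp`; the *tail* starts after the
breakpoint region. A balanced RT comprises two junctions with
complementary connection types (CT): either head-to-tail twice
(3' to 5' and 5' to 3') or head-to-head plus tail-to-tail (5' to 5'
and 3' to 3'); in the latter case one segment of each junction must be
reverse-complemented so that every derived chromosome reads 5' to 3'.
The CT dialect fixes "first" as the lexicographically smaller
chromosome name: `3to3` joins the two tails, `5to5` the two heads,
`3to5` tail-of-first to head-of-second, `5to3` the converse. The exact
encoding used by any given external caller is not standardized, so the
VCF reader maps whatever CT key it finds onto this dialect and the
writer derives the bracket ALT notation from it; the two encodings can
never disagree.

Every junction is processed in *junction orientation*: the first
chromosome's segment read 5'→3' into the junction, then any inserted
bases, then the second segment. A head segment runs along the
reference; a tail segment is reverse-complemented. Microhomology and
insertion calls are therefore orientation-independent, but an insertion
sequence may be reported as the reverse complement of the sequence seen
on a derived chromosome — consumers comparing insertions should compare
up to reverse complement.

# Junction architecture: detection model

Let the junction consensus (assembled from the split reads by
per-position majority vote, reads anchored by genomic arithmetic so
that differing but equivalent aligner placements still stack) have
length $n$. Let $L$ be the longest prefix of the consensus exactly
matching the first chromosome's reference continued past its breakend,
and $R$ the longest suffix matching the second chromosome's reference
extended back before its retained start. With $g = n - L - R$:

* $g < 0$: **microhomology** of $h = -g$ bases — a tract present in
  both reference flanks, making the junction position ambiguous within
  $h$ bases. Both extremal placements are reported; the left-most is
  the canonical position (the alternate differs by exactly $h$ on each
  chromosome).
* $g = 0$: **blunt-end ligation**.
* $g > 0$: **micro-insertion** of the $g$ unmatched bases, absent from
  both flanks.

If fewer than `anchor_k` (default 20) bases anchor the consensus on
either side, the junction is reported unresolved rather than guessed —
the behaviour consistent with an IMPRECISE call.

**Bases lost.** On each chromosome the lost interval is the run of
bases strictly between the retained head end and the retained tail
start, where "retained" is homology-maximal: bases covered by junction
microhomology match a retained flank and are not counted as lost. This
matches the published reporting convention for RT junctions. One
consequence worth stating explicitly: the *physical* gap between
retained segments equals reported loss plus adjacent homology, so the
exact conservation identity used by the tests is

$$\mathrm{len}(der_1)+\mathrm{len}(der_2) =
  \mathrm{len}(A)+\mathrm{len}(B) - \sum \mathrm{gap} + \sum \mathrm{ins}.$$

**Derived chromosomes.** `derive_chromosomes()` is pure 1-based
arithmetic: a head contributes `bp` bases, a tail `len - pos + 1`;
derived length = both segments plus any insertion. Megabase values are
rounded half-up to one decimal and only at reporting. On the published
pig RT coordinates this arithmetic reproduces the printed derived
lengths exactly (86.2/196.7 Mb, 210.9/52.7 Mb, 153.7/200.5 Mb); for
one published RT the printed coordinate and the printed Mb
decomposition contradict each other (they differ by an order of
magnitude on one chromosome), and the package computes from
coordinates rather than attempting to reproduce both.

# Filters

* **basic**: keep calls with filter status PASS (support of at least 3
  discordant pairs or 3 split reads, and MAPQ above 20) that were
  refined by split reads (PRECISE).
* **strict** (the "final" tier, meant for ~30-fold samples): MAPQ
  equal to the maximum (60), at least 10 split reads, at most
  2 × intended coverage discordant pairs (ceiling 60 at 30-fold,
  scaled with coverage), and SRQ strictly above 0.9.
* **relaxed** (for lower coverage): calls that failed the caller's
  quality filter (LowQual) are retained if they have at least 5 split
  reads. The published description states only what was *additionally*
  retained; the default composition here is (PASS or LowQual) with
  SR ≥ 5, and `filter_config(relaxed_union_strict = TRUE)` selects the
  alternative reading (strict survivors ∪ qualifying LowQual calls).
  Every strict survivor is retained by both compositions.

Reciprocal matching then pairs junctions on the same chromosome pair
with complementary CTs whose breakends on each shared chromosome lie
within `pair_window` (default 100 bp). The window is applied in the
blind screen as well as in the targeted mode.

# Breakpoint-pattern classification

At a genuine RT breakend the locus shows concordant, high-MAPQ reads
from the intact homologue on both sides plus discordant pairs and
split reads from the derived chromosome. Repeat artifacts show either
(a) discordant/split evidence with the good concordant reads lacking,
or (b) forward and reverse discordant pairs overlapping in the same
area. Thresholds (config-exposed, `classify_config()`):

* window 500 bp around the breakend;
* minimum mean concordant depth on the intact side = coverage/3
  (10 at 30-fold) — the published description is qualitative ("good
  reads lacking"), so this quantification is this package's own;
* minimum discordant count per orientation 3;
* **footprint-overlap requirement** for the bidirectional artifact
  class: because a true RT has its two breakends on one chromosome
  only a few bases apart, both discordant orientations legitimately
  appear near the locus — but their footprints *abut* (forward reads
  end at the head breakend, reverse reads start at the tail breakend)
  rather than overlap. A locus is REPEAT_BIDIRECTIONAL only when both
  orientations are supported *and* their footprints overlap by at
  least 20 bp. Without this condition every true RT breakend would be
  misclassified as the artifact pattern.

The "intact side" is to the right of a head (5') breakend and to the
left of a tail (3') breakend. AMBIGUOUS is surfaced, never dropped,
and fails the default decision policy, which confirms an RT only when
all four breakends are RT-like and the locus recurs in no other cohort
sample (recurrent inter-chromosomal adjacencies are repeat-driven).
The policy is relaxable (`min_rt_like = 3`) for the targeted rescue of
breakpoints inside repeats.

# The simulator

The simulator emulates the sequencing design of a 30-fold Illumina
150 bp paired-end run of a diploid carrier: one haplotype normal, one
carrying both derived chromosomes. Defaults
(`sim_config()`): read length 150, median insert 307 with a lognormal
spread whose IQR is ~15% of the median (only the median is published),
per-base substitution errors at rate 0 (errors exercise consensus
building but add nothing to the geometry), each haplotype at half the
configured coverage. Subsampling fractions 0.30/0.50/0.60 emulate the
10/15/20-fold titration.

`plant_translocation()` writes requested microhomology literally into
the unretained gap bases of the reference (so the flanks genuinely
share the tract) and then iteratively breaks any accidental flank
agreement that would change the detected type or homology length,
treating "must differ" constraints from both junctions jointly — the
two junctions can constrain the same gap base when losses are small.
If the constraints are unsatisfiable (homology demanded where a flank
is locked by the other junction) planting errors out rather than
silently delivering a different architecture.

`emit_truth_alignments()` plays the role of the aligner: reads are
placed at their true coordinates; junction-crossing reads become split
records when both sides align at least 15 bases (below that, the
overhang is soft-clipped, as real aligners do), and with microhomology
the split placement is varied across the $h+1$ equivalent positions,
as real aligners scatter them. The repeat model relocates reads lying
fully inside an interspersed repeat copy to a random other copy with
probability 0.5 and caps their MAPQ at 12 (families of 2–3
near-identical copies) or 0 (≥ 4 equally good placements); reads
straddling a copy boundary gain an artifact supplementary alignment
with probability 0.3. These two mechanisms generate, end to end, the
repeat-only and bidirectional artifact patterns and the
false-negative-with-targeted-rescue behaviour of breakpoints inside a
SINE-like element.

What the simulator does **not** emulate: indels and quality-score
structure, GC and mappability bias, PCR duplicates, chimeric library
artifacts, mosaicism, and genuine alignment ambiguity beyond the
explicit repeat model. Passing tests therefore demonstrate correctness
of the detection logic under idealized mapping, not performance on
real libraries.

# Evidence counting and a known sensitivity margin

PE counts every discordant pair, including fragments that also carry a
split read; SR counts split records plus soft-clipped records whose
clip boundary matches the junction with at least 5 clipped bases (the
clipped-read rescue hybrid callers perform when realigning reads
against the assembled consensus).

A quantitative consequence of the published design is worth knowing:
at 30-fold diploid coverage, a junction on the derived haplotype is
crossed by roughly Poisson(15) reads, so the strict tier's "at least
10 split reads" sits near the 92% quantile per junction and ~86% per
RT (both junctions must pass). Requiring every simulated carrier to
survive the strict blind screen is therefore not achievable with
certainty at 30-fold — the same margin that makes the relaxed tier
necessary at 20-fold and below. The test suite asserts the idealized
expectation and documents the shortfall rather than loosening
thresholds; the robust properties (specificity, relaxed ≥ strict,
monotonicity in coverage) hold exactly, and junction-architecture
parameter recovery is exact in effectively every replicate — the rare
miss (about 1 in 200 junctions) is a fragment-sampling coverage hole
at the junction leaving too few crossing reads, not a
characterization error.

# Numerical and degenerate-input choices

* Clustering window for discordant pairs: 500 bp (≈ insert median +
  3 spreads); any window that merges same-junction pairs and separates
  the two reciprocal junctions (≥ 10 kb apart in all tests) works.
* Split-group window: 15 bp, above the largest homology exercised.
* MAPQ aggregation: median (the external caller's exact rule is not
  published); PASS/LowQual is a pure function of (PE, SR, MAPQ).
* Consensus ties break deterministically (alphabetical); sparse
  single-read consensus edges are trimmed before flank matching so a
  single erroneous edge base cannot defeat exact anchoring.
* Empty inputs yield empty outputs everywhere; a PRECISE record
  without split reads is demoted on read with a warning; a BND record
  without partner coordinates is skipped with a warning; malformed VCF
  errors with its line number.
* Chromosomes shorter than one fragment are skipped with a warning;
  unplaced/mitochondrial contigs are excluded from calling by name.

# Problem sizes used by the tests

Unit tests run on two-chromosome genomes of 42–150 kb at 30-fold
coverage (about 2,000–10,000 fragments), chosen so the full suite
exercises every stage — including 100-replicate parameter recovery and
a 20-replicate coverage titration — in a few minutes on one core. The
acceptance script (`scripts/acceptance.R`) uses the same sizes.
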