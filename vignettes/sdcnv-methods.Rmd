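---
title: "Read-depth discovery of segmental duplications and CNVs: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-depth discovery of segmental duplications and CNVs: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdcnv)
library(dplyr)
```

## The problem

Segmental duplications (SDs) — stretches of more than 1 kb duplicated at
90% or higher identity — and copy number variants (CNVs) are discovered
from whole-genome sequencing by two complementary routes. Whole-genome
assembly comparison (WGAC) aligns an assembly against itself and finds
duplicated intervals directly, with precise boundaries but poor
reliability at very high identity, where assembly artifacts mimic
duplications. Whole-genome shotgun sequence detection (WSSD) maps an
individual's reads to the reference — keeping *every* placement of every
multi-mapped read — and reads copy number off the depth of coverage:
windows whose corrected depth sits far above the genome-wide average are
duplicated, far below deleted. `sdcnv` implements both routes, their
combination into an SD database, the cross-individual CNV-region (CNVR)
statistics built on top, and a synthetic-genome simulator that makes the
whole pipeline testable against known truth.

## Windows and the fragmentation effect

WSSD computes depth in three window types, all sized in *units* rather
than bases: sliding **long windows** (detection; default 5,000 units
sliding by 1,000), tiling **short windows** (call-edge refinement; 1,000
units) and tiling **copy windows** (copy-number estimation; 1,000
units). Before mapping, the reference is hard-masked: repeat bases are
replaced by N so reads cannot be placed there.

The original window currency counts *non-masked characters*. That
definition has a blind spot with long reads: a region of alternating
short masked and clean blocks (say 50 bp each) contains half its bases
unmasked, yet no 100-bp read fits between the masks, so no read can ever
be placed there. A window sized by unmasked characters will span such a
region, receive no reads, and look exactly like a deletion. We call this
the *fragmentation effect*; it grows with read length and is why a
36-bp-read-era convention misbehaves on 100-bp data.

The enhanced currency counts **unique hits**: distinct start positions
at which a full-length read lies entirely on unmasked bases
(`compute_unique_hit_track()`). Fragmented regions contribute no units,
so no window mass, and the false-deletion substrate disappears. On fully
unmasked sequence the two dialects tile identically except within the
last read-length of the sequence end, so nothing is lost where masking
is absent. The worked 4-kb example (first 2 kb alternating 50-bp N and
clean blocks) splits into 3 copy windows under the original dialect —
the first covering the whole fragmented 2 kb with zero mappable
positions — and 2 under the enhanced dialect:

```{r fig6}
set.seed(1)
s <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
for (b in seq(0, 1999, by = 100)) substr(s, b + 1, b + 50) <- strrep("N", 50)
nrow(build_windows(c(chr = s), "original", "copy", read_length = 100))
nrow(build_windows(c(chr = s), "enhanced", "copy", read_length = 100))
```

Two window-geometry conventions are deliberate choices the method's
description leaves open:

* **Window spans.** A window's genomic footprint runs from its first
  unit to its last unit + 1 (original) or + read length (enhanced);
  tiling kinds keep a trailing window holding at least half the unit
  quota and otherwise merge it into its predecessor (sliding kinds drop
  such tails, whose units the previous window already covers). The
  half-quota rule preserves the worked example's two-window outcome.
* **"Unique" means distinct, not single-copy.** A unique hit is a
  distinct clean start position, not a position unique genome-wide:
  accumulating multi-mapped depth over duplicated sequence is the
  essence of the read-depth signal, so discarding multi-mappable
  positions would defeat the method. Only the forward strand defines the
  track; reverse-strand placements are recorded at their forward-strand
  start when counted.

## From placements to calls

The bundled mapper (`map_reads_exact()`) reports *all* placements of
each read on both strands within a mismatch budget (0–2), via pigeonhole
seeding over a 2-bit k-mer index; reference N never matches. Placements
are reported even over masked bases — masking is then enforced in one
place, `filter_masked_placements()`, which removes placements whose read
span touches an N, exactly what mapping against the hard-masked genome
would have done. Depth is the count of placement *starts* per window
span (half-open), the simplest rule consistent with integer per-window
counts; multi-mapped placements all count.

Raw counts are GC-corrected with per-1%-GC-bin factors
`mean(all) / mean(bin)` fitted on windows outside known SDs and gaps
(`fit_gc_correction()`); bins with fewer than 20 windows fall back to
factor 1 rather than amplify noise. Control statistics (mu, sigma) of
corrected depth come from iterative 3-sigma trimming to convergence
(`fit_control_stats()`), with a minimum-sigma floor of 0.5 reads so that
near-constant toy fixtures cannot produce infinite z-scores.

Duplications and deletions are called symmetrically by the **6-of-7
rule**: a seed is any stretch where at least 6 of 7 consecutive long
windows deviate beyond mu ± 3 sigma ("significantly deviating"
quantified as the conventional 3-sigma multiplier); overlapping seeds
merge, the call span is the union of deviating windows, edges shrink to
the outermost deviating short windows, and calls with more than half
their span in assembly gaps are dropped as artifacts. Under the default
geometry the shortest possible call is (6 − 1) × 1,000 + 5,000 = 10,000
units — 10 kb on mappable sequence — which is why sub-10-kb variation is
invisible by construction. Copy number per copy window is the diploid
ratio `2 × depth / mu_copy`, using the copy-window control mean (not the
long-window one; the two window sizes have different count scales). Sex
chromosomes are not treated specially here: the simulator emulates
autosomal diploid individuals only.

## WGAC at desk scale

Full WGAC "fuguizes" the genome: it removes annotated repeats, BLASTs
the remainder against itself, and reinserts coordinates. The package
realizes the same intent with primitives that are exact and testable at
megabase scale: all k-mer matches between distinct positions seed the
search, and high-copy repeats are suppressed by an occurrence cap —
every base covered by a k-mer whose genome-wide canonical count exceeds
`max_occ` is treated as repeat-masked, and k-mers touching such bases
are excluded (this removes repeat-boundary seeds too, which would
otherwise leak through the plain count rule at copy numbers just above
the cap). Anchors sharing a diagonal within a 300-bp band chain when
consecutive anchors sit within 2 kb; each chain is trimmed to its
cluster's median diagonal (±30 bp indel tolerance, which keeps stray
same-band anchors from inflating the aligned span) and globally aligned
with match +1, mismatch −1, affine gap open −4 / extend −2. Identity is
matches over *all* alignment columns, gap columns included; alignment
length is the shorter of the two intervals. The SD definition then
filters: length strictly over 1 kb, identity at least 90%.

High-identity WGAC (≥ 94%) is only trusted where WSSD agrees: an
alignment passes if at least half the bases of the union of its two
intervals overlap WSSD intervals (the support fraction is a choice; the
cited criterion is not restated in the text). The final database is the
provenance-tracked union of low-identity WGAC, filtered high-identity
WGAC and WSSD, merged to outermost endpoints. *Ancestral* SDs — copies
diverged below 95% identity, hence old — are the merged sub-95% stratum;
the identity threshold, not any implied divergence date, is what the
code implements. Intra-contig alignment distances (for the per-distance
summary) are measured between the closest endpoints of the two
intervals, zero when they overlap.

## CNVRs, hotspots, genes

CNV calls union across individuals into CNVRs at ≥ 1 bp overlap
(abutting calls stay separate), classified gain / loss / both by their
carrier events. Hotspots require a carrier quorum in each of two sample
groups (default 2 and 2, the natural quorum for a small cohort split into,
say, three commercial and ten indigenous animals; the grouping is a
sample sheet, not a constant). Gene copy
number is the median over copy windows overlapping the gene by ≥ 1 bp
(even counts: mean of the two middle values); copy-number-variable genes
are protein-coding genes whose CN range across individuals strictly
exceeds 2.0.

## Permutation enrichment and GC structure

Overlap significance uses the method's own randomization scheme and
nothing analytic: each replicate relocates every query region to a
uniform random position — contig chosen in proportion to its room —
with no overlap among placed regions or with forbidden intervals,
10,000 replicates by default. The statistic is the number of *feature*
intervals hit (the phrasing of the headline results counts features, not
queries; both are reported). Significance is the add-one empirical tail
`p = (1 + #{null ≥ obs}) / (reps + 1)`, never zero, with minimum
`1/(reps+1)`; fold is observed over the null mean, reported as infinite
when the null mean is zero and as 0 when nothing is observed.

Breakpoint segments are 2-kb windows *centered* on each CNVR boundary
(the "covering a 2-kb segment" convention is read as ±1 kb; an
inside/outside-only alternative exists but the centered reading is
symmetric and parameter-free), clipped at contig edges. Their pooled GC
is compared with the genome background by relocating the segments with
the same placement engine. GC peaks are 500-bp windows, slid by 100 bp
(a step the description leaves open; 100 bp balances resolution against
fivefold redundancy), whose GC is at least 1.5× that of their centered
10-kb background; overlapping qualifying windows merge into one peak so
density per Mb is not double-counted. Breakpoint–peak association is
the fraction of segments whose midpoint lies within 1 kb of a peak,
with the same relocation null.

## The simulator: what it emulates, what it does not

`generate_reference()` plants, without mutual overlap: assembly gaps (N
runs), high-copy repeat families (recorded in the repeat track, hence
hard-masked downstream), *fragmented regions* (alternating masked/clean
blocks emulating dense interspersed repeats — the fragmentation-effect
substrate), and SD pairs whose second copy is point-mutated at a chosen
divergence (≤ 10%). `simulate_individual()` applies integer-copy-number
events to two haplotypes — a CN-c event leaves c/2 of the reference
dosage; extra duplication copies go in tandem by default (dispersed is
available; the read-depth signal cannot tell the difference, which is
why the default does not matter). `simulate_reads()` draws single-end
reads at Poisson-distributed count `coverage × length / read_length`,
uniform starts, optional GC bias by rejection; read depth uses only
placement starts, so read pairing would add nothing and is not
simulated. Defaults are the scale of contemporary livestock resequencing panels,
at desk size: 100-bp reads at 10× coverage (per-animal coverage in such
panels typically runs 10–17×).

The simulator does **not** emulate sequencing errors beyond uniform
mismatches, quality scores, indels, alignment ambiguity from
low-complexity sequence, or reference mis-assembly. Passing tests
therefore demonstrate the statistical machinery — window construction,
bias correction, calling geometry, permutation calibration — not
robustness to real-data artifacts; on real data the upstream mapper and
QC own those problems (the placement filter hook is where read-level QC
would plug in).

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere; 1-based only inside
  BED/SAM files per those formats.
* Control fitting errors below 30 usable windows rather than return an
  unreliable model; GC bins thin out to factor 1.
* A read longer than its contig yields an empty mappability track, not
  an error; fully masked window spans have flagged (NA) GC and are
  excluded from correction.
* The trimming loop stops when mu moves by less than 1e-6 × mu or at
  100 iterations; refitting on the returned control set reproduces mu
  to that tolerance.
* Ties at thresholds: identity ≥ 90% and ≥ 94% are inclusive, ancestral
  < 95% and gene-CN range > 2.0 are strict, WSSD support ≥ 0.5 is
  inclusive, the GC-peak ratio ≥ 1.5 is inclusive — each following the
  wording of the rule it implements.
* At 8–10% SD divergence an exact-match (0-mismatch) read no longer
  cross-maps between copies, so WSSD cannot see such SDs; that is the
  method's documented identity floor and the reason the high-identity
  WGAC stratum is the one requiring WSSD support.

## Problem sizes

The test suite and the acceptance script run entirely on simulated
data: parameter recovery on a 10-Mb single-contig genome at 10×
(one 20-kb CN-4 duplication, one 15-kb CN-0 deletion), the dialect
comparison on 2-Mb genomes with a 100-kb fragmented region, WGAC
recovery on 300-kb genomes, and permutation calibration with 800
features × 150 queries at 500–1,000 replicates. These sizes hold the
full-suite runtime to minutes while keeping every window, call and
null-distribution statistic in the regime where its expected behavior
is unambiguous.

## Known limitations

Breakpoints are window-quantized: the caller reports rough spans, not
base-pair breakpoints — an inherent property of read-depth evidence.
Sub-10-kb events are invisible under the default geometry. The WGAC
stage is a desk-scale reconstruction: it has no BLAST-grade sensitivity
model and is not meant for gigabase genomes. Sex-chromosome ploidy,
paired-end and split-read evidence, and sub-window copy-number mosaics
are out of scope.
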