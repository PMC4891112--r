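---
title: "Models and methods behind chromoshatter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chromoshatter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`chromoshatter` studies one question at desk scale: given a cell whose
nucleus has been hit by a focused burst of ionizing radiation, can the
resulting chromothripsis-like rearrangement storm be detected from
mate-pair sequencing and SNP-array data — and can every step of that
detection be verified? Because no real data set with known truth
exists for this problem, the package's first component is a generator
that *states* a world (genomes, rearrangements, reads, probes) and its
second component re-detects that world. This vignette documents the
models, the parameters that matter, the numerical choices, and the
limits of what a green test establishes.

## The stated world

### Reference and derivative genomes

References are i.i.d. random sequences at a target GC fraction (default
0.41, the human genome-wide value). The bundled demonstration case uses
the 14-junction / 16-segment alteration set of a proton-microbeam
irradiated oral carcinoma subline. Real coordinates (tens to hundreds
of Mb) are compressed by an order-preserving piecewise-linear map: gaps
between breakpoint anchors of at most 1 kb are kept *exactly* — so the
famous 5 bp and 377 bp breakpoint proximities survive to the base —
while larger gaps collapse to a 5 kb pad and 10 kb margins flank each
chromosome. A strictly affine per-chromosome map cannot do this (small
distances would scale with the compression factor), which is why the
map is piecewise. Chromosomes without breakpoints are included as 25 kb
decoys so that the localization null has a realistic karyotype to
spread breakpoints over.

Each rearrangement plants exactly **one** novel junction:

| type | construction | discordant-pair signature |
|------|--------------|---------------------------|
| `LD` | splice out `(pos1, pos2]` | FR at excessive distance |
| `RF` | tandem-duplicate `[pos1, pos2]` (one duplication joint) | reverse–forward |
| `FF` | fold back: keep `[1..pos1]`, append the reverse complement of `(pos1..pos2]`, drop the tail | forward–forward |
| `CT` | unbalanced fusion chromosome `chrA[1..pos1] + chrB[pos2+1..]`, originals retained | inter-chromosomal |

A balanced inversion would create two junctions and break the
one-event/one-junction bookkeeping of the demonstration set, which
lists single junctions; the fold-back construction is the standard
single-junction realization. Events whose footprints collide (the
bundled set contains two genuine containments) are placed on additional
copies of the chromosome — the aneuploidy of the modelled cell line,
which carries several copies of each chromosome, makes this the
biologically honest resolution rather than an error.

### Junction chemistry

Chemistry is planted by *retrofitting the reference* before the
derivative is assembled: for an m-bp microhomology the m bases ending
side 1 are copied onto the m reference bases entering side 2, and any
accidental base identity that would lengthen (or, for blunt joints and
insertions, create) a homology is broken by a single-base edit.
Insertions may carry a templated origin: the template is written into
the reference at a stated offset, where the offset names the template's
*reading start* — the forward-strand start for forward templates and
the forward-strand end for reverse ones (so "79 bp upstream of
breakpoint 2 in reverse orientation" means the reverse-complement
reading begins 79 bp upstream). All samples, parental ones included,
are then simulated from the same retrofitted reference, so the edits
are junction-neutral everywhere except at the planted fusion.

Two bookkeeping notes on the bundled set: the 34-nt printed insertion
of junction ID167 is described as "33 bp" in the accompanying prose —
the package carries the printed string and reports the measured length;
and three junctions with no recorded chemistry are carried as blunt,
which is what makes the 9/3/2 census come out.

### Reads

125 bp FR paired-end fragments, insert 300 ± 30 bp, 30× base coverage
per derivative sequence, error-free by default — the stated sequencing
world (125 bp was the platform's maximum read length; mate-pair
libraries were prepared, but FR is the definition of "normal"
orientation used by the classification, so FR fragments are simulated).
Mapping is emulated by lifting derivative coordinates through the block
map: a read overlapping a junction is assigned to the side covering at
least half of it, its position extrapolated linearly — a stated
simplification of soft-clipped BWA mapping. Consistent with soft-clip
semantics, the per-read mismatch count records *injected sequencing
errors only*; junction-overhang bases are treated as clipped. (An
earlier variant that counted overhang bases as mismatches
systematically starved junctions flanking long insertions and
contradicted the intended "error-free reads have zero mismatches"
contract.) Sequences are stored aligned to the forward reference
strand, the SAM convention; consumers that need the physical read
(e.g. the realignment filter) reconstruct it from the strand column.

### Probe tracks

SNP probes sit every 1 kb; the signal is the local copy number plus
Gaussian noise (SD 0.3 per track — note a differential track therefore
has SD ≈ 0.42). 30 % of probes are heterozygous; their BAF sits at 0.5
in balanced two-copy regions, at 1/3 or 2/3 in three-copy regions that
retain both parental alleles, and at {0, 1} in LOH regions (deletions
by default). The 16-segment truth is rescaled to 60 probes per segment
with 45-probe neutral gaps — comfortably above the 30-probe
identification minimum, including the one real pair of adjacent
deletions separated by a tiny neutral gap.

### Dosimetry

Thin-slab dosimetry: each proton deposits LET × path energy in a
cylinder of spot-area cross-section, so
`D = n · LET / (ρ · A)` — exactly linear in the proton count and
independent of path length. With LET 11.7 keV/µm and a 2 µm spot this
gives 59.7 / 119.3 Gy for 100 / 200 protons. Published figures for this
beam quote 55 / 110 Gy; the rounding or attenuation assumptions behind
those numbers are not stated, so the function reports the physics value
and this paragraph records the discrepancy instead of forcing
agreement.

## The detection cascade

Pairs are canonicalized (lower chromosome/position first) and
classified: `PROPER` = same chromosome, FR, start distance ≤ 500 bp;
`CT` = chromosomes differ; FR beyond 500 bp = `LD`; RF = duplication
type; FF and its mirror RR are folded into one class. Discordant pairs
of identical class and chromosome assignment cluster by single linkage
when **both** breakpoint footprints lie within 500 bp — requiring both
ends is a deliberate choice (a rearrangement has two breakpoints;
one-sided matching would merge unrelated events). The consensus
breakpoint is the innermost aligned base toward the junction (maximal
end over forward reads, minimal start over reverse reads).

The filter chain then applies, in order: support ≥ 3 (">2 read pairs");
subtraction of any cluster matching a parental cluster in class,
chromosome pair and both breakpoints within 500 bp (parental clusters
are kept unthresholded — any parental evidence disqualifies);
realignment; mismatch ≤ 2 per read plus at least one perfect pair; and
the support threshold again, mirroring its appearance at both ends of
the published scheme.

The realignment filter stands in for a BLAST remap of supporting
reads: an exact-word (31-mer, stride 16) seeded, ungapped diagonal
extension scored +1/−2, with Karlin–Altschul E-values (λ = 1.33,
K = 0.621, search space twice the genome length) — a self-contained
blastn surrogate, deterministic and offline. A pair is discarded when
its **best-scoring** placements form an FR pair within 500 bp at
E < 10⁻⁷: the mapping-error signature of a pair that has a perfectly
ordinary home in the reference. Using best placements (not all
above-threshold local hits) is essential: a junction-straddling read
always has partial-flank hits near its mate, and counting those would
veto every true pair.

## Junction classification

The classifier extends the junction sequence's left flank along the
side-1 reference and its right flank along side 2 (exact matching only
— all observed microhomologies are exact 1–4 bp strings) and reads the
*maximal-extent overlap*: positive overlap = microhomology, zero =
blunt, negative = insertion. Parsimony is built in: a k-bp homology
always beats a (k−1)-bp-plus-insertion reading. The flanks must anchor
(≥ `flank` matching bases each side) or a no-anchor error is raised.
Insertion origins are searched by exact match of the insertion and its
reverse complement within 500 bp of each breakpoint (the one known
templated case lies 79 bp away; 500 bp bounds cost while covering it
comfortably), reporting the nearest hit's reading-start offset.

## Copy-number segmentation

The published analysis used a proprietary genomic-segmentation
algorithm with three printed parameters (30-probe minimum, p 0.001,
signal-to-noise 0.3) and inclusive thresholds ≤ 1.8 / ≥ 2.6 (the
Methods' inclusive form is adopted over the Results' strict form; with
continuous signals the difference has measure zero). The substitute
implemented here is deliberately *not* a clone. It is a deterministic
recursive segment-vs-rest scan: within an interval, the inner segment
maximizing the two-sample t statistic against the remainder is located
with **no length constraint**; the interval splits only if that most
significant region spans ≥ 30 probes, reaches p < 0.001, and moves the
mean by ≥ 0.3 × the track's robust noise SD (MAD of first differences
divided by √2, robust to true breakpoints). A dominant region shorter
than 30 probes stops the recursion: a sub-minimal region is not
identifiable as an alteration, *and no diluted larger window is
reported in its place*. This is the point where plain single-changepoint
binary segmentation fails — it would isolate a 29-probe run inside a
30-probe window and call it — and why the scan form was chosen. The t
statistic uses the pooled-variance form: at the configured minimum
sizes it coincides with Welch's, and it keeps two-probe low-variance
noise windows from dominating the unconstrained scan. The p-value is
nominal (computed from the maximal t without selection correction), as
is usual for such scan surrogates; the 30-probe and SNR gates carry the
real specificity. Amp/Del calls below 30 probes after merging are
reverted to neutral, completing the minimal-region semantics.

Segment lengths are reported as `end − start` (not `end − start + 1`);
this is the convention that reproduces every printed length in the
bundled 16-segment table exactly.

## Chromothripsis scoring

The three criteria are qualitative in origin; the flag implemented here
is an explicit operationalization with every threshold exposed:

* **Localization** — observed per-chromosome breakpoint counts against
  a null placing the same number of breakpoints independently,
  probability proportional to chromosome length (the simplest
  defensible null; probe-density weighting would be a config variant).
  The p-value uses the add-one estimator `(1 + b)/(n_perm + 1)`, which
  is super-uniform under the null — the plain fraction is
  anti-conservative at finite `n_perm`. Caveat: an intra-chromosomal
  event contributes two co-located breakends by construction, so an
  isolated deletion can look "localized"; the breakpoint-count floor
  below absorbs this.
* **Oscillation** — switches between the two most frequent copy states
  of the chromosome's segment sequence, other states ignored.
* **Heterozygosity** — a segment retains heterozygosity when the median
  *folded* BAF (`min(BAF, 1 − BAF)`) of informative probes exceeds
  0.15. The folded form matters: in copy-neutral LOH the informative
  probes split between BAF ≈ 0 and ≈ 1, and a plain median can land
  midway between the modes and fake retention. Fewer than 10
  informative probes yields `NA` (indeterminate), distinct from
  `FALSE`.

A chromosome is flagged when it has ≥ 3 breakpoints, localization
p < 0.05, and either ≥ 2 oscillations or a heterozygosity-retaining
amplification. On the demonstration case chromosomes 5 and 7 are
flagged, and chromosome 2 — six breakpoints and two
heterozygosity-retaining gains — also meets the rule; the report prints
the evidence columns precisely so such judgement calls stay visible.

## What the synthetic world does not test

Reads are error-free, uniquely placeable (i.i.d. sequence has no
repeats), and "mapped" by truthful coordinate lifting; there are no PCR
duplicates, chimeric artifacts, or mappability holes. The published
real-data funnel — 91 candidate clusters reduced to 14 validated
junctions — reflects exactly those nuisances, and nothing here
reproduces or tests that attrition; only the filter *mechanics* are
exercised. Likewise array normalization (from raw intensities to copy
units) is upstream of this package, and the probe model's noise is
white, while real arrays show wavy, GC-correlated noise. A green test
therefore establishes correctness of the algorithms under their stated
models, not performance on real libraries.

## Determinism and budgets

Every stochastic step takes a seed and derives per-stage substreams
from it; identical configuration and seed give byte-identical outputs,
including written files. At the stated scale (≈ 0.6 Mb reference,
≈ 100k pairs per sample, ≈ 2k probes) the full cascade runs in well
under a minute on one CPU; the acceptance script regenerates both
targets from scratch in ≈ 20 s. Per-junction final support at 30× is
≈ 20 pairs (minimum 9 observed over 14 junctions × 6 seeds), so the
"exactly 14 calls, zero false positives" outcome is robust to the seed
rather than a lucky draw.
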