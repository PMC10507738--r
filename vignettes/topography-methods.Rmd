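---
title: "Methods: topography of mutational signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topography of mutational signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(topomut)
```

`topomut` asks, for each mutational signature, whether its mutations fall
on the genome differently from chance — with respect to transcription and
replication strand, replication timing, and the occupancy of
topographical features such as nucleosomes, CTCF sites and histone
marks. "Chance" is made concrete by simulation: background catalogs that
keep everything about the real catalog except position. This vignette
documents the models, the tunable parameters, the numerical choices, and
what the synthetic fixtures do and do not establish.

## The null model: context-preserving simulation

Every analysis is a comparison of the real catalog against `n_reps`
(default 100) simulated replicates. For each real mutation, a replicate
draws a new position uniformly among the loci of the same chromosome
whose reference context reproduces the mutation's channel — for a
substitution, the canonical pyrimidine-oriented trinucleotide (32
classes, both strands eligible); for a doublet, the canonical reference
doublet; for an indel, loci whose flanking sequence yields the same
ID-83 class. The alternate allele is carried over
(reverse-complemented when the drawn locus holds the context on the
opposite strand), so the per-(sample, chromosome, channel) burden is
conserved *exactly* in every replicate; this is asserted in the test
suite over all fixtures.

Positions are drawn with replacement (two simulated mutations may share
a locus; on realistic pool sizes collisions are negligible) and real
positions remain eligible. Each replicate r has its own RNG stream
seeded from (seed, r), so replicate sets are reproducible and
order-insensitive. When the input carries a per-mutation `signature`
column the conservation groups are additionally split by signature,
which yields per-signature null counts directly; this is equivalent to
simulating each signature's subset separately.

## Channel schemas

SBS-6 classes substitutions by the pyrimidine of the mutated base pair
(C>A … T>G); SBS-96 adds the two immediate flanks; DBS-78 collapses
doublet substitutions and their reverse complements onto a canonical
78-channel catalogue (kept in the package as a normative table and
verified exhaustively by the tests); ID-83 types indels by size, the
affected base's pyrimidine (1 bp events), flanking tandem-repeat copy
number, and deletion microhomology (both flanks scanned, maximum taken).
Mutations whose required context contains an ambiguous base (N) are
excluded and counted rather than imputed.

Signature assignment takes the argmax of the per-mutation probability
row when it reaches `prob_cutoff` (default 0.5 — at least an even chance
that the signature generated the mutation), with lexicographic
tie-breaking for determinism. The same cutoff is used wherever mutations
must be unambiguously attributed, and per-signature analyses require at
least `min_mutations` (default 1,000) attributed mutations.

## Strand annotation

A mutation's strand is the reference strand carrying its pyrimidine.
Inside a protein-coding gene, the mutation is TRANSCRIBED when that
pyrimidine lies on the template strand (i.e. its strand differs from the
gene's annotated strand), UNTRANSCRIBED otherwise; regions covered by
genes on both strands are excluded as bidirectional, and everything else
is NONTRANSCRIBED. Genic/intergenic analysis reuses these labels
(genic = any gene hit).

Replication strand derives from a wavelet-smoothed Repli-seq profile
with printed initiation zones (peaks) and termination zones (valleys).
Between consecutive anchor midpoints the signal is treated as monotone:
a positive slope marks a leading-strand region on the + strand, a
negative slope a lagging-strand region; slope is taken as the sign of
the signal difference between anchors rather than per-base
differentiation, because the wavelet-smoothed input is piecewise
monotone and sub-threshold oscillations are noise. Stretches shorter
than `min_stretch` (default 10 kb) are dropped, and `term_trim`
(default 25 kb) of last-replicated DNA is removed on each flank of every
valley midpoint (`trim_both = FALSE` trims only the approach side; the
two-sided default reflects that the latest-replicating DNA surrounds the
termination zone). A mutation in a leading-plus region with its
pyrimidine on the + strand is LEADING; each strand flip toggles the
label; mutations outside the map are UNASSIGNED.

## Asymmetry statistics

For each signature and six-class channel, counts on the two strata enter
`OR = (real_a/real_b)/(sim_a/sim_b)` with a two-sided Fisher exact test
on the 2×2 table. The Fisher p is computed directly from the
hypergeometric density with the standard "sum of tables no more
probable" rule (a small relative tolerance of 1e-7 guards floating-point
ties); it matches `stats::fisher.test` to 1e-9 and an independent
binomial-coefficient enumeration to ~1e-14 over all tables with total
≤ 60. Simulated counts entering the table are the per-replicate mean
rounded to the nearest integer — pooling sums across replicates would
inflate the Fisher sample size roughly `n_reps`-fold and manufacture
significance; the sum is available as a config alternative but is not
the default. Benjamini–Hochberg correction is applied across one
analysis family (all signatures × channels of one run and stratum
type), and a cell is reported only when `q <= 0.05` *and* the odds
ratio departs from 1 by strictly more than `or_min = 1.10` in either
direction. The genic/intergenic family supports an asymmetry
correction that rebuilds the genic count as twice the larger of the
transcribed/untranscribed counts, removing any transcription-strand
contribution from the fold change.

## Replication timing

Timing segments are sorted by signal value descending (ties by genomic
order) and split into ten deciles, each holding as close to 10% of the
total signal mass as whole segments allow. Segments are atomic; the
filling rule targets the *remaining* mass divided by the remaining
deciles, which keeps every decile near 10% and never starves the last
ones. Densities are counts per attributable (non-N) base, normalised to
the densest decile; mutations outside the covered genome are excluded
and counted. The simulated ensemble supplies a per-decile mean, sample
standard deviation and a normal-approximation 95% CI of the mean. The
trend call fits OLS against decile index 1..10: INCREASING needs a
two-sided slope p ≤ 0.05 *and* non-strict monotonicity (plateaus
allowed — strict monotonicity would reject real plateaus); DECREASING is
symmetric; everything else is FLAT.

## Strand-coordinated mutagenesis

Within a sample, maximal runs of consecutive substitutions sharing the
six-class channel, the pyrimidine strand and the assigned signature,
with every inter-mutational gap strictly below `imd = 10,000` bp, are
collected; singletons are discarded. "Same context" is pinned at the
six-class level (a config allows SBS-96 strictness). Mutations removed
by the probability filter do not exist for distance purposes: two
retained mutations ≥ imd apart never merge across a removed site. Counts
per (signature, length) are z-tested against the per-replicate counts
(two-sided normal), BH-corrected across cells. Zero-variance cells are
degenerate: p = 1 when the observation equals the common simulated
value, else a zero sentinel plus a degeneracy flag — the observation
lies outside anything the null produced, and the flag warns that no
finite z quantifies it.

## Occupancy and abundance

The occupancy window spans 2,001 positions (offsets −1000…+1000; offset
0 is the mutation start); windows overrunning a chromosome are skipped
and counted. Averaging is two-round: over mutations per dataset (K),
then unweighted over datasets (M) — weighting by mutation count is a
config alternative, but the unweighted mean treats each experimental
dataset as one observation of the feature. Cohort-vs-global similarity
is Pearson r over the central ±500 bp with a Fisher-z p value; the
offsets are autocorrelated and are deliberately not decorrelated, so
the p value is optimistic — the r ≥ 0.5 requirement is the binding
constraint. Abundance uses the ±50 bp window (101 positions including
offset 0): the real mean signal is z-tested against the per-replicate
means, p values from multiple datasets are combined with Fisher's
method, fold changes averaged, and calls require `q <= 0.05` plus at
least a 5% departure of the fold change from 1 (applied uniformly to
all features; configurable).

## Cohort stratification

The APOBEC3 presence ratio is `ln(n_SBS2∪SBS13) / ln(n_other)`,
computable when the numerator count is ≥ 1 and the denominator count
≥ 2. HIGH is ratio ≥ 0.90 and MID is the open interval (0.75, 0.90);
LOW is therefore ratio ≤ 0.75 — the alternative reading that would send
ratios ≥ 0.75 to LOW contradicts the MID interval, so the boundary
0.75 itself is LOW. MID samples are excluded from downstream group
re-analyses. Group burden comparisons use the fold of medians and a
two-sided Mann–Whitney U test (exact where R's implementation allows).

## The synthetic-data generator

Fixtures emulate the real inputs at toy scale: uniform-composition
genomes (default three 2 Mb chromosomes — large enough that every
trinucleotide context occurs tens of thousands of times, as the
simulator requires), genes of 20 kb every 50 kb on random strands with
one antisense overlap per chromosome (bidirectional exclusion), a
200 kb-period sawtooth timing profile with printed peaks/valleys
(which makes leading/lagging base totals exactly symmetric), and
constant/cosine (nucleosome-like, 190 bp period)/peaked (CTCF-like)
feature tracks. All randomness flows from one spec seed through named
substreams, so adding a component never perturbs the others.

Planted effects are realized by re-weighting uniformly drawn candidate
loci: transcription or replication odds ratios multiply the weight of
transcribed/lagging candidates, a timing gradient tilts weights
linearly across deciles, an occupancy fold places the analytically
computed fraction of mutations at elevated-signal sites, and
strand-coordinated runs are inserted with sub-threshold gaps. Three
generator design choices matter for interpretation:

- Allocation across weight classes is deterministic (largest-remainder),
  with positions uniform within a class. The planted effect is thereby
  realized near-exactly, so recovery tests measure the analysis
  machinery rather than compounding generator and analysis noise. A
  fully binomial generator at n = 3,000 would itself wander ±5% around
  a planted odds ratio of 2.
- Planted strand effects restrict the signature's mutations to the two
  compared strata, so a requested n is the number of informative
  mutations for the odds ratio.
- The recovery gradient for timing is 6× early→late: with ten deciles
  and n = 5,000, a shallower gradient leaves adjacent-decile density
  steps at the scale of counting noise, and the monotonicity half of
  the INCREASING call becomes a coin flip per step.

What the fixtures do **not** emulate: realistic base composition and
repeat structure, chromatin-scale autocorrelation of real ENCODE
tracks, inter-sample heterogeneity, or clustered mutation processes
beyond the inserted runs. Passing recovery tests therefore shows the
estimators are correct and calibrated under the stated generative
model, not that real-data effect sizes will be recovered with the same
precision.

## Problem sizes and runtime choices

The test suite runs the parameter-recovery suites at 30 seeds (tx/rep
odds ratio 2.0 at n = 3,000; timing gradient and flat at n = 5,000;
occupancy fold 1.5 at n = 2,000), strand-coordinated recovery at 10
seeds (5 runs of length 6 over a 300-mutation background) and null
calibration at 50 seeds (three 1,000-mutation null signatures), all
with 25 simulation replicates per seed over a shared 3×2 Mb genome;
the 100-replicate default is exercised separately together with the
exact-conservation assertion. These sizes keep each suite in the
minutes range on one CPU while leaving the planted effects many
standard errors above their thresholds.

## Known limitations

- The simulator preserves context at the trinucleotide / doublet /
  ID-class level only; extended context (pentanucleotide) biases in
  real data would leak into the null.
- Fisher exact tests on mean-rounded simulated counts treat the null
  ratio as if observed once; the replicate-averaging uncertainty is
  ignored (conservative at large `n_reps`).
- The similarity p value ignores spatial autocorrelation (see above).
- bigWig is not parsed; tracks must be provided as wig/bedGraph (the
  upstream conversion is a one-liner with standard genome-browser
  utilities).
- Inputs are assumed to share one assembly; only chromosome-name
  overlap is checked.
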