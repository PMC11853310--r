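---
title: "Per-read m6A analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-read m6A analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery behind `permod`: what each
stage assumes, which parameters matter and why their defaults are what they
are, what the synthetic-data generators do and do not emulate, and the
design decisions taken where the problem was genuinely open.

## The problem

Nanopore direct RNA sequencing reads single native RNA molecules, so a
modification-aware basecaller can report, per read and per base, the
probability that the base is N6-methyladenosine (m6A). Two computational
problems surround that capability. Upstream, training such a basecaller
requires per-read modification labels, which in vivo data lacks: mRNA is
substoichiometrically modified, so even at a known m6A site only a fraction
of wild-type reads actually carry the methyl group. Downstream, per-read
probability calls need to be turned into site calls, stoichiometry
estimates and single-molecule analyses, with calibrated thresholds and
error rates. `permod` implements both.

## Semi-supervised per-read labeling

### Feature schema

Each aligned base of each read is described by 9 features in RNA002 mode:
signal intensity (SI, normalized current, unitless), the basecaller's
modification/error probability (MP), dwell time at the position (DT) and 10
bases upstream (DT10), both in raw signal samples, and five trace values —
the basecaller's per-base posterior for the reference base (TR) and for
each of A, C, G, T/U (TA, TC, TG, TT). The RNA004 schema widens this to 13
features at each of the positions -1, 0, +1 (39 columns): per-position
signal-intensity mean and standard deviation, the two dwell times, six
basecaller probabilities (including N for the stay state and the reference
base) and the three most likely k-mers from the basecalling model. Trace is
typically the single most discriminative feature — provided the features
were extracted with a basecalling model trained on modification-free data,
since default models have effectively learned to call m6A as A and emit
uninformative traces.

### Aggregation and balancing

Features are aggregated per centered 7-mer across all reference positions.
Differential read depth is a confounder: if the treated sample contributes
more reads than the control at a position, any per-position batch effect
masquerades as a modification signal. `aggregate_by_kmer()` therefore
downsamples both samples at every position to
`min(control, treated, max_reads_per_position)` with a seed derived from
the position key, and drops positions missing one sample. The per-position
cap (default 50) keeps high-coverage positions from dominating a 7-mer's
aggregate.

### K-mer selection

For each 7-mer with at least `n_min = 30` reads per sample, a two-sided
two-sample Kolmogorov–Smirnov test is run per tested feature (by default
the two features with the highest mean per-k-mer KS statistic, with ties
broken by the fixed feature order — in practice TR and SI, or TR and TA
when the trace effect dominates). P-values are Benjamini–Hochberg-adjusted
across 7-mers within each feature; a 7-mer is selected when any tested
feature reaches adjusted p < 0.01 with KS statistic D ≥ 0.1. The adjusted-α
and the effect floor are configurable; the floor exists because at high
coverage trivially small distributional shifts become significant. 7-mers
below `n_min` are *skipped*, not declared unmodified: absence of evidence
at low coverage is not evidence of absence.

### Three-stage labeling

Reads of a selected 7-mer are split 50:50 into train and test, stratified
by sample. Stage 1 trains gradient-boosted trees (100 trees, depth 3,
learning rate 0.1 — small enough to be fast, expressive enough for 9
features) on the train half using sample of origin as a surrogate label:
all control reads "unmodified", all treated reads "modified". That label is
wrong for exactly the unmodified fraction of the treated sample, which is
why stage 1 is not final. Stage 2 marks train reads with stage-1
probability inside (0.3, 0.7) as unknown and assigns them by label
propagation over a symmetric k-nearest-neighbour kernel (k = 10) on
z-scored features; confident stage-1 labels are clamped and never change.
The (0.3, 0.7) band is symmetric and configurable; it trades label purity
against training-set size. Stage 3 trains a fresh gradient-boosting
classifier on the relabeled train half and predicts every test read, whose
labels (with probabilities as confidence) are the pipeline's output. If
propagation fails to converge within 1000 iterations the stage-1 hard
labels are kept and the result is flagged.

All randomness flows from one pipeline seed; each 7-mer's seed is derived
deterministically from (seed, 7-mer), so results per 7-mer do not depend on
how many other 7-mers were processed.

One consequence of the design is worth stating: the labeler cannot signal
"no modification anywhere" by itself — its surrogate labels always bisect
the data. Null protection comes from the KS selection gate, which a 7-mer
with identical samples does not pass. The tests exercise exactly that
contract: on null data no 7-mer is selected and no read is labeled.

### RNA004-style evaluation

For the RNA004 schema the package evaluates per-7-mer separability with a
supervised Random Forest: per position the samples are balanced to the
lower coverage, positions under 100 reads are skipped, only 7-mers whose
central base is the sole candidate base are kept (for m6A, `BBBABBB`), the
data is split 50:50 and the test-half ROC AUC is reported. AUC is computed
from the rank (Mann–Whitney) statistic, which is exact and is cross-checked
in the tests against an independent ROC implementation to 1e-9.

## Site calling and thresholds

A read base is "modified" when its modification probability is ≥ τ (closed
inequality). A site passes when coverage ≥ 25 and modified-read fraction
≥ 5% — at exactly 25× that means at least 2 modified reads. The default
per-read τ for site calling is 0.5; for stoichiometry estimation τ = 0.1 is
the Youden-optimal operating point of the calibrated probability
distributions, and `youden_threshold()` recomputes the optimum for any pair
of labeled probability samples on a 0.01-step grid (ties resolved toward
the smallest τ, which favors sensitivity). Frequencies are computed over
reads overlapping the position; deletions contribute no call and hence are
excluded from the denominator. Stored frequencies are never pseudocounted;
a 0.001 pseudocount is appropriate only for log-scale display.

The false positive rate on a known-unmodified control is the fraction of
testable positions (coverage ≥ 25) that pass; the replicable variant counts
positions passing in all replicates among those testable in all replicates,
which can only be smaller.

## Single-molecule analytics

**Co-occurrence.** For sites A and B on one transcript, with modification
frequencies \(f_A, f_B\) computed on the \(C\) reads spanning both sites,
the observed count of doubly modified reads is compared to the independence
expectation \(Exp = f_A f_B C\):

\[ NSD = \frac{Obs - Exp}{\sqrt{Exp\,(1 - f_A f_B)}} \]

the number of binomial standard deviations from independence. Under
independence NSD has mean 0 and variance approaching 1, which the tests
verify by simulation at C = 10,000. Pairs require C ≥ 200 and Exp ≥ 2 —
below that the normal approximation to the binomial is poor and single
reads move NSD by whole units. Three choices here were open and are the
package's own: the pair coverage \(C\) is the count of reads spanning
*both* sites (not transcript-wide coverage), so Obs, Exp and C share a
denominator; Obs is a read count, matching the units of \(Exp = f_A f_B C\);
and \(f_A, f_B\) are recomputed on the spanning-read subset rather than
taken from genome-wide site calls. The NSD distribution is compared to a
single seeded normal null sample of the same size and standard deviation
centered at 0 (one draw, not an average over draws, to keep the comparison
a proper two-sample test), and correlated with log10 genomic distance.

**PolyA association.** Reads are binned by whether any base reaches the
per-read threshold (optionally restricted to called sites), tails shorter
than 10 nt are discarded as unreliable estimates, and tail lengths are
compared by two-sided Mann–Whitney. Because a few highly expressed genes
can dominate, the `per_gene_median` scope first collapses each gene to one
median per group.

**Exon-boundary distance.** The distance of a site to the closer of its
containing exon's first and last base (a site on the boundary has distance
0). The chance control draws DRACH-motif positions (D ∈ {A,G,U}, R ∈ {A,G},
H ∈ {A,C,U}) uniformly without replacement from the exons of the same
transcripts, matched in count per transcript, with a fixed seed; observed
and control distances run through the same code path so only the position
source differs.

**Isoform comparison.** Sites observed on ≥ 2 isoforms with per-isoform
coverage ≥ 40 in every replicate are compared within replicate by the mean
absolute pairwise frequency difference; significance uses a two-proportion
test on the extreme isoform pair, BH-adjusted across sites, and a site is
"replicated" only when significant with the same isoform ordering in all
replicates. The significance recipe is the package's own choice and is
labeled as such in the output.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the statistical structure the pipeline assumes,
with ground truth retained for every read:

- **Feature tables**: per-7-mer baselines with SI ~ Normal(μ_k, σ_k) and a
  modified shift of `delta_si`·σ_k (default 2 SD); trace and MP ~ Beta with
  separate class parameters (unmodified TR high, modified TR near 0); DT,
  DT10 ~ log-Normal with a multiplicative modified factor (default 1.5).
  Two-parameter families were chosen deliberately — they match the
  qualitative shapes of the real feature distributions while keeping every
  effect a single interpretable knob.
- **Substoichiometry**: treated reads are modified at per-site rate `s`,
  controls at a residual ε (default 0.03 where a knockout-like control is
  emulated — writer knockouts are not completely devoid of the
  modification; ε = 0 emulates in vitro transcribed controls).
- **Modification probabilities**: unmodified ~ Beta(0.3, 30) and modified
  ~ Beta(4.3, 2), calibrated once so the class medians are ≈ 0.002 and
  ≈ 0.70, the observed medians for fully unmodified and fully modified
  reads.
- **Co-occurring sites**: the per-read pair of modification indicators is
  drawn from the exact bivariate Bernoulli with
  \(P_{11} = f_A f_B + \rho \sqrt{f_A(1-f_A) f_B(1-f_B)}\), ρ being the
  indicator correlation, checked against the Fréchet bounds. A Gaussian
  copula would provide the same one-parameter coupling but requires
  numerical inversion for the same result; the closed form preserves
  marginals exactly and makes the attainable ρ range explicit.
- **Mixtures**: exact counts `round(n·target)` drawn without replacement
  from fully modified and fully unmodified pools over the *same* reference
  and site set, mirroring how benchmark mixtures are subsampled from fully
  modified and unmodified synthetic constructs.

Not emulated: raw current signal, basecalling errors beyond the MP/trace
features, alignment artifacts (the synthetic alignments are ungapped),
coverage gradients along transcripts, or sequence-dependent effect sizes.
Passing tests on this data therefore demonstrate correctness of the
statistical machinery under its stated assumptions, not end-to-end accuracy
on real flowcell data, where feature distributions are heavier-tailed and
position-correlated.

## Numerical choices and degenerate inputs

- Probability bytes: `encode = min(floor(p·256), 255)`,
  `decode = (byte + 0.5)/256`; the round trip is within 1/256 by
  construction. `MM`/`ML` offsets are expanded in original molecule
  orientation; insertions and soft clips yield no reference call.
- Coordinates are 0-based half-open internally; GFF3 is converted on read,
  bedMethyl written in its native convention.
- Youden grid: 0.01 steps on [0, 1]; ties take the smallest τ.
- KS p-values are floored at the smallest positive double before BH to
  avoid zero-adjusted artifacts at extreme separations.
- Label propagation z-scores features, maps constant features to 0, uses a
  symmetric unweighted KNN kernel, and declares convergence at max change
  < 1e-6.
- Empty inputs degrade cleanly: header-only feature tables give empty
  record sets, empty call sets give header-only alignments and empty
  bedMethyl files, transcripts with fewer than two called sites give an
  empty co-occurrence summary with `n_eligible = 0`.

## Problem sizes used in the validation suite

The test and acceptance suites run at sizes chosen to make the statistical
assertions sharp while staying quick on a laptop: labeling recovery uses 20
affected 7-mers at 500 reads per sample per 7-mer (accuracy ≥ 0.90
expected at 50% stoichiometry with a 2 SD signal shift and trace effect);
null selection control uses 200 7-mers at 40 reads per sample; NSD
calibration uses 1,000 replicates at pair coverage 10,000; mixture recovery
uses 4,000-read mixtures at 6.25–50% targets; oracle-equivalence checks use
100 random score sets each.

## Known limitations

- The labeler assumes the control sample is (nearly) modification-free at
  the tested 7-mers; a contaminated control biases stage-1 labels in both
  directions and shrinks, rather than inflates, the detected effect.
- Per-position balancing discards reads in the deeper sample; with very
  asymmetric designs this is wasteful but protects against depth
  confounding.
- The NSD null comparison uses a normal null sample; for very small pair
  counts the Mann–Whitney comparison is low-powered.
- Multi-mapping reads are assumed resolved upstream; the isoform analyses
  trust the assignment classes (`unique`, `fsm`, `mono_exon_match`) of the
  upstream assigner.
- The exon-distance control requires transcript sequences whose coordinate
  frame matches the annotation; mismatched frames silently shrink the
  DRACH pool.
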