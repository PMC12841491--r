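---
title: "Methods: recurrence-based problematic-region masking for exome CNV callers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recurrence-based problematic-region masking for exome CNV callers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvmask)
```

# The problem and the model

Read-depth CNV detection from exome capture data is precision-limited.
Capture efficiency varies bait by bait and sample by sample; baits in
repetitive or segmentally duplicated sequence collect mis-mapped reads; and
each caller's normalization reacts to this instability in its own way. The
practical consequence is that a caller's false positives are not uniformly
scattered: a subset of baits is called again and again across unrelated
samples.

`cnvmask` formalizes the countermeasure. For a cohort of $N$ samples and a
single caller, let $S_b$ be the set of distinct samples in which the caller
emits at least one call (deletion or duplication) overlapping bait $b$. The
bait's recurrence fraction is

$$ r_b = \frac{|S_b|}{N}, $$

and the caller's *problematic region* mask is $\{\,b : r_b > \tau\,\}$ with
$\tau = 0.10$ by default. The threshold is strict: with $N = 180$, a bait
called in 18 samples ($r_b = 0.10$) is not flagged, one called in 19 is.
Real CNVs polymorphic at ~10 % frequency would be masked too; the premise —
shared by any recurrence blacklist — is that at such recurrence, within one
caller, technical artifact dominates, and that whatever is lost is
recoverable by orthogonal methods.

Masking is evaluated, not assumed. The package benchmarks each caller
against an independent truth set before and after masking, and tests the
per-sample change in false positives with a paired signed-rank test.

## Evaluation unit

All accounting is at the level of one capture bait in one sample. Exome
callers report events whose breakpoints are unknowable from capture data
alone, and array truth CNVs have probe-level resolution; the bait is the
finest unit both sides can agree on. A call spanning $k$ baits contributes
$k$ units; duplicate or overlapping calls at one bait collapse to one unit.
Coordinates are 0-based half-open (BED convention) throughout; array CNV
tables, conventionally 1-based inclusive, are converted at the reader
boundary. Strand is ignored; `chr` prefixes are stripped so dialects mix
safely.

## Truth-set construction

Array (CMA-style) CNVs pass a fixed-order cascade:

1. **Probe support** — fewer than `min_snp_probes` (default 10) SNP probes
   ⇒ rejected.
2. **Polymorphic locus** — all input CNVs are merged across samples
   (gap = 0); a merged locus overlapped by CNVs from more than
   `max_polymorphic_samples` (default 4) *distinct* samples is polymorphic,
   and every CNV touching it is rejected.
3. **Bait overlap** — a CNV overlapping no target bait is invisible to the
   exome and excluded from the denominator.

The audit records exactly one reason per rejected CNV — the first failing
rule in the order above — so audit files are deterministic and
machine-diffable. Sample counting for rule 2 happens on the full input,
before any other rule; the alternative (counting after the probe filter)
is defensible but less conservative, and the choice is recorded in the
audit semantics rather than left implicit. An optional `manual_pass`
column, when present, is honoured as a final rule; the manual log2-ratio /
B-allele-frequency review it represents is outside the package's scope.

Kept CNVs expand to per-(sample, bait) truth labels. Labels live per
sample, so a deletion in one sample and a duplication in another at the
same bait never conflict.

## Classification and metrics

Per sample and caller, with `type_aware = TRUE` (default): a truth bait
covered by a call of the same type is a TP; a truth bait without one is an
FN; a called bait with no matching truth unit is an FP. A DEL call at a DUP
truth bait is therefore an FP *and* leaves the FN standing — the stricter
reading, exposed as a switch (`type_aware = FALSE` pools types) because
published benchmarks are often silent on it. True negatives are never
materialized; with ~20,000 baits × cohort they would dominate every table
while supporting no reported quantity.

Sensitivity is $TP/(TP+FN)$ and PPV $TP/(TP+FP)$; PPV for a caller with no
calls is *undefined* (`NA`), never 0. Displayed values are rounded
half-even to 3 decimals; raw fractions are retained internally. Per-caller
cross-concordance tabulates, for every truth unit, which callers detected
it, yielding caller-specific fractions and the union sensitivity (the OR
across callers), which is by construction at least the best single
caller's.

## Bait features and the resampling comparison

Flagged baits are characterized by four features: mean per-base
mappability (a 35-mer-uniqueness-style track, consumed, never computed —
generating such a track is upstream alignment infrastructure), GC fraction
of the bait sequence (G+C over non-N bases), the intersample coefficient
of variation of RPKM, and segmental-duplication overlap (boolean, with the
covered fraction retained).

RPKM is $\mathrm{reads} \times 10^9 / (\mathrm{bait\ length\ [bp]} \times
\mathrm{total\ mapped\ reads})$; totals may be supplied as a sidecar (the
simulator always does) and default to on-target column sums otherwise. The
CV uses the $n-1$ standard deviation across samples and is missing (not
zero) for baits with zero mean coverage, which are excluded from the
comparisons.

Because flagged sets are small (hundreds of baits) and the background is
large (~20,000), a direct two-group test would mix unequal-size artifacts
into the comparison. Instead, each of `n_iter` (default 1000) iterations
draws, without replacement, exactly as many background baits as there are
flagged baits and applies a two-sided Wilcoxon rank-sum test per feature.
The variant is pinned for reproducibility: normal approximation with
continuity correction and average ranks for ties (group sizes here are far
beyond exact-test regimes). All iterations are driven sequentially by one
seed, so a run is bit-reproducible.

## Filtration and the paired test

Masking removes every (sample, bait) unit at a flagged bait from the calls
*and* from the truth denominator. Removing flagged truth units is forced
by the arithmetic: a caller cannot be penalized as FN at a bait where its
calls are categorically discarded. Consequently each caller's post-filter
truth denominator is its own (masks are caller-specific; a union-mask
workflow is possible by passing a combined mask explicitly). Sensitivity
can rise after masking only through denominator reduction — the identity
$TP + FN = \mathrm{truth}$ is asserted on every result.

An alternative granularity — dropping an entire call event when it touches
a merged problematic region — is provided (`filter_calls()`) for users who
want event-level filtering, but the bait-unit semantics is the default
because it sidesteps the question of whether a partially overlapping CNV
should be removed or trimmed.

Pre/post differences in per-sample FP (and TP) counts are tested with a
two-sided Wilcoxon signed-rank test over the truth-cohort samples (the
only samples with defined FP counts). Zero differences are dropped, the
standard convention; with fewer than two non-zero differences the result
is reported as *not testable* (`NA`), not as significant or as $p = 1$.
Note one structural fact: masking can only remove units, so all paired
differences are non-negative, and any caller whose own mask is non-empty
has, by the definition of flagging, many affected samples — its test will
essentially always be significant. A non-significant outcome therefore
occurs exactly when a caller's mask is empty or nearly so, which is the
behaviour the clean-caller profile in the simulator exhibits by design.

# The synthetic-data generator

The simulator produces a complete, internally consistent study so every
stage is testable offline; protected patient data never enter the tests.
It emulates the *statistical structure* the pipeline depends on, not the
biology of any genome or the algorithm of any caller.

**What it generates.** A toy genome of 8 × 2 Mb chromosomes with i.i.d.
base composition (background GC 0.45) and GC-depressed artifact
neighborhoods (default shift −0.10), so GC estimation has signal; 20,000
baits of 120 bp on a regular grid; a two-segment-per-bait mappability
track (background Beta(20, 1.5), artifact baits decremented by 0.25); an
artifact-locus pool of 8-bait runs assigned per caller with heavy overlap
across callers (the call-happiest caller's loci are a superset of the
others'), each locus co-located with a segmental duplication with
probability 0.8 against a 5 % background rate; array CNVs for a 44-sample
array subset: 98 clean CNVs across 39 samples (39:59 DEL:DUP) plus
low-probe decoys and two 6-sample polymorphic loci that exercise the truth
filters; per-caller calls (per truth exon: Bernoulli(sensitivity); per
artifact locus per sample: Bernoulli(recurrence), spanning the locus; plus
sporadic single-bait FPs on non-artifact baits); and a Poisson-lognormal
read-count matrix whose lognormal dispersion is solved so background baits
hit a target RPKM CV of 0.18 and artifact baits 2.5 × that.

**Scaled parameters.** Clinical array CNVs span roughly 5 kb to several
Mb. On a 16 Mb toy genome that distribution would make merged truth loci
chain across many samples and collide with the polymorphic filter, so the
simulator's default size distribution is log-uniform on 20–80 kb — the
same shape, scaled to the genome, with the 20 kb floor chosen so every
clean CNV carries ≥ 10 synthetic SNP probes at the default probe density
of 1 per 2 kb (floor 1) and the probe filter bites only the decoys.
Because truth CNVs are placed uniformly and independently, merged loci can
still occasionally chain > 4 samples and lose a few clean CNVs to the
polymorphic rule; the kept count is reported, not assumed.

**Caller profiles.** Four caricatures: `deepcall` (sensitivity 0.76, 60
artifact loci at 30 % recurrence, call-happy), `segtrace` (0.66, 30 loci),
`mixport` (0.17, 35 loci — sensitive to little, still artifact-heavy), and
`conserv` (0.77, 3 loci at 4 % recurrence, sporadic rate 0.005 — clean,
with sub-threshold systematic noise). The first three have most of their
false-positive load at plantable recurrent loci; `conserv`'s mask is empty
at the default threshold. Nothing about the real tools' algorithms is
emulated, and reproducing any published call-count table is a non-goal.

**What passing tests do and do not show.** The simulator's artifacts are
planted at fixed loci with homogeneous recurrence, its noise is
exchangeable across samples, and its depth matrix has no batch structure,
GC-depth coupling, or sex-chromosome effects. Tests on it demonstrate that
the pipeline's arithmetic, set operations, threshold semantics and
statistics behave as designed — parameter recovery, monotonicity,
direction of feature shifts. They do not demonstrate that 10 % is the
right threshold for any real cohort, nor that real callers' artifact
fractions match the profiles.

# Numerical and design choices

* **Half-open book-ended merge**: intervals meeting at a coordinate merge
  at `gap = 0`, preserving union-of-covered-bases semantics exactly.
* **Overlap threshold**: any ≥ 1 bp overlap counts, everywhere (bait
  hits, truth overlap, segdups, masks). A minimum-reciprocal-overlap
  refinement was considered and rejected: published exon-level benchmarks
  specify only "overlap", and 1 bp is the unique parameter-free reading.
* **Recurrence atom**: recurrence is computed per bait and flagged baits
  are then merged into regions, rather than thresholding merged regions
  directly — the bait is the unit all downstream accounting uses, and
  per-region thresholding would make a region's fate depend on how calls
  happened to chain. Pooling DEL and DUP for recurrence is the default
  (artifacts are depth artifacts first, typed second); a type-restricted
  mode exists.
* **Seeds**: `simulate_cohort` and `compare_features` consume explicit
  integer seeds; nothing reads the global RNG state implicitly. Identical
  seeds give byte-identical bundles and iteration tables.
* **Degenerate inputs**: empty call sets classify to all-FN with PPV
  `NA`; an all-covering mask yields zero counts and undefined metrics
  rather than division errors; a single-sample depth matrix refuses CV; a
  zero-total sample names itself in the RPKM error.
* **Problem sizes**: the test suite exercises small cohorts (tens of
  samples, 1–4 thousand baits) throughout and one default-scale cohort
  (180 × 20,000, 1000 resampling iterations) in the acceptance checks;
  the full suite runs in about a minute.

# Limitations

* The mask is cohort- and kit-specific by construction; thresholds should
  be re-derived per laboratory, and the 10 % default is a proof-of-principle
  setting, not a universal constant.
* Bait-level masking removes diagnostic territory: flagged baits overlap
  real genes, and calls there need orthogonal confirmation rather than
  silent discard — the mask BED is the hand-off point for that review.
* The truth side assumes array CNVs with probe counts; no CEL/ChAS parsing
  or log2-ratio recomputation is attempted.
* Event-level breakpoint accuracy, size-stratified summaries beyond the
  provided grouping option, and gene/annotation overlays of flagged
  regions are out of scope.
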