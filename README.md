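# cnvmask

Exome-sequencing CNV callers have a precision problem: alongside genuine
copy-number events they emit large numbers of false positives, and a
disproportionate share of those false positives are *systematic* — the same
capture baits are called over and over across unrelated samples, in a
pattern specific to each caller. `cnvmask` provides a tested pipeline for

1. **benchmarking** exome CNV callers at the capture-bait ("exon") level
   against an orthogonal truth set derived from chromosomal-microarray
   (CMA) CNVs,
2. **detecting caller-specific problematic regions** by cohort recurrence —
   baits where one caller emits calls in more than a threshold fraction of
   the cohort,
3. **characterizing** those regions (mappability, GC content, intersample
   RPKM coefficient of variation, segmental-duplication overlap) with a
   resampling Wilcoxon comparison against equal-size background draws, and
4. **filtering** call sets with the resulting mask and quantifying the
   effect with paired signed-rank tests.

It is aimed at clinical-genomics and methods groups who run read-depth CNV
callers (ExomeDepth, CNVkit, CoNIFER, cn.MOPS, …) on exome cohorts and need
a reproducible way to separate recurrent technical artifacts from real
variation.

## The method

**Truth set.** Array CNVs pass a three-rule cascade: at least 10 SNP
probes; not inside a highly polymorphic locus (a merged CNV region carrying
events from more than 4 distinct samples); overlap with at least one
sequencing target bait. Surviving CNVs are expanded to per-bait truth
labels: every bait overlapped by a kept CNV is a truth exon for that
sample, typed DEL or DUP.

**Benchmark.** The evaluation unit is one bait in one sample. For caller
*c*: a truth bait covered by a matching-type call is a TP, an uncovered
truth bait an FN, a called bait absent from that sample's truth an FP, and

    Sensitivity = TP / (TP + FN)        PPV = TP / (TP + FP)

**Problematic regions.** For each caller, each bait *b* gets a recurrence
fraction r<sub>b</sub> = (distinct cohort samples with ≥ 1 overlapping
call) / N over the *full* cohort, both CNV types pooled. Baits with
r<sub>b</sub> > 0.10 (strictly) form the caller's mask: at N = 180, a bait
called in 18 samples is kept, one called in 19 is flagged.

**Filtration.** Masked baits are removed from the calls *and* from the
truth denominator (each caller is filtered with its own mask), metrics are
recomputed, and per-sample FP/TP changes are tested with a two-sided
Wilcoxon signed-rank test (zero differences dropped).

## Worked example

Everything below is synthetic: `simulate_cohort()` generates a complete
study (toy genome, baits, mappability track, segdups, array CNVs, per-caller
calls with planted artifact loci, depth matrix) so the pipeline can be
exercised without patient data.

```r
library(cnvmask)

cfg <- sim_config(seed = 7, n_samples = 60, n_cma_samples = 20,
                  n_truth_samples = 16, n_baits = 4000, n_chrom = 4,
                  chrom_length = 8e5, n_truth_cnvs = 30,
                  truth_size_range = c(2e4, 5e4),
                  n_lowprobe_decoys = 5, n_polymorphic_loci = 1)
bundle <- simulate_cohort(cfg)
run <- run_pipeline(bundle, cohort_size = 60, n_iter = 200, seed = 7)
print(run)
#> cnvmask run: 30 truth CNVs / 1311 truth exon units; union sensitivity 0.980
#>     caller sensitivity_pre sensitivity_post ppv_pre ppv_post masked_baits
#> 1  conserv           0.759            0.759   0.773    0.773            0
#> 2 deepcall           0.779            0.779   0.316    0.865          480
#> 3  mixport           0.164            0.152   0.137    0.647          280
#> 4 segtrace           0.660            0.659   0.424    0.926          240
```

The four emulated callers differ in how much of their false-positive load
is recurrent artifact. `deepcall` (call-happy, 60 planted artifact loci)
gains ×2.7 in PPV once its mask is applied; `conserv`'s systematic noise
recurs in only ~4 % of samples, stays below the 10 % threshold, and its
filtration is a no-op — the caller-specific masks adapt to each caller's
failure mode. Flagged baits look the way artifact-prone regions do:

```r
run$feature_comparisons$deepcall$summary[, -4]
#>       feature mean_flagged mean_background frac_p_lt_0.05 direction
#> 1 mappability    0.6797054       0.9287541              1     lower
#> 2          gc    0.3481771       0.4491723              1     lower
#> 3     rpkm_cv    0.4335888       0.1497739              1    higher
```

i.e. in every one of the 200 resampling iterations the flagged baits have
significantly lower mappability and GC and a higher RPKM coefficient of
variation than an equal-size random draw of background baits. The
per-sample false-positive drop is highly significant for the artifact-heavy
callers and untestable (no change) for the clean one:

```r
run$report[c("caller", "fp_pre", "fp_post", "p_fp")]
#>     caller fp_pre fp_post         p_fp
#> 1  conserv    293     293           NA
#> 2 deepcall   2206     142 0.0004740306
#> 3  mixport   1355     102 0.0004678189
#> 4 segtrace   1177      65 0.0004667892
```

`run_pipeline(..., out_dir = "results/run")` writes the same content as
TSV/BED files (report grid, per-bait recurrence, masks, feature
comparisons, per-sample counts) plus a `run_log.tsv` with checksums, the
seed and all thresholds. A shell wrapper is provided:

```sh
Rscript scripts/run_pipeline.R --simulate --seed 7 --data-dir simdata --out-dir results/run
```

Real data enter through the same plain-text formats the simulator writes:
a bait BED, BED-style call tables (`chrom start end type sample caller`),
an array CNV TSV (1-based inclusive, converted on read), a bait × sample
read-count matrix with a totals sidecar, a mappability bedGraph and a
segdup BED. See `?read_bundle` and the individual readers.

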