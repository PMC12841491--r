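#' Per-bait cohort recurrence of one caller's calls
#'
#' For each target bait, counts the distinct cohort samples in which the
#' caller emitted at least one call (either type; DEL and DUP are pooled)
#' overlapping that bait, and divides by the full cohort size. The
#' denominator is the whole sequencing cohort, not only truth-positive
#' samples. Duplicated calls within one sample never inflate the count.
#'
#' @param calls call data.frame for a single caller.
#' @param baits sorted bait table.
#' @param cohort_size number of samples in the cohort; must be at least the
#'   number of distinct samples observed in `calls`.
#' @param types CNV types to count (default both; pass `"DEL"` or `"DUP"`
#'   for a type-split analysis).
#' @return data.frame `bait_id`, `n_samples_called`, `fraction`, one row per
#'   bait (zero rows included).
#' @export
bait_recurrence <- function(calls, baits, cohort_size,
                            types = c("DEL", "DUP")) {
  stopifnot(cohort_size >= 1)
  baits <- check_sorted_baits(baits)
  calls <- validate_intervals(as.data.frame(calls), "calls")
  if ("caller" %in% names(calls) && length(unique(calls$caller)) > 1L)
    stop("recurrence is per caller; got calls from: ",
         paste(unique(calls$caller), collapse = ", "))
  calls <- calls[calls$type %in% types, , drop = FALSE]
  n_obs <- length(unique(calls$sample))
  if (n_obs > cohort_size)
    stop("cohort_size (", cohort_size, ") smaller than the ", n_obs,
         " distinct samples observed")
  n <- integer(nrow(baits))
  if (nrow(calls)) {
    hits <- findOverlaps(to_granges(calls), to_granges(baits))
    per_bait <- tapply(calls$sample[queryHits(hits)], subjectHits(hits),
                       function(s) length(unique(s)))
    n[as.integer(names(per_bait))] <- as.integer(per_bait)
  }
  data.frame(bait_id = baits$bait_id, n_samples_called = n,
             fraction = n / cohort_size, stringsAsFactors = FALSE)
}

#' Build a problematic-region mask from recurrence fractions
#'
#' A bait is flagged when its recurrence fraction is strictly greater than
#' the threshold ("more than 10% of the cohort"): at a cohort of 180 and the
#' default threshold 0.10, 18/180 is not flagged and 19/180 is. Flagged
#' baits are merged (gap = 0) into problematic regions.
#'
#' @param rec recurrence table from [bait_recurrence()].
#' @param baits sorted bait table (same bait universe as `rec`).
#' @param threshold recurrence fraction, strict lower bound for flagging
#'   (default 0.10); must lie in (0, 1).
#' @param caller caller id recorded in the mask.
#' @return object of class `problematic_mask`: list with `caller`,
#'   `flagged_baits` (character vector), `merged_regions` (interval
#'   data.frame), `threshold` and `recurrence` (the flagged subset of
#'   `rec`).
#' @export
build_mask <- function(rec, baits, threshold = 0.10, caller = NA_character_) {
  stopifnot(threshold > 0, threshold < 1)
  baits <- check_sorted_baits(baits)
  if (!all(rec$bait_id %in% baits$bait_id))
    stop("recurrence table references baits outside the bait set")
  flagged <- rec$bait_id[rec$fraction > threshold]
  fb <- baits[baits$bait_id %in% flagged, , drop = FALSE]
  structure(list(caller = caller,
                 flagged_baits = as.character(flagged),
                 merged_regions = merge_intervals(
                   fb[c("chrom", "start", "end")], gap = 0L),
                 threshold = threshold,
                 recurrence = rec[rec$fraction > threshold, , drop = FALSE]),
            class = "problematic_mask")
}

#' @export
print.problematic_mask <- function(x, ...) {
  cat("Problematic mask", if (!is.na(x$caller)) paste0(" [", x$caller, "]"),
      ": ", length(x$flagged_baits), " baits in ", nrow(x$merged_regions),
      " merged regions (recurrence > ", x$threshold, ")\n", sep = "")
  invisible(x)
}

#' RPKM-normalize a read-count matrix
#'
#' RPKM = reads x 10^9 / (bait length in bp x total mapped reads of the
#' sample): reads per kilobase of target per million mapped reads.
#'
#' @param counts numeric matrix, baits x samples, raw read counts; rownames
#'   are bait ids, colnames sample ids.
#' @param bait_lengths named numeric vector of bait lengths in bp (names =
#'   bait ids), or a bait table with `bait_id`/`start`/`end`.
#' @param total_reads per-sample total mapped reads; defaults to the on-
#'   target column sums of `counts`.
#' @return matrix of RPKM values, same dimnames as `counts`.
#' @export
rpkm_normalize <- function(counts, bait_lengths,
                           total_reads = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative read counts")
  if (is.data.frame(bait_lengths))
    bait_lengths <- stats::setNames(bait_lengths$end - bait_lengths$start,
                                    bait_lengths$bait_id)
  len <- bait_lengths[rownames(counts)]
  if (any(is.na(len))) stop("bait lengths missing for some matrix rows")
  if (any(len <= 0)) stop("bait lengths must be positive")
  if (is.null(names(total_reads))) names(total_reads) <- colnames(counts)
  tot <- total_reads[colnames(counts)]
  zero <- names(tot)[is.na(tot) | tot <= 0]
  if (length(zero))
    stop("zero or missing total mapped reads for sample(s): ",
         paste(zero, collapse = ", "))
  sweep(sweep(counts, 1, as.numeric(len), "/"), 2, as.numeric(tot), "/") * 1e9
}

#' Intersample coefficient of variation of RPKM, per bait
#'
#' CV = sample standard deviation (n - 1 denominator) divided by the mean,
#' across samples. Baits with zero mean coverage get `NA` (missing), never
#' 0, and are excluded from downstream feature comparisons.
#'
#' @param rpkm numeric matrix, baits x samples (at least two columns).
#' @return named numeric vector of CVs (names = rownames of `rpkm`).
#' @export
rpkm_cv <- function(rpkm) {
  rpkm <- as.matrix(rpkm)
  if (ncol(rpkm) < 2L)
    stop("coefficient of variation needs at least two samples")
  mu <- rowMeans(rpkm)
  n <- ncol(rpkm)
  sd <- sqrt(rowSums((rpkm - mu)^2) / (n - 1))
  cv <- ifelse(mu > 0, sd / mu, NA_real_)
  stats::setNames(cv, rownames(rpkm))
}

#' GC content of baits from a reference sequence
#'
#' Fraction (G + C) / (non-N length) of the bait's sequence; `NA` when the
#' bait is entirely N. Case-insensitive.
#'
#' @param baits sorted bait table.
#' @param seqs a [Biostrings::DNAStringSet] (or named character vector)
#'   whose names match the baits' chromosomes (with or without a `chr`
#'   prefix).
#' @return named numeric vector of GC fractions (names = bait ids).
#' @export
gc_content <- function(baits, seqs) {
  baits <- check_sorted_baits(baits)
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  names(seqs) <- normalize_chrom(names(seqs))
  out <- rep(NA_real_, nrow(baits))
  for (chr in unique(baits$chrom)) {
    if (!chr %in% names(seqs))
      stop("no reference sequence for chromosome ", chr)
    idx <- which(baits$chrom == chr)
    if (any(baits$end[idx] > length(seqs[[chr]])))
      stop("bait interval beyond the end of chromosome ", chr)
    v <- Biostrings::Views(seqs[[chr]], start = baits$start[idx] + 1L,
                           end = baits$end[idx])
    freq <- Biostrings::letterFrequency(v, letters = c("GC", "N"))
    denom <- (baits$end[idx] - baits$start[idx]) - freq[, "N"]
    out[idx] <- ifelse(denom > 0, freq[, "G|C"] / denom, NA_real_)
  }
  stats::setNames(out, baits$bait_id)
}

#' Annotate baits with mappability, GC, RPKM CV and segdup overlap
#'
#' Per-bait mappability is the per-base mean of a bedGraph-style score track
#' over the bases of the bait the track covers; a bait with no coverage at
#' all gets `NA`. A per-bait track (columns `bait_id`, `mappability`) is
#' accepted as-is. Segmental-duplication overlap is any >= 1 bp overlap with
#' the segdup BED; the covered fraction of the bait is retained alongside
#' the boolean.
#'
#' @param baits sorted bait table.
#' @param mappability bedGraph-style data.frame (`chrom start end score`) or
#'   per-bait data.frame (`bait_id`, `mappability`); `NULL` to skip.
#' @param segdups interval data.frame of segmental duplications; `NULL` to
#'   skip.
#' @param rpkm_cv named per-bait CV vector (from [rpkm_cv()]); `NULL` to
#'   skip.
#' @param gc named per-bait GC vector (from [gc_content()]); overrides any
#'   `gc` column already in `baits`.
#' @return data.frame `bait_id`, `chrom`, `start`, `end`, `mappability`,
#'   `gc`, `rpkm_cv`, `segdup`, `segdup_fraction`.
#' @export
annotate_baits <- function(baits, mappability = NULL, segdups = NULL,
                           rpkm_cv = NULL, gc = NULL) {
  baits <- check_sorted_baits(baits)
  out <- data.frame(bait_id = baits$bait_id, chrom = baits$chrom,
                    start = baits$start, end = baits$end,
                    stringsAsFactors = FALSE)
  out$mappability <- if ("mappability" %in% names(baits))
    baits$mappability else NA_real_
  out$gc <- if ("gc" %in% names(baits)) baits$gc else NA_real_

  if (!is.null(mappability)) {
    if ("bait_id" %in% names(mappability)) {
      out$mappability <-
        mappability$mappability[match(out$bait_id, mappability$bait_id)]
    } else {
      mappability <- validate_intervals(as.data.frame(mappability),
                                        "mappability track")
      if (!"score" %in% names(mappability))
        stop("bedGraph mappability needs a score column")
      bg <- to_granges(baits)
      tg <- to_granges(mappability)
      hits <- findOverlaps(bg, tg)
      ov <- GenomicRanges::pintersect(bg[queryHits(hits)], tg[subjectHits(hits)])
      w <- GenomicRanges::width(ov)
      s <- mappability$score[subjectHits(hits)]
      num <- tapply(w * s, queryHits(hits), sum)
      den <- tapply(w, queryHits(hits), sum)
      mp <- rep(NA_real_, nrow(baits))
      mp[as.integer(names(num))] <- as.numeric(num) / as.numeric(den)
      out$mappability <- mp
    }
  }
  if (!is.null(segdups) && nrow(segdups)) {
    segdups <- merge_intervals(segdups, gap = 0L)
    hits <- findOverlaps(to_granges(baits), to_granges(segdups))
    ov <- GenomicRanges::pintersect(to_granges(baits)[queryHits(hits)],
                                    to_granges(segdups)[subjectHits(hits)])
    cov <- tapply(GenomicRanges::width(ov), queryHits(hits), sum)
    frac <- numeric(nrow(baits))
    frac[as.integer(names(cov))] <-
      as.numeric(cov) / (baits$end - baits$start)[as.integer(names(cov))]
    out$segdup_fraction <- frac
    out$segdup <- frac > 0
  } else {
    out$segdup_fraction <- if (is.null(segdups)) NA_real_ else 0
    out$segdup <- if (is.null(segdups)) NA else FALSE
  }
  out$rpkm_cv <- if (!is.null(rpkm_cv))
    as.numeric(rpkm_cv[out$bait_id]) else NA_real_
  if (!is.null(gc)) out$gc <- as.numeric(gc[out$bait_id])
  out[c("bait_id", "chrom", "start", "end", "mappability", "gc", "rpkm_cv",
        "segdup", "segdup_fraction")]
}

#' Compare features of flagged baits against random background draws
#'
#' Repeats, `n_iter` times: draw (without replacement) as many background
#' (non-flagged) baits as there are flagged baits, then compare flagged vs
#' drawn values of each feature with a two-sided Wilcoxon rank-sum test
#' (normal approximation with continuity correction, average ranks for
#' ties). `NA` feature values are dropped within each group. The fixed
#' variant and the single seed make the whole resampling reproducible.
#'
#' @param features annotated bait table from [annotate_baits()].
#' @param mask a [problematic_mask][build_mask()].
#' @param feature_cols features to test (default mappability, gc, rpkm_cv).
#' @param n_iter number of resampling iterations (default 1000).
#' @param seed integer seed for the sampling; `NULL` leaves the RNG state
#'   alone.
#' @return list with `iterations` (data.frame `iteration`, `feature`,
#'   `statistic`, `p`) and `summary` (per feature: flagged mean, mean of the
#'   background draws, median p, fraction of iterations with p < 0.05, and
#'   the direction of the difference).
#' @export
compare_features <- function(features, mask,
                             feature_cols = c("mappability", "gc", "rpkm_cv"),
                             n_iter = 1000L, seed = NULL) {
  stopifnot(inherits(mask, "problematic_mask"))
  flagged <- features$bait_id %in% mask$flagged_baits
  if (!any(flagged)) stop("no problematic regions to compare")
  n_flag <- sum(flagged)
  bg_idx <- which(!flagged)
  if (length(bg_idx) < n_flag)
    stop("fewer background baits (", length(bg_idx),
         ") than flagged baits (", n_flag, ")")
  if (!is.null(seed)) set.seed(seed)

  flag_vals <- lapply(feature_cols, function(f) features[[f]][flagged])
  names(flag_vals) <- feature_cols
  res <- vector("list", n_iter)
  bg_means <- matrix(NA_real_, n_iter, length(feature_cols),
                     dimnames = list(NULL, feature_cols))
  for (i in seq_len(n_iter)) {
    draw <- sample(bg_idx, n_flag)
    rows <- lapply(feature_cols, function(f) {
      a <- flag_vals[[f]]; b <- features[[f]][draw]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      wt <- suppressWarnings(
        stats::wilcox.test(a, b, alternative = "two.sided",
                           exact = FALSE, correct = TRUE))
      data.frame(iteration = i, feature = f,
                 statistic = unname(wt$statistic), p = wt$p.value,
                 stringsAsFactors = FALSE)
    })
    bg_means[i, ] <- vapply(feature_cols,
                            function(f) mean(features[[f]][draw], na.rm = TRUE),
                            numeric(1))
    res[[i]] <- do.call(rbind, rows)
  }
  iterations <- do.call(rbind, res)
  summary <- do.call(rbind, lapply(feature_cols, function(f) {
    p <- iterations$p[iterations$feature == f]
    mf <- mean(flag_vals[[f]], na.rm = TRUE)
    mb <- mean(bg_means[, f])
    data.frame(feature = f,
               mean_flagged = mf, mean_background = mb,
               median_p = stats::median(p),
               frac_p_lt_0.05 = mean(p < 0.05),
               direction = if (isTRUE(mf > mb)) "higher" else
                 if (isTRUE(mf < mb)) "lower" else "none",
               stringsAsFactors = FALSE)
  }))
  list(iterations = iterations, summary = summary,
       n_flagged = n_flag, n_iter = n_iter)
}
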