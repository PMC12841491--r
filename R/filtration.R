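#' Apply a problematic-region mask to a classification
#'
#' Removes every (sample, bait) evaluation unit whose bait is flagged — from
#' the calls *and* from the truth denominator, so post-filter sensitivity can
#' rise only through denominator reduction, never through invented TPs. Each
#' caller is masked with its own mask; pass a union mask explicitly for
#' consensus workflows.
#'
#' @param cls an `exon_classification` (single caller, or the caller named
#'   in the mask).
#' @param mask a [problematic_mask][build_mask()].
#' @param baits sorted bait table; used to verify the mask refers to known
#'   baits.
#' @return the filtered `exon_classification`.
#' @export
apply_mask <- function(cls, mask, baits = NULL) {
  stopifnot(inherits(mask, "problematic_mask"))
  if (!is.null(baits)) {
    baits <- check_sorted_baits(baits)
    unknown <- setdiff(mask$flagged_baits, baits$bait_id)
    if (length(unknown))
      stop("mask references unknown baits: ",
           paste(utils::head(unknown, 5), collapse = ", "))
  }
  keep <- !(cls$bait_id %in% mask$flagged_baits)
  out <- cls[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, type_aware = attr(cls, "type_aware"),
            cohort = attr(cls, "cohort"), callers = attr(cls, "callers"),
            class = c("exon_classification", "data.frame"))
}

#' Drop whole calls overlapping a mask (event-level filtration)
#'
#' Alternative filtration granularity: a call is removed entirely when it
#' overlaps any merged problematic region by >= 1 bp. The default pipeline
#' masks at the bait level instead ([apply_mask()]); this mode documents the
#' other reading, in which a partially overlapping CNV event is discarded
#' rather than trimmed.
#'
#' @param calls call data.frame.
#' @param mask a [problematic_mask][build_mask()].
#' @return the surviving calls.
#' @export
filter_calls <- function(calls, mask) {
  stopifnot(inherits(mask, "problematic_mask"))
  if (nrow(mask$merged_regions) == 0L || nrow(calls) == 0L) return(calls)
  calls <- validate_intervals(as.data.frame(calls), "calls")
  hits <- findOverlaps(to_granges(calls), to_granges(mask$merged_regions))
  drop <- unique(queryHits(hits))
  if (length(drop)) calls[-drop, , drop = FALSE] else calls
}

#' Paired Wilcoxon signed-rank test on per-sample counts
#'
#' Two-sided signed-rank test on per-sample differences (pre - post).
#' Zero differences are dropped (standard convention); with fewer than two
#' non-zero differences the result is marked not testable (`p = NA`) rather
#' than significant or 0. The normal approximation with continuity
#' correction is used throughout, as tied integer differences preclude the
#' exact distribution.
#'
#' @param pre,post named numeric vectors of per-sample counts over one
#'   sample roster.
#' @return list with `p`, `statistic`, `n_nonzero`, `direction`
#'   (`"decrease"`, `"increase"`, `"mixed"` or `"none"`) and `testable`.
#' @export
paired_signed_rank <- function(pre, post) {
  if (!is.null(names(pre)) && !is.null(names(post))) {
    if (!setequal(names(pre), names(post)))
      stop("pre and post cover different sample rosters")
    post <- post[names(pre)]
  } else if (length(pre) != length(post)) {
    stop("pre and post must have equal length")
  }
  d <- pre - post
  nz <- sum(d != 0)
  direction <- if (all(d == 0)) "none"
  else if (all(d >= 0)) "decrease"
  else if (all(d <= 0)) "increase"
  else "mixed"
  if (nz < 2L)
    return(list(p = NA_real_, statistic = NA_real_, n_nonzero = nz,
                direction = direction, testable = FALSE))
  wt <- suppressWarnings(
    stats::wilcox.test(pre, post, paired = TRUE, alternative = "two.sided",
                       exact = FALSE, correct = TRUE))
  list(p = wt$p.value, statistic = unname(wt$statistic), n_nonzero = nz,
       direction = direction, testable = TRUE)
}

per_sample_counts <- function(cls) {
  cohort <- attr(cls, "cohort")
  f <- factor(cls$sample, levels = cohort)
  data.frame(sample = cohort,
             tp = as.integer(table(f[cls$label == "TP"])),
             fp = as.integer(table(f[cls$label == "FP"])),
             fn = as.integer(table(f[cls$label == "FN"])),
             stringsAsFactors = FALSE)
}

#' Pre/post filtration outcome for one caller
#'
#' Applies the caller's mask to its classification, recomputes the benchmark
#' metrics, tabulates per-sample TP/FP/FN before and after, and tests the
#' per-sample FP and TP changes with the paired signed-rank test.
#'
#' @param cls the caller's pre-filter `exon_classification`.
#' @param mask the caller's [problematic_mask][build_mask()].
#' @param baits sorted bait table (mask sanity check).
#' @return object of class `filter_outcome`: list with `caller`, `pre` and
#'   `post` metric rows, `per_sample` (per-sample counts, pre and post),
#'   `tests` (signed-rank results for FP and TP) and `mask_size`.
#' @export
filtration_outcome <- function(cls, mask, baits = NULL) {
  post_cls <- apply_mask(cls, mask, baits)
  pre <- benchmark_metrics(cls, condition = "PRE")
  post <- benchmark_metrics(post_cls, condition = "POST")
  ps_pre <- per_sample_counts(cls)
  ps_post <- per_sample_counts(post_cls)
  tests <- list(
    fp = paired_signed_rank(stats::setNames(ps_pre$fp, ps_pre$sample),
                            stats::setNames(ps_post$fp, ps_post$sample)),
    tp = paired_signed_rank(stats::setNames(ps_pre$tp, ps_pre$sample),
                            stats::setNames(ps_post$tp, ps_post$sample)))
  structure(list(caller = pre$caller[1L], pre = pre, post = post,
                 per_sample = list(pre = ps_pre, post = ps_post),
                 tests = tests,
                 mask_size = length(mask$flagged_baits)),
            class = "filter_outcome")
}

#' @export
print.filter_outcome <- function(x, ...) {
  cat("Filtration outcome for ", x$caller, " (", x$mask_size,
      " masked baits)\n", sep = "")
  print(summarize_outcomes(list(x)))
  invisible(x)
}

#' Summarize filtration outcomes as a report grid
#'
#' One row per caller with the truth denominator, TP/FP/FN, sensitivity and
#' PPV under both conditions, the sensitivity gain in percentage points, the
#' PPV fold-change (post / pre; `NA` when pre-PPV is 0 or undefined) and the
#' signed-rank p-values for per-sample FP and TP changes. Sensitivity and
#' PPV are rounded half-even to 3 decimals for display; the underlying
#' [filtration_outcome()] objects keep raw fractions.
#'
#' @param outcomes list of [filtration_outcome()] objects.
#' @return data.frame, one row per caller.
#' @export
summarize_outcomes <- function(outcomes) {
  stopifnot(length(outcomes) >= 1L)
  rows <- lapply(outcomes, function(o) {
    stopifnot(inherits(o, "filter_outcome"))
    pre <- o$pre; post <- o$post
    data.frame(
      caller = o$caller,
      truth_pre = pre$truth, tp_pre = pre$tp, fp_pre = pre$fp, fn_pre = pre$fn,
      sensitivity_pre = round(pre$sensitivity, 3),
      ppv_pre = round(pre$ppv, 3),
      truth_post = post$truth, tp_post = post$tp, fp_post = post$fp,
      fn_post = post$fn,
      sensitivity_post = round(post$sensitivity, 3),
      ppv_post = round(post$ppv, 3),
      sensitivity_gain_pp = round(100 * (post$sensitivity - pre$sensitivity), 1),
      ppv_fold_change = if (isTRUE(pre$ppv > 0)) post$ppv / pre$ppv else NA_real_,
      p_fp = o$tests$fp$p, p_tp = o$tests$tp$p,
      masked_baits = o$mask_size,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
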