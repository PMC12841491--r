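#' Classify caller calls against the truth set at the bait level
#'
#' The evaluation unit is one capture bait within one sample for one caller.
#' Calls are mapped to the baits they overlap (>= 1 bp); duplicate calls at a
#' bait collapse to one unit. Per sample:
#' * a truth bait covered by at least one qualifying call is a true positive
#'   (TP);
#' * a truth bait with no qualifying call is a false negative (FN);
#' * a called bait absent from that sample's truth is a false positive (FP).
#'
#' With `type_aware = TRUE` (default) a call qualifies only when its type
#' (DEL/DUP) matches the truth label, so a DEL call at a DUP truth bait is
#' counted as an FP while the truth bait stays FN. With `type_aware = FALSE`
#' types are pooled and units are plain (sample, bait) pairs.
#'
#' True negatives are never materialized: the benchmark reports no
#' specificity, and the bait universe would dominate every table.
#'
#' @param calls call data.frame (`chrom start end type sample caller`),
#'   restricted to samples in the truth cohort.
#' @param truth a [truth_exon_set][expand_to_truth_exons()].
#' @param baits sorted bait table.
#' @param type_aware logical; require DEL/DUP agreement for a TP (default
#'   TRUE).
#' @return object of class `exon_classification`: data.frame with columns
#'   `sample`, `bait_id`, `caller`, `label` (TP/FP/FN), `call_type`,
#'   `truth_type`, plus attributes `type_aware` and `cohort` (the truth
#'   sample roster).
#' @export
classify_calls <- function(calls, truth, baits, type_aware = TRUE) {
  stopifnot(inherits(truth, "truth_exon_set"))
  baits <- check_sorted_baits(baits)
  calls <- validate_intervals(as.data.frame(calls), "calls")
  check_cnv_type(calls$type)
  unknown <- setdiff(unique(calls$sample), truth$samples)
  if (length(unknown))
    stop("calls reference samples outside the truth cohort: ",
         paste(sort(unknown), collapse = ", "))

  callers <- sort(unique(calls$caller))
  if (!length(callers)) callers <- "caller"

  # map every call row to the baits it overlaps
  if (nrow(calls)) {
    hits <- findOverlaps(to_granges(calls), to_granges(baits))
    called <- data.table(sample = calls$sample[queryHits(hits)],
                         caller = calls$caller[queryHits(hits)],
                         bait_id = baits$bait_id[subjectHits(hits)],
                         call_type = calls$type[queryHits(hits)])
  } else {
    called <- data.table(sample = character(), caller = character(),
                         bait_id = character(), call_type = character())
  }

  truth_units <- as.data.table(truth$exons)   # sample, bait_id, truth_type
  if (!type_aware) {
    called[, call_type := "ANY"]
    truth_units <- unique(truth_units[, .(sample, bait_id)])[, truth_type := "ANY"]
  }
  called <- unique(called)

  out <- vector("list", length(callers))
  for (i in seq_along(callers)) {
    ck <- called[caller == callers[i]]
    tkey <- paste(truth_units$sample, truth_units$bait_id, truth_units$truth_type)
    ckey <- paste(ck$sample, ck$bait_id, ck$call_type)
    tp <- tkey %in% ckey
    truth_part <- data.table(sample = truth_units$sample,
                             bait_id = truth_units$bait_id,
                             caller = callers[i],
                             label = ifelse(tp, "TP", "FN"),
                             call_type = ifelse(tp, truth_units$truth_type,
                                                NA_character_),
                             truth_type = truth_units$truth_type)
    fp <- !(ckey %in% tkey)
    fp_part <- data.table(sample = ck$sample[fp], bait_id = ck$bait_id[fp],
                          caller = callers[i], label = "FP",
                          call_type = ck$call_type[fp],
                          truth_type = NA_character_)
    out[[i]] <- rbind(truth_part, fp_part)
  }
  cls <- as.data.frame(data.table::rbindlist(out))
  cls <- cls[order(cls$caller, cls$sample, cls$bait_id, cls$label), ,
             drop = FALSE]
  rownames(cls) <- NULL
  structure(cls, type_aware = type_aware, cohort = truth$samples,
            callers = callers,
            class = c("exon_classification", "data.frame"))
}

#' Benchmark metrics from a classification
#'
#' Sensitivity = TP / (TP + FN); positive predictive value (PPV) =
#' TP / (TP + FP). PPV is `NA` (undefined), not 0, when a caller makes no
#' calls. The truth denominator is TP + FN, i.e. the truth exon units that
#' survive whatever mask was applied.
#'
#' @param cls an `exon_classification`.
#' @param condition label stored in the result (`"PRE"` or `"POST"`,
#'   free-form).
#' @return data.frame with one row per caller: `caller`, `condition`,
#'   `truth`, `tp`, `fp`, `fn`, `sensitivity`, `ppv` (raw fractions; round
#'   only for display).
#' @export
benchmark_metrics <- function(cls, condition = "PRE") {
  callers <- attr(cls, "callers")
  if (is.null(callers)) callers <- sort(unique(cls$caller))
  rows <- lapply(callers, function(ck) {
    lab <- cls$label[cls$caller == ck]
    tp <- sum(lab == "TP"); fp <- sum(lab == "FP"); fn <- sum(lab == "FN")
    data.frame(caller = ck, condition = condition,
               truth = tp + fn, tp = tp, fp = fp, fn = fn,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Metrics from raw counts
#'
#' Convenience wrapper applying the sensitivity/PPV arithmetic directly to
#' TP/FP/FN counts (e.g. counts transcribed from a published benchmark
#' table).
#'
#' @param tp,fp,fn non-negative integer vectors (recycled).
#' @return data.frame with `truth`, `sensitivity`, `ppv`; `ppv` is `NA` when
#'   `tp + fp == 0`.
#' @export
metrics_from_counts <- function(tp, fp, fn) {
  stopifnot(all(tp >= 0), all(fp >= 0), all(fn >= 0))
  data.frame(truth = tp + fn,
             tp = tp, fp = fp, fn = fn,
             sensitivity = ifelse(tp + fn > 0, tp / (tp + fn), NA_real_),
             ppv = ifelse(tp + fp > 0, tp / (tp + fp), NA_real_))
}

#' Cross-caller concordance at the truth-exon level
#'
#' For every truth exon unit, tabulates which callers detected it (TP).
#' Reports, per caller, the fraction of its TPs that no other caller found
#' (caller-specific) and the complementary shared fraction, plus the union
#' sensitivity: the sensitivity of the per-exon OR across all callers.
#'
#' @param cls an `exon_classification` covering two or more callers built
#'   from one truth set (every caller must carry the identical truth units;
#'   anything else is an error).
#' @return list with `per_exon` (truth unit x caller detection matrix in
#'   long form with a `n_callers` column), `per_caller` (data.frame
#'   `caller`, `tp`, `specific_fraction`, `shared_fraction`),
#'   `detected_by` (table of truth units by number of detecting callers) and
#'   `union_sensitivity`.
#' @export
caller_concordance <- function(cls) {
  dt <- as.data.table(as.data.frame(cls))
  callers <- sort(unique(dt$caller))
  truth_rows <- dt[label %in% c("TP", "FN")]
  truth_rows[, unit := paste(sample, bait_id, truth_type)]
  units_by_caller <- split(truth_rows$unit, truth_rows$caller)
  ref <- sort(units_by_caller[[1L]])
  for (u in units_by_caller)
    if (!identical(sort(u), ref))
      stop("classifications do not share one truth set")

  tp_rows <- truth_rows[label == "TP"]
  det <- table(factor(tp_rows$unit, levels = ref))
  n_units <- length(ref)
  detected_by <- table(factor(as.integer(det), levels = 0:length(callers)))

  per_caller <- do.call(rbind, lapply(callers, function(ck) {
    mine <- tp_rows$unit[tp_rows$caller == ck]
    n_tp <- length(mine)
    specific <- if (n_tp) sum(det[mine] == 1L) / n_tp else NA_real_
    data.frame(caller = ck, tp = n_tp,
               specific_fraction = specific,
               shared_fraction = if (n_tp) 1 - specific else NA_real_,
               sensitivity = n_tp / n_units,
               stringsAsFactors = FALSE)
  }))
  per_exon <- data.frame(unit = ref, n_callers = as.integer(det),
                         stringsAsFactors = FALSE)
  list(per_exon = per_exon,
       per_caller = per_caller,
       detected_by = detected_by,
       union_sensitivity = sum(det > 0L) / n_units)
}
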