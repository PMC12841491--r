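#' Run the full benchmarking-and-masking pipeline
#'
#' Sequences the stages end to end: truth-set construction from the array
#' CNV table; pre-filter bait-level benchmarking of every caller;
#' per-caller recurrence masks over the full cohort; bait annotation
#' (mappability, GC, RPKM CV, segdup overlap) with the resampling Wilcoxon
#' comparison of flagged versus background baits; mask filtration with
#' recomputed metrics and paired signed-rank tests; and cross-caller
#' concordance. All randomness (the background resampling) flows from one
#' seed recorded in the run log.
#'
#' @param bundle a [sim_bundle][simulate_cohort()] or the list returned by
#'   [read_bundle()]: needs `baits`, `array_cnvs`, `calls`, `counts`,
#'   `total_reads`, `mappability`, `segdups`, and `genome` (genome may be
#'   `NULL` if `baits` already carries a `gc` column).
#' @param cohort_size full cohort size used as the recurrence denominator;
#'   defaults to the number of distinct samples in `calls`.
#' @param mask_threshold recurrence fraction above which a bait is flagged
#'   (default 0.10, strict).
#' @param type_aware require DEL/DUP agreement for a TP (default TRUE).
#' @param n_iter resampling iterations for the feature comparison (default
#'   1000).
#' @param seed seed for the resampling (default 1).
#' @param truth_cfg a [truth_filter_config()].
#' @param out_dir directory for the report files; `NULL` writes nothing.
#' @return list of class `cnvmask_run` with `truth`, `truth_audit`,
#'   `classifications`, `pre_metrics`, `masks`, `features`,
#'   `feature_comparisons`, `outcomes`, `report` (the summary grid),
#'   `concordance`, and `params`.
#' @export
run_pipeline <- function(bundle, cohort_size = NULL,
                         mask_threshold = 0.10, type_aware = TRUE,
                         n_iter = 1000L, seed = 1L,
                         truth_cfg = truth_filter_config(),
                         out_dir = NULL) {
  baits <- check_sorted_baits(bundle$baits)
  calls <- bundle$calls
  if (is.null(cohort_size)) cohort_size <- length(unique(calls$sample))

  ## stage: truth
  flt <- tryCatch(filter_array_cnvs(bundle$array_cnvs, baits, truth_cfg),
                  error = function(e) stop("truth stage: ",
                                           conditionMessage(e), call. = FALSE))
  truth <- expand_to_truth_exons(flt$kept, baits)
  if (nrow(truth$exons) == 0L) stop("truth stage: empty truth set")
  type_counts <- table(factor(truth$exons$truth_type,
                              levels = c("DEL", "DUP")))
  stopifnot(sum(type_counts) == nrow(truth$exons))  # DEL + DUP = all exons

  ## stage: pre-filter benchmark
  cohort_calls <- calls[calls$sample %in% truth$samples, , drop = FALSE]
  cls <- tryCatch(classify_calls(cohort_calls, truth, baits,
                                 type_aware = type_aware),
                  error = function(e) stop("benchmark stage: ",
                                           conditionMessage(e), call. = FALSE))
  pre <- benchmark_metrics(cls, condition = "PRE")
  conc <- caller_concordance(cls)

  ## stage: recurrence masks (full cohort denominator)
  callers <- sort(unique(calls$caller))
  masks <- lapply(callers, function(ck) {
    rec <- bait_recurrence(calls[calls$caller == ck, , drop = FALSE],
                           baits, cohort_size = cohort_size)
    build_mask(rec, baits, threshold = mask_threshold, caller = ck)
  })
  names(masks) <- callers

  ## stage: bait features + flagged-vs-background comparison
  rpkm <- rpkm_normalize(bundle$counts, baits,
                         total_reads = bundle$total_reads)
  cv <- rpkm_cv(rpkm)
  gc <- if (!is.null(bundle$genome)) gc_content(baits, bundle$genome)
  else NULL
  features <- annotate_baits(baits, mappability = bundle$mappability,
                             segdups = bundle$segdups, rpkm_cv = cv,
                             gc = gc)
  comparisons <- lapply(callers, function(ck) {
    if (length(masks[[ck]]$flagged_baits) == 0L) return(NULL)
    compare_features(features, masks[[ck]], n_iter = n_iter, seed = seed)
  })
  names(comparisons) <- callers

  ## stage: filtration + paired tests
  outcomes <- lapply(callers, function(ck) {
    one <- structure(cls[cls$caller == ck, , drop = FALSE],
                     type_aware = attr(cls, "type_aware"),
                     cohort = attr(cls, "cohort"), callers = ck,
                     class = c("exon_classification", "data.frame"))
    filtration_outcome(one, masks[[ck]], baits)
  })
  names(outcomes) <- callers
  report <- summarize_outcomes(outcomes)

  run <- structure(list(truth = truth, truth_audit = flt$audit,
                        classifications = cls, pre_metrics = pre,
                        masks = masks, features = features,
                        feature_comparisons = comparisons,
                        outcomes = outcomes, report = report,
                        concordance = conc,
                        params = list(cohort_size = cohort_size,
                                      mask_threshold = mask_threshold,
                                      type_aware = type_aware,
                                      n_iter = n_iter, seed = seed,
                                      truth_cfg = unclass(truth_cfg))),
                   class = "cnvmask_run")
  if (!is.null(out_dir)) write_run(run, baits, out_dir)
  run
}

#' @export
print.cnvmask_run <- function(x, ...) {
  cat("cnvmask run: ", x$truth$n_cnvs, " truth CNVs / ",
      nrow(x$truth$exons), " truth exon units; union sensitivity ",
      sprintf("%.3f", x$concordance$union_sensitivity), "\n", sep = "")
  print(x$report[c("caller", "sensitivity_pre", "sensitivity_post",
                   "ppv_pre", "ppv_post", "masked_baits")])
  invisible(x)
}

# Writes the report bundle; every file is listed in run_log.tsv together
# with its md5 and the md5 of the serialized parameters, so any output can
# be traced to the exact configuration that produced it.
write_run <- function(run, baits, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  put <- function(x, name) {
    p <- file.path(out_dir, name)
    data.table::fwrite(x, p, sep = "\t")
    paths[[length(paths) + 1L]] <<- p
    p
  }
  put(run$report, "report.tsv")
  put(as.data.frame(run$classifications), "classification.tsv")
  put(run$truth_audit, "truth_audit.tsv")
  wp <- file.path(out_dir, "truth_exons.tsv")
  write_truth_set(run$truth, baits, wp); paths[[length(paths) + 1L]] <- wp
  for (ck in names(run$masks)) {
    m <- run$masks[[ck]]
    if (nrow(m$merged_regions)) {
      bp <- file.path(out_dir, paste0("mask_", ck, ".bed"))
      write_bed(m$merged_regions, bp); paths[[length(paths) + 1L]] <- bp
    }
    put(m$recurrence, paste0("recurrence_", ck, ".tsv"))
    cmp <- run$feature_comparisons[[ck]]
    if (!is.null(cmp)) {
      put(cmp$iterations, paste0("feature_iterations_", ck, ".tsv"))
      put(cmp$summary, paste0("feature_summary_", ck, ".tsv"))
    }
  }
  put(run$concordance$per_caller, "concordance.tsv")
  per_sample <- do.call(rbind, lapply(names(run$outcomes), function(ck) {
    o <- run$outcomes[[ck]]
    both <- rbind(o$per_sample$pre, o$per_sample$post)
    rownames(both) <- NULL
    data.frame(caller = rep(ck, nrow(both)),
               condition = rep(c("PRE", "POST"),
                               each = nrow(o$per_sample$pre)),
               both, stringsAsFactors = FALSE)
  }))
  put(per_sample, "per_sample_counts.tsv")

  tmp <- tempfile()
  saveRDS(run$params, tmp)
  cfg_hash <- unname(substr(tools::md5sum(tmp), 1, 12))
  unlink(tmp)
  log <- data.frame(file = basename(unlist(paths)),
                    md5 = unname(tools::md5sum(unlist(paths))),
                    config_hash = cfg_hash,
                    seed = run$params$seed,
                    mask_threshold = run$params$mask_threshold,
                    cohort_size = run$params$cohort_size,
                    stringsAsFactors = FALSE)
  data.table::fwrite(log, file.path(out_dir, "run_log.tsv"), sep = "\t")
  invisible(out_dir)
}
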