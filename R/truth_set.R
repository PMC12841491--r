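#' Truth-set filter configuration
#'
#' Filter cascade used to turn raw array (CMA-style) CNV tables into a
#' high-confidence truth set: (1) drop CNVs supported by fewer than
#' `min_snp_probes` SNP probes; (2) drop CNVs inside highly polymorphic loci,
#' i.e. merged CNV regions carrying events from more than
#' `max_polymorphic_samples` distinct samples; (3) require overlap with at
#' least one sequencing target bait.
#'
#' @param min_snp_probes minimum SNP-probe support to keep a CNV (default 10,
#'   i.e. "fewer than ten" are excluded).
#' @param max_polymorphic_samples a merged locus is polymorphic when CNVs from
#'   strictly more than this many distinct samples overlap it (default 4).
#' @param require_bait_overlap drop CNVs hitting no target bait (default TRUE).
#' @return list of class `truth_filter_config`.
#' @export
truth_filter_config <- function(min_snp_probes = 10L,
                                max_polymorphic_samples = 4L,
                                require_bait_overlap = TRUE) {
  stopifnot(min_snp_probes >= 1L, max_polymorphic_samples >= 0L)
  structure(list(min_snp_probes = as.integer(min_snp_probes),
                 max_polymorphic_samples = as.integer(max_polymorphic_samples),
                 require_bait_overlap = isTRUE(require_bait_overlap)),
            class = "truth_filter_config")
}

#' Read an array CNV table
#'
#' Header `chrom start end type sample snp_probes [manual_pass]` with 1-based
#' inclusive coordinates, which are converted to the package-wide 0-based
#' half-open convention on read (`start - 1`).
#'
#' @param path path to the tab-separated file.
#' @return data.frame of array CNVs in 0-based half-open coordinates.
#' @export
read_array_cnvs <- function(path) {
  x <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  req <- c("chrom", "start", "end", "type", "sample", "snp_probes")
  if (!all(req %in% names(x)))
    stop("array CNV table needs columns: ", paste(req, collapse = " "))
  x$start <- x$start - 1L          # 1-based inclusive -> 0-based half-open
  x <- validate_intervals(x, basename(path))
  check_cnv_type(x$type)
  if (any(x$snp_probes < 0)) stop("negative snp_probes")
  x[order(x$chrom, x$start), , drop = FALSE]
}

#' Filter array CNVs into truth candidates
#'
#' Applies the probe-count, polymorphic-locus and bait-overlap rules in that
#' fixed order. The audit reports, per CNV, the first failing rule only, so
#' audit files are deterministic. When a `manual_pass` logical column is
#' present it is honoured as a final rule (`manual` in the audit); the manual
#' log2-ratio / B-allele-frequency review itself is out of scope.
#'
#' Polymorphic loci are found by merging *all* input CNVs across samples
#' (gap = 0) and counting distinct samples per merged locus; every CNV
#' overlapping a locus with more than `cfg$max_polymorphic_samples` samples is
#' excluded. Sample counting happens before any other filter.
#'
#' @param cnvs array CNV data.frame (0-based half-open; see
#'   [read_array_cnvs()]).
#' @param baits sorted bait table.
#' @param cfg a [truth_filter_config()].
#' @return list with `kept` (surviving CNVs) and `audit` (per-CNV data.frame
#'   with a `status` of `kept`, `probe_count`, `polymorphic`, `no_bait` or
#'   `manual`).
#' @export
filter_array_cnvs <- function(cnvs, baits, cfg = truth_filter_config()) {
  stopifnot(inherits(cfg, "truth_filter_config"))
  cnvs <- validate_intervals(cnvs, "array CNVs")
  if (cfg$require_bait_overlap && (is.null(baits) || nrow(baits) == 0L))
    stop("bait-overlap filtering requested but the bait set is empty")
  baits <- check_sorted_baits(baits)
  n <- nrow(cnvs)
  status <- rep("kept", n)

  # polymorphic loci from the full, unfiltered input
  loci <- merge_intervals(cnvs[c("chrom", "start", "end")], gap = 0L)
  if (nrow(loci)) {
    hits <- findOverlaps(to_granges(cnvs), to_granges(loci))
    samples_per_locus <- tapply(cnvs$sample[queryHits(hits)],
                                subjectHits(hits),
                                function(s) length(unique(s)))
    poly_loci <- as.integer(names(samples_per_locus))[
      samples_per_locus > cfg$max_polymorphic_samples]
    in_poly <- unique(queryHits(hits)[subjectHits(hits) %in% poly_loci])
  } else {
    in_poly <- integer()
  }

  has_bait <- rep(TRUE, n)
  if (cfg$require_bait_overlap && n > 0L) {
    bh <- findOverlaps(to_granges(cnvs), to_granges(baits))
    has_bait <- seq_len(n) %in% queryHits(bh)
  }

  fail_probe <- cnvs$snp_probes < cfg$min_snp_probes
  status[!has_bait] <- "no_bait"
  status[seq_len(n) %in% in_poly] <- "polymorphic"
  status[fail_probe] <- "probe_count"      # first rule wins: applied last
  if ("manual_pass" %in% names(cnvs)) {
    manual_fail <- status == "kept" & !is.na(cnvs$manual_pass) & !cnvs$manual_pass
    status[manual_fail] <- "manual"
  }

  audit <- cbind(cnvs[c("chrom", "start", "end", "type", "sample", "snp_probes")],
                 status = status, stringsAsFactors = FALSE)
  list(kept = cnvs[status == "kept", , drop = FALSE], audit = audit)
}

#' Expand filtered CNVs to a per-bait truth set
#'
#' Every bait overlapped by a kept CNV becomes a truth exon for that CNV's
#' sample, labelled with the CNV's type. Labels are kept per (sample,
#' bait), so a DEL in one sample and a DUP in another at the same bait never
#' conflict; within one sample a bait hit by both a DEL and a DUP keeps both
#' labels (one unit per type) and the condition is reported in `conflicts`.
#'
#' @param kept filtered CNV data.frame (`$kept` from [filter_array_cnvs()]).
#' @param baits sorted bait table.
#' @return object of class `truth_exon_set`: list with `exons` (data.frame
#'   `sample`, `bait_id`, `truth_type`), `n_cnvs`, `n_samples`, `samples`,
#'   and `conflicts` (sample/bait pairs carrying both labels).
#' @export
expand_to_truth_exons <- function(kept, baits) {
  baits <- check_sorted_baits(baits)
  if (nrow(kept) == 0L) {
    exons <- data.frame(sample = character(), bait_id = character(),
                        truth_type = character(), stringsAsFactors = FALSE)
  } else {
    hits <- findOverlaps(to_granges(kept), to_granges(baits))
    exons <- data.frame(sample = kept$sample[queryHits(hits)],
                        bait_id = baits$bait_id[subjectHits(hits)],
                        truth_type = kept$type[queryHits(hits)],
                        stringsAsFactors = FALSE)
    exons <- unique(exons)           # same-sample same-type duplicates collapse
  }
  key <- paste(exons$sample, exons$bait_id)
  conflicts <- unique(key[duplicated(key)])
  structure(list(exons = exons[order(exons$sample, exons$bait_id), ,
                               drop = FALSE],
                 n_cnvs = nrow(kept),
                 n_samples = length(unique(kept$sample)),
                 samples = sort(unique(kept$sample)),
                 conflicts = conflicts),
            class = "truth_exon_set")
}

#' @export
print.truth_exon_set <- function(x, ...) {
  tab <- table(x$exons$truth_type)
  cat("Truth exon set: ", nrow(x$exons), " exon units (",
      paste(names(tab), as.integer(tab), collapse = ", "),
      ") from ", x$n_cnvs, " CNVs in ", x$n_samples, " samples\n", sep = "")
  invisible(x)
}

#' Write a truth exon set as TSV
#'
#' Columns `bait_id chrom start end truth_type samples`, one row per
#' (bait, type) with the contributing samples comma-joined.
#'
#' @param truth a `truth_exon_set`.
#' @param baits sorted bait table (coordinates for the output).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_set <- function(truth, baits, path) {
  ex <- truth$exons
  agg <- stats::aggregate(sample ~ bait_id + truth_type, data = ex,
                          FUN = function(s) paste(sort(unique(s)), collapse = ","))
  idx <- match(agg$bait_id, baits$bait_id)
  out <- data.frame(bait_id = agg$bait_id,
                    chrom = baits$chrom[idx], start = baits$start[idx],
                    end = baits$end[idx], truth_type = agg$truth_type,
                    samples = agg$sample, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$truth_type), , drop = FALSE]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
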