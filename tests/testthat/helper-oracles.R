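# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's interval machinery: everything is per-base set
# enumeration or quadratic loops over plain data.frames.

base_set <- function(chrom, start, end) {
  if (end <= start) character() else paste(chrom, start:(end - 1L))
}

oracle_overlaps <- function(a, b) {
  length(intersect(base_set(a$chrom, a$start, a$end),
                   base_set(b$chrom, b$start, b$end))) >= 1L
}

oracle_covered_bases <- function(df) {
  unique(unlist(Map(base_set, df$chrom, df$start, df$end), use.names = FALSE))
}

# all-pairs O(n*m) overlap scan
oracle_baits_hit <- function(call, baits) {
  hit <- baits$chrom == call$chrom & baits$start < call$end &
    call$start < baits$end
  baits$bait_id[hit][order(baits$start[hit])]
}

# set algebra over (sample, bait, type) triples
oracle_classify <- function(calls, truth_exons, baits, type_aware = TRUE) {
  called <- character()
  for (i in seq_len(nrow(calls))) {
    ids <- oracle_baits_hit(calls[i, ], baits)
    if (length(ids))
      called <- c(called, paste(calls$sample[i], ids,
                                if (type_aware) calls$type[i] else "ANY"))
  }
  called <- unique(called)
  tkey <- unique(paste(truth_exons$sample, truth_exons$bait_id,
                       if (type_aware) truth_exons$truth_type else "ANY"))
  list(tp = sum(tkey %in% called),
       fn = sum(!tkey %in% called),
       fp = sum(!called %in% tkey))
}

rand_intervals <- function(n, chroms = c("1", "2"), max_pos = 10000,
                           max_len = 400) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE), start = start,
             end = start + len, stringsAsFactors = FALSE)
}

make_baits <- function(n, chrom = "1", spacing = 100L, width = 60L,
                       offset = 0L) {
  start <- offset + (seq_len(n) - 1L) * spacing
  df <- data.frame(chrom = chrom, start = start, end = start + width,
                   bait_id = sprintf("%s_b%04d", chrom, seq_len(n)),
                   stringsAsFactors = FALSE)
  df[order(df$chrom, df$start), ]
}

# two-chromosome bait grid used across benchmark/problematic fixtures
grid_baits <- function(n_per_chrom = 50) {
  rbind(make_baits(n_per_chrom, "1"), make_baits(n_per_chrom, "2"))
}

bait_call <- function(baits, bait_id, sample, type = "DEL",
                      caller = "caller") {
  i <- match(bait_id, baits$bait_id)
  data.frame(chrom = baits$chrom[i], start = baits$start[i],
             end = baits$end[i], type = rep_len(type, length(i)),
             sample = rep_len(sample, length(i)),
             caller = rep_len(caller, length(i)), stringsAsFactors = FALSE)
}

make_truth <- function(exons_df, n_cnvs = NA_integer_) {
  samples <- sort(unique(exons_df$sample))
  structure(list(exons = exons_df[order(exons_df$sample, exons_df$bait_id), ],
                 n_cnvs = n_cnvs, n_samples = length(samples),
                 samples = samples, conflicts = character()),
            class = "truth_exon_set")
}

tiny_sim_cfg <- function(seed = 1, ...) {
  defaults <- list(
    seed = seed, n_samples = 40L, n_cma_samples = 14L,
    n_truth_samples = 10L, n_baits = 1200L, n_chrom = 3L,
    chrom_length = 3e5, n_truth_cnvs = 16L,
    truth_size_range = c(2e4, 4e4), n_lowprobe_decoys = 4L,
    n_polymorphic_loci = 1L,
    caller_profiles = list(
      hot = list(sensitivity = 0.8, n_artifact_loci = 6L,
                 artifact_recurrence = 0.35, sporadic_fp_rate = 0.003),
      cool = list(sensitivity = 0.7, n_artifact_loci = 2L,
                  artifact_recurrence = 0.04, sporadic_fp_rate = 0.004)))
  dots <- list(...)
  args <- utils::modifyList(defaults, dots)
  if ("caller_profiles" %in% names(dots))
    args$caller_profiles <- dots$caller_profiles   # replace, never merge
  do.call(sim_config, args)
}
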