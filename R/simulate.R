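#' Synthetic-cohort configuration
#'
#' Parameters of the seeded study generator. Defaults describe a cohort of
#' 180 exome samples over 20,000 capture baits on a toy multi-chromosome
#' genome, with an array-typed subset contributing a truth set, four
#' emulated callers with planted recurrent artifact loci, and bait-level
#' depth matrices whose intersample variability is elevated at artifact
#' loci. Caller profiles are deliberate caricatures of read-depth exome
#' callers (a call-happy high-recurrence caller, two intermediate ones, and
#' a conservative caller whose systematic noise stays below the recurrence
#' threshold); they do not emulate any real tool's algorithm.
#'
#' @param seed integer seed driving every random draw.
#' @param n_samples cohort size (default 180).
#' @param n_cma_samples samples with array data (default 44).
#' @param n_truth_samples array samples contributing surviving truth CNVs
#'   (default 39); the remainder carry only rejected events.
#' @param n_baits number of capture baits (default 20000).
#' @param n_chrom,chrom_length toy genome shape (default 8 x 2 Mb).
#' @param bait_length bait width in bp (default 120).
#' @param n_truth_cnvs clean array CNVs planted across the truth samples
#'   (default 98, split `del_dup_ratio`).
#' @param truth_size_range log-uniform CNV size range in bp (default
#'   20-80 kb, a scaled-down echo of clinical array CNV sizes so that every
#'   clean CNV carries >= 10 synthetic SNP probes at 1 probe / 2 kb).
#' @param del_dup_ratio deletions:duplications among clean CNVs (default
#'   39:59).
#' @param n_lowprobe_decoys array CNVs sized 5-18 kb, i.e. below the
#'   ten-probe filter (default 15).
#' @param n_polymorphic_loci loci where `polymorphic_locus_samples` distinct
#'   samples carry overlapping array CNVs, to exercise the polymorphic
#'   filter (default 2 loci of 6 samples).
#' @param polymorphic_locus_samples see above.
#' @param probe_per_bp synthetic SNP-probe density (default 1/2000, floor 1).
#' @param artifact_locus_span baits per artifact locus (default 8).
#' @param artifact_mappability_decrement mean mappability drop at artifact
#'   baits (default 0.25).
#' @param artifact_cv_multiplier target RPKM-CV ratio artifact/background
#'   (default 2.5).
#' @param artifact_gc_shift GC-fraction shift of artifact neighborhoods in
#'   the toy genome (default -0.10).
#' @param segdup_colocation probability that an artifact locus lies in a
#'   segmental duplication (default 0.8).
#' @param background_segdup_rate fraction of background baits inside
#'   segdups (default 0.05).
#' @param background_cv target intersample RPKM CV at background baits
#'   (default 0.18).
#' @param mean_depth mean reads per bait (default 150).
#' @param caller_profiles named list; each profile has `sensitivity`
#'   (per-truth-exon detection probability), `n_artifact_loci`,
#'   `artifact_recurrence` (per-locus per-sample call probability) and
#'   `sporadic_fp_rate` (per-bait per-sample false-call probability).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 180L,
                       n_cma_samples = 44L,
                       n_truth_samples = 39L,
                       n_baits = 20000L,
                       n_chrom = 8L,
                       chrom_length = 2e6,
                       bait_length = 120L,
                       n_truth_cnvs = 98L,
                       truth_size_range = c(2e4, 8e4),
                       del_dup_ratio = c(39, 59),
                       n_lowprobe_decoys = 15L,
                       n_polymorphic_loci = 2L,
                       polymorphic_locus_samples = 6L,
                       probe_per_bp = 1 / 2000,
                       artifact_locus_span = 8L,
                       artifact_mappability_decrement = 0.25,
                       artifact_cv_multiplier = 2.5,
                       artifact_gc_shift = -0.10,
                       segdup_colocation = 0.8,
                       background_segdup_rate = 0.05,
                       background_cv = 0.18,
                       mean_depth = 150,
                       caller_profiles = default_caller_profiles()) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_truth_samples <= cfg$n_cma_samples,
            cfg$n_cma_samples <= cfg$n_samples,
            cfg$truth_size_range[1] > 0,
            cfg$truth_size_range[2] >= cfg$truth_size_range[1],
            cfg$truth_size_range[2] < cfg$chrom_length,
            all(vapply(cfg$caller_profiles, function(p)
              p$sensitivity >= 0 && p$sensitivity <= 1 &&
                p$artifact_recurrence >= 0 && p$artifact_recurrence <= 1 &&
                p$sporadic_fp_rate >= 0 && p$sporadic_fp_rate <= 1,
              logical(1))))
  structure(cfg, class = "sim_config")
}

#' Default emulated caller profiles
#'
#' Four caricatures spanning the behaviors seen among read-depth exome CNV
#' callers: `deepcall` (sensitive, call-happy, many recurrent artifact
#' loci), `segtrace` and `mixport` (intermediate artifact loads; `mixport`
#' with low sensitivity), and `conserv` (sensitive and clean — its few
#' systematic loci recur in only ~4% of samples, below any 10% recurrence
#' threshold, so its mask is empty and filtration is a no-op).
#'
#' @return named list of profile lists.
#' @export
default_caller_profiles <- function() {
  list(
    deepcall = list(sensitivity = 0.76, n_artifact_loci = 60L,
                    artifact_recurrence = 0.30, sporadic_fp_rate = 0.0025),
    segtrace = list(sensitivity = 0.66, n_artifact_loci = 30L,
                    artifact_recurrence = 0.30, sporadic_fp_rate = 0.0015),
    conserv  = list(sensitivity = 0.77, n_artifact_loci = 3L,
                    artifact_recurrence = 0.04, sporadic_fp_rate = 0.005),
    mixport  = list(sensitivity = 0.17, n_artifact_loci = 35L,
                    artifact_recurrence = 0.30, sporadic_fp_rate = 0.002)
  )
}

runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

#' Simulate a full synthetic study
#'
#' Generates, deterministically for a fixed seed, every input the pipeline
#' consumes: a bait set on a toy genome, the genome sequence itself (i.i.d.
#' base composition with GC-shifted artifact neighborhoods), a per-base
#' mappability track, segmental duplications co-located with artifact loci,
#' an array CNV table (clean truth CNVs plus low-probe and polymorphic
#' decoys), per-caller call tables with planted recurrent artifact loci and
#' sporadic false positives, a bait x sample read-count matrix with elevated
#' intersample variability at artifact baits, and a ground-truth manifest.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_bundle` with elements `baits`, `genome`
#'   (DNAStringSet), `mappability` (bedGraph data.frame), `segdups`,
#'   `array_cnvs`, `calls`, `counts`, `total_reads`, `manifest`, `config`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)

  samples <- sprintf("S%03d", seq_len(cfg$n_samples))
  cma_samples <- sort(sample(samples, cfg$n_cma_samples))
  truth_samples <- sort(sample(cma_samples, cfg$n_truth_samples))

  ## ---- baits on a toy genome ----------------------------------------------
  chroms <- paste0("c", seq_len(cfg$n_chrom))
  per_chrom <- cfg$n_baits %/% cfg$n_chrom
  extra <- cfg$n_baits %% cfg$n_chrom
  nb_chrom <- rep(per_chrom, cfg$n_chrom) + c(rep(1L, extra),
                                              rep(0L, cfg$n_chrom - extra))
  baits <- do.call(rbind, lapply(seq_len(cfg$n_chrom), function(i) {
    nb <- nb_chrom[i]
    spacing <- floor(cfg$chrom_length / nb)
    start <- (seq_len(nb) - 1L) * spacing +
      floor((spacing - cfg$bait_length) / 2)
    data.frame(chrom = chroms[i], start = as.integer(start),
               end = as.integer(start + cfg$bait_length),
               stringsAsFactors = FALSE)
  }))
  baits$bait_id <- sprintf("b%05d", seq_len(nrow(baits)))
  baits <- check_sorted_baits(baits)
  nb <- nrow(baits)

  ## ---- artifact locus pool, shared across callers --------------------------
  max_loci <- max(vapply(cfg$caller_profiles,
                         function(p) as.numeric(p$n_artifact_loci),
                         numeric(1)))
  pool_size <- max(ceiling(1.2 * max_loci), max_loci + 10L)
  span <- cfg$artifact_locus_span
  if (pool_size * span * 3L > nb)
    stop("infeasible config: artifact loci would cover most of the bait set")
  # locus start baits, spaced so loci never touch or cross a chromosome
  idx_by_chrom <- split(seq_len(nb), baits$chrom)
  slots <- unlist(lapply(idx_by_chrom, function(ii)
    ii[seq(1L, length(ii) - span, by = span * 3L)]), use.names = FALSE)
  if (length(slots) < pool_size)
    stop("infeasible config: not enough room for ", pool_size,
         " artifact loci")
  pool_starts <- sort(sample(slots, pool_size))
  pool_loci <- lapply(pool_starts, function(s) seq(s, s + span - 1L))
  # a call-happy caller takes the head of the pool; others draw subsets of
  # its loci so problematic regions overlap across callers
  caller_ids <- names(cfg$caller_profiles)
  locus_assign <- list()
  head_n <- cfg$caller_profiles[[which.max(vapply(
    cfg$caller_profiles, function(p) as.numeric(p$n_artifact_loci),
    numeric(1)))]]$n_artifact_loci
  for (ck in caller_ids) {
    k <- cfg$caller_profiles[[ck]]$n_artifact_loci
    locus_assign[[ck]] <- if (k >= head_n) seq_len(k)
    else sort(sample(seq_len(head_n), k))
  }
  used_loci <- sort(unique(unlist(locus_assign)))
  artifact_baits_idx <- as.integer(sort(unique(unlist(pool_loci[used_loci]))))

  ## ---- toy genome with GC-shifted artifact neighborhoods -------------------
  gc_bg <- 0.45
  gc_art <- min(max(gc_bg + cfg$artifact_gc_shift, 0.05), 0.95)
  p_bg <- c(A = (1 - gc_bg) / 2, C = gc_bg / 2, G = gc_bg / 2,
            T = (1 - gc_bg) / 2)
  p_art <- c(A = (1 - gc_art) / 2, C = gc_art / 2, G = gc_art / 2,
             T = (1 - gc_art) / 2)
  letters4 <- c("A", "C", "G", "T")
  genome <- vector("list", cfg$n_chrom)
  names(genome) <- chroms
  art_by_chrom <- split(artifact_baits_idx,
                        baits$chrom[artifact_baits_idx])
  for (i in seq_len(cfg$n_chrom)) {
    L <- cfg$chrom_length
    s <- sample(letters4, L, replace = TRUE, prob = p_bg)
    idx <- art_by_chrom[[chroms[i]]]
    if (!is.null(idx)) for (j in idx) {
      a <- max(1L, baits$start[j] - 400L + 1L)
      b <- min(L, baits$end[j] + 400L)
      s[a:b] <- sample(letters4, b - a + 1L, replace = TRUE, prob = p_art)
    }
    genome[[i]] <- paste(s, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(unlist(genome))
  names(genome) <- chroms

  ## ---- mappability track (two segments per bait) ---------------------------
  map_target <- stats::rbeta(nb, 20, 1.5)
  map_target[artifact_baits_idx] <-
    pmax(0.02, map_target[artifact_baits_idx] -
           cfg$artifact_mappability_decrement)
  half <- floor(cfg$bait_length / 2)
  jit <- stats::runif(nb, 0, 0.04)
  mappability <- data.frame(
    chrom = rep(baits$chrom, each = 2L),
    start = as.integer(rbind(baits$start, baits$start + half)),
    end = as.integer(rbind(baits$start + half, baits$end)),
    score = pmin(1, pmax(0, as.numeric(rbind(map_target - jit,
                                             map_target + jit)))),
    stringsAsFactors = FALSE)

  ## ---- segmental duplications ----------------------------------------------
  seg <- list()
  for (li in used_loci) {
    if (stats::runif(1) < cfg$segdup_colocation) {
      idx <- pool_loci[[li]]
      seg[[length(seg) + 1L]] <- data.frame(
        chrom = baits$chrom[idx[1]],
        start = max(0L, baits$start[idx[1]] - 200L),
        end = baits$end[idx[length(idx)]] + 200L,
        stringsAsFactors = FALSE)
    }
  }
  n_bg_seg <- ceiling(cfg$background_segdup_rate * nb / 4)
  bg_idx <- sample(setdiff(seq_len(nb - 4L), artifact_baits_idx), n_bg_seg)
  for (j in bg_idx) {
    seg[[length(seg) + 1L]] <- data.frame(
      chrom = baits$chrom[j], start = baits$start[j],
      end = min(baits$end[j] + 3000L, cfg$chrom_length),
      stringsAsFactors = FALSE)
  }
  segdups <- merge_intervals(do.call(rbind, seg), gap = 0L)

  ## ---- array CNVs: clean truth + decoys ------------------------------------
  n_del <- round(cfg$n_truth_cnvs * cfg$del_dup_ratio[1] /
                   sum(cfg$del_dup_ratio))
  types <- sample(c(rep("DEL", n_del), rep("DUP", cfg$n_truth_cnvs - n_del)))
  # every truth sample carries >= 1 CNV; counts stay small (2-3 at defaults)
  owner <- sample(rep(truth_samples, length.out = cfg$n_truth_cnvs))
  place_cnv <- function(n, lo, hi) {
    len <- round(runif_log(n, lo, hi))
    chrom <- sample(chroms, n, replace = TRUE)
    start <- floor(stats::runif(n) * (cfg$chrom_length - len - 1))
    data.frame(chrom = chrom, start = as.integer(start),
               end = as.integer(start + len), stringsAsFactors = FALSE)
  }
  clean <- place_cnv(cfg$n_truth_cnvs, cfg$truth_size_range[1],
                     cfg$truth_size_range[2])
  clean$type <- types
  clean$sample <- owner

  decoy_low <- place_cnv(cfg$n_lowprobe_decoys, 5e3, 1.8e4)
  decoy_low$type <- sample(c("DEL", "DUP"), cfg$n_lowprobe_decoys,
                           replace = TRUE)
  decoy_low$sample <- sample(cma_samples, cfg$n_lowprobe_decoys,
                             replace = TRUE)

  poly <- list()
  clean_gr <- to_granges(clean)
  for (k in seq_len(cfg$n_polymorphic_loci)) {
    repeat {
      site <- place_cnv(1L, 4e4, 6e4)
      if (length(findOverlaps(to_granges(site), clean_gr)) == 0L) break
    }
    carriers <- sample(cma_samples, cfg$polymorphic_locus_samples)
    jitter <- as.integer(stats::runif(length(carriers), 0, 2000))
    poly[[k]] <- data.frame(chrom = site$chrom,
                            start = site$start + jitter,
                            end = site$end + jitter,
                            type = sample(c("DEL", "DUP"), 1),
                            sample = carriers, stringsAsFactors = FALSE)
  }
  array_cnvs <- rbind(clean, decoy_low, do.call(rbind, poly))
  array_cnvs$snp_probes <- pmax(1L, floor((array_cnvs$end - array_cnvs$start) *
                                            cfg$probe_per_bp))
  array_cnvs <- array_cnvs[order(array_cnvs$chrom, array_cnvs$start), ,
                           drop = FALSE]
  rownames(array_cnvs) <- NULL

  ## ---- truth exons (what the emulated callers can detect) ------------------
  flt <- filter_array_cnvs(array_cnvs, baits)
  truth <- expand_to_truth_exons(flt$kept, baits)

  ## ---- per-caller call tables ----------------------------------------------
  calls <- list()
  for (ck in caller_ids) {
    p <- cfg$caller_profiles[[ck]]
    calls[[ck]] <- emulate_caller(
      caller_id = ck, profile = p, truth = truth, baits = baits,
      samples = samples,
      artifact_loci = pool_loci[locus_assign[[ck]]],
      artifact_bait_pool = artifact_baits_idx)
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL

  ## ---- depth matrix ---------------------------------------------------------
  v0 <- 0.1^2 + 1 / cfg$mean_depth      # sample-scale + Poisson variance share
  cv2sigma <- function(cv) sqrt(log(1 + max(cv^2 - v0, 1e-4)))
  sig_bg <- cv2sigma(cfg$background_cv)
  sig_art <- cv2sigma(cfg$background_cv * cfg$artifact_cv_multiplier)
  mu_bait <- cfg$mean_depth * exp(stats::rnorm(nb, 0, 0.25))
  s_scale <- exp(stats::rnorm(cfg$n_samples, 0, 0.1))
  sig <- rep(sig_bg, nb)
  sig[artifact_baits_idx] <- sig_art
  lam <- outer(mu_bait, s_scale) *
    exp(matrix(stats::rnorm(nb * cfg$n_samples, 0, sig), nrow = nb) -
          sig^2 / 2)
  counts <- matrix(stats::rpois(nb * cfg$n_samples, lam), nrow = nb,
                   dimnames = list(baits$bait_id, samples))
  total_reads <- stats::setNames(round(colSums(counts) * 1.25), samples)

  ## ---- manifest -------------------------------------------------------------
  planted <- lapply(caller_ids, function(ck) {
    p <- cfg$caller_profiles[[ck]]
    if (p$artifact_recurrence > 0.10)
      baits$bait_id[sort(unlist(pool_loci[locus_assign[[ck]]]))]
    else character()
  })
  names(planted) <- caller_ids
  manifest <- list(
    samples = samples, cma_samples = cma_samples,
    truth_samples = truth_samples,
    artifact_baits = stats::setNames(
      lapply(caller_ids,
             function(ck) baits$bait_id[sort(unlist(pool_loci[locus_assign[[ck]]]))]),
      caller_ids),
    planted_flagged = planted,
    artifact_pool = baits$bait_id[artifact_baits_idx],
    n_clean_cnvs = cfg$n_truth_cnvs,
    truth_filter_audit = flt$audit)

  structure(list(baits = baits, genome = genome, mappability = mappability,
                 segdups = segdups, array_cnvs = array_cnvs, calls = calls,
                 counts = counts, total_reads = total_reads,
                 truth = truth, manifest = manifest, config = cfg),
            class = "sim_bundle")
}

#' Emulate one caller's cohort-wide call set
#'
#' Detection model: every truth exon unit of the caller's cohort is called
#' with probability `profile$sensitivity`; every artifact locus is called,
#' spanning its full bait run, in each sample independently with probability
#' `profile$artifact_recurrence`; sporadic false positives land on
#' non-artifact baits at `profile$sporadic_fp_rate` per bait per sample with
#' a random type. Calls are emitted at bait granularity (one row per called
#' bait), which is the unit every downstream stage counts in.
#'
#' @param caller_id caller name written into the calls.
#' @param profile profile list (see [sim_config()]).
#' @param truth a `truth_exon_set`.
#' @param baits sorted bait table.
#' @param samples full cohort sample roster.
#' @param artifact_loci list of integer vectors of bait row indices.
#' @param artifact_bait_pool bait row indices excluded from sporadic FPs.
#' @return call data.frame (`chrom start end type sample caller`).
#' @export
emulate_caller <- function(caller_id, profile, truth, baits, samples,
                           artifact_loci, artifact_bait_pool = integer()) {
  nb <- nrow(baits)
  parts <- list()

  # truth detection
  te <- truth$exons
  if (nrow(te)) {
    hit <- stats::runif(nrow(te)) < profile$sensitivity
    det <- te[hit, , drop = FALSE]
    if (nrow(det)) {
      idx <- match(det$bait_id, baits$bait_id)
      parts$truth <- data.frame(chrom = baits$chrom[idx],
                                start = baits$start[idx],
                                end = baits$end[idx],
                                type = det$truth_type, sample = det$sample,
                                caller = rep(caller_id, nrow(det)),
                                stringsAsFactors = FALSE)
    }
  }

  # recurrent artifact loci
  art <- list()
  for (loc in artifact_loci) {
    typ <- sample(c("DEL", "DUP"), 1, prob = c(0.7, 0.3))
    called_in <- samples[stats::runif(length(samples)) <
                           profile$artifact_recurrence]
    if (length(called_in)) {
      art[[length(art) + 1L]] <- data.frame(
        chrom = baits$chrom[rep(loc, length(called_in))],
        start = baits$start[rep(loc, length(called_in))],
        end = baits$end[rep(loc, length(called_in))],
        type = typ, sample = rep(called_in, each = length(loc)),
        caller = caller_id, stringsAsFactors = FALSE)
    }
  }
  if (length(art)) parts$artifact <- do.call(rbind, art)

  # sporadic false positives
  free <- setdiff(seq_len(nb), artifact_bait_pool)
  n_fp <- stats::rbinom(length(samples), length(free),
                        profile$sporadic_fp_rate)
  tot <- sum(n_fp)
  if (tot) {
    idx <- unlist(lapply(n_fp, function(k) sample(free, k)))
    parts$sporadic <- data.frame(
      chrom = baits$chrom[idx], start = baits$start[idx],
      end = baits$end[idx],
      type = sample(c("DEL", "DUP"), tot, replace = TRUE),
      sample = rep(samples, n_fp), caller = caller_id,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, parts)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), type = character(),
                      sample = character(), caller = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat("Synthetic cohort: ", length(x$manifest$samples), " samples, ",
      nrow(x$baits), " baits, ", nrow(x$array_cnvs), " array CNVs, ",
      nrow(x$calls), " call units from ",
      length(unique(x$calls$caller)), " callers\n", sep = "")
  invisible(x)
}

#' Write a simulated bundle to disk
#'
#' Emits the bundle as the plain-text formats the pipeline readers consume:
#' `baits.bed`, `genome.fa`, `mappability.bedgraph`, `segdups.bed`,
#' `array_cnvs.tsv` (1-based inclusive, as array exports are),
#' `calls.tsv`, `depth_counts.tsv` + `total_reads.tsv`, and
#' `manifest_planted.tsv`.
#'
#' @param bundle a `sim_bundle`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bed(bundle$baits[c("chrom", "start", "end", "bait_id")],
            file.path(dir, "baits.bed"))
  Biostrings::writeXStringSet(bundle$genome, file.path(dir, "genome.fa"))
  write_bed(bundle$mappability, file.path(dir, "mappability.bedgraph"))
  write_bed(bundle$segdups, file.path(dir, "segdups.bed"))
  ac <- bundle$array_cnvs
  ac$start <- ac$start + 1L            # back to 1-based inclusive on disk
  data.table::fwrite(ac, file.path(dir, "array_cnvs.tsv"), sep = "\t")
  write_calls(bundle$calls, file.path(dir, "calls.tsv"))
  cnt <- data.table::as.data.table(bundle$counts, keep.rownames = "bait_id")
  data.table::fwrite(cnt, file.path(dir, "depth_counts.tsv"), sep = "\t")
  data.table::fwrite(data.frame(sample = names(bundle$total_reads),
                                total_reads = as.numeric(bundle$total_reads)),
                     file.path(dir, "total_reads.tsv"), sep = "\t")
  pl <- bundle$manifest$planted_flagged
  data.table::fwrite(
    data.frame(caller = rep(names(pl), lengths(pl)),
               bait_id = unlist(pl, use.names = FALSE)),
    file.path(dir, "manifest_planted.tsv"), sep = "\t")
  invisible(dir)
}

#' Read a simulated bundle back from disk
#'
#' @param dir directory written by [write_bundle()].
#' @return list with the same table elements as a `sim_bundle` (the genome
#'   as a DNAStringSet).
#' @export
read_bundle <- function(dir) {
  baits <- read_baits(file.path(dir, "baits.bed"))
  counts_dt <- data.table::fread(file.path(dir, "depth_counts.tsv"),
                                 sep = "\t")
  counts <- as.matrix(counts_dt[, -1])
  rownames(counts) <- counts_dt[[1L]]
  totals <- data.table::fread(file.path(dir, "total_reads.tsv"), sep = "\t")
  planted <- data.table::fread(file.path(dir, "manifest_planted.tsv"),
                               sep = "\t", data.table = FALSE)
  list(baits = baits,
       genome = Biostrings::readDNAStringSet(file.path(dir, "genome.fa")),
       mappability = read_bed(file.path(dir, "mappability.bedgraph"),
                              extra_names = "score"),
       segdups = read_bed(file.path(dir, "segdups.bed")),
       array_cnvs = read_array_cnvs(file.path(dir, "array_cnvs.tsv")),
       calls = read_calls(file.path(dir, "calls.tsv")),
       counts = counts,
       total_reads = stats::setNames(totals$total_reads, totals$sample),
       planted_flagged = split(planted$bait_id, planted$caller))
}
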