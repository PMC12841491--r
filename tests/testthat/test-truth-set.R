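baits <- grid_baits(50)

cnv_row <- function(chrom, start, end, sample, type = "DEL",
                    snp_probes = 20L) {
  data.frame(chrom = chrom, start = start, end = end, type = type,
             sample = sample, snp_probes = snp_probes,
             stringsAsFactors = FALSE)
}

test_that("probe-count filter uses a strict lower bound of ten", {
  cnvs <- rbind(cnv_row("1", 0, 500, "s1", snp_probes = 9L),
                cnv_row("1", 1000, 1500, "s2", snp_probes = 10L))
  res <- filter_array_cnvs(cnvs, baits)
  expect_identical(res$audit$status, c("probe_count", "kept"))
  expect_equal(nrow(res$kept), 1L)
})

test_that("polymorphic loci are rejected above four distinct samples", {
  shared5 <- do.call(rbind, lapply(paste0("s", 1:5), function(s)
    cnv_row("1", 100, 600, s)))
  res5 <- filter_array_cnvs(shared5, baits)
  expect_true(all(res5$audit$status == "polymorphic"))

  shared4 <- do.call(rbind, lapply(paste0("s", 1:4), function(s)
    cnv_row("1", 100, 600, s)))
  res4 <- filter_array_cnvs(shared4, baits)
  expect_true(all(res4$audit$status == "kept"))

  # duplicated events from one sample do not inflate the locus count
  dup_sample <- rbind(shared4, cnv_row("1", 150, 550, "s1"))
  expect_true(all(filter_array_cnvs(dup_sample, baits)$audit$status == "kept"))
})

test_that("bait-overlap rule and audit ordering (probe > polymorphic > bait)", {
  off_target <- cnv_row("1", 5100, 5900, "s1")   # beyond last bait end
  expect_identical(filter_array_cnvs(off_target, baits)$audit$status,
                   "no_bait")
  # a CNV failing probe count AND polymorphic AND bait overlap reports the
  # probe rule, the first in the cascade
  many <- do.call(rbind, lapply(paste0("s", 1:6), function(s)
    cnv_row("1", 5100, 5900, s, snp_probes = 3L)))
  expect_true(all(filter_array_cnvs(many, baits)$audit$status ==
                    "probe_count"))
  expect_error(filter_array_cnvs(cnv_row("1", 0, 100, "s1"), baits[0, ]),
               "empty")
})

test_that("manual_pass column is honoured when present", {
  cnvs <- rbind(cnv_row("1", 0, 500, "s1"), cnv_row("1", 1000, 1500, "s2"))
  cnvs$manual_pass <- c(FALSE, TRUE)
  res <- filter_array_cnvs(cnvs, baits)
  expect_identical(res$audit$status, c("manual", "kept"))
})

test_that("filter cascade is monotone in its thresholds", {
  set.seed(44)
  for (rep in 1:5) {
    cnvs <- rand_intervals(40, chroms = c("1", "2"), max_pos = 4500,
                           max_len = 800)
    cnvs$type <- sample(c("DEL", "DUP"), 40, replace = TRUE)
    cnvs$sample <- sample(paste0("s", 1:8), 40, replace = TRUE)
    cnvs$snp_probes <- sample.int(20, 40, replace = TRUE)
    strict <- filter_array_cnvs(cnvs, baits, truth_filter_config(10, 2))
    loose <- filter_array_cnvs(cnvs, baits, truth_filter_config(5, 6))
    key <- function(k) paste(k$chrom, k$start, k$end, k$sample)
    expect_true(all(key(strict$kept) %in% key(loose$kept)))
  }
})

test_that("truth expansion matches the quadratic overlap oracle", {
  one <- cnv_row("1", 10, 460, "s1")   # covers baits 1-5
  truth <- expand_to_truth_exons(one, baits)
  expect_equal(nrow(truth$exons), 5L)
  expect_identical(truth$exons$bait_id, baits$bait_id[1:5])

  set.seed(45)
  cnvs <- rand_intervals(30, chroms = c("1", "2"), max_pos = 4500,
                         max_len = 700)
  cnvs$type <- sample(c("DEL", "DUP"), 30, replace = TRUE)
  cnvs$sample <- sample(paste0("s", 1:6), 30, replace = TRUE)
  truth <- expand_to_truth_exons(cnvs, baits)
  expected <- unique(do.call(rbind, lapply(seq_len(30), function(i) {
    ids <- oracle_baits_hit(cnvs[i, ], baits)
    if (!length(ids)) return(NULL)
    data.frame(sample = cnvs$sample[i], bait_id = ids,
               truth_type = cnvs$type[i], stringsAsFactors = FALSE)
  })))
  expect_equal(nrow(truth$exons), nrow(expected))
  expect_setequal(paste(truth$exons$sample, truth$exons$bait_id,
                        truth$exons$truth_type),
                  paste(expected$sample, expected$bait_id,
                        expected$truth_type))
  # total exon units = DEL units + DUP units
  tab <- table(truth$exons$truth_type)
  expect_equal(sum(tab), nrow(truth$exons))
})

test_that("truth construction is deterministic and round-trips to disk", {
  cnvs <- rbind(cnv_row("1", 0, 500, "s1"), cnv_row("2", 900, 1700, "s2",
                                                    type = "DUP"))
  r1 <- filter_array_cnvs(cnvs, baits)
  r2 <- filter_array_cnvs(cnvs, baits)
  expect_identical(r1, r2)
  truth <- expand_to_truth_exons(r1$kept, baits)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "truth.tsv")
  write_truth_set(truth, baits, p)
  expect_identical(readLines(p), {write_truth_set(truth, baits, p); readLines(p)})

  # array reader converts 1-based inclusive to half-open
  ac <- data.frame(chrom = "1", start = 1, end = 100, type = "DEL",
                   sample = "s1", snp_probes = 12)
  pa <- file.path(dir, "array.tsv")
  data.table::fwrite(ac, pa, sep = "\t")
  back <- read_array_cnvs(pa)
  expect_equal(back$start, 0L)
  expect_equal(back$end, 100)
})
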