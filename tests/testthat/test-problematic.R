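baits <- grid_baits(50)

recur_calls <- function(bait_id, samples, type = "DEL") {
  bait_call(baits, rep(bait_id, length(samples)), samples, type = type)
}

test_that("recurrence flagging is strictly greater-than the threshold", {
  # 18 of 180 is exactly 10%: not flagged; 19 of 180 is
  calls18 <- recur_calls("1_b0005", sprintf("s%03d", 1:18))
  calls19 <- recur_calls("1_b0005", sprintf("s%03d", 1:19))
  rec18 <- bait_recurrence(calls18, baits, cohort_size = 180)
  rec19 <- bait_recurrence(calls19, baits, cohort_size = 180)
  expect_equal(rec18$fraction[rec18$bait_id == "1_b0005"], 0.10)
  expect_length(build_mask(rec18, baits)$flagged_baits, 0L)
  expect_identical(build_mask(rec19, baits)$flagged_baits, "1_b0005")
})

test_that("recurrence counts distinct samples and checks the cohort size", {
  doubled <- rbind(recur_calls("1_b0001", c("a", "b")),
                   recur_calls("1_b0001", c("a", "b"), type = "DUP"))
  rec <- bait_recurrence(doubled, baits, cohort_size = 10)
  expect_equal(rec$n_samples_called[rec$bait_id == "1_b0001"], 2L)
  expect_error(bait_recurrence(recur_calls("1_b0001", letters[1:5]), baits,
                               cohort_size = 3), "smaller")
  mixed <- rbind(recur_calls("1_b0001", "a"), recur_calls("1_b0002", "a"))
  mixed$caller <- c("x", "y")
  expect_error(bait_recurrence(mixed, baits, cohort_size = 5), "per caller")
})

test_that("per-bait recurrence equals a brute-force distinct-sample tally", {
  set.seed(48)
  calls <- rand_intervals(150, chroms = c("1", "2"), max_pos = 4800,
                          max_len = 250)
  calls$type <- sample(c("DEL", "DUP"), 150, replace = TRUE)
  calls$sample <- sample(paste0("s", 1:20), 150, replace = TRUE)
  rec <- bait_recurrence(calls, baits, cohort_size = 20)
  for (i in sample(nrow(baits), 40)) {
    covering <- vapply(seq_len(nrow(calls)), function(j)
      baits$bait_id[i] %in% oracle_baits_hit(calls[j, ], baits), logical(1))
    expect_equal(rec$n_samples_called[i],
                 length(unique(calls$sample[covering])))
  }
})

test_that("mask size is non-increasing in the threshold", {
  set.seed(49)
  calls <- rand_intervals(200, chroms = c("1", "2"), max_pos = 4800,
                          max_len = 400)
  calls$type <- "DEL"
  calls$sample <- sample(paste0("s", 1:15), 200, replace = TRUE)
  rec <- bait_recurrence(calls, baits, cohort_size = 15)
  grid <- c(0.05, 0.10, 0.15, 0.30, 0.60)
  masks <- lapply(grid, function(t) build_mask(rec, baits, threshold = t))
  for (i in seq_along(grid)[-1])
    expect_true(all(masks[[i]]$flagged_baits %in%
                      masks[[i - 1]]$flagged_baits))
  none <- build_mask(data.frame(bait_id = baits$bait_id,
                                n_samples_called = 0L, fraction = 0),
                     baits)
  expect_length(none$flagged_baits, 0L)
  expect_equal(nrow(none$merged_regions), 0L)
})

test_that("RPKM formula: unit case, scale invariance, elementwise oracle", {
  counts <- matrix(10, 1, 1, dimnames = list("b1", "s1"))
  expect_equal(as.numeric(rpkm_normalize(counts, c(b1 = 1000),
                                         total_reads = c(s1 = 1e6))), 10)
  set.seed(50)
  m <- matrix(rpois(60, 40), 10, 6,
              dimnames = list(paste0("b", 1:10), paste0("s", 1:6)))
  len <- setNames(sample(100:2000, 10), rownames(m))
  tot <- setNames(runif(6, 1e5, 1e7), colnames(m))
  r <- rpkm_normalize(m, len, tot)
  for (i in 1:10) for (j in 1:6)
    expect_equal(r[i, j], m[i, j] * 1e9 / (len[[i]] * tot[[j]]))
  expect_equal(rpkm_normalize(2 * m, len, 2 * tot), r)
  bad <- tot; bad["s3"] <- 0
  expect_error(rpkm_normalize(m, len, bad), "s3")
})

test_that("RPKM CV uses the n-1 standard deviation and NA at zero mean", {
  m <- rbind(const = c(5, 5, 5), pair = c(1, 3, NA), zero = c(0, 0, 0))
  expect_equal(unname(rpkm_cv(m[c(1, 3), ])["const"]), 0)
  cv <- rpkm_cv(matrix(c(1, 3), 1, dimnames = list("pair", NULL)))
  expect_equal(unname(cv), sqrt(2) / 2)        # sd([1,3]) / mean = 1.414/2
  expect_true(is.na(rpkm_cv(m[c(1, 3), ])["zero"]))
  expect_error(rpkm_cv(matrix(1:3, 3, 1)), "two samples")
})

test_that("GC content counts G+C over non-N bases", {
  b <- data.frame(chrom = "z", start = c(0, 4, 8), end = c(4, 8, 12),
                  bait_id = c("x", "y", "w"), stringsAsFactors = FALSE)
  seqs <- Biostrings::DNAStringSet(c(z = "ATGCGGGGANNN"))
  gc <- gc_content(b, seqs)
  expect_equal(unname(gc["x"]), 0.5)      # ATGC
  expect_equal(unname(gc["y"]), 1.0)      # GGGG
  expect_equal(unname(gc["w"]), 0.0)      # ANNN -> A only
  expect_error(gc_content(data.frame(chrom = "z", start = 0, end = 99,
                                     bait_id = "q"), seqs), "beyond")

  set.seed(51)
  toy <- paste(sample(c("A", "C", "G", "T", "N"), 10000, replace = TRUE,
                      prob = c(.3, .2, .2, .29, .01)), collapse = "")
  bb <- make_baits(50, "t", spacing = 190, width = 80)
  got <- gc_content(bb, c(t = toy))
  chars <- strsplit(toy, "")[[1]]
  for (i in seq_len(50)) {
    win <- chars[(bb$start[i] + 1):bb$end[i]]
    expect_equal(unname(got[i]), sum(win %in% c("G", "C")) /
                   sum(win != "N"))
  }
})

test_that("bait annotation averages mappability per base and marks segdups", {
  b <- make_baits(3, "1", spacing = 200, width = 100)
  full <- data.frame(chrom = "1", start = 0, end = 1000, score = 1.0)
  ann <- annotate_baits(b, mappability = full)
  expect_equal(ann$mappability, rep(1, 3))

  halves <- data.frame(chrom = "1", start = c(0, 50), end = c(50, 2000),
                       score = c(0, 1))
  ann2 <- annotate_baits(b, mappability = halves)
  expect_equal(ann2$mappability[1], 0.5)     # half score-0, half score-1
  expect_equal(ann2$mappability[2:3], c(1, 1))

  set.seed(52)
  segs <- data.frame(chrom = "1",
                     start = seq(0, 580, by = 20), end = seq(20, 600, by = 20),
                     score = runif(30))
  ann3 <- annotate_baits(b, mappability = segs)
  for (i in 1:3) {
    base_scores <- rep(NA_real_, 600)
    for (j in seq_len(nrow(segs)))
      base_scores[(segs$start[j] + 1):segs$end[j]] <- segs$score[j]
    expect_equal(ann3$mappability[i],
                 mean(base_scores[(b$start[i] + 1):b$end[i]]))
  }
  # no coverage -> NA
  ann4 <- annotate_baits(b, mappability = data.frame(chrom = "1", start = 0,
                                                     end = 10, score = 1))
  expect_true(is.na(ann4$mappability[2]))

  sd <- data.frame(chrom = "1", start = 150, end = 260)
  ann5 <- annotate_baits(b, segdups = sd)
  expect_identical(ann5$segdup, c(FALSE, TRUE, FALSE))
  expect_equal(ann5$segdup_fraction[2], 0.6)   # 60 of 100 bases covered
})

test_that("feature resampling: null behaviour, separation, reproducibility", {
  set.seed(53)
  n <- 400
  feats <- data.frame(bait_id = paste0("b", 1:n),
                      mappability = runif(n), gc = runif(n),
                      rpkm_cv = runif(n), stringsAsFactors = FALSE)
  flag <- paste0("b", 1:200)
  mask <- structure(list(caller = "x", flagged_baits = flag,
                         merged_regions = data.frame(), threshold = 0.1),
                    class = "problematic_mask")
  null_res <- compare_features(feats, mask, n_iter = 40, seed = 9)
  expect_gt(min(null_res$summary$median_p), 0.05)   # same distribution

  sep <- feats
  sep$mappability[1:50] <- sep$mappability[1:50] + 10  # flagged all larger
  mask50 <- structure(list(caller = "x", flagged_baits = paste0("b", 1:50),
                           merged_regions = data.frame(), threshold = 0.1),
                      class = "problematic_mask")
  sep_res <- compare_features(sep, mask50, feature_cols = "mappability",
                              n_iter = 25, seed = 9)
  expect_true(all(sep_res$iterations$p < 0.001))
  expect_identical(sep_res$summary$direction, "higher")

  r1 <- compare_features(feats, mask, n_iter = 15, seed = 123)
  r2 <- compare_features(feats, mask, n_iter = 15, seed = 123)
  expect_identical(r1, r2)

  empty <- structure(list(caller = "x", flagged_baits = character(),
                          merged_regions = data.frame(), threshold = 0.1),
                     class = "problematic_mask")
  expect_error(compare_features(feats, empty), "no problematic")
})
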