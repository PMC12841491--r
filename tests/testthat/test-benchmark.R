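baits <- grid_baits(50)

simple_truth <- function() {
  make_truth(data.frame(
    sample = c("s1", "s1", "s2"),
    bait_id = c("1_b0001", "1_b0002", "2_b0010"),
    truth_type = c("DEL", "DEL", "DUP"), stringsAsFactors = FALSE))
}

test_that("no calls yields all-FN; identical calls yield perfect metrics", {
  truth <- simple_truth()
  empty <- bait_call(baits, character(), character())
  cls0 <- classify_calls(empty, truth, baits)
  m0 <- benchmark_metrics(cls0)
  expect_equal(m0$tp, 0L)
  expect_equal(m0$fn, 3L)
  expect_equal(m0$fp, 0L)
  expect_true(is.na(m0$ppv))    # undefined, not zero

  exact <- bait_call(baits, truth$exons$bait_id, truth$exons$sample,
                     type = truth$exons$truth_type)
  m1 <- benchmark_metrics(classify_calls(exact, truth, baits))
  expect_equal(m1$sensitivity, 1)
  expect_equal(m1$ppv, 1)
  expect_equal(m1$truth, 3L)
})

test_that("type-aware mode counts a wrong-type call as FP plus FN", {
  truth <- make_truth(data.frame(sample = "s1", bait_id = "1_b0001",
                                 truth_type = "DUP"))
  del_call <- bait_call(baits, "1_b0001", "s1", type = "DEL")
  aware <- benchmark_metrics(classify_calls(del_call, truth, baits,
                                            type_aware = TRUE))
  expect_equal(c(aware$tp, aware$fp, aware$fn), c(0L, 1L, 1L))
  pooled <- benchmark_metrics(classify_calls(del_call, truth, baits,
                                             type_aware = FALSE))
  expect_equal(c(pooled$tp, pooled$fp, pooled$fn), c(1L, 0L, 0L))
})

test_that("duplicate calls collapse to one unit; unknown samples error", {
  truth <- simple_truth()
  dup <- bait_call(baits, rep("1_b0001", 3), rep("s1", 3))
  m <- benchmark_metrics(classify_calls(dup, truth, baits))
  expect_equal(m$tp, 1L)
  expect_equal(m$fp, 0L)
  stranger <- bait_call(baits, "1_b0001", "nobody")
  expect_error(classify_calls(stranger, truth, baits), "nobody")
})

test_that("classification counts equal the set-algebra oracle on fixtures", {
  set.seed(46)
  samples <- paste0("s", 1:10)
  for (rep in 1:5) {
    truth_df <- unique(data.frame(
      sample = sample(samples, 60, replace = TRUE),
      bait_id = sample(baits$bait_id, 60, replace = TRUE),
      truth_type = sample(c("DEL", "DUP"), 60, replace = TRUE),
      stringsAsFactors = FALSE))
    truth_df <- truth_df[!duplicated(truth_df[c("sample", "bait_id")]), ]
    truth <- make_truth(truth_df)
    calls <- rand_intervals(80, chroms = c("1", "2"), max_pos = 4800,
                            max_len = 300)
    calls$type <- sample(c("DEL", "DUP"), 80, replace = TRUE)
    calls$sample <- sample(samples, 80, replace = TRUE)
    calls$caller <- "x"
    for (aware in c(TRUE, FALSE)) {
      m <- benchmark_metrics(classify_calls(calls, truth, baits,
                                            type_aware = aware))
      o <- oracle_classify(calls, truth$exons, baits, type_aware = aware)
      expect_equal(m$tp, o$tp)
      expect_equal(m$fn, o$fn)
      expect_equal(m$fp, o$fp)
      expect_equal(m$tp + m$fn, m$truth)
    }
  }
})

test_that("extra FPs never change sensitivity; extra TPs never lower PPV", {
  truth <- simple_truth()
  calls <- bait_call(baits, c("1_b0001", "1_b0020"), c("s1", "s2"),
                     type = c("DEL", "DEL"))
  base <- benchmark_metrics(classify_calls(calls, truth, baits))
  plus_fp <- rbind(calls, bait_call(baits, "1_b0030", "s2", type = "DUP"))
  with_fp <- benchmark_metrics(classify_calls(plus_fp, truth, baits))
  expect_equal(with_fp$sensitivity, base$sensitivity)
  plus_tp <- rbind(calls, bait_call(baits, "1_b0002", "s1", type = "DEL"))
  with_tp <- benchmark_metrics(classify_calls(plus_tp, truth, baits))
  expect_gte(with_tp$ppv, base$ppv)
})

test_that("concordance: shared and specific fractions, union sensitivity", {
  truth <- simple_truth()
  same <- rbind(bait_call(baits, truth$exons$bait_id, truth$exons$sample,
                          type = truth$exons$truth_type, caller = "a"),
                bait_call(baits, truth$exons$bait_id, truth$exons$sample,
                          type = truth$exons$truth_type, caller = "b"))
  cc <- caller_concordance(classify_calls(same, truth, baits))
  expect_equal(cc$per_caller$shared_fraction, c(1, 1))
  expect_equal(cc$union_sensitivity, 1)

  disjoint <- rbind(bait_call(baits, "1_b0001", "s1", "DEL", caller = "a"),
                    bait_call(baits, "1_b0002", "s1", "DEL", caller = "a"),
                    bait_call(baits, "2_b0010", "s2", "DUP", caller = "b"))
  cc2 <- caller_concordance(classify_calls(disjoint, truth, baits))
  expect_equal(cc2$union_sensitivity, 1)
  expect_equal(cc2$per_caller$specific_fraction, c(1, 1))
  expect_gte(cc2$union_sensitivity, max(cc2$per_caller$sensitivity))
})

test_that("concordance union counts equal a brute-force bitmask tally", {
  set.seed(47)
  samples <- paste0("s", 1:6)
  truth_df <- unique(data.frame(
    sample = sample(samples, 40, replace = TRUE),
    bait_id = sample(baits$bait_id, 40, replace = TRUE),
    truth_type = "DEL", stringsAsFactors = FALSE))
  truth <- make_truth(truth_df)
  callers <- paste0("c", 1:4)
  picks <- lapply(callers, function(ck) truth_df[sample(nrow(truth_df), 20), ])
  names(picks) <- callers
  calls <- do.call(rbind, lapply(callers, function(ck)
    bait_call(baits, picks[[ck]]$bait_id, picks[[ck]]$sample, type = "DEL",
              caller = ck)))
  cls <- classify_calls(calls, truth, baits)
  cc <- caller_concordance(cls)
  # oracle: per truth unit, bitmask over callers with a TP
  mask <- sapply(callers, function(ck) {
    key <- paste(picks[[ck]]$sample, picks[[ck]]$bait_id)
    paste(truth_df$sample, truth_df$bait_id) %in% key
  })
  counts <- rowSums(mask)
  expect_equal(unname(as.integer(cc$detected_by)),
               unname(as.integer(table(factor(counts, levels = 0:4)))))
  expect_equal(cc$union_sensitivity, mean(counts > 0))
})

test_that("published-counts helper reproduces ratios and flags empty calls", {
  m <- metrics_from_counts(tp = 2114, fp = 83135, fn = 674)
  expect_equal(round(m$sensitivity, 3), 0.758)
  expect_equal(round(m$ppv, 3), 0.025)
  expect_true(is.na(metrics_from_counts(0, 0, 5)$ppv))
})
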