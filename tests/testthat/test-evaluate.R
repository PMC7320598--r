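make_records <- function(ids, hscore, opt, unaligned = rep(FALSE, length(ids))) {
  data.frame(qname = ids, score = hscore, unaligned = unaligned,
             stringsAsFactors = FALSE)
}

test_that("correct-by-score status follows the definition exactly", {
  heur <- make_records(c("a", "b", "c"), c(-12L, -20L, NA),
                       unaligned = c(FALSE, FALSE, TRUE))
  opt <- data.frame(id = c("a", "b", "c"), best_score = c(-12L, -12L, -80L))
  a <- score_audit(heur, opt)
  expect_equal(a$records$status, c("correct_by_score", "incorrect_by_score",
                                   "unaligned"))
  # unaligned reads are counted, as not correct
  expect_equal(sum(a$summary$n), 3L)
})

test_that("a heuristic score above the optimum raises a scoring-mismatch error", {
  heur <- make_records("a", -5L)
  opt <- data.frame(id = "a", best_score = -10L)
  expect_error(score_audit(heur, opt), "scoring mismatch.*'a'")
  expect_error(score_audit(make_records("zz", -5L),
                           data.frame(id = "a", best_score = 0L)),
               "'zz'.*absent")
})

test_that("self-comparison is 100% correct in every score bin", {
  set.seed(79)
  n <- 60
  opt <- data.frame(id = paste0("r", 1:n),
                    best_score = sample(-90:0, n, replace = TRUE))
  heur <- make_records(opt$id, opt$best_score)
  a <- score_audit(heur, opt)
  expect_true(all(a$summary$frac_correct == 1))
  expect_true(all(a$summary$frac_incorrect == 0))
  expect_true(all(a$summary$frac_unaligned == 0))
})

test_that("status fractions partition every bin and the whole set", {
  set.seed(83)
  n <- 200
  opt <- data.frame(id = paste0("r", 1:n),
                    best_score = sample(-120:0, n, replace = TRUE))
  hscore <- opt$best_score - sample(0:12, n, replace = TRUE)
  unaligned <- runif(n) < 0.15
  heur <- make_records(opt$id, ifelse(unaligned, NA, hscore), unaligned = unaligned)
  a <- score_audit(heur, opt, bin_width = 25)
  sums <- a$summary$frac_correct + a$summary$frac_incorrect + a$summary$frac_unaligned
  expect_equal(sums, rep(1, nrow(a$summary)))
  expect_equal(sum(a$summary$n), n)
  tab <- table(a$records$status)
  expect_equal(sum(tab), n)
})

test_that("location correctness applies the bp tolerance on anchored coordinates", {
  heur <- data.frame(qname = c("a", "b", "c"), pos = c(1000L, 1000L, 500L),
                     rname = "ref", unaligned = c(FALSE, FALSE, FALSE),
                     stringsAsFactors = FALSE)
  truth <- data.frame(id = c("a", "b", "c"), coord = c(1003L, 1006L, 500L))
  la <- location_audit(heur, truth, tolerance = 5)
  expect_equal(la$records$correct, c(TRUE, FALSE, TRUE))
  la0 <- location_audit(heur, truth, tolerance = 0)
  expect_equal(la0$records$correct, c(FALSE, FALSE, TRUE))
  expect_error(location_audit(heur, truth[1:2, ]), "no truth entry")
})

test_that("leftmost CIGAR positions convert to rightmost-base anchors", {
  # 30M starting at 101 ends at 130; a 1 bp deletion extends the span by one
  heur <- data.frame(qname = c("a", "b"), pos = c(101L, 101L),
                     cigar = c("30M", "15M1D15M"),
                     unaligned = c(FALSE, FALSE), stringsAsFactors = FALSE)
  truth <- data.frame(id = c("a", "b"), coord = c(130L, 131L))
  la <- location_audit(heur, truth, tolerance = 0)
  expect_true(all(la$records$correct))
})

test_that("MAPQ calibration recovers the phred-scale error definition", {
  rec <- data.frame(mapq = rep(10L, 1000), correct = rep(c(FALSE, TRUE), c(100, 900)))
  cal <- mapq_calibration(rec)
  expect_equal(cal$empirical_mapq, 10, tolerance = 1e-12)
  expect_equal(cal$n, 1000L)
  # zero-incorrect bins are capped and flagged, never infinite
  rec2 <- data.frame(mapq = 30L, correct = TRUE)
  cal2 <- mapq_calibration(rec2)
  expect_equal(cal2$empirical_mapq, 60)
  expect_true(cal2$capped)
  expect_equal(nrow(mapq_calibration(data.frame(mapq = integer(0),
                                                correct = logical(0)))), 0L)
})

test_that("sweep ratios are 1.00 against itself and match hand computation", {
  set.seed(89)
  n <- 50
  opt <- data.frame(id = paste0("r", 1:n), best_score = sample(-50:0, n, TRUE))
  # baseline: reads 1..40 aligned, 39-40 suboptimal by 3, the rest unaligned
  base_scores <- opt$best_score - c(rep(0L, 38), 3L, 3L, rep(0L, 10))
  base <- score_audit(make_records(opt$id, ifelse(seq_len(n) <= 40, base_scores, NA),
                                   unaligned = seq_len(n) > 40), opt)
  sw <- sweep_report(list(default = list(records = base$records, time = 10),
                          default2 = list(records = base$records, time = 10)),
                     baseline = "default")
  expect_equal(unname(sw$ratios[, "default"]), rep(1, 5))
  expect_equal(unname(sw$ratios[, "default2"]), rep(1, 5))

  # hand-computed: 41 aligned (2 suboptimal by 2), halved time
  tuned_scores <- opt$best_score - c(rep(0L, 39), 2L, 2L, rep(0L, 9))
  run2 <- score_audit(make_records(opt$id, ifelse(seq_len(n) <= 41, tuned_scores, NA),
                                   unaligned = seq_len(n) > 41), opt)
  sw2 <- sweep_report(list(default = list(records = base$records, time = 10),
                           tuned = list(records = run2$records, time = 5)),
                      baseline = "default")
  expect_equal(unname(sw2$ratios["pct_aligned", "tuned"]), 41 / 40)
  expect_equal(unname(sw2$ratios["pct_correct_score", "tuned"]), 39 / 38)
  expect_equal(unname(sw2$ratios["mean_as_diff_incorrect", "tuned"]), 2 / 3)
  expect_equal(unname(sw2$ratios["mean_as_diff_aligned", "tuned"]),
               (4 / 41) / (6 / 40))
  expect_equal(unname(sw2$ratios["time", "tuned"]), 0.5)

  expect_error(sweep_report(list(a = list(records = base$records, time = 1),
                                 b = list(records = base$records[-1, ], time = 1)),
                            baseline = "a"),
               "same read set")
  expect_error(sweep_report(list(a = list(records = base$records, time = 1)),
                            baseline = "zz"),
               "not among")
})

test_that("an aligned-fraction gain of 2% reports as ratio 1.02", {
  n <- 100
  opt <- data.frame(id = paste0("r", 1:n), best_score = rep(-10L, n))
  base <- score_audit(make_records(opt$id, ifelse(seq_len(n) <= 50, -10L, NA),
                                   unaligned = seq_len(n) > 50), opt)
  more <- score_audit(make_records(opt$id, ifelse(seq_len(n) <= 51, -10L, NA),
                                   unaligned = seq_len(n) > 51), opt)
  sw <- sweep_report(list(default = list(records = base$records, time = 1),
                          vg = list(records = more$records, time = 1)),
                     baseline = "default")
  expect_equal(unname(sw$ratios["pct_aligned", "vg"]), 1.02)
})
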