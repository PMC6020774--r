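test_that("the standard design has the documented structure", {
  d <- study_design()
  expect_equal(length(d$list_values), 24)
  expect_equal(mean(d$list_values), 6.5)
  expect_equal(sum(d$list_values == 12), 4)
  expect_error(study_design(high_values = c(2, 3), low_values = c(1, 4)),
               "high value")
})

test_that("list scoring matches the worked example and hand-derived cases", {
  sc <- score_list(worked_example_record())
  expect_equal(sc$actual, 45)
  expect_equal(sc$chance, 26)
  expect_equal(sc$ideal, 48)
  expect_equal(round(selectivity_index(sc), 2), 0.86)
  expect_equal(sc$n_high_recalled, 4)
  expect_equal(sc$n_low_recalled, 0)

  # zero recall: everything zero, selectivity undefined
  d <- study_design()
  sc0 <- score_list(recall_record(d$list_values, logical(24)))
  expect_equal(sc0$actual, 0)
  expect_equal(sc0$chance, 0)
  expect_equal(sc0$ideal, 0)
  expect_true(is.na(sc0$selectivity))
  expect_error(selectivity_index(sc0), "undefined")

  # low-value-preferring recall {1,2,3}: (6 - 19.5)/(36 - 19.5)
  idx <- c(which(d$list_values == 1)[1], which(d$list_values == 2)[1],
           which(d$list_values == 3)[1])
  sc_low <- score_list(recall_record(d$list_values, idx))
  expect_equal(sc_low$selectivity, (6 - 19.5) / (36 - 19.5), tolerance = 1e-12)

  # perfectly selective: the four 12-point words
  sc_top <- score_list(recall_record(d$list_values, which(d$list_values == 12)))
  expect_equal(selectivity_index(sc_top), 1)

  # full recall: denominator collapses
  sc_all <- score_list(recall_record(d$list_values, !logical(24)))
  expect_equal(sc_all$actual, 156)
  expect_true(is.na(sc_all$selectivity))

  expect_error(recall_record(numeric(0), logical(0)), "at least one")
})

test_that("selectivity <= 1 over all subsets of a toy list (brute force)", {
  values <- c(1, 2, 3, 10, 11, 12)
  for (bits in 0:63) {
    idx <- which(bitwAnd(bits, 2^(0:5)) > 0)
    if (length(idx) == 0 || length(idx) == 6) next
    oracle <- brute_force_score(values, idx)
    sc <- score_list(recall_record(values, idx),
                     design = study_design(words_per_list = 6,
                                           n_high_per_list = 3,
                                           n_low_per_list = 3))
    expect_equal(sc$selectivity, oracle$selectivity, tolerance = 1e-12)
    expect_lte(sc$selectivity, 1 + 1e-12)
  }
})

test_that("a uniformly random recalled subset has mean selectivity near 0", {
  set.seed(7)
  d <- study_design()
  n_draws <- 20000
  sel <- numeric(0)
  rec <- matrix(runif(n_draws * 24) < 0.5, n_draws, 24)
  for (i in seq_len(n_draws)) {
    s <- score_list(recall_record(d$list_values, rec[i, ]))
    if (!is.na(s$selectivity)) sel <- c(sel, s$selectivity)
  }
  se <- sd(sel) / sqrt(length(sel))
  expect_lt(abs(mean(sel)), 3 * se)
})

test_that("scores are invariant to word order and chance is 6.5 * n_recalled", {
  set.seed(11)
  d <- study_design()
  for (rep in 1:20) {
    idx <- sample(24, sample(1:23, 1))
    perm <- sample(24)
    a <- score_list(recall_record(d$list_values, seq_len(24) %in% idx))
    b <- score_list(recall_record(d$list_values[perm],
                                  perm %in% idx))
    expect_equal(a[c("actual", "chance", "ideal", "selectivity")],
                 b[c("actual", "chance", "ideal", "selectivity")])
    expect_equal(a$chance, 6.5 * length(idx))
  }
})

test_that("subject summaries average lists and drop undefined selectivity", {
  d <- study_design()
  top4 <- recall_record(d$list_values, which(d$list_values == 12))
  s <- subject_summary(rep(list(top4), 5))
  expect_equal(s$mean_high_recall, 4)
  expect_equal(s$mean_low_recall, 0)
  expect_equal(s$mean_selectivity, 1)
  expect_equal(s$n_lists_scored, 5)

  # worked example + an all-recalled list: undefined list excluded from the
  # selectivity mean only
  full <- recall_record(d$list_values, !logical(24))
  s2 <- subject_summary(list(worked_example_record(), full))
  expect_equal(s2$mean_selectivity, selectivity_index(score_list(worked_example_record())))
  expect_equal(s2$mean_high_recall, (4 + 12) / 2)

  # nothing recalled on any list
  none <- recall_record(d$list_values, logical(24))
  s3 <- subject_summary(list(none, none))
  expect_equal(s3$mean_high_recall, 0)
  expect_equal(s3$mean_low_recall, 0)
  expect_true(is.na(s3$mean_selectivity))
})

test_that("paired and one-sample t match hand arithmetic and conventions", {
  pt1 <- paired_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(pt1$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(pt1$df, 2)
  # t = 0 when x == y elementwise up to centering
  expect_equal(paired_t(c(1, 2, 3), c(3, 2, 1))$t, 0)
  expect_warning(out <- paired_t(c(2, 3, 4), c(1, 2, 3)), "zero variance")
  expect_true(is.infinite(out$t))

  ot <- one_sample_t(c(0.5, 0.6, 0.7), 0)
  expect_equal(ot$t, 0.6 / (0.1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(one_sample_t(c(-1, 0, 1), 0)$t, 0)
  expect_equal(one_sample_t(rnorm(19))$df, 18)
  # cross-check p-value against stats::t.test on a non-degenerate case
  x <- c(0.61, 0.43, 0.70, 0.52, 0.66)
  expect_equal(one_sample_t(x, 0.5)$p,
               stats::t.test(x, mu = 0.5)$p.value, tolerance = 1e-12)
})

test_that("behavioral TSV round trip validates and rescores identically", {
  cfg <- effect_config(n_subjects = 5, seed = 31)
  trials <- simulate_recall(draw_traits(cfg), study_design(), cfg, seed = 32)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(trials, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_recall_tsv(path)
  expect_equal(score_cohort_behavior(back), score_cohort_behavior(trials))

  bad <- trials
  bad$value[1] <- 7
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_recall_tsv(path2), "value")
})

test_that("vectorized cohort scoring agrees with the per-list reference", {
  cfg <- effect_config(n_subjects = 12, seed = 41)
  trials <- simulate_recall(draw_traits(cfg), study_design(), cfg, seed = 42)
  fast <- score_cohort_behavior(trials)
  for (id in unique(trials$subject_id)) {
    sub <- trials[trials$subject_id == id, ]
    recs <- lapply(split(sub, sub$list_id), function(ls)
      recall_record(ls$value, as.logical(ls$recalled)))
    ref <- subject_summary(recs)
    row <- fast[fast$subject_id == id, ]
    expect_equal(row$mean_high_recall, ref$mean_high_recall)
    expect_equal(row$mean_low_recall, ref$mean_low_recall)
    expect_equal(row$mean_selectivity, ref$mean_selectivity)
  }
})
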