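test_that("stage extraction restricts to the window on the same grid", {
  s <- random_series(601, seed = 1)
  seg <- extract_stage(s, c(0, 300))
  expect_equal(length(seg$values), 301)
  expect_equal(seg$values, s$values[1:301])
  expect_equal(seg$start_time, 0)

  expect_error(extract_stage(s, c(500, 900)), class = "hrv_range_error")
  expect_error(extract_stage(s, c(0, 100), role = "stage1"),
               class = "hrv_validation_error")
  expect_error(extract_stage(s, c(0, 250), role = "stage2"),
               class = "hrv_validation_error")
  # validity mask carried over
  s$valid[10] <- FALSE
  expect_false(extract_stage(s, c(0, 300))$valid[10])
})

test_that("stage_spec enforces lengths and non-overlap", {
  expect_s3_class(stage_spec(c(0, 300), c(900, 1200)), "stage_spec")
  expect_error(stage_spec(c(0, 100), c(900, 1200)),
               class = "hrv_validation_error")
  expect_error(stage_spec(c(0, 300), c(900, 1100)),
               class = "hrv_validation_error")
  expect_error(stage_spec(c(700, 1000), c(900, 1200)),
               class = "hrv_validation_error")
})

test_that("summaries use linear-interpolation quartiles", {
  s <- summarize_values(c(1, 2, 3, 4))
  expect_equal(s$mean, 2.5)
  expect_equal(s$median, 2.5)
  expect_equal(s$iqr, 1.5) # Q1 = 1.75, Q3 = 3.25

  one <- summarize_values(5)
  expect_equal(one$mean, 5)
  expect_equal(one$median, 5)
  expect_equal(one$iqr, 0)

  const <- summarize_values(rep(2, 4))
  expect_equal(const$median, 2)
  expect_equal(const$iqr, 0)

  expect_error(summarize_values(numeric(0)), class = "hrv_insufficient_data")

  # agreement with an independent quantile route and translation equivariance
  withr::with_seed(8, {
    for (i in 1:10) {
      x <- rnorm(sample(3:30, 1))
      sm <- summarize_values(x)
      expect_equal(sm$iqr, unname(diff(quantile(x, c(0.25, 0.75)))),
                   tolerance = 1e-12)
      sh <- summarize_values(x + 11.5)
      expect_equal(sh$mean, sm$mean + 11.5, tolerance = 1e-12)
      expect_equal(sh$median, sm$median + 11.5, tolerance = 1e-12)
      expect_equal(sh$iqr, sm$iqr, tolerance = 1e-12)
    }
  })
})

test_that("rank-sum worked examples hold", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1)
  expect_true(r$exact)

  self <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(self$p_value, 1.0)
  expect_false(self$exact) # ties force the midrank normal approximation

  expect_error(rank_sum_test(numeric(0), 1:3),
               class = "hrv_insufficient_data")
})

test_that("exact branch agrees with full enumeration of labelings", {
  withr::with_seed(17, {
    for (i in 1:30) {
      na <- sample(2:5, 1)
      nb <- sample(2:5, 1)
      pooled <- sample(seq_len(50), na + nb) # distinct values, no ties
      a <- pooled[seq_len(na)]
      b <- pooled[-seq_len(na)]
      r <- rank_sum_test(a, b)
      expect_true(r$exact)
      expect_equal(r$p_value, ranksum_enumeration_oracle(a, b),
                   tolerance = 1e-12)
    }
  })
})

test_that("rank-sum is symmetric in its groups and U_a + U_b = n_a n_b", {
  withr::with_seed(23, {
    for (i in 1:15) {
      a <- rnorm(sample(3:12, 1))
      b <- rnorm(sample(3:12, 1), mean = 0.5)
      ra <- rank_sum_test(a, b)
      rb <- rank_sum_test(b, a)
      expect_equal(ra$p_value, rb$p_value, tolerance = 1e-12)
      expect_equal(ra$U + rb$U, length(a) * length(b))
    }
  })
})

make_cohort_frame <- function(seed, suppression = NULL, n = 18) {
  resting <- synthetic_config(duration = 1500)
  transition <- if (is.null(suppression)) NULL else {
    transition_config(t0 = 300, suppression_factor = suppression)
  }
  co <- generate_cohort(n, resting, transition, seed = seed)
  cohort_stage_descriptors(co$recordings,
                           stage_spec(c(0, 300), c(900, 1200)))
}

test_that("an anesthesia cohort shows significant SD1 and SD2 decreases", {
  ps <- make_cohort_frame(seed = 101, suppression = 0.3)
  report <- compare_stages(ps)
  expect_s3_class(report, "stage_comparison_report")
  for (metric in c("sd1", "sd2")) {
    m <- report[[metric]]
    expect_lt(m$stage2$median, m$stage1$median)
    expect_lt(m$p_value, 0.05)
    expect_true(m$significant)
  }
  expect_equal(report$n_subjects, 18)
})

test_that("a resting cohort shows no significant stage difference", {
  ps <- make_cohort_frame(seed = 202, suppression = NULL)
  report <- compare_stages(ps)
  expect_gte(report$sd1$p_value, 0.05)
  expect_gte(report$sd2$p_value, 0.05)
  expect_false(report$sd1$significant)
})

test_that("subjects missing a stage are excluded with a warning", {
  ps <- make_cohort_frame(seed = 303, suppression = 0.3, n = 4)
  ps <- ps[!(ps$subject == "S02" & ps$stage == "stage2"), ]
  expect_warning(report <- compare_stages(ps), "S02")
  expect_equal(report$n_subjects, 3)
  expect_equal(report$excluded, "S02")
})

test_that("fewer than two complete subjects is an error", {
  ps <- data.frame(subject = "S01", stage = c("stage1", "stage2"),
                   sd1 = c(2, 1), sd2 = c(5, 2))
  expect_error(compare_stages(ps), class = "hrv_insufficient_data")
})

test_that("the report serializes to JSON with both metrics and p-values", {
  ps <- make_cohort_frame(seed = 404, suppression = 0.3, n = 6)
  report <- compare_stages(ps)
  f <- withr::local_tempfile(fileext = ".json")
  report_to_json(report, f)
  parsed <- jsonlite::fromJSON(f)
  expect_true(all(c("sd1", "sd2", "alpha", "n_subjects") %in% names(parsed)))
  expect_true(parsed$sd1$p_value >= 0 && parsed$sd1$p_value <= 1)
  expect_equal(parsed$sd2$stage1$n, 6)
})
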