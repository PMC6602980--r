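test_that("window_spec validates its fields and warns outside 5-120 s", {
  expect_error(window_spec(step = 25), class = "hrv_config_error")
  expect_error(window_spec(min_pairs = 1), class = "hrv_config_error")
  expect_warning(window_spec(window_length = 200, step = 5),
                 "outside the investigated")
  spec <- window_spec()
  expect_equal(spec$window_length, 20)
  expect_equal(spec$step, 5)
  expect_equal(spec$min_pairs, 3L)
})

test_that("a 60 s series at 1 Hz yields 9 emissions at t = 20, 25, ..., 60", {
  s <- random_series(61, seed = 2)
  tr <- sliding_trace(s, window_spec(20, 5))
  expect_equal(nrow(tr), 9)
  expect_equal(tr$t_end, seq(20, 60, by = 5))
  expect_true(all(tr$n_pairs == 20))
  expect_false(anyNA(tr$sd1))
})

test_that("a series shorter than one window gives an empty trace", {
  tr <- sliding_trace(random_series(15, seed = 4), window_spec(20, 5))
  expect_s3_class(tr, "sliding_window_trace")
  expect_equal(nrow(tr), 0)
})

test_that("a constant series emits sd1 = sd2 = 0 everywhere", {
  tr <- sliding_trace(hr_series(rep(72, 61)), window_spec(20, 5))
  expect_true(all(tr$sd1 == 0))
  expect_true(all(tr$sd2 == 0))
})

test_that("windows with too few valid pairs are emitted as missing rows", {
  s <- random_series(61, seed = 6)
  # invalidate most of the samples in (40, 60] so that window loses its pairs
  s$valid[43:61] <- c(rep(FALSE, 17), TRUE, TRUE)
  tr <- sliding_trace(s, window_spec(20, 5))
  expect_equal(nrow(tr), 9) # grid stays regular
  expect_true(any(is.na(tr$sd1)))
  expect_true(all(tr$n_pairs[is.na(tr$sd1)] < 3))
})

test_that("emission count obeys floor((D - W)/step) + 1 on random geometries", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      n <- sample(30:240, 1)
      W <- sample(5:25, 1)
      step <- sample(seq_len(W), 1)
      s <- random_series(n, seed = seed + 1000)
      D <- n - 1
      tr <- suppressWarnings(sliding_trace(s, window_spec(W, step)))
      expected <- if (D < W) 0L else floor((D - W) / step) + 1L
      expect_equal(nrow(tr), expected)
      if (expected > 0) expect_equal(tr$t_end[1], W)
    })
  }
})

test_that("no emission before the full window has been buffered", {
  eng <- stream_engine(window_spec(20, 5))
  out <- lapply(0:19, function(t) stream_push(eng, t, 65))
  expect_true(all(vapply(out, nrow, integer(1)) == 0))
  first <- stream_push(eng, 20, 65)
  expect_equal(nrow(first), 1)
  expect_equal(first$t_end, 20)
})

test_that("out-of-order pushes raise an ordering error", {
  eng <- stream_engine(window_spec(20, 5))
  stream_push(eng, 0, 60)
  stream_push(eng, 1, 61)
  expect_error(stream_push(eng, 0.5, 62), class = "hrv_ordering_error")
})

test_that("online emissions equal the batch trace element-wise", {
  for (seed in 1:15) {
    withr::with_seed(seed, {
      n <- sample(25:150, 1)
      W <- sample(c(10, 20, 30), 1)
      step <- sample(c(1, 5, W), 1)
    })
    s <- random_series(n, seed = seed + 500)
    spec <- window_spec(W, step)
    batch <- sliding_trace(s, spec)
    online <- stream_replay(s, spec)
    expect_identical(online$t_end, batch$t_end)
    expect_identical(online$sd1, batch$sd1)
    expect_identical(online$sd2, batch$sd2)
    expect_identical(online$n_pairs, batch$n_pairs)
  }
})

test_that("online filtering matches offline filter-then-trace", {
  base <- generate_hr(synthetic_config(duration = 120, seed = 21))
  inj <- inject_ectopics(base, rate = 0.05, magnitude = 0.5, seed = 22)
  spec <- window_spec(20, 5)
  offline <- sliding_trace(filter_ectopic(inj$series), spec)
  online <- stream_replay(inj$series, spec, filter = filter_config())
  expect_identical(online$sd1, offline$sd1)
  expect_identical(online$sd2, offline$sd2)
  expect_identical(online$n_pairs, offline$n_pairs)
})

test_that("window sweep emission counts follow the count formula", {
  s <- random_series(601, seed = 31)
  traces <- window_length_sweep(s, c(5, 20, 40, 60, 120), step = 5)
  expect_named(traces, c("w5", "w20", "w40", "w60", "w120"))
  expect_equal(vapply(traces, nrow, integer(1)),
               c(w5 = 120L, w20 = 117L, w40 = 113L, w60 = 109L, w120 = 97L))

  single <- window_length_sweep(s, 20, step = 5)
  expect_identical(as.data.frame(single$w20),
                   as.data.frame(sliding_trace(s, window_spec(20, 5))))

  expect_length(window_length_sweep(s, numeric(0)), 0)
})

test_that("variability suppression shows up in the trace means", {
  cfg <- synthetic_config(duration = 600, noise_sd = 2, lag1_autocorr = 0.6,
                          rsa_amplitude = 0, seed = 41)
  s <- inject_transition(generate_hr(cfg),
                         transition_config(t0 = 300, suppression_factor = 0.3))
  tr <- sliding_trace(s, window_spec(20, 5))
  pre <- tr$t_end <= 300
  post <- tr$t_end > 320  # windows entirely past the transition
  for (metric in c("sd1", "sd2")) {
    m_pre <- mean(tr[[metric]][pre], na.rm = TRUE)
    m_post <- mean(tr[[metric]][post], na.rm = TRUE)
    expect_lt(m_post, m_pre)
    expect_equal(m_post / m_pre, 0.3, tolerance = 0.25)
  }
})
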