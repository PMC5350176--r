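# Displacement-rate estimation, breath segmentation, artifact detection and
# the exclusion rules.

make_trace <- function(x, fs = 30, extra = list()) {
  displacement_trace((seq_along(x) - 1) / fs, c(list(total = x), extra))
}

test_that("displacement rate matches closed-form derivatives", {
  fs <- 30
  t <- seq(0, 60, by = 1 / fs)
  x <- sin(2 * pi * 0.33 * t)
  tr <- make_trace(x)
  r <- compute_rate(tr)
  truth <- 2 * pi * 0.33 * cos(2 * pi * 0.33 * t)
  core <- 30:(length(t) - 30)
  expect_lt(max(abs(r - truth)[core]) / max(abs(truth)), 0.01)

  expect_equal(compute_rate(make_trace(rep(3, 200))), rep(0, 200),
               tolerance = 1e-12)

  ramp <- compute_rate(make_trace(2 * t))
  expect_equal(ramp[core], rep(2, length(core)), tolerance = 1e-9)

  expect_error(compute_rate(tr, "thorax"), "not present")
})

test_that("a 0.333 Hz sinusoid over 300 s yields 99 complete breaths", {
  fs <- 30
  t <- seq(0, 300, by = 1 / fs)
  tr <- displacement_trace(t, list(total = sin(2 * pi * 0.333 * t)))
  br <- detect_breaths(tr)
  expect_equal(nrow(br), 99)
  expect_true(all(br$start_index < br$peak_index &
                    br$peak_index < br$end_index))
  # shared boundaries between consecutive breaths
  expect_equal(br$end_index[-nrow(br)], br$start_index[-1])
  # total covered time cannot exceed the trace
  expect_lte(sum(br$end_time - br$start_time), 300)
})

test_that("degenerate traces detect no breaths", {
  expect_warning(br <- detect_breaths(make_trace(rep(1, 300))), "fewer than 2")
  expect_equal(nrow(br), 0)
})

test_that("detected boundaries match generator ground truth within one sample", {
  rec <- quiet_subject(seed = 31, duration = 150)
  a <- slp_analyze(rec)
  gt <- rec$ground_truth
  # edge losses of at most one breath (plus the truncated final breath)
  expect_gte(nrow(a$breaths), nrow(gt) - 2)
  m <- match_ground_truth(a, rec)
  expect_lt(max(abs(m$start_time - m$truth$t_start)), 1 / 30 + 1e-9)
})

test_that("breath detection is invariant to displacement scale and offset", {
  rec <- quiet_subject(seed = 17, duration = 90)
  x <- rec$trace$channels$total
  br0 <- filter_breaths(detect_breaths(make_trace(x)))
  br1 <- filter_breaths(detect_breaths(make_trace(3.7 * x + 11)))
  br2 <- filter_breaths(detect_breaths(make_trace(0.02 * x - 5)))
  expect_identical(br0[c("start_index", "peak_index", "end_index", "valid")],
                   br1[c("start_index", "peak_index", "end_index", "valid")])
  expect_identical(br0[c("start_index", "peak_index", "end_index", "valid")],
                   br2[c("start_index", "peak_index", "end_index", "valid")])
})

test_that("clean traces have no artifacts; injected ones are found", {
  rec <- quiet_subject(seed = 41, duration = 120)
  expect_equal(nrow(detect_artifacts(rec$trace)), 0)

  # three coughs at known times
  sp <- subject_spec(duration = 120, seed = 77)
  clean <- generate_subject_recording(sp)
  t <- clean$trace$time
  x <- clean$trace$channels$total
  for (t0 in c(30, 60, 90)) {
    tau <- t - t0
    x <- x + ifelse(tau >= 0 & tau <= 0.4,
                    3 * sin(2 * pi * 2 * tau / 0.4) * sin(pi * tau / 0.4)^2, 0)
  }
  art <- detect_artifacts(make_trace(x))
  coughs <- art[art$kind == "cough_transient", ]
  expect_gte(nrow(coughs), 3)
  for (t0 in c(30, 60, 90))
    expect_true(any(coughs$start_time < t0 + 0.4 & coughs$end_time > t0))

  # a 2 s dropout
  xm <- clean$trace$channels$total
  xm[t >= 50 & t < 52] <- NA
  art <- detect_artifacts(make_trace(xm))
  dr <- art[art$kind == "dropout", ]
  expect_equal(nrow(dr), 1)
  expect_equal(dr$end_time - dr$start_time, 2, tolerance = 2 / 30)

  # a baseline jump
  xj <- clean$trace$channels$total + 5 * (t > 60)
  art <- detect_artifacts(make_trace(xj))
  expect_true(any(art$kind == "motion" & art$start_time < 61 &
                    art$end_time > 59))
})

test_that("the 25% amplitude and extreme-duration rules flag the right breaths", {
  # four breaths with amplitudes 10, 10, 10, 2: median 10, threshold 2.5
  fs <- 30
  amp <- c(10, 10, 10, 2)
  br <- filter_breaths(detect_breaths(
    breath_train(lapply(amp, function(a) breath_shape_spec(1.4, 1.6, a, 1)))))
  expect_equal(nrow(br), 4)
  expect_identical(br$too_small, amp < 2.5)
  expect_identical(br$valid, amp >= 2.5)

  # identical breaths: everything valid
  br <- filter_breaths(detect_breaths(
    breath_train(replicate(5, breath_shape_spec(1.4, 1.6, 1, 1.2),
                           simplify = FALSE))))
  expect_equal(nrow(br), 5)
  expect_true(all(br$valid))

  # one breath with tE 10x the median is an extreme-duration outlier
  specs <- c(replicate(6, breath_shape_spec(1.2, 1.4, 1, 1.2),
                       simplify = FALSE),
             list(breath_shape_spec(1.2, 14, 1, 2)))
  br <- filter_breaths(detect_breaths(breath_train(specs)), K = 5)
  expect_equal(sum(br$extreme_duration), 1)
  tE <- br$end_time - br$peak_time
  expect_true(br$extreme_duration[which.max(tE)])
})

test_that("breaths overlapping artifact intervals are excluded", {
  rec <- quiet_subject(seed = 51, duration = 90)
  br <- detect_breaths(rec$trace)
  art <- data.frame(start_time = br$peak_time[3], end_time = br$peak_time[3],
                    kind = "cough_transient")
  fb <- filter_breaths(br, art)
  expect_true(fb$artifact_overlap[3])
  expect_false(fb$valid[3])
  expect_true(all(fb$valid[-3]))
})

test_that("the >50% affected rule rejects recordings strictly above half", {
  mk <- function(n_bad, n = 100) {
    data.frame(valid = c(rep(FALSE, n_bad), rep(TRUE, n - n_bad)))
  }
  expect_false(assess_recording(mk(51))$accepted)
  expect_true(assess_recording(mk(50))$accepted)
  expect_true(assess_recording(mk(0))$accepted)
  r <- assess_recording(mk(0)[0, , drop = FALSE])
  expect_false(r$accepted)
  expect_match(r$reason, "no breaths")
})
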