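# Per-breath parameter extraction: timing, rate, loop, regional, phase.

fs <- 30

breath_train_trace <- function(spec, n = 6) {
  breath_train(replicate(n, spec, simplify = FALSE), fs)
}

test_that("timing indices follow directly from breath boundaries", {
  tr <- displacement_trace(seq(0, 10, by = 1 / 10),
                           list(total = sin(seq(0, 10, by = 1 / 10))))
  b <- list(start_index = 1, peak_index = 13, end_index = 30,
            start_time = 0, peak_time = 1.2, end_time = 2.9)
  tm <- compute_timing(b, tr)
  expect_equal(tm$tI, 1.2)
  expect_equal(tm$tE, 1.7)
  expect_equal(tm$tTot, 2.9)
  expect_equal(tm$rr, 60 / 2.9, tolerance = 1e-12)
  expect_equal(tm$tI_over_tE, 1.2 / 1.7, tolerance = 1e-12)
  expect_equal(tm$tI_over_tTot, 1.2 / 2.9, tolerance = 1e-12)
  # identity tying the two ratios together
  expect_equal(tm$tI_over_tTot, tm$tI_over_tE / (1 + tm$tI_over_tE),
               tolerance = 1e-9)
  b$peak_time <- 0; b$peak_index <- 1
  expect_error(compute_timing(b, tr), "degenerate")
})

test_that("half-cosine inspiration peaks its rate at mid-limb", {
  tr <- breath_train_trace(breath_shape_spec(1.5, 1.5, 1, 1))
  a <- slp_analyze(tr)
  expect_gt(nrow(a$records), 2)
  expect_lt(abs(median(a$records$tptif_over_tI) - 0.5), 1.5 / (30 * 1.5))
  # symmetric breath: equal peak rates
  expect_equal(median(a$records$ptif / a$records$ptef), 1, tolerance = 0.01)
  expect_true(all(a$records$tptif_over_tI > 0 & a$records$tptif_over_tI <= 1))
  expect_true(all(a$records$tptef_over_tE > 0 & a$records$tptef_over_tE <= 1))
})

test_that("amplitude scaling doubles rates but leaves normalized times alone", {
  tr1 <- breath_train_trace(breath_shape_spec(1.3, 1.6, 1, 1.3))
  tr2 <- breath_train_trace(breath_shape_spec(1.3, 1.6, 2, 1.3))
  a1 <- slp_analyze(tr1); a2 <- slp_analyze(tr2)
  expect_equal(median(a2$records$ptif) / median(a1$records$ptif), 2,
               tolerance = 1e-6)
  expect_equal(median(a2$records$ptef) / median(a1$records$ptef), 2,
               tolerance = 1e-6)
  expect_equal(a2$records$tptif_over_tI, a1$records$tptif_over_tI,
               tolerance = 1e-9)
  expect_equal(a2$records$ie50, a1$records$ie50, tolerance = 1e-9)
})

test_that("loop indices recover designed IE50 and invert under time reversal", {
  # symmetric sinusoidal breath: IE50 = 1
  t <- seq(0, 3, by = 1 / fs)
  one <- (1 - cos(2 * pi * t / 3)) / 2
  x <- c(one, one[-1], one[-1], one[-1])
  tr <- displacement_trace((seq_along(x) - 1) / fs, list(total = x))
  a <- slp_analyze(tr)
  expect_equal(median(a$records$ie50), 1, tolerance = 0.01)

  tr <- breath_train_trace(breath_shape_spec(1.18, 1.7, 1, 1.53))
  a <- slp_analyze(tr)
  expect_equal(median(a$records$ie50), 1.53, tolerance = 0.02 * 1.53)
})

test_that("relative contribution reproduces amplitude shares", {
  t <- seq(0, 30, by = 1 / fs)
  base <- (1 - cos(2 * pi * t / 3)) / 2
  tr <- displacement_trace(t, list(total = 10 * base, thorax = 4 * base,
                                   abdomen = 6 * base))
  br <- detect_breaths(tr)
  b <- br[3, ]
  expect_equal(compute_relative_contribution(b, tr, "thorax", "total"), 40,
               tolerance = 1e-9)
  expect_equal(compute_relative_contribution(b, tr, "abdomen", "total"), 60,
               tolerance = 1e-9)
  expect_equal(compute_relative_contribution(b, tr, "total", "total"), 100)
  # antiphase compartments cancel: denominator has no excursion
  tr2 <- displacement_trace(t, list(total = base - base,
                                    thorax = base, abdomen = -base))
  b2 <- b
  expect_error(compute_relative_contribution(b2, tr2, "thorax", "total"),
               "zero excursion")
})

test_that("Konno-Mead phase recovers sinusoidal offsets with sign", {
  for (delta in c(-90, -45, -20, 0, 20, 45, 90)) {
    tr <- sinusoid_phase_trace(delta)
    br <- detect_breaths(tr)
    ph <- compute_phase(br[2, ], tr, "thorax", "abdomen")
    expect_lt(abs(ph$phase_deg - delta), 1)
    if (delta == 0) expect_equal(ph$rotation, "degenerate")
  }
  # identical signals: zero width, zero phase
  t <- seq(0, 16, by = 1 / fs)
  ref <- -cos(2 * pi * t / 4)
  tr <- displacement_trace(t, list(total = 2 * ref, thorax = ref,
                                   abdomen = ref))
  br <- detect_breaths(tr)
  ph <- compute_phase(br[1, ], tr, "thorax", "abdomen")
  expect_equal(ph$m, 0, tolerance = 1e-9)
  expect_equal(ph$phase_deg, 0)
  # m <= s always
  expect_lte(ph$m, ph$s)
  expect_error(compute_phase(br[1, ], displacement_trace(
    t, list(total = ref, thorax = ref, abdomen = rep(0, length(t)))),
    "thorax", "abdomen"), "zero excursion")
})

test_that("breath records degrade gracefully without regional channels", {
  rec <- quiet_subject(seed = 9, duration = 60)
  total_only <- displacement_trace(rec$trace$time,
                                   list(total = rec$trace$channels$total))
  a <- slp_analyze(total_only)
  expect_true(all(is.na(a$records$rct)))
  expect_true(all(is.na(a$records$taa_deg)))
  expect_true(all(is.na(a$records$hta_deg)))
  expect_true(all(!is.na(a$records$ie50)))
  expect_true(all(!is.na(a$records$tI)))
})

test_that("records are emitted only for valid breaths", {
  rec <- quiet_subject(seed = 12, duration = 90)
  br <- detect_breaths(rec$trace)
  art <- data.frame(start_time = br$peak_time[2], end_time = br$peak_time[2],
                    kind = "motion")
  fb <- filter_breaths(br, art)
  tab <- breath_table(rec$trace, fb)
  expect_false(2 %in% tab$breath_id)
  expect_equal(nrow(tab), sum(fb$valid))
})

test_that("ratio parameters are invariant to scale and offset; rates scale", {
  rec <- quiet_subject(seed = 23, duration = 90)
  tr0 <- rec$trace
  c <- 3.7
  tr1 <- displacement_trace(tr0$time,
                            lapply(tr0$channels, function(v) c * v + 11))
  a0 <- slp_analyze(tr0); a1 <- slp_analyze(tr1)
  for (col in c("tI", "tE", "tTot", "rr", "tI_over_tE", "tI_over_tTot",
                "tptif_over_tI", "tptef_over_tE", "ie50", "rct", "taa_deg",
                "hta_deg"))
    expect_equal(a1$records[[col]], a0$records[[col]], tolerance = 1e-9,
                 label = col)
  for (col in c("ptif", "ptef", "tif50", "tef50"))
    expect_equal(a1$records[[col]], c * a0$records[[col]], tolerance = 1e-9,
                 label = col)
})

test_that("pipeline IE50 agrees with the dense-grid oracle on random breaths", {
  rec <- generate_subject_recording(
    subject_spec(duration = 300, seed = 67, median_ie50 = 1.53,
                 ie50_within_iqr = 0.63, median_tI = 1.18, median_tE = 1.70))
  a <- slp_analyze(rec)
  m <- match_ground_truth(a, rec)
  oracle <- mapply(dense_ie50, m$truth$tI, m$truth$tE, m$truth$amplitude,
                   m$truth$shape_p, n_grid = 2e4)
  expect_gt(nrow(m$records), 80)
  expect_lt(max(abs(m$records$ie50 / oracle - 1)), 0.02)
})
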