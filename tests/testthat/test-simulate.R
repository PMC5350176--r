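# Subject and cohort waveform generation: determinism, calibration
# identities, regional construction, artifacts.

test_that("identical seeds give identical recordings, including written files", {
  sp <- subject_spec(duration = 60, seed = 11,
                     artifact_rates = c(cough = 1, motion = 1, dropout = 1))
  r1 <- generate_subject_recording(sp)
  r2 <- generate_subject_recording(sp)
  expect_identical(r1$trace$channels, r2$trace$channels)
  expect_identical(r1$ground_truth, r2$ground_truth)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_trace(r1$trace, f1); write_trace(r2$trace, f2)
  expect_identical(readLines(f1), readLines(f2))
  # generation restores the caller's RNG stream
  set.seed(99); a <- rnorm(1)
  set.seed(99); invisible(generate_subject_recording(sp)); b <- rnorm(1)
  expect_identical(a, b)
})

test_that("breath count tracks duration over median breath period", {
  rec <- generate_subject_recording(
    subject_spec(duration = 300, seed = 5, median_tI = 1.4, median_tE = 1.6,
                 tI_within_iqr = 0.1, tE_within_iqr = 0.1))
  expect_gt(nrow(rec$ground_truth), 85)
  expect_lt(nrow(rec$ground_truth), 115)
  expect_error(generate_subject_recording(subject_spec(duration = 2, seed = 1)),
               "fewer than 2")
})

test_that("in-phase compartments sum to the total and carry the configured share", {
  rec <- generate_subject_recording(
    subject_spec(duration = 60, seed = 3, taa_deg = 0, hta_deg = 0,
                 rct_percent = 40))
  ch <- rec$trace$channels
  expect_equal(ch$thorax + ch$abdomen, ch$total, tolerance = 1e-12)
  gt <- rec$ground_truth
  for (k in c(2, 5, 8)) {
    sel <- rec$trace$time >= gt$t_start[k] & rec$trace$time <= gt$t_end[k]
    p2p <- function(v) max(v[sel]) - min(v[sel])
    expect_equal(100 * p2p(ch$thorax) / p2p(ch$total), 40, tolerance = 1e-9)
  }
})

test_that("between-subject distributions reproduce the configured median and IQR", {
  # analytic identity of the log-normal (median, IQR) parameterization
  for (cfg in list(c(1.22, 0.29), c(1.53, 0.35), c(0.63, 0.32))) {
    s <- slptidal:::ln_sigma_from_iqr(cfg[1], cfg[2])
    q <- stats::qlnorm(c(0.25, 0.5, 0.75), log(cfg[1]), s)
    expect_equal(q[2], cfg[1], tolerance = 1e-12)
    expect_equal(q[3] - q[1], cfg[2], tolerance = 1e-12)
  }
  # empirical convergence of the sampler at n = 2000
  set.seed(42)
  draws <- slptidal:::rlnorm_med_iqr(2000, 1.53, 0.35)
  expect_equal(stats::median(draws), 1.53, tolerance = 0.02 * 1.53)
  expect_equal(stats::IQR(draws), 0.35, tolerance = 0.02 * 1.53)
})

test_that("cohort generation couples FEV1 and IE50 at the requested rank correlation", {
  cs <- slp_cohort_preset("asthma_pre", master_seed = 8)
  cs$n_subjects <- 200L
  cs$ie50_fev1_rank_correlation <- -1
  # only the metadata draw matters here; skip waveform synthesis
  draw_meta <- function(cs) slptidal:::with_seed(cs$master_seed,
                                                 slptidal:::draw_cohort_subjects(cs))
  md <- draw_meta(cs)
  expect_equal(stats::cor(rank(md$fev1_pct_pred), rank(md$median_ie50)), -1)
  cs$ie50_fev1_rank_correlation <- -0.49
  md <- draw_meta(cs)
  expect_equal(stats::cor(md$fev1_pct_pred, md$median_ie50,
                          method = "spearman"), -0.49, tolerance = 0.12)
  expect_error(cohort_spec(ie50_fev1_rank_correlation = -1.2), "infeasible")
  expect_error(cohort_spec(n_subjects = 1), "n_subjects")
})

test_that("a two-subject cohort generates valid recordings", {
  cs <- slp_cohort_preset("healthy", master_seed = 2)
  cs$n_subjects <- 2L
  cs$duration <- 40
  co <- generate_cohort(cs)
  expect_length(co$recordings, 2)
  expect_equal(nrow(co$metadata), 2)
  expect_s3_class(co$recordings[[1]]$trace, "displacement_trace")
})

test_that("cohort generation is deterministic in the master seed", {
  cs <- slp_cohort_preset("healthy", master_seed = 7)
  cs$n_subjects <- 2L; cs$duration <- 30
  c1 <- generate_cohort(cs); c2 <- generate_cohort(cs)
  expect_identical(c1$metadata, c2$metadata)
  expect_identical(c1$recordings[[2]]$trace$channels,
                   c2$recordings[[2]]$trace$channels)
})

test_that("injected artifacts are recorded with their intervals", {
  sp <- subject_spec(duration = 120, seed = 21,
                     artifact_rates = c(cough = 2, motion = 1, dropout = 1))
  rec <- generate_subject_recording(sp)
  expect_gt(nrow(rec$artifacts), 0)
  expect_true(all(rec$artifacts$end_time > rec$artifacts$start_time))
  expect_true(all(rec$artifacts$kind %in%
                    c("cough_transient", "motion", "dropout")))
  # dropouts really are missing samples
  dr <- rec$artifacts[rec$artifacts$kind == "dropout", ]
  if (nrow(dr) > 0) {
    sel <- rec$trace$time >= dr$start_time[1] &
      rec$trace$time <= dr$end_time[1]
    expect_true(anyNA(rec$trace$channels$total[sel]))
  }
})

test_that("cohort specs round-trip through JSON with unknown keys rejected", {
  cs <- slp_cohort_preset("asthma_post", master_seed = 13)
  f <- tempfile(fileext = ".json")
  write_cohort_spec(cs, f)
  cs2 <- read_cohort_spec(f)
  expect_equal(unclass(cs)[order(names(cs))], unclass(cs2)[order(names(cs2))],
               tolerance = 1e-12)
  bad <- jsonlite::read_json(f, simplifyVector = TRUE)
  bad$not_a_knob <- 1
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(bad, f2, auto_unbox = TRUE, digits = NA)
  expect_error(read_cohort_spec(f2), "unknown configuration keys")
})
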