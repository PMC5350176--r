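# Synthetic tidal-breathing waveform generator.
#
# Subjects are simulated as a stream of breaths whose per-breath parameters
# (tI, tE, IE50, amplitude) are drawn around subject-level medians with a
# configurable within-subject dispersion; subject-level medians are in turn
# drawn from between-subject distributions calibrated so that their analytic
# median and IQR equal a target cohort's printed summary values. Everything is
# parameterized by (median, IQR) because that is how tidal-breathing cohorts
# are reported.

QN75 <- stats::qnorm(0.75)

# log-sd of a log-normal with given median and IQR:
# IQR = m * (exp(q*s) - exp(-q*s)) = 2 m sinh(q s), q = qnorm(.75)
ln_sigma_from_iqr <- function(median, iqr) {
  stopifnot(median > 0, iqr >= 0)
  asinh(iqr / (2 * median)) / QN75
}

rlnorm_med_iqr <- function(n, median, iqr) {
  stats::rlnorm(n, meanlog = log(median), sdlog = ln_sigma_from_iqr(median, iqr))
}

# run code under a local RNG state seeded with `seed`, restoring the caller's
# stream afterwards
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

#' Subject-level simulation specification
#'
#' Defines one simulated recording: subject medians of the breath parameters,
#' within-subject (breath-to-breath) dispersions expressed as IQRs, regional
#' geometry (thoracic contribution and phase lags), an FEV1 covariate, and
#' artifact event rates.
#'
#' Within-subject variation is log-normal around the subject median for
#' strictly positive parameters, with the IQR of the distribution equal to the
#' configured `*_within_iqr` exactly. Log inspiratory and expiratory times are
#' drawn with correlation `timing_corr`, reflecting that slow breaths are slow
#' in both phases.
#'
#' @param group_label one of `"healthy"`, `"asthma_pre"`, `"asthma_post"`.
#' @param duration recording length in seconds (default 300, a 5-min
#'   assessment).
#' @param sampling_rate Hz (default 30).
#' @param median_tI,median_tE subject median inspiratory/expiratory time (s).
#' @param tI_within_iqr,tE_within_iqr breath-to-breath IQRs of tI and tE (s).
#' @param timing_corr correlation of log tI and log tE across breaths.
#' @param median_ie50 subject median IE50; `ie50_within_iqr` its
#'   breath-to-breath IQR.
#' @param amplitude subject median breath amplitude (a.u.);
#'   `amplitude_within_iqr` its breath-to-breath IQR.
#' @param rct_percent thoracic contribution to total peak-to-peak amplitude,
#'   in (0, 100).
#' @param taa_deg,hta_deg thoracoabdominal and left-right hemithoracic phase
#'   lags in degrees, each in \[-90, 90\]; positive means the reference
#'   compartment (thorax; left hemithorax) leads.
#' @param fev1_pct_pred FEV1 as percent of predicted (covariate only).
#' @param artifact_rates named numeric vector of events per minute for
#'   `cough`, `motion`, `dropout`.
#' @param seed integer seed; identical specs give bit-identical recordings.
#' @return a validated `subject_spec` list.
#' @export
subject_spec <- function(group_label = "healthy",
                         duration = 300,
                         sampling_rate = 30,
                         median_tI = 1.33, median_tE = 1.63,
                         tI_within_iqr = 0.27, tE_within_iqr = 0.39,
                         timing_corr = 0.3,
                         median_ie50 = 1.22, ie50_within_iqr = 0.47,
                         amplitude = 1, amplitude_within_iqr = 0.15,
                         rct_percent = 42, taa_deg = 11, hta_deg = 3,
                         fev1_pct_pred = 100,
                         artifact_rates = c(cough = 0, motion = 0, dropout = 0),
                         seed = 1L) {
  stopifnot(
    group_label %in% c("healthy", "asthma_pre", "asthma_post"),
    duration > 0, sampling_rate >= 10,
    median_tI > 0, median_tE > 0, median_ie50 > 0, amplitude > 0,
    tI_within_iqr >= 0, tE_within_iqr >= 0, ie50_within_iqr >= 0,
    amplitude_within_iqr >= 0,
    rct_percent > 0, rct_percent < 100,
    abs(taa_deg) <= 90, abs(hta_deg) <= 90,
    all(artifact_rates >= 0)
  )
  rates <- c(cough = 0, motion = 0, dropout = 0)
  rates[names(artifact_rates)] <- artifact_rates
  spec <- list(group_label = group_label, duration = duration,
               sampling_rate = sampling_rate,
               median_tI = median_tI, median_tE = median_tE,
               tI_within_iqr = tI_within_iqr, tE_within_iqr = tE_within_iqr,
               timing_corr = timing_corr,
               median_ie50 = median_ie50, ie50_within_iqr = ie50_within_iqr,
               amplitude = amplitude,
               amplitude_within_iqr = amplitude_within_iqr,
               rct_percent = rct_percent, taa_deg = taa_deg,
               hta_deg = hta_deg, fev1_pct_pred = fev1_pct_pred,
               artifact_rates = rates, seed = as.integer(seed))
  class(spec) <- "subject_spec"
  spec
}

# shift a uniformly sampled signal by `lag` seconds (positive = delay),
# linear interpolation, edges extended
shift_signal <- function(time, x, lag) {
  if (lag == 0) return(x)
  stats::approx(time, x, xout = time - lag, rule = 2)$y
}

# draw the per-breath parameter table for one subject (enough breaths to
# cover `duration` seconds)
draw_breaths <- function(spec) {
  n_guess <- ceiling(spec$duration / (spec$median_tI + spec$median_tE) * 1.6) + 4
  s_tI <- ln_sigma_from_iqr(spec$median_tI, spec$tI_within_iqr)
  s_tE <- ln_sigma_from_iqr(spec$median_tE, spec$tE_within_iqr)
  repeat {
    z1 <- stats::rnorm(n_guess)
    z2 <- spec$timing_corr * z1 +
      sqrt(1 - spec$timing_corr^2) * stats::rnorm(n_guess)
    tI <- exp(log(spec$median_tI) + s_tI * z1)
    tE <- exp(log(spec$median_tE) + s_tE * z2)
    ie50 <- rlnorm_med_iqr(n_guess, spec$median_ie50, spec$ie50_within_iqr)
    amp <- rlnorm_med_iqr(n_guess, spec$amplitude, spec$amplitude_within_iqr)
    if (sum(tI + tE) >= spec$duration + spec$median_tI + spec$median_tE) break
    n_guess <- n_guess * 2
  }
  # keep targets inside the attainable range of the shape family (the
  # clamp is hit only in the extreme tails of the draw)
  lo <- ie50_of_shape(59.9, tI, tE)
  hi <- ie50_of_shape(0.051, tI, tE)
  ie50 <- pmin(pmax(ie50, lo), hi)
  k <- which(cumsum(tI + tE) >= spec$duration)[1]
  idx <- seq_len(k)
  data.frame(breath_id = idx, tI = tI[idx], tE = tE[idx],
             ie50 = ie50[idx], amplitude = amp[idx])
}

inject_artifacts <- function(time, channels, spec, amp_ref) {
  dur <- time[length(time)]
  fs <- spec$sampling_rate
  rates <- spec$artifact_rates
  events <- list()
  add_event <- function(kind, t0, t1) {
    events[[length(events) + 1]] <<- data.frame(start_time = t0, end_time = t1,
                                                kind = kind)
  }
  n_ev <- function(rate) stats::rpois(1, rate * dur / 60)

  for (i in seq_len(n_ev(rates[["cough"]]))) {
    d <- stats::runif(1, 0.3, 0.6)
    t0 <- stats::runif(1, 2, dur - 2 - d)
    a <- 3 * amp_ref * sample(c(-1, 1), 1)
    tau <- time - t0
    w <- ifelse(tau >= 0 & tau <= d,
                a * sin(2 * pi * 2 * tau / d) * sin(pi * tau / d)^2, 0)
    channels <- lapply(channels, function(x) x + w)
    add_event("cough_transient", t0, t0 + d)
  }
  for (i in seq_len(n_ev(rates[["motion"]]))) {
    d <- 0.6
    t0 <- stats::runif(1, 2, dur - 2 - d)
    a <- stats::runif(1, 1.5, 3) * amp_ref * sample(c(-1, 1), 1)
    step <- a * stats::pnorm(time, mean = t0 + d / 2, sd = d / 6)
    channels <- lapply(channels, function(x) x + step)
    add_event("motion", t0, t0 + d)
  }
  for (i in seq_len(n_ev(rates[["dropout"]]))) {
    d <- min(stats::rlnorm(1, log(0.6), 0.4), 3)
    t0 <- stats::runif(1, 2, dur - 2 - d)
    sel <- time >= t0 & time <= t0 + d
    channels <- lapply(channels, function(x) { x[sel] <- NA_real_; x })
    add_event("dropout", t0, t0 + d)
  }
  art <- if (length(events)) do.call(rbind, events) else
    data.frame(start_time = numeric(0), end_time = numeric(0),
               kind = character(0))
  list(channels = channels, artifacts = art[order(art$start_time), ,
                                            drop = FALSE])
}

#' Generate one subject's displacement recording with ground truth
#'
#' Concatenates synthetic breaths drawn from the subject's within-subject
#' distributions into a continuous baseline-anchored total-displacement
#' waveform, derives regional channels as amplitude shares with the
#' configured phase lags, and injects artifacts at the configured rates.
#'
#' The total channel is the designed waveform exactly, so the ground-truth
#' table is exact for total-channel parameters. The thorax channel is
#' `rct_percent/100` of the total; the abdomen channel is the complementary
#' share of the total delayed by `taa_deg/360` of the median breath period;
#' hemithorax channels are half-thorax shares offset by the `hta_deg` lag
#' (left leading). Compartments therefore sum exactly to the total only when
#' `taa_deg = 0`.
#'
#' @param spec a [subject_spec()].
#' @return an object of class `slp_recording`: list with `trace`
#'   (a [displacement_trace()]), `ground_truth` (per-breath parameter table
#'   with boundary times), `artifacts` (injected artifact intervals), and
#'   `spec`.
#' @export
generate_subject_recording <- function(spec) {
  stopifnot(inherits(spec, "subject_spec"))
  with_seed(spec$seed, {
    fs <- spec$sampling_rate
    br <- draw_breaths(spec)
    if (nrow(br) < 2)
      stop("duration too short: fewer than 2 complete breaths")
    br$shape_p <- mapply(solve_shape_parameter, br$ie50, br$tI, br$tE)
    br$t_start <- c(0, cumsum(br$tI + br$tE))[seq_len(nrow(br))]
    br$t_peak <- br$t_start + br$tI
    br$t_end <- br$t_start + br$tI + br$tE

    n <- round(spec$duration * fs) + 1
    time <- seq.int(0, n - 1) / fs
    idx <- findInterval(time, br$t_start)
    total <- numeric(n)
    for (k in seq_len(nrow(br))) {
      sel <- idx == k
      if (!any(sel)) next
      total[sel] <- breath_profile(time[sel] - br$t_start[k],
                                   br$tI[k], br$tE[k],
                                   br$amplitude[k], br$shape_p[k])
    }

    w <- spec$rct_percent / 100
    tTot_med <- stats::median(br$tI + br$tE)
    lag_taa <- spec$taa_deg / 360 * tTot_med
    lag_hta <- spec$hta_deg / 360 * tTot_med
    thorax <- w * total
    abdomen <- (1 - w) * shift_signal(time, total, lag_taa)
    channels <- list(
      total = total,
      thorax = thorax,
      abdomen = abdomen,
      thorax_left = 0.5 * shift_signal(time, thorax, -lag_hta / 2),
      thorax_right = 0.5 * shift_signal(time, thorax, lag_hta / 2),
      abdomen_left = 0.5 * abdomen,
      abdomen_right = 0.5 * abdomen
    )

    inj <- inject_artifacts(time, channels, spec, amp_ref = spec$amplitude)
    br$rct <- spec$rct_percent
    br$taa_deg <- spec$taa_deg
    br$hta_deg <- spec$hta_deg
    structure(list(
      trace = displacement_trace(time, inj$channels, fs),
      ground_truth = br,
      artifacts = inj$artifacts,
      spec = spec
    ), class = "slp_recording")
  })
}

#' @export
print.slp_recording <- function(x, ...) {
  cat(sprintf("<slp_recording> %s subject, %d generated breaths, %d artifacts\n",
              x$spec$group_label, nrow(x$ground_truth), nrow(x$artifacts)))
  print(x$trace)
  invisible(x)
}

#' Cohort-level simulation specification
#'
#' Between-subject distributions for each subject-level parameter,
#' parameterized by (median, IQR): log-normal for strictly positive
#' parameters, normal (truncated to the physical range) for the thoracic
#' contribution and phase angles. By construction the analytic median and IQR
#' of each between-subject distribution equal the configured values. The
#' subject-level median IE50 and the FEV1 covariate are coupled through a
#' Gaussian copula on ranks hitting a target Spearman correlation.
#'
#' @param group_label cohort label.
#' @param n_subjects number of subjects (>= 2).
#' @param m_tI,m_tE,m_ie50 between-subject (median, IQR) pairs,
#'   `c(median, iqr)`, for the subject medians of tI, tE, IE50.
#' @param v_tI,v_tE,v_ie50 (median, IQR) pairs for the subjects'
#'   within-subject IQRs of tI, tE, IE50.
#' @param mt_corr between-subject correlation of log median tI and log
#'   median tE. Printed cohort tables report the ratio mtI/tE with a much
#'   tighter IQR than independent tI and tE draws would give; this
#'   correlation is solved from the ratio row's (median, IQR).
#' @param rct,taa,hta (median, IQR) pairs for thoracic contribution (%) and
#'   phase angles (degrees); sampled from truncated normals.
#' @param fev1 `c(mean, sd)` of FEV1 (% predicted), normal.
#' @param ie50_fev1_rank_correlation target Spearman correlation between the
#'   subject median IE50 and FEV1, in \[-1, 1\].
#' @param duration,sampling_rate recording settings passed to each subject.
#' @param artifact_rates events per minute per artifact class.
#' @param master_seed integer; drives subject parameter draws and per-subject
#'   seeds.
#' @return a validated `cohort_spec` list.
#' @export
cohort_spec <- function(group_label = "healthy", n_subjects = 41,
                        m_tI = c(1.33, 0.46), m_tE = c(1.63, 0.64),
                        m_ie50 = c(1.22, 0.29),
                        v_tI = c(0.27, 0.17), v_tE = c(0.39, 0.21),
                        v_ie50 = c(0.47, 0.18),
                        mt_corr = 0.85,
                        rct = c(41.96, 20.04), taa = c(11.19, 9.92),
                        hta = c(3.21, 1.70),
                        fev1 = c(100, 10),
                        ie50_fev1_rank_correlation = 0,
                        duration = 300, sampling_rate = 30,
                        artifact_rates = c(cough = 0.3, motion = 0.2,
                                           dropout = 0.2),
                        master_seed = 1L) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (abs(ie50_fev1_rank_correlation) > 1)
    stop("infeasible rank correlation: |rho| must be <= 1")
  if (abs(mt_corr) > 1) stop("infeasible timing correlation")
  spec <- list(group_label = group_label, n_subjects = as.integer(n_subjects),
               m_tI = m_tI, m_tE = m_tE, m_ie50 = m_ie50,
               v_tI = v_tI, v_tE = v_tE, v_ie50 = v_ie50, mt_corr = mt_corr,
               rct = rct, taa = taa, hta = hta, fev1 = fev1,
               ie50_fev1_rank_correlation = ie50_fev1_rank_correlation,
               duration = duration, sampling_rate = sampling_rate,
               artifact_rates = artifact_rates,
               master_seed = as.integer(master_seed))
  class(spec) <- "cohort_spec"
  spec
}

#' Preset cohort configurations
#'
#' Returns a [cohort_spec()] calibrated so that the analytic between-subject
#' medians and IQRs equal the published group summaries for a healthy
#' pediatric cohort (n = 41), an asthma cohort before bronchodilator (n = 30),
#' or the same asthma cohort after bronchodilator. FEV1 (% predicted) is
#' normal with the group's reported mean and SD and, for the
#' prebronchodilator asthma group, rank-correlated with the subject median
#' IE50 at rho = -0.49.
#'
#' @param group `"healthy"`, `"asthma_pre"`, or `"asthma_post"`.
#' @param master_seed seed forwarded to [cohort_spec()].
#' @param ... further overrides forwarded to [cohort_spec()].
#' @return a `cohort_spec`.
#' @export
slp_cohort_preset <- function(group = c("healthy", "asthma_pre", "asthma_post"),
                              master_seed = 1L, ...) {
  group <- match.arg(group)
  args <- switch(group,
    healthy = list(
      group_label = "healthy", n_subjects = 41,
      m_tI = c(1.33, 0.46), m_tE = c(1.63, 0.64), m_ie50 = c(1.22, 0.29),
      v_tI = c(0.27, 0.17), v_tE = c(0.39, 0.21), v_ie50 = c(0.47, 0.18),
      mt_corr = 0.87,
      rct = c(41.96, 20.04), taa = c(11.19, 9.92), hta = c(3.21, 1.70),
      fev1 = c(100, 10), ie50_fev1_rank_correlation = 0),
    asthma_pre = list(
      group_label = "asthma_pre", n_subjects = 30,
      m_tI = c(1.18, 0.20), m_tE = c(1.70, 0.47), m_ie50 = c(1.53, 0.35),
      v_tI = c(0.24, 0.14), v_tE = c(0.44, 0.35), v_ie50 = c(0.63, 0.32),
      mt_corr = 0.90,
      rct = c(39.18, 11.30), taa = c(11.89, 8.71), hta = c(3.29, 1.54),
      fev1 = c(68.4, 12.5), ie50_fev1_rank_correlation = -0.49),
    asthma_post = list(
      group_label = "asthma_post", n_subjects = 30,
      m_tI = c(1.13, 0.30), m_tE = c(1.60, 0.43), m_ie50 = c(1.45, 0.24),
      v_tI = c(0.23, 0.10), v_tE = c(0.43, 0.21), v_ie50 = c(0.60, 0.38),
      mt_corr = 0.78,
      rct = c(39.11, 12.80), taa = c(11.73, 11.44), hta = c(3.05, 1.26),
      fev1 = c(81.2, 11.2), ie50_fev1_rank_correlation = 0)
  )
  overrides <- list(...)
  args[names(overrides)] <- overrides
  args$master_seed <- master_seed
  do.call(cohort_spec, args)
}

# draw the subject-level parameter table (no waveforms); assumes the caller
# controls the RNG state
draw_cohort_subjects <- function(spec) {
  n <- spec$n_subjects
  # Gaussian copula: Pearson correlation of the latent normals that yields
  # the target Spearman correlation
  rho_s <- spec$ie50_fev1_rank_correlation
  r_z <- 2 * sin(pi * rho_s / 6)
  z1 <- stats::rnorm(n)
  z2 <- r_z * z1 + sqrt(max(0, 1 - r_z^2)) * stats::rnorm(n)
  m_ie50 <- exp(log(spec$m_ie50[1]) +
                  ln_sigma_from_iqr(spec$m_ie50[1], spec$m_ie50[2]) * z1)
  fev1 <- spec$fev1[1] + spec$fev1[2] * z2
  # correlated subject-level timing medians
  s_ti <- ln_sigma_from_iqr(spec$m_tI[1], spec$m_tI[2])
  s_te <- ln_sigma_from_iqr(spec$m_tE[1], spec$m_tE[2])
  zt1 <- stats::rnorm(n)
  zt2 <- spec$mt_corr * zt1 + sqrt(1 - spec$mt_corr^2) * stats::rnorm(n)
  data.frame(
    subject_id = sprintf("%s_%02d", spec$group_label, seq_len(n)),
    group = spec$group_label,
    fev1_pct_pred = fev1,
    median_ie50 = m_ie50,
    median_tI = exp(log(spec$m_tI[1]) + s_ti * zt1),
    median_tE = exp(log(spec$m_tE[1]) + s_te * zt2),
    ie50_within_iqr = rlnorm_med_iqr(n, spec$v_ie50[1], spec$v_ie50[2]),
    tI_within_iqr = rlnorm_med_iqr(n, spec$v_tI[1], spec$v_tI[2]),
    tE_within_iqr = rlnorm_med_iqr(n, spec$v_tE[1], spec$v_tE[2]),
    rct_percent = rnorm_trunc(n, spec$rct[1], spec$rct[2], 5, 95),
    taa_deg = rnorm_trunc(n, spec$taa[1], spec$taa[2], -90, 90),
    hta_deg = rnorm_trunc(n, spec$hta[1], spec$hta[2], -90, 90)
  )
}

rnorm_trunc <- function(n, median, iqr, lo, hi) {
  sd <- iqr / (2 * QN75)
  pmin(pmax(stats::rnorm(n, median, sd), lo), hi)
}

#' Generate a cohort of subject recordings
#'
#' Draws each subject's parameters from the cohort's between-subject
#' distributions (IE50 and FEV1 jointly through a Gaussian copula on ranks),
#' then synthesizes each subject's full waveform recording.
#'
#' @param spec a [cohort_spec()].
#' @return list with `recordings` (list of [generate_subject_recording()]
#'   outputs) and `metadata` (one row per subject: id, group, FEV1, and the
#'   ground-truth subject-level parameters).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$master_seed, {
    n <- spec$n_subjects
    subj <- draw_cohort_subjects(spec)
    seeds <- sample.int(.Machine$integer.max - 1L, n)

    recordings <- vector("list", n)
    for (i in seq_len(n)) {
      sp <- subject_spec(
        group_label = spec$group_label,
        duration = spec$duration, sampling_rate = spec$sampling_rate,
        median_tI = subj$median_tI[i], median_tE = subj$median_tE[i],
        tI_within_iqr = subj$tI_within_iqr[i],
        tE_within_iqr = subj$tE_within_iqr[i],
        median_ie50 = subj$median_ie50[i],
        ie50_within_iqr = subj$ie50_within_iqr[i],
        rct_percent = subj$rct_percent[i],
        taa_deg = subj$taa_deg[i], hta_deg = subj$hta_deg[i],
        fev1_pct_pred = subj$fev1_pct_pred[i],
        artifact_rates = spec$artifact_rates,
        seed = seeds[i]
      )
      recordings[[i]] <- generate_subject_recording(sp)
    }
    list(recordings = recordings, metadata = subj)
  })
}

#' Read / write a cohort specification as JSON
#'
#' @param path file path.
#' @return `read_cohort_spec` returns a [cohort_spec()];
#'   `write_cohort_spec` returns `path` invisibly.
#' @export
read_cohort_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(cohort_spec))
  extra <- setdiff(names(x), c(known, "schema_version"))
  if (length(extra))
    stop("unknown configuration keys: ", paste(extra, collapse = ", "))
  x$schema_version <- NULL
  if (!is.null(x$artifact_rates)) x$artifact_rates <- unlist(x$artifact_rates)
  do.call(cohort_spec, x)
}

#' @rdname read_cohort_spec
#' @param spec a [cohort_spec()] to serialize.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  out <- unclass(spec)
  out$artifact_rates <- as.list(out$artifact_rates)
  out <- c(list(schema_version = 1L), out)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
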