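# Independent oracles used across the suite. These deliberately avoid the
# package's closed forms and interpolation code paths.

# IE50 of a continuous breath profile by dense-grid numerical
# differentiation: central differences on a 1e5-point grid, 50% crossings
# located on the grid, rates read off at the bracketing step.
dense_ie50 <- function(tI, tE, amplitude = 1, shape, n_grid = 1e5) {
  t <- seq(0, tI + tE, length.out = n_grid)
  x <- breath_profile(t, tI, tE, amplitude, shape)
  dt <- t[2] - t[1]
  rate <- c(NA, (x[3:n_grid] - x[1:(n_grid - 2)]) / (2 * dt), NA)
  ins <- which(t <= tI)
  exp_ <- which(t > tI)
  rate_at_level <- function(idx, level) {
    v <- x[idx] - level
    j <- which(v[-length(v)] * v[-1] <= 0)[1]
    mean(abs(rate[idx[c(j, j + 1)]]), na.rm = TRUE)
  }
  tif50 <- rate_at_level(ins, amplitude / 2)
  tef50 <- rate_at_level(exp_, amplitude / 2)
  tif50 / tef50
}

# CLES by explicit pair enumeration (double loop)
brute_cles <- function(x, y) {
  wins <- 0
  for (xi in x) for (yi in y) {
    if (yi > xi) wins <- wins + 1
    else if (yi == xi) wins <- wins + 0.5
  }
  100 * wins / (length(x) * length(y))
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
exact_mwu_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  u_stat <- function(sel) {
    r <- rank(pool)
    sum(r[sel]) - n2 * (n2 + 1) / 2
  }
  obs <- u_stat((n1 + 1):(n1 + n2))
  combos <- utils::combn(n1 + n2, n2)
  us <- apply(combos, 2, u_stat)
  mu <- n1 * n2 / 2
  mean(abs(us - mu) >= abs(obs - mu))
}

# one full sinusoidal breath (trough to trough) with the second compartment
# delayed by `delta_deg` degrees of the cycle
sinusoid_phase_trace <- function(delta_deg, period = 4, fs = 30) {
  t <- seq(0, 4 * period, by = 1 / fs)
  ref <- -cos(2 * pi * t / period)
  sec <- -cos(2 * pi * (t / period - delta_deg / 360))
  displacement_trace(t, list(total = ref + sec, thorax = ref, abdomen = sec))
}

# recording helper with clean defaults
quiet_subject <- function(seed, duration = 120, ...) {
  generate_subject_recording(subject_spec(duration = duration, seed = seed, ...))
}

match_ground_truth <- function(analysis, recording) {
  gt <- recording$ground_truth
  br <- analysis$breaths
  m <- analysis$records
  bi <- match(m$breath_id, br$breath_id)
  k <- vapply(br$start_time[bi],
              function(st) which.min(abs(gt$t_start - st)), integer(1))
  list(records = m, truth = gt[k, ], start_time = br$start_time[bi])
}

# concatenate breaths into a trace with partial lead-in/lead-out limbs so
# every listed breath has interior trough boundaries
breath_train <- function(specs, fs = 30) {
  segs <- lapply(specs, generate_breath, sampling_rate = fs)
  x <- Reduce(function(a, b) c(a, b[-1]), segs)
  lead <- rev(segs[[1]][2:40])
  tail_ <- segs[[1]][2:40]
  x <- c(lead, x, tail_)
  displacement_trace((seq_along(x) - 1) / fs, list(total = x))
}
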