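# Independent oracles (brute-force enumerations) and small fixture
# builders shared across the test files.

# O(n^2) trailing-window median: explicit membership per window
brute_rolling_median <- function(time, values, window = 30) {
  vapply(seq_along(time), function(i) {
    median(values[time > time[i] - window & time <= time[i]])
  }, numeric(1))
}

# max trailing-window median with window end inside the final interval
brute_peak_final <- function(time, values, ramp_end, window = 30,
                             final_s = 60) {
  meds <- brute_rolling_median(time, values, window)
  max(meds[time >= ramp_end - final_s])
}

# Benjamini-Hochberg step-up from the definition: q_(i) = min_{j>=i}
# p_(j) * m / j, capped at 1, original order restored
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  q
}

# BH step-up rejection set at level alpha, straight from the procedure:
# reject the k smallest p-values, k = max{ i : p_(i) <= alpha * i / m }
brute_bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ok <- which(p[o] <= alpha * seq_len(m) / m)
  if (length(ok) == 0) return(integer(0))
  sort(o[seq_len(max(ok))])
}

# gas-exchange series with random irregular sampling, for oracle checks
random_session <- function(n = 200, seed = 1) {
  set.seed(seed)
  time <- cumsum(runif(n, 0.5, 3))
  n_unl <- max(5L, floor(n * 0.3))
  phase <- c(rep("unloaded", n_unl), rep("ramp", n - n_unl))
  tibble::tibble(
    time_s = time,
    vo2 = runif(n, 5, 40),
    vco2 = runif(n, 5, 45),
    ve = runif(n, 10, 120),
    hr = round(runif(n, 80, 190)),
    workload = ifelse(phase == "ramp", seq_len(n) * 0.5, 0),
    phase = phase)
}

# exact piecewise-linear VCO2-vs-VO2 session; `vat` should lie on the
# ramp VO2 grid for exact-recovery assertions
piecewise_session <- function(vat, s1, s2, v0 = 7, peak = 25, n_ramp = 240,
                              unloaded_s = 60, grid = 2, rer0 = 0.8) {
  t_unl <- seq(0, unloaded_s - grid, by = grid)
  t_ramp <- seq(unloaded_s, unloaded_s + (n_ramp - 1) * grid, by = grid)
  vo2_r <- seq(v0, peak, length.out = n_ramp)
  b0 <- rer0 * v0 - s1 * v0
  vco2_r <- ifelse(vo2_r <= vat, b0 + s1 * vo2_r,
                   b0 + s1 * vat + s2 * (vo2_r - vat))
  n_u <- length(t_unl)
  tibble::tibble(
    time_s = c(t_unl, t_ramp),
    vo2 = c(rep(v0, n_u), vo2_r),
    vco2 = c(rep(rer0 * v0, n_u), vco2_r),
    ve = 2 + 2 * c(rep(rer0 * v0, n_u), vco2_r),
    hr = seq(90, 170, length.out = n_u + n_ramp),
    workload = c(rep(0, n_u), seq(0, 150, length.out = n_ramp)),
    phase = c(rep("unloaded", n_u), rep("ramp", n_ramp)))
}

# the ramp VO2 grid of piecewise_session, to pick on-grid breakpoints
piecewise_grid <- function(v0 = 7, peak = 25, n_ramp = 240) {
  seq(v0, peak, length.out = n_ramp)
}

hr_rec <- function(id, times_s, hr = 70, context = "unknown",
                   origin = "2020-01-06") {
  tibble::tibble(
    participant_id = id,
    timestamp = as.POSIXct(origin, tz = "UTC") + times_s,
    hr_bpm = rep_len(hr, length(times_s)),
    context = rep_len(context, length(times_s)))
}

step_rec <- function(id, start_s, end_s, steps, origin = "2020-01-06") {
  t0 <- as.POSIXct(origin, tz = "UTC")
  tibble::tibble(participant_id = rep_len(id, length(start_s)),
                 start = t0 + start_s, end = t0 + end_s,
                 steps = steps)
}
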