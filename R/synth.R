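# Synthetic cohort, smartwatch-stream and CPET-session generators with
# known ground truth. Every downstream stage (stream processing, gas-
# exchange indices, association battery) is exercisable against planted
# truth without any external data.

#' Parameters for the synthetic cohort generator
#'
#' Bundles every knob of the generator with defaults chosen to emulate a
#' middle-aged community cohort wearing a smartwatch during waking hours:
#' mean age 53 (SD 9) years, mean nonactive heart rate 73 (SD 6) bpm,
#' mean 7269 (SD 2760) daily steps, and a median daily wear time near
#' 14 hours. A single latent fitness factor (SD 1) links the watch
#' summaries to the CPET indices: each +1 SD of fitness lowers nonactive
#' HR by `beta_hr_per_sd_fitness` bpm and raises daily steps by
#' `beta_steps_per_sd_fitness`.
#'
#' The recording-interval signature separating active from sedentary HR
#' records is planted exactly: gaps between consecutive HR records in an
#' active hour are below `gap_cut_s` (60 s) with probability
#' `1 - gap_leakage`, and gaps in a sedentary hour are above it with the
#' same probability. Hourly step totals are at or above
#' `hourly_step_cut` in active hours and below it in sedentary hours,
#' each crossed with probability `step_leakage`.
#'
#' @param n_participants Number of participants (>= 1).
#' @param follow_up_days_range Two integers; per-participant follow-up is
#'   drawn uniformly from this range (days).
#' @param latent_fitness_sd SD of the latent fitness factor.
#' @param beta_hr_per_sd_fitness Planted effect of fitness on nonactive
#'   HR, bpm per SD (negative: fitter participants have lower HR).
#' @param beta_steps_per_sd_fitness Planted effect of fitness on daily
#'   steps, steps per SD.
#' @param hr_noise_sd Within-person SD of individual HR records, bpm.
#' @param hr_mean,hr_between_sd Population mean nonactive HR and the
#'   between-person residual SD (bpm) after the fitness effect.
#' @param steps_mean,steps_between_sd Population mean daily steps and the
#'   between-person residual SD after the fitness effect.
#' @param active_fraction Proportion of waking time spent active.
#' @param active_bout_hours Mean length of an active bout, in whole
#'   clock hours (activity is generated at hour resolution).
#' @param wear_hours_mean,wear_hours_sd Daily wear time distribution
#'   (hours); wear is a contiguous block inside the waking window.
#' @param waking_window Two clock hours (24 h) bounding the waking day;
#'   no records are generated outside it.
#' @param gap_active_median_s,gap_sedentary_median_s Median HR recording
#'   interval in active and sedentary hours (seconds).
#' @param gap_cut_s Interval cut separating the two modes (seconds).
#' @param gap_leakage Probability an interval crosses `gap_cut_s` into
#'   the other mode's side.
#' @param hourly_step_cut Step-count cut separating active from
#'   sedentary hours.
#' @param step_leakage Probability an hourly step total crosses
#'   `hourly_step_cut`.
#' @param active_hr_elevation Mean HR elevation during activity (bpm).
#' @param context_labeled_frac Fraction of HR records carrying a
#'   device-supplied motion-context label.
#' @param bmi_fitness_slope BMI decrease per SD of fitness (kg/m^2).
#' @param start_date Earliest enrollment date; enrollment is spread
#'   uniformly over the following year.
#' @param tz Timezone in which all record timestamps are expressed.
#' @param cpet List of CPET-session settings; see
#'   [generate_cpet_sessions()].
#' @param seed Integer seed; all generator output is a deterministic
#'   function of the parameters including the seed.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_participants = 100,
                          follow_up_days_range = c(60, 200),
                          latent_fitness_sd = 1,
                          beta_hr_per_sd_fitness = -2.4,
                          beta_steps_per_sd_fitness = 1268,
                          hr_noise_sd = 5,
                          hr_mean = 73,
                          hr_between_sd = 5.5,
                          steps_mean = 7269,
                          steps_between_sd = 2450,
                          active_fraction = 0.25,
                          active_bout_hours = 2,
                          wear_hours_mean = 14,
                          wear_hours_sd = 1,
                          waking_window = c(7, 22),
                          gap_active_median_s = 40,
                          gap_sedentary_median_s = 420,
                          gap_cut_s = 60,
                          gap_leakage = 0.01,
                          hourly_step_cut = 30,
                          step_leakage = 0.01,
                          active_hr_elevation = 30,
                          context_labeled_frac = 0.31,
                          bmi_fitness_slope = 1.5,
                          start_date = "2019-01-01",
                          tz = "UTC",
                          cpet = list(),
                          seed = 1L) {
  check_that(is.numeric(n_participants) && length(n_participants) == 1 &&
               n_participants >= 1, "n_participants", "must be >= 1")
  check_that(length(follow_up_days_range) == 2 &&
               follow_up_days_range[1] >= 1 &&
               follow_up_days_range[1] <= follow_up_days_range[2],
             "follow_up_days_range", "must be an increasing pair of days >= 1")
  for (f in c("latent_fitness_sd", "hr_noise_sd", "hr_between_sd",
              "steps_between_sd", "wear_hours_sd")) {
    check_that(get(f) >= 0, f, "must be >= 0")
  }
  check_that(active_fraction >= 0 && active_fraction <= 1,
             "active_fraction", "must lie in [0, 1]")
  check_that(gap_leakage >= 0 && gap_leakage <= 1, "gap_leakage",
             "must lie in [0, 1]")
  check_that(step_leakage >= 0 && step_leakage <= 1, "step_leakage",
             "must lie in [0, 1]")
  check_that(wear_hours_mean >= 0, "wear_hours_mean", "must be >= 0")
  check_that(gap_active_median_s > 0 && gap_sedentary_median_s > 0,
             "gap_active_median_s", "gap medians must be positive")
  check_that(active_bout_hours >= 1, "active_bout_hours", "must be >= 1 hour")

  cpet_defaults <- list(
    grid_s = 2, unloaded_s = 180, ramp_s = 600, ramp_rate_w_min = 15,
    vo2_unloaded = 7, vslope_lower = 0.95, vslope_upper_mean = 1.30,
    vslope_upper_sd = 0.03, rer_start = 0.82, noise_sd = 0.8,
    ve_noise_sd = 1.5, hr_noise_sd = 2,
    ve_vco2_nadir_mean = 27, ve_vco2_nadir_sd = 2.3,
    ve_vco2_fitness_slope = 1.0,
    pct_max_hr_mean = 90, pct_max_hr_sd = 9, pct_max_hr_fitness_slope = 2,
    sbp_w_slope_base = 0.29, sbp_w_slope_female = 0.09,
    sbp_w_slope_fitness = -0.03, sbp_w_slope_sd = 0.10)
  cpet <- utils::modifyList(cpet_defaults, cpet)
  check_that(cpet$ramp_rate_w_min > 0, "cpet$ramp_rate_w_min",
             "ramp rate must be positive")
  check_that(cpet$grid_s > 0, "cpet$grid_s", "must be positive")

  p <- list(
    n_participants = as.integer(n_participants),
    follow_up_days_range = as.integer(follow_up_days_range),
    latent_fitness_sd = latent_fitness_sd,
    beta_hr_per_sd_fitness = beta_hr_per_sd_fitness,
    beta_steps_per_sd_fitness = beta_steps_per_sd_fitness,
    hr_noise_sd = hr_noise_sd, hr_mean = hr_mean,
    hr_between_sd = hr_between_sd,
    steps_mean = steps_mean, steps_between_sd = steps_between_sd,
    active_fraction = active_fraction,
    active_bout_hours = active_bout_hours,
    wear_hours_mean = wear_hours_mean, wear_hours_sd = wear_hours_sd,
    waking_window = as.integer(waking_window),
    gap_active_median_s = gap_active_median_s,
    gap_sedentary_median_s = gap_sedentary_median_s,
    gap_cut_s = gap_cut_s, gap_leakage = gap_leakage,
    hourly_step_cut = hourly_step_cut, step_leakage = step_leakage,
    active_hr_elevation = active_hr_elevation,
    context_labeled_frac = context_labeled_frac,
    bmi_fitness_slope = bmi_fitness_slope,
    start_date = as.Date(start_date), tz = tz,
    cpet = cpet, seed = as.integer(seed))
  class(p) <- "cohort_params"
  p
}

#' Generate a synthetic cohort with latent fitness
#'
#' Draws one row per participant: demographics, anthropometrics,
#' cardiometabolic covariates, treatment flags, enrollment season and
#' state — everything the fully adjusted association model uses — plus a
#' ground-truth table carrying the latent fitness factor, the true peak
#' VO2 and ventilatory-threshold VO2, and the participant-level targets
#' for nonactive HR and daily steps that the stream generator realises.
#'
#' @param params A [cohort_params()] object.
#' @return List with elements `covariates` and `truth` (tibbles).
#' @export
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(child_seed(params$seed, "cohort"))
  n <- params$n_participants
  id <- sprintf("P%04d", seq_len(n))

  latent <- rnorm(n, 0, params$latent_fitness_sd)
  age <- pmin(85, pmax(25, rnorm(n, 53, 9)))
  sex <- ifelse(runif(n) < 0.59, "female", "male")
  race <- ifelse(runif(n) < 0.91, "white", "other")
  height_cm <- ifelse(sex == "male", rnorm(n, 178, 7), rnorm(n, 164, 6.5))
  bmi <- pmax(16, rnorm(n, 28, 5) - params$bmi_fitness_slope * latent)
  weight_kg <- bmi * (height_cm / 100)^2
  current_smoker <- as.integer(runif(n) < 0.07)
  total_chol <- pmax(90, rnorm(n, 190, 35))
  hdl <- pmax(20, rnorm(n, 56, 15))
  glucose <- pmax(60, rnorm(n, 97, 14) + 18 * (runif(n) < 0.05))
  diabetes <- as.integer(glucose >= 126 | runif(n) < 0.01)
  rest_sbp <- pmax(85, rnorm(n, 118, 14))
  htn_med <- as.integer(runif(n) < plogis(-2.2 + 0.05 * (age - 53)))
  hypertension <- as.integer(rest_sbp >= 140 | htn_med == 1)
  lipid_med <- as.integer(runif(n) < plogis(-1.8 + 0.05 * (age - 53)))
  hyperlipidemia <- as.integer(total_chol >= 200 | lipid_med == 1)
  hr_lowering_med <- as.integer(runif(n) < 0.10)
  prevalent_cvd <- as.integer(runif(n) < 0.03)
  enroll_date <- params$start_date + floor(runif(n, 0, 365))
  month <- as.integer(format(enroll_date, "%m"))
  season <- c("winter", "winter", "spring", "spring", "spring", "summer",
              "summer", "summer", "fall", "fall", "fall", "winter")[month]
  state <- sample(c("MA", "NH", "RI", "CT", "other"), n, replace = TRUE,
                  prob = c(0.70, 0.08, 0.07, 0.05, 0.10))
  fr <- params$follow_up_days_range
  follow_up_days <- as.integer(floor(runif(n, fr[1], fr[2] + 1)))

  peak_mean <- ifelse(sex == "male", 26.6, 21.6)
  true_peak_vo2 <- pmax(10, peak_mean + 4 * latent + rnorm(n, 0, 4.5))
  true_vat_vo2 <- true_peak_vo2 * runif(n, 0.50, 0.58)
  target_nonactive_hr <-
    params$hr_mean + params$beta_hr_per_sd_fitness * latent +
    rnorm(n, 0, params$hr_between_sd)
  target_daily_steps <-
    pmax(500, params$steps_mean + params$beta_steps_per_sd_fitness * latent +
           rnorm(n, 0, params$steps_between_sd))

  covariates <- tibble::tibble(
    participant_id = id, age = age, sex = sex, race = race,
    height_cm = height_cm, weight_kg = weight_kg, bmi = bmi,
    current_smoker = current_smoker, total_chol = total_chol, hdl = hdl,
    glucose = glucose, diabetes = diabetes, rest_sbp = rest_sbp,
    hypertension = hypertension, hyperlipidemia = hyperlipidemia,
    htn_med = htn_med, lipid_med = lipid_med,
    hr_lowering_med = hr_lowering_med, prevalent_cvd = prevalent_cvd,
    season = season, state = state, enroll_date = enroll_date,
    follow_up_days = follow_up_days)
  truth <- tibble::tibble(
    participant_id = id, latent_fitness = latent,
    true_peak_vo2 = true_peak_vo2, true_vat_vo2 = true_vat_vo2,
    target_nonactive_hr = target_nonactive_hr,
    target_daily_steps = target_daily_steps)
  list(covariates = covariates, truth = truth)
}

#' Generate raw smartwatch HR and step streams
#'
#' Realises second-resolution HR records and hourly step intervals for
#' every participant in a cohort. Each waking day is a contiguous wear
#' block inside the waking window; wear hours alternate between active
#' and sedentary states under a two-state Markov chain at hour
#' resolution. Active hours record HR densely (median interval
#' `gap_active_median_s`) and carry at least `hourly_step_cut` steps;
#' sedentary hours record sparsely and carry fewer. Recording intervals
#' cross the 60 s cut with exactly probability `gap_leakage`, planting
#' the interval-frequency signature the motion-context classifier
#' exploits. No records fall outside wear periods.
#'
#' @param cohort Output of [generate_cohort()].
#' @param params The same [cohort_params()] object.
#' @param participants Optional character vector restricting output to a
#'   subset of participant ids.
#' @return List with tibbles `hr` (participant_id, timestamp, hr_bpm,
#'   context, true_context) and `steps` (participant_id, start, end,
#'   steps). `context` is the device label, `unknown` where unlabeled;
#'   `true_context` is ground truth.
#' @export
generate_watch_streams <- function(cohort, params = cohort_params(),
                                   participants = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(child_seed(params$seed, "watch"))
  cov <- cohort$covariates
  tru <- cohort$truth
  if (!is.null(participants)) {
    cov <- cov[cov$participant_id %in% participants, , drop = FALSE]
    tru <- tru[tru$participant_id %in% participants, , drop = FALSE]
  }
  tz <- params$tz
  win <- params$waking_window
  win_len <- win[2] - win[1]

  empty <- list(
    hr = tibble::tibble(participant_id = character(),
                        timestamp = as.POSIXct(character(), tz = tz),
                        hr_bpm = numeric(), context = character(),
                        true_context = character()),
    steps = tibble::tibble(participant_id = character(),
                           start = as.POSIXct(character(), tz = tz),
                           end = as.POSIXct(character(), tz = tz),
                           steps = numeric()))
  if (nrow(cov) == 0) return(empty)

  # --- participant-day table ------------------------------------------------
  days <- tibble::tibble(
    participant_id = rep(cov$participant_id, cov$follow_up_days),
    day_index = sequence(cov$follow_up_days),
    enroll = rep(cov$enroll_date, cov$follow_up_days))
  days$date <- days$enroll + days$day_index - 1L
  nd <- nrow(days)
  if (params$wear_hours_mean <= 0) {
    n_wear <- rep(0L, nd)
  } else {
    n_wear <- pmin(win_len, pmax(
      0L, as.integer(round(rnorm(nd, params$wear_hours_mean,
                                 params$wear_hours_sd)))))
  }
  offset <- floor(runif(nd) * (win_len - n_wear + 1))
  days$wear_start <- win[1] + offset
  days$n_wear <- n_wear

  # --- hour-level activity chain (vectorised over days, loop over slots) ----
  p_act <- params$active_fraction
  if (p_act >= 1) {
    a11 <- 1; a01 <- 1
  } else if (p_act <= 0) {
    a11 <- 0; a01 <- 0
  } else {
    a11 <- 1 - 1 / params$active_bout_hours
    a01 <- min(1, p_act * (1 - a11) / (1 - p_act))
  }
  state <- matrix(FALSE, nd, win_len)
  state[, 1] <- runif(nd) < p_act
  if (win_len > 1) {
    for (k in 2:win_len) {
      u <- runif(nd)
      state[, k] <- ifelse(state[, k - 1], u < a11, u < a01)
    }
  }

  # expand to wear hours only
  slot <- rep(seq_len(win_len), each = nd)
  day_id <- rep(seq_len(nd), times = win_len)
  worn <- slot > (days$wear_start[day_id] - win[1]) &
    slot <= (days$wear_start[day_id] - win[1]) + days$n_wear[day_id]
  hours <- tibble::tibble(
    day_id = day_id[worn],
    hour_of_day = win[1] + slot[worn] - 1L,
    active = c(state)[worn])
  if (nrow(hours) == 0) return(empty)
  hours$participant_id <- days$participant_id[hours$day_id]
  hours$date <- days$date[hours$day_id]
  hours$hour_start <- as.POSIXct(as.character(hours$date), tz = tz) +
    hours$hour_of_day * 3600
  hours <- hours[order(hours$participant_id, hours$hour_start), ]
  nh <- nrow(hours)

  # --- hourly step totals ---------------------------------------------------
  cut <- params$hourly_step_cut
  active_by_day <- tapply(hours$active, hours$day_id, sum)
  hours$n_active_day <- as.integer(active_by_day[as.character(hours$day_id)])
  target_steps <- setNames(tru$target_daily_steps, tru$participant_id)
  share <- target_steps[hours$participant_id] /
    pmax(1L, hours$n_active_day)
  leak <- runif(nh) < params$step_leakage
  steps_active <- pmax(cut, round(share * exp(rnorm(nh, 0, 0.25))))
  steps_sed <- pmin(cut - 1, rpois(nh, 8))
  hours$hour_steps <- ifelse(
    hours$active,
    ifelse(leak, floor(runif(nh, 0, cut)), steps_active),
    ifelse(leak, floor(runif(nh, cut, 4 * cut)), steps_sed))

  # --- HR record times: per-hour gap draws, cumulative-sum per hour ---------
  # sdlog fixes the untruncated crossing probability at 1%; truncated
  # sampling in rgap then plants the configured leakage exactly.
  sd_act <- abs(log(params$gap_cut_s) - log(params$gap_active_median_s)) /
    qnorm(0.99)
  sd_sed <- abs(log(params$gap_sedentary_median_s) - log(params$gap_cut_s)) /
    qnorm(0.99)

  gen_mode <- function(idx, median_s, sdlog, side, m_draws) {
    h <- length(idx)
    if (h == 0) {
      return(tibble::tibble(hour_row = integer(), t_in_hour = numeric()))
    }
    gaps <- rgap(h * m_draws, log(median_s), sdlog, params$gap_cut_s,
                 side, params$gap_leakage)
    cs <- cumsum(gaps)
    base <- c(0, cs[seq(m_draws, h * m_draws - m_draws, by = m_draws)])
    t_in <- cs - rep(base, each = m_draws)
    keep <- t_in < 3600
    tibble::tibble(hour_row = rep(idx, each = m_draws)[keep],
                   t_in_hour = t_in[keep])
  }
  m_act <- as.integer(ceiling(3600 / params$gap_active_median_s * 1.5)) + 10L
  m_sed <- max(8L, as.integer(ceiling(3600 / params$gap_sedentary_median_s *
                                        3))) + 8L
  rec_a <- gen_mode(which(hours$active), params$gap_active_median_s, sd_act,
                    "below", m_act)
  rec_s <- gen_mode(which(!hours$active), params$gap_sedentary_median_s,
                    sd_sed, "above", m_sed)
  rec <- rbind(rec_a, rec_s)
  if (nrow(rec) == 0) return(empty)
  rec$participant_id <- hours$participant_id[rec$hour_row]
  rec$timestamp <- hours$hour_start[rec$hour_row] + floor(rec$t_in_hour)
  rec$active <- hours$active[rec$hour_row]

  target_hr <- setNames(tru$target_nonactive_hr, tru$participant_id)
  nr <- nrow(rec)
  rec$hr_bpm <- round(pmin(220, pmax(35,
    target_hr[rec$participant_id] +
      ifelse(rec$active, params$active_hr_elevation, 0) +
      rnorm(nr, 0, params$hr_noise_sd))))
  labeled <- runif(nr) < params$context_labeled_frac
  rec$true_context <- ifelse(rec$active, "active", "sedentary")
  rec$context <- ifelse(labeled, rec$true_context, "unknown")

  hr <- tibble::as_tibble(rec[order(rec$participant_id, rec$timestamp),
                              c("participant_id", "timestamp", "hr_bpm",
                                "context", "true_context")])
  # drop same-second duplicates so timestamps are strictly increasing
  dup <- duplicated(hr[c("participant_id", "timestamp")])
  hr <- hr[!dup, ]

  steps <- tibble::tibble(
    participant_id = hours$participant_id,
    start = hours$hour_start,
    end = hours$hour_start + 3600,
    steps = as.numeric(hours$hour_steps))
  steps <- steps[order(steps$participant_id, steps$start), ]

  list(hr = hr, steps = tibble::as_tibble(steps))
}

#' Generate one participant's smartwatch streams
#'
#' Convenience wrapper around [generate_watch_streams()] for a single
#' participant.
#' @inheritParams generate_watch_streams
#' @param participant A participant id present in the cohort.
#' @return Same shape as [generate_watch_streams()].
#' @export
generate_watch_stream <- function(participant, cohort,
                                  params = cohort_params()) {
  if (!participant %in% cohort$covariates$participant_id) {
    stop(sprintf("participant '%s' not found in cohort", participant),
         call. = FALSE)
  }
  generate_watch_streams(cohort, params, participants = participant)
}

#' Generate breath-by-breath CPET sessions
#'
#' Emulates a cycle-ergometer ramp test on a regular sampling grid:
#' 3 minutes of unloaded pedaling followed by incremental ramp exercise
#' at `ramp_rate_w_min`. VO2 rises linearly in expectation to the
#' participant's true peak; VCO2 follows a continuous two-segment linear
#' function of VO2 with the slope break planted at the true ventilatory
#' anaerobic threshold (slope below 1 before the break, above 1 after),
#' so the V-slope detector has an identifiable target. VE tracks VCO2
#' through a U-shaped ventilatory-efficiency profile whose minimum is
#' the participant's planted VE/VCO2 nadir. HR ramps toward a planted
#' percentage of the age-predicted maximum. Rest and peak systolic blood
#' pressures realise a planted pressure-to-workload slope.
#'
#' @param cohort Output of [generate_cohort()].
#' @param params A [cohort_params()] object; the `cpet` element holds
#'   grid spacing, ramp settings and noise SDs.
#' @param participants Optional id subset.
#' @return List with `breath` (tibble: participant_id, time_s, vo2,
#'   vco2, ve, hr, workload, phase; vo2/vco2 in mL/kg/min, ve in L/min),
#'   `sbp` (participant_id, rest_sbp, peak_sbp, peak_workload_w) and
#'   `session_truth` (planted nadir, %max HR and SBP/W slope).
#' @export
generate_cpet_sessions <- function(cohort, params = cohort_params(),
                                   participants = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  cp <- params$cpet
  if (cp$ramp_rate_w_min <= 0) {
    stop("invalid `cpet$ramp_rate_w_min`: ramp rate must be positive",
         call. = FALSE)
  }
  set.seed(child_seed(params$seed, "cpet"))
  cov <- cohort$covariates
  tru <- cohort$truth
  if (!is.null(participants)) {
    keep <- cov$participant_id %in% participants
    cov <- cov[keep, , drop = FALSE]
    tru <- tru[tru$participant_id %in% participants, , drop = FALSE]
  }
  n <- nrow(cov)
  stopifnot(all(tru$true_vat_vo2 < tru$true_peak_vo2))

  # per-participant session parameters
  s1 <- rep(cp$vslope_lower, n)
  s2 <- pmax(s1 + 0.1, rnorm(n, cp$vslope_upper_mean, cp$vslope_upper_sd))
  nadir <- pmax(20, cp$ve_vco2_nadir_mean -
                  cp$ve_vco2_fitness_slope * tru$latent_fitness +
                  rnorm(n, 0, cp$ve_vco2_nadir_sd))
  pct_max_hr <- pmin(108, pmax(
    60, cp$pct_max_hr_mean + cp$pct_max_hr_fitness_slope *
      tru$latent_fitness + rnorm(n, 0, cp$pct_max_hr_sd)))
  slope_sbp <- pmax(0.05, cp$sbp_w_slope_base +
                      cp$sbp_w_slope_female * (cov$sex == "female") +
                      cp$sbp_w_slope_fitness * tru$latent_fitness +
                      rnorm(n, 0, cp$sbp_w_slope_sd))
  peak_w <- cp$ramp_rate_w_min * cp$ramp_s / 60
  rest_sbp <- cov$rest_sbp
  peak_sbp <- round(rest_sbp + slope_sbp * peak_w)

  t_all <- seq(0, cp$unloaded_s + cp$ramp_s, by = cp$grid_s)
  phase <- ifelse(t_all < cp$unloaded_s, "unloaded", "ramp")
  n_t <- length(t_all)

  breath <- vector("list", n)
  for (i in seq_len(n)) {
    peak <- tru$true_peak_vo2[i]
    vat <- tru$true_vat_vo2[i]
    v0 <- min(cp$vo2_unloaded, vat * 0.8)
    vo2_true <- ifelse(phase == "unloaded", v0,
                       v0 + (peak - v0) * (t_all - cp$unloaded_s) / cp$ramp_s)
    b0 <- cp$rer_start * v0 - s1[i] * v0
    vco2_true <- ifelse(vo2_true <= vat,
                        b0 + s1[i] * vo2_true,
                        b0 + s1[i] * vat + s2[i] * (vo2_true - vat))
    u <- t_all / max(t_all)
    ratio <- nadir[i] + (32 - nadir[i]) * ((u - 0.7) / 0.7)^2
    ve_true <- ratio * vco2_true * cov$weight_kg[i] / 1000
    hr_max_pred <- 208 - 0.7 * cov$age[i]
    hr_peak <- pct_max_hr[i] / 100 * hr_max_pred
    hr_true <- ifelse(phase == "unloaded", 90,
                      90 + (hr_peak - 90) * (t_all - cp$unloaded_s) / cp$ramp_s)
    workload <- ifelse(phase == "unloaded", 0,
                       cp$ramp_rate_w_min * (t_all - cp$unloaded_s) / 60)
    breath[[i]] <- tibble::tibble(
      participant_id = cov$participant_id[i],
      time_s = t_all,
      vo2 = pmax(0.5, vo2_true + rnorm(n_t, 0, cp$noise_sd)),
      vco2 = pmax(0.5, vco2_true + rnorm(n_t, 0, cp$noise_sd)),
      ve = pmax(1, ve_true + rnorm(n_t, 0, cp$ve_noise_sd)),
      hr = round(pmax(40, hr_true + rnorm(n_t, 0, cp$hr_noise_sd))),
      workload = workload,
      phase = phase)
  }
  list(
    breath = dplyr::bind_rows(breath),
    sbp = tibble::tibble(participant_id = cov$participant_id,
                         rest_sbp = round(rest_sbp), peak_sbp = peak_sbp,
                         peak_workload_w = peak_w),
    session_truth = tibble::tibble(
      participant_id = cov$participant_id,
      true_ve_vco2_nadir = nadir, true_pct_max_hr = pct_max_hr,
      true_sbp_w_slope = slope_sbp))
}

#' Generate one participant's CPET session
#' @inheritParams generate_cpet_sessions
#' @param participant A participant id present in the cohort.
#' @export
generate_cpet_session <- function(participant, cohort,
                                  params = cohort_params()) {
  if (!participant %in% cohort$covariates$participant_id) {
    stop(sprintf("participant '%s' not found in cohort", participant),
         call. = FALSE)
  }
  generate_cpet_sessions(cohort, params, participants = participant)
}

#' Participant-level synthetic summaries (fast path)
#'
#' Draws watch summaries and CPET indices directly at the participant
#' level from the same latent-fitness model the stream and session
#' generators realise, skipping record-level simulation. Intended for
#' simulation studies of the association battery, where hundreds of
#' cohorts are needed and the record-level detail is irrelevant.
#'
#' @param params A [cohort_params()] object.
#' @return List with `covariates`, `watch_summaries`, `cpet_results`
#'   and `truth` tibbles, shaped like the outputs of the full pipeline.
#' @export
generate_summaries <- function(params = cohort_params()) {
  cohort <- generate_cohort(params)
  set.seed(child_seed(params$seed, "summaries"))
  cov <- cohort$covariates
  tru <- cohort$truth
  cp <- params$cpet
  n <- nrow(cov)

  n_days <- cov$follow_up_days
  watch <- tibble::tibble(
    participant_id = cov$participant_id,
    nonactive_hr_mean = tru$target_nonactive_hr + rnorm(n, 0, 0.15),
    n_nonactive_records = as.integer(round(n_days * 80)),
    mean_daily_steps = tru$target_daily_steps + rnorm(n, 0, 60),
    n_hr_days = n_days, n_step_days = n_days,
    median_wear_hours = pmin(15, pmax(8, round(rnorm(n, params$wear_hours_mean,
                                                     params$wear_hours_sd)))),
    include_hr = n_days >= 30, include_steps = n_days >= 30)
  watch$include_primary <- watch$include_hr & watch$include_steps

  nadir <- pmax(20, cp$ve_vco2_nadir_mean -
                  cp$ve_vco2_fitness_slope * tru$latent_fitness +
                  rnorm(n, 0, cp$ve_vco2_nadir_sd))
  pct_max_hr <- pmin(108, pmax(
    60, cp$pct_max_hr_mean + cp$pct_max_hr_fitness_slope *
      tru$latent_fitness + rnorm(n, 0, cp$pct_max_hr_sd)))
  slope_sbp <- pmax(0.05, cp$sbp_w_slope_base +
                      cp$sbp_w_slope_female * (cov$sex == "female") +
                      cp$sbp_w_slope_fitness * tru$latent_fitness +
                      rnorm(n, 0, cp$sbp_w_slope_sd))
  peak <- pmax(8, tru$true_peak_vo2 + rnorm(n, 0, 0.3))
  vat <- pmin(peak * 0.95, pmax(5, tru$true_vat_vo2 + rnorm(n, 0, 0.4)))
  cpet_results <- tibble::tibble(
    participant_id = cov$participant_id,
    peak_vo2 = peak,
    pct_predicted_peak_vo2 = percent_predicted_peak_vo2(
      peak, cov$age, cov$sex, cov$height_cm, cov$weight_kg),
    vat_vo2 = vat,
    ve_vco2_nadir = nadir,
    pct_predicted_max_hr = pct_max_hr,
    sbp_w_slope = slope_sbp,
    peak_rer = pmax(0.95, rnorm(n, 1.12, 0.035)),
    vat_low_confidence = FALSE)
  list(covariates = cov, watch_summaries = watch,
       cpet_results = cpet_results, truth = tru)
}

#' Simulate a regression-calibration cohort with a planted exposure effect
#'
#' Builds an analysis table in which the coefficient of the
#' population-standardized exposure is exactly `beta` (in outcome units
#' per SD), with the full adjusted covariate set available and the
#' exposure mildly correlated with age and BMI. Used to check type-I
#' error, confidence-interval coverage and estimate recovery of the
#' model-fitting machinery against known truth.
#'
#' @param n Sample size.
#' @param beta Planted effect, outcome units per SD of exposure.
#' @param outcome `"nonactive_hr"` (residual SD 6) or `"daily_steps"`
#'   (residual SD 2500).
#' @param seed Integer seed.
#' @return Tibble with the outcome, an `exposure` column (raw scale) and
#'   all adjusted-model covariates.
#' @export
simulate_association_data <- function(n, beta, outcome = "nonactive_hr",
                                      seed = 1L) {
  outcome <- match.arg(outcome, c("nonactive_hr", "daily_steps"))
  cohort <- generate_cohort(cohort_params(n_participants = n, seed = seed))
  cov <- cohort$covariates
  set.seed(child_seed(seed, "assoc-sim"))
  x_raw <- 0.3 * (cov$bmi - 28) / 5 - 0.2 * (cov$age - 53) / 9 + rnorm(n)
  x_z <- (x_raw - mean(x_raw)) / sd_pop(x_raw)
  lin <- -0.06 * (cov$age - 53) + 1.2 * (cov$sex == "male") +
    0.12 * (cov$bmi - 28) + 1.5 * cov$current_smoker
  if (outcome == "nonactive_hr") {
    y <- 73 + lin + beta * x_z + rnorm(n, 0, 6)
  } else {
    y <- 7269 - 120 * lin + beta * x_z + rnorm(n, 0, 2500)
  }
  out <- cov
  out$exposure <- 25 + 5 * x_raw
  out[[outcome]] <- y
  out$median_wear_hours <- pmin(15, pmax(8, round(rnorm(n, 14, 1))))
  out
}
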