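# Cardiopulmonary exercise test indices from breath-by-breath gas
# exchange: rolling 30-s medians, peak VO2, percent-predicted peak VO2,
# V-slope ventilatory anaerobic threshold, VE/VCO2 nadir,
# percent-predicted maximum HR, SBP-to-workload slope, and peak RER.

#' Reference-equation coefficients
#'
#' Predicted peak VO2 for cycle ergometry uses the sex-specific linear
#' equations of the standard exercise-testing reference: for men,
#' predicted VO2 (mL/min) = weight * (50.72 - 0.372 * age); for women,
#' predicted VO2 (mL/min) = (weight + 43) * (22.78 - 0.17 * age), with
#' weight in kg and age in years. Predicted maximum HR is the regression
#' estimate 208 - 0.7 * age. Both sets of coefficients are configuration
#' values and can be overridden per call.
#'
#' @format A list with elements `wasserman_hansen` (per-sex `a`, `b`,
#'   `weight_offset`) and `tanaka` (`intercept`, `age_slope`).
#' @export
cpet_reference_coefs <- list(
  wasserman_hansen = list(
    male = list(a = 50.72, b = 0.372, weight_offset = 0),
    female = list(a = 22.78, b = 0.17, weight_offset = 43)),
  tanaka = list(intercept = 208, age_slope = 0.7))

#' Trailing 30-second rolling medians
#'
#' For each sample time t, the median of values observed in the
#' right-closed window (t - window, t]. Windows are defined in time, not
#' sample count; windows holding fewer than `min_samples` values are
#' flagged.
#'
#' @param time Numeric sample times, strictly increasing (seconds).
#' @param values Numeric values aligned with `time`.
#' @param window Window length in seconds.
#' @param min_samples Windows with fewer samples are flagged.
#' @return Tibble `time`, `med`, `n_in_window`, `flagged`.
#' @export
rolling_median <- function(time, values, window = 30, min_samples = 3) {
  if (length(time) == 0) stop("empty series", call. = FALSE)
  stopifnot(length(time) == length(values), !is.unsorted(time, strictly = TRUE))
  if (length(time) >= 2 && window >= (max(time) - min(time)) * 2) {
    # window must be short relative to the series for a rolling summary
    # to be meaningful; a window twice the span is certainly an error
    stop("window longer than the series span", call. = FALSE)
  }
  n <- length(time)
  # left index of each window: first j with time[j] > time[i] - window
  left <- findInterval(time - window, time) + 1L
  med <- vapply(seq_len(n),
                function(i) median(values[left[i]:i]), numeric(1))
  n_in <- seq_len(n) - left + 1L
  tibble::tibble(time = time, med = med, n_in_window = n_in,
                 flagged = n_in < min_samples)
}

# ramp-phase subset with basic checks
ramp_phase <- function(series) {
  r <- series[series$phase == "ramp", , drop = FALSE]
  if (nrow(r) == 0) stop("no ramp phase in series", call. = FALSE)
  r
}

# highest rolling median with window end inside the final `final_s`
# seconds of the ramp phase
peak_windowed <- function(series, values_ramp, window = 30, final_s = 60) {
  r <- ramp_phase(series)
  span <- max(r$time_s) - min(r$time_s)
  if (span < final_s) {
    stop(sprintf("ramp phase spans %.0f s; at least %.0f s required",
                 span, final_s), call. = FALSE)
  }
  rm <- rolling_median(r$time_s, values_ramp, window = window)
  final <- rm$time >= max(r$time_s) - final_s
  max(rm$med[final])
}

#' Peak VO2
#'
#' The highest trailing 30-second median VO2 whose window ends within
#' the final minute of ramp exercise. Recovery samples are ignored.
#'
#' @param series Gas-exchange tibble with `time_s`, `vo2`, `phase`.
#' @param window,final_s Window and final-interval lengths (seconds).
#' @return Peak VO2 in the units of `vo2` (mL/kg/min).
#' @export
peak_vo2 <- function(series, window = 30, final_s = 60) {
  r <- ramp_phase(series)
  peak_windowed(series, r$vo2, window = window, final_s = final_s)
}

#' Percent-predicted peak VO2
#'
#' 100 x measured / predicted peak VO2, with the prediction from the
#' sex-specific cycle-ergometry reference equations (see
#' [cpet_reference_coefs]). Measured VO2 is per kg; the predicted
#' absolute value (mL/min) is divided by body weight for the ratio.
#'
#' @param measured_vo2 Measured peak VO2, mL/kg/min.
#' @param age Years.
#' @param sex `"male"` or `"female"` (vectorized).
#' @param height_cm,weight_kg Anthropometrics; height is accepted for
#'   interface completeness (the shipped equations use weight and age).
#' @param coefs Coefficient list, overridable.
#' @return Percentage (100 = exactly predicted).
#' @export
percent_predicted_peak_vo2 <- function(measured_vo2, age, sex,
                                       height_cm = NULL, weight_kg,
                                       coefs = cpet_reference_coefs$wasserman_hansen) {
  stopifnot(all(weight_kg > 0), all(age > 0), all(measured_vo2 > 0))
  sex <- match.arg(sex, c("male", "female"), several.ok = TRUE)
  sex <- rep_len(sex, length(measured_vo2))
  a <- ifelse(sex == "male", coefs$male$a, coefs$female$a)
  b <- ifelse(sex == "male", coefs$male$b, coefs$female$b)
  off <- ifelse(sex == "male", coefs$male$weight_offset,
                coefs$female$weight_offset)
  predicted_ml_min <- (weight_kg + off) * (a - b * age)
  if (any(predicted_ml_min <= 0)) {
    stop("nonpositive predicted peak VO2; check age/weight inputs",
         call. = FALSE)
  }
  100 * measured_vo2 / (predicted_ml_min / weight_kg)
}

#' Ventilatory anaerobic threshold by the V-slope method
#'
#' Fits a continuous two-segment piecewise-linear least-squares model of
#' VCO2 on VO2 over the ramp phase. The breakpoint is searched over a
#' candidate grid of interior sample VO2 values (restricted below the
#' `upper_quantile` quantile of ramp VO2 to stay clear of the
#' respiratory-compensation region), keeping only candidates where the
#' upper slope exceeds the lower slope, and choosing the candidate
#' minimizing the residual sum of squares. The fit is flagged
#' low-confidence when the relative RSS improvement over a single
#' straight line falls below `min_improvement` (including the degenerate
#' exactly-linear case).
#'
#' Both channels are first smoothed with a centered moving average of
#' `smooth_s` seconds along the time axis, the conventional taming of
#' breath-to-breath noise before a V-slope fit; without it, noise on
#' the VO2 axis biases the breakpoint low (errors-in-regressor
#' attenuation). Centered averaging leaves a noise-free breakpoint in
#' place.
#'
#' @param series Gas-exchange tibble with `time_s`, `vo2`, `vco2`,
#'   `phase`.
#' @param min_segment Minimum samples required on each side of the
#'   breakpoint.
#' @param upper_quantile Candidates restricted below this quantile of
#'   ramp VO2.
#' @param min_improvement Relative RSS improvement under which the fit
#'   is flagged.
#' @param smooth_s Centered moving-average window (seconds) applied to
#'   VO2 and VCO2 before fitting; 0 disables smoothing.
#' @return List `vat_vo2` (VO2 at the breakpoint, `NA` when no
#'   admissible breakpoint exists), `low_confidence`, `slopes`
#'   (lower/upper), `rss`, `rss_line`.
#' @export
detect_vat <- function(series, min_segment = 5, upper_quantile = 0.9,
                       min_improvement = 0.02, smooth_s = 10) {
  r <- ramp_phase(series)
  if (nrow(r) < 20) stop("ramp phase has fewer than 20 samples",
                         call. = FALSE)
  r <- r[order(r$time_s), , drop = FALSE]
  vo2 <- r$vo2
  vco2 <- r$vco2
  if (smooth_s > 0) {
    dt <- median(diff(r$time_s))
    k <- max(1L, round(smooth_s / dt))
    if (k %% 2 == 0) k <- k + 1L  # symmetric window
    if (k > 1 && nrow(r) > 2 * k) {
      vo2 <- as.numeric(stats::filter(vo2, rep(1 / k, k), sides = 2))
      vco2 <- as.numeric(stats::filter(vco2, rep(1 / k, k), sides = 2))
      keep <- !is.na(vo2)
      vo2 <- vo2[keep]
      vco2 <- vco2[keep]
    }
  }
  o <- order(vo2)
  x <- vo2[o]
  y <- vco2[o]
  n <- length(x)
  fit_line <- lm.fit(cbind(1, x), y)
  rss_line <- sum(fit_line$residuals^2)

  lo <- min_segment
  hi <- n - min_segment
  qcap <- quantile(x, upper_quantile, names = FALSE)
  cand <- which(seq_len(n) >= lo & seq_len(n) <= hi & x <= qcap)
  cand <- cand[!duplicated(x[cand])]
  best <- list(rss = Inf, c = NA_real_, s_lo = NA_real_, s_hi = NA_real_)
  for (j in cand) {
    cpt <- x[j]
    hinge <- pmax(x - cpt, 0)
    f <- lm.fit(cbind(1, x, hinge), y)
    if (any(is.na(f$coefficients))) next
    b <- f$coefficients
    if (b[3] <= 0) next  # upper slope must exceed lower slope
    rss <- sum(f$residuals^2)
    if (rss < best$rss) {
      best <- list(rss = rss, c = cpt, s_lo = unname(b[2]),
                   s_hi = unname(b[2] + b[3]))
    }
  }
  if (!is.finite(best$rss)) {
    return(list(vat_vo2 = NA_real_, low_confidence = TRUE,
                slopes = c(lower = NA_real_, upper = NA_real_),
                rss = NA_real_, rss_line = rss_line))
  }
  tss <- sum((y - mean(y))^2)
  improvement <- if (rss_line <= 1e-12 * tss) {
    0  # already an exact straight line: no breakpoint evidence
  } else {
    1 - best$rss / rss_line
  }
  list(vat_vo2 = best$c,
       low_confidence = improvement < min_improvement,
       slopes = c(lower = best$s_lo, upper = best$s_hi),
       rss = best$rss, rss_line = rss_line)
}

#' VE/VCO2 nadir
#'
#' The lowest trailing 30-second median of the per-sample VE/VCO2 ratio
#' observed during exercise (unloaded pedaling plus ramp; recovery is
#' excluded). VE is L/min; VCO2 is converted to L/min using
#' `weight_kg` when supplied in mL/kg/min.
#'
#' @param series Gas-exchange tibble with `time_s`, `ve`, `vco2`,
#'   `phase`.
#' @param weight_kg Body weight, required when `vco2_unit` is
#'   `"ml_kg_min"`.
#' @param vco2_unit `"ml_kg_min"` (default) or `"ml_min"`.
#' @param window Window length in seconds.
#' @return The dimensionless nadir.
#' @export
ve_vco2_nadir <- function(series, weight_kg = NULL,
                          vco2_unit = c("ml_kg_min", "ml_min"), window = 30) {
  vco2_unit <- match.arg(vco2_unit)
  ex <- series[series$phase %in% c("unloaded", "ramp"), , drop = FALSE]
  if (nrow(ex) == 0) stop("no exercise phase in series", call. = FALSE)
  if (any(ex$vco2 <= 0)) stop("nonpositive VCO2 in series", call. = FALSE)
  vco2_l <- if (vco2_unit == "ml_kg_min") {
    stopifnot(!is.null(weight_kg), weight_kg > 0)
    ex$vco2 * weight_kg / 1000
  } else {
    ex$vco2 / 1000
  }
  ratio <- ex$ve / vco2_l
  rm <- rolling_median(ex$time_s, ratio, window = window)
  min(rm$med)
}

#' Percent-predicted maximum heart rate
#'
#' 100 x peak exercise HR / (intercept - age_slope * age), with the peak
#' HR taken as the highest trailing 30-second median HR during the ramp
#' phase and the age-predicted maximum from the regression-based
#' formula (208 - 0.7 * age by default).
#'
#' @param series Gas-exchange tibble with `time_s`, `hr`, `phase`.
#' @param age Years.
#' @param coefs Tanaka-formula coefficients, overridable.
#' @param window Window length in seconds.
#' @return Percentage.
#' @export
percent_predicted_max_hr <- function(series, age,
                                     coefs = cpet_reference_coefs$tanaka,
                                     window = 30) {
  stopifnot("hr" %in% names(series))
  r <- ramp_phase(series)
  rm <- rolling_median(r$time_s, r$hr, window = window)
  peak_hr <- max(rm$med)
  100 * peak_hr / (coefs$intercept - coefs$age_slope * age)
}

#' Systolic blood pressure to workload slope
#'
#' (peak SBP - rest SBP) / peak workload, in mm Hg per watt. A negative
#' numerator (hypotensive response) is allowed and returned signed with
#' a warning flag.
#'
#' @param rest_sbp,peak_sbp mm Hg.
#' @param peak_workload Watts, must be positive.
#' @return List `slope` (mm Hg/W) and `hypotensive_flag`.
#' @export
sbp_w_slope <- function(rest_sbp, peak_sbp, peak_workload) {
  if (any(peak_workload <= 0)) {
    stop("peak workload must be positive", call. = FALSE)
  }
  slope <- (peak_sbp - rest_sbp) / peak_workload
  list(slope = slope, hypotensive_flag = slope < 0)
}

#' Peak respiratory exchange ratio
#'
#' The highest trailing 30-second median of VCO2/VO2 whose window ends
#' within the final minute of ramp exercise; used as the volitional
#' effort marker (a session with peak RER below 1.05 is flagged for the
#' effort-restricted sensitivity analysis; the 1.05 cut is inclusive,
#' so 1.05 itself passes).
#'
#' @param series Gas-exchange tibble with `time_s`, `vo2`, `vco2`,
#'   `phase` (VO2 and VCO2 in the same units).
#' @param window,final_s Window and final-interval lengths (seconds).
#' @return The dimensionless peak RER.
#' @export
peak_rer <- function(series, window = 30, final_s = 60) {
  r <- ramp_phase(series)
  peak_windowed(series, r$vco2 / r$vo2, window = window, final_s = final_s)
}

#' All CPET indices for one session
#'
#' Derives the six fitness indices plus peak RER from one participant's
#' gas-exchange series, blood pressures and anthropometrics.
#'
#' @param series Gas-exchange tibble for one participant.
#' @param age,sex,height_cm,weight_kg Anthropometrics.
#' @param rest_sbp,peak_sbp,peak_workload Blood pressures (mm Hg) and
#'   peak workload (W).
#' @param rer_cut Effort cut; sessions at or above it pass the
#'   volitional-effort filter.
#' @return One-row tibble shaped like the `cpet_results` stage output.
#' @export
process_cpet_session <- function(series, age, sex, height_cm, weight_kg,
                                 rest_sbp, peak_sbp, peak_workload,
                                 rer_cut = 1.05) {
  pv <- peak_vo2(series)
  vat <- detect_vat(series)
  sbp <- sbp_w_slope(rest_sbp, peak_sbp, peak_workload)
  rer <- peak_rer(series)
  tibble::tibble(
    peak_vo2 = pv,
    pct_predicted_peak_vo2 = percent_predicted_peak_vo2(
      pv, age, sex, height_cm, weight_kg),
    vat_vo2 = vat$vat_vo2,
    ve_vco2_nadir = ve_vco2_nadir(series, weight_kg = weight_kg),
    pct_predicted_max_hr = percent_predicted_max_hr(series, age),
    sbp_w_slope = sbp$slope,
    peak_rer = rer,
    vat_low_confidence = vat$low_confidence,
    hypotensive_flag = sbp$hypotensive_flag,
    adequate_effort = rer >= rer_cut)
}

#' CPET stage over a cohort
#'
#' Applies [process_cpet_session()] to every participant present in a
#' breath table.
#'
#' @param breath Stacked gas-exchange tibble (`participant_id` column).
#' @param sbp Tibble `participant_id`, `rest_sbp`, `peak_sbp`,
#'   `peak_workload_w`.
#' @param anthro Tibble with `participant_id`, `age`, `sex`,
#'   `height_cm`, `weight_kg`.
#' @param rer_cut Effort cut for the adequate-effort flag.
#' @return Tibble of per-participant CPET results.
#' @export
process_cpet <- function(breath, sbp, anthro, rer_cut = 1.05) {
  ids <- unique(breath$participant_id)
  rows <- lapply(ids, function(id) {
    ser <- breath[breath$participant_id == id, , drop = FALSE]
    a <- anthro[anthro$participant_id == id, , drop = FALSE]
    b <- sbp[sbp$participant_id == id, , drop = FALSE]
    if (nrow(a) != 1 || nrow(b) != 1) {
      stop(sprintf("missing anthropometrics or SBP for participant '%s'", id),
           call. = FALSE)
    }
    res <- process_cpet_session(ser, a$age, a$sex, a$height_cm, a$weight_kg,
                                b$rest_sbp, b$peak_sbp, b$peak_workload_w,
                                rer_cut = rer_cut)
    dplyr::bind_cols(tibble::tibble(participant_id = id), res)
  })
  dplyr::bind_rows(rows)
}
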