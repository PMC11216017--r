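test_that("hourly step totals apportion and conserve counts", {
  # wholly inside one hour
  one <- step_rec("A", 10 * 3600, 10.5 * 3600, 300)
  hs <- hourly_steps(one)
  expect_equal(hs$steps, 300)
  expect_equal(format(hs$hour, "%H", tz = "UTC"), "10")

  # spanning an hour boundary: uniform apportioning splits 60 as 30/30
  spl <- step_rec("A", 10.75 * 3600, 11.25 * 3600, 60)
  hs2 <- hourly_steps(spl)
  expect_equal(hs2$steps, c(30, 30))

  # conservation on random streams
  set.seed(4)
  dur <- runif(200, 30, 3000)
  gap <- runif(200, 10, 500)
  starts <- cumsum(gap + c(0, dur[-200]))
  recs <- step_rec("B", starts, starts + dur, rpois(200, 40))
  hs3 <- hourly_steps(recs)
  expect_equal(sum(hs3$steps), sum(recs$steps))
  # complete span: zero-filled hours present
  span_hours <- as.numeric(max(hs3$hour) - min(hs3$hour), units = "hours")
  expect_equal(nrow(hs3), span_hours + 1)

  # overlapping intervals rejected
  bad <- step_rec("C", c(0, 1800), c(3600, 5400), c(10, 10))
  expect_error(hourly_steps(bad), "overlapping")
})

test_that("motion-context inference applies both conditions", {
  t0 <- 12 * 3600
  base <- hr_rec("A", c(t0, t0 + 120, t0 + 130), hr = 70)
  no_steps <- step_rec("A", t0, t0 + 3600, 0)
  lab <- infer_motion_context(base, hourly_steps(no_steps))
  # record 2: gap 120 s, hour steps 0 -> nonactive
  expect_equal(lab$context_resolved[2], "nonactive")
  # record 3: gap 10 s -> active despite zero steps
  expect_equal(lab$context_resolved[3], "active")

  # hour total exactly at the cut: "less than 30" is strict -> active
  at_cut <- step_rec("A", t0, t0 + 3600, 30)
  lab2 <- infer_motion_context(base, hourly_steps(at_cut))
  expect_equal(lab2$context_resolved[2], "active")

  # device labels are authoritative
  dev <- hr_rec("A", c(t0, t0 + 120), context = c("sedentary", "active"))
  lab3 <- infer_motion_context(dev, hourly_steps(no_steps))
  expect_equal(lab3$context_resolved, c("nonactive", "active"))

  # first record of a day falls back to the following gap
  first <- hr_rec("A", c(t0, t0 + 10), hr = 70)
  lab4 <- infer_motion_context(first, hourly_steps(no_steps))
  expect_equal(lab4$gap_s[1], 10)
  expect_equal(lab4$context_resolved[1], "active")

  # empty input passes through
  lab5 <- infer_motion_context(hr_rec("A", numeric(0)), NULL)
  expect_equal(nrow(lab5), 0)
})

test_that("context classification recovers planted ground truth", {
  p <- cohort_params(n_participants = 4, follow_up_days_range = c(8, 10),
                     seed = 17)
  s <- generate_watch_streams(generate_cohort(p), p)
  lab <- infer_motion_context(s$hr, hourly_steps(s$steps,
                                                 complete_span = FALSE))
  truth <- ifelse(lab$true_context == "sedentary", "nonactive", "active")
  expect_gte(mean(lab$context_resolved == truth), 0.95)
})

test_that("wear time counts distinct record-bearing clock hours", {
  hr <- hr_rec("A", c(8.2, 8.4, 9.1, 21.9) * 3600)
  st <- step_rec("A", 9.5 * 3600, 9.6 * 3600, 100)
  wt <- wear_time(hr, st)
  expect_equal(wt$wear_hours, 3)  # hours 8, 9, 21

  # no records
  wt0 <- wear_time(hr_rec("A", numeric(0)), step_rec("A", numeric(0),
                                                     numeric(0), numeric(0)))
  expect_equal(nrow(wt0), 0)

  # records in every hour of the day
  hr24 <- hr_rec("A", (0:23) * 3600 + 10)
  wt24 <- wear_time(hr24, step_rec("A", numeric(0), numeric(0), numeric(0)))
  expect_equal(wt24$wear_hours, 24)
})

test_that("person-day validity uses strict less-than thresholds", {
  day_s <- function(day, hours, steps_per_hour) {
    # `hours` record-bearing hours each with an HR record and one step
    # interval carrying steps_per_hour
    off <- (day - 1) * 86400
    list(hr = hr_rec("A", off + (7 + seq_len(hours) - 1) * 3600 + 5),
         st = step_rec("A", off + (7 + seq_len(hours) - 1) * 3600,
                       off + (7 + seq_len(hours)) * 3600,
                       rep(steps_per_hour, hours)))
  }
  # wear 6 h, 999 steps total -> invalid (steps below 1000)
  a <- day_s(1, 6, 166.5)
  a$st$steps <- c(166, 166, 166, 167, 167, 167)  # 999
  # wear 5 h, exactly 1000 steps -> valid (cuts are strict)
  b <- day_s(2, 5, 200)
  # wear 4 h -> invalid regardless of steps
  c_ <- day_s(3, 4, 400)
  hr <- rbind(a$hr, b$hr, c_$hr)
  st <- rbind(a$st, b$st, c_$st)
  ds <- summarize_days(hr, st)
  expect_equal(ds$valid_step_day, c(FALSE, TRUE, FALSE))
  expect_equal(ds$daily_steps, c(999, 1000, 1600))
  expect_equal(ds$wear_hours, c(6, 5, 4))
})

test_that("relaxing a validity threshold never removes valid days", {
  p <- cohort_params(n_participants = 3, follow_up_days_range = c(6, 8),
                     seed = 23)
  s <- generate_watch_streams(generate_cohort(p), p)
  strict <- summarize_days(s$hr, s$steps, min_wear_hours = 5,
                           min_daily_steps = 1000)
  lax_wear <- summarize_days(s$hr, s$steps, min_wear_hours = 3,
                             min_daily_steps = 1000)
  lax_steps <- summarize_days(s$hr, s$steps, min_wear_hours = 5,
                              min_daily_steps = 500)
  expect_gte(sum(lax_wear$valid_step_day), sum(strict$valid_step_day))
  expect_gte(sum(lax_steps$valid_step_day), sum(strict$valid_step_day))
})

test_that("participant summaries average nonactive records and gate on days", {
  # 31 days, one valid day short of the HR cut for participant B
  mk <- function(id, n_days) {
    hr <- dplyr::bind_rows(lapply(seq_len(n_days), function(d) {
      hr_rec(id, (d - 1) * 86400 + c(10 * 3600, 10 * 3600 + 120,
                                     10 * 3600 + 300),
             hr = c(70, 72, 74))
    }))
    st <- dplyr::bind_rows(lapply(seq_len(n_days), function(d) {
      # hour 10 (where the HR records sit) stays under the 30-step cut,
      # the other hours carry the day over the 1000-step validity cut
      step_rec(id, (d - 1) * 86400 + (7:12) * 3600,
               (d - 1) * 86400 + (8:13) * 3600, c(200, 200, 200, 20, 200,
                                                  200))
    }))
    list(hr = hr, st = st)
  }
  a <- mk("A", 30)
  b <- mk("B", 29)
  hr <- rbind(a$hr, b$hr)
  st <- rbind(a$st, b$st)
  out <- process_watch(hr, st, min_wear_hours = 5, min_daily_steps = 1000,
                       min_days = 30)
  ps <- out$participant_summaries
  # records are sparse (gaps >= 120 s) in an under-30-step hour: nonactive
  expect_true(all(out$labeled_hr$context_resolved == "nonactive"))
  expect_equal(ps$nonactive_hr_mean, c(72, 72))
  expect_equal(ps$n_nonactive_records, c(90L, 87L))
  # 30-day inclusion cut is inclusive: 30 days in, 29 days out
  expect_equal(ps$include_hr, c(TRUE, FALSE))
  expect_equal(ps$include_steps, c(TRUE, FALSE))
  expect_equal(ps$include_primary, c(TRUE, FALSE))
})

test_that("nonactive HR mean is the unweighted record mean", {
  hr <- hr_rec("A", c(10, 40, 70) * 60 + 36000, hr = c(70, 72, 74))
  st <- step_rec("A", 36000, 36000 + 2 * 3600, 0)
  out <- process_watch(hr, st, min_days = 1)
  ps <- out$participant_summaries
  # all three records sparse (gaps 30 min) and zero steps -> nonactive
  expect_equal(ps$n_nonactive_records, 3L)
  expect_equal(ps$nonactive_hr_mean, 72)
})
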