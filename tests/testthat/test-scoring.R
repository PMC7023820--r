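test_that("match_presses reproduces hand-scored responses", {
  cfg <- protocol_config()
  ev <- data.frame(
    time_ms = c(0, 1000, 1450, 5000, 5400, 5900, 121000, 124500),
    event = c("mode", "stim", "press", "stim", "press", "press",
              "stim", "press"),
    arg = c("parallel", "left", "left", "right", "left", "right",
            "left", "right"))
  rec <- match_presses(trial_log(ev, protocol = cfg))

  # correct response: rt 450, resolved at the first press
  expect_equal(rec$rt_ms[1], 450)
  expect_false(rec$is_error[1])
  expect_equal(rec$resolution_ms[1], 1450)
  expect_true(is.na(rec$correction_ms[1]))

  # error response: rt 400 to the wrong pedal, corrected 500 ms later
  expect_equal(rec$rt_ms[2], 400)
  expect_true(rec$is_error[2])
  expect_equal(rec$correction_ms[2], 500)

  # cross-mode hesitation: contralateral pedal correct, rt 3500 > 3 s
  expect_equal(rec$mode[3], "cross")
  expect_equal(rec$correct_pedal[3], "right")
  expect_equal(rec$rt_ms[3], 3500)
  expect_false(rec$is_error[3])
  expect_true(rec$is_hesitation[3])
})

test_that("hesitation is strictly greater-than the 3000 ms threshold", {
  expect_true(is_hesitation(3001, 3000))
  expect_false(is_hesitation(3000, 3000))
  expect_false(is_hesitation(0, 3000))
  expect_error(is_hesitation(-1, 3000), ">= 0")
})

test_that("the six indicators match the hand-scored micro-log", {
  ind <- compute_indicators(match_presses(micro_log_fixture()))
  expect_equal(ind$n_responses, 4)
  expect_equal(ind$mean_rt_ms, (450 + 400 + 650) / 3)  # 500
  expect_equal(ind$pedal_error_pct, 25)
  expect_equal(ind$hesitation_pct, 25)
  expect_equal(ind$hesitation_length_s, 3.5)
  expect_equal(ind$error_correction_ms, 500)
  expect_equal(ind$cross_mode_effect_ms, 650 - (450 + 400) / 2)  # 225
})

test_that("degenerate trials report missing indicators, never zeros", {
  # all-correct single-mode trial: no cross-mode effect, no corrections
  ev <- data.frame(time_ms = c(0, 1000, 1500, 3000, 3500),
                   event = c("mode", "stim", "press", "stim", "press"),
                   arg = c("parallel", "left", "left", "right", "right"))
  cfg <- protocol_config(trial_duration_ms = 10000,
                         block_duration_ms = 10000)
  ind <- compute_indicators(match_presses(trial_log(ev, protocol = cfg)))
  expect_equal(ind$mean_rt_ms, 500)
  expect_equal(ind$pedal_error_pct, 0)
  expect_equal(ind$hesitation_pct, 0)
  expect_true(is.na(ind$hesitation_length_s))
  expect_true(is.na(ind$error_correction_ms))
  expect_true(is.na(ind$cross_mode_effect_ms))

  # all hesitations: mean RT undefined, hesitation 100%
  ev2 <- data.frame(time_ms = c(0, 1000, 4500, 8000, 11600),
                    event = c("mode", "stim", "press", "stim", "press"),
                    arg = c("parallel", "left", "left", "right", "right"))
  ind2 <- compute_indicators(match_presses(trial_log(ev2, protocol = cfg)))
  expect_true(is.na(ind2$mean_rt_ms))
  expect_equal(ind2$hesitation_pct, 100)
  expect_equal(ind2$hesitation_length_s, 3.55)

  # no responded stimulus at all
  ev3 <- data.frame(time_ms = c(0, 1000), event = c("mode", "stim"),
                    arg = c("parallel", "left"))
  expect_error(compute_indicators(match_presses(trial_log(ev3, protocol = cfg))),
               "empty trial")
})

test_that("unattributed presses are ignored with a warning", {
  ev <- data.frame(time_ms = c(0, 500, 1000, 1400, 1600),
                   event = c("mode", "press", "stim", "press", "press"),
                   arg = c("parallel", "right", "left", "left", "right"))
  expect_warning(rec <- match_presses(trial_log(ev)),
                 "2 press\\(es\\) with no pending stimulus")
  expect_equal(nrow(rec), 1)
  expect_equal(rec$rt_ms[1], 400)
})

test_that("row order of the event table does not affect scoring", {
  log <- simulate_trial(preset_profile("older"), seed = 21)
  ref <- compute_indicators(match_presses(log))
  for (rep in 1:5) {
    shuffled <- log$events[sample(nrow(log$events)), ]
    log2 <- trial_log(shuffled, protocol = log$meta$protocol)
    expect_equal(compute_indicators(match_presses(log2)), ref)
  }
})

test_that("mean RT ignores added hesitations; error rate survives time rescaling", {
  base <- micro_log_fixture()
  ind <- compute_indicators(match_presses(base))

  # splice two extra hesitation responses into the final parallel block
  ev <- rbind(base$events,
              data.frame(time_ms = c(250000, 253300, 260000, 263500),
                         event = c("stim", "press", "stim", "press"),
                         arg = c("left", "left", "right", "right")))
  ind2 <- compute_indicators(match_presses(trial_log(ev)))
  expect_equal(ind2$mean_rt_ms, ind$mean_rt_ms)
  expect_equal(ind2$n_hesitations, ind$n_hesitations + 2)

  # rescaling every timestamp leaves the error percentage unchanged
  cfg3 <- protocol_config(trial_duration_ms = 3 * 360000,
                          block_duration_ms = 3 * 120000,
                          hesitation_threshold_ms = 3 * 3000)
  ev3 <- base$events
  ev3$time_ms <- ev3$time_ms * 3L
  ind3 <- compute_indicators(match_presses(trial_log(ev3, protocol = cfg3)),
                             hesitation_threshold_ms = 9000)
  expect_equal(ind3$pedal_error_pct, ind$pedal_error_pct)
  expect_equal(ind3$hesitation_pct, ind$hesitation_pct)
})

test_that("sequential matcher agrees with the brute-force oracle on random logs", {
  withr::with_seed(4242, {
    for (i in 1:200) {
      log <- random_micro_log()
      seq_rec <- suppressWarnings(match_presses(log))
      bf_rec <- brute_force_match(log)
      expect_identical(seq_rec, bf_rec)
    }
  })
})

test_that("indicator tables round-trip through the canonical CSV layout", {
  tab <- score_logs(simulate_cohort(n_young = 2, n_middle = 0, n_older = 1,
                                    base_seed = 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_indicators(tab, path)
  header <- readLines(path, n = 1)
  expect_equal(header, paste(
    c("subject_id", "age_group", "sex", "start_mode", "n_responses",
      "n_errors", "n_hesitations", "mean_rt_ms", "pedal_error_pct",
      "hesitation_pct", "hesitation_length_s", "error_correction_ms",
      "cross_mode_effect_ms"), collapse = ","))
  back <- read_indicators(path)
  expect_equal(back$mean_rt_ms, tab$mean_rt_ms)
  expect_equal(back$subject_id, tab$subject_id)
})
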