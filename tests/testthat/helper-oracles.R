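# Independent quadratic-time press-stimulus matcher: for every stimulus, scan
# ALL presses. A stimulus's window runs from its onset to the next onset; the
# first (non-middle) press in the window is the response, the earliest
# correct-pedal press in the window is the resolution. Kept deliberately
# separate from the package's sequential matcher.
brute_force_match <- function(log) {
  cfg <- log$meta$protocol
  tl <- build_mode_timeline(cfg)
  ev <- log$events
  stim <- ev[ev$event == "stim", , drop = FALSE]
  press <- ev[ev$event == "press" & ev$arg != "middle", , drop = FALSE]
  ns <- nrow(stim)
  rows <- vector("list", ns)
  for (i in seq_len(ns)) {
    onset <- stim$time_ms[i]
    wend <- if (i < ns) stim$time_ms[i + 1L] else Inf
    mode <- mode_at(tl, min(onset, cfg$trial_duration_ms - 1L))
    correct <- correct_side(stim$arg[i], mode)
    in_win <- press$time_ms >= onset & press$time_ms < wend
    first_ms <- NA_integer_; first_pedal <- NA_character_
    res_ms <- NA_integer_; rt <- NA_integer_
    is_err <- NA; is_hes <- NA; corr <- NA_integer_
    if (any(in_win)) {
      cand_t <- press$time_ms[in_win]
      cand_p <- press$arg[in_win]
      k <- which.min(cand_t)
      first_ms <- cand_t[k]
      first_pedal <- cand_p[k]
      rt <- first_ms - onset
      is_err <- first_pedal != correct
      is_hes <- rt > cfg$hesitation_threshold_ms
      hit <- which(cand_p == correct)
      if (length(hit) > 0) {
        res_ms <- min(cand_t[hit])
        if (is_err) corr <- res_ms - first_ms
      }
    }
    rows[[i]] <- data.frame(
      stim_onset_ms = onset, stim_side = stim$arg[i], mode = mode,
      correct_pedal = correct, first_press_ms = first_ms,
      first_press_pedal = first_pedal, resolution_ms = res_ms, rt_ms = rt,
      is_error = is_err, is_hesitation = is_hes, correction_ms = corr,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  rownames(out) <- NULL
  out
}

# Random small trial log exercising the matcher's corner cases: correct
# responses, single and repeated wrong presses, hesitations, middle-pedal
# presses, stray presses after a resolution, and an occasional unresolved
# trailing stimulus. Uses the current RNG stream.
random_micro_log <- function() {
  cfg <- protocol_config(trial_duration_ms = 60000, block_duration_ms = 15000,
                         isi_min_ms = 600, isi_max_ms = 1500,
                         hesitation_threshold_ms = 3000)
  tl <- build_mode_timeline(cfg)
  times <- as.integer(tl$start_ms); kinds <- rep("mode", nrow(tl)); args <- tl$mode
  n_stim <- sample(3:8, 1)
  prev_res <- 0L
  for (i in seq_len(n_stim)) {
    onset <- prev_res + sample(cfg$isi_min_ms:cfg$isi_max_ms, 1)
    if (onset >= cfg$trial_duration_ms) break
    side <- sample(c("left", "right"), 1)
    mode <- mode_at(tl, onset)
    correct <- correct_side(side, mode)
    wrong <- setdiff(c("left", "right"), correct)
    times <- c(times, onset); kinds <- c(kinds, "stim"); args <- c(args, side)
    scenario <- sample(c("correct", "error", "double_error", "unresolved"), 1,
                       prob = c(0.5, 0.25, 0.15, 0.1))
    lat <- sample(c(sample(80:1200, 1), sample(3001:4000, 1)), 1,
                  prob = c(0.85, 0.15))
    t1 <- onset + lat
    if (runif(1) < 0.15) {  # stray middle press before the response
      times <- c(times, onset + max(1L, lat - 40L))
      kinds <- c(kinds, "press"); args <- c(args, "middle")
    }
    if (scenario == "unresolved" && i < n_stim) scenario <- "correct"
    if (scenario == "unresolved") {
      if (runif(1) < 0.5) {  # wrong press, never corrected
        times <- c(times, t1); kinds <- c(kinds, "press"); args <- c(args, wrong)
      }
      prev_res <- t1
      next
    }
    if (scenario == "correct") {
      times <- c(times, t1); kinds <- c(kinds, "press"); args <- c(args, correct)
      res <- t1
    } else if (scenario == "error") {
      d <- sample(100:500, 1)
      times <- c(times, t1, t1 + d); kinds <- c(kinds, "press", "press")
      args <- c(args, wrong, correct)
      res <- t1 + d
    } else {  # two wrong presses, then the correct one
      d1 <- sample(80:250, 1); d2 <- d1 + sample(80:250, 1)
      times <- c(times, t1, t1 + d1, t1 + d2)
      kinds <- c(kinds, "press", "press", "press")
      args <- c(args, wrong, wrong, correct)
      res <- t1 + d2
    }
    if (runif(1) < 0.15) {  # stray press after resolution, before next onset
      times <- c(times, res + sample(50:400, 1))
      kinds <- c(kinds, "press")
      args <- c(args, sample(c("left", "right"), 1))
    }
    prev_res <- res
  }
  trial_log(data.frame(time_ms = times, event = kinds, arg = args,
                       stringsAsFactors = FALSE),
            subject_id = "micro", protocol = cfg)
}

# Hand-scored four-response fixture: two parallel-block responses (one clean,
# one error with a 500 ms correction), then two cross-block responses (one
# 3.5 s hesitation, one clean 650 ms).
micro_log_fixture <- function() {
  ev <- data.frame(
    time_ms = c(0, 120000, 240000,          # mode events
                1000, 1450,                  # P: correct left, rt 450
                5000, 5400, 5900,            # P: error (rt 400, corr 500)
                121000, 124500,              # C: correct (contra), rt 3500
                130000, 130650),             # C: correct, rt 650
    event = c("mode", "mode", "mode",
              "stim", "press",
              "stim", "press", "press",
              "stim", "press",
              "stim", "press"),
    arg = c("parallel", "cross", "parallel",
            "left", "left",
            "right", "left", "right",
            "left", "right",
            "right", "left"),
    stringsAsFactors = FALSE
  )
  trial_log(ev, subject_id = "fixture", protocol = protocol_config())
}

# standard error of a pooled proportion
prop_se <- function(p_hat, n) sqrt(p_hat * (1 - p_hat) / n)

# delta-method SE of a ratio of two independent estimates
ratio_se <- function(num, se_num, den, se_den) {
  (num / den) * sqrt((se_num / num)^2 + (se_den / den)^2)
}
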