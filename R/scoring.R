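#' Match pedal presses to stimuli
#'
#' Joins each stimulus to the presses it elicited, reproducing the
#' apparatus's resolution semantics: a stimulus stays lit (and the buzzer
#' sounds after a wrong press) until the correct pedal is pressed, which
#' resolves it. Presses are attributed to the stimulus whose window --
#' from its onset to the next stimulus onset -- contains them; within that
#' window the first press of the correct pedal is the resolution. Presses
#' outside any window, or left over after a resolution, have no pending
#' stimulus and are ignored with a warning. Middle-pedal presses are skipped
#' (the protocol uses only left and right).
#'
#' Response time (RT) is the latency from stimulus onset to the FIRST press,
#' correct or not; the error correction time runs from that first (wrong)
#' press to the first correct press. A trailing stimulus with no press yields
#' a record with missing response fields.
#'
#' @param log A validated [trial_log()].
#' @return A data.frame with one row per stimulus: `stim_onset_ms`,
#'   `stim_side`, `mode`, `correct_pedal`, `first_press_ms`,
#'   `first_press_pedal`, `resolution_ms`, `rt_ms`, `is_error`,
#'   `is_hesitation`, `correction_ms`. Unresolved fields are `NA`.
#' @examples
#' cfg <- protocol_config()
#' ev <- data.frame(time_ms = c(0, 1000, 1450),
#'                  event = c("mode", "stim", "press"),
#'                  arg = c("parallel", "left", "left"))
#' match_presses(trial_log(ev, protocol = cfg))
#' @export
match_presses <- function(log) {
  stopifnot(inherits(log, "pspvt_trial_log"))
  cfg <- log$meta$protocol
  tl <- build_mode_timeline(cfg)
  ev <- log$events

  stim <- ev[ev$event == "stim", , drop = FALSE]
  press <- ev[ev$event == "press" & ev$arg != "middle", , drop = FALSE]
  ns <- nrow(stim)
  np <- nrow(press)

  out <- data.frame(
    stim_onset_ms = stim$time_ms,
    stim_side = stim$arg,
    mode = character(ns),
    correct_pedal = character(ns),
    first_press_ms = rep(NA_integer_, ns),
    first_press_pedal = rep(NA_character_, ns),
    resolution_ms = rep(NA_integer_, ns),
    rt_ms = rep(NA_integer_, ns),
    is_error = rep(NA, ns),
    is_hesitation = rep(NA, ns),
    correction_ms = rep(NA_integer_, ns),
    stringsAsFactors = FALSE
  )
  if (ns > 0) {
    # mode of a stimulus is the mode at its onset (clamped into the trial for
    # a stimulus logged at/after the nominal end)
    onset_clamped <- pmin(stim$time_ms, cfg$trial_duration_ms - 1L)
    out$mode <- mode_at(tl, onset_clamped)
    out$correct_pedal <- correct_side(stim$arg, out$mode)
  }

  orphans <- 0L
  j <- 1L
  for (i in seq_len(ns)) {
    onset <- stim$time_ms[i]
    window_end <- if (i < ns) stim$time_ms[i + 1L] else Inf
    while (j <= np && press$time_ms[j] < onset) {
      orphans <- orphans + 1L
      j <- j + 1L
    }
    if (j > np || press$time_ms[j] >= window_end) next
    out$first_press_ms[i] <- press$time_ms[j]
    out$first_press_pedal[i] <- press$arg[j]
    out$rt_ms[i] <- press$time_ms[j] - onset
    out$is_error[i] <- press$arg[j] != out$correct_pedal[i]
    out$is_hesitation[i] <- is_hesitation(out$rt_ms[i],
                                          cfg$hesitation_threshold_ms)
    # scan the window for the resolving (correct) press
    k <- j
    while (k <= np && press$time_ms[k] < window_end &&
           press$arg[k] != out$correct_pedal[i]) {
      k <- k + 1L
    }
    if (k <= np && press$time_ms[k] < window_end) {
      out$resolution_ms[i] <- press$time_ms[k]
      if (out$is_error[i]) {
        out$correction_ms[i] <- press$time_ms[k] - out$first_press_ms[i]
      }
      # presses after the resolution but before the next stimulus are orphans
      j <- k + 1L
      while (j <= np && press$time_ms[j] < window_end) {
        orphans <- orphans + 1L
        j <- j + 1L
      }
    } else {
      # unresolved: consume the rest of the window
      while (j <= np && press$time_ms[j] < window_end) j <- j + 1L
    }
  }
  if (j <= np) orphans <- orphans + (np - j + 1L)
  if (orphans > 0) {
    warning(sprintf("%d press(es) with no pending stimulus ignored", orphans),
            call. = FALSE)
  }
  out
}

#' Classify a response time as a hesitation
#'
#' A hesitation (response freezing) is a first-press latency strictly greater
#' than the threshold: 3000 ms is not a hesitation, 3001 ms is.
#'
#' @param rt_ms First-press latency, ms (>= 0). Vectorised.
#' @param threshold_ms Hesitation threshold, ms (default 3000).
#' @return Logical.
#' @export
is_hesitation <- function(rt_ms, threshold_ms = 3000) {
  if (any(rt_ms < 0, na.rm = TRUE)) stop("rt_ms must be >= 0", call. = FALSE)
  rt_ms > threshold_ms
}

#' Compute the six pedal-response indicators of one trial
#'
#' Summarises matched response records into the trial-level indicators:
#' \describe{
#'   \item{mean_rt_ms}{Mean first-press RT excluding hesitations, ms.}
#'   \item{pedal_error_pct}{Wrong-first-press stimuli / responded stimuli, %.}
#'   \item{hesitation_pct}{Hesitations / responded stimuli, %.}
#'   \item{hesitation_length_s}{Mean RT of hesitations, s.}
#'   \item{error_correction_ms}{Mean delay from wrong press to correct press
#'     over error responses, ms.}
#'   \item{cross_mode_effect_ms}{Mean non-hesitation RT in cross mode minus
#'     parallel mode, ms (the Simon-type cost of the crossed mapping).}
#' }
#' The denominator of both percentages is the number of responded stimuli
#' (those with at least one attributed press); unanswered trailing stimuli
#' are excluded from every denominator. Error-trial first-press RTs count in
#' `mean_rt_ms` (only hesitations are excluded); a hesitating error counts in
#' both percentages but its RT contributes only to `hesitation_length_s`.
#' An indicator whose denominator is empty is `NA`, never 0.
#'
#' @param records The data.frame returned by [match_presses()].
#' @param hesitation_threshold_ms Threshold used to (re)classify hesitations.
#' @return One-row data.frame of class `pspvt_indicators` with counts
#'   `n_responses`, `n_errors`, `n_hesitations` and the six indicators.
#' @export
compute_indicators <- function(records, hesitation_threshold_ms = 3000) {
  r <- records[!is.na(records$first_press_ms), , drop = FALSE]
  if (nrow(r) == 0) stop("empty trial: no responded stimuli", call. = FALSE)
  hes <- is_hesitation(r$rt_ms, hesitation_threshold_ms)
  err <- r$is_error

  mean_or_na <- function(x) if (length(x) == 0) NA_real_ else mean(x)
  non_hes_rt <- as.numeric(r$rt_ms[!hes])
  cross_rt <- as.numeric(r$rt_ms[!hes & r$mode == "cross"])
  par_rt <- as.numeric(r$rt_ms[!hes & r$mode == "parallel"])
  corr <- as.numeric(r$correction_ms[err & !is.na(r$correction_ms)])

  out <- data.frame(
    n_responses = nrow(r),
    n_errors = sum(err),
    n_hesitations = sum(hes),
    mean_rt_ms = mean_or_na(non_hes_rt),
    pedal_error_pct = 100 * sum(err) / nrow(r),
    hesitation_pct = 100 * sum(hes) / nrow(r),
    hesitation_length_s = mean_or_na(as.numeric(r$rt_ms[hes])) / 1000,
    error_correction_ms = mean_or_na(corr),
    cross_mode_effect_ms =
      if (length(cross_rt) == 0 || length(par_rt) == 0) NA_real_
      else mean(cross_rt) - mean(par_rt),
    stringsAsFactors = FALSE
  )
  class(out) <- c("pspvt_indicators", "data.frame")
  out
}

#' Score one trial log end to end
#'
#' Convenience wrapper: matches presses, computes indicators, and prepends
#' the subject metadata columns used by the cohort-level statistics.
#'
#' @param log A [trial_log()].
#' @return One-row data.frame: `subject_id`, `age_group`, `sex`,
#'   `start_mode`, then the [compute_indicators()] columns.
#' @export
score_trial <- function(log) {
  rec <- match_presses(log)
  ind <- compute_indicators(rec, log$meta$protocol$hesitation_threshold_ms)
  cbind(
    data.frame(subject_id = log$meta$subject_id,
               age_group = log$meta$age_group,
               sex = log$meta$sex,
               start_mode = log$meta$start_mode,
               stringsAsFactors = FALSE),
    as.data.frame(ind)
  )
}

#' Score several logs into one indicator table
#'
#' @param logs A list of [trial_log()] objects.
#' @return data.frame, one row per log, in [score_trial()] layout.
#' @export
score_logs <- function(logs) {
  out <- do.call(rbind, lapply(logs, score_trial))
  rownames(out) <- NULL
  out
}

indicator_columns <- c(
  "subject_id", "age_group", "sex", "start_mode",
  "n_responses", "n_errors", "n_hesitations",
  "mean_rt_ms", "pedal_error_pct", "hesitation_pct",
  "hesitation_length_s", "error_correction_ms", "cross_mode_effect_ms"
)

#' Write an indicator table to CSV
#'
#' One row per trial, columns fixed to the canonical order; missing
#' indicators become empty cells.
#'
#' @param indicators data.frame from [score_trial()] / [score_logs()].
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_indicators <- function(indicators, path) {
  missing_cols <- setdiff(indicator_columns, names(indicators))
  if (length(missing_cols) > 0) {
    stop(sprintf("indicator table missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  utils::write.csv(indicators[indicator_columns], path,
                   row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read an indicator table written by [write_indicators()]
#'
#' @param path Source CSV path.
#' @return data.frame with empty cells restored as `NA`.
#' @export
read_indicators <- function(path) {
  header <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  classes <- if ("subject_id" %in% header) {
    c(subject_id = "character")
  } else {
    NA
  }
  utils::read.csv(path, stringsAsFactors = FALSE, colClasses = classes)
}
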