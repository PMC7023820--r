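#' Construct a trial log
#'
#' A trial log is the on-disk unit of a PS-PVT session: subject metadata, the
#' protocol configuration, and the ordered stream of timestamped events the
#' apparatus records -- which circle was lit and when (`stim`), which pedal
#' was pressed and when (`press`), and the response-mapping mode in effect
#' (`mode`).
#'
#' Events are sorted by `time_ms` with ties broken in the order
#' mode < stim < press, so a press falling exactly on a block boundary is
#' deterministically interpreted under the new mode. A valid log carries
#' exactly one `mode` event at t = 0. The three-pedal device's middle pedal
#' is representable in `press` events; it is preserved by I/O, flagged by
#' [validate_trial_log()], and ignored by the scorer.
#'
#' @param events data.frame with columns `time_ms` (integer ms >= 0),
#'   `event` (`"mode"`, `"stim"`, `"press"`), and `arg` (mode name for mode
#'   events, `"left"`/`"right"` for stim, `"left"`/`"middle"`/`"right"` for
#'   press).
#' @param subject_id,age_group,sex Subject metadata. `age_group` is one of
#'   `"young"`, `"middle"`, `"older"`, `"unknown"`.
#' @param protocol The [protocol_config()] under which the events were (or
#'   are presumed) generated; its `start_mode` doubles as the log's start
#'   mode.
#' @return An object of class `pspvt_trial_log`: a list with elements `meta`
#'   and `events`.
#' @export
trial_log <- function(events,
                      subject_id = "unknown",
                      age_group = c("unknown", "young", "middle", "older"),
                      sex = "unknown",
                      protocol = protocol_config()) {
  age_group <- match.arg(age_group)
  validate_protocol_config(protocol)
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  required <- c("time_ms", "event", "arg")
  if (!all(required %in% names(events))) {
    stop("events must have columns time_ms, event, arg", call. = FALSE)
  }
  events <- events[required]
  events$time_ms <- as.integer(events$time_ms)
  events$event <- as.character(events$event)
  events$arg <- as.character(events$arg)

  bad <- !events$event %in% c("mode", "stim", "press")
  if (any(bad)) {
    stop(sprintf("unknown event kind '%s'", events$event[which(bad)[1]]),
         call. = FALSE)
  }
  legal <- event_arg_legal(events$event, events$arg)
  if (any(!legal)) {
    i <- which(!legal)[1]
    stop(sprintf("illegal arg '%s' for event '%s'",
                 events$arg[i], events$event[i]), call. = FALSE)
  }
  if (any(events$time_ms < 0)) {
    stop("event times must be >= 0", call. = FALSE)
  }

  events <- sort_events(events)
  at0 <- events$event == "mode" & events$time_ms == 0L
  if (sum(at0) != 1L) {
    stop("a trial log requires exactly one mode event at t = 0", call. = FALSE)
  }

  structure(
    list(
      meta = list(
        subject_id = as.character(subject_id),
        age_group = age_group,
        sex = as.character(sex),
        start_mode = protocol$start_mode,
        protocol = protocol
      ),
      events = events
    ),
    class = "pspvt_trial_log"
  )
}

event_arg_legal <- function(event, arg) {
  (event == "mode" & arg %in% c("parallel", "cross")) |
    (event == "stim" & arg %in% c("left", "right")) |
    (event == "press" & arg %in% c("left", "middle", "right"))
}

# canonical ordering: time, then mode < stim < press at equal time
sort_events <- function(events) {
  rank <- match(events$event, c("mode", "stim", "press"))
  o <- order(events$time_ms, rank)
  out <- events[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

events_are_sorted <- function(events) {
  rank <- match(events$event, c("mode", "stim", "press"))
  key <- events$time_ms * 4 + rank
  !is.unsorted(key)
}

#' @export
print.pspvt_trial_log <- function(x, ...) {
  n <- table(factor(x$events$event, levels = c("mode", "stim", "press")))
  cat(sprintf("PS-PVT trial log: subject %s (%s, %s), start mode %s\n",
              x$meta$subject_id, x$meta$age_group, x$meta$sex,
              x$meta$start_mode))
  cat(sprintf("  %d events: %d mode, %d stim, %d press\n",
              nrow(x$events), n[["mode"]], n[["stim"]], n[["press"]]))
  invisible(x)
}

#' Write a trial log to CSV
#'
#' The format is UTF-8 CSV with leading `#key=value` comment lines carrying
#' the metadata (subject_id, age_group, sex, start_mode and every protocol
#' field), a header line `time_ms,event,arg`, then one row per event. The
#' file round-trips exactly through [read_trial_log()].
#'
#' @param log A `pspvt_trial_log`.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(log, path) {
  stopifnot(inherits(log, "pspvt_trial_log"))
  p <- log$meta$protocol
  num <- function(x) format(x, scientific = FALSE, trim = TRUE, digits = 15)
  meta_lines <- c(
    paste0("#subject_id=", log$meta$subject_id),
    paste0("#age_group=", log$meta$age_group),
    paste0("#sex=", log$meta$sex),
    paste0("#start_mode=", p$start_mode),
    paste0("#trial_duration_ms=", num(p$trial_duration_ms)),
    paste0("#block_duration_ms=", num(p$block_duration_ms)),
    paste0("#isi_min_ms=", num(p$isi_min_ms)),
    paste0("#isi_max_ms=", num(p$isi_max_ms)),
    paste0("#side_probability_left=", num(p$side_probability_left)),
    paste0("#hesitation_threshold_ms=", num(p$hesitation_threshold_ms))
  )
  rows <- sprintf("%d,%s,%s", log$events$time_ms, log$events$event,
                  log$events$arg)
  res <- try(writeLines(c(meta_lines, "time_ms,event,arg", rows), path,
                        useBytes = TRUE), silent = TRUE)
  if (inherits(res, "try-error")) {
    stop(sprintf("failed to write trial log to '%s': %s", path,
                 attr(res, "condition")$message), call. = FALSE)
  }
  invisible(path)
}

#' Read a trial log from CSV
#'
#' Parses the dialect written by [write_trial_log()]. Unknown event or
#' argument tokens raise a parse error naming the offending line; a missing
#' t = 0 mode event is a validation error. Events found out of order are
#' re-sorted with a warning, yielding the same log as the sorted file.
#'
#' @param path Source file path.
#' @return A `pspvt_trial_log`.
#' @export
read_trial_log <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read trial log '%s': no such file", path),
         call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  is_meta <- startsWith(lines, "#")
  meta <- list()
  for (ln in lines[is_meta]) {
    m <- regmatches(ln, regexec("^#([A-Za-z_]+)=(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  body_idx <- which(!is_meta & nzchar(trimws(lines)))
  if (length(body_idx) == 0 || lines[body_idx[1]] != "time_ms,event,arg") {
    stop(sprintf("'%s': missing header line 'time_ms,event,arg'", path),
         call. = FALSE)
  }
  data_idx <- body_idx[-1]

  n <- length(data_idx)
  time_ms <- integer(n)
  event <- character(n)
  arg <- character(n)
  for (i in seq_len(n)) {
    lineno <- data_idx[i]
    parts <- strsplit(lines[lineno], ",", fixed = TRUE)[[1]]
    if (length(parts) != 3) {
      stop(sprintf("'%s' line %d: expected 3 comma-separated fields",
                   path, lineno), call. = FALSE)
    }
    t <- suppressWarnings(as.integer(parts[1]))
    if (is.na(t) || t < 0) {
      stop(sprintf("'%s' line %d: bad time '%s'", path, lineno, parts[1]),
           call. = FALSE)
    }
    if (!parts[2] %in% c("mode", "stim", "press")) {
      stop(sprintf("'%s' line %d: unknown event kind '%s'",
                   path, lineno, parts[2]), call. = FALSE)
    }
    if (!event_arg_legal(parts[2], parts[3])) {
      stop(sprintf("'%s' line %d: illegal arg '%s' for event '%s'",
                   path, lineno, parts[3], parts[2]), call. = FALSE)
    }
    time_ms[i] <- t
    event[i] <- parts[2]
    arg[i] <- parts[3]
  }
  events <- data.frame(time_ms = time_ms, event = event, arg = arg,
                       stringsAsFactors = FALSE)
  if (!events_are_sorted(events)) {
    warning(sprintf("'%s': events out of order; re-sorting", path),
            call. = FALSE)
  }
  if (!any(events$event == "mode" & events$time_ms == 0L)) {
    stop(sprintf("'%s': no mode event at t = 0", path), call. = FALSE)
  }

  proto_args <- list()
  for (key in c("trial_duration_ms", "block_duration_ms", "isi_min_ms",
                "isi_max_ms", "side_probability_left",
                "hesitation_threshold_ms")) {
    if (!is.null(meta[[key]])) proto_args[[key]] <- as.numeric(meta[[key]])
  }
  if (!is.null(meta$start_mode)) proto_args$start_mode <- meta$start_mode
  protocol <- do.call(protocol_config, proto_args)

  trial_log(
    events,
    subject_id = if (is.null(meta$subject_id)) "unknown" else meta$subject_id,
    age_group = if (is.null(meta$age_group)) "unknown" else meta$age_group,
    sex = if (is.null(meta$sex)) "unknown" else meta$sex,
    protocol = protocol
  )
}

#' Validate a trial log
#'
#' A total check: returns a data.frame of findings instead of throwing, one
#' row per issue with a `severity` (`"error"` or `"warning"`), the index of
#' the first implicated event (`NA` for log-level findings) and a message.
#' An empty result means every invariant holds. Warnings cover protocol-level
#' oddities a log can legally contain: overlapping stimuli (a new stimulus
#' before the previous one was resolved by a correct press), presses of the
#' unused middle pedal, and presses with no pending stimulus.
#'
#' @param log A `pspvt_trial_log` (or anything structured like one).
#' @return data.frame with columns `severity`, `event_index`, `message`.
#' @export
validate_trial_log <- function(log) {
  findings <- list()
  add <- function(severity, index, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      severity = severity, event_index = index, message = message,
      stringsAsFactors = FALSE)
  }
  ev <- log$events
  if (!events_are_sorted(ev)) {
    add("error", NA_integer_, "events not in canonical order")
    ev <- sort_events(ev)
  }
  if (any(ev$time_ms < 0)) {
    add("error", which(ev$time_ms < 0)[1], "negative event time")
  }
  if (sum(ev$event == "mode" & ev$time_ms == 0L) != 1L) {
    add("error", NA_integer_, "expected exactly one mode event at t = 0")
  }
  legal <- event_arg_legal(ev$event, ev$arg)
  if (any(!legal)) {
    i <- which(!legal)[1]
    add("error", i, sprintf("illegal arg '%s' for event '%s'",
                            ev$arg[i], ev$event[i]))
  }
  mid <- which(ev$event == "press" & ev$arg == "middle")
  if (length(mid) > 0) {
    add("warning", mid[1],
        sprintf("%d middle-pedal press(es): middle pedal unused by protocol",
                length(mid)))
  }

  # overlapping stimuli / orphan presses need the mode timeline
  if (all(legal) && !is.null(log$meta$protocol)) {
    tl <- build_mode_timeline(log$meta$protocol)
    dur <- log$meta$protocol$trial_duration_ms
    pending_correct <- NA_character_
    pending_idx <- NA_integer_
    for (i in seq_len(nrow(ev))) {
      kind <- ev$event[i]
      if (kind == "stim") {
        if (!is.na(pending_correct)) {
          add("warning", i,
              "overlapping stimuli: new stimulus before previous resolved")
        }
        t <- min(ev$time_ms[i], dur - 1L)
        pending_correct <- correct_side(ev$arg[i], mode_at(tl, t))
        pending_idx <- i
      } else if (kind == "press" && ev$arg[i] != "middle") {
        if (is.na(pending_correct)) {
          add("warning", i, "press with no pending stimulus")
        } else if (ev$arg[i] == pending_correct) {
          pending_correct <- NA_character_
        }
      }
    }
  }

  if (length(findings) == 0) {
    return(data.frame(severity = character(), event_index = integer(),
                      message = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, findings)
  rownames(out) <- NULL
  out
}
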