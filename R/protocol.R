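#' Protocol configuration for a pedal selective vigilance trial
#'
#' Defines the temporal structure of one trial: total duration, the length of
#' the alternating parallel/cross response-mapping blocks, the inter-stimulus
#' interval (ISI) law, the left/right stimulus probability, and the response
#' freezing ("hesitation") threshold used by the scorer.
#'
#' All times are integer milliseconds from trial start (t = 0 at the start of
#' the first block). The defaults describe a 6-min trial whose response mode
#' switches between parallel and cross every 2 min, stimuli arriving at a
#' uniform 2-6 s interval after the previous stimulus is resolved, and a 3 s
#' hesitation threshold.
#'
#' @param trial_duration_ms Total trial length, ms. Default 360000 (6 min).
#' @param block_duration_ms Length of each response-mapping block, ms.
#'   Default 120000 (2 min).
#' @param start_mode Mode of the first block, `"parallel"` or `"cross"`.
#' @param isi_min_ms,isi_max_ms Bounds of the uniform inter-stimulus interval,
#'   measured from the resolution (first correct press) of the previous
#'   stimulus to the next onset. Defaults 2000 and 6000.
#' @param side_probability_left Probability that a stimulus appears on the
#'   left. Default 0.5.
#' @param hesitation_threshold_ms First-press latency strictly above this is
#'   classified as a hesitation. Default 3000.
#'
#' @return An object of class `pspvt_protocol` (a named list of the fields
#'   above).
#' @examples
#' cfg <- protocol_config()
#' build_mode_timeline(cfg)
#' @export
protocol_config <- function(trial_duration_ms = 360000,
                            block_duration_ms = 120000,
                            start_mode = c("parallel", "cross"),
                            isi_min_ms = 2000,
                            isi_max_ms = 6000,
                            side_probability_left = 0.5,
                            hesitation_threshold_ms = 3000) {
  start_mode <- match.arg(start_mode)
  cfg <- structure(
    list(
      trial_duration_ms = as.integer(trial_duration_ms),
      block_duration_ms = as.integer(block_duration_ms),
      start_mode = start_mode,
      isi_min_ms = as.integer(isi_min_ms),
      isi_max_ms = as.integer(isi_max_ms),
      side_probability_left = as.numeric(side_probability_left),
      hesitation_threshold_ms = as.integer(hesitation_threshold_ms)
    ),
    class = "pspvt_protocol"
  )
  validate_protocol_config(cfg)
  cfg
}

validate_protocol_config <- function(cfg) {
  stopifnot(inherits(cfg, "pspvt_protocol"))
  check <- function(ok, field, why) {
    if (!isTRUE(ok)) {
      stop(sprintf("invalid protocol config: field '%s' %s", field, why),
           call. = FALSE)
    }
  }
  check(is.finite(cfg$trial_duration_ms) && cfg$trial_duration_ms > 0,
        "trial_duration_ms", "must be > 0")
  # a block longer than the trial is legal: the single block is truncated
  check(is.finite(cfg$block_duration_ms) && cfg$block_duration_ms > 0,
        "block_duration_ms", "must be > 0")
  check(cfg$start_mode %in% c("parallel", "cross"),
        "start_mode", "must be 'parallel' or 'cross'")
  check(is.finite(cfg$isi_min_ms) && cfg$isi_min_ms >= 0,
        "isi_min_ms", "must be >= 0")
  check(is.finite(cfg$isi_max_ms) && cfg$isi_max_ms >= cfg$isi_min_ms,
        "isi_max_ms", "must be >= isi_min_ms")
  check(is.finite(cfg$side_probability_left) &&
          cfg$side_probability_left >= 0 && cfg$side_probability_left <= 1,
        "side_probability_left", "must be in [0, 1]")
  check(is.finite(cfg$hesitation_threshold_ms) &&
          cfg$hesitation_threshold_ms > 0,
        "hesitation_threshold_ms", "must be > 0")
  invisible(cfg)
}

#' @export
print.pspvt_protocol <- function(x, ...) {
  cat("PS-PVT protocol configuration\n")
  cat(sprintf("  trial: %d ms, blocks of %d ms starting in %s mode\n",
              x$trial_duration_ms, x$block_duration_ms, x$start_mode))
  cat(sprintf("  ISI uniform on [%d, %d] ms after previous resolution\n",
              x$isi_min_ms, x$isi_max_ms))
  cat(sprintf("  P(left stimulus) = %g, hesitation threshold %d ms\n",
              x$side_probability_left, x$hesitation_threshold_ms))
  invisible(x)
}

#' Read a protocol configuration from a flat key-value file
#'
#' The file holds one `key = value` (or `key: value`) pair per line, keys
#' named exactly as the arguments of [protocol_config()]. Blank lines and
#' lines starting with `#` are ignored. Keys not present keep their defaults;
#' unknown keys are an error.
#'
#' @param path Path to the configuration file.
#' @return A `pspvt_protocol` object.
#' @export
read_protocol_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  args <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*[=:]\\s*(.+)$", ln))[[1]]
    if (length(m) != 3) {
      stop(sprintf("cannot parse config line: '%s'", ln), call. = FALSE)
    }
    key <- m[2]
    val <- trimws(m[3])
    fields <- names(formals(protocol_config))
    if (!key %in% fields) {
      stop(sprintf("unknown config key '%s'", key), call. = FALSE)
    }
    args[[key]] <- if (key == "start_mode") val else as.numeric(val)
  }
  do.call(protocol_config, args)
}

#' Build the block timeline of parallel/cross modes
#'
#' Tiles `[0, trial_duration_ms)` with half-open blocks of
#' `block_duration_ms`, alternating modes from `start_mode`; the final block
#' is truncated at the trial end.
#'
#' @param config A [protocol_config()] object.
#' @return A data.frame of class `pspvt_timeline` with columns `start_ms`
#'   (inclusive), `end_ms` (exclusive) and `mode`.
#' @examples
#' build_mode_timeline(protocol_config(start_mode = "cross"))
#' @export
build_mode_timeline <- function(config) {
  validate_protocol_config(config)
  n_blocks <- ceiling(config$trial_duration_ms / config$block_duration_ms)
  start <- (seq_len(n_blocks) - 1L) * config$block_duration_ms
  end <- pmin(start + config$block_duration_ms, config$trial_duration_ms)
  modes <- c("parallel", "cross")
  if (config$start_mode == "cross") modes <- rev(modes)
  tl <- data.frame(
    start_ms = as.integer(start),
    end_ms = as.integer(end),
    mode = modes[(seq_len(n_blocks) - 1L) %% 2L + 1L],
    stringsAsFactors = FALSE
  )
  structure(tl,
            class = c("pspvt_timeline", "data.frame"),
            trial_duration_ms = config$trial_duration_ms)
}

#' Mode in effect at a time point
#'
#' Looks up the response-mapping mode of the half-open block containing each
#' time point; a block boundary instant belongs to the later block.
#'
#' @param timeline A [build_mode_timeline()] result.
#' @param t_ms Time(s) in ms from trial start; must satisfy
#'   `0 <= t_ms < trial_duration_ms`.
#' @return Character vector of `"parallel"` / `"cross"`.
#' @export
mode_at <- function(timeline, t_ms) {
  dur <- attr(timeline, "trial_duration_ms")
  if (any(t_ms < 0 | t_ms >= dur)) {
    stop(sprintf("t_ms out of range [0, %d)", dur), call. = FALSE)
  }
  idx <- findInterval(t_ms, timeline$start_ms)
  timeline$mode[idx]
}

#' Sample the onset and side of the next stimulus
#'
#' The next onset is the previous stimulus's resolution time plus a uniform
#' draw on `[isi_min_ms, isi_max_ms]` (rounded to integer ms); the side is
#' left with probability `side_probability_left`. Returns `NULL` once the
#' sampled onset falls at or beyond the trial end, which terminates stimulus
#' generation. Uses R's global random number stream.
#'
#' @param config A [protocol_config()] object.
#' @param prev_resolution_ms Resolution time (first correct press) of the
#'   previous stimulus; use 0 at trial start.
#' @return `list(onset_ms =, side =)` or `NULL` at trial end.
#' @export
sample_next_stimulus <- function(config, prev_resolution_ms) {
  if (prev_resolution_ms < 0) {
    stop("prev_resolution_ms must be >= 0", call. = FALSE)
  }
  isi <- round(stats::runif(1, config$isi_min_ms, config$isi_max_ms))
  onset <- as.integer(prev_resolution_ms + isi)
  if (onset >= config$trial_duration_ms) {
    return(NULL)
  }
  side <- if (stats::runif(1) < config$side_probability_left) "left" else "right"
  list(onset_ms = onset, side = side)
}

#' Correct pedal for a stimulus under a response-mapping mode
#'
#' In parallel mode the correct pedal is ipsilateral to the lit circle; in
#' cross mode it is contralateral. Vectorised over both arguments.
#'
#' @param stimulus_side `"left"` or `"right"`.
#' @param mode `"parallel"` or `"cross"`.
#' @return The correct pedal side, `"left"` or `"right"`.
#' @examples
#' correct_side("left", "parallel") # "left"
#' correct_side("left", "cross")    # "right"
#' @export
correct_side <- function(stimulus_side, mode) {
  if (!all(stimulus_side %in% c("left", "right"))) {
    stop("stimulus_side must be 'left' or 'right'", call. = FALSE)
  }
  if (!all(mode %in% c("parallel", "cross"))) {
    stop("mode must be 'parallel' or 'cross'", call. = FALSE)
  }
  flipped <- ifelse(stimulus_side == "left", "right", "left")
  ifelse(mode == "parallel", stimulus_side, flipped)
}
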