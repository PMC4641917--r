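#' Construct a sequence of 4-bit control-interface events
#'
#' Each fNIRS module is driven over a 4-bit parallel interface with lines
#' RST, TRIG, CH1 and CH0. An event records the logic levels of all four
#' lines at a point in time; the semantics (see [decode_control()]) are that
#' CH1:CH0 select one of the four optode channels, a rising edge on TRIG
#' activates the selected channel — always starting at 750 nm after a reset,
#' with every further rising edge toggling between 750 and 850 nm — and a
#' high RST turns all channels off and re-arms the 750 nm start.
#'
#' @param time event times in seconds (non-decreasing within a module).
#' @param rst,trig,ch1,ch0 logic levels, each exactly 0 or 1.
#' @param module_id integer module address(es), default 0.
#' @return a `data.frame` of class `control_events` with one row per event.
#' @seealso [decode_control()], [encode_control()]
#' @export
control_events <- function(time, rst, trig, ch1, ch0, module_id = 0L) {
  n <- length(time)
  ev <- data.frame(
    time = as.numeric(time),
    module_id = as.integer(rep_len(module_id, n)),
    rst = as.integer(rst), trig = as.integer(trig),
    ch1 = as.integer(ch1), ch0 = as.integer(ch0)
  )
  for (line in c("rst", "trig", "ch1", "ch0")) {
    if (!all(ev[[line]] %in% c(0L, 1L))) {
      stop_input("control line `%s` must be exactly 0 or 1", line)
    }
  }
  if (any(ev$time < 0)) stop_input("event times must be >= 0")
  for (m in unique(ev$module_id)) {
    tm <- ev$time[ev$module_id == m]
    if (is.unsorted(tm)) {
      stop_input("event times for module %d are not non-decreasing", m)
    }
  }
  class(ev) <- c("control_events", "data.frame")
  ev
}

#' Decode a control-event sequence into the channel activation timeline
#'
#' Replays the module's interface state machine: the channel-select lines are
#' latched at each TRIG rising edge, the first rising edge after a reset
#' activates the selected channel at 750 nm, each subsequent rising edge
#' toggles the active wavelength between 750 and 850 nm, and RST high forces
#' all channels off and re-arms the 750 nm start.
#'
#' @param events a `control_events` data frame (possibly several modules).
#' @return a `data.frame` with columns `time`, `module_id`, `channel`
#'   (0-3, `NA` = all off) and `wavelength` (nm, `NA` = all off), one row per
#'   state change.
#' @export
decode_control <- function(events) {
  if (!inherits(events, "control_events")) {
    events <- control_events(events$time, events$rst, events$trig,
                             events$ch1, events$ch0,
                             if (is.null(events$module_id)) 0L else events$module_id)
  }
  out <- list()
  for (m in sort(unique(events$module_id))) {
    ev <- events[events$module_id == m, , drop = FALSE]
    prev_trig <- 0L
    armed_wl <- 750
    active <- FALSE
    for (i in seq_len(nrow(ev))) {
      if (ev$rst[i] == 1L) {
        if (active) {
          out[[length(out) + 1L]] <- data.frame(
            time = ev$time[i], module_id = m,
            channel = NA_integer_, wavelength = NA_real_)
        }
        active <- FALSE
        armed_wl <- 750
        prev_trig <- ev$trig[i]
        next
      }
      if (ev$trig[i] == 1L && prev_trig == 0L) {
        ch <- 2L * ev$ch1[i] + ev$ch0[i]
        out[[length(out) + 1L]] <- data.frame(
          time = ev$time[i], module_id = m,
          channel = ch, wavelength = armed_wl)
        armed_wl <- if (armed_wl == 750) 850 else 750
        active <- TRUE
      }
      prev_trig <- ev$trig[i]
    }
  }
  if (length(out) == 0L) {
    return(data.frame(time = numeric(), module_id = integer(),
                      channel = integer(), wavelength = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$time, res$module_id), , drop = FALSE]
}

#' Build a time-division-multiplexing schedule
#'
#' The instrument interrogates its optode channels sequentially: each slot
#' activates one (module, channel, wavelength) combination, waits a dwell
#' time for the demodulated signal to settle, then the shared ADC converts
#' the sample. Slots are ordered module-major, channel-minor, with 750 nm
#' before 850 nm for every channel, and a frame visits every slot once, so
#' the per-channel-wavelength sampling rate is `1 / frame_period`.
#'
#' @param n_modules number of fNIRS modules (>= 1).
#' @param channels_per_module active optode channels per module (1-4).
#' @param dwell_time settling time after channel activation, seconds.
#'   Default 0.024 s, sized so that a fully populated 4-channel module with
#'   the stock 80.3 ms ADC conversion samples each channel-wavelength near
#'   1.2 Hz.
#' @param conversion_time ADC conversion time per slot, seconds (default
#'   0.0803 s, the stock 16-bit converter).
#' @return a `tdm_schedule` list with `slots` (data frame: `module_id`,
#'   `channel`, `wavelength`, `offset` within the frame), `dwell_time`,
#'   `conversion_time`, `frame_period` and `sample_rate`.
#' @examples
#' sched <- build_tdm_schedule(1, 4)
#' sched$frame_period  # 8 slots x 104.3 ms = 834.4 ms
#' @export
build_tdm_schedule <- function(n_modules = 1L, channels_per_module = 4L,
                               dwell_time = 0.024, conversion_time = 0.0803) {
  check_scalar(n_modules, "n_modules", lower = 1)
  check_scalar(channels_per_module, "channels_per_module", lower = 1, upper = 4)
  check_scalar(dwell_time, "dwell_time", lower = 0, allow_equal_lower = FALSE)
  check_scalar(conversion_time, "conversion_time", lower = 0, allow_equal_lower = FALSE)
  slots <- expand.grid(
    wavelength = WAVELENGTHS,
    channel = seq_len(channels_per_module) - 1L,
    module_id = seq_len(n_modules) - 1L,
    KEEP.OUT.ATTRS = FALSE
  )[, c("module_id", "channel", "wavelength")]
  slots$offset <- (seq_len(nrow(slots)) - 1L) * (dwell_time + conversion_time)
  frame_period <- nrow(slots) * (dwell_time + conversion_time)
  structure(
    list(slots = slots, dwell_time = dwell_time,
         conversion_time = conversion_time,
         frame_period = frame_period, sample_rate = 1 / frame_period),
    class = "tdm_schedule"
  )
}

#' @export
print.tdm_schedule <- function(x, ...) {
  cat(sprintf(
    "TDM schedule: %d slots (%d module(s) x %d channel(s) x 2 wavelengths)\n",
    nrow(x$slots), length(unique(x$slots$module_id)),
    length(unique(x$slots$channel))))
  cat(sprintf("  dwell %.1f ms + conversion %.1f ms -> frame %.1f ms (%.3f Hz per channel-wavelength)\n",
              1e3 * x$dwell_time, 1e3 * x$conversion_time,
              1e3 * x$frame_period, x$sample_rate))
  invisible(x)
}

# Slot activation timeline of a schedule over `n_frames` frames.
schedule_timeline <- function(schedule, n_frames = 1L) {
  stopifnot(inherits(schedule, "tdm_schedule"))
  frames <- (seq_len(n_frames) - 1L) * schedule$frame_period
  out <- do.call(rbind, lapply(frames, function(t0) {
    data.frame(time = t0 + schedule$slots$offset,
               module_id = schedule$slots$module_id,
               channel = schedule$slots$channel,
               wavelength = schedule$slots$wavelength)
  }))
  rownames(out) <- NULL
  out
}

#' Encode a TDM schedule into 4-bit control events
#'
#' Emits, for every slot, the control-line pattern that reproduces the
#' schedule's activation timeline on the interface state machine: before each
#' 750 nm slot an RST pulse re-arms the wavelength toggle, the channel-select
#' lines are set, and a TRIG rising edge activates the slot; the paired
#' 850 nm slot needs only a TRIG low/high cycle since the toggle advances the
#' wavelength. `decode_control(encode_control(s))` reproduces
#' `schedule_timeline(s)` exactly.
#'
#' @param schedule a [build_tdm_schedule()] result.
#' @param n_frames number of frames to encode (default 1).
#' @return a `control_events` data frame.
#' @export
encode_control <- function(schedule, n_frames = 1L) {
  stopifnot(inherits(schedule, "tdm_schedule"))
  if (nrow(schedule$slots) == 0L) stop_input("schedule has no slots")
  tl <- schedule_timeline(schedule, n_frames)
  rows <- vector("list", nrow(tl))
  for (i in seq_len(nrow(tl))) {
    s <- tl[i, ]
    ch1 <- as.integer(s$channel >= 2)
    ch0 <- as.integer(s$channel %% 2)
    if (s$wavelength == 750) {
      # reset (all off, re-arm 750), release, select + trig low, trig rise
      rows[[i]] <- data.frame(
        time = s$time, module_id = s$module_id,
        rst = c(1L, 0L, 0L, 0L), trig = c(0L, 0L, 0L, 1L),
        ch1 = c(0L, 0L, ch1, ch1), ch0 = c(0L, 0L, ch0, ch0))
    } else {
      rows[[i]] <- data.frame(
        time = s$time, module_id = s$module_id,
        rst = c(0L, 0L), trig = c(0L, 1L),
        ch1 = ch1, ch0 = ch0)
    }
  }
  ev <- do.call(rbind, rows)
  control_events(ev$time, ev$rst, ev$trig, ev$ch1, ev$ch0, ev$module_id)
}

# ---- ASCII CSV packet codec -------------------------------------------------

PACKET_COLUMNS <- c("timestamp", "module_id", "channel", "wavelength", "adc_code")

#' Serialize acquisition packets to the instrument's ASCII CSV format
#'
#' One packet per line with a one-line header; columns are
#' `timestamp` (s), `module_id`, `channel` (0-3), `wavelength` (nm) and
#' `adc_code` (16-bit). The codec round-trips all in-range field values
#' losslessly.
#'
#' @param packets a data frame with the five packet columns (a
#'   [simulate_acquisition()] recording qualifies).
#' @param path optional file path; if omitted the CSV text is returned.
#' @return `path` invisibly, or the CSV text as a character scalar.
#' @export
write_packets <- function(packets, path = NULL) {
  packets <- as.data.frame(packets)
  if (!all(PACKET_COLUMNS %in% names(packets))) {
    stop_input("packets must have columns %s", paste(PACKET_COLUMNS, collapse = ", "))
  }
  p <- packets[, PACKET_COLUMNS]
  if (any(p$adc_code < 0 | p$adc_code > 65535)) {
    stop_input("adc_code out of 16-bit range")
  }
  lines <- c(
    paste(PACKET_COLUMNS, collapse = ","),
    sprintf("%s,%d,%d,%s,%d",
            format(p$timestamp, digits = 15, trim = TRUE, scientific = FALSE),
            as.integer(p$module_id), as.integer(p$channel),
            format(p$wavelength, trim = TRUE), as.integer(p$adc_code))
  )
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(text)
  writeLines(lines, path)
  invisible(path)
}

#' Parse ASCII CSV packets
#'
#' @param text CSV text (character scalar, possibly multi-line) or the path
#'   of a packet file written by [write_packets()].
#' @return a data frame with the five packet columns.
#' @export
parse_packets <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    lines <- readLines(text)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  }
  lines_all <- lines
  keep <- nzchar(trimws(lines_all))
  first <- which(keep)[1]
  if (is.na(first)) stop_input("no packet data found")
  start <- first
  if (identical(trimws(lines_all[first]), paste(PACKET_COLUMNS, collapse = ","))) {
    start <- first + 1L
  }
  idx <- which(keep & seq_along(lines_all) >= start)
  parse_row <- function(i) {
    fields <- strsplit(lines_all[i], ",", fixed = TRUE)[[1]]
    if (length(fields) != 5L) {
      stop_input("packet parse error at line %d: expected 5 fields, got %d",
                 i, length(fields))
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) {
      stop_input("packet parse error at line %d: non-numeric field `%s`",
                 i, fields[which(is.na(vals))[1]])
    }
    vals
  }
  m <- t(vapply(idx, parse_row, numeric(5)))
  out <- data.frame(
    timestamp = m[, 1], module_id = as.integer(m[, 2]),
    channel = as.integer(m[, 3]), wavelength = m[, 4],
    adc_code = as.integer(m[, 5]))
  if (any(out$adc_code < 0 | out$adc_code > 65535)) {
    stop_input("adc_code out of 16-bit range in packet data")
  }
  if (any(out$channel < 0 | out$channel > 3)) {
    stop_input("channel out of range 0-3 in packet data")
  }
  out
}
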