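#' Multichannel LFP recording container
#'
#' Bundles a voltage matrix with its sampling rate, stimulation onset times
#' and free-form metadata. Voltages are in microvolts; times are in seconds,
#' 0-based from the recording start (plus `t0`), and stimulation onsets mark
#' the rising edge of the ultrasound sync pulse.
#'
#' @param samples numeric matrix, channels x time (a vector is treated as one
#'   channel), in uV.
#' @param fs sampling rate in Hz.
#' @param t0 recording start time in seconds (default 0).
#' @param stim_onsets numeric vector of stimulation onset times (s), strictly
#'   increasing and inside the recording.
#' @param channel_ids optional character labels, one per channel.
#' @param meta named list of free-form metadata (group label, intensity,
#'   anesthesia state, phase table, ...).
#' @return An object of class `lfp_recording`.
#' @export
recording <- function(samples, fs, t0 = 0, stim_onsets = numeric(),
                      channel_ids = NULL, meta = list()) {
  if (is.vector(samples) && is.numeric(samples))
    samples <- matrix(samples, nrow = 1L)
  if (!is.matrix(samples) || !is.numeric(samples))
    stopf("`samples` must be a numeric matrix (channels x time)")
  check_number(fs, "fs", min = 0, strict = TRUE)
  check_number(t0, "t0")
  n <- ncol(samples)
  if (length(stim_onsets)) {
    if (is.unsorted(stim_onsets, strictly = TRUE))
      stopf("`stim_onsets` must be strictly increasing")
    t_end <- t0 + n / fs
    if (any(stim_onsets < t0) || any(stim_onsets > t_end))
      stopf("all `stim_onsets` must lie within [%g, %g] s", t0, t_end)
  }
  if (is.null(channel_ids))
    channel_ids <- paste0("ch", seq_len(nrow(samples)))
  if (length(channel_ids) != nrow(samples))
    stopf("`channel_ids` length (%d) != number of channels (%d)",
          length(channel_ids), nrow(samples))
  rownames(samples) <- channel_ids
  structure(
    list(samples = samples, fs = fs, t0 = t0,
         stim_onsets = as.numeric(stim_onsets),
         channel_ids = as.character(channel_ids), meta = meta),
    class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs))
  cat(sprintf("  stim onsets: %d", length(x$stim_onsets)))
  if (length(x$stim_onsets))
    cat(sprintf(" (first %.3g s, last %.3g s)",
                x$stim_onsets[1], x$stim_onsets[length(x$stim_onsets)]))
  cat("\n")
  if (length(x$meta)) cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `lfp_recording`.
#' @return numeric scalar, seconds.
#' @export
rec_duration <- function(rec) ncol(rec$samples) / rec$fs

#' Extract stimulation onset times from a sync channel
#'
#' Finds rising-edge threshold crossings of the sync signal. Edges closer
#' together than `refractory` are merged (first edge kept) so that
#' within-burst pulse-repetition edges are not double counted; the default
#' refractory window equals the protocol sonication duration (0.3 s).
#'
#' @param sync numeric vector, the sync channel.
#' @param fs sampling rate (Hz).
#' @param threshold crossing level; defaults to the midpoint of the signal
#'   range. Must lie strictly between the signal extremes to detect anything.
#' @param refractory merge window in seconds (default 0.3).
#' @param t0 time of the first sample (s).
#' @return numeric vector of onset times (s), strictly increasing; empty if
#'   there are no crossings.
#' @export
extract_sync_onsets <- function(sync, fs, threshold = NULL, refractory = 0.3,
                                t0 = 0) {
  check_number(fs, "fs", min = 0, strict = TRUE)
  if (is.null(threshold)) threshold <- (min(sync) + max(sync)) / 2
  above <- sync >= threshold
  idx <- which(!above[-length(above)] & above[-1]) + 1L
  if (!length(idx)) return(numeric())
  times <- t0 + (idx - 1L) / fs
  # iterative merge: an edge is kept only if > refractory after the last kept
  out <- times[1L]
  for (tt in times[-1L]) if (tt - out[length(out)] > refractory) out <- c(out, tt)
  out
}

#' Ultrasound stimulation protocol
#'
#' Pulse-schedule and intensity parameters for a pulsed focused-ultrasound
#' protocol. Defaults follow a standard sonogenetics paradigm: 1.0 MHz
#' fundamental, 1.0 kHz pulse repetition frequency, 50% duty cycle, 0.5 ms
#' tone bursts, 0.3 s sonication per stimulus, 3 s inter-stimulus interval,
#' 150 s experimental phases, with an empirical calibration table pairing
#' spatial-peak temporal-average intensities (mW/cm^2) with peak negative
#' pressures (MPa).
#'
#' @param ff fundamental frequency (MHz).
#' @param prf pulse repetition frequency (kHz).
#' @param dc duty cycle, fraction in (0, 1].
#' @param tbd tone burst duration (ms).
#' @param sd_ sonication duration per stimulus (s).
#' @param isi inter-stimulus interval (s).
#' @param phase_len duration of each experimental phase (s).
#' @param levels data.frame with columns `ispta` (mW/cm^2) and `pnp` (MPa):
#'   the empirical intensity/pressure calibration table.
#' @return A validated object of class `stim_protocol`.
#' @seealso [validate_protocol()]
#' @export
stim_protocol <- function(ff = 1.0, prf = 1.0, dc = 0.5, tbd = 0.5,
                          sd_ = 0.3, isi = 3, phase_len = 150,
                          levels = data.frame(ispta = c(100, 250, 400),
                                              pnp = c(0.15, 0.25, 0.35))) {
  p <- structure(list(ff = ff, prf = prf, dc = dc, tbd = tbd, sd = sd_,
                      isi = isi, phase_len = phase_len, levels = levels),
                 class = "stim_protocol")
  validate_protocol(p)
}

#' Validate a stimulation protocol
#'
#' Checks positivity of all fields and the internal consistency
#' `dc = tbd * prf` (ms x kHz) to within 1e-9.
#'
#' @param p a `stim_protocol`.
#' @return `p`, invisibly unchanged, if valid; otherwise an error naming the
#'   inconsistent fields.
#' @export
validate_protocol <- function(p) {
  stopifnot(inherits(p, "stim_protocol"))
  for (f in c("ff", "prf", "tbd", "sd", "isi", "phase_len"))
    check_number(p[[f]], f, min = 0, strict = TRUE)
  check_number(p$dc, "dc", min = 0, strict = TRUE)
  if (p$dc > 1) stopf("`dc` must be a fraction in (0, 1], got %g", p$dc)
  if (abs(p$dc - p$tbd * p$prf) > 1e-9)
    stopf("inconsistent protocol: dc (%g) != tbd * prf (%g ms x %g kHz = %g)",
          p$dc, p$tbd, p$prf, p$tbd * p$prf)
  lv <- p$levels
  if (!is.data.frame(lv) || !nrow(lv) ||
      !all(c("ispta", "pnp") %in% names(lv)) ||
      any(lv$ispta <= 0) || any(lv$pnp <= 0))
    stopf("`levels` must be a non-empty data.frame with positive `ispta` and `pnp`")
  p
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf(paste0("<stim_protocol> FF %g MHz, PRF %g kHz, DC %g%%, TBD %g ms, ",
                     "SD %g s, ISI %g s, phase %g s\n"),
              x$ff, x$prf, 100 * x$dc, x$tbd, x$sd, x$isi, x$phase_len))
  cat("  calibration levels (Ispta mW/cm^2 -> PNP MPa):",
      paste(sprintf("%g->%g", x$levels$ispta, x$levels$pnp), collapse = ", "), "\n")
  invisible(x)
}

#' Read a stimulation protocol from a YAML or JSON config file
#'
#' @param path config file; keys `ff, prf, dc, tbd, sd, isi, phase_len` and a
#'   `levels` table (`ispta`, `pnp` vectors).
#' @return a validated `stim_protocol`.
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) stopf("protocol file not found: %s", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  lv <- cfg$levels
  levels <- if (is.null(lv)) formals(stim_protocol)$levels else
    data.frame(ispta = as.numeric(unlist(lv$ispta)),
               pnp = as.numeric(unlist(lv$pnp)))
  if (is.call(levels) || is.null(levels)) levels <- eval(formals(stim_protocol)$levels)
  stim_protocol(ff = cfg$ff %||% 1.0, prf = cfg$prf %||% 1.0,
                dc = cfg$dc %||% 0.5, tbd = cfg$tbd %||% 0.5,
                sd_ = cfg$sd %||% 0.3, isi = cfg$isi %||% 3,
                phase_len = cfg$phase_len %||% 150, levels = levels)
}

#' Behavioral event table
#'
#' Carrier for pre-scored behavioral events (zone bouts, arm entries,
#' immobility bouts) as labeled `[start, stop]` intervals in seconds.
#'
#' @param label character vector of event labels.
#' @param start,stop numeric vectors of bout start/stop times (s),
#'   `start <= stop`, non-negative.
#' @return a `data.frame` of class `event_table`.
#' @export
event_table <- function(label, start, stop) {
  if (length(label) != length(start) || length(start) != length(stop))
    stopf("`label`, `start`, `stop` must have equal length")
  start <- as.numeric(start); stop <- as.numeric(stop)
  if (any(start < 0) || any(stop < 0)) stopf("event times must be non-negative")
  if (any(start > stop)) stopf("every event must have start <= stop")
  structure(data.frame(label = as.character(label), start = start, stop = stop,
                       stringsAsFactors = FALSE),
            class = c("event_table", "data.frame"))
}

#' Read a behavioral event table from CSV
#' @param path CSV file with columns `label,start_s,stop_s` (or `start,stop`).
#' @return an [event_table()].
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stopf("event table not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  st <- d$start %||% d$start_s
  sp <- d$stop %||% d$stop_s
  if (is.null(d$label) || is.null(st) || is.null(sp))
    stopf("event table needs columns label, start[_s], stop[_s]")
  event_table(d$label, st, sp)
}
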