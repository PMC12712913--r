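# Ultrasound-evoked potential quantification. N1 is operationalized as the
# first local minimum within the 0-500 ms post-onset search window whose
# (smoothed) depth exceeds a noise floor of `floor_mult` times the pre-onset
# standard deviation. Trough location is picked on a lightly smoothed trace
# for stability; the amplitude is read from the raw trace at that sample so a
# noiseless injected trough is recovered exactly.

#' Trial-average evoked waveform
#'
#' Pointwise mean and standard error across kept trials.
#'
#' @param ep an `lfp_epochs` (after [baseline_correct()]).
#' @return list with `mean`, `sem`, `times`, `fs`, `n` (kept trials).
#' @export
average_uep <- function(ep) {
  stopifnot(inherits(ep, "lfp_epochs"))
  keep <- which(ep$kept)
  if (!length(keep)) stopf("empty-epoch error: all trials rejected")
  x <- ep$x[keep, , drop = FALSE]
  n <- nrow(x)
  m <- colMeans(x)
  sem <- if (n > 1L) apply(x, 2L, sd) / sqrt(n) else rep(0, ncol(x))
  list(mean = m, sem = sem, times = ep$times, fs = ep$fs, n = n)
}

#' Detect the N1 trough in an evoked trace
#'
#' After optional moving-average smoothing, finds the first local minimum
#' inside the search window whose smoothed value is at or below
#' `-floor_mult * noise_sd`; reports its magnitude (from the unsmoothed
#' trace) and latency. Absence of a qualifying trough is a non-response, not
#' an error.
#'
#' @param trace baseline-corrected waveform (uV).
#' @param fs sampling rate (Hz).
#' @param t_start time of the first sample relative to onset (s), e.g. -1;
#'   ignored if `times` is given.
#' @param times optional vector of sample times relative to onset (s).
#' @param search `c(start, end)` of the search window (s), default 0-0.5.
#' @param smooth moving-average width (s); 0 disables (default 0.005).
#' @param floor_mult significance floor in units of the pre-onset SD
#'   (default 3). If the floor degenerates to zero (noiseless baseline), 5%
#'   of the largest in-window excursion is used instead.
#' @param noise_sd pre-onset noise SD (uV); default: SD of the trace before
#'   t = 0 (required if the trace has no pre-onset samples).
#' @return list with `amplitude` (uV, positive trough magnitude), `latency`
#'   (ms post-onset) and `responded` (logical); amplitude/latency are `NA`
#'   for a non-response.
#' @export
detect_n1 <- function(trace, fs, t_start = NULL, times = NULL,
                      search = c(0, 0.5), smooth = 0.005, floor_mult = 3,
                      noise_sd = NULL) {
  if (is.null(times)) {
    if (is.null(t_start)) stopf("provide `times` or `t_start`")
    times <- t_start + (seq_along(trace) - 1L) / fs
  }
  if (length(times) != length(trace)) stopf("`times` must match `trace`")
  if (is.null(noise_sd)) {
    pre <- times < 0
    if (!any(pre))
      stopf("no pre-onset samples: supply `noise_sd` explicitly")
    noise_sd <- sd(trace[pre])
    if (is.na(noise_sd)) noise_sd <- 0
  }
  floor_v <- floor_mult * noise_sd
  xs <- if (smooth > 0) moving_average(trace, round(smooth * fs)) else trace
  non_response <- list(amplitude = NA_real_, latency = NA_real_,
                       responded = FALSE)
  win <- which(times >= search[1] & times <= search[2])
  if (length(win) < 3L) return(non_response)
  # degenerate noiseless baseline: fall back to a relative floor so numerical
  # ripple in an otherwise clean trace is not reported as a trough
  if (floor_v <= 0) floor_v <- 0.05 * max(abs(xs[win]))
  iw <- win[-c(1L, length(win))]
  is_min <- xs[iw] <= xs[iw - 1L] & xs[iw] < xs[iw + 1L] & xs[iw] < 0 &
    xs[iw] <= -floor_v
  if (!any(is_min)) return(non_response)
  i <- iw[which(is_min)[1L]]
  list(amplitude = abs(trace[i]), latency = 1000 * times[i], responded = TRUE)
}

#' Per-trial N1 metrics for an epoch set
#'
#' Runs [detect_n1()] on every kept trial.
#'
#' @param ep a baseline-corrected `lfp_epochs`.
#' @inheritParams detect_n1
#' @return data.frame with columns `trial`, `amplitude_uV`, `latency_ms`,
#'   `responded`.
#' @export
uep_metrics <- function(ep, search = c(0, 0.5), smooth = 0.005,
                        floor_mult = 3, noise_sd = NULL) {
  stopifnot(inherits(ep, "lfp_epochs"))
  keep <- which(ep$kept)
  rows <- lapply(keep, function(i) {
    r <- detect_n1(ep$x[i, ], ep$fs, times = ep$times, search = search,
                   smooth = smooth, floor_mult = floor_mult,
                   noise_sd = noise_sd)
    data.frame(trial = i, amplitude_uV = r$amplitude, latency_ms = r$latency,
               responded = r$responded)
  })
  do.call(rbind, rows)
}

#' Evoked-response metrics across stimulation intensities
#'
#' Full per-session pipeline: filter, epoch, baseline-correct, per-trial N1
#' detection; returns trial-level metrics tagged by intensity plus a
#' per-intensity summary (non-responses are excluded from amplitude/latency
#' means but reported as a rate).
#'
#' @param sessions list of `list(rec = <recording>, intensity = <mW/cm^2>)`.
#' @param fspec a [filter_spec()] (or `NULL` to skip filtering).
#' @param window epoch window (s).
#' @param channel channel to analyze.
#' @param ... passed to [uep_metrics()].
#' @return list with `trials` (data.frame: intensity, trial, amplitude_uV,
#'   latency_ms, responded) and `summary` (per-intensity means +/- SEM and
#'   non-response rate).
#' @export
uep_by_intensity <- function(sessions, fspec = filter_spec(),
                             window = c(-1, 2), channel = 1L, ...) {
  trials <- do.call(rbind, lapply(sessions, function(s) {
    rec <- if (is.null(fspec)) s$rec else apply_filters(s$rec, fspec)
    ep <- baseline_correct(epoch_recording(rec, window, channel))
    m <- uep_metrics(ep, ...)
    cbind(intensity = s$intensity, m)
  }))
  agg <- lapply(split(trials, trials$intensity), function(d) {
    resp <- d[d$responded, , drop = FALSE]
    n_r <- nrow(resp)
    data.frame(
      intensity = d$intensity[1L], n_trials = nrow(d), n_responded = n_r,
      nonresponse_rate = 1 - n_r / nrow(d),
      mean_amplitude_uV = if (n_r) mean(resp$amplitude_uV) else NA_real_,
      sem_amplitude_uV = if (n_r > 1) sd(resp$amplitude_uV) / sqrt(n_r) else NA_real_,
      mean_latency_ms = if (n_r) mean(resp$latency_ms) else NA_real_,
      sem_latency_ms = if (n_r > 1) sd(resp$latency_ms) / sqrt(n_r) else NA_real_)
  })
  summary <- do.call(rbind, agg)
  summary <- summary[order(summary$intensity), , drop = FALSE]
  rownames(summary) <- NULL
  list(trials = trials, summary = summary)
}
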