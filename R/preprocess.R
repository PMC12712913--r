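# Signal-cleaning chain: line-noise notches, Butterworth bandpass (zero-phase
# by default so evoked latencies are not biased by group delay), epoching,
# baseline correction and template-based ultrasound-artifact rejection.

#' Filtering specification
#'
#' @param low,high bandpass corner frequencies (Hz). Defaults 0.5-100 Hz, the
#'   LFP analysis band.
#' @param order Butterworth prototype order (default 2).
#' @param notch_freqs line-interference notch frequencies (Hz): 50 Hz mains
#'   and its odd harmonics by default.
#' @param notch_q notch quality factor (centre frequency / -3 dB width).
#' @param zero_phase logical; forward-backward filtering (no group delay,
#'   squared magnitude response). `FALSE` gives single-pass causal filtering.
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(low = 0.5, high = 100, order = 2,
                        notch_freqs = c(50, 150, 250, 350), notch_q = 30,
                        zero_phase = TRUE) {
  check_number(low, "low", min = 0, strict = TRUE)
  check_number(high, "high", min = low, strict = TRUE)
  check_number(order, "order", min = 1)
  check_number(notch_q, "notch_q", min = 0, strict = TRUE)
  structure(list(low = low, high = high, order = as.integer(order),
                 notch_freqs = notch_freqs, notch_q = notch_q,
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

# Biquad IIR notch at f0 with quality factor Q (RBJ cookbook design).
design_notch <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

filter_one <- function(x, fspec, fs) {
  x <- x - mean(x)
  run <- if (fspec$zero_phase)
    function(b, a, x) signal::filtfilt(signal::Arma(b = b, a = a), x)
  else
    function(b, a, x) as.numeric(signal::filter(signal::Arma(b = b, a = a), x))
  for (f0 in fspec$notch_freqs) {
    nt <- design_notch(f0, fs, fspec$notch_q)
    x <- run(nt$b, nt$a, x)
  }
  bp <- signal::butter(fspec$order, c(fspec$low, fspec$high) / (fs / 2),
                       type = "pass")
  run(bp$b, bp$a, x)
}

#' Apply the notch + bandpass cleaning chain
#'
#' Removes the DC offset, applies each notch filter and then the Butterworth
#' bandpass, per channel. Zero-phase (forward-backward) application by
#' default. Requires `fs > 2 * high` and all notch frequencies below Nyquist.
#'
#' @param x an [recording()] or a numeric vector/matrix (channels x time).
#' @param fspec a [filter_spec()].
#' @param fs sampling rate (Hz); taken from the recording when `x` is one.
#' @return object of the same shape/class as `x`, filtered.
#' @export
apply_filters <- function(x, fspec = filter_spec(), fs = NULL) {
  UseMethod("apply_filters")
}

#' @export
apply_filters.lfp_recording <- function(x, fspec = filter_spec(), fs = NULL) {
  x$samples <- apply_filters.default(x$samples, fspec, fs = x$fs)
  x
}

#' @export
apply_filters.default <- function(x, fspec = filter_spec(), fs = NULL) {
  stopifnot(inherits(fspec, "filter_spec"))
  if (is.null(fs)) stopf("`fs` is required when filtering a plain array")
  if (fs <= 2 * fspec$high)
    stopf("sampling rate %g Hz too low for a %g Hz bandpass edge", fs, fspec$high)
  if (any(fspec$notch_freqs >= fs / 2))
    stopf("notch frequencies must be below Nyquist (%g Hz)", fs / 2)
  if (is.matrix(x)) {
    out <- t(apply(x, 1L, filter_one, fspec = fspec, fs = fs))
    dimnames(out) <- dimnames(x)
    out
  } else filter_one(as.numeric(x), fspec, fs)
}

#' Cut stimulation-aligned epochs
#'
#' Extracts a trials x time matrix of windows around each stimulation onset
#' (default -1 to +2 s). Onsets whose window falls partly outside the
#' recording are dropped with a warning rather than zero-padded.
#'
#' @param rec an [recording()] with `stim_onsets`.
#' @param window `c(pre, post)` in seconds relative to onset, `pre < 0 < post`.
#' @param channel channel index or label to epoch.
#' @return object of class `lfp_epochs`: list with `x` (trials x samples),
#'   `times` (s relative to onset), `fs`, `onsets`, `kept` (logical
#'   artifact-rejection mask, all `TRUE` initially) and `window`.
#' @export
epoch_recording <- function(rec, window = c(-1, 2), channel = 1L) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (!(window[1] < 0 && window[2] > 0))
    stopf("epoch window must cover the onset (pre < 0 < post)")
  if (!length(rec$stim_onsets)) stopf("empty-epoch error: recording has no onsets")
  fs <- rec$fs
  sig <- rec$samples[channel, ]
  nsamp <- round((window[2] - window[1]) * fs)
  times <- window[1] + (seq_len(nsamp) - 1L) / fs
  i_on <- round((rec$stim_onsets - rec$t0) * fs) + 1L
  i0 <- i_on + round(window[1] * fs)
  i1 <- i0 + nsamp - 1L
  ok <- i0 >= 1L & i1 <= length(sig)
  if (!any(ok)) stopf("empty-epoch error: no onset supports the %g..%g s window",
                      window[1], window[2])
  if (any(!ok))
    warning(sprintf("%d trial(s) partly outside the recording were dropped",
                    sum(!ok)))
  idx <- which(ok)
  x <- matrix(0, nrow = length(idx), ncol = nsamp)
  for (k in seq_along(idx)) x[k, ] <- sig[i0[idx[k]]:i1[idx[k]]]
  structure(list(x = x, times = times, fs = fs,
                 onsets = rec$stim_onsets[idx],
                 kept = rep(TRUE, length(idx)), window = window),
            class = "lfp_epochs")
}

#' @export
print.lfp_epochs <- function(x, ...) {
  cat(sprintf("<lfp_epochs> %d trial(s) (%d kept) x %d samples @ %g Hz, window %g..%g s\n",
              nrow(x$x), sum(x$kept), ncol(x$x), x$fs, x$window[1], x$window[2]))
  invisible(x)
}

#' Baseline-correct epochs
#'
#' Subtracts from each trial its mean over the pre-onset reference window, so
#' every trial has zero mean there. Idempotent.
#'
#' @param ep an [epoch_recording()] result.
#' @param ref_window `c(start, end)` in seconds relative to onset, inside the
#'   epoch window; default the full pre-onset second.
#' @return the corrected `lfp_epochs`.
#' @export
baseline_correct <- function(ep, ref_window = c(-1, 0)) {
  stopifnot(inherits(ep, "lfp_epochs"))
  if (ref_window[1] < ep$window[1] || ref_window[2] > ep$window[2])
    stopf("reference window must lie inside the epoch window")
  sel <- ep$times >= ref_window[1] & ep$times < ref_window[2]
  if (!any(sel)) stopf("reference window contains no samples")
  ep$x <- ep$x - rowMeans(ep$x[, sel, drop = FALSE])
  ep
}

#' Flag trials matching a non-biological artifact template
#'
#' Slides the artifact template over each trial's post-onset search window
#' and computes the maximal normalized cross-correlation (Pearson, per lag).
#' Trials reaching `rho_min` are marked rejected in `kept`; the flagged count
#' is attached as attribute `n_flagged`.
#'
#' @param ep an `lfp_epochs`.
#' @param template numeric artifact waveform (e.g. [artifact_template()]),
#'   sampled at `ep$fs`, shorter than the search window, non-constant.
#' @param rho_min correlation threshold in (0, 1]; default 0.8.
#' @param search `c(start, end)` seconds relative to onset to scan.
#' @return the `lfp_epochs` with updated `kept` and a `rho` vector of
#'   per-trial maximal correlations.
#' @export
reject_artifacts <- function(ep, template, rho_min = 0.8, search = c(0, 0.5)) {
  stopifnot(inherits(ep, "lfp_epochs"))
  template <- as.numeric(template)
  if (sd(template) == 0) stopf("artifact template has zero variance")
  sel <- which(ep$times >= search[1] & ep$times <= search[2])
  m <- length(template)
  if (m > length(sel))
    stopf("template (%d samples) longer than the search window (%d samples)",
          m, length(sel))
  rho <- vapply(seq_len(nrow(ep$x)), function(i) {
    seg <- ep$x[i, sel]
    lags <- seq_len(length(seg) - m + 1L)
    max(vapply(lags, function(l) {
      w <- seg[l:(l + m - 1L)]
      if (sd(w) == 0) return(-1)
      cor(template, w)
    }, numeric(1L)))
  }, numeric(1L))
  flagged <- rho >= rho_min
  ep$kept <- ep$kept & !flagged
  ep$rho <- rho
  attr(ep, "n_flagged") <- sum(flagged)
  ep
}
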