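# Welch spectral estimation and band-power summaries. Conventions: one-sided
# density scaling (uV^2/Hz), Hanning window, 8 s segments with 50% overlap by
# default (0.125 Hz resolution: the delta band starts at 0.5 Hz, and a coarser
# grid biases its lower edge through window smearing and segment demeaning),
# trapezoidal band integration on contiguous edges so relative power sums to
# 100%.

#' Canonical frequency-band scheme
#'
#' delta 0.5-4, theta 4-8, alpha 8-12, beta 12-30, gamma 30-100 Hz;
#' contiguous and spanning the total analysis range 0.5-100 Hz.
#'
#' @return data.frame with columns `band`, `low`, `high` and attribute
#'   `total` (the full analysis range).
#' @export
band_scheme <- function() {
  structure(data.frame(band = c("delta", "theta", "alpha", "beta", "gamma"),
                       low = c(0.5, 4, 8, 12, 30),
                       high = c(4, 8, 12, 30, 100),
                       stringsAsFactors = FALSE),
            total = c(0.5, 100))
}

#' Welch power spectral density
#'
#' Hanning-windowed averaged periodogram with density scaling: integrating
#' the one-sided PSD over frequency approximates the signal variance.
#' Segments are demeaned before windowing.
#'
#' @param x numeric signal (uV).
#' @param fs sampling rate (Hz).
#' @param seg_len segment length in seconds (default 8, i.e. 0.125 Hz
#'   resolution; coarser grids bias the 0.5 Hz delta edge).
#' @param overlap fractional overlap in `[0, 1)` (default 0.5).
#' @return list of class `lfp_psd` with `freq` (Hz) and `psd` (uV^2/Hz).
#' @export
welch_psd <- function(x, fs, seg_len = 8, overlap = 0.5) {
  check_number(fs, "fs", min = 0, strict = TRUE)
  if (overlap < 0 || overlap >= 1) stopf("`overlap` must be in [0, 1)")
  nseg <- round(seg_len * fs)
  if (nseg < 2L) stopf("segment must contain at least 2 samples")
  if (length(x) < nseg)
    stopf("signal (%d samples) shorter than one segment (%d)", length(x), nseg)
  w <- signal::hanning(nseg)
  U <- sum(w^2)
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  nfreq <- nseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(stats::fft(seg))^2
    acc <- acc + P[seq_len(nfreq)]
  }
  psd <- acc / (length(starts) * fs * U)
  scale2 <- rep(2, nfreq)
  scale2[1L] <- 1
  if (nseg %% 2L == 0L) scale2[nfreq] <- 1   # Nyquist bin not doubled
  structure(list(freq = (seq_len(nfreq) - 1L) * fs / nseg, psd = psd * scale2),
            class = "lfp_psd")
}

# trapezoidal band integral over [lo, hi] with interpolated edge points
integrate_band <- function(freq, psd, lo, hi) {
  if (lo < min(freq) || hi > max(freq))
    stopf("PSD grid does not cover the band %g-%g Hz", lo, hi)
  inside <- freq > lo & freq < hi
  f <- c(lo, freq[inside], hi)
  p <- c(approx(freq, psd, lo)$y, psd[inside], approx(freq, psd, hi)$y)
  trapz(f, p)
}

#' Band-power summary from a PSD
#'
#' Integrates the PSD over each canonical band (trapezoidal rule on the
#' contiguous band edges, so the bands partition the total range exactly) and
#' reports absolute band powers, relative power (percent of total power in
#' the full analysis range), total power in dB relative to `p_ref`, and the
#' theta/gamma relative-power ratio.
#'
#' @param p an [welch_psd()] result, or a list with `freq` and `psd`.
#' @param scheme a [band_scheme()].
#' @param p_ref dB reference power (uV^2), default 1.
#' @return object of class `band_power_summary`: list with `band_power`
#'   (named, uV^2), `rp` (named, %), `total_power` (uV^2), `total_power_db`,
#'   `tg_ratio`.
#' @export
band_powers <- function(p, scheme = band_scheme(), p_ref = 1) {
  freq <- p$freq; psd <- p$psd
  total_range <- attr(scheme, "total") %||% c(min(scheme$low), max(scheme$high))
  bp <- vapply(seq_len(nrow(scheme)), function(i)
    integrate_band(freq, psd, scheme$low[i], scheme$high[i]), numeric(1L))
  names(bp) <- scheme$band
  total <- integrate_band(freq, psd, total_range[1], total_range[2])
  if (total <= 0) stopf("total power is zero: relative power undefined")
  rp <- 100 * bp / total
  structure(list(band_power = bp, rp = rp, total_power = total,
                 total_power_db = 10 * log10(total / p_ref),
                 tg_ratio = unname(rp["theta"] / rp["gamma"]),
                 p_ref = p_ref),
            class = "band_power_summary")
}

#' @export
print.band_power_summary <- function(x, ...) {
  cat(sprintf("<band_power_summary> total %.4g uV^2 (%.2f dB re %g uV^2)\n",
              x$total_power, x$total_power_db, x$p_ref))
  cat("  relative power (%):",
      paste(sprintf("%s %.2f", names(x$rp), x$rp), collapse = ", "), "\n")
  cat(sprintf("  theta/gamma ratio: %.3f\n", x$tg_ratio))
  invisible(x)
}

#' Stimulation-normalized power change across session phases
#'
#' Filters the recording, splits it at the labeled phase boundaries
#' (`meta$phases`: pre / stim / post), estimates per-phase Welch total and
#' band powers, and reports the normalized change
#' `(stim - pre) / pre * 100` (%) for total power and per band, plus the
#' post-stimulation recovery `(post - pre) / pre * 100`.
#'
#' @param rec an [recording()] with a `meta$phases` table (as produced by
#'   [build_session()]).
#' @param fspec a [filter_spec()] applied before estimation; `NULL` to skip.
#' @param scheme a [band_scheme()].
#' @param channel channel to analyze.
#' @param seg_len,overlap Welch parameters.
#' @return object of class `power_change`: list with `per_phase` (data.frame
#'   phase x total + band powers), `rp` (phase x band matrix, %),
#'   `change_pct`, `post_recovery_pct`, `band_change_pct` (named).
#' @export
phase_power_change <- function(rec, fspec = filter_spec(),
                               scheme = band_scheme(), channel = 1L,
                               seg_len = 8, overlap = 0.5) {
  stopifnot(inherits(rec, "lfp_recording"))
  phases <- rec$meta$phases
  if (is.null(phases) || !all(c("pre", "stim", "post") %in% phases$phase))
    stopf("recording lacks labeled pre/stim/post phases in meta$phases")
  if (!is.null(fspec)) rec <- apply_filters(rec, fspec)
  sig <- rec$samples[channel, ]
  fs <- rec$fs
  res <- lapply(seq_len(nrow(phases)), function(i) {
    i0 <- round((phases$start[i] - rec$t0) * fs) + 1L
    i1 <- min(round((phases$end[i] - rec$t0) * fs), length(sig))
    band_powers(welch_psd(sig[i0:i1], fs, seg_len, overlap), scheme)
  })
  names(res) <- phases$phase
  tot <- vapply(res, `[[`, numeric(1L), "total_power")
  bp <- t(vapply(res, `[[`, numeric(nrow(scheme)), "band_power"))
  rp <- t(vapply(res, `[[`, numeric(nrow(scheme)), "rp"))
  per_phase <- data.frame(phase = phases$phase, total_power = tot, bp,
                          row.names = NULL, check.names = FALSE)
  structure(list(
    per_phase = per_phase, rp = rp,
    change_pct = 100 * (tot[["stim"]] - tot[["pre"]]) / tot[["pre"]],
    post_recovery_pct = 100 * (tot[["post"]] - tot[["pre"]]) / tot[["pre"]],
    band_change_pct = 100 * (bp["stim", ] - bp["pre", ]) / bp["pre", ]),
    class = "power_change")
}

#' @export
print.power_change <- function(x, ...) {
  cat(sprintf("<power_change> stim vs pre: %+.2f%%; post vs pre: %+.2f%%\n",
              x$change_pct, x$post_recovery_pct))
  cat("  per-band change (%):",
      paste(sprintf("%s %+.1f", names(x$band_change_pct), x$band_change_pct),
            collapse = ", "), "\n")
  invisible(x)
}

#' Short-time spectrogram with optional baseline normalization
#'
#' Hanning-windowed short-time power (density scaling) on a sliding window.
#' When `ref_window` is given, power is additionally expressed in dB relative
#' to the mean power per frequency bin over that (pre-onset) time range.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param win window length (s); `win * fs >= 2`.
#' @param step hop between window centers (s).
#' @param ref_window optional `c(start, end)` in the same time coordinates as
#'   `t` (first sample at 0 s) used as the dB reference.
#' @param t0 time of the first sample (s), e.g. a negative pre-onset offset.
#' @return list of class `lfp_spectrogram`: `t` (window centers, s), `freq`
#'   (Hz), `power` (freq x time, uV^2/Hz), and `db_rel` (freq x time) when
#'   `ref_window` is given.
#' @export
lfp_spectrogram <- function(x, fs, win = 1, step = 0.25, ref_window = NULL,
                            t0 = 0) {
  nwin <- round(win * fs)
  if (nwin < 2L) stopf("window must contain at least 2 samples")
  if (length(x) < nwin) stopf("signal shorter than one window")
  hop <- max(1L, round(step * fs))
  starts <- seq(1L, length(x) - nwin + 1L, by = hop)
  w <- signal::hanning(nwin)
  U <- sum(w^2)
  nfreq <- nwin %/% 2L + 1L
  P <- matrix(0, nrow = nfreq, ncol = length(starts))
  for (k in seq_along(starts)) {
    seg <- x[starts[k]:(starts[k] + nwin - 1L)]
    seg <- (seg - mean(seg)) * w
    P[, k] <- Mod(stats::fft(seg))[seq_len(nfreq)]^2
  }
  P <- P / (fs * U)
  P[-1L, ] <- 2 * P[-1L, ]
  if (nwin %% 2L == 0L) P[nfreq, ] <- P[nfreq, ] / 2
  tt <- t0 + (starts - 1L + nwin / 2) / fs
  out <- list(t = tt, freq = (seq_len(nfreq) - 1L) * fs / nwin, power = P)
  if (!is.null(ref_window)) {
    sel <- tt >= ref_window[1] & tt <= ref_window[2]
    if (!any(sel)) stopf("reference window contains no spectrogram frames")
    ref <- rowMeans(P[, sel, drop = FALSE])
    out$db_rel <- 10 * log10(sweep(P, 1L, pmax(ref, .Machine$double.xmin), "/"))
  }
  structure(out, class = "lfp_spectrogram")
}
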