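# Synthetic LFP session generator. Background activity is synthesized per
# canonical band in the Fourier domain (Gaussian coefficients on disjoint
# frequency supports), which makes band contents exactly orthogonal in-sample
# and lets each band be rescaled to its exact target variance: the generator's
# band fractions are, by construction, the relative power a spectral pipeline
# should recover up to filtering and windowing effects.

#' Generative specification for one synthetic animal/session
#'
#' @param band_fractions named numeric vector of relative-power targets for
#'   the canonical bands (`delta`, `theta`, `alpha`, `beta`, `gamma`),
#'   non-negative, summing to 1 (tolerance 1e-9).
#' @param total_rms overall background scale (uV RMS).
#' @param evoked `NULL`, or a list describing the ultrasound-evoked N1
#'   template: `n1_amp` (uV, trough magnitude), `latency` (ms post-onset),
#'   `width` (ms, FWHM of the negative lobe), `jitter_amp` (fractional SD of
#'   trial-to-trial amplitude), `jitter_lat` (ms SD of latency).
#' @param stim_power_gain multiplicative broadband power change applied to the
#'   background during the stimulation phase (e.g. 0.212 for +21.2%).
#' @param line_noise `NULL`, or list `amp50` (uV at 50 Hz), `harmonics` (Hz),
#'   `harmonic_amps` (uV; default `amp50 * 2^-(1:k)`).
#' @param artifact `NULL`, or list `wave` (numeric template added at each
#'   onset) and optional `prob` (per-onset occurrence probability, default 1).
#' @param fs synthesis sampling rate (Hz); at least 200 Hz so the gamma band
#'   is below Nyquist. Default 1 kHz (the LFP analysis band ends at 100 Hz).
#' @param phase_len experimental phase duration (s).
#' @param seed RNG seed for reproducible sessions.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(band_fractions, total_rms = 50, evoked = NULL,
                       stim_power_gain = 0, line_noise = NULL,
                       artifact = NULL, fs = 1000, phase_len = 150,
                       seed = NULL) {
  bands <- band_scheme()
  if (is.null(names(band_fractions)))
    names(band_fractions) <- bands$band[seq_along(band_fractions)]
  if (!setequal(names(band_fractions), bands$band))
    stopf("`band_fractions` must be named %s", paste(bands$band, collapse = ", "))
  band_fractions <- band_fractions[bands$band]
  if (any(band_fractions < 0))
    stopf("`band_fractions` must be non-negative")
  if (abs(sum(band_fractions) - 1) > 1e-9)
    stopf("`band_fractions` must sum to 1 (got %.12g)", sum(band_fractions))
  check_number(total_rms, "total_rms", min = 0)
  check_number(fs, "fs", min = 200)
  check_number(phase_len, "phase_len", min = 0, strict = TRUE)
  check_number(stim_power_gain, "stim_power_gain", min = -1)
  if (!is.null(evoked)) {
    for (f in c("n1_amp", "latency", "width"))
      check_number(evoked[[f]] %||% NA_real_, paste0("evoked$", f), min = 0)
    evoked$jitter_amp <- evoked$jitter_amp %||% 0
    evoked$jitter_lat <- evoked$jitter_lat %||% 0
    if (evoked$latency + evoked$width > 500)
      stopf("evoked latency + width must stay within the 0-500 ms analysis window")
  }
  structure(list(band_fractions = band_fractions, total_rms = total_rms,
                 evoked = evoked, stim_power_gain = stim_power_gain,
                 line_noise = line_noise, artifact = artifact, fs = fs,
                 phase_len = phase_len, seed = seed),
            class = "synth_spec")
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf("<synth_spec> fs %g Hz, %g uV RMS, stim gain %+.1f%%\n",
              x$fs, x$total_rms, 100 * x$stim_power_gain))
  cat("  band fractions:",
      paste(sprintf("%s %.3f", names(x$band_fractions), x$band_fractions),
            collapse = ", "), "\n")
  if (!is.null(x$evoked))
    cat(sprintf("  evoked N1: %g uV at %g ms (width %g ms)\n",
                x$evoked$n1_amp, x$evoked$latency, x$evoked$width))
  invisible(x)
}

# Band-limited Gaussian noise via Fourier synthesis: unit-variance-ish signal
# supported on [lo, hi) Hz, rescaled afterwards by the caller.
fourier_band_noise <- function(n, fs, lo, hi) {
  nf <- (n - 1L) %/% 2L                    # positive-frequency bins
  f <- (1:nf) * fs / n
  sel <- which(f >= lo & f < hi)
  if (!length(sel)) return(numeric(n))
  coef <- complex(real = rnorm(length(sel)), imaginary = rnorm(length(sel)))
  spec <- complex(real = numeric(n), imaginary = numeric(n))
  spec[1L + sel] <- coef
  spec[n + 1L - sel] <- Conj(coef)
  Re(stats::fft(spec, inverse = TRUE)) / n
}

#' Generate spontaneous background LFP
#'
#' Sum of independent band-limited Gaussian noise processes, one per
#' canonical band, with per-band variance equal to
#' `band_fractions * total_rms^2` (exactly, per realization) and hence total
#' RMS `total_rms`. Deterministic given `seed`.
#'
#' @param spec a [synth_spec()].
#' @param duration seconds (> 0).
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return numeric vector of length `round(duration * spec$fs)`, in uV.
#' @export
make_background <- function(spec, duration, seed = spec$seed) {
  stopifnot(inherits(spec, "synth_spec"))
  check_number(duration, "duration", min = 0, strict = TRUE)
  n <- round(duration * spec$fs)
  bands <- band_scheme()
  with_seed(seed, {
    x <- numeric(n)
    for (i in seq_len(nrow(bands))) {
      frac <- spec$band_fractions[[bands$band[i]]]
      if (frac <= 0) next
      b <- fourier_band_noise(n, spec$fs, bands$low[i], bands$high[i])
      r <- sqrt(mean(b^2))
      if (r > 0) x <- x + b * (sqrt(frac) * spec$total_rms / r)
    }
    x
  })
}

# Biphasic evoked template with dominant negative lobe: negative Gaussian
# trough plus a smaller, broader positive rebound. Returned scaled so the
# minimum is exactly -1, together with the sample offset of that minimum.
evoked_template <- function(width_ms, fs) {
  sigma <- width_ms / 1000 / (2 * sqrt(2 * log(2)))  # FWHM -> sd, seconds
  tt <- seq(-4 * sigma, 7 * sigma, by = 1 / fs)
  raw <- -exp(-tt^2 / (2 * sigma^2)) +
    0.3 * exp(-(tt - 2.5 * sigma)^2 / (2 * (1.8 * sigma)^2))
  i_min <- which.min(raw)
  list(wave = raw / abs(raw[i_min]), i_trough = i_min)
}

#' Inject stimulation-locked evoked potentials
#'
#' Overlap-adds a biphasic template (dominant negative lobe) at each onset so
#' that the trough of magnitude `n1_amp` falls `latency` ms after the onset,
#' with optional per-trial amplitude and latency jitter. Onsets whose
#' template would fall outside the signal are skipped with a warning.
#'
#' @param x numeric signal (uV).
#' @param fs sampling rate (Hz).
#' @param onsets onset times (s, relative to sample 1 at t = 0).
#' @param evoked evoked parameter list (see [synth_spec()]).
#' @param seed RNG seed for the jitter draws.
#' @return the signal with evoked responses added.
#' @export
inject_evoked <- function(x, fs, onsets, evoked, seed = NULL) {
  if (is.null(evoked) || evoked$n1_amp == 0 || !length(onsets)) return(x)
  tpl <- evoked_template(evoked$width, fs)
  with_seed(seed, {
    n <- length(x)
    skipped <- 0L
    for (on in onsets) {
      amp <- evoked$n1_amp * (1 + evoked$jitter_amp * rnorm(1L))
      lat <- evoked$latency + evoked$jitter_lat * rnorm(1L)
      i_tr <- round((on + lat / 1000) * fs) + 1L
      i0 <- i_tr - tpl$i_trough + 1L
      i1 <- i0 + length(tpl$wave) - 1L
      if (i0 < 1L || i1 > n) { skipped <- skipped + 1L; next }
      x[i0:i1] <- x[i0:i1] + amp * tpl$wave
    }
    if (skipped > 0L)
      warning(sprintf("%d onset(s) outside the signal were skipped", skipped))
    x
  })
}

#' Inject 50 Hz line noise and odd harmonics
#'
#' Adds sinusoids at 50 Hz and the listed odd harmonics with random (seeded)
#' phases. Default harmonic amplitudes halve at each step (ratio
#' 1:0.5:0.25:0.125 including the fundamental).
#'
#' @param x numeric signal (uV).
#' @param fs sampling rate (Hz).
#' @param amp50 amplitude at 50 Hz (uV); 0 returns `x` unchanged.
#' @param harmonics harmonic frequencies (Hz), all below `fs / 2`.
#' @param harmonic_amps amplitudes for `harmonics` (uV).
#' @param seed RNG seed for the phases.
#' @return the signal with line interference added.
#' @export
inject_line_noise <- function(x, fs, amp50, harmonics = c(150, 250, 350),
                              harmonic_amps = NULL, seed = NULL) {
  if (amp50 == 0) return(x)
  freqs <- c(50, harmonics)
  if (any(freqs >= fs / 2))
    stopf("line-noise components must be below Nyquist (%g Hz)", fs / 2)
  amps <- c(amp50, harmonic_amps %||% (amp50 * 0.5^seq_along(harmonics)))
  with_seed(seed, {
    tt <- (seq_along(x) - 1L) / fs
    for (k in seq_along(freqs))
      x <- x + amps[k] * sin(2 * pi * freqs[k] * tt + runif(1L, 0, 2 * pi))
    x
  })
}

#' Build a full pre/stimulation/post session
#'
#' Concatenates three phases of `spec$phase_len` seconds of background
#' activity; the stimulation-phase background is scaled so its total power is
#' `(1 + stim_power_gain)` times the flanking phases. Stimulation onsets run
#' at the protocol cadence (one every `sd + isi` seconds) through the
#' stimulation phase and are recorded in `stim_onsets`; evoked responses,
#' artifact templates and line noise are injected on top. Phase boundaries
#' are stored in `meta$phases` for [phase_power_change()].
#'
#' @param spec a [synth_spec()].
#' @param protocol a [stim_protocol()].
#' @return an [recording()] of duration `3 * spec$phase_len`.
#' @export
build_session <- function(spec, protocol = stim_protocol()) {
  stopifnot(inherits(spec, "synth_spec"))
  validate_protocol(protocol)
  pl <- spec$phase_len
  period <- protocol$sd + protocol$isi
  n_stim <- floor(pl / period)
  onsets <- pl + (seq_len(n_stim) - 1L) * period
  with_seed(spec$seed, {
    x <- c(make_background(spec, pl, seed = NULL),
           sqrt(1 + spec$stim_power_gain) * make_background(spec, pl, seed = NULL),
           make_background(spec, pl, seed = NULL))
    x <- inject_evoked(x, spec$fs, onsets, spec$evoked, seed = NULL)
    if (!is.null(spec$artifact)) {
      prob <- spec$artifact$prob %||% 1
      w <- spec$artifact$wave
      for (on in onsets) {
        if (runif(1L) > prob) next
        i0 <- round(on * spec$fs) + 1L
        i1 <- i0 + length(w) - 1L
        if (i1 <= length(x)) x[i0:i1] <- x[i0:i1] + w
      }
    }
    if (!is.null(spec$line_noise))
      x <- inject_line_noise(x, spec$fs, spec$line_noise$amp50,
                             spec$line_noise$harmonics %||% c(150, 250, 350),
                             spec$line_noise$harmonic_amps, seed = NULL)
    recording(x, fs = spec$fs, stim_onsets = onsets,
              meta = list(phases = data.frame(
                            phase = c("pre", "stim", "post"),
                            start = c(0, pl, 2 * pl),
                            end = c(pl, 2 * pl, 3 * pl)),
                          stim_power_gain = spec$stim_power_gain))
  })
}

#' Simulate a block of evoked-potential trials
#'
#' Generates a single continuous segment of background activity with
#' `n_trials` stimulation onsets at the protocol cadence and evoked responses
#' injected per `spec$evoked`; used for ultrasound-evoked-potential
#' benchmarking where the session structure (pre/stim/post phases) is not
#' needed.
#'
#' @param spec a [synth_spec()] with a non-`NULL` `evoked` component.
#' @param protocol a [stim_protocol()].
#' @param n_trials number of stimulation trials.
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return an [recording()] with `n_trials` stimulation onsets, padded so
#'   every onset supports a (-1, +2) s epoch.
#' @export
simulate_uep_trials <- function(spec, protocol = stim_protocol(), n_trials = 50,
                                seed = spec$seed) {
  stopifnot(inherits(spec, "synth_spec"))
  validate_protocol(protocol)
  period <- protocol$sd + protocol$isi
  dur <- 1.5 + n_trials * period + 2.5
  onsets <- 1.5 + (seq_len(n_trials) - 1L) * period
  with_seed(seed, {
    x <- make_background(spec, dur, seed = NULL)
    x <- inject_evoked(x, spec$fs, onsets, spec$evoked, seed = NULL)
    if (!is.null(spec$line_noise))
      x <- inject_line_noise(x, spec$fs, spec$line_noise$amp50,
                             spec$line_noise$harmonics %||% c(150, 250, 350),
                             spec$line_noise$harmonic_amps, seed = NULL)
    recording(x, fs = spec$fs, stim_onsets = onsets)
  })
}

#' Non-biological ultrasound artifact template
#'
#' Exponentially decaying oscillation emulating the sharp stimulation
#' transient seen in post-mortem control recordings; used both to inject
#' artifacts into synthetic sessions and as the matching template for
#' [reject_artifacts()].
#'
#' @param fs sampling rate (Hz).
#' @param dur duration (s).
#' @param f_ring ringing frequency (Hz).
#' @param tau decay time constant (s).
#' @param amp peak amplitude (uV).
#' @return numeric waveform.
#' @export
artifact_template <- function(fs, dur = 0.05, f_ring = 80, tau = 0.01,
                              amp = 1) {
  tt <- seq(0, dur, by = 1 / fs)
  amp * exp(-tt / tau) * sin(2 * pi * f_ring * tt)
}
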