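# Shared fixtures: all synthetic, built in code.

default_protocol <- function(...) stim_protocol(...)

# synth_spec with positional fractions (delta..gamma) and small-session defaults
quick_spec <- function(fractions = c(0.5, 0.24, 0.10, 0.11, 0.05),
                       total_rms = 50, fs = 1000, phase_len = 30, seed = 1,
                       ...) {
  synth_spec(band_fractions = stats::setNames(fractions, band_scheme()$band),
             total_rms = total_rms, fs = fs, phase_len = phase_len,
             seed = seed, ...)
}

# epochs object with hand-set trial rows (built through the real constructor)
epochs_from_rows <- function(rows, fs = 1000, window = c(-1, 2)) {
  nsamp <- ncol(rows)
  dur <- nsamp / fs
  onset <- -window[1]
  rec <- recording(numeric(nsamp), fs = fs, stim_onsets = onset)
  ep <- epoch_recording(rec, window = c(window[1], dur + window[1]))
  ep$x <- rows
  ep$kept <- rep(TRUE, nrow(rows))
  ep$onsets <- rep(onset, nrow(rows))
  ep
}

rms <- function(x) sqrt(mean(x^2))

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

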