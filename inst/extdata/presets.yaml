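# Group presets for the synthetic-session generator.
#
# Band fractions, stimulation power gains and evoked N1 amplitudes follow the
# published group summary statistics where such a value exists; remaining
# entries (control-group band composition, gains at intensities reported as
# non-significant, evoked latencies/widths, line-noise and background scales)
# are fixed representative values for isoflurane-anesthetized rat hippocampus.
# Intensity keys i100/i250/i400 are Ispta levels in mW/cm^2.
fs: 1000
phase_len: 150
total_rms: 50          # background scale for spontaneous / power sessions (uV RMS)
uep_rms: 6             # background scale for evoked-trial sessions (uV RMS)
line_noise:
  amp50: 10
  harmonics: [150, 250, 350]
  harmonic_amps: [5, 2.5, 1.25]
groups:
  CON:
    band_fractions: {delta: 0.50, theta: 0.24, alpha: 0.10, beta: 0.11, gamma: 0.05}
    stim_power_gain: {i100: 0.1492, i250: 0.1492, i400: 0.1492}
    evoked:
      i100: null
      i250: {n1_amp: 20.0, latency: 115, width: 20, jitter_amp: 0.05, jitter_lat: 5}
      i400: {n1_amp: 36.2, latency: 100, width: 20, jitter_amp: 0.05, jitter_lat: 5}
  MscL-G22S:
    band_fractions: {delta: 0.52, theta: 0.22, alpha: 0.10, beta: 0.11, gamma: 0.05}
    stim_power_gain: {i100: 0.0971, i250: 0.0667, i400: 0.212}
    evoked:
      i100: {n1_amp: 17.5, latency: 120, width: 20, jitter_amp: 0.05, jitter_lat: 5}
      i250: {n1_amp: 28.0, latency: 100, width: 20, jitter_amp: 0.05, jitter_lat: 5}
      i400: {n1_amp: 40.16, latency: 80, width: 20, jitter_amp: 0.05, jitter_lat: 5}
  MscL-G22N:
    band_fractions: {delta: 0.6029, theta: 0.2057, alpha: 0.0851, beta: 0.0957, gamma: 0.0106}
    stim_power_gain: {i100: 0.0342, i250: 0.0342, i400: 0.0342}
    evoked:
      i100: null
      i250: null
      i400: {n1_amp: 24.2, latency: 95, width: 20, jitter_amp: 0.05, jitter_lat: 5}
  MscS:
    band_fractions: {delta: 0.48, theta: 0.25, alpha: 0.10, beta: 0.11, gamma: 0.06}
    stim_power_gain: {i100: 0.1995, i250: 0.0840, i400: 0.0002}
    evoked:
      i100: null
      i250: null
      i400: null
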