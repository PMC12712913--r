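test_that("synth spec validates band fractions", {
  expect_error(quick_spec(c(0.5, 0.5, 0.1, 0, 0)), "sum to 1")
  expect_error(quick_spec(c(1.2, -0.2, 0, 0, 0)), "non-negative")
  expect_s3_class(quick_spec(), "synth_spec")
})

test_that("degenerate all-delta background concentrates Welch power in 0.5-4 Hz", {
  spec <- quick_spec(c(1, 0, 0, 0, 0), seed = 7)
  x <- make_background(spec, 60)
  p <- welch_psd(x, spec$fs)
  in_delta <- band_powers(p)$rp[["delta"]]
  expect_gte(in_delta, 95)
})

test_that("background generation is deterministic given the seed", {
  spec <- quick_spec(seed = 11)
  expect_identical(make_background(spec, 10), make_background(spec, 10))
  expect_false(identical(make_background(spec, 10, seed = 12),
                         make_background(spec, 10, seed = 11)))
  # and does not disturb the caller's RNG stream
  set.seed(99); a <- rnorm(1)
  set.seed(99); invisible(make_background(spec, 1)); b <- rnorm(1)
  expect_identical(a, b)
})

test_that("generator band fractions are recovered through the spectral pipeline", {
  # property: random simplex draws, 150 s at 1 kHz, per-band error <= 3 points
  set.seed(202)
  for (k in 1:5) {
    fr <- rexp(5); fr <- fr / sum(fr)
    spec <- quick_spec(fr, seed = 300 + k)
    x <- make_background(spec, 150)
    rp <- band_powers(welch_psd(x, spec$fs))$rp
    expect_lt(max(abs(rp - 100 * fr)), 3)
  }
})

test_that("evoked injection places an exact trough at the requested latency", {
  fs <- 1000
  x <- numeric(5 * fs)
  ev <- list(n1_amp = 40, latency = 80, width = 20, jitter_amp = 0, jitter_lat = 0)
  y <- inject_evoked(x, fs, onsets = 2, ev)
  i_min <- which.min(y)
  expect_equal(min(y), -40, tolerance = 1e-9)
  expect_equal((i_min - 1) / fs - 2, 0.080, tolerance = 1.5 / fs)

  expect_identical(inject_evoked(x, fs, 2, modifyList(ev, list(n1_amp = 0))), x)
  expect_warning(inject_evoked(x, fs, onsets = 4.999, ev), "skipped")
})

test_that("line noise adds harmonics at the stated amplitude ratios", {
  fs <- 1000
  x <- numeric(30 * fs)
  y <- inject_line_noise(x, fs, amp50 = 10, seed = 5)
  p <- welch_psd(y, fs)
  peak_amp <- vapply(c(50, 150, 250, 350), function(f0) {
    sel <- p$freq >= f0 - 1 & p$freq <= f0 + 1
    sqrt(2 * trapz(p$freq[sel], p$psd[sel]))   # sine amplitude from band power
  }, numeric(1))
  expect_equal(peak_amp / peak_amp[1], c(1, 0.5, 0.25, 0.125), tolerance = 0.1)

  expect_identical(inject_line_noise(x, fs, amp50 = 0), x)
  expect_error(inject_line_noise(x, fs, amp50 = 1, harmonics = 600), "Nyquist")
})

test_that("sessions have three phases, cadenced onsets, and the power gain", {
  spec <- quick_spec(phase_len = 150, seed = 3, stim_power_gain = 0)
  rec <- build_session(spec)
  expect_equal(rec_duration(rec), 450)
  expect_length(rec$stim_onsets, 45)          # floor(150 / 3.3)
  expect_equal(diff(rec$stim_onsets), rep(3.3, 44), tolerance = 1e-9)
  expect_equal(rec$meta$phases$phase, c("pre", "stim", "post"))

  # gain 0: pre and stim power agree to estimator noise
  pc <- phase_power_change(rec, fspec = NULL)
  expect_lt(abs(pc$change_pct), 5)
})

test_that("identical spec and seed give identical sessions", {
  spec <- quick_spec(phase_len = 20, seed = 8,
                     evoked = list(n1_amp = 30, latency = 80, width = 20,
                                   jitter_amp = 0.05, jitter_lat = 5))
  expect_identical(build_session(spec)$samples, build_session(spec)$samples)
})

test_that("packaged presets load into valid specs", {
  spec <- load_preset("MscL-G22N", mode = "spontaneous", seed = 1)
  expect_equal(sum(spec$band_fractions), 1, tolerance = 1e-9)
  expect_equal(spec$band_fractions[["delta"]], 0.6029)
  expect_null(spec$evoked)
  s2 <- load_preset("MscL-G22S", 400, mode = "session", seed = 1)
  expect_equal(s2$stim_power_gain, 0.212)
  expect_equal(s2$evoked$n1_amp, 40.16)
  s3 <- load_preset("MscL-G22S", 400, mode = "uep", seed = 1)
  expect_lt(s3$total_rms, s2$total_rms)
  expect_error(load_preset("CON", 300), "intensity")
})
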