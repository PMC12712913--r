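test_that("notch removes 50 Hz while the passband is preserved", {
  fs <- 1000
  tt <- (0:(20 * fs - 1)) / fs
  mid <- seq(5 * fs, 15 * fs)   # avoid filter edge transients

  x50 <- sin(2 * pi * 50 * tt)
  y50 <- apply_filters(x50, filter_spec(), fs = fs)
  expect_lt(rms(y50[mid]) / rms(x50[mid]), 0.01)

  x10 <- sin(2 * pi * 10 * tt)
  y10 <- apply_filters(x10, filter_spec(), fs = fs)
  expect_equal(rms(y10[mid]) / rms(x10[mid]), 1, tolerance = 0.05)
})

test_that("the filter chain is linear", {
  fs <- 500
  set.seed(1)
  x <- rnorm(fs * 4); y <- rnorm(fs * 4)
  fsp <- filter_spec(notch_freqs = c(50, 150))
  lhs <- apply_filters(2 * x + 3 * y, fsp, fs = fs)
  rhs <- 2 * apply_filters(x, fsp, fs = fs) + 3 * apply_filters(y, fsp, fs = fs)
  expect_equal(lhs, rhs, tolerance = 1e-8)
})

test_that("single-pass Butterworth magnitude response is -3 dB at the band edges", {
  fs <- 1000
  fsp <- filter_spec()
  bw <- signal::butter(fsp$order, c(fsp$low, fsp$high) / (fs / 2), type = "pass")
  mag2 <- function(f) {
    z <- exp(-1i * 2 * pi * f / fs)
    Mod(sum(bw$b * z^(0:(length(bw$b) - 1))) /
        sum(bw$a * z^(0:(length(bw$a) - 1))))^2
  }
  expect_equal(mag2(0.5), 0.5, tolerance = 0.05)
  expect_equal(mag2(100), 0.5, tolerance = 0.05)
  expect_gt(mag2(10), 0.95)
})

test_that("zero-phase filtering does not shift an injected trough", {
  fs <- 1000
  x <- numeric(6 * fs)
  ev <- list(n1_amp = 40, latency = 80, width = 20, jitter_amp = 0, jitter_lat = 0)
  x <- inject_evoked(x, fs, onsets = 3, ev)
  y <- apply_filters(x, filter_spec(), fs = fs)
  expect_lte(abs(which.min(y) - which.min(x)), 1)
})

test_that("filtering validates the sampling rate", {
  expect_error(apply_filters(rnorm(1000), filter_spec(), fs = 150), "too low")
  expect_error(apply_filters(rnorm(1000), filter_spec(), fs = 600), "Nyquist")
})

test_that("epoching cuts one trial per usable onset and drops edge trials", {
  spec <- quick_spec(phase_len = 30, seed = 5)
  rec <- build_session(spec)
  ep <- epoch_recording(rec)
  expect_equal(nrow(ep$x), length(rec$stim_onsets))
  expect_equal(ncol(ep$x), 3 * rec$fs)
  expect_equal(range(ep$times), c(-1, 2 - 1 / rec$fs))

  # first onset cannot support 1 s of pre-onset baseline
  early <- recording(rnorm(2000), fs = 1000, stim_onsets = c(0.5, 1.5))
  expect_warning(ep2 <- epoch_recording(early, window = c(-1, 0.4)), "dropped")
  expect_equal(nrow(ep2$x), 1L)

  none <- recording(rnorm(2000), fs = 1000)
  expect_error(epoch_recording(none), "no onsets")
})

test_that("baseline correction zeroes the reference window and is idempotent", {
  rows <- matrix(rnorm(3 * 3000), nrow = 3) + 7
  ep <- epochs_from_rows(rows)
  bc <- baseline_correct(ep)
  sel <- bc$times >= -1 & bc$times < 0
  expect_equal(rowMeans(bc$x[, sel]), rep(0, 3), tolerance = 1e-12)
  expect_equal(baseline_correct(bc)$x, bc$x, tolerance = 1e-12)

  # a flat-baseline trial keeps its trough amplitude
  tr <- numeric(3000)
  tr[1500] <- -40
  ep1 <- epochs_from_rows(rbind(tr))
  expect_equal(min(baseline_correct(ep1)$x), -40, tolerance = 1e-9)
})

test_that("artifact rejection flags template matches and keeps noise", {
  fs <- 1000
  tpl <- artifact_template(fs, amp = 30)
  set.seed(9)
  art_trial <- numeric(3000)
  idx <- 1001 + 50 + seq_along(tpl)   # inside the 0-0.5 s search window
  art_trial[idx] <- 3 * tpl
  art_trial <- art_trial + rnorm(3000, sd = 0.05)
  noise_trials <- matrix(rnorm(5 * 3000, sd = 10), nrow = 5)
  ep <- epochs_from_rows(rbind(art_trial, noise_trials), fs = fs)
  out <- reject_artifacts(ep, tpl, rho_min = 0.8)
  expect_false(out$kept[1])
  expect_true(all(out$kept[-1]))
  expect_equal(attr(out, "n_flagged"), 1L)

  # rho_min above 1 can never flag; rho_min <= 1 always flags an exact match
  expect_true(all(reject_artifacts(ep, tpl, rho_min = 1 + 1e-9)$kept))
  exact <- numeric(3000); exact[idx] <- tpl
  ep_e <- epochs_from_rows(rbind(exact), fs = fs)
  expect_false(reject_artifacts(ep_e, tpl, rho_min = 1)$kept[1])

  expect_error(reject_artifacts(ep, rep(1, 100)), "zero variance")
})

test_that("artifact flag rate is monotone in template SNR", {
  fs <- 1000
  tpl <- artifact_template(fs, amp = 1)
  set.seed(31)
  rate <- vapply(c(0, 0.5, 1, 2, 8), function(snr) {
    rows <- t(vapply(1:30, function(i) {
      tr <- rnorm(3000)
      tr[1050 + seq_along(tpl)] <- tr[1050 + seq_along(tpl)] + snr * sd(tpl) * tpl / sd(tpl)
      tr
    }, numeric(3000)))
    out <- reject_artifacts(epochs_from_rows(rows, fs = fs), tpl, rho_min = 0.5)
    mean(!out$kept)
  }, numeric(1))
  expect_true(all(diff(rate) >= 0))
  expect_equal(rate[1], 0)
  expect_equal(rate[length(rate)], 1)
})
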