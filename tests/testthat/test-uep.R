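test_that("trial averaging returns mean and SEM with CLT scaling", {
  tr <- sin(seq(0, 2 * pi, length.out = 3000))
  ep <- epochs_from_rows(rbind(tr, tr, tr))
  av <- average_uep(ep)
  expect_equal(av$mean, tr)
  expect_equal(max(av$sem), 0)

  ep2 <- epochs_from_rows(rbind(tr, -tr))
  expect_equal(max(abs(average_uep(ep2)$mean)), 0)

  set.seed(14)
  n <- 200; sigma <- 2
  rows <- matrix(rep(tr, n), nrow = n, byrow = TRUE) +
    matrix(rnorm(n * 3000, sd = sigma), nrow = n)
  expect_equal(mean(average_uep(epochs_from_rows(rows))$sem),
               sigma / sqrt(n), tolerance = 0.1)

  ep$kept[] <- FALSE
  expect_error(average_uep(ep), "rejected")
})

test_that("N1 detection recovers a noiseless injected trough exactly", {
  fs <- 1000
  x <- numeric(3 * fs)
  ev <- list(n1_amp = 40, latency = 80, width = 20, jitter_amp = 0, jitter_lat = 0)
  x <- inject_evoked(x, fs, onsets = 1, ev)   # trace runs -1..2 s around onset
  r <- detect_n1(x, fs, t_start = -1)
  expect_true(r$responded)
  expect_equal(r$amplitude, 40, tolerance = 1e-6)
  expect_equal(r$latency, 80, tolerance = 1000 * 1.5 / fs)

  flat <- detect_n1(numeric(3 * fs), fs, t_start = -1)
  expect_false(flat$responded)
})

test_that("N1 detection is shift- and scale-equivariant", {
  fs <- 1000
  x <- inject_evoked(numeric(3 * fs), fs, 1,
                     list(n1_amp = 30, latency = 100, width = 20,
                          jitter_amp = 0, jitter_lat = 0))
  r0 <- detect_n1(x, fs, t_start = -1)
  r_shift <- detect_n1(x, fs, times = -1.05 + (seq_along(x) - 1) / fs)
  expect_equal(r_shift$latency, r0$latency - 50, tolerance = 1e-9)
  r_scale <- detect_n1(2.5 * x, fs, t_start = -1)
  expect_equal(r_scale$amplitude, 2.5 * r0$amplitude, tolerance = 1e-9)
  expect_equal(r_scale$latency, r0$latency)
})

test_that("the first qualifying trough wins regardless of depth", {
  fs <- 1000
  x <- numeric(3 * fs)
  x <- inject_evoked(x, fs, 1, list(n1_amp = 30, latency = 100, width = 20,
                                    jitter_amp = 0, jitter_lat = 0))
  x <- inject_evoked(x, fs, 1, list(n1_amp = 60, latency = 250, width = 20,
                                    jitter_amp = 0, jitter_lat = 0))
  r <- detect_n1(x, fs, t_start = -1, noise_sd = 5)   # floor 15 < both troughs
  expect_equal(r$latency, 100, tolerance = 2)
  expect_equal(r$amplitude, 30, tolerance = 1)
})

test_that("troughs below the significance floor are non-responses", {
  fs <- 1000
  x <- inject_evoked(numeric(3 * fs), fs, 1,
                     list(n1_amp = 10, latency = 100, width = 20,
                          jitter_amp = 0, jitter_lat = 0))
  expect_false(detect_n1(x, fs, t_start = -1, noise_sd = 5)$responded)  # floor 15
  expect_true(detect_n1(x, fs, t_start = -1, noise_sd = 2)$responded)   # floor 6
})

test_that("intensity-response tables are monotone for monotone presets", {
  protocol <- stim_protocol()
  amps <- c(10, 20, 40); lats <- c(120, 100, 80)
  sessions <- lapply(1:3, function(i) {
    spec <- quick_spec(total_rms = 1, seed = 40 + i,
                       evoked = list(n1_amp = amps[i], latency = lats[i],
                                     width = 20, jitter_amp = 0.05,
                                     jitter_lat = 2))
    list(rec = simulate_uep_trials(spec, protocol, n_trials = 15),
         intensity = c(100, 250, 400)[i])
  })
  res <- uep_by_intensity(sessions)
  expect_true(all(diff(res$summary$mean_amplitude_uV) > 0))
  expect_true(all(diff(res$summary$mean_latency_ms) < 0))
  expect_true(all(res$summary$nonresponse_rate < 0.2))
  expect_named(res$trials,
               c("intensity", "trial", "amplitude_uV", "latency_ms", "responded"))
})

test_that("sessions without an evoked response are scored as non-responders", {
  spec <- quick_spec(total_rms = 5, seed = 50)   # no evoked component
  rec <- apply_filters(simulate_uep_trials(spec, n_trials = 20))
  ep <- baseline_correct(epoch_recording(rec))
  m <- uep_metrics(ep)
  expect_gte(mean(!m$responded), 0.7)
})
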