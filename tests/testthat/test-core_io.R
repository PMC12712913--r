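test_that("recording container enforces its invariants", {
  x <- matrix(rnorm(200), nrow = 2)
  rec <- recording(x, fs = 100, stim_onsets = c(0.2, 0.5))
  expect_s3_class(rec, "lfp_recording")
  expect_equal(rec_duration(rec), 1)
  expect_error(recording(x, fs = 0), "fs")
  expect_error(recording(x, fs = 100, stim_onsets = c(0.5, 0.2)), "increasing")
  expect_error(recording(x, fs = 100, stim_onsets = 5), "within")
  expect_error(recording(x, fs = 100, channel_ids = "only_one"), "channels")
})

test_that("delimited and binary formats round-trip samples and onsets", {
  set.seed(42)
  rec <- recording(matrix(rnorm(2 * 500, sd = 40), nrow = 2), fs = 500,
                   stim_onsets = c(0.25, 0.75),
                   channel_ids = c("hpc1", "hpc2"))
  tmp <- withr::local_tempdir()

  ptxt <- file.path(tmp, "rec.tsv")
  write_recording(rec, ptxt, format = "delimited")
  back <- read_recording(ptxt)
  expect_equal(back$samples, rec$samples, tolerance = 1e-9)
  expect_true(max(abs(back$samples - rec$samples)) < 1e-6)
  expect_equal(back$stim_onsets, rec$stim_onsets)
  expect_equal(back$channel_ids, rec$channel_ids)

  pbin <- file.path(tmp, "rec.bin")
  write_recording(rec, pbin, format = "binary")
  b1 <- read_recording(pbin)
  expect_equal(b1$samples, rec$samples, tolerance = 1e-5) # float32 storage
  # a second binary round-trip of the float32 data is bit-exact
  write_recording(b1, file.path(tmp, "rec2.bin"), format = "binary")
  b2 <- read_recording(file.path(tmp, "rec2.bin"))
  expect_identical(b2$samples, b1$samples)
})

test_that("sync channel is consumed into stimulation onsets on read", {
  fs <- 1000
  sync <- numeric(fs)
  sync[(0.5 * fs + 1):(0.5 * fs + 51)] <- 5   # rising edge exactly at 0.5 s
  rec <- recording(rbind(rnorm(fs), sync), fs = fs,
                   channel_ids = c("lfp", "sync"))
  tmp <- withr::local_tempfile()
  write_recording(rec, tmp, format = "delimited")
  back <- read_recording(tmp, sync_channel = "sync")
  expect_equal(back$stim_onsets, 0.5, tolerance = 2 / fs)
  expect_equal(nrow(back$samples), 1L)
  expect_false("sync" %in% back$channel_ids)
})

test_that("missing sidecar and empty files raise structure errors", {
  tmp <- withr::local_tempdir()
  pbin <- file.path(tmp, "x.bin")
  writeBin(rnorm(10), pbin, size = 4)
  expect_error(read_recording(pbin, format = "binary"), "sidecar")
  pempty <- file.path(tmp, "empty.tsv")
  file.create(pempty)
  expect_error(read_recording(pempty, fs = 100), "empty")
})

test_that("rising-edge extraction finds pulses and merges refractory edges", {
  fs <- 100
  x <- numeric(30 * fs)
  for (on in c(10, 20)) x[(on * fs + 1):(on * fs + 20)] <- 5
  expect_equal(extract_sync_onsets(x, fs, threshold = 2.5), c(10, 20))
  expect_identical(extract_sync_onsets(rep(1, 1000), fs), numeric())

  # protocol cadence: SD 0.3 s on / ISI 3 s off, floor(150 / 3.3) = 45 pulses
  y <- numeric(152 * fs)
  starts <- seq(0.5, by = 3.3, length.out = floor(150 / 3.3))
  for (on in starts) y[round(on * fs + 1):round((on + 0.3) * fs)] <- 5
  got <- extract_sync_onsets(y, fs, threshold = 2.5)
  expect_length(got, floor(150 / 3.3))
  expect_equal(diff(got), rep(3.3, length(got) - 1), tolerance = 2 / fs)

  # any threshold strictly between levels recovers the same count
  for (thr in c(0.5, 2, 4.5))
    expect_length(extract_sync_onsets(y, fs, threshold = thr), length(starts))
})

test_that("protocol validation enforces dc = tbd * prf and positivity", {
  expect_s3_class(stim_protocol(prf = 1.0, tbd = 0.5, dc = 0.5), "stim_protocol")
  expect_s3_class(stim_protocol(prf = 2.0, tbd = 0.25, dc = 0.5), "stim_protocol")
  expect_error(stim_protocol(prf = 1.0, tbd = 1.0, dc = 0.5), "tbd \\* prf")
  expect_error(stim_protocol(isi = -1), "isi")
  expect_error(stim_protocol(levels = data.frame(ispta = 100, pnp = -1)), "levels")
})

test_that("protocol config files load and validate", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("ff: 1.0", "prf: 2.0", "tbd: 0.25", "dc: 0.5", "sd: 0.3",
               "isi: 3", "phase_len: 150",
               "levels: {ispta: [100, 400], pnp: [0.15, 0.35]}"), tmp)
  p <- read_protocol(tmp)
  expect_equal(p$prf, 2.0)
  expect_equal(p$levels$pnp, c(0.15, 0.35))
})

test_that("event tables validate interval sanity", {
  et <- event_table(c("immobile", "center"), c(0, 10), c(5, 12))
  expect_s3_class(et, "event_table")
  expect_error(event_table("a", 5, 3), "start <= stop")
  expect_error(event_table("a", -1, 3), "non-negative")
})
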