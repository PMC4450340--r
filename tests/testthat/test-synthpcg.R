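test_that("recordings are bit-reproducible from (config, seed)", {
  cfg <- beat_config(hr = 120)
  r1 <- generate_recording(5, cfg, snr_db = 5, seed = 9)
  r2 <- generate_recording(5, cfg, snr_db = 5, seed = 9)
  expect_identical(r1$signal$samples, r2$signal$samples)
  expect_identical(r1$annotations, r2$annotations)
  r3 <- generate_recording(5, cfg, snr_db = 5, seed = 10)
  expect_false(identical(r1$signal$samples, r3$signal$samples))
})

test_that("jitter-free beats are deterministic with exact sound placement", {
  cfg <- beat_config(hr = 60, jitter = 0, systole_fraction = 0.35)
  b1 <- generate_beat(cfg)
  b2 <- generate_beat(cfg)
  expect_identical(b1$signal$samples, b2$signal$samples)
  # S2 placed at systole_fraction of the 1 s period, past the 20 ms lead-in
  expect_equal(b1$annotations$onset_s[2], 0.02 + 0.35, tolerance = 1e-9)
  expect_equal(b1$annotations$label, c("S1", "S2"))
  # distinct seeds share the annotation grid when jitter = 0
  ra <- generate_recording(4, cfg, snr_db = 10, seed = 1)
  rb <- generate_recording(4, cfg, snr_db = 10, seed = 2)
  expect_identical(ra$annotations, rb$annotations)
  expect_false(identical(ra$signal$samples, rb$signal$samples))
})

test_that("a 10 s recording at 60 bpm holds exactly 10 annotated beats", {
  rec <- generate_recording(10, beat_config(hr = 60, jitter = 0), seed = 3)
  expect_equal(nrow(rec$annotations), 20)
  expect_identical(rec$annotations$label, rep(c("S1", "S2"), 10))
  # non-overlap and strict ordering
  expect_true(all(diff(as.vector(t(rec$annotations[, 1:2]))) > 0))
})

test_that("added noise hits the requested SNR within half a dB", {
  for (snr in c(10, 5, 0)) {
    clean <- generate_recording(8, beat_config(hr = 90), seed = 31)
    noisy <- generate_recording(8, beat_config(hr = 90), snr_db = snr,
                                seed = 31)
    noise <- noisy$signal$samples - clean$signal$samples
    measured <- 10 * log10(mean(clean$signal$samples^2) / mean(noise^2))
    expect_lt(abs(measured - snr), 0.5)
  }
})

test_that("HR coupling lowers the S2 spectral centroid at high heart rate", {
  centroid_s2 <- function(hr) {
    rec <- generate_recording(4, beat_config(hr = hr), seed = 17)
    a <- rec$annotations
    i <- which(a$label == "S2")[1]
    seg <- signal_slice(rec$signal, a$onset_s[i], a$offset_s[i])
    sp <- abs(stats::fft(seg$samples))^2
    fr <- (seq_along(sp) - 1) * seg$fs / length(sp)
    half <- fr <= seg$fs / 2
    sum(fr[half] * sp[half]) / sum(sp[half])
  }
  expect_lt(centroid_s2(180), centroid_s2(60))
})

test_that("invalid configurations are rejected", {
  expect_error(beat_config(hr = 300), "hr")
  expect_error(beat_config(systole_fraction = 0.9), "systole_fraction")
  expect_error(beat_config(jitter = -0.1), "nonnegative")
  # S2 spilling past the period at very high HR with a long systole
  long_s2 <- data.frame(freq = 90, dur = 0.2, amp = 1, onset = 0)
  expect_error(generate_beat(beat_config(hr = 210, s2_components = long_s2,
                                         systole_fraction = 0.6,
                                         jitter = 0)),
               "configuration error")
  expect_error(generate_recording(0.1, beat_config(hr = 60)), "duration")
})

test_that("WAV files round-trip (float exactly, PCM16 to quantization)", {
  rec <- generate_recording(2, beat_config(hr = 90), seed = 5)
  x <- rec$signal
  x <- time_signal(x$samples / max(abs(x$samples)) * 0.9, x$fs)

  f32 <- tempfile(fileext = ".wav")
  write_wav(x, f32, bits = 32)
  back <- read_wav(f32)
  expect_equal(back$fs, x$fs)
  expect_equal(back$samples, x$samples, tolerance = 1e-7)

  p16 <- tempfile(fileext = ".wav")
  write_wav(x, p16, bits = 16)
  back16 <- read_wav(p16)
  expect_lt(max(abs(back16$samples - x$samples)), 1 / 32768)
  unlink(c(f32, p16))
})

test_that("write_recording emits WAV plus a matching annotation sidecar", {
  rec <- generate_recording(3, beat_config(hr = 120), seed = 8)
  wav <- tempfile(fileext = ".wav")
  write_recording(rec, wav)
  csv <- sub("\\.wav$", ".csv", wav)
  expect_true(file.exists(csv))
  ann <- read_segments(csv)
  expect_identical(ann, rec$annotations)
  aud <- read_wav(wav)
  expect_equal(length(aud$samples), length(rec$signal$samples))
  unlink(c(wav, csv))
})

test_that("stereo WAV input is rejected with a clear message", {
  path <- tempfile(fileext = ".wav")
  con <- file(path, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + 8L, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # two channels
  writeBin(8000L, con, size = 4, endian = "little")
  writeBin(32000L, con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(8L, con, size = 4, endian = "little")
  writeBin(c(0L, 0L, 0L, 0L), con, size = 2, endian = "little")
  close(con)
  expect_error(read_wav(path), "mono")
  unlink(path)
})
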