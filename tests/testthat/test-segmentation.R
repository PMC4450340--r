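fake_env <- function(values, fs = 100) {
  structure(list(values = values, times = (seq_along(values) - 1) / fs,
                 fs = fs, exponent_n = 1.5, smooth_len = NA_real_),
            class = "sse_envelope")
}

test_that("SSE envelope handles degenerate columns by the 0*log0 convention", {
  # one normalized coefficient equal to 1 contributes -1*log(1) = 0;
  # all-zero columns contribute 0
  m <- matrix(0, 3, 4)
  m[2, 2] <- 5
  st <- structure(list(coef = rbind(0, m + 0i), freqs = 0:3, times = 0:3,
                       fs = 1, alpha = 1), class = "st_matrix")
  env <- sse_envelope(st, exponent_n = 1.5)
  expect_equal(env$values, rep(0, 4))
  expect_error(sse_envelope(structure(list(coef = matrix(0 + 0i, 2, 2),
                                           freqs = 0:1, times = 0:1, fs = 1,
                                           alpha = 1), class = "st_matrix")),
               "degenerate")
  expect_error(sse_envelope(st, exponent_n = -1), "positive")
})

test_that("envelope is nonnegative for arbitrary signals", {
  set.seed(5)
  for (i in 1:5) {
    x <- time_signal(rnorm(600), fs = 600)
    env <- sse_envelope(s_transform(x, alpha = runif(1, 0.5, 2),
                                    max_freq = 250, target_fs = NULL))
    expect_true(all(env$values >= 0))
  }
})

test_that("exponent 1.5 compresses intensity contrast less than 2", {
  # for 0 < x < y <= 1 the faint/loud ratio is larger at n = 1.5
  set.seed(9)
  x <- runif(200, 1e-4, 0.999)
  y <- pmin(x + runif(200, 1e-4, 0.5), 1)
  expect_true(all(x^1.5 / y^1.5 > x^2 / y^2))
})

test_that("the faint-sound boost of n = 1.5 is visible in real envelopes", {
  fs <- 2000
  loud <- gabor_atom(40, 0.08, fs, 1, amp = 1, center = 0.25)
  faint <- gabor_atom(100, 0.05, fs, 1, amp = 0.12, center = 0.75)
  x <- time_signal(loud + faint, fs)
  peak_ratio <- function(n) {
    env <- sse_envelope(s_transform(x, 1, 250, target_fs = NULL), n)
    half <- length(env$values) %/% 2
    max(env$values[(half + 1):length(env$values)]) / max(env$values[1:half])
  }
  expect_gt(peak_ratio(1.5), peak_ratio(2))
})

test_that("moving-average smoothing has the documented closed forms", {
  const <- fake_env(rep(3, 50))
  expect_equal(smooth_envelope(const, 0.05)$values, rep(3, 50))

  imp <- fake_env(c(rep(0, 30), 1, rep(0, 30)))
  sm <- smooth_envelope(imp, 0.05)           # W = 5 samples at fs 100
  expect_equal(sum(sm$values > 0), 5)
  expect_equal(max(sm$values), 1 / 5)
  expect_equal(length(sm$values), 61)
  expect_equal(sum(sm$values), sum(imp$values))

  set.seed(3)
  noise <- fake_env(abs(rnorm(500)))
  expect_lt(var(smooth_envelope(noise, 0.02)$values), var(noise$values))
  expect_error(smooth_envelope(fake_env(1:5), 1), "longer")
})

test_that("detection returns ordered, bounded, non-overlapping segments", {
  rec <- generate_recording(4, beat_config(hr = 60, jitter = 0), seed = 1)
  segs <- segment_sounds(rec$signal)
  expect_equal(nrow(segs), 8)                # 4 beats, S1 + S2 each
  expect_true(all(segs$label == "unknown"))
  expect_true(all(diff(segs$onset_s) > 0))
  expect_true(all(segs$offset_s > segs$onset_s))
  expect_true(all(segs$onset_s[-1] >= segs$offset_s[-nrow(segs)]))
  durs <- segs$offset_s - segs$onset_s
  expect_true(all(durs >= 0.04 & durs <= 0.25))
  # onsets within 20 ms of the annotated ground truth
  expect_lt(max(abs(segs$onset_s - rec$annotations$onset_s)), 0.02)
})

test_that("quiet envelopes yield no detections; close bursts merge", {
  # a constant envelope never crosses its own adaptive threshold
  expect_equal(nrow(detect_sounds(fake_env(rep(4, 2000), fs = 1000))), 0)
  # isolated blips shorter than min_dur are rejected
  blips <- rep(0, 2000)
  blips[c(500:510, 1200:1215)] <- 1
  expect_equal(nrow(detect_sounds(fake_env(blips, fs = 1000))), 0)

  two <- rep(0, 1000)
  two[300:360] <- 1
  two[371:431] <- 1          # 10 ms gap at fs 1000 < min_gap 20 ms
  merged <- detect_sounds(fake_env(two, fs = 1000), max_dur = 0.3)
  expect_equal(nrow(merged), 1)
  expect_error(detect_sounds(fake_env(two, fs = 1000), thresh_frac = 1.2),
               "thresh_frac")
})

test_that("segment tables round-trip losslessly through CSV and JSON", {
  segs <- data.frame(onset_s = c(0.123456789012345, 2 / 3),
                     offset_s = c(0.2, 0.987654321098765),
                     label = c("S1", "S2"), stringsAsFactors = FALSE)
  for (ext in c("csv", "json")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_segments(segs, path)
    back <- read_segments(path)
    expect_identical(back$onset_s, segs$onset_s)
    expect_identical(back$offset_s, segs$offset_s)
    expect_identical(back$label, segs$label)
    unlink(path)
  }
  p0 <- tempfile(fileext = ".csv")
  write_segments(segs[0, ], p0)
  expect_equal(nrow(read_segments(p0)), 0)
  unlink(p0)
})
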