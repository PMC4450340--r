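# st_matrix with hand-set axes (unit grid spacings when times = 0:(n-1),
# freqs = 1:m after the DC row)
fake_st <- function(mag_matrix) {
  nr <- nrow(mag_matrix)
  nc <- ncol(mag_matrix)
  structure(list(coef = rbind(rep(0, nc), mag_matrix + 0i),
                 freqs = 0:nr, times = 0:(nc - 1), fs = 1, alpha = 1),
            class = "st_matrix")
}

test_that("time marginal of the S-transform reproduces the Fourier spectrum", {
  set.seed(42)
  for (n in c(128, 1000, 4096)) {
    x <- time_signal(rnorm(n), fs = 500)
    st <- s_transform(x, alpha = runif(1, 0.5, 2), max_freq = 250,
                      target_fs = NULL)
    keep <- st$freqs > 0
    marg <- rowSums(st$coef[keep, , drop = FALSE]) / x$fs
    bins <- round(st$freqs[keep] * n / x$fs)
    ref <- stats::fft(x$samples)[bins + 1] / x$fs
    expect_lt(max(abs(marg - ref) / abs(ref)), 1e-6)
  }
})

test_that("a constant signal has no energy at positive frequencies", {
  x <- time_signal(rep(2.5, 400), fs = 200)
  st <- s_transform(x, alpha = 1.3, max_freq = 80, target_fs = NULL)
  expect_lt(max(abs(st$coef[st$freqs > 0, ])), 1e-9 * 2.5)
  # DC row carries the mean
  expect_equal(unique(Re(st$coef[1, ])), 2.5)
})

test_that("a pure sinusoid concentrates at its own frequency bin", {
  fs <- 200
  x <- time_signal(sin(2 * pi * 10 * seq(0, 1, by = 1 / fs)), fs = fs)
  st <- s_transform(x, alpha = 1, max_freq = 50, target_fs = NULL)
  band <- which(st$freqs > 0)
  interior <- seq(20, ncol(st$coef) - 20)
  peaks <- st$freqs[band][apply(abs(st$coef[band, interior]), 2, which.max)]
  expect_true(all(abs(peaks - 10) < 0.5))
})

test_that("FFT implementation matches direct numerical integration", {
  set.seed(7)
  fs <- 256
  for (n in c(128, 256)) {
    x <- gabor_atom(freq = 40, dur = 0.2, fs = fs, total = (n - 1) / fs)
    x <- x + 0.2 * rnorm(length(x))
    for (alpha in c(0.6, 1, 1.8)) {
      st <- s_transform(time_signal(x, fs), alpha = alpha, max_freq = 64,
                        target_fs = NULL)
      sub_f <- which(st$freqs >= 16 & st$freqs <= 64)
      sub_t <- seq(1, length(st$times), by = 8)
      ref <- st_direct(x, fs, alpha, st$freqs[sub_f], st$times[sub_t])
      got <- st$coef[sub_f, sub_t]
      rel <- max(abs(got - ref)) / max(abs(ref))
      expect_lt(rel, 0.01)
    }
  }
})

test_that("input validation rejects bad signals and parameters", {
  expect_error(time_signal(c(1, NA, 3), 100), "non-finite")
  expect_error(time_signal(1, 100), "at least 2")
  expect_error(time_signal(1:10, -1), "positive")
  x <- time_signal(sin(1:100), 100)
  expect_error(s_transform(x, alpha = 0), "alpha")
  expect_error(s_transform(x, alpha = 1, max_freq = 100, target_fs = NULL),
               "Nyquist")
})

test_that("concentration measure closed forms hold on unit grids", {
  m <- matrix(0, 4, 5)
  m[2, 3] <- 7           # single nonzero cell -> CM = 1 for any amplitude
  expect_equal(concentration_measure(fake_st(m)), 1)

  n_cells <- 6 * 8       # uniform matrix -> CM = 1 / sqrt(N)
  u <- matrix(3.2, 6, 8)
  expect_equal(concentration_measure(fake_st(u)), 1 / sqrt(n_cells))

  expect_error(concentration_measure(fake_st(matrix(0, 3, 3))),
               "degenerate")
})

test_that("CM is scale-invariant and prefers transients over noise", {
  set.seed(11)
  x <- gabor_atom(100, 0.05, fs = 1000, total = 0.5)
  noise <- rnorm(length(x))
  noise <- noise * sqrt(sum(x^2) / sum(noise^2))   # equal energy
  st_x <- s_transform(time_signal(x, 1000), 1, 250, target_fs = NULL)
  st_k <- s_transform(time_signal(-3.7 * x, 1000), 1, 250, target_fs = NULL)
  st_n <- s_transform(time_signal(noise, 1000), 1, 250, target_fs = NULL)
  expect_equal(concentration_measure(st_x), concentration_measure(st_k))
  expect_gt(concentration_measure(st_x), concentration_measure(st_n))
})

test_that("optimize_alpha is a deterministic, scale- and order-invariant grid search", {
  x <- time_signal(gabor_atom(60, 0.08, fs = 1000, total = 0.4), 1000)
  p <- optimize_alpha(x, target_fs = NULL)
  expect_length(p$alpha_grid, 16)
  expect_equal(p$alpha_grid[1], 0.5)
  expect_equal(p$alpha_grid[16], 2.0)
  expect_equal(p$cm_values[match(p$alpha_opt, p$alpha_grid)],
               max(p$cm_values))

  ks <- time_signal(-0.01 * x$samples, 1000)
  p2 <- optimize_alpha(ks, target_fs = NULL)
  expect_equal(p2$cm_values, p$cm_values)
  expect_equal(p2$alpha_opt, p$alpha_opt)

  shuffled <- optimize_alpha(x, alpha_grid = rev(seq(0.5, 2, 0.1)),
                             target_fs = NULL)
  expect_equal(shuffled$alpha_opt, p$alpha_opt)
  expect_error(optimize_alpha(x, alpha_grid = numeric(0)), "nonempty")
  expect_error(optimize_alpha(x, alpha_grid = c(1, -1)), "positive")
})

test_that("alpha_opt separates S1-like from S2-like transients", {
  fs <- 2000
  # S1-like: two overlapping low-frequency tonal bursts
  s1 <- gabor_atom(35, 0.08, fs, 0.2, center = 0.08) +
    0.85 * gabor_atom(65, 0.07, fs, 0.2, center = 0.12)
  # S2-like: short, higher-frequency, frequency-spread burst
  s2 <- gabor_atom(90, 0.055, fs, 0.2) + 0.8 * gabor_atom(135, 0.05, fs, 0.2)
  a1 <- optimize_alpha(time_signal(s1, fs), target_fs = NULL)$alpha_opt
  a2 <- optimize_alpha(time_signal(s2, fs), target_fs = NULL)$alpha_opt
  expect_gt(a1, a2)
})
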