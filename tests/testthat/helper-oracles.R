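# Independent oracles kept deliberately naive; they never share code with
# the implementation paths they check.

# Direct numerical integration of the S-transform definition: for each
# (time, frequency) cell, sum x(tau) * w(tau - t, f) * exp(-2i*pi*f*tau)
# over tau, with the unit-area Gaussian window sigma(f) = alpha / f.  The
# window is periodized (wrap offsets +/- one signal length) because the
# discrete transform acts on the circular extension of the signal.
st_direct <- function(samples, fs, alpha, freqs, times) {
  n <- length(samples)
  tau <- (seq_len(n) - 1) / fs
  span <- n / fs
  out <- matrix(0 + 0i, nrow = length(freqs), ncol = length(times))
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    sdev <- alpha / f
    for (j in seq_along(times)) {
      t0 <- times[j]
      w <- 0
      for (wrap in c(-span, 0, span)) {
        d <- tau - t0 + wrap
        w <- w + exp(-d^2 / (2 * sdev^2)) / (sdev * sqrt(2 * pi))
      }
      out[i, j] <- sum(samples * w * exp(-2i * pi * f * tau)) / fs
    }
  }
  out
}

# AUC by explicit pair counting (ties count one half).
auc_pairs <- function(scores, positive) {
  sp <- scores[positive]
  sn <- scores[!positive]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments.
mw_exact_enum <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  combs <- utils::combn(length(pooled), n)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * length(b) / 2
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# A deterministic Gaussian-windowed sinusoid test signal.
gabor_atom <- function(freq, dur, fs = 2000, total = 0.3, amp = 1,
                       center = total / 2) {
  t <- seq(0, total, by = 1 / fs)
  amp * exp(-(t - center)^2 / (2 * (dur / 6)^2)) * sin(2 * pi * freq * (t - center))
}

# Shared tiny corpus for feature-direction checks (truth-segment features
# across the heart-rate ladder); cached per test run.
make_feature_corpus <- function(hr_levels = c(60, 120, 180), duration = 6,
                                snr_db = NULL, seed = 101) {
  feats <- lapply(hr_levels, function(hr) {
    rec <- generate_recording(duration, beat_config(hr = hr),
                              snr_db = snr_db, seed = seed + hr)
    fx <- segment_features(rec$signal, rec$annotations)
    fx$true_label <- rec$annotations$label
    fx
  })
  do.call(rbind, feats)
}
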