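#' Synthetic heart-beat configuration
#'
#' Parameterizes the sound model used to emulate stress-test
#' phonocardiograms.  Each heart sound is a superposition of
#' Gaussian-windowed sinusoids (Morlet-like transients) whose S-transform is
#' analytically predictable.  Defaults encode the physiological structure of
#' the two sounds: S1 is longer, lower-pitched and multi-component — two
#' temporally staggered narrowband tones at 35 and 65 Hz spanning ~115 ms;
#' S2 is shorter, higher-pitched and more click-like — two frequency-spread
#' components at 90 and 135 Hz overlapping within ~60 ms.
#' Systole occupies `systole_fraction` of the beat and, when left `NULL`,
#' grows linearly from 0.35 at 60 bpm toward 0.5 at 200 bpm: the
#' systole/diastole convergence that defeats interval-based S1/S2
#' classification under stress.  As HR rises the S2 component frequencies
#' and amplitudes soften proportionally to `hr_hf_coupling`, emulating the
#' gradual drop in S2 high-frequency content with heart rate.
#'
#' @param hr Heart rate in beats per minute, in [40, 220].
#' @param s1_components,s2_components `data.frame`s with columns `freq`
#'   (Hz), `dur` (total component duration in s, ±3 standard deviations of
#'   the Gaussian window), `amp` (relative amplitude) and `onset` (s,
#'   relative to the sound onset).
#' @param systole_fraction Fraction of the beat period from S1 onset to S2
#'   onset, in [0.2, 0.6], or `NULL` for the HR-dependent default.
#' @param jitter Coefficient of variation of per-beat timing, amplitude and
#'   frequency perturbations (0 disables all randomness in the beat shapes).
#' @param hr_hf_coupling Dimensionless slope of S2 softening with heart
#'   rate: S2 component frequencies and amplitudes are scaled linearly in
#'   HR from 1 at 60 bpm down to `1 - hr_hf_coupling` at 198 bpm.
#' @param fs Sampling rate of the generated audio, Hz.
#' @return An object of class `beat_config`.
#' @examples
#' beat_config(hr = 150)
#' @export
beat_config <- function(hr = 60,
                        s1_components = data.frame(
                          freq = c(35, 65), dur = c(0.08, 0.07),
                          amp = c(1, 0.85), onset = c(0, 0.045)),
                        s2_components = data.frame(
                          freq = c(90, 135), dur = c(0.055, 0.05),
                          amp = c(1, 0.8), onset = c(0, 0.01)),
                        systole_fraction = NULL,
                        jitter = 0.1,
                        hr_hf_coupling = 0.5,
                        fs = 2000) {
  if (!(hr >= 40 && hr <= 220))
    stop("`hr` must lie in [40, 220] bpm", call. = FALSE)
  for (comp in list(s1_components, s2_components)) {
    stopifnot(is.data.frame(comp),
              all(c("freq", "dur", "amp", "onset") %in% names(comp)))
    if (any(comp$dur <= 0) || any(comp$freq <= 0) || any(comp$amp <= 0))
      stop("component freq/dur/amp must all be positive", call. = FALSE)
  }
  if (is.null(systole_fraction))
    systole_fraction <- 0.35 + 0.15 * min(1, max(0, (hr - 60) / 140))
  if (!(systole_fraction >= 0.2 && systole_fraction <= 0.6))
    stop("`systole_fraction` must lie in [0.2, 0.6]", call. = FALSE)
  if (jitter < 0 || hr_hf_coupling < 0)
    stop("`jitter` and `hr_hf_coupling` must be nonnegative", call. = FALSE)
  structure(list(hr = hr,
                 s1_components = s1_components,
                 s2_components = s2_components,
                 systole_fraction = systole_fraction,
                 jitter = jitter,
                 hr_hf_coupling = hr_hf_coupling,
                 fs = fs),
            class = "beat_config")
}

#' @export
print.beat_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<beat_config> %g bpm, systole fraction %.3f, jitter %g, ",
    "HR-HF coupling %g, fs %g Hz\n  S1: %d components (%s Hz), ",
    "S2: %d components (%s Hz)\n"),
    x$hr, x$systole_fraction, x$jitter, x$hr_hf_coupling, x$fs,
    nrow(x$s1_components), paste(round(x$s1_components$freq), collapse = "/"),
    nrow(x$s2_components), paste(round(x$s2_components$freq), collapse = "/")))
  invisible(x)
}

# S2 softening factor: 1 at resting HR (60 bpm), falling linearly to
# 1 - hr_hf_coupling at 198 bpm.  The decline of S2 high-frequency content
# with heart rate is gradual across the whole stress range, so the coupling
# is linear in HR rather than switched on above a rate threshold.
s2_softening <- function(config, hr) {
  if (hr <= 60 || config$hr_hf_coupling == 0) return(1)
  max(0.4, 1 - config$hr_hf_coupling * min(1, (hr - 60) / 138))
}

# Render one sound (component superposition) into a waveform buffer.
# Returns the (onset, offset) actually occupied, in seconds from t0.
render_sound <- function(buf, fs, t0, comps) {
  t <- (seq_along(buf) - 1L) / fs
  for (i in seq_len(nrow(comps))) {
    sdev <- comps$dur[i] / 6
    tc <- t0 + comps$onset[i] + comps$dur[i] / 2
    buf <- buf + comps$amp[i] * exp(-(t - tc)^2 / (2 * sdev^2)) *
      sin(2 * pi * comps$freq[i] * (t - tc))
  }
  list(buf = buf,
       onset = t0 + min(comps$onset),
       offset = t0 + max(comps$onset + comps$dur))
}

# Per-beat multiplicative jitter on a component table: frequencies,
# amplitudes, durations and relative onsets all vary with the same
# coefficient of variation, as beat-to-beat sound morphology does.
jitter_components <- function(comps, jitter) {
  if (jitter == 0) return(comps)
  n <- nrow(comps)
  comps$freq <- comps$freq * (1 + jitter * stats::rnorm(n))
  comps$amp <- comps$amp * pmax(0.2, 1 + jitter * stats::rnorm(n))
  comps$dur <- comps$dur * pmax(0.5, 1 + jitter * stats::rnorm(n))
  comps$onset <- pmax(0, comps$onset + jitter * comps$dur * stats::rnorm(n))
  comps$freq <- pmax(10, comps$freq)
  comps
}

#' Generate a single synthetic heart beat
#'
#' Renders one beat period: S1 near the beat start, S2 at
#' `systole_fraction` of the period, each a superposition of
#' Gaussian-windowed sinusoids, with per-beat jitter on timings, amplitudes
#' and frequencies and HR-dependent S2 softening (see [beat_config()]).
#' Draws from R's RNG only when `jitter > 0`; with `jitter = 0` the output
#' is a pure function of the configuration.
#'
#' @param config A [beat_config()].
#' @return A list: `signal` (a [time_signal()] of one beat period) and
#'   `annotations` (two-row segment `data.frame` labelled S1, S2).
#' @export
generate_beat <- function(config) {
  stopifnot(inherits(config, "beat_config"))
  fs <- config$fs
  period <- 60 / config$hr
  n <- round(period * fs)
  buf <- numeric(n)

  s1 <- jitter_components(config$s1_components, config$jitter)
  s2 <- jitter_components(config$s2_components, config$jitter)
  soft <- s2_softening(config, config$hr)
  s2$freq <- s2$freq * soft
  s2$amp <- s2$amp * soft

  s1_t0 <- 0.02
  # feasibility is a property of the nominal configuration
  nom_s1_end <- s1_t0 + max(config$s1_components$onset +
                              config$s1_components$dur)
  nom_s2_t0 <- s1_t0 + config$systole_fraction * period
  nom_s2_end <- nom_s2_t0 + max(config$s2_components$onset +
                                  config$s2_components$dur)
  if (nom_s1_end >= nom_s2_t0)
    stop("configuration error: S1 and S2 overlap at ", config$hr, " bpm",
         call. = FALSE)
  if (nom_s2_end >= period)
    stop("configuration error: S2 spills past the beat period at ",
         config$hr, " bpm", call. = FALSE)

  sf <- config$systole_fraction
  if (config$jitter > 0)
    sf <- sf * (1 + 0.5 * config$jitter * stats::rnorm(1))
  s1_span <- max(s1$onset + s1$dur)
  s2_span <- max(s2$onset + s2$dur)
  # clamp the jittered systole so per-beat draws stay feasible
  s2_t0 <- s1_t0 + sf * period
  s2_t0 <- min(max(s2_t0, s1_t0 + s1_span + 0.01),
               period - s2_span - 1 / fs)

  r1 <- render_sound(buf, fs, s1_t0, s1)
  r2 <- render_sound(r1$buf, fs, s2_t0, s2)
  ann <- data.frame(onset_s = c(r1$onset, r2$onset),
                    offset_s = c(r1$offset, r2$offset),
                    label = c("S1", "S2"),
                    stringsAsFactors = FALSE)
  list(signal = time_signal(r2$buf, fs), annotations = ann)
}

#' Generate an annotated synthetic stress-test recording
#'
#' Concatenates beats at the configured heart rate to fill `duration`
#' seconds (any sub-beat remainder is silent), optionally adds white
#' Gaussian noise at a prescribed signal-to-noise ratio, and returns the
#' waveform together with ground-truth onset/offset/label annotations that
#' stand in for an ECG-derived gold standard.  Output is a deterministic
#' function of `(config, snr_db, seed)`.
#'
#' @param duration Recording length in seconds (default 10, one stress-test
#'   workload recording); must cover at least one beat period.
#' @param config A [beat_config()].
#' @param snr_db Target signal-to-noise ratio in dB (noise power measured
#'   against the mean power of the clean waveform), or `NULL` for no noise.
#' @param seed Integer seed; all beat jitter and noise derive from it.
#' @return An object of class `pcg_recording`: list with `signal`
#'   ([time_signal()]), `annotations` (segment `data.frame` alternating
#'   S1/S2), `config`, `snr_db`, `seed`.
#' @examples
#' rec <- generate_recording(duration = 5, config = beat_config(hr = 90),
#'                           snr_db = 10, seed = 42)
#' rec
#' @export
generate_recording <- function(duration = 10, config = beat_config(),
                               snr_db = NULL, seed = 1) {
  stopifnot(inherits(config, "beat_config"))
  period <- 60 / config$hr
  if (duration < period)
    stop("`duration` must cover at least one beat period", call. = FALSE)
  fs <- config$fs
  with_seed(seed, {
    beat_n <- round(period * fs)
    total_n <- round(duration * fs)
    n_beats <- total_n %/% beat_n
    samples <- numeric(total_n)
    ann <- vector("list", n_beats)
    for (b in seq_len(n_beats)) {
      beat <- generate_beat(config)
      i0 <- (b - 1L) * beat_n
      samples[i0 + seq_len(beat_n)] <- beat$signal$samples
      a <- beat$annotations
      a$onset_s <- a$onset_s + i0 / fs
      a$offset_s <- a$offset_s + i0 / fs
      ann[[b]] <- a
    }
    annotations <- do.call(rbind, ann)
    measured_snr <- NA_real_
    if (!is.null(snr_db)) {
      p_sig <- mean(samples^2)
      sigma <- sqrt(p_sig / 10^(snr_db / 10))
      samples <- samples + stats::rnorm(total_n, sd = sigma)
    }
    structure(list(signal = time_signal(samples, fs),
                   annotations = annotations,
                   config = config,
                   snr_db = if (is.null(snr_db)) NA_real_ else snr_db,
                   seed = seed),
              class = "pcg_recording")
  })
}

#' @export
print.pcg_recording <- function(x, ...) {
  cat(sprintf(
    "<pcg_recording> %.1f s @ %g Hz, %g bpm, %d annotated sounds, SNR %s, seed %d\n",
    signal_duration(x$signal), x$signal$fs, x$config$hr,
    nrow(x$annotations),
    if (is.na(x$snr_db)) "clean" else paste0(x$snr_db, " dB"), x$seed))
  invisible(x)
}

#' Write a synthetic recording to disk
#'
#' Writes the audio as WAV and the ground-truth annotations as a sidecar
#' CSV or JSON in the same schema the segmentation module emits.
#'
#' @param rec A [generate_recording()] result.
#' @param wav_path Output WAV path.
#' @param annotations_path Output annotation path (`.csv` or `.json`);
#'   default replaces the WAV extension with `.csv`.
#' @param bits WAV bit depth (see [write_wav()]).
#' @return `wav_path`, invisibly.
#' @export
write_recording <- function(rec, wav_path,
                            annotations_path = sub("\\.wav$", ".csv",
                                                   wav_path,
                                                   ignore.case = TRUE),
                            bits = 16) {
  stopifnot(inherits(rec, "pcg_recording"))
  peak <- max(abs(rec$signal$samples))
  x <- rec$signal
  if (bits == 16 && peak > 0) x <- time_signal(x$samples / peak * 0.99, x$fs)
  write_wav(x, wav_path, bits = bits)
  write_segments(rec$annotations, annotations_path)
  invisible(wav_path)
}
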