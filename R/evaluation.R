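#' Area under the ROC curve by the rank statistic
#'
#' Computes AUC as the normalized Mann–Whitney U statistic with mid-ranks
#' for ties: the probability that a randomly chosen positive-class score
#' exceeds a randomly chosen negative-class score (ties counting 1/2).
#' The returned value is oriented so that it is always \eqn{\ge 0.5}; the
#' `"direction"` attribute is `1` when positives score higher and `-1` when
#' the raw AUC was below 0.5, and the `"auc_raw"` attribute keeps the
#' unoriented value.
#'
#' @param scores Numeric feature values.
#' @param labels Class labels, same length: logical, 0/1, or `"S1"`/`"S2"`
#'   (S2 is the positive class).
#' @return Oriented AUC in [0.5, 1] with attributes `direction`, `auc_raw`.
#' @examples
#' roc_auc(c(1, 3, 2, 4), c(0, 0, 1, 1))
#' @export
roc_auc <- function(scores, labels) {
  pos <- as_positive(labels)
  if (length(scores) != length(pos))
    stop("`scores` and `labels` lengths differ", call. = FALSE)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  raw <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(max(raw, 1 - raw),
            direction = if (raw >= 0.5) 1 else -1,
            auc_raw = raw)
}

as_positive <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    if (!all(labels %in% c("S1", "S2")))
      stop("character labels must be 'S1'/'S2'", call. = FALSE)
    labels == "S2"
  } else {
    as.logical(labels)
  }
}

#' Two-sided Mann–Whitney (Wilcoxon rank-sum) p-value
#'
#' Thin wrapper over [stats::wilcox.test()]: exact enumeration for small
#' tie-free groups (both below 20), otherwise the normal approximation with
#' tie correction and continuity correction.
#'
#' @param group_a,group_b Nonempty numeric vectors.
#' @return Two-sided p-value in (0, 1].
#' @examples
#' mann_whitney(c(1, 2, 3), c(10, 11, 12))  # exact: 0.1
#' @export
mann_whitney <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be nonempty", call. = FALSE)
  small <- length(group_a) < 20L && length(group_b) < 20L
  ties <- anyDuplicated(c(group_a, group_b)) > 0L
  p <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = small && !ties,
                       correct = TRUE)$p.value)
  min(max(p, .Machine$double.xmin), 1)
}

#' Match detected segments to ground truth
#'
#' A detection matches a true sound when their intervals overlap by at
#' least `min_overlap` of the shorter interval; matches are assigned
#' greedily by decreasing overlap, one-to-one.  Unmatched detections are
#' false positives; unmatched true sounds are misses.
#'
#' @param detected,truth Segment `data.frame`s (`onset_s`, `offset_s`,
#'   `label`); `truth` carries the true labels.
#' @param min_overlap Overlap fraction threshold (default 0.5).
#' @return A list: `matched` (the detected rows that matched, with
#'   `true_label` and `truth_row` columns), `sensitivity`
#'   (matched / true sounds) and `false_positive_rate`
#'   (unmatched detections / detections; 0 when there are none).
#' @export
match_segments <- function(detected, truth, min_overlap = 0.5) {
  stopifnot(is.data.frame(detected), is.data.frame(truth))
  nd <- nrow(detected)
  nt <- nrow(truth)
  if (nd == 0L || nt == 0L) {
    m <- cbind(detected[integer(0), , drop = FALSE],
               true_label = character(0), truth_row = integer(0))
    return(list(matched = m,
                sensitivity = if (nt == 0L) NA_real_ else 0,
                false_positive_rate = if (nd == 0L) 0 else 1))
  }
  ov <- matrix(0, nd, nt)
  for (i in seq_len(nd)) {
    lo <- pmax(detected$onset_s[i], truth$onset_s)
    hi <- pmin(detected$offset_s[i], truth$offset_s)
    shorter <- pmin(detected$offset_s[i] - detected$onset_s[i],
                    truth$offset_s - truth$onset_s)
    ov[i, ] <- pmax(hi - lo, 0) / pmax(shorter, .Machine$double.eps)
  }
  pairs <- which(ov >= min_overlap, arr.ind = TRUE)
  res <- integer(0)
  if (nrow(pairs) > 0L) {
    ord <- order(ov[pairs], decreasing = TRUE)
    used_d <- logical(nd)
    used_t <- logical(nt)
    keep <- matrix(0L, 0L, 2L)
    for (k in ord) {
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      if (!used_d[i] && !used_t[j]) {
        keep <- rbind(keep, c(i, j))
        used_d[i] <- TRUE
        used_t[j] <- TRUE
      }
    }
    keep <- keep[order(keep[, 1L]), , drop = FALSE]
    matched <- detected[keep[, 1L], , drop = FALSE]
    matched$true_label <- truth$label[keep[, 2L]]
    matched$truth_row <- keep[, 2L]
  } else {
    matched <- cbind(detected[integer(0), , drop = FALSE],
                     true_label = character(0), truth_row = integer(0))
  }
  list(matched = matched,
       sensitivity = nrow(matched) / nt,
       false_positive_rate = (nd - nrow(matched)) / nd)
}

# Derive per-"subject" configurations from a base config: component
# frequencies and amplitudes get a fixed multiplicative offset per
# subject, emulating inter-subject variability in sound morphology.
subject_configs <- function(base, n_subjects, seed) {
  lapply(seq_len(n_subjects), function(s) {
    with_seed(seed * 1000L + s, {
      cfg <- base
      for (fld in c("s1_components", "s2_components")) {
        comp <- cfg[[fld]]
        comp$freq <- comp$freq * stats::runif(nrow(comp), 0.92, 1.08)
        comp$amp <- comp$amp * stats::runif(nrow(comp), 0.85, 1.15)
        cfg[[fld]] <- comp
      }
      cfg
    })
  })
}

set_config_hr <- function(config, hr) {
  beat_config(hr = hr,
              s1_components = config$s1_components,
              s2_components = config$s2_components,
              systole_fraction = NULL,
              jitter = config$jitter,
              hr_hf_coupling = config$hr_hf_coupling,
              fs = config$fs)
}

# Segment (or take truth), extract features, and tag with true labels.
# Returns NULL when matching finds fewer than one sound.
recording_features <- function(rec, use_truth = FALSE, ...) {
  truth <- rec$annotations
  if (use_truth) {
    segs <- truth
    feats <- segment_features(rec$signal, segs, ...)
    feats$true_label <- truth$label
    return(list(features = feats, sensitivity = 1, false_positive_rate = 0))
  }
  det <- segment_sounds(rec$signal)
  m <- match_segments(det, truth)
  if (nrow(m$matched) == 0L)
    return(list(features = NULL, sensitivity = m$sensitivity,
                false_positive_rate = m$false_positive_rate))
  feats <- segment_features(rec$signal, m$matched[, c("onset_s", "offset_s",
                                                      "label")], ...)
  feats$true_label <- m$matched$true_label
  list(features = feats, sensitivity = m$sensitivity,
       false_positive_rate = m$false_positive_rate)
}

feature_cols <- c("alpha_opt", "beta", "gamma", "hfs")

feature_stats <- function(feats) {
  s1 <- feats$true_label == "S1"
  out <- lapply(feature_cols, function(fc) {
    v <- feats[[fc]]
    if (sum(s1) < 2L || sum(!s1) < 2L)
      return(data.frame(feature = fc, auc = NA_real_, mean_s1 = NA_real_,
                        sd_s1 = NA_real_, mean_s2 = NA_real_,
                        sd_s2 = NA_real_, p_value = NA_real_))
    data.frame(feature = fc,
               auc = as.numeric(roc_auc(v, feats$true_label)),
               mean_s1 = mean(v[s1]), sd_s1 = stats::sd(v[s1]),
               mean_s2 = mean(v[!s1]), sd_s2 = stats::sd(v[!s1]),
               p_value = mann_whitney(v[s1], v[!s1]))
  })
  do.call(rbind, out)
}

#' Run the desk-scale evaluation benchmark
#'
#' Generates a synthetic stress-test corpus ("subjects" are perturbed
#' generator configurations, each recorded across a heart-rate ladder),
#' segments every recording, matches detections to ground truth, extracts
#' all per-segment features, and reports:
#' \itemize{
#'   \item pooled per-feature AUC, class means/SDs and Mann–Whitney
#'     p-values, plus per-subject AUCs;
#'   \item an AUC-per-SNR noise-robustness table over `snr_levels`;
#'   \item the mean/SD of the per-beat high-frequency-content ratio
#'     S2/S1 across `hf_hr_levels` (computed on ground-truth segments);
#'   \item aggregate segmentation sensitivity and false-positive rate on
#'     the clean corpus.
#' }
#' Everything is a pure function of `(settings, seed)`.
#'
#' @param config Base [beat_config()] (its `hr` is overridden per level).
#' @param hr_levels Heart-rate ladder in bpm.
#' @param n_per_hr Recordings per subject per HR level.
#' @param n_subjects Number of synthetic subjects.
#' @param duration Recording length in seconds.
#' @param snr_levels SNR levels (dB) for the noise-robustness table;
#'   `NULL` skips it.
#' @param hf_hr_levels HR levels for the S2/S1 frequency-ratio curve;
#'   `NULL` skips it.
#' @param use_truth Extract features on ground-truth segments instead of
#'   detections (skips the segmentation stage; useful for feature studies).
#' @param seed Integer master seed.
#' @param verbose Print per-stage progress.
#' @return An object of class `pcg_benchmark`.
#' @export
run_benchmark <- function(config = beat_config(),
                          hr_levels = c(60, 90, 120, 150, 180, 198),
                          n_per_hr = 1, n_subjects = 2, duration = 10,
                          snr_levels = c(10, 5, 0),
                          hf_hr_levels = c(60, 120, 180),
                          use_truth = FALSE, seed = 1, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  configs <- subject_configs(config, n_subjects, seed)

  run_corpus <- function(snr_db) {
    feats <- list()
    sens <- fpr <- numeric(0)
    per_subject <- vector("list", n_subjects)
    k <- 0L
    for (s in seq_len(n_subjects)) {
      sub_feats <- list()
      for (hr in hr_levels) {
        cfg <- set_config_hr(configs[[s]], hr)
        for (r in seq_len(n_per_hr)) {
          k <- k + 1L
          rec_seed <- seed * 100000L + s * 10000L + round(hr) * 10L + r
          rec <- generate_recording(duration, cfg, snr_db = snr_db,
                                    seed = rec_seed)
          rf <- recording_features(rec, use_truth = use_truth)
          sens <- c(sens, rf$sensitivity)
          fpr <- c(fpr, rf$false_positive_rate)
          if (!is.null(rf$features)) {
            rf$features$subject <- s
            rf$features$hr <- hr
            feats[[length(feats) + 1L]] <- rf$features
            sub_feats[[length(sub_feats) + 1L]] <- rf$features
          }
        }
      }
      per_subject[[s]] <- if (length(sub_feats)) do.call(rbind, sub_feats)
                          else NULL
    }
    list(features = if (length(feats)) do.call(rbind, feats) else NULL,
         per_subject = per_subject,
         sensitivity = mean(sens, na.rm = TRUE),
         false_positive_rate = mean(fpr, na.rm = TRUE))
  }

  say("clean corpus (%d subjects x %d HR levels x %d)...",
      n_subjects, length(hr_levels), n_per_hr)
  clean <- run_corpus(NULL)
  if (is.null(clean$features))
    stop("benchmark degenerate: no segment of either class was recovered",
         call. = FALSE)
  per_feature <- feature_stats(clean$features)
  per_subject_auc <- do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    f <- clean$per_subject[[s]]
    st <- if (is.null(f)) NULL else feature_stats(f)
    data.frame(subject = s, feature = feature_cols,
               auc = if (is.null(st)) NA_real_ else st$auc)
  }))

  noise_table <- NULL
  if (!is.null(snr_levels)) {
    rows <- list(data.frame(snr_db = Inf,
                            t(stats::setNames(per_feature$auc,
                                              per_feature$feature))))
    for (snr in snr_levels) {
      say("noise corpus at %g dB...", snr)
      noisy <- run_corpus(snr)
      st <- if (is.null(noisy$features)) NULL else
        feature_stats(noisy$features)
      rows[[length(rows) + 1L]] <-
        data.frame(snr_db = snr,
                   t(stats::setNames(if (is.null(st)) rep(NA_real_, 4)
                                     else st$auc, feature_cols)))
    }
    noise_table <- do.call(rbind, rows)
  }

  hf_ratio <- NULL
  if (!is.null(hf_hr_levels)) {
    say("HR / high-frequency-content sweep...")
    rows <- lapply(hf_hr_levels, function(hr) {
      ratios <- numeric(0)
      for (s in seq_len(n_subjects)) {
        cfg <- set_config_hr(configs[[s]], hr)
        for (r in 1:3) {
          rec <- generate_recording(duration, cfg, snr_db = NULL,
                                    seed = seed * 100000L + s * 10000L +
                                      round(hr) * 10L + 900L + r)
          x <- decimate_signal(rec$signal, 2000)
          a <- rec$annotations
          hf <- vapply(seq_len(nrow(a)), function(i) {
            mid <- (a$onset_s[i] + a$offset_s[i]) / 2
            half <- max(0.18, a$offset_s[i] - a$onset_s[i]) / 2
            hf_content(signal_slice(x, mid - half, mid + half),
                       target_fs = NULL)
          }, numeric(1))
          # per-recording ratio of class means: per-beat ratios are heavy-
          # tailed because the S1 denominator is a small jittered fraction
          m1 <- mean(hf[a$label == "S1"])
          m2 <- mean(hf[a$label == "S2"])
          if (m1 > 0) ratios <- c(ratios, m2 / m1)
        }
      }
      data.frame(hr = hr, mean_ratio = mean(ratios),
                 sd_ratio = stats::sd(ratios), n_recordings = length(ratios))
    })
    hf_ratio <- do.call(rbind, rows)
  }

  structure(list(per_feature = per_feature,
                 per_subject_auc = per_subject_auc,
                 noise_table = noise_table,
                 hf_ratio = hf_ratio,
                 segmentation = list(
                   sensitivity = clean$sensitivity,
                   false_positive_rate = clean$false_positive_rate),
                 features = clean$features,
                 settings = list(hr_levels = hr_levels, n_per_hr = n_per_hr,
                                 n_subjects = n_subjects,
                                 duration = duration,
                                 snr_levels = snr_levels,
                                 hf_hr_levels = hf_hr_levels,
                                 use_truth = use_truth, seed = seed)),
            class = "pcg_benchmark")
}

#' @export
print.pcg_benchmark <- function(x, ...) {
  cat("<pcg_benchmark>\n")
  cat(sprintf("  corpus: %d subjects x HR {%s} bpm x %d rec x %.0f s (seed %d)\n",
              x$settings$n_subjects,
              paste(x$settings$hr_levels, collapse = ", "),
              x$settings$n_per_hr, x$settings$duration, x$settings$seed))
  if (!x$settings$use_truth)
    cat(sprintf("  segmentation: sensitivity %.3f, false-positive rate %.3f\n",
                x$segmentation$sensitivity,
                x$segmentation$false_positive_rate))
  cat("  per-feature discrimination (pooled):\n")
  pf <- x$per_feature
  for (i in seq_len(nrow(pf)))
    cat(sprintf("    %-9s AUC %.3f | S1 %.3g +/- %.2g | S2 %.3g +/- %.2g | p %.2g\n",
                pf$feature[i], pf$auc[i], pf$mean_s1[i], pf$sd_s1[i],
                pf$mean_s2[i], pf$sd_s2[i], pf$p_value[i]))
  if (!is.null(x$noise_table)) {
    cat("  AUC by SNR (dB):\n")
    print(x$noise_table, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$hf_ratio)) {
    cat("  high-frequency-content ratio S2/S1 by HR:\n")
    print(x$hf_ratio, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
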