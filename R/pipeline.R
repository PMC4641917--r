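# Physiological analysis pipeline: MBLL inversion, artifact preprocessing,
# trial extraction, slope features, LDA cross-validation, average response.

#' Hemodynamic time series container
#'
#' @param hbo,hbr samples x channels matrices (micromolar).
#' @param fs sampling rate, Hz.
#' @param t optional time axis, seconds (default `(0:(n-1))/fs`).
#' @return a `hemo_series` list.
#' @export
hemo_series <- function(hbo, hbr, fs, t = NULL) {
  hbo <- as.matrix(hbo); hbr <- as.matrix(hbr)
  if (!all(dim(hbo) == dim(hbr))) stop_input("hbo and hbr must have equal dimensions")
  check_scalar(fs, "fs", lower = 0, allow_equal_lower = FALSE)
  if (is.null(t)) t <- (seq_len(nrow(hbo)) - 1) / fs
  structure(list(hbo = hbo, hbr = hbr, fs = fs, t = t), class = "hemo_series")
}

#' Optical densities from raw intensities
#'
#' `dOD(t) = -log10(I(t) / I_baseline)`, with the baseline taken as the mean
#' intensity over the first `baseline_s` seconds of the recording.
#'
#' @param intensity positive intensity samples (any proportional unit —
#'   common gains cancel in the ratio).
#' @param fs sampling rate, Hz.
#' @param baseline_s baseline window, seconds (default 5).
#' @return dOD vector.
#' @export
od_from_intensity <- function(intensity, fs, baseline_s = 5) {
  if (any(intensity <= 0)) stop_input("intensities must be positive")
  n0 <- max(1L, floor(baseline_s * fs))
  i0 <- mean(intensity[seq_len(min(n0, length(intensity)))])
  -log10(intensity / i0)
}

#' Invert the modified Beer-Lambert law
#'
#' Solves the per-sample 2x2 extinction system for (dHbO, dHbR) from the
#' optical-density changes at the two wavelengths; the exact inverse of
#' [mbll_forward()].
#'
#' @param dod750,dod850 optical-density changes at 750 and 850 nm (vectors
#'   or matrices of equal shape).
#' @param constants an [optical_constants()] object.
#' @return a list with `hbo` and `hbr` (micromolar, same shape as input).
#' @export
mbll_invert <- function(dod750, dod850, constants = optical_constants()) {
  e <- constants$extinction * constants$distance * constants$dpf
  inv <- solve(e)
  hbo <- inv["HbO", "750"] * dod750 + inv["HbO", "850"] * dod850
  hbr <- inv["HbR", "750"] * dod750 + inv["HbR", "850"] * dod850
  list(hbo = hbo, hbr = hbr)
}

#' Convert a raw recording into a hemodynamic time series
#'
#' Demultiplexes the recording's per-channel-wavelength streams, dequantizes
#' the ADC codes, forms optical densities against the early-recording
#' baseline, and inverts the MBLL. Samples of the two wavelengths of one
#' channel are taken in adjacent TDM slots and are aligned to a common
#' per-frame time axis.
#'
#' @param recording a [simulate_acquisition()] result (or a parsed packet
#'   data frame with an attached `config` attribute).
#' @param constants an [optical_constants()] object.
#' @param baseline_s baseline window for the dOD reference, seconds.
#' @return a `hemo_series`.
#' @export
recording_to_series <- function(recording, constants = optical_constants(),
                                baseline_s = 5) {
  adc <- attr(recording, "config")$adc
  if (is.null(adc)) adc <- adc_config()
  fs <- attr(recording, "sample_rate")
  if (is.null(fs)) {
    stop_input("recording carries no sample_rate attribute")
  }
  chans <- sort(unique(recording$channel))
  n_frames <- min(vapply(chans, function(ch)
    sum(recording$channel == ch & recording$wavelength == 750), integer(1)))
  if (n_frames < 1L) stop_input("recording is empty")
  hbo <- matrix(NA_real_, n_frames, length(chans))
  hbr <- matrix(NA_real_, n_frames, length(chans))
  t_axis <- NULL
  for (j in seq_along(chans)) {
    ch <- chans[j]
    i750 <- dequantize(head(recording$adc_code[
      recording$channel == ch & recording$wavelength == 750], n_frames), adc)
    i850 <- dequantize(head(recording$adc_code[
      recording$channel == ch & recording$wavelength == 850], n_frames), adc)
    dod750 <- od_from_intensity(i750, fs, baseline_s)
    dod850 <- od_from_intensity(i850, fs, baseline_s)
    conc <- mbll_invert(dod750, dod850, constants)
    hbo[, j] <- conc$hbo
    hbr[, j] <- conc$hbr
    if (is.null(t_axis)) {
      t_axis <- head(recording$timestamp[
        recording$channel == ch & recording$wavelength == 750], n_frames)
    }
  }
  hemo_series(hbo, hbr, fs, t = t_axis)
}

#' Piecewise linear detrending in fixed windows
#'
#' Splits the series into consecutive non-overlapping windows of
#' `window_s` seconds and subtracts the least-squares line within each;
#' a trailing partial window is detrended the same way.
#'
#' @param x numeric vector or samples x channels matrix.
#' @param fs sampling rate, Hz.
#' @param window_s window length, seconds (default 300).
#' @return detrended data, same shape as `x`.
#' @export
detrend_windows <- function(x, fs, window_s = 300) {
  if (length(x) == 0L) stop_input("empty input")
  check_scalar(window_s, "window_s", lower = 0, allow_equal_lower = FALSE)
  if (is.matrix(x)) return(apply(x, 2, detrend_windows, fs = fs, window_s = window_s))
  n <- length(x)
  w <- max(2L, round(window_s * fs))
  out <- numeric(n)
  start <- 1L
  while (start <= n) {
    idx <- start:min(start + w - 1L, n)
    if (length(idx) < 2L) {
      out[idx] <- 0
    } else {
      tt <- seq_along(idx)
      fit <- lm.fit(cbind(1, tt), x[idx])
      out[idx] <- fit$residuals
    }
    start <- start + w
  }
  out
}

#' Subtract a centered moving average
#'
#' `x'(t) = x(t) - mean(x over [t - h, t + h])` with `h = half_window_s`;
#' the averaging window includes the current sample and is truncated at the
#' series edges.
#'
#' @param x numeric vector or samples x channels matrix.
#' @param fs sampling rate, Hz.
#' @param half_window_s half window, seconds (default 30).
#' @return high-passed data, same shape as `x`.
#' @export
subtract_moving_average <- function(x, fs, half_window_s = 30) {
  if (length(x) == 0L) stop_input("empty input")
  check_scalar(half_window_s, "half_window_s", lower = 0, allow_equal_lower = FALSE)
  if (is.matrix(x)) {
    return(apply(x, 2, subtract_moving_average, fs = fs,
                 half_window_s = half_window_s))
  }
  n <- length(x)
  h <- round(half_window_s * fs)
  ma <- vapply(seq_len(n), function(i)
    mean(x[max(1L, i - h):min(n, i + h)]), numeric(1))
  x - ma
}

#' Zero-phase elliptic low-pass filter
#'
#' Order-6 elliptic IIR low-pass (0.5 dB passband ripple, 40 dB stopband
#' attenuation by default) applied forward-backward so trial windows are not
#' shifted by group delay. The default 0.5 Hz cutoff removes the cardiac
#' pulse band while preserving the slow hemodynamic response.
#'
#' @param x numeric vector or samples x channels matrix.
#' @param fs sampling rate, Hz; must exceed `2 * fc`.
#' @param order filter order (default 6).
#' @param fc cutoff frequency, Hz (default 0.5).
#' @param rp passband ripple, dB (default 0.5).
#' @param rs stopband attenuation, dB (default 40).
#' @return filtered data, same shape as `x`.
#' @export
lowpass <- function(x, fs, order = 6L, fc = 0.5, rp = 0.5, rs = 40) {
  if (fs <= 2 * fc) {
    stop_input("fs = %g Hz must exceed twice the cutoff (%g Hz)", fs, fc)
  }
  flt <- signal::ellip(order, rp, rs, fc / (fs / 2))
  if (is.matrix(x)) return(apply(x, 2, function(col) signal::filtfilt(flt, col)))
  signal::filtfilt(flt, x)
}

#' Standard preprocessing chain
#'
#' Applies, in order: windowed linear detrending, moving-average
#' subtraction, and the zero-phase elliptic low-pass, to both chromophores
#' of a [hemo_series()].
#'
#' @param series a `hemo_series`.
#' @param detrend_window_s detrending window, seconds (default 300).
#' @param ma_half_window_s moving-average half window, seconds (default 30).
#' @param lp_fc low-pass cutoff, Hz (default 0.5).
#' @return the preprocessed `hemo_series`.
#' @export
preprocess_series <- function(series, detrend_window_s = 300,
                              ma_half_window_s = 30, lp_fc = 0.5) {
  stopifnot(inherits(series, "hemo_series"))
  tf <- function(m) {
    m <- detrend_windows(m, series$fs, detrend_window_s)
    m <- subtract_moving_average(m, series$fs, ma_half_window_s)
    lowpass(m, series$fs, fc = lp_fc)
  }
  hemo_series(tf(series$hbo), tf(series$hbr), series$fs, series$t)
}

#' Extract labeled trial windows
#'
#' Task windows are the 10 s starting 5 s after stimulus onset (so the
#' hemodynamic response has developed); pause windows are the last 10 s of
#' each 25-30 s pause (so hemoglobin levels have returned toward baseline).
#' Long-rest segments are never used. Windows that would run past the end of
#' the series are dropped with a warning.
#'
#' @param series a `hemo_series`.
#' @param protocol an [generate_protocol()] object.
#' @param task_offset_s delay of the task window after onset, seconds
#'   (default 5).
#' @param window_s window length, seconds (default 10).
#' @return a `trial_set` list: `trials` (list of samples x channels x 2
#'   arrays), `labels` (task/pause), `onsets` (window start, s), `fs`.
#' @export
extract_trials <- function(series, protocol, task_offset_s = 5, window_s = 10) {
  stopifnot(inherits(series, "hemo_series"),
            inherits(protocol, "experiment_protocol"))
  n_win <- round(window_s * series$fs)
  if (n_win < 2L) stop_input("trial window shorter than 2 samples")
  starts <- c(); labels <- c()
  for (i in seq_len(nrow(protocol))) {
    lab <- protocol$label[i]
    if (lab == "task") {
      starts <- c(starts, protocol$onset[i] + task_offset_s)
      labels <- c(labels, "task")
    } else if (lab == "pause") {
      starts <- c(starts, protocol$onset[i] + protocol$duration[i] - window_s)
      labels <- c(labels, "pause")
    }  # long_rest: excluded
  }
  trials <- list(); kept_labels <- c(); kept_onsets <- c(); dropped <- 0L
  for (k in seq_along(starts)) {
    i0 <- which(series$t >= starts[k])[1]
    if (is.na(i0) || i0 + n_win - 1L > length(series$t)) {
      dropped <- dropped + 1L
      next
    }
    idx <- i0:(i0 + n_win - 1L)
    arr <- array(c(series$hbo[idx, , drop = FALSE],
                   series$hbr[idx, , drop = FALSE]),
                 dim = c(n_win, ncol(series$hbo), 2),
                 dimnames = list(NULL, NULL, c("HbO", "HbR")))
    trials[[length(trials) + 1L]] <- arr
    kept_labels <- c(kept_labels, labels[k])
    kept_onsets <- c(kept_onsets, starts[k])
  }
  if (dropped > 0L) {
    warning(sprintf("%d trial window(s) exceeded the series end and were dropped",
                    dropped), call. = FALSE)
  }
  structure(list(trials = trials, labels = kept_labels, onsets = kept_onsets,
                 fs = series$fs, window_s = window_s),
            class = "trial_set")
}

# closed-form least-squares slope of y against time (seconds)
ls_slope <- function(y, fs) {
  t <- (seq_along(y) - 1) / fs
  sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
}

#' Per-trial slope features
#'
#' For each trial, channel and chromophore, the slope of the least-squares
#' line fitted to the window — the feature the single-trial classification
#' runs on.
#'
#' @param trial_set an [extract_trials()] result.
#' @return a `trial_features` data frame: one column per
#'   channel x chromophore (`slope_ch<i>_<HbO|HbR>`, micromolar/s), plus
#'   `label` and `onset`.
#' @export
slope_features <- function(trial_set) {
  stopifnot(inherits(trial_set, "trial_set"))
  if (length(trial_set$trials) == 0L) stop_input("trial set is empty")
  dims <- dim(trial_set$trials[[1]])
  if (dims[1] < 2L) stop_input("trial windows must have at least 2 samples")
  n_ch <- dims[2]
  feats <- t(vapply(trial_set$trials, function(arr) {
    as.numeric(vapply(c("HbO", "HbR"), function(chromo)
      vapply(seq_len(n_ch), function(ch)
        ls_slope(arr[, ch, chromo], trial_set$fs), numeric(1)),
      numeric(n_ch)))
  }, numeric(2 * n_ch)))
  colnames(feats) <- c(paste0("slope_ch", seq_len(n_ch), "_HbO"),
                       paste0("slope_ch", seq_len(n_ch), "_HbR"))
  out <- as.data.frame(feats)
  out$label <- trial_set$labels
  out$onset <- trial_set$onsets
  class(out) <- c("trial_features", "data.frame")
  out
}

# Pooled-covariance two-class LDA with a small ridge for numerical safety.
lda_train <- function(X, y) {
  classes <- sort(unique(y))
  stopifnot(length(classes) == 2L)
  X <- as.matrix(X)
  mu <- lapply(classes, function(cl) colMeans(X[y == cl, , drop = FALSE]))
  pool <- matrix(0, ncol(X), ncol(X))
  for (cl in classes) {
    Xc <- X[y == cl, , drop = FALSE]
    if (nrow(Xc) > 1L) {
      pool <- pool + cov(Xc) * (nrow(Xc) - 1L)
    }
  }
  pool <- pool / max(1L, nrow(X) - 2L)
  ridge <- 1e-8 * mean(diag(pool)) + 1e-12
  pool <- pool + diag(ridge, ncol(X))
  w <- solve(pool, mu[[2]] - mu[[1]])
  threshold <- as.numeric((mu[[1]] + mu[[2]]) %*% w) / 2  # equal priors
  list(w = w, threshold = threshold, classes = classes)
}

lda_predict <- function(model, X) {
  score <- as.numeric(as.matrix(X) %*% model$w)
  ifelse(score > model$threshold, model$classes[2], model$classes[1])
}

#' LDA classification with stratified k-fold cross-validation
#'
#' Classifies trials from their slope features with linear discriminant
#' analysis (pooled covariance, equal priors) under stratified k-fold
#' cross-validation, and tests the fold accuracies against the 0.5 chance
#' level of the balanced two-class problem with a one-sided t-test.
#'
#' @param features a [slope_features()] data frame (columns `slope_*` and
#'   `label`), or any data frame with feature columns plus `label`.
#' @param k number of folds (default 10).
#' @param seed RNG seed for the fold shuffle.
#' @return a `cv_result` list: `fold_accuracy`, `mean_accuracy`, `p_value`
#'   (one-sided vs 0.5), `k`, `n_trials`.
#' @export
lda_crossval <- function(features, k = 10L, seed = 0L) {
  y <- features$label
  if (length(unique(y)) < 2L) stop_input("need two classes to classify")
  X <- as.matrix(features[, grep("^slope_", names(features)), drop = FALSE])
  if (ncol(X) == 0L) {
    X <- as.matrix(features[, setdiff(names(features), c("label", "onset")),
                            drop = FALSE])
  }
  n <- nrow(X)
  if (n < k) stop_input("need at least k = %d trials, got %d", k, n)
  folds <- integer(n)
  with_local_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  acc <- vapply(seq_len(k), function(f) {
    test <- folds == f
    if (!any(test)) return(NA_real_)
    model <- lda_train(X[!test, , drop = FALSE], y[!test])
    mean(lda_predict(model, X[test, , drop = FALSE]) == y[test])
  }, numeric(1))
  acc <- acc[!is.na(acc)]
  m <- mean(acc)
  p <- if (sd(acc) == 0) {
    if (m > 0.5) 0 else 1
  } else {
    t.test(acc, mu = 0.5, alternative = "greater")$p.value
  }
  structure(list(fold_accuracy = acc, mean_accuracy = m, p_value = p,
                 k = k, n_trials = n),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("LDA %d-fold cross-validation on %d trials\n", x$k, x$n_trials))
  cat(sprintf("  mean accuracy %.3f (folds %s)\n", x$mean_accuracy,
              paste(sprintf("%.2f", x$fold_accuracy), collapse = " ")))
  cat(sprintf("  one-sided t-test vs chance 0.5: p = %.4g\n", x$p_value))
  invisible(x)
}

#' Average hemodynamic response across trials
#'
#' Sample-wise mean and standard error of the (baseline-referenced) response
#' across all trials of each condition, on a window around the event onset.
#' The baseline is the mean of the pre-onset part of the window.
#'
#' @param series a `hemo_series`.
#' @param protocol an [generate_protocol()] object.
#' @param window window around onset, seconds (default `c(-5, 25)`).
#' @param conditions event labels to average (default task and pause).
#' @return a list per condition, each with `t` (seconds relative to onset)
#'   and, per chromophore, `mean` and `se` matrices (time x channels);
#'   `n_trials` gives the number of trials averaged.
#' @export
average_response <- function(series, protocol, window = c(-5, 25),
                             conditions = c("task", "pause")) {
  stopifnot(inherits(series, "hemo_series"),
            inherits(protocol, "experiment_protocol"))
  n_pre <- round(-window[1] * series$fs)
  n_tot <- round((window[2] - window[1]) * series$fs)
  out <- list()
  for (cond in conditions) {
    onsets <- protocol$onset[protocol$label == cond]
    segs_hbo <- list(); segs_hbr <- list()
    for (on in onsets) {
      i_on <- which(series$t >= on)[1]
      i0 <- i_on - n_pre
      if (is.na(i_on) || i0 < 1L || i0 + n_tot - 1L > length(series$t)) next
      idx <- i0:(i0 + n_tot - 1L)
      base_idx <- idx[seq_len(max(1L, n_pre))]
      hbo <- sweep(series$hbo[idx, , drop = FALSE], 2,
                   colMeans(series$hbo[base_idx, , drop = FALSE]))
      hbr <- sweep(series$hbr[idx, , drop = FALSE], 2,
                   colMeans(series$hbr[base_idx, , drop = FALSE]))
      segs_hbo[[length(segs_hbo) + 1L]] <- hbo
      segs_hbr[[length(segs_hbr) + 1L]] <- hbr
    }
    if (length(segs_hbo) == 0L) stop_input("no complete trials for condition `%s`", cond)
    stack <- function(segs) {
      arr <- simplify2array(segs)  # time x ch x trial
      if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
      list(mean = apply(arr, c(1, 2), mean),
           se = apply(arr, c(1, 2), function(v)
             if (length(v) > 1L) sd(v) / sqrt(length(v)) else 0))
    }
    out[[cond]] <- c(
      list(t = window[1] + (seq_len(n_tot) - 1) / series$fs,
           n_trials = length(segs_hbo)),
      list(hbo = stack(segs_hbo), hbr = stack(segs_hbr)))
  }
  out
}

#' Run the full single-trial BCI pipeline
#'
#' From a raw recording (or an already-inverted `hemo_series`):
#' MBLL inversion, windowed detrending, moving-average subtraction,
#' zero-phase elliptic low-pass, trial extraction, slope features, and LDA
#' with stratified 10-fold cross-validation; also computes the average
#' hemodynamic response per condition.
#'
#' @param recording a [simulate_acquisition()] recording or a `hemo_series`.
#' @param protocol the experiment protocol the data was acquired under.
#' @param constants an [optical_constants()] object (ignored for a
#'   `hemo_series` input).
#' @param k cross-validation folds (default 10).
#' @param seed fold-shuffle seed.
#' @return a list: `series` (preprocessed), `trials`, `features`, `cv`
#'   (a `cv_result`), `avg` (average responses).
#' @export
run_bci_pipeline <- function(recording, protocol,
                             constants = optical_constants(),
                             k = 10L, seed = 0L) {
  series <- if (inherits(recording, "hemo_series")) {
    recording
  } else {
    recording_to_series(recording, constants)
  }
  pre <- preprocess_series(series)
  trials <- extract_trials(pre, protocol)
  features <- slope_features(trials)
  cv <- lda_crossval(features, k = k, seed = seed)
  avg <- average_response(pre, protocol)
  list(series = pre, trials = trials, features = features, cv = cv, avg = avg)
}
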