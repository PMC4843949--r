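#' Re-reference a recording to the common average
#'
#' Subtracts, at every sample, the mean across channels; channel offsets
#' common to all channels are removed and the output has zero mean over
#' channels at every sample.
#'
#' @param recording a `raw_recording`.
#' @return the re-referenced recording.
#' @export
rereference_common_average <- function(recording) {
  if (nrow(recording$data) < 2) {
    stop("common-average reference requires at least 2 channels")
  }
  recording$data <- sweep(recording$data, 2, colMeans(recording$data))
  recording
}

# zero-phase (forward-backward) Butterworth filtering of a channels x
# samples matrix; edge transients handled by odd-reflection padding
filtfilt_mat <- function(X, flt, npad = 2000) {
  npad <- min(npad, ncol(X) - 1)
  t(apply(X, 1, function(ch) {
    iir_filtfilt_cpp(ch, flt$b, flt$a, npad)
  }))
}

#' Apply the band-limiting filter chain
#'
#' Zero-phase forward-backward Butterworth filters: high-pass (order 4),
#' low-pass (order 4), then a band-stop notch (order 2 per band edge)
#' for line noise.
#'
#' @param recording a `raw_recording`.
#' @param highpass high-pass cutoff (Hz), default 0.5.
#' @param lowpass low-pass cutoff (Hz), default 70.
#' @param stopband two-element band-stop interval (Hz), default c(49, 50).
#' @return filtered recording.
#' @export
apply_filters <- function(recording, highpass = 0.5, lowpass = 70,
                          stopband = c(49, 50)) {
  fs <- recording$fs
  nyq <- fs / 2
  if (lowpass >= nyq || max(stopband) >= nyq) {
    stop("filter cutoff at or above the Nyquist frequency (", nyq, " Hz)")
  }
  X <- recording$data
  X <- filtfilt_mat(X, signal::butter(4, highpass / nyq, type = "high"))
  X <- filtfilt_mat(X, signal::butter(4, lowpass / nyq, type = "low"))
  X <- filtfilt_mat(X, signal::butter(2, stopband / nyq, type = "stop"))
  recording$data <- X
  recording$filters <- list(highpass = highpass, lowpass = lowpass,
                            stopband = stopband)
  recording
}

# Kaiser-windowed sinc polyphase rational resampler (zero-phase, edge
# reflection padding); p/q in lowest terms
resample_poly <- function(x, p, q, half_len = 10, beta = 8) {
  n <- length(x)
  N <- 2 * half_len * max(p, q) + 1
  fc <- 1 / (2 * max(p, q))
  k <- seq(-(N - 1) / 2, (N - 1) / 2)
  h <- ifelse(k == 0, 2 * fc, sin(2 * pi * fc * k) / (pi * k))
  w <- besselI(beta * sqrt(pmax(0, 1 - (2 * k / (N - 1))^2)), 0) /
    besselI(beta, 0)
  h <- h * w * p
  npad <- ceiling((N - 1) / 2 / p) + 4
  xp <- c(rev(x[2:(npad + 1)]), x, rev(x[(n - npad):(n - 1)]))
  nout <- floor(((n - 1) * p) / q) + 1
  fir_resample_cpp(xp, h, p, q, nout, npad * p)
}

#' Downsample a recording
#'
#' Polyphase rational-ratio resampling (Kaiser-windowed sinc, zero phase)
#' of every channel; event markers are remapped to the nearest new sample.
#' Anti-alias protection is expected from the preceding low-pass stage
#' (the polyphase filter adds its own).
#'
#' @param recording a `raw_recording`.
#' @param target target sampling rate (Hz), default 200.
#' @return downsampled recording.
#' @export
downsample_recording <- function(recording, target = 200) {
  fs <- recording$fs
  if (target > fs) stop("target rate exceeds the original sampling rate")
  if (target == fs) return(recording)
  frac <- .rational(target / fs)
  X <- t(apply(recording$data, 1, function(ch) {
    resample_poly(ch, frac[1], frac[2])
  }))
  recording$data <- X
  recording$fs <- target
  if (!is.null(recording$events)) {
    recording$events$sample <- pmin(ncol(X), pmax(1L,
      as.integer(round((recording$events$sample - 1) * target / fs) + 1L)))
  }
  recording
}

.rational <- function(x, max_den = 1000) {
  for (q in seq_len(max_den)) {
    p <- x * q
    if (abs(p - round(p)) < 1e-9) return(c(round(p), q))
  }
  stop("resampling ratio is not rational within tolerance")
}

#' Epoch a recording and baseline-correct
#'
#' Cuts peristimulus windows around each event marker and removes, per
#' trial and channel, the mean over the baseline window. Trials whose
#' window would extend beyond the recording are dropped with a warning.
#'
#' @param recording a `raw_recording` with events.
#' @param window_ms peristimulus window (ms), default c(-100, 300),
#'   inclusive at both ends.
#' @param baseline_ms baseline window (ms), default c(-100, 0).
#' @return object of class `epoched_data`: list with `data` (trials x
#'   channels x samples), `time_ms`, `conditions`, `rejected` (logical),
#'   `fs`, `labels`.
#' @export
epoch_and_baseline <- function(recording, window_ms = c(-100, 300),
                               baseline_ms = c(-100, 0)) {
  fs <- recording$fs
  rel <- seq(round(window_ms[1] * fs / 1000), round(window_ms[2] * fs / 1000))
  time_ms <- rel * 1000 / fs
  bl <- which(time_ms >= baseline_ms[1] & time_ms <= baseline_ms[2])
  n <- ncol(recording$data)
  ok <- recording$events$sample + min(rel) >= 1 &
    recording$events$sample + max(rel) <= n
  if (any(!ok)) {
    warning(sum(!ok), " trial(s) dropped: window outside the recording")
  }
  ev <- recording$events[ok, , drop = FALSE]
  nt <- nrow(ev)
  arr <- array(0, dim = c(nt, nrow(recording$data), length(rel)))
  for (i in seq_len(nt)) {
    seg <- recording$data[, ev$sample[i] + rel, drop = FALSE]
    arr[i, , ] <- seg - rowMeans(seg[, bl, drop = FALSE])
  }
  structure(list(data = arr, time_ms = time_ms,
                 conditions = ev$condition,
                 rejected = rep(FALSE, nt), fs = fs,
                 labels = recording$labels, group = recording$group,
                 subject = recording$subject),
            class = "epoched_data")
}

#' @export
print.epoched_data <- function(x, ...) {
  cat("Epoched data:", dim(x$data)[1], "trials x", dim(x$data)[2],
      "channels x", dim(x$data)[3], "samples (",
      min(x$time_ms), "to", max(x$time_ms), "ms );",
      sum(x$rejected), "rejected\n")
  invisible(x)
}

#' Remove ocular (blink) independent components
#'
#' Decomposes the data into `n_components` independent components
#' (symmetric FastICA), identifies components whose time course correlates
#' with a frontal blink template (FP1/FP2 average, band-limited to the
#' 0.5-4 Hz blink band) above `threshold` in absolute value, zeroes at
#' most `max_removed` of them (largest |r| first) and back-projects.
#'
#' @param x an `epoched_data` or `raw_recording` object.
#' @param n_components number of components (default 17).
#' @param max_removed maximum number of removed components (default 2).
#' @param threshold absolute correlation threshold (default 0.7).
#' @param seed seed for the (deterministic) ICA initialization.
#' @param gate when `TRUE` (default) the identified components are
#'   suppressed only where they are active (|s| above `gate_mad` robust
#'   SDs, dilated by `gate_pad_ms`); blinks are temporally sparse, so this
#'   removes their energy while sparing evoked variance that leaks into
#'   the component estimate. `FALSE` zeroes the whole component.
#' @param gate_mad activity threshold in MAD units (default 6; blink
#'   bursts exceed this by an order of magnitude, evoked leakage does
#'   not).
#' @param gate_pad_ms dilation of the activity mask (default 200 ms).
#' @return `x` with cleaned data and an `ocular_report` element: data.frame
#'   of per-component blink correlation and removal flag.
#' @export
remove_ocular_components <- function(x, n_components = 17, max_removed = 2,
                                     threshold = 0.7, seed = 1,
                                     gate = TRUE, gate_mad = 6,
                                     gate_pad_ms = 200) {
  epoched <- inherits(x, "epoched_data")
  if (epoched) {
    d <- dim(x$data)
    X <- matrix(aperm(x$data, c(2, 3, 1)), d[2], d[1] * d[3])
  } else {
    X <- x$data
  }
  if (n_components > nrow(X)) {
    stop("n_components exceeds the channel count")
  }
  dec <- tryCatch(fastica_decompose(X, n_components, seed = seed),
                  error = function(e) {
                    stop("ICA decomposition failed: ",
                         conditionMessage(e))
                  })
  fs <- x$fs
  fp <- which(toupper(if (epoched) x$labels else x$labels) %in%
                c("FP1", "FP2"))
  if (length(fp) == 0) stop("no frontal (FP1/FP2) channels for template")
  template <- colMeans(X[fp, , drop = FALSE])
  bl <- signal::butter(2, c(0.5, 4) / (fs / 2), type = "pass")
  template <- signal::filtfilt(bl, template)
  r <- as.numeric(stats::cor(t(dec$S), template))
  cand <- which(abs(r) > threshold)
  removed <- cand[order(abs(r[cand]), decreasing = TRUE)]
  removed <- removed[seq_len(min(length(removed), max_removed))]
  report <- data.frame(component = seq_len(n_components), r = r,
                       removed = seq_len(n_components) %in% removed)
  if (length(removed)) {
    S <- dec$S
    for (k in removed) {
      if (gate) {
        act <- abs(S[k, ]) > gate_mad * stats::mad(S[k, ])
        pad <- max(1L, round(gate_pad_ms / 1000 * fs))
        act <- stats::filter(as.numeric(act), rep(1, 2 * pad + 1),
                             sides = 2) > 0
        act[is.na(act)] <- FALSE
        S[k, act] <- 0
      } else {
        S[k, ] <- 0
      }
    }
    Xc <- dec$A %*% S + dec$center
  } else {
    Xc <- X
  }
  if (epoched) {
    x$data <- aperm(array(Xc, dim = c(d[2], d[3], d[1])), c(3, 1, 2))
  } else {
    x$data <- Xc
  }
  x$ocular_report <- report
  x
}

#' Flag trials exceeding an absolute amplitude threshold
#'
#' A trial is rejected iff its maximum absolute amplitude over all
#' channels and samples exceeds the threshold.
#'
#' @param epochs an `epoched_data`.
#' @param threshold_uv rejection threshold (microvolts), default 70.
#' @return `epochs` with updated `rejected` flags and a `rejection_log`
#'   element with per-condition counts.
#' @export
reject_artifacts <- function(epochs, threshold_uv = 70) {
  if (threshold_uv <= 0) stop("threshold must be positive")
  peak <- apply(abs(epochs$data), 1, max)
  epochs$rejected <- peak > threshold_uv
  epochs$rejection_log <- as.data.frame(
    table(condition = epochs$conditions, rejected = epochs$rejected))
  epochs
}

# Tukey bisquare weights for standardized residuals
bisquare_w <- function(u) ifelse(abs(u) < 1, (1 - u^2)^2, 0)

#' Robust (bisquare-weighted) average over trials
#'
#' Iteratively reweighted mean per channel and time point: residuals are
#' standardized per channel/time point by the median absolute deviation
#' (estimated once, from the residuals about the plain mean), weighted
#' with the Tukey bisquare function (tuning constant 4.685), and iterated
#' until the largest weight change falls below 1e-4 (at most 20
#' iterations). A zero-phase 70 Hz low-pass is applied to the average
#' afterwards, as is standard after robust averaging.
#'
#' @param epochs an `epoched_data` (rejected trials are excluded).
#' @param condition condition label to average.
#' @param lowpass_hz post-averaging low-pass cutoff (default 70); `NA`
#'   skips the filter (e.g. when sampling below 140 Hz).
#' @return object of class `evoked_response`: list with `data`
#'   (channels x samples), `time_ms`, `condition`, `group`, `n_trials`,
#'   `weights` (trials x channels x samples), `fs`, `labels`.
#' @export
robust_average <- function(epochs, condition, lowpass_hz = 70) {
  keep <- which(epochs$conditions == condition & !epochs$rejected)
  if (length(keep) < 2) {
    stop("need at least 2 non-rejected trials for condition '", condition,
         "' (have ", length(keep), ")")
  }
  Y <- epochs$data[keep, , , drop = FALSE]
  nt <- dim(Y)[1]
  dch <- dim(Y)[2]
  dsm <- dim(Y)[3]
  Ym <- matrix(Y, nt, dch * dsm)       # trials x (channel, sample)
  cc <- 4.685
  M <- colMeans(Ym)
  s <- apply(abs(Ym - rep(M, each = nt)), 2, stats::median) / 0.6745
  s[s < 1e-12] <- Inf                  # no spread: keep full weights
  W <- matrix(1, nt, ncol(Ym))
  for (it in seq_len(20)) {
    U <- (Ym - rep(M, each = nt)) / rep(cc * s, each = nt)
    Wn <- bisquare_w(U)
    dmax <- max(abs(Wn - W))
    W <- Wn
    M <- colSums(Ym * W) / pmax(colSums(W), 1e-12)
    if (dmax < 1e-4) break
  }
  W <- array(W, dim = dim(Y))
  M <- matrix(M, dch, dsm)
  if (!is.na(lowpass_hz) && lowpass_hz < epochs$fs / 2) {
    M <- filtfilt_mat(M, signal::butter(4, lowpass_hz / (epochs$fs / 2),
                                        type = "low"))
  }
  structure(list(data = M, time_ms = epochs$time_ms, condition = condition,
                 group = epochs$group, n_trials = nt, weights = W,
                 fs = epochs$fs, labels = epochs$labels),
            class = "evoked_response")
}

#' @export
print.evoked_response <- function(x, ...) {
  cat("Evoked response [", x$condition,
      if (!is.null(x$group)) paste0(", ", x$group), "]: ",
      nrow(x$data), " channels x ", ncol(x$data), " samples, ",
      x$n_trials, " trials\n", sep = "")
  invisible(x)
}

#' Grand averages over subjects per group and condition
#'
#' Unweighted mean of subject evoked responses within every
#' (group, condition) cell.
#'
#' @param evoked_list list of `evoked_response` objects carrying `group`
#'   and `condition`.
#' @param groups,conditions cell labels; defaults cover the standard
#'   design.
#' @return named list (`group.condition`) of `evoked_response` objects,
#'   one per cell, in group-major order.
#' @export
grand_average <- function(evoked_list,
                          groups = c("controls", "relatives", "patients"),
                          conditions = c("standard", "deviant")) {
  out <- list()
  for (g in groups) {
    for (cn in conditions) {
      members <- Filter(function(e) identical(e$group, g) &&
                          identical(e$condition, cn), evoked_list)
      if (length(members) == 0) {
        stop("no evoked responses for cell (", g, ", ", cn, ")")
      }
      M <- Reduce(`+`, lapply(members, `[[`, "data")) / length(members)
      tmpl <- members[[1]]
      out[[paste(g, cn, sep = ".")]] <- structure(
        list(data = M, time_ms = tmpl$time_ms, condition = cn, group = g,
             n_trials = sum(vapply(members, `[[`, numeric(1), "n_trials")),
             n_subjects = length(members), fs = tmpl$fs,
             labels = tmpl$labels),
        class = "evoked_response")
    }
  }
  out
}

#' Full sensor-space preprocessing chain for one subject
#'
#' Re-reference to common average, Butterworth filter chain, downsampling,
#' epoching with baseline correction, ICA ocular removal, amplitude-based
#' trial rejection, and robust averaging per condition (with the
#' post-averaging 70 Hz low-pass).
#'
#' @param recording a `raw_recording`.
#' @param target_fs downsampling target (Hz), default 200.
#' @param reject_uv rejection threshold (microvolts), default 70.
#' @param conditions conditions to average (default both).
#' @param ica_seed seed for the ICA initialization.
#' @return list of `evoked_response` objects (one per condition), with the
#'   ocular report attached as an attribute `ocular_report`.
#' @export
preprocess_subject <- function(recording, target_fs = 200, reject_uv = 70,
                               conditions = c("standard", "deviant"),
                               ica_seed = 1) {
  rec <- rereference_common_average(recording)
  rec <- apply_filters(rec)
  rec <- downsample_recording(rec, target_fs)
  ep <- epoch_and_baseline(rec)
  ep <- remove_ocular_components(ep, n_components = nrow(rec$data),
                                 seed = ica_seed)
  ep <- reject_artifacts(ep, reject_uv)
  out <- lapply(conditions, function(cn) robust_average(ep, cn))
  names(out) <- conditions
  attr(out, "ocular_report") <- ep$ocular_report
  out
}
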