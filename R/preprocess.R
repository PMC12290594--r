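#' Zero-phase Butterworth IIR filter
#'
#' Designs a Butterworth filter (high-pass, low-pass, or band-pass
#' depending on which cutoffs are given) and applies it forward and
#' backward (`signal::filtfilt`) to every channel, so the net response is
#' the squared magnitude with zero phase shift.
#'
#' @param rec an [recording()] object.
#' @param low lower cutoff in Hz (high-pass edge), or `NULL`.
#' @param high upper cutoff in Hz (low-pass edge), or `NULL`.
#' @param order filter order of the one-directional design (default 2).
#' @param bidirectional apply forward-backward (default `TRUE`); if
#'   `FALSE`, a single causal pass is used.
#' @return The filtered recording, same length.
#' @export
butter_filter <- function(rec, low = NULL, high = NULL, order = 2L,
                          bidirectional = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$rate / 2
  for (f in c(low, high))
    if (!is.null(f) && f >= nyq)
      stop("cutoff ", f, " Hz is at or above Nyquist (", nyq, " Hz)")
  if (is.null(low) && is.null(high)) stop("give at least one cutoff")
  if (!is.null(low) && !is.null(high) && low >= high)
    stop("low cutoff must be below high cutoff")
  flt <- if (!is.null(low) && !is.null(high))
    signal::butter(order, c(low, high) / nyq, type = "pass")
  else if (!is.null(low))
    signal::butter(order, low / nyq, type = "high")
  else
    signal::butter(order, high / nyq, type = "low")
  rec$data <- t(apply(rec$data, 1, function(x) {
    if (bidirectional) signal::filtfilt(flt, x)
    else as.numeric(signal::filter(flt, x))
  }))
  rownames(rec$data) <- rec$ch_names
  log_op(rec, sprintf("butter_filter(low=%s, high=%s, order=%d, bidir=%s)",
                      deparse(low), deparse(high), order, bidirectional))
}

#' Zero-phase FIR band-pass filter
#'
#' Windowed-sinc (Hamming) linear-phase FIR band-pass, applied non-causally
#' with the group delay compensated, as used for the 2-20 Hz band that
#' feeds the microstate analysis.
#'
#' @param rec an [recording()] object.
#' @param low,high band edges in Hz.
#' @param order filter order (number of taps minus one); must be even.
#' @param window taper; only `"hamming"` is implemented.
#' @return The filtered recording, same length.
#' @export
fir_bandpass <- function(rec, low = 2, high = 20, order = 2000L,
                         window = "hamming") {
  stopifnot(inherits(rec, "eeg_recording"))
  window <- match.arg(window, "hamming")
  nyq <- rec$rate / 2
  if (!(low < high && high < nyq)) stop("need 0 < low < high < Nyquist")
  order <- as.integer(order)
  if (order %% 2L) stop("order must be even for exact delay compensation")
  if (n_samples(rec) <= order + 1L)
    stop("signal shorter than the filter (", order + 1L, " taps)")
  h <- signal::fir1(order, c(low, high) / nyq, type = "pass",
                    window = signal::hamming(order + 1L))
  half <- order %/% 2L
  ns <- n_samples(rec)
  rec$data <- t(apply(rec$data, 1, function(x) {
    # reflect-pad so edges see stationary context, then centre the output
    # (FFT overlap-add convolution; the kernel is symmetric = zero phase)
    xp <- c(rev(x[seq_len(half)]), x, rev(x[(ns - half + 1L):ns]))
    y <- signal::fftfilt(h, xp)
    as.numeric(y[(order + 1L):(order + ns)])
  }))
  rownames(rec$data) <- rec$ch_names
  log_op(rec, sprintf("fir_bandpass(%g-%g Hz, order=%d)", low, high, order))
}

#' Resample a recording
#'
#' Anti-alias filtered rational resampling (`signal::resample`). Event
#' sample indices are rescaled by the rate ratio and rounded to nearest.
#'
#' @param rec an [recording()] object.
#' @param target_rate new sampling frequency in Hz.
#' @return The resampled recording with `round(samples * target/rate)`
#'   samples.
#' @export
resample_recording <- function(rec, target_rate) {
  stopifnot(inherits(rec, "eeg_recording"), target_rate > 0)
  if (abs(target_rate - rec$rate) < 1e-12)
    return(log_op(rec, "resample (identity)"))
  new_n <- as.integer(round(n_samples(rec) * target_rate / rec$rate))
  out <- t(apply(rec$data, 1, resample_fft, new_n = new_n))
  ev <- rec$events
  if (nrow(ev)) {
    ev$sample <- pmax(1L, pmin(new_n, as.integer(
      round(ev$sample * target_rate / rec$rate))))
  }
  out_rec <- recording(out, rate = target_rate, ch_names = rec$ch_names,
                       ch_types = rec$ch_types, events = ev,
                       positions = rec$positions, log = rec$log)
  log_op(out_rec, sprintf("resample(%g -> %g Hz)", rec$rate, target_rate))
}

# Fourier-domain resampling: truncating (or zero-padding) the spectrum is
# an ideal anti-alias (interpolation) filter for the retained band.
resample_fft <- function(x, new_n) {
  n <- length(x)
  X <- stats::fft(x)
  Y <- complex(new_n)
  half <- min(n, new_n) %/% 2L
  Y[1:(half + 1L)] <- X[1:(half + 1L)]
  if (half > 0L) Y[new_n - (1:half) + 1L] <- X[n - (1:half) + 1L]
  if (min(n, new_n) %% 2L == 0L && half > 0L) {
    # split the shared Nyquist bin to keep the signal real
    if (new_n < n) {
      Y[half + 1L] <- X[half + 1L] + X[n - half + 1L]
    } else if (new_n > n) {
      Y[half + 1L] <- X[half + 1L] / 2
      Y[new_n - half + 1L] <- X[half + 1L] / 2
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Average-artifact subtraction for gradient artifacts
#'
#' Removes a periodic acquisition artifact (e.g., MR gradient switching)
#' by subtracting, within each trigger-locked epoch, the sliding average
#' of the `n_avg` nearest epochs (centered window, truncated at the record
#' edges). Samples outside trigger coverage are untouched.
#'
#' @param rec an [recording()] object.
#' @param volume_triggers an `event_selection` (or integer sample vector)
#'   of acquisition triggers; inter-trigger spacing must be constant to
#'   within one sample.
#' @param n_avg number of epochs averaged into the template (default 15).
#' @param channels channel indices/names to correct (default: all).
#' @return The corrected recording.
#' @export
aas_correct <- function(rec, volume_triggers, n_avg = 15L, channels = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  trg <- as_event_selection(volume_triggers)$indices
  if (length(trg) == 0L) stop("no volume triggers")
  if (length(trg) < n_avg)
    stop("need at least n_avg = ", n_avg, " triggers, got ", length(trg))
  itv <- diff(trg)
  per <- stats::median(itv)
  off <- which(abs(itv - per) > 1)
  if (length(off))
    stop("irregular trigger spacing at trigger ", off[1], ": interval ",
         itv[off[1]], " vs period ", per)
  if (is.null(channels)) channels <- seq_len(nrow(rec$data))
  if (is.character(channels)) channels <- match(channels, rec$ch_names)
  per <- as.integer(per)
  n_ep <- length(trg)
  use <- trg + per - 1L <= n_samples(rec)
  epochs <- array(0, dim = c(length(channels), per, n_ep))
  for (e in which(use))
    epochs[, , e] <- rec$data[channels, trg[e]:(trg[e] + per - 1L)]
  half <- n_avg %/% 2L
  for (e in which(use)) {
    lo <- max(1L, e - half)
    hi <- min(n_ep, lo + n_avg - 1L)
    lo <- max(1L, hi - n_avg + 1L)
    idx <- intersect(lo:hi, which(use))
    tmpl <- apply(epochs[, , idx, drop = FALSE], c(1, 2), mean)
    rec$data[channels, trg[e]:(trg[e] + per - 1L)] <-
      rec$data[channels, trg[e]:(trg[e] + per - 1L)] - tmpl
  }
  log_op(rec, sprintf("aas_correct(n_triggers=%d, n_avg=%d)", n_ep, n_avg))
}

#' Carbon-wire-loop regression
#'
#' Removes motion-induced artifact by projecting each EEG channel onto a
#' time-lag-embedded basis of the carbon-wire-loop (CWL) channels and
#' subtracting the least-squares fit. CWL channels are dropped from the
#' output.
#'
#' @param rec an [recording()] object with at least one `"cwl"` channel.
#' @param max_lag_s maximum lead/lag of the embedding in seconds
#'   (default 0.1); lags run from `-max_lag_s` to `+max_lag_s` in samples.
#' @param window_s length of independent regression windows in seconds,
#'   or `NULL` (default) for one global regression.
#' @return The cleaned recording without the CWL channels.
#' @export
cwl_regress <- function(rec, max_lag_s = 0.1, window_s = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  cwl <- which(rec$ch_types == "cwl")
  if (!length(cwl)) stop("no CWL channels in recording")
  keep <- which(rec$ch_types != "cwl")
  eeg <- which(rec$ch_types == "eeg")
  L <- as.integer(round(max_lag_s * rec$rate))
  ns <- n_samples(rec)
  C <- rec$data[cwl, , drop = FALSE]
  # lag-embedded regressor matrix (zero-padded shifts)
  lags <- -L:L
  reg <- matrix(0, nrow = ns, ncol = length(cwl) * length(lags))
  k <- 0L
  for (i in seq_along(cwl)) for (l in lags) {
    k <- k + 1L
    if (l >= 0) reg[(1L + l):ns, k] <- C[i, seq_len(ns - l)]
    else reg[seq_len(ns + l), k] <- C[i, (1L - l):ns]
  }
  fit_window <- function(rows) {
    Y <- t(rec$data[eeg, rows, drop = FALSE])
    Xr <- reg[rows, , drop = FALSE]
    B <- qr.coef(qr(Xr), Y)
    B[is.na(B)] <- 0
    t(Y - Xr %*% B)
  }
  if (is.null(window_s)) {
    rec$data[eeg, ] <- fit_window(seq_len(ns))
  } else {
    w <- max(1L, as.integer(round(window_s * rec$rate)))
    starts <- seq(1L, ns, by = w)
    for (s in starts) {
      rows <- s:min(ns, s + w - 1L)
      rec$data[eeg, rows] <- fit_window(rows)
    }
  }
  out <- recording(rec$data[keep, , drop = FALSE], rate = rec$rate,
                   ch_names = rec$ch_names[keep],
                   ch_types = rec$ch_types[keep], events = rec$events,
                   positions = rec$positions[keep, , drop = FALSE],
                   log = rec$log)
  log_op(out, sprintf("cwl_regress(max_lag_s=%g, window_s=%s, n_cwl=%d)",
                      max_lag_s, deparse(window_s), length(cwl)))
}

#' Reject segments with excessive band power
#'
#' Computes band power (default 15-30 Hz) in sliding windows, flags
#' windows whose power exceeds `threshold_factor` times the median window
#' power, merges contiguous flags, excises the flagged spans and
#' concatenates the remainder. Events inside excised spans are dropped
#' (with a provenance warning); later events are shifted.
#'
#' @param rec an [recording()] object.
#' @param band numeric length-2, band edges in Hz.
#' @param window_s sliding-window length in seconds (default 1).
#' @param step_s window step in seconds (default 0.25).
#' @param threshold_factor multiple of the median band power above which a
#'   window is rejected (default 8).
#' @return A list with the excised `recording` and `mask`, a data frame of
#'   rejected half-open intervals (`start`, `stop`, in samples of the
#'   input).
#' @export
reject_spectral_segments <- function(rec, band = c(15, 30), window_s = 1,
                                     step_s = 0.25, threshold_factor = 8) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(band[1] > 0 && band[2] < rec$rate / 2 && band[1] < band[2]))
    stop("band must lie within (0, Nyquist)")
  ns <- n_samples(rec)
  w <- as.integer(round(window_s * rec$rate))
  st <- max(1L, as.integer(round(step_s * rec$rate)))
  starts <- seq(1L, max(1L, ns - w + 1L), by = st)
  eeg <- eeg_channels(rec)
  freqs <- (seq_len(w) - 1L) * rec$rate / w
  in_band <- freqs >= band[1] & freqs <= band[2]
  pow <- vapply(starts, function(s) {
    seg <- rec$data[eeg, s:(s + w - 1L), drop = FALSE]
    sp <- abs(stats::mvfft(t(seg)))^2
    mean(sp[in_band, , drop = FALSE])
  }, numeric(1))
  med <- stats::median(pow)
  flagged <- pow > threshold_factor * med   # strict: all-zero input passes
  mask <- data.frame(start = integer(), stop = integer())
  if (any(flagged)) {
    iv <- cbind(starts[flagged], pmin(ns + 1L, starts[flagged] + w))
    # merge overlapping / adjacent intervals
    o <- order(iv[, 1])
    iv <- iv[o, , drop = FALSE]
    merged <- iv[1, , drop = FALSE]
    for (i in seq_len(nrow(iv))[-1]) {
      if (iv[i, 1] <= merged[nrow(merged), 2])
        merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], iv[i, 2])
      else merged <- rbind(merged, iv[i, ])
    }
    mask <- data.frame(start = merged[, 1], stop = merged[, 2])
  }
  cut <- sum(mask$stop - mask$start)
  if (cut >= ns) stop("no data survives rejection")
  if (nrow(mask)) {
    drop_idx <- unlist(mapply(function(a, b) a:(b - 1L), mask$start,
                              mask$stop, SIMPLIFY = FALSE))
    keep <- setdiff(seq_len(ns), drop_idx)
    ev <- rec$events
    if (nrow(ev)) {
      inside <- ev$sample %in% drop_idx
      ev <- ev[!inside, , drop = FALSE]
      ev$sample <- vapply(ev$sample, function(s)
        s - sum(drop_idx < s), integer(1))
    }
    out <- recording(rec$data[, keep, drop = FALSE], rate = rec$rate,
                     ch_names = rec$ch_names, ch_types = rec$ch_types,
                     events = ev, positions = rec$positions, log = rec$log)
  } else out <- rec
  out <- log_op(out, sprintf(
    "reject_spectral_segments(band=%g-%g, factor=%g): %d segment(s), %d samples cut",
    band[1], band[2], threshold_factor, nrow(mask), cut))
  list(recording = out, mask = mask)
}

#' Common-average re-reference
#'
#' Subtracts the instantaneous mean over EEG channels from every EEG
#' channel. Non-EEG channels are untouched. Idempotent.
#'
#' @param rec an [recording()] object with at least two EEG channels.
#' @return The re-referenced recording.
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  eeg <- eeg_channels(rec)
  if (length(eeg) < 2L) stop("need at least 2 EEG channels")
  m <- colMeans(rec$data[eeg, , drop = FALSE])
  rec$data[eeg, ] <- sweep(rec$data[eeg, , drop = FALSE], 2, m)
  log_op(rec, "rereference_average")
}

#' Detect and interpolate bad channels
#'
#' Flags an EEG channel as bad when its maximum absolute correlation with
#' every other EEG channel falls below `correlation_threshold`, or when it
#' is nearly flat (standard deviation below `flat_threshold_uv`). Flagged
#' channels are replaced by the inverse-distance-weighted average of the
#' 4 nearest good channels (sensor positions required).
#'
#' @param rec an [recording()] object with `positions`.
#' @param correlation_threshold minimum max-|correlation| with any other
#'   channel (default 0.4).
#' @param flat_threshold_uv flatness bound in microvolts (default 1e-4).
#' @return list of the repaired `recording` and `interpolated` labels.
#' @export
bad_channels <- function(rec, correlation_threshold = 0.4,
                         flat_threshold_uv = 1e-4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(rec$positions)) stop("sensor positions required")
  eeg <- eeg_channels(rec)
  X <- rec$data[eeg, , drop = FALSE]
  sds <- apply(X, 1, stats::sd)
  flat <- sds < flat_threshold_uv
  cc <- suppressWarnings(abs(stats::cor(t(X))))
  diag(cc) <- 0
  cc[is.na(cc)] <- 0
  uncorr <- apply(cc, 1, max) < correlation_threshold
  bad <- which(flat | uncorr)
  if (length(bad) > length(eeg) / 2) stop("recording unusable: ",
                                          length(bad), " bad channels")
  good <- setdiff(seq_along(eeg), bad)
  for (b in bad) {
    d <- sqrt(colSums((t(rec$positions[eeg[good], , drop = FALSE]) -
                         rec$positions[eeg[b], ])^2))
    nn <- good[order(d)][seq_len(min(4L, length(good)))]
    wts <- 1 / pmax(d[order(d)][seq_len(min(4L, length(good)))], 1e-9)
    wts <- wts / sum(wts)
    rec$data[eeg[b], ] <- as.numeric(wts %*% rec$data[eeg[nn], , drop = FALSE])
  }
  labels <- rec$ch_names[eeg[bad]]
  rec <- log_op(rec, sprintf("bad_channels: interpolated [%s]",
                             paste(labels, collapse = ", ")))
  list(recording = rec, interpolated = labels)
}
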