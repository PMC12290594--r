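#' Epoch a recording around triggers
#'
#' Cuts fixed-length epochs `[trigger + offset, trigger + offset +
#' duration)` around each trigger. Epochs that would extend beyond the
#' recording are dropped (their count is logged in the returned object).
#'
#' @param rec an [recording()] object.
#' @param triggers an `event_selection` or integer sample vector.
#' @param offset_s epoch start relative to the trigger, seconds
#'   (default -0.2).
#' @param duration_s epoch length in seconds (default 0.7).
#' @param channels channel indices to include (default: EEG channels).
#' @return An `epoch_tensor`: list with `data` (channels x epochs x
#'   samples array), `offset_s`, `rate`, `n_dropped`.
#' @export
epoch_around <- function(rec, triggers, offset_s = -0.2, duration_s = 0.7,
                         channels = NULL) {
  stopifnot(inherits(rec, "eeg_recording"), duration_s > 0)
  trg <- as_event_selection(triggers)$indices
  if (is.null(channels)) channels <- eeg_channels(rec)
  off <- as.integer(round(offset_s * rec$rate))
  T <- as.integer(round(duration_s * rec$rate))
  starts <- trg + off
  ok <- starts >= 1L & starts + T - 1L <= n_samples(rec)
  if (!any(ok)) stop("no usable triggers: all epochs out of bounds")
  starts <- starts[ok]
  arr <- array(0, dim = c(length(channels), length(starts), T))
  for (e in seq_along(starts))
    arr[, e, ] <- rec$data[channels, starts[e]:(starts[e] + T - 1L)]
  structure(list(data = arr, offset_s = offset_s, rate = rec$rate,
                 n_dropped = sum(!ok)),
            class = "epoch_tensor")
}

#' Average consecutive epochs
#'
#' Groups the epochs, in their original order, into disjoint consecutive
#' blocks of `n_avg`, averages each block over the epoch axis (leftover
#' epochs beyond the last full block are discarded), and concatenates the
#' block averages along time. Averaging attenuates activity that is not
#' locked to the triggers by roughly `1/n_avg` in power.
#'
#' @param x an `epoch_tensor` from [epoch_around()].
#' @param n_avg block size N (default 25).
#' @param demean remove each channel's within-epoch mean before averaging
#'   (default `TRUE`).
#' @return A `stacked_averages`: list with `data` (channels x
#'   `T * floor(E/N)` matrix), `n_avg`, `n_groups`.
#' @export
average_consecutive <- function(x, n_avg = 25L, demean = TRUE) {
  stopifnot(inherits(x, "epoch_tensor"))
  E <- dim(x$data)[2]
  if (E < n_avg)
    stop("only ", E, " epochs but n_avg = ", n_avg,
         "; use a smaller n_avg or a longer recording")
  G <- E %/% n_avg
  C <- dim(x$data)[1]; T <- dim(x$data)[3]
  arr <- x$data
  if (demean) {
    mu <- apply(arr, c(1, 2), mean)
    arr <- arr - array(mu, dim = c(C, E, T))
  }
  out <- matrix(0, nrow = C, ncol = T * G)
  for (g in seq_len(G)) {
    idx <- ((g - 1L) * n_avg + 1L):(g * n_avg)
    out[, ((g - 1L) * T + 1L):(g * T)] <-
      apply(arr[, idx, , drop = FALSE], c(1, 3), mean)
  }
  structure(list(data = out, n_avg = n_avg, n_groups = G),
            class = "stacked_averages")
}

#' Draw random reference triggers
#'
#' Uniform sample positions (without replacement, sorted) such that an
#' epoch of the given geometry around each trigger lies fully inside the
#' recording. Used to build the reference covariance that the
#' heartbeat-locked covariance is contrasted against.
#'
#' @param rec an [recording()] object.
#' @param count number of triggers.
#' @param offset_s,duration_s epoch geometry, as in [epoch_around()].
#' @param seed RNG seed (required for reproducibility).
#' @return An `event_selection`.
#' @export
random_triggers <- function(rec, count, offset_s = -0.2, duration_s = 0.7,
                            seed = NULL) {
  stopifnot(inherits(rec, "eeg_recording"), count >= 1)
  off <- as.integer(round(offset_s * rec$rate))
  T <- as.integer(round(duration_s * rec$rate))
  lo <- max(1L, 1L - off)
  hi <- n_samples(rec) - off - T + 1L
  if (hi - lo + 1L < count)
    stop("recording too short for ", count, " reference epochs")
  idx <- with_seed(seed, sort(sample(lo:hi, count, replace = FALSE)))
  structure(list(label_pattern = "<random>", indices = as.integer(idx)),
            class = "event_selection")
}

spatial_cov <- function(X) {
  X <- X - rowMeans(X)
  tcrossprod(X) / (ncol(X) - 1L)
}

#' Fit a joint-decorrelation model of heartbeat-locked artifact
#'
#' Estimates spatial components that preferentially capture
#' heartbeat-locked (ballistocardiogram, BCG) variance by a generalized
#' eigendecomposition contrasting two covariances: `Cart_bar`, from
#' R-peak-locked epochs averaged in consecutive blocks of `n_avg` (which
#' attenuates ongoing brain activity relative to the artifact), and
#' `Cref_bar`, built identically from an equal number of random reference
#' triggers. The generalized eigenvalues `lambda` measure the
#' artifact-to-reference variance ratio per component.
#'
#' Because averaging `n_avg` epochs also reduces noise by a known amount,
#' the eigenvalues are rescaled into signal-to-noise-improvement units:
#' the unaveraged reference covariance `Cref_raw` is projected through the
#' eigenvectors, the mean of the resulting diagonal defines the empirical
#' noise-reduction ratio `gamma_bar`, and
#' `lambda_tilde = (lambda - 1) / gamma_bar + 1`. Under no
#' heartbeat-locked structure the rescaled eigenvalues concentrate around
#' 1; a component with `lambda_tilde = 2` carries twice the power during
#' heartbeats than during reference periods.
#'
#' @param rec an [recording()] object (band-limited, artifact-epochable).
#' @param r_peaks `event_selection` of ECG R-peak triggers.
#' @param n_avg epochs per average block (default 25).
#' @param offset_s,duration_s epoch geometry (defaults -0.2 s, 0.7 s).
#' @param seed RNG seed for the random reference triggers.
#' @param shrinkage ridge weight toward the scaled identity applied to
#'   `Cref_bar` before the eigendecomposition (default 1e-6); guards
#'   against rank deficiency after average referencing.
#' @param exclude_r_overlap if `TRUE`, reference triggers overlapping an
#'   R-peak epoch are resampled away (default `FALSE`).
#' @return A `jd_model`: list with `filters` (W, columns sorted by
#'   descending eigenvalue, normalized so `t(W) %*% Cref_bar %*% W = I`),
#'   `patterns` (A = Cref_bar W), `eigvals`, `rescaled`, `gamma_bar`,
#'   `cov_art`, `cov_ref_avg`, `cov_ref_raw`, `channels`, `seed`.
#' @export
fit_jd <- function(rec, r_peaks, n_avg = 25L, offset_s = -0.2,
                   duration_s = 0.7, seed = NULL, shrinkage = 1e-6,
                   exclude_r_overlap = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"))
  r_peaks <- as_event_selection(r_peaks)
  chans <- eeg_channels(rec)
  ep_art <- epoch_around(rec, r_peaks, offset_s, duration_s, chans)
  E <- dim(ep_art$data)[2]
  if (E < n_avg) stop("need at least n_avg = ", n_avg, " R-peak epochs")
  ref <- random_triggers(rec, E, offset_s, duration_s, seed = seed)
  if (exclude_r_overlap) {
    T <- as.integer(round(duration_s * rec$rate))
    span <- function(t) (t + round(offset_s * rec$rate)) + seq_len(T) - 1L
    art_cover <- unique(unlist(lapply(r_peaks$indices, span)))
    tries <- 0L
    while (any(ref$indices %in% (art_cover - round(offset_s * rec$rate))) &&
           tries < 50L) {
      bad <- ref$indices %in% (art_cover - round(offset_s * rec$rate))
      repl <- random_triggers(rec, sum(bad), offset_s, duration_s,
                              seed = if (is.null(seed)) NULL
                                     else seed + 1000L + tries)
      ref$indices <- sort(c(ref$indices[!bad], repl$indices))
      tries <- tries + 1L
    }
  }
  ep_ref <- epoch_around(rec, ref, offset_s, duration_s, chans)
  Xart <- average_consecutive(ep_art, n_avg)
  Xref <- average_consecutive(ep_ref, n_avg)
  Cart <- spatial_cov(Xart$data)
  Cref_avg <- spatial_cov(Xref$data)
  # unaveraged reference covariance: same epochs, concatenated raw
  C <- dim(ep_ref$data)[1]
  raw <- matrix(aperm(ep_ref$data, c(1, 3, 2)), nrow = C)
  Cref_raw <- spatial_cov(raw)

  ged <- ged_solve(Cart, Cref_avg, shrinkage)
  gamma_bar <- mean(diag(t(ged$W) %*% Cref_raw %*% ged$W))
  structure(list(filters = ged$W, patterns = Cref_avg %*% ged$W,
                 eigvals = ged$lambda,
                 rescaled = rescale_eigenvalues(ged$lambda, gamma_bar),
                 gamma_bar = gamma_bar, cov_art = Cart,
                 cov_ref_avg = Cref_avg, cov_ref_raw = Cref_raw,
                 channels = chans, ch_names = rec$ch_names[chans],
                 n_avg = n_avg, seed = seed),
            class = "jd_model")
}

# Generalized eigendecomposition Cart w = lambda Cref w via whitening;
# W normalized so t(W) Cref W = I, eigenvalues sorted descending.
ged_solve <- function(Cart, Cref, shrinkage = 1e-6) {
  C <- nrow(Cref)
  Creg <- (1 - shrinkage) * Cref + shrinkage * (sum(diag(Cref)) / C) * diag(C)
  er <- eigen(Creg, symmetric = TRUE)
  if (min(er$values) <= 0)
    stop("reference covariance is rank deficient; increase shrinkage")
  S <- er$vectors %*% diag(1 / sqrt(er$values), C)
  M <- t(S) %*% Cart %*% S
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)
  W <- S %*% em$vectors
  list(lambda = pmax(em$values, 0), W = W)
}

#' @export
print.jd_model <- function(x, ...) {
  cat(sprintf("<jd_model> %d components, gamma_bar = %.2f\n",
              length(x$eigvals), x$gamma_bar))
  cat("  rescaled eigenvalues:",
      paste(sprintf("%.3f", utils::head(x$rescaled, 8)), collapse = " "),
      if (length(x$rescaled) > 8) "...\n" else "\n")
  invisible(x)
}

#' Rescale generalized eigenvalues by the noise-reduction ratio
#'
#' `lambda_tilde = (lambda - 1) / gamma_bar + 1`. This maps the raw
#' artifact-to-reference variance ratios onto the scale of
#' signal-to-noise-ratio improvement beyond what block averaging alone
#' provides; 1 is the fixed point (no heartbeat-locked excess).
#'
#' @param eigvals numeric vector of generalized eigenvalues.
#' @param gamma_bar positive noise-reduction ratio.
#' @return Rescaled eigenvalues, order preserved.
#' @export
rescale_eigenvalues <- function(eigvals, gamma_bar) {
  if (!is.numeric(gamma_bar) || gamma_bar <= 0)
    stop("gamma_bar must be positive")
  (eigvals - 1) / gamma_bar + 1
}

#' Reject artifact components from a recording
#'
#' Out-projects the joint-decorrelation components whose rescaled
#' eigenvalue strictly exceeds the threshold:
#' `cleaned = X - A[, rej] %*% (t(W[, rej]) %*% X)`. Unrejected component
#' time courses are unchanged; applying the same rejection twice is a
#' no-op (projection).
#'
#' @param rec an [recording()] object (channels matching the model).
#' @param model a `jd_model` from [fit_jd()].
#' @param threshold rejection threshold on the rescaled eigenvalues
#'   (ties are kept).
#' @return A `jd_rejection`: list with `rejected_indices` (prefix of the
#'   eigenvalue-sorted order), `threshold`, `cleaned` recording.
#' @export
apply_jd <- function(rec, model, threshold) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(model, "jd_model"))
  chans <- model$channels
  if (!identical(rec$ch_names[chans], model$ch_names))
    stop("recording channels do not match the model")
  rej <- which(model$rescaled > threshold)
  cleaned <- rec
  if (length(rej)) {
    X <- rec$data[chans, , drop = FALSE]
    A <- model$patterns[, rej, drop = FALSE]
    W <- model$filters[, rej, drop = FALSE]
    cleaned$data[chans, ] <- X - A %*% (t(W) %*% X)
  }
  cleaned <- log_op(cleaned, sprintf(
    "apply_jd(threshold=%g): rejected %d/%d components", threshold,
    length(rej), length(model$rescaled)))
  structure(list(rejected_indices = rej, threshold = threshold,
                 cleaned = cleaned),
            class = "jd_rejection")
}

#' Replicated BCG reduction
#'
#' The reference periods are drawn at random, so the joint-decorrelation
#' rejection is not deterministic. This runs `replicates` independent
#' fit-and-apply passes with seeds `base_seed`, `base_seed + 1`, ...,
#' returning one `jd_rejection` per replicate.
#'
#' @param rec an [recording()] object.
#' @param r_peaks `event_selection` of R-peak triggers.
#' @param threshold rescaled-eigenvalue rejection threshold.
#' @param n_avg epochs per average block (default 25).
#' @param replicates number of independent passes (default 10).
#' @param base_seed seed of the first replicate.
#' @param ... further arguments passed to [fit_jd()].
#' @return List of `jd_rejection` objects, one per replicate.
#' @export
run_bcg_reduction <- function(rec, r_peaks, threshold, n_avg = 25L,
                              replicates = 10L, base_seed = 1L, ...) {
  lapply(seq_len(replicates), function(r) {
    model <- fit_jd(rec, r_peaks, n_avg = n_avg,
                    seed = base_seed + r - 1L, ...)
    apply_jd(rec, model, threshold)
  })
}
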