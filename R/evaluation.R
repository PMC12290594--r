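# The three-step evaluation workflow: sweep the BCG rejection threshold
# with replicated random reference selections, keep (threshold,
# replicate) cells whose duration/occurrence/coverage mean ICCs all reach
# 0.5, then pick the cross-day combination with the most similar
# thresholds. Plus Welch PSD and ERP quality-control computations.

#' Sweep the BCG rejection threshold
#'
#' For every replicate, one joint-decorrelation model is fitted per
#' subject (the random reference selection defines the replicate) and
#' every threshold of the grid is applied to that model; the cleaned
#' recordings are backfitted with the fixed templates, metrics are
#' computed, and the mean ICC against the outside-scanner metrics is
#' recorded per metric. A `"none"` row (no rejection) is the
#' deterministic control.
#'
#' @param inside_recs list of [recording()] objects, one per subject.
#' @param outside_metrics list of `microstate_metrics`, same subjects.
#' @param templates ordered `microstate_templates` used for backfitting.
#' @param r_peak_label event-label pattern of the R-peak triggers
#'   (default `"^R$"`).
#' @param grid numeric threshold grid (default `seq(1.05, 1.20, 0.01)`).
#' @param include_none include the no-rejection control row
#'   (default `TRUE`).
#' @param replicates independent reference draws (default 10).
#' @param n_avg epochs per average block (default 25).
#' @param seed base RNG seed.
#' @param smooth_window_ms,penalty backfitting parameters.
#' @param fir_band length-2 band (Hz) of the zero-phase FIR band-pass
#'   applied after rejection and before backfitting, mirroring the
#'   pipeline ordering (artifact rejection on broadband data, microstate
#'   analysis on 2-20 Hz); `NULL` disables.
#' @param fir_order FIR order (default 2000).
#' @return A `sweep_result`: list with `table` (threshold, replicate,
#'   metric, mean_icc), `pass_mask` (threshold x replicate logical:
#'   duration, occurrence and coverage means all >= 0.5), `grid`,
#'   `metrics` (per threshold and replicate, the per-subject metrics),
#'   `seed`.
#' @export
threshold_sweep <- function(inside_recs, outside_metrics, templates,
                            r_peak_label = "^R$",
                            grid = seq(1.05, 1.20, by = 0.01),
                            include_none = TRUE, replicates = 10L,
                            n_avg = 25L, seed = 1L,
                            smooth_window_ms = 20, penalty = 1,
                            fir_band = c(2, 20), fir_order = 2000L) {
  stopifnot(length(inside_recs) == length(outside_metrics))
  grid <- sort(grid)
  thr_names <- c(if (include_none) "none", sprintf("%.2f", grid))
  n_sub <- length(inside_recs)
  post <- function(rec) {
    if (!is.null(fir_band))
      rec <- fir_bandpass(rec, fir_band[1], fir_band[2], fir_order)
    ms_metrics(backfit(rec, templates, smooth_window_ms, penalty))
  }
  rows <- list()
  metrics_store <- stats::setNames(
    lapply(thr_names, function(t) vector("list", replicates)), thr_names)
  none_metrics <- NULL
  if (include_none) none_metrics <- lapply(inside_recs, post)
  for (r in seq_len(replicates)) {
    models <- lapply(seq_len(n_sub), function(i)
      fit_jd(inside_recs[[i]], select_events(inside_recs[[i]], r_peak_label),
             n_avg = n_avg, seed = seed + 1000L * r + i))
    for (tn in thr_names) {
      if (tn == "none") {
        mets <- none_metrics
      } else {
        thr <- as.numeric(tn)
        mets <- lapply(seq_len(n_sub), function(i)
          post(apply_jd(inside_recs[[i]], models[[i]], thr)$cleaned))
      }
      metrics_store[[tn]][[r]] <- mets
      rep_out <- pair_reliability(
        paired_metrics(outside_metrics, mets,
                       pairing_label = sprintf("outside vs inside@%s", tn)),
        reps = 0L)
      rows[[length(rows) + 1L]] <- data.frame(
        threshold = tn, replicate = r,
        metric = names(rep_out$mean_icc),
        mean_icc = unname(rep_out$mean_icc), stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  pass <- matrix(FALSE, nrow = length(thr_names), ncol = replicates,
                 dimnames = list(thr_names, NULL))
  for (tn in thr_names) for (r in seq_len(replicates)) {
    v <- tab$mean_icc[tab$threshold == tn & tab$replicate == r &
                        tab$metric %in% c("duration", "occurrence",
                                          "coverage")]
    pass[tn, r] <- all(!is.na(v)) && all(v >= 0.5)
  }
  structure(list(table = tab, pass_mask = pass, grid = grid,
                 include_none = include_none, metrics = metrics_store,
                 seed = seed),
            class = "sweep_result")
}

#' Candidate thresholds from a sweep
#'
#' Candidates are the (threshold, replicate) cells whose duration,
#' occurrence and coverage mean ICCs all reached 0.5 (the `"none"`
#' control row is never a candidate). Replicates are ranked by the length
#' of their longest contiguous run of passing thresholds (ties: more
#' total passes, then lower replicate number).
#'
#' @param sweep a `sweep_result` from [threshold_sweep()].
#' @return List with `candidates` (data frame threshold, replicate) and
#'   `replicate_ranking` (replicate, longest_run, total_passes), both
#'   possibly empty.
#' @export
select_candidates <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  pm <- sweep$pass_mask
  thr_rows <- rownames(pm) != "none"
  pm <- pm[thr_rows, , drop = FALSE]
  cand <- which(pm, arr.ind = TRUE)
  candidates <- data.frame(
    threshold = as.numeric(rownames(pm)[cand[, 1]]),
    replicate = as.integer(cand[, 2]))
  candidates <- candidates[order(candidates$replicate,
                                 candidates$threshold), , drop = FALSE]
  rownames(candidates) <- NULL
  longest_run <- function(v) {
    if (!any(v)) return(0L)
    r <- rle(v)
    max(r$lengths[r$values])
  }
  rk <- data.frame(replicate = seq_len(ncol(pm)),
                   longest_run = apply(pm, 2, longest_run),
                   total_passes = colSums(pm))
  rk <- rk[order(-rk$longest_run, -rk$total_passes, rk$replicate), ,
           drop = FALSE]
  rownames(rk) <- NULL
  list(candidates = candidates, replicate_ranking = rk)
}

#' Cross-day threshold selection
#'
#' Evaluates the reliability of every combination of day-1 and day-2
#' candidate cells (using the per-subject metrics stored in the sweeps),
#' keeps the combinations whose duration/occurrence/coverage mean ICCs
#' all reach 0.5, and selects the one minimizing the threshold difference
#' between days (ties: lower thresholds).
#'
#' @param day1_sweep,day2_sweep `sweep_result` objects of the two days.
#' @param day1_candidates,day2_candidates candidate data frames from
#'   [select_candidates()].
#' @param reps permutation repetitions per evaluated combination
#'   (default 0: skip).
#' @param seed RNG seed for the permutations.
#' @return List with `grid` (one row per combination: thresholds,
#'   replicates, mean ICCs, pass flag) and `selection` (the selected row,
#'   or `NULL` when nothing passes).
#' @export
cross_day_select <- function(day1_sweep, day2_sweep,
                             day1_candidates, day2_candidates,
                             reps = 0L, seed = NULL) {
  if (!nrow(day1_candidates) || !nrow(day2_candidates))
    stop("candidate lists must be non-empty")
  rows <- list()
  for (i in seq_len(nrow(day1_candidates))) {
    for (j in seq_len(nrow(day2_candidates))) {
      t1 <- day1_candidates$threshold[i]; r1 <- day1_candidates$replicate[i]
      t2 <- day2_candidates$threshold[j]; r2 <- day2_candidates$replicate[j]
      m1 <- day1_sweep$metrics[[sprintf("%.2f", t1)]][[r1]]
      m2 <- day2_sweep$metrics[[sprintf("%.2f", t2)]][[r2]]
      rep_out <- pair_reliability(
        paired_metrics(m1, m2, pairing_label = "day1 vs day2"),
        reps = reps, seed = seed)
      mi <- rep_out$mean_icc
      rows[[length(rows) + 1L]] <- data.frame(
        threshold_day1 = t1, replicate_day1 = r1,
        threshold_day2 = t2, replicate_day2 = r2,
        duration = mi["duration"], occurrence = mi["occurrence"],
        coverage = mi["coverage"], transition = mi["transition"],
        pass = all(!is.na(mi[1:3])) && all(mi[1:3] >= 0.5))
    }
  }
  grid <- do.call(rbind, c(rows, make.row.names = FALSE))
  passing <- grid[grid$pass, , drop = FALSE]
  selection <- NULL
  if (nrow(passing)) {
    d <- abs(passing$threshold_day1 - passing$threshold_day2)
    o <- order(d, passing$threshold_day1, passing$threshold_day2)
    selection <- passing[o[1], , drop = FALSE]
  }
  list(grid = grid, selection = selection)
}

#' Welch power spectral density
#'
#' Averaged modified periodograms (Hamming taper) per channel over
#' sliding windows, then averaged across EEG channels; one-sided,
#' microvolts squared per Hz.
#'
#' @param rec an [recording()] object.
#' @param window_s window length in seconds (default 2).
#' @param overlap fractional window overlap (default 0.5).
#' @return List with `freq`, `mean` (channel-averaged PSD), `sd` (across
#'   channels), `per_channel` matrix.
#' @export
welch_psd <- function(rec, window_s = 2, overlap = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- n_samples(rec)
  w <- as.integer(round(window_s * rec$rate))
  if (w > n) stop("window longer than recording")
  step <- max(1L, as.integer(round(w * (1 - overlap))))
  starts <- seq(1L, n - w + 1L, by = step)
  taper <- 0.54 - 0.46 * cos(2 * pi * (seq_len(w) - 1L) / (w - 1L))
  u <- sum(taper^2)
  eeg <- eeg_channels(rec)
  n_f <- w %/% 2L + 1L
  psd <- matrix(0, nrow = n_f, ncol = length(eeg))
  for (s in starts) {
    seg <- rec$data[eeg, s:(s + w - 1L), drop = FALSE] * rep(taper, each =
                                                               length(eeg))
    sp <- abs(stats::mvfft(t(seg)))^2 / (rec$rate * u)
    sp <- sp[seq_len(n_f), , drop = FALSE]
    sp[2:(n_f - 1L), ] <- 2 * sp[2:(n_f - 1L), ]   # one-sided
    psd <- psd + sp
  }
  psd <- psd / length(starts)
  freq <- (seq_len(n_f) - 1L) * rec$rate / w
  list(freq = freq, mean = rowMeans(psd),
       sd = apply(psd, 1, stats::sd), per_channel = psd)
}

#' Event-related potential
#'
#' Epochs the recording around the selected events, subtracts each
#' channel's baseline-window mean per epoch, and averages per event
#' class. Out-of-bounds epochs are dropped.
#'
#' @param rec an [recording()] object.
#' @param events an `event_selection`, or a label pattern.
#' @param window epoch window relative to the event, seconds
#'   (default `c(-0.1, 0.6)`).
#' @param baseline baseline window in seconds (default `c(-0.1, 0)`).
#' @return List with `evoked` (channels x time mean), `times`,
#'   `n_epochs`.
#' @export
erp <- function(rec, events, window = c(-0.1, 0.6),
                baseline = c(-0.1, 0)) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.character(events)) events <- select_events(rec, events)
  ep <- epoch_around(rec, events, offset_s = window[1],
                     duration_s = diff(window))
  times <- window[1] + (seq_len(dim(ep$data)[3]) - 1L) / rec$rate
  bl <- times >= baseline[1] & times <= baseline[2]
  if (!any(bl)) stop("baseline window contains no samples")
  C <- dim(ep$data)[1]; E <- dim(ep$data)[2]
  for (e in seq_len(E))
    ep$data[, e, ] <- ep$data[, e, ] -
      rowMeans(ep$data[, e, bl, drop = FALSE])
  list(evoked = apply(ep$data, c(1, 3), mean), times = times,
       n_epochs = E)
}
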