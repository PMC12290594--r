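#' Construct an EEG recording
#'
#' The central container of the package: a multichannel time series in
#' microvolts together with its sampling rate, channel metadata, event
#' markers and a provenance log. All processing functions take and return
#' objects of this class.
#'
#' Sample indices are 1-based throughout the package; epochs and segment
#' masks use half-open intervals `[start, stop)`.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param rate sampling frequency in Hz (> 0).
#' @param ch_names character vector of unique channel labels, one per row
#'   of `data`.
#' @param ch_types per-channel role, each one of `"eeg"`, `"ecg"`, `"cwl"`,
#'   `"other"`. Recycled if length 1.
#' @param events data frame with columns `sample` (integer, in
#'   `[1, ncol(data)]`) and `label` (character), or `NULL` for none.
#' @param positions optional numeric matrix, channels x 3, sensor positions
#'   on (approximately) the unit sphere.
#' @param log character vector of provenance entries.
#' @return An object of class `eeg_recording`.
#' @examples
#' rec <- recording(matrix(rnorm(500), 2, 250), rate = 250,
#'                  ch_names = c("Cz", "Pz"))
#' rec
#' @export
recording <- function(data, rate, ch_names = NULL,
                      ch_types = "eeg", events = NULL,
                      positions = NULL, log = character()) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be a numeric matrix")
  if (is.null(ch_names)) ch_names <- paste0("ch", seq_len(nrow(data)))
  ch_names <- as.character(ch_names)
  if (length(ch_names) != nrow(data))
    stop("length(ch_names) must equal nrow(data)")
  if (anyDuplicated(ch_names))
    stop("duplicate channel labels: ",
         paste(unique(ch_names[duplicated(ch_names)]), collapse = ", "))
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a single positive number")
  if (length(ch_types) == 1L) ch_types <- rep(ch_types, nrow(data))
  if (length(ch_types) != nrow(data))
    stop("ch_types must have one entry per channel")
  bad <- setdiff(unique(ch_types), c("eeg", "ecg", "cwl", "other"))
  if (length(bad)) stop("unknown channel types: ", paste(bad, collapse = ", "))
  events <- normalize_events(events, ncol(data))
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    if (nrow(positions) != nrow(data) || ncol(positions) != 3L)
      stop("positions must be a channels x 3 matrix")
  }
  rownames(data) <- ch_names
  structure(list(data = data, rate = rate, ch_names = ch_names,
                 ch_types = ch_types, events = events,
                 positions = positions, log = as.character(log)),
            class = "eeg_recording")
}

normalize_events <- function(events, n_samples) {
  if (is.null(events) || (is.data.frame(events) && nrow(events) == 0L))
    return(data.frame(sample = integer(), label = character(),
                      stringsAsFactors = FALSE))
  events <- as.data.frame(events)
  if (!all(c("sample", "label") %in% names(events)))
    stop("events must have columns 'sample' and 'label'")
  events$sample <- as.integer(round(events$sample))
  events$label <- as.character(events$label)
  if (any(events$sample < 1L | events$sample > n_samples))
    stop("event sample index out of range [1, ", n_samples, "]")
  events <- events[order(events$sample), c("sample", "label"), drop = FALSE]
  rownames(events) <- NULL
  events
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate))
  tab <- table(x$ch_types)
  cat("  channels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  cat(sprintf("  events: %d (%d labels)\n", nrow(x$events),
              length(unique(x$events$label))))
  if (length(x$log))
    cat("  log:", utils::tail(x$log, 1L), sprintf("(%d entries)\n",
        length(x$log)))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec an `eeg_recording`.
#' @return integer sample count.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Indices of EEG-type channels
#' @param rec an `eeg_recording`.
#' @return integer vector of channel row indices with type `"eeg"`.
#' @export
eeg_channels <- function(rec) which(rec$ch_types == "eeg")

# Append one provenance entry; every public operation calls this exactly once.
log_op <- function(rec, entry) {
  rec$log <- c(rec$log, entry)
  rec
}

#' Select events by label pattern
#'
#' Matches event labels against a regular expression and returns the sorted,
#' de-duplicated sample indices of the matching events.
#'
#' @param rec an `eeg_recording`.
#' @param label_pattern regular expression matched against event labels
#'   (`grepl`); use e.g. `"^R$"` for exact matching.
#' @return An object of class `event_selection`: list with `label_pattern`
#'   and sorted integer `indices`. An empty selection is allowed.
#' @export
select_events <- function(rec, label_pattern) {
  stopifnot(inherits(rec, "eeg_recording"))
  hit <- grepl(label_pattern, rec$events$label)
  idx <- sort(unique(rec$events$sample[hit]))
  structure(list(label_pattern = label_pattern, indices = as.integer(idx)),
            class = "event_selection")
}

#' @export
print.event_selection <- function(x, ...) {
  cat(sprintf("<event_selection> pattern '%s': %d events\n",
              x$label_pattern, length(x$indices)))
  invisible(x)
}

as_event_selection <- function(x) {
  if (inherits(x, "event_selection")) return(x)
  structure(list(label_pattern = "<explicit>",
                 indices = as.integer(sort(unique(x)))),
            class = "event_selection")
}

# Run expr with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}
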