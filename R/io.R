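#' Load an EEG recording from disk
#'
#' Reads BrainVision (`.vhdr`/`.vmrk`/`.eeg` triplet), EDF/EDF+ (`.edf`),
#' or the package's lossless native container (`.rds`). Amplitudes are
#' converted to microvolts on load; annotations become events; channel
#' order follows the file.
#'
#' @param path path to the file (`.vhdr` for BrainVision).
#' @param format one of `"brainvision"`, `"edf"`, `"container"`, or
#'   `"auto"` (default: inferred from the file extension).
#' @return An [recording()] object.
#' @seealso [save_recording()]
#' @export
load_recording <- function(path, format = c("auto", "brainvision", "edf",
                                            "container")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     vhdr = "brainvision",
                     edf = "edf",
                     rds = "container",
                     stop("cannot infer format from extension '.", ext,
                          "'; pass format= explicitly"))
  }
  switch(format,
         brainvision = read_brainvision(path),
         edf = read_edf(path),
         container = read_container(path))
}

#' Save an EEG recording to disk
#'
#' BrainVision output is IEEE float32 (lossless for float32-representable
#' microvolt data); EDF output is 16-bit quantized and drops a trailing
#' partial second (1-second data records); the native container is
#' lossless and is the recommended intermediate between pipeline stages.
#'
#' @param rec an [recording()] object with at least one sample.
#' @param path output path (`.vhdr`, `.edf`, or `.rds`).
#' @param format as in [load_recording()].
#' @return The path written (the `.vhdr` path for BrainVision), invisibly.
#' @export
save_recording <- function(rec, path, format = c("auto", "brainvision",
                                                 "edf", "container")) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (n_samples(rec) == 0L) stop("empty recording")
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     vhdr = "brainvision",
                     edf = "edf",
                     rds = "container",
                     stop("cannot infer format from extension '.", ext, "'"))
  }
  out <- switch(format,
                brainvision = write_brainvision(rec, path),
                edf = write_edf(rec, path),
                container = write_container(rec, path))
  invisible(out)
}

read_container <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "eeg_recording"))
    stop("container does not hold an eeg_recording")
  obj
}

write_container <- function(rec, path) {
  saveRDS(rec, path, version = 3)
  path
}
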