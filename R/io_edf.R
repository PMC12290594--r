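# EDF / EDF+C reader and writer.
#
# Samples are stored as little-endian 16-bit integers scaled linearly
# between per-signal physical and digital extrema, so a write/read
# round-trip is exact only to the 16-bit quantization step
# (phys_range / 65535). Events are carried in an "EDF Annotations" signal
# as time-stamped annotation lists (TALs), making the output EDF+C.
#
# The writer uses 1-second data records and therefore drops a trailing
# partial second (with a provenance warning on the returned path's side);
# the native .rds container is the lossless intermediate.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

write_edf <- function(rec, path) {
  rate <- rec$rate
  if (abs(rate - round(rate)) > 1e-9)
    stop("EDF export requires an integer sampling rate; resample first")
  rate <- as.integer(round(rate))
  n_ch <- nrow(rec$data)
  n_rec <- n_samples(rec) %/% rate
  if (n_rec < 1L) stop("recording shorter than one EDF data record (1 s)")
  kept <- n_rec * rate
  ev <- rec$events[rec$events$sample <= kept, , drop = FALSE]

  # integer physical bounds: format exactly in the 8-char ASCII fields
  pmin <- floor(apply(rec$data[, seq_len(kept), drop = FALSE], 1, min))
  pmax <- ceiling(apply(rec$data[, seq_len(kept), drop = FALSE], 1, max))
  pmax <- ifelse(pmax <= pmin, pmin + 1, pmax)

  # assemble per-record TAL byte blocks; each TAL is nul-terminated
  onsets <- (ev$sample - 1) / rate
  rec_of <- pmin(floor(onsets), n_rec - 1)
  tals <- lapply(seq_len(n_rec) - 1L, function(r) {
    blocks <- list(c(charToRaw(sprintf("+%g\x14\x14", r)), as.raw(0L)))
    for (i in which(rec_of == r))
      blocks[[length(blocks) + 1L]] <-
        c(charToRaw(sprintf("+%.6f\x14%s\x14", onsets[i], ev$label[i])),
          as.raw(0L))
    do.call(c, blocks)
  })
  ann_bytes <- max(vapply(tals, length, integer(1))) + 2L
  ann_samp <- as.integer(ceiling(ann_bytes / 2))  # 2 bytes per "sample"

  ns <- n_ch + 1L
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edf_pad(x, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8); wr("X X X X", 80)
  wr("Startdate 01-JAN-2026 X X X", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256L * (1L + ns), 8); wr("EDF+C", 44)
  wr(n_rec, 8); wr("1", 8); wr(ns, 4)
  labs <- c(substr(rec$ch_names, 1, 16), "EDF Annotations")
  for (l in labs) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)                       # transducer
  for (i in seq_len(ns)) wr(if (i <= n_ch) "uV" else "", 8)
  for (i in seq_len(ns)) wr(if (i <= n_ch) pmin[i] else -1, 8)
  for (i in seq_len(ns)) wr(if (i <= n_ch) pmax[i] else 1, 8)
  for (i in seq_len(ns)) wr(-32768L, 8)
  for (i in seq_len(ns)) wr(32767L, 8)
  for (i in seq_len(ns)) wr("", 80)                       # prefilter
  for (i in seq_len(ns)) wr(if (i <= n_ch) rate else ann_samp, 8)
  for (i in seq_len(ns)) wr("", 32)

  scale <- 65535 / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * rate + 1L):(r * rate)
    for (i in seq_len(n_ch)) {
      dig <- round((rec$data[i, cols] - pmin[i]) * scale[i]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2L,
               endian = "little")
    }
    tal <- tals[[r]]
    writeBin(c(tal, raw(2L * ann_samp - length(tal))), con)
  }
  path
}

read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  ver <- rd(8)
  if (!identical(ver, "0"))
    stop("EDF header: unsupported version field '", ver, "'")
  rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("EDF header: bad signal count field")
  labs <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  dims <- vapply(seq_len(ns), function(i) rd(8), character(1))
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)

  is_ann <- labs == "EDF Annotations"
  sig <- which(!is_ann)
  if (!length(sig)) stop("EDF header: no data signals")
  rate <- spr[sig[1]] / rec_dur
  if (any(spr[sig] != spr[sig[1]]))
    stop("EDF header: signals with differing sampling rates are unsupported")
  unit_scale <- ifelse(grepl("^mV$", dims[sig]), 1000,
                       ifelse(grepl("^V$", dims[sig]), 1e6, 1))

  data <- matrix(0, nrow = length(sig), ncol = n_rec * spr[sig[1]])
  ann_raw <- list()
  gain <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (is_ann[i]) {
        ann_raw[[length(ann_raw) + 1L]] <- readBin(con, "raw",
                                                   n = 2L * spr[i])
      } else {
        dig <- readBin(con, "integer", n = spr[i], size = 2L,
                       endian = "little", signed = TRUE)
        j <- match(i, sig)
        data[j, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
          (pmin[i] + (dig - dmin[i]) * gain[i]) * unit_scale[j]
      }
    }
  }

  events <- NULL
  if (length(ann_raw)) {
    all_raw <- do.call(c, ann_raw)
    # split the byte stream into nul-terminated TALs
    nul <- which(all_raw == as.raw(0L))
    starts <- c(1L, utils::head(nul, -1L) + 1L)
    tals <- character(0)
    for (b in seq_along(nul)) {
      if (starts[b] <= nul[b] - 1L) {
        chunk <- all_raw[starts[b]:(nul[b] - 1L)]
        if (length(chunk)) tals <- c(tals, rawToChar(chunk))
      }
    }
    samp <- integer(); lab <- character()
    for (tal in tals) {
      fields <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
      if (length(fields) < 2) next
      txt <- fields[-1]
      txt <- txt[nzchar(txt)]
      if (!length(txt)) next  # record-keeping timestamp TAL
      onset <- as.numeric(sub("\x15.*$", "", fields[1]))
      for (t in txt) {
        samp <- c(samp, as.integer(round(onset * rate)) + 1L)
        lab <- c(lab, t)
      }
    }
    if (length(samp))
      events <- data.frame(sample = samp, label = lab,
                           stringsAsFactors = FALSE)
  }

  nm <- labs[sig]
  recording(data, rate = rate, ch_names = nm,
            ch_types = guess_ch_type(nm), events = events,
            log = sprintf("load_recording(edf: %s)", basename(path)))
}
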