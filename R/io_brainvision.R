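# BrainVision (.vhdr/.vmrk/.eeg) reader and writer.
#
# The header and marker files are INI-style text; the data file is raw
# binary, multiplexed or vectorized, IEEE float32 or int16 with a
# per-channel resolution. The writer emits IEEE_FLOAT_32 MULTIPLEXED with
# resolution 1 in microvolts, which is lossless for float32-representable
# data.

parse_vhdr_ini <- function(lines) {
  sec <- NULL
  out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      sec <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[sec]])) out[[sec]] <- list()
    } else if (grepl("=", ln) && !is.null(sec)) {
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      out[[sec]][[key]] <- val
    }
  }
  out
}

vhdr_field <- function(ini, section, key) {
  v <- ini[[section]][[key]]
  if (is.null(v))
    stop(sprintf("BrainVision header: missing field '%s' in [%s]",
                 key, section))
  v
}

# Infer channel role from its label; BrainVision carries no type field.
guess_ch_type <- function(nm) {
  ifelse(grepl("^(ECG|EKG)", nm, ignore.case = TRUE), "ecg",
         ifelse(grepl("^CWL", nm, ignore.case = TRUE), "cwl", "eeg"))
}

read_brainvision <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ini <- parse_vhdr_ini(readLines(path, warn = FALSE))
  if (is.null(ini[["Common Infos"]]))
    stop("BrainVision header: missing field '[Common Infos]' in header")
  dir <- dirname(path)
  data_file <- file.path(dir, vhdr_field(ini, "Common Infos", "DataFile"))
  marker_file <- ini[["Common Infos"]][["MarkerFile"]]
  fmt <- toupper(vhdr_field(ini, "Common Infos", "DataFormat"))
  if (fmt != "BINARY")
    stop("BrainVision header: unsupported DataFormat '", fmt, "'")
  orient <- toupper(vhdr_field(ini, "Common Infos", "DataOrientation"))
  n_ch <- as.integer(vhdr_field(ini, "Common Infos", "NumberOfChannels"))
  si_us <- as.numeric(vhdr_field(ini, "Common Infos", "SamplingInterval"))
  rate <- 1e6 / si_us
  bin_fmt <- toupper(vhdr_field(ini, "Binary Infos", "BinaryFormat"))

  chs <- ini[["Channel Infos"]]
  if (is.null(chs) || length(chs) < n_ch)
    stop("BrainVision header: missing field 'Ch", length(chs) + 1,
         "' in [Channel Infos]")
  ch_names <- character(n_ch)
  resolution <- rep(1, n_ch)
  for (i in seq_len(n_ch)) {
    parts <- strsplit(chs[[paste0("Ch", i)]], ",")[[1]]
    ch_names[i] <- gsub("\\\\1", ",", trimws(parts[1]))
    if (length(parts) >= 3 && nzchar(trimws(parts[3])))
      resolution[i] <- as.numeric(parts[3])
  }

  if (!file.exists(data_file))
    stop("BrainVision triplet inconsistency: data file '",
         basename(data_file), "' named in header does not exist")
  sz <- file.info(data_file)$size
  if (bin_fmt == "IEEE_FLOAT_32") {
    what <- "numeric"; bytes <- 4L
  } else if (bin_fmt == "INT_16") {
    what <- "integer"; bytes <- 2L
  } else stop("BrainVision header: unsupported BinaryFormat '", bin_fmt, "'")
  n_total <- as.integer(sz / (bytes * n_ch)) * n_ch
  con <- file(data_file, "rb")
  on.exit(close(con))
  raw_vals <- readBin(con, what, n = n_total, size = bytes,
                      endian = "little", signed = TRUE)
  n_samp <- length(raw_vals) %/% n_ch
  if (orient == "MULTIPLEXED") {
    data <- matrix(raw_vals, nrow = n_ch, ncol = n_samp)
  } else if (orient == "VECTORIZED") {
    data <- t(matrix(raw_vals, nrow = n_samp, ncol = n_ch))
  } else stop("BrainVision header: unsupported DataOrientation '", orient, "'")
  data <- data * resolution

  events <- NULL
  if (!is.null(marker_file)) {
    mf <- file.path(dir, marker_file)
    if (!file.exists(mf))
      stop("BrainVision triplet inconsistency: marker file '", marker_file,
           "' named in header does not exist")
    mini <- parse_vhdr_ini(readLines(mf, warn = FALSE))
    mks <- mini[["Marker Infos"]]
    if (!is.null(mks)) {
      samp <- integer(); lab <- character()
      for (key in names(mks)) {
        if (!grepl("^Mk[0-9]+$", key)) next
        parts <- strsplit(mks[[key]], ",")[[1]]
        if (trimws(parts[1]) == "New Segment") next
        desc <- trimws(parts[2])
        if (!nzchar(desc)) desc <- trimws(parts[1])
        pos <- as.integer(parts[3])
        if (pos >= 1 && pos <= n_samp) {
          samp <- c(samp, pos); lab <- c(lab, gsub("\\\\1", ",", desc))
        }
      }
      if (length(samp))
        events <- data.frame(sample = samp, label = lab,
                             stringsAsFactors = FALSE)
    }
  }

  recording(data, rate = rate, ch_names = ch_names,
            ch_types = guess_ch_type(ch_names), events = events,
            log = sprintf("load_recording(brainvision: %s)", basename(path)))
}

write_brainvision <- function(rec, path) {
  stem <- sub("\\.vhdr$", "", path)
  vhdr <- paste0(stem, ".vhdr")
  vmrk <- paste0(stem, ".vmrk")
  eeg <- paste0(stem, ".eeg")
  n_ch <- nrow(rec$data)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", basename(eeg)),
    paste0("MarkerFile=", basename(vmrk)),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", n_ch),
    paste0("SamplingInterval=", format(1e6 / rec$rate, digits = 15)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(n_ch),
            gsub(",", "\\\\1", rec$ch_names)))
  writeLines(hdr, vhdr, useBytes = TRUE)
  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", basename(eeg)),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0")
  if (nrow(rec$events))
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                        seq_len(nrow(rec$events)) + 1L,
                        gsub(",", "\\\\1", rec$events$label),
                        rec$events$sample))
  writeLines(mk, vmrk, useBytes = TRUE)
  con <- file(eeg, "wb")
  writeBin(as.numeric(rec$data), con, size = 4L, endian = "little")
  close(con)
  vhdr
}
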