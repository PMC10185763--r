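# Minimal EDF/EDF+ input and output.
#
# EDF stores an ASCII header (256 bytes + 256 per signal) followed by data
# records of little-endian int16 samples, linearly mapped between a digital
# and a physical range per signal. This reader handles plain EDF and the
# EDF+ "EDF Annotations" channel (time-stamped annotation lists), which is
# exposed as an event_list. No R package in the dependency set reads EDF,
# so the format is parsed here directly.

.edf_field <- function(raw, start, len) {
  trimws(rawToChar(raw[start:(start + len - 1L)]))
}

.edf_pad <- function(x, len) {
  x <- as.character(x)
  if (nchar(x) > len) x <- substr(x, 1L, len)
  formatC(x, width = -len)   # left-justified, space padded
}

#' Read an EDF/EDF+ file
#'
#' Reads all ordinary signal channels at their single common sampling rate
#' and, when an EDF+ annotation channel is present, parses its time-stamped
#' annotations into an [event_list()] (onsets converted to 0-based sample
#' indices). Files whose ordinary channels have different sampling rates
#' are rejected; no resampling is performed. Non-numeric annotation labels
#' are mapped to dense integer codes in first-appearance order (the mapping
#' is reported via `message()` and stored in the `label_map` attribute of
#' the returned events).
#'
#' @param path Path to an EDF/EDF+ file.
#' @return A [continuous_recording()]; `$events` is an [event_list()] or
#'   `NULL`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 256L)
  if (length(hdr) < 256L) stop("corrupt EDF header: file too short")
  n_header <- suppressWarnings(as.integer(.edf_field(hdr, 185L, 8L)))
  n_records <- suppressWarnings(as.integer(.edf_field(hdr, 237L, 8L)))
  rec_dur <- suppressWarnings(as.numeric(.edf_field(hdr, 245L, 8L)))
  ns <- suppressWarnings(as.integer(.edf_field(hdr, 253L, 4L)))
  if (is.na(ns) || ns < 1L || is.na(rec_dur) || rec_dur <= 0)
    stop("corrupt EDF header")
  sig_hdr <- readBin(con, "raw", 256L * ns)
  if (length(sig_hdr) < 256L * ns) stop("corrupt EDF header: truncated")
  # offsets within the per-signal header block, in bytes per field group:
  # label 16, transducer 80, phys dim 8, phys min 8, phys max 8,
  # dig min 8, dig max 8, prefilter 80, n samples 8, reserved 32
  off <- c(label = 0L, transducer = 16L, dim = 96L, pmin = 104L, pmax = 112L,
           dmin = 120L, dmax = 128L, prefilter = 136L, nsamp = 216L)
  getf <- function(name, len) vapply(seq_len(ns), function(s)
    .edf_field(sig_hdr, off[[name]] * ns + (s - 1L) * len + 1L, len), "")
  labels <- getf("label", 16L)
  phys_min <- as.numeric(getf("pmin", 8L))
  phys_max <- as.numeric(getf("pmax", 8L))
  dig_min <- as.numeric(getf("dmin", 8L))
  dig_max <- as.numeric(getf("dmax", 8L))
  nsamp <- as.integer(getf("nsamp", 8L))
  if (anyNA(c(phys_min, phys_max, dig_min, dig_max, nsamp)))
    stop("corrupt EDF header: unparseable signal fields")

  is_annot <- labels == "EDF Annotations"
  data_raw <- readBin(con, "raw", n = file.size(path) - n_header)
  rec_bytes <- sum(nsamp) * 2L
  if (is.na(n_records) || n_records < 0L)
    n_records <- length(data_raw) %/% rec_bytes
  if (length(data_raw) < n_records * rec_bytes)
    stop("corrupt EDF file: truncated data records")

  sig_idx <- which(!is_annot)
  if (!length(sig_idx)) stop("EDF file contains no signal channels")
  fs_all <- nsamp[sig_idx] / rec_dur
  if (length(unique(fs_all)) > 1L)
    stop("heterogeneous sampling rates across channels: ",
         paste(unique(fs_all), collapse = ", "), " Hz")
  fs <- fs_all[1]

  offsets <- cumsum(c(0L, nsamp * 2L))  # byte offset of each signal in a record
  signals <- matrix(0, nrow = length(sig_idx), ncol = n_records * nsamp[sig_idx[1]])
  annot_txt <- character(0)
  for (r in seq_len(n_records)) {
    base <- (r - 1L) * rec_bytes
    for (j in seq_along(sig_idx)) {
      s <- sig_idx[j]
      seg <- data_raw[(base + offsets[s] + 1L):(base + offsets[s] + nsamp[s] * 2L)]
      dig <- readBin(seg, "integer", n = nsamp[s], size = 2L, signed = TRUE,
                     endian = "little")
      phys <- phys_min[s] + (dig - dig_min[s]) *
        (phys_max[s] - phys_min[s]) / (dig_max[s] - dig_min[s])
      signals[j, ((r - 1L) * nsamp[s] + 1L):(r * nsamp[s])] <- phys
    }
    for (s in which(is_annot)) {
      seg <- data_raw[(base + offsets[s] + 1L):(base + offsets[s] + nsamp[s] * 2L)]
      seg[seg == as.raw(0L)] <- as.raw(10L)   # TAL separator -> newline
      annot_txt <- c(annot_txt, strsplit(rawToChar(seg), "\n", fixed = TRUE)[[1]])
    }
  }

  events <- .parse_edf_annotations(annot_txt, fs)
  continuous_recording(signals, fs, labels[sig_idx], events)
}

# Annotations are TALs: "+onset[\x15duration]\x14text\x14...", one per
# element of txt (already split on the NUL TAL separator).
.parse_edf_annotations <- function(txt, fs) {
  tals <- txt[nzchar(txt)]
  if (!length(tals)) return(NULL)
  onsets <- numeric(0); texts <- character(0)
  for (tal in tals) {
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    if (length(parts) < 2L) next   # bare timestamp TAL
    stamp <- strsplit(parts[1], "\x15", fixed = TRUE)[[1]][1]
    onset <- suppressWarnings(as.numeric(stamp))
    if (is.na(onset)) next
    for (lab in parts[-1]) {
      if (!nzchar(lab)) next
      onsets <- c(onsets, onset)
      texts <- c(texts, lab)
    }
  }
  if (!length(onsets)) return(NULL)
  ord <- order(onsets)
  onsets <- onsets[ord]; texts <- texts[ord]
  num <- suppressWarnings(as.integer(texts))
  if (anyNA(num)) {
    levels <- unique(texts)
    num <- match(texts, levels) - 1L
    message("annotation labels mapped to integers: ",
            paste(sprintf("%s=%d", levels, seq_along(levels) - 1L),
                  collapse = ", "))
    ev <- event_list(round(onsets * fs), num)
    attr(ev, "label_map") <- levels
    ev
  } else {
    event_list(round(onsets * fs), num)
  }
}

#' Write a continuous recording as EDF
#'
#' Minimal EDF writer used for round trips and fixtures: one-second data
#' records, symmetric physical range per channel, 16-bit quantization,
#' physical dimension microvolts, no annotation channel. The recording is
#' truncated to a whole number of seconds (with a warning) because EDF
#' records have fixed duration.
#'
#' @param recording A [continuous_recording()].
#' @param path Output path.
#' @param physical_max Optional physical range bound; defaults to the
#'   maximum absolute sample value per channel.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, physical_max = NULL) {
  stopifnot(inherits(recording, "continuous_recording"))
  fs <- recording$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  X <- recording$data
  n_records <- ncol(X) %/% fs
  if (n_records < 1L) stop("recording shorter than one EDF record (1 s)")
  if (ncol(X) != n_records * fs) {
    warning("recording truncated to ", n_records, " whole second(s)")
    X <- X[, seq_len(n_records * fs), drop = FALSE]
  }
  ns <- nrow(X)
  pmax <- if (is.null(physical_max)) pmax(apply(abs(X), 1L, max), 1e-9)
          else rep_len(physical_max, ns)
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, len) writeChar(.edf_pad(x, len), con, nchars = len,
                                   eos = NULL)
  wr("0", 8L)                             # version
  wr("X X X X", 80L)                      # patient id
  wr("Startdate X X X X", 80L)            # recording id
  wr("01.01.01", 8L); wr("00.00.00", 8L)  # start date/time
  wr(256L + 256L * ns, 8L)                # header bytes
  wr("", 44L)
  wr(n_records, 8L)
  wr("1", 8L)                             # record duration, s
  wr(ns, 4L)
  for (nm in recording$channel_names) wr(nm, 16L)
  for (i in seq_len(ns)) wr("", 80L)                      # transducer
  for (i in seq_len(ns)) wr("uV", 8L)                     # phys dim
  for (i in seq_len(ns)) wr(sprintf("%.6g", -pmax[i]), 8L)
  for (i in seq_len(ns)) wr(sprintf("%.6g", pmax[i]), 8L)
  for (i in seq_len(ns)) wr(dmin, 8L)
  for (i in seq_len(ns)) wr(dmax, 8L)
  for (i in seq_len(ns)) wr("", 80L)                      # prefilter
  for (i in seq_len(ns)) wr(fs, 8L)                       # samples per record
  for (i in seq_len(ns)) wr("", 32L)

  for (r in seq_len(n_records)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns)) {
      dig <- round((X[i, cols] + pmax[i]) / (2 * pmax[i]) * (dmax - dmin) + dmin)
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
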