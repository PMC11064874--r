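#' Read a WFDB record (minimal reader)
#'
#' Reads single- or multi-channel PhysioNet WFDB records stored in the two
#' formats used by the MIT-BIH databases: format 212 (two channels packed
#' into 3 bytes per sample pair) and format 16 (16-bit little-endian).
#' Samples are converted to physical units via the per-channel gain and
#' baseline from the header.
#'
#' @param record Path to the record (with or without the `.hea` extension).
#' @param channel 1-based channel index (default 1).
#' @return An [ecg_signal] in physical units.
#' @export
read_wfdb <- function(record, channel = 1L) {
  hea <- if (grepl("\\.hea$", record)) record else paste0(record, ".hea")
  if (!file.exists(hea))
    stop_invalid_input(sprintf("header file not found: %s", hea))
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  head_fields <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n_sig <- as.integer(head_fields[2])
  fs <- if (length(head_fields) >= 3) as.numeric(sub("/.*", "", head_fields[3])) else 250
  n_samp <- if (length(head_fields) >= 4) as.integer(head_fields[4]) else NA_integer_
  if (is.na(n_sig) || n_sig < 1)
    stop_invalid_input("malformed WFDB header")
  if (channel < 1 || channel > n_sig)
    stop_invalid_input(sprintf("channel %d out of range (record has %d)",
                               channel, n_sig))
  sig_lines <- lines[2:(1 + n_sig)]
  sig <- lapply(sig_lines, function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    fmt <- sub("x.*|:.*|\\+.*", "", f[2])
    gain_field <- if (length(f) >= 3) f[3] else "200"
    gain <- as.numeric(sub("\\(.*", "", sub("/.*", "", gain_field)))
    baseline <- if (grepl("\\(", gain_field))
      as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_field)) else 0
    if (is.na(gain) || gain == 0) gain <- 200
    list(file = f[1], fmt = fmt, gain = gain, baseline = baseline)
  })
  fmts <- vapply(sig, `[[`, "", "fmt")
  if (length(unique(vapply(sig, `[[`, "", "file"))) != 1L)
    stop_invalid_input("multi-file WFDB records are not supported")
  dat <- file.path(dirname(hea), sig[[1]]$file)
  if (!file.exists(dat))
    stop_invalid_input(sprintf("signal file not found: %s", dat))
  raw_bytes <- readBin(dat, "raw", n = file.info(dat)$size)
  fmt <- unique(fmts)
  if (length(fmt) != 1L || !fmt %in% c("212", "16"))
    stop_invalid_input(sprintf("unsupported WFDB format(s): %s",
                               paste(fmts, collapse = ", ")))
  adc <- if (fmt == "212") decode_fmt212(raw_bytes, n_sig) else
    decode_fmt16(raw_bytes, n_sig)
  if (!is.na(n_samp)) adc <- adc[seq_len(min(nrow(adc), n_samp)), , drop = FALSE]
  ch <- sig[[channel]]
  ecg_signal((adc[, channel] - ch$baseline) / ch$gain, fs)
}

# Format 212: successive 12-bit two's-complement samples packed in 3-byte
# groups; bytes 1 and 3 are the low 8 bits, byte 2 holds the two high
# nibbles (low nibble -> first sample, high nibble -> second sample).
decode_fmt212 <- function(bytes, n_sig) {
  n_grp <- length(bytes) %/% 3L
  b <- matrix(as.integer(bytes[seq_len(3L * n_grp)]), nrow = 3L)
  s1 <- b[1, ] + bitwShiftL(bitwAnd(b[2, ], 0x0FL), 8L)
  s2 <- b[3, ] + bitwShiftL(bitwShiftR(b[2, ], 4L), 8L)
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  flat <- as.vector(rbind(s1, s2))
  n_frames <- length(flat) %/% n_sig
  matrix(flat[seq_len(n_frames * n_sig)], ncol = n_sig, byrow = TRUE)
}

# Format 16: 16-bit little-endian two's complement, channel-interleaved.
decode_fmt16 <- function(bytes, n_sig) {
  vals <- readBin(bytes, "integer", n = length(bytes) %/% 2L, size = 2L,
                  signed = TRUE, endian = "little")
  n_frames <- length(vals) %/% n_sig
  matrix(vals[seq_len(n_frames * n_sig)], ncol = n_sig, byrow = TRUE)
}

#' Read a signal from a one-column CSV or plain-text file
#'
#' Accepts one sample per line; a non-numeric first line is treated as a
#' header.  Multi-column files use `column`.
#'
#' @param path Input file.
#' @param fs Sampling rate in Hz (not stored in the file).
#' @param column Column index for multi-column files (default 1).
#' @return An [ecg_signal].
#' @export
read_signal_csv <- function(path, fs, column = 1L) {
  if (!file.exists(path))
    stop_invalid_input(sprintf("input file not found: %s", path))
  first <- readLines(path, n = 1L)
  has_header <- suppressWarnings(
    any(is.na(as.numeric(strsplit(first, ",")[[1]]))))
  df <- read.csv(path, header = has_header)
  ecg_signal(as.numeric(df[[column]]), fs)
}
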