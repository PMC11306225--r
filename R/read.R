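# Readers for the two supported on-disk layouts: WFDB header+signal records
# (as distributed by the MIMIC-II waveform archive) and delimited text tables
# with a time column (the Aurora-BP sample-data layout).

CANONICAL_FS <- 125

# Map raw channel descriptions to canonical names.
canonical_channel <- function(desc) {
  d <- toupper(trimws(desc))
  if (grepl("PLETH|PPG", d)) return("PPG")
  if (grepl("^ABP|ART", d)) return("ABP")
  if (d %in% c("I", "II", "III", "V", "MCL1") || grepl("ECG|EKG", d)) return("ECG")
  NA_character_
}

#' Read a WFDB record
#'
#' Minimal reader for WFDB header (`.hea`) plus binary signal (`.dat`)
#' pairs in formats 212, 16 and 80, the formats used by the MIMIC-II
#' waveform archive. Channels are mapped to canonical names
#' (PLETH -> PPG, ABP/ART -> ABP, lead II etc. -> ECG); digital values are
#' converted to physical units via each signal's gain and baseline.
#'
#' @param path Path to the `.hea` file (with or without the extension).
#' @param resample_to Optional target sampling rate in Hz; when given and
#'   different from the header rate, channels are polyphase-resampled and
#'   the original rate is kept in `$meta$original_fs`.
#' @return A [signal_record()]. The patient id is parsed from the WFDB
#'   record-naming convention (`<patient>_<record>`).
#' @export
read_wfdb_record <- function(path, resample_to = NULL) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stopf("WFDB header not found: %s", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  head_tok <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(head_tok) < 3L) stopf("malformed WFDB header line: %s", lines[1L])
  rec_name <- sub("/.*$", "", head_tok[1L])
  n_sig <- as.integer(head_tok[2L])
  fs <- as.numeric(sub("/.*$", "", head_tok[3L]))
  n_samp <- if (length(head_tok) >= 4L) as.integer(head_tok[4L]) else NA_integer_
  if (is.na(n_sig) || n_sig < 1L) stopf("header declares no signals")

  sig <- lapply(lines[2L:(1L + n_sig)], function(l) {
    tok <- strsplit(trimws(l), "\\s+")[[1L]]
    fmt <- sub("[x:+].*$", "", tok[2L])
    gain_spec <- if (length(tok) >= 3L) tok[3L] else "200"
    gain <- as.numeric(sub("[(/].*$", "", gain_spec))
    if (!is.finite(gain) || gain == 0) gain <- 200
    baseline <- if (grepl("\\(", gain_spec)) {
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_spec))
    } else if (length(tok) >= 5L && !is.na(suppressWarnings(as.numeric(tok[5L])))) {
      as.numeric(tok[5L])  # adc_zero
    } else 0
    desc <- if (length(tok) >= 9L) paste(tok[9L:length(tok)], collapse = " ") else tok[1L]
    list(file = tok[1L], format = fmt, gain = gain, baseline = baseline, desc = desc)
  })

  files <- unique(vapply(sig, `[[`, "", "file"))
  digital <- vector("list", n_sig)
  for (f in files) {
    idx <- which(vapply(sig, `[[`, "", "file") == f)
    fmt <- sig[[idx[1L]]]$format
    datp <- file.path(dirname(hea), f)
    if (!file.exists(datp)) stopf("WFDB signal file not found: %s", datp)
    raw <- readBin(datp, "raw", n = file.info(datp)$size)
    vals <- switch(fmt,
      "16" = {
        v <- readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
                     signed = TRUE, endian = "little")
        v
      },
      "80" = as.integer(raw) - 128L,
      "212" = decode_fmt212(raw),
      stopf("unsupported WFDB signal format: %s", fmt)
    )
    k <- length(idx)
    usable <- (length(vals) %/% k) * k
    m <- matrix(vals[seq_len(usable)], nrow = k)
    for (j in seq_along(idx)) digital[[idx[j]]] <- m[j, ]
  }

  channels <- list()
  for (j in seq_len(n_sig)) {
    nm <- canonical_channel(sig[[j]]$desc)
    if (is.na(nm) || nm %in% names(channels)) next
    v <- digital[[j]]
    if (!is.na(n_samp) && n_samp > 0L && length(v) >= n_samp) v <- v[seq_len(n_samp)]
    channels[[nm]] <- (v - sig[[j]]$baseline) / sig[[j]]$gain
  }
  if (length(channels) == 0L)
    stopf("record %s has no recognized PPG/ABP/ECG channel", rec_name)
  lens <- vapply(channels, length, 0L)
  channels <- lapply(channels, function(v) v[seq_len(min(lens))])

  ids <- strsplit(rec_name, "[_-]")[[1L]]
  rec <- signal_record(
    patient_id = ids[1L],
    record_id = if (length(ids) > 1L) paste(ids[-1L], collapse = "-") else rec_name,
    channels = channels, fs = fs
  )
  if (!is.null(resample_to) && resample_to != fs) rec <- resample_record(rec, resample_to)
  rec
}

# WFDB format 212: two 12-bit two's-complement samples packed in 3 bytes.
decode_fmt212 <- function(raw) {
  b <- as.integer(raw)
  n3 <- (length(b) %/% 3L) * 3L
  b1 <- b[seq(1L, n3, by = 3L)]
  b2 <- b[seq(2L, n3, by = 3L)]
  b3 <- b[seq(3L, n3, by = 3L)]
  s1 <- b1 + bitwShiftL(bitwAnd(b2, 0x0FL), 8L)
  s2 <- b3 + bitwShiftL(bitwAnd(b2, 0xF0L), 4L)
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  as.integer(rbind(s1, s2))
}

#' Read a columnar text record
#'
#' Reads a delimited text file with a time column and one or more signal
#' columns (the Aurora-BP sample-data layout). Sampling must be regular:
#' the time column has to be strictly increasing with jitter below 10% of
#' the median sample period.
#'
#' @param path Delimited text file (separator sniffed from the header line).
#' @param schema Named character vector mapping canonical channel names to
#'   column names, e.g. `c(PPG = "ppg", ECG = "ecg")`.
#' @param time_col Name of the time column (seconds). Default `"t"`.
#' @param patient_id,record_id Identifiers; default to the file name.
#' @param resample_to Optional target sampling rate (Hz).
#' @return A [signal_record()].
#' @export
read_table_record <- function(path, schema, time_col = "t",
                              patient_id = NULL, record_id = NULL,
                              resample_to = NULL) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.csv(path, sep = sep, check.names = FALSE)
  if (!time_col %in% names(df)) stopf("time column '%s' not found", time_col)
  t <- as.numeric(df[[time_col]])
  if (length(t) < 2L) stopf("need at least two samples")
  dt <- diff(t)
  if (any(dt <= 0)) stopf("time column is not strictly increasing")
  period <- median(dt)
  if (any(abs(dt - period) > 0.1 * period))
    stopf("irregular sampling: jitter exceeds 10%% of the sample period")
  fs <- 1 / period
  missing_cols <- setdiff(unname(schema), names(df))
  if (length(missing_cols))
    stopf("schema columns not in file: %s", paste(missing_cols, collapse = ", "))
  channels <- lapply(schema, function(col) as.numeric(df[[col]]))
  names(channels) <- names(schema)
  base <- sub("\\.[^.]*$", "", basename(path))
  rec <- signal_record(patient_id %||% base, record_id %||% base, channels, fs)
  if (!is.null(resample_to) && abs(resample_to - fs) > 1e-9)
    rec <- resample_record(rec, resample_to)
  rec
}

#' Write a record as a columnar text table
#'
#' Inverse of [read_table_record()]: one `t` column in seconds plus one
#' column per channel.
#'
#' @param record A `signal_record`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table_record <- function(record, path) {
  n <- length(record$channels[[1L]])
  df <- data.frame(t = (seq_len(n) - 1L) / record$fs)
  for (nm in names(record$channels)) df[[nm]] <- record$channels[[nm]]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Resample every channel of a record
#'
#' Polyphase resampling to a new rate using a rational approximation of the
#' rate ratio (denominator capped at 1000).
#'
#' @param record A `signal_record`.
#' @param fs_target Target sampling rate, Hz.
#' @return The resampled record; `$meta$original_fs` records the input rate.
#' @export
resample_record <- function(record, fs_target) {
  ratio <- fs_target / record$fs
  pq <- rational_approx(ratio, 1000L)
  out <- record
  out$channels <- lapply(record$channels, function(x)
    as.numeric(signal::resample(x, pq[1L], pq[2L])))
  lens <- vapply(out$channels, length, 0L)
  out$channels <- lapply(out$channels, function(v) v[seq_len(min(lens))])
  out$fs <- fs_target
  out$meta <- c(record$meta, list(original_fs = record$fs))
  out
}

# Continued-fraction rational approximation p/q of x with q <= max_q.
rational_approx <- function(x, max_q = 1000L) {
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L
  r <- x
  for (i in 1:64) {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_q) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < 1e-12) break
    if (abs(r - a) < 1e-12) break
    r <- 1 / (r - a)
  }
  c(as.integer(round(p1)), as.integer(round(q1)))
}
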