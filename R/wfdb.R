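#' Write a single-channel record in minimal WFDB format
#'
#' Writes `<record>.hea` and `<record>.dat` (format 16: little-endian int16).
#' Only the subset of the header needed to round-trip a single-lead, uniformly
#' sampled record is produced: record line plus one signal line with gain and
#' units. Amplitudes are quantized at `gain` ADC units per mV.
#'
#' @param ecg an `ecg_record` (see [gen_ecg()]).
#' @param dir output directory (created if missing).
#' @param record record name (defaults to the subject id).
#' @param gain ADC units per millivolt.
#' @return invisibly, the record path prefix.
#' @export
write_wfdb <- function(ecg, dir, record = ecg$subject_id, gain = 1000) {
  stopifnot(inherits(ecg, "ecg_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  adc <- as.integer(round(ecg$samples * gain))
  adc[adc > 32767L] <- 32767L
  adc[adc < -32768L] <- -32768L
  hea <- file.path(dir, paste0(record, ".hea"))
  dat <- file.path(dir, paste0(record, ".dat"))
  n <- length(adc)
  writeLines(c(
    sprintf("%s 1 %g %d", record, ecg$fs, n),
    sprintf("%s.dat 16 %g/mV 16 0 %d 0 0 ECG", record, gain, adc[1])
  ), hea)
  con <- file(dat, "wb")
  on.exit(close(con))
  writeBin(adc, con, size = 2L, endian = "little")
  invisible(file.path(dir, record))
}

#' Read a record written by [write_wfdb()]
#'
#' @param path record path prefix (no extension).
#' @return an `ecg_record`.
#' @export
read_wfdb <- function(path) {
  hea <- readLines(paste0(path, ".hea"))
  rec <- strsplit(hea[1], " +")[[1]]
  sig <- strsplit(hea[2], " +")[[1]]
  fs <- as.numeric(rec[3])
  n <- as.integer(rec[4])
  gain <- as.numeric(sub("/mV$", "", sig[3]))
  con <- file(paste0(path, ".dat"), "rb")
  on.exit(close(con))
  adc <- readBin(con, "integer", n = n, size = 2L, signed = TRUE, endian = "little")
  ecg_record(basename(path), fs = fs, samples = adc / gain, t0 = 0)
}
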