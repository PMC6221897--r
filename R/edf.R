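#' Construct a continuous multichannel recording
#'
#' @param data channel x time numeric matrix, in µV.
#' @param sampling_rate Sampling rate in Hz (shared by all channels).
#' @param channel_labels Unique channel label strings.
#' @return An object of class `plv_recording`.
#' @export
new_recording <- function(data, sampling_rate, channel_labels) {
  stopifnot(is.matrix(data), nrow(data) == length(channel_labels))
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique", call. = FALSE)
  }
  structure(
    list(data = data, sampling_rate = sampling_rate,
         channel_labels = as.character(channel_labels)),
    class = "plv_recording"
  )
}

#' @export
print.plv_recording <- function(x, ...) {
  cat(sprintf("<plv_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate))
  invisible(x)
}

pad8 <- function(x) {
  s <- as.character(x)
  if (nchar(s) > 8) s <- substr(s, 1, 8)
  formatC(s, width = 8, flag = "-")
}

padn <- function(x, n) {
  s <- as.character(x)
  if (nchar(s) > n) s <- substr(s, 1, n)
  formatC(s, width = n, flag = "-")
}

# 8-char ASCII numeric field fitting EDF header slots
num8 <- function(x) {
  s <- formatC(signif(x, 7), format = "g", digits = 7, width = 1)
  while (nchar(s) > 8) {
    s <- formatC(signif(x, 7), format = "g",
                 digits = max(1, 7 - (nchar(s) - 8)), width = 1)
    x <- signif(x, 6)
  }
  pad8(s)
}

#' Write a recording as a 16-bit EDF file
#'
#' Standard European Data Format: 256-byte fixed header plus 256 bytes per
#' signal, then little-endian 16-bit data records of one second each. The
#' final record is zero-padded when the recording length is not a whole number
#' of seconds. Physical calibration (min/max) is taken from each channel's data
#' range.
#'
#' @param recording A `plv_recording`; the sampling rate must be an integer.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "plv_recording"))
  fs <- recording$sampling_rate
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate", call. = FALSE)
  fs <- as.integer(fs)
  x <- recording$data
  nc <- nrow(x)
  n <- ncol(x)
  n_rec <- ceiling(n / fs)
  if (n_rec * fs > n) {
    x <- cbind(x, matrix(0, nrow = nc, ncol = n_rec * fs - n))
  }

  pmin_ <- apply(x, 1, min)
  pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ <= 0
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768L
  dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL, useBytes = TRUE)
  wr(pad8("0"))
  wr(padn("synthetic subject", 80))
  wr(padn("plvnet session", 80))
  wr(padn("01.01.20", 8)); wr(padn("00.00.00", 8))
  wr(pad8(256 * (nc + 1)))
  wr(padn("", 44))
  wr(pad8(n_rec))
  wr(pad8(1))
  wr(formatC(as.character(nc), width = 4, flag = "-"))
  for (lab in recording$channel_labels) wr(padn(lab, 16))
  for (i in seq_len(nc)) wr(padn("", 80))          # transducer
  for (i in seq_len(nc)) wr(pad8("uV"))            # physical dimension
  for (i in seq_len(nc)) wr(num8(pmin_[i]))
  for (i in seq_len(nc)) wr(num8(pmax_[i]))
  for (i in seq_len(nc)) wr(pad8(dmin))
  for (i in seq_len(nc)) wr(pad8(dmax))
  for (i in seq_len(nc)) wr(padn("", 80))          # prefiltering
  for (i in seq_len(nc)) wr(pad8(fs))
  for (i in seq_len(nc)) wr(padn("", 32))

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    block <- matrix(0L, nrow = fs, ncol = nc)
    for (i in seq_len(nc)) {
      d <- round((x[i, idx] - pmin_[i]) * scale[i]) + dmin
      block[, i] <- as.integer(pmin(pmax(d, dmin), dmax))
    }
    writeBin(as.integer(as.vector(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a 16-bit EDF file
#'
#' Samples are rescaled to physical units using the header calibration
#' (physical/digital min/max per signal). All signals must share one sampling
#' rate.
#'
#' @param path Path to an EDF file.
#' @return A `plv_recording`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  version <- trimws(rd(8))
  if (!identical(version, "0")) {
    stop("malformed EDF header (version field not '0')", call. = FALSE)
  }
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(trimws(rd(8)))
  rd(44)
  n_rec <- as.integer(trimws(rd(8)))
  rec_dur <- as.numeric(trimws(rd(8)))
  nc <- as.integer(trimws(rd(4)))
  if (is.na(nc) || nc < 1 || is.na(header_bytes) ||
      header_bytes != 256 * (nc + 1)) {
    stop("malformed EDF header", call. = FALSE)
  }
  labels <- trimws(vapply(seq_len(nc), function(i) rd(16), ""))
  rd(80 * nc)
  rd(8 * nc)
  pmin_ <- as.numeric(trimws(vapply(seq_len(nc), function(i) rd(8), "")))
  pmax_ <- as.numeric(trimws(vapply(seq_len(nc), function(i) rd(8), "")))
  dmin <- as.numeric(trimws(vapply(seq_len(nc), function(i) rd(8), "")))
  dmax <- as.numeric(trimws(vapply(seq_len(nc), function(i) rd(8), "")))
  rd(80 * nc)
  spr <- as.integer(trimws(vapply(seq_len(nc), function(i) rd(8), "")))
  rd(32 * nc)
  if (length(unique(spr)) != 1) {
    stop("unsupported EDF: signals have mixed sampling rates", call. = FALSE)
  }
  fs <- spr[1] / rec_dur

  data <- matrix(0, nrow = nc, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = nc * spr[1], size = 2,
                   endian = "little", signed = TRUE)
    block <- matrix(raw, nrow = spr[1], ncol = nc)
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (i in seq_len(nc)) {
      g <- (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i])
      data[i, idx] <- (block[, i] - dmin[i]) * g + pmin_[i]
    }
  }
  new_recording(data, fs, labels)
}
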