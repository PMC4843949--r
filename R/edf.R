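# Minimal EDF (European Data Format) writer/reader for package recordings.
# Signals are stored as 16-bit integers with physical units of microvolts;
# event markers are carried in an extra "TRIG" signal (0 = none,
# 1 = standard, 2 = deviant at the onset sample). Fixed start date/time
# keep output byte-reproducible.

pad_field <- function(x, width) {
  s <- substr(format(x, trim = TRUE), 1, width)
  formatC(s, width = -width)   # left-justified, space padded
}

#' Write a recording to an EDF file
#'
#' @param recording a `raw_recording` (data in microvolts).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  X <- recording$data
  fs <- recording$fs
  if (fs != round(fs)) stop("EDF export requires an integer sampling rate")
  trig <- numeric(ncol(X))
  if (!is.null(recording$events)) {
    trig[recording$events$sample] <-
      ifelse(recording$events$condition == "deviant", 2, 1)
  }
  X <- rbind(X, trig)
  labels <- c(recording$labels, "TRIG")
  ns <- nrow(X)
  # pad to whole 1 s records
  n_rec <- ceiling(ncol(X) / fs)
  if (ncol(X) < n_rec * fs) {
    X <- cbind(X, matrix(0, ns, n_rec * fs - ncol(X)))
  }
  pmin_ <- apply(X, 1, min)
  pmax_ <- apply(X, 1, max)
  flat <- pmax_ - pmin_ < 1e-9
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768
  dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) {
    writeChar(paste(pad_field(x, width), collapse = ""), con,
              eos = NULL, useBytes = TRUE)
  }
  wr("0", 8)
  wr("X X X X", 80)
  wr("Startdate 01-JAN-2000 X X X", 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(256 * (1 + ns), 8)
  wr("", 44)
  wr(n_rec, 8)
  wr("1", 8)
  wr(ns, 4)
  wr(labels, 16)
  wr(rep("", ns), 80)
  wr(rep("uV", ns), 8)
  wr(sprintf("%.6g", pmin_), 8)
  wr(sprintf("%.6g", pmax_), 8)
  wr(rep(dmin, ns), 8)
  wr(rep(dmax, ns), 8)
  wr(rep("", ns), 80)
  wr(rep(fs, ns), 8)
  wr(rep("", ns), 32)
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  D <- round(sweep(sweep(X, 1, pmin_), 1, scale, "/")) + dmin
  for (r in seq_len(n_rec)) {
    ix <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(D[, ix])), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @return a `raw_recording` (the trailing zero padding of the last
#'   record is retained; events are recovered from the TRIG channel).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    trimws(readChar(con, width, useBytes = TRUE))
  }
  rd(8)                      # version
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                      # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  stopifnot(length(unique(spr)) == 1)
  fs <- spr[1] / rec_dur
  X <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      v <- readBin(con, "integer", spr[s], size = 2, endian = "little")
      X[s, ((r - 1) * spr[s] + 1):(r * spr[s])] <- v
    }
  }
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  X <- sweep(sweep(X, 1, dmin), 1, scale, "*") + pmin_
  ti <- which(labels == "TRIG")
  events <- NULL
  if (length(ti) == 1) {
    trig <- round(X[ti, ])
    on_ix <- which(trig > 0)
    events <- data.frame(sample = on_ix,
                         condition = ifelse(trig[on_ix] == 2, "deviant",
                                            "standard"),
                         stringsAsFactors = FALSE)
    X <- X[-ti, , drop = FALSE]
    labels <- labels[-ti]
  }
  structure(list(data = X, fs = fs, labels = labels, events = events),
            class = "raw_recording")
}

#' Save / load the package's epoch container
#'
#' Epoched data and evoked responses are plain R lists; they are
#' serialized with `saveRDS` and can be exported to CSV (channels x time)
#' with [write_evoked_csv()].
#'
#' @param x an `epoched_data` or `evoked_response`.
#' @param path file path.
#' @return `path` invisibly (`save_epochs`); the restored object
#'   (`load_epochs`).
#' @export
save_epochs <- function(x, path) {
  saveRDS(x, path)
  invisible(path)
}

#' @rdname save_epochs
#' @export
load_epochs <- function(path) readRDS(path)

#' Export an evoked response as CSV (channels x time)
#'
#' @param evoked an `evoked_response`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_evoked_csv <- function(evoked, path) {
  df <- as.data.frame(evoked$data)
  colnames(df) <- sprintf("t%+.1fms", evoked$time_ms)
  df <- cbind(channel = evoked$labels, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
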