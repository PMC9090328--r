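#' Raw dual-wavelength intensity recording
#'
#' Continuous-wave fNIRS intensity time series at two wavelengths (780 and
#' 850 nm) sampled uniformly, with stimulus event markers. Intensities are
#' in arbitrary positive units; only ratios matter downstream.
#'
#' @param montage a \code{nirs_montage}
#' @param intensity numeric array \code{channel x wavelength x time},
#'   strictly positive; wavelength order must match \code{wavelengths}
#' @param fs sampling rate in Hz
#' @param events data.frame with columns \code{time_s}, \code{condition}
#' @param wavelengths numeric length-2; reordered internally to (780, 850)
#' @return object of class \code{nirs_recording}
#' @export
raw_recording <- function(montage, intensity, fs, events,
                          wavelengths = c(780, 850)) {
  if (!inherits(montage, "nirs_montage")) stop("montage must be a nirs_montage")
  if (length(dim(intensity)) != 3) stop("intensity must be channel x wavelength x time")
  nch <- nrow(montage$channels)
  if (dim(intensity)[1] != nch) stop("intensity has ", dim(intensity)[1],
                                     " channels but montage defines ", nch)
  if (dim(intensity)[2] != 2 || length(wavelengths) != 2)
    stop("exactly two wavelengths required")
  if (!setequal(wavelengths, c(780, 850)))
    stop("wavelengths must be 780 and 850 nm, got: ", paste(wavelengths, collapse = ", "))
  ord <- order(wavelengths)           # normalise to (780, 850)
  intensity <- intensity[, ord, , drop = FALSE]
  if (any(!is.finite(intensity)) || any(intensity <= 0))
    stop("intensities must be finite and strictly positive")
  if (!is.data.frame(events) || !all(c("time_s", "condition") %in% names(events)))
    stop("events must be a data.frame with columns time_s, condition")
  duration <- (dim(intensity)[3] - 1) / fs
  if (nrow(events) && (any(events$time_s < 0) || any(events$time_s > duration)))
    stop("events must lie within the recording span [0, ", duration, "] s")
  dimnames(intensity) <- list(montage$channels$channel, c("780", "850"), NULL)
  structure(list(montage = montage, wavelengths = c(780, 850), fs = fs,
                 intensity = intensity, events = events),
            class = "nirs_recording")
}

#' @export
print.nirs_recording <- function(x, ...) {
  cat("fNIRS recording:", dim(x$intensity)[1], "channels x 2 wavelengths x",
      dim(x$intensity)[3], "samples @", x$fs, "Hz;",
      nrow(x$events), "events\n")
  invisible(x)
}

recording_time <- function(rec) (seq_len(dim(rec$intensity)[3]) - 1) / rec$fs

#' Write a recording to disk
#'
#' The CSV dialect is a directory of four plain-text tables:
#' \code{intensity.csv} (time_s, channel, wavelength_nm, intensity) in long
#' format, \code{montage.csv} (optode_id, kind, x_mm, y_mm, z_mm),
#' \code{channels.csv} (channel, source, detector) and \code{events.csv}
#' (time_s, condition). Round trips are lossless to text float precision
#' (15 significant digits).
#'
#' @param rec a \code{nirs_recording}
#' @param path directory to create/write into
#' @param format only \code{"csv"} is supported
#' @return \code{path}, invisibly
#' @export
write_recording <- function(rec, path, format = c("csv", "snirf")) {
  format <- match.arg(format)
  if (format == "snirf")
    stop("snirf/HDF5 output is not supported by this build; use format = 'csv'")
  if (!inherits(rec, "nirs_recording")) stop("not a nirs_recording")
  if (nrow(rec$montage$channels) == 0) stop("recording has an empty channel list")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tm <- recording_time(rec)
  nch <- dim(rec$intensity)[1]; nt <- dim(rec$intensity)[3]
  long <- data.frame(
    time_s = rep(tm, each = nch * 2),
    channel = rep(rec$montage$channels$channel, times = 2 * nt),
    wavelength_nm = rep(rep(c(780, 850), each = nch), times = nt),
    intensity = as.vector(rec$intensity)
  )
  fmt <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  long$time_s <- fmt(long$time_s); long$intensity <- fmt(long$intensity)
  utils::write.csv(long, file.path(path, "intensity.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(rec$montage$optodes, file.path(path, "montage.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(rec$montage$channels, file.path(path, "channels.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(rec$events, file.path(path, "events.csv"), row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a recording from disk
#'
#' @param path directory written by \code{\link{write_recording}}
#' @param format only \code{"csv"} is supported
#' @return a \code{nirs_recording}
#' @export
read_recording <- function(path, format = c("csv", "snirf")) {
  format <- match.arg(format)
  if (format == "snirf")
    stop("snirf/HDF5 input is not supported by this build; use format = 'csv'")
  for (f in c("intensity.csv", "montage.csv", "channels.csv", "events.csv"))
    if (!file.exists(file.path(path, f))) stop("missing file: ", f)
  opt <- utils::read.csv(file.path(path, "montage.csv"), stringsAsFactors = FALSE)
  ch <- utils::read.csv(file.path(path, "channels.csv"), stringsAsFactors = FALSE)
  m <- montage(opt, ch)
  long <- utils::read.csv(file.path(path, "intensity.csv"), stringsAsFactors = FALSE)
  need <- c("time_s", "channel", "wavelength_nm", "intensity")
  if (!all(need %in% names(long)))
    stop("intensity.csv malformed; missing column(s): ",
         paste(setdiff(need, names(long)), collapse = ", "))
  ev <- utils::read.csv(file.path(path, "events.csv"), stringsAsFactors = FALSE)
  if (nrow(ev) == 0) ev <- data.frame(time_s = numeric(0), condition = character(0))
  tm <- sort(unique(long$time_s))
  nt <- length(tm); nch <- nrow(ch)
  if (nt > 1) {
    dt <- diff(tm)
    if (max(abs(dt - dt[1])) > 1e-6) stop("intensity.csv: time axis not uniform")
  }
  fs <- if (nt > 1) 1 / (tm[2] - tm[1]) else 10
  arr <- array(NA_real_, c(nch, 2, nt))
  ci <- match(long$channel, ch$channel)
  wi <- match(long$wavelength_nm, c(780, 850))
  ti <- match(long$time_s, tm)
  if (anyNA(ci)) stop("intensity.csv: unknown channel label")
  if (anyNA(wi)) stop("intensity.csv: wavelength_nm must be 780 or 850")
  arr[cbind(ci, wi, ti)] <- long$intensity
  if (anyNA(arr)) stop("intensity.csv: incomplete channel x wavelength x time grid")
  raw_recording(m, arr, fs, ev)
}
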