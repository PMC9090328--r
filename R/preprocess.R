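#' Epoch time grid
#'
#' The standard half-open epoch grid: baseline samples in [-5, 0) and
#' post-stimulus samples in [0, 30); 350 samples at 10 Hz, of which 300 are
#' post-stimulus.
#'
#' @param fs sampling rate (Hz)
#' @param window epoch window in seconds
#' @return numeric vector of epoch times (s), stimulus at 0
#' @export
epoch_time <- function(fs = 10, window = c(-5, 30)) {
  seq(window[1], window[2] - 1 / fs, by = 1 / fs)
}

#' Prune channels with poor signal quality
#'
#' A channel is removed when, at either wavelength, its mean raw intensity
#' falls below \code{intensity_min} or its raw SNR (mean over SD of the
#' intensity series) falls below \code{snr_min}.
#'
#' @param rec a \code{nirs_recording}
#' @param intensity_min mean-intensity threshold (a.u.)
#' @param snr_min SNR threshold
#' @return list with \code{recording} (pruned) and \code{removed}
#'   (data.frame channel, reason)
#' @export
prune_channels <- function(rec, intensity_min = 0.01, snr_min = 2) {
  nch <- dim(rec$intensity)[1]
  reason <- character(nch)
  for (ch in seq_len(nch)) {
    for (w in 1:2) {
      x <- rec$intensity[ch, w, ]
      m <- mean(x); s <- stats::sd(x)
      if (m < intensity_min) {
        reason[ch] <- "intensity"
      } else if (s > 0 && m / s < snr_min) {
        if (reason[ch] == "") reason[ch] <- "snr"
      }
    }
  }
  drop <- which(reason != "")
  if (length(drop) == nch) stop("all channels removed by pruning")
  removed <- data.frame(channel = rec$montage$channels$channel[drop],
                        reason = reason[drop], stringsAsFactors = FALSE)
  if (length(drop)) {
    keep <- setdiff(seq_len(nch), drop)
    m2 <- rec$montage
    m2$channels <- m2$channels[keep, , drop = FALSE]
    rec <- raw_recording(m2, rec$intensity[keep, , , drop = FALSE], rec$fs,
                         rec$events)
  }
  list(recording = rec, removed = removed)
}

#' Convert intensities to optical density
#'
#' \eqn{OD(t) = -\ln(I(t) / \bar I)} per channel and wavelength, with the
#' channel's whole-recording mean intensity as reference, so each OD series
#' is zero-mean-ish by construction and invariant to intensity rescaling.
#'
#' @param rec a \code{nirs_recording}
#' @return object of class \code{nirs_od}: list with \code{values}
#'   (channel x wavelength x time), \code{fs}, \code{stages}
#' @export
to_optical_density <- function(rec) {
  if (any(rec$intensity <= 0)) stop("intensities must be strictly positive")
  v <- rec$intensity
  for (ch in seq_len(dim(v)[1])) for (w in 1:2) {
    v[ch, w, ] <- -log(v[ch, w, ] / mean(v[ch, w, ]))
  }
  structure(list(values = v, fs = rec$fs,
                 channels = rec$montage$channels$channel,
                 stages = "od"),
            class = "nirs_od")
}

.sliding_stat <- function(x, w, fun_range = TRUE) {
  # windowed peak-to-peak (fun_range) or SD over every window of length w;
  # value assigned to every sample the window contains
  n <- length(x)
  nwin <- n - w + 1
  if (fun_range) {
    # running max/min via cummax trick would be overkill; w is ~10 samples
    mx <- vapply(seq_len(nwin), function(i) max(x[i:(i + w - 1)]), 0)
    mn <- vapply(seq_len(nwin), function(i) min(x[i:(i + w - 1)]), 0)
    mx - mn
  } else {
    cs <- cumsum(c(0, x)); cs2 <- cumsum(c(0, x^2))
    s <- cs[(w + 1):(n + 1)] - cs[1:nwin]
    s2 <- cs2[(w + 1):(n + 1)] - cs2[1:nwin]
    v <- (s2 - s^2 / w) / (w - 1)
    sqrt(pmax(v, 0))
  }
}

#' Detect motion artifacts on optical density
#'
#' A sample is flagged when any 1 s sliding window containing it has a
#' peak-to-peak OD change above \code{amp_thresh} or a windowed SD above
#' \code{sd_thresh} times the series' median windowed SD (the multiplicative
#' reading of the ">15" criterion; Homer-style semantics).
#'
#' @param od a \code{nirs_od}
#' @param amp_thresh peak-to-peak OD threshold
#' @param sd_thresh multiple of the median windowed SD
#' @param window_s window length (s)
#' @return logical matrix channel x time (TRUE = artifact), attribute
#'   \code{"per_wavelength"} keeps the wavelength-resolved masks
#' @export
detect_motion <- function(od, amp_thresh = 0.7, sd_thresh = 15, window_s = 1) {
  w <- round(window_s * od$fs)
  nt <- dim(od$values)[3]
  if (w > nt) stop("motion window longer than the series")
  nch <- dim(od$values)[1]
  mask <- matrix(FALSE, nch, nt)
  for (ch in seq_len(nch)) for (wl in 1:2) {
    x <- od$values[ch, wl, ]
    pp <- .sliding_stat(x, w, TRUE)
    sdv <- .sliding_stat(x, w, FALSE)
    med <- stats::median(sdv)
    winbad <- pp > amp_thresh | (med > 0 & sdv > sd_thresh * med)
    if (any(winbad)) {
      bad <- which(winbad)
      for (i in bad) mask[ch, i:(i + w - 1)] <- TRUE
    }
  }
  mask
}

#' Wavelet-based motion artifact correction
#'
#' Per channel and wavelength: periodised Daubechies-2 decomposition to
#' maximum dyadic depth; within each detail level, coefficients lying more
#' than \code{iqr_factor} interquartile ranges beyond the quartiles are set
#' to zero; the series is replaced by the reconstruction. Artifact-free
#' series pass through nearly unchanged because a smooth series has
#' near-zero detail coefficients.
#'
#' @param od a \code{nirs_od}
#' @param mask artifact mask from \code{\link{detect_motion}}; channels with
#'   no flagged samples are left untouched (pass \code{NULL} to correct all)
#' @param iqr_factor outlier fence width
#' @return corrected \code{nirs_od}
#' @export
wavelet_correct <- function(od, mask = NULL, iqr_factor = 1.5) {
  nt <- dim(od$values)[3]
  if (nt < 8) stop("series shorter than the wavelet filter support")
  nch <- dim(od$values)[1]
  out <- od
  for (ch in seq_len(nch)) {
    if (!is.null(mask) && !any(mask[ch, ])) next
    for (wl in 1:2) {
      x <- od$values[ch, wl, ]
      w <- .dwt(x)
      for (j in seq_along(w$details)) {
        d <- w$details[[j]]
        q <- stats::quantile(d, c(0.25, 0.75), names = FALSE)
        iqr <- q[2] - q[1]
        lo <- q[1] - iqr_factor * iqr
        hi <- q[2] + iqr_factor * iqr
        d[d < lo | d > hi] <- 0
        w$details[[j]] <- d
      }
      out$values[ch, wl, ] <- .idwt(w)
    }
  }
  out$stages <- c(od$stages, "wavelet")
  out
}

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass (default order 3, 0.01--0.5 Hz) applied forward and
#' backward (\code{filtfilt}) for zero phase distortion; removes
#' instrumental drift and cardiac oscillations.
#'
#' @param od a \code{nirs_od}
#' @param low,high band edges (Hz)
#' @param order Butterworth order
#' @return filtered \code{nirs_od}
#' @export
bandpass <- function(od, low = 0.01, high = 0.5, order = 3) {
  nyq <- od$fs / 2
  if (high >= nyq) stop("high edge must be below the Nyquist frequency")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  out <- od
  for (ch in seq_len(dim(od$values)[1])) for (wl in 1:2) {
    out$values[ch, wl, ] <- signal::filtfilt(bf, od$values[ch, wl, ])
  }
  out$stages <- c(od$stages, "bandpass")
  out
}

#' Remove global components by PCA
#'
#' Treats channels x wavelengths as variables and time samples as
#' observations, removes the projection onto the first
#' \code{n_components} principal components -- the standard correction for
#' systemic physiological signals shared across the array.
#'
#' @param od a \code{nirs_od}
#' @param n_components number of components to remove (0 = identity)
#' @return corrected \code{nirs_od}
#' @export
remove_global_pca <- function(od, n_components = 1) {
  if (n_components == 0) return(od)
  nch <- dim(od$values)[1]; nt <- dim(od$values)[3]
  if (2 * nch <= n_components) stop("fewer channel series than components")
  X <- rbind(od$values[, 1, , drop = TRUE], od$values[, 2, , drop = TRUE])
  if (nch == 1) X <- matrix(X, nrow = 2)
  X <- t(X)                               # time x (2 nch)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = n_components, nv = n_components)
  Xr <- Xc - sv$u %*% (diag(sv$d[seq_len(n_components)], n_components) %*%
                         t(sv$v))
  Xr <- sweep(Xr, 2, mu, `+`)
  out <- od
  out$values[, 1, ] <- t(Xr)[seq_len(nch), ]
  out$values[, 2, ] <- t(Xr)[nch + seq_len(nch), ]
  out$stages <- c(od$stages, "pca")
  out
}

#' Epoch haemoglobin series around stimulus events and average
#'
#' Cuts per-trial epochs on the standard grid (default -5 to 30 s, stimulus
#' at 0), optionally subtracts each trial's baseline mean ([-5, 0) s), and
#' averages retained trials. Trials whose window falls outside the
#' recording are dropped with a logged reason. A single-trial condition
#' (e.g. lance) passes through unchanged apart from baseline correction.
#'
#' @param haemo a \code{nirs_haemo}
#' @param events data.frame (time_s, condition)
#' @param window epoch window (s)
#' @param baseline_correct subtract per-trial baseline mean
#' @param subject subject identifier carried through
#' @return list of class \code{nirs_epochs}: \code{trials} (trial x channel
#'   x chromophore x time), \code{average} (a \code{nirs_epoch_avg}),
#'   \code{time}, \code{retained} (logical per event), \code{reasons}
#' @export
epoch_and_average <- function(haemo, events, window = c(-5, 30),
                              baseline_correct = TRUE, subject = NA) {
  fs <- haemo$fs
  tm <- epoch_time(fs, window)
  nt <- length(tm)
  nch <- dim(haemo$values)[1]
  ntot <- dim(haemo$values)[3]
  nev <- nrow(events)
  keep <- logical(nev); reasons <- character(nev)
  trials <- array(NA_real_, c(nev, nch, 2, nt))
  for (e in seq_len(nev)) {
    i0 <- round(events$time_s[e] * fs) + 1       # sample at stimulus
    idx <- i0 + round(tm * fs)
    if (idx[1] < 1 || idx[nt] > ntot) {
      reasons[e] <- "window outside recording"
      next
    }
    tr <- haemo$values[, , idx, drop = FALSE]
    dim(tr) <- c(nch, 2, nt)
    if (baseline_correct) {
      bl <- tm < 0
      for (ch in seq_len(nch)) for (cc in 1:2)
        tr[ch, cc, ] <- tr[ch, cc, ] - mean(tr[ch, cc, bl])
    }
    trials[e, , , ] <- tr
    keep[e] <- TRUE
  }
  if (!any(keep)) stop("no trial with full window coverage")
  avg <- apply(trials[keep, , , , drop = FALSE], c(2, 3, 4), mean)
  dimnames(avg) <- list(haemo$channels, c("HbO", "Hb"), NULL)
  average <- structure(list(values = avg, time = tm, fs = fs,
                            n_trials = sum(keep), subject = subject),
                       class = "nirs_epoch_avg")
  structure(list(trials = trials[keep, , , , drop = FALSE],
                 average = average, time = tm, fs = fs,
                 condition = if (nev) events$condition[which(keep)[1]] else NA,
                 retained = keep, reasons = reasons, subject = subject),
            class = "nirs_epochs")
}

#' Full preprocessing chain for one recording
#'
#' Fixed stage order: prune, optical density, motion detection, wavelet
#' correction, band-pass, PCA, modified Beer-Lambert, epoching. Stages can
#' be toggled for diagnostic runs; the applied order is recorded in the
#' returned \code{stages}.
#'
#' @param rec a \code{nirs_recording}
#' @param cfg an \code{\link{analysis_config}}
#' @param stages character subset of
#'   \code{c("prune", "motion", "bandpass", "pca")} to enable (OD,
#'   Beer-Lambert and epoching always run)
#' @param subject subject id carried into the epochs
#' @return list: \code{epochs} (a \code{nirs_epochs}), \code{removed}
#'   (pruned channels), \code{motion_mask}, \code{stages} (applied order)
#' @export
preprocess_recording <- function(rec, cfg = analysis_config(),
                                 stages = c("prune", "motion", "bandpass", "pca"),
                                 subject = NA) {
  applied <- character(0)
  removed <- data.frame(channel = character(0), reason = character(0))
  if ("prune" %in% stages) {
    pr <- prune_channels(rec, cfg$prune_intensity_min, cfg$prune_snr_min)
    rec <- pr$recording; removed <- pr$removed
    applied <- c(applied, "prune")
  }
  od <- to_optical_density(rec)
  applied <- c(applied, "od")
  mask <- NULL
  if ("motion" %in% stages) {
    mask <- detect_motion(od, cfg$motion_amp_thresh, cfg$motion_sd_thresh,
                          cfg$motion_window_s)
    od <- wavelet_correct(od, mask, cfg$wavelet_iqr_factor)
    applied <- c(applied, "motion")
  }
  if ("bandpass" %in% stages) {
    od <- bandpass(od, cfg$bandpass_low_hz, cfg$bandpass_high_hz,
                   cfg$bandpass_order)
    applied <- c(applied, "bandpass")
  }
  if ("pca" %in% stages) {
    od <- remove_global_pca(od, cfg$pca_components)
    applied <- c(applied, "pca")
  }
  haemo <- beer_lambert(od, rec$montage, cfg$dpf)
  applied <- c(applied, "beer_lambert")
  ep <- epoch_and_average(haemo, rec$events, cfg$epoch_window_s,
                          baseline_correct = TRUE, subject = subject)
  applied <- c(applied, "epoch")
  list(epochs = ep, removed = removed, motion_mask = mask, stages = applied)
}
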