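#' Group baseline mixture distribution
#'
#' The group baseline at a channel/chromophore is the equal-weight normal
#' mixture of the subjects' pre-stimulus baselines: mean
#' \eqn{\mu_B = S^{-1} \sum_i \mu_i} and variance
#' \eqn{\sigma^2_B = S^{-2} \sum_i \sigma^2_i}, where \eqn{\mu_i} and
#' \eqn{\sigma^2_i} are subject i's mean and variance over the [-5, 0) s
#' baseline segment. Channels present in fewer than 2 subjects are marked
#' untestable (NA).
#'
#' @param epochs list of per-subject \code{nirs_epoch_avg} sharing a channel
#'   set (NA-filled channels are treated as missing for that subject)
#' @return list of class \code{baseline_distribution}: \code{mu},
#'   \code{var} (channel x chromophore matrices), \code{S} (subjects per
#'   channel), \code{channels}
#' @export
build_baseline <- function(epochs) {
  stopifnot(length(epochs) >= 2)
  tm <- epochs[[1]]$time
  bl <- tm < 0
  nch <- dim(epochs[[1]]$values)[1]
  chn <- dimnames(epochs[[1]]$values)[[1]]
  mu <- var <- matrix(0, nch, 2)
  S <- matrix(0L, nch, 2)
  for (ep in epochs) {
    for (ch in seq_len(nch)) for (cc in 1:2) {
      x <- ep$values[ch, cc, bl]
      if (anyNA(x)) next
      mu[ch, cc] <- mu[ch, cc] + mean(x)
      var[ch, cc] <- var[ch, cc] + stats::var(x)
      S[ch, cc] <- S[ch, cc] + 1L
    }
  }
  ok <- S >= 2L
  mu[ok] <- mu[ok] / S[ok]
  var[ok] <- var[ok] / S[ok]^2
  mu[!ok] <- NA_real_; var[!ok] <- NA_real_
  structure(list(mu = mu, var = var, S = S, channels = chn),
            class = "baseline_distribution")
}

#' Pointwise post-stimulus significance test
#'
#' At every post-stimulus sample, compares the S subject values against the
#' group baseline distribution with a two-tailed t-test, Bonferroni
#' corrected over \code{channels x post-stimulus samples} comparisons. The
#' baseline enters as a nominal group of S observations with mean
#' \eqn{\mu_B} and per-observation variance \eqn{S \sigma^2_B} (so the
#' baseline mean's variance is \eqn{\sigma^2_B}); Welch degrees of freedom.
#' Set \code{one_sample = TRUE} for the simpler one-sample t against
#' \eqn{\mu_B}.
#'
#' @param epochs list of per-subject \code{nirs_epoch_avg}
#' @param baseline a \code{\link{build_baseline}} result on the same group
#' @param alpha two-tailed significance level before correction
#' @param n_comparisons Bonferroni denominator; default channels x
#'   post-stimulus samples
#' @param one_sample use the one-sample variant
#' @return list of class \code{channel_significance}: arrays
#'   \code{t}, \code{p}, \code{significant}, \code{direction}
#'   (channel x chromophore x post sample), \code{post_time},
#'   \code{n_comparisons}, \code{alpha}, \code{fs}
#' @export
pointwise_test <- function(epochs, baseline, alpha = 0.01,
                           n_comparisons = NULL, one_sample = FALSE) {
  tm <- epochs[[1]]$time
  post <- tm >= 0
  post_time <- tm[post]
  nch <- dim(epochs[[1]]$values)[1]
  np <- sum(post)
  if (is.null(n_comparisons)) n_comparisons <- nch * np
  S <- length(epochs)
  tt <- pp <- array(NA_real_, c(nch, 2, np))
  for (cc in 1:2) {
    # subjects x (channels x post samples)
    X <- vapply(epochs, function(e) e$values[, cc, post], matrix(0, nch, np))
    if (nch == 1) dim(X) <- c(1, np, S)
    m1 <- apply(X, c(1, 2), mean)
    v1 <- apply(X, c(1, 2), stats::var)
    muB <- baseline$mu[, cc]; varB <- baseline$var[, cc]
    se2 <- v1 / S + varB                     # + (S*varB)/S
    tstat <- (m1 - muB) / sqrt(se2)
    if (one_sample) {
      tstat <- (m1 - muB) / sqrt(v1 / S)
      df <- matrix(S - 1, nch, np)
    } else {
      df <- se2^2 / ((v1 / S)^2 / (S - 1) + varB^2 / (S - 1))
    }
    zero <- se2 == 0
    if (any(zero, na.rm = TRUE)) {
      warning("zero variance in both groups at some samples")
      tstat[zero] <- ifelse(m1[zero] != muB[row(m1)[zero]], Inf, 0)
    }
    tt[, cc, ] <- tstat
    pp[, cc, ] <- 2 * stats::pt(-abs(tstat), df)
  }
  sig <- pp <= alpha / n_comparisons
  sig[is.na(sig)] <- FALSE
  dirn <- sign(tt)
  structure(list(t = tt, p = pp, significant = sig, direction = dirn,
                 post_time = post_time, n_comparisons = n_comparisons,
                 alpha = alpha, fs = epochs[[1]]$fs,
                 channels = baseline$channels),
            class = "channel_significance")
}

#' Continuity filter on significance runs
#'
#' Clears maximal runs of same-direction significant samples shorter than
#' \code{min_duration_s}; longer runs are kept intact. A change of
#' direction breaks a run.
#'
#' @param sig a \code{channel_significance}
#' @param min_duration_s minimum run duration (s)
#' @return the filtered \code{channel_significance}
#' @export
continuity_filter <- function(sig, min_duration_s = 1) {
  min_len <- round(min_duration_s * sig$fs)
  nch <- dim(sig$significant)[1]
  np <- dim(sig$significant)[3]
  for (ch in seq_len(nch)) for (cc in 1:2) {
    s <- sig$significant[ch, cc, ]
    d <- sig$direction[ch, cc, ]
    state <- ifelse(s, d, 0)              # -1, 0, +1
    r <- rle(state)
    bad <- r$values != 0 & r$lengths < min_len
    if (any(bad)) {
      r$values[bad] <- 0
      state <- inverse.rle(r)
      sig$significant[ch, cc, ] <- state != 0
    }
  }
  sig$min_run_s <- min_duration_s
  sig
}

#' Classify per-channel response type
#'
#' A channel is \emph{canonical} when it retains any significant HbO
#' increase or Hb decrease run, \emph{inverse} when it retains only HbO
#' decreases and/or Hb increases, and \emph{none} otherwise. The dominant
#' chromophore's peak amplitude and latency over retained samples are
#' reported (HbO if it has retained runs, else Hb).
#'
#' @param sig a continuity-filtered \code{channel_significance}
#' @param epochs the group epochs (for amplitudes); may be omitted, in
#'   which case amplitudes are NA
#' @return data.frame: channel, class, peak_uM, peak_latency_s
#' @export
classify_response <- function(sig, epochs = NULL) {
  nch <- dim(sig$significant)[1]
  cls <- character(nch)
  peak <- lat <- rep(NA_real_, nch)
  gmean <- NULL
  if (!is.null(epochs)) {
    post <- epochs[[1]]$time >= 0
    arr <- vapply(epochs, function(e) e$values[, , post, drop = FALSE],
                  array(0, c(nch, 2, sum(post))))
    gmean <- apply(arr, c(1, 2, 3), mean)
  }
  for (ch in seq_len(nch)) {
    hbo_up <- any(sig$significant[ch, 1, ] & sig$direction[ch, 1, ] > 0)
    hbo_dn <- any(sig$significant[ch, 1, ] & sig$direction[ch, 1, ] < 0)
    hb_up  <- any(sig$significant[ch, 2, ] & sig$direction[ch, 2, ] > 0)
    hb_dn  <- any(sig$significant[ch, 2, ] & sig$direction[ch, 2, ] < 0)
    cls[ch] <- if (hbo_up || hb_dn) "canonical"
      else if (hbo_dn || hb_up) "inverse" else "none"
    if (!is.null(gmean) && cls[ch] != "none") {
      cc <- if (any(sig$significant[ch, 1, ])) 1 else 2
      ret <- which(sig$significant[ch, cc, ])
      i <- ret[which.max(abs(gmean[ch, cc, ret]))]
      peak[ch] <- gmean[ch, cc, i]
      lat[ch] <- sig$post_time[i]
    }
  }
  data.frame(channel = sig$channels, class = cls, peak_uM = peak,
             peak_latency_s = lat, stringsAsFactors = FALSE)
}

#' Signal-to-noise ratio of two averaged conditions
#'
#' SNR scales with peak amplitude times the square root of the number of
#' averaged trials; the returned value is
#' \eqn{(peak_a \sqrt{n_a}) / (peak_b \sqrt{n_b})}.
#'
#' @param peak_a,peak_b peak amplitudes (uM), positive
#' @param n_a,n_b trial counts
#' @param digits rounding applied to the returned ratio (reports use 2)
#' @return dimensionless ratio
#' @export
snr_ratio <- function(peak_a, n_a, peak_b, n_b, digits = 2) {
  if (peak_b == 0) stop("peak_b must be non-zero")
  stopifnot(peak_a > 0, peak_b > 0, n_a >= 1, n_b >= 1)
  round((peak_a * sqrt(n_a)) / (peak_b * sqrt(n_b)), digits)
}

#' Habituation check across stimulus repetitions
#'
#' Splits each subject's trials into first and last halves (the middle
#' trial of an odd count goes to the first half), averages each half per
#' subject, and runs a per-sample two-sample t-test between the two sets of
#' half-averages across subjects, Bonferroni corrected over channels x
#' samples. Verdict is "habituation" only when some same-direction
#' significant run lasts at least 1 s.
#'
#' @param epochs_list list of per-subject \code{nirs_epochs} (trial-level)
#' @param alpha significance level
#' @param min_run_s continuity requirement (s)
#' @return list: \code{verdict} in \code{c("habituation", "no habituation",
#'   "untestable")}, \code{p} (channel x chromophore x sample)
#' @export
habituation_check <- function(epochs_list, alpha = 0.05, min_run_s = 1) {
  ntr <- vapply(epochs_list, function(e) dim(e$trials)[1], 0L)
  if (any(ntr < 4)) return(list(verdict = "untestable", p = NULL))
  half_avg <- function(e, which_half) {
    n <- dim(e$trials)[1]
    cut <- ceiling(n / 2)
    idx <- if (which_half == 1) seq_len(cut) else (cut + 1):n
    apply(e$trials[idx, , , , drop = FALSE], c(2, 3, 4), mean)
  }
  first <- lapply(epochs_list, half_avg, 1)
  last <- lapply(epochs_list, half_avg, 2)
  S <- length(epochs_list)
  nch <- dim(first[[1]])[1]; nt <- dim(first[[1]])[3]
  A <- array(unlist(first), c(nch, 2, nt, S))
  B <- array(unlist(last), c(nch, 2, nt, S))
  m1 <- apply(A, 1:3, mean); m2 <- apply(B, 1:3, mean)
  v1 <- apply(A, 1:3, stats::var); v2 <- apply(B, 1:3, stats::var)
  se2 <- v1 / S + v2 / S
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / S)^2 / (S - 1) + (v2 / S)^2 / (S - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  ncomp <- nch * nt
  sig <- p <= alpha / ncomp
  sig[is.na(sig)] <- FALSE
  fs <- epochs_list[[1]]$fs
  min_len <- round(min_run_s * fs)
  habit <- FALSE
  for (ch in seq_len(nch)) for (cc in 1:2) {
    state <- ifelse(sig[ch, cc, ], sign(tstat[ch, cc, ]), 0)
    r <- rle(state)
    if (any(r$values != 0 & r$lengths >= min_len)) habit <- TRUE
  }
  list(verdict = if (habit) "habituation" else "no habituation", p = p)
}
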