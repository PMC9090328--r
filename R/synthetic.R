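#' Haemodynamic response specification
#'
#' Parameterises the canonical evoked response the generator injects: a
#' smooth unimodal increase in oxy-haemoglobin peaking at \code{latency_s}
#' with value \code{amplitude_uM}, accompanied by a smaller, slightly
#' delayed decrease in deoxy-haemoglobin (\code{hb_ratio} times a copy of
#' the HbO curve shifted by \code{hb_delay_s}).
#'
#' @param amplitude_uM HbO peak amplitude (uM)
#' @param latency_s HbO peak latency (s, in (0, 30])
#' @param duration_s response duration; the curve has decayed to ~10% of
#'   peak this long after onset
#' @param hb_ratio Hb/HbO amplitude ratio (negative)
#' @param onset_s onset delay after the stimulus
#' @param hb_delay_s delay of the Hb copy relative to HbO
#' @return list of class \code{hrf_spec}
#' @export
hrf_spec <- function(amplitude_uM = 0.35, latency_s = 15.8, duration_s = 30,
                     hb_ratio = -0.3, onset_s = 0.5, hb_delay_s = 1) {
  stopifnot(latency_s > 0, latency_s <= 30, duration_s > 0,
            is.finite(amplitude_uM), latency_s > onset_s)
  structure(list(amplitude_uM = amplitude_uM, latency_s = latency_s,
                 duration_s = duration_s, hb_ratio = hb_ratio,
                 onset_s = onset_s, hb_delay_s = hb_delay_s),
            class = "hrf_spec")
}

# unit-peak gamma-shaped bump: ((u/m) e^(1 - u/m))^p, zero for u <= 0
.hrf_shape <- function(t, onset, mode, p) {
  u <- t - onset
  h <- numeric(length(t))
  pos <- u > 0
  x <- u[pos] / mode
  h[pos] <- (x * exp(1 - x))^p
  h
}

#' Evaluate a haemodynamic response on a time grid
#'
#' @param spec an \code{\link{hrf_spec}}
#' @param time numeric vector of epoch times (s), stimulus at 0; must cover
#'   the peak latency
#' @return list with \code{hbo} and \code{hb} numeric vectors (uM); each
#'   curve is rescaled so its on-grid extremum equals the specified
#'   amplitude (times \code{hb_ratio} for Hb), and is identically zero for
#'   \code{time <= onset_s}
#' @export
make_hrf <- function(spec, time) {
  if (spec$latency_s < min(time) || spec$latency_s > max(time))
    stop("peak latency ", spec$latency_s, " s lies outside the time grid")
  if (spec$amplitude_uM == 0)
    return(list(hbo = numeric(length(time)), hb = numeric(length(time))))
  mode <- spec$latency_s - spec$onset_s
  # sharpness: decay to 10% of peak at onset + duration
  xr <- spec$duration_s / mode
  p <- log(0.1) / log(xr * exp(1 - xr))
  if (!is.finite(p) || p <= 0) p <- 8
  hbo <- .hrf_shape(time, spec$onset_s, mode, p)
  hbo <- hbo / max(hbo) * spec$amplitude_uM
  hb <- .hrf_shape(time, spec$onset_s + spec$hb_delay_s, mode, p)
  hb <- hb / max(hb) * (spec$hb_ratio * spec$amplitude_uM)
  list(hbo = hbo, hb = hb)
}

#' Spatial activation pattern specification
#'
#' @param peak_node node index of the activation peak
#' @param sigma_mm isotropic Gaussian scale of the focal component
#' @param kind \code{"focal"} or \code{"widespread"}; widespread adds an
#'   elongated Gaussian component along \code{direction}
#' @param direction 3-vector, extension direction of the widespread
#'   component (normalised internally)
#' @param extra_scale_mm along-direction scale of the widespread component
#' @return list of class \code{spatial_spec}
#' @export
spatial_spec <- function(peak_node, sigma_mm = 10,
                         kind = c("focal", "widespread"),
                         direction = c(0, -1, 0), extra_scale_mm = 30) {
  kind <- match.arg(kind)
  stopifnot(sigma_mm > 0, extra_scale_mm > 0, length(direction) == 3)
  structure(list(peak_node = as.integer(peak_node), sigma_mm = sigma_mm,
                 kind = kind, direction = direction / sqrt(sum(direction^2)),
                 extra_scale_mm = extra_scale_mm),
            class = "spatial_spec")
}

#' Node-wise activation weights for a spatial pattern
#'
#' Focal patterns are isotropic Gaussians in Euclidean distance from the
#' peak node (an adequate geodesic proxy on smooth patches at scales of
#' 5 mm and above). Widespread patterns add an anisotropic Gaussian
#' component elongated along the specified direction, modulated by
#' (1 - focal) so the peak stays unique with weight exactly 1 and the
#' widespread map dominates the focal one node-wise.
#'
#' @param spec a \code{\link{spatial_spec}}
#' @param mesh a \code{cortical_mesh}
#' @return numeric vector of weights in [0, 1], one per node
#' @export
make_spatial_map <- function(spec, mesh) {
  n <- nrow(mesh$nodes)
  if (spec$peak_node < 1 || spec$peak_node > n) stop("peak node not on mesh")
  delta <- sweep(mesh$nodes, 2, mesh$nodes[spec$peak_node, ])
  d2 <- rowSums(delta^2)
  w <- exp(-d2 / (2 * spec$sigma_mm^2))
  if (spec$kind == "widespread") {
    dpar <- delta %*% spec$direction
    d2perp <- d2 - dpar^2
    we <- exp(-(d2perp / (2 * spec$sigma_mm^2) + dpar^2 / (2 * spec$extra_scale_mm^2)))
    w <- pmin(w + 0.9 * we * (1 - w), 1)
  }
  w[spec$peak_node] <- 1
  as.numeric(w)
}

#' Physiological / instrumental noise specification
#'
#' Amplitudes in uM (concentration-equivalent); frequencies in Hz (all
#' below the 5 Hz Nyquist of a 10 Hz recording). The global systemic
#' component is one shared slow time series added to every channel with
#' channel-specific gains -- exactly the structure single-component PCA
#' removal targets. Motion artifacts are brief high-amplitude excursions.
#'
#' @param white_sd white noise SD
#' @param cardiac,respiratory,mayer \code{c(freq_hz, amplitude)} pairs
#' @param global_amp amplitude of the shared systemic component
#' @param motion_rate_per_min,motion_amp,motion_dur_s artifact process
#' @return list of class \code{noise_spec}
#' @export
noise_spec <- function(white_sd = 0.15,
                       cardiac = c(2.3, 0.10), respiratory = c(0.7, 0.10),
                       mayer = c(0.1, 0.15), global_amp = 0.5,
                       motion_rate_per_min = 0, motion_amp = 3,
                       motion_dur_s = 1) {
  for (v in list(cardiac, respiratory, mayer)) {
    if (v[1] >= 5) stop("noise frequencies must be below the 5 Hz Nyquist")
    if (v[2] < 0) stop("amplitudes must be non-negative")
  }
  stopifnot(white_sd >= 0, global_amp >= 0, motion_amp >= 0)
  structure(list(white_sd = white_sd, cardiac = cardiac,
                 respiratory = respiratory, mayer = mayer,
                 global_amp = global_amp,
                 motion_rate_per_min = motion_rate_per_min,
                 motion_amp = motion_amp, motion_dur_s = motion_dur_s),
            class = "noise_spec")
}

.zero_noise <- function() noise_spec(white_sd = 0, cardiac = c(2.3, 0),
                                     respiratory = c(0.7, 0), mayer = c(0.1, 0),
                                     global_amp = 0, motion_rate_per_min = 0)

# slow random walk band-limited by an exponential moving average; SD ~ 1
.slow_series <- function(nt, fs, tau_s = 10) {
  a <- exp(-1 / (fs * tau_s))
  x <- stats::filter(stats::rnorm(nt), a, method = "recursive")
  x <- as.numeric(x)
  x / stats::sd(x)
}

#' Simulate one subject's raw dual-wavelength recording
#'
#' Channel concentration series are built as
#' \code{sensitivity \%*\% (spatial map) x HRF(t)} summed over trials, plus
#' physiological noise, motion artifacts and a shared global systemic
#' component; concentrations are converted to intensities through the exact
#' forward modified Beer-Lambert model so the preprocessing chain can
#' recover them. Events are placed with inter-stimulus intervals drawn
#' uniformly from [35, 60] s after a 35 s lead-in, with a 40 s tail.
#'
#' @param hrf an \code{\link{hrf_spec}}
#' @param pattern a \code{\link{spatial_spec}}
#' @param mont a \code{nirs_montage}
#' @param mesh a \code{cortical_mesh}
#' @param J channels x nodes \code{sensitivity_matrix}
#' @param noise a \code{\link{noise_spec}}
#' @param n_trials number of stimulus presentations (>= 1)
#' @param seed integer RNG seed (full determinism)
#' @param condition condition label attached to the events
#' @param fs sampling rate (Hz)
#' @param dpf,extinction Beer-Lambert forward-model constants
#' @param i0 reference intensity (a.u.)
#' @return list with \code{recording} (a \code{nirs_recording}) and
#'   \code{truth}: node amplitude map, true peak node and latency, the
#'   noise-free channel concentration response (channel x chromophore x
#'   time) and the event times
#' @export
simulate_subject <- function(hrf, pattern, mont, mesh, J, noise = noise_spec(),
                             n_trials = 11, seed = 1, condition = "touch",
                             fs = 10, dpf = 4.39,
                             extinction = extinction_default(), i0 = 1) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  set.seed(as.integer(seed))
  nch <- nrow(mont$channels)
  # events
  isi <- stats::runif(n_trials, 35, 60)
  ev_t <- 35 + cumsum(c(0, isi[-n_trials]))
  dur <- ev_t[n_trials] + 40
  nt <- ceiling(dur * fs) + 1
  tm <- (seq_len(nt) - 1) / fs
  # channel gains from the spatial pattern through the forward model
  map <- make_spatial_map(pattern, mesh)
  gain <- as.numeric(J$weights %*% map)          # n_ch
  # single-trial response kernel on a 0..35 s support
  kt <- seq(0, 35, by = 1 / fs)
  k <- make_hrf(hrf, kt)
  resp <- array(0, c(nch, 2, nt))
  for (e in ev_t) {
    i0s <- round(e * fs) + 1
    idx <- i0s:min(i0s + length(kt) - 1, nt)
    ki <- seq_along(idx)
    resp[, 1, idx] <- resp[, 1, idx] + outer(gain, k$hbo[ki])
    resp[, 2, idx] <- resp[, 2, idx] + outer(gain, k$hb[ki])
  }
  conc <- resp
  # physiological noise per channel and chromophore
  add_osc <- function(freq, amp) {
    if (amp == 0) return(NULL)
    for (ch in seq_len(nch)) for (cc in 1:2) {
      ph <- stats::runif(1, 0, 2 * pi)
      conc[ch, cc, ] <<- conc[ch, cc, ] + amp * sin(2 * pi * freq * tm + ph)
    }
  }
  add_osc(noise$cardiac[1], noise$cardiac[2])
  add_osc(noise$respiratory[1], noise$respiratory[2])
  add_osc(noise$mayer[1], noise$mayer[2])
  if (noise$white_sd > 0)
    conc <- conc + array(stats::rnorm(length(conc), sd = noise$white_sd), dim(conc))
  if (noise$global_amp > 0) {
    g <- .slow_series(nt, fs) * noise$global_amp
    gains <- stats::runif(nch, 0.5, 1.5)
    for (cc in 1:2) conc[, cc, ] <- conc[, cc, ] + outer(gains, g)
  }
  n_art <- stats::rpois(1, noise$motion_rate_per_min * dur / 60)
  art_t <- if (n_art > 0) sort(stats::runif(n_art, 5, dur - 5)) else numeric(0)
  for (a in art_t) {
    idx <- which(tm >= a & tm < a + noise$motion_dur_s)
    sgn <- sample(c(-1, 1), 1)
    conc[, , idx] <- conc[, , idx] + sgn * noise$motion_amp
  }
  od <- beer_lambert_forward(conc, mont, dpf = dpf, extinction = extinction)
  intens <- i0 * exp(-od)
  events <- data.frame(time_s = ev_t, condition = condition,
                       stringsAsFactors = FALSE)
  rec <- raw_recording(mont, intens, fs, events)
  truth <- list(node_amplitude = hrf$amplitude_uM * map,
                peak_node = pattern$peak_node,
                peak_latency_s = hrf$latency_s,
                channel_response = resp, channel_gain = gain,
                event_times = ev_t, artifact_times = art_t)
  list(recording = rec, truth = truth)
}

#' Simulate a study-sized group of recordings
#'
#' Default group structure mirrors the study: 16 heel-touch subjects, 11
#' hand-touch subjects and 11 heel-lance subjects; lance subjects contribute
#' exactly one trial, touch subjects 6--15 trials. Per-subject seeds are
#' derived deterministically from the master seed.
#'
#' @param conditions named list of per-condition settings; each entry is a
#'   list with \code{n_subjects}, \code{hrf} (\code{hrf_spec}),
#'   \code{pattern} (\code{spatial_spec}) and \code{n_trials} (scalar or
#'   range to sample uniformly)
#' @param mont,mesh,J shared montage, mesh, sensitivity matrix
#' @param noise a \code{\link{noise_spec}}
#' @param seed master seed
#' @return named list per condition: list of \code{simulate_subject}
#'   results, plus the shared ground-truth specs
#' @export
simulate_group <- function(conditions, mont, mesh, J, noise = noise_spec(),
                           seed = 1) {
  out <- list()
  ci <- 0
  for (cond in names(conditions)) {
    ci <- ci + 1
    spec <- conditions[[cond]]
    if (spec$n_subjects < 2) stop("n_subjects must be >= 2")
    subs <- vector("list", spec$n_subjects)
    for (i in seq_len(spec$n_subjects)) {
      # derive in double precision: products of a large master seed
      # overflow 32-bit integers
      sseed <- as.integer((as.numeric(seed) * 131 + ci * 7919 +
                             i * 104729) %% 2147483629)
      set.seed(sseed)
      ntr <- if (length(spec$n_trials) == 2) {
        sample(spec$n_trials[1]:spec$n_trials[2], 1)
      } else spec$n_trials
      subs[[i]] <- simulate_subject(spec$hrf, spec$pattern, mont, mesh, J,
                                    noise = noise, n_trials = ntr,
                                    seed = sseed, condition = cond)
    }
    out[[cond]] <- subs
  }
  out
}

#' Study-default condition specifications
#'
#' Heel touch: 16 subjects, focal pattern, 0.35 uM peaking at 15.8 s.
#' Hand touch: 11 subjects, focal pattern at a more lateral node, 0.33 uM at
#' 9.2 s. Heel lance: 11 subjects, one trial each, widespread pattern
#' sharing the heel peak node, 0.96 uM at 14.5 s.
#'
#' @param mesh the mesh the patterns live on; peak nodes default to the node
#'   nearest (0, 15, .) for heel and (20, -15, .) for hand
#' @return named list suitable for \code{\link{simulate_group}}
#' @export
default_conditions <- function(mesh) {
  nearest <- function(xy) {
    which.min((mesh$nodes[, 1] - xy[1])^2 + (mesh$nodes[, 2] - xy[2])^2)
  }
  heel <- nearest(c(0, 15)); hand <- nearest(c(20, -15))
  list(
    touch_heel = list(n_subjects = 16, n_trials = c(6, 15),
                      hrf = hrf_spec(0.35, 15.8),
                      pattern = spatial_spec(heel, 10, "focal")),
    touch_hand = list(n_subjects = 11, n_trials = c(6, 15),
                      hrf = hrf_spec(0.33, 9.2),
                      pattern = spatial_spec(hand, 10, "focal")),
    lance_heel = list(n_subjects = 11, n_trials = 1,
                      hrf = hrf_spec(0.96, 14.5),
                      pattern = spatial_spec(heel, 10, "widespread",
                                             direction = c(1, -1.5, 0)))
  )
}

#' Epoch-level group generator for the statistical suites
#'
#' Generates per-subject trial-averaged haemoglobin epochs directly on the
#' standard (-5, 30] s grid: channel signal = (sensitivity x spatial map)
#' outer HRF, plus AR(1) temporally correlated noise whose SD is divided by
#' the square root of the per-subject trial count (emulating trial
#' averaging). Much cheaper than full raw-intensity simulation; used where
#' only the group statistics are under test.
#'
#' @param n_subjects group size
#' @param hrf,pattern response specification (\code{amplitude_uM = 0} for a
#'   noise-only group)
#' @param mont,mesh,J montage, mesh, sensitivity matrix
#' @param noise_sd stationary SD of the single-trial AR(1) noise (uM)
#' @param ar AR(1) coefficient at 10 Hz
#' @param n_trials scalar or range; per-subject trial counts
#' @param seed integer seed
#' @param fs sampling rate
#' @return list with \code{epochs} (list of \code{nirs_epoch_avg}) and
#'   \code{truth} (channel gains, node map, peak node/latency)
#' @export
simulate_average_epochs <- function(n_subjects, hrf, pattern, mont, mesh, J,
                                    noise_sd = 0.15, ar = 0.9,
                                    n_trials = c(6, 15), seed = 1, fs = 10) {
  set.seed(as.integer(seed))
  tm <- epoch_time(fs)
  nt <- length(tm)
  nch <- nrow(mont$channels)
  map <- make_spatial_map(pattern, mesh)
  gain <- as.numeric(J$weights %*% map)
  k <- if (hrf$amplitude_uM != 0) make_hrf(hrf, tm) else
    list(hbo = numeric(nt), hb = numeric(nt))
  sig <- array(0, c(nch, 2, nt))
  sig[, 1, ] <- outer(gain, k$hbo)
  sig[, 2, ] <- outer(gain, k$hb)
  innov_sd <- sqrt(1 - ar^2)          # unit stationary SD
  epochs <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    ntr <- if (length(n_trials) == 2) sample(n_trials[1]:n_trials[2], 1) else n_trials
    sd_i <- noise_sd / sqrt(ntr)
    noise <- array(0, c(nch, 2, nt))
    for (ch in seq_len(nch)) for (cc in 1:2) {
      noise[ch, cc, ] <- as.numeric(stats::filter(
        stats::rnorm(nt, sd = innov_sd), ar, method = "recursive")) * sd_i
    }
    v <- sig + noise
    # per-subject baseline correction, as in the preprocessing chain
    bl <- tm < 0
    for (ch in seq_len(nch)) for (cc in 1:2)
      v[ch, cc, ] <- v[ch, cc, ] - mean(v[ch, cc, bl])
    dimnames(v) <- list(mont$channels$channel, c("HbO", "Hb"), NULL)
    epochs[[i]] <- structure(list(values = v, time = tm, fs = fs,
                                  n_trials = ntr, subject = i),
                             class = "nirs_epoch_avg")
  }
  list(epochs = epochs,
       truth = list(channel_gain = gain, node_amplitude = hrf$amplitude_uM * map,
                    peak_node = pattern$peak_node,
                    peak_latency_s = hrf$latency_s))
}
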