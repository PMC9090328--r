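#' Analysis configuration
#'
#' Collects every numeric constant of the pipeline in one place. The defaults
#' are the values used throughout the neonatal somatosensory mapping analysis:
#' channel pruning at mean intensity < 0.01 (a.u.) or raw SNR < 2; motion
#' detection on optical density with amplitude change > 0.7 or a windowed SD
#' exceeding 15 times the series' median windowed SD over a 1 s window;
#' 0.01--0.5 Hz band-pass; differential pathlength factor 4.39; epochs from
#' -5 to 30 s around the stimulus; pointwise two-tailed alpha 0.01 with
#' Bonferroni over channels x post-stimulus samples; runs retained only when
#' continuously significant for at least 1 s; zeroth-order Tikhonov
#' hyperparameter 0.1 (scaled by the largest singular value of the
#' sensitivity matrix); 1000 bootstrap repetitions; condition-comparison
#' alpha 0.025 per tail (0.05 for peak location, a one-sided distance).
#'
#' @param ... named overrides of any default listed below.
#' @return A named list of class \code{nirs_config}.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    prune_intensity_min  = 0.01,   # a.u., mean raw intensity
    prune_snr_min        = 2,      # mean / SD of raw intensity
    motion_amp_thresh    = 0.7,    # OD peak-to-peak within window
    motion_sd_thresh     = 15,     # x median windowed SD
    motion_window_s      = 1,      # s
    wavelet_iqr_factor   = 1.5,    # outlier fence on detail coefficients
    bandpass_low_hz      = 0.01,
    bandpass_high_hz     = 0.5,
    bandpass_order       = 3,      # Butterworth, applied forward-backward
    pca_components       = 1,      # global components removed per subject
    dpf                  = 4.39,   # differential pathlength factor
    epoch_window_s       = c(-5, 30),
    baseline_window_s    = c(-5, 0),
    alpha_pointwise      = 0.01,
    min_run_s            = 1,      # continuity filter
    alpha_image          = 0.01,   # node-wise peak-window test
    peak_halfwindow_s    = 2.5,    # 5 s window around peak latency
    tikhonov_lambda      = 0.1,
    tikhonov_scaled      = TRUE,   # lambda x largest singular value of J
    bootstrap_reps       = 1000,
    alpha_two_tailed     = 0.025,  # per tail, signed metric differences
    alpha_location       = 0.05,   # one-sided, peak distance
    seed                 = 1L
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  structure(cfg, class = "nirs_config")
}
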