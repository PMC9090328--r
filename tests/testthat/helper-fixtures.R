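# Shared fixtures, built once per test run and memoised. Everything is
# generated in code; no data files ship with the package.

.fx <- new.env(parent = emptyenv())

# Suite mesh used by the statistical suites: 13 x 13 curved patch over
# 90 x 90 mm. The 7.5 mm node spacing exceeds the reconstruction
# point-spread flat-top, so single-node peak identification is
# well-conditioned (see the methods vignette).
fx_mesh <- function() {
  if (is.null(.fx$mesh)) .fx$mesh <- make_patch_mesh(13, 13, 90, 90, 120)
  .fx$mesh
}

fx_mont <- function() {
  if (is.null(.fx$mont)) .fx$mont <- default_montage(fx_mesh())
  .fx$mont
}

fx_jac <- function() {
  if (is.null(.fx$jac)) .fx$jac <- synthetic_jacobian(fx_mont(), fx_mesh())
  .fx$jac
}

# node nearest the heel representation used throughout the simulations
fx_heel <- function() {
  m <- fx_mesh()
  which.min((m$nodes[, 1] - 0)^2 + (m$nodes[, 2] - 15)^2)
}

# small planar mesh for cheap geometric/oracle tests
fx_flat_mesh <- function() {
  if (is.null(.fx$flat)) .fx$flat <- make_patch_mesh(7, 7, 60, 60, Inf)
  .fx$flat
}

# a tiny 2-source/2-detector montage with 30 mm separations; 2 channels
fx_tiny_montage <- function() {
  optodes <- data.frame(
    optode_id = c("S1", "S2", "D1", "D2"),
    kind = c("S", "S", "D", "D"),
    x_mm = c(0, 60, 30, 90),
    y_mm = 0, z_mm = 0,
    stringsAsFactors = FALSE)
  channels <- data.frame(
    channel = c("CH1", "CH2"),
    source = c("S1", "S2"),
    detector = c("D1", "D2"),
    stringsAsFactors = FALSE)
  montage(optodes, channels)
}

# a noise-free recording carrying a known concentration pattern
fx_clean_recording <- function(amp = 0.5, n_trials = 2, seed = 7) {
  quiet <- noise_spec(white_sd = 0, cardiac = c(2.3, 0),
                      respiratory = c(0.7, 0), mayer = c(0.1, 0),
                      global_amp = 0, motion_rate_per_min = 0)
  simulate_subject(hrf_spec(amp, 15.8), spatial_spec(fx_heel(), 10, "focal"),
                   fx_mont(), fx_mesh(), fx_jac(), noise = quiet,
                   n_trials = n_trials, seed = seed)
}

# node-level image groups for the surrogate machinery: a known spatial map
# times an HRF time course plus spatially white AR(1) noise. This is the
# model class the per-node phase-randomised surrogate is designed for.
fx_node_images <- function(n, seed, mesh = fx_mesh(), amp = 0.5,
                           latency = 15, sd = 0.15, ar = 0.9) {
  tt <- epoch_time()
  nt <- length(tt)
  nn <- nrow(mesh$nodes)
  heel <- which.min((mesh$nodes[, 1] - 0)^2 + (mesh$nodes[, 2] - 15)^2)
  map <- make_spatial_map(spatial_spec(heel, 10, "focal"), mesh)
  h <- if (amp != 0) make_hrf(hrf_spec(amp, latency), tt) else
    list(hbo = numeric(nt), hb = numeric(nt))
  sig_hbo <- outer(map, h$hbo)
  sig_hb <- outer(map, h$hb)
  set.seed(as.integer(seed))
  innov <- sd * sqrt(1 - ar^2)
  ar_noise <- function() {
    m <- matrix(stats::rnorm(nn * nt, sd = innov), nn, nt)
    for (j in 2:nt) m[, j] <- ar * m[, j - 1] + m[, j]
    m
  }
  lapply(seq_len(n), function(i)
    list(hbo = sig_hbo + ar_noise(), hb = sig_hb + ar_noise(), time = tt))
}
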