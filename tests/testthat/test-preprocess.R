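test_that("epoch grid has 50 baseline and 300 post-stimulus samples", {
  tm <- epoch_time()
  expect_length(tm, 350)
  expect_equal(sum(tm < 0), 50)
  expect_equal(sum(tm >= 0), 300)
  expect_equal(tm[1], -5)
  expect_equal(tm[350], 29.9)
})

test_that("prune_channels removes weak and noisy channels with reasons", {
  m <- fx_tiny_montage()
  nt <- 200
  set.seed(1)
  intens <- array(1 + 0.01 * rnorm(2 * 2 * nt), c(2, 2, nt))
  intens[2, 1, ] <- 0.001 * (1 + 0.001 * rnorm(nt))   # below intensity floor
  rec <- raw_recording(m, abs(intens), 10,
                       data.frame(time_s = 1, condition = "x"))
  pr <- prune_channels(rec)
  expect_equal(dim(pr$recording$intensity)[1], 1)
  expect_true("CH2" %in% pr$removed$channel)
  expect_match(pr$removed$reason[pr$removed$channel == "CH2"], "intensity")

  # SNR pruning: mean/SD below 2
  intens2 <- array(1, c(2, 2, nt))
  intens2[1, 1, ] <- abs(1 + rnorm(nt))               # SD ~ 1 -> SNR ~ 1
  rec2 <- raw_recording(m, intens2, 10,
                        data.frame(time_s = 1, condition = "x"))
  pr2 <- prune_channels(rec2)
  expect_true("CH1" %in% pr2$removed$channel)
  expect_match(pr2$removed$reason[pr2$removed$channel == "CH1"], "snr|SNR")

  # all channels failing is an error
  rec3 <- raw_recording(m, array(1e-6, c(2, 2, nt)) * (1 + 0 * intens), 10,
                        data.frame(time_s = 1, condition = "x"))
  expect_error(prune_channels(rec3), "[Aa]ll channels")
})

test_that("optical density of a constant intensity is zero", {
  m <- fx_tiny_montage()
  rec <- raw_recording(m, array(2.5, c(2, 2, 100)), 10,
                       data.frame(time_s = 1, condition = "x"))
  od <- to_optical_density(rec)
  expect_true(all(od$values == 0))
})

test_that("motion detection flags amplitude spikes and high-variance windows", {
  m <- fx_tiny_montage()
  nt <- 600
  set.seed(2)
  intens <- array(exp(0.005 * rnorm(2 * 2 * nt)), c(2, 2, nt))
  # a 1 uM-scale OD jump on channel 1 around sample 300
  intens[1, 1, 300:304] <- intens[1, 1, 300:304] * exp(-2)
  rec <- raw_recording(m, intens, 10, data.frame(time_s = 1, condition = "x"))
  od <- to_optical_density(rec)
  mask <- detect_motion(od)
  expect_true(any(mask[1, 295:310]))
  expect_false(any(mask[2, ]))
})

test_that("wavelet correction shrinks spikes and leaves clean channels alone", {
  m <- fx_tiny_montage()
  nt <- 512
  set.seed(3)
  base <- 0.02 * sin(2 * pi * 0.05 * (1:nt) / 10) + 0.002 * rnorm(nt)
  spike <- base
  spike[250:254] <- spike[250:254] + 1.5
  vals <- array(0, c(2, 2, nt))
  vals[1, 1, ] <- spike; vals[1, 2, ] <- spike
  vals[2, 1, ] <- base;  vals[2, 2, ] <- base
  od <- list(values = vals, fs = 10, channels = m$channels$channel)
  class(od) <- "nirs_od"
  mask <- matrix(FALSE, 2, nt); mask[1, 245:260] <- TRUE
  corr <- wavelet_correct(od, mask)
  # flagged channel: spike energy strongly reduced
  expect_lt(max(abs(corr$values[1, 1, 245:260] - base[245:260])),
            0.5 * max(abs(spike[245:260] - base[245:260])))
  # unflagged channel untouched
  expect_identical(corr$values[2, , ], od$values[2, , ])
})

test_that("wavelet transform reconstructs clean series exactly", {
  # with no flagged samples and an enormous outlier fence nothing is zeroed,
  # so correction must be a perfect round-trip of the DWT
  m <- fx_tiny_montage()
  nt <- 300                            # non-power-of-2 exercises padding
  set.seed(4)
  vals <- array(rnorm(2 * 2 * nt), c(2, 2, nt))
  od <- list(values = vals, fs = 10, channels = m$channels$channel)
  class(od) <- "nirs_od"
  corr <- wavelet_correct(od, mask = NULL, iqr_factor = 1e12)
  expect_equal(corr$values, od$values, tolerance = 1e-12)
})

test_that("bandpass rejects drift and cardiac bands, passes the HRF band", {
  m <- fx_tiny_montage()
  nt <- 3000; fs <- 10
  t <- (1:nt) / fs
  sig <- function(f) sin(2 * pi * f * t)
  vals <- array(0, c(2, 2, nt))
  vals[1, 1, ] <- 5 + 0.001 * t + sig(0.1)   # drift + in-band
  vals[2, 1, ] <- sig(2.3)                   # cardiac
  od <- list(values = vals, fs = fs, channels = m$channels$channel)
  class(od) <- "nirs_od"
  filt <- bandpass(od)
  mid <- 500:2500                            # avoid filter edges
  inband <- filt$values[1, 1, mid]
  expect_gt(stats::sd(inband), 0.5)          # 0.1 Hz survives
  expect_lt(max(abs(filt$values[2, 1, mid])), 0.05)  # 2.3 Hz rejected
  expect_lt(abs(mean(filt$values[1, 1, mid])), 0.05) # drift rejected
  expect_error(bandpass(od, high = 5), "Nyquist")
})

test_that("global PCA removal strips a shared component", {
  m <- fx_tiny_montage()
  nt <- 400
  set.seed(5)
  g <- cumsum(rnorm(nt)); g <- (g - mean(g)) / stats::sd(g)
  vals <- array(0.01 * rnorm(2 * 2 * nt), c(2, 2, nt))
  for (ch in 1:2) for (cc in 1:2) vals[ch, cc, ] <- vals[ch, cc, ] + 3 * g
  od <- list(values = vals, fs = 10, channels = m$channels$channel)
  class(od) <- "nirs_od"
  clean <- remove_global_pca(od)
  expect_lt(stats::sd(clean$values[1, 1, ]), 0.1 * stats::sd(od$values[1, 1, ]))
  expect_identical(remove_global_pca(od, 0), od)
})

test_that("epoching drops trials without full windows and baselines to zero", {
  m <- fx_tiny_montage()
  nt <- 700; fs <- 10
  set.seed(6)
  vals <- array(rnorm(2 * 2 * nt), c(2, 2, nt))
  haemo <- list(values = vals, fs = fs, channels = m$channels$channel)
  class(haemo) <- "nirs_haemo"
  ev <- data.frame(time_s = c(2, 30, 68),  # first and last overflow the window
                   condition = "touch", stringsAsFactors = FALSE)
  ep <- epoch_and_average(haemo, ev)
  expect_equal(sum(ep$retained), 1)
  expect_equal(which(ep$retained), 2L)
  expect_match(ep$reasons[1], "window")
  expect_equal(ep$average$n_trials, 1)
  bl <- ep$time < 0
  for (ch in 1:2) for (cc in 1:2)
    expect_equal(mean(ep$average$values[ch, cc, bl]), 0, tolerance = 1e-12)
  expect_error(epoch_and_average(haemo, ev[1, , drop = FALSE]), "full window")
})

test_that("preprocessing chain records its applied stages in order", {
  sim <- fx_clean_recording()
  out <- preprocess_recording(sim$recording)
  expect_equal(out$stages,
               c("prune", "od", "motion", "bandpass", "pca",
                 "beer_lambert", "epoch"))
  out2 <- preprocess_recording(sim$recording, stages = c("prune"))
  expect_false("pca" %in% out2$stages)
  expect_s3_class(out$epochs, "nirs_epochs")
})

test_that("noise-free simulation is recovered through the minimal chain", {
  # forward-generate a known response, push it through prune + OD +
  # Beer-Lambert + epoching, and compare the averaged epoch against the
  # known channel-space response kernel
  sim <- fx_clean_recording(amp = 0.5, n_trials = 2)
  out <- preprocess_recording(sim$recording, stages = "prune")
  avg <- out$epochs$average
  tm <- out$epochs$time
  k <- make_hrf(hrf_spec(0.5, 15.8), tm)
  gain <- sim$truth$channel_gain
  want_hbo <- outer(gain, k$hbo)
  want_hbo <- want_hbo - rowMeans(want_hbo[, tm < 0, drop = FALSE])
  got <- avg$values[, 1, ]
  expect_equal(unname(got), unname(want_hbo), tolerance = 1e-8)
  # peak amplitude within 2% of the generated amplitude at the best channel
  best <- which.max(gain)
  expect_equal(max(got[best, ]), 0.5 * max(gain), tolerance = 0.02)
})
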