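test_that("HRF kernel peaks at the requested latency and amplitude", {
  tm <- epoch_time()
  for (spec in list(hrf_spec(0.35, 15.8), hrf_spec(0.96, 14.5),
                    hrf_spec(0.33, 9.2))) {
    k <- make_hrf(spec, tm)
    expect_equal(max(k$hbo), spec$amplitude_uM, tolerance = 1e-12)
    expect_equal(tm[which.max(k$hbo)], spec$latency_s, tolerance = 0.051)
    # nothing before stimulus onset
    expect_true(all(k$hbo[tm <= spec$onset_s] == 0))
    # Hb is a scaled, delayed mirror
    expect_equal(min(k$hb), spec$hb_ratio * spec$amplitude_uM,
                 tolerance = 1e-6)
  }
  expect_equal(make_hrf(hrf_spec(0, 15), tm)$hbo, numeric(length(tm)))
  expect_error(make_hrf(hrf_spec(0.5, 15), seq(20, 30, 0.1)), "outside")
  expect_error(hrf_spec(latency_s = -1))
})

test_that("focal spatial pattern is a Gaussian with a unique unit peak", {
  mesh <- fx_mesh()
  heel <- fx_heel()
  w <- make_spatial_map(spatial_spec(heel, 10, "focal"), mesh)
  expect_equal(w[heel], 1)
  expect_equal(sum(w == 1), 1)
  d2 <- rowSums(sweep(mesh$nodes, 2, mesh$nodes[heel, ])^2)
  expect_equal(w, exp(-d2 / 200), tolerance = 1e-12)
  expect_error(make_spatial_map(spatial_spec(10000L), mesh), "not on mesh")
})

test_that("widespread pattern dominates the focal one with a unique peak", {
  mesh <- fx_mesh()
  heel <- fx_heel()
  wf <- make_spatial_map(spatial_spec(heel, 10, "focal"), mesh)
  ww <- make_spatial_map(
    spatial_spec(heel, 10, "widespread", c(1, -1.5, 0), extra_scale_mm = 40),
    mesh)
  expect_equal(ww[heel], 1)
  expect_equal(sum(ww == 1), 1)               # peak stays unique
  expect_true(all(ww >= wf - 1e-12))          # node-wise dominance
  # generated half-max area ratio is at least 2
  ratio <- sum(mesh$node_area[ww >= 0.5]) / sum(mesh$node_area[wf >= 0.5])
  expect_gte(ratio, 2)
})

test_that("noise_spec rejects frequencies above Nyquist", {
  expect_error(noise_spec(cardiac = c(6, 0.1)), "Nyquist")
  expect_silent(noise_spec())
})

test_that("simulate_subject is deterministic and respects the protocol", {
  a <- simulate_subject(hrf_spec(0.5, 15.8), spatial_spec(fx_heel(), 10),
                        fx_mont(), fx_mesh(), fx_jac(), n_trials = 3, seed = 11)
  b <- simulate_subject(hrf_spec(0.5, 15.8), spatial_spec(fx_heel(), 10),
                        fx_mont(), fx_mesh(), fx_jac(), n_trials = 3, seed = 11)
  c <- simulate_subject(hrf_spec(0.5, 15.8), spatial_spec(fx_heel(), 10),
                        fx_mont(), fx_mesh(), fx_jac(), n_trials = 3, seed = 12)
  expect_identical(a$recording$intensity, b$recording$intensity)
  expect_false(identical(a$recording$intensity, c$recording$intensity))
  # inter-stimulus intervals within the sampled range
  isi <- diff(a$truth$event_times)
  expect_true(all(isi >= 35 & isi <= 60))
  expect_equal(nrow(a$recording$events), 3)
  expect_error(simulate_subject(hrf_spec(), spatial_spec(fx_heel()),
                                fx_mont(), fx_mesh(), fx_jac(), n_trials = 0),
               "n_trials")
})

test_that("default study conditions mirror the protocol numbers", {
  cond <- default_conditions(fx_mesh())
  expect_setequal(names(cond), c("touch_heel", "touch_hand", "lance_heel"))
  expect_equal(cond$touch_heel$n_subjects, 16)
  expect_equal(cond$touch_hand$n_subjects, 11)
  expect_equal(cond$lance_heel$n_subjects, 11)
  expect_equal(cond$lance_heel$n_trials, 1)
  expect_equal(cond$touch_heel$n_trials, c(6, 15))
  expect_equal(cond$touch_heel$hrf$amplitude_uM, 0.35)
  expect_equal(cond$touch_hand$hrf$amplitude_uM, 0.33)
  expect_equal(cond$lance_heel$hrf$amplitude_uM, 0.96)
  expect_equal(cond$touch_heel$hrf$latency_s, 15.8)
  expect_equal(cond$touch_hand$hrf$latency_s, 9.2)
  expect_equal(cond$lance_heel$hrf$latency_s, 14.5)
  expect_equal(cond$lance_heel$pattern$kind, "widespread")
  expect_equal(cond$touch_heel$pattern$kind, "focal")
})

test_that("simulate_group derives distinct per-subject seeds", {
  cond <- list(a = list(n_subjects = 2, n_trials = 1,
                        hrf = hrf_spec(0.5, 15), pattern = spatial_spec(fx_heel())))
  g1 <- simulate_group(cond, fx_mont(), fx_mesh(), fx_jac(), seed = 3)
  g2 <- simulate_group(cond, fx_mont(), fx_mesh(), fx_jac(), seed = 3)
  expect_identical(g1$a[[1]]$recording$intensity,
                   g2$a[[1]]$recording$intensity)
  expect_false(identical(g1$a[[1]]$recording$intensity,
                         g1$a[[2]]$recording$intensity))
})

test_that("epoch-level generator matches its stated model", {
  g <- simulate_average_epochs(4, hrf_spec(0.5, 15), spatial_spec(fx_heel()),
                               fx_mont(), fx_mesh(), fx_jac(),
                               noise_sd = 0.1, seed = 21)
  expect_length(g$epochs, 4)
  e <- g$epochs[[1]]
  expect_s3_class(e, "nirs_epoch_avg")
  expect_equal(dim(e$values), c(24, 2, 350))
  bl <- e$time < 0
  for (ch in c(1, 24)) for (cc in 1:2)
    expect_equal(mean(e$values[ch, cc, bl]), 0, tolerance = 1e-12)
  expect_true(all(vapply(g$epochs, `[[`, 0L, "n_trials") %in% 6:15))
  # zero noise reproduces the deterministic channel signal
  g0 <- simulate_average_epochs(2, hrf_spec(0.5, 15), spatial_spec(fx_heel()),
                                fx_mont(), fx_mesh(), fx_jac(),
                                noise_sd = 0, seed = 1)
  tm <- g0$epochs[[1]]$time
  k <- make_hrf(hrf_spec(0.5, 15), tm)
  want <- outer(g0$truth$channel_gain, k$hbo)
  want <- want - rowMeans(want[, tm < 0, drop = FALSE])
  expect_equal(unname(g0$epochs[[1]]$values[, 1, ]), want, tolerance = 1e-10)
})

test_that("full chain recovers the generated amplitude within tolerance", {
  # moderately noisy single subject through the complete preprocessing
  # chain; the best channel's averaged peak stays within a few percent
  noise <- noise_spec(white_sd = 0.05, global_amp = 0.3)
  sim <- simulate_subject(hrf_spec(0.8, 15.8), spatial_spec(fx_heel(), 10),
                          fx_mont(), fx_mesh(), fx_jac(), noise = noise,
                          n_trials = 10, seed = 31)
  out <- preprocess_recording(sim$recording)
  best <- which.max(sim$truth$channel_gain)
  got <- max(out$epochs$average$values[best, 1, ])
  want <- 0.8 * max(sim$truth$channel_gain)
  expect_lt(abs(got - want) / want, 0.15)
})
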