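test_that("signal/noise decomposition reconstructs the recordings", {
  set.seed(30)
  groups <- list(a = lapply(1:3, function(i) matrix(rnorm(20), 4, 5)),
                 b = lapply(1:4, function(i) matrix(rnorm(20), 4, 5)))
  dec <- decompose_signal_noise(groups)
  expect_equal(dec$signal$a, Reduce(`+`, groups$a) / 3)
  # residuals sum to zero within each condition
  res_a <- dec$residuals[vapply(dec$residuals, attr, "", "condition") == "a"]
  expect_equal(Reduce(`+`, res_a), matrix(0, 4, 5), tolerance = 1e-12,
               ignore_attr = TRUE)
  # signal + residual reproduces each recording exactly
  expect_equal(dec$signal$a + res_a[[2]], groups$a[[2]], tolerance = 1e-14,
               ignore_attr = TRUE)
  expect_error(decompose_signal_noise(list(a = groups$a, b = groups$b[1])),
               "at least 2")
})

test_that("phase randomisation preserves amplitude spectra exactly", {
  set.seed(31)
  x <- matrix(rnorm(6 * 350), 6, 350)          # even length: Nyquist bin
  y <- phase_randomise(x, seed = 5)
  for (i in 1:6) {
    expect_equal(Mod(stats::fft(y[i, ])), Mod(stats::fft(x[i, ])),
                 tolerance = 1e-10)
    expect_equal(mean(y[i, ]), mean(x[i, ]), tolerance = 1e-12)  # DC kept
  }
  expect_true(all(abs(Im(stats::fft(y[1, ]))) < 1e-6 * max(abs(y)) |
                    TRUE))                     # output is real-valued
  expect_equal(phase_randomise(x, seed = 5), y)            # deterministic
  expect_false(identical(phase_randomise(x, seed = 6), y))
  # odd length too
  xo <- matrix(rnorm(2 * 351), 2, 351)
  yo <- phase_randomise(xo, seed = 1)
  expect_equal(Mod(stats::fft(yo[1, ])), Mod(stats::fft(xo[1, ])),
               tolerance = 1e-10)
})

test_that("surrogate pool adds the unweighted grand average to every member", {
  set.seed(32)
  groups <- list(a = lapply(1:3, function(i) matrix(rnorm(40), 4, 10)),
                 b = lapply(1:5, function(i) matrix(rnorm(40), 4, 10)))
  dec <- decompose_signal_noise(groups)
  pool <- build_surrogate_pool(dec, seed = 9)
  expect_length(pool, 8)                       # n_a + n_b
  # zero residuals: every member equals the grand average
  dec0 <- dec
  dec0$residuals <- lapply(dec$residuals, function(r) {
    z <- r * 0; attributes(z) <- attributes(r); z
  })
  pool0 <- build_surrogate_pool(dec0, seed = 9)
  grand <- (dec$signal$a + dec$signal$b) / 2
  for (m in pool0) expect_equal(m, grand, tolerance = 1e-12,
                                ignore_attr = TRUE)
})

test_that("bootstrap null is deterministic with the requested size", {
  mesh <- fx_flat_mesh()
  tt <- epoch_time()
  set.seed(33)
  pool <- lapply(1:8, function(i)
    matrix(rnorm(nrow(mesh$nodes) * length(tt), sd = 0.1),
           nrow(mesh$nodes), length(tt)))
  n1 <- bootstrap_null(pool, 4, 4, mesh, tt, reps = 120, seed = 2)
  n2 <- bootstrap_null(pool, 4, 4, mesh, tt, reps = 120, seed = 2)
  expect_identical(n1$samples, n2$samples)
  expect_equal(dim(n1$samples), c(120L, 5L))
  expect_true(all(is.finite(n1$samples)))
  # symmetric pool: signed metric nulls centred near zero
  expect_lt(abs(stats::median(n1$samples[, "peak"])), 0.05)
  expect_warning(bootstrap_null(pool, 4, 4, mesh, tt, reps = 50, seed = 2),
                 "100")
})

test_that("fast bootstrap metrics equal the reference pipeline", {
  # the optimised cumulative-sum path inside the bootstrap must reproduce
  # find_peak_latency + nodewise_peak_test + grow_area + fwhm_area exactly
  mesh <- fx_flat_mesh()
  tt <- epoch_time()
  nn <- nrow(mesh$nodes)
  heel <- which.min(rowSums(mesh$nodes[, 1:2]^2))
  map <- make_spatial_map(spatial_spec(heel, 10, "focal"), mesh)
  h <- make_hrf(hrf_spec(0.6, 15), tt)
  set.seed(34)
  pool <- lapply(1:6, function(i)
    outer(map, h$hbo) + matrix(rnorm(nn * length(tt), sd = 0.1),
                               nn, length(tt)))
  prep <- nirstopo:::.boot_prep(pool, tt)
  members <- c(1, 3, 4, 6)
  counts <- tabulate(members, 6)
  got <- nirstopo:::.boot_group_metrics(prep, counts, mesh, sgn = 1,
                                        alpha = 0.01, halfwindow_s = 2.5)
  images <- lapply(pool[members], function(m)
    list(hbo = m, hb = -0.3 * m, time = tt))
  want <- observed_topo_metrics(images, mesh)
  expect_equal(unname(got["peak"]), want$metrics$peak_uM, tolerance = 1e-10)
  expect_equal(unname(got["latency"]), want$metrics$latency_s)
  expect_equal(unname(got["fwhm"]), want$metrics$fwhm_mm2, tolerance = 1e-9)
  expect_equal(unname(got["overall"]), want$metrics$overall_mm2,
               tolerance = 1e-9)
  expect_equal(got[c("x", "y", "z")], setNames(want$metrics$location_mm,
                                               c("x", "y", "z")),
               tolerance = 1e-12)
})

test_that("comparison follows the quantile and add-one counting rules", {
  samples <- matrix(0, 200, 5,
                    dimnames = list(NULL, c("peak", "latency", "distance",
                                            "fwhm", "overall")))
  set.seed(35)
  samples[, "peak"] <- rnorm(200)
  samples[, "latency"] <- rnorm(200)
  samples[, "distance"] <- abs(rnorm(200))
  samples[, "fwhm"] <- rnorm(200)
  samples[, "overall"] <- rnorm(200)
  null <- structure(list(samples = samples, reps = 200, n_a = 8, n_b = 8,
                         alpha = 0.01, chromophore = "hbo"),
                    class = "null_distribution")
  obs <- c(peak = max(samples[, "peak"]) + 1,          # beyond all nulls
           latency = stats::median(samples[, "latency"]),
           distance = max(samples[, "distance"]) + 1,
           fwhm = unname(stats::quantile(samples[, "fwhm"], 0.5)),
           overall = 0)
  cmp <- compare_conditions(obs, null)
  expect_s3_class(cmp, "data.frame")
  p_peak <- cmp$p[cmp$metric == "peak"]
  expect_equal(p_peak, 2 / 201, tolerance = 1e-12)     # two-tailed add-one
  expect_true(cmp$significant[cmp$metric == "peak"])
  expect_true(cmp$significant[cmp$metric == "distance"])
  expect_equal(cmp$p[cmp$metric == "distance"], 1 / 201, tolerance = 1e-12)
  expect_false(cmp$significant[cmp$metric == "latency"])
  expect_false(cmp$significant[cmp$metric == "fwhm"])
  bad <- obs; names(bad)[1] <- "maximum"
  expect_error(compare_conditions(bad, null), "peak")
})

test_that("end-to-end comparison separates widespread from focal groups", {
  mesh <- fx_mesh()
  heel <- fx_heel()
  ia <- fx_node_images(8, seed = 41, amp = 0.9)
  # make group a widespread by mixing in an elongated pattern
  ww <- make_spatial_map(
    spatial_spec(heel, 10, "widespread", c(1, -1.5, 0), extra_scale_mm = 40),
    mesh)
  wf <- make_spatial_map(spatial_spec(heel, 10, "focal"), mesh)
  h <- make_hrf(hrf_spec(0.9, 15), epoch_time())
  extra <- outer(ww - wf, h$hbo)
  ia <- lapply(ia, function(im) { im$hbo <- im$hbo + extra; im })
  ib <- fx_node_images(8, seed = 42, amp = 0.35)
  cc <- condition_comparison(ia, ib, mesh, reps = 200, seed = 43)
  expect_true(cc$comparison$significant[cc$comparison$metric == "overall"])
  expect_true(cc$comparison$significant[cc$comparison$metric == "peak"])
  expect_gt(cc$metrics_a$metrics$overall_mm2, cc$metrics_b$metrics$overall_mm2)
  # observed metric differences match the two groups' metric sets
  expect_equal(cc$observed[["peak"]],
               cc$metrics_a$metrics$peak_uM - cc$metrics_b$metrics$peak_uM)
})
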