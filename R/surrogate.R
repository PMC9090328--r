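#' Decompose grouped image series into signal and noise
#'
#' The signal estimate per condition is the mean over that condition's
#' recordings; each recording's residual is the recording minus its
#' condition signal (so residuals average to zero exactly).
#'
#' @param groups named list of conditions, each a list of node x time
#'   matrices (one per recording)
#' @return list: \code{signal} (named list of node x time matrices),
#'   \code{residuals} (flat list over all recordings, with a
#'   \code{condition} attribute each)
#' @export
decompose_signal_noise <- function(groups) {
  if (any(vapply(groups, length, 0L) < 2))
    stop("each condition needs at least 2 recordings")
  signal <- lapply(groups, function(g) Reduce(`+`, g) / length(g))
  residuals <- list()
  for (cond in names(groups)) {
    for (m in groups[[cond]]) {
      r <- m - signal[[cond]]
      attr(r, "condition") <- cond
      residuals[[length(residuals) + 1]] <- r
    }
  }
  list(signal = signal, residuals = residuals)
}

#' Phase-randomised surrogate of a multivariate time series
#'
#' Independently for each node (row): discrete Fourier transform, rotation
#' of every positive-frequency phase by an i.i.d. draw from U[0, 2pi),
#' Hermitian symmetry enforced (DC and Nyquist bins left real and
#' unrotated), inverse transform. The surrogate has exactly the original
#' per-node amplitude spectrum but scrambled temporal alignment.
#'
#' @param series node x time numeric matrix (uniform time grid)
#' @param seed optional integer seed (otherwise the current RNG state is
#'   used)
#' @return surrogate node x time matrix (real)
#' @export
phase_randomise <- function(series, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  series <- as.matrix(series)
  n <- ncol(series)
  Fz <- stats::mvfft(t(series))             # time x node
  npos <- if (n %% 2 == 0) n / 2 - 1 else (n - 1) / 2
  if (npos > 0) {
    pos <- 2:(npos + 1)
    theta <- matrix(stats::runif(npos * nrow(series), 0, 2 * pi),
                    npos, nrow(series))
    rot <- exp(1i * theta)
    Fz[pos, ] <- Fz[pos, , drop = FALSE] * rot
    Fz[n + 2 - pos, ] <- Conj(Fz[pos, , drop = FALSE])
  }
  t(Re(stats::mvfft(Fz, inverse = TRUE)) / n)
}

#' Build the pool of surrogate recordings
#'
#' Every residual (from both conditions) is phase-randomised and the grand
#' average signal -- the unweighted mean of the two condition signals -- is
#' added back, giving a pool of surrogate recordings with no systematic
#' between-set difference.
#'
#' @param decomposition a \code{\link{decompose_signal_noise}} result
#' @param seed optional integer seed
#' @param weighted use the recording-count-weighted grand average instead
#'   of the unweighted condition mean
#' @return list of surrogate node x time matrices
#' @export
build_surrogate_pool <- function(decomposition, seed = NULL, weighted = FALSE) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  sig <- decomposition$signal
  grand <- if (weighted) {
    conds <- vapply(decomposition$residuals, attr, "", "condition")
    w <- table(conds)[names(sig)]
    Reduce(`+`, Map(`*`, sig, as.numeric(w))) / sum(w)
  } else {
    Reduce(`+`, sig) / length(sig)
  }
  lapply(decomposition$residuals, function(r) grand + phase_randomise(r))
}

# Fast single-group topographic metrics used inside the bootstrap.
# Mirrors find_peak_latency + nodewise_peak_test(pooled) + grow_area +
# fwhm_area + peak_metrics exactly, but works from precomputed time
# cumulative sums so each repetition costs O(nodes x members).
.boot_prep <- function(pool, time) {
  m <- length(pool)
  nn <- nrow(pool[[1]]); nt <- ncol(pool[[1]])
  post <- which(time >= 0); base <- which(time < 0)
  P <- matrix(0, nn * length(post), m)
  CS <- matrix(0, nn * (nt + 1), m)    # flat: column t+1 at rows t*nn + 1:nn
  CS2 <- matrix(0, nn * (nt + 1), m)
  for (i in seq_len(m)) {
    x <- pool[[i]]
    P[, i] <- as.vector(x[, post])
    run <- numeric(nn); run2 <- numeric(nn)
    for (t in seq_len(nt)) {
      xt <- x[, t]
      run <- run + xt; run2 <- run2 + xt * xt
      CS[t * nn + seq_len(nn), i] <- run
      CS2[t * nn + seq_len(nn), i] <- run2
    }
  }
  b0 <- base[1] - 1L; b1 <- base[length(base)]
  rows_b1 <- b1 * nn + seq_len(nn); rows_b0 <- b0 * nn + seq_len(nn)
  Bx_m <- CS[rows_b1, , drop = FALSE] - CS[rows_b0, , drop = FALSE]
  Bx2_m <- CS2[rows_b1, , drop = FALSE] - CS2[rows_b0, , drop = FALSE]
  list(P = P, CS = CS, CS2 = CS2, Bx_m = Bx_m, Bx2_m = Bx2_m,
       nn = nn, nt = nt, m = m, time = time, post = post, base = base)
}

.boot_group_metrics <- function(prep, counts, mesh, sgn, alpha, halfwindow_s,
                                Mv = NULL) {
  nn <- prep$nn; tm <- prep$time
  n_members <- sum(counts)
  if (is.null(Mv)) Mv <- prep$P %*% (counts / n_members) # post-window mean image
  k <- if (sgn > 0) which.max(Mv) else which.min(Mv)     # earliest time, lowest node
  lat <- tm[prep$post[(k - 1) %/% nn + 1]]
  win <- which(tm >= lat - halfwindow_s & tm < lat + halfwindow_s)
  a <- win[1] - 1L; b <- win[length(win)]
  rows_a <- a * nn + seq_len(nn); rows_b <- b * nn + seq_len(nn)
  n1 <- n_members * length(win)
  n2 <- n_members * length(prep$base)
  Sx <- (prep$CS[rows_b, , drop = FALSE] - prep$CS[rows_a, , drop = FALSE]) %*% counts
  Sx2 <- (prep$CS2[rows_b, , drop = FALSE] - prep$CS2[rows_a, , drop = FALSE]) %*% counts
  Bx <- prep$Bx_m %*% counts
  Bx2 <- prep$Bx2_m %*% counts
  m1 <- Sx / n1; m2 <- Bx / n2
  v1 <- (Sx2 - Sx^2 / n1) / (n1 - 1)
  v2 <- (Bx2 - Bx^2 / n2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tstat), n1 + n2 - 2)
  mask <- as.vector(p <= alpha / nn & is.finite(tstat))
  change <- as.vector(m1 - m2)
  peak_node <- which.max(sgn * change)
  # region growing (as grow_area, without the object wrappers)
  seed <- peak_node
  if (!any(mask)) {
    overall <- 0; fwhm <- 0
  } else {
    if (!mask[seed]) {
      cand <- which(mask)
      d2 <- rowSums(sweep(mesh$nodes[cand, , drop = FALSE], 2,
                          mesh$nodes[seed, ])^2)
      seed <- cand[which.min(d2)]
    }
    visited <- logical(nn); visited[seed] <- TRUE; frontier <- seed
    while (length(frontier)) {
      nb <- unique(unlist(mesh$adjacency[frontier], use.names = FALSE))
      nb <- nb[mask[nb] & !visited[nb]]
      visited[nb] <- TRUE; frontier <- nb
    }
    overall <- sum(mesh$node_area[visited])
    ok <- visited & abs(change) >= 0.5 * abs(change[seed])
    vis2 <- logical(nn)
    if (ok[seed]) {
      vis2[seed] <- TRUE; frontier <- seed
      while (length(frontier)) {
        nb <- unique(unlist(mesh$adjacency[frontier], use.names = FALSE))
        nb <- nb[ok[nb] & !vis2[nb]]
        vis2[nb] <- TRUE; frontier <- nb
      }
    }
    fwhm <- sum(mesh$node_area[vis2])
  }
  loc <- unname(mesh$nodes[seed, ])
  c(peak = unname(change[seed]), latency = lat,
    x = loc[1], y = loc[2], z = loc[3], fwhm = fwhm, overall = overall)
}

#' Bootstrap null distribution of topographic metric differences
#'
#' Each repetition draws two sets (sizes \code{n_a}, \code{n_b}) from the
#' surrogate pool with replacement and re-runs the full topographic
#' pipeline on each (group mean, peak latency, node-wise peak-window test
#' with Bonferroni, region growing, FWHM), collecting the metric
#' differences A - B.
#'
#' @param pool list of surrogate node x time matrices
#' @param n_a,n_b set sizes (the original group sizes)
#' @param mesh the \code{cortical_mesh}
#' @param time epoch time grid
#' @param reps repetitions (default 1000; fewer than 100 triggers a
#'   quantile-resolution warning)
#' @param seed optional integer seed
#' @param chromophore sign convention: \code{"hbo"} peaks positive,
#'   \code{"hb"} negative
#' @param alpha node-wise test level (Bonferroni over nodes)
#' @param halfwindow_s peak window half-width (s)
#' @return object of class \code{null_distribution}: matrix \code{samples}
#'   (reps x 5: peak, latency, distance, fwhm, overall) plus the settings
#' @export
bootstrap_null <- function(pool, n_a, n_b, mesh, time, reps = 1000,
                           seed = NULL, chromophore = c("hbo", "hb"),
                           alpha = 0.01, halfwindow_s = 2.5) {
  chromophore <- match.arg(chromophore)
  if (reps < 100) warning("fewer than 100 repetitions: poor quantile resolution")
  if (!is.null(seed)) set.seed(as.integer(seed))
  sgn <- if (chromophore == "hbo") 1 else -1
  prep <- .boot_prep(pool, time)
  out <- matrix(NA_real_, reps, 5,
                dimnames = list(NULL, c("peak", "latency", "distance",
                                        "fwhm", "overall")))
  CA <- matrix(0, prep$m, reps); CB <- matrix(0, prep$m, reps)
  for (r in seq_len(reps)) {
    CA[, r] <- tabulate(sample.int(prep$m, n_a, replace = TRUE), prep$m)
    CB[, r] <- tabulate(sample.int(prep$m, n_b, replace = TRUE), prep$m)
  }
  chunk <- 50L
  for (r0 in seq(1L, reps, by = chunk)) {
    rr <- r0:min(r0 + chunk - 1L, reps)
    # group-mean post-window images for the whole chunk in one BLAS-3 call
    MA <- prep$P %*% (CA[, rr, drop = FALSE] / n_a)
    MB <- prep$P %*% (CB[, rr, drop = FALSE] / n_b)
    for (j in seq_along(rr)) {
      r <- rr[j]
      ga <- .boot_group_metrics(prep, CA[, r], mesh, sgn, alpha, halfwindow_s,
                                Mv = MA[, j])
      gb <- .boot_group_metrics(prep, CB[, r], mesh, sgn, alpha, halfwindow_s,
                                Mv = MB[, j])
      out[r, ] <- c(ga["peak"] - gb["peak"],
                    ga["latency"] - gb["latency"],
                    sqrt(sum((ga[c("x", "y", "z")] - gb[c("x", "y", "z")])^2)),
                    ga["fwhm"] - gb["fwhm"],
                    ga["overall"] - gb["overall"])
    }
  }
  structure(list(samples = out, reps = reps, n_a = n_a, n_b = n_b,
                 alpha = alpha, chromophore = chromophore),
            class = "null_distribution")
}

#' Compare observed metric differences against the bootstrap null
#'
#' Signed metrics (peak amplitude, latency, FWHM area, overall area) are
#' significant when the observed difference falls outside the central
#' interval between the \code{alpha_two_tailed} and
#' \code{1 - alpha_two_tailed} null quantiles; the peak-location distance
#' (non-negative) is one-sided at \code{alpha_location}. Empirical p values
#' use the add-one convention, so the smallest attainable p is
#' \code{1 / (reps + 1)}.
#'
#' @param observed named numeric vector with entries \code{peak},
#'   \code{latency}, \code{distance}, \code{fwhm}, \code{overall}
#'   (differences A - B; distance is |A - B| in mm)
#' @param null a \code{\link{bootstrap_null}} result
#' @param alpha_two_tailed per-tail level for signed metrics
#' @param alpha_location one-sided level for the peak distance
#' @return data.frame of class \code{comparison_result}: metric, observed,
#'   lower/upper null quantile, p, significant
#' @export
compare_conditions <- function(observed, null, alpha_two_tailed = 0.025,
                               alpha_location = 0.05) {
  metrics <- c("peak", "latency", "distance", "fwhm", "overall")
  if (!all(metrics %in% names(observed)))
    stop("observed must name all of: ", paste(metrics, collapse = ", "))
  R <- nrow(null$samples)
  rows <- lapply(metrics, function(m) {
    s <- null$samples[, m]
    obs <- observed[[m]]
    if (m == "distance") {
      hi <- stats::quantile(s, 1 - alpha_location, names = FALSE)
      p <- (1 + sum(s >= obs)) / (R + 1)
      sig <- obs > hi
      lo <- NA_real_
    } else {
      lo <- stats::quantile(s, alpha_two_tailed, names = FALSE)
      hi <- stats::quantile(s, 1 - alpha_two_tailed, names = FALSE)
      p <- min(1, 2 * min((1 + sum(s <= obs)) / (R + 1),
                          (1 + sum(s >= obs)) / (R + 1)))
      sig <- obs < lo || obs > hi
    }
    data.frame(metric = m, observed = obs, null_lower = lo, null_upper = hi,
               p = p, significant = sig, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_result", "data.frame")
  out
}

#' Observed topographic metrics for one group of image series
#'
#' Convenience wrapper running the full single-group pipeline: group peak
#' latency, node-wise peak-window test, region growing and FWHM.
#'
#' @param images list of \code{nirs_image}
#' @param mesh the mesh
#' @param chromophore \code{"hbo"} or \code{"hb"}
#' @param alpha node-wise level
#' @param halfwindow_s peak window half-width
#' @return list: \code{metrics} (a \code{topo_metrics}), \code{map}, \code{area}
#' @export
observed_topo_metrics <- function(images, mesh, chromophore = c("hbo", "hb"),
                                  alpha = 0.01, halfwindow_s = 2.5) {
  chromophore <- match.arg(chromophore)
  pk <- find_peak_latency(images, chromophore)
  map <- nodewise_peak_test(images, pk$latency_s, chromophore, alpha,
                            halfwindow_s)
  area <- suppressWarnings(grow_area(map, mesh))
  list(metrics = peak_metrics(map, mesh, area), map = map, area = area,
       peak = pk)
}

#' Full between-condition comparison pipeline
#'
#' Computes observed topographic metrics for both groups, builds the
#' phase-scrambled surrogate pool, bootstraps the null distribution of
#' metric differences and returns the comparison table.
#'
#' @param images_a,images_b per-subject \code{nirs_image} lists
#' @param mesh the mesh
#' @param time epoch time grid
#' @param chromophore \code{"hbo"} or \code{"hb"}
#' @param reps bootstrap repetitions
#' @param seed integer seed (full determinism)
#' @param alpha node-wise test level
#' @param halfwindow_s peak window half-width
#' @param alpha_two_tailed,alpha_location comparison levels
#' @return list: \code{comparison} (a \code{comparison_result}),
#'   \code{observed} (named differences), \code{null}, \code{metrics_a},
#'   \code{metrics_b}
#' @export
condition_comparison <- function(images_a, images_b, mesh, time = NULL,
                                 chromophore = c("hbo", "hb"), reps = 1000,
                                 seed = 1, alpha = 0.01, halfwindow_s = 2.5,
                                 alpha_two_tailed = 0.025,
                                 alpha_location = 0.05) {
  chromophore <- match.arg(chromophore)
  if (is.null(time)) time <- images_a[[1]]$time
  oa <- observed_topo_metrics(images_a, mesh, chromophore, alpha, halfwindow_s)
  ob <- observed_topo_metrics(images_b, mesh, chromophore, alpha, halfwindow_s)
  observed <- c(peak = oa$metrics$peak_uM - ob$metrics$peak_uM,
                latency = oa$metrics$latency_s - ob$metrics$latency_s,
                distance = peak_distance(oa$metrics, ob$metrics),
                fwhm = oa$metrics$fwhm_mm2 - ob$metrics$fwhm_mm2,
                overall = oa$metrics$overall_mm2 - ob$metrics$overall_mm2)
  groups <- list(a = lapply(images_a, `[[`, chromophore),
                 b = lapply(images_b, `[[`, chromophore))
  dec <- decompose_signal_noise(groups)
  set.seed(as.integer(seed))
  pool <- build_surrogate_pool(dec)
  null <- bootstrap_null(pool, length(images_a), length(images_b), mesh,
                         time, reps = reps, chromophore = chromophore,
                         alpha = alpha, halfwindow_s = halfwindow_s)
  list(comparison = compare_conditions(observed, null, alpha_two_tailed,
                                       alpha_location),
       observed = observed, null = null,
       metrics_a = oa, metrics_b = ob)
}
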