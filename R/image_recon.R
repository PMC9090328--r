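#' Synthetic channel-to-node sensitivity matrix
#'
#' Distance-based stand-in for a photon-transport Jacobian: the weight of
#' channel c at node n is proportional to
#' \eqn{\exp(-(d_s(n) + d_d(n)) / decay)} with \eqn{d_s, d_d} the Euclidean
#' distances from the node to the channel's source and detector optodes;
#' rows are normalised to unit sum.
#'
#' @param mont a \code{nirs_montage}
#' @param mesh a \code{cortical_mesh} in the same coordinate frame
#' @param depth_decay_mm decay length (mm)
#' @return object of class \code{sensitivity_matrix}: list with
#'   \code{weights} (channels x nodes), \code{channels}
#' @export
synthetic_jacobian <- function(mont, mesh, depth_decay_mm = 15) {
  ps <- optode_position(mont, mont$channels$source)
  pd <- optode_position(mont, mont$channels$detector)
  nch <- nrow(ps); nn <- nrow(mesh$nodes)
  # frame sanity: some node must be near the array
  opt <- as.matrix(mont$optodes[, c("x_mm", "y_mm", "z_mm")])
  mind <- min(sqrt(outer(rowSums(opt^2), rowSums(mesh$nodes^2), `+`) -
                     2 * opt %*% t(mesh$nodes)))
  if (!is.finite(mind) || mind > 100)
    stop("montage/mesh frame mismatch: no node within 100 mm of any optode")
  W <- matrix(0, nch, nn)
  for (ch in seq_len(nch)) {
    ds <- sqrt(colSums((t(mesh$nodes) - ps[ch, ])^2))
    dd <- sqrt(colSums((t(mesh$nodes) - pd[ch, ])^2))
    W[ch, ] <- exp(-(ds + dd) / depth_decay_mm)
  }
  rs <- rowSums(W)
  if (any(rs <= 0)) stop("channel with zero total sensitivity")
  W <- W / rs
  structure(list(weights = W, channels = mont$channels$channel),
            class = "sensitivity_matrix")
}

#' Zeroth-order Tikhonov image reconstruction
#'
#' Linear, cortically constrained reconstruction of channel data onto the
#' mesh at each time point, in the underdetermined form
#' \deqn{x = J^T (J J^T + (\lambda s_1)^2 I)^{-1} y,}
#' where \eqn{s_1} is the largest singular value of J when
#' \code{scaled = TRUE} (the usual diffuse-optical convention for a
#' dimensionless hyperparameter), or 1 for an absolute \eqn{\lambda}. The
#' operator is precomputed once, so reconstruction is linear in y.
#'
#' @param y channel x time matrix (or a \code{nirs_epoch_avg}, reconstructed
#'   per chromophore)
#' @param J a \code{sensitivity_matrix}
#' @param lambda regularisation hyperparameter
#' @param scaled scale lambda by the largest singular value of J
#' @return for a matrix input: node x time matrix; for a
#'   \code{nirs_epoch_avg}: object of class \code{nirs_image} with
#'   \code{hbo}, \code{hb} (node x time), \code{time}, \code{subject}
#' @export
tikhonov_reconstruct <- function(y, J, lambda = 0.1, scaled = TRUE) {
  A <- tikhonov_operator(J, lambda, scaled)
  if (inherits(y, "nirs_epoch_avg")) {
    structure(list(hbo = A %*% y$values[, 1, ], hb = A %*% y$values[, 2, ],
                   time = y$time, subject = y$subject),
              class = "nirs_image")
  } else {
    A %*% y
  }
}

#' Precompute the Tikhonov reconstruction operator
#' @inheritParams tikhonov_reconstruct
#' @return node x channel matrix \code{A} with \code{x = A y}
#' @export
tikhonov_operator <- function(J, lambda = 0.1, scaled = TRUE) {
  W <- J$weights
  if (all(W == 0)) stop("all-zero sensitivity matrix")
  s1 <- if (scaled) svd(W, nu = 0, nv = 0)$d[1] else 1
  G <- W %*% t(W)
  diag(G) <- diag(G) + (lambda * s1)^2
  t(W) %*% solve(G)
}

#' Peak latency of the group-average image
#'
#' Averages the image time series over subjects and returns the latency and
#' node of the maximum change anywhere across the cortex in the
#' post-stimulus window (maximum for HbO, minimum for Hb). Ties break to
#' the earliest latency, then the lowest node index.
#'
#' @param images list of \code{nirs_image}
#' @param chromophore \code{"hbo"} or \code{"hb"}
#' @return list: \code{latency_s}, \code{node}, \code{mean_image}
#'   (node x time group mean)
#' @export
find_peak_latency <- function(images, chromophore = c("hbo", "hb")) {
  chromophore <- match.arg(chromophore)
  tm <- images[[1]]$time
  M <- Reduce(`+`, lapply(images, `[[`, chromophore)) / length(images)
  post <- which(tm >= 0)
  Mp <- M[, post, drop = FALSE]
  v <- if (chromophore == "hbo") Mp else -Mp
  if (max(v) == min(v)) warning("degenerate (constant) group image; tie broken to earliest sample")
  # column-major scan over node x time: earliest time wins, then lowest node
  best <- which(v == max(v), arr.ind = TRUE)[1, ]
  list(latency_s = tm[post[best[2]]], node = unname(best[1]), mean_image = M)
}

#' Node-wise peak-window significance test
#'
#' For every node, compares the 5 s window centred on the identified peak
#' latency against the 5 s pre-stimulus baseline with a two-tailed t-test,
#' Bonferroni corrected over the number of nodes. Both distributions are
#' built by concatenating the individual subjects' samples (the pooled
#' construction); \code{pooled = FALSE} instead uses per-subject window
#' means (S values per side). The mean-change image is masked by
#' significance.
#'
#' @param images list of \code{nirs_image} (one per subject)
#' @param latency_s peak latency from \code{\link{find_peak_latency}}
#' @param chromophore \code{"hbo"} or \code{"hb"}
#' @param alpha two-tailed level before Bonferroni
#' @param halfwindow_s half-width of the peak window (s)
#' @param pooled concatenate subject samples (default) or use subject means
#' @return object of class \code{activation_map}: \code{mean_change},
#'   \code{t}, \code{p}, \code{mask}, \code{masked_change},
#'   \code{latency_s}, \code{peak_node}, \code{window_idx}, \code{alpha},
#'   \code{chromophore}
#' @export
nodewise_peak_test <- function(images, latency_s, chromophore = c("hbo", "hb"),
                               alpha = 0.01, halfwindow_s = 2.5, pooled = TRUE) {
  chromophore <- match.arg(chromophore)
  tm <- images[[1]]$time
  win <- which(tm >= latency_s - halfwindow_s & tm < latency_s + halfwindow_s)
  full <- sum(tm >= 0 & tm < 2 * halfwindow_s)
  if (length(win) < full) warning("peak window clipped by the epoch edge")
  base <- which(tm < 0)
  S <- length(images)
  X <- lapply(images, `[[`, chromophore)
  nn <- nrow(X[[1]])
  if (pooled) {
    P <- do.call(cbind, lapply(X, function(m) m[, win, drop = FALSE]))
    B <- do.call(cbind, lapply(X, function(m) m[, base, drop = FALSE]))
    n1 <- ncol(P); n2 <- ncol(B)
    m1 <- rowMeans(P); m2 <- rowMeans(B)
    v1 <- rowSums((P - m1)^2) / (n1 - 1)
    v2 <- rowSums((B - m2)^2) / (n2 - 1)
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    Pm <- vapply(X, function(m) rowMeans(m[, win, drop = FALSE]), numeric(nn))
    Bm <- vapply(X, function(m) rowMeans(m[, base, drop = FALSE]), numeric(nn))
    m1 <- rowMeans(Pm); m2 <- rowMeans(Bm)
    v1 <- apply(Pm, 1, stats::var); v2 <- apply(Bm, 1, stats::var)
    se2 <- v1 / S + v2 / S
    tstat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / S)^2 / (S - 1) + (v2 / S)^2 / (S - 1))
  }
  p <- 2 * stats::pt(-abs(tstat), df)
  p[!is.finite(tstat)] <- 1
  mask <- p <= alpha / nn
  mean_change <- m1 - m2
  Mmean <- Reduce(`+`, X) / S
  v <- if (chromophore == "hbo") mean_change else -mean_change
  structure(list(mean_change = mean_change, t = tstat, p = p, mask = mask,
                 masked_change = ifelse(mask, mean_change, 0),
                 latency_s = latency_s,
                 peak_node = which.max(v),
                 window_idx = win, baseline_idx = base, alpha = alpha,
                 chromophore = chromophore),
            class = "activation_map")
}
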