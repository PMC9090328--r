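#' Optode montage
#'
#' A montage binds source and detector positions (mm) to measurement
#' channels. Channel labels follow 10-5 naming where available; the default
#' builder uses synthetic labels.
#'
#' @param optodes data.frame with columns \code{optode_id}, \code{kind}
#'   (\code{"S"} or \code{"D"}), \code{x_mm}, \code{y_mm}, \code{z_mm}.
#' @param channels data.frame with columns \code{channel} (unique label),
#'   \code{source}, \code{detector} (optode ids).
#' @return object of class \code{nirs_montage}.
#' @export
montage <- function(optodes, channels) {
  stopifnot(is.data.frame(optodes), is.data.frame(channels))
  need_o <- c("optode_id", "kind", "x_mm", "y_mm", "z_mm")
  need_c <- c("channel", "source", "detector")
  if (!all(need_o %in% names(optodes))) stop("optodes must have columns: ", paste(need_o, collapse = ", "))
  if (!all(need_c %in% names(channels))) stop("channels must have columns: ", paste(need_c, collapse = ", "))
  if (anyDuplicated(channels$channel)) stop("channel labels must be unique")
  if (anyDuplicated(optodes$optode_id)) stop("optode ids must be unique")
  if (!all(optodes$kind %in% c("S", "D"))) stop("optode kind must be 'S' or 'D'")
  src <- optodes$optode_id[optodes$kind == "S"]
  det <- optodes$optode_id[optodes$kind == "D"]
  if (!all(channels$source %in% src)) {
    bad <- setdiff(channels$source, src)
    stop("channel references missing source optode(s): ", paste(bad, collapse = ", "))
  }
  if (!all(channels$detector %in% det)) {
    bad <- setdiff(channels$detector, det)
    stop("channel references missing detector optode(s): ", paste(bad, collapse = ", "))
  }
  m <- structure(list(optodes = optodes, channels = channels), class = "nirs_montage")
  d <- channel_distances(m)
  if (any(!is.finite(d)) || any(d <= 0)) stop("source-detector distances must be strictly positive")
  m
}

optode_position <- function(m, id) {
  i <- match(id, m$optodes$optode_id)
  cbind(m$optodes$x_mm[i], m$optodes$y_mm[i], m$optodes$z_mm[i])
}

#' Source-detector distances (mm) per channel
#' @param m a \code{nirs_montage}
#' @return named numeric vector, one entry per channel
#' @export
channel_distances <- function(m) {
  ps <- optode_position(m, m$channels$source)
  pd <- optode_position(m, m$channels$detector)
  d <- sqrt(rowSums((ps - pd)^2))
  names(d) <- m$channels$channel
  d
}

#' Channel midpoints (mm), used to position channels over the cortex
#' @param m a \code{nirs_montage}
#' @return matrix n_channel x 3
#' @export
channel_positions <- function(m) {
  ps <- optode_position(m, m$channels$source)
  pd <- optode_position(m, m$channels$detector)
  (ps + pd) / 2
}

#' Validate a montage and report source-detector separations
#'
#' Separations outside the nominal 25--40 mm operating range are flagged
#' with a warning but never removed.
#'
#' @param m a \code{nirs_montage}
#' @param range_mm acceptable separation range, default \code{c(25, 40)}
#' @return data.frame (channel, distance_mm, flagged)
#' @export
validate_montage <- function(m, range_mm = c(25, 40)) {
  if (!inherits(m, "nirs_montage")) stop("not a nirs_montage")
  d <- channel_distances(m)
  flagged <- d < range_mm[1] | d > range_mm[2]
  if (any(flagged)) {
    warning("channel(s) outside [", range_mm[1], ", ", range_mm[2], "] mm separation: ",
            paste(names(d)[flagged], collapse = ", "))
  }
  data.frame(channel = names(d), distance_mm = unname(d), flagged = unname(flagged),
             stringsAsFactors = FALSE)
}

#' Default peri-rolandic style montage over a patch mesh
#'
#' Lays out an alternating grid of sources and detectors above the centre of
#' a mesh, connecting horizontally and vertically adjacent source-detector
#' pairs. With the default 4 x 4 optode grid at 28 mm pitch this yields
#' 8 sources, 8 detectors and 24 channels at 28 mm separation, a stand-in
#' for the study's 21-channel, 8-source/8-detector array (separations
#' 25--40 mm).
#'
#' @param mesh a \code{cortical_mesh}; optodes are placed on a plane 8 mm
#'   above the mesh surface centre
#' @param nx,ny optode grid dimensions
#' @param pitch_mm optode spacing
#' @return a \code{nirs_montage}
#' @export
default_montage <- function(mesh, nx = 4, ny = 4, pitch_mm = 28) {
  ctr <- colMeans(mesh$nodes)
  ztop <- max(mesh$nodes[, 3]) + 8
  xs <- (seq_len(nx) - (nx + 1) / 2) * pitch_mm + ctr[1]
  ys <- (seq_len(ny) - (ny + 1) / 2) * pitch_mm + ctr[2]
  grid <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  # checkerboard: sources on even parity, detectors on odd
  kind <- ifelse((grid$ix + grid$iy) %% 2 == 0, "S", "D")
  ids <- character(nrow(grid))
  ids[kind == "S"] <- paste0("S", seq_len(sum(kind == "S")))
  ids[kind == "D"] <- paste0("D", seq_len(sum(kind == "D")))
  optodes <- data.frame(optode_id = ids, kind = kind,
                        x_mm = xs[grid$ix], y_mm = ys[grid$iy], z_mm = ztop,
                        stringsAsFactors = FALSE)
  # channels: horizontally/vertically adjacent optode pairs (always S-D by parity)
  ch <- list()
  idx <- function(ix, iy) (iy - 1) * nx + ix
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    for (nb in list(c(ix + 1, iy), c(ix, iy + 1))) {
      if (nb[1] > nx || nb[2] > ny) next
      a <- idx(ix, iy); b <- idx(nb[1], nb[2])
      s <- if (kind[a] == "S") a else b
      d <- if (kind[a] == "S") b else a
      ch[[length(ch) + 1]] <- data.frame(source = ids[s], detector = ids[d],
                                         stringsAsFactors = FALSE)
    }
  }
  ch <- do.call(rbind, ch)
  ch$channel <- paste0("CH", seq_len(nrow(ch)))
  montage(optodes, ch[, c("channel", "source", "detector")])
}
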