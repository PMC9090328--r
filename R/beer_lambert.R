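#' Haemoglobin extinction coefficients
#'
#' Base-10 molar extinction coefficients (cm^-1 M^-1) for oxy- and
#' deoxy-haemoglobin at 780 and 850 nm, from the Prahl/OMLC compilation of
#' haemoglobin spectra. Rows are wavelengths (780, 850), columns are
#' chromophores (HbO, Hb). Any table with the same shape can be passed to
#' \code{\link{beer_lambert}} to swap compilations.
#'
#' @export
extinction_default <- function() {
  matrix(c(710.00, 1075.44,
           1058.00, 691.32),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("780", "850"), c("HbO", "Hb")))
}

# natural-log extinction in cm^-1 per uM
.ext_natural_uM <- function(ext10) ext10 * log(10) * 1e-6

#' Modified Beer-Lambert conversion: optical density to concentration
#'
#' Per channel, solves the 2x2 linear system
#' \deqn{\Delta OD(\lambda) = d \cdot DPF \cdot \sum_c \epsilon(\lambda, c)\, \Delta c}
#' for \eqn{\Delta c = (\Delta[HbO], \Delta[Hb])}, with \eqn{d} the
#' source-detector distance in cm, the differential pathlength factor
#' \eqn{DPF = 4.39} by default, and \eqn{\epsilon} the (natural-log)
#' extinction coefficients. Concentrations come out in micromolar.
#'
#' @param od a \code{nirs_od} series (see \code{\link{to_optical_density}})
#' @param montage the recording's \code{nirs_montage} (for distances)
#' @param dpf differential pathlength factor
#' @param extinction base-10 molar extinction table, see
#'   \code{\link{extinction_default}}
#' @return object of class \code{nirs_haemo}: list with \code{values}
#'   (channel x chromophore(HbO, Hb) x time, uM) and \code{fs}
#' @export
beer_lambert <- function(od, montage, dpf = 4.39, extinction = extinction_default()) {
  E <- .ext_natural_uM(extinction)            # 2x2, rows wavelength, cols chromophore
  if (abs(det(E)) < 1e-18) stop("extinction matrix is singular")
  Einv <- solve(E)
  d_cm <- channel_distances(montage) / 10
  v <- od$values
  nch <- dim(v)[1]; nt <- dim(v)[3]
  if (nch != length(d_cm)) stop("channel count mismatch between OD series and montage")
  out <- array(0, c(nch, 2, nt),
               dimnames = list(dimnames(v)[[1]], c("HbO", "Hb"), NULL))
  for (ch in seq_len(nch)) {
    out[ch, , ] <- (Einv %*% v[ch, , ]) / (d_cm[ch] * dpf)
  }
  structure(list(values = out, fs = od$fs, channels = dimnames(v)[[1]],
                 stages = c(od$stages, "beer_lambert")),
            class = "nirs_haemo")
}

#' Forward modified Beer-Lambert: concentration to optical density
#'
#' Exact inverse of \code{\link{beer_lambert}}; used by the synthetic-data
#' generator so that preprocessing recovers the injected concentrations.
#'
#' @param haemo channel x chromophore(HbO, Hb) x time array in uM
#' @inheritParams beer_lambert
#' @return channel x wavelength(780, 850) x time array of OD values
#' @export
beer_lambert_forward <- function(haemo, montage, dpf = 4.39,
                                 extinction = extinction_default()) {
  E <- .ext_natural_uM(extinction)
  d_cm <- channel_distances(montage) / 10
  nch <- dim(haemo)[1]; nt <- dim(haemo)[3]
  out <- array(0, c(nch, 2, nt))
  for (ch in seq_len(nch)) {
    out[ch, , ] <- (E %*% haemo[ch, , ]) * (d_cm[ch] * dpf)
  }
  out
}
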