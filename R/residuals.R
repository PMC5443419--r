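#' Back-project a concentration image to channel attenuation
#'
#' Applies the multispectral operator to a reconstructed image, predicting
#' the channel x wavelength attenuation changes it explains. Linear in the
#' image.
#'
#' @param image A `concentration_image`.
#' @param system A `multispectral_system` with the same chromophore set.
#' @return Matrix (channels x wavelengths), OD, with wavelength colnames.
#' @export
back_project <- function(image, system) {
  stopifnot(inherits(image, "concentration_image"),
            inherits(system, "multispectral_system"))
  if (!identical(unname(image$chromophores), unname(system$chromophores)))
    stop("chromophore sets differ between image and system")
  pred <- ms_apply(system, image$data)
  matrix(pred, system$n_channels,
         dimnames = list(NULL, as.character(system$wavelengths)))
}

#' Two- vs three-chromophore residual-difference spectra
#'
#' For one measured frame reconstructed with both the three-chromophore
#' (HbO2, HHb, oxCCO) and the two-chromophore (hemoglobin-only) model,
#' computes per channel the residual spectra `r_k = dA - prediction_k` and
#' returns their difference `r2 - r3`: the spectral structure the
#' two-chromophore model fails to explain. If a genuine oxCCO change is in
#' the data, this difference takes the shape of the oxCCO extinction
#' spectrum in channels sampling the activation; far from it the difference
#' is close to nil. Residuals are computed in reconstruction voxel space,
#' before any surface mapping.
#'
#' @param dA_measured Measured attenuation frame (channels x wavelengths),
#'   OD.
#' @param image3,image2 `concentration_image`s from the 3- and 2-chromophore
#'   reconstructions of that same frame.
#' @param system3,system2 The matching `multispectral_system`s.
#' @param time_s Time label of the frame, s (default 20, the expected
#'   activation peak); both images must carry the same label if labelled.
#' @return A `residual_spectra` object: list with `diff` (channels x
#'   wavelengths), `r2`, `r3`, `wavelengths`, `time_s`.
#' @export
residual_difference <- function(dA_measured, image3, image2, system3,
                                system2, time_s = 20) {
  dA_measured <- matrix(as.numeric(dA_measured), system3$n_channels)
  if (!isTRUE(all.equal(system3$wavelengths, system2$wavelengths)))
    stop("the two systems use different wavelength grids")
  t3 <- image3$time_s; t2 <- image2$time_s
  if (!is.na(t3) && !is.na(t2) && t3 != t2)
    stop("images are from different frames (", t3, " s vs ", t2, " s)")
  r3 <- dA_measured - back_project(image3, system3)
  r2 <- dA_measured - back_project(image2, system2)
  structure(list(diff = r2 - r3, r2 = r2, r3 = r3,
                 wavelengths = system3$wavelengths, time_s = time_s),
            class = "residual_spectra")
}

#' @export
print.residual_spectra <- function(x, ...) {
  cat("<residual_spectra> ", nrow(x$diff), " channels x ",
      length(x$wavelengths), " wavelengths at t = ", x$time_s, " s\n",
      sep = "")
  invisible(x)
}

#' Tidy residual-difference spectra
#'
#' @param x A `residual_spectra`.
#' @return Tibble with channel, wavelength_nm, r2, r3, diff columns.
#' @export
tidy_residuals <- function(x) {
  stopifnot(inherits(x, "residual_spectra"))
  nch <- nrow(x$diff)
  tibble::tibble(
    channel = rep(seq_len(nch), times = length(x$wavelengths)),
    wavelength_nm = rep(x$wavelengths, each = nch),
    r2 = as.vector(x$r2), r3 = as.vector(x$r3), diff = as.vector(x$diff)
  )
}

#' Compare a residual-difference spectrum with a reference spectrum
#'
#' Quantifies how closely a per-channel residual-difference spectrum follows
#' a reference chromophore extinction spectrum: Pearson correlation across
#' wavelengths, plus the wavelength at which a 3-point moving average of the
#' difference spectrum peaks.
#'
#' @param spectrum Numeric vector over wavelengths (one channel's difference
#'   spectrum).
#' @param reference Numeric reference spectrum on the same wavelength grid.
#' @param wavelengths Wavelength axis, nm.
#' @return List with `correlation` and `peak_wavelength_nm`.
#' @export
spectrum_similarity <- function(spectrum, reference, wavelengths) {
  stopifnot(length(spectrum) == length(reference),
            length(spectrum) == length(wavelengths))
  if (stats::sd(spectrum) == 0 || stats::sd(reference) == 0)
    stop("correlation undefined for a constant spectrum")
  sm <- stats::filter(spectrum, rep(1 / 3, 3), sides = 2)
  sm[1] <- spectrum[1]; sm[length(sm)] <- spectrum[length(spectrum)]
  list(correlation = stats::cor(spectrum, reference),
       peak_wavelength_nm = wavelengths[which.max(sm)])
}
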