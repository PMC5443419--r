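#' Channel-wise modified Beer-Lambert (UCLn) spectroscopy
#'
#' Recovers chromophore concentration-change time courses per channel from
#' multi-wavelength attenuation changes by least squares over wavelengths,
#' the UCLn flavour of the modified Beer-Lambert law: for each channel and
#' time point,
#'
#'   dA(lambda) = E(lambda, .) %*% dC * d * DPF(lambda)
#'
#' is solved for `dC` via the Moore-Penrose pseudoinverse of the DPF-scaled
#' extinction matrix, i.e. `dC = pinv(E) %*% (dA / (d * DPF))`. Wavelengths
#' are weighted uniformly. Works for either the three-chromophore set
#' (HbO2, HHb, oxCCO) or the two-chromophore hemoglobin-only set.
#'
#' @param dA An `attenuation_series` (OD units).
#' @param E Extinction matrix from [extinction_matrix()], wavelengths x
#'   chromophores, uM^-1 mm^-1; its rows must match `dA$wavelengths_nm`.
#' @param distances Per-channel source-detector distance, mm (recycled if
#'   scalar).
#' @param dpf A `dpf_model` (default: packaged adult-head table).
#' @return A `channel_concentration_series`: list with `data` (array channel
#'   x chromophore x time, uM), `chromophores`, `channel_ids`, `sample_rate`.
#' @export
ucln_fit <- function(dA, E, distances, dpf = load_dpf()) {
  stopifnot(inherits(dA, "attenuation_series"), is.matrix(E))
  nwl <- length(dA$wavelengths_nm)
  if (nrow(E) != nwl)
    stop("extinction matrix has ", nrow(E), " wavelength rows but the ",
         "attenuation series has ", nwl)
  if (nwl < ncol(E))
    stop("need at least as many wavelengths (", nwl, ") as chromophores (",
         ncol(E), ")")
  nch <- dim(dA$data)[1]
  distances <- rep_len(distances, nch)
  if (any(distances <= 0)) stop("source-detector distances must be positive")
  dpf_wl <- dpf_at(dA$wavelengths_nm, dpf)

  Es <- E * dpf_wl  # row-scaled: pathlength-weighted extinction
  sv <- svd(Es)
  if (min(sv$d) < max(sv$d) * 1e-10)
    stop("extinction matrix is rank deficient (condition ",
         format(max(sv$d) / max(min(sv$d), .Machine$double.xmin), digits = 3),
         "); check for duplicated chromophores")
  pinv <- sv$v %*% (t(sv$u) / sv$d)

  nt <- dim(dA$data)[3]
  out <- array(0, c(nch, ncol(E), nt))
  for (c in seq_len(nch)) {
    # wavelengths x time slab for this channel, divided by distance
    slab <- matrix(dA$data[c, , ], nrow = nwl) / distances[c]
    out[c, , ] <- pinv %*% slab
  }
  chroms <- colnames(E)
  if (is.null(chroms)) chroms <- paste0("chrom", seq_len(ncol(E)))
  structure(list(data = out, chromophores = chroms,
                 channel_ids = dA$channel_ids, sample_rate = dA$sample_rate),
            class = "channel_concentration_series")
}

#' @export
print.channel_concentration_series <- function(x, ...) {
  d <- dim(x$data)
  cat("<channel_concentration_series> ", d[1], " channels x {",
      paste(x$chromophores, collapse = ", "), "} x ", d[3], " samples @ ",
      x$sample_rate, " Hz (uM)\n", sep = "")
  invisible(x)
}

#' Tidy channel concentrations into a long tibble
#'
#' @param x A `channel_concentration_series`.
#' @return Tibble with columns channel, chromophore, time_s, delta_conc_uM.
#' @export
tidy_concentrations <- function(x) {
  stopifnot(inherits(x, "channel_concentration_series"))
  d <- dim(x$data)
  tibble::tibble(
    channel = rep(x$channel_ids, times = d[2] * d[3]),
    chromophore = rep(rep(x$chromophores, each = d[1]), times = d[3]),
    time_s = rep((seq_len(d[3]) - 1) / x$sample_rate, each = d[1] * d[2]),
    delta_conc_uM = as.vector(x$data)
  )
}

#' Write channel concentrations to CSV
#'
#' @param x A `channel_concentration_series`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_concentrations_csv <- function(x, path) {
  utils::write.csv(tidy_concentrations(x), path, row.names = FALSE)
  invisible(path)
}
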