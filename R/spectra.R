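#' Chromophore extinction spectra and DPF models
#'
#' The package ships near-infrared specific-absorption spectra for the three
#' chromophores used in broadband NIRS/DOT: oxy-hemoglobin (`"HbO2"`),
#' deoxy-hemoglobin (`"HHb"`), and oxidized cytochrome c oxidase (`"oxCCO"`).
#' The oxCCO spectrum is the *oxidized-minus-reduced difference* spectrum --
#' the quantity that multiplies a change in CCO redox state -- stored as a
#' non-negative magnitude. The packaged tables are smooth synthetic stand-ins
#' anchored to published literature values (see the file headers under
#' `inst/extdata/`); all forward/inverse computations in the package use the
#' same table, so self-consistency, not the exact digitization, is what
#' matters for correctness.
#'
#' Tabulated values are stored in mM^-1 cm^-1 and converted on load to the
#' package's canonical units, uM^-1 mm^-1 (multiply by 1e-4).
#'
#' @name spectra
NULL

.CHROMOPHORES <- c(HbO2 = "extinction_hbo2_synthetic.csv",
                   HHb = "extinction_hhb_synthetic.csv",
                   oxCCO = "extinction_oxcco_diff_synthetic.csv")

.read_spectrum_csv <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#")
  names(tab) <- c("wavelength_nm", "value")
  if (is.unsorted(tab$wavelength_nm, strictly = TRUE))
    stop("spectrum wavelengths must be strictly increasing: ", path)
  tab
}

#' Load a chromophore extinction spectrum
#'
#' @param chromophore One of `"HbO2"`, `"HHb"`, `"oxCCO"`, or a path to a
#'   two-column CSV (`wavelength_nm,value`, `#`-comment header) holding a
#'   spectrum in mM^-1 cm^-1.
#' @return An object of class `chromophore_spectrum`: list with `chromophore`,
#'   `wavelengths_nm`, and `epsilon` in uM^-1 mm^-1.
#' @export
load_extinction <- function(chromophore) {
  if (chromophore %in% names(.CHROMOPHORES)) {
    path <- system.file("extdata", .CHROMOPHORES[[chromophore]],
                        package = "ccodot", mustWork = TRUE)
    name <- chromophore
  } else if (file.exists(chromophore)) {
    path <- chromophore
    name <- sub("\\.csv$", "", basename(chromophore))
  } else {
    stop("unknown chromophore '", chromophore, "'; expected one of ",
         paste(names(.CHROMOPHORES), collapse = ", "), " or a CSV path")
  }
  tab <- .read_spectrum_csv(path)
  eps <- tab$value * 1e-4  # mM^-1 cm^-1 -> uM^-1 mm^-1
  if (any(!is.finite(eps)) || any(eps < 0))
    stop("extinction values must be finite and non-negative: ", path)
  if (min(tab$wavelength_nm) > 740 || max(tab$wavelength_nm) < 900)
    stop("spectrum must cover at least 740-900 nm: ", path)
  structure(list(chromophore = name,
                 wavelengths_nm = tab$wavelength_nm,
                 epsilon = eps),
            class = "chromophore_spectrum")
}

#' @export
print.chromophore_spectrum <- function(x, ...) {
  cat("<chromophore_spectrum> ", x$chromophore, ": ",
      min(x$wavelengths_nm), "-", max(x$wavelengths_nm), " nm, ",
      length(x$epsilon), " knots (uM^-1 mm^-1)\n", sep = "")
  invisible(x)
}

.interp_spectrum <- function(wl_tab, val_tab, wavelengths, what) {
  out_lo <- wavelengths < min(wl_tab) - 1e-9
  out_hi <- wavelengths > max(wl_tab) + 1e-9
  if (any(out_lo | out_hi)) {
    bad <- wavelengths[out_lo | out_hi][1]
    stop("wavelength ", bad, " nm outside the tabulated range [",
         min(wl_tab), ", ", max(wl_tab), "] nm for ", what)
  }
  stats::approx(wl_tab, val_tab, xout = wavelengths, rule = 1)$y
}

#' Extinction-coefficient matrix
#'
#' Builds the wavelength-by-chromophore matrix of specific absorption
#' coefficients used both by the modified Beer-Lambert fit and by the
#' multispectral Jacobian assembly. Entries are linearly interpolated from the
#' tabulated spectra; column order follows the request order.
#'
#' @param chromophores Character vector of chromophore identifiers, or a list
#'   of `chromophore_spectrum` objects.
#' @param wavelengths Numeric vector of wavelengths, nm.
#' @return Matrix (length(wavelengths) x length(chromophores)) in
#'   uM^-1 mm^-1, with dimnames.
#' @export
extinction_matrix <- function(chromophores, wavelengths) {
  stopifnot(length(wavelengths) >= 1, all(is.finite(wavelengths)))
  specs <- lapply(chromophores, function(ch) {
    if (inherits(ch, "chromophore_spectrum")) ch else load_extinction(ch)
  })
  E <- vapply(specs, function(sp) {
    .interp_spectrum(sp$wavelengths_nm, sp$epsilon, wavelengths,
                     sp$chromophore)
  }, numeric(length(wavelengths)))
  E <- matrix(E, nrow = length(wavelengths),
              dimnames = list(wavelength = as.character(wavelengths),
                              chromophore = vapply(specs, `[[`, "",
                                                   "chromophore")))
  E
}

#' Differential pathlength factor models
#'
#' `load_dpf()` reads the packaged adult-head DPF wavelength-dependence table
#' (a synthetic smooth stand-in; see the file header) or a user CSV.
#' `dpf_constant()` builds a flat model; with a constant DPF all channel-space
#' concentrations are scaled by a single factor, which preserves relative time
#' courses but not absolute scale -- a warning is attached to the model.
#'
#' @param path Optional path to a two-column CSV (`wavelength_nm,value`).
#' @return A `dpf_model`: list with `wavelengths_nm`, `dpf`.
#' @export
load_dpf <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "dpf_adult_head_synthetic.csv",
                        package = "ccodot", mustWork = TRUE)
  tab <- .read_spectrum_csv(path)
  if (any(tab$value <= 0)) stop("DPF values must be positive: ", path)
  structure(list(wavelengths_nm = tab$wavelength_nm, dpf = tab$value),
            class = "dpf_model")
}

#' @rdname load_dpf
#' @param value Constant DPF value (default 6.0).
#' @param range Wavelength range, nm, over which the constant model is defined.
#' @export
dpf_constant <- function(value = 6.0, range = c(650, 1000)) {
  stopifnot(value > 0, length(range) == 2, range[1] < range[2])
  warning("constant DPF: channel-space concentrations are uniformly scaled; ",
          "relative time courses are unaffected", call. = FALSE)
  structure(list(wavelengths_nm = range, dpf = rep(value, 2)),
            class = "dpf_model")
}

#' Evaluate a DPF model at given wavelengths
#'
#' @param wavelengths Numeric vector, nm.
#' @param model A `dpf_model` (default: packaged adult-head table).
#' @return Numeric vector of DPF values (> 0).
#' @export
dpf_at <- function(wavelengths, model = load_dpf()) {
  stopifnot(inherits(model, "dpf_model"))
  .interp_spectrum(model$wavelengths_nm, model$dpf, wavelengths, "DPF model")
}
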