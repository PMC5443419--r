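#' Channel time-series containers
#'
#' Raw broadband acquisitions are held as `intensity_series` and converted
#' attenuation data as `attenuation_series`. Both wrap a 3-D array with
#' dimensions channel x wavelength x time plus axis metadata; attenuation is
#' in log10 (optical density, OD) units.
#'
#' @param data Numeric array, channel x wavelength x time.
#' @param wavelengths_nm Wavelength axis, nm.
#' @param sample_rate Sampling rate, Hz.
#' @param channel_ids Optional channel labels (default `ch1..chN`).
#' @return An `intensity_series` / `attenuation_series` object.
#' @name timeseries
NULL

.check_series_dims <- function(data, wavelengths_nm, channel_ids) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (dim(data)[2] != length(wavelengths_nm))
    stop("wavelength axis length ", length(wavelengths_nm),
         " does not match data dim 2 (", dim(data)[2], ")")
  if (!is.null(channel_ids) && length(channel_ids) != dim(data)[1])
    stop("channel_ids length does not match data dim 1")
}

#' @rdname timeseries
#' @export
intensity_series <- function(data, wavelengths_nm, sample_rate = 1,
                             channel_ids = NULL) {
  .check_series_dims(data, wavelengths_nm, channel_ids)
  if (any(data <= 0)) {
    idx <- which(data <= 0, arr.ind = TRUE)[1, ]
    stop("intensities must be strictly positive; first violation at channel ",
         idx[1], ", wavelength index ", idx[2], ", time index ", idx[3])
  }
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(dim(data)[1]))
  structure(list(data = data, wavelengths_nm = wavelengths_nm,
                 sample_rate = sample_rate, channel_ids = channel_ids),
            class = "intensity_series")
}

#' @rdname timeseries
#' @param reference_intensity The reference intensity I0 the attenuation is
#'   relative to (bookkeeping only).
#' @export
attenuation_series <- function(data, wavelengths_nm, sample_rate = 1,
                               channel_ids = NULL, reference_intensity = NA) {
  .check_series_dims(data, wavelengths_nm, channel_ids)
  if (any(!is.finite(data))) stop("attenuation values must be finite")
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(dim(data)[1]))
  structure(list(data = data, wavelengths_nm = wavelengths_nm,
                 sample_rate = sample_rate, channel_ids = channel_ids,
                 reference_intensity = reference_intensity),
            class = "attenuation_series")
}

#' @export
print.attenuation_series <- function(x, ...) {
  d <- dim(x$data)
  cat("<attenuation_series> ", d[1], " channels x ", d[2], " wavelengths (",
      min(x$wavelengths_nm), "-", max(x$wavelengths_nm), " nm) x ", d[3],
      " samples @ ", x$sample_rate, " Hz\n", sep = "")
  invisible(x)
}

#' @export
print.intensity_series <- function(x, ...) {
  d <- dim(x$data)
  cat("<intensity_series> ", d[1], " channels x ", d[2], " wavelengths x ",
      d[3], " samples @ ", x$sample_rate, " Hz\n", sep = "")
  invisible(x)
}

#' Stimulation paradigm
#'
#' Describes a block paradigm: `n_epochs` repetitions of `stim_duration_s`
#' of stimulation followed by `rest_duration_s` of rest. Defaults follow a
#' 20 s on / 20 s off visual block design with 10 epochs (400 s total).
#'
#' @param onsets_s Stimulus onset times, s. Default: back-to-back epochs
#'   starting at 0.
#' @param stim_duration_s Stimulation duration, s.
#' @param rest_duration_s Rest duration, s.
#' @param n_epochs Number of epochs.
#' @return A `paradigm` object.
#' @export
paradigm <- function(onsets_s = NULL, stim_duration_s = 20,
                     rest_duration_s = 20, n_epochs = 10) {
  epoch_len <- stim_duration_s + rest_duration_s
  if (is.null(onsets_s)) onsets_s <- epoch_len * (seq_len(n_epochs) - 1)
  stopifnot(length(onsets_s) == n_epochs)
  if (n_epochs > 1 && any(diff(sort(onsets_s)) < epoch_len - 1e-9))
    stop("epoch windows overlap")
  structure(list(onsets_s = onsets_s, stim_duration_s = stim_duration_s,
                 rest_duration_s = rest_duration_s, n_epochs = n_epochs),
            class = "paradigm")
}

#' Convert intensities to attenuation changes
#'
#' Attenuation at each channel, wavelength and time point is
#' `A = log10(I0 / I)` with `I0` an arbitrary reference intensity
#' (default 1e5). Changes in `A` over time are independent of `I0`.
#'
#' @param I An `intensity_series`.
#' @param I0 Reference intensity (> 0), default `1e5`.
#' @return An `attenuation_series`.
#' @export
intensity_to_attenuation <- function(I, I0 = 1e5) {
  stopifnot(inherits(I, "intensity_series"), I0 > 0)
  attenuation_series(log10(I0 / I$data), I$wavelengths_nm, I$sample_rate,
                     I$channel_ids, reference_intensity = I0)
}

#' Recover intensities from an attenuation series
#'
#' Inverse of [intensity_to_attenuation()]: `I = I0 * 10^(-A)`.
#'
#' @param A An `attenuation_series` with a recorded reference intensity.
#' @param I0 Reference intensity; defaults to the recorded one.
#' @return An `intensity_series`.
#' @export
attenuation_to_intensity <- function(A, I0 = A$reference_intensity) {
  stopifnot(inherits(A, "attenuation_series"), is.finite(I0), I0 > 0)
  intensity_series(I0 * 10^(-A$data), A$wavelengths_nm, A$sample_rate,
                   A$channel_ids)
}

#' Band-pass filter an attenuation series
#'
#' Applies a Butterworth band-pass (default fifth order, 0.01--0.25 Hz) to
#' every channel/wavelength trace. Filtering is zero-phase
#' (forward--backward), so block-averaged hemodynamics are not phase shifted;
#' set `zero_phase = FALSE` for a causal single pass. Each trace is demeaned
#' before filtering to suppress the start-up transient; the pass band
#' excludes DC, so the output mean is ~0 per trace.
#'
#' @param series An `attenuation_series`.
#' @param low_hz,high_hz Band edges, Hz.
#' @param order Butterworth order (per band edge).
#' @param zero_phase Forward-backward filtering (default TRUE).
#' @return A filtered `attenuation_series`.
#' @export
bandpass <- function(series, low_hz = 0.01, high_hz = 0.25, order = 5,
                     zero_phase = TRUE) {
  stopifnot(inherits(series, "attenuation_series"))
  fs <- series$sample_rate
  if (!(0 < low_hz && low_hz < high_hz && high_hz < fs / 2))
    stop("band [", low_hz, ", ", high_hz, "] Hz invalid for sample rate ",
         fs, " Hz (need 0 < low < high < Nyquist)")
  nt <- dim(series$data)[3]
  min_len <- 3 * (2 * order + 1)  # forward-backward warm-up headroom
  if (nt < min_len)
    stop("series too short to filter: ", nt, " samples < required ", min_len)
  filt <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  out <- series$data
  nc <- dim(out)[1]; nw <- dim(out)[2]
  for (c in seq_len(nc)) {
    for (w in seq_len(nw)) {
      x <- out[c, w, ]
      x <- x - mean(x)
      out[c, w, ] <- if (zero_phase) signal::filtfilt(filt, x)
                     else signal::filter(filt, x)
    }
  }
  attenuation_series(out, series$wavelengths_nm, fs, series$channel_ids,
                     series$reference_intensity)
}

#' Block-average an attenuation series over stimulation epochs
#'
#' Cuts the recording into one window of `epoch_len_s` per stimulus onset,
#' re-zeroes each window by subtracting its own value at onset (so the output
#' is the mean change relative to stimulus onset; switch off with
#' `rezero = FALSE`), and averages across epochs.
#'
#' @param series An `attenuation_series`.
#' @param paradigm A [paradigm()].
#' @param epoch_len_s Window length, s (default 40).
#' @param rezero Subtract the onset sample per epoch before averaging.
#' @return An `attenuation_series` with `epoch_len_s * sample_rate` samples.
#' @export
block_average <- function(series, paradigm, epoch_len_s = 40, rezero = TRUE) {
  stopifnot(inherits(series, "attenuation_series"),
            inherits(paradigm, "paradigm"))
  fs <- series$sample_rate
  nt <- dim(series$data)[3]
  len <- as.integer(round(epoch_len_s * fs))
  starts <- as.integer(round(paradigm$onsets_s * fs)) + 1L
  if (any(starts < 1L) || any(starts + len - 1L > nt))
    stop("epoch window extends past the recording (",
         nt, " samples at ", fs, " Hz)")
  d <- dim(series$data)
  acc <- array(0, c(d[1], d[2], len))
  for (s in starts) {
    ep <- series$data[, , s:(s + len - 1L), drop = FALSE]
    if (rezero) ep <- sweep(ep, c(1, 2), series$data[, , s])
    acc <- acc + ep
  }
  attenuation_series(acc / length(starts), series$wavelengths_nm, fs,
                     series$channel_ids, series$reference_intensity)
}

#' Subsample the wavelength axis to a reconstruction grid
#'
#' Reduces a broadband wavelength axis to a discrete grid (default 740 to
#' 900 nm in 10-nm steps, 17 wavelengths) by taking, for each grid point, the
#' measured sample nearest in wavelength (ties resolved toward the lower
#' wavelength). Nearest-sample selection rather than interpolation is used
#' because broadband spectrometer bins are dense relative to the grid.
#'
#' @param series An `attenuation_series`.
#' @param grid Target wavelengths, nm.
#' @return An `attenuation_series` on the grid wavelengths.
#' @export
select_wavelengths <- function(series, grid = seq(740, 900, by = 10)) {
  stopifnot(inherits(series, "attenuation_series"))
  wl <- series$wavelengths_nm
  if (any(grid < min(wl) - 1e-9) || any(grid > max(wl) + 1e-9))
    stop("grid wavelength outside measured range [", min(wl), ", ", max(wl),
         "] nm")
  idx <- vapply(grid, function(g) {
    d <- abs(wl - g)
    which(d <= min(d) + 1e-12)[1]  # tie -> lower wavelength
  }, integer(1))
  attenuation_series(series$data[, idx, , drop = FALSE], grid,
                     series$sample_rate, series$channel_ids,
                     series$reference_intensity)
}

#' Tidy a channel time-series into a long tibble
#'
#' @param x An `attenuation_series` or `intensity_series`.
#' @param ... Unused.
#' @return A tibble with columns channel, wavelength_nm, time_s, value.
#' @export
as_tibble_series <- function(x, ...) {
  d <- dim(x$data)
  tibble::tibble(
    channel = rep(x$channel_ids, times = d[2] * d[3]),
    wavelength_nm = rep(rep(x$wavelengths_nm, each = d[1]), times = d[3]),
    time_s = rep((seq_len(d[3]) - 1) / x$sample_rate, each = d[1] * d[2]),
    value = as.vector(x$data)
  )
}
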