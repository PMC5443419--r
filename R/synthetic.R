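#' Standard 32-channel optode array
#'
#' Builds the broadband imaging array used throughout the package: 4 sources
#' in a central row and 14 detector slots in two rows (7 above, 7 below),
#' with each source paired to its 8 nearest detectors, giving
#' 4 x 8 = 32 multidistance, overlapping channels. The array is laid out on
#' the z = 0 surface of the geometry, centred on the face unless a center is
#' given. Within-row pitch defaults to 15 mm and the detector rows sit
#' `row_offset` above/below the source row.
#'
#' @param geometry A `voxel_grid`; the array must fit on its z = 0 face.
#' @param pitch Within-row optode pitch, mm.
#' @param row_offset Distance from the source row to each detector row, mm.
#' @param center Optional (x, y) center of the array, mm.
#' @param channels_per_source Detectors paired to each source (default 8).
#' @param source_sigma Optode profile standard deviation, mm.
#' @return An `optode_array` with 32 channels under the defaults.
#' @export
make_array <- function(geometry, pitch = 15, row_offset = 15, center = NULL,
                       channels_per_source = 8, source_sigma = 2) {
  ext <- geometry$dims * geometry$spacing
  if (is.null(center)) center <- geometry$origin[1:2] + ext[1:2] / 2
  det_x <- center[1] + ((1:7) - 4) * pitch
  det <- rbind(cbind(det_x, center[2] - row_offset, 0),
               cbind(det_x, center[2] + row_offset, 0))
  src_x <- center[1] + ((1:4) - 2.5) * pitch
  src <- cbind(src_x, center[2], 0)
  colnames(src) <- colnames(det) <- c("x", "y", "z")

  pts <- rbind(src, det)
  lo <- geometry$origin; hi <- geometry$origin + ext
  if (any(pts[, 1] < lo[1]) || any(pts[, 1] > hi[1]) ||
      any(pts[, 2] < lo[2]) || any(pts[, 2] > hi[2]))
    stop("array footprint (", diff(range(pts[, 1])), " x ",
         diff(range(pts[, 2])), " mm) exceeds the domain face (",
         ext[1], " x ", ext[2], " mm)")

  channels <- do.call(rbind, lapply(1:4, function(s) {
    d <- sqrt(rowSums(sweep(det, 2, src[s, ])^2))
    nearest <- order(d)[seq_len(channels_per_source)]
    data.frame(source = s, detector = nearest)
  }))
  optode_array(src, det, channels, source_sigma = source_sigma)
}

#' Focal activation blob
#'
#' A spherical, smoothly tapered activation confined to brain tissue, with
#' per-chromophore peak amplitudes and a trapezoidal time course (linear
#' rise, plateau to stimulus end, linear fall). Defaults emulate a focal
#' functional activation: +1.0 uM HbO2, -0.3 uM HHb, +0.1 uM oxCCO -- the
#' oxCCO change an order of magnitude below hemoglobin.
#'
#' @param center Blob center, mm.
#' @param radius Blob radius, mm.
#' @param amplitudes Named peak amplitudes, uM.
#' @param rise_s,fall_s Temporal rise and fall times, s.
#' @return An `activation_blob`.
#' @export
activation_blob <- function(center, radius = 10,
                            amplitudes = c(HbO2 = 1.0, HHb = -0.3,
                                           oxCCO = 0.1),
                            rise_s = 5, fall_s = 10) {
  stopifnot(radius > 0, length(center) == 3, rise_s >= 0, fall_s >= 0)
  structure(list(center = center, radius = radius, amplitudes = amplitudes,
                 rise_s = rise_s, fall_s = fall_s),
            class = "activation_blob")
}

# Spatial map of the blob on a grid: raised-cosine taper inside the radius,
# restricted to brain-labelled voxels when the geometry carries labels.
.blob_map <- function(blob, geometry) {
  cc <- voxel_centers(geometry)
  r <- sqrt((cc[, 1] - blob$center[1])^2 + (cc[, 2] - blob$center[2])^2 +
            (cc[, 3] - blob$center[3])^2)
  w <- ifelse(r < blob$radius, cos(pi / 2 * r / blob$radius)^2, 0)
  if (!is.null(geometry$labels)) {
    inside <- brain_mask(geometry)
    if (!inside[which.min(r)])
      stop("blob center is not inside brain-labelled tissue")
    w[!inside] <- 0
  }
  w
}

# Trapezoidal temporal profile of one epoch, evaluated at times since onset.
.blob_profile <- function(blob, t, stim_duration_s) {
  p <- numeric(length(t))
  up <- t >= 0 & t < blob$rise_s
  p[up] <- t[up] / max(blob$rise_s, .Machine$double.eps)
  plateau <- t >= blob$rise_s & t <= stim_duration_s
  p[plateau] <- 1
  down <- t > stim_duration_s & t < stim_duration_s + blob$fall_s
  p[down] <- 1 - (t[down] - stim_duration_s) / blob$fall_s
  p
}

#' Measurement noise model
#'
#' Additive Gaussian noise on attenuation, OD units, optionally scaled per
#' wavelength; fully determined by its seed.
#'
#' @param sd Attenuation noise standard deviation, OD (default 5e-4).
#' @param wavelength_scale Optional per-wavelength multiplier on `sd`.
#' @param seed Integer seed.
#' @return A `noise_model`.
#' @export
noise_model <- function(sd = 5e-4, wavelength_scale = NULL, seed = 1L) {
  stopifnot(sd >= 0)
  structure(list(sd = sd, wavelength_scale = wavelength_scale,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Simulate a broadband DOT experiment with known ground truth
#'
#' Generates a full synthetic acquisition: 10 epochs of 20 s stimulation /
#' 20 s rest at 1 Hz sampling (configurable via `paradigm`), a focal
#' activation blob modulating all three chromophores, channel attenuation
#' changes computed through the wavelength Jacobians (linearized Rytov
#' forward model), seeded Gaussian attenuation noise, and conversion to
#' intensities about the modelled baseline `I0 * 10^(-A0)`. When
#' `simulation_geometry` is supplied (e.g. the same slab at twice the
#' resolution), the forward computation runs on that grid instead, so
#' reconstruction tests can avoid the matched-operator inverse crime.
#'
#' @param geometry A labelled `slab_geometry` (reconstruction grid).
#' @param optics A `tissue_optics` table.
#' @param array An `optode_array`.
#' @param blob An [activation_blob()].
#' @param paradigm A [paradigm()].
#' @param wavelengths Simulation wavelength grid, nm (default the 17-point
#'   reconstruction grid; use a denser grid to exercise
#'   [select_wavelengths()]).
#' @param noise A [noise_model()].
#' @param I0 Reference intensity.
#' @param sample_rate Sampling rate, Hz.
#' @param duration_s Recording length, s (default covers the paradigm).
#' @param simulation_geometry Optional finer `slab_geometry` for the forward
#'   computation (inverse-crime control).
#' @param bc Boundary condition for the forward model.
#' @param jacobians Optional precomputed list of `wavelength_jacobian`s on
#'   the simulation grid (one per wavelength, in order), to amortize forward
#'   solves across repeated simulations.
#' @return A `dot_simulation`: list with `intensity` (an
#'   `intensity_series`), `truth` (peak-amplitude `concentration_image` on
#'   the simulation grid), `truth_profile` (temporal profile, one value per
#'   sample), `attenuation_clean` (noise-free attenuation changes, channels
#'   x wavelengths x time), plus the inputs.
#' @export
simulate_experiment <- function(geometry, optics, array, blob, paradigm,
                                wavelengths = seq(740, 900, by = 10),
                                noise = noise_model(), I0 = 1e5,
                                sample_rate = 1, duration_s = NULL,
                                simulation_geometry = NULL, bc = "robin",
                                jacobians = NULL) {
  stopifnot(inherits(blob, "activation_blob"), inherits(noise, "noise_model"))
  chroms <- names(blob$amplitudes)
  E <- extinction_matrix(chroms, wavelengths)
  sim_geom <- if (is.null(simulation_geometry)) geometry
              else simulation_geometry
  if (is.null(duration_s))
    duration_s <- max(paradigm$onsets_s) + paradigm$stim_duration_s +
      paradigm$rest_duration_s

  map <- .blob_map(blob, sim_geom)                    # unit spatial profile
  truth <- concentration_image(outer(map, blob$amplitudes),
                               voxel_grid(sim_geom$dims, sim_geom$spacing,
                                          sim_geom$origin),
                               chroms)

  # channel x wavelength response to a unit temporal profile
  basis <- matrix(0, nrow(array$channels), length(wavelengths))
  amp0 <- matrix(0, nrow(array$channels), length(wavelengths))
  if (!is.null(jacobians) && length(jacobians) != length(wavelengths))
    stop("need one precomputed Jacobian per wavelength")
  for (l in seq_along(wavelengths)) {
    jac <- if (is.null(jacobians)) {
      compute_jacobian(sim_geom, optics, array, wavelengths[l], bc = bc)
    } else jacobians[[l]]
    dmua <- as.numeric(truth$data %*% E[l, ])          # uM * uM^-1 mm^-1
    basis[, l] <- as.numeric(jac$J %*% dmua)
    amp0[, l] <- jac$amplitude
  }

  t <- seq(0, duration_s - 1 / sample_rate, by = 1 / sample_rate)
  prof <- numeric(length(t))
  for (on in paradigm$onsets_s)
    prof <- prof + .blob_profile(blob, t - on, paradigm$stim_duration_s)

  nch <- nrow(array$channels); nwl <- length(wavelengths); nt <- length(t)
  dA_clean <- array(0, c(nch, nwl, nt))
  for (k in seq_len(nt)) dA_clean[, , k] <- basis * prof[k]

  dA <- dA_clean
  if (noise$sd > 0) {
    set.seed(noise$seed)
    sdw <- if (is.null(noise$wavelength_scale)) rep(1, nwl)
           else rep_len(noise$wavelength_scale, nwl)
    eps <- array(stats::rnorm(nch * nwl * nt), c(nch, nwl, nt))
    dA <- dA + sweep(eps, 2, noise$sd * sdw, `*`)
  }

  A0 <- -log10(amp0)                                  # baseline attenuation
  Atot <- sweep(dA, c(1, 2), A0, `+`)
  intensity <- intensity_series(I0 * 10^(-Atot), wavelengths, sample_rate)

  structure(list(intensity = intensity, truth = truth, truth_profile = prof,
                 attenuation_clean = dA_clean,
                 geometry = geometry, simulation_geometry = simulation_geometry,
                 optics = optics, array = array, blob = blob,
                 paradigm = paradigm, wavelengths = wavelengths,
                 noise = noise, I0 = I0),
            class = "dot_simulation")
}

#' @export
print.dot_simulation <- function(x, ...) {
  d <- dim(x$intensity$data)
  cat("<dot_simulation> ", d[1], " channels x ", d[2], " wavelengths x ",
      d[3], " s; blob at (", paste(x$blob$center, collapse = ", "),
      ") mm, r = ", x$blob$radius, " mm\n", sep = "")
  invisible(x)
}

#' Default desk-scale phantom
#'
#' Convenience constructor bundling the standard study conditions: a
#' 120 x 72 x 40 mm layered slab (6 mm scalp, 6 mm skull, 2 mm CSF, brain
#' below) at the requested spacing, the 32-channel array centred on its
#' surface, an extended cortical activation blob (15-mm radius, centred
#' under the array at the cortical surface, 16 mm deep -- emulating the
#' spatially extended response of visual cortex to a full-field
#' checkerboard), and the 20 s / 20 s x 10-epoch paradigm.
#'
#' @param spacing Voxel spacing, mm (default 2).
#' @param size_mm Domain extent, mm.
#' @return List with `geometry`, `optics`, `array`, `blob`, `paradigm`.
#' @export
phantom_default <- function(spacing = 2, size_mm = c(120, 72, 40)) {
  geometry <- slab_geometry(size_mm, spacing = spacing)
  array <- make_array(geometry)
  center <- c(geometry$origin[1:2] + size_mm[1:2] / 2, 16)
  list(geometry = geometry, optics = load_tissue_optics(),
       array = array,
       blob = activation_blob(center = center, radius = 15),
       paradigm = paradigm())
}
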