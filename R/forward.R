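#' Optode arrays
#'
#' An `optode_array` holds source and detector positions (mm) and the list of
#' source-detector pairs (channels) that define the measurements. Sources and
#' detectors are modelled on the domain boundary as Gaussian profiles with a
#' 2-mm standard deviation (truncated at 3 sigma and renormalized to unit
#' power); optode positions are snapped to the nearest boundary face.
#'
#' @param sources,detectors Numeric matrices (n x 3) of positions, mm.
#' @param channels Data frame with integer columns `source` and `detector`
#'   (1-based indices into the position matrices).
#' @param source_sigma Gaussian profile standard deviation, mm.
#' @return An `optode_array`.
#' @export
optode_array <- function(sources, detectors, channels, source_sigma = 2) {
  sources <- as.matrix(sources); detectors <- as.matrix(detectors)
  stopifnot(ncol(sources) == 3, ncol(detectors) == 3,
            all(c("source", "detector") %in% names(channels)))
  if (any(channels$source < 1) || any(channels$source > nrow(sources)) ||
      any(channels$detector < 1) || any(channels$detector > nrow(detectors)))
    stop("channel references an optode that does not exist")
  if (anyDuplicated(channels[, c("source", "detector")]))
    stop("duplicate channels in array")
  structure(list(sources = sources, detectors = detectors,
                 channels = as.data.frame(channels)[, c("source", "detector")],
                 source_sigma = source_sigma),
            class = "optode_array")
}

#' @export
print.optode_array <- function(x, ...) {
  cat("<optode_array> ", nrow(x$sources), " sources, ", nrow(x$detectors),
      " detectors, ", nrow(x$channels), " channels (profile sigma ",
      x$source_sigma, " mm)\n", sep = "")
  invisible(x)
}

#' Per-channel source-detector distances
#'
#' @param array An `optode_array`.
#' @return Numeric vector of Euclidean source-detector distances, mm.
#' @export
channel_distances <- function(array) {
  stopifnot(inherits(array, "optode_array"))
  s <- array$sources[array$channels$source, , drop = FALSE]
  d <- array$detectors[array$channels$detector, , drop = FALSE]
  sqrt(rowSums((s - d)^2))
}

# Internal-reflection parameter for the partial-current (Robin) boundary:
# effective reflection coefficient from the refractive-index mismatch.
.reflection_parameter <- function(n) {
  reff <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
  (1 + reff) / (1 - reff)
}

# Resolve per-voxel optical properties from a tissue table or explicit vectors
.voxel_optics <- function(geometry, props, wavelength) {
  n <- prod(geometry$dims)
  if (inherits(props, "tissue_optics")) {
    if (is.null(geometry$labels))
      stop("tissue_optics properties require a labelled geometry")
    tis <- optics_at(props, geometry$tissues, wavelength)
    lab <- as.vector(geometry$labels)
    list(mua = unname(tis$mua[lab]), musp = unname(tis$musp[lab]),
         n_refractive = props$n_refractive)
  } else {
    stopifnot(is.list(props), !is.null(props$mua), !is.null(props$musp))
    list(mua = rep_len(props$mua, n), musp = rep_len(props$musp, n),
         n_refractive = if (is.null(props$n_refractive)) 1.4
                        else props$n_refractive)
  }
}

#' Discretized continuous-wave diffusion operator
#'
#' Assembles and factorizes the 7-point finite-volume discretization of
#' `-div(kappa grad(Phi)) + mua Phi = q` with `kappa = 1/(3 (mua + musp))`
#' on a regular voxel grid. The default boundary condition is the
#' partial-current (Robin) condition with an internal-reflection parameter
#' derived from the refractive-index mismatch (default n = 1.4); a pure
#' Neumann (zero-flux) condition is available for comparison. The factorized
#' system is reused across right-hand sides (all sources and detectors of an
#' array share one factorization per wavelength).
#'
#' @param geometry A `voxel_grid` (labelled if `props` is a tissue table).
#' @param props A `tissue_optics` object, or a list with per-voxel (or
#'   scalar) `mua` and `musp`, mm^-1, and optionally `n_refractive`.
#' @param wavelength Wavelength, nm (used only to look up tissue properties).
#' @param bc `"robin"` (default) or `"neumann"`.
#' @return A `diffusion_system` with the sparse operator, its Cholesky
#'   factorization and the voxel-wise optical properties.
#' @export
diffusion_system <- function(geometry, props, wavelength = NA,
                             bc = c("robin", "neumann")) {
  bc <- match.arg(bc)
  vo <- .voxel_optics(geometry, props, wavelength)
  mua <- vo$mua; musp <- vo$musp
  if (any(mua < 0) || any(musp <= 0)) stop("require mua >= 0 and musp > 0")
  d <- geometry$dims; h <- geometry$spacing; n <- prod(d)
  kappa <- 1 / (3 * (mua + musp))
  idx <- array(seq_len(n), d)

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diag_acc <- mua * h^3
  for (ax in 1:3) {
    if (d[ax] < 2) next
    a <- switch(ax,
                as.vector(idx[-d[1], , , drop = FALSE]),
                as.vector(idx[, -d[2], , drop = FALSE]),
                as.vector(idx[, , -d[3], drop = FALSE]))
    b <- switch(ax,
                as.vector(idx[-1, , , drop = FALSE]),
                as.vector(idx[, -1, , drop = FALSE]),
                as.vector(idx[, , -1, drop = FALSE]))
    cpl <- h * 2 * kappa[a] * kappa[b] / (kappa[a] + kappa[b])
    ii <- c(ii, a, b); jj <- c(jj, b, a); xx <- c(xx, -cpl, -cpl)
    diag_acc[a] <- diag_acc[a] + cpl  # a, b each unique within one axis
    diag_acc[b] <- diag_acc[b] + cpl
  }
  if (bc == "robin") {
    A_refl <- .reflection_parameter(vo$n_refractive)
    for (ax in 1:3) {
      for (side in c(1L, d[ax])) {
        cells <- switch(ax,
                        as.vector(idx[side, , ]),
                        as.vector(idx[, side, ]),
                        as.vector(idx[, , side]))
        diag_acc[cells] <- diag_acc[cells] +
          h^2 / (2 * A_refl + h / (2 * kappa[cells]))
      }
    }
  }
  A <- Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
                            x = c(xx, diag_acc), dims = c(n, n))
  A <- Matrix::forceSymmetric(A, uplo = "L")
  fac <- tryCatch(Matrix::Cholesky(A, LDL = FALSE),
                  error = function(e) stop("diffusion system is singular or ",
                                           "not positive definite: ",
                                           conditionMessage(e)))
  structure(list(geometry = geometry, A = A, factor = fac, mua = mua,
                 musp = musp, kappa = kappa, bc = bc,
                 n_refractive = vo$n_refractive, wavelength = wavelength),
            class = "diffusion_system")
}

# Source vector (total power 1) for an optode: Gaussian boundary profile
# snapped to the nearest face, or a point source at an interior position.
.source_vector <- function(geometry, position, sigma = 2,
                           type = c("gaussian", "point")) {
  type <- match.arg(type)
  d <- geometry$dims; h <- geometry$spacing; o <- geometry$origin
  n <- prod(d)
  q <- numeric(n)
  if (type == "point") {
    ijk <- pmin(pmax(ceiling((position - o) / h), 1L), d)
    q[ijk[1] + (ijk[2] - 1) * d[1] + (ijk[3] - 1) * d[1] * d[2]] <- 1
    return(q)
  }
  # nearest of the six boundary planes
  lo <- position - o; hi <- o + d * h - position
  dists <- c(lo[1], hi[1], lo[2], hi[2], lo[3], hi[3])
  face <- which.min(dists)
  ax <- ceiling(face / 2)                 # normal axis
  side <- if (face %% 2 == 1) 1L else d[ax]
  tang <- setdiff(1:3, ax)
  idx <- array(seq_len(n), d)
  cells <- switch(ax, idx[side, , ], idx[, side, ], idx[, , side])
  cells <- as.vector(cells)
  cc <- voxel_centers(geometry)[cells, , drop = FALSE]
  r2 <- (cc[, tang[1]] - position[tang[1]])^2 +
        (cc[, tang[2]] - position[tang[2]])^2
  w <- exp(-r2 / (2 * sigma^2))
  w[sqrt(r2) > 3 * sigma] <- 0
  if (sum(w) <= 0) stop("optode profile does not overlap the boundary face")
  q[cells] <- w / sum(w)
  q
}

#' Solve the diffusion approximation for one source
#'
#' @param system A `diffusion_system` (or a `voxel_grid`, in which case
#'   `props`/`wavelength`/`bc` are used to build one).
#' @param source Either a list with `position` (mm) and optionally `sigma`
#'   (mm) and `type` (`"gaussian"` boundary profile or `"point"`), or a
#'   numeric right-hand-side vector over voxels.
#' @param props,wavelength,bc Used only when `system` is a geometry.
#' @return Numeric vector: fluence per voxel (positive where light reaches).
#' @export
solve_diffusion <- function(system, source, props = NULL, wavelength = NA,
                            bc = "robin") {
  if (inherits(system, "voxel_grid"))
    system <- diffusion_system(system, props, wavelength, bc)
  stopifnot(inherits(system, "diffusion_system"))
  q <- if (is.numeric(source)) source
       else do.call(.source_vector, c(list(geometry = system$geometry),
                                      source))
  as.numeric(Matrix::solve(system$factor, q))
}

#' Channel-by-voxel sensitivity (Jacobian) at one wavelength
#'
#' Computes the Rytov-form sensitivity of channel log10 attenuation to voxel
#' absorption changes by the adjoint method:
#' `J[ch, v] = Phi_src(v) * Phi_det(v) * V_v / (amplitude(ch) * ln 10)`,
#' where `Phi_src`/`Phi_det` are the fluence fields of the channel's source
#' and (reciprocal) detector, `V_v` the voxel volume, and `amplitude(ch)` the
#' modelled detector reading. The `ln 10` factor converts natural-log to
#' log10 (OD) sensitivity, matching attenuation defined as
#' `log10(I0 / I)`. Rows are symmetric under source-detector exchange
#' (reciprocity). This is the exact derivative of the discrete forward model,
#' so small-perturbation finite differences reproduce `J` closely.
#'
#' @param geometry A `voxel_grid`.
#' @param props Optical properties (see [diffusion_system()]).
#' @param array An `optode_array`.
#' @param wavelength Wavelength, nm.
#' @param bc Boundary condition.
#' @param system Optional prebuilt `diffusion_system` to reuse.
#' @return A `wavelength_jacobian`: list with `J` (channels x voxels),
#'   `wavelength`, `amplitude` (modelled channel signal), `grid`.
#' @export
compute_jacobian <- function(geometry, props, array, wavelength,
                             bc = "robin", system = NULL) {
  stopifnot(inherits(array, "optode_array"))
  if (is.null(system))
    system <- diffusion_system(geometry, props, wavelength, bc)
  n <- prod(geometry$dims)
  h <- geometry$spacing
  qs <- vapply(seq_len(nrow(array$sources)), function(i) {
    .source_vector(geometry, array$sources[i, ], array$source_sigma)
  }, numeric(n))
  qd <- vapply(seq_len(nrow(array$detectors)), function(i) {
    .source_vector(geometry, array$detectors[i, ], array$source_sigma)
  }, numeric(n))
  phi_s <- as.matrix(Matrix::solve(system$factor, qs))
  phi_d <- as.matrix(Matrix::solve(system$factor, qd))

  ch <- array$channels
  nch <- nrow(ch)
  J <- matrix(0, nch, n)
  amp <- numeric(nch)
  for (k in seq_len(nch)) {
    amp[k] <- sum(qd[, ch$detector[k]] * phi_s[, ch$source[k]])
    if (amp[k] <= 0)
      stop("channel ", k, " has zero modelled signal (source ",
           ch$source[k], ", detector ", ch$detector[k], ")")
    J[k, ] <- phi_s[, ch$source[k]] * phi_d[, ch$detector[k]] * h^3 /
      (amp[k] * log(10))
  }
  structure(list(J = J, wavelength = wavelength, amplitude = amp,
                 grid = voxel_grid(geometry$dims, geometry$spacing,
                                   geometry$origin)),
            class = "wavelength_jacobian")
}

#' @export
print.wavelength_jacobian <- function(x, ...) {
  cat("<wavelength_jacobian> ", x$wavelength, " nm: ", nrow(x$J),
      " channels x ", ncol(x$J), " voxels\n", sep = "")
  invisible(x)
}
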