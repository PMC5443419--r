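#' Regular voxel grids and layered slab phantoms
#'
#' The forward model and reconstruction both operate on regular voxel grids.
#' A `voxel_grid` is a box of `dims` voxels with isotropic `spacing` (mm) and
#' an `origin` (mm, the corner of the first voxel); voxel centers sit at
#' `origin + (index - 1/2) * spacing`. A `slab_geometry` adds a tissue label
#' per voxel: a layered head-like phantom with superficial scalp and skull
#' layers, a thin cerebrospinal-fluid (CSF) layer, and brain (grey matter)
#' below, stacked along +z (depth); the optode surface is the z = 0 face.
#'
#' @param dims Integer vector (nx, ny, nz).
#' @param spacing Voxel edge length, mm.
#' @param origin Corner of the grid, mm.
#' @return A `voxel_grid`.
#' @export
voxel_grid <- function(dims, spacing, origin = c(0, 0, 0)) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 1), spacing > 0,
            length(origin) == 3)
  structure(list(dims = dims, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @rdname voxel_grid
#' @param size_mm Physical extent (x, y, z), mm.
#' @param layers Named numeric vector of superficial layer thicknesses, mm,
#'   in depth order; remaining depth is labelled `"gm"`. Default 6 mm scalp,
#'   6 mm skull, 2 mm CSF (12 mm of extracerebral tissue over a thin CSF
#'   layer, brain below).
#' @export
slab_geometry <- function(size_mm = c(60, 60, 40), spacing = 2,
                          layers = c(scalp = 6, skull = 6, csf = 2)) {
  dims <- as.integer(round(size_mm / spacing))
  g <- voxel_grid(dims, spacing)
  zc <- (seq_len(dims[3]) - 0.5) * spacing  # depth of voxel centers
  lab_z <- rep("gm", dims[3])
  top <- 0
  for (i in seq_along(layers)) {
    lab_z[zc > top & zc <= top + layers[i]] <- names(layers)[i]
    top <- top + layers[i]
  }
  labels <- array(rep(lab_z, each = dims[1] * dims[2]), dims)
  g$labels <- labels
  g$tissues <- unique(lab_z)
  class(g) <- c("slab_geometry", "voxel_grid")
  g
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<", class(x)[1], "> ", paste(x$dims, collapse = " x "), " voxels @ ",
      x$spacing, " mm (", paste(x$dims * x$spacing, collapse = " x "),
      " mm)\n", sep = "")
  if (!is.null(x$tissues))
    cat("  tissues:", paste(x$tissues, collapse = ", "), "\n")
  invisible(x)
}

#' Voxel-center coordinates
#'
#' @param grid A `voxel_grid`.
#' @return Matrix (n_voxels x 3) of voxel-center coordinates, mm, in
#'   column-major (x fastest) voxel order.
#' @export
voxel_centers <- function(grid) {
  d <- grid$dims; h <- grid$spacing; o <- grid$origin
  cbind(
    x = o[1] + (rep(seq_len(d[1]), times = d[2] * d[3]) - 0.5) * h,
    y = o[2] + (rep(rep(seq_len(d[2]), each = d[1]), times = d[3]) - 0.5) * h,
    z = o[3] + (rep(seq_len(d[3]), each = d[1] * d[2]) - 0.5) * h
  )
}

#' Logical mask of brain voxels
#'
#' @param geometry A `slab_geometry`.
#' @return Logical vector over voxels (TRUE for grey/white matter).
#' @export
brain_mask <- function(geometry) {
  stopifnot(!is.null(geometry$labels))
  as.vector(geometry$labels %in% c("gm", "wm"))
}

#' Tissue optical properties
#'
#' `load_tissue_optics()` reads a per-tissue table of absorption (`mua_mm`)
#' and reduced scattering (`musp_mm`) coefficients versus wavelength. The
#' packaged default is a synthetic literature-plausible table (see the file
#' header); supply your own CSV with columns
#' `tissue,wavelength_nm,mua_mm,musp_mm` to override. `optics_at()` linearly
#' interpolates the table at one wavelength.
#'
#' @param path Optional CSV path; default the packaged table.
#' @param n_refractive Tissue refractive index used for the boundary
#'   condition (default 1.4).
#' @return A `tissue_optics` object.
#' @export
load_tissue_optics <- function(path = NULL, n_refractive = 1.4) {
  if (is.null(path))
    path <- system.file("extdata", "tissue_optics_synthetic.csv",
                        package = "ccodot", mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#")
  stopifnot(all(c("tissue", "wavelength_nm", "mua_mm", "musp_mm") %in%
                  names(tab)))
  if (any(tab$mua_mm < 0) || any(tab$musp_mm <= 0))
    stop("require mua >= 0 and musp > 0 in ", path)
  structure(list(table = tab, n_refractive = n_refractive),
            class = "tissue_optics")
}

#' @rdname load_tissue_optics
#' @param optics A `tissue_optics` object.
#' @param tissues Character vector of tissue names.
#' @param wavelength Wavelength, nm.
#' @return List with named vectors `mua` and `musp` (mm^-1) over `tissues`.
#' @export
optics_at <- function(optics, tissues, wavelength) {
  stopifnot(inherits(optics, "tissue_optics"), length(wavelength) == 1)
  tab <- optics$table
  vals <- lapply(tissues, function(ti) {
    sub <- tab[tab$tissue == ti, ]
    if (nrow(sub) == 0) stop("no optical properties for tissue '", ti, "'")
    if (wavelength < min(sub$wavelength_nm) ||
        wavelength > max(sub$wavelength_nm))
      stop("wavelength ", wavelength, " nm outside optics table for '",
           ti, "'")
    c(mua = stats::approx(sub$wavelength_nm, sub$mua_mm, wavelength)$y,
      musp = stats::approx(sub$wavelength_nm, sub$musp_mm, wavelength)$y)
  })
  m <- do.call(rbind, vals)
  list(mua = stats::setNames(m[, "mua"], tissues),
       musp = stats::setNames(m[, "musp"], tissues))
}

#' Mass-preserving resampling between regular grids
#'
#' Resamples a voxel field from one regular grid onto another by exact
#' cell-overlap integration (the tensor product of one-dimensional interval
#' overlaps), so that the integral `sum(field * voxel_volume)` is conserved
#' whenever the target grid covers the source domain. Used to move forward
#' solutions and ground-truth images between simulation and reconstruction
#' grids, including the mismatched-resolution (inverse-crime control) path.
#'
#' @param field Numeric array on `from$dims` (or a vector of that length).
#' @param from,to `voxel_grid` objects.
#' @return Numeric array on `to$dims`.
#' @export
project_to_grid <- function(field, from, to) {
  stopifnot(inherits(from, "voxel_grid"), inherits(to, "voxel_grid"))
  if (length(field) != prod(from$dims))
    stop("field length does not match source grid")
  W <- lapply(1:3, function(ax) {
    .overlap_matrix(from$origin[ax], from$spacing, from$dims[ax],
                    to$origin[ax], to$spacing, to$dims[ax])
  })
  if (all(vapply(W, function(w) sum(w) == 0, logical(1))))
    stop("source and target grids do not intersect")
  a <- array(as.numeric(field), from$dims)
  # contract axis by axis: integral over target cells of the source field
  m <- W[[1]] %*% matrix(a, from$dims[1])                       # tx x (sy sz)
  a <- array(m, c(to$dims[1], from$dims[2], from$dims[3]))
  m <- W[[2]] %*% matrix(aperm(a, c(2, 1, 3)), from$dims[2])    # ty x (tx sz)
  a <- aperm(array(m, c(to$dims[2], to$dims[1], from$dims[3])), c(2, 1, 3))
  m <- W[[3]] %*% matrix(aperm(a, c(3, 1, 2)), from$dims[3])    # tz x (tx ty)
  a <- aperm(array(m, c(to$dims[3], to$dims[1], to$dims[2])), c(2, 3, 1))
  a / to$spacing^3  # integral -> mean value per target voxel
}

# 1-D interval-overlap matrix: entry (t, s) = |target cell t  ∩  source cell s|
.overlap_matrix <- function(o_s, h_s, n_s, o_t, h_t, n_t) {
  s_lo <- o_s + (seq_len(n_s) - 1) * h_s
  t_lo <- o_t + (seq_len(n_t) - 1) * h_t
  lo <- outer(t_lo, s_lo, function(a, b) pmax(a, b))
  hi <- outer(t_lo + h_t, s_lo + h_s, function(a, b) pmin(a, b))
  pmax(hi - lo, 0)
}
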