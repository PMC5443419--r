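#' Multispectral forward operator
#'
#' Assembles the stacked multispectral system that maps chromophore
#' concentration-change images to channel attenuation changes at every
#' wavelength. Row block `l` (one per wavelength) is
#' `[J_l eps_l^c1, J_l eps_l^c2, ...]`: each wavelength Jacobian scaled by
#' the chromophore's specific absorption coefficient at that wavelength.
#' The operator is applied matrix-free -- the scaled blocks are never
#' materialized -- with a forward and an exactly consistent adjoint.
#'
#' @param jacobians List of `wavelength_jacobian`s, one per row of `E`.
#' @param E Extinction matrix (wavelengths x chromophores, uM^-1 mm^-1) from
#'   [extinction_matrix()]; row order must match `jacobians`.
#' @param chromophores Optional chromophore names (default `colnames(E)`).
#' @return A `multispectral_system`.
#' @export
multispectral_system <- function(jacobians, E, chromophores = colnames(E)) {
  stopifnot(is.list(jacobians), is.matrix(E))
  if (length(jacobians) != nrow(E))
    stop("need one Jacobian per wavelength row of E (", nrow(E), "), got ",
         length(jacobians))
  wl <- vapply(jacobians, `[[`, numeric(1), "wavelength")
  n_vox <- unique(vapply(jacobians, function(j) ncol(j$J), integer(1)))
  nch <- unique(vapply(jacobians, function(j) nrow(j$J), integer(1)))
  if (length(n_vox) != 1 || length(nch) != 1)
    stop("Jacobians have inconsistent shapes")
  if (is.null(chromophores)) chromophores <- paste0("chrom", seq_len(ncol(E)))
  structure(list(jacobians = lapply(jacobians, `[[`, "J"), eps = E,
                 wavelengths = wl, chromophores = chromophores,
                 n_vox = n_vox, n_channels = nch,
                 grid = jacobians[[1]]$grid),
            class = "multispectral_system")
}

#' @export
print.multispectral_system <- function(x, ...) {
  cat("<multispectral_system> ", x$n_channels, " channels x ",
      length(x$wavelengths), " wavelengths -> ", x$n_vox, " voxels x {",
      paste(x$chromophores, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Apply a multispectral system (forward / adjoint)
#'
#' Forward: maps `x` (voxels x chromophores, flattened chromophore-major) to
#' the stacked data vector (channels within wavelength, wavelengths as
#' blocks). Adjoint: the transpose map.
#'
#' @param system A `multispectral_system`.
#' @param x Numeric vector (or matrix/array reshaped to length
#'   `n_vox * n_chromophores` for forward, `n_channels * n_wavelengths` for
#'   adjoint).
#' @param adjoint Apply the transpose.
#' @return Numeric vector.
#' @export
ms_apply <- function(system, x, adjoint = FALSE) {
  nwl <- length(system$wavelengths); nc <- length(system$chromophores)
  if (!adjoint) {
    X <- matrix(as.numeric(x), system$n_vox, nc)
    V <- X %*% t(system$eps)                      # n_vox x nwl: delta-mua
    y <- vapply(seq_len(nwl), function(l) {
      as.numeric(system$jacobians[[l]] %*% V[, l])
    }, numeric(system$n_channels))
    as.numeric(y)
  } else {
    Y <- matrix(as.numeric(x), system$n_channels, nwl)
    W <- vapply(seq_len(nwl), function(l) {
      as.numeric(Matrix::crossprod(system$jacobians[[l]], Y[, l]))
    }, numeric(system$n_vox))
    as.numeric(W %*% system$eps)
  }
}

#' Reconstruction configuration
#'
#' Settings for the regularized multispectral inversion: Tikhonov
#' hyperparameter, background concentrations used to sphere the solution
#' space so regularization weighs every chromophore equally, and iterative
#' solver controls. Defaults follow common adult-head values: background
#' 56 uM HbO2, 24 uM HHb, 12.8 uM oxCCO; hyperparameter 1e-4; LSQR capped at
#' 50 iterations with tolerance 1e-5.
#'
#' @param lambda_reg Regularization hyperparameter (> 0).
#' @param background Named background concentrations, uM, one per
#'   chromophore to reconstruct (2- or 3-chromophore set).
#' @param max_iter Maximum LSQR iterations.
#' @param tol LSQR stopping tolerance.
#' @return A `recon_config`.
#' @export
recon_config <- function(lambda_reg = 1e-4,
                         background = c(HbO2 = 56, HHb = 24, oxCCO = 12.8),
                         max_iter = 50, tol = 1e-5) {
  if (!is.numeric(lambda_reg) || lambda_reg <= 0)
    stop("lambda_reg must be positive")
  stopifnot(all(background > 0), max_iter >= 1, tol > 0)
  structure(list(lambda_reg = lambda_reg, background = background,
                 max_iter = max_iter, tol = tol,
                 chromophores = names(background)),
            class = "recon_config")
}

# ---- discrete spatial gradient (first-order Tikhonov penalty) --------------

# Forward differences along each axis, zero-gradient at the far face.
# Input: vector over voxels; output: vector of length 3 * n_vox.
.grad_apply <- function(x, dims) {
  a <- array(x, dims)
  gx <- array(0, dims); gy <- array(0, dims); gz <- array(0, dims)
  if (dims[1] > 1) gx[-dims[1], , ] <- a[-1, , ] - a[-dims[1], , ]
  if (dims[2] > 1) gy[, -dims[2], ] <- a[, -1, ] - a[, -dims[2], ]
  if (dims[3] > 1) gz[, , -dims[3]] <- a[, , -1] - a[, , -dims[3]]
  c(gx, gy, gz)
}

.grad_adjoint <- function(y, dims) {
  n <- prod(dims)
  gx <- array(y[seq_len(n)], dims)
  gy <- array(y[n + seq_len(n)], dims)
  gz <- array(y[2 * n + seq_len(n)], dims)
  out <- array(0, dims)
  if (dims[1] > 1) {
    out[-1, , ] <- out[-1, , ] + gx[-dims[1], , ]
    out[-dims[1], , ] <- out[-dims[1], , ] - gx[-dims[1], , ]
  }
  if (dims[2] > 1) {
    out[, -1, ] <- out[, -1, ] + gy[, -dims[2], ]
    out[, -dims[2], ] <- out[, -dims[2], ] - gy[, -dims[2], ]
  }
  if (dims[3] > 1) {
    out[, , -1] <- out[, , -1] + gz[, , -dims[3]]
    out[, , -dims[3]] <- out[, , -dims[3]] - gz[, , -dims[3]]
  }
  as.numeric(out)
}

# ---- LSQR (Paige & Saunders) -----------------------------------------------

# Matrix-free LSQR for min ||b - A x||. Aop(x, adjoint) applies the operator.
.lsqr <- function(Aop, b, max_iter = 50, tol = 1e-5) {
  u <- b
  beta <- sqrt(sum(u^2))
  if (beta == 0) return(list(x = Aop(b, TRUE) * 0, iterations = 0L,
                             rnorm = 0))
  u <- u / beta
  v <- Aop(u, TRUE)
  alpha <- sqrt(sum(v^2))
  if (alpha > 0) v <- v / alpha
  w <- v
  x <- numeric(length(v))
  phibar <- beta; rhobar <- alpha
  anorm <- 0
  it <- 0L
  for (it in seq_len(max_iter)) {
    u <- Aop(v, FALSE) - alpha * u
    beta <- sqrt(sum(u^2))
    if (beta > 0) u <- u / beta
    vnew <- Aop(u, TRUE) - beta * v
    alpha_new <- sqrt(sum(vnew^2))
    if (alpha_new > 0) vnew <- vnew / alpha_new
    anorm <- sqrt(anorm^2 + alpha^2 + beta^2)
    rho <- sqrt(rhobar^2 + beta^2)
    cs <- rhobar / rho; sn <- beta / rho
    theta <- sn * alpha_new
    rhobar <- -cs * alpha_new
    phi <- cs * phibar
    phibar <- sn * phibar
    x <- x + (phi / rho) * w
    w <- vnew - (theta / rho) * w
    v <- vnew; alpha <- alpha_new
    if (any(!is.finite(x)))
      stop("LSQR diverged (non-finite iterate at iteration ", it, ")")
    arnorm <- phibar * alpha * abs(cs)   # ||A' r||
    if (arnorm <= tol * anorm * phibar) break       # ||A'r||/(||A|| ||r||)
    if (phibar <= tol * sqrt(sum(b^2))) break       # relative residual
  }
  list(x = x, iterations = it, rnorm = phibar)
}

# ---- reconstruction --------------------------------------------------------

#' Concentration-change image
#'
#' @param data Matrix (voxels x chromophores), uM.
#' @param grid A `voxel_grid`.
#' @param chromophores Chromophore names.
#' @param time_s Time label, s.
#' @return A `concentration_image`.
#' @export
concentration_image <- function(data, grid, chromophores, time_s = NA) {
  data <- as.matrix(data)
  stopifnot(nrow(data) == prod(grid$dims),
            ncol(data) == length(chromophores), all(is.finite(data)))
  colnames(data) <- chromophores
  structure(list(data = data, grid = grid, chromophores = chromophores,
                 time_s = time_s),
            class = "concentration_image")
}

#' @export
print.concentration_image <- function(x, ...) {
  cat("<concentration_image> {", paste(x$chromophores, collapse = ", "),
      "} on ", paste(x$grid$dims, collapse = " x "), " grid",
      if (!is.na(x$time_s)) paste0(" at t = ", x$time_s, " s"), "\n",
      sep = "")
  invisible(x)
}

#' Extract one chromophore volume from a concentration image
#'
#' @param image A `concentration_image`.
#' @param chromophore Chromophore name.
#' @return 3-D numeric array on the image grid.
#' @export
image_volume <- function(image, chromophore) {
  stopifnot(chromophore %in% image$chromophores)
  array(image$data[, chromophore], image$grid$dims)
}

#' Regularized multispectral image reconstruction
#'
#' Solves the first-order Tikhonov regularized least-squares problem
#'
#'   min  || dA - A x ||^2 + lambda || grad(x / C_b) ||^2
#'
#' for the chromophore concentration-change image `x`, where `A` is the
#' multispectral operator and the penalty acts on the spatial gradient of the
#' *sphered* image (each chromophore divided by its background concentration
#' `C_b`), so regularization is applied equally to every chromophore. The
#' problem is posed in sphered variables `y = x / C_b` as the augmented
#' least-squares system `[A S; sqrt(lambda) L] y = [dA; 0]` with
#' `S = diag(C_b)` and `L` the forward-difference gradient, and solved with
#' LSQR starting from zero (deterministic). The noise covariance is the
#' identity; a diagonal weighting can be applied upstream to `dA`.
#'
#' @param dA Numeric matrix (channels x wavelengths) or stacked vector of
#'   attenuation changes, OD.
#' @param system A `multispectral_system`.
#' @param config A [recon_config()]; its chromophore set must match the
#'   system's.
#' @return A `concentration_image` (uM) with attributes `iterations`,
#'   `rnorm_data` (data-residual norm) and `penalty_norm` (gradient norm of
#'   the sphered solution).
#' @export
reconstruct <- function(dA, system, config = recon_config()) {
  stopifnot(inherits(system, "multispectral_system"),
            inherits(config, "recon_config"))
  if (!identical(unname(config$chromophores), unname(system$chromophores)))
    stop("chromophore sets differ between system (",
         paste(system$chromophores, collapse = ","), ") and config (",
         paste(config$chromophores, collapse = ","), ")")
  b_data <- as.numeric(dA)
  nwl <- length(system$wavelengths)
  m1 <- system$n_channels * nwl
  if (length(b_data) != m1)
    stop("dA has length ", length(b_data), ", expected channels x ",
         "wavelengths = ", m1)
  if (any(!is.finite(b_data))) stop("dA must be finite")
  nc <- length(system$chromophores)
  n_vox <- system$n_vox
  dims <- system$grid$dims
  cb <- as.numeric(config$background)
  sq <- sqrt(config$lambda_reg)

  Aop <- function(z, adjoint = FALSE) {
    if (!adjoint) {
      Y <- matrix(z, n_vox, nc)
      xphys <- sweep(Y, 2, cb, `*`)
      pen <- as.numeric(vapply(seq_len(nc), function(c)
        .grad_apply(Y[, c], dims), numeric(3 * n_vox)))
      c(ms_apply(system, xphys), sq * pen)
    } else {
      z1 <- z[seq_len(m1)]
      z2 <- z[-seq_len(m1)]
      X <- matrix(ms_apply(system, z1, adjoint = TRUE), n_vox, nc)
      X <- sweep(X, 2, cb, `*`)
      P <- matrix(z2, 3 * n_vox, nc)
      for (c in seq_len(nc))
        X[, c] <- X[, c] + sq * .grad_adjoint(P[, c], dims)
      as.numeric(X)
    }
  }

  if (all(b_data == 0)) {
    sol <- list(x = numeric(n_vox * nc), iterations = 0L)
  } else {
    sol <- .lsqr(Aop, c(b_data, numeric(3 * n_vox * nc)),
                 max_iter = config$max_iter, tol = config$tol)
  }
  Y <- matrix(sol$x, n_vox, nc)
  X <- sweep(Y, 2, cb, `*`)
  pred <- ms_apply(system, X)
  img <- concentration_image(X, system$grid, system$chromophores)
  attr(img, "iterations") <- sol$iterations
  attr(img, "lambda_reg") <- config$lambda_reg
  attr(img, "rnorm_data") <- sqrt(sum((b_data - pred)^2))
  attr(img, "penalty_norm") <- sqrt(sum(vapply(seq_len(nc), function(c)
    sum(.grad_apply(Y[, c], dims)^2), numeric(1))))
  img
}

#' L-curve hyperparameter selection
#'
#' Reconstructs over a grid of hyperparameters and returns the one at the
#' point of maximum curvature of the log-log (data residual norm, penalty
#' norm) curve, together with the full curve for inspection.
#'
#' @param dA Attenuation-change matrix/vector, as in [reconstruct()].
#' @param system A `multispectral_system`.
#' @param config Base [recon_config()]; `lambda_reg` is overridden per grid
#'   point.
#' @param lambda_grid Positive hyperparameter grid (>= 5 points spanning at
#'   least two decades).
#' @return List with `lambda` (selected), `curve` (tibble: lambda,
#'   residual_norm, penalty_norm, curvature).
#' @export
lcurve_select <- function(dA, system, config = recon_config(),
                          lambda_grid = 10^seq(-5, -2, length.out = 9)) {
  lambda_grid <- sort(lambda_grid)
  if (length(lambda_grid) < 5 ||
      max(lambda_grid) / min(lambda_grid) < 100 || any(lambda_grid <= 0))
    stop("lambda_grid must hold >= 5 positive values spanning >= 2 decades")
  fits <- lapply(lambda_grid, function(l) {
    cfg <- config; cfg$lambda_reg <- l
    img <- reconstruct(dA, system, cfg)
    c(res = attr(img, "rnorm_data"), pen = attr(img, "penalty_norm"))
  })
  res <- vapply(fits, `[[`, numeric(1), "res")
  pen <- vapply(fits, `[[`, numeric(1), "pen")
  t <- log(lambda_grid)
  xi <- log(pmax(res, .Machine$double.xmin))
  eta <- log(pmax(pen, .Machine$double.xmin))
  d1x <- .cgrad(xi, t); d1y <- .cgrad(eta, t)
  d2x <- .cgrad(d1x, t); d2y <- .cgrad(d1y, t)
  curv <- (d1x * d2y - d1y * d2x) / (d1x^2 + d1y^2)^1.5
  best <- which.max(curv)
  list(lambda = lambda_grid[best],
       curve = tibble::tibble(lambda = lambda_grid, residual_norm = res,
                              penalty_norm = pen, curvature = curv))
}

# central differences on a possibly non-uniform abscissa
.cgrad <- function(y, x) {
  n <- length(y)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  d
}

#' Project a volumetric image onto surface nodes
#'
#' Assigns to each surface node the mean of voxel values whose centers lie
#' within `radius` (default 3 mm); nodes with no voxel in range get `NA`
#' (flagged missing, never zero). Used to map reconstructed volumes onto a
#' cortical-surface-like node set for display.
#'
#' @param image A `concentration_image`.
#' @param nodes Matrix (n x 3) of node coordinates, mm.
#' @param radius Search radius, mm.
#' @return Matrix (n_nodes x n_chromophores) of node values.
#' @export
surface_project <- function(image, nodes, radius = 3) {
  stopifnot(inherits(image, "concentration_image"))
  if (radius <= 0) stop("radius must be positive")
  nodes <- as.matrix(nodes)
  cc <- voxel_centers(image$grid)
  out <- matrix(NA_real_, nrow(nodes), length(image$chromophores),
                dimnames = list(NULL, image$chromophores))
  r2 <- radius^2
  for (i in seq_len(nrow(nodes))) {
    d2 <- (cc[, 1] - nodes[i, 1])^2 + (cc[, 2] - nodes[i, 2])^2 +
          (cc[, 3] - nodes[i, 3])^2
    sel <- d2 <= r2
    if (any(sel)) out[i, ] <- colMeans(image$data[sel, , drop = FALSE])
  }
  out
}
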