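# Mini DOT fixture: shallow slab, dense overlapping 9+9 optode grid.
mini_dot <- function() {
  memo("mini_dot", {
    g <- voxel_grid(c(10, 10, 5), 4)
    pos <- as.matrix(expand.grid(x = c(8, 20, 32), y = c(8, 20, 32)))
    src <- cbind(pos, 0); det <- cbind(pos + 6, 0)
    ch <- expand.grid(source = 1:9, detector = 1:9)
    d <- sqrt(rowSums((src[ch$source, ] - det[ch$detector, ])^2))
    arr <- optode_array(src, det, ch[d < 25, ])
    wl <- seq(740, 900, 40)
    jacs <- lapply(wl, function(w)
      compute_jacobian(g, homog_props(), arr, w))
    cc <- voxel_centers(g)
    smooth <- exp(-((cc[, 1] - 20)^2 + (cc[, 2] - 20)^2 +
                    (cc[, 3] - 6)^2) / 200)
    list(grid = g, jacs = jacs, wl = wl, smooth = smooth,
         sys3 = multispectral_system(jacs,
                  extinction_matrix(c("HbO2", "HHb", "oxCCO"), wl)),
         sys2 = multispectral_system(jacs,
                  extinction_matrix(c("HbO2", "HHb"), wl)))
  })
}

test_that("multispectral operator equals the dense stacked matrix", {
  sys <- toy_system()
  Ad <- dense_stack(sys)
  set.seed(12)
  for (k in 1:5) {
    x <- rnorm(ncol(Ad))
    expect_lt(max(abs(Ad %*% x - ms_apply(sys, x))), 1e-12)
  }
  # adjoint identity on random vector pairs
  for (k in 1:20) {
    x <- rnorm(ncol(Ad)); y <- rnorm(nrow(Ad))
    expect_lt(abs(sum(ms_apply(sys, x) * y) -
                  sum(x * ms_apply(sys, y, adjoint = TRUE))), 1e-10)
  }
})

test_that("a single-wavelength, unit-extinction system is the Jacobian itself", {
  set.seed(2)
  grid <- voxel_grid(c(4, 3, 2), 2)
  J <- matrix(rnorm(3 * 24), 3)
  jac <- structure(list(J = J, wavelength = 800, grid = grid),
                   class = "wavelength_jacobian")
  E <- matrix(1, 1, 1, dimnames = list("800", "HbO2"))
  sys <- multispectral_system(list(jac), E)
  x <- rnorm(24)
  expect_equal(ms_apply(sys, x), as.numeric(J %*% x), tolerance = 1e-14)
})

test_that("LSQR reconstruction matches the dense regularized oracle", {
  sys <- toy_system(dims = c(5, 4, 3))          # 180 unknowns
  cfg <- recon_config(lambda_reg = 1e-3, max_iter = 2000, tol = 1e-14)
  set.seed(77)
  b <- rnorm(sys$n_channels * length(sys$wavelengths)) * 1e-3
  img <- reconstruct(b, sys, cfg)
  xd <- dense_reconstruct(b, sys, cfg)
  expect_lt(sqrt(sum((img$data - xd)^2)) / sqrt(sum(xd^2)), 1e-4)
})

test_that("zero data reconstructs to exactly zero", {
  sys <- toy_system()
  img <- reconstruct(numeric(sys$n_channels * length(sys$wavelengths)), sys)
  expect_true(all(img$data == 0))
})

test_that("system assembly rejects wavelength/Jacobian mismatches", {
  sys <- toy_system()
  jacs <- lapply(seq_along(sys$wavelengths), function(l)
    structure(list(J = sys$jacobians[[l]], wavelength = sys$wavelengths[l],
                   grid = sys$grid), class = "wavelength_jacobian"))
  E <- extinction_matrix(c("HbO2", "HHb"), c(sys$wavelengths, 900))
  expect_error(multispectral_system(jacs, E), "one Jacobian per wavelength")
})

test_that("reconstruction errors are informative", {
  sys <- toy_system()
  expect_error(recon_config(lambda_reg = -1), "positive")
  expect_error(reconstruct(1:5, sys), "expected channels")
  expect_error(reconstruct(rep(NaN, sys$n_channels *
                                 length(sys$wavelengths)), sys), "finite")
  cfg2 <- recon_config(background = c(HbO2 = 56, HHb = 24))
  expect_error(reconstruct(numeric(sys$n_channels *
                                     length(sys$wavelengths)), sys, cfg2),
               "chromophore sets differ")
})

test_that("a smooth three-chromophore field is recovered from noiseless data", {
  fx <- mini_dot()
  truth <- outer(fx$smooth, c(1, -0.3, 0.1))
  b <- ms_apply(fx$sys3, truth)
  img <- reconstruct(b, fx$sys3,
                     recon_config(lambda_reg = 1e-6, max_iter = 300,
                                  tol = 1e-10))
  for (c in 1:3)
    expect_gt(abs(cor(img$data[, c], truth[, c])), 0.7)
  expect_gt(cor(img$data[, 1], truth[, 1]), 0)     # signs, not just shape
  expect_lt(cor(img$data[, 2], img$data[, 1]), 0)  # HHb anti-correlated
  # centroid of the dominant chromophore within one truth length scale (10 mm)
  cen <- pos_centroid(img$data[, 1], fx$grid)
  truth_cen <- pos_centroid(truth[, 1], fx$grid)
  expect_lt(sqrt(sum((cen - truth_cen)^2)), 10)
})

test_that("reconstruction without an oxCCO signal shows little cross-talk", {
  fx <- mini_dot()
  truth <- outer(fx$smooth, c(1, -0.3, 0))
  b <- ms_apply(fx$sys3, truth)
  img <- reconstruct(b, fx$sys3, recon_config(max_iter = 300, tol = 1e-10))
  expect_lt(sqrt(sum(img$data[, 3]^2)), 0.1 * sqrt(sum(img$data[, 1]^2)))
})

test_that("reconstruction is linear in the data once converged", {
  sys <- toy_system(dims = c(4, 3, 2))
  set.seed(3)
  b <- rnorm(sys$n_channels * length(sys$wavelengths)) * 1e-3
  cfg <- recon_config(max_iter = 3000, tol = 1e-14)
  i1 <- reconstruct(b, sys, cfg)
  i2 <- reconstruct(3 * b, sys, cfg)
  expect_equal(i2$data, 3 * i1$data, tolerance = 1e-6)
})

test_that("sphering scales the penalty, not the physical solution shape", {
  # the background-concentration sphering makes the *penalty* invariant
  # under jointly scaling one chromophore's C_b and image by s
  dims <- c(6, 5, 4)
  set.seed(10)
  x <- array(rnorm(prod(dims)), dims)
  p1 <- sum(ccodot:::.grad_apply(as.numeric(x) / 12.8, dims)^2)
  p2 <- sum(ccodot:::.grad_apply(as.numeric(3 * x) / (3 * 12.8), dims)^2)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("the L-curve trades residual against penalty with an interior corner", {
  fx <- mini_dot()
  truth <- outer(fx$smooth, c(1, -0.3, 0.1))
  set.seed(8)
  b <- ms_apply(fx$sys3, truth)
  bn <- b + rnorm(length(b), sd = 2e-5)
  lc <- lcurve_select(bn, fx$sys3, recon_config(max_iter = 80),
                      lambda_grid = 10^seq(-5, -2, length.out = 9))
  expect_true(all(diff(lc$curve$residual_norm) >= -1e-12))
  expect_true(all(diff(lc$curve$penalty_norm) <= 1e-12))
  best <- which(lc$curve$lambda == lc$lambda)
  expect_gt(best, 1)
  expect_lt(best, nrow(lc$curve))
  expect_error(lcurve_select(bn, fx$sys3, lambda_grid = c(1e-4, 2e-4)),
               "decades")
})

test_that("surface projection averages voxels within the radius", {
  grid <- voxel_grid(c(10, 10, 6), 2)
  # constant volume -> constant surface values
  img <- concentration_image(matrix(5, prod(grid$dims), 1), grid, "HbO2")
  nodes <- rbind(c(10, 10, 6), c(4, 4, 2))
  expect_equal(as.numeric(surface_project(img, nodes, radius = 3)),
               c(5, 5))
  # tiny radius at a voxel center picks that voxel
  cc <- voxel_centers(grid)
  vals <- matrix(seq_len(prod(grid$dims)), ncol = 1)
  img2 <- concentration_image(vals, grid, "v")
  expect_equal(as.numeric(surface_project(img2, cc[123, , drop = FALSE],
                                          radius = 0.9)), 123)
  # linear ramp: node value equals the field within one spacing-slope step
  ramp <- matrix(cc[, 1], ncol = 1)
  img3 <- concentration_image(ramp, grid, "v")
  node <- matrix(c(9, 11, 7), 1)
  got <- as.numeric(surface_project(img3, node, radius = 3))
  expect_lt(abs(got - 9), grid$spacing)
  # out-of-range node is NA, not zero
  expect_true(is.na(surface_project(img, matrix(c(90, 90, 90), 1), 3)[1]))
  expect_error(surface_project(img, nodes, radius = 0), "positive")
})
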