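test_that("fluence is linear in source power and monotone in absorption", {
  g <- voxel_grid(c(12, 12, 8), 3)
  sys <- diffusion_system(g, homog_props())
  src <- list(position = c(18, 18, 0))
  phi <- solve_diffusion(sys, src)
  expect_true(all(phi > 0))
  q <- ccodot:::.source_vector(g, c(18, 18, 0))
  expect_equal(solve_diffusion(sys, 2 * q), 2 * phi, tolerance = 1e-12)
  # raising absorption strictly lowers the interior fluence
  sys_hi <- diffusion_system(g, homog_props(mua = 0.02))
  expect_true(all(solve_diffusion(sys_hi, src) < phi))
})

test_that("depth decay matches the semi-infinite diffusion Green's function", {
  # closed-form oracle: point source at depth 1/musp plus negative image
  # source across the extrapolated boundary
  mua <- 0.01; musp <- 1.0
  n <- 41; nz <- 20; h <- 2
  g <- voxel_grid(c(n, n, nz), h)
  sys <- diffusion_system(g, homog_props(mua, musp))
  phi <- solve_diffusion(sys, list(position = c(n * h / 2, n * h / 2, 1),
                                   type = "point"))
  a <- array(phi, g$dims)
  mid <- ceiling(n / 2)
  z <- (seq_len(nz) - 0.5) * h
  prof <- a[mid, mid, ]
  kappa <- 1 / (3 * (mua + musp))
  mueff <- sqrt(mua / kappa)
  zb <- 2 * ccodot:::.reflection_parameter(1.4) * kappa
  z0 <- 1 / musp
  green <- (exp(-mueff * abs(z - z0)) / abs(z - z0) -
            exp(-mueff * (z + z0 + 2 * zb)) / (z + z0 + 2 * zb)) /
           (4 * pi * kappa)
  iref <- which.min(abs(z - 4))
  sel <- z >= 3.5 & z <= 25
  ratio <- (prof[sel] / prof[iref]) / (green[sel] / green[iref])
  expect_lt(max(abs(ratio - 1)), 0.10)
})

test_that("Jacobian rows are reciprocal, non-negative, and match perturbations", {
  g <- voxel_grid(c(20, 20, 20), 2)  # 40 mm cube
  props <- homog_props()
  src <- matrix(c(12, 20, 0), 1)
  det <- matrix(c(28, 20, 0), 1)
  fwd <- optode_array(src, det, data.frame(source = 1, detector = 1))
  rev <- optode_array(det, src, data.frame(source = 1, detector = 1))
  sys <- diffusion_system(g, props)
  Jf <- compute_jacobian(g, props, fwd, 800, system = sys)
  Jr <- compute_jacobian(g, props, rev, 800, system = sys)
  expect_true(all(Jf$J >= 0))
  expect_lt(max(abs(Jf$J - Jr$J)) / max(abs(Jf$J)), 1e-8)

  # finite-difference oracle: uniform absorption bump
  dmua <- 1e-4
  sys2 <- diffusion_system(g, homog_props(mua = props$mua + dmua))
  J2 <- compute_jacobian(g, homog_props(mua = props$mua + dmua), fwd, 800,
                         system = sys2)
  dA_true <- -log10(J2$amplitude / Jf$amplitude)
  dA_lin <- sum(Jf$J) * dmua
  expect_equal(dA_lin, dA_true, tolerance = 0.02)

  # random sparse perturbations up to 1e-3 mm^-1
  set.seed(9)
  for (k in 1:3) {
    dm <- numeric(prod(g$dims))
    idx <- sample(length(dm), 200)
    dm[idx] <- runif(200, 0, 1e-3)
    sysp <- diffusion_system(g, list(mua = props$mua + dm, musp = props$musp))
    Jp <- compute_jacobian(g, list(mua = props$mua + dm,
                                   musp = props$musp), fwd, 800,
                           system = sysp)
    dA_true <- -log10(Jp$amplitude / Jf$amplitude)
    dA_lin <- sum(Jf$J * dm)
    expect_equal(dA_lin, dA_true, tolerance = 0.05)
  }
})

test_that("channel predictions converge under grid refinement", {
  # attenuation change from a fixed smooth absorption bump on grids
  # h = 4, 2, 1 mm: successive differences must shrink (Cauchy behaviour)
  size <- c(48, 48, 24)
  src <- matrix(c(15, 24, 0), 1); det <- matrix(c(33, 24, 0), 1)
  arr <- optode_array(src, det, data.frame(source = 1, detector = 1))
  dA_at <- function(h) {
    g <- voxel_grid(round(size / h), h)
    J <- compute_jacobian(g, homog_props(), arr, 800)
    cc <- voxel_centers(g)
    r2 <- (cc[, 1] - 24)^2 + (cc[, 2] - 24)^2 + (cc[, 3] - 8)^2
    sum(J$J * (1e-3 * exp(-r2 / (2 * 6^2))))
  }
  v <- vapply(c(4, 2, 1), dA_at, numeric(1))
  expect_lt(abs(v[3] - v[2]), abs(v[2] - v[1]))
})

test_that("degenerate and invalid forward inputs are rejected", {
  g <- voxel_grid(c(8, 8, 6), 3)
  expect_error(diffusion_system(g, list(mua = 0.01, musp = -1)), "musp > 0")
  expect_error(optode_array(matrix(0, 1, 3), matrix(1, 1, 3),
                            data.frame(source = 1, detector = 2)),
               "does not exist")
})

test_that("grid projection preserves mass and recovers smooth fields", {
  from <- voxel_grid(c(16, 16, 8), 2)
  cc <- voxel_centers(from)
  f <- exp(-((cc[, 1] - 16)^2 + (cc[, 2] - 16)^2 + (cc[, 3] - 8)^2) / 800)
  # identity map
  expect_equal(as.numeric(project_to_grid(f, from, from)), f,
               tolerance = 1e-12)
  # constant stays constant, integral conserved under coarsening
  to <- voxel_grid(c(8, 8, 4), 4)
  cst <- project_to_grid(rep(2, prod(from$dims)), from, to)
  expect_equal(as.numeric(cst), rep(2, prod(to$dims)), tolerance = 1e-12)
  g2 <- project_to_grid(f, from, to)
  expect_equal(sum(g2) * to$spacing^3, sum(f) * from$spacing^3,
               tolerance = 0.005)
  # down- then up-sampling recovers a smooth field within 5% RMS
  back <- project_to_grid(as.numeric(g2), to, from)
  expect_lt(sqrt(mean((back - f)^2)) / sqrt(mean(f^2)), 0.05)
  far <- voxel_grid(c(4, 4, 4), 2, origin = c(500, 500, 500))
  expect_error(project_to_grid(f, from, far), "do not intersect")
})
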