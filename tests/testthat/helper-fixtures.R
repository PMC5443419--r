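# Shared fixtures, built in code. Heavy end-to-end objects are memoized in a
# package-local environment so several test files can reuse one computation.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Small random dense multispectral toy: real extinction spectra, synthetic
# dense Jacobians. Well-suited to dense-oracle comparisons.
toy_system <- function(seed = 42, dims = c(5, 4, 3), n_channels = 6,
                       wavelengths = c(760, 800, 840, 880),
                       chromophores = c("HbO2", "HHb", "oxCCO")) {
  set.seed(seed)
  grid <- voxel_grid(dims, 2)
  nv <- prod(dims)
  jacs <- lapply(wavelengths, function(wl) {
    structure(list(J = matrix(stats::rnorm(n_channels * nv), n_channels),
                   wavelength = wl, grid = grid),
              class = "wavelength_jacobian")
  })
  E <- extinction_matrix(chromophores, wavelengths)
  multispectral_system(jacs, E)
}

# Dense stacked matrix equivalent of a multispectral system (oracle).
dense_stack <- function(system) {
  do.call(rbind, lapply(seq_along(system$wavelengths), function(l) {
    do.call(cbind, lapply(seq_along(system$chromophores), function(c) {
      system$jacobians[[l]] * system$eps[l, c]
    }))
  }))
}

# Dense gradient operator for one chromophore block (oracle).
dense_grad <- function(dims) {
  nv <- prod(dims)
  sapply(seq_len(nv), function(i) {
    e <- numeric(nv); e[i] <- 1
    ccodot:::.grad_apply(e, dims)
  })
}

# Dense augmented-system solve (pseudo-inverse of [A S; sqrt(lam) L]) --
# the normal-equations oracle for reconstruct().
dense_reconstruct <- function(b, system, config) {
  nv <- system$n_vox
  nc <- length(system$chromophores)
  Ad <- dense_stack(system)
  Lg <- dense_grad(system$grid$dims)
  L <- kronecker(diag(nc), Lg)
  S <- diag(rep(as.numeric(config$background), each = nv))
  M <- rbind(Ad %*% S, sqrt(config$lambda_reg) * L)
  sv <- svd(M)
  keep <- sv$d > max(sv$d) * 1e-12
  rhs <- c(as.numeric(b), numeric(nrow(L)))
  y <- sv$v[, keep] %*% ((t(sv$u[, keep]) %*% rhs) / sv$d[keep])
  matrix(rep(as.numeric(config$background), each = nv) * y, nv, nc)
}

# Small layered slab for forward-model tests.
small_slab <- function(spacing = 3, size = c(48, 48, 30)) {
  slab_geometry(size, spacing = spacing)
}

# Homogeneous optical properties helper.
homog_props <- function(mua = 0.01, musp = 1) list(mua = mua, musp = musp)

# Weighted centroid of the positive part of one chromophore image.
pos_centroid <- function(values, grid) {
  w <- pmax(values, 0)
  cc <- voxel_centers(grid)
  colSums(cc * w) / sum(w)
}

# End-to-end study fixture at desk scale (3-mm grid): one noiseless and one
# noisy acquisition of the default phantom, preprocessed, reconstructed with
# the 3- and 2-chromophore models at the 20-s frame. Memoized: several test
# files share it.
e2e_study <- function() {
  memo("e2e_study", {
    ph <- phantom_default(spacing = 3)
    wl <- seq(740, 900, 10)
    jacs <- lapply(wl, function(w)
      compute_jacobian(ph$geometry, ph$optics, ph$array, w))
    E3 <- extinction_matrix(c("HbO2", "HHb", "oxCCO"), wl)
    E2 <- extinction_matrix(c("HbO2", "HHb"), wl)
    sys3 <- multispectral_system(jacs, E3)
    sys2 <- multispectral_system(jacs, E2)
    cfg3 <- recon_config()
    cfg2 <- recon_config(background = c(HbO2 = 56, HHb = 24))

    run_one <- function(sd, seed) {
      sim <- simulate_experiment(ph$geometry, ph$optics, ph$array, ph$blob,
                                 ph$paradigm,
                                 noise = noise_model(sd = sd, seed = seed),
                                 jacobians = jacs)
      blocked <- block_average(bandpass(
        intensity_to_attenuation(sim$intensity)), ph$paradigm)
      frame <- blocked$data[, , 21]          # t = 20 s
      img3 <- reconstruct(frame, sys3, cfg3)
      img2 <- reconstruct(frame, sys2, cfg2)
      list(sim = sim, blocked = blocked, frame = frame,
           img3 = img3, img2 = img2)
    }
    list(ph = ph, wl = wl, jacs = jacs, sys3 = sys3, sys2 = sys2,
         cfg3 = cfg3, cfg2 = cfg2, E3 = E3,
         clean = run_one(0, 1), noisy = run_one(5e-4, 1234))
  })
}

# Mismatched-resolution (inverse-crime control) fixture: data simulated on a
# 2-mm grid, reconstructed on a 4-mm grid.
e2e_crime <- function() {
  memo("e2e_crime", {
    ph <- phantom_default(spacing = 4)
    fine <- slab_geometry(c(120, 72, 40), spacing = 2)
    wl <- seq(740, 900, 10)
    sim <- simulate_experiment(ph$geometry, ph$optics, ph$array, ph$blob,
                               ph$paradigm, noise = noise_model(sd = 0),
                               simulation_geometry = fine)
    jacs <- lapply(wl, function(w)
      compute_jacobian(ph$geometry, ph$optics, ph$array, w))
    sys3 <- multispectral_system(jacs,
              extinction_matrix(c("HbO2", "HHb", "oxCCO"), wl))
    blocked <- block_average(bandpass(
      intensity_to_attenuation(sim$intensity)), ph$paradigm)
    img3 <- reconstruct(blocked$data[, , 21], sys3, recon_config())
    truth_coarse <- vapply(1:3, function(c)
      as.numeric(project_to_grid(sim$truth$data[, c], sim$truth$grid,
                                 img3$grid)),
      numeric(prod(img3$grid$dims)))
    list(ph = ph, sim = sim, img3 = img3, truth_coarse = truth_coarse)
  })
}
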