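wl17 <- seq(740, 900, by = 10)

synth_attenuation <- function(dC, E, d, dpf_model, nt = 3) {
  # forward modified Beer-Lambert: dA = E dC * d * DPF(lambda)
  dpf <- dpf_at(rownames_to_wl(E), dpf_model)
  a <- as.numeric(E %*% dC) * d * dpf
  attenuation_series(array(rep(a, nt), c(1, length(a), nt)),
                     rownames_to_wl(E), 1)
}

rownames_to_wl <- function(E) as.numeric(rownames(E))

test_that("UCLn fit is exact on noiseless model data and zero on zero data", {
  E <- extinction_matrix(c("HbO2", "HHb", "oxCCO"), wl17)
  dpf <- load_dpf()
  dC <- c(1.2, -0.4, 0.15)
  d <- 30
  dA <- synth_attenuation(dC, E, d, dpf)
  fit <- ucln_fit(dA, E, distances = d, dpf = dpf)
  expect_equal(dim(fit$data), c(1L, 3L, 3L))
  for (k in 1:3)
    expect_equal(as.numeric(fit$data[1, , k]), dC, tolerance = 1e-10)

  zero <- attenuation_series(array(0, c(2, 17, 4)), wl17, 1)
  fz <- ucln_fit(zero, E, distances = c(25, 30), dpf = dpf)
  expect_true(all(fz$data == 0))
})

test_that("UCLn residuals are orthogonal to the DPF-scaled extinction columns", {
  set.seed(5)
  E <- extinction_matrix(c("HbO2", "HHb", "oxCCO"), wl17)
  dpf <- load_dpf()
  d <- 28
  a <- rnorm(17) * 1e-3
  dA <- attenuation_series(array(a, c(1, 17, 1)), wl17, 1)
  fit <- ucln_fit(dA, E, distances = d, dpf = dpf)
  Es <- E * dpf_at(wl17, dpf)
  resid <- a / d - as.numeric(Es %*% fit$data[1, , 1])
  expect_lt(max(abs(crossprod(Es, resid))), 1e-10)
})

test_that("UCLn is unbiased under additive attenuation noise", {
  # Monte-Carlo oracle: mean of 200 noisy fits within 3 SE of the truth
  set.seed(2024)
  E <- extinction_matrix(c("HbO2", "HHb", "oxCCO"), wl17)
  dpf <- load_dpf()
  dC <- c(1.0, -0.3, 0.1)
  d <- 30
  clean <- as.numeric(E %*% dC) * d * dpf_at(wl17, dpf)
  draws <- replicate(200, {
    dA <- attenuation_series(array(clean + rnorm(17, sd = 1e-4),
                                   c(1, 17, 1)), wl17, 1)
    ucln_fit(dA, E, distances = d, dpf = dpf)$data[1, , 1]
  })
  m <- rowMeans(draws)
  se <- apply(draws, 1, sd) / sqrt(ncol(draws))
  expect_true(all(abs(m - dC) < 3 * se + 1e-12))
})

test_that("adding a wavelength never worsens noiseless recovery", {
  E17 <- extinction_matrix(c("HbO2", "HHb", "oxCCO"), wl17)
  dpf <- load_dpf()
  dC <- c(0.8, -0.2, 0.05)
  d <- 25
  err_for <- function(wl_set) {
    E <- extinction_matrix(c("HbO2", "HHb", "oxCCO"), wl_set)
    a <- as.numeric(E %*% dC) * d * dpf_at(wl_set, dpf)
    dA <- attenuation_series(array(a, c(1, length(wl_set), 1)), wl_set, 1)
    max(abs(ucln_fit(dA, E, distances = d, dpf = dpf)$data[1, , 1] - dC))
  }
  e3 <- err_for(c(780, 810, 850))
  e4 <- err_for(c(780, 810, 850, 880))
  expect_lte(e4, e3 + 1e-12)
  expect_lt(err_for(wl17), 1e-10)
})

test_that("degenerate extinction systems are rejected", {
  E <- extinction_matrix(c("HbO2", "HbO2"), wl17)  # duplicated chromophore
  dA <- attenuation_series(array(1e-3, c(1, 17, 1)), wl17, 1)
  expect_error(ucln_fit(dA, E, distances = 30), "rank deficient")
  E3 <- extinction_matrix(c("HbO2", "HHb"), seq(740, 880, 10))
  expect_error(ucln_fit(dA, E3, distances = 30), "wavelength rows")
  expect_error(ucln_fit(dA, extinction_matrix(c("HbO2", "HHb"), wl17),
                        distances = -5), "positive")
})

test_that("two-chromophore mode and tidy output work", {
  E <- extinction_matrix(c("HbO2", "HHb"), wl17)
  dpf <- load_dpf()
  dC <- c(0.5, -0.1)
  a <- as.numeric(E %*% dC) * 30 * dpf_at(wl17, dpf)
  dA <- attenuation_series(array(a, c(1, 17, 1)), wl17, 1)
  fit <- ucln_fit(dA, E, distances = 30, dpf = dpf)
  expect_identical(fit$chromophores, c("HbO2", "HHb"))
  expect_equal(as.numeric(fit$data[1, , 1]), dC, tolerance = 1e-10)
  tab <- tidy_concentrations(fit)
  expect_identical(nrow(tab), 2L)
  expect_identical(names(tab),
                   c("channel", "chromophore", "time_s", "delta_conc_uM"))
})
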