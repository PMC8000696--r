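# Additive spectral model, molar-fluorescence estimation, smoothing.

make_speciation <- function(conc) {
  # minimal speciation stand-in with named concentrations
  structure(list(free = conc[names(conc) %in% c("S", "Q")],
                 complexes = conc[!names(conc) %in% c("S", "Q")],
                 residual = 0, iterations = 0L),
            class = "speciation")
}

test_that("a single-species spectrum is concentration times phi", {
  g <- wavelength_grid("emission", wavelengths = 300:310)
  phi <- matrix(100e6, 1, 11, dimnames = list("S", NULL))   # 100 per uM
  sp <- compute_spectrum(make_speciation(c(S = 2e-6)), phi, g)
  expect_equal(sp$intensities, rep(200, 11))
})

test_that("spectra are additive and homogeneous in concentrations", {
  g <- wavelength_grid("sync15", wavelengths = seq(230, 400, 10))
  nw <- length(g$wavelengths)
  set.seed(7)
  phi <- matrix(runif(2 * nw, 0, 1e9), 2, nw, dimnames = list(c("S", "SQ"), NULL))
  c1 <- c(S = 2e-6, SQ = 0); c2 <- c(S = 0, SQ = 1.5e-6)
  both <- compute_spectrum(make_speciation(c1 + c2), phi, g)$intensities
  sum2 <- compute_spectrum(make_speciation(c1), phi, g)$intensities +
    compute_spectrum(make_speciation(c2), phi, g)$intensities
  expect_equal(both, sum2, tolerance = 1e-12)
  dbl <- compute_spectrum(make_speciation(2 * (c1 + c2)), phi, g)$intensities
  expect_equal(dbl, 2 * both, tolerance = 1e-12)
})

test_that("phi estimation round-trips noiseless synthetic data", {
  x <- sim_preset("diflunisal", seed = 3, noise = 0, step = 5)
  ser <- speciation_series(x$model,
                           data.frame(total_s = x$ds$compositions$total_s_um * 1e-6,
                                      total_q = x$ds$compositions$total_q_um * 1e-6))
  for (md in names(x$ds$spectra)) {
    est <- estimate_molar_fluorescence(ser, x$ds$spectra[[md]], model = x$model)
    phi_true <- phi_from_truth(x$truth, x$ds$grids[[md]])
    scale <- max(abs(phi_true))
    expect_lt(max(abs(est$phi[rownames(phi_true), ] - phi_true)) / scale, 1e-8)
  }
})

test_that("estimated phi is the exact least-squares minimizer", {
  x <- sim_preset("naproxen", seed = 4, noise = 0.01, step = 10)
  ser <- speciation_series(x$model,
                           data.frame(total_s = x$ds$compositions$total_s_um * 1e-6,
                                      total_q = x$ds$compositions$total_q_um * 1e-6))
  C <- species_concentrations(ser, x$model, fluorescent_only = TRUE)
  Y <- x$ds$spectra$emission
  est <- suppressWarnings(estimate_molar_fluorescence(C, Y))
  rss <- sum(est$residuals^2)
  expect_equal(rss, sum(est$rss_per_wavelength), tolerance = 1e-10)
  for (k in 1:4) {
    pert <- est$phi
    i <- sample(nrow(pert), 1); j <- sample(ncol(pert), 1)
    pert[i, j] <- pert[i, j] * 1.001 + 1
    expect_gt(sum((Y - C %*% pert)^2), rss)
  }
})

test_that("degenerate phi problems are reported", {
  # single fluorescent species, one solution: phi = intensity / concentration
  C <- matrix(1e-6, 1, 1, dimnames = list(NULL, "S"))
  est <- estimate_molar_fluorescence(C, matrix(50, 1, 3))
  expect_equal(unname(est$phi[1, ]), rep(50 / 1e-6, 3))
  # all-zero observations give phi = 0
  C2 <- matrix(c(1e-6, 2e-6), 2, 1, dimnames = list(NULL, "S"))
  est0 <- estimate_molar_fluorescence(C2, matrix(0, 2, 4))
  expect_true(all(est0$phi == 0))
  # collinear concentration profiles are named in the error
  C3 <- cbind(S = c(1e-6, 2e-6, 3e-6), SQ = c(2e-6, 4e-6, 6e-6))
  expect_error(estimate_molar_fluorescence(C3, matrix(1, 3, 2)),
               "collinear")
})

test_that("negative phi estimates warn, and the nonneg solver removes them", {
  C <- cbind(S = c(1, 2, 3, 4) * 1e-6, SQ = c(0.1, 0.5, 1.2, 2.1) * 1e-6)
  set.seed(1)
  # data generated with a negative second-species contribution
  Y <- C %*% rbind(rep(2e8, 5), rep(-5e7, 5)) + matrix(rnorm(20, 0, 1), 4, 5)
  expect_warning(est <- estimate_molar_fluorescence(C, Y), "negative")
  est_nn <- suppressWarnings(estimate_molar_fluorescence(C, Y, nonneg = TRUE))
  expect_true(all(est_nn$phi >= 0))
  expect_gte(sum(est_nn$residuals^2) + 1e-9, sum(est$residuals^2))
})

test_that("Savitzky-Golay reproduces low-order polynomials and rejects bad windows", {
  g <- wavelength_grid("emission", wavelengths = 300:340)
  x <- seq_along(g$wavelengths)
  y <- 2 + 0.5 * x - 0.03 * x^2 + 0.001 * x^3
  sm <- smooth_spectrum(spectrum(g, y), window = 11, polyorder = 3)
  expect_equal(sm$intensities, y, tolerance = 1e-9)
  expect_error(smooth_spectrum(spectrum(g, y), window = 1), "odd integer")
  expect_error(smooth_spectrum(spectrum(g, y), window = 10), "odd")
  expect_error(smooth_spectrum(spectrum(g, y), window = 11, polyorder = 11),
               "polyorder")
  expect_error(smooth_spectrum(spectrum(g, y), window = 101), "length")
})

test_that("smoothing a noisy flat spectrum reduces its variance", {
  g <- wavelength_grid("emission", wavelengths = 295:550)
  set.seed(11)
  y <- 100 + rnorm(length(g$wavelengths), 0, 5)
  sm <- smooth_spectrum(spectrum(g, y), window = 11, polyorder = 3)
  expect_lt(var(sm$intensities), var(y))
})

test_that("wavelength grids enforce monotonicity and mode defaults", {
  expect_error(wavelength_grid("emission", wavelengths = c(300, 300, 301)),
               "strictly increasing")
  g <- wavelength_grid("sync60")
  expect_equal(range(g$wavelengths), c(230, 400))
  expect_equal(g$delta, 60)
  e <- wavelength_grid("emission")
  expect_equal(range(e$wavelengths), c(295, 550))
  expect_equal(e$excitation, 285)
})
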