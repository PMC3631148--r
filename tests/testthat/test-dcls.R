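test_that("design matrix has the expected structure", {
  lib <- small_library()
  d <- build_design(lib)
  expect_equal(ncol(d$matrix), 2 + 1 + 4)
  expect_equal(colnames(d$matrix)[3:7], c("B", "P0", "P1", "P2", "P3"))
  # [-1,1] mapping: P1 vanishes at the axis midpoint, P0 is constant
  mid <- (d$matrix[1, "P1"] + d$matrix[256, "P1"]) / 2
  expect_equal(unname(mid), 0)
  expect_equal(unname(d$matrix[, "P0"]), rep(1, 256))
  expect_equal(qr(d$matrix)$rank, 7L)
  expect_true(is.finite(d$condition_number))
})

test_that("exactly representable spectra are recovered to machine precision", {
  lib <- small_library()
  s <- 2 * lib$flavors[[1]]$intensities + 3 * lib$flavors[[2]]$intensities +
    0.5 * lib$background$intensities
  fit <- dcls_fit(s, lib)
  expect_equal(unname(fit$weights), c(2, 3), tolerance = 1e-10)
  expect_equal(fit$background_weight, 0.5, tolerance = 1e-10)
  expect_equal(unname(fit$baseline_coeffs), rep(0, 4), tolerance = 1e-8)
  expect_lt(l2norm(fit$residual), 1e-10)
})

test_that("coefficients match an independent normal-equations oracle", {
  # 100 random small instances; spectra not representable by the design
  set.seed(2024)
  for (i in 1:100) {
    # 32-channel instances need proportionally broader peaks to stay resolved
    lib <- build_library(100 + i, spectral_axis(800, 1800, 32),
                         n_flavors = 2, n_peaks = 3,
                         width_range = c(40, 80), smoothness = 500)
    d <- build_design(lib)
    y <- rnorm(32)
    oracle <- drop(normal_equations_fit(d$matrix, y))
    fit <- dcls_fit(y, lib)
    got <- c(fit$weights, fit$background_weight, fit$baseline_coeffs)
    expect_equal(unname(got), unname(oracle), tolerance = 1e-8)
  }
})

test_that("residual is orthogonal to the design and norms decompose", {
  lib <- small_library()
  sp <- compose_spectrum(lib, mixture_truth(c(1, 2), 1, 0.3), 11)
  fit <- dcls_fit(sp, lib)
  X <- fit$design$matrix
  r <- fit$residual
  for (j in seq_len(ncol(X)))
    expect_lt(abs(sum(r * X[, j])) / (l2norm(r) * l2norm(X[, j])), 1e-8)
  s <- sp$intensities
  expect_equal(sum(s^2), sum(fit$fitted_full^2) + sum(r^2),
               tolerance = 1e-10)
})

test_that("fit is scale equivariant and unbiased under noise", {
  lib <- small_library()
  sp <- compose_spectrum(lib, mixture_truth(c(1, 2), 1, 0.2), 3)
  f1 <- dcls_fit(sp$intensities, lib)
  f2 <- dcls_fit(2.5 * sp$intensities, lib)
  expect_equal(2.5 * f1$weights, f2$weights, tolerance = 1e-10)
  expect_equal(2.5 * f1$background_weight, f2$background_weight,
               tolerance = 1e-10)

  # unbiasedness across 10,000 noisy replicates
  truth <- mixture_truth(c(1, 2), 1, 0.2)
  S <- batch_compose(lib, truth, 10000L, 17)
  d <- build_design(lib)
  W <- qr.coef(qr(d$matrix), S)[d$flavor_cols, ]
  mc_se <- 0.2 * 4 / sqrt(10000)   # generous Monte-Carlo band
  expect_lt(abs(mean(W[1, ]) - 1), mc_se)
  expect_lt(abs(mean(W[2, ]) - 2), mc_se)
})

test_that("fitted weight is linear in true concentration over 3 decades", {
  lib <- small_library()
  conc <- 10^seq(-1.5, 1.5, length.out = 13)
  w <- vapply(seq_along(conc), function(i) {
    sp <- compose_spectrum(lib, mixture_truth(c(conc[i], 0), 1, 0.005),
                           400 + i)
    unname(dcls_fit(sp, lib)$weights[1])
  }, numeric(1))
  slope <- unname(coef(lm(w ~ conc))["conc"])
  expect_equal(slope, 1, tolerance = 0.02)
})

test_that("nonnegative mode zeroes absent flavors without biasing others", {
  lib <- small_library(seed = 21, n_flavors = 3)
  # flavor 2 absent; heavy noise can push its OLS weight negative
  sp <- compose_spectrum(lib, mixture_truth(c(1, 0, 0.5), 1, 0.4), 5)
  fit <- dcls_fit(sp, lib, nonneg = TRUE)
  expect_true(all(fit$weights >= 0))
  # unconstrained and constrained agree when OLS is already nonnegative
  sp2 <- compose_spectrum(lib, mixture_truth(c(1, 1, 1), 1, 0.01), 6)
  expect_equal(dcls_fit(sp2, lib, nonneg = TRUE)$weights,
               dcls_fit(sp2, lib)$weights, tolerance = 1e-10)
})

test_that("invalid inputs are rejected", {
  lib <- small_library()
  expect_error(dcls_fit(c(1, 2, 3), lib), "channels")
  expect_error(dcls_fit(rep(NaN, 256), lib), "non-finite")
})
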