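test_that("RFE is 1 for a perfect fit and 0 for an orthogonal spectrum", {
  lib <- small_library()
  s <- 2 * lib$flavors[[1]]$intensities + 0.5 * lib$background$intensities
  expect_equal(rfe(dcls_fit(s, lib)), 1, tolerance = 1e-9)

  # spectrum orthogonal to every design column -> projection is zero
  d <- build_design(lib)
  q <- qr.Q(qr(d$matrix), complete = TRUE)[, ncol(d$matrix) + 1L]
  fit <- dcls_fit(q, lib)
  expect_equal(rfe(fit), 0, tolerance = 1e-8)
})

test_that("SRI is 1 for noiseless mixtures and ~0 for pure background", {
  lib <- small_library()
  s <- compose_spectrum(lib, mixture_truth(c(1, 2), 3, 0), 1)
  expect_equal(sri(dcls_fit(s, lib)), 1, tolerance = 1e-9)

  # pure background + noise, zero particles
  vals <- vapply(1:20, function(i) {
    sp <- compose_spectrum(lib, mixture_truth(c(0, 0), 1, 0.05), i)
    sri(dcls_fit(sp, lib))
  }, numeric(1))
  expect_lt(mean(vals), 0.35)
})

test_that("SRI returns the no-signal sentinel when nothing remains", {
  lib <- small_library()
  # exact pure background: the background column absorbs everything
  fit <- dcls_fit(2 * lib$background$intensities, lib)
  s <- sri(fit)
  expect_true(is.na(s))
  expect_true(isTRUE(attr(s, "no_signal")))
})

test_that("RFE inflates with background while SRI stays put", {
  lib <- small_library()
  n_rep <- 200L
  mets <- function(k) {
    truth <- mixture_truth(c(1, 1), k, 0.15)
    S <- batch_compose(lib, truth, n_rep, 31)
    vals <- vapply(seq_len(n_rep), function(j) {
      f <- dcls_fit(S[, j], lib)
      c(rfe(f), sri(f))
    }, numeric(2))
    rowMeans(vals)
  }
  lo <- mets(1); hi <- mets(10)
  expect_gt(hi[1], lo[1])                       # RFE biased toward 1 at 10B
  expect_lt(abs(hi[2] - lo[2]) / lo[2], 0.10)   # SRI insensitive
})

test_that("RFE and SRI stay in [0,1] and degrade monotonically with noise", {
  lib <- small_library()
  sigmas <- c(0.02, 0.1, 0.3, 0.8)
  means <- vapply(sigmas, function(s) {
    truth <- mixture_truth(c(1, 1), 1, s)
    S <- batch_compose(lib, truth, 100, 13)
    vals <- vapply(1:100, function(j) {
      f <- dcls_fit(S[, j], lib)
      c(rfe(f), sri(f))
    }, numeric(2))
    expect_true(all(vals >= 0 & vals <= 1))
    rowMeans(vals)
  }, numeric(2))
  expect_true(all(diff(means[1, ]) <= 0))
  expect_true(all(diff(means[2, ]) <= 0))
})

test_that("percent, composite, and ratio errors follow their definitions", {
  expect_equal(percent_error(1.0, 1.1), 10)
  expect_equal(percent_error(2, 2), 0)
  expect_error(percent_error(0, 1), "zero")

  expect_equal(composite_error(10), 10)
  expect_equal(composite_error(c(10, 10)), 10)
  expect_equal(composite_error(c(0, 10)), sqrt(50))
  expect_equal(composite_error(c(-10, 10)), 10)   # sign-blind RMS
  expect_equal(composite_error(c(3, -4, 0)), composite_error(c(0, 3, -4)))
  expect_error(composite_error(numeric(0)), "at least one")

  expect_equal(unname(ratio_error(c(5, 1), c(5, 1), 2)), 0)
  expect_equal(unname(ratio_error(c(5, 1), c(5.5, 1), 2)), 10)
  # three-flavor panel: strong target 5:1, weak target 1:1 vs control
  re <- ratio_error(c(5, 1, 1), c(5.5, 0.9, 1), 3)
  expect_equal(unname(re), c(10, -10))
  expect_message(out <- ratio_error(c(5, 1), c(5, -0.1), 2), "unreliable")
  expect_true(all(is.na(out)))
})

test_that("single-flavor fit errors are normally distributed", {
  lib <- build_library(7, small_axis(), n_flavors = 1)
  truth <- mixture_truth(1, 1, 0.15)
  S <- batch_compose(lib, truth, 5000L, 23)
  d <- build_design(lib)
  w <- qr.coef(qr(d$matrix), S)[1, ]
  errs <- percent_error(1, w)
  # weights are linear in Gaussian noise, so errors are exactly Gaussian;
  # Shapiro-Wilk at the usual 1% level
  expect_gt(stats::shapiro.test(errs)$p.value, 0.01)
  expect_lt(abs(mean(errs)), 4 * sd(errs) / sqrt(5000))
})
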